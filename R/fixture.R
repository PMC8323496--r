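# Published marginal counts for the N = 8072 cohort. Each element lists the
# per-level counts (severity order, most severe first for the fill rule) and
# the missing count; every set sums to 8072.
cohort_marginal_counts <- function() {
  list(
    depression = list(counts = c(caseness = 1215, at_risk = 2087, normal = 4722),
                      missing = 48),
    anxiety = list(counts = c(clinical = 599, borderline = 316, non_clinical = 6412),
                   missing = 745),
    inhibition = list(counts = c(very_high = 1017, high = 673, borderline = 855,
                                 normal = 5497), missing = 30),
    peers = list(counts = c(very_high = 920, high = 663, borderline = 1058,
                            normal = 5401), missing = 30),
    gender = list(counts = c(girl = 4380, boy = 3389, other_pns = 158),
                  missing = 145)
  )
}

#' Deterministic fixture cohort with the published cross-tabulation
#'
#' Builds a constant 8072-row table whose pain and suicidality columns
#' reproduce the published joint distribution exactly: 1794 participants
#' with combined pain (717 with suicidality, 1077 without), 6216 without
#' pain (889 with suicidality, 5327 without) and 62 with missing pain
#' (5 with suicidality, 39 without, 18 with missing suicidality), giving
#' column totals of 1611 suicidality-present, 6443 absent and 18 missing.
#'
#' Rows are ordered by descending severity of the (pain, suicidality)
#' pattern: pain+suicidality first, then pain only, suicidality only,
#' neither, and finally the pain-missing groups. The remaining columns
#' (depression, anxiety, inhibition, peers, gender) are filled down this
#' fixed row order by a deterministic rank-ordered rule: each column
#' assigns its most severe level to the first rows, then the next level,
#' and so on, with missing values last; gender is filled girl, boy,
#' other/prefer-not-to-say, missing. Only the printed margins and the
#' printed pain-by-suicidality joint are guaranteed — the joint of the
#' filled columns is an admissible, deliberately artificial allocation.
#'
#' @return a [cohort_table()] with columns `pain`, `suicidality`,
#'   `depression`, `anxiety`, `inhibition`, `peers`, `gender`.
#' @export
make_printed_fixture <- function() {
  groups <- data.frame(
    pain = c("present", "present", "absent", "absent", NA, NA, NA),
    suicidality = c("present", "absent", "present", "absent",
                    "present", "absent", NA),
    n = c(717, 1077, 889, 5327, 5, 39, 18),
    stringsAsFactors = FALSE
  )
  pain <- rep(groups$pain, groups$n)
  suic <- rep(groups$suicidality, groups$n)
  n_total <- length(pain) # 8072

  fill_column <- function(spec_entry, level_order) {
    counts <- spec_entry$counts[level_order]
    rep(c(names(counts), NA), c(unname(counts), spec_entry$missing))
  }
  marg <- cohort_marginal_counts()
  lv <- known_column_levels()

  out <- data.frame(
    pain = factor(pain, levels = lv$pain$levels),
    suicidality = factor(suic, levels = lv$suicidality$levels),
    stringsAsFactors = FALSE
  )
  for (nm in c("depression", "anxiety", "inhibition", "peers", "gender")) {
    vals <- fill_column(marg[[nm]], names(marg[[nm]]$counts))
    out[[nm]] <- factor(vals, levels = lv[[nm]]$levels, ordered = lv[[nm]]$ordered)
  }
  stopifnot(nrow(out) == 8072)
  cohort_table(out, provenance = list(generator = "make_printed_fixture"))
}
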