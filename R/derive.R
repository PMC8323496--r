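#' Derive the binary suicidality variable from its three items
#'
#' Coded present if at least one item is answered yes; both other
#' responses (no, prefer-not-to-say) count towards absent. A participant
#' is missing only when all three items are missing — the only coherent
#' reading of an at-least-one-item rule.
#'
#' @param a,b,c vectors with values `"yes"`, `"no"`, `"pns"` or `NA`.
#' @return factor with levels `absent`, `present` (`NA` = missing).
#' @export
derive_suicidality <- function(a, b, c) {
  check_codes(list(a = a, b = b, c = c), c("yes", "no", "pns"))
  any_yes <- (!is.na(a) & a == "yes") | (!is.na(b) & b == "yes") |
    (!is.na(c) & c == "yes")
  all_missing <- is.na(a) & is.na(b) & is.na(c)
  out <- ifelse(any_yes, "present", ifelse(all_missing, NA, "absent"))
  factor(out, levels = c("absent", "present"))
}

#' Derive six-month pain from the SDQ somatic item
#'
#' `not_true` codes pain absent; `somewhat_true` and `certainly_true` code
#' pain present.
#'
#' @param response vector with values `"not_true"`, `"somewhat_true"`,
#'   `"certainly_true"` or `NA`.
#' @return factor with levels `absent`, `present`.
#' @export
derive_pain_sdq <- function(response) {
  check_codes(list(sdq_pain = response),
              c("not_true", "somewhat_true", "certainly_true"))
  out <- ifelse(is.na(response), NA,
                ifelse(response == "not_true", "absent", "present"))
  factor(out, levels = c("absent", "present"))
}

#' Derive today-pain from the CHU-9D pain item
#'
#' Score 0 ("no pain today") codes absent; 1-4 code present.
#'
#' @param score integer vector in 0-4 (or `NA`).
#' @return factor with levels `absent`, `present`.
#' @export
derive_pain_chu <- function(score) {
  if (any(!is.na(score) & (score < 0 | score > 4 | score != round(score)))) {
    stop_input("chu_pain scores must be integers in 0-4")
  }
  out <- ifelse(is.na(score), NA, ifelse(score == 0, "absent", "present"))
  factor(out, levels = c("absent", "present"))
}

#' Combine the two pain indicators into the analysis pain variable
#'
#' Present only when both indicators are present; an observed absent on
#' either indicator rules out "both present", so any absent gives absent
#' regardless of the other value (including missing). Present-plus-missing
#' is missing: "both present" can neither be confirmed nor excluded. The
#' rule is symmetric in its two arguments.
#'
#' @param pain_6m,pain_today vectors with values `"present"`, `"absent"`
#'   or `NA`.
#' @return factor with levels `absent`, `present`.
#' @export
combine_pain <- function(pain_6m, pain_today) {
  check_codes(list(pain_6m = pain_6m, pain_today = pain_today),
              c("present", "absent"))
  both <- !is.na(pain_6m) & !is.na(pain_today) &
    pain_6m == "present" & pain_today == "present"
  any_absent <- (!is.na(pain_6m) & pain_6m == "absent") |
    (!is.na(pain_today) & pain_today == "absent")
  out <- ifelse(both, "present", ifelse(any_absent, "absent", NA))
  factor(out, levels = c("absent", "present"))
}

#' Band a CES-D total into the published depression categories
#'
#' Scores 0-15 are normal, 16-27 at risk and 28-60 caseness.
#'
#' @param total integer vector in 0-60 (or `NA`).
#' @return ordered factor `normal < at_risk < caseness`.
#' @export
categorize_cesd <- function(total) {
  total <- as.numeric(total)
  if (any(!is.na(total) & (total < 0 | total > 60 | total != round(total)))) {
    stop_input("CES-D totals must be integers in 0-60")
  }
  out <- cut(total, breaks = c(-1, 15, 27, 60),
             labels = c("normal", "at_risk", "caseness"), ordered_result = TRUE)
  out
}

#' Band an instrument score into ordinal categories
#'
#' Generic half-open banding: band k covers `[cutpoints[k], cutpoints[k+1])`,
#' so a score at an exact cutpoint falls in the upper band. Scores outside
#' `[min(cutpoints), max(cutpoints))` are rejected.
#'
#' @param score numeric vector (or `NA`).
#' @param cutpoints strictly increasing numeric vector of band edges
#'   (length = number of bands + 1).
#' @param labels band labels, least severe first.
#' @return ordered factor over `labels`.
#' @export
categorize_band <- function(score, cutpoints, labels) {
  if (any(diff(cutpoints) <= 0)) stop_input("cutpoints must be strictly increasing")
  if (length(labels) != length(cutpoints) - 1) {
    stop_input("need one label per band (length(cutpoints) - 1)")
  }
  bad <- !is.na(score) & (score < cutpoints[1] | score >= cutpoints[length(cutpoints)])
  if (any(bad)) {
    stop_input("scores outside [", cutpoints[1], ", ",
               cutpoints[length(cutpoints)], ")")
  }
  band <- findInterval(score, cutpoints)
  factor(labels[band], levels = labels, ordered = TRUE)
}

#' Default band tables for the score-derived ordinal variables
#'
#' The published analysis bands anxiety into three levels and peer
#' problems / inhibitory control deficits into four, but the exact
#' cutpoints live in unpublished supplementary material. These defaults
#' are therefore explicit assumptions shipped with the package: the
#' four-band tables follow published self-report banding for the two
#' difficulty subscales and the anxiety table uses the conventional
#' borderline (65) and clinical (70) t-score thresholds. Every cutpoint is
#' overridable wherever banding is performed.
#' @export
band_defaults <- function() {
  list(
    anxiety = list(cutpoints = c(0, 65, 70, 101),
                   labels = c("non_clinical", "borderline", "clinical")),
    peers = list(cutpoints = c(0, 3, 5, 7, 11),
                 labels = c("normal", "borderline", "high", "very_high")),
    inhibition = list(cutpoints = c(0, 6, 7, 8, 11),
                      labels = c("normal", "borderline", "high", "very_high"))
  )
}

#' Derive all six analysis variables from raw items
#'
#' Applies the full coding scheme to a raw item table (as produced by
#' [sample_cohort_items()] or read from CSV): suicidality from the three
#' items, the two pain indicators, the combined pain variable, the CES-D
#' depression bands and the three banded scores. A derivation audit
#' (counts per derived level, including missing) is attached as the
#' `"audit"` attribute.
#'
#' @param raw a table with the raw item columns.
#' @param bands band tables as in [band_defaults()].
#' @return a [cohort_table()] with columns `suicidality`, `depression`,
#'   `anxiety`, `inhibition`, `peers`, `pain`, `pain_6m`, `pain_today`
#'   and `gender` (carried through when present).
#' @export
derive_cohort <- function(raw, bands = band_defaults()) {
  need <- c("suicidality_item_a", "suicidality_item_b", "suicidality_item_c",
            "sdq_pain", "chu_pain", "cesd_total", "anxiety_score",
            "peers_score", "inhibition_score")
  miss <- setdiff(need, names(raw))
  if (length(miss)) stop_input("raw table lacks columns: ", paste(miss, collapse = ", "))

  as_chr <- function(x) if (is.factor(x)) as.character(x) else x
  pain_6m <- derive_pain_sdq(as_chr(raw$sdq_pain))
  pain_today <- derive_pain_chu(raw$chu_pain)
  out <- data.frame(
    suicidality = derive_suicidality(as_chr(raw$suicidality_item_a),
                                     as_chr(raw$suicidality_item_b),
                                     as_chr(raw$suicidality_item_c)),
    depression = categorize_cesd(raw$cesd_total),
    anxiety = categorize_band(raw$anxiety_score, bands$anxiety$cutpoints,
                              bands$anxiety$labels),
    inhibition = categorize_band(raw$inhibition_score, bands$inhibition$cutpoints,
                                 bands$inhibition$labels),
    peers = categorize_band(raw$peers_score, bands$peers$cutpoints,
                            bands$peers$labels),
    pain = combine_pain(as_chr(pain_6m), as_chr(pain_today)),
    pain_6m = pain_6m, pain_today = pain_today
  )
  if (!is.null(raw$gender)) out$gender <- raw$gender

  audit <- lapply(out, function(col) {
    tab <- table(col, useNA = "always")
    stats::setNames(as.integer(tab), ifelse(is.na(names(tab)), "missing", names(tab)))
  })
  res <- cohort_table(out, provenance = c(
    provenance(raw) %||% list(),
    list(derived = TRUE)
  ))
  attr(res, "audit") <- audit
  res
}

#' Complete-case filter
#'
#' Drops rows with any missing value among the given columns and records
#' the number removed (message + `"n_removed"` attribute).
#'
#' @param table a cohort table.
#' @param columns columns required to be observed.
#' @return the filtered table.
#' @export
complete_case_filter <- function(table, columns) {
  miss <- setdiff(columns, names(table))
  if (length(miss)) stop_input("unknown columns: ", paste(miss, collapse = ", "))
  keep <- stats::complete.cases(table[, columns, drop = FALSE])
  removed <- sum(!keep)
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (removed > 0) message(sprintf("complete-case filter: removed %d of %d rows",
                                   removed, length(keep)))
  if (nrow(out) == 0) warning("complete-case filter removed every row")
  attr(out, "n_removed") <- removed
  out
}

#' Restrict to participants with binary gender
#'
#' Keeps rows whose gender is girl or boy, dropping other /
#' prefer-not-to-say and missing gender.
#'
#' @param table a cohort table with a `gender` column.
#' @return the filtered table.
#' @export
exclude_nonbinary_gender <- function(table) {
  if (is.null(table$gender)) stop_input("table has no 'gender' column")
  keep <- !is.na(table$gender) & table$gender %in% c("girl", "boy")
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(!keep)
  out
}

check_codes <- function(args, valid) {
  for (nm in names(args)) {
    x <- args[[nm]]
    if (is.factor(x)) x <- as.character(x)
    bad <- !is.na(x) & !(x %in% valid)
    if (any(bad)) {
      stop_input("invalid code(s) in '", nm, "': ",
                 paste(unique(x[bad]), collapse = ", "))
    }
  }
  invisible(TRUE)
}
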