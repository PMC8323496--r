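#' End-to-end analysis pipeline
#'
#' Reproduces the full analysis sequence on a cohort table: variable
#' derivation (when raw items are supplied), participant flow
#' (raw -> binary gender -> complete case), descriptive level counts with
#' gender tests (chi-squared for binary, Wilcoxon for ordinal variables),
#' crude and depression-stratified odds ratios, pairwise network models
#' for the whole sample and per gender, a depression-moderated network
#' with level-conditioned weights matrices, predictability and
#' expected-influence descriptors, and (optionally) bootstrap stability.
#' All artefacts are written to `out_dir` as CSV/TSV and the run is
#' deterministic given the seed.
#'
#' @param config named list (or path to a YAML file) with entries:
#'   `cohort` (a cohort table) or `input` (CSV path) or `generator`
#'   (`"fixture"` or a [cohort_margin_spec()]); optional `column_map`,
#'   `nodes`, `moderator` (default `"depression"`), `gender_col`
#'   (`"gender"`; set `NULL` to skip gender analyses), `estimation`
#'   (an [estimation_config()]), `bootstrap_B` (default 0 = skip),
#'   `out_dir` (default: no files written), `seed`.
#' @return an object of class `run_report`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- config$seed
  if (!is.null(seed)) set.seed(seed)

  stage <- function(label, expr) {
    tryCatch(expr, error = function(e) {
      stop_input("pipeline stage '", label, "' failed: ", conditionMessage(e))
    })
  }

  cohort <- stage("input", {
    if (!is.null(config$cohort)) config$cohort
    else if (!is.null(config$input)) read_cohort_csv(config$input, config$column_map)
    else if (identical(config$generator, "fixture")) make_printed_fixture()
    else if (inherits(config$generator, "cohort_margin_spec")) {
      sample_cohort_items(config$generator)
    } else stop("config needs 'cohort', 'input' or 'generator'")
  })

  derived <- stage("derive", {
    if ("suicidality_item_a" %in% names(cohort)) derive_cohort(cohort)
    else cohort
  })

  nodes <- config$nodes %||%
    intersect(c("suicidality", "depression", "anxiety", "inhibition",
                "peers", "pain"), names(derived))
  moderator <- config$moderator %||% "depression"
  gender_col <- if ("gender_col" %in% names(config)) config$gender_col else "gender"
  if (!is.null(gender_col) && !gender_col %in% names(derived)) gender_col <- NULL
  est_cfg <- config$estimation %||% estimation_config()

  n_raw <- nrow(derived)
  gendered <- if (!is.null(gender_col)) exclude_nonbinary_gender(derived) else derived
  cc <- suppressMessages(complete_case_filter(derived, nodes))
  flow <- data.frame(
    stage = c("raw", "binary_gender", "complete_case"),
    n = c(n_raw, nrow(gendered), nrow(cc))
  )

  descriptives <- stage("descriptives", {
    describe_levels(derived, nodes, gender_col)
  })

  assoc <- stage("assoc", {
    ct <- table(cc$pain, cc$suicidality)
    crude <- odds_ratio_2x2(ct["present", "present"], ct["present", "absent"],
                            ct["absent", "present"], ct["absent", "absent"])
    strat <- stratified_or(derived, "suicidality", "pain", moderator,
                           stratum = gender_col)
    gender_or <- NULL
    if (!is.null(gender_col)) {
      gender_or <- lapply(c("girl", "boy"), function(g) {
        sub <- gendered[gendered[[gender_col]] == g, , drop = FALSE]
        sub <- suppressMessages(complete_case_filter(sub, c("pain", "suicidality")))
        ctg <- table(sub$pain, sub$suicidality)
        odds_ratio_2x2(ctg["present", "present"], ctg["present", "absent"],
                       ctg["absent", "present"], ctg["absent", "absent"])
      })
      names(gender_or) <- c("girl", "boy")
    }
    list(crude = crude, stratified = strat, by_gender = gender_or)
  })

  networks <- stage("network", {
    out <- list(whole = estimate_network(derived, est_cfg, nodes = nodes))
    if (!is.null(gender_col)) {
      for (g in c("girl", "boy")) {
        sub <- gendered[gendered[[gender_col]] == g, , drop = FALSE]
        out[[g]] <- estimate_network(sub, est_cfg, nodes = nodes)
      }
    }
    out
  })

  moderated <- NULL
  if (moderator %in% nodes) {
    moderated <- stage("moderated", {
      m <- fit_moderated(derived, moderator, est_cfg, nodes = nodes)
      list(model = m, conditioned = conditioned_weights(m))
    })
  }

  descriptors <- stage("descriptors", {
    pred <- predictability(networks$whole, derived)
    ei <- expected_influence(networks$whole$weights, networks$whole$signs)
    eiv <- if (length(nodes) >= 3) ei_variance_correlation(ei, cc) else NULL
    list(predictability = pred, influence = ei, ei_variance = eiv)
  })

  boot <- NULL
  B <- config$bootstrap_B %||% 0
  if (B > 0) {
    boot <- stage("bootstrap", {
      bseed <- if (!is.null(seed)) seed + 1L else NULL
      bootstrap_network(derived, est_cfg, B = B, seed = bseed, nodes = nodes)
    })
  }

  report <- structure(list(
    flow = flow, descriptives = descriptives, assoc = assoc,
    networks = networks, moderated = moderated, descriptors = descriptors,
    bootstrap = boot, nodes = nodes, moderator = moderator, seed = seed,
    r_version = as.character(getRversion())
  ), class = "run_report")

  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

describe_levels <- function(derived, nodes, gender_col) {
  rows <- list()
  for (nd in nodes) {
    col <- derived[[nd]]
    tab <- table(col, useNA = "always")
    gender_p <- NA_real_
    if (!is.null(gender_col)) {
      gtab <- derived[!is.na(derived[[gender_col]]) &
                        derived[[gender_col]] %in% c("girl", "boy"), ]
      gcol <- factor(gtab[[gender_col]], levels = c("girl", "boy"))
      ok <- !is.na(gtab[[nd]])
      if (nlevels(droplevels(factor(gtab[[nd]][ok]))) >= 2 &&
          length(unique(gcol[ok])) == 2) {
        if (nlevels(factor(col)) == 2) {
          succ <- tapply(gtab[[nd]][ok] == levels(factor(col))[2], gcol[ok], sum)
          tot <- tapply(ok, gcol, sum)[names(succ)]
          gender_p <- chisq_equal_proportions(as.integer(succ),
                                              as.integer(tot))$p_value
        } else {
          gender_p <- wilcoxon_rank_sum(gtab[[nd]][ok & gcol == "girl"],
                                        gtab[[nd]][ok & gcol == "boy"])$p_value
        }
      }
    }
    rows[[nd]] <- data.frame(
      variable = nd,
      level = ifelse(is.na(names(tab)), "missing", names(tab)),
      n = as.integer(tab),
      pct = round(100 * as.integer(tab) / length(col), 1),
      gender_test_p = gender_p
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a pipeline report to disk
#'
#' One file per artefact: participant flow, descriptive counts, odds
#' ratio tables, weights/sign matrices per sample, conditioned matrices
#' per moderator level, descriptor and bootstrap tables, plus a run
#' metadata YAML (seed, node set, R version).
#'
#' @param report a `run_report`.
#' @param dir output directory (created if needed).
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, f) utils::write.csv(x, file.path(dir, f), row.names = FALSE)
  w(report$flow, "participant_flow.csv")
  w(report$descriptives, "descriptives.csv")

  cr <- report$assoc$crude
  crude_df <- data.frame(estimate = cr$estimate, ci_low = cr$ci_low,
                         ci_high = cr$ci_high, p_value = cr$p_value,
                         n = cr$n_used, method = cr$method)
  if (!is.null(report$assoc$by_gender)) {
    for (g in names(report$assoc$by_gender)) {
      gg <- report$assoc$by_gender[[g]]
      crude_df <- rbind(crude_df, data.frame(
        estimate = gg$estimate, ci_low = gg$ci_low, ci_high = gg$ci_high,
        p_value = gg$p_value, n = gg$n_used, method = paste0(gg$method, "_", g)))
    }
  }
  w(crude_df, "or_crude.csv")
  w(report$assoc$stratified, "or_stratified.csv")

  for (nm in names(report$networks)) {
    write_network_csv(report$networks[[nm]], dir, prefix = paste0("network_", nm))
  }
  if (!is.null(report$moderated)) {
    for (lv in names(report$moderated$conditioned)) {
      utils::write.csv(report$moderated$conditioned[[lv]],
                       file.path(dir, paste0("network_conditioned_", lv, ".csv")))
    }
  }
  desc <- merge(report$descriptors$predictability, report$descriptors$influence,
                by = "node", sort = FALSE)
  w(desc, "descriptors.csv")
  if (!is.null(report$bootstrap)) {
    write_bootstrap_tsv(report$bootstrap, file.path(dir, "bootstrap_edges.tsv"))
  }
  yaml::write_yaml(list(seed = report$seed, nodes = report$nodes,
                        moderator = report$moderator,
                        r_version = report$r_version),
                   file.path(dir, "run_metadata.yaml"))
  invisible(dir)
}

#' @export
print.run_report <- function(x, ...) {
  cat("run_report\n")
  cat(sprintf("  flow: raw %d -> binary gender %d -> complete case %d\n",
              x$flow$n[1], x$flow$n[2], x$flow$n[3]))
  cr <- x$assoc$crude
  cat(sprintf("  pain-suicidality OR = %.2f [%.2f, %.2f]\n",
              cr$estimate, cr$ci_low, cr$ci_high))
  ei <- x$descriptors$influence
  top <- ei$node[which.max(ei$ei1)]
  cat(sprintf("  most influential node: %s (EI1 = %.2f, EI2 = %.2f)\n", top,
              max(ei$ei1), ei$ei2[which.max(ei$ei1)]))
  invisible(x)
}
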