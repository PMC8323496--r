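#' Nonparametric bootstrap of network edge stability
#'
#' Resamples participants with replacement `B` times, re-estimates the
#' (pairwise or moderated) network on every resample — re-running the full
#' pipeline including penalty selection, unless `refit_lambda = FALSE`
#' fixes each node's selected penalty from the full-data fit — and
#' summarises each edge by its percentile 95% CI and the proportion of
#' resamples in which it was nonzero. For moderated models the proportion
#' of resamples with a zero moderation block is reported per pair (the
#' stability statement for an absent moderation effect). Resamples in
#' which some analysis column collapses to a single observed level are
#' skipped and counted; more than 20% skipped is an error.
#'
#' @param table cohort table (complete cases on `nodes` are used).
#' @param config an [estimation_config()].
#' @param B number of bootstrap resamples (default 200).
#' @param seed master seed; per-resample draws derive from it, so the
#'   whole summary is reproducible bit for bit.
#' @param moderated estimate moderated networks?
#' @param moderator moderator node (required when `moderated`).
#' @param nodes analysis columns (default: all factor columns).
#' @param refit_lambda re-select the penalty on each resample (default
#'   `TRUE`, the full-pipeline bootstrap).
#' @return an object of class `mgm_boot`: `edges` (data.frame with
#'   estimate, ci_low, ci_high, prop_nonzero per edge), `moderation`
#'   (per-pair prop_zero; moderated runs only), `B`, `seed`, `n_skipped`.
#' @export
bootstrap_network <- function(table, config = estimation_config(), B = 200,
                              seed = NULL, moderated = FALSE, moderator = NULL,
                              nodes = NULL, refit_lambda = TRUE) {
  if (B < 1) stop_input("B must be >= 1")
  if (moderated && is.null(moderator)) stop_input("moderated runs need a moderator")
  nodes <- nodes %||% names(table)[vapply(table, is.factor, logical(1))]
  tab <- suppressMessages(complete_case_filter(table, nodes))[, nodes, drop = FALSE]
  n <- nrow(tab)

  fit_once <- function(dat, cfg) {
    if (moderated) fit_moderated(dat, moderator, cfg, nodes = nodes)
    else estimate_network(dat, cfg, nodes = nodes)
  }
  full <- fit_once(tab, config)

  if (!is.null(seed)) set.seed(seed)
  idx_mat <- matrix(sample.int(n, n * B, replace = TRUE), n, B)

  p <- length(nodes)
  ut <- which(upper.tri(full$weights), arr.ind = TRUE)
  edge_names <- paste(nodes[ut[, 1]], nodes[ut[, 2]], sep = "--")
  W_boot <- matrix(NA_real_, nrow(ut), B, dimnames = list(edge_names, NULL))
  M_boot <- if (moderated) matrix(NA_real_, nrow(ut), B,
                                  dimnames = list(edge_names, NULL)) else NULL
  skipped <- 0L

  for (b in seq_len(B)) {
    dat <- tab[idx_mat[, b], , drop = FALSE]
    single <- vapply(dat, function(col) {
      length(unique(col[!is.na(col)])) < 2
    }, logical(1))
    if (any(single)) { skipped <- skipped + 1L; next }
    cfg <- config
    if (!refit_lambda) {
      # fix the path to each node's selected penalty is per-node; approximate
      # by handing the solver the full-data selected penalties as the path
      sel <- vapply(full$fits, `[[`, numeric(1), "selected_lambda")
      cfg$lambda_path <- sort(unique(sel), decreasing = TRUE)
      if (length(cfg$lambda_path) < 2) {
        cfg$lambda_path <- c(cfg$lambda_path * 1.0001, cfg$lambda_path)
      }
    }
    # rare level configurations can still defeat the solver (e.g. a response
    # class drawn once); such resamples are skipped and counted too
    mod_b <- tryCatch(suppressWarnings(fit_once(dat, cfg)),
                      error = function(e) NULL)
    if (is.null(mod_b)) { skipped <- skipped + 1L; next }
    W_boot[, b] <- mod_b$weights[ut]
    if (moderated) M_boot[, b] <- mod_b$mod_weights[ut]
  }
  if (skipped > 0.2 * B) {
    stop_input("more than 20% of resamples skipped (", skipped, " of ", B, ")")
  }

  ok <- !is.na(W_boot[1, ])
  qs <- t(apply(W_boot[, ok, drop = FALSE], 1, stats::quantile,
                probs = c(0.025, 0.975), names = FALSE))
  edges <- data.frame(
    edge = edge_names,
    node_s = nodes[ut[, 1]], node_t = nodes[ut[, 2]],
    estimate = full$weights[ut],
    ci_low = qs[, 1], ci_high = qs[, 2],
    prop_nonzero = rowMeans(W_boot[, ok, drop = FALSE] > 0),
    row.names = NULL
  )
  moderation <- NULL
  if (moderated) {
    others <- !(nodes[ut[, 1]] == moderator | nodes[ut[, 2]] == moderator)
    moderation <- data.frame(
      edge = edge_names[others],
      estimate = full$mod_weights[ut][others],
      prop_zero = rowMeans(M_boot[others, ok, drop = FALSE] == 0),
      row.names = NULL
    )
  }
  structure(list(edges = edges, moderation = moderation, B = B, seed = seed,
                 n_skipped = skipped, n_used = n, moderated = moderated,
                 moderator = moderator, full_model = full),
            class = "mgm_boot")
}

#' @export
print.mgm_boot <- function(x, ...) {
  cat(sprintf("mgm_boot: B = %d (%d skipped), n = %d%s\n", x$B, x$n_skipped,
              x$n_used,
              if (x$moderated) paste0(", moderated by ", x$moderator) else ""))
  print(utils::head(x$edges[order(-x$edges$estimate),
                            c("edge", "estimate", "ci_low", "ci_high",
                              "prop_nonzero")], 6), row.names = FALSE)
  invisible(x)
}

#' Write a bootstrap summary as TSV
#' @param boot an `mgm_boot`.
#' @param path output file.
#' @export
write_bootstrap_tsv <- function(boot, path) {
  utils::write.table(boot$edges, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  if (!is.null(boot$moderation)) {
    utils::write.table(boot$moderation,
                       sub("(\\.tsv)?$", "_moderation.tsv", path, perl = TRUE),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
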