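#' Nodewise predictability (classification accuracy)
#'
#' For each node, the in-sample proportion of rows whose observed level is
#' the highest-probability level under the node's fitted regression
#' (`accuracy_full`), against the intercept-only baseline — the modal
#' category's relative frequency (`accuracy_intercept`) — and their
#' difference (`improvement`). Computed in sample, matching the
#' single-number reporting convention of the method.
#'
#' @param model an `mgm_network` or `mgm_moderated`.
#' @param table the cohort table to evaluate on (typically the estimation
#'   table); complete cases on the model's nodes are used.
#' @param nodes nodes to report (default: all).
#' @return data.frame: node, accuracy_intercept, accuracy_full, improvement.
#' @export
predictability <- function(model, table, nodes = NULL) {
  nodes <- nodes %||% model$nodes
  if (!all(nodes %in% model$nodes)) stop_input("node absent from model")
  tab <- suppressMessages(complete_case_filter(table, model$nodes))
  tab <- tab[, model$nodes, drop = FALSE]

  rows <- lapply(nodes, function(nd) {
    fit <- model$fits[[nd]]
    ed <- encode_design(tab, nd, moderator = model$moderator)
    if (!identical(colnames(ed$X), colnames(fit$coefficients))) {
      stop_input("table schema does not match the model fit for node '", nd, "'")
    }
    eta <- ed$X %*% t(fit$coefficients)
    eta <- sweep(eta, 2, fit$intercepts, "+")
    pred <- fit$y_levels[max.col(eta, ties.method = "first")]
    obs <- as.character(ed$y)
    acc_full <- mean(pred == obs)
    acc_int <- max(table(ed$y)) / length(obs)
    data.frame(node = nd, accuracy_intercept = acc_int,
               accuracy_full = acc_full,
               improvement = acc_full - acc_int)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' One- and two-step expected influence
#'
#' `ei1(i)` is the signed sum of node i's incident edge weights;
#' `ei2(i) = ei1(i) + sum_j s_ij w_ij ei1(j)` adds the influence
#' propagated through each neighbour's own one-step influence. Edges with
#' no defined sign (any pair involving a node with more than two levels)
#' contribute positively, consistent with reporting all weights as
#' non-negative magnitudes.
#'
#' @param weights symmetric non-negative matrix with zero diagonal.
#' @param signs optional character matrix (`"+"`, `"-"`, `"undefined"` or
#'   `NA`); `"-"` flips the contribution.
#' @return data.frame: node, ei1, ei2.
#' @export
expected_influence <- function(weights, signs = NULL) {
  weights <- as.matrix(weights)
  if (nrow(weights) != ncol(weights) ||
      !isTRUE(all.equal(weights, t(weights), tolerance = 1e-8))) {
    stop_input("weights must be a symmetric matrix")
  }
  if (any(diag(weights) != 0)) stop_input("weights must have a zero diagonal")
  S <- matrix(1, nrow(weights), ncol(weights))
  if (!is.null(signs)) S[which(signs == "-")] <- -1
  sw <- S * weights
  ei1 <- rowSums(sw)
  ei2 <- ei1 + as.vector(sw %*% ei1)
  nodes <- rownames(weights) %||% paste0("V", seq_len(nrow(weights)))
  data.frame(node = nodes, ei1 = ei1, ei2 = ei2, row.names = NULL)
}

#' Correlation between expected influence and node variance
#'
#' Diagnostic for restricted symptom variability: Pearson correlation
#' (with p-value) between the nodes' one-step expected influence and their
#' variances. Binary nodes use p(1-p); ordinal nodes the population
#' variance of their 0-based integer level codes.
#'
#' @param influence data.frame from [expected_influence()].
#' @param table cohort table holding the node columns (complete cases per
#'   node).
#' @return an [assoc_result()] with estimate r; node variances in
#'   `$variances`.
#' @export
ei_variance_correlation <- function(influence, table) {
  nodes <- influence$node
  if (length(nodes) < 3) stop_input("need at least 3 nodes")
  v <- vapply(nodes, function(nd) {
    col <- table[[nd]]
    if (is.null(col)) stop_input("column '", nd, "' absent from table")
    codes <- as.integer(factor(col)) - 1L
    pop_var(codes[!is.na(codes)])
  }, numeric(1))
  if (stats::sd(influence$ei1) == 0) {
    return(assoc_result(NA_real_, n_used = length(nodes),
                        method = "ei_variance_pearson_undefined_constant_ei",
                        extra = list(variances = v)))
  }
  ct <- stats::cor.test(influence$ei1, v, method = "pearson")
  assoc_result(unname(ct$estimate), ct$conf.int[1], ct$conf.int[2], ct$p.value,
               length(nodes), method = "ei_variance_pearson",
               extra = list(variances = v))
}
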