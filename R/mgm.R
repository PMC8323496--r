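#' Estimation settings for mixed graphical models
#'
#' @param gamma EBIC hyperparameter (default 0.5, the value used for the
#'   cohort analysis; 0 recovers plain BIC selection).
#' @param lambda_path optional decreasing vector of penalty values; by
#'   default a 50-point log-spaced path from the data-derived lambda_max
#'   down to `lambda_min_ratio * lambda_max` is used.
#' @param nlambda,lambda_min_ratio path construction controls when
#'   `lambda_path` is `NULL`.
#' @param combine_rule `"AND"` (edge kept only when selected in both
#'   nodewise regressions; conservative default) or `"OR"`.
#' @param max_iter,tol optimiser controls passed to the coordinate-descent
#'   solver.
#' @param seed integer recorded in the config (estimation itself is
#'   deterministic).
#' @export
estimation_config <- function(gamma = 0.5, lambda_path = NULL, nlambda = 50,
                              lambda_min_ratio = 0.01,
                              combine_rule = c("AND", "OR"),
                              max_iter = 1e5, tol = 1e-7, seed = NULL) {
  combine_rule <- match.arg(combine_rule)
  if (!is.finite(gamma) || gamma < 0) stop_input("gamma must be finite and >= 0")
  if (!is.null(lambda_path)) {
    if (any(diff(lambda_path) >= 0) || any(lambda_path <= 0)) {
      stop_input("lambda_path must be strictly decreasing and positive")
    }
  }
  structure(list(gamma = gamma, lambda_path = lambda_path, nlambda = nlambda,
                 lambda_min_ratio = lambda_min_ratio, combine_rule = combine_rule,
                 max_iter = max_iter, tol = tol, seed = seed),
            class = "estimation_config")
}

#' Dummy-encoded design for one nodewise regression
#'
#' One-hot encodes every predictor node with its first level as the
#' (dropped) reference; the response stays as level codes. When a
#' moderator is given and differs from the target, elementwise products of
#' predictor dummies with moderator dummies are appended (the three-way
#' interaction terms); when the target is the moderator itself, products
#' of all predictor-pair dummies are appended, so every three-way term
#' involving the moderator appears in exactly the regressions whose
#' response it involves. Predictors with a single observed level are
#' excluded with a warning.
#'
#' @param table complete-case table of factor columns.
#' @param target name of the response node.
#' @param moderator optional moderator node name.
#' @return list with `y` (factor), `X` (numeric matrix), `colmap`
#'   (data.frame: type `"pair"`/`"inter"`, node1, level1, node2, level2).
#' @export
encode_design <- function(table, target, moderator = NULL) {
  if (!target %in% names(table)) stop_input("unknown target '", target, "'")
  y <- factor(table[[target]])
  predictors <- setdiff(names(table), target)

  usable <- character(0)
  dummies <- list()
  for (nd in predictors) {
    f <- factor(table[[nd]])
    obs <- levels(droplevels(f))
    if (length(obs) < 2) {
      warning("predictor '", nd, "' has a single observed level; excluded")
      next
    }
    f <- droplevels(f)
    lv <- levels(f)
    D <- vapply(lv[-1], function(l) as.numeric(f == l), numeric(length(f)))
    D <- matrix(D, ncol = length(lv) - 1,
                dimnames = list(NULL, paste0(nd, "=", lv[-1])))
    dummies[[nd]] <- list(D = D, levels = lv)
    usable <- c(usable, nd)
  }
  if (length(usable) == 0) stop_input("no usable predictors for '", target, "'")

  X <- do.call(cbind, lapply(dummies, `[[`, "D"))
  colmap <- do.call(rbind, lapply(usable, function(nd) {
    lv <- dummies[[nd]]$levels
    data.frame(type = "pair", node1 = nd, level1 = seq_along(lv)[-1],
               node2 = NA_character_, level2 = NA_integer_,
               stringsAsFactors = FALSE)
  }))

  if (!is.null(moderator)) {
    if (identical(moderator, target)) {
      pairs <- utils::combn(usable, 2, simplify = FALSE)
      for (pr in pairs) {
        Xi <- interaction_columns(dummies, pr[1], pr[2])
        X <- cbind(X, Xi$D)
        colmap <- rbind(colmap, Xi$map)
      }
    } else {
      if (!moderator %in% usable) {
        stop_input("moderator '", moderator, "' unusable (missing or single-level)")
      }
      for (nd in setdiff(usable, moderator)) {
        Xi <- interaction_columns(dummies, nd, moderator)
        X <- cbind(X, Xi$D)
        colmap <- rbind(colmap, Xi$map)
      }
    }
  }
  rownames(colmap) <- NULL
  list(y = y, X = X, colmap = colmap,
       predictor_levels = lapply(dummies, `[[`, "levels"))
}

interaction_columns <- function(dummies, nd1, nd2) {
  D1 <- dummies[[nd1]]$D; D2 <- dummies[[nd2]]$D
  cols <- list(); map <- list()
  for (j in seq_len(ncol(D1))) {
    for (k in seq_len(ncol(D2))) {
      cols[[length(cols) + 1]] <- D1[, j] * D2[, k]
      map[[length(map) + 1]] <- data.frame(
        type = "inter", node1 = nd1, level1 = j + 1L,
        node2 = nd2, level2 = k + 1L, stringsAsFactors = FALSE)
    }
  }
  D <- do.call(cbind, cols)
  mp <- do.call(rbind, map)
  colnames(D) <- paste0(mp$node1, "=", mp$level1, ":", mp$node2, "=", mp$level2)
  list(D = D, map = mp)
}

#' Fit one nodewise L1-penalised multinomial regression with EBIC selection
#'
#' Fits the multinomial-logistic lasso along the penalty path (intercepts
#' unpenalised, predictors unstandardised — all columns are 0/1
#' indicators) and selects the penalty minimising
#' `EBIC = -2 loglik + df log(n) + 2 gamma df log(p_total)`, where `df`
#' counts the nonzero non-intercept coefficients and `p_total` is the
#' number of candidate non-intercept parameters of this regression. Ties
#' are broken towards the sparser (larger penalty) model.
#'
#' @param y response factor (>= 2 observed levels).
#' @param X design matrix from [encode_design()].
#' @param config an [estimation_config()].
#' @param colmap column map from [encode_design()] (carried in the fit for
#'   aggregation and prediction).
#' @param node response node label.
#' @return an object of class `nodewise_fit`.
#' @export
fit_nodewise <- function(y, X, config = estimation_config(), colmap = NULL,
                         node = NULL) {
  y <- droplevels(factor(y))
  K <- nlevels(y)
  if (K < 2) stop_input("response has fewer than 2 observed levels")
  if (nrow(X) != length(y)) stop_input("rows of X must match length of y")
  n <- length(y)

  padded <- FALSE
  if (ncol(X) < 2) { # glmnet needs >= 2 columns; a zero column is inert
    X <- cbind(X, `.pad` = 0)
    padded <- TRUE
  }
  p_cand <- ncol(X) - padded
  p_total <- p_cand * K

  fit <- glmnet::glmnet(X, y, family = "multinomial",
                        lambda = config$lambda_path,
                        nlambda = config$nlambda,
                        lambda.min.ratio = config$lambda_min_ratio,
                        standardize = FALSE, thresh = config$tol,
                        maxit = config$max_iter)
  nlam <- length(fit$lambda)
  if (nlam == 0) stop_input("no penalty value converged for node '", node, "'")

  dev <- (1 - fit$dev.ratio) * fit$nulldev # -2 loglik (saturated loglik = 0)
  df <- rep(0L, nlam)
  for (k in seq_len(K)) {
    bk <- fit$beta[[k]]
    if (padded) bk <- bk[-nrow(bk), , drop = FALSE]
    df <- df + Matrix::colSums(bk != 0)
  }
  ebic <- dev + df * log(n) + 2 * config$gamma * df * log(p_total)
  j <- which.min(ebic) # first minimum = largest lambda among ties

  beta <- t(vapply(seq_len(K), function(k) {
    bk <- as.matrix(fit$beta[[k]])[, j]
    if (padded) bk <- bk[-length(bk)]
    bk
  }, numeric(p_cand)))
  beta <- matrix(beta, nrow = K, ncol = p_cand,
                 dimnames = list(levels(y), setdiff(colnames(X), ".pad")))

  structure(list(
    node = node, y_levels = levels(y),
    selected_lambda = fit$lambda[j],
    coefficients = beta,
    intercepts = stats::setNames(as.numeric(fit$a0[, j]), levels(y)),
    loglik = -dev[j] / 2, df = as.integer(df[j]), ebic = ebic[j],
    lambda_path = fit$lambda, ebic_path = ebic, dev_path = dev,
    df_path = as.integer(df),
    n = n, p_total = p_total, colmap = colmap
  ), class = "nodewise_fit")
}

# K_s x (L_t - 1) matrix of cross-parameters for predictor node `other`
cross_block <- function(fit, other) {
  sel <- fit$colmap$type == "pair" & fit$colmap$node1 == other
  fit$coefficients[, sel, drop = FALSE]
}

#' Aggregate nodewise fits into a weighted network
#'
#' For each node pair the two cross-parameter blocks (each node regressed
#' on the other) are combined: under the AND rule an edge is present only
#' when both blocks contain a nonzero parameter (under OR, either); the
#' edge weight is the mean absolute value of all parameters in both
#' blocks, and zero for absent edges. An edge sign is defined only for
#' binary-binary pairs whose two regressions agree on the direction of the
#' log-odds; all other present edges are `"undefined"` (between variables
#' with more than two levels several parameters describe one edge, so no
#' single sign exists).
#'
#' @param fits named list of `nodewise_fit` objects, one per node.
#' @param config the [estimation_config()] used.
#' @param n_used number of complete cases the fits were estimated on.
#' @return an object of class `mgm_network` with `weights`, `signs`,
#'   `blocks`, `fits`, `config`, `n_used`.
#' @export
aggregate_edges <- function(fits, config = estimation_config(), n_used = NA) {
  nodes <- names(fits)
  if (is.null(nodes) || any(vapply(fits, function(f) is.null(f$colmap), logical(1)))) {
    stop_input("fits must be a named list of nodewise fits with column maps")
  }
  for (f in fits) {
    others <- unique(f$colmap$node1[f$colmap$type == "pair"])
    if (!all(others %in% nodes)) stop_input("inconsistent node sets across fits")
  }
  p <- length(nodes)
  W <- matrix(0, p, p, dimnames = list(nodes, nodes))
  S <- matrix(NA_character_, p, p, dimnames = list(nodes, nodes))
  blocks <- list()

  for (i in seq_len(p - 1)) {
    for (jj in (i + 1):p) {
      s <- nodes[i]; t <- nodes[jj]
      bs <- cross_block(fits[[s]], t)
      bt <- cross_block(fits[[t]], s)
      nz_s <- any(bs != 0); nz_t <- any(bt != 0)
      present <- if (config$combine_rule == "AND") nz_s && nz_t else nz_s || nz_t
      blocks[[edge_key(s, t)]] <- list(from_s = bs, from_t = bt, present = present)
      if (present) {
        W[i, jj] <- W[jj, i] <- mean(abs(c(bs, bt)))
        both_binary <- nrow(bs) == 2 && nrow(bt) == 2 &&
          ncol(bs) == 1 && ncol(bt) == 1
        if (both_binary) {
          d_s <- bs[2, 1] - bs[1, 1]
          d_t <- bt[2, 1] - bt[1, 1]
          if (d_s != 0 && d_t != 0 && sign(d_s) == sign(d_t)) {
            S[i, jj] <- S[jj, i] <- if (d_s > 0) "+" else "-"
          } else S[i, jj] <- S[jj, i] <- "undefined"
        } else S[i, jj] <- S[jj, i] <- "undefined"
      }
    }
  }
  structure(list(nodes = nodes, weights = W, signs = S, blocks = blocks,
                 fits = fits, config = config, n_used = n_used,
                 moderator = NULL),
            class = "mgm_network")
}

#' Estimate a pairwise mixed graphical model
#'
#' Runs one L1-penalised multinomial regression per node (EBIC-selected)
#' on the complete cases of the given columns and aggregates the fits into
#' a weighted network. Rows with missing values in the analysis columns
#' are removed first (complete-case analysis) and the number of rows used
#' is recorded.
#'
#' @param table a cohort table of categorical columns.
#' @param config an [estimation_config()].
#' @param nodes columns to use (default: all factor columns).
#' @return an `mgm_network`.
#' @export
estimate_network <- function(table, config = estimation_config(), nodes = NULL) {
  nodes <- nodes %||% names(table)[vapply(table, is.factor, logical(1))]
  if (length(nodes) < 2) stop_input("need at least 2 categorical nodes")
  tab <- suppressMessages(complete_case_filter(table, nodes))[, nodes, drop = FALSE]

  fits <- stats::setNames(vector("list", length(nodes)), nodes)
  for (nd in nodes) {
    ed <- encode_design(tab, nd)
    fits[[nd]] <- fit_nodewise(ed$y, ed$X, config, colmap = ed$colmap, node = nd)
  }
  aggregate_edges(fits, config, n_used = nrow(tab))
}

#' @export
print.mgm_network <- function(x, ...) {
  ne <- sum(x$weights[upper.tri(x$weights)] > 0)
  cat(sprintf("mgm_network: %d nodes, %d edge(s), n = %s (gamma = %g, %s rule)\n",
              length(x$nodes), ne, x$n_used, x$config$gamma, x$config$combine_rule))
  if (ne > 0) {
    ut <- which(upper.tri(x$weights) & x$weights > 0, arr.ind = TRUE)
    ord <- order(x$weights[ut], decreasing = TRUE)
    ut <- ut[utils::head(ord, 5), , drop = FALSE]
    for (r in seq_len(nrow(ut))) {
      cat(sprintf("  %s--%s  w=%.3f (%s)\n", x$nodes[ut[r, 1]], x$nodes[ut[r, 2]],
                  x$weights[ut[r, 1], ut[r, 2]], x$signs[ut[r, 1], ut[r, 2]]))
    }
  }
  invisible(x)
}

#' Adjusted odds ratio of a binary-binary edge
#'
#' Interpretation-dependent derived quantity: the conditional log odds of
#' one binary node given the other is the difference of the two response
#' class parameters, so the adjusted odds ratio is reported as the
#' exponential of the average of the two regressions' log-odds estimates.
#'
#' @param model an `mgm_network`.
#' @param s,t names of two binary nodes.
#' @export
edge_adjusted_or <- function(model, s, t) {
  bl <- model$blocks[[edge_key(s, t)]]
  if (is.null(bl)) stop_input("unknown edge")
  if (nrow(bl$from_s) != 2 || ncol(bl$from_s) != 1 ||
      nrow(bl$from_t) != 2 || ncol(bl$from_t) != 1) {
    stop_input("adjusted OR is defined only for binary-binary edges")
  }
  d_s <- bl$from_s[2, 1] - bl$from_s[1, 1]
  d_t <- bl$from_t[2, 1] - bl$from_t[1, 1]
  exp(mean(c(d_s, d_t)))
}

#' Write weights / sign matrices and the edge list
#'
#' @param model an `mgm_network`.
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @export
write_network_csv <- function(model, dir, prefix = "network") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(model$weights, file.path(dir, paste0(prefix, "_weights.csv")))
  utils::write.csv(model$signs, file.path(dir, paste0(prefix, "_signs.csv")),
                   na = "")
  ut <- which(upper.tri(model$weights), arr.ind = TRUE)
  el <- data.frame(node_s = model$nodes[ut[, 1]], node_t = model$nodes[ut[, 2]],
                   weight = model$weights[ut], sign = model$signs[ut])
  el <- el[el$weight > 0, , drop = FALSE]
  utils::write.table(el, file.path(dir, paste0(prefix, "_edges.tsv")),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(dir)
}
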