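#' Gibbs sampler for a categorical Markov random field
#'
#' Draws `n` participants from the joint distribution defined by an
#' [mgm_spec()]. Each participant is simulated as an independent chain
#' (states initialised uniformly at random) and the chains are updated in
#' parallel: one sweep updates every node once from its full conditional,
#' which is the multinomial-logistic distribution implied by the node's
#' thresholds plus all incident pairwise and three-way potentials. Because
#' chains are independent, `burn_in` sweeps per chain suffice; `thin - 1`
#' additional sweeps are applied before the final state is recorded (kept
#' for API symmetry with single-chain samplers).
#'
#' @param spec an [mgm_spec()].
#' @param n number of participants (chains) to draw.
#' @param burn_in sweeps before the state is recorded (default 1000;
#'   small categorical models mix fast, the default is conservative).
#' @param thin extra sweeps added to the burn-in (default 1).
#' @param seed integer seed; if `NULL`, the spec's seed is used.
#' @return a [cohort_table()] of factor columns labelled by the node
#'   schemas.
#' @export
gibbs_sample_mgm <- function(spec, n, burn_in = 1000, thin = 1, seed = NULL) {
  stopifnot(inherits(spec, "mgm_spec"))
  if (n < 1 || burn_in < 0 || thin < 1) {
    stop_input("need n >= 1, burn_in >= 0, thin >= 1")
  }
  seed <- seed %||% spec$seed
  if (!is.null(seed)) set.seed(seed)

  p <- length(spec$nodes)
  L <- spec$n_levels
  cond <- precompute_conditionals(spec)

  x <- vapply(seq_len(p), function(s) sample.int(L[s], n, replace = TRUE),
              integer(n))
  x <- matrix(x, nrow = n)

  sweeps <- burn_in + (thin - 1)
  for (sw in seq_len(max(sweeps, 1))) {
    for (s in seq_len(p)) {
      x[, s] <- draw_node_conditional(cond[[s]], x, n, L[s])
    }
  }

  out <- as.data.frame(lapply(seq_len(p), function(s) {
    factor(spec$nodes[[s]]$level_labels[x[, s]],
           levels = spec$nodes[[s]]$level_labels,
           ordered = spec$nodes[[s]]$ordered)
  }), col.names = names(spec$nodes))
  cohort_table(out, provenance = list(
    generator = "gibbs_sample_mgm", seed = seed,
    burn_in = burn_in, thin = thin, n = n
  ))
}

# per node: threshold vector, incident pairwise blocks oriented node-first,
# incident moderation blocks with the node in slot 1 (flattened for fast
# vectorised lookup)
precompute_conditionals <- function(spec) {
  p <- length(spec$nodes)
  L <- spec$n_levels
  cond <- vector("list", p)
  for (s in seq_len(p)) {
    cond[[s]] <- list(threshold = spec$thresholds[[s]], pairwise = list(),
                      moderation = list(), L = L[s])
  }
  for (key in names(spec$pairwise)) {
    st <- as.integer(strsplit(key, "|", fixed = TRUE)[[1]])
    th <- spec$pairwise[[key]]
    cond[[st[1]]]$pairwise[[length(cond[[st[1]]]$pairwise) + 1]] <-
      list(other = st[2], theta = th)
    cond[[st[2]]]$pairwise[[length(cond[[st[2]]]$pairwise) + 1]] <-
      list(other = st[1], theta = t(th))
  }
  for (key in names(spec$moderation)) {
    stm <- as.integer(strsplit(key, "|", fixed = TRUE)[[1]])
    th <- spec$moderation[[key]]
    perms <- list(c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
    for (k in 1:3) {
      self <- stm[perms[[k]][1]]
      others <- stm[perms[[k]][2:3]]
      th_k <- aperm(th, perms[[k]])
      cond[[self]]$moderation[[length(cond[[self]]$moderation) + 1]] <-
        list(others = others, theta = as.vector(th_k), dims = dim(th_k))
    }
  }
  cond
}

draw_node_conditional <- function(cd, x, n, Ls) {
  pot <- matrix(cd$threshold, nrow = n, ncol = Ls, byrow = TRUE)
  for (b in cd$pairwise) {
    # theta is Ls x L_other; pick the column given by the neighbour state
    pot <- pot + t(b$theta[, x[, b$other], drop = FALSE])
  }
  for (b in cd$moderation) {
    d <- b$dims
    off <- (x[, b$others[1]] - 1) * d[1] + (x[, b$others[2]] - 1) * d[1] * d[2]
    for (l in seq_len(Ls)) pot[, l] <- pot[, l] + b$theta[l + off]
  }
  # categorical draw via inverse cdf, vectorised over rows
  mx <- pot[cbind(seq_len(n), max.col(pot, ties.method = "first"))]
  pot <- exp(pot - mx)
  cum <- pot[, 1]
  u <- stats::runif(n) * rowSums(pot)
  draw <- rep(1L, n)
  if (Ls > 1) {
    for (l in 2:Ls) {
      draw <- draw + (u > cum)
      cum <- cum + pot[, l]
    }
  }
  draw
}
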