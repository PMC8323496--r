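#' Node schema for a categorical Markov random field
#'
#' @param name node label.
#' @param level_labels character vector of level labels (length >= 2).
#' @param ordered whether the node is ordinal.
#' @return an object of class `node_schema`.
#' @export
node_schema <- function(name, level_labels, ordered = TRUE) {
  stopifnot(is.character(name), length(name) == 1)
  if (length(level_labels) < 2) stop_input("a node needs at least 2 levels")
  structure(
    list(name = name, n_levels = length(level_labels),
         ordered = isTRUE(ordered), level_labels = as.character(level_labels)),
    class = "node_schema"
  )
}

#' The six-node analysis schema
#'
#' Suicidality (2 levels), depression (3), anxiety (3), inhibitory control
#' deficits (4), peer problems (4) and combined pain (2) — the node set of
#' the cohort analysis, in weights-matrix order.
#' @export
analysis_schema <- function() {
  list(
    node_schema("suicidality", c("absent", "present"), ordered = FALSE),
    node_schema("depression", c("normal", "at_risk", "caseness")),
    node_schema("anxiety", c("non_clinical", "borderline", "clinical")),
    node_schema("inhibition", c("normal", "borderline", "high", "very_high")),
    node_schema("peers", c("normal", "borderline", "high", "very_high")),
    node_schema("pain", c("absent", "present"), ordered = FALSE)
  )
}

#' Specification of a categorical Markov random field
#'
#' Defines the joint distribution
#' P(x) proportional to exp( sum_s tau_s(x_s) + sum_(s<t) theta_st(x_s,x_t)
#' + sum_(s<t;m) theta_stm(x_s,x_t,x_m) )
#' over categorical nodes, with per-level threshold (category potential)
#' vectors, pairwise interaction matrices and optional three-way
#' (moderation) tensors. Potentials are over-parameterised; the sampler
#' does not require identification constraints. Absent blocks are
#' all-zero.
#'
#' @param nodes list of [node_schema()] objects.
#' @param thresholds named list: per node, numeric vector of length
#'   `n_levels` (default all zero).
#' @param pairwise list of entries `list(s=, t=, theta=)` where `theta` is
#'   an `n_levels(s) x n_levels(t)` matrix; node names or indices.
#' @param moderation list of entries `list(s=, t=, m=, theta=)` where
#'   `theta` is an `n_levels(s) x n_levels(t) x n_levels(m)` array.
#' @param seed optional integer recorded with the spec.
#' @return an object of class `mgm_spec`.
#' @export
mgm_spec <- function(nodes, thresholds = NULL, pairwise = list(),
                     moderation = list(), seed = NULL) {
  stopifnot(is.list(nodes), length(nodes) >= 1)
  names(nodes) <- vapply(nodes, function(x) x$name, character(1))
  if (anyDuplicated(names(nodes))) stop_input("duplicate node names")
  L <- vapply(nodes, function(x) x$n_levels, integer(1))

  if (is.null(thresholds)) thresholds <- lapply(L, function(k) rep(0, k))
  thresholds <- thresholds[names(nodes)]
  for (nm in names(nodes)) {
    th <- thresholds[[nm]]
    if (is.null(th)) th <- rep(0, L[[nm]])
    if (length(th) != L[[nm]] || !all(is.finite(th))) {
      stop_input("thresholds for node '", nm, "' must be finite, length ", L[[nm]])
    }
    thresholds[[nm]] <- as.numeric(th)
  }

  node_idx <- function(x) {
    if (is.character(x)) {
      i <- match(x, names(nodes))
      if (is.na(i)) stop_input("unknown node '", x, "'")
      i
    } else as.integer(x)
  }

  pw <- list()
  for (b in pairwise) {
    s <- node_idx(b$s); t <- node_idx(b$t)
    if (s == t) stop_input("pairwise block must join two distinct nodes")
    th <- as.matrix(b$theta)
    if (s > t) { tmp <- s; s <- t; t <- tmp; th <- t(th) }
    if (!all(dim(th) == c(L[s], L[t])) || !all(is.finite(th))) {
      stop_input("pairwise block (", names(nodes)[s], ",", names(nodes)[t],
                 ") must be finite with dims ", L[s], "x", L[t])
    }
    key <- paste(s, t, sep = "|")
    if (!is.null(pw[[key]])) stop_input("duplicate pairwise block for ", key)
    pw[[key]] <- th
  }

  md <- list()
  for (b in moderation) {
    s <- node_idx(b$s); t <- node_idx(b$t); m <- node_idx(b$m)
    if (length(unique(c(s, t, m))) != 3) {
      stop_input("moderation block needs three distinct nodes")
    }
    th <- b$theta
    if (s > t) { tmp <- s; s <- t; t <- tmp; th <- aperm(th, c(2, 1, 3)) }
    if (!all(dim(th) == c(L[s], L[t], L[m])) || !all(is.finite(th))) {
      stop_input("moderation block (", names(nodes)[s], ",", names(nodes)[t],
                 ",", names(nodes)[m], ") has wrong dims or non-finite entries")
    }
    key <- paste(s, t, m, sep = "|")
    if (!is.null(md[[key]])) stop_input("duplicate moderation block for ", key)
    md[[key]] <- th
  }

  structure(
    list(nodes = nodes, n_levels = L, thresholds = thresholds,
         pairwise = pw, moderation = md, seed = seed),
    class = "mgm_spec"
  )
}

#' @export
print.mgm_spec <- function(x, ...) {
  cat(sprintf("mgm_spec: %d nodes (%s levels), %d pairwise block(s), %d moderation block(s)\n",
              length(x$nodes), paste(x$n_levels, collapse = "/"),
              length(x$pairwise), length(x$moderation)))
  invisible(x)
}

# unnormalised log potential of one configuration (integer level codes)
log_potential <- function(spec, x) {
  lp <- sum(mapply(function(th, xi) th[xi], spec$thresholds, x))
  for (key in names(spec$pairwise)) {
    st <- as.integer(strsplit(key, "|", fixed = TRUE)[[1]])
    lp <- lp + spec$pairwise[[key]][x[st[1]], x[st[2]]]
  }
  for (key in names(spec$moderation)) {
    stm <- as.integer(strsplit(key, "|", fixed = TRUE)[[1]])
    lp <- lp + spec$moderation[[key]][x[stm[1]], x[stm[2]], x[stm[3]]]
  }
  lp
}

#' Exact joint distribution of a small categorical MRF
#'
#' Enumerates every configuration and normalises the exponentiated
#' potentials. Intended for validation on small models (the state space is
#' the product of the level counts).
#'
#' @param spec an [mgm_spec()].
#' @param max_states guard on the state-space size (default 1e5).
#' @return data.frame with one row per configuration: node level codes and
#'   a `prob` column summing to 1.
#' @export
mgm_joint <- function(spec, max_states = 1e5) {
  stopifnot(inherits(spec, "mgm_spec"))
  if (prod(spec$n_levels) > max_states) {
    stop_input("state space too large for enumeration")
  }
  grid <- do.call(expand.grid, lapply(spec$n_levels, seq_len))
  names(grid) <- names(spec$nodes)
  lp <- apply(as.matrix(grid), 1, function(x) log_potential(spec, x))
  p <- exp(lp - max(lp))
  grid$prob <- p / sum(p)
  grid
}

#' Write / read an `mgm_spec` as YAML
#' @param spec an [mgm_spec()].
#' @param path file path.
#' @export
write_mgm_spec_yaml <- function(spec, path) {
  obj <- list(
    nodes = lapply(spec$nodes, function(nd) {
      list(name = nd$name, ordered = nd$ordered, level_labels = nd$level_labels)
    }),
    thresholds = spec$thresholds,
    pairwise = lapply(names(spec$pairwise), function(key) {
      st <- as.integer(strsplit(key, "|", fixed = TRUE)[[1]])
      list(s = names(spec$nodes)[st[1]], t = names(spec$nodes)[st[2]],
           theta = as.vector(spec$pairwise[[key]]),
           dim = dim(spec$pairwise[[key]]))
    }),
    moderation = lapply(names(spec$moderation), function(key) {
      stm <- as.integer(strsplit(key, "|", fixed = TRUE)[[1]])
      list(s = names(spec$nodes)[stm[1]], t = names(spec$nodes)[stm[2]],
           m = names(spec$nodes)[stm[3]],
           theta = as.vector(spec$moderation[[key]]),
           dim = dim(spec$moderation[[key]]))
    }),
    seed = spec$seed
  )
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_mgm_spec_yaml
#' @export
read_mgm_spec_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  nodes <- lapply(obj$nodes, function(nd) {
    node_schema(nd$name, nd$level_labels, ordered = nd$ordered)
  })
  pw <- lapply(obj$pairwise, function(b) {
    list(s = b$s, t = b$t, theta = array(as.numeric(b$theta), dim = b$dim))
  })
  md <- lapply(obj$moderation, function(b) {
    list(s = b$s, t = b$t, m = b$m,
         theta = array(as.numeric(b$theta), dim = b$dim))
  })
  mgm_spec(nodes, thresholds = obj$thresholds, pairwise = pw, moderation = md,
           seed = obj$seed)
}
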