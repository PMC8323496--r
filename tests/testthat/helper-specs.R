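# shared builders for synthetic model specifications used across test files

quiet <- function(expr) suppressMessages(suppressWarnings(expr))

# two binary nodes coupled through a single corner potential
binary_pair_spec <- function(theta = 1) {
  sch <- list(node_schema("A", c("0", "1"), ordered = FALSE),
              node_schema("B", c("0", "1"), ordered = FALSE))
  mgm_spec(sch, pairwise = list(
    list(s = "A", t = "B", theta = matrix(c(0, 0, 0, theta), 2, 2))))
}

# the published whole-sample weights matrix (row/column order: suicidality,
# depression, anxiety, inhibition, peers, pain)
reported_weights <- function() {
  nodes <- c("suicidality", "depression", "anxiety", "inhibition", "peers", "pain")
  W <- matrix(0, 6, 6, dimnames = list(nodes, nodes))
  W["suicidality", "depression"] <- 0.90
  W["suicidality", "anxiety"] <- 0.22
  W["suicidality", "inhibition"] <- 0.11
  W["suicidality", "peers"] <- 0.12
  W["suicidality", "pain"] <- 0.17
  W["depression", "anxiety"] <- 0.85
  W["depression", "inhibition"] <- 0.40
  W["depression", "peers"] <- 0.65
  W["depression", "pain"] <- 0.64
  W["anxiety", "inhibition"] <- 0.19
  W["anxiety", "peers"] <- 0.28
  W["anxiety", "pain"] <- 0.30
  W["inhibition", "peers"] <- 0.07
  W["inhibition", "pain"] <- 0.17
  W["peers", "pain"] <- 0.07
  W + t(W)
}

# six-node generator parameterised from the reported weights: thresholds at
# the cohort marginal logits, pairwise corner blocks proportional to the
# weights; edges below `zero_below` are omitted so false-positive recovery
# is testable
cohort_like_spec <- function(zero_below = 0.10, scale = 1) {
  marg <- list(
    suicidality = c(0.80, 0.20),
    depression = c(0.588, 0.262, 0.150),
    anxiety = c(0.875, 0.043, 0.082),
    inhibition = c(0.684, 0.106, 0.084, 0.126),
    peers = c(0.672, 0.132, 0.082, 0.114),
    pain = c(0.778, 0.222))
  sch <- analysis_schema()
  nodes <- vapply(sch, `[[`, character(1), "name")
  L <- vapply(sch, `[[`, integer(1), "n_levels")
  thr <- lapply(nodes, function(nd) log(marg[[nd]] / marg[[nd]][1]))
  names(thr) <- nodes
  W <- reported_weights()
  pw <- list()
  for (i in 1:5) {
    for (j in (i + 1):6) {
      w <- W[i, j]
      if (w < zero_below) next
      th <- matrix(0, L[i], L[j])
      th[-1, -1] <- scale * w
      pw[[length(pw) + 1]] <- list(s = nodes[i], t = nodes[j], theta = th)
    }
  }
  mgm_spec(sch, thresholds = thr, pairwise = pw)
}

# three-node moderation testbed: binary X, Y and a 3-level moderator M;
# `delta` is the conditional log-odds-ratio difference between the extreme
# moderator levels
moderation_spec <- function(delta = 0.8, base_theta = 0.2) {
  sch <- list(node_schema("X", c("0", "1"), ordered = FALSE),
              node_schema("Y", c("0", "1"), ordered = FALSE),
              node_schema("M", c("0", "1", "2")))
  th3 <- array(0, c(2, 2, 3))
  th3[2, 2, 3] <- delta
  mgm_spec(sch,
    thresholds = list(X = c(0, -1), Y = c(0, -1), M = c(0, -0.5, -1)),
    pairwise = list(
      list(s = "X", t = "Y", theta = matrix(c(0, 0, 0, base_theta), 2, 2)),
      list(s = "X", t = "M", theta = rbind(0, c(0, 0.3, 0.5))),
      list(s = "Y", t = "M", theta = rbind(0, c(0, 0.3, 0.5)))),
    moderation = if (delta != 0) {
      list(list(s = "X", t = "Y", m = "M", theta = th3))
    } else list())
}

# pairwise-only variant of the moderation testbed
pairwise_only_spec <- function(base_theta = 0.5) {
  moderation_spec(delta = 0, base_theta = base_theta)
}

# small cohort-like sample for estimation tests
make_six_node_table <- function(n = 500, seed = 1) {
  gibbs_sample_mgm(cohort_like_spec(), n, burn_in = 50, seed = seed)
}

# independent test-side enumeration of a small MRF joint (kept free of the
# package's mgm_joint so the two can cross-validate each other)
enumerate_joint <- function(thresholds, pairwise = list(), moderation = list()) {
  L <- vapply(thresholds, length, integer(1))
  grid <- do.call(expand.grid, lapply(L, seq_len))
  lp <- apply(as.matrix(grid), 1, function(x) {
    v <- sum(mapply(function(th, xi) th[xi], thresholds, x))
    for (b in pairwise) v <- v + b$theta[x[b$i], x[b$j]]
    for (b in moderation) v <- v + b$theta[x[b$i], x[b$j], x[b$k]]
    v
  })
  p <- exp(lp - max(lp))
  grid$prob <- p / sum(p)
  grid
}

# empirical joint of sampled data over the given columns as integer level
# codes (aligned with the code grids used by enumeration)
empirical_joint <- function(data, cols) {
  coded <- as.data.frame(lapply(data[cols], as.integer))
  tab <- as.data.frame(table(lapply(coded, factor, exclude = NULL)),
                       stringsAsFactors = FALSE)
  names(tab)[seq_along(cols)] <- cols
  for (cl in cols) tab[[cl]] <- as.integer(as.character(tab[[cl]]))
  tab$p <- tab$Freq / sum(tab$Freq)
  tab
}

# total-variation distance between a spec's exact joint and sampled data
tv_distance <- function(spec, data) {
  j <- mgm_joint(spec)
  cols <- names(spec$nodes)
  emp <- empirical_joint(data, cols)
  m <- merge(j, emp, by = cols, all.x = TRUE)
  m$p[is.na(m$p)] <- 0
  0.5 * sum(abs(m$prob - m$p))
}
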