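test_that("printed fixture reproduces the published cross-tabulation exactly", {
  fx <- make_printed_fixture()
  expect_equal(nrow(fx), 8072)
  ct <- table(fx$pain, fx$suicidality)
  expect_equal(unname(ct["present", "present"]), 717)
  expect_equal(unname(ct["present", "absent"]), 1077)
  expect_equal(unname(ct["absent", "present"]), 889)
  expect_equal(unname(ct["absent", "absent"]), 5327)
  expect_equal(sum(fx$pain == "present", na.rm = TRUE), 1794)
  expect_equal(sum(is.na(fx$pain)), 62)
  expect_equal(sum(fx$suicidality == "present", na.rm = TRUE), 1611)
  expect_equal(sum(fx$suicidality == "absent", na.rm = TRUE), 6443)
  expect_equal(sum(is.na(fx$suicidality)), 18)
  # the printed margins force every suicidality-missing row into the
  # pain-missing group
  expect_equal(sum(is.na(fx$pain) & is.na(fx$suicidality)), 18)
})

test_that("printed fixture carries the published marginal counts and is constant", {
  fx <- make_printed_fixture()
  expect_equal(as.vector(table(fx$depression)[c("normal", "at_risk", "caseness")]),
               c(4722, 2087, 1215))
  expect_equal(as.vector(table(fx$anxiety)[c("non_clinical", "borderline", "clinical")]),
               c(6412, 316, 599))
  expect_equal(as.vector(table(fx$inhibition)), c(5497, 855, 673, 1017))
  expect_equal(as.vector(table(fx$peers)), c(5401, 1058, 663, 920))
  expect_equal(as.vector(table(fx$gender)), c(4380, 3389, 158))
  expect_identical(make_printed_fixture(), fx)
})

test_that("gibbs sampler honours thresholds under independence", {
  spec <- mgm_spec(list(node_schema("A", c("0", "1"), ordered = FALSE)),
                   thresholds = list(A = c(0, log(3))))
  d <- gibbs_sample_mgm(spec, 50000, burn_in = 20, seed = 2)
  # softmax of (0, log 3) puts 0.75 on the second level
  expect_lt(abs(mean(d$A == "1") - 0.75), 3 * sqrt(0.75 * 0.25 / 50000) + 0.002)
})

test_that("gibbs sampler matches exact enumeration for a coupled binary pair", {
  spec <- binary_pair_spec(theta = 1)
  d <- gibbs_sample_mgm(spec, 50000, burn_in = 100, seed = 1)
  # independent enumeration: cells proportional to (1, 1, 1, e)
  truth <- c(1, 1, 1, exp(1)) / (3 + exp(1))
  emp <- as.vector(prop.table(table(d$A, d$B)))
  for (i in 1:4) {
    mc_se <- sqrt(truth[i] * (1 - truth[i]) / 50000)
    expect_lt(abs(emp[i] - truth[i]), 3 * mc_se + 0.002)
  }
})

test_that("planted three-way potential shifts the conditional odds ratio as enumerated", {
  spec <- moderation_spec(delta = 1.5, base_theta = 0)
  d <- gibbs_sample_mgm(spec, 60000, burn_in = 100, seed = 11)
  cond_or <- function(m) {
    sub <- d[d$M == m, ]
    ct <- table(sub$X, sub$Y)
    (ct[1, 1] * ct[2, 2]) / (ct[1, 2] * ct[2, 1])
  }
  # independent enumeration of the 12-cell joint
  joint <- enumerate_joint(
    thresholds = list(X = c(0, -1), Y = c(0, -1), M = c(0, -0.5, -1)),
    pairwise = list(list(i = 1, j = 3, theta = rbind(0, c(0, 0.3, 0.5))),
                    list(i = 2, j = 3, theta = rbind(0, c(0, 0.3, 0.5)))),
    moderation = list(list(i = 1, j = 2, k = 3,
                           theta = { a <- array(0, c(2, 2, 3)); a[2, 2, 3] <- 1.5; a })))
  true_or <- function(m) {
    p <- function(x, y) joint$prob[joint$X == x & joint$Y == y & joint$M == m]
    (p(1, 1) * p(2, 2)) / (p(1, 2) * p(2, 1))
  }
  expect_equal(true_or(1), 1, tolerance = 1e-12)
  expect_gt(true_or(3), exp(1.4))
  expect_gt(cond_or("2"), cond_or("0") * 2) # planted direction, extreme level
  expect_lt(abs(log(cond_or("2")) - log(true_or(3))), 0.25)
  expect_lt(abs(log(cond_or("0")) - log(true_or(1))), 0.25)
})

test_that("gibbs joint is close to enumeration in total variation on a mixed model", {
  set.seed(3)
  sch <- list(node_schema("A", c("1", "2"), ordered = FALSE),
              node_schema("B", c("1", "2", "3")),
              node_schema("C", c("1", "2", "3", "4")))
  spec <- mgm_spec(sch,
    thresholds = list(A = c(0, 0.4), B = c(0, -0.2, 0.3), C = c(0, 0.1, -0.3, 0.2)),
    pairwise = list(list(s = "A", t = "B", theta = matrix(rnorm(6, 0, 0.4), 2, 3)),
                    list(s = "B", t = "C", theta = matrix(rnorm(12, 0, 0.4), 3, 4))))
  d <- gibbs_sample_mgm(spec, 20000, burn_in = 150, seed = 4)
  expect_equal(sum(mgm_joint(spec)$prob), 1, tolerance = 1e-9)
  expect_lt(tv_distance(spec, d), 0.05)
})

test_that("gibbs sampler is reproducible and validates its inputs", {
  spec <- binary_pair_spec(0.5)
  d1 <- gibbs_sample_mgm(spec, 200, burn_in = 10, seed = 5)
  d2 <- gibbs_sample_mgm(spec, 200, burn_in = 10, seed = 5)
  expect_identical(d1, d2)
  expect_error(gibbs_sample_mgm(spec, 0, 10, seed = 1), "n >= 1")
  expect_error(
    mgm_spec(list(node_schema("A", c("0", "1")), node_schema("B", c("0", "1"))),
             pairwise = list(list(s = "A", t = "B", theta = matrix(Inf, 2, 2)))),
    "finite")
  expect_error(
    mgm_spec(list(node_schema("A", c("0", "1")), node_schema("B", c("0", "1", "2"))),
             pairwise = list(list(s = "A", t = "B", theta = matrix(0, 2, 2)))),
    "dims")
})

test_that("item generator hits its target marginals within Monte-Carlo error", {
  ms <- cohort_margin_spec(n = 8000, seed = 42)
  raw <- sample_cohort_items(ms)
  se3 <- function(p, n) 3 * sqrt(p * (1 - p) / n)
  n_ok <- sum(!is.na(raw$sdq_pain))
  expect_lt(abs(mean(raw$sdq_pain == "not_true", na.rm = TRUE) - 0.489),
            se3(0.489, n_ok))
  expect_lt(abs(mean(raw$chu_pain == 0, na.rm = TRUE) - 0.696), se3(0.696, 8000))
  dv <- derive_cohort(raw)
  expect_lt(abs(mean(dv$depression == "normal", na.rm = TRUE) - 0.5885),
            se3(0.5885, 8000))
  expect_lt(abs(mean(dv$anxiety == "clinical", na.rm = TRUE) - 0.0818),
            se3(0.0818, 7000))
  expect_lt(abs(mean(dv$peers == "very_high", na.rm = TRUE) - 0.1144),
            se3(0.1144, 8000))
  expect_lt(abs(mean(dv$suicidality == "present", na.rm = TRUE) - 0.20), 0.02)
})

test_that("pain items attain the target rank correlation and track the latent sign", {
  ms <- cohort_margin_spec(n = 8000, seed = 42)
  raw <- sample_cohort_items(ms)
  res <- spearman_bootstrap_ci(raw$sdq_pain, raw$chu_pain, B = 100, seed = 1)
  expect_gt(res$estimate, 0.26)
  expect_lt(res$estimate, 0.32)
  expect_lt(res$ci_high - res$ci_low, 0.08)

  # independence and sign preservation under monotone thresholding
  for (r in c(-0.3, 0, 0.3)) {
    R <- diag(7)
    dimnames(R) <- dimnames(default_latent_correlations())
    R["pain6", "painT"] <- R["painT", "pain6"] <- r
    msr <- cohort_margin_spec(n = 20000, seed = 9, latent_correlations = R,
                              missing_rates = c(suicidality_items = 0, sdq_pain = 0,
                                                chu_pain = 0, cesd = 0, anxiety = 0,
                                                peers = 0, inhibition = 0, gender = 0))
    rr <- sample_cohort_items(msr)
    rho <- suppressWarnings(
      stats::cor(as.integer(rr$sdq_pain), rr$chu_pain, method = "spearman"))
    if (r == 0) expect_lt(abs(rho), 0.03) else expect_equal(sign(rho), sign(r))
  }
})

test_that("infeasible margin specifications fail with a named constraint", {
  expect_error(cohort_margin_spec(gender_probs = c(girl = 0.6, boy = 0.6)),
               "gender_probs")
  R <- default_latent_correlations()
  R["suic", "dep"] <- R["dep", "suic"] <- 0.999
  R["suic", "anx"] <- R["anx", "suic"] <- -0.999
  expect_error(cohort_margin_spec(latent_correlations = R), "positive definite")
  expect_error(cohort_margin_spec(suicidality_loading = 1.2), "loading")
})

test_that("model and margin specifications round-trip through YAML", {
  spec <- moderation_spec(delta = 0.7)
  f <- tempfile(fileext = ".yaml")
  write_mgm_spec_yaml(spec, f)
  back <- read_mgm_spec_yaml(f)
  expect_equal(back$thresholds, spec$thresholds)
  expect_equal(back$pairwise, spec$pairwise)
  expect_equal(back$moderation, spec$moderation)

  ms <- cohort_margin_spec(n = 123, seed = 4)
  f2 <- tempfile(fileext = ".yaml")
  write_margin_spec_yaml(ms, f2)
  ms2 <- read_margin_spec_yaml(f2)
  expect_equal(ms2$latent_correlations, ms$latent_correlations)
  expect_equal(ms2$n, ms$n)
  expect_identical(sample_cohort_items(ms2), sample_cohort_items(ms))
})
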