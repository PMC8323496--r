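#' Target margins and latent structure for the item-level generator
#'
#' Collects everything [sample_cohort_items()] needs: per-item marginal
#' probabilities (matching the published cohort characteristics), the
#' latent Gaussian-copula correlation matrix linking the instruments, the
#' common-factor loading of the three suicidality items, missingness rates
#' and the cohort size. Defaults reproduce the published marginal
#' prevalences; the pain-item latent correlation (0.40) was calibrated
#' once so the two discretised pain items attain a Spearman correlation of
#' about 0.29, and the suicidality loading (0.90) so the any-item-yes
#' prevalence is about 20%.
#'
#' @param n cohort size (default 8072).
#' @param seed integer seed.
#' @param sdq_pain_probs,chu_pain_probs marginal probabilities for the
#'   3-level six-month pain item and the 5-level today-pain item.
#' @param suicidality_item_probs yes-probabilities of the three
#'   suicidality items.
#' @param suicidality_loading common-factor loading of the three items.
#' @param pns_rate probability a non-yes suicidality response is recorded
#'   as prefer-not-to-say.
#' @param depression_band_probs,anxiety_band_probs,peers_band_probs,inhibition_band_probs
#'   target band probabilities (least severe first) for the score-derived
#'   ordinal variables.
#' @param gender_probs probabilities for girl / boy / other-or-prefer-not-to-say.
#' @param latent_correlations 7x7 correlation matrix over the latent layer
#'   (order: suicidality factor, six-month pain, today pain, depression,
#'   anxiety, peer problems, inhibitory control deficits).
#' @param missing_rates named missingness rates applied completely at
#'   random per instrument.
#' @return an object of class `cohort_margin_spec`.
#' @export
cohort_margin_spec <- function(
    n = 8072, seed = NULL,
    sdq_pain_probs = c(not_true = 0.489, somewhat_true = 0.380, certainly_true = 0.131),
    chu_pain_probs = c(0.696, 0.150, 0.090, 0.044, 0.020),
    suicidality_item_probs = c(a = 0.159, b = 0.111, c = 0.074),
    suicidality_loading = 0.90,
    pns_rate = 0.02,
    depression_band_probs = c(normal = 0.5885, at_risk = 0.2601, caseness = 0.1514),
    anxiety_band_probs = c(non_clinical = 0.8751, borderline = 0.0431, clinical = 0.0818),
    peers_band_probs = c(normal = 0.6716, borderline = 0.1316, high = 0.0824,
                         very_high = 0.1144),
    inhibition_band_probs = c(normal = 0.6835, borderline = 0.1063, high = 0.0837,
                              very_high = 0.1265),
    gender_probs = c(girl = 0.5525, boy = 0.4276, other_pns = 0.0199),
    latent_correlations = default_latent_correlations(),
    missing_rates = c(suicidality_items = 0.0022, sdq_pain = 0.0042,
                      chu_pain = 0.0067, cesd = 0.0059, anxiety = 0.0923,
                      peers = 0.0037, inhibition = 0.0037, gender = 0.0180)) {
  spec <- structure(as.list(environment()), class = "cohort_margin_spec")
  validate_margin_spec(spec)
  spec
}

#' @rdname cohort_margin_spec
#' @export
default_latent_correlations <- function() {
  nm <- c("suic", "pain6", "painT", "dep", "anx", "peers", "inhib")
  R <- matrix(c(
    1.00, 0.47, 0.42, 0.55, 0.40, 0.30, 0.25,
    0.47, 1.00, 0.40, 0.35, 0.30, 0.20, 0.15,
    0.42, 0.40, 1.00, 0.30, 0.25, 0.15, 0.12,
    0.55, 0.35, 0.30, 1.00, 0.60, 0.40, 0.35,
    0.40, 0.30, 0.25, 0.60, 1.00, 0.30, 0.25,
    0.30, 0.20, 0.15, 0.40, 0.30, 1.00, 0.30,
    0.25, 0.15, 0.12, 0.35, 0.25, 0.30, 1.00), 7, 7,
    dimnames = list(nm, nm))
  R
}

validate_margin_spec <- function(spec) {
  check_probs <- function(p, what) {
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
      stop_input("infeasible margin spec: '", what,
                 "' probabilities must be non-negative and sum to 1")
    }
  }
  check_probs(spec$sdq_pain_probs, "sdq_pain_probs")
  check_probs(spec$chu_pain_probs, "chu_pain_probs")
  check_probs(spec$depression_band_probs, "depression_band_probs")
  check_probs(spec$anxiety_band_probs, "anxiety_band_probs")
  check_probs(spec$peers_band_probs, "peers_band_probs")
  check_probs(spec$inhibition_band_probs, "inhibition_band_probs")
  check_probs(spec$gender_probs, "gender_probs")
  if (any(spec$suicidality_item_probs <= 0 | spec$suicidality_item_probs >= 1)) {
    stop_input("infeasible margin spec: suicidality item probabilities must lie in (0,1)")
  }
  if (abs(spec$suicidality_loading) >= 1) {
    stop_input("infeasible margin spec: |suicidality_loading| must be < 1")
  }
  R <- spec$latent_correlations
  if (!isTRUE(all.equal(R, t(R))) || any(abs(diag(R) - 1) > 1e-9)) {
    stop_input("infeasible margin spec: latent_correlations must be a correlation matrix")
  }
  ok <- tryCatch({ chol(R); TRUE }, error = function(e) FALSE)
  if (!ok) {
    stop_input("infeasible margin spec: latent_correlations is not positive definite")
  }
  invisible(spec)
}

# monotone band-uniform mapping: u in [0,1) -> integer score, hitting the
# band probabilities exactly and spreading scores uniformly within a band
band_uniform_score <- function(u, band_probs, band_lo, band_hi) {
  cum <- cumsum(band_probs)
  band <- findInterval(u, c(0, cum[-length(cum)]), rightmost.closed = FALSE)
  band[band < 1] <- 1
  band[band > length(band_probs)] <- length(band_probs)
  lo <- band_lo[band]; hi <- band_hi[band]
  within <- (u - c(0, cum)[band]) / band_probs[band]
  pmin(lo + floor(within * (hi - lo + 1)), hi)
}

#' Sample raw item-level cohort data from a correlated latent layer
#'
#' Generates one row per participant with the raw questionnaire items the
#' derivation rules consume: three suicidality items (yes / no /
#' prefer-not-to-say), the 3-level six-month pain item, the 5-level
#' today-pain item, a 0-60 depression-scale total, anxiety / peer-problems
#' / inhibitory-control scores and gender. A multivariate-normal latent
#' layer is thresholded (Gaussian copula) so each derived variable
#' approximates its target marginal while cross-variable rank
#' correlations are controlled by the latent correlation matrix; score
#' variables use a monotone band-uniform transform so the derived band
#' probabilities are hit exactly in expectation. Missingness is applied
#' completely at random per instrument (jointly for the three suicidality
#' items, mirroring how the source items go missing together).
#'
#' @param margins a [cohort_margin_spec()].
#' @return a [cohort_table()] of raw items.
#' @export
sample_cohort_items <- function(margins = cohort_margin_spec()) {
  stopifnot(inherits(margins, "cohort_margin_spec"))
  validate_margin_spec(margins)
  if (!is.null(margins$seed)) set.seed(margins$seed)
  n <- margins$n

  Rchol <- chol(margins$latent_correlations)
  z <- matrix(stats::rnorm(n * 7), n, 7) %*% Rchol
  colnames(z) <- colnames(margins$latent_correlations)

  lam <- margins$suicidality_loading
  item_yes <- function(p_yes, noise) {
    zi <- lam * z[, "suic"] + sqrt(1 - lam^2) * noise
    zi > stats::qnorm(1 - p_yes)
  }
  eps <- matrix(stats::rnorm(n * 3), n, 3)
  yes <- cbind(item_yes(margins$suicidality_item_probs[1], eps[, 1]),
               item_yes(margins$suicidality_item_probs[2], eps[, 2]),
               item_yes(margins$suicidality_item_probs[3], eps[, 3]))
  pns <- matrix(stats::runif(n * 3) < margins$pns_rate, n, 3)
  item_code <- function(k) {
    out <- ifelse(yes[, k], "yes", ifelse(pns[, k], "pns", "no"))
    factor(out, levels = c("no", "yes", "pns"))
  }

  u_p6 <- stats::pnorm(z[, "pain6"])
  sdq <- cut(u_p6, breaks = c(0, cumsum(margins$sdq_pain_probs)),
             labels = c("not_true", "somewhat_true", "certainly_true"),
             include.lowest = TRUE, ordered_result = TRUE)
  u_pt <- stats::pnorm(z[, "painT"])
  chu <- findInterval(u_pt, cumsum(margins$chu_pain_probs)[-5]) # 0..4

  cesd <- band_uniform_score(stats::pnorm(z[, "dep"]), margins$depression_band_probs,
                             band_lo = c(0, 16, 28), band_hi = c(15, 27, 60))
  anx <- band_uniform_score(stats::pnorm(z[, "anx"]), margins$anxiety_band_probs,
                            band_lo = c(0, 65, 70), band_hi = c(64, 69, 100))
  peers <- band_uniform_score(stats::pnorm(z[, "peers"]), margins$peers_band_probs,
                              band_lo = c(0, 3, 5, 7), band_hi = c(2, 4, 6, 10))
  inhib <- band_uniform_score(stats::pnorm(z[, "inhib"]), margins$inhibition_band_probs,
                              band_lo = c(0, 6, 7, 8), band_hi = c(5, 6, 7, 10))

  gender <- factor(
    sample(names(margins$gender_probs), n, replace = TRUE,
           prob = margins$gender_probs),
    levels = c("girl", "boy", "other_pns"))

  out <- data.frame(
    suicidality_item_a = item_code(1), suicidality_item_b = item_code(2),
    suicidality_item_c = item_code(3),
    sdq_pain = sdq, chu_pain = as.integer(chu), cesd_total = as.integer(cesd),
    anxiety_score = as.integer(anx), peers_score = as.integer(peers),
    inhibition_score = as.integer(inhib), gender = gender
  )

  mr <- margins$missing_rates
  mcar <- function(rate) stats::runif(n) < rate
  drop_suic <- mcar(mr[["suicidality_items"]])
  out$suicidality_item_a[drop_suic] <- NA
  out$suicidality_item_b[drop_suic] <- NA
  out$suicidality_item_c[drop_suic] <- NA
  out$sdq_pain[mcar(mr[["sdq_pain"]])] <- NA
  out$chu_pain[mcar(mr[["chu_pain"]])] <- NA
  out$cesd_total[mcar(mr[["cesd"]])] <- NA
  out$anxiety_score[mcar(mr[["anxiety"]])] <- NA
  out$peers_score[mcar(mr[["peers"]])] <- NA
  out$inhibition_score[mcar(mr[["inhibition"]])] <- NA
  out$gender[mcar(mr[["gender"]])] <- NA

  cohort_table(out, provenance = list(
    generator = "sample_cohort_items", seed = margins$seed, n = n
  ))
}

#' Write / read a `cohort_margin_spec` as YAML
#' @param spec a [cohort_margin_spec()].
#' @param path file path.
#' @export
write_margin_spec_yaml <- function(spec, path) {
  obj <- unclass(spec)
  for (f in c("sdq_pain_probs", "chu_pain_probs", "suicidality_item_probs",
              "depression_band_probs", "anxiety_band_probs", "peers_band_probs",
              "inhibition_band_probs", "gender_probs", "missing_rates")) {
    obj[[f]] <- as.list(obj[[f]]) # keep names through YAML maps
  }
  obj$latent_correlations <- list(
    names = colnames(spec$latent_correlations),
    values = as.vector(spec$latent_correlations)
  )
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_margin_spec_yaml
#' @export
read_margin_spec_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  nm <- obj$latent_correlations$names
  R <- matrix(as.numeric(obj$latent_correlations$values), length(nm), length(nm),
              dimnames = list(nm, nm))
  obj$latent_correlations <- R
  for (f in c("sdq_pain_probs", "chu_pain_probs", "suicidality_item_probs",
              "depression_band_probs", "anxiety_band_probs", "peers_band_probs",
              "inhibition_band_probs", "gender_probs", "missing_rates")) {
    obj[[f]] <- unlist(obj[[f]])
  }
  do.call(cohort_margin_spec, obj)
}
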