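codes3 <- c("yes", "no", "pns", NA)

test_that("suicidality coding enumerates correctly over all item combinations", {
  for (a in codes3) for (b in codes3) for (c in codes3) {
    got <- as.character(derive_suicidality(a, b, c))
    # expected per the published rule: present on any yes; absent for both
    # other responses; missing only when nothing was answered
    n_yes <- sum(c(a, b, c) == "yes", na.rm = TRUE)
    n_answered <- sum(!is.na(c(a, b, c)))
    expected <- if (n_yes >= 1) "present"
    else if (n_answered == 0) NA_character_ else "absent"
    expect_identical(got, expected,
                     info = paste("items:", paste(c(a, b, c), collapse = "/")))
  }
})

test_that("suicidality coding matches the published worked cases", {
  expect_identical(as.character(derive_suicidality("yes", "no", "pns")), "present")
  expect_identical(as.character(derive_suicidality("no", "no", "no")), "absent")
  expect_identical(as.character(derive_suicidality("pns", "pns", "pns")), "absent")
  expect_error(derive_suicidality("maybe", "no", "no"), "invalid code")
})

test_that("suicidality coding is monotone towards present", {
  rank_out <- function(x) match(ifelse(is.na(x), "missing", x),
                                c("missing", "absent", "present"))
  for (a in codes3) for (b in codes3) for (c in codes3) {
    base <- rank_out(as.character(derive_suicidality(a, b, c)))
    for (slot in 1:3) {
      items <- c(a, b, c)
      items[slot] <- "yes"
      bumped <- rank_out(as.character(derive_suicidality(items[1], items[2], items[3])))
      expect_gte(bumped, base)
    }
  }
})

test_that("six-month pain follows the item response coding", {
  expect_identical(as.character(derive_pain_sdq("not_true")), "absent")
  expect_identical(as.character(derive_pain_sdq("somewhat_true")), "present")
  expect_identical(as.character(derive_pain_sdq("certainly_true")), "present")
  expect_true(is.na(derive_pain_sdq(NA)))
  expect_error(derive_pain_sdq("sometimes"), "invalid code")
})

test_that("today-pain codes 0 absent and 1-4 present", {
  expect_identical(as.character(derive_pain_chu(0)), "absent")
  expect_identical(as.character(derive_pain_chu(c(1, 2, 3, 4))),
                   rep("present", 4))
  expect_true(is.na(derive_pain_chu(NA)))
  expect_error(derive_pain_chu(5), "0-4")
  expect_error(derive_pain_chu(-1), "0-4")
})

test_that("combined pain requires both indicators and is symmetric", {
  lv <- c("present", "absent", NA)
  expected <- function(x, y) {
    if (!is.na(x) && !is.na(y) && x == "present" && y == "present") return("present")
    if ((!is.na(x) && x == "absent") || (!is.na(y) && y == "absent")) return("absent")
    NA_character_
  }
  for (x in lv) for (y in lv) {
    expect_identical(as.character(combine_pain(x, y)), expected(x, y))
    expect_identical(as.character(combine_pain(x, y)),
                     as.character(combine_pain(y, x)))
  }
  expect_identical(as.character(combine_pain("absent", NA)), "absent")
  expect_identical(as.character(combine_pain("present", NA)), NA_character_)
})

test_that("depression banding respects the published boundaries", {
  expect_identical(as.character(categorize_cesd(c(0, 15, 16, 27, 28, 60))),
                   c("normal", "normal", "at_risk", "at_risk",
                     "caseness", "caseness"))
  expect_true(is.na(categorize_cesd(NA)))
  expect_error(categorize_cesd(61), "0-60")
  expect_error(categorize_cesd(-1), "0-60")
})

test_that("generic banding uses half-open intervals with the upper band at cutpoints", {
  cp <- c(0, 3, 5, 7, 11)
  lb <- c("normal", "borderline", "high", "very_high")
  expect_identical(as.character(categorize_band(2, cp, lb)), "normal")
  expect_identical(as.character(categorize_band(3, cp, lb)), "borderline")
  expect_identical(as.character(categorize_band(5, cp, lb)), "high")
  expect_identical(as.character(categorize_band(10, cp, lb)), "very_high")
  expect_error(categorize_band(11, cp, lb), "outside")
  expect_error(categorize_band(2, c(0, 3, 3, 7), lb[1:3]), "strictly increasing")
  anx <- band_defaults()$anxiety
  expect_identical(levels(categorize_band(50, anx$cutpoints, anx$labels)),
                   c("non_clinical", "borderline", "clinical"))
})

test_that("derivations are pure functions of their inputs", {
  set.seed(1)
  for (i in 1:20) {
    a <- sample(codes3, 1); b <- sample(codes3, 1); c <- sample(codes3, 1)
    expect_identical(derive_suicidality(a, b, c), derive_suicidality(a, b, c))
  }
})

test_that("complete-case filtering reproduces the printed participant flow", {
  fx <- make_printed_fixture()
  cc <- quiet(complete_case_filter(fx, c("pain", "suicidality")))
  expect_equal(nrow(cc), 8010)
  expect_equal(attr(cc, "n_removed"), 62)
  nomiss <- data.frame(a = factor(c("x", "y")), b = 1:2)
  expect_equal(nrow(quiet(complete_case_filter(nomiss, c("a", "b")))), 2)
  expect_error(complete_case_filter(nomiss, "zzz"), "unknown columns")
})

test_that("non-binary gender exclusion matches the printed counts", {
  fx <- make_printed_fixture()
  kept <- exclude_nonbinary_gender(fx)
  expect_equal(nrow(kept), 7769)
  expect_true(all(kept$gender %in% c("girl", "boy")))
  empty <- fx[0, ]
  expect_equal(nrow(exclude_nonbinary_gender(empty)), 0)
})

test_that("full derivation pipeline types every analysis column and audits counts", {
  ms <- cohort_margin_spec(n = 400, seed = 7)
  raw <- sample_cohort_items(ms)
  dv <- derive_cohort(raw)
  expect_setequal(intersect(c("suicidality", "depression", "anxiety", "inhibition",
                              "peers", "pain"), names(dv)),
                  c("suicidality", "depression", "anxiety", "inhibition",
                    "peers", "pain"))
  audit <- attr(dv, "audit")
  expect_equal(sum(audit$suicidality), 400)
  expect_true(all(c("missing") %in% names(audit$pain)))
})
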