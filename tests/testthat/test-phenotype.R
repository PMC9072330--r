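test_that("frailty scoring reproduces the category definitions", {
  expect_equal(as.character(classify_frailty(c(1, 1, 1, 0, 0))), "frail")
  expect_equal(as.character(classify_frailty(c(0, 0, 0, 0, 0))), "robust")
  expect_equal(as.character(classify_frailty(c(1, 0, 0, 0, 0))), "prefrail")
  expect_equal(as.character(classify_frailty(c(1, 1, 0, 0, 0))), "prefrail")
  # ambiguous under completion of the missing item
  expect_equal(as.character(classify_frailty(c(1, 1, 0, 0, NA))), "indeterminate")
  # already certain despite a missing item
  expect_equal(as.character(classify_frailty(c(1, 1, 1, 1, NA))), "frail")
  expect_error(classify_frailty(c(1, 1, 2, 0, 0)), "coded 0, 1 or NA")
  expect_error(classify_frailty(c(1, 1, 0, 0)), "five columns")
})

test_that("missing-item rule equals invariance over all completions of the profile", {
  # every composition of (positives, negatives, missing) summing to 5
  for (pos in 0:5) for (miss in 0:(5 - pos)) {
    neg <- 5 - pos - miss
    items <- c(rep(1, pos), rep(0, neg), rep(NA, miss))
    got <- as.character(classify_frailty(items))
    # oracle: enumerate all 2^miss completions; assign only if invariant
    completions <- if (miss == 0) list(integer(0)) else
      asplit(as.matrix(expand.grid(rep(list(0:1), miss))), 1)
    states <- unique(vapply(completions, function(fill)
      oracle_state_complete(c(rep(1, pos), rep(0, neg), fill)), character(1)))
    expected <- if (length(states) == 1) states else "indeterminate"
    expect_equal(got, expected,
                 info = sprintf("pos=%d neg=%d miss=%d", pos, neg, miss))
  }
})

test_that("scoring is monotone and never indeterminate on complete items", {
  complete <- as.matrix(expand.grid(rep(list(0:1), 5)))
  states <- classify_frailty(complete)
  expect_false(any(states == "indeterminate"))
  sev <- c(robust = 0, prefrail = 1, frail = 2)
  # flipping any absent item to present never moves toward robust
  for (i in seq_len(nrow(complete))) {
    for (j in which(complete[i, ] == 0)) {
      bumped <- complete[i, ]; bumped[j] <- 1
      expect_gte(sev[as.character(classify_frailty(bumped))],
                 sev[as.character(states[i])])
    }
  }
})

test_that("transition classification covers every case exactly once", {
  for (b in c("robust", "prefrail", "frail"))
    for (f in c("robust", "prefrail", "frail", "indeterminate"))
      for (d in c(TRUE, FALSE)) {
        out <- classify_transition(b, f, d)
        expect_length(out, 1)
        expect_false(is.na(out))
      }
  expect_equal(as.character(classify_transition("frail", "robust", FALSE)), "improvement")
  expect_equal(as.character(classify_transition("prefrail", "indeterminate", TRUE)), "worsening")
  expect_equal(as.character(classify_transition("prefrail", "prefrail", FALSE)), "no_change")
  expect_equal(as.character(classify_transition("robust", "indeterminate", FALSE)), "unknown")
  # death overrides a recorded follow-up improvement
  expect_equal(as.character(classify_transition("frail", "robust", TRUE)), "worsening")
  expect_error(classify_transition("indeterminate", "robust", FALSE),
               class = "frailtrans_baseline_indeterminate")
})

test_that("improvement and worsening are anti-symmetric under state swap", {
  states <- c("robust", "prefrail", "frail")
  for (a in states) for (b in states) {
    ab <- as.character(classify_transition(a, b, FALSE))
    ba <- as.character(classify_transition(b, a, FALSE))
    if (a == b) {
      expect_equal(ab, "no_change")
    } else {
      expect_true((ab == "improvement") == (ba == "worsening"))
    }
  }
})

test_that("predictor derivation applies the printed cutpoints exactly", {
  d <- derive_predictors(data.frame(
    egfr = c(59.9, 60, NA), acr = c(30, 29.9, NA), n_medications = c(5, 4, NA),
    hba1c = c(6.4, 6.5, NA), antidiabetic_drug = c(TRUE, FALSE, FALSE),
    bmi = c(24.9, 25, 30), n_hospitalizations = c(0, 2, 3)
  ))
  expect_equal(d$egfr_lt60, c(TRUE, FALSE, NA))
  expect_equal(d$acr_ge30, c(TRUE, FALSE, NA))
  expect_equal(d$polypharmacy, c(TRUE, FALSE, NA))
  expect_equal(d$diabetes, c(TRUE, TRUE, NA))  # drug intake alone suffices
  expect_equal(as.character(d$bmi_cat), c("<25", "25-29.9", ">=30"))
  expect_equal(as.character(d$hospitalization_cat), c("0", "1-2", ">=3"))
  expect_error(derive_predictors(data.frame(egfr = -1)), "negative")
})

test_that("cohort classification drops baseline-indeterminate participants", {
  fx <- reference_transition_fixture()
  # corrupt two baseline profiles into ambiguity (1 positive, 2 missing)
  fx$bl_shrinking[1:2] <- NA
  fx$bl_slowness[1:2] <- NA
  fx$bl_exhaustion[1:2] <- 1L
  cl <- classify_cohort(fx)
  expect_equal(attr(cl, "n_excluded_baseline"), 2L)
  expect_equal(nrow(cl), nrow(fx) - 2L)
  expect_false(any(is.na(cl$transition_outcome)))
})
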