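# naive pairwise enumeration, the oracle for the rank-based implementation
c_index_pairs <- function(scores, y) {
  y <- as.logical(y)
  num <- 0; den <- 0
  for (i in which(y)) for (j in which(!y)) {
    den <- den + 1
    num <- num + if (scores[i] > scores[j]) 1 else if (scores[i] == scores[j]) 0.5 else 0
  }
  num / den
}

test_that("c-index equals pairwise enumeration and the survival package", {
  expect_equal(c_index(c(0.9, 0.8, 0.7, 0.1), c(1, 0, 1, 0)), 0.75)
  expect_equal(c_index(1:10, c(rep(0, 5), rep(1, 5))), 1.0)
  expect_equal(c_index(rep(0.3, 8), rep(c(0, 1), 4)), 0.5)
  expect_error(c_index(1:4, c(1, 1, 1, 1)), "both outcome classes")
  set.seed(89)
  for (r in 1:20) {
    n <- sample(10:40, 1)
    s <- sample(seq(0, 1, 0.1), n, replace = TRUE)  # ties likely
    y <- c(0, 1, rbinom(n - 2, 1, 0.4))
    expect_equal(c_index(s, y), c_index_pairs(s, y), tolerance = 1e-12)
  }
  if (requireNamespace("survival", quietly = TRUE)) {
    set.seed(90)
    s <- rnorm(200); y <- rbinom(200, 1, 0.3)
    cc <- survival::concordance(y ~ s)$concordance
    expect_equal(c_index(s, y), cc, tolerance = 1e-12)
  }
})

test_that("c-index is invariant under strictly monotone score transforms", {
  set.seed(91)
  for (r in 1:100) {
    n <- 50
    s <- rnorm(n); y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    base <- c_index(s, y)
    expect_equal(c_index(exp(s), y), base, tolerance = 1e-12)
    expect_equal(c_index(5 * s - 3, y), base, tolerance = 1e-12)
    expect_equal(c_index(plogis(s), y), base, tolerance = 1e-12)
  }
})

test_that("a fixed external scoring rule has zero optimism", {
  set.seed(97)
  d <- data.frame(x = rnorm(100))
  y <- rbinom(100, 1, plogis(d$x))
  h <- harrell_optimism(
    d, y,
    fit_fun = NULL,                               # nothing is learned
    predict_fun = function(model, data) data$x,   # fixed external formula
    metric_fun = function(s, y) c_index(s, y), B = 30
  )
  expect_equal(unname(h$corrected), unname(h$apparent), tolerance = 1e-12)
  expect_true(all(abs(h$optimism) < 1e-12, na.rm = TRUE))
})

test_that("the optimism loop matches a naive double-for reference on shared resamples", {
  set.seed(101)
  n <- 80
  d <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
  y <- rbinom(n, 1, plogis(0.8 * d$x1))
  idx <- lapply(1:10, function(b) sample.int(n, n, replace = TRUE))
  fit_fun <- function(data, yy) fit_logistic(cbind(1, data$x1, data$x2), yy)
  pred_fun <- function(m, data) drop(cbind(1, data$x1, data$x2) %*% m$coefficients)
  h <- harrell_optimism(d, y, fit_fun, pred_fun,
                        function(s, yy) c_index(s, yy), B = 10, indices = idx)
  # reference: independently coded loop over the same index vectors
  app <- c_index(pred_fun(fit_fun(d, y), d), y)
  opts <- numeric(0)
  for (b in 1:10) {
    ib <- idx[[b]]
    if (sum(y[ib]) %in% c(0, n)) next
    mb <- fit_fun(d[ib, ], y[ib])
    opts <- c(opts, c_index(pred_fun(mb, d[ib, ]), y[ib]) - c_index(pred_fun(mb, d), y))
  }
  expect_equal(unname(h$corrected), app - mean(opts), tolerance = 1e-12)
})

test_that("pure-noise models show the known overfitting direction", {
  set.seed(103)
  ok_dir <- logical(5); toward_half <- logical(5)
  for (r in 1:5) {
    d <- as.data.frame(matrix(rnorm(200 * 10), 200, 10))
    d$frailty_baseline <- factor("prefrail", levels = c("robust", "prefrail", "frail"))
    d$transition_outcome <- factor(ifelse(rbinom(200, 1, 0.4) == 1, "worsening", "no_change"),
                                   levels = transition_levels())
    stack <- identical_stack(d, m = 2)
    res <- optimism_corrected_auc(stack, paste0("V", 1:10), "worsening",
                                  bootstraps = 25, seed = 200 + r)
    ok_dir[r] <- all(res$apparent - res$corrected > 0)
    toward_half[r] <- abs(mean(res$corrected) - 0.5) < abs(mean(res$apparent) - 0.5)
  }
  expect_gte(mean(ok_dir), 0.8)
  expect_gte(mean(toward_half), 0.8)
})

test_that("AUC interval: degenerate scores, instability flag, 1/sqrt(n) scaling", {
  y <- rep(c(0, 1), 50)
  ci <- auc_ci(rep(0.5, 100), y, reps = 50, seed = 1)
  expect_equal(ci$se, 0)
  expect_equal(ci$low, ci$high)
  expect_warning(auc_ci(rnorm(100), y, reps = 2, seed = 1), "unstable")
  expect_error(auc_ci(rnorm(100), y, reps = 1), ">= 2")
  ses <- vapply(c(200, 800, 3200), function(n) {
    set.seed(n)
    s <- rnorm(n); yy <- rbinom(n, 1, plogis(s))
    auc_ci(s, yy, reps = 400, seed = 5)$se
  }, numeric(1))
  expect_true(all(diff(ses) < 0))
  expect_lt(ses[2] / ses[1], 0.75)  # roughly halves per 4x n
  expect_gt(ses[2] / ses[1], 0.3)
})

test_that("calibration recovers (0, 1) under the true model and 0.5 slope under doubling", {
  set.seed(107)
  n <- 20000
  lp <- rnorm(n, -0.5, 1.2)
  y <- rbinom(n, 1, plogis(lp))
  cal <- calibration(lp, y)
  expect_lt(abs(cal["slope"] - 1), 0.05)
  expect_lt(abs(cal["intercept"]), 0.05)
  cal2 <- calibration(2 * lp, y)
  expect_lt(abs(cal2["slope"] - 0.5), 0.05)
  expect_error(calibration(lp, rep(1, n)), "single-class")
  expect_error(calibration(rep(0.2, 100), rep(c(0, 1), 50)), "constant")
})

test_that("bias-corrected calibration: decile partition, shrinkage direction, self-consistency", {
  set.seed(109)
  # well-specified model, generous n: corrected slope stays near 1
  n <- 2000
  d <- data.frame(x = rnorm(n))
  d$frailty_baseline <- factor("prefrail", levels = c("robust", "prefrail", "frail"))
  lp <- -0.8 + 1.1 * d$x
  d$transition_outcome <- factor(ifelse(rbinom(n, 1, plogis(lp)) == 1, "worsening", "no_change"),
                                 levels = transition_levels())
  stack <- identical_stack(d, m = 2)
  cal <- bias_corrected_calibration(stack, "x", "worsening", bootstraps = 40, seed = 7)
  expect_true(all(cal$slope >= 0.9 & cal$slope <= 1.1))
  # decile curve partitions each imputation's sample
  for (i in seq_len(stack$m)) {
    cv <- cal$curve[cal$curve$imputation == i, ]
    expect_equal(sum(cv$n), n)
    expect_lte(nrow(cv), 10)
    expect_gte(nrow(cv), 8)
  }
  expect_true(all(diff(cal$curve$predicted[cal$curve$imputation == 1]) > 0))
  # overfitted noise model: corrected slope < 1
  d2 <- as.data.frame(matrix(rnorm(150 * 8), 150, 8))
  d2$frailty_baseline <- factor("prefrail", levels = c("robust", "prefrail", "frail"))
  d2$transition_outcome <- factor(ifelse(rbinom(150, 1, 0.5) == 1, "worsening", "no_change"),
                                  levels = transition_levels())
  cal2 <- bias_corrected_calibration(identical_stack(d2, 2), paste0("V", 1:8),
                                     "worsening", bootstraps = 40, seed = 11)
  expect_true(all(cal2$slope < 1))
})

test_that("full validation on a zero-missingness stack does not depend on m", {
  set.seed(113)
  d <- make_model_df(400)
  v2 <- validate_model(identical_stack(d, 2), "x_strong", "worsening",
                       bootstraps = 15, auc_reps = 100, calibration_bootstraps = 15,
                       seed = 3)
  v4 <- validate_model(identical_stack(d, 4), "x_strong", "worsening",
                       bootstraps = 15, auc_reps = 100, calibration_bootstraps = 15,
                       seed = 3)
  # apparent performance is identical across imputations and across m;
  # the bootstrap correction is a Monte-Carlo quantity, equal in expectation
  expect_equal(length(unique(v2$apparent_auc)), 1L)
  expect_equal(unique(v2$apparent_auc), unique(v4$apparent_auc), tolerance = 1e-12)
  expect_equal(v2$c_index, v4$c_index, tolerance = 0.05)
  expect_true(v2$c_index_ci[1] <= v2$c_index & v2$c_index <= v2$c_index_ci[2])
})
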