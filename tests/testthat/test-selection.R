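test_that("logistic fitting matches an independent likelihood maximiser", {
  set.seed(41)
  n <- 200
  x1 <- rnorm(n); x2 <- runif(n) < 0.5
  y <- runif(n) < plogis(-0.5 + 0.8 * x1 + 1.1 * x2)
  X <- cbind(1, x1, x2 = as.numeric(x2))
  fit <- fit_logistic(X, y)
  # independent oracle: direct numerical maximisation of the hand-coded
  # log-likelihood, no IRLS involved
  nll <- function(b) {
    eta <- drop(X %*% b)
    -sum(y * eta - log1p(exp(eta)))
  }
  opt <- optim(c(0, 0, 0), nll, method = "BFGS",
               control = list(reltol = 1e-14, maxit = 1000))
  expect_equal(unname(fit$coefficients), opt$par, tolerance = 5e-4)
  expect_equal(fit$logLik, -opt$value, tolerance = 1e-6)
  expect_false(fit$separation)
})

test_that("an intercept-only balanced fit estimates logit(0.5) = 0", {
  X <- matrix(1, 100, 1)
  y <- rep(c(0, 1), 50)
  fit <- fit_logistic(X, y)
  expect_lt(abs(fit$coefficients[1]), 1e-8)
})

test_that("perfect separation is flagged and ridge-stabilised", {
  n <- 60
  x <- c(rnorm(n / 2, -3), rnorm(n / 2, 3))
  y <- x > 0
  fit <- fit_logistic(cbind(1, x), y)
  expect_true(fit$separation)
  expect_true(all(is.finite(fit$coefficients)))
  expect_true(all(is.finite(diag(fit$vcov))))
})

test_that("AIC follows 2k - 2 logLik and behaves on nested refits", {
  fake <- list(logLik = -100, k = 3)
  expect_equal(aic(fake), 206)
  expect_equal(aic(fake, k = 4) - aic(fake, k = 3), 2)
  set.seed(43)
  n <- 300
  x1 <- rnorm(n); x2 <- rnorm(n)
  y <- runif(n) < plogis(0.5 * x1)
  f_small <- fit_logistic(cbind(1, x1), y)
  f_big <- fit_logistic(cbind(1, x1, x2), y)
  # nested-model identity computed from independently refit pieces
  expect_equal(aic(f_big) - aic(f_small),
               2 * (f_big$k - f_small$k) - 2 * (f_big$logLik - f_small$logLik),
               tolerance = 1e-10)
})

test_that("backward AIC keeps signal, drops noise, and matches a drop1-based oracle", {
  expect_equal(backward_select_aic(data.frame(y = rep(c(0, 1), 20)), "y",
                                   character())$selected, character())
  set.seed(47)
  n <- 2000
  strong <- runif(n) < 0.5
  noise <- rnorm(n)
  y <- runif(n) < plogis(-0.5 + 1.5 * strong)
  d <- data.frame(y = y, strong = strong, noise = noise)
  res <- backward_select_aic(d, "y", c("strong", "noise"))
  # oracle: exhaustive enumeration of all 2^2 candidate subsets
  subset_aic <- vapply(list(character(), "strong", "noise", c("strong", "noise")),
                       function(s) {
                         mm <- if (length(s)) model.matrix(reformulate(s), d)
                               else matrix(1, n, 1)
                         f <- fit_logistic(mm, y)
                         aic(f)
                       }, numeric(1))
  expect_equal(res$selected, "strong")
  expect_equal(res$aic, min(subset_aic), tolerance = 1e-8)
  expect_lte(res$aic, res$aic_full)

  # p = 4 toy: greedy path equals an independently coded drop1/glm loop
  set.seed(53)
  n <- 500
  d4 <- data.frame(a = rnorm(n), b = runif(n) < 0.5,
                   g = factor(sample(c("x", "y", "z"), n, TRUE)), c = rnorm(n))
  d4$y <- runif(n) < plogis(-0.2 + 0.9 * d4$a + 0.8 * (d4$g == "z"))
  res4 <- backward_select_aic(d4, "y", c("a", "b", "g", "c"))
  f <- glm(y ~ a + b + g + c, data = d4, family = binomial())
  repeat {
    dr <- drop1(f)
    if (min(dr$AIC[-1]) >= dr$AIC[1] - 1e-8) break
    worst <- rownames(dr)[-1][which.min(dr$AIC[-1])]
    f <- update(f, paste(". ~ . -", worst))
  }
  oracle_terms <- sort(attr(terms(f), "term.labels"))
  expect_equal(res4$selected, oracle_terms)
  expect_equal(res4$aic, AIC(f), tolerance = 1e-6)
})

test_that("selection configuration enforces its invariants", {
  expect_error(selection_config(frequency_threshold = 1.2), "0, 1")
  expect_error(selection_config(bootstraps_per_imputation = 0), ">= 1")
  cfg <- selection_config("improvement", 50, 0.5)
  expect_equal(cfg$outcome, "improvement")
})

test_that("stability selection tallies, selects by threshold, and is order-invariant", {
  set.seed(59)
  d <- make_model_df(800, beta_strong = 1.5)
  stack <- identical_stack(d, m = 2)
  cands <- c("x_strong", "x_noise", "frailty_baseline")
  cfg <- selection_config("worsening", bootstraps_per_imputation = 15,
                          candidates = cands, seed = 61)
  res <- stability_select(stack, cfg)
  expect_equal(res$total_samples, 30)
  expect_lte(res$samples_used, 30)
  expect_true(all(res$frequencies >= 0 & res$frequencies <= 1))
  expect_true(all(res$selected %in% cands))
  expect_gte(res$frequencies[["x_strong"]], 0.9)
  # noise retention: judged over replicate cohort draws (a single draw can
  # make a noise column spuriously predictive)
  noise_freq <- vapply(1:5, function(r) {
    set.seed(600 + r)
    dr <- make_model_df(800, beta_strong = 1.5)
    sr <- stability_select(identical_stack(dr, 2),
                           selection_config("worsening", 15, candidates = cands,
                                            seed = 700 + r))
    sr$frequencies[["x_noise"]]
  }, numeric(1))
  expect_lt(mean(noise_freq), 0.5)
  # permuting the candidate order changes nothing
  cfg_perm <- selection_config("worsening", bootstraps_per_imputation = 15,
                               candidates = rev(cands), seed = 61)
  expect_identical(res$frequencies, stability_select(stack, cfg_perm)$frequencies)
  # raising the threshold never enlarges the selected set
  hi <- selection_config("worsening", 15, frequency_threshold = 0.8,
                         candidates = cands, seed = 61)
  expect_true(all(stability_select(stack, hi)$selected %in% res$selected))
})

test_that("improvement models exclude the baseline-robust and relevel to frail", {
  d <- make_model_df(300, outcome = "improvement")
  d$frailty_baseline[1:50] <- "robust"
  sub <- analysis_subset(d, "improvement")
  expect_false(any(sub$frailty_baseline == "robust"))
  expect_equal(levels(sub$frailty_baseline)[1], "frail")
  expect_equal(nrow(sub), 250)
  all_sub <- analysis_subset(d, "worsening")
  expect_equal(nrow(all_sub), 300)
})
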