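# shared fixture builders (all generated in code, seed-pinned by callers)

# analysis table with a binary strong predictor and a noise predictor, with
# the outcome drawn from a known logistic law; shaped like an imputed
# dataset (frailty_baseline + transition_outcome present)
make_model_df <- function(n, beta_strong = 1.5, intercept = -1, outcome = "worsening") {
  x_strong <- runif(n) < 0.5
  x_noise <- rnorm(n)
  lp <- intercept + beta_strong * x_strong
  y <- runif(n) < plogis(lp)
  data.frame(
    x_strong = x_strong, x_noise = x_noise,
    frailty_baseline = factor(sample(c("prefrail", "frail"), n, TRUE),
                              levels = c("robust", "prefrail", "frail")),
    transition_outcome = factor(ifelse(y, outcome, "no_change"),
                                levels = transition_levels())
  )
}

# complete-data stack of m identical copies (no missingness)
identical_stack <- function(df, m = 2) {
  impute_chained(df, m = m, iterations = 1, seed = 1)
}

# single-stratum config for generator tests
one_stratum_config <- function(n, mechanism = "matrix", logistic = NULL,
                               covariates = NULL, missingness = NULL,
                               loss_rate = 0.05, seed = 1L) {
  base <- default_bis_config()$strata$woman
  s <- base
  s$n <- n
  if (!is.null(covariates)) s$covariates <- covariates
  s$missingness <- missingness
  s$loss_rate <- loss_rate
  cohort_config(list(woman = s), mechanism = mechanism, logistic = logistic,
                seed = seed)
}

# fully observed classification of a complete 5-item profile (test oracle)
oracle_state_complete <- function(items) {
  pos <- sum(items)
  if (pos >= 3) "frail" else if (pos == 0) "robust" else "prefrail"
}
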