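#' Concordance index (AUC) by the midrank formula
#'
#' Over all (event, non-event) pairs, a concordant pair counts 1, a tied
#' score 0.5 and a discordant pair 0; the c-index is the average. Computed
#' via midranks in O(n log n), which is exactly the pairwise enumeration
#' value. Invariant under strictly monotone transforms of the scores.
#'
#' @param scores Numeric risk scores.
#' @param outcomes Binary outcomes (0/1 or logical).
#' @return The c-index in [0, 1].
#' @examples
#' c_index(c(0.9, 0.8, 0.7, 0.1), c(1, 0, 1, 0))  # 0.75
#' @export
c_index <- function(scores, outcomes) {
  y <- as.logical(outcomes)
  stopifnot(length(scores) == length(y), !anyNA(scores), !anyNA(y))
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0 || n0 == 0) stop("c-index undefined: both outcome classes must be present")
  r <- rank(scores)  # midranks handle ties as 0.5
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Harrell's bootstrap optimism correction for an arbitrary metric
#'
#' Generic engine: fit a model on each bootstrap resample, evaluate the
#' metric on the resample and on the original data, and average the
#' difference (the optimism). Corrected = apparent - mean optimism. Used for
#' both the c-index and the calibration intercept/slope; a `fit_fun` that
#' ignores its data (a fixed external scoring rule) yields optimism
#' identically zero.
#'
#' @param data Data.frame of predictors.
#' @param y Binary outcome vector.
#' @param fit_fun `function(data, y)` returning a model object, or `NULL`
#'   for a fixed external scoring rule: with nothing refit there is no
#'   source of optimism and the correction is structurally zero.
#' @param predict_fun `function(model, data)` returning scores.
#' @param metric_fun `function(scores, y)` returning a numeric vector.
#' @param B Number of bootstrap resamples.
#' @param indices Optional list of B resample index vectors (for exact
#'   reproduction with an external loop); drawn internally otherwise.
#' @param max_retry Redraws allowed when a resample has a single outcome
#'   class (only when `indices` is NULL).
#' @return List: `apparent`, `optimism` (B x length(metric) matrix),
#'   `corrected`, `b_used`.
#' @export
harrell_optimism <- function(data, y, fit_fun, predict_fun, metric_fun, B,
                             indices = NULL, max_retry = 10) {
  y <- as.numeric(y)
  n <- length(y)
  if (is.null(fit_fun)) {
    apparent <- metric_fun(predict_fun(NULL, data), y)
    return(list(apparent = apparent,
                optimism = matrix(0, B, length(apparent)),
                corrected = apparent, b_used = 0L))
  }
  model0 <- fit_fun(data, y)
  apparent <- metric_fun(predict_fun(model0, data), y)
  opt <- matrix(NA_real_, B, length(apparent))
  b_used <- 0L
  for (b in seq_len(B)) {
    if (!is.null(indices)) {
      idx <- indices[[b]]
      if (sum(y[idx]) %in% c(0, n)) next
    } else {
      ok <- FALSE
      for (try in seq_len(max_retry)) {
        idx <- sample.int(n, n, replace = TRUE)
        if (!sum(y[idx]) %in% c(0, length(idx))) { ok <- TRUE; break }
      }
      if (!ok) next
    }
    mb <- fit_fun(data[idx, , drop = FALSE], y[idx])
    perf_boot <- metric_fun(predict_fun(mb, data[idx, , drop = FALSE]), y[idx])
    perf_orig <- metric_fun(predict_fun(mb, data), y)
    opt[b, ] <- perf_boot - perf_orig
    b_used <- b_used + 1L
  }
  mean_opt <- colMeans(opt, na.rm = TRUE)
  mean_opt[is.nan(mean_opt)] <- 0
  list(apparent = apparent, optimism = opt,
       corrected = apparent - mean_opt, b_used = b_used)
}

refit_tools <- function(terms) {
  list(
    fit = function(data, y) {
      mm <- if (length(terms)) build_design(data, sort(unique(terms)))$mm
            else matrix(1, nrow(data), 1, dimnames = list(NULL, "(Intercept)"))
      fit_logistic(mm, y)
    },
    predict = function(model, data) {
      linear_predictor(model$coefficients, data, terms)
    }
  )
}

#' Optimism-corrected c-index across an imputed stack
#'
#' Per imputation, runs the Harrell loop with the *fixed* selected term set
#' (selection is not re-run inside the validation bootstraps), giving
#' apparent AUC, mean optimism and corrected AUC; the single reported
#' c-index is the mean of the per-imputation corrected values.
#'
#' @param stack Imputed stack (datasets with `frailty_baseline` and
#'   `transition_outcome`).
#' @param terms Selected predictor columns.
#' @param outcome `"improvement"` or `"worsening"`.
#' @param bootstraps Resamples per imputation (default 200).
#' @param seed Integer seed.
#' @return List: `apparent` (M-vector), `corrected` (M-vector),
#'   `corrected_pooled`, `optimism_mean` (M-vector).
#' @export
optimism_corrected_auc <- function(stack, terms, outcome, bootstraps = 200, seed = 1L) {
  set.seed(seed)
  tools <- refit_tools(terms)
  res <- lapply(stack$datasets, function(dset) {
    d <- analysis_subset(dset, outcome)
    harrell_optimism(d, d$.y, tools$fit, tools$predict,
                     function(s, y) c_index(s, y), bootstraps)
  })
  apparent <- vapply(res, function(r) r$apparent, numeric(1))
  corrected <- vapply(res, function(r) r$corrected, numeric(1))
  list(apparent = apparent, corrected = corrected,
       corrected_pooled = mean(corrected),
       optimism_mean = apparent - corrected)
}

#' Bootstrap confidence interval for the c-index
#'
#' The standard error is the standard deviation of the c-index over `reps`
#' bootstrap resamples of the (score, outcome) pairs; the interval is
#' `estimate +/- 1.96 SE`, truncated to [0, 1].
#'
#' @param scores,outcomes Scores and binary outcomes of a completed dataset.
#' @param estimate Centre of the interval (e.g. the corrected pooled
#'   c-index); defaults to `c_index(scores, outcomes)`.
#' @param reps Bootstrap replications (default 2000; values < 30 are
#'   accepted but flagged with a warning as unstable).
#' @param seed Integer seed.
#' @return List: `low`, `high`, `se`, `reps`.
#' @export
auc_ci <- function(scores, outcomes, estimate = c_index(scores, outcomes),
                   reps = 2000, seed = 1L) {
  if (reps < 2) stop("reps must be >= 2")
  if (reps < 30) warning("auc_ci with reps = ", reps, " is unstable")
  set.seed(seed)
  y <- as.logical(outcomes)
  n <- length(y)
  aucs <- rep(NA_real_, reps)
  for (r in seq_len(reps)) {
    idx <- sample.int(n, n, replace = TRUE)
    if (sum(y[idx]) %in% c(0, n)) next
    aucs[r] <- c_index(scores[idx], y[idx])
  }
  se <- stats::sd(aucs, na.rm = TRUE)
  list(low = max(0, estimate - 1.96 * se), high = min(1, estimate + 1.96 * se),
       se = se, reps = reps)
}

#' Logistic calibration intercept and slope
#'
#' Slope: coefficient of the linear predictor in a logistic regression of
#' the outcome on it. Intercept: from the recalibration model with the
#' linear predictor as a fixed offset. Ideal values are 0 and 1.
#'
#' @param lp Linear predictors (logit scale), non-constant.
#' @param outcomes Binary outcomes, both classes present.
#' @return Named vector `c(intercept =, slope =)`.
#' @export
calibration <- function(lp, outcomes) {
  y <- as.numeric(outcomes)
  if (length(unique(y)) < 2) stop("calibration undefined: single-class outcome")
  if (stats::sd(lp) < 1e-12) stop("calibration undefined: constant linear predictor")
  slope <- fit_logistic(cbind(`(Intercept)` = 1, lp = lp), y)$coefficients["lp"]
  fit_off <- stats::glm(y ~ 1, family = stats::binomial(), offset = lp)
  c(intercept = unname(stats::coef(fit_off)[1]), slope = unname(slope))
}

#' Bias-corrected calibration across an imputed stack
#'
#' Per imputation, applies the Harrell optimism loop to the calibration
#' intercept and slope of the selected model (the apparent values are 0 and
#' 1 by construction of the maximum-likelihood fit; the correction measures
#' how far they shrink on new data), and reports the per-imputation
#' corrected values, their ranges, and a decile calibration curve (observed
#' event proportion per predicted-probability decile, per imputation).
#'
#' @inheritParams optimism_corrected_auc
#' @param bootstraps Resamples per imputation (default 200).
#' @return List of class `calibration_report`: `intercept` and `slope`
#'   (M-vectors, corrected), `intercept_range`, `slope_range`, `curve`
#'   (data.frame: imputation, bin, predicted, observed, n).
#' @export
bias_corrected_calibration <- function(stack, terms, outcome, bootstraps = 200,
                                       seed = 1L) {
  set.seed(seed)
  tools <- refit_tools(terms)
  metric <- function(s, y) calibration(s, y)
  intercepts <- slopes <- numeric(stack$m)
  curve <- NULL
  for (i in seq_len(stack$m)) {
    d <- analysis_subset(stack$datasets[[i]], outcome)
    h <- harrell_optimism(d, d$.y, tools$fit, tools$predict, metric, bootstraps)
    intercepts[i] <- h$corrected["intercept"]
    slopes[i] <- h$corrected["slope"]
    p <- stats::plogis(tools$predict(tools$fit(d, d$.y), d))
    qs <- unique(stats::quantile(p, probs = seq(0, 1, 0.1)))
    bin <- cut(p, breaks = qs, include.lowest = TRUE, labels = FALSE)
    for (b in sort(unique(bin))) {
      sel <- bin == b
      curve <- rbind(curve, data.frame(
        imputation = i, bin = b, predicted = mean(p[sel]),
        observed = mean(d$.y[sel]), n = sum(sel)
      ))
    }
  }
  structure(list(intercept = intercepts, slope = slopes,
                 intercept_range = range(intercepts), slope_range = range(slopes),
                 curve = curve),
            class = "calibration_report")
}

#' @export
print.calibration_report <- function(x, ...) {
  cat(sprintf("Bias-corrected calibration: intercept %.2f to %.2f, slope %.2f to %.2f (m = %d)\n",
              x$intercept_range[1], x$intercept_range[2],
              x$slope_range[1], x$slope_range[2], length(x$slope)))
  invisible(x)
}

#' Full internal validation of a selected model
#'
#' Combines the optimism-corrected c-index (with a bootstrap-SE confidence
#' interval computed on the first completed dataset's apparent scores,
#' centred at the corrected pooled value) and bias-corrected calibration.
#'
#' @inheritParams optimism_corrected_auc
#' @param auc_reps Bootstrap replications for the AUC standard error
#'   (default 2000).
#' @param calibration_bootstraps Resamples per imputation for the
#'   calibration correction (default 200).
#' @return Object of class `validation_report`.
#' @export
validate_model <- function(stack, terms, outcome, bootstraps = 200,
                           auc_reps = 2000, calibration_bootstraps = 200,
                           seed = 1L) {
  auc <- optimism_corrected_auc(stack, terms, outcome, bootstraps, seed = seed)
  d1 <- analysis_subset(stack$datasets[[1]], outcome)
  tools <- refit_tools(terms)
  scores1 <- tools$predict(tools$fit(d1, d1$.y), d1)
  ci <- auc_ci(scores1, d1$.y, estimate = auc$corrected_pooled,
               reps = auc_reps, seed = seed + 1L)
  cal <- bias_corrected_calibration(stack, terms, outcome,
                                    calibration_bootstraps, seed = seed + 2L)
  structure(list(outcome = outcome, terms = terms,
                 apparent_auc = auc$apparent, corrected_auc = auc$corrected,
                 c_index = auc$corrected_pooled, c_index_ci = c(ci$low, ci$high),
                 auc_se = ci$se, calibration = cal),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("Internal validation (%s): c-index %.2f (%.2f-%.2f)\n",
              x$outcome, x$c_index, x$c_index_ci[1], x$c_index_ci[2]))
  print(x$calibration)
  invisible(x)
}
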