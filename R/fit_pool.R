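#' Pool estimates across imputations by Rubin's rules
#'
#' Pooled estimate = mean of the per-imputation estimates; between-imputation
#' variance B = their sample variance; within-imputation variance W = mean of
#' the per-imputation variances; total variance T = W + (1 + 1/M) B. Degrees
#' of freedom follow the Barnard-Rubin small-sample formula when a
#' complete-data df is supplied, else the classic (M - 1) / lambda^2.
#'
#' @param estimates Numeric vector of M per-imputation estimates (M >= 2).
#' @param variances Their squared standard errors (all > 0, same length).
#' @param dfcom Complete-data residual degrees of freedom (n - k), or `Inf`.
#' @return List: `estimate`, `between`, `within`, `total`, `se`, `df`,
#'   `fmi` (fraction of missing information), `m`.
#' @examples
#' rubin_pool(c(1, 3), c(1, 1))  # pooled 2, between 2, total 4
#' @export
rubin_pool <- function(estimates, variances, dfcom = Inf) {
  m <- length(estimates)
  if (m < 2) stop("Rubin pooling requires M >= 2 imputations")
  stopifnot(length(variances) == m, all(variances > 0))
  qbar <- mean(estimates)
  B <- stats::var(estimates)
  W <- mean(variances)
  Tv <- W + (1 + 1 / m) * B
  lambda <- (1 + 1 / m) * B / Tv
  if (lambda < 1e-12) {
    df <- dfcom
    fmi <- 0
  } else {
    df_old <- (m - 1) / lambda^2
    if (is.finite(dfcom)) {
      df_obs <- (dfcom + 1) / (dfcom + 3) * dfcom * (1 - lambda)
      df <- 1 / (1 / df_old + 1 / df_obs)
    } else {
      df <- df_old
    }
    fmi <- (lambda + 2 / (df + 3)) / (1 + lambda)
  }
  list(estimate = qbar, between = B, within = W, total = Tv,
       se = sqrt(Tv), df = df, fmi = fmi, m = m)
}

#' Fit a selected model on every imputed dataset and pool
#'
#' Fits the logistic model with the selected terms on the analysis subset of
#' each imputed dataset, pools coefficients and variances term-wise by
#' Rubin's rules, and reports odds ratios with 95% confidence intervals on
#' the pooled scale (t quantiles at the Barnard-Rubin df). The analysis n
#' and the event count (rounded mean across imputations) are recorded.
#'
#' @param stack An imputed stack whose datasets contain `frailty_baseline`
#'   and `transition_outcome` (e.g. from [impute_cohort()]).
#' @param terms Character vector of selected predictor columns (may be
#'   empty: intercept-only).
#' @param outcome `"improvement"` or `"worsening"` (sets the analysis
#'   subset: improvement models exclude baseline-robust participants).
#' @param level Confidence level (default 0.95).
#' @return Object of class `pooled_model`: `terms` data.frame (term,
#'   estimate, se, OR, CI bounds, df, fmi), `m`, `outcome`, `n_analysis`,
#'   `n_events`, `flagged` (any per-imputation ridge-stabilised fit).
#' @export
fit_on_stack <- function(stack, terms, outcome, level = 0.95) {
  stopifnot(inherits(stack, "imputed_stack"))
  terms <- sort(unique(terms))
  est <- se2 <- NULL
  flagged <- FALSE
  n_events <- n_analysis <- integer(stack$m)
  for (i in seq_len(stack$m)) {
    d <- analysis_subset(stack$datasets[[i]], outcome)
    y <- as.numeric(d$.y)
    mm <- if (length(terms)) build_design(d, terms)$mm
          else matrix(1, nrow(d), 1, dimnames = list(NULL, "(Intercept)"))
    fit <- fit_logistic(mm, y)
    if (fit$separation) flagged <- TRUE
    if (is.null(est)) {
      est <- matrix(NA_real_, ncol(mm), stack$m, dimnames = list(colnames(mm), NULL))
      se2 <- est
    }
    est[, i] <- fit$coefficients
    se2[, i] <- diag(fit$vcov)
    n_events[i] <- sum(y)
    n_analysis[i] <- nrow(d)
  }
  dfcom <- n_analysis[1] - nrow(est)
  pooled <- lapply(seq_len(nrow(est)), function(j)
    rubin_pool(est[j, ], se2[j, ], dfcom = dfcom))
  tcrit <- vapply(pooled, function(p) stats::qt(1 - (1 - level) / 2, p$df), numeric(1))
  coefs <- vapply(pooled, `[[`, numeric(1), "estimate")
  ses <- vapply(pooled, `[[`, numeric(1), "se")
  tab <- data.frame(
    term = rownames(est),
    estimate = coefs, se = ses,
    or = exp(coefs),
    ci_low = exp(coefs - tcrit * ses),
    ci_high = exp(coefs + tcrit * ses),
    df = vapply(pooled, `[[`, numeric(1), "df"),
    fmi = vapply(pooled, `[[`, numeric(1), "fmi"),
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(terms = tab, m = stack$m, outcome = outcome,
                 selected = terms,
                 n_analysis = n_analysis[1],
                 n_events = round(mean(n_events)),
                 flagged = flagged),
            class = "pooled_model")
}

#' @export
print.pooled_model <- function(x, digits = 2, ...) {
  cat(sprintf("Pooled logistic model (%s): n = %d, events = %d, m = %d%s\n",
              x$outcome, x$n_analysis, x$n_events, x$m,
              if (x$flagged) " [ridge-stabilised fit in >=1 imputation]" else ""))
  tab <- x$terms
  cat(paste(sprintf("  %-28s OR %6.2f (%5.2f-%6.2f)", tab$term, tab$or,
                    tab$ci_low, tab$ci_high), collapse = "\n"), "\n")
  invisible(x)
}

#' Linear predictor of a pooled (or per-imputation) model on new data
#'
#' @param coefs Named coefficient vector (names as in the model design).
#' @param data Data.frame with the model's predictor columns.
#' @param terms The predictor columns the design was built from.
#' @return Numeric linear predictor.
#' @export
linear_predictor <- function(coefs, data, terms) {
  mm <- if (length(terms)) build_design(data, sort(unique(terms)))$mm
        else matrix(1, nrow(data), 1, dimnames = list(NULL, "(Intercept)"))
  drop(mm[, names(coefs), drop = FALSE] %*% coefs)
}

#' Variance inflation factors of a design matrix
#'
#' `VIF_j = 1 / (1 - R^2_j)` where `R^2_j` comes from regressing column j on
#' all other columns (with intercept). Columns in an exact linear dependence
#' are reported as `Inf` and flagged.
#'
#' @param x Numeric design matrix (no intercept column, >= 2 columns, no
#'   missing values).
#' @param flag_threshold Flag VIFs above this value (default 5).
#' @return data.frame: `column`, `vif`, `flagged`.
#' @export
vif <- function(x, flag_threshold = 5) {
  x <- as.matrix(x)
  stopifnot(ncol(x) >= 2, !anyNA(x))
  out <- data.frame(column = colnames(x) %||% paste0("x", seq_len(ncol(x))),
                    vif = NA_real_, flagged = FALSE, stringsAsFactors = FALSE)
  for (j in seq_len(ncol(x))) {
    xj <- x[, j]
    Z <- cbind(1, x[, -j, drop = FALSE])
    fit <- stats::lm.fit(Z, xj)
    tss <- sum((xj - mean(xj))^2)
    rss <- sum(fit$residuals^2)
    r2 <- if (tss < 1e-300) 0 else 1 - rss / tss
    out$vif[j] <- if (1 - r2 < 1e-10) Inf else 1 / (1 - r2)
    out$flagged[j] <- out$vif[j] > flag_threshold
  }
  out
}

#' VIF diagnostics for the full candidate design of an imputed stack
#'
#' Computes [vif()] on the dummy-coded design of all candidate predictors in
#' the first imputed dataset (the conventional place to check
#' multicollinearity before selection).
#'
#' @param stack An imputed stack.
#' @param candidates Candidate columns (default the standard 18).
#' @return The [vif()] table.
#' @export
vif_candidates <- function(stack, candidates = candidate_predictors()) {
  d <- stack$datasets[[1]]
  mm <- build_design(d, sort(candidates))$mm[, -1, drop = FALSE]
  vif(mm)
}
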