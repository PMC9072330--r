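#' Maximum-likelihood logistic regression on a design matrix
#'
#' Thin wrapper around [stats::glm.fit()] returning the pieces the selection
#' and imputation machinery needs: coefficients, their covariance,
#' log-likelihood, and convergence/separation flags. On (quasi-)complete
#' separation or non-convergence the fit is repeated with a small L2 penalty
#' on the non-intercept coefficients (ridge-stabilised IRLS), so that
#' bootstrap resamples of small strata never abort a selection run.
#'
#' @param x Design matrix (include the intercept column yourself, e.g. via
#'   `model.matrix`).
#' @param y Binary outcome (0/1 or logical), length `nrow(x)`.
#' @param ridge L2 penalty used by the fallback (and applied directly when
#'   `force_ridge = TRUE`). The intercept is never penalised.
#' @param force_ridge Apply the penalty unconditionally.
#' @return List of class `frail_logit`: `coefficients`, `vcov`, `logLik`,
#'   `fitted`, `converged`, `separation`, `ridge_used`, `n`, `k`.
#' @export
fit_logistic <- function(x, y, ridge = 1e-2, force_ridge = FALSE) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  stopifnot(length(y) == nrow(x), all(y %in% c(0, 1)))
  if (nrow(x) <= ncol(x)) stop("need more observations than parameters")
  separation <- FALSE
  if (!force_ridge) {
    fit <- withCallingHandlers(
      stats::glm.fit(x, y, family = stats::binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)) ||
            grepl("algorithm did not converge", conditionMessage(w))) {
          separation <<- TRUE
          invokeRestart("muffleWarning")
        }
      }
    )
    mu <- fit$fitted.values
    if (!fit$converged || any(mu < 1e-8 | mu > 1 - 1e-8) ||
        any(abs(fit$coefficients) > 15, na.rm = TRUE) || anyNA(fit$coefficients)) {
      separation <- TRUE
    }
    if (!separation) {
      w <- mu * (1 - mu)
      info <- crossprod(x * sqrt(w))
      vc <- tryCatch(solve(info), error = function(e) NULL)
      if (!is.null(vc)) {
        return(structure(list(
          coefficients = fit$coefficients, vcov = vc,
          logLik = -fit$deviance / 2, fitted = mu,
          converged = TRUE, separation = FALSE, ridge_used = 0,
          n = nrow(x), k = ncol(x)
        ), class = "frail_logit"))
      }
      separation <- TRUE
    }
  }
  # ridge-stabilised IRLS fallback
  pen <- rep(ridge, ncol(x))
  icol <- which(apply(x, 2, function(v) all(v == v[1])))  # intercept-like columns
  pen[icol] <- 0
  beta <- rep(0, ncol(x))
  for (it in 1:100) {
    eta <- drop(x %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    H <- crossprod(x * sqrt(w)) + diag(pen, ncol(x))
    beta_new <- drop(solve(H, crossprod(x, w * z)))
    if (max(abs(beta_new - beta)) < 1e-8) { beta <- beta_new; break }
    beta <- beta_new
  }
  mu <- stats::plogis(drop(x %*% beta))
  w <- pmax(mu * (1 - mu), 1e-10)
  H <- crossprod(x * sqrt(w)) + diag(pen, ncol(x))
  ll <- sum(y * log(pmax(mu, 1e-12)) + (1 - y) * log(pmax(1 - mu, 1e-12)))
  structure(list(
    coefficients = stats::setNames(beta, colnames(x)), vcov = solve(H),
    logLik = ll, fitted = mu, converged = TRUE,
    separation = separation || force_ridge, ridge_used = ridge,
    n = nrow(x), k = ncol(x)
  ), class = "frail_logit")
}

#' @export
print.frail_logit <- function(x, ...) {
  cat(sprintf("Logistic fit: n = %d, k = %d, logLik = %.3f%s\n", x$n, x$k, x$logLik,
              if (x$separation) " [ridge-stabilised: separation]" else ""))
  print(x$coefficients)
  invisible(x)
}

#' Akaike information criterion
#'
#' `AIC = 2k - 2 logLik`.
#'
#' @param fit A `frail_logit` (or any object with a `logLik` element).
#' @param k Parameter count; defaults to the fit's column count.
#' @return Numeric AIC value.
#' @export
aic <- function(fit, k = fit$k) {
  2 * k - 2 * fit$logLik
}
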