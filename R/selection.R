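# Term-block machinery: a multi-level factor enters and leaves the model as
# one term, not as separate dummies.

build_design <- function(data, candidates) {
  for (cv in candidates) {
    if (is.factor(data[[cv]])) data[[cv]] <- droplevels(data[[cv]])
  }
  mm <- stats::model.matrix(stats::reformulate(candidates), data = data)
  assign <- attr(mm, "assign")  # 0 = intercept, i = i-th candidate
  list(mm = mm, assign = assign)
}

#' Backward elimination by AIC with term blocks
#'
#' Greedy backward selection: starting from the model with every candidate,
#' repeatedly drop the term whose removal lowers the AIC the most, stopping
#' when no removal lowers it. Multi-level factors are dropped as whole
#' blocks. Ties (equal AIC improvement to within 1e-8) are broken by the
#' term with the smallest maximum absolute Wald z in the current model, then
#' by alphabetical candidate name, so the outcome does not depend on the
#' order the candidates are supplied in.
#'
#' @param data Complete data.frame containing the candidates and the outcome.
#' @param outcome Name of a binary (0/1 or logical) outcome column.
#' @param candidates Character vector of candidate column names (may be
#'   empty: intercept-only model).
#' @param ridge Passed to [fit_logistic()] (separation fallback).
#' @return List: `selected` (retained candidates, in canonical order),
#'   `aic` (final model AIC), `aic_full` (all-candidate AIC), `path`
#'   (dropped terms in order), `fit` (final `frail_logit`).
#' @export
backward_select_aic <- function(data, outcome, candidates, ridge = 1e-2) {
  y <- as.numeric(data[[outcome]])
  candidates <- sort(unique(candidates))
  if (!length(candidates)) {
    fit <- fit_logistic(matrix(1, nrow(data), 1, dimnames = list(NULL, "(Intercept)")), y,
                        ridge = ridge)
    return(list(selected = character(), aic = aic(fit), aic_full = aic(fit),
                path = character(), fit = fit))
  }
  d <- build_design(data, candidates)
  current <- seq_along(candidates)
  cols_of <- function(terms) which(d$assign %in% c(0L, terms))
  fit <- fit_logistic(d$mm[, cols_of(current), drop = FALSE], y, ridge = ridge)
  cur_aic <- aic(fit)
  aic_full <- cur_aic
  path <- character()
  repeat {
    if (!length(current)) break
    drop_aic <- rep(NA_real_, length(current))
    for (i in seq_along(current)) {
      sub <- current[-i]
      f <- tryCatch(fit_logistic(d$mm[, cols_of(sub), drop = FALSE], y, ridge = ridge),
                    error = function(e) NULL)
      if (is.null(f)) {
        warning("fit without term '", candidates[current[i]], "' failed; removal skipped")
        next
      }
      drop_aic[i] <- aic(f)
    }
    if (all(is.na(drop_aic)) || min(drop_aic, na.rm = TRUE) >= cur_aic - 1e-8) break
    best <- which(drop_aic <= min(drop_aic, na.rm = TRUE) + 1e-8)
    if (length(best) > 1) {
      # data-driven tie-break: drop the weakest term (smallest max |Wald z|)
      se <- sqrt(diag(fit$vcov))
      z <- abs(fit$coefficients / se)
      keepcols <- cols_of(current)
      zmax <- vapply(best, function(i) {
        cc <- which(d$assign[keepcols] == current[i])
        max(z[cc])
      }, numeric(1))
      best <- best[order(zmax, candidates[current[best]])][1]
    }
    path <- c(path, candidates[current[best]])
    current <- current[-best]
    fit <- fit_logistic(d$mm[, cols_of(current), drop = FALSE], y, ridge = ridge)
    cur_aic <- aic(fit)
  }
  list(selected = candidates[current], aic = cur_aic, aic_full = aic_full,
       path = path, fit = fit)
}

#' Configuration for bootstrap-stability variable selection
#'
#' @param outcome `"improvement"` or `"worsening"`.
#' @param bootstraps_per_imputation Bootstrap resamples drawn from each
#'   imputed dataset (default 200, giving 10 x 200 = 2000 samples with the
#'   default imputation count).
#' @param frequency_threshold Selection-frequency threshold (default 0.50).
#' @param candidates Candidate predictor columns (default the 18 standard
#'   candidates, [candidate_predictors()]).
#' @param seed Integer seed.
#' @return List of class `selection_config`.
#' @export
selection_config <- function(outcome = c("worsening", "improvement"),
                             bootstraps_per_imputation = 200,
                             frequency_threshold = 0.5,
                             candidates = candidate_predictors(),
                             seed = 1L) {
  outcome <- match.arg(outcome)
  if (frequency_threshold <= 0 || frequency_threshold > 1) {
    stop("frequency_threshold must lie in (0, 1]")
  }
  if (bootstraps_per_imputation < 1) stop("bootstraps_per_imputation must be >= 1")
  structure(list(outcome = outcome,
                 bootstraps_per_imputation = as.integer(bootstraps_per_imputation),
                 frequency_threshold = frequency_threshold,
                 candidates = candidates, seed = as.integer(seed)),
            class = "selection_config")
}

#' Restrict an analysis table to the participants a transition model applies to
#'
#' Improvement models are fit on baseline prefrail and frail participants
#' only (a robust participant cannot improve); worsening models use everyone.
#' The baseline frailty status factor is releveled to reference `frail`.
#'
#' @param data Analysis data.frame with `frailty_baseline` and
#'   `transition_outcome`.
#' @param outcome `"improvement"` or `"worsening"`.
#' @return The subset, with a logical `.y` outcome column appended.
#' @export
analysis_subset <- function(data, outcome) {
  if (outcome == "improvement") {
    data <- data[data$frailty_baseline != "robust", , drop = FALSE]
  }
  # reference level frail (kept first so it is the Ref of the dummy coding)
  data$frailty_baseline <- factor(as.character(data$frailty_baseline),
                                  levels = intersect(c("frail", "prefrail", "robust"),
                                                     unique(as.character(data$frailty_baseline))))
  data$.y <- data$transition_outcome == outcome
  data
}

#' Bootstrap-stability variable selection across an imputed stack
#'
#' For each of the M imputed datasets, draws B bootstrap resamples (with
#' replacement, resample size = analysis n), applies backward AIC selection
#' to each, and tallies how often every candidate is retained. A candidate
#' is selected when its frequency over the M x B samples reaches the
#' threshold. A resample with zero (or all) events is redrawn up to 10
#' times, then skipped with the tally denominator adjusted.
#'
#' An events-per-variable warning (not an error) is emitted when the
#' analysis events per candidate parameter fall below 10.
#'
#' @param stack An [impute_chained()] stack whose datasets contain the
#'   candidates, `frailty_baseline` and `transition_outcome`.
#' @param config A [selection_config()].
#' @return Object of class `selection_result`: `frequencies` (named,
#'   canonical order), `selected`, `total_samples`, `samples_used`,
#'   `config`.
#' @export
stability_select <- function(stack, config) {
  stopifnot(inherits(stack, "imputed_stack"), inherits(config, "selection_config"))
  set.seed(config$seed)
  cands <- sort(unique(config$candidates))
  tally <- stats::setNames(rep(0, length(cands)), cands)
  total <- stack$m * config$bootstraps_per_imputation
  used <- 0L
  epv_warned <- FALSE
  for (dset in stack$datasets) {
    d <- analysis_subset(dset, config$outcome)
    n <- nrow(d)
    n_par <- ncol(build_design(d, cands)$mm) - 1L
    if (!epv_warned && sum(d$.y) / n_par < 10) {
      warning(sprintf("events per parameter = %.1f (< 10): candidate set may be too large for the event count",
                      sum(d$.y) / n_par))
      epv_warned <- TRUE
    }
    for (b in seq_len(config$bootstraps_per_imputation)) {
      ok <- FALSE
      for (try in 1:10) {
        idx <- sample.int(n, n, replace = TRUE)
        ev <- sum(d$.y[idx])
        if (ev > 0 && ev < n) { ok <- TRUE; break }
      }
      if (!ok) next
      sel <- backward_select_aic(d[idx, , drop = FALSE], ".y", cands)$selected
      tally[sel] <- tally[sel] + 1
      used <- used + 1L
    }
  }
  freqs <- tally / used
  structure(list(
    frequencies = freqs,
    selected = names(freqs)[freqs >= config$frequency_threshold],
    total_samples = total, samples_used = used, config = config
  ), class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("Stability selection (%s): %d/%d bootstrap-imputation samples used\n",
              x$config$outcome, x$samples_used, x$total_samples))
  f <- sort(x$frequencies, decreasing = TRUE)
  sel <- names(f) %in% x$selected
  cat(paste(sprintf("  %-22s %5.1f%%%s", names(f), 100 * f,
                    ifelse(sel, "  *", "")), collapse = "\n"), "\n")
  cat(sprintf("  * selected (frequency >= %d%%): %d candidates\n",
              round(100 * x$config$frequency_threshold), length(x$selected)))
  invisible(x)
}
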