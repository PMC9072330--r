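# Chained-equations multiple imputation.
#
# Each incomplete variable is imputed from a conditional model on all other
# variables (including the outcome), with proper parameter draws so that
# between-imputation variability reflects estimation uncertainty:
#   continuous        -> Bayesian linear regression draw (optionally PMM)
#   binary            -> logistic draw (ridge-stabilised on separation)
#   factor >= 3 levels -> multinomial-logistic draw (nnet, weight-decay
#                         fallback on degeneracy)

impute_var_numeric <- function(X_obs, y_obs, X_mis, pmm = FALSE, k_pmm = 5) {
  qrX <- qr(X_obs)
  keep <- qrX$pivot[seq_len(qrX$rank)]
  X_obs <- X_obs[, keep, drop = FALSE]
  X_mis <- X_mis[, keep, drop = FALSE]
  n <- nrow(X_obs); p <- ncol(X_obs)
  fit <- stats::lm.fit(X_obs, y_obs)
  res <- fit$residuals
  df <- max(n - p, 1)
  sigma2 <- sum(res^2) / stats::rchisq(1, df)
  XtXi <- chol2inv(chol(crossprod(X_obs) + diag(1e-10, p)))
  beta <- drop(fit$coefficients + t(chol(sigma2 * XtXi)) %*% stats::rnorm(p))
  pred_mis <- drop(X_mis %*% beta)
  if (!pmm) {
    return(pred_mis + stats::rnorm(nrow(X_mis), 0, sqrt(sigma2)))
  }
  pred_obs <- drop(X_obs %*% beta)
  vapply(pred_mis, function(pm) {
    cand <- order(abs(pred_obs - pm))[seq_len(min(k_pmm, length(pred_obs)))]
    y_obs[sample(cand, 1)]
  }, numeric(1))
}

impute_var_binary <- function(X_obs, y_obs, X_mis, ridge = 1e-2) {
  qrX <- qr(X_obs)
  keep <- qrX$pivot[seq_len(qrX$rank)]
  fit <- fit_logistic(X_obs[, keep, drop = FALSE], y_obs, ridge = ridge)
  beta <- MASS::mvrnorm(1, fit$coefficients, fit$vcov)
  p <- stats::plogis(drop(X_mis[, keep, drop = FALSE] %*% beta))
  stats::runif(nrow(X_mis)) < p
}

impute_var_multinomial <- function(df_obs, y_obs, df_mis, ridge = 0.05) {
  df_obs$.target <- droplevels(y_obs)
  lev <- levels(df_obs$.target)
  fit <- NULL
  for (decay in c(0, ridge)) {
    fit <- tryCatch({
      f <- nnet::multinom(.target ~ ., data = df_obs, trace = FALSE,
                          Hess = TRUE, decay = decay, maxit = 200)
      vc <- tryCatch(solve(f$Hessian), error = function(e) NULL)
      if (is.null(vc) || any(!is.finite(vc))) NULL else list(fit = f, vcov = vc)
    }, error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit)) {  # last resort: marginal draw
    return(factor(sample(as.character(y_obs), nrow(df_mis), replace = TRUE), levels = lev))
  }
  co <- stats::coef(fit$fit)
  if (is.null(dim(co))) co <- matrix(co, nrow = 1)
  cvec <- as.vector(t(co))
  nc <- min(length(cvec), nrow(fit$vcov))
  draw <- cvec
  draw[seq_len(nc)] <- MASS::mvrnorm(1, cvec[seq_len(nc)],
                                     fit$vcov[seq_len(nc), seq_len(nc), drop = FALSE])
  co_draw <- matrix(draw, nrow = nrow(co), byrow = TRUE)
  mm <- stats::model.matrix(stats::delete.response(stats::terms(fit$fit)), df_mis)
  eta <- cbind(0, mm %*% t(co_draw))
  pr <- exp(eta - apply(eta, 1, max))
  pr <- pr / rowSums(pr)
  idx <- apply(pr, 1, function(p) sample.int(length(lev), 1, prob = p))
  factor(lev[idx], levels = levels(y_obs))
}

#' Multiple imputation by chained equations
#'
#' Produces `m` completed copies of `data`. Missing cells are initialised by
#' sampling observed values, then `iterations` chained sweeps update each
#' incomplete variable from a conditional model on all other variables.
#' Originally observed cells are never altered; the `m` streams are
#' independent and the whole procedure is deterministic for a fixed seed.
#'
#' @param data A data.frame of numeric, logical and factor columns. At least
#'   one column must be fully observed; no column may be entirely missing.
#' @param m Number of imputations (>= 2; pooling is undefined for m = 1).
#' @param iterations Chained-equation sweeps per dataset (default 10).
#' @param seed Integer seed.
#' @param pmm Use predictive-mean matching for continuous variables instead
#'   of Bayesian-linear draws.
#' @param forbidden_level Optional special case for one factor column:
#'   `list(var =, level =, when = <logical vector>)` declaring that `level`
#'   is observed exactly for the rows where `when` is `TRUE` and must never
#'   be drawn for the others (used for death as an absorbing, fully observed
#'   follow-up destination: conditional fits then use the other rows only).
#' @return Object of class `imputed_stack`: `datasets` (list of m completed
#'   data.frames), `m`, `iterations`, `seed`, `where` (logical matrix of
#'   originally missing cells), `original`.
#' @export
impute_chained <- function(data, m = 10, iterations = 10, seed = 1L,
                           pmm = FALSE, forbidden_level = NULL) {
  stopifnot(is.data.frame(data))
  if (m < 2) stop("m must be >= 2: pooling is undefined for a single imputation")
  where <- is.na(data)
  miss_count <- colSums(where)
  if (any(miss_count == nrow(data))) {
    stop("variable(s) entirely missing: ",
         paste(names(data)[miss_count == nrow(data)], collapse = ", "))
  }
  if (all(miss_count == 0)) {
    return(structure(list(datasets = rep(list(data), m), m = as.integer(m),
                          iterations = as.integer(iterations), seed = as.integer(seed),
                          where = where, original = data), class = "imputed_stack"))
  }
  if (!any(miss_count == 0)) stop("need at least one fully observed variable")
  incomplete <- names(sort(miss_count[miss_count > 0]))  # fewest-missing first
  set.seed(seed)
  stream_seeds <- sample.int(.Machine$integer.max - 1L, m)
  datasets <- vector("list", m)
  for (d in seq_len(m)) {
    set.seed(stream_seeds[d])
    comp <- data
    for (v in incomplete) {  # initial fill from the observed margins
      obs <- comp[[v]][!where[, v]]
      comp[[v]][where[, v]] <- sample(obs, miss_count[v], replace = TRUE)
    }
    for (it in seq_len(iterations)) {
      for (v in incomplete) {
        mis <- where[, v]
        fit_rows <- !mis
        lev_block <- !is.null(forbidden_level) && forbidden_level$var == v
        if (lev_block) fit_rows <- fit_rows & !forbidden_level$when
        preds <- setdiff(names(comp), v)
        # constant columns (e.g. gender in a single-stratum table) carry no
        # information and would make the design singular
        preds <- preds[vapply(comp[preds], function(x) length(unique(x)) > 1, logical(1))]
        mm <- if (length(preds)) {
          stats::model.matrix(stats::reformulate(preds),
                              data = droplevels_safe(comp[preds]))
        } else matrix(1, nrow(comp), 1, dimnames = list(NULL, "(Intercept)"))
        target <- data[[v]]
        if (is.numeric(target)) {
          comp[[v]][mis] <- impute_var_numeric(mm[fit_rows, , drop = FALSE],
                                               comp[[v]][fit_rows],
                                               mm[mis, , drop = FALSE], pmm = pmm)
        } else if (is.logical(target) ||
                   (is.factor(target) && nlevels_used(target, lev_block, forbidden_level) == 2)) {
          yb <- comp[[v]][fit_rows]
          if (is.factor(target)) {
            lv <- levels(droplevels(factor(yb)))
            if (length(lv) == 1) {
              comp[[v]][mis] <- factor(lv, levels = levels(target))
              next
            }
            draw <- impute_var_binary(mm[fit_rows, , drop = FALSE], yb == lv[2],
                                      mm[mis, , drop = FALSE])
            comp[[v]][mis] <- factor(ifelse(draw, lv[2], lv[1]), levels = levels(target))
          } else {
            comp[[v]][mis] <- impute_var_binary(mm[fit_rows, , drop = FALSE],
                                                as.logical(yb), mm[mis, , drop = FALSE])
          }
        } else if (is.factor(target)) {
          if (!length(preds)) {
            comp[[v]][mis] <- factor(sample(as.character(comp[[v]][fit_rows]),
                                            sum(mis), replace = TRUE),
                                     levels = levels(target))
            next
          }
          dd <- droplevels_safe(comp[preds])  # consistent levels across fit/draw rows
          comp[[v]][mis] <- impute_var_multinomial(
            dd[fit_rows, , drop = FALSE],
            comp[[v]][fit_rows],
            dd[mis, , drop = FALSE]
          )
        } else {
          stop("cannot impute column '", v, "' of class ", class(target)[1])
        }
      }
    }
    datasets[[d]] <- comp
  }
  structure(list(datasets = datasets, m = as.integer(m),
                 iterations = as.integer(iterations), seed = as.integer(seed),
                 where = where, original = data), class = "imputed_stack")
}

nlevels_used <- function(target, lev_block, forbidden_level) {
  lv <- levels(target)
  if (lev_block) lv <- setdiff(lv, forbidden_level$level)
  length(lv)
}

droplevels_safe <- function(df) {
  df[] <- lapply(df, function(x) if (is.factor(x)) droplevels(x) else x)
  df
}

#' @export
print.imputed_stack <- function(x, ...) {
  cat(sprintf("Imputed stack: m = %d, iterations = %d, %d incomplete variable(s), n = %d\n",
              x$m, x$iterations, sum(colSums(x$where) > 0), nrow(x$original)))
  invisible(x)
}

#' Per-variable imputation diagnostics
#'
#' One row per originally incomplete variable: missing count, the observed
#' summary (mean for numeric, prevalence or modal level for categorical),
#' the across-imputation mean of the imputed values, the between-imputation
#' variance of the imputed per-dataset means, and a flag for imputed
#' categories absent from the observed data. A complete-data stack yields a
#' zero-row table.
#'
#' @param stack An `imputed_stack`.
#' @return A data.frame.
#' @export
imputation_diagnostics <- function(stack) {
  stopifnot(inherits(stack, "imputed_stack"))
  vars <- names(which(colSums(stack$where) > 0))
  out <- data.frame(variable = character(), n_missing = integer(),
                    observed_mean = numeric(), imputed_mean = numeric(),
                    between_imputation_var = numeric(), novel_category = logical(),
                    stringsAsFactors = FALSE)
  for (v in vars) {
    mis <- stack$where[, v]
    obs <- stack$original[[v]][!mis]
    num <- function(x) {
      if (is.numeric(x)) x
      else if (is.logical(x)) as.numeric(x)
      else as.numeric(as.integer(x))  # factor codes
    }
    imp_means <- vapply(stack$datasets, function(d) mean(num(d[[v]][mis])), numeric(1))
    novel <- if (is.factor(stack$original[[v]])) {
      any(vapply(stack$datasets, function(d)
        any(!as.character(d[[v]][mis]) %in% as.character(obs)), logical(1)))
    } else FALSE
    out <- rbind(out, data.frame(
      variable = v, n_missing = sum(mis), observed_mean = mean(num(obs)),
      imputed_mean = mean(imp_means),
      between_imputation_var = stats::var(imp_means),
      novel_category = novel, stringsAsFactors = FALSE
    ))
  }
  out
}

#' Impute a classified cohort's analysis table
#'
#' Builds the analysis table (the 18 candidate predictors, gender, and the
#' follow-up destination including death), runs [impute_chained()] with the
#' follow-up state imputed only for surviving, lost-to-follow-up
#' participants (death is claims-verified and never imputed), and recomputes
#' the transition outcome in every completed dataset so the death override
#' stays exact.
#'
#' @param classified A cohort from [classify_cohort()].
#' @param m,iterations,seed,pmm Passed to [impute_chained()].
#' @return An `imputed_stack` whose datasets additionally carry
#'   `transition_outcome` recomputed from the completed follow-up state.
#' @export
impute_cohort <- function(classified, m = 10, iterations = 10, seed = 1L, pmm = FALSE) {
  fu <- as.character(classified$frailty_followup)
  fu[classified$died_in_followup] <- "death"
  fu[fu == "indeterminate"] <- NA
  tab <- classified[, c("gender", candidate_predictors()), drop = FALSE]
  tab$fu_state <- factor(fu, levels = c("robust", "prefrail", "frail", "death"))
  stack <- impute_chained(tab, m = m, iterations = iterations, seed = seed, pmm = pmm,
                          forbidden_level = list(var = "fu_state", level = "death",
                                                 when = classified$died_in_followup))
  stack$datasets <- lapply(stack$datasets, function(d) {
    died <- d$fu_state == "death"
    d$transition_outcome <- classify_transition(
      d$frailty_baseline,
      ifelse(died, NA, as.character(d$fu_state)),
      died
    )
    d
  })
  stack
}
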