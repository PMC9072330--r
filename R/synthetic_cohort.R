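#' Build a validated synthetic-cohort configuration
#'
#' A configuration holds, per gender stratum, the sample size, age
#' distribution (normal, truncated at the cohort eligibility age of 70),
#' baseline frailty-state probabilities, covariate prevalences / level
#' probabilities, the transition mechanism, a loss-to-follow-up rate for
#' survivors, and per-field missingness rates. Covariate dependence is a
#' Gaussian copula over latent normal scores (default: independence).
#'
#' Two transition mechanisms are supported: `"matrix"` draws each
#' participant's destination (robust / prefrail / frail / death) from the
#' per-gender 3x4 row of their baseline state; `"logistic"` draws worsening
#' with probability `plogis(intercept + x'beta)` from configured coefficient
#' vectors on (numeric or logical) predictors, then improvement among
#' non-worsening participants with a non-robust baseline, so that the
#' worsening log-odds are exactly linear in the configured coefficients —
#' the mode used for parameter-recovery testing.
#'
#' @param strata Named list (`woman`, `man`) of per-stratum settings; see
#'   [default_bis_config()] for the full shape.
#' @param mechanism `"matrix"` or `"logistic"`.
#' @param logistic For the logistic mechanism: list with numeric vectors
#'   `worsening` and `improvement` (first element the intercept, remaining
#'   elements named after cohort columns) and optional destination-detail
#'   splits `p_death_prefail_worsen`, `robust_worsen_split`,
#'   `frail_improve_split`.
#' @param dependence Optional correlation matrix over the latent scores of
#'   (age, then the covariates in order); `NULL` = independence.
#' @param seed Default random seed used by [generate_cohort()].
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(strata, mechanism = c("matrix", "logistic"),
                          logistic = NULL, dependence = NULL, seed = 1L) {
  mechanism <- match.arg(mechanism)
  stopifnot(is.list(strata), length(strata) >= 1, !is.null(names(strata)))
  for (nm in names(strata)) {
    s <- strata[[nm]]
    if (!is.numeric(s$n) || s$n <= 0) stop("stratum '", nm, "': n must be > 0")
    p <- s$baseline_state_probs
    if (length(p) != 3 || abs(sum(p) - 1) > 1e-9 || any(p < 0)) {
      stop("stratum '", nm, "': baseline_state_probs must be a 3-vector summing to 1")
    }
    if (mechanism == "matrix") {
      tm <- s$transition_matrix
      if (is.null(tm) || !all(dim(tm) == c(3, 4)) ||
          any(abs(rowSums(tm) - 1) > 1e-9) || any(tm < 0)) {
        stop("stratum '", nm, "': transition_matrix must be 3x4 with rows summing to 1")
      }
    }
    if (!is.null(s$loss_rate) && (s$loss_rate < 0 || s$loss_rate > 1)) {
      stop("stratum '", nm, "': loss_rate must lie in [0,1]")
    }
    for (cv in names(s$covariates)) {
      pv <- s$covariates[[cv]]
      if (length(pv) > 1 && abs(sum(pv) - 1) > 1e-9) {
        stop("stratum '", nm, "': level probabilities for '", cv, "' must sum to 1")
      }
      if (any(pv < 0 | pv > 1)) stop("stratum '", nm, "': probabilities for '", cv, "' outside [0,1]")
    }
    mr <- s$missingness
    if (!is.null(mr) && any(unlist(lapply(mr, function(r) if (is.list(r)) r$rate else r)) < 0 |
                            unlist(lapply(mr, function(r) if (is.list(r)) r$rate else r)) > 1)) {
      stop("stratum '", nm, "': missingness rates must lie in [0,1]")
    }
  }
  if (mechanism == "logistic" && (is.null(logistic) ||
      is.null(logistic$worsening) || is.null(logistic$improvement))) {
    stop("logistic mechanism requires 'logistic' coefficient vectors for worsening and improvement")
  }
  structure(list(strata = strata, mechanism = mechanism, logistic = logistic,
                 dependence = dependence, seed = as.integer(seed)),
            class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  for (nm in names(x$strata)) {
    s <- x$strata[[nm]]
    cat(sprintf("  %-6s n = %d, baseline (robust/prefrail/frail) = %s\n", nm, s$n,
                paste(sprintf("%.3f", s$baseline_state_probs), collapse = "/")))
  }
  cat("  mechanism:", x$mechanism, "\n")
  invisible(x)
}

# Table-calibrated per-stratum counts; prevalences are taken among known
# values, missingness rates are the per-gender 'Unknown' fractions.
bis_stratum <- function(n, age_mean, age_sd, state_counts, cov, miss, tmat_counts,
                        unknown_by_state) {
  deaths <- tmat_counts[, 4]
  nondeath <- tmat_counts[, 1:3]
  n_state <- rowSums(tmat_counts) + unknown_by_state
  tm <- matrix(0, 3, 4, dimnames = list(c("robust", "prefrail", "frail"),
                                        c("robust", "prefrail", "frail", "death")))
  # deaths are claims-verified (never lost): their probability is exact;
  # surviving destinations are rescaled so unknowns follow the observed
  # survivor distribution within their baseline state
  for (i in 1:3) {
    tm[i, 4] <- deaths[i] / n_state[i]
    tm[i, 1:3] <- nondeath[i, ] / sum(nondeath[i, ]) * (1 - tm[i, 4])
  }
  loss <- sum(unknown_by_state) / (sum(n_state) - sum(deaths))
  list(n = n, age_mean = age_mean, age_sd = age_sd, age_min = 70,
       baseline_state_probs = state_counts / sum(state_counts),
       covariates = cov, missingness = miss,
       transition_matrix = tm, loss_rate = loss)
}

#' Default configuration calibrated to the published cohort marginals
#'
#' Returns a [cohort_config()] whose per-gender sample sizes (637 women, 521
#' men), baseline frailty-state probabilities, covariate prevalences (taken
#' among known values), missingness rates (the per-gender "Unknown"
#' fractions) and loss-to-follow-up rates match the published descriptive
#' tables of the source cohort. The per-cell transition matrices are
#' reconstructed from the per-gender transition-group compositions and the
#' reported per-state death fractions; the within-worsening and
#' within-improvement destination splits are approximate (the per-cell
#' figures are only published graphically) and lean on adjacent-state
#' transitions being the most frequent.
#'
#' @param complete If `TRUE`, all missingness rates and the loss rate are
#'   set to zero, yielding a fully observed cohort.
#' @param seed Default seed stored in the config.
#' @return A `cohort_config`.
#' @examples
#' cfg <- default_bis_config()
#' cfg$strata$woman$baseline_state_probs  # 115/637, 282/637, 240/637
#' @export
default_bis_config <- function(complete = FALSE, seed = 1L) {
  women <- bis_stratum(
    n = 637, age_mean = 84.1, age_sd = 5.6,
    state_counts = c(robust = 115, prefrail = 282, frail = 240),
    cov = list(
      education = c(low = 417, middle = 148, high = 71) / 636,
      smoking = 176 / 634,
      self_rated_health = 368 / 635,
      living_alone = 393 / 612,
      bmi_cat = c(225, 251, 154) / 630,
      polypharmacy = 470 / 637,
      hospitalization_cat = c(284, 230, 123) / 637,
      cognitive_impairment = 55 / 605,
      stroke = 75 / 637,
      chf = 390 / 637,
      diabetes = 171 / 629,
      cancer = 134 / 637,
      osteoarthritis = 558 / 637,
      copd = 254 / 637,
      egfr_lt60 = 468 / 615,
      acr_ge30 = 137 / 588
    ),
    miss = list(education = 1 / 637, smoking = 3 / 637,
                self_rated_health = 2 / 637, living_alone = 25 / 637,
                bmi_cat = 7 / 637, polypharmacy = 0,
                cognitive_impairment = 32 / 637, diabetes = 8 / 637,
                egfr_lt60 = 22 / 637, acr_ge30 = 49 / 637),
    tmat_counts = rbind(robust   = c(52, 48, 5, 2),
                        prefrail = c(48, 142, 47, 17),
                        frail    = c(5, 48, 110, 43)),
    unknown_by_state = c(8, 28, 34)
  )
  men <- bis_stratum(
    n = 521, age_mean = 84.8, age_sd = 5.7,
    state_counts = c(robust = 110, prefrail = 250, frail = 161),
    cov = list(
      education = c(low = 269, middle = 87, high = 161) / 517,
      smoking = 356 / 520,
      self_rated_health = 266 / 520,
      living_alone = 159 / 508,
      bmi_cat = c(152, 258, 101) / 511,
      polypharmacy = 378 / 520,
      hospitalization_cat = c(205, 218, 98) / 521,
      cognitive_impairment = 40 / 485,
      stroke = 81 / 521,
      chf = 366 / 521,
      diabetes = 170 / 514,
      cancer = 181 / 521,
      osteoarthritis = 377 / 521,
      copd = 196 / 521,
      egfr_lt60 = 379 / 509,
      acr_ge30 = 169 / 493
    ),
    miss = list(education = 4 / 521, smoking = 1 / 521,
                self_rated_health = 1 / 521, living_alone = 13 / 521,
                bmi_cat = 10 / 521, polypharmacy = 1 / 521,
                cognitive_impairment = 36 / 521, diabetes = 7 / 521,
                egfr_lt60 = 12 / 521, acr_ge30 = 28 / 521),
    tmat_counts = rbind(robust   = c(55, 36, 5, 2),
                        prefrail = c(36, 127, 49, 15),
                        frail    = c(3, 20, 61, 53)),
    unknown_by_state = c(12, 23, 24)
  )
  if (complete) {
    for (nm in c("woman", "man")) {
      s <- switch(nm, woman = women, man = men)
      s$missingness <- lapply(s$missingness, function(r) 0)
      s$loss_rate <- 0
      if (nm == "woman") women <- s else men <- s
    }
  }
  cohort_config(list(woman = women, man = men), mechanism = "matrix", seed = seed)
}

draw_items <- function(states, prefix) {
  n <- length(states)
  m <- matrix(0L, n, 5, dimnames = list(NULL, paste0(prefix, frailty_items())))
  counts <- integer(n)
  counts[states == "prefrail"] <- sample(1:2, sum(states == "prefrail"), replace = TRUE)
  counts[states == "frail"] <- sample(3:5, sum(states == "frail"), replace = TRUE)
  for (i in which(counts > 0)) m[i, sample.int(5, counts[i])] <- 1L
  m
}

draw_covariates <- function(s, dependence) {
  covs <- s$covariates
  vars <- c("age", names(covs))
  p <- length(vars)
  if (is.null(dependence)) {
    z <- matrix(stats::rnorm(s$n * p), s$n, p)
  } else {
    stopifnot(all(dim(dependence) == p))
    z <- MASS::mvrnorm(s$n, mu = rep(0, p), Sigma = dependence)
  }
  colnames(z) <- vars
  u <- stats::pnorm(z)
  out <- data.frame(row.names = seq_len(s$n))
  # age: normal truncated below the eligibility age
  f_lo <- stats::pnorm(s$age_min %||% 70, s$age_mean, s$age_sd)
  out$age <- stats::qnorm(f_lo + u[, "age"] * (1 - f_lo), s$age_mean, s$age_sd)
  lvls <- list(education = education_levels(), bmi_cat = bmi_levels(),
               hospitalization_cat = hospitalization_levels())
  for (cv in names(covs)) {
    pv <- covs[[cv]]
    if (length(pv) == 1) {
      out[[cv]] <- u[, cv] < pv
    } else {
      lv <- lvls[[cv]] %||% names(pv)
      out[[cv]] <- factor(lv[findInterval(u[, cv], cumsum(pv), left.open = TRUE) + 1L],
                          levels = lv)
    }
  }
  # binary covariates stored with their field meaning
  out$smoking <- factor(ifelse(out$smoking, "ever", "never"), levels = c("never", "ever"))
  out$self_rated_health <- factor(
    ifelse(out$self_rated_health, "moderate_to_very_poor", "excellent_good"),
    levels = c("excellent_good", "moderate_to_very_poor"))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

logistic_lp <- function(coefs, data) {
  lp <- rep(coefs[[1]], nrow(data))
  nms <- names(coefs)[-1]
  if (length(nms)) {
    for (nm in nms) {
      x <- data[[nm]]
      if (is.null(x)) stop("logistic mechanism references unknown column '", nm, "'")
      if (!is.numeric(x) && !is.logical(x)) {
        stop("logistic mechanism coefficients must reference numeric or logical columns ('",
             nm, "' is ", class(x)[1], ")")
      }
      lp <- lp + coefs[[nm]] * as.numeric(x)
    }
  }
  lp
}

draw_destination <- function(config, s, cov, base_state) {
  n <- nrow(cov)
  dest_levels <- c("robust", "prefrail", "frail", "death")
  if (config$mechanism == "matrix") {
    dest <- character(n)
    for (st in c("robust", "prefrail", "frail")) {
      idx <- which(base_state == st)
      if (length(idx)) {
        dest[idx] <- sample(dest_levels, length(idx), replace = TRUE,
                            prob = s$transition_matrix[st, ])
      }
    }
    return(factor(dest, levels = dest_levels))
  }
  lg <- config$logistic
  p_w <- stats::plogis(logistic_lp(lg$worsening, cov))
  p_i <- stats::plogis(logistic_lp(lg$improvement, cov))
  worsen <- stats::runif(n) < p_w
  improve <- !worsen & base_state != "robust" & stats::runif(n) < p_i
  p_death_pw <- lg$p_death_prefail_worsen %||% 0.25
  rw_split <- lg$robust_worsen_split %||% c(prefrail = 0.85, frail = 0.10, death = 0.05)
  fi_split <- lg$frail_improve_split %||% c(prefrail = 0.9, robust = 0.1)
  dest <- as.character(base_state)  # default: no change
  idx <- which(worsen & base_state == "frail")
  dest[idx] <- "death"
  idx <- which(worsen & base_state == "prefrail")
  dest[idx] <- ifelse(stats::runif(length(idx)) < p_death_pw, "death", "frail")
  idx <- which(worsen & base_state == "robust")
  if (length(idx)) dest[idx] <- sample(names(rw_split), length(idx), TRUE, prob = rw_split)
  idx <- which(improve & base_state == "prefrail")
  dest[idx] <- "robust"
  idx <- which(improve & base_state == "frail")
  if (length(idx)) dest[idx] <- sample(names(fi_split), length(idx), TRUE, prob = fi_split)
  factor(dest, levels = dest_levels)
}

#' Generate a synthetic cohort
#'
#' Draws, per gender stratum: baseline frailty states (one multinomial draw
#' of the stratum counts), baseline items consistent with the drawn state
#' (a prefrail participant receives 1-2 positive items, a frail one 3-5,
#' identities uniform), covariates through the Gaussian copula, a follow-up
#' destination from the configured transition mechanism, loss to follow-up
#' (blanking follow-up items of survivors), and finally MAR missingness on
#' the covariates. Deterministic for a fixed seed.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed; defaults to `config$seed`.
#' @return An object of class `synthetic_cohort`: a list with `records`
#'   (the cohort data.frame, after masking) and `truth` (the pre-missingness
#'   records, the drawn baseline states and destinations, and the config).
#' @export
generate_cohort <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(seed)
  strata_out <- list()
  for (nm in names(config$strata)) {
    s <- config$strata[[nm]]
    counts <- as.vector(stats::rmultinom(1, s$n, s$baseline_state_probs))
    base_state <- factor(rep(c("robust", "prefrail", "frail"), counts),
                         levels = c("robust", "prefrail", "frail"))
    base_state <- sample(base_state)  # shuffle so state is not row-ordered
    cov <- draw_covariates(s, config$dependence)
    dest <- draw_destination(config, s, cov, base_state)
    died <- dest == "death"
    bl <- draw_items(as.character(base_state), "bl_")
    fu_state <- as.character(dest)
    fu <- draw_items(ifelse(died, "death", fu_state), "fu_")
    fu[died, ] <- NA_integer_
    lost <- !died & stats::runif(s$n) < (s$loss_rate %||% 0)
    fu[lost, ] <- NA_integer_
    rec <- cbind(
      data.frame(id = paste0(substr(nm, 1, 1), seq_len(s$n)),
                 gender = factor(nm, levels = names(config$strata))),
      cov, as.data.frame(bl), as.data.frame(fu),
      data.frame(died_in_followup = died, followup_time = 2.1)
    )
    strata_out[[nm]] <- list(rec = rec, base_state = base_state, dest = dest)
  }
  records <- do.call(rbind, lapply(strata_out, `[[`, "rec"))
  rownames(records) <- NULL
  truth <- list(
    records_complete = records,
    baseline_state = unlist(lapply(strata_out, function(x) as.character(x$base_state)),
                            use.names = FALSE),
    destination = unlist(lapply(strata_out, function(x) as.character(x$dest)),
                         use.names = FALSE),
    config = config, seed = seed
  )
  # MAR masking last, per stratum rates
  masked <- records
  for (nm in names(config$strata)) {
    rates <- config$strata[[nm]]$missingness
    if (length(rates)) {
      idx <- which(masked$gender == nm)
      masked[idx, ] <- apply_missingness(masked[idx, , drop = FALSE], rates,
                                         seed = NULL)
    }
  }
  structure(list(records = masked, truth = truth), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d participants (%s)\n", nrow(x$records),
              paste(sprintf("%s %d", levels(x$records$gender),
                            table(x$records$gender)), collapse = ", ")))
  invisible(x)
}

#' Apply missing-at-random masking to cohort fields
#'
#' Masks each named field at the configured rate. A rate entry is either a
#' scalar (MCAR) or `list(rate =, depends_on =, log_or =)` for MAR where the
#' missingness log-odds depend on one *observed* conditioning covariate; the
#' intercept is solved so the marginal rate matches `rate`. Missingness never
#' depends on the masked value itself.
#'
#' @param cohort Cohort data.frame.
#' @param rates Named list of rates (names must be cohort columns).
#' @param seed Optional seed (NULL = use the current RNG stream).
#' @return The cohort with masked cells set to `NA`.
#' @export
apply_missingness <- function(cohort, rates, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(cohort)
  for (field in names(rates)) {
    if (!field %in% names(cohort)) {
      stop("missingness rate given for unknown field '", field, "'")
    }
    r <- rates[[field]]
    if (is.list(r)) {
      x <- as.numeric(cohort[[r$depends_on]])
      if (any(is.na(x))) stop("MAR conditioning covariate '", r$depends_on, "' must be fully observed")
      if (r$rate <= 0) next
      if (r$rate >= 1) { cohort[[field]][seq_len(n)] <- NA; next }
      alpha <- stats::uniroot(
        function(a) mean(stats::plogis(a + r$log_or * x)) - r$rate,
        interval = c(-40, 40), tol = 1e-10
      )$root
      p <- stats::plogis(alpha + r$log_or * x)
    } else {
      if (r == 0) next
      p <- rep(r, n)
    }
    mask <- stats::runif(n) < p
    cohort[[field]][mask] <- NA
  }
  cohort
}
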