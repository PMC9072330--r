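round_half_up <- function(x, digits = 0) {
  s <- 10^digits
  floor(x * s + 0.5) / s
}

# deterministic rolling hash of the serialised object, for the manifest
# (31-based; all intermediates stay below 2^53 so arithmetic is exact)
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h <- 5381
  for (b in bytes) h <- (h * 31 + b) %% 2^31
  sprintf("%08x", h)
}

#' Descriptive baseline table, stratified
#'
#' Counts and percentages (of the stratum size, half-up rounded to integer
#' percent, matching the conventions of published cohort tables) per level
#' of every categorical/logical variable, including an `Unknown` row where
#' values are missing; age is summarised as mean (SD).
#'
#' @param cohort Classified cohort data.frame.
#' @param by Stratifying column (default `"gender"`); use `NULL` for the
#'   total column only.
#' @param variables Columns to describe (default: the candidate predictors
#'   present, plus `frailty_baseline` and `transition_outcome` when
#'   present).
#' @return Long data.frame: `variable`, `level`, `stratum`, `n`, `pct`
#'   (`NA` for continuous summaries, which instead fill `mean`, `sd`).
#' @export
describe_baseline <- function(cohort, by = "gender", variables = NULL) {
  if (is.null(variables)) {
    variables <- intersect(c(candidate_predictors(), "transition_outcome"),
                           names(cohort))
  }
  strata <- list(total = rep(TRUE, nrow(cohort)))
  if (!is.null(by)) {
    lv <- levels(factor(cohort[[by]]))
    if (length(lv) == 0 || nrow(cohort) == 0) warning("empty stratifying column")
    for (l in lv) strata[[l]] <- cohort[[by]] == l & !is.na(cohort[[by]])
  }
  out <- NULL
  for (v in variables) {
    x <- cohort[[v]]
    for (snm in names(strata)) {
      sel <- strata[[snm]]
      N <- sum(sel)
      if (N == 0) { warning("empty stratum '", snm, "'"); next }
      xs <- x[sel]
      if (is.numeric(x)) {
        out <- rbind(out, data.frame(
          variable = v, level = "mean (SD)", stratum = snm, n = N, pct = NA_real_,
          mean = mean(xs, na.rm = TRUE), sd = stats::sd(xs, na.rm = TRUE)))
      } else {
        f <- if (is.logical(x)) factor(ifelse(xs, "yes", "no"), c("yes", "no")) else factor(xs)
        tab <- table(f, useNA = "no")
        rows <- data.frame(variable = v, level = names(tab), stratum = snm,
                           n = as.integer(tab),
                           pct = round_half_up(100 * as.integer(tab) / N),
                           mean = NA_real_, sd = NA_real_)
        if (anyNA(xs)) {
          rows <- rbind(rows, data.frame(variable = v, level = "Unknown", stratum = snm,
                                         n = sum(is.na(xs)),
                                         pct = round_half_up(100 * sum(is.na(xs)) / N),
                                         mean = NA_real_, sd = NA_real_))
        }
        out <- rbind(out, rows)
      }
    }
  }
  rownames(out) <- NULL
  out
}

#' Transition matrix and outcome counts of a classified cohort
#'
#' Per gender, the 3x5 table of relative destination frequencies (robust /
#' prefrail / frail / death, plus unknown reported separately) conditioned
#' on the baseline state, each row summing to 1, together with aggregate
#' transition-outcome counts. Percentages of transitioned participants are
#' reported with both denominators (participants with a determined outcome,
#' and all participants).
#'
#' @param classified A cohort from [classify_cohort()].
#' @return Object of class `transition_summary`: `matrices` (per-gender 3x5
#'   proportions), `outcome_counts` (per gender + total), `n_transitioned`,
#'   `pct_of_determined`, `pct_of_all`, `deaths`, `pct_deaths_of_worsened`.
#' @export
transition_summary <- function(classified) {
  dest <- as.character(classified$frailty_followup)
  dest[classified$died_in_followup] <- "death"
  dest[dest == "indeterminate"] <- "unknown"
  dest <- factor(dest, levels = c("robust", "prefrail", "frail", "death", "unknown"))
  base <- factor(as.character(classified$frailty_baseline),
                 levels = c("robust", "prefrail", "frail"))
  genders <- levels(factor(classified$gender))
  mats <- list()
  for (g in genders) {
    sel <- classified$gender == g
    tab <- table(base[sel], dest[sel])
    mats[[g]] <- sweep(tab, 1, pmax(rowSums(tab), 1), "/")
  }
  oc <- table(classified$gender, classified$transition_outcome)
  counts <- rbind(oc, total = colSums(oc))
  n_trans <- counts["total", "improvement"] + counts["total", "worsening"]
  n_known <- sum(counts["total", c("improvement", "no_change", "worsening")])
  deaths <- sum(classified$died_in_followup)
  structure(list(
    matrices = mats, outcome_counts = counts,
    n_transitioned = unname(n_trans),
    pct_of_determined = round_half_up(100 * n_trans / n_known),
    pct_of_all = round_half_up(100 * n_trans / nrow(classified)),
    deaths = deaths,
    pct_deaths_of_worsened = round_half_up(100 * deaths / counts["total", "worsening"])
  ), class = "transition_summary")
}

#' @export
print.transition_summary <- function(x, ...) {
  cat(sprintf("Frailty transitions: %d transitioned (%d%% of determined, %d%% of all); %d deaths (%d%% of worsened)\n",
              x$n_transitioned, x$pct_of_determined, x$pct_of_all,
              x$deaths, x$pct_deaths_of_worsened))
  print(x$outcome_counts)
  invisible(x)
}

#' Settings for the end-to-end analysis
#'
#' @param m,iterations Imputation count and chained sweeps.
#' @param select_bootstraps,frequency_threshold Stability-selection settings.
#' @param optimism_bootstraps,auc_reps,calibration_bootstraps Validation
#'   settings.
#' @param seed Global seed; per-stage streams are derived from it.
#' @return List of class `analysis_settings`.
#' @export
analysis_settings <- function(m = 10, iterations = 10, select_bootstraps = 200,
                              frequency_threshold = 0.5, optimism_bootstraps = 200,
                              auc_reps = 2000, calibration_bootstraps = 200,
                              seed = 1L) {
  structure(list(m = m, iterations = iterations,
                 select_bootstraps = select_bootstraps,
                 frequency_threshold = frequency_threshold,
                 optimism_bootstraps = optimism_bootstraps, auc_reps = auc_reps,
                 calibration_bootstraps = calibration_bootstraps,
                 seed = as.integer(seed)),
            class = "analysis_settings")
}

#' Run the full gender-stratified transition analysis
#'
#' Executes simulate/ingest, classification, descriptives, per-gender
#' imputation, stability selection, pooled fitting and internal validation
#' for the two modellable outcomes (improvement and worsening; no-change is
#' structurally not modelled), i.e. four models in total. Deterministic for
#' a fixed seed; the manifest records the derived per-stage seeds and a
#' configuration hash.
#'
#' @param input A [cohort_config()] (a synthetic cohort is generated) or a
#'   cohort data.frame.
#' @param settings An [analysis_settings()].
#' @return Object of class `analysis_bundle`: `descriptives`, `transitions`,
#'   `models` (named `outcome.gender` list of `pooled_model`),
#'   `validation` (matching list of `validation_report`), `selection`
#'   (matching list of `selection_result`), `vif`, `manifest`.
#' @export
run_full <- function(input, settings = analysis_settings()) {
  seed <- settings$seed
  if (inherits(input, "cohort_config")) {
    cohort <- generate_cohort(input, seed = seed)$records
  } else {
    cohort <- as.data.frame(input)
  }
  classified <- classify_cohort(cohort)
  n0 <- nrow(classified)
  descriptives <- describe_baseline(classified)
  transitions <- transition_summary(classified)
  genders <- levels(factor(classified$gender))
  models <- validation <- selection <- list()
  vifs <- list()
  stage_seed <- function(k) (seed * 1000L + k) %% .Machine$integer.max
  k <- 0L
  for (g in genders) {
    sub <- classified[classified$gender == g, , drop = FALSE]
    stopifnot(nrow(sub) + sum(classified$gender != g) == n0)  # conservation
    k <- k + 1L
    stack <- impute_cohort(sub, m = settings$m, iterations = settings$iterations,
                           seed = stage_seed(k))
    vifs[[g]] <- vif_candidates(stack)
    for (oc in c("improvement", "worsening")) {
      key <- paste(oc, g, sep = ".")
      k <- k + 1L
      sel <- stability_select(stack, selection_config(
        outcome = oc, bootstraps_per_imputation = settings$select_bootstraps,
        frequency_threshold = settings$frequency_threshold, seed = stage_seed(k)))
      k <- k + 1L
      models[[key]] <- fit_on_stack(stack, sel$selected, oc)
      validation[[key]] <- validate_model(
        stack, sel$selected, oc, bootstraps = settings$optimism_bootstraps,
        auc_reps = settings$auc_reps,
        calibration_bootstraps = settings$calibration_bootstraps,
        seed = stage_seed(k))
      selection[[key]] <- sel
      # structural identity: improvement analysis n = stratum n - baseline robust
      if (oc == "improvement") {
        stopifnot(models[[key]]$n_analysis ==
                    nrow(sub) - sum(sub$frailty_baseline == "robust"))
      }
    }
  }
  manifest <- list(
    seed = seed, settings = unclass(settings),
    config_hash = config_hash(list(input = input, settings = settings)),
    n_participants = n0,
    n_excluded_baseline = attr(classified, "n_excluded_baseline"),
    package_version = as.character(utils::packageVersion("frailtrans"))
  )
  structure(list(descriptives = descriptives, transitions = transitions,
                 models = models, validation = validation, selection = selection,
                 vif = vifs, manifest = manifest),
            class = "analysis_bundle")
}

#' @export
print.analysis_bundle <- function(x, ...) {
  cat(sprintf("Frailty-transition analysis bundle: %d participants, %d models\n",
              x$manifest$n_participants, length(x$models)))
  print(x$transitions)
  for (nm in names(x$models)) {
    cat("\n--", nm, "--\n")
    print(x$models[[nm]])
    print(x$validation[[nm]])
  }
  invisible(x)
}
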