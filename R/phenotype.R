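#' Names of the five frailty phenotype items
#'
#' The phenotype comprises five binary items: shrinking, exhaustion, low
#' physical activity, slowness and weakness. Cohort tables carry them twice,
#' prefixed `bl_` (baseline) and `fu_` (follow-up), coded 1 = present,
#' 0 = absent, `NA` = missing.
#'
#' Item operationalisation from raw measurements (grip strength, gait speed,
#' activity questionnaires, ...) is site-specific and deliberately out of
#' scope: items are consumed pre-scored. Adapt upstream scoring to this
#' ternary coding before calling [classify_frailty()].
#'
#' @return Character vector of length five.
#' @export
frailty_items <- function() {
  c("shrinking", "exhaustion", "low_physical_activity", "slowness", "weakness")
}

#' Levels of the frailty state and transition taxonomies
#' @name taxonomy-levels
#' @return Character vectors of level names, in severity / canonical order.
#' @export
frailty_state_levels <- function() c("robust", "prefrail", "frail", "indeterminate")

#' @rdname taxonomy-levels
#' @export
transition_levels <- function() c("improvement", "no_change", "worsening", "unknown")

item_matrix <- function(items) {
  if (is.null(dim(items))) {
    items <- matrix(as.numeric(items), nrow = 1)
  } else {
    items <- as.matrix(as.data.frame(lapply(as.data.frame(items), as.numeric)))
  }
  if (ncol(items) != 5L) {
    stop("frailty items must have exactly five columns (one per item)")
  }
  bad <- !(items %in% c(0, 1) | is.na(items))
  if (any(bad)) stop("frailty items must be coded 0, 1 or NA")
  items
}

#' Score the five-item frailty phenotype
#'
#' Classifies each profile of five ternary items (present / absent / missing)
#' into `frail` (at least three items present), `prefrail` (one or two items),
#' `robust` (none of the five items) or `indeterminate`.
#'
#' Missing items are handled conservatively: a state is assigned only when it
#' is invariant to every possible completion of the missing items —
#' `frail` whenever observed positives already reach 3; `robust` only with
#' five observed negatives; `prefrail` only when positives are 1 or 2 *and*
#' positives + missing stay at or below 2, so that no completion can reach
#' the frail threshold and none can reach zero. Any profile whose category
#' depends on the unobserved items is `indeterminate`. On fully observed
#' items no profile is ever indeterminate.
#'
#' @param items A length-5 vector, or a matrix / data.frame with five columns
#'   (one row per participant), coded 1 = present, 0 = absent, NA = missing.
#' @return A factor with levels `robust`, `prefrail`, `frail`,
#'   `indeterminate` (one element per row).
#' @examples
#' classify_frailty(c(1, 1, 1, 0, 0))   # frail
#' classify_frailty(c(0, 0, 0, 0, 0))   # robust
#' classify_frailty(c(1, 1, 0, 0, NA))  # indeterminate (could be prefrail or frail)
#' @export
classify_frailty <- function(items) {
  m <- item_matrix(items)
  pos <- rowSums(m == 1, na.rm = TRUE)
  miss <- rowSums(is.na(m))
  state <- rep("indeterminate", nrow(m))
  state[pos >= 3] <- "frail"
  state[pos == 0 & miss == 0] <- "robust"
  state[pos %in% c(1, 2) & (pos + miss) <= 2] <- "prefrail"
  factor(state, levels = frailty_state_levels())
}

#' Classify the frailty transition outcome
#'
#' Compares baseline and follow-up frailty states under the severity order
#' robust < prefrail < frail. Death within the follow-up window counts as
#' worsening from any baseline state and overrides whatever follow-up items
#' were recorded. A decrease in severity is `improvement`, an increase is
#' `worsening`, equality is `no_change`; a survivor whose follow-up state is
#' indeterminate is `unknown` (lost to follow-up).
#'
#' Participants with an indeterminate *baseline* state cannot be classified
#' and are expected to be excluded upstream; passing one raises an error of
#' class `frailtrans_baseline_indeterminate`.
#'
#' @param baseline,followup Frailty states (factor or character, levels as in
#'   [frailty_state_levels()]). `followup` may be `NA`, treated as
#'   indeterminate.
#' @param died Logical vector: died within the follow-up window.
#' @return Factor with levels `improvement`, `no_change`, `worsening`,
#'   `unknown`.
#' @examples
#' classify_transition("frail", "robust", died = FALSE)     # improvement
#' classify_transition("prefrail", "indeterminate", TRUE)   # worsening (death)
#' @export
classify_transition <- function(baseline, followup, died) {
  baseline <- as.character(baseline)
  followup <- as.character(followup)
  followup[is.na(followup)] <- "indeterminate"
  died <- as.logical(died)
  sev <- c(robust = 0, prefrail = 1, frail = 2)
  if (any(is.na(baseline)) || any(!baseline %in% names(sev))) {
    stop(structure(
      class = c("frailtrans_baseline_indeterminate", "error", "condition"),
      list(message = "baseline frailty state is indeterminate or missing; exclude these participants upstream",
           call = sys.call(-1))
    ))
  }
  n <- max(length(baseline), length(followup), length(died))
  baseline <- rep_len(baseline, n); followup <- rep_len(followup, n)
  died <- rep_len(died, n)
  out <- rep("unknown", n)
  alive_known <- !died & followup %in% names(sev)
  d <- sev[followup[alive_known]] - sev[baseline[alive_known]]
  out[alive_known] <- ifelse(d < 0, "improvement", ifelse(d > 0, "worsening", "no_change"))
  out[died] <- "worsening"
  factor(out, levels = transition_levels())
}

#' Derive dichotomised clinical predictors from raw measurements
#'
#' Applies the standard cutpoints: reduced kidney function as eGFR
#' < 60 ml/min/1.73 m^2, kidney damage as albumin-to-creatinine ratio
#' >= 30 mg/g, polypharmacy as >= 5 medications, diabetes mellitus as
#' HbA1c >= 6.5% or intake of any antidiabetic drug, BMI in bands
#' < 25 / 25-29.9 / >= 30 kg/m^2, and hospitalisations in the two prior
#' years banded 0 / 1-2 / >= 3. All inequalities are applied exactly as
#' stated (strict `<` for eGFR, inclusive `>=` elsewhere). Missing raw
#' values propagate to missing derived values.
#'
#' @param raw A data.frame with any of the columns `egfr`, `acr`,
#'   `n_medications`, `hba1c`, `antidiabetic_drug`, `bmi`,
#'   `n_hospitalizations`. Absent columns are skipped.
#' @return A data.frame with the derivable columns among `egfr_lt60`,
#'   `acr_ge30`, `polypharmacy`, `diabetes`, `bmi_cat`,
#'   `hospitalization_cat`.
#' @examples
#' derive_predictors(data.frame(egfr = c(59.9, 60), acr = c(30, 29.9)))
#' @export
derive_predictors <- function(raw) {
  raw <- as.data.frame(raw)
  num_cols <- intersect(
    c("egfr", "acr", "n_medications", "hba1c", "bmi", "n_hospitalizations"),
    names(raw)
  )
  for (col in num_cols) {
    if (any(raw[[col]] < 0, na.rm = TRUE)) {
      stop("negative value in raw measurement '", col, "'")
    }
  }
  out <- data.frame(row.names = seq_len(nrow(raw)))
  if ("egfr" %in% names(raw)) out$egfr_lt60 <- raw$egfr < 60
  if ("acr" %in% names(raw)) out$acr_ge30 <- raw$acr >= 30
  if ("n_medications" %in% names(raw)) out$polypharmacy <- raw$n_medications >= 5
  if (all(c("hba1c", "antidiabetic_drug") %in% names(raw))) {
    ad <- as.logical(raw$antidiabetic_drug)
    hi <- raw$hba1c >= 6.5
    # drug intake alone is sufficient even when HbA1c is missing
    out$diabetes <- ifelse(!is.na(ad) & ad, TRUE, hi)
  }
  if ("bmi" %in% names(raw)) {
    out$bmi_cat <- cut(raw$bmi, breaks = c(-Inf, 25, 30, Inf),
                       labels = bmi_levels(), right = FALSE)
  }
  if ("n_hospitalizations" %in% names(raw)) {
    out$hospitalization_cat <- cut(raw$n_hospitalizations,
                                   breaks = c(-Inf, 0.5, 2.5, Inf),
                                   labels = hospitalization_levels())
  }
  out
}

bmi_levels <- function() c("<25", "25-29.9", ">=30")
hospitalization_levels <- function() c("0", "1-2", ">=3")
education_levels <- function() c("low", "middle", "high")

#' The 18 candidate predictors considered for every prognostic model
#'
#' Age, education (CASMIN-short), smoking, self-rated health, living alone,
#' BMI category, polypharmacy, hospitalisation band, cognitive impairment,
#' stroke, congestive heart failure, diabetes mellitus, cancer,
#' osteoarthritis, COPD, eGFR < 60, ACR >= 30 and baseline frailty status.
#'
#' @return Character vector of cohort-table column names.
#' @export
candidate_predictors <- function() {
  c("age", "education", "smoking", "self_rated_health", "living_alone",
    "bmi_cat", "polypharmacy", "hospitalization_cat", "cognitive_impairment",
    "stroke", "chf", "diabetes", "cancer", "osteoarthritis", "copd",
    "egfr_lt60", "acr_ge30", "frailty_baseline")
}

#' Score and classify a whole cohort table
#'
#' Adds `frailty_baseline`, `frailty_followup` and `transition_outcome`
#' columns computed from the `bl_*` / `fu_*` item columns and
#' `died_in_followup`. Participants with an indeterminate baseline state are
#' dropped (mirroring the upstream exclusion of participants with missing
#' baseline frailty scores) and their count reported via the
#' `n_excluded_baseline` attribute.
#'
#' @param cohort Cohort data.frame with the ten item columns and
#'   `died_in_followup`.
#' @return The classified cohort (possibly fewer rows), with attribute
#'   `n_excluded_baseline`.
#' @export
classify_cohort <- function(cohort) {
  bl <- cohort[, paste0("bl_", frailty_items()), drop = FALSE]
  fu <- cohort[, paste0("fu_", frailty_items()), drop = FALSE]
  base_state <- classify_frailty(bl)
  keep <- base_state != "indeterminate"
  n_excl <- sum(!keep)
  cohort <- cohort[keep, , drop = FALSE]
  cohort$frailty_baseline <- factor(as.character(base_state[keep]),
                                    levels = frailty_state_levels()[1:3])
  cohort$frailty_followup <- classify_frailty(fu[keep, , drop = FALSE])
  cohort$transition_outcome <- classify_transition(
    cohort$frailty_baseline, cohort$frailty_followup, cohort$died_in_followup
  )
  attr(cohort, "n_excluded_baseline") <- n_excl
  cohort
}
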