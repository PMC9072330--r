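#' Deterministic cohort fixture with the published transition bookkeeping
#'
#' Builds a 1158-row cohort whose per-gender baseline states, follow-up
#' destinations, deaths and losses to follow-up equal the counts
#' reconstructed from the published tables (women: 115/282/240 robust /
#' prefrail / frail; men: 110/250/161; improvement 160, worsening 322,
#' unknown 129). Items are filled deterministically (the first k items
#' positive for a state requiring k), so classification is exact and no
#' randomness is involved. Covariates are not populated: the fixture
#' exercises the phenotype and descriptive stages, not the models.
#'
#' @return A cohort data.frame ready for [classify_cohort()].
#' @export
reference_transition_fixture <- function() {
  # per gender: rows = baseline state, cols = destination counts
  counts <- list(
    woman = list(robust   = c(robust = 52, prefrail = 48, frail = 5, death = 2, unknown = 8),
                 prefrail = c(robust = 48, prefrail = 142, frail = 47, death = 17, unknown = 28),
                 frail    = c(robust = 5, prefrail = 48, frail = 110, death = 43, unknown = 34)),
    man = list(robust   = c(robust = 55, prefrail = 36, frail = 5, death = 2, unknown = 12),
               prefrail = c(robust = 36, prefrail = 127, frail = 49, death = 15, unknown = 23),
               frail    = c(robust = 3, prefrail = 20, frail = 61, death = 53, unknown = 24))
  )
  items_for <- function(state) {
    k <- switch(state, robust = 0L, prefrail = 1L, frail = 3L, death = NA_integer_,
                unknown = NA_integer_)
    if (is.na(k)) rep(NA_integer_, 5) else c(rep(1L, k), rep(0L, 5 - k))
  }
  rows <- list()
  for (g in names(counts)) {
    for (st in names(counts[[g]])) {
      for (dest in names(counts[[g]][[st]])) {
        n <- counts[[g]][[st]][[dest]]
        if (n == 0) next
        bl <- matrix(rep(items_for(st), n), n, 5, byrow = TRUE)
        fu <- matrix(rep(items_for(dest), n), n, 5, byrow = TRUE)
        colnames(bl) <- paste0("bl_", frailty_items())
        colnames(fu) <- paste0("fu_", frailty_items())
        rows[[length(rows) + 1]] <- cbind(
          data.frame(gender = factor(g, levels = c("woman", "man")),
                     died_in_followup = dest == "death", followup_time = 2.1),
          as.data.frame(bl), as.data.frame(fu))
      }
    }
  }
  out <- do.call(rbind, rows)
  out$id <- paste0("p", seq_len(nrow(out)))
  rownames(out) <- NULL
  out
}
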