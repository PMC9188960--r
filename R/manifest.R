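#' Cohort manifest of the severe-epilepsy PRS study
#'
#' Per-cohort case and control counts of the eleven analysed cohorts: six
#' epilepsy cohorts (three DEE, three epilepsy-with-ID) and five control-only
#' cohorts, with the published column totals attached as the
#' `printed_totals` attribute. Screen-positive / screen-negative are the case
#' subsets with / without an identifiable likely damaging rare variant.
#'
#' @return data.frame with columns `cohort`, `n_cases`, `n_screen_positive`,
#'   `n_screen_negative`, `n_controls`, `phenotype`, and attribute
#'   `printed_totals` (named numeric: cases, screen_positive, screen_negative,
#'   controls).
#' @export
dee_cohort_manifest <- function() {
  m <- data.frame(
    cohort = c("Epi25", "Partners Biobank", "Epi4K", "QSkin", "CENet",
               "Canadian Controls", "DDD", "UK Biobank", "Irish Lighthouse",
               "Irish Controls", "Genomics England"),
    n_cases = c(1094L, 0L, 266L, 0L, 171L, 0L, 897L, 0L, 82L, 0L, 249L),
    n_screen_positive = c(163L, 0L, 44L, 0L, 40L, 0L, 152L, 0L, 29L, 0L, 32L),
    n_screen_negative = c(931L, 0L, 77L, 0L, 86L, 0L, 745L, 0L, 53L, 0L, 217L),
    n_controls = c(0L, 19762L, 0L, 15717L, 0L, 6901L, 0L, 400835L, 0L,
                   2404L, 1931L),
    phenotype = c("DEE", "Controls only", "DEE", "Controls only", "DEE",
                  "Controls only", "Seizures + ID", "Controls only",
                  "Epilepsy + ID", "Controls only", "Epilepsy + ID and controls"),
    stringsAsFactors = FALSE)
  attr(m, "printed_totals") <- c(cases = 2759, screen_positive = 460,
                                 screen_negative = 2109, controls = 447760)
  m
}

#' Validate a cohort manifest and compute study totals
#'
#' Sums case, screen-positive, screen-negative and control counts over the
#' cohorts; unassigned cases are those neither screen-positive nor
#' screen-negative (cases lacking rare-variant data). Control-only cohorts
#' contribute only to the control total. When the manifest carries a
#' `printed_totals` attribute (published column totals), those are reported
#' alongside the recomputed sums without reconciliation — the published
#' control total need not equal the sum of the listed control cohorts.
#'
#' @param manifest data.frame with columns `cohort`, `n_cases`,
#'   `n_screen_positive`, `n_screen_negative`, `n_controls`.
#' @return list with `n_cases`, `n_screen_positive`, `n_screen_negative`,
#'   `n_unassigned`, `n_controls` (recomputed sums), `per_cohort_unassigned`
#'   (named vector over epilepsy cohorts), and `printed_totals` (or `NULL`).
#' @export
validate_manifest <- function(manifest) {
  if (nrow(manifest) == 0)
    return(list(n_cases = 0, n_screen_positive = 0, n_screen_negative = 0,
                n_unassigned = 0, n_controls = 0,
                per_cohort_unassigned = numeric(0), printed_totals = NULL))
  cols <- c("n_cases", "n_screen_positive", "n_screen_negative", "n_controls")
  for (col in cols) {
    if (is.null(manifest[[col]])) stop("manifest missing column: ", col)
    if (any(manifest[[col]] < 0)) stop("negative count in column: ", col)
  }
  unassigned <- manifest$n_cases - manifest$n_screen_positive -
    manifest$n_screen_negative
  if (any(unassigned < 0))
    stop("inconsistent manifest: screen-positive + screen-negative exceed ",
         "cases in cohort(s) ",
         paste(manifest$cohort[unassigned < 0], collapse = ", "))
  epi <- manifest$n_cases > 0
  list(n_cases = sum(manifest$n_cases),
       n_screen_positive = sum(manifest$n_screen_positive),
       n_screen_negative = sum(manifest$n_screen_negative),
       n_unassigned = sum(unassigned),
       n_controls = sum(manifest$n_controls),
       per_cohort_unassigned = setNames(unassigned[epi], manifest$cohort[epi]),
       printed_totals = attr(manifest, "printed_totals"))
}
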