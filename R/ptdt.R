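#' Mid-parent polygenic scores
#'
#' The average of the two parental PRS per trio — the child's expected score
#' under null (symmetric) transmission.
#'
#' @param trios data.frame with `father_id`, `mother_id`, `child_id`.
#' @param prs a scored sample table (columns `id` and `z`, or `raw` when no
#'   `z` is present); every trio member must be scored.
#' @param scale which score column to use: `"z"` (default) or `"raw"`.
#' @return numeric vector of mid-parent scores, one per trio, named by child.
#' @export
midparent_prs <- function(trios, prs, scale = c("z", "raw")) {
  scale <- match.arg(scale)
  col <- if (scale == "z" && !is.null(prs$z)) "z" else "raw"
  look <- function(ids) {
    idx <- match(ids, prs$id)
    if (anyNA(idx)) {
      bad <- which(is.na(idx))
      stop("unscored trio member(s) for child ",
           paste(trios$child_id[bad], collapse = ", "))
    }
    prs[[col]][idx]
  }
  fa <- look(trios$father_id)
  mo <- look(trios$mother_id)
  look(trios$child_id)  # validates children are scored too
  setNames((fa + mo) / 2, trios$child_id)
}

#' Polygenic transmission disequilibrium test
#'
#' Standardised per-trio deviation
#' `dev_t = (child_prs_t - midparent_t) / SD(midparent)` (SD over the
#' analysed trios, n-1 denominator), tested against zero with a two-sided
#' one-sample t-test. Over-transmission of risk alleles to affected children
#' appears as a positive mean deviation.
#'
#' @param trios data.frame with `father_id`, `mother_id`, `child_id`.
#' @param prs scored sample table (see [midparent_prs()]).
#' @param stratum label recorded in the result (`"all"`,
#'   `"screen_pos"`, `"screen_neg"`).
#' @param scale score column to use, `"z"` or `"raw"`.
#' @return list of class `ptdt_result`: `n_trios`, `mean_deviation`,
#'   `sd_deviation`, `t_stat`, `df`, `p`, `stratum`.
#' @export
ptdt_test <- function(trios, prs, stratum = "all", scale = c("z", "raw")) {
  scale <- match.arg(scale)
  n <- nrow(trios)
  if (n < 2) stop("pTDT needs at least 2 trios (got ", n, ")")
  mp <- midparent_prs(trios, prs, scale)
  sd_mp <- sd(mp)
  if (!is.finite(sd_mp) || sd_mp == 0)
    stop("degenerate pTDT: zero variance of mid-parent scores")
  col <- if (scale == "z" && !is.null(prs$z)) "z" else "raw"
  child <- prs[[col]][match(trios$child_id, prs$id)]
  dev <- (child - mp) / sd_mp
  m <- mean(dev)
  s <- sd(dev)
  # constant deviations: a zero mean is a null result, a non-zero mean is
  # unbounded evidence
  t_stat <- if (s == 0) { if (m == 0) 0 else sign(m) * Inf }
    else m / (s / sqrt(n))
  structure(list(n_trios = n, mean_deviation = m, sd_deviation = s,
                 t_stat = t_stat, df = n - 1,
                 p = 2 * pt(-abs(t_stat), df = n - 1),
                 stratum = stratum),
            class = "ptdt_result")
}

#' @method print ptdt_result
#' @export
print.ptdt_result <- function(x, ...) {
  cat(sprintf(
    "pTDT [%s]: n = %d trios, mean deviation = %.4f, t = %.3f (df %d), p = %.3g\n",
    x$stratum, x$n_trios, x$mean_deviation, x$t_stat, x$df, x$p))
  invisible(x)
}

#' pTDT overall and stratified by screen status
#'
#' Runs [ptdt_test()] on all trios and on the subsets whose child is
#' screen-positive / screen-negative. Strata with fewer than 2 trios are
#' reported as skipped. The mid-parent SD is recomputed within each stratum.
#'
#' @param trios data.frame with `father_id`, `mother_id`, `child_id`.
#' @param prs scored sample table.
#' @param samples sample table with `id` and `screen_status` (children).
#' @param scale score column, `"z"` or `"raw"`.
#' @return named list of `ptdt_result` objects (`all`, `screen_pos`,
#'   `screen_neg`); skipped strata hold `list(skipped = TRUE, n_trios = n)`.
#' @export
ptdt_stratified <- function(trios, prs, samples, scale = c("z", "raw")) {
  scale <- match.arg(scale)
  status <- samples$screen_status[match(trios$child_id, samples$id)]
  subsets <- list(all = rep(TRUE, nrow(trios)),
                  screen_pos = status %in% "positive",
                  screen_neg = status %in% "negative")
  lapply(names(subsets), function(nm) {
    sub <- trios[subsets[[nm]], , drop = FALSE]
    if (nrow(sub) < 2)
      return(list(skipped = TRUE, n_trios = nrow(sub), stratum = nm))
    ptdt_test(sub, prs, stratum = nm, scale = scale)
  }) |> setNames(names(subsets))
}
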