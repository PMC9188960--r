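#' Inverse-variance fixed-effects meta-analysis
#'
#' Weights `w_i = 1/se_i^2`; pooled estimate `sum(w b)/sum(w)` with standard
#' error `sqrt(1/sum(w))`; Cochran's `Q = sum w (b - pooled)^2` on `k - 1`
#' degrees of freedom; `I2 = max(0, (Q - df)/Q) * 100` (0 when `k = 1` or
#' `Q = 0`); two-sided Wald p-value.
#'
#' @param betas per-study log-odds estimates.
#' @param ses per-study standard errors (> 0).
#' @return list of class `meta_result`: `pooled_beta`, `pooled_se`, `z`,
#'   `p`, `q_stat`, `df`, `i2` (percentage), `tau2`, `model`, `k`.
#' @export
meta_fixed <- function(betas, ses) {
  k <- length(betas)
  if (k == 0) stop("no studies supplied")
  if (length(ses) != k) stop("betas and ses must have equal length")
  if (any(!is.finite(ses)) || any(ses <= 0))
    stop("all standard errors must be positive and finite")
  w <- 1 / ses^2
  pooled <- sum(w * betas) / sum(w)
  pooled_se <- sqrt(1 / sum(w))
  q <- sum(w * (betas - pooled)^2)
  df <- k - 1
  i2 <- if (k == 1 || q == 0) 0 else max(0, (q - df) / q) * 100
  z <- pooled / pooled_se
  structure(list(pooled_beta = pooled, pooled_se = pooled_se, z = z,
                 p = 2 * pnorm(-abs(z)), q_stat = q, df = df, i2 = i2,
                 tau2 = 0, model = "fixed", k = k),
            class = "meta_result")
}

#' DerSimonian-Laird random-effects meta-analysis
#'
#' Method-of-moments between-study variance
#' `tau2 = max(0, (Q - df) / (sum(w) - sum(w^2)/sum(w)))` with fixed-effects
#' weights, then inverse-variance pooling with `w*_i = 1/(se_i^2 + tau2)`.
#' Heterogeneity statistics (Q, I2) are those of the fixed-effects weights.
#'
#' @inheritParams meta_fixed
#' @return list of class `meta_result` with `model = "random"`.
#' @export
meta_random_dl <- function(betas, ses) {
  k <- length(betas)
  if (k < 2) stop("random-effects meta-analysis needs at least 2 studies")
  fe <- meta_fixed(betas, ses)
  w <- 1 / ses^2
  tau2 <- max(0, (fe$q_stat - fe$df) / (sum(w) - sum(w^2) / sum(w)))
  ws <- 1 / (ses^2 + tau2)
  pooled <- sum(ws * betas) / sum(ws)
  pooled_se <- sqrt(1 / sum(ws))
  z <- pooled / pooled_se
  structure(list(pooled_beta = pooled, pooled_se = pooled_se, z = z,
                 p = 2 * pnorm(-abs(z)), q_stat = fe$q_stat, df = fe$df,
                 i2 = fe$i2, tau2 = tau2, model = "random", k = k),
            class = "meta_result")
}

#' @method print meta_result
#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("%s-effects meta-analysis of %d studies\n", x$model, x$k))
  cat(sprintf("pooled beta = %.4f (se %.4f), p = %.3g\n",
              x$pooled_beta, x$pooled_se, x$p))
  cat(sprintf("Q = %.3f (df %d), I2 = %.1f%%, tau2 = %.4f\n",
              x$q_stat, x$df, x$i2, x$tau2))
  invisible(x)
}

#' Forest-plot table of per-cohort and pooled estimates
#'
#' One row per cohort with its log-odds, standard error, 95% CI
#' (`beta +/- 1.96 se`) and inverse-variance weight percentage (random-effects
#' weights when the pooled model is random), followed by the pooled row.
#'
#' @param results named list of `assoc_result` objects (names = cohorts), or
#'   a data.frame with columns `cohort`, `beta`, `se`.
#' @param meta a [meta_fixed()] or [meta_random_dl()] result.
#' @return data.frame: `cohort`, `beta`, `se`, `ci_low`, `ci_high`,
#'   `weight_pct`.
#' @export
forest_table <- function(results, meta) {
  if (is.data.frame(results)) {
    tab <- results[, c("cohort", "beta", "se")]
  } else {
    stopifnot(length(results) > 0)
    tab <- data.frame(cohort = names(results),
                      beta = vapply(results, `[[`, numeric(1), "beta"),
                      se = vapply(results, `[[`, numeric(1), "se"),
                      stringsAsFactors = FALSE)
  }
  w <- 1 / (tab$se^2 + meta$tau2)
  tab$ci_low <- tab$beta - 1.96 * tab$se
  tab$ci_high <- tab$beta + 1.96 * tab$se
  tab$weight_pct <- 100 * w / sum(w)
  pooled <- data.frame(cohort = sprintf("pooled (%s)", meta$model),
                       beta = meta$pooled_beta, se = meta$pooled_se,
                       ci_low = meta$pooled_beta - 1.96 * meta$pooled_se,
                       ci_high = meta$pooled_beta + 1.96 * meta$pooled_se,
                       weight_pct = 100, stringsAsFactors = FALSE)
  out <- rbind(tab, pooled)
  rownames(out) <- NULL
  out
}
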