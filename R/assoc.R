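#' Logistic PRS association with covariates
#'
#' Maximum-likelihood logistic regression of case status on the normalised
#' PRS with an intercept and optional covariates (conventionally sex and the
#' top four PCs). Reports the PRS log-odds per SD with Wald statistics and
#' Nagelkerke pseudo-R2 relative to the covariates-only null model.
#' Quasi-complete separation and rank-deficient designs raise errors.
#'
#' @param y binary outcome (0/1, logical, or "case"/"control").
#' @param prs_z numeric PRS per sample (normalised scale).
#' @param covariates optional data.frame or matrix of numeric covariates
#'   (e.g. sex and PCs). Unknown sex (0/NA under the pedigree convention)
#'   should be mean-coded by the caller via [code_sex()].
#' @return list of class `assoc_result`: `beta`, `se`, `z`, `p`,
#'   `r2_nagelkerke`, `n_cases`, `n_controls`, `covariate_names`,
#'   `loglik_full`, `loglik_null`.
#' @export
fit_logistic <- function(y, prs_z, covariates = NULL) {
  if (is.character(y) || is.factor(y)) y <- as.character(y) == "case"
  y <- as.numeric(y)
  stopifnot(all(y %in% c(0, 1)), length(y) == length(prs_z))
  if (length(unique(y)) < 2)
    stop("both outcome classes must be present")
  df <- data.frame(y = y, prs = prs_z)
  cov_names <- character(0)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    stopifnot(nrow(covariates) == length(y))
    cov_names <- names(covariates)
    df <- cbind(df, covariates)
  }
  x <- model.matrix(~ ., data = df[, -1, drop = FALSE])
  qr_x <- qr(x)
  if (qr_x$rank < ncol(x)) {
    dropped <- colnames(x)[qr_x$pivot[(qr_x$rank + 1):ncol(x)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  fit <- suppressWarnings(
    glm(y ~ ., data = df, family = binomial(),
        control = glm.control(epsilon = 1e-10, maxit = 100)))
  mu <- fit$fitted.values
  if (any(mu < 1e-8 | mu > 1 - 1e-8) && any(abs(coef(fit)) > 15))
    stop("quasi-complete separation: fitted probabilities pinned at 0/1 ",
         "with diverging coefficients")
  beta <- unname(coef(fit)["prs"])
  se <- sqrt(vcov(fit)["prs", "prs"])
  zst <- beta / se
  null_fit <- if (length(cov_names))
    glm(y ~ ., data = df[, c("y", cov_names), drop = FALSE],
        family = binomial(),
        control = glm.control(epsilon = 1e-10, maxit = 100))
  else glm(y ~ 1, data = df, family = binomial(),
           control = glm.control(epsilon = 1e-10, maxit = 100))
  ll_full <- as.numeric(logLik(fit))
  ll_null <- as.numeric(logLik(null_fit))
  structure(list(beta = beta, se = se, z = zst,
                 p = 2 * pnorm(-abs(zst)),
                 r2_nagelkerke = nagelkerke_r2(ll_full, ll_null, length(y)),
                 n_cases = sum(y == 1), n_controls = sum(y == 0),
                 covariate_names = cov_names,
                 loglik_full = ll_full, loglik_null = ll_null),
            class = "assoc_result")
}

#' @method print assoc_result
#' @export
print.assoc_result <- function(x, ...) {
  cat(sprintf("PRS association: beta = %.4f (se %.4f), z = %.2f, p = %.3g\n",
              x$beta, x$se, x$z, x$p))
  cat(sprintf("Nagelkerke R2 = %.4f; %d cases / %d controls\n",
              x$r2_nagelkerke, x$n_cases, x$n_controls))
  invisible(x)
}

#' Nagelkerke pseudo-R-squared
#'
#' Cox-Snell `R2_CS = 1 - exp(2 (ll_null - ll_full) / n)`, rescaled by its
#' maximum `1 - exp(2 ll_null / n)` and clipped to \[0, 1\].
#'
#' @param loglik_full,loglik_null log-likelihoods of the full and null
#'   models (`loglik_full >= loglik_null`).
#' @param n sample size.
#' @return Nagelkerke R2 in \[0, 1\].
#' @export
nagelkerke_r2 <- function(loglik_full, loglik_null, n) {
  stopifnot(n >= 1)
  if (loglik_full < loglik_null - 1e-8)
    stop("full-model log-likelihood below null-model log-likelihood")
  if (loglik_null == 0)
    stop("null log-likelihood of 0 leaves Nagelkerke R2 undefined")
  r2_cs <- 1 - exp(2 * (loglik_null - loglik_full) / n)
  r2 <- r2_cs / (1 - exp(2 * loglik_null / n))
  min(1, max(0, r2))
}

#' Numeric sex covariate from pedigree coding
#'
#' Sex 1/2 passes through as numeric; 0/NA (unknown) is replaced by the mean
#' of the known values, with a warning.
#'
#' @param sex integer vector coded 1 (male), 2 (female), 0/NA (unknown).
#' @return numeric vector.
#' @export
code_sex <- function(sex) {
  sex <- as.numeric(sex)
  unknown <- is.na(sex) | sex == 0
  if (any(unknown)) {
    warning(sum(unknown), " sample(s) with unknown sex mean-coded")
    sex[unknown] <- mean(sex[!unknown])
  }
  sex
}

#' Three-group pairwise PRS comparison
#'
#' Pairwise covariate-adjusted logistic fits between controls,
#' screen-positive cases and screen-negative cases, with Bonferroni
#' adjustment over the three contrasts. Orientation is fixed so that a
#' positive log-odds means elevated PRS in cases relative to controls
#' (contrasts `control_vs_pos`, `control_vs_neg`) and in screen-positive
#' relative to screen-negative cases (`pos_vs_neg`). A failing contrast is
#' reported with its error message and does not abort the others.
#'
#' @param prs_z numeric PRS per sample.
#' @param groups character vector in
#'   `{"control", "screen_pos", "screen_neg"}`.
#' @param covariates optional covariate data.frame aligned with `prs_z`.
#' @return data.frame of class `pairwise_comparison`: one row per contrast
#'   with `contrast`, `beta`, `se`, `z`, `p`, `p_adj`, `n0`, `n1`, `error`.
#' @export
pairwise_group_comparison <- function(prs_z, groups, covariates = NULL) {
  stopifnot(length(prs_z) == length(groups))
  valid <- c("control", "screen_pos", "screen_neg")
  if (!all(groups %in% valid))
    stop("groups must be one of: ", paste(valid, collapse = ", "))
  contrasts <- list(control_vs_pos = c("control", "screen_pos"),
                    control_vs_neg = c("control", "screen_neg"),
                    pos_vs_neg = c("screen_neg", "screen_pos"))
  rows <- lapply(names(contrasts), function(nm) {
    pair <- contrasts[[nm]]
    sel <- groups %in% pair
    res <- tryCatch({
      if (!all(pair %in% groups[sel]))
        stop("empty group in contrast ", nm, ": ",
             paste(setdiff(pair, groups[sel]), collapse = ", "))
      y <- as.numeric(groups[sel] == pair[2])  # later-listed group coded 1
      cov_sub <- if (is.null(covariates)) NULL
        else as.data.frame(covariates)[sel, , drop = FALSE]
      fit_logistic(y, prs_z[sel], cov_sub)
    }, error = function(e) e)
    if (inherits(res, "error"))
      data.frame(contrast = nm, beta = NA_real_, se = NA_real_, z = NA_real_,
                 p = NA_real_, p_adj = NA_real_, n0 = NA_integer_,
                 n1 = NA_integer_, error = conditionMessage(res),
                 stringsAsFactors = FALSE)
    else
      data.frame(contrast = nm, beta = res$beta, se = res$se, z = res$z,
                 p = res$p, p_adj = NA_real_, n0 = res$n_controls,
                 n1 = res$n_cases, error = NA_character_,
                 stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- pmin(1, out$p * 3)  # Bonferroni over the three contrasts
  class(out) <- c("pairwise_comparison", "data.frame")
  out
}
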