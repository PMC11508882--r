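#' Tidy a fitted logistic risk model
#'
#' @param x A `pgs_logit`.
#' @param exponentiate Report odds ratios instead of log-odds.
#' @param ... Unused.
#' @return A tibble: `term`, `estimate`, `std.error`, `statistic`,
#'   `p.value`.
#' @exportS3Method generics::tidy
#' @export
tidy.pgs_logit <- function(x, exponentiate = FALSE, ...) {
  co <- summary(x$fit)$coefficients
  out <- tibble::tibble(
    term = rownames(co), estimate = co[, "Estimate"],
    std.error = co[, "Std. Error"], statistic = co[, "z value"],
    p.value = co[, "Pr(>|z|)"]
  )
  if (exponentiate) out$estimate <- exp(out$estimate)
  out
}

#' One-row summary of a fitted logistic risk model
#' @param x A `pgs_logit`.
#' @param ... Unused.
#' @return A tibble: `n`, `logLik`, `AIC`, `converged`, `separation`.
#' @exportS3Method generics::glance
#' @export
glance.pgs_logit <- function(x, ...) {
  tibble::tibble(n = x$n, logLik = x$log_lik,
                 AIC = stats::AIC(x$fit),
                 converged = x$converged, separation = x$separation)
}

#' ROC staircase points of a `pgs_roc`
#' @param x A `pgs_roc`.
#' @param ... Unused.
#' @return A tibble of `(fpr, tpr)` points from (0,0) to (1,1).
#' @exportS3Method generics::tidy
#' @export
tidy.pgs_roc <- function(x, ...) x$roc_points

#' One-row AUC summary of a `pgs_roc`
#' @param x A `pgs_roc`.
#' @param ... Unused.
#' @return A tibble: `auc`, `ci_low`, `ci_high`, `n_cases`, `n_controls`.
#' @exportS3Method generics::glance
#' @export
glance.pgs_roc <- function(x, ...) {
  tibble::tibble(auc = x$auc, ci_low = x$ci_low, ci_high = x$ci_high,
                 n_cases = x$n_cases, n_controls = x$n_controls)
}

#' Model comparison table of a `pgs_model_suite`
#' @param x A `pgs_model_suite`.
#' @param ... Unused.
#' @return The comparison tibble (one row per fitted model).
#' @exportS3Method generics::tidy
#' @export
tidy.pgs_model_suite <- function(x, ...) x$comparison

#' One-row summary of a `pgs_model_suite`
#' @param x A `pgs_model_suite`.
#' @param ... Unused.
#' @return A tibble with the best combined model and its DeLong p-value.
#' @exportS3Method generics::glance
#' @export
glance.pgs_model_suite <- function(x, ...) {
  comb <- x$comparison[x$comparison$model == "combined", ]
  best <- comb[which.max(comb$auc), ]
  tibble::tibble(n_scores = sum(x$comparison$model == "pgs_only"),
                 best_pgs = best$pgs_id, best_auc = best$auc,
                 best_delong_p = best$delong_p,
                 covariates = paste(x$selected_covariates, collapse = ","))
}

#' Match table of a harmonization result
#' @param x A `pgs_match`.
#' @param ... Unused.
#' @return The matches tibble (`geno_col`, `identifier`, `weight`,
#'   `effect_is_alt`).
#' @exportS3Method generics::tidy
#' @export
tidy.pgs_match <- function(x, ...) x$matches

#' Coverage report of a harmonization result
#' @param x A `pgs_match`.
#' @param ... Unused.
#' @return The one-row `harmonization_report` tibble.
#' @exportS3Method generics::glance
#' @export
glance.pgs_match <- function(x, ...) x$report
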