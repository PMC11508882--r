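#' ROC curve and AUC with DeLong confidence interval
#'
#' The AUC is computed by the Mann-Whitney formulation (probability that a
#' random case outscores a random control, with half credit for ties) via
#' midranks. Its variance uses DeLong's placement-value estimator:
#' `var = var(V10)/m + var(V01)/n`, where `V10`/`V01` are the case and
#' control placement values. The 95% CI is `auc +/- 1.96 sqrt(var)`,
#' clipped to `[0, 1]`.
#'
#' @param outcome Binary vector (logical, 0/1, or `"case"`/`"control"`);
#'   cases are the positive class.
#' @param score Numeric per-sample score.
#' @return A `pgs_roc` object: list with `auc`, `ci_low`, `ci_high`, `var`,
#'   `n_cases`, `n_controls`, placement values, and `roc_points`, the
#'   (fpr, tpr) staircase from (0,0) to (1,1).
#' @export
roc_auc <- function(outcome, score) {
  y <- as_case_indicator(outcome)
  ok <- !is.na(y) & !is.na(score)
  y <- y[ok]; score <- score[ok]
  m <- sum(y == 1); n <- sum(y == 0)
  if (m == 0 || n == 0) stop("roc_auc: need both cases and controls",
                             call. = FALSE)

  pl <- placement_values(score[y == 1], score[y == 0])
  auc <- mean(pl$v10)
  v <- stats::var(pl$v10) / m + stats::var(pl$v01) / n
  half <- 1.96 * sqrt(max(v, 0))

  x <- score[y == 1]; z <- score[y == 0]
  thr <- sort(unique(score), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(x >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(z >= t), numeric(1))
  roc_points <- tibble::tibble(fpr = c(0, fpr, 1), tpr = c(0, tpr, 1))

  structure(
    list(auc = auc, ci_low = max(0, auc - half), ci_high = min(1, auc + half),
         var = v, n_cases = m, n_controls = n,
         v10 = pl$v10, v01 = pl$v01, roc_points = roc_points),
    class = "pgs_roc"
  )
}

# DeLong placement values via midranks (O((m+n) log(m+n))):
# v10_i = P(control < case_i) + 0.5 P(control == case_i), v01 analogous.
placement_values <- function(x, z) {
  m <- length(x); n <- length(z)
  r_all <- rank(c(x, z), ties.method = "average")
  r_x <- rank(x, ties.method = "average")
  r_z <- rank(z, ties.method = "average")
  v10 <- (r_all[seq_len(m)] - r_x) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - r_z) / m
  list(v10 = v10, v01 = v01)
}

as_case_indicator <- function(outcome) {
  if (is.character(outcome) || is.factor(outcome)) {
    as.numeric(as.character(outcome) == "case")
  } else {
    as.numeric(outcome != 0)
  }
}

#' @export
print.pgs_roc <- function(x, ...) {
  cat(sprintf("<pgs_roc> AUC = %.3f (95%% CI %.3f-%.3f), %d cases / %d controls\n",
              x$auc, x$ci_low, x$ci_high, x$n_cases, x$n_controls))
  invisible(x)
}

#' Paired DeLong test for two correlated AUCs
#'
#' DeLong's (1988) comparison of two ROC areas measured on the same
#' samples: per-sample placement values for each score give a 2x2
#' covariance of the AUC estimates;
#' `z = (auc_a - auc_b) / sqrt(var_a + var_b - 2 cov)`, two-sided normal
#' p-value. If the variance of the difference vanishes (e.g., identical
#' scores), `z = 0` and `p = 1` by convention.
#'
#' @param outcome Binary outcome shared by both scores.
#' @param score_a,score_b Numeric scores on the same samples.
#' @return A one-row `delong_test` tibble: `auc_a`, `auc_b`, `delta`,
#'   `z_statistic`, `p_value`, `n_cases`, `n_controls`.
#' @export
delong_paired_test <- function(outcome, score_a, score_b) {
  y <- as_case_indicator(outcome)
  ok <- !is.na(y) & !is.na(score_a) & !is.na(score_b)
  y <- y[ok]; score_a <- score_a[ok]; score_b <- score_b[ok]
  m <- sum(y == 1); n <- sum(y == 0)
  if (m == 0 || n == 0) stop("delong_paired_test: need both classes",
                             call. = FALSE)

  pa <- placement_values(score_a[y == 1], score_a[y == 0])
  pb <- placement_values(score_b[y == 1], score_b[y == 0])
  auc_a <- mean(pa$v10); auc_b <- mean(pb$v10)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  var_delta <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n

  delta <- auc_a - auc_b
  if (!is.finite(var_delta) || var_delta <= .Machine$double.eps) {
    z <- 0; p <- 1
  } else {
    z <- delta / sqrt(var_delta)
    p <- 2 * stats::pnorm(-abs(z))
  }
  out <- tibble::tibble(auc_a = auc_a, auc_b = auc_b, delta = delta,
                        z_statistic = z, p_value = p,
                        n_cases = m, n_controls = n)
  class(out) <- c("delong_test", class(out))
  out
}
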