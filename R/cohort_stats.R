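#' Two-sample Kolmogorov-Smirnov test
#'
#' Wraps [stats::ks.test()] with the convention used throughout the package:
#' the exact small-sample p-value when `n_a * n_b <= 10000`, the asymptotic
#' Kolmogorov distribution otherwise. Ties force the asymptotic path (the
#' exact distribution assumes continuity).
#'
#' @param a,b Numeric vectors (both non-empty).
#' @return A one-row tibble: `statistic` (sup-norm ECDF distance),
#'   `p_value`, `n_a`, `n_b`, `method`.
#' @export
ks_two_sample <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) == 0L || length(b) == 0L) {
    stop("ks_two_sample: empty group", call. = FALSE)
  }
  exact <- as.double(length(a)) * length(b) <= 10000 &&
    !anyDuplicated(c(a, b))
  res <- suppressWarnings(stats::ks.test(a, b, exact = exact))
  tibble::tibble(
    statistic = unname(res$statistic), p_value = res$p.value,
    n_a = length(a), n_b = length(b),
    method = if (exact) "ks_exact" else "ks_asymptotic"
  )
}

#' Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Two-sided normal approximation with midrank ties, tie correction and
#' continuity correction, via [stats::wilcox.test()]. `statistic` is the U
#' statistic for group `a`.
#'
#' @param a,b Numeric vectors (both non-empty).
#' @return A one-row tibble: `statistic`, `p_value`, `n_a`, `n_b`, `method`.
#' @export
mann_whitney <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) == 0L || length(b) == 0L) {
    stop("mann_whitney: empty group", call. = FALSE)
  }
  res <- suppressWarnings(
    stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)
  )
  tibble::tibble(
    statistic = unname(res$statistic), p_value = res$p.value,
    n_a = length(a), n_b = length(b), method = "mann_whitney_normal"
  )
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided p-value by the probability-mass method (the sum of
#' hypergeometric probabilities no larger than the observed table's), via
#' [stats::fisher.test()]. The reported `statistic` is the sample
#' cross-product (ad/bc) odds ratio.
#'
#' @param tab A 2x2 matrix of non-negative integer counts with all margins
#'   positive.
#' @return A one-row tibble: `statistic` (cross-product OR), `p_value`,
#'   `n_a`, `n_b` (row totals), `method`.
#' @export
fisher_exact <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(2L, 2L)), all(tab >= 0),
            all(tab == round(tab)))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("fisher_exact: zero margin", call. = FALSE)
  }
  res <- stats::fisher.test(tab)
  tibble::tibble(
    statistic = (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1]),
    p_value = res$p.value,
    n_a = sum(tab[1, ]), n_b = sum(tab[2, ]),
    method = "fisher_exact"
  )
}

# covariates the correlation screen and summary work over, with their types
cohort_covariates <- function() {
  list(
    continuous = c("age", "bmi", "total_chol", "hdl", "ldl",
                   "triglycerides", "glycaemia", "pas", "pad"),
    binary = c("sex", "diabetes", "hypertension", "hypercholesterolemia"),
    ordinal = c("smoking")
  )
}

encode_covariate <- function(x, name) {
  if (name == "sex") return(as.numeric(x == "M"))
  if (name == "smoking") {
    return(c(no = 0, former = 1, yes = 2)[as.character(x)])
  }
  if (is.character(x) || is.factor(x)) return(as.numeric(x == "yes"))
  as.numeric(x)
}

#' Screen score-covariate correlations
#'
#' Pearson correlation of a per-sample score against every cohort covariate,
#' on pairwise-complete observations. Binary covariates are encoded 0/1
#' (sex: F=0, M=1; yes/no: no=0, yes=1) and smoking as the ordinal
#' no=0, former=1, yes=2. A covariate is flagged when `|r|` strictly exceeds
#' `threshold`.
#'
#' @param scores Numeric per-sample score vector aligned to `cohort` rows.
#' @param cohort A cohort tibble (see [simulate_phenotypes()] for the
#'   column convention).
#' @param threshold Flagging threshold on `|r|` (default 0.75).
#' @return A tibble: `covariate`, `r`, `n`, `flagged`.
#' @export
correlation_screen <- function(scores, cohort, threshold = 0.75) {
  stopifnot(length(scores) == nrow(cohort))
  vars <- cohort_covariates()
  covs <- intersect(unlist(vars), names(cohort))
  purrr::map_dfr(covs, function(v) {
    x <- encode_covariate(cohort[[v]], v)
    ok <- !is.na(x) & !is.na(scores)
    n <- sum(ok)
    r <- if (n >= 3 && stats::sd(x[ok]) > 0 && stats::sd(scores[ok]) > 0) {
      stats::cor(scores[ok], x[ok])
    } else {
      NA_real_
    }
    tibble::tibble(covariate = v, r = r, n = n,
                   flagged = !is.na(r) && abs(r) > threshold)
  })
}

#' Percentile-threshold odds ratio
#'
#' Logistic regression of case status on the indicator that a sample's score
#' lies strictly above the q-th percentile, the reference being everyone at
#' or below it, optionally adjusted for covariates (default: age, sex, BMI).
#' The OR is `exp` of the indicator coefficient; the 95% CI is Wald on the
#' log-odds scale (asymmetric on the OR scale), with a profile-likelihood
#' option.
#'
#' @param scores Numeric per-sample raw scores aligned to `cohort` rows.
#' @param cohort Cohort tibble with a `status` column (`"case"`/`"control"`).
#' @param q Percentile threshold in (0, 1); default 0.8.
#' @param adjust Character vector of adjustment covariates; `character(0)`
#'   for the unadjusted OR.
#' @param percentile_basis `"cohort"` ranks over everyone; `"controls"` sets
#'   the cut from the control distribution.
#' @param ci `"wald"` (default) or `"profile"`.
#' @return A one-row `percentile_or` tibble: `q`, `odds_ratio`, `ci_low`,
#'   `ci_high`, `p_value`, `n_above`, `n_below`, `n`, `separation`,
#'   `adjusted_for`.
#' @export
percentile_or <- function(scores, cohort, q = 0.8,
                          adjust = c("age", "sex", "bmi"),
                          percentile_basis = c("cohort", "controls"),
                          ci = c("wald", "profile")) {
  stopifnot(length(scores) == nrow(cohort), q > 0, q < 1)
  percentile_basis <- match.arg(percentile_basis)
  ci <- match.arg(ci)

  if (percentile_basis == "controls") {
    ctrl <- scores[cohort$status == "control"]
    pct <- vapply(scores, function(x) mean(ctrl <= x), numeric(1))
  } else {
    pct <- score_percentiles(scores)
  }
  above <- pct > q

  dat <- tibble::tibble(
    y = as.numeric(cohort$status == "case"),
    above = as.numeric(above)
  )
  for (v in adjust) dat[[v]] <- encode_covariate(cohort[[v]], v)
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]

  tab <- table(factor(dat$above, levels = c(1, 0)),
               factor(dat$y, levels = c(1, 0)))
  sep <- any(tab == 0)

  out <- tibble::tibble(
    q = q, odds_ratio = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
    p_value = NA_real_, n_above = sum(dat$above == 1),
    n_below = sum(dat$above == 0), n = nrow(dat),
    separation = sep,
    adjusted_for = paste(adjust, collapse = ",")
  )

  if (sep) {
    direction <- if (tab[1, 2] == 0 || tab[2, 1] == 0) "inf" else "zero"
    out$odds_ratio <- if (direction == "inf") Inf else 0
    warning("percentile_or: complete separation at q = ", q,
            "; OR non-estimable (direction: ", direction, ")")
    class(out) <- c("percentile_or", class(out))
    return(out)
  }

  fit <- stats::glm(y ~ ., data = dat, family = stats::binomial(),
                    control = stats::glm.control(epsilon = 1e-12,
                                                 maxit = 100))
  co <- summary(fit)$coefficients["above", ]
  out$odds_ratio <- exp(co[["Estimate"]])
  out$p_value <- co[["Pr(>|z|)"]]
  if (ci == "wald") {
    out$ci_low <- exp(co[["Estimate"]] - 1.96 * co[["Std. Error"]])
    out$ci_high <- exp(co[["Estimate"]] + 1.96 * co[["Std. Error"]])
  } else {
    pr <- suppressMessages(stats::confint(fit, parm = "above", level = 0.95))
    out$ci_low <- exp(pr[[1L]]); out$ci_high <- exp(pr[[2L]])
  }
  class(out) <- c("percentile_or", class(out))
  out
}

#' Percentile odds ratios over a threshold grid
#'
#' @inheritParams percentile_or
#' @param qs Vector of percentile thresholds (default 0.80, 0.90, 0.95).
#' @return A `percentile_or` tibble with one row per threshold.
#' @export
percentile_or_table <- function(scores, cohort, qs = c(0.8, 0.9, 0.95),
                                adjust = c("age", "sex", "bmi"), ...) {
  purrr::map_dfr(qs, function(q)
    percentile_or(scores, cohort, q = q, adjust = adjust, ...))
}

#' Cohort summary table
#'
#' A study-description table: per continuous variable the mean (SD) by group
#' with a Mann-Whitney p-value; per binary variable counts by group with a
#' Fisher p-value; smoking as yes-vs-no and former-vs-no Fisher tests with
#' "no" as the reference level. The analyzed n (non-missing in both groups)
#' is reported per row, since per-variable missingness changes the
#' denominators of the categorical tests.
#'
#' @param cohort Cohort tibble with `status` plus any subset of the standard
#'   covariates.
#' @return A tibble: `variable`, `level`, `type`, `case`, `control`
#'   (formatted summaries), `n_case`, `n_control`, `p_value`, `test`.
#' @export
summarize_cohort <- function(cohort) {
  stopifnot("status" %in% names(cohort))
  is_case <- cohort$status == "case"
  vars <- cohort_covariates()
  rows <- list()

  fmt <- function(x) sprintf("%.1f (±%.1f)", mean(x), stats::sd(x))
  for (v in intersect(vars$continuous, names(cohort))) {
    x <- cohort[[v]]
    ok <- !is.na(x)
    a <- x[ok & is_case]; b <- x[ok & !is_case]
    p <- if (length(a) && length(b)) mann_whitney(a, b)$p_value else NA_real_
    rows[[length(rows) + 1L]] <- tibble::tibble(
      variable = v, level = NA_character_, type = "continuous",
      case = fmt(a), control = fmt(b),
      n_case = length(a), n_control = length(b),
      p_value = p, test = "mann_whitney"
    )
  }

  for (v in intersect(vars$binary, names(cohort))) {
    x <- cohort[[v]]
    ok <- !is.na(x)
    pos_level <- if (v == "sex") "M" else "yes"
    tab <- rbind(
      c(sum(x[ok & is_case] == pos_level), sum(x[ok & !is_case] == pos_level)),
      c(sum(x[ok & is_case] != pos_level), sum(x[ok & !is_case] != pos_level))
    )
    p <- if (all(rowSums(tab) > 0) && all(colSums(tab) > 0)) {
      fisher_exact(tab)$p_value
    } else {
      NA_real_
    }
    rows[[length(rows) + 1L]] <- tibble::tibble(
      variable = v, level = pos_level, type = "binary",
      case = as.character(tab[1, 1]), control = as.character(tab[1, 2]),
      n_case = sum(ok & is_case), n_control = sum(ok & !is_case),
      p_value = p, test = "fisher_exact"
    )
  }

  if ("smoking" %in% names(cohort)) {
    x <- cohort$smoking
    ok <- !is.na(x)
    for (lev in c("yes", "former")) {
      tab <- rbind(
        c(sum(x[ok & is_case] == lev), sum(x[ok & !is_case] == lev)),
        c(sum(x[ok & is_case] == "no"), sum(x[ok & !is_case] == "no"))
      )
      p <- if (all(rowSums(tab) > 0) && all(colSums(tab) > 0)) {
        fisher_exact(tab)$p_value
      } else {
        NA_real_
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        variable = "smoking", level = paste0(lev, "_vs_no"),
        type = "categorical",
        case = as.character(tab[1, 1]), control = as.character(tab[1, 2]),
        n_case = sum(ok & is_case), n_control = sum(ok & !is_case),
        p_value = p, test = "fisher_exact"
      )
    }
  }

  dplyr::bind_rows(rows)
}
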