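#' Compute per-sample raw polygenic scores
#'
#' The score is the weighted sum of effect-allele dosages,
#' `score_j = sum_i w_i * d*_ij`, where `d*` is the orientation-resolved
#' dosage (`d` when the effect allele is ALT, `2 - d` when it is REF).
#'
#' @param match A `pgs_match` from [harmonize()].
#' @param geno The `genotype_matrix` the match was built against.
#' @param missing_policy How to treat missing dosages: `"mean_impute"`
#'   (default) substitutes the variant's sample-mean dosage, keeping scores
#'   comparable across samples with unequal missingness; `"omit"` drops the
#'   term for that sample.
#' @return A tibble with columns `sample_id` and `raw`.
#' @export
compute_prs <- function(match, geno,
                        missing_policy = c("mean_impute", "omit")) {
  stopifnot(inherits(match, "pgs_match"), inherits(geno, "genotype_matrix"))
  missing_policy <- match.arg(missing_policy)
  m <- match$matches
  if (nrow(m) == 0L) {
    stop("empty match table: score undefined", call. = FALSE)
  }
  stopifnot(all(m$geno_col >= 1L), all(m$geno_col <= ncol(geno$dosage)))

  d <- geno$dosage[, m$geno_col, drop = FALSE]
  flip <- !m$effect_is_alt
  if (any(flip)) d[, flip] <- 2 - d[, flip, drop = FALSE]

  if (anyNA(d)) {
    if (missing_policy == "mean_impute") {
      mu <- colMeans(d, na.rm = TRUE)
      mu[is.nan(mu)] <- 0  # variant missing in every sample
      idx <- which(is.na(d), arr.ind = TRUE)
      d[idx] <- mu[idx[, 2L]]
    } else {
      d[is.na(d)] <- 0
    }
  }

  tibble::tibble(sample_id = geno$sample_ids, raw = as.vector(d %*% m$weight))
}

#' Standardize raw scores against a reference set
#'
#' `z = (raw - mean_ref) / sd_ref`, with the sample (n-1) standard
#' deviation. Explicit `center`/`scale` override the reference — useful when
#' standardization constants come from a source population rather than the
#' analyzed (e.g., case-control balanced) sample.
#'
#' @param raw Numeric vector of raw scores.
#' @param reference Logical or integer index of the reference samples
#'   (default: all).
#' @param center,scale Optional explicit standardization constants.
#' @return Numeric vector of z-scores.
#' @export
standardize_scores <- function(raw, reference = NULL,
                               center = NULL, scale = NULL) {
  if (is.null(center) != is.null(scale)) {
    stop("supply both center and scale, or neither", call. = FALSE)
  }
  if (is.null(center)) {
    ref <- if (is.null(reference)) raw else raw[reference]
    ref <- ref[!is.na(ref)]
    if (length(ref) < 2L) stop("reference needs >= 2 samples", call. = FALSE)
    center <- mean(ref)
    scale <- stats::sd(ref)
  }
  if (!is.finite(scale) || scale <= 0) {
    stop("zero variance in reference: cannot standardize", call. = FALSE)
  }
  (raw - center) / scale
}

#' Empirical percentile of each score
#'
#' `percentile_j = rank_j / n` with ties sharing their maximum rank, so
#' "above the q-th percentile" is the strict comparison `percentile > q`.
#'
#' @param raw Numeric vector of scores.
#' @return Numeric vector of percentiles in `(0, 1]`.
#' @export
score_percentiles <- function(raw) {
  stopifnot(length(raw) >= 1L)
  rank(raw, ties.method = "max") / length(raw)
}

#' Score a cohort with one scoring file
#'
#' Convenience chain: [harmonize()] then [compute_prs()], plus
#' standardization and percentiles. Percentile thresholds are computed over
#' the full cohort by default; `percentile_basis = "controls"` ranks against
#' the control distribution instead (`status` required in that case).
#'
#' @param score A `scoring_file`.
#' @param geno A `genotype_matrix`.
#' @param status Optional per-sample status vector aligned with
#'   `geno$sample_ids` (`"case"`/`"control"`), needed for the controls-only
#'   percentile basis.
#' @param percentile_basis `"cohort"` (default) or `"controls"`.
#' @inheritParams harmonize
#' @inheritParams compute_prs
#' @return A `pgs_scores` tibble: `sample_id`, `pgs_id`, `raw`, `z`,
#'   `percentile`, with the `harmonization_report` attached as attribute
#'   `"report"`.
#' @export
score_pgs <- function(score, geno, status = NULL,
                      ambiguous_policy = c("drop", "keep"),
                      missing_policy = c("mean_impute", "omit"),
                      percentile_basis = c("cohort", "controls")) {
  percentile_basis <- match.arg(percentile_basis)
  match <- harmonize(score, geno, ambiguous_policy)
  prs <- compute_prs(match, geno, missing_policy)
  prs$pgs_id <- score$pgs_id
  prs$z <- standardize_scores(prs$raw)
  if (percentile_basis == "controls") {
    if (is.null(status)) stop("controls-only percentiles need status",
                              call. = FALSE)
    ctrl <- prs$raw[status == "control"]
    prs$percentile <- vapply(prs$raw, function(x) mean(ctrl <= x), numeric(1))
  } else {
    prs$percentile <- score_percentiles(prs$raw)
  }
  out <- prs[, c("sample_id", "pgs_id", "raw", "z", "percentile")]
  attr(out, "report") <- match$report
  class(out) <- c("pgs_scores", class(out))
  out
}

#' Score a cohort with several scoring files
#'
#' @param scores A list of `scoring_file` objects.
#' @param geno A `genotype_matrix`.
#' @param ... Passed to [score_pgs()].
#' @return A list with `scores` (long tibble over all files) and `coverage`
#'   (one `harmonization_report` row per file). Files with no matchable
#'   variant are skipped with a warning.
#' @export
score_pgs_set <- function(scores, geno, ...) {
  per <- list(); reports <- list()
  for (sf in scores) {
    match <- harmonize(sf, geno)
    reports[[length(reports) + 1L]] <- match$report
    if (nrow(match$matches) == 0L) {
      warning("score ", sf$pgs_id, " has no matchable variants; skipped")
      next
    }
    per[[length(per) + 1L]] <- score_pgs(sf, geno, ...)
  }
  list(scores = dplyr::bind_rows(per), coverage = dplyr::bind_rows(reports))
}
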