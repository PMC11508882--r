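#' Pairwise between-area score distribution tests
#'
#' Kolmogorov-Smirnov test of every score between every unordered pair of
#' subpopulation (macro-area) labels — the between-group block of a
#' stratified transferability table. Raw p-values are reported by default;
#' an optional multiplicity correction is applied per score block when
#' requested.
#'
#' @param data Tibble with one numeric column per score plus a group label
#'   column.
#' @param score_cols Names of the score columns.
#' @param area_col Name of the area label column (default `"macro_area"`).
#' @param min_group Minimum samples per group (default 2); smaller groups
#'   are skipped with a warning.
#' @param p_adjust `"none"` (default), `"bonferroni"` or `"BH"`.
#' @return A `stratified_ks` tibble: `comparison`, `group_a`, `group_b`,
#'   `pgs_id`, `statistic`, `p_value`, `n_a`, `n_b`.
#' @export
pairwise_area_ks <- function(data, score_cols, area_col = "macro_area",
                             min_group = 2,
                             p_adjust = c("none", "bonferroni", "BH")) {
  p_adjust <- match.arg(p_adjust)
  areas <- sort(unique(data[[area_col]]))
  sizes <- table(data[[area_col]])
  small <- names(sizes)[sizes < min_group]
  if (length(small) > 0) {
    warning("skipping groups below min size: ", paste(small, collapse = ", "))
    areas <- setdiff(areas, small)
  }
  if (length(areas) < 2) stop("need >= 2 usable areas", call. = FALSE)

  pairs <- utils::combn(areas, 2, simplify = FALSE)
  out <- purrr::map_dfr(pairs, function(pr) {
    a <- data[data[[area_col]] == pr[[1L]], , drop = FALSE]
    b <- data[data[[area_col]] == pr[[2L]], , drop = FALSE]
    purrr::map_dfr(score_cols, function(sc) {
      res <- ks_two_sample(a[[sc]], b[[sc]])
      tibble::tibble(comparison = "area_pairwise",
                     group_a = pr[[1L]], group_b = pr[[2L]], pgs_id = sc,
                     statistic = res$statistic, p_value = res$p_value,
                     n_a = res$n_a, n_b = res$n_b)
    })
  })
  finish_stratified(out, p_adjust)
}

#' Female-versus-male score distribution tests within each area
#'
#' @inheritParams pairwise_area_ks
#' @param sex_col Name of the sex column (`"F"`/`"M"`).
#' @return A `stratified_ks` tibble; `group_a` is the area, `group_b` the
#'   `"F_vs_M"` contrast, `n_a`/`n_b` the female/male counts.
#' @export
sex_within_area_ks <- function(data, score_cols, sex_col = "sex",
                               area_col = "macro_area", min_group = 2,
                               p_adjust = c("none", "bonferroni", "BH")) {
  p_adjust <- match.arg(p_adjust)
  two_group_within_area(data, score_cols, area_col,
                        split_var = sex_col, level_a = "F", level_b = "M",
                        comparison = "sex_within_area", min_group,
                        p_adjust)
}

#' Case-versus-control score distribution tests within each area
#'
#' @inheritParams pairwise_area_ks
#' @param status_col Name of the status column (`"case"`/`"control"`).
#' @return A `stratified_ks` tibble; `n_a`/`n_b` are case/control counts.
#' @export
case_control_within_area <- function(data, score_cols,
                                     status_col = "status",
                                     area_col = "macro_area", min_group = 2,
                                     p_adjust = c("none", "bonferroni", "BH")) {
  p_adjust <- match.arg(p_adjust)
  two_group_within_area(data, score_cols, area_col,
                        split_var = status_col, level_a = "case",
                        level_b = "control",
                        comparison = "case_control_within_area", min_group,
                        p_adjust)
}

two_group_within_area <- function(data, score_cols, area_col, split_var,
                                  level_a, level_b, comparison, min_group,
                                  p_adjust) {
  areas <- sort(unique(data[[area_col]]))
  out <- purrr::map_dfr(areas, function(ar) {
    d <- data[data[[area_col]] == ar, , drop = FALSE]
    a <- d[d[[split_var]] == level_a, , drop = FALSE]
    b <- d[d[[split_var]] == level_b, , drop = FALSE]
    if (nrow(a) < min_group || nrow(b) < min_group) {
      warning("area ", ar, " skipped: group below ", min_group, " samples")
      return(NULL)
    }
    purrr::map_dfr(score_cols, function(sc) {
      res <- ks_two_sample(a[[sc]], b[[sc]])
      tibble::tibble(comparison = comparison, group_a = ar,
                     group_b = paste0(level_a, "_vs_", level_b), pgs_id = sc,
                     statistic = res$statistic, p_value = res$p_value,
                     n_a = res$n_a, n_b = res$n_b)
    })
  })
  finish_stratified(out, p_adjust)
}

finish_stratified <- function(out, p_adjust) {
  if (p_adjust != "none" && nrow(out) > 0) {
    out <- out |>
      dplyr::group_by(.data$pgs_id) |>
      dplyr::mutate(p_value = stats::p.adjust(.data$p_value,
                                              method = p_adjust)) |>
      dplyr::ungroup()
  }
  class(out) <- c("stratified_ks", class(out))
  out
}

#' Reshape a stratified test table to the wide (pairs x scores) layout
#'
#' @param x A `stratified_ks` tibble.
#' @return A wide tibble: one row per comparison, one p-value column per
#'   score.
#' @export
ks_matrix_wide <- function(x) {
  x |>
    dplyr::mutate(contrast = ifelse(
      .data$comparison == "area_pairwise",
      paste(.data$group_a, "vs.", .data$group_b),
      sprintf("%s (%d vs. %d)", .data$group_a, .data$n_a, .data$n_b))) |>
    dplyr::select("comparison", "contrast", "pgs_id", "p_value") |>
    tidyr::pivot_wider(names_from = "pgs_id", values_from = "p_value")
}

#' Per-area discrimination of each score
#'
#' [roc_auc()] of every score within every area. Areas lacking either class
#' (or below `min_group` in either class) are skipped with a warning; small
#' areas legitimately produce wide DeLong intervals.
#'
#' @inheritParams case_control_within_area
#' @param min_group Minimum cases and controls per area (default 1).
#' @return A tibble: `macro_area`, `pgs_id`, `auc`, `ci_low`, `ci_high`,
#'   `n_cases`, `n_controls`.
#' @export
auc_by_area <- function(data, score_cols, status_col = "status",
                        area_col = "macro_area", min_group = 1) {
  areas <- sort(unique(data[[area_col]]))
  purrr::map_dfr(areas, function(ar) {
    d <- data[data[[area_col]] == ar, , drop = FALSE]
    y <- as_case_indicator(d[[status_col]])
    if (sum(y == 1) < min_group || sum(y == 0) < min_group) {
      warning("area ", ar, " skipped: needs both classes")
      return(NULL)
    }
    purrr::map_dfr(score_cols, function(sc) {
      r <- roc_auc(d[[status_col]], d[[sc]])
      tibble::tibble(macro_area = ar, pgs_id = sc, auc = r$auc,
                     ci_low = r$ci_low, ci_high = r$ci_high,
                     n_cases = r$n_cases, n_controls = r$n_controls)
    })
  })
}
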