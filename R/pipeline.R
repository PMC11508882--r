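#' Assemble a pipeline run configuration
#'
#' Collects every threshold of the evaluation protocol as a named,
#' defaulted key: imputation quality and call-rate cuts, the
#' score-covariate correlation flag threshold, the percentile grid for
#' stratified odds ratios, and the model-building geometry. Exactly one of
#' `input` (paths to a VCF, scoring files and a covariate table) or
#' `simulation` (a [sim_config()]) must be supplied; the default simulates.
#'
#' @param input `NULL`, or a list with `vcf`, `scoring_files` (character
#'   vector of paths) and `covariates` (TSV path with the cohort columns).
#' @param simulation `NULL`, or a [sim_config()].
#' @param rsq_min Imputation-quality cut at load (default 0.6).
#' @param call_rate_min Variant call-rate cut (default 0.95).
#' @param correlation_threshold Flag threshold for the covariate screen
#'   (default 0.75).
#' @param percentiles Percentile-OR thresholds (default 0.80/0.90/0.95).
#' @param adjust Adjustment covariates for the percentile ORs.
#' @param split_fraction,cv_folds,cv_repeats Model protocol geometry
#'   (defaults 0.8, 10, 10).
#' @param boruta_iterations,alpha Boruta knobs.
#' @param seed Run-level seed.
#' @return A validated `run_config` list.
#' @export
run_config <- function(input = NULL, simulation = NULL,
                       rsq_min = 0.6, call_rate_min = 0.95,
                       correlation_threshold = 0.75,
                       percentiles = c(0.8, 0.9, 0.95),
                       adjust = c("age", "sex", "bmi"),
                       split_fraction = 0.8, cv_folds = 10, cv_repeats = 10,
                       boruta_iterations = 50, alpha = 0.01, seed = 1) {
  if (is.null(input) && is.null(simulation)) simulation <- sim_config(seed = seed)
  if (!is.null(input) && !is.null(simulation)) {
    stop("run_config: supply exactly one of 'input' or 'simulation'",
         call. = FALSE)
  }
  if (!is.null(input)) {
    stopifnot(is.list(input),
              all(c("vcf", "scoring_files", "covariates") %in% names(input)))
  }
  check_range <- function(x, field, lo, hi) {
    if (any(x < lo | x > hi)) {
      stop("run_config field '", field, "' outside [", lo, ", ", hi, "]",
           call. = FALSE)
    }
  }
  check_range(rsq_min, "rsq_min", 0, 1)
  check_range(call_rate_min, "call_rate_min", 0, 1)
  check_range(correlation_threshold, "correlation_threshold", 0, 1)
  check_range(percentiles, "percentiles", 1e-6, 1 - 1e-6)
  check_range(split_fraction, "split_fraction", 1e-6, 1 - 1e-6)
  structure(
    list(input = input, simulation = simulation, rsq_min = rsq_min,
         call_rate_min = call_rate_min,
         correlation_threshold = correlation_threshold,
         percentiles = percentiles, adjust = adjust,
         split_fraction = split_fraction, cv_folds = cv_folds,
         cv_repeats = cv_repeats, boruta_iterations = boruta_iterations,
         alpha = alpha, seed = seed),
    class = "run_config"
  )
}

#' Read a run configuration from a YAML file
#'
#' The file mirrors [run_config()]'s arguments as top-level keys; an
#' optional `simulation` block mirrors [sim_config()]'s arguments. Every
#' omitted key keeps its default, so the protocol's standard thresholds
#' apply unless overridden.
#'
#' @param path Path to a YAML document.
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$simulation)) {
    sim_args <- raw$simulation
    for (f in c("n_per_area", "fst", "covariate_effects")) {
      if (!is.null(sim_args[[f]])) sim_args[[f]] <- unlist(sim_args[[f]])
    }
    raw$simulation <- do.call(sim_config, sim_args)
  }
  do.call(run_config, raw)
}

# reproducibility header written at the top of every pipeline output file
output_header <- function(config) {
  c(paste0("# pgseval ", as.character(utils::packageVersion("pgseval"))),
    paste0("# seed=", config$seed),
    paste0("# config_hash=", rlang::hash(unclass(config))),
    paste0("# created=", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")))
}

write_output_tsv <- function(x, path, config) {
  writeLines(output_header(config), path)
  readr::write_tsv(x, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Write a synthetic fixture set (pipeline entry point)
#'
#' Thin wrapper over [write_fixture_set()] driven by a [run_config()];
#' prints the manifest path.
#'
#' @param config A `run_config` whose `simulation` block is set.
#' @param outdir Output directory.
#' @return The manifest list, invisibly.
#' @export
run_simulate <- function(config, outdir) {
  stopifnot(inherits(config, "run_config"), !is.null(config$simulation))
  manifest <- write_fixture_set(outdir, config$simulation)
  message("manifest: ", manifest$path)
  invisible(manifest)
}

# load (or simulate) the inputs a run works on
assemble_inputs <- function(config) {
  if (!is.null(config$input)) {
    geno <- read_genotypes(config$input$vcf, rsq_min = config$rsq_min)
    geno <- variant_qc(geno, call_rate_min = config$call_rate_min)
    scoring_files <- lapply(config$input$scoring_files, read_scoring_file)
    names(scoring_files) <- vapply(scoring_files, `[[`, character(1), "pgs_id")
    cohort <- readr::read_tsv(config$input$covariates,
                              show_col_types = FALSE)
    list(geno = geno, scoring_files = scoring_files, cohort = cohort)
  } else {
    sim <- simulate_cohort(config$simulation)
    sim
  }
}

#' Score a cohort against every configured scoring file
#'
#' Chains read, QC, harmonization, score computation, standardization and
#' percentiles for each scoring file; writes one per-sample score TSV per
#' score plus a combined coverage TSV when `outdir` is given. Scores with
#' no matchable variants are skipped with a warning, not an error.
#'
#' @param config A [run_config()].
#' @param outdir Optional output directory for TSVs.
#' @return A list: `scores` (long tibble: `sample_id`, `pgs_id`, `raw`,
#'   `z`, `percentile`), `coverage` (one harmonization row per file).
#' @export
run_score <- function(config, outdir = NULL) {
  stopifnot(inherits(config, "run_config"))
  inp <- assemble_inputs(config)
  res <- score_pgs_set(inp$scoring_files, inp$geno)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    for (id in unique(res$scores$pgs_id)) {
      write_output_tsv(res$scores[res$scores$pgs_id == id, ],
                       file.path(outdir, paste0("scores_", id, ".tsv")),
                       config)
    }
    write_output_tsv(res$coverage, file.path(outdir, "coverage.tsv"), config)
  }
  c(res, list(geno = inp$geno, cohort = inp$cohort))
}

#' Run the full evaluation protocol
#'
#' Computes, per score: case-versus-control Kolmogorov-Smirnov and
#' Mann-Whitney tests, the covariate correlation screen, and
#' percentile-threshold adjusted odds ratios; then the three-model
#' predictive suite with Boruta selection and DeLong comparisons; and the
#' stratified blocks (pairwise-area KS, sex-within-area KS,
#' case-control-within-area KS, per-area AUC). Writes one TSV per table
#' when `outdir` is given, each with a reproducibility comment header.
#'
#' @param config A [run_config()].
#' @param outdir Optional output directory.
#' @return A named list of tibbles: `summary`, `coverage`,
#'   `case_control_tests`, `correlation`, `percentile_or`,
#'   `model_comparison`, `area_ks`, `sex_ks`, `case_control_area_ks`,
#'   `auc_by_area`; plus `suite` (the `pgs_model_suite`).
#' @export
run_evaluate <- function(config, outdir = NULL) {
  stopifnot(inherits(config, "run_config"))
  scored <- run_score(config, outdir = NULL)
  cohort <- scored$cohort
  scores_wide <- scored$scores |>
    dplyr::select("sample_id", "pgs_id", "z") |>
    tidyr::pivot_wider(names_from = "pgs_id", values_from = "z")
  data <- dplyr::inner_join(cohort, scores_wide, by = "sample_id")
  score_ids <- setdiff(names(scores_wide), "sample_id")

  is_case <- data$status == "case"
  cc_tests <- purrr::map_dfr(score_ids, function(id) {
    ks <- ks_two_sample(data[[id]][is_case], data[[id]][!is_case])
    mw <- mann_whitney(data[[id]][is_case], data[[id]][!is_case])
    tibble::tibble(pgs_id = id,
                   ks_statistic = ks$statistic, ks_p = ks$p_value,
                   mw_statistic = mw$statistic, mw_p = mw$p_value,
                   n_cases = ks$n_a, n_controls = ks$n_b)
  })

  correlation <- purrr::map_dfr(score_ids, function(id) {
    dplyr::mutate(
      correlation_screen(data[[id]], data,
                         threshold = config$correlation_threshold),
      pgs_id = id, .before = 1)
  })

  or_tbl <- purrr::map_dfr(score_ids, function(id) {
    raw <- scored$scores$raw[scored$scores$pgs_id == id][
      match(data$sample_id,
            scored$scores$sample_id[scored$scores$pgs_id == id])]
    dplyr::mutate(
      percentile_or_table(raw, data, qs = config$percentiles,
                          adjust = config$adjust),
      pgs_id = id, .before = 1)
  })

  covariate_cols <- intersect(
    c("age", "sex", "bmi", "hdl", "ldl", "triglycerides", "glycaemia",
      "smoking", "diabetes", "hypertension", "pas", "pad"),
    names(data))
  suite <- evaluate_models(
    data, score_cols = score_ids, covariate_cols = covariate_cols,
    split_fraction = config$split_fraction, cv_folds = config$cv_folds,
    cv_repeats = config$cv_repeats,
    boruta_iterations = config$boruta_iterations, alpha = config$alpha,
    seed = config$seed)

  area_ks <- pairwise_area_ks(data, score_ids)
  sex_ks <- sex_within_area_ks(data, score_ids)
  cc_area_ks <- case_control_within_area(data, score_ids)
  area_auc <- auc_by_area(data, score_ids)

  out <- list(
    summary = summarize_cohort(cohort),
    coverage = scored$coverage,
    case_control_tests = cc_tests,
    correlation = correlation,
    percentile_or = or_tbl,
    model_comparison = suite$comparison,
    area_ks = area_ks,
    sex_ks = sex_ks,
    case_control_area_ks = cc_area_ks,
    auc_by_area = area_auc,
    suite = suite,
    scores = scored$scores
  )
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    tables <- out[!(names(out) %in% c("suite", "scores"))]
    for (nm in names(tables)) {
      write_output_tsv(tables[[nm]],
                       file.path(outdir, paste0(nm, ".tsv")), config)
    }
    write_output_tsv(out$scores, file.path(outdir, "scores.tsv"), config)
  }
  out
}
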