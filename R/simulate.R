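#' Configuration for the synthetic structured-population cohort
#'
#' Defaults emulate a multi-area Italian case-control study: four
#' geographic macro-areas with sizes 2030/420/744/68, a balanced
#' case-control design (about half cases), modest between-area
#' allele-frequency divergence (Balding-Nichols F_ST, larger for the
#' island population), a polygenic liability with odds ratio 2 per 1 SD of
#' the true score, and conventional cardiometabolic covariate effects.
#'
#' @param areas Area labels.
#' @param n_per_area Named cohort sizes per area (cases + controls).
#' @param n_variants Number of independent biallelic variants.
#' @param fst Named per-area Balding-Nichols divergence in (0, 1).
#' @param ancestral_freq_range Uniform bounds for ancestral allele
#'   frequencies.
#' @param causal_fraction Fraction of variants with non-zero true weight.
#' @param or_per_sd Odds ratio per 1 SD of the standardized true score.
#' @param covariate_effects Named log-odds coefficients (per SD or per
#'   level) of the covariates in the liability.
#' @param base_rate Population case probability at average risk.
#' @param case_fraction Case share of the emitted cohort.
#' @param oversample Population pool size as a multiple of the cohort.
#' @param low_rsq_fraction Fraction of variants given imputation quality
#'   below 0.6, to exercise the load-time filter.
#' @param ambiguous_geno_fraction Fraction of variants given
#'   strand-ambiguous (A/T or C/G) REF/ALT pairs.
#' @param score_coverage Coverage of the large emitted scoring file
#'   (matched / declared variants).
#' @param score_overlap Variant-sharing fraction between the two large
#'   emitted files.
#' @param flip_fraction Fraction of large-file records recorded on the
#'   opposite strand.
#' @param mismatch_fraction Fraction of large-file records with
#'   irreconcilable alleles (spent inside the non-covered budget).
#' @param weight_noise_sd Relative SD of noise added to emitted weights.
#' @param n_confounded Variants in the structure-confounded score.
#' @param seed Integer seed; every downstream draw derives from it.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(areas = c("North", "Center", "South", "Sardinia"),
                       n_per_area = c(North = 2030, Center = 420,
                                      South = 744, Sardinia = 68),
                       n_variants = 400,
                       fst = c(North = 0.002, Center = 0.002,
                               South = 0.004, Sardinia = 0.015),
                       ancestral_freq_range = c(0.05, 0.95),
                       causal_fraction = 0.25,
                       or_per_sd = 2,
                       covariate_effects = c(age = 0.04, sex = 0.35,
                                             bmi = 0.07, smoking = 0.45,
                                             diabetes = 0.9,
                                             hypertension = 0.5,
                                             hdl = -0.8, ldl = 0.35),
                       base_rate = 0.2,
                       case_fraction = 0.5,
                       oversample = 3,
                       low_rsq_fraction = 0.05,
                       ambiguous_geno_fraction = 0.02,
                       score_coverage = 0.774,
                       score_overlap = 0.57,
                       flip_fraction = 0.10,
                       mismatch_fraction = 0.02,
                       weight_noise_sd = 0.05,
                       n_confounded = 100,
                       seed = 1) {
  cfg <- list(areas = areas, n_per_area = n_per_area,
              n_variants = n_variants, fst = fst,
              ancestral_freq_range = ancestral_freq_range,
              causal_fraction = causal_fraction, or_per_sd = or_per_sd,
              covariate_effects = covariate_effects, base_rate = base_rate,
              case_fraction = case_fraction, oversample = oversample,
              low_rsq_fraction = low_rsq_fraction,
              ambiguous_geno_fraction = ambiguous_geno_fraction,
              score_coverage = score_coverage,
              score_overlap = score_overlap,
              flip_fraction = flip_fraction,
              mismatch_fraction = mismatch_fraction,
              weight_noise_sd = weight_noise_sd,
              n_confounded = n_confounded, seed = seed)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  check <- function(ok, field, why) {
    if (!all(ok)) stop("invalid sim_config field '", field, "': ", why,
                       call. = FALSE)
  }
  check(length(cfg$areas) >= 1, "areas", "need at least one area")
  check(length(cfg$n_per_area) == length(cfg$areas) && all(cfg$n_per_area > 0),
        "n_per_area", "one positive count per area")
  check(cfg$n_variants >= 1, "n_variants", "must be positive")
  check(length(cfg$fst) == length(cfg$areas) &&
          all(cfg$fst > 0 & cfg$fst < 1),
        "fst", "one value per area, each in (0, 1)")
  check(length(cfg$ancestral_freq_range) == 2 &&
          cfg$ancestral_freq_range[1] > 0 &&
          cfg$ancestral_freq_range[2] < 1 &&
          diff(cfg$ancestral_freq_range) > 0,
        "ancestral_freq_range", "need 0 < low < high < 1")
  check(cfg$causal_fraction > 0 && cfg$causal_fraction <= 1,
        "causal_fraction", "must be in (0, 1]")
  check(cfg$or_per_sd > 0, "or_per_sd", "must be positive")
  check(cfg$base_rate > 0 && cfg$base_rate < 1, "base_rate", "in (0, 1)")
  check(cfg$case_fraction > 0 && cfg$case_fraction < 1,
        "case_fraction", "must be in (0, 1)")
  check(cfg$oversample >= 1, "oversample", "must be >= 1")
  for (f in c("low_rsq_fraction", "ambiguous_geno_fraction",
              "flip_fraction", "mismatch_fraction")) {
    check(cfg[[f]] >= 0 && cfg[[f]] < 1, f, "must be in [0, 1)")
  }
  check(cfg$score_coverage > 0 && cfg$score_coverage <= 1,
        "score_coverage", "must be in (0, 1]")
  check(cfg$score_overlap >= 0 && cfg$score_overlap <= 1,
        "score_overlap", "must be in [0, 1]")
  check(is.numeric(cfg$seed) && length(cfg$seed) == 1, "seed",
        "single integer")
  invisible(cfg)
}

#' Simulate structured-population genotypes (Balding-Nichols model)
#'
#' For each variant an ancestral frequency `p` is drawn uniformly on the
#' configured range; each area's frequency is Beta-distributed with shapes
#' `p (1 - F) / F` and `(1 - p)(1 - F) / F` (mean `p`, variance
#' `F p (1 - p)`); genotypes are Hardy-Weinberg `Binomial(2, p_area)`. The
#' pool simulated here is `oversample` times the cohort size; case-control
#' sampling happens in [simulate_phenotypes()].
#'
#' @param config A [sim_config()].
#' @return A list with `geno` (a `genotype_matrix` for the whole pool,
#'   hard-call dosages) and `truth` (true weights, per-area frequencies,
#'   per-sample areas, generative coefficients).
#' @export
simulate_genotypes <- function(config) {
  validate_sim_config(config)
  with_seed(config$seed, {
    nv <- config$n_variants
    k <- length(config$areas)
    pool_sizes <- pmax(1L, round(config$oversample * config$n_per_area))
    n_pool <- sum(pool_sizes)

    p_anc <- stats::runif(nv, config$ancestral_freq_range[1],
                          config$ancestral_freq_range[2])
    area_freq <- matrix(NA_real_, nv, k,
                        dimnames = list(NULL, config$areas))
    for (a in seq_len(k)) {
      f <- config$fst[[a]]
      area_freq[, a] <- stats::rbeta(nv, p_anc * (1 - f) / f,
                                     (1 - p_anc) * (1 - f) / f)
    }
    # keep frequencies away from fixation so scores retain variance
    area_freq <- pmin(pmax(area_freq, 1e-4), 1 - 1e-4)

    pool_area <- rep(config$areas, pool_sizes)
    dosage <- matrix(NA_real_, n_pool, nv)
    row0 <- 0L
    for (a in seq_len(k)) {
      na <- pool_sizes[[a]]
      dosage[row0 + seq_len(na), ] <- matrix(
        stats::rbinom(na * nv, 2L, rep(area_freq[, a], each = na)), na, nv)
      row0 <- row0 + na
    }

    # variant metadata: non-ambiguous REF/ALT pairs except a small fraction
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, nv, replace = TRUE)
    alt <- vapply(ref, function(r) {
      sample(setdiff(bases, c(r, flip_strand(r))), 1L)
    }, character(1))
    n_amb <- round(config$ambiguous_geno_fraction * nv)
    if (n_amb > 0) {
      amb_idx <- sample(nv, n_amb)
      alt[amb_idx] <- flip_strand(ref[amb_idx])
    }

    rsq <- stats::runif(nv, 0.75, 1)
    n_low <- round(config$low_rsq_fraction * nv)
    if (n_low > 0) rsq[sample(nv, n_low)] <- stats::runif(n_low, 0.30, 0.59)

    chrom <- as.character(rep_len(1:22, nv))
    pos <- integer(nv)
    for (ch in unique(chrom)) {
      i <- which(chrom == ch)
      pos[i] <- 10000L + 1000L * seq_along(i)
    }
    variants <- tibble::tibble(
      chrom = chrom, pos = pos, id = paste0("rs", 100000L + seq_len(nv)),
      ref = ref, alt = alt, rsq = rsq, call_rate = 1
    )
    sample_ids <- sprintf("S%06d", seq_len(n_pool))
    geno <- new_genotype_matrix(dosage, variants, sample_ids)

    n_causal <- max(1L, round(config$causal_fraction * nv))
    causal_idx <- sort(sample(nv, n_causal))
    weights <- numeric(nv)
    weights[causal_idx] <- stats::rnorm(n_causal, 0, 0.15)

    truth <- list(
      weights = weights, causal_idx = causal_idx, area_freq = area_freq,
      ancestral_freq = p_anc, pool_area = pool_area,
      beta_g = log(config$or_per_sd),
      beta0 = stats::qlogis(config$base_rate),
      covariate_effects = config$covariate_effects,
      seed = config$seed
    )
    list(geno = geno, truth = truth)
  })
}

# generative covariate draws; means/SDs loosely follow a young MI cohort
draw_covariates <- function(n) {
  age <- stats::rnorm(n, 40, 4.9)
  bmi <- stats::rnorm(n, 26, 3.8)
  total_chol <- stats::rnorm(n, 5.5, 1.2)
  tibble::tibble(
    age = age,
    sex = ifelse(stats::runif(n) < 0.885, "M", "F"),
    bmi = bmi,
    total_chol = total_chol,
    hdl = pmax(stats::rnorm(n, 1.2, 0.3), 0.3),
    ldl = pmax(stats::rnorm(n, 3.4, 1.2), 0.5),
    triglycerides = pmax(stats::rnorm(n, 1.7, 1.1), 0.2),
    glycaemia = pmax(stats::rnorm(n, 5.6, 1.5), 2.5),
    smoking = sample(c("yes", "no", "former"), n, replace = TRUE,
                     prob = c(0.30, 0.25, 0.45)),
    diabetes = ifelse(
      stats::runif(n) < stats::plogis(-4 + 0.04 * (age - 40) +
                                        0.08 * (bmi - 26)), "yes", "no"),
    hypertension = ifelse(
      stats::runif(n) < stats::plogis(-1.8 + 0.05 * (age - 40) +
                                        0.10 * (bmi - 26)), "yes", "no"),
    hypercholesterolemia = ifelse(total_chol > 6.2, "yes", "no"),
    pas = stats::rnorm(n, 128, 18),
    pad = stats::rnorm(n, 82, 12)
  )
}

# centered numeric encodings used inside the generative liability
liability_terms <- function(cov, effects) {
  enc <- list(
    age = (cov$age - 40) / 4.9,
    sex = as.numeric(cov$sex == "M") - 0.885,
    bmi = (cov$bmi - 26) / 3.8,
    smoking = c(no = 0, former = 1, yes = 2)[cov$smoking] - 1.05,
    diabetes = as.numeric(cov$diabetes == "yes") - 0.02,
    hypertension = as.numeric(cov$hypertension == "yes") - 0.14,
    hdl = (cov$hdl - 1.2) / 0.3,
    ldl = (cov$ldl - 3.4) / 1.2
  )
  eta <- numeric(nrow(cov))
  for (nm in names(effects)) {
    if (!is.null(enc[[nm]])) eta <- eta + effects[[nm]] * enc[[nm]]
  }
  eta
}

#' Simulate phenotypes and sample a case-control cohort
#'
#' Covariates are drawn from documented cardiometabolic distributions; the
#' true score is the weighted ALT-dosage sum standardized over the *pool*
#' (the population); case probability is
#' `plogis(beta0 + log(or_per_sd) * z_true + sum(beta_c * c))`; the cohort
#' is then sampled case-control per area to the configured case fraction.
#' The first four genetic principal components of the sampled cohort are
#' appended as covariates.
#'
#' @param geno The pool `genotype_matrix` from [simulate_genotypes()].
#' @param truth Its truth record (augmented in place and returned as an
#'   attribute `"truth"` of the result).
#' @param config The [sim_config()].
#' @return A cohort tibble (`sample_id`, `status`, covariates,
#'   `macro_area`, `pc1`..`pc4`), with the augmented truth record attached
#'   as attribute `"truth"`.
#' @export
simulate_phenotypes <- function(geno, truth, config) {
  validate_sim_config(config)
  with_seed(config$seed + 1L, {
    n_pool <- length(geno$sample_ids)
    cov <- draw_covariates(n_pool)

    raw <- as.vector(geno$dosage %*% truth$weights)
    score_center <- mean(raw)
    score_scale <- stats::sd(raw)
    z <- if (score_scale > 0) (raw - score_center) / score_scale else raw * 0

    eta <- truth$beta0 + truth$beta_g * z +
      liability_terms(cov, truth$covariate_effects)
    y <- stats::rbinom(n_pool, 1L, stats::plogis(eta))

    keep <- integer(0)
    for (a in seq_along(config$areas)) {
      in_area <- truth$pool_area == config$areas[[a]]
      n_target <- config$n_per_area[[a]]
      n_cases <- round(config$case_fraction * n_target)
      n_ctrls <- n_target - n_cases
      cases <- which(in_area & y == 1)
      ctrls <- which(in_area & y == 0)
      if (length(cases) < n_cases || length(ctrls) < n_ctrls) {
        stop("cannot reach case_fraction = ", config$case_fraction,
             " in area ", config$areas[[a]],
             ": raise base_rate or oversample", call. = FALSE)
      }
      keep <- c(keep, sample(cases, n_cases), sample(ctrls, n_ctrls))
    }
    keep <- sort(keep)

    cohort <- dplyr::bind_cols(
      tibble::tibble(sample_id = geno$sample_ids[keep],
                     status = ifelse(y[keep] == 1, "case", "control")),
      cov[keep, , drop = FALSE],
      tibble::tibble(macro_area = truth$pool_area[keep])
    )

    d <- geno$dosage[keep, , drop = FALSE]
    sds <- apply(d, 2, stats::sd)
    pc <- stats::prcomp(d[, sds > 0, drop = FALSE], center = TRUE,
                        scale. = TRUE)
    for (i in 1:4) cohort[[paste0("pc", i)]] <- pc$x[, i]

    truth$score_center <- score_center
    truth$score_scale <- score_scale
    truth$liability <- eta[keep]
    truth$z_true <- z[keep]
    truth$population_prevalence <- mean(y)
    truth$cohort_ids <- cohort$sample_id
    attr(cohort, "truth") <- truth
    cohort
  })
}

#' Emit synthetic PGS-Catalog-style scoring files with known truth
#'
#' Four files exercising the harmonization paths:
#' \describe{
#'   \item{SIM000001}{small rsID-dialect file over a causal subset.}
#'   \item{SIM000002}{large chr:pos-dialect file over all causal variants,
#'     padded with absent and mismatched records to a configured coverage,
#'     with a fraction of strand-complemented (flip) records.}
#'   \item{SIM000003}{file sharing a configured fraction of its variants
#'     with SIM000002.}
#'   \item{SIM000004}{structure-confounded score: non-causal variants with
#'     weights proportional to the allele-frequency difference between the
#'     first two areas plus noise — the signature of residual
#'     stratification.}
#' }
#' Present records are drawn from strand-unambiguous variants so that the
#' configured coverage is what harmonization reports under the drop policy.
#'
#' @param geno A `genotype_matrix` whose variant metadata the files refer
#'   to.
#' @param truth The truth record from [simulate_genotypes()].
#' @param config The [sim_config()].
#' @return A named list of `scoring_file` objects.
#' @export
simulate_scoring_files <- function(geno, truth, config) {
  validate_sim_config(config)
  with_seed(config$seed + 2L, {
    v <- geno$variants
    nv <- nrow(v)
    unambiguous <- which(v$alt != flip_strand(v$ref))
    causal <- intersect(truth$causal_idx, unambiguous)
    noise_sd <- config$weight_noise_sd * stats::sd(truth$weights[causal])

    record_for <- function(idx, weight, dialect, flipped = FALSE,
                           mismatched = FALSE) {
      ref <- v$ref[idx]; alt <- v$alt[idx]
      orient_alt <- stats::runif(length(idx)) < 0.5
      ea <- ifelse(orient_alt, alt, ref)
      oa <- ifelse(orient_alt, ref, alt)
      w <- ifelse(orient_alt, weight, -weight)
      if (flipped) { ea <- flip_strand(ea); oa <- flip_strand(oa) }
      if (mismatched) {
        # replace the allele pair with one disjoint from {ref, alt} and
        # their complements, so no reconciliation is possible
        bases <- c("A", "C", "G", "T")
        for (j in seq_along(idx)) {
          forbidden <- unique(c(ref[j], alt[j],
                                flip_strand(c(ref[j], alt[j]))))
          free <- setdiff(bases, forbidden)
          if (length(free) == 0) {
            # all four bases taken: (comp(ref), alt) is never direct, flip
            # or ambiguous when ref/alt and their complements are distinct
            ea[j] <- flip_strand(ref[j])
            oa[j] <- alt[j]
          } else {
            ea[j] <- free[[1L]]
            oa[j] <- ref[j]
          }
        }
      }
      tibble::tibble(
        identifier = if (dialect == "rsid") v$id[idx]
                     else paste0(v$chrom[idx], ":", v$pos[idx]),
        chrom = v$chrom[idx], pos = v$pos[idx],
        effect_allele = ea, other_allele = oa, weight = w
      )
    }

    absent_records <- function(n, offset) {
      if (n == 0) return(NULL)
      tibble::tibble(
        identifier = paste0("rs", 900000L + offset + seq_len(n)),
        chrom = "21", pos = 900000000L + offset * 1000L + seq_len(n),
        effect_allele = "A", other_allele = "C",
        weight = stats::rnorm(n, 0, noise_sd + 1e-6)
      )
    }

    files <- list()

    # 1: small causal subset, rsID dialect
    idx1 <- sort(sample(causal, min(30L, length(causal))))
    w1 <- truth$weights[idx1] + stats::rnorm(length(idx1), 0, noise_sd)
    files$SIM000001 <- new_scoring_file(
      "SIM000001", "synthetic coronary artery disease",
      c(source = "pgseval synthetic truth"),
      record_for(idx1, w1, "rsid"))

    # 2: all causal, chr:pos dialect, coverage-controlled, with flips
    idx2 <- causal
    n_present <- length(idx2)
    n_total <- max(n_present, round(n_present / config$score_coverage))
    n_noncov <- n_total - n_present
    n_mm <- min(round(config$mismatch_fraction * n_total), n_noncov,
                length(setdiff(unambiguous, idx2)))
    n_abs <- n_noncov - n_mm
    w2 <- truth$weights[idx2] + stats::rnorm(n_present, 0, noise_sd)
    rec2 <- record_for(idx2, w2, "chrpos")
    n_flip <- round(config$flip_fraction * n_present)
    if (n_flip > 0) {
      fidx <- sample(n_present, n_flip)
      rec2[fidx, c("effect_allele", "other_allele")] <-
        lapply(rec2[fidx, c("effect_allele", "other_allele")], flip_strand)
    }
    mm_idx <- sample(setdiff(unambiguous, idx2), n_mm)
    rec2 <- dplyr::bind_rows(
      rec2,
      if (n_mm > 0) record_for(mm_idx, stats::rnorm(n_mm, 0, noise_sd + 1e-6),
                               "chrpos", mismatched = TRUE),
      absent_records(n_abs, 0L))
    files$SIM000002 <- new_scoring_file(
      "SIM000002", "synthetic coronary artery disease",
      c(source = "pgseval synthetic truth"), rec2)

    # 3: overlap-controlled against file 2's present variants
    n3 <- min(length(idx2), length(unambiguous) - length(idx2))
    n_shared <- round(config$score_overlap * n3)
    pool_new <- setdiff(unambiguous, c(idx2, mm_idx))
    n_new <- min(n3 - n_shared, length(pool_new))
    idx3 <- sort(c(sample(idx2, n_shared), sample(pool_new, n_new)))
    w3 <- truth$weights[idx3] + stats::rnorm(length(idx3), 0, noise_sd)
    files$SIM000003 <- new_scoring_file(
      "SIM000003", "synthetic coronary artery disease",
      c(source = "pgseval synthetic truth"),
      record_for(idx3, w3, "rsid"))

    # 4: structure-confounded, non-causal
    noncausal <- setdiff(unambiguous, truth$causal_idx)
    idx4 <- sort(sample(noncausal, min(config$n_confounded,
                                       length(noncausal))))
    dfreq <- if (ncol(truth$area_freq) >= 2) {
      truth$area_freq[idx4, 1] - truth$area_freq[idx4, 2]
    } else {
      stats::rnorm(length(idx4), 0, 0.05)  # no divergence axis to confound
    }
    w4 <- dfreq / max(stats::sd(dfreq), 1e-8) * 0.1 +
      stats::rnorm(length(idx4), 0, 0.01)
    files$SIM000004 <- new_scoring_file(
      "SIM000004", "synthetic structure-confounded score",
      c(source = "pgseval synthetic truth"),
      record_for(idx4, w4, "rsid"))

    lapply(files, validate_scoring_file)
    files
  })
}

#' Simulate a full synthetic cohort
#'
#' Chains [simulate_genotypes()], [simulate_phenotypes()] and
#' [simulate_scoring_files()], returning the cohort-subset genotypes (the
#' pool is discarded).
#'
#' @param config A [sim_config()].
#' @return A list: `geno` (cohort `genotype_matrix`), `cohort` (tibble),
#'   `scoring_files` (named list), `truth`, `config`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  sim <- simulate_genotypes(config)
  cohort <- simulate_phenotypes(sim$geno, sim$truth, config)
  truth <- attr(cohort, "truth")
  files <- simulate_scoring_files(sim$geno, truth, config)
  geno <- subset_samples(sim$geno, cohort$sample_id)
  list(geno = geno, cohort = cohort, scoring_files = files,
       truth = truth, config = config)
}

#' Write a genotype matrix as a plain-text VCF
#'
#' Minimal VCFv4.2 writer for fixtures: biallelic sites with `Rsq` in INFO
#' and `GT:DS` per sample (GT from rounded dosage, DS the dosage itself).
#'
#' @param geno A `genotype_matrix`.
#' @param path Output path (`.vcf`).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(geno, path) {
  v <- geno$variants
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=pgseval-synthetic",
    "##INFO=<ID=Rsq,Number=1,Type=Float,Description=\"Imputation quality\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"ALT dosage\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", geno$sample_ids), collapse = "\t")
  )
  gt_of <- c("0/0", "0/1", "1/1")
  body <- vapply(seq_len(nrow(v)), function(i) {
    d <- geno$dosage[, i]
    cell <- ifelse(is.na(d), "./.:.",
                   paste0(gt_of[round(pmin(pmax(d, 0), 2)) + 1L], ":",
                          formatC(d, format = "g", digits = 6)))
    paste(c(v$chrom[i], v$pos[i], v$id[i], v$ref[i], v$alt[i], ".", "PASS",
            paste0("Rsq=", formatC(v$rsq[i], format = "g", digits = 6)),
            "GT:DS", cell), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write a complete fixture set to disk
#'
#' Simulates a cohort and writes: the cohort VCF (`genotypes.vcf`), one
#' scoring file per emitted score, the covariate table
#' (`covariates.tsv`), the truth record (`truth.json`) and a manifest
#' (`manifest.json`) recording the seed and a hash of the configuration.
#'
#' @param outdir Output directory (created if missing).
#' @param config A [sim_config()].
#' @return Invisibly, the manifest as a list (with `$path` for its file).
#' @export
write_fixture_set <- function(outdir, config = sim_config()) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_cohort(config)

  vcf_path <- file.path(outdir, "genotypes.vcf")
  write_vcf(sim$geno, vcf_path)

  score_paths <- vapply(sim$scoring_files, function(sf) {
    p <- file.path(outdir, paste0(sf$pgs_id, ".txt"))
    write_scoring_file(sf, p)
    p
  }, character(1))

  cov_path <- file.path(outdir, "covariates.tsv")
  readr::write_tsv(sim$cohort, cov_path)

  truth_path <- file.path(outdir, "truth.json")
  tr <- sim$truth
  jsonlite::write_json(
    list(weights = tr$weights, causal_idx = tr$causal_idx,
         area_freq = tr$area_freq, beta0 = tr$beta0, beta_g = tr$beta_g,
         covariate_effects = as.list(tr$covariate_effects),
         score_center = tr$score_center, score_scale = tr$score_scale,
         population_prevalence = tr$population_prevalence,
         seed = tr$seed),
    truth_path, digits = NA, auto_unbox = TRUE)

  manifest <- list(
    seed = config$seed,
    config_hash = rlang::hash(unclass(config)),
    n_samples = length(sim$geno$sample_ids),
    n_variants = nrow(sim$geno$variants),
    files = c(vcf = vcf_path, unname(score_paths), covariates = cov_path,
              truth = truth_path)
  )
  manifest_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE)
  manifest$path <- manifest_path
  invisible(manifest)
}
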