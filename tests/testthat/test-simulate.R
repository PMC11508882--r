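test_that("configuration validation names the offending field", {
  expect_error(sim_config(fst = c(North = 1.5, Center = 0.01, South = 0.01,
                                  Sardinia = 0.01)), "fst")
  expect_error(sim_config(case_fraction = 1.2), "case_fraction")
  expect_error(sim_config(n_variants = 0), "n_variants")
  expect_error(sim_config(ancestral_freq_range = c(0.9, 0.1)),
               "ancestral_freq_range")
})

test_that("area frequencies collapse to the ancestral ones as divergence vanishes", {
  cfg <- small_sim_config(seed = 41, n_variants = 500,
                          fst = c(North = 1e-6, South = 1e-6),
                          n_per_area = c(North = 10, South = 10))
  g <- simulate_genotypes(cfg)
  for (a in 1:2) {
    expect_lt(max(abs(g$truth$area_freq[, a] - g$truth$ancestral_freq)), 0.01)
  }
})

test_that("realized divergence matches the target on the Hudson scale", {
  cfg <- small_sim_config(seed = 42, n_variants = 1000,
                          fst = c(North = 0.1, South = 0.1),
                          n_per_area = c(North = 50, South = 50))
  g <- simulate_genotypes(cfg)
  p1 <- g$truth$area_freq[, 1]; p2 <- g$truth$area_freq[, 2]
  # Hudson-style ratio-of-sums estimator on the true subpopulation freqs
  fst_hat <- sum((p1 - p2)^2) / sum(p1 * (1 - p2) + p2 * (1 - p1))
  expect_gt(fst_hat, 0.05)
  expect_lt(fst_hat, 0.15)
})

test_that("simulation is bit-identical under a fixed seed", {
  cfg <- small_sim_config(seed = 43, n_variants = 80,
                          n_per_area = c(North = 40, South = 40))
  s1 <- simulate_cohort(cfg)
  s2 <- simulate_cohort(cfg)
  expect_identical(s1$geno$dosage, s2$geno$dosage)
  expect_identical(s1$cohort, s2$cohort)
  expect_identical(lapply(s1$scoring_files, `[[`, "variants"),
                   lapply(s2$scoring_files, `[[`, "variants"))
  s3 <- simulate_cohort(small_sim_config(seed = 44, n_variants = 80,
                                         n_per_area = c(North = 40, South = 40)))
  expect_false(identical(s1$geno$dosage, s3$geno$dosage))
})

test_that("a null genetic model yields indistinguishable case/control scores", {
  ps <- vapply(1:20, function(i) {
    cfg <- small_sim_config(
      seed = 100 + i, n_variants = 60,
      n_per_area = c(North = 60, South = 60),
      oversample = 6, or_per_sd = 1,
      covariate_effects = c(age = 0, sex = 0, bmi = 0, smoking = 0,
                            diabetes = 0, hypertension = 0, hdl = 0, ldl = 0))
    sim <- simulate_cohort(cfg)
    sc <- score_pgs(sim$scoring_files$SIM000001, sim$geno)
    z <- sc$z[match(sim$cohort$sample_id, sc$sample_id)]
    ks_two_sample(z[sim$cohort$status == "case"],
                  z[sim$cohort$status == "control"])$p_value
  }, numeric(1))
  # p-values should look uniform: mean near 1/2, no pile-up at zero
  expect_gt(mean(ps), 0.25)
  expect_lt(mean(ps), 0.75)
  expect_lt(mean(ps < 0.05), 0.25)
})

test_that("the true score's discrimination matches the binormal prediction", {
  cfg <- small_sim_config(seed = 45, n_variants = 120,
                          n_per_area = c(North = 3000, South = 3000),
                          oversample = 3, base_rate = 0.3)
  sim <- simulate_cohort(cfg)
  truth <- sim$truth
  z <- truth$z_true
  case <- sim$cohort$status == "case"
  delta <- mean(z[case]) - mean(z[!case])
  pooled <- sqrt(var(z[case]) + var(z[!case]))
  predicted <- pnorm(delta / pooled)
  empirical <- roc_auc(sim$cohort$status, z)$auc
  expect_lt(abs(empirical - predicted), 0.03)
})

test_that("emitted scoring files hit their coverage and overlap targets", {
  cfg <- small_sim_config(seed = 46, n_variants = 800, causal_fraction = 0.3,
                          n_per_area = c(North = 60, South = 60))
  sim <- simulate_cohort(cfg)
  r2 <- harmonize(sim$scoring_files$SIM000002, sim$geno)$report
  expect_lt(abs(r2$coverage - cfg$score_coverage), 0.02)
  expect_gt(r2$n_matched_flip, 0)           # strand-complemented records exist
  expect_gt(r2$n_mismatch_dropped + r2$n_absent, 0)

  key <- function(sf) paste(sf$variants$chrom, sf$variants$pos)
  k2 <- key(sim$scoring_files$SIM000002)
  k3 <- key(sim$scoring_files$SIM000003)
  overlap <- length(intersect(k2, k3)) / length(k3)
  expect_lt(abs(overlap - cfg$score_overlap), 0.02)

  # both identifier dialects are emitted
  expect_true(any(grepl("^rs", sim$scoring_files$SIM000001$variants$identifier)))
  expect_true(all(grepl(":", sim$scoring_files$SIM000002$variants$identifier[
    seq_len(5)])))
})

test_that("a zero-noise full-coverage file reproduces the true score exactly", {
  cfg <- small_sim_config(seed = 47, n_variants = 200,
                          n_per_area = c(North = 80, South = 80),
                          weight_noise_sd = 0, score_coverage = 1,
                          mismatch_fraction = 0,
                          ambiguous_geno_fraction = 0)
  sim <- simulate_cohort(cfg)
  sc <- score_pgs(sim$scoring_files$SIM000002, sim$geno)
  true_raw <- as.vector(sim$geno$dosage %*% sim$truth$weights)
  # REF-oriented records shift the score by a constant; correlation is exact
  expect_equal(cor(sc$raw, true_raw), 1, tolerance = 1e-12)
})

test_that("phenotype sampling hits the case fraction or fails with advice", {
  cfg <- small_sim_config(seed = 48, n_variants = 60,
                          n_per_area = c(North = 100, South = 50))
  sim <- simulate_cohort(cfg)
  tab <- table(sim$cohort$macro_area, sim$cohort$status)
  expect_equal(unname(tab["North", "case"]), 50)
  expect_equal(unname(tab["South", "case"]), 25)
  expect_equal(nrow(sim$cohort), 150)
  # cohort carries the four genetic PCs
  expect_true(all(paste0("pc", 1:4) %in% names(sim$cohort)))

  bad <- small_sim_config(seed = 49, n_variants = 40, base_rate = 0.01,
                          case_fraction = 0.9,
                          n_per_area = c(North = 100, South = 100))
  g <- simulate_genotypes(bad)
  expect_error(simulate_phenotypes(g$geno, g$truth, bad),
               "base_rate or oversample")
})

test_that("fixture sets round-trip from disk and hash their configuration", {
  outdir <- file.path(tempdir(), "fixture_test")
  on.exit(unlink(outdir, recursive = TRUE))
  cfg <- small_sim_config(seed = 50, n_variants = 60,
                          n_per_area = c(North = 30, South = 30))
  man <- write_fixture_set(outdir, cfg)
  expect_true(file.exists(file.path(outdir, "genotypes.vcf")))
  expect_true(file.exists(file.path(outdir, "covariates.tsv")))
  expect_true(file.exists(file.path(outdir, "truth.json")))
  expect_true(file.exists(man$path))

  sim <- simulate_cohort(cfg)
  back <- read_genotypes(file.path(outdir, "genotypes.vcf"), rsq_min = 0)
  expect_equal(unname(back$dosage), unname(sim$geno$dosage))
  cov <- readr::read_tsv(file.path(outdir, "covariates.tsv"),
                         show_col_types = FALSE)
  expect_equal(cov$status, sim$cohort$status)

  man2 <- write_fixture_set(outdir, cfg)
  expect_identical(man2$config_hash, man$config_hash)
  man3 <- write_fixture_set(
    outdir, small_sim_config(seed = 50, n_variants = 61,
                             n_per_area = c(North = 30, South = 30)))
  expect_false(identical(man3$config_hash, man$config_hash))
})
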