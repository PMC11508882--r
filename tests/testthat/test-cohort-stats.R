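test_that("KS statistic and p behave at the boundaries", {
  same <- ks_two_sample(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_equal(ks_two_sample(c(1, 2, 3), c(4, 5, 6))$statistic, 1)
  expect_error(ks_two_sample(numeric(0), 1:3), "empty")
})

test_that("KS p matches a permutation null within Monte-Carlo error", {
  set.seed(314)
  a <- rnorm(200); b <- rnorm(200)
  obs <- ks_two_sample(a, b)

  pooled <- c(a, b)
  ord <- order(pooled)
  n_a <- 200L; n_b <- 200L
  lab <- rep(c(1 / n_a, -1 / n_b), c(n_a, n_b))
  ks_stat <- function(l) max(abs(cumsum(l[ord])))
  # permute labels, not values: the sorted order is fixed
  d_perm <- replicate(10000, ks_stat(sample(lab)))
  p_perm <- mean(d_perm >= obs$statistic - 1e-12)
  expect_lt(abs(obs$p_value - p_perm), 0.03)
})

test_that("Mann-Whitney U matches complete separation and the AUC identity", {
  expect_equal(mann_whitney(c(1, 2), c(3, 4))$statistic, 0)
  expect_gt(mann_whitney(1:20, 1:20)$p_value, 0.95)
  expect_error(mann_whitney(1:3, numeric(0)), "empty")

  set.seed(5)
  for (i in 1:5) {
    a <- sample(1:10, 40, replace = TRUE)  # heavy ties
    b <- sample(3:12, 60, replace = TRUE)
    u <- mann_whitney(a, b)$statistic
    auc <- roc_auc(rep(c(1, 0), c(40, 60)), c(a, b))$auc
    expect_equal(u / (40 * 60), auc, tolerance = 1e-12)
  }
})

test_that("Fisher's exact test reproduces printed contingency p-values", {
  # sex split of a 576-person case-control study
  expect_equal(fisher_exact(rbind(c(184, 102), c(186, 104)))$p_value, 1.0,
               tolerance = 1e-9)
  # former-vs-never smoking in the same study
  expect_equal(fisher_exact(rbind(c(79, 99), c(86, 123)))$p_value, 0.54,
               tolerance = 0.005)
  # 2x2 identity permutation: both tables with these margins equiprobable
  expect_equal(fisher_exact(rbind(c(1, 0), c(0, 1)))$p_value, 1.0)
  expect_error(fisher_exact(rbind(c(0, 0), c(1, 2))), "zero margin")
})

test_that("Fisher's test is invariant under simultaneous row and column swaps", {
  set.seed(11)
  for (i in 1:10) {
    tab <- matrix(rpois(4, 30) + 1, 2, 2)
    swapped <- tab[2:1, 2:1]
    expect_equal(fisher_exact(swapped)$p_value, fisher_exact(tab)$p_value)
    expect_equal(fisher_exact(swapped)$statistic, fisher_exact(tab)$statistic)
  }
})

test_that("rank tests are invariant under strictly monotone transforms", {
  set.seed(12)
  a <- rnorm(60); b <- rnorm(80, 0.4)
  f <- function(x) exp(x) + x^3  # strictly increasing
  expect_equal(ks_two_sample(f(a), f(b)), ks_two_sample(a, b))
  mw1 <- mann_whitney(a, b); mw2 <- mann_whitney(f(a), f(b))
  expect_equal(mw2$statistic, mw1$statistic)
  expect_equal(mw2$p_value, mw1$p_value)
})

test_that("the correlation screen encodes, flags strictly, and handles degeneracy", {
  set.seed(13)
  n <- 1000
  cohort <- tibble::tibble(
    sample_id = as.character(1:n),
    status = sample(c("case", "control"), n, TRUE),
    age = rnorm(n, 50, 8), sex = sample(c("M", "F"), n, TRUE),
    bmi = rnorm(n, 26, 4),
    diabetes = sample(c("yes", "no"), n, TRUE, prob = c(0.1, 0.9)),
    smoking = sample(c("yes", "no", "former"), n, TRUE),
    pas = rep(120, n)  # zero variance
  )
  scr <- correlation_screen(cohort$age, cohort, threshold = 0.75)
  expect_equal(scr$r[scr$covariate == "age"], 1)
  expect_true(scr$flagged[scr$covariate == "age"])
  # independent covariates stay far below the flag line at n = 1000
  expect_true(all(abs(scr$r[scr$covariate %in%
                              c("bmi", "sex", "diabetes", "smoking")]) < 0.1))
  # zero-variance covariate reported as missing, not an error
  expect_true(is.na(scr$r[scr$covariate == "pas"]))
  # strict inequality: r = 1 is not flagged at threshold 1
  scr1 <- correlation_screen(cohort$age, cohort, threshold = 1)
  expect_false(scr1$flagged[scr1$covariate == "age"])
})

test_that("the unadjusted percentile OR equals the cross-product ratio", {
  set.seed(14)
  for (i in 1:5) {
    n <- 400
    scores <- rnorm(n)
    cohort <- tibble::tibble(
      sample_id = as.character(1:n),
      status = ifelse(runif(n) < stats::plogis(0.8 * scores), "case", "control"))
    for (q in c(0.8, 0.9)) {
      res <- percentile_or(scores, cohort, q = q, adjust = character(0))
      above <- score_percentiles(scores) > q
      tab <- table(above, cohort$status == "case")
      oracle <- (tab["TRUE", "TRUE"] * tab["FALSE", "FALSE"]) /
        (tab["TRUE", "FALSE"] * tab["FALSE", "TRUE"])
      expect_equal(res$odds_ratio, unname(oracle), tolerance = 1e-8)
      expect_equal(res$n_above + res$n_below, n)
    }
  }
})

test_that("adjusted percentile ORs carry Wald intervals and covariates", {
  set.seed(15)
  n <- 600
  scores <- rnorm(n)
  cohort <- tibble::tibble(
    sample_id = as.character(1:n),
    status = ifelse(runif(n) < stats::plogis(scores), "case", "control"),
    age = rnorm(n, 50, 8), sex = sample(c("M", "F"), n, TRUE),
    bmi = rnorm(n, 26, 4))
  res <- percentile_or(scores, cohort, q = 0.8)
  expect_equal(res$adjusted_for, "age,sex,bmi")
  expect_true(res$ci_low <= res$odds_ratio && res$odds_ratio <= res$ci_high)
  expect_gt(res$odds_ratio, 1)
  # profile CIs exist and bracket the estimate too
  pro <- percentile_or(scores, cohort, q = 0.8, ci = "profile")
  expect_true(pro$ci_low <= pro$odds_ratio && pro$odds_ratio <= pro$ci_high)
})

test_that("complete separation is flagged, with direction, not estimated", {
  n <- 100
  scores <- 1:n
  cohort <- tibble::tibble(
    sample_id = as.character(1:n),
    status = rep(c("control", "case"), each = 50))  # cases all above
  expect_warning(
    res <- percentile_or(scores, cohort, q = 0.8, adjust = character(0)),
    "separation")
  expect_true(res$separation)
  expect_identical(res$odds_ratio, Inf)
})

test_that("the cohort summary reproduces printed counts and brute-force tallies", {
  # rebuild a cohort from a published sex split: 184/186 male, 102/104 female
  sex_cohort <- tibble::tibble(
    sample_id = as.character(1:576),
    status = rep(c("case", "control"), c(286, 290)),
    sex = c(rep("M", 184), rep("F", 102), rep("M", 186), rep("F", 104)))
  s <- summarize_cohort(sex_cohort)
  sex_row <- s[s$variable == "sex", ]
  expect_equal(sex_row$p_value, 1.0, tolerance = 1e-9)
  expect_equal(as.integer(sex_row$case), 184L)
  expect_equal(as.integer(sex_row$control), 186L)

  set.seed(16)
  n <- 300
  cohort <- tibble::tibble(
    sample_id = as.character(1:n),
    status = sample(c("case", "control"), n, TRUE),
    age = rnorm(n, 50, 8),
    smoking = sample(c("yes", "no", "former"), n, TRUE),
    diabetes = sample(c("yes", "no"), n, TRUE))
  s2 <- summarize_cohort(cohort)
  dia <- s2[s2$variable == "diabetes", ]
  expect_equal(as.integer(dia$case),
               sum(cohort$diabetes == "yes" & cohort$status == "case"))
  smk <- s2[s2$variable == "smoking" & s2$level == "former_vs_no", ]
  expect_equal(as.integer(smk$case),
               sum(cohort$smoking == "former" & cohort$status == "case"))
  # a covariate with the same multiset of values in both groups tests near 1
  vals <- rnorm(max(table(cohort$status)))
  cohort$bmi <- NA_real_
  for (g in c("case", "control")) {
    idx <- which(cohort$status == g)
    cohort$bmi[idx] <- vals[seq_along(idx)]
  }
  s3 <- summarize_cohort(cohort)
  expect_gt(s3$p_value[s3$variable == "bmi"], 0.8)
})
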