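test_that("the stratified split preserves class balance and is seeded", {
  cohort <- tibble::tibble(sample_id = as.character(1:200),
                           status = rep(c("case", "control"), each = 100))
  sp <- stratified_split(cohort, 0.8, seed = 1)
  tab <- table(sp$split, cohort$status)
  expect_equal(unname(tab["train", ]), c(80, 80))
  expect_equal(unname(tab["test", ]), c(20, 20))
  expect_identical(stratified_split(cohort, 0.8, seed = 1), sp)
  expect_false(identical(stratified_split(cohort, 0.8, seed = 2), sp))
  expect_setequal(sp$sample_id, cohort$sample_id)
  expect_error(stratified_split(tibble::tibble(
    sample_id = c("a", "b"), status = c("case", "control"))), ">= 2")
})

test_that("logistic fits recover the closed-form OR of a binary feature", {
  set.seed(20)
  n <- 500
  x <- rbinom(n, 1, 0.4)
  y <- rbinom(n, 1, plogis(-0.5 + 0.9 * x))
  dat <- tibble::tibble(status = ifelse(y == 1, "case", "control"), x = x)
  fit <- fit_logistic(dat, "status", "x")
  tab <- table(x, y)
  oracle <- log((tab["1", "1"] * tab["0", "0"]) /
                  (tab["1", "0"] * tab["0", "1"]))
  expect_equal(unname(fit$coefficients["x"]), oracle, tolerance = 1e-8)
})

test_that("the null intercept and a known logit model are recovered", {
  set.seed(21)
  n <- 2000
  dat <- tibble::tibble(status = rep(c("case", "control"), c(800, 1200)),
                        x = rnorm(n))
  fit <- fit_logistic(dat, "status", "x")
  se0 <- sqrt(fit$vcov["(Intercept)", "(Intercept)"])
  expect_lt(abs(fit$coefficients[["(Intercept)"]] - log(800 / 1200)), 3 * se0)

  n <- 5000
  beta <- c(`(Intercept)` = -0.3, x1 = 0.7, x2 = -0.4)
  x1 <- rnorm(n); x2 <- rnorm(n)
  y <- rbinom(n, 1, plogis(beta[1] + beta[2] * x1 + beta[3] * x2))
  fit2 <- fit_logistic(tibble::tibble(status = y, x1 = x1, x2 = x2),
                       "status", c("x1", "x2"))
  for (term in names(beta)) {
    se <- sqrt(fit2$vcov[term, term])
    expect_lt(abs(fit2$coefficients[[term]] - beta[[term]]), 3 * se)
  }
})

test_that("degenerate designs are reported by name and separation flagged", {
  dat <- tibble::tibble(status = rep(c("case", "control"), 25),
                        good = rnorm(50), flat = rep(1, 50))
  expect_error(fit_logistic(dat, "status", c("good", "flat")), "flat")
  dat$dup <- dat$good
  expect_error(fit_logistic(dat, "status", c("good", "dup")), "dup")

  sep <- tibble::tibble(status = rep(c("control", "case"), each = 25),
                        x = c(rnorm(25, -3), rnorm(25, 3)))
  fit <- fit_logistic(sep, "status", "x")
  expect_true(fit$separation)
})

test_that("Boruta confirms a planted signal and rejects noise and constants", {
  set.seed(22)
  n <- 500
  signal <- rnorm(n)
  y <- rbinom(n, 1, plogis(3 * signal))
  x <- tibble::tibble(signal = signal,
                      n1 = rnorm(n), n2 = rnorm(n), n3 = rnorm(n),
                      n4 = rnorm(n), n5 = rnorm(n))
  res <- boruta_select(x, y, n_iterations = 30, seed = 23)
  expect_s3_class(res, "pgs_boruta")
  expect_equal(res$decision[res$feature == "signal"], "confirmed")
  noise <- res$decision[res$feature != "signal"]
  expect_false(any(noise == "confirmed"))
  expect_true(all(res$hit_count <= res$n_iterations))

  # zero-variance feature can never beat a shadow
  x$flat <- 1
  res2 <- boruta_select(x, y, n_iterations = 30, seed = 24)
  expect_equal(res2$decision[res2$feature == "flat"], "rejected")
})

test_that("all-noise candidates confirm nothing", {
  set.seed(25)
  n <- 300
  y <- rbinom(n, 1, 0.5)
  x <- as.data.frame(matrix(rnorm(n * 5), n, 5))
  res <- boruta_select(x, y, n_iterations = 25, seed = 26)
  expect_false(any(res$decision == "confirmed"))
})

test_that("AUC equals brute-force pair counting with half-credit ties", {
  expect_equal(roc_auc(c(1, 1, 0, 0), c(5, 4, 2, 1))$auc, 1.0)
  expect_error(roc_auc(rep(1, 5), rnorm(5)), "both cases and controls")

  set.seed(27)
  for (i in 1:5) {
    y <- rbinom(120, 1, 0.45)
    if (length(unique(y)) < 2) next
    s <- sample(1:12, 120, replace = TRUE)  # many ties
    r <- roc_auc(y, s)
    cases <- s[y == 1]; ctrls <- s[y == 0]
    brute <- (sum(outer(cases, ctrls, ">")) +
                0.5 * sum(outer(cases, ctrls, "=="))) /
      (length(cases) * length(ctrls))
    expect_equal(r$auc, brute, tolerance = 1e-12)
    expect_true(r$ci_low <= r$auc && r$auc <= r$ci_high)
    # staircase is monotone from (0,0) to (1,1)
    expect_true(all(diff(r$roc_points$fpr) >= 0))
    expect_true(all(diff(r$roc_points$tpr) >= 0))
    expect_equal(unlist(r$roc_points[1, ]), c(fpr = 0, tpr = 0))
    expect_equal(unlist(r$roc_points[nrow(r$roc_points), ]),
                 c(fpr = 1, tpr = 1))
  }
})

test_that("AUC is invariant under strictly increasing score transforms", {
  set.seed(28)
  y <- rbinom(200, 1, 0.5)
  s <- rnorm(200, y)
  expect_equal(roc_auc(y, plogis(3 * s) + s^3 / 100)$auc, roc_auc(y, s)$auc)
})

test_that("a score independent of outcome sits at AUC one half", {
  set.seed(29)
  y <- rep(c(1, 0), each = 1000)
  expect_lt(abs(roc_auc(y, rnorm(2000))$auc - 0.5), 0.03)
})

test_that("AUC and DeLong variance agree with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(30)
  y <- rbinom(150, 1, 0.5)
  s <- rnorm(150, 0.8 * y)
  r <- roc_auc(y, s)
  pr <- pROC::roc(y, s, quiet = TRUE, direction = "<")
  expect_equal(r$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-12)
  expect_equal(r$var, as.numeric(pROC::var(pr, method = "delong")),
               tolerance = 1e-10)

  s2 <- 0.5 * s + rnorm(150)
  dl <- delong_paired_test(y, s, s2)
  ref <- pROC::roc.test(pr, pROC::roc(y, s2, quiet = TRUE, direction = "<"),
                        method = "delong", paired = TRUE)
  expect_equal(dl$z_statistic, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(dl$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("the paired DeLong test degrades gracefully and matches a bootstrap", {
  set.seed(31)
  y <- rbinom(150, 1, 0.5)
  s <- rnorm(150, y)
  same <- delong_paired_test(y, s, s)
  expect_equal(same$delta, 0)
  expect_equal(same$z_statistic, 0)
  expect_equal(same$p_value, 1)

  # bootstrap oracle for the variance of the AUC difference
  s2 <- 0.6 * s + 0.8 * rnorm(150)
  dl <- delong_paired_test(y, s, s2)
  var_delong <- (dl$delta / dl$z_statistic)^2
  boot <- replicate(2000, {
    idx <- sample(150, replace = TRUE)
    if (length(unique(y[idx])) < 2) return(NA_real_)
    roc_auc(y[idx], s[idx])$auc - roc_auc(y[idx], s2[idx])$auc
  })
  expect_lt(abs(var_delong - var(boot, na.rm = TRUE)) / var(boot, na.rm = TRUE),
            0.15)
})

test_that("the model suite ties its pieces together coherently", {
  set.seed(32)
  cfg <- small_sim_config(seed = 33, n_per_area = c(North = 200, South = 200))
  sim <- simulate_cohort(cfg)
  sc <- score_pgs(sim$scoring_files$SIM000002, sim$geno)
  data <- dplyr::mutate(sim$cohort,
                        prs = sc$z[match(sample_id, sc$sample_id)])
  suite <- evaluate_models(
    data, score_cols = "prs",
    covariate_cols = c("age", "sex", "bmi", "hdl", "ldl", "smoking",
                       "diabetes", "hypertension"),
    cv_folds = 3, cv_repeats = 2, boruta_iterations = 20, seed = 34)
  cmp <- suite$comparison
  expect_equal(nrow(cmp), 3L)
  expect_setequal(cmp$model, c("covariates", "pgs_only", "combined"))
  expect_true(all(cmp$auc >= 0 & cmp$auc <= 1))
  expect_true(all(cmp$ci_low <= cmp$auc & cmp$auc <= cmp$ci_high))
  expect_false(is.na(cmp$delong_p[cmp$model == "combined"]))

  # single-feature logistic is monotone in the score: identical test AUC
  test_ids <- suite$split$sample_id[suite$split$split == "test"]
  test_rows <- data[data$sample_id %in% test_ids, ]
  direct <- roc_auc(test_rows$status, test_rows$prs)$auc
  expect_equal(cmp$auc[cmp$model == "pgs_only"], direct, tolerance = 1e-12)

  # tidy/glance interfaces
  expect_identical(tidy(suite), cmp)
  expect_equal(glance(suite)$best_pgs, "prs")
})
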