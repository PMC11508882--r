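#' Stratified train/test split
#'
#' Splits a cohort into training and test sets preserving the case/control
#' ratio within one sample of exactness; deterministic given `seed`.
#'
#' @param cohort Cohort tibble with `sample_id` and `status`.
#' @param fraction Training fraction in (0, 1); default 0.8.
#' @param seed Integer seed.
#' @return A tibble `sample_id`, `split` (`"train"`/`"test"`).
#' @export
stratified_split <- function(cohort, fraction = 0.8, seed = 1) {
  stopifnot(fraction > 0, fraction < 1)
  y <- as_case_indicator(cohort$status)
  if (sum(y == 1) < 2 || sum(y == 0) < 2) {
    stop("stratified_split: need >= 2 cases and >= 2 controls", call. = FALSE)
  }
  with_seed(seed, {
    split <- rep("test", nrow(cohort))
    for (cls in c(0, 1)) {
      idx <- which(y == cls)
      n_tr <- round(fraction * length(idx))
      split[sample(idx, n_tr)] <- "train"
    }
    tibble::tibble(sample_id = cohort$sample_id, split = split)
  })
}

#' Fit a logistic risk model
#'
#' Maximum-likelihood logistic regression by iteratively reweighted least
#' squares (via [stats::glm()]), with rank-deficiency and separation
#' diagnostics. Constant or aliased feature columns are an error naming the
#' offending columns; quasi-separation (fitted probabilities numerically 0
#' or 1, or runaway coefficients) sets the `separation` flag.
#'
#' @param data Data frame of numeric features plus the outcome column.
#' @param outcome Name of the binary outcome column (default `"status"`,
#'   case = positive).
#' @param features Character vector of feature column names (default: all
#'   columns except the outcome).
#' @return A `pgs_logit` object: coefficients, Wald covariance,
#'   log-likelihood, convergence and separation flags, and the underlying
#'   `glm` fit. Use [generics::tidy()] / [generics::glance()] on it.
#' @export
fit_logistic <- function(data, outcome = "status", features = NULL) {
  if (is.null(features)) features <- setdiff(names(data), outcome)
  stopifnot(length(features) >= 1L)
  y <- as_case_indicator(data[[outcome]])
  x <- data[, features, drop = FALSE]
  x[] <- lapply(names(x), function(v) encode_covariate(x[[v]], v))
  ok <- stats::complete.cases(x) & !is.na(y)
  x <- x[ok, , drop = FALSE]; y <- y[ok]

  const <- vapply(x, function(col) stats::var(col) == 0, logical(1))
  if (any(const)) {
    stop("constant feature column(s): ",
         paste(features[const], collapse = ", "), call. = FALSE)
  }
  mm <- cbind(`(Intercept)` = 1, as.matrix(x))
  qr_mm <- qr(mm)
  if (qr_mm$rank < ncol(mm)) {
    bad <- colnames(mm)[qr_mm$pivot[(qr_mm$rank + 1):ncol(mm)]]
    stop("rank-deficient design; aliased column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }

  dat <- data.frame(y = y, x, check.names = FALSE)
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ ., data = dat, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-10, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        sep <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  if (any(abs(stats::coef(fit)[-1L]) > 15)) sep <- TRUE

  structure(
    list(coefficients = stats::coef(fit), vcov = stats::vcov(fit),
         log_lik = as.numeric(stats::logLik(fit)),
         converged = fit$converged, separation = sep,
         n = nrow(dat), features = features, fit = fit),
    class = "pgs_logit"
  )
}

#' @export
print.pgs_logit <- function(x, ...) {
  cat("<pgs_logit> n =", x$n, if (x$separation) "(separation flagged)", "\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Predict case probabilities from a fitted logistic model
#' @param object A `pgs_logit`.
#' @param newdata Data frame containing the model's feature columns.
#' @param ... Unused.
#' @return Numeric vector of case probabilities.
#' @export
predict.pgs_logit <- function(object, newdata, ...) {
  x <- newdata[, object$features, drop = FALSE]
  x[] <- lapply(names(x), function(v) encode_covariate(x[[v]], v))
  eta <- as.matrix(cbind(1, x)) %*% object$coefficients
  stats::plogis(as.vector(eta))
}

#' Boruta all-relevant feature selection
#'
#' For each iteration, every candidate feature gets a "shadow" copy with its
#' values permuted across samples; a random-forest importance learner
#' (\pkg{ranger}, permutation importance) is fitted on real plus shadow
#' features, and a feature scores a *hit* when its importance exceeds the
#' best shadow importance. Features are confirmed (rejected) when a
#' two-sided binomial test of their hit count against p = 0.5, Bonferroni-
#' corrected over candidates, is significant in the upper (lower) tail;
#' rejected features leave the active set (step-down). Features undecided
#' after `n_iterations` are tentative.
#'
#' @param x Data frame or matrix of candidate features (>= 2 columns).
#' @param y Binary outcome.
#' @param n_iterations Number of shadow iterations (>= 20; default 50).
#' @param alpha Decision level (default 0.01).
#' @param seed Integer seed.
#' @param num_trees,max_depth Forest size and depth cap for the learner.
#' @return A `pgs_boruta` tibble: `feature`, `decision`
#'   (`confirmed`/`rejected`/`tentative`), `hit_count`, `n_iterations`.
#' @export
boruta_select <- function(x, y, n_iterations = 50, alpha = 0.01, seed = 1,
                          num_trees = 200, max_depth = 5) {
  x <- as.data.frame(x)
  stopifnot(ncol(x) >= 2L, n_iterations >= 20)
  x[] <- lapply(names(x), function(v) encode_covariate(x[[v]], v))
  yf <- factor(as_case_indicator(y), levels = c(0, 1))
  k <- ncol(x)
  feats <- names(x)
  hits <- stats::setNames(integer(k), feats)
  trials <- stats::setNames(integer(k), feats)
  decision <- stats::setNames(rep("tentative", k), feats)

  with_seed(seed, {
    for (iter in seq_len(n_iterations)) {
      active <- feats[decision == "tentative"]
      if (length(active) == 0L) break
      xa <- x[, active, drop = FALSE]
      shadows <- as.data.frame(lapply(xa, sample))
      names(shadows) <- paste0(".shadow_", names(shadows))
      df <- cbind(xa, shadows, .y = yf)
      rf <- ranger::ranger(
        dependent.variable.name = ".y", data = df,
        num.trees = num_trees, max.depth = max_depth,
        importance = "permutation", probability = FALSE,
        seed = sample.int(.Machine$integer.max, 1), num.threads = 1
      )
      imp <- rf$variable.importance
      max_shadow <- max(imp[names(shadows)])
      hit <- imp[active] > max_shadow
      hits[active] <- hits[active] + hit
      trials[active] <- trials[active] + 1L

      for (f in active) {
        p_hi <- stats::pbinom(hits[[f]] - 1L, trials[[f]], 0.5,
                              lower.tail = FALSE)
        p_lo <- stats::pbinom(hits[[f]], trials[[f]], 0.5)
        if (p_hi < alpha / k) decision[[f]] <- "confirmed"
        else if (p_lo < alpha / k) decision[[f]] <- "rejected"
      }
    }
  })

  out <- tibble::tibble(feature = feats, decision = unname(decision),
                        hit_count = unname(hits),
                        n_iterations = unname(trials))
  class(out) <- c("pgs_boruta", class(out))
  out
}

# stratified k-fold assignment, deterministic under the caller's RNG state
make_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# mean held-fold AUC over repeated stratified CV
cv_auc <- function(data, features, outcome, folds, repeats) {
  y <- as_case_indicator(data[[outcome]])
  aucs <- c()
  for (r in seq_len(repeats)) {
    fold <- make_folds(y, folds)
    for (f in seq_len(folds)) {
      tr <- data[fold != f, , drop = FALSE]
      te <- data[fold == f, , drop = FALSE]
      if (length(unique(as_case_indicator(te[[outcome]]))) < 2) next
      fit <- fit_logistic(tr, outcome, features)
      p <- predict(fit, te)
      aucs <- c(aucs, roc_auc(te[[outcome]], p)$auc)
    }
  }
  mean(aucs)
}

#' Evaluate the three-model suite for each polygenic score
#'
#' The full model-building protocol: stratified 80/20 split; Boruta
#' selection of covariates on the training set; then, per score, three
#' logistic models — covariates-only, score-only, covariates + score —
#' each with repeated stratified cross-validation inside the training set
#' (mean CV AUC, an internal sanity check) and a headline AUC with DeLong
#' CI on the held-out test set; finally a paired DeLong test of
#' covariates-only versus covariates + score on the test set.
#'
#' @param data Cohort tibble containing `sample_id`, `status`, the
#'   covariate columns and one numeric column per score.
#' @param score_cols Names of the per-score columns.
#' @param covariate_cols Names of candidate covariate columns.
#' @param split_fraction Training fraction (default 0.8).
#' @param cv_folds,cv_repeats Cross-validation geometry (defaults 10 and 10).
#' @param boruta Run Boruta selection (default TRUE); if nothing is
#'   confirmed, all candidates are kept with a warning.
#' @param boruta_iterations,alpha Boruta knobs (see [boruta_select()]).
#' @param seed Run-level seed; fans out deterministically to split, Boruta
#'   and CV.
#' @return A `pgs_model_suite`: list with `comparison` (tibble: `pgs_id`,
#'   `model`, `features`, `cv_auc`, `auc`, `ci_low`, `ci_high`,
#'   `delong_p`), `boruta`, `selected_covariates`, `split`, `seed`, and the
#'   per-model test-set `pgs_roc` objects.
#' @export
evaluate_models <- function(data, score_cols, covariate_cols,
                            split_fraction = 0.8, cv_folds = 10,
                            cv_repeats = 10, boruta = TRUE,
                            boruta_iterations = 50, alpha = 0.01, seed = 1) {
  stopifnot(all(score_cols %in% names(data)),
            all(covariate_cols %in% names(data)),
            "status" %in% names(data))
  split <- stratified_split(data, split_fraction, seed = seed + 1L)
  train <- data[split$split == "train", , drop = FALSE]
  test <- data[split$split == "test", , drop = FALSE]

  sel <- covariate_cols
  bor <- NULL
  if (boruta && length(covariate_cols) >= 2) {
    bor <- boruta_select(train[, covariate_cols, drop = FALSE],
                         train$status, n_iterations = boruta_iterations,
                         alpha = alpha, seed = seed + 2L)
    sel <- bor$feature[bor$decision == "confirmed"]
    if (length(sel) == 0L) {
      warning("Boruta confirmed no covariates; using all candidates")
      sel <- covariate_cols
    }
  }

  eval_one <- function(features, pgs_id, model, cv_seed) {
    fit <- fit_logistic(train, "status", features)
    p_test <- predict(fit, test)
    roc <- roc_auc(test$status, p_test)
    cv <- with_seed(cv_seed,
                    cv_auc(train, features, "status", cv_folds, cv_repeats))
    list(row = tibble::tibble(
      pgs_id = pgs_id, model = model,
      features = paste(features, collapse = ","),
      cv_auc = cv, auc = roc$auc, ci_low = roc$ci_low,
      ci_high = roc$ci_high, delong_p = NA_real_),
      pred = p_test, roc = roc)
  }

  cov_model <- eval_one(sel, NA_character_, "covariates", seed + 3L)
  rows <- list(cov_model$row)
  rocs <- list(covariates = cov_model$roc)
  for (i in seq_along(score_cols)) {
    sc <- score_cols[[i]]
    m_pgs <- eval_one(sc, sc, "pgs_only", seed + 10L + 3L * i)
    m_comb <- eval_one(c(sel, sc), sc, "combined", seed + 11L + 3L * i)
    dl <- delong_paired_test(test$status, m_comb$pred, cov_model$pred)
    m_comb$row$delong_p <- dl$p_value
    rows <- c(rows, list(m_pgs$row, m_comb$row))
    rocs[[paste0(sc, "_pgs_only")]] <- m_pgs$roc
    rocs[[paste0(sc, "_combined")]] <- m_comb$roc
  }

  structure(
    list(comparison = dplyr::bind_rows(rows), boruta = bor,
         selected_covariates = sel, split = split, seed = seed, rocs = rocs),
    class = "pgs_model_suite"
  )
}

#' @export
print.pgs_model_suite <- function(x, ...) {
  cat("<pgs_model_suite> seed =", x$seed, "| covariates:",
      paste(x$selected_covariates, collapse = ", "), "\n")
  print(x$comparison)
  invisible(x)
}
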