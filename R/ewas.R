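#' EWAS model specification
#'
#' Describes how each probe is fitted: which covariate groups enter the
#' adjustment set, the estimator (OLS with heteroscedasticity-consistent
#' sandwich standard errors, or a family random-intercept linear mixed
#' model), the HC variant, and the minimum per-probe sample size.
#'
#' The default estimator is OLS with HC3 sandwich standard errors; `HC3` is
#' the default of the sandwich covariance implementation the robust fits
#' rely on.  `robust = FALSE` gives classical OLS standard errors (used by
#' one discovery study because of its small per-ethnicity samples).
#'
#' @param covariates covariate groups to adjust for; any of `"age"`,
#'   `"sex"`, `"smoking_status"`, `"pack_years"`, `"cells"`, `"pcs"`,
#'   `"batch"`, or names of individual columns of the covariate table.
#' @param estimator `"ols_hc"` or `"family_lmm"`.
#' @param hc_type sandwich variant: `"HC0"`, `"HC1"` or `"HC3"`.
#' @param robust if `FALSE`, classical OLS standard errors are reported.
#' @param min_n minimum samples per probe; defaults to the number of model
#'   parameters plus two.
#' @return object of class `ewas_model_spec`.
#' @export
ewas_model_spec <- function(covariates = c("age", "sex", "smoking_status",
                                           "pack_years", "cells", "pcs",
                                           "batch"),
                            estimator = c("ols_hc", "family_lmm"),
                            hc_type = c("HC3", "HC1", "HC0"),
                            robust = TRUE,
                            min_n = NULL) {
  structure(list(covariates = covariates,
                 estimator = match.arg(estimator),
                 hc_type = match.arg(hc_type),
                 robust = isTRUE(robust),
                 min_n = min_n),
            class = "ewas_model_spec")
}

# Expand covariate group names into the columns of a covariate table and
# return the model matrix (with intercept).  Cell proportions sum to one,
# so the last cell column is dropped.
build_ewas_design <- function(covariates,
                              include = c("age", "sex", "smoking_status",
                                          "pack_years", "cells", "pcs",
                                          "batch")) {
  cols <- character(0)
  for (grp in include) {
    grp_cols <- switch(grp,
      cells = {
        cc <- intersect(.cell_types, names(covariates))
        if (length(cc)) head(cc, -1) else character(0)
      },
      pcs = grep("^PC[0-9]+$", names(covariates), value = TRUE),
      if (grp %in% names(covariates)) grp else NULL)
    if (is.null(grp_cols))
      stopf("covariate '%s' not found in the covariate table", grp)
    cols <- c(cols, grp_cols)
  }
  if (!length(cols)) return(matrix(1, nrow(covariates), 1,
                                   dimnames = list(NULL, "(Intercept)")))
  X <- model.matrix(stats::reformulate(cols), data = covariates)
  # drop constant non-intercept columns (e.g. single-level factors coded away)
  keep <- c(TRUE, apply(X[, -1, drop = FALSE], 2, function(v) var(v) > 0))
  X[, keep, drop = FALSE]
}

.skipped_result <- function(probe_id, n, reason) {
  data.frame(probe_id = probe_id, n = n, effect = NA_real_, se = NA_real_,
             z = NA_real_, p = NA_real_, direction = NA_character_,
             degenerate = FALSE, reason = reason, stringsAsFactors = FALSE)
}

#' Fit the association between eGFR and one methylation probe
#'
#' Regresses eGFR on the probe's beta value plus covariates by ordinary
#' least squares, with coefficient variance from the heteroscedasticity-
#' consistent sandwich estimator (or classical OLS variance when
#' `spec$robust` is `FALSE`).  Two-sided p-values use the standard normal
#' reference for the z statistic, matching the downstream fixed-effect
#' combination convention.
#'
#' A fit with (numerically) zero residual variance is flagged degenerate
#' and reported with the sentinel p-value `1e-300`.
#'
#' @param egfr outcome vector (mL/min/1.73 m^2).
#' @param beta_probe methylation beta predictor, same length.
#' @param covariates covariate data.frame (expanded via the model spec) or a
#'   numeric design matrix used as-is (an intercept is added if absent).
#' @param spec an [ewas_model_spec()].
#' @param probe_id optional label carried into the result.
#' @return one-row data.frame: probe_id, n, effect, se, z, p, direction,
#'   degenerate, reason.
#' @export
fit_probe <- function(egfr, beta_probe, covariates,
                      spec = ewas_model_spec(), probe_id = NA_character_) {
  Z <- if (is.matrix(covariates)) {
    if (!any(apply(covariates, 2, function(v) all(v == v[1]))))
      cbind(`(Intercept)` = 1, covariates) else covariates
  } else build_ewas_design(covariates, spec$covariates)
  ok <- complete.cases(egfr, beta_probe, Z)
  y <- egfr[ok]; b <- beta_probe[ok]; Z <- Z[ok, , drop = FALSE]
  n <- length(y)
  k <- ncol(Z) + 1L
  min_n <- spec$min_n %||% (k + 1L)
  if (n < min_n) return(.skipped_result(probe_id, n, "below_min_n"))

  X <- cbind(beta = b, Z)
  fit <- lm(y ~ X - 1)
  cf <- coef(fit)
  if (any(is.na(cf)))
    return(.skipped_result(probe_id, n, "rank_deficient"))

  rss <- sum(resid(fit)^2)
  degenerate <- rss < 1e-20 * max(1, sum(y^2))
  vc <- if (degenerate || !spec$robust)
    suppressWarnings(stats::vcov(fit))   # perfect fits warn in summary.lm
  else
    sandwich::vcovHC(fit, type = spec$hc_type)
  effect <- unname(cf["Xbeta"])
  se <- sqrt(vc["Xbeta", "Xbeta"])
  if (degenerate) {
    z <- NA_real_; p <- 1e-300
  } else {
    z <- effect / se
    p <- 2 * pnorm(-abs(z))
  }
  data.frame(probe_id = probe_id, n = n, effect = effect, se = se, z = z,
             p = p, direction = if (effect >= 0) "+" else "-",
             degenerate = degenerate, reason = NA_character_,
             stringsAsFactors = FALSE)
}

#' Family-aware probe fit (random intercept per family)
#'
#' Fits the same mean model as [fit_probe()] but with a Normal random
#' intercept shared by members of a family, by REML.  When every family is
#' a singleton the model is not identified and the fit reduces to OLS with
#' classical standard errors; on non-convergence the probe falls back to
#' the sandwich OLS estimator and is flagged in `reason`.
#'
#' @inheritParams fit_probe
#' @param family_ids family label per sample.
#' @return one-row data.frame as in [fit_probe()].
#' @export
fit_probe_family <- function(egfr, beta_probe, covariates, family_ids,
                             spec = ewas_model_spec(estimator = "family_lmm"),
                             probe_id = NA_character_) {
  Z <- if (is.matrix(covariates)) covariates
       else build_ewas_design(covariates, spec$covariates)
  ok <- complete.cases(egfr, beta_probe, Z, family_ids)
  y <- egfr[ok]; b <- beta_probe[ok]
  Z <- Z[ok, , drop = FALSE]; fam <- as.character(family_ids[ok])
  n <- length(y)
  k <- ncol(Z) + 1L
  min_n <- spec$min_n %||% (k + 1L)
  if (n < min_n) return(.skipped_result(probe_id, n, "below_min_n"))

  if (length(unique(fam)) == n) {
    # all singletons: family variance unidentifiable, GLS == OLS
    out <- fit_probe(y, b, Z, ewas_model_spec(robust = FALSE, min_n = min_n),
                     probe_id = probe_id)
    out$reason <- "singleton_families_ols"
    return(out)
  }

  Zc <- Z[, colnames(Z) != "(Intercept)", drop = FALSE]
  df <- data.frame(.y = y, .beta = b, Zc, .fam = fam, check.names = TRUE)
  rhs <- c(".beta", colnames(df)[!(colnames(df) %in% c(".y", ".fam"))][-1],
           "(1 | .fam)")
  form <- as.formula(paste(".y ~", paste(rhs, collapse = " + ")))
  fit <- tryCatch(
    lme4::lmer(form, data = df, REML = TRUE,
               control = lme4::lmerControl(check.conv.singular = "ignore",
                                           calc.derivs = FALSE)),
    error = function(e) NULL, warning = function(w) NULL)
  if (is.null(fit)) {
    out <- fit_probe(y, b, Z, ewas_model_spec(hc_type = spec$hc_type,
                                              min_n = min_n),
                     probe_id = probe_id)
    out$reason <- "lmm_nonconvergence_ols_fallback"
    return(out)
  }
  fx <- lme4::fixef(fit)
  effect <- unname(fx[".beta"])
  se <- sqrt(as.matrix(stats::vcov(fit))[".beta", ".beta"])
  z <- effect / se
  data.frame(probe_id = probe_id, n = n, effect = effect, se = se, z = z,
             p = 2 * pnorm(-abs(z)),
             direction = if (effect >= 0) "+" else "-",
             degenerate = FALSE, reason = NA_character_,
             stringsAsFactors = FALSE)
}

# Vectorised OLS + sandwich engine over a beta matrix with a common design.
# Frisch-Waugh residualisation gives, per probe, the same coefficient and
# HC0/HC1/HC3/classical variance as the full augmented regression.
ewas_engine_ols <- function(y, B, Z, hc_type = "HC3", robust = TRUE) {
  n <- length(y)
  k <- ncol(Z) + 1L
  qz <- qr(Z)
  ry <- qr.resid(qz, y)
  RB <- qr.resid(qz, B)
  sxx <- colSums(RB^2)
  testable <- sxx > 1e-12
  effect <- se <- rep(NA_real_, ncol(B))
  degenerate <- rep(FALSE, ncol(B))
  effect[testable] <- colSums(RB[, testable, drop = FALSE] * ry) / sxx[testable]

  RBt <- RB[, testable, drop = FALSE]
  Et <- ry - sweep(RBt, 2, effect[testable], "*")  # full-model residuals
  rss <- colSums(Et^2)
  deg <- rss < 1e-20 * max(1, sum(y^2))
  sxt <- sxx[testable]
  se_t <- if (!robust) {
    sqrt(rss / (n - k) / sxt)
  } else if (hc_type == "HC0") {
    sqrt(colSums((RBt * Et)^2) / sxt^2)
  } else if (hc_type == "HC1") {
    sqrt(colSums((RBt * Et)^2) / sxt^2 * n / (n - k))
  } else { # HC3: full-model hat values h_i = h_Z,i + rb_ij^2 / sxx_j
    Q <- qr.Q(qz)
    hz <- rowSums(Q^2)
    H <- sweep(RBt^2, 2, sxt, "/") + hz
    W <- Et / (1 - H)
    sqrt(colSums((RBt * W)^2) / sxt^2)
  }
  se[testable] <- se_t
  degenerate[testable] <- deg
  z <- effect / se
  p <- 2 * pnorm(-abs(z))
  z[degenerate & !is.na(degenerate)] <- NA_real_
  p[degenerate & !is.na(degenerate)] <- 1e-300
  list(effect = effect, se = se, z = z, p = p,
       testable = testable, degenerate = degenerate, k = k)
}

#' Run an epigenome-wide association scan on a cohort
#'
#' Fits every probe of a cohort dataset against eGFR with the requested
#' estimator and covariate adjustment, and reports the genomic inflation
#' factor over all tested probes.  The OLS/sandwich path uses a vectorised
#' residualisation engine equivalent to per-probe [fit_probe()]; the family
#' estimator loops [fit_probe_family()].
#'
#' @param dataset a `cohort_dataset` (or any list with `beta`, `egfr`,
#'   `covariates`, optionally `family_id`).
#' @param spec an [ewas_model_spec()].
#' @return object of class `ewas`: list with `results` (data.frame sorted as
#'   the input probes: probe_id, n, effect, se, z, p, direction), `lambda`,
#'   `n_tested`, `skipped` (probe_id + reason), `estimator`, `cohort_id`.
#' @export
run_ewas <- function(dataset, spec = ewas_model_spec()) {
  B <- dataset$beta
  y <- dataset$egfr
  if (is.null(B) || is.null(y)) stopf("dataset must contain beta and egfr")
  Z <- build_ewas_design(dataset$covariates, spec$covariates)
  n <- length(y)
  k <- ncol(Z) + 1L
  min_n <- spec$min_n %||% (k + 1L)
  probe_ids <- colnames(B) %||% sprintf("probe%05d", seq_len(ncol(B)))

  if (ncol(B) == 0) {
    res <- data.frame(probe_id = character(0), n = integer(0),
                      effect = numeric(0), se = numeric(0), z = numeric(0),
                      p = numeric(0), direction = character(0))
    return(structure(list(results = res, lambda = NA_real_,
                          n_tested = 0L,
                          skipped = data.frame(probe_id = character(0),
                                               reason = character(0)),
                          estimator = spec$estimator,
                          cohort_id = dataset$spec$cohort_id %||% NA_character_),
                     class = "ewas"))
  }

  complete_rows <- complete.cases(y, Z) & !apply(is.na(B), 1, any)
  if (spec$estimator == "ols_hc" && all(complete_rows)) {
    if (n < min_n) stopf("cohort smaller than min_n = %d", min_n)
    eng <- ewas_engine_ols(y, B, Z, spec$hc_type, spec$robust)
    res <- data.frame(probe_id = probe_ids, n = n, effect = eng$effect,
                      se = eng$se, z = eng$z, p = eng$p,
                      direction = ifelse(eng$effect >= 0, "+", "-"),
                      stringsAsFactors = FALSE)
    skipped <- data.frame(probe_id = probe_ids[!eng$testable],
                          reason = rep("rank_deficient", sum(!eng$testable)),
                          stringsAsFactors = FALSE)
    res <- res[eng$testable, , drop = FALSE]
  } else {
    fit1 <- if (spec$estimator == "family_lmm") {
      if (is.null(dataset$family_id)) stopf("family_lmm requires family_id")
      function(j) fit_probe_family(y, B[, j], Z, dataset$family_id, spec,
                                   probe_id = probe_ids[j])
    } else {
      function(j) fit_probe(y, B[, j], Z, spec, probe_id = probe_ids[j])
    }
    rows <- lapply(seq_len(ncol(B)), fit1)
    all_res <- do.call(rbind, rows)
    keep <- !is.na(all_res$effect)
    res <- all_res[keep, c("probe_id", "n", "effect", "se", "z", "p",
                           "direction")]
    skipped <- all_res[!keep, c("probe_id", "reason")]
  }
  rownames(res) <- NULL
  lambda <- if (nrow(res)) genomic_lambda(res$p) else NA_real_
  structure(list(results = res, lambda = lambda, n_tested = nrow(res),
                 skipped = skipped, estimator = spec$estimator,
                 cohort_id = dataset$spec$cohort_id %||% NA_character_),
            class = "ewas")
}

#' Genomic inflation factor
#'
#' Lambda is the median of the observed one-degree-of-freedom chi-square
#' statistics implied by the p-values, divided by the null median
#' (`qchisq(0.5, 1)` = 0.4549364).  Values near 1 indicate a well-calibrated
#' test statistic distribution.
#'
#' @param p_values vector of p-values in (0, 1].
#' @return lambda (positive scalar).
#' @export
genomic_lambda <- function(p_values) {
  if (!length(p_values)) stopf("empty p-value vector")
  if (any(is.na(p_values)) || any(p_values <= 0) || any(p_values > 1))
    stopf("p-values must lie in (0, 1]")
  median(qchisq(p_values, df = 1, lower.tail = FALSE)) / qchisq(0.5, 1)
}

#' @export
print.ewas <- function(x, ...) {
  cat(sprintf("EWAS scan (%s): %d probes tested, %d skipped, lambda = %.3f\n",
              x$estimator, x$n_tested, nrow(x$skipped), x$lambda))
  invisible(x)
}

#' @export
summary.ewas <- function(object, n_top = 10, ...) {
  res <- object$results[order(object$results$p), , drop = FALSE]
  cat(sprintf("EWAS scan of cohort '%s' (%s estimator)\n",
              object$cohort_id, object$estimator))
  cat(sprintf("  probes tested: %d, skipped: %d\n", object$n_tested,
              nrow(object$skipped)))
  cat(sprintf("  genomic inflation lambda: %.3f\n", object$lambda))
  cat(sprintf("  top %d probes:\n", min(n_top, nrow(res))))
  print(utils::head(res, n_top), row.names = FALSE)
  invisible(object)
}

#' @export
as.data.frame.ewas <- function(x, ...) x$results
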