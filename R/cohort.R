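#' Specify a synthetic cohort
#'
#' A cohort spec captures the study-design quantities of one simulated
#' cohort: its size, ethnicity, methylation array, the probes carrying a
#' planted eGFR association (and the target effect each should show in the
#' downstream EWAS, in eGFR units per unit beta), confounder loadings,
#' optional family structure, the logit-scale residual noise, and the seed.
#'
#' @param cohort_id cohort label.
#' @param ethnicity one of `"EA"`, `"AA"`, `"HL"`.
#' @param n_samples number of participants (>= 1).
#' @param array methylation array, `"k450"` or `"epic"`; selects which
#'   manifest probes are assayed.
#' @param planted_dmps data.frame with columns `probe_id` and `effect`
#'   (target EWAS effect, eGFR mL/min/1.73 m^2 per unit beta), or `NULL`.
#' @param confounder_config named list of loading SDs on the logit-methylation
#'   scale: `age`, `sex`, `smoking`, `pack_years`, `cell`, `batch`.  Each probe
#'   draws its loadings from Normal(0, sd).
#' @param family_config `NULL` for unrelated samples, or a list with
#'   `n_families` and `phenotype_icc` (within-family correlation of
#'   log-creatinine, in \[0,1)); an optional `methylation_icc` defaults to
#'   `phenotype_icc` and controls a shared per-family intercept on
#'   logit-methylation.
#' @param noise_sd residual SD on the logit-methylation scale.
#' @param seed RNG seed; identical specs generate identical datasets.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(cohort_id, ethnicity = c("EA", "AA", "HL"),
                        n_samples, array = c("epic", "k450"),
                        planted_dmps = NULL,
                        confounder_config = list(age = 0.004, sex = 0.05,
                                                 smoking = 0.05,
                                                 pack_years = 0.002,
                                                 cell = 0.4, batch = 0.05),
                        family_config = NULL,
                        noise_sd = 0.5,
                        seed = 1) {
  ethnicity <- match.arg(ethnicity)
  array <- match.arg(array)
  if (n_samples < 1) stopf("n_samples must be >= 1")
  if (!is.null(planted_dmps)) {
    stopifnot(is.data.frame(planted_dmps),
              all(c("probe_id", "effect") %in% names(planted_dmps)))
    if (any(!is.finite(planted_dmps$effect))) stopf("planted effects must be finite")
  }
  if (!is.null(family_config)) {
    icc <- family_config$phenotype_icc
    if (is.null(icc) || icc < 0 || icc >= 1)
      stopf("family_config$phenotype_icc must lie in [0, 1)")
    family_config$methylation_icc <- family_config$methylation_icc %||% icc
    if (is.null(family_config$n_families)) stopf("family_config needs n_families")
  }
  if (noise_sd <= 0) stopf("noise_sd must be positive")
  structure(list(cohort_id = cohort_id, ethnicity = ethnicity,
                 n_samples = as.integer(n_samples), array = array,
                 planted_dmps = planted_dmps,
                 confounder_config = confounder_config,
                 family_config = family_config,
                 noise_sd = noise_sd, seed = seed),
            class = "cohort_spec")
}

# Blood cell types emitted by the generator (reference-based deconvolution
# style fractions).  Gran dominates whole blood.
.cell_types <- c("CD4T", "CD8T", "NK", "Bcell", "Mono", "Gran")
.cell_alpha <- c(CD4T = 9, CD8T = 5, NK = 3, Bcell = 3, Mono = 4, Gran = 36)

# Dirichlet draws via normalised gammas.
rdirichlet_mat <- function(n, alpha) {
  g <- matrix(rgamma(n * length(alpha), shape = rep(alpha, each = n)), nrow = n)
  sw <- g / rowSums(g)
  colnames(sw) <- names(alpha)
  sw
}

#' Generate one synthetic cohort dataset
#'
#' Draws covariates (age, sex, smoking status and pack-years, blood cell
#' proportions, genotype PCs, batch), serum creatinine (lognormal with age
#' and sex shifts), eGFR via the CKD-EPI equation, and a samples-by-probes
#' beta matrix.  Planted probes receive a logit-scale slope on standardised
#' eGFR, calibrated by internal pilot simulation so that the downstream
#' covariate-adjusted regression of eGFR on beta recovers the target effect
#' in expectation; null probes carry confounder structure and noise only.
#' With family structure, a shared Normal intercept per family enters both
#' log-creatinine and logit-methylation.
#'
#' @param spec a [cohort_spec()].
#' @param manifest probe manifest (see [generate_probe_manifest()]).
#' @return an object of class `cohort_dataset`: list with elements `beta`
#'   (matrix, samples x probes, entries strictly inside (0,1)), `covariates`
#'   (data.frame), `creatinine`, `egfr`, `family_id` (or `NULL`), `truth`
#'   (named planted effect per probe, 0 for nulls), and `spec`.
#' @export
generate_cohort <- function(spec, manifest) {
  stopifnot(inherits(spec, "cohort_spec"))
  check_manifest(manifest)
  probes <- manifest_for_array(manifest, spec$array)
  if (!is.null(spec$planted_dmps)) {
    missing_p <- setdiff(spec$planted_dmps$probe_id, probes$probe_id)
    if (length(missing_p))
      stopf("planted probe(s) not assayed on array '%s': %s", spec$array,
            paste(missing_p, collapse = ", "))
  }
  n <- spec$n_samples
  p <- nrow(probes)

  with_seed(spec$seed, {
    ## ---- covariates -----------------------------------------------------
    age <- runif(n, 45, 80)
    sex <- rbinom(n, 1, 0.5)            # 1 = female
    smoking_status <- factor(sample(c("never", "past", "current"), n, TRUE,
                                    prob = c(0.5, 0.3, 0.2)),
                             levels = c("never", "past", "current"))
    pack_years <- ifelse(smoking_status == "never", 0,
                         rgamma(n, shape = 2, scale = 10))
    cells <- rdirichlet_mat(n, .cell_alpha)
    pcs <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("PC", 1:4)))
    batch <- factor(sample(paste0("batch", 1:2), n, TRUE))

    covariates <- data.frame(age = age, sex = sex,
                             smoking_status = smoking_status,
                             pack_years = pack_years,
                             cells, pcs, batch = batch,
                             stringsAsFactors = FALSE)

    ## ---- family structure ----------------------------------------------
    family_id <- NULL
    fam_pheno <- numeric(n)
    fam_idx <- NULL
    n_fam <- 0L
    if (!is.null(spec$family_config)) {
      fc <- spec$family_config
      n_fam <- as.integer(fc$n_families)
      family_id <- sprintf("fam%04d", sort(rep_len(seq_len(n_fam), n)))
      fam_idx <- match(family_id, unique(family_id))
      rho <- fc$phenotype_icc
      sd_scr <- 0.2                      # lognormal sigma for creatinine
      if (rho > 0) {
        u <- rnorm(n_fam, 0, sqrt(rho / (1 - rho)) * sd_scr)
        fam_pheno <- u[fam_idx]
      }
    }

    ## ---- phenotype ------------------------------------------------------
    meanlog <- log(0.72 + 0.18 * (sex == 0)) + 0.003 * (age - 60) + fam_pheno
    creatinine <- exp(rnorm(n, meanlog, 0.2))
    egfr <- compute_ckd_epi_egfr(creatinine, age,
                                 is_female = sex == 1,
                                 is_black = spec$ethnicity == "AA")

    ## ---- methylation ----------------------------------------------------
    # Bimodal probe intercepts on the logit scale (hypo / hyper / mid).
    comp <- sample(1:3, p, TRUE, prob = c(0.35, 0.35, 0.30))
    intercept <- rnorm(p, mean = c(-2.5, 2.5, 0)[comp],
                       sd = c(0.7, 0.7, 1.0)[comp])
    if (!is.null(spec$planted_dmps) && nrow(spec$planted_dmps)) {
      # planted DMPs emulate variable CpGs: trait-associated probes sit at
      # intermediate methylation, not at the saturated hypo/hyper modes
      jp <- match(spec$planted_dmps$probe_id, probes$probe_id)
      intercept[jp] <- rnorm(length(jp), 0, 1)
    }

    # Per-probe confounder loadings; the confounder design uses the same
    # quantities the downstream EWAS adjusts for, so nulls stay null.
    cc <- spec$confounder_config
    conf_design <- cbind(age = age - 60, sex = sex,
                         past = as.numeric(smoking_status == "past"),
                         current = as.numeric(smoking_status == "current"),
                         pack_years = pack_years,
                         sweep(cells[, -ncol(cells), drop = FALSE], 2,
                               colMeans(cells[, -ncol(cells), drop = FALSE])),
                         batch = as.numeric(batch) - 1)
    load_sd <- c(cc$age %||% 0, cc$sex %||% 0, cc$smoking %||% 0,
                 cc$smoking %||% 0, cc$pack_years %||% 0,
                 rep(cc$cell %||% 0, ncol(cells) - 1), cc$batch %||% 0)
    loadings <- matrix(rnorm(p * ncol(conf_design), 0, rep(load_sd, each = p)),
                       nrow = p)
    logit <- conf_design %*% t(loadings)          # n x p
    logit <- sweep(logit, 2, intercept, "+")

    if (n_fam > 0) {
      icc_m <- spec$family_config$methylation_icc
      if (icc_m > 0) {
        G <- matrix(rnorm(n_fam * p, 0, sqrt(icc_m / (1 - icc_m)) * spec$noise_sd),
                    n_fam, p)
        logit <- logit + G[fam_idx, , drop = FALSE]
      }
    }

    ## ---- planted effects -------------------------------------------------
    truth <- setNames(numeric(p), probes$probe_id)
    z_egfr <- as.numeric(scale(egfr))
    design <- build_ewas_design(covariates)
    qz <- qr(design)
    ry <- qr.resid(qz, egfr)
    if (!is.null(spec$planted_dmps) && nrow(spec$planted_dmps)) {
      for (i in seq_len(nrow(spec$planted_dmps))) {
        pid <- spec$planted_dmps$probe_id[i]
        target <- spec$planted_dmps$effect[i]
        j <- match(pid, probes$probe_id)
        slope <- calibrate_logit_slope(target, logit[, j], z_egfr, qz, ry,
                                       spec$noise_sd)
        logit[, j] <- logit[, j] + slope * z_egfr
        truth[pid] <- target
      }
    }

    logit <- logit + matrix(rnorm(n * p, 0, spec$noise_sd), n, p)
    beta <- plogis(logit)
    # logit is finite, so plogis lies strictly inside (0,1); guard against
    # round-to-one at extreme magnitudes anyway.
    eps <- .Machine$double.eps
    beta[beta >= 1] <- 1 - eps
    beta[beta <= 0] <- eps
    dimnames(beta) <- list(sprintf("s%04d", seq_len(n)), probes$probe_id)

    structure(list(beta = beta, covariates = covariates,
                   creatinine = creatinine, egfr = egfr,
                   family_id = family_id, truth = truth, spec = spec),
              class = "cohort_dataset")
  })
}

# Solve, by monotone bracketing + uniroot on a common-random-numbers pilot
# simulation, for the logit-scale slope on standardised eGFR that makes the
# downstream covariate-adjusted regression of eGFR on beta recover `target`
# in expectation.  `base_logit` is the probe's systematic logit component,
# `qz` the QR of the adjustment design, `ry` the eGFR residuals on it.
calibrate_logit_slope <- function(target, base_logit, z_egfr, qz, ry,
                                  noise_sd, nrep = 25) {
  if (target == 0) return(0)
  n <- length(base_logit)
  E <- matrix(rnorm(n * nrep, 0, noise_sd), n, nrep)
  syy <- sum(ry * ry)
  achieved <- function(s) {
    B <- plogis(base_logit + s * z_egfr + E)
    rb <- qr.resid(qz, B)
    mean(colSums(rb * ry) / colSums(rb * rb))
  }
  sgn <- sign(target)
  f <- function(s) sgn * (achieved(sgn * s))   # work on the positive branch
  tgt <- abs(target)
  lo <- 0; flo <- 0
  hi <- 0.1
  repeat {
    fhi <- f(hi)
    if (fhi >= tgt) break
    if (fhi < flo || hi > 64)
      stopf("target effect %.3g is not attainable for this probe (max ~%.3g)",
            target, sgn * max(fhi, flo))
    lo <- hi; flo <- fhi
    hi <- hi * 2
  }
  root <- stats::uniroot(function(s) f(s) - tgt, lower = lo, upper = hi,
                         tol = 1e-4)$root
  sgn * root
}

#' @export
print.cohort_dataset <- function(x, ...) {
  sp <- x$spec
  cat(sprintf("Synthetic cohort '%s' (%s, array %s)\n",
              sp$cohort_id, sp$ethnicity, sp$array))
  cat(sprintf("  samples: %d   probes: %d   planted DMPs: %d\n",
              nrow(x$beta), ncol(x$beta), sum(x$truth != 0)))
  cat(sprintf("  eGFR: median %.1f [%.1f, %.1f] mL/min/1.73m2\n",
              median(x$egfr), quantile(x$egfr, 0.025), quantile(x$egfr, 0.975)))
  if (!is.null(x$family_id))
    cat(sprintf("  families: %d\n", length(unique(x$family_id))))
  invisible(x)
}
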