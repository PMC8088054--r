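#' Detection p-value filtering of probes and samples
#'
#' Applies the standard array QC rule: first remove probes whose detection
#' p-value exceeds `probe_p` in strictly more than `probe_frac` of samples,
#' then remove samples whose detection p exceeds `probe_p` in strictly more
#' than `sample_frac` of the retained probes.  Fractions are strict (">"),
#' and sample failure rates are evaluated against the post-probe-filter
#' probe set.
#'
#' @param beta samples x probes beta matrix.
#' @param detp detection p-value matrix of identical shape.
#' @param probe_p detection p-value cutoff.
#' @param probe_frac maximum tolerated failing-sample fraction per probe.
#' @param sample_frac maximum tolerated failing-probe fraction per sample.
#' @return list with `beta` (filtered) and `report`, a `qc_report` listing
#'   removed probes/samples and before/after counts.
#' @export
filter_by_detection <- function(beta, detp, probe_p = 0.01,
                                probe_frac = 0.10, sample_frac = 0.01) {
  if (!identical(dim(beta), dim(detp)))
    stopf("beta and detp must have identical dimensions")
  fail <- detp > probe_p
  probe_fail_frac <- colMeans(fail)
  bad_probes <- probe_fail_frac > probe_frac
  fail2 <- fail[, !bad_probes, drop = FALSE]
  sample_fail_frac <- if (ncol(fail2)) rowMeans(fail2) else rep(0, nrow(fail))
  bad_samples <- sample_fail_frac > sample_frac

  out <- beta[!bad_samples, !bad_probes, drop = FALSE]
  if (!length(out)) warnf("detection filtering left an empty matrix")
  report <- structure(list(
    probes_removed_detection = colnames(beta)[bad_probes] %||%
      which(bad_probes),
    samples_removed_detection = rownames(beta)[bad_samples] %||%
      which(bad_samples),
    probes_removed_blacklist = character(0),
    n_probes_before = ncol(beta), n_probes_after = ncol(out),
    n_samples_before = nrow(beta), n_samples_after = nrow(out)),
    class = "qc_report")
  list(beta = out, report = report)
}

#' Remove blacklisted probes
#'
#' Removes probes on a blacklist (cross-reactive probes, probes overlapping
#' polymorphic sites in the relevant ancestry group, ...).  Blacklist
#' entries absent from the matrix are ignored but counted.
#'
#' @param beta samples x probes beta matrix with probe ids as column names.
#' @param blacklist character vector of probe ids to drop.
#' @param manifest optional manifest (unused for filtering; retained so
#'   callers can pass the probe universe alongside).
#' @return list with `beta` and a `qc_report`.
#' @export
remove_blacklisted_probes <- function(beta, blacklist, manifest = NULL) {
  present <- intersect(blacklist, colnames(beta))
  absent <- setdiff(blacklist, colnames(beta))
  out <- beta[, !(colnames(beta) %in% present), drop = FALSE]
  if (!ncol(out)) warnf("blacklist removed every probe")
  report <- structure(list(
    probes_removed_detection = character(0),
    samples_removed_detection = character(0),
    probes_removed_blacklist = present,
    n_blacklist_absent = length(absent),
    n_probes_before = ncol(beta), n_probes_after = ncol(out),
    n_samples_before = nrow(beta), n_samples_after = nrow(out)),
    class = "qc_report")
  list(beta = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report\n")
  cat(sprintf("  probes:  %d -> %d (%d detection, %d blacklist)\n",
              x$n_probes_before, x$n_probes_after,
              length(x$probes_removed_detection),
              length(x$probes_removed_blacklist)))
  cat(sprintf("  samples: %d -> %d (%d detection)\n",
              x$n_samples_before, x$n_samples_after,
              length(x$samples_removed_detection)))
  if (!is.null(x$n_blacklist_absent) && x$n_blacklist_absent > 0)
    cat(sprintf("  blacklist entries absent from matrix: %d\n",
                x$n_blacklist_absent))
  invisible(x)
}

#' Beta to M-value transform
#'
#' \eqn{M = \log_2(\beta / (1 - \beta))}, with betas clamped to
#' `[epsilon, 1 - epsilon]` first so the transform stays finite.  Strictly
#' increasing on the clamped domain; [m_to_beta()] inverts it.
#'
#' @param beta beta values in \[0, 1\] (vector or matrix).
#' @param epsilon clamp distance from the boundary.
#' @return M-values of the same shape.
#' @export
beta_to_m <- function(beta, epsilon = 1e-6) {
  if (any(beta < 0 | beta > 1, na.rm = TRUE))
    stopf("beta values must lie in [0, 1]")
  b <- pmin(pmax(beta, epsilon), 1 - epsilon)
  out <- log2(b / (1 - b))
  if (is.matrix(beta)) dim(out) <- dim(beta)
  if (!is.null(dimnames(beta))) dimnames(out) <- dimnames(beta)
  out
}

#' Inverse of the M-value transform
#'
#' @param m M-values.
#' @return beta values in (0, 1).
#' @export
m_to_beta <- function(m) {
  x <- 2^m
  x / (1 + x)
}
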