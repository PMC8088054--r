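#' Fixed-effect inverse-variance meta-analysis
#'
#' Combines per-study summary statistics probe-by-probe with weights
#' \eqn{w_i = 1/SE_i^2}: combined effect \eqn{\sum w_i b_i / \sum w_i},
#' combined SE \eqn{(\sum w_i)^{-1/2}}, z and two-sided normal p, plus
#' Cochran's Q, \eqn{I^2}, and a per-study direction string.  Probes
#' contributed by fewer than `min_studies` studies are excluded (with the
#' count reported in the `dropped` attribute), mirroring the
#' minimum-two-studies rule of multi-cohort EWAS practice.
#'
#' @param summaries data.frame of per-study results with columns `probe_id`,
#'   `effect`, `se`, and optionally `study_id`, `n`, `ethnicity`.
#' @param min_studies minimum contributing studies per probe.
#' @return object of class `ewas_meta`: a data.frame with columns probe_id,
#'   effect, se, z, p, q_cochran, i_squared, df, n_studies, n_total,
#'   direction; attribute `dropped` holds the excluded probe ids.
#' @export
ivw_meta <- function(summaries, min_studies = 2) {
  stopifnot(all(c("probe_id", "effect", "se") %in% names(summaries)))
  if (any(!is.finite(summaries$se)) || any(summaries$se <= 0))
    stopf("all standard errors must be positive and finite")
  if (!"study_id" %in% names(summaries))
    summaries$study_id <- sprintf("study%02d", seq_len(nrow(summaries)))
  if (!"n" %in% names(summaries)) summaries$n <- NA_integer_

  keep_map <- min_studies_filter(split(seq_len(nrow(summaries)),
                                       summaries$probe_id), k = min_studies)
  dropped <- setdiff(unique(summaries$probe_id), names(keep_map))

  rows <- lapply(names(keep_map), function(pid) {
    s <- summaries[keep_map[[pid]], , drop = FALSE]
    s <- s[order(s$study_id), , drop = FALSE]
    w <- 1 / s$se^2
    eff <- sum(w * s$effect) / sum(w)
    se <- 1 / sqrt(sum(w))
    z <- eff / se
    q <- sum(w * (s$effect - eff)^2)
    df <- nrow(s) - 1L
    i2 <- if (q > 0) max(0, (q - df) / q) * 100 else 0
    data.frame(probe_id = pid, effect = eff, se = se, z = z,
               p = 2 * pnorm(-abs(z)), q_cochran = q, i_squared = i2,
               df = df, n_studies = nrow(s),
               n_total = if (all(is.na(s$n))) NA_integer_ else
                 sum(s$n, na.rm = TRUE),
               direction = paste(ifelse(s$effect >= 0, "+", "-"),
                                 collapse = ""),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(probe_id = character(0))
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  class(out) <- c("ewas_meta", "data.frame")
  out
}

#' Drop probes observed in fewer than k studies
#'
#' @param probe_to_summaries named list mapping probe_id to per-study entries.
#' @param k minimum number of contributing studies.
#' @return the filtered mapping (attribute `n_dropped` records the count).
#' @export
min_studies_filter <- function(probe_to_summaries, k = 2) {
  keep <- vapply(probe_to_summaries, function(x) length(x) >= k, logical(1))
  out <- probe_to_summaries[keep]
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Back out a standard error from an effect and two-sided p-value
#'
#' Inverts the normal-theory relation \eqn{p = 2\Phi(-|b|/SE)}:
#' \eqn{SE = |b| / \Phi^{-1}(1 - p/2)}.  Used to reconstruct standard
#' errors from published tables that print only effect and p.
#'
#' @param effect nonzero effect estimate.
#' @param p two-sided p-value strictly inside (0, 1).
#' @return standard error.
#' @export
se_from_effect_p <- function(effect, p) {
  if (any(p <= 0) || any(p >= 1)) stopf("p must lie strictly in (0, 1)")
  if (any(effect == 0)) stopf("effect must be nonzero")
  abs(effect) / qnorm(p / 2, lower.tail = FALSE)
}

#' Benjamini-Hochberg discovery at a given FDR
#'
#' Step-up FDR control; q-values come from `p.adjust(method = "BH")` and a
#' probe is discovered when its q-value is at most `alpha`.
#'
#' @param p_values p-values in (0, 1].
#' @param alpha target false-discovery rate.
#' @return list with `q_values` and the integer `rejected` index set.
#' @export
bh_fdr <- function(p_values, alpha = 0.05) {
  if (!length(p_values)) return(list(q_values = numeric(0), rejected = integer(0)))
  if (any(p_values <= 0) || any(p_values > 1)) stopf("p-values must lie in (0, 1]")
  q <- p.adjust(p_values, method = "BH")
  list(q_values = q, rejected = which(q <= alpha))
}

#' Benjamini-Yekutieli corrected q-values
#'
#' Step-up correction valid under arbitrary dependence, with the harmonic
#' factor \eqn{c(m) = \sum_{i=1}^m 1/i}; wraps `p.adjust(method = "BY")`.
#'
#' @param p_values p-values in (0, 1].
#' @return q-values, clipped at 1 and monotone.
#' @export
by_correct <- function(p_values) {
  if (!length(p_values)) return(numeric(0))
  if (any(p_values <= 0) || any(p_values > 1)) stopf("p-values must lie in (0, 1]")
  p.adjust(p_values, method = "BY")
}

#' Bonferroni-adjusted significance threshold
#'
#' @param alpha family-wise error rate.
#' @param m number of tests (>= 1).
#' @return `alpha / m`.
#' @examples
#' bonferroni_threshold(0.05, 78)  # 6.4e-04 at printed precision
#' @export
bonferroni_threshold <- function(alpha = 0.05, m) {
  if (m < 1) stopf("m must be >= 1")
  alpha / m
}

#' Call replication of discovery probes
#'
#' A discovery probe replicates when its replication p-value is at or below
#' the Bonferroni threshold for the number of discovery probes carried
#' forward, and (by default) the replication effect direction matches the
#' discovery direction.  Probes absent from the replication table are
#' reported as untested, not dropped.
#'
#' @param discovery,replication `ewas_meta` results (or data.frames with
#'   probe_id, effect, p).
#' @param alpha family-wise alpha for the Bonferroni threshold.
#' @param require_concordance require matching effect signs.
#' @param m number of tests behind the threshold; defaults to the number of
#'   discovery probes.
#' @return data.frame with one row per discovery probe: discovery and
#'   replication effect/p, the threshold, concordance and replication flags,
#'   and a reason for non-replication.
#' @export
call_replication <- function(discovery, replication, alpha = 0.05,
                             require_concordance = TRUE, m = nrow(discovery)) {
  thr <- bonferroni_threshold(alpha, m)
  idx <- match(discovery$probe_id, replication$probe_id)
  rep_eff <- replication$effect[idx]
  rep_p <- replication$p[idx]
  concordant <- sign(discovery$effect) == sign(rep_eff)
  passes_p <- !is.na(rep_p) & rep_p <= thr
  replicated <- passes_p & (!require_concordance | (concordant %in% TRUE))
  reason <- ifelse(is.na(idx), "untested",
            ifelse(!passes_p, "above_threshold",
            ifelse(!replicated, "discordant", NA_character_)))
  data.frame(probe_id = discovery$probe_id,
             discovery_effect = discovery$effect, discovery_p = discovery$p,
             replication_effect = rep_eff, replication_p = rep_p,
             bonferroni_threshold = thr,
             concordant = concordant, replicated = replicated,
             reason = reason, stringsAsFactors = FALSE)
}

#' Combine discovery and replication estimates for one probe
#'
#' A two-entry fixed-effect inverse-variance combination of the discovery
#' and replication summary estimates, as shown in the combined column of
#' multi-stage EWAS result tables.
#'
#' @param discovery,replication single-probe entries: lists or one-row
#'   data.frames with `effect` and `se` (or `p`, from which the SE is
#'   reconstructed via [se_from_effect_p()]).
#' @return one-row `ewas_meta` data.frame.
#' @export
combine_discovery_replication <- function(discovery, replication) {
  if (is.null(discovery) || !length(discovery) ||
      is.null(replication) || !length(replication))
    stopf("missing discovery or replication entry")
  one <- function(x, stage) {
    if (is.null(x)) stopf("missing %s entry", stage)
    se <- x$se %||% se_from_effect_p(x$effect, x$p)
    data.frame(probe_id = x$probe_id %||% "probe", study_id = stage,
               effect = x$effect, se = se, stringsAsFactors = FALSE)
  }
  d <- one(as.list(discovery), "discovery")
  r <- one(as.list(replication), "replication")
  if (d$probe_id != r$probe_id)
    stopf("discovery and replication refer to different probes")
  ivw_meta(rbind(d, r), min_studies = 2)
}

#' @export
print.ewas_meta <- function(x, ...) {
  cat(sprintf("Fixed-effect IVW meta-analysis: %d probes (%d dropped by the minimum-study rule)\n",
              nrow(x), length(attr(x, "dropped"))))
  NextMethod()
}
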