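# Base-graphics diagnostics: QQ and Manhattan plots for EWAS scans, forest
# plots for meta-analyses, and tissue enrichment profiles.

#' Plot an EWAS scan
#'
#' `type = "qq"` draws observed vs expected -log10 p with the genomic
#' inflation factor in the legend; `type = "manhattan"` plots -log10 p
#' along the genome (requires a manifest for probe positions).
#'
#' @param x an `ewas` object.
#' @param type `"qq"` or `"manhattan"`.
#' @param manifest probe manifest (manhattan only).
#' @param ... passed to [graphics::plot()].
#' @export
plot.ewas <- function(x, type = c("qq", "manhattan"), manifest = NULL, ...) {
  type <- match.arg(type)
  p <- x$results$p
  if (type == "qq") {
    obs <- sort(-log10(p))
    exp <- sort(-log10(stats::ppoints(length(p))))
    graphics::plot(exp, obs, pch = 16, cex = 0.5,
                   xlab = expression(Expected ~ -log[10](p)),
                   ylab = expression(Observed ~ -log[10](p)), ...)
    abline(0, 1, col = "red")
    legend("topleft", bty = "n",
           legend = sprintf("lambda = %.3f", x$lambda))
  } else {
    if (is.null(manifest)) stopf("manhattan plot needs a manifest")
    idx <- match(x$results$probe_id, manifest$probe_id)
    chrom <- manifest$chrom[idx]
    pos <- manifest$pos[idx]
    chroms <- unique(chrom[order(match(chrom, unique(manifest$chrom)))])
    offset <- setNames(cumsum(c(0, head(vapply(chroms, function(ch)
      max(pos[chrom == ch]), numeric(1)), -1))), chroms)
    gx <- pos + offset[chrom]
    col <- grey(c(0.2, 0.6))[(match(chrom, chroms) %% 2) + 1]
    graphics::plot(gx, -log10(x$results$p), col = col, pch = 16, cex = 0.4,
                   xaxt = "n", xlab = "chromosome",
                   ylab = expression(-log[10](p)), ...)
    mid <- vapply(chroms, function(ch) mean(range(gx[chrom == ch])),
                  numeric(1))
    axis(1, at = mid, labels = sub("^chr", "", chroms), las = 2)
  }
  invisible(x)
}

#' Forest plot of per-study effects for one probe
#'
#' Per-study effect estimates with 95% intervals (effect +/- 1.96 SE) and,
#' below them, the fixed-effect combined estimate.
#'
#' @param summaries per-study summary data.frame (probe_id, study_id,
#'   effect, se).
#' @param probe_id the probe to plot.
#' @param meta optional `ewas_meta` table holding the combined estimate.
#' @param ... passed to [graphics::plot()].
#' @export
forest_plot <- function(summaries, probe_id, meta = NULL, ...) {
  s <- summaries[summaries$probe_id == probe_id, , drop = FALSE]
  if (!nrow(s)) stopf("probe '%s' not found in summaries", probe_id)
  s <- s[order(s$study_id), , drop = FALSE]
  labels <- s$study_id
  eff <- s$effect
  lo <- eff - 1.96 * s$se
  hi <- eff + 1.96 * s$se
  if (!is.null(meta)) {
    m <- meta[meta$probe_id == probe_id, , drop = FALSE]
    if (nrow(m)) {
      labels <- c(labels, "combined (FE)")
      eff <- c(eff, m$effect)
      lo <- c(lo, m$effect - 1.96 * m$se)
      hi <- c(hi, m$effect + 1.96 * m$se)
    }
  }
  yy <- rev(seq_along(eff))
  graphics::plot(range(c(lo, hi, 0)), range(yy) + c(-0.5, 0.5), type = "n",
                 yaxt = "n", xlab = "effect (eGFR per unit beta)",
                 ylab = "", main = probe_id, ...)
  segments(lo, yy, hi, yy)
  points(eff, yy, pch = c(rep(15, nrow(s)), 18)[seq_along(eff)])
  abline(v = 0, lty = 2, col = "grey40")
  axis(2, at = yy, labels = labels, las = 1, cex.axis = 0.8)
  invisible(NULL)
}

#' Plot a tissue enrichment profile
#'
#' -log10 empirical p per tissue, ordered by significance, with the
#' Benjamini-Yekutieli 0.05 significance marked.
#'
#' @param x an `enrichment_result`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.enrichment_result <- function(x, ...) {
  lp <- -log10(x$empirical_p)
  graphics::plot(seq_along(lp), lp, pch = 16,
                 col = ifelse(x$by_q <= 0.05, "black", "grey60"),
                 xaxt = "n", xlab = "", ylab = expression(-log[10](p)), ...)
  axis(1, at = seq_along(lp), labels = x$tissue, las = 2, cex.axis = 0.7)
  invisible(x)
}
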