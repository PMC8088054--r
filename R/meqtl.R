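# cis-meQTL scanning on M-values and empirical resampling overlap tests
# connecting GWAS SNPs, meQTL target CpGs, EWAS DMPs and tissue hotspots.

#' Enumerate cis SNP-CpG pairs
#'
#' All same-chromosome SNP-CpG pairs whose distance is at most `window`
#' base pairs (boundary inclusive, the conventional +/-1 Mb cis window).
#'
#' @param snp_manifest data.frame with snp_id, chrom, pos (1-based).
#' @param cpg_manifest probe manifest (probe_id, chrom, pos).
#' @param window cis window in bp.
#' @return data.frame with snp_id, cpg_id, distance.
#' @export
cis_pairs <- function(snp_manifest, cpg_manifest, window = 1e6) {
  if (window <= 0) stopf("window must be positive")
  rows <- lapply(intersect(unique(snp_manifest$chrom),
                           unique(cpg_manifest$chrom)), function(ch) {
    s <- snp_manifest[snp_manifest$chrom == ch, , drop = FALSE]
    g <- cpg_manifest[cpg_manifest$chrom == ch, , drop = FALSE]
    d <- abs(outer(s$pos, g$pos, "-"))
    hit <- which(d <= window, arr.ind = TRUE)
    if (!nrow(hit)) return(NULL)
    data.frame(snp_id = s$snp_id[hit[, 1]],
               cpg_id = g$probe_id[hit[, 2]],
               distance = d[hit], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(snp_id = character(0), cpg_id = character(0),
                      distance = numeric(0))
  rownames(out) <- NULL
  out
}

#' Nominal cis-meQTL scan
#'
#' For each cis pair, fits the additive model M ~ dosage + covariates by
#' least squares and reports the per-allele slope (M-units), its classical
#' standard error, and the two-sided t-reference p-value.  Monomorphic
#' SNPs are skipped with a reason.
#'
#' @param m_matrix samples x CpGs M-value matrix.
#' @param genotypes a `genotype_set` (or list with a `dosage` matrix).
#' @param covariate_matrix numeric covariate matrix (no intercept needed) or
#'   `NULL` for an intercept-only adjustment.
#' @param pairs cis pair table from [cis_pairs()].
#' @return data.frame of `meqtl_record`s: snp_id, cpg_id, distance, effect,
#'   se, p; skipped pairs in attribute `skipped`.
#' @export
meqtl_scan <- function(m_matrix, genotypes, covariate_matrix = NULL, pairs) {
  dosage <- genotypes$dosage
  if (nrow(m_matrix) != nrow(dosage))
    stopf("sample dimensions of M matrix and dosages differ")
  n <- nrow(m_matrix)
  Z <- cbind(`(Intercept)` = rep(1, n), covariate_matrix)
  qz <- qr(Z)
  k <- ncol(Z) + 1L
  if (n <= k) stopf("too few samples for the covariate model")

  miss <- setdiff(unique(pairs$snp_id), colnames(dosage))
  if (length(miss)) stopf("unknown SNP(s): %s", paste(miss, collapse = ", "))
  miss <- setdiff(unique(pairs$cpg_id), colnames(m_matrix))
  if (length(miss)) stopf("unknown CpG(s): %s", paste(miss, collapse = ", "))

  RG <- qr.resid(qz, dosage[, unique(pairs$snp_id), drop = FALSE])
  RM <- qr.resid(qz, m_matrix[, unique(pairs$cpg_id), drop = FALSE])

  eff <- se <- p <- rep(NA_real_, nrow(pairs))
  mono <- logical(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    g <- dosage[, pairs$snp_id[i]]
    if (var(g) == 0) { mono[i] <- TRUE; next }
    rg <- RG[, pairs$snp_id[i]]
    rm_ <- RM[, pairs$cpg_id[i]]
    sxx <- sum(rg^2)
    b <- sum(rg * rm_) / sxx
    rss <- sum((rm_ - b * rg)^2)
    s <- sqrt(rss / (n - k) / sxx)
    eff[i] <- b; se[i] <- s
    p[i] <- 2 * pt(-abs(b / s), df = n - k)
  }
  out <- data.frame(snp_id = pairs$snp_id, cpg_id = pairs$cpg_id,
                    distance = pairs$distance, effect = eff, se = se, p = p,
                    stringsAsFactors = FALSE)
  skipped <- data.frame(snp_id = pairs$snp_id[mono],
                        cpg_id = pairs$cpg_id[mono],
                        reason = rep("monomorphic", sum(mono)),
                        stringsAsFactors = FALSE)
  out <- out[!mono, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Classify meQTL CpGs by nominal association
#'
#' A CpG is "associated" when any of its records has p below `assoc_p`, and
#' "non-associated" when all of its records have p above `nonassoc_p`; CpGs
#' in the gap belong to neither set.  The two sets are disjoint by
#' construction.
#'
#' @param records meQTL record table from [meqtl_scan()].
#' @param assoc_p,nonassoc_p nominal thresholds.
#' @return list with character vectors `associated` and `non_associated`.
#' @export
classify_meqtl_cpgs <- function(records, assoc_p = 0.05, nonassoc_p = 0.95) {
  if (!nrow(records))
    return(list(associated = character(0), non_associated = character(0)))
  min_p <- tapply(records$p, records$cpg_id, min)
  list(associated = names(min_p)[min_p < assoc_p],
       non_associated = names(min_p)[min_p > nonassoc_p])
}

# Shared resampling machinery: given per-SNP "hit CpG" sets, the observed
# statistic counts distinct hit CpGs across the query SNPs; each simulation
# redraws |query| SNPs uniformly without replacement from the background
# pool and recomputes it.
.snp_set_overlap_test <- function(per_snp_hits, query_snps, background_pool,
                                  n_sims, seed, statistic_definition) {
  if (length(background_pool) < length(query_snps))
    stopf("background pool (%d) smaller than the query (%d)",
          length(background_pool), length(query_snps))
  stat <- function(snps) {
    length(unique(unlist(per_snp_hits[snps], use.names = FALSE)))
  }
  observed <- stat(query_snps)
  k <- length(query_snps)
  bg <- with_seed(seed, vapply(seq_len(n_sims), function(i) {
    stat(sample(background_pool, k))
  }, numeric(1)))
  ee <- empirical_enrichment(observed, bg)
  structure(list(observed = observed, n_background_sets = n_sims,
                 background_mean = ee$mean, background_sd = ee$sd,
                 empirical_p = ee$empirical_p,
                 statistic_definition = statistic_definition),
            class = "overlap_test")
}

#' Empirical overlap test: GWAS SNPs, meQTL targets, EWAS DMPs
#'
#' Counts the distinct CpGs that are significant meQTL targets of at least
#' one query SNP and also belong to the DMP set, then compares the count
#' with `n_sims` random SNP sets of the same size drawn uniformly without
#' replacement from the background pool.  Empirical p uses the add-one
#' estimator.
#'
#' @param query_snps SNP ids of interest (e.g. trait GWAS SNPs).
#' @param meqtl_records meQTL record table with snp_id, cpg_id, p.
#' @param dmp_cpgs CpG ids of the EWAS DMP set.
#' @param background_pool SNP ids to resample from.
#' @param n_sims number of background simulations.
#' @param seed RNG seed.
#' @param sig_p records with p below this count as significant meQTLs.
#' @return object of class `overlap_test`.
#' @export
snp_meqtl_dmp_overlap_test <- function(query_snps, meqtl_records, dmp_cpgs,
                                       background_pool, n_sims = 1000,
                                       seed = 1, sig_p = 0.05) {
  sig <- meqtl_records[meqtl_records$p < sig_p, , drop = FALSE]
  sig <- sig[sig$cpg_id %in% dmp_cpgs, , drop = FALSE]
  per_snp <- split(sig$cpg_id, sig$snp_id)
  .snp_set_overlap_test(per_snp, query_snps, background_pool, n_sims, seed,
                        "distinct DMP CpGs that are significant meQTL targets of >=1 query SNP")
}

#' Empirical overlap test: meQTL target CpGs vs tissue hotspots
#'
#' Counts the distinct significant meQTL target CpGs of the query SNPs whose
#' interrogated base falls inside the tissue's open-chromatin intervals,
#' against the same uniform SNP-resampling null as
#' [snp_meqtl_dmp_overlap_test()].
#'
#' @inheritParams snp_meqtl_dmp_overlap_test
#' @param intervals an `interval_collection`.
#' @param tissue tissue whose intervals are used.
#' @param cpg_manifest manifest giving CpG positions.
#' @return object of class `overlap_test`.
#' @export
meqtl_hotspot_overlap_test <- function(query_snps, meqtl_records, intervals,
                                       tissue, cpg_manifest, background_pool,
                                       n_sims = 1000, seed = 1, sig_p = 0.05) {
  sig <- meqtl_records[meqtl_records$p < sig_p, , drop = FALSE]
  targets <- unique(sig$cpg_id)
  idx <- match(targets, cpg_manifest$probe_id)
  if (anyNA(idx))
    stopf("meQTL target CpG(s) missing from manifest: %s",
          paste(targets[is.na(idx)], collapse = ", "))
  if (!tissue %in% names(intervals)) stopf("unknown tissue '%s'", tissue)
  in_hotspot <- targets[
    probe_overlap_indicator(cpg_manifest[idx, , drop = FALSE],
                            intervals[tissue])[, 1]]
  sig <- sig[sig$cpg_id %in% in_hotspot, , drop = FALSE]
  per_snp <- split(sig$cpg_id, sig$snp_id)
  .snp_set_overlap_test(per_snp, query_snps, background_pool, n_sims, seed,
                        "distinct significant meQTL target CpGs of query SNPs inside tissue hotspots")
}

#' Fraction of kidney meQTL CpGs that are also blood meQTL CpGs
#'
#' @param kidney_meqtl_cpgs nonempty CpG id vector (kidney).
#' @param blood_meqtl_cpgs CpG id vector (blood).
#' @return percentage, rounded to one decimal.
#' @export
blood_kidney_overlap_fraction <- function(kidney_meqtl_cpgs,
                                          blood_meqtl_cpgs) {
  kidney <- unique(kidney_meqtl_cpgs)
  if (!length(kidney)) stopf("kidney CpG set is empty")
  round(100 * length(intersect(kidney, blood_meqtl_cpgs)) / length(kidney), 1)
}

#' @export
print.overlap_test <- function(x, ...) {
  cat("Empirical overlap test\n")
  cat(sprintf("  statistic: %s\n", x$statistic_definition))
  cat(sprintf("  observed %d vs background mean %.3f (sd %.3f) over %d sets\n",
              x$observed, x$background_mean, x$background_sd,
              x$n_background_sets))
  cat(sprintf("  empirical p = %.4g\n", x$empirical_p))
  invisible(x)
}
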