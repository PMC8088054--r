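# Synthetic fixtures accompanying the cohort generator: detection p-value
# matrices, genotype dosages with planted cis-meQTL links, and tissue
# open-chromatin interval collections with a planted enriched tissue.

#' Generate a detection p-value matrix with designated failures
#'
#' Background cells draw detection p from Uniform(0, 0.005) (comfortably
#' below the 0.01 QC cutoff); every (probe, sample) cell designated to fail
#' draws from (0.01, 1].
#'
#' @param dataset a `cohort_dataset` (only its beta dimnames are used).
#' @param fail_probes named list: probe_id -> sample ids (or a fraction in
#'   (0,1\] of randomly chosen samples) in which that probe fails.
#' @param fail_samples named list: sample_id -> probe ids (or fraction) in
#'   which that sample fails.
#' @param seed RNG seed.
#' @return matrix of detection p-values, same dimnames as `dataset$beta`.
#' @export
generate_detection_p <- function(dataset, fail_probes = list(),
                                 fail_samples = list(), seed = 1) {
  B <- dataset$beta
  probes <- colnames(B); samples <- rownames(B)
  bad_p <- setdiff(names(fail_probes), probes)
  bad_s <- setdiff(names(fail_samples), samples)
  if (length(bad_p)) stopf("unknown probe(s): %s", paste(bad_p, collapse = ", "))
  if (length(bad_s)) stopf("unknown sample(s): %s", paste(bad_s, collapse = ", "))

  with_seed(seed, {
    detp <- matrix(runif(length(B), 0, 0.005), nrow(B), ncol(B),
                   dimnames = dimnames(B))
    resolve <- function(spec, universe) {
      if (is.numeric(spec) && length(spec) == 1 && spec > 0 && spec <= 1)
        sample(universe, ceiling(spec * length(universe)))
      else {
        unknown <- setdiff(spec, universe)
        if (length(unknown)) stopf("unknown id(s): %s",
                                   paste(unknown, collapse = ", "))
        spec
      }
    }
    for (pid in names(fail_probes)) {
      rows <- resolve(fail_probes[[pid]], samples)
      detp[rows, pid] <- runif(length(rows), 0.01 + 1e-9, 1)
    }
    for (sid in names(fail_samples)) {
      cols <- resolve(fail_samples[[sid]], probes)
      detp[sid, cols] <- runif(length(cols), 0.01 + 1e-9, 1)
    }
    detp
  })
}

#' Generate Hardy-Weinberg genotype dosages with planted cis-meQTL links
#'
#' Dosages are additive minor-allele counts drawn Binomial(2, MAF) per SNP,
#' with MAFs uniform over `maf_range`.  Planted links record the truth
#' (SNP, CpG, effect in M-units per allele); apply them to an M-value
#' matrix with [plant_meqtl_effects()].
#'
#' @param n_samples number of samples (rows).
#' @param snp_manifest data.frame with snp_id, chrom, pos (1-based).
#' @param maf_range MAF bounds, inside (0, 0.5].
#' @param planted_meqtls data.frame with snp_id, probe_id, effect; or NULL.
#' @param probe_ids universe of CpG ids the planted links may reference
#'   (defaults to accepting any).
#' @param seed RNG seed.
#' @return object of class `genotype_set`: list with `snp_manifest`,
#'   `dosage` (samples x SNPs), `maf`, `truth_meqtl`.
#' @export
generate_genotypes <- function(n_samples, snp_manifest,
                               maf_range = c(0.05, 0.5),
                               planted_meqtls = NULL, probe_ids = NULL,
                               seed = 1) {
  stopifnot(all(c("snp_id", "chrom", "pos") %in% names(snp_manifest)))
  if (any(snp_manifest$pos < 1)) stopf("SNP positions must be >= 1")
  if (maf_range[1] <= 0 || maf_range[2] > 0.5)
    stopf("maf_range must lie inside (0, 0.5]")
  if (!is.null(planted_meqtls)) {
    stopifnot(all(c("snp_id", "probe_id", "effect") %in% names(planted_meqtls)))
    bad <- setdiff(planted_meqtls$snp_id, snp_manifest$snp_id)
    if (length(bad)) stopf("planted link references unknown SNP(s): %s",
                           paste(bad, collapse = ", "))
    if (!is.null(probe_ids)) {
      bad <- setdiff(planted_meqtls$probe_id, probe_ids)
      if (length(bad)) stopf("planted link references unknown probe(s): %s",
                             paste(bad, collapse = ", "))
    }
  }
  m <- nrow(snp_manifest)
  with_seed(seed, {
    maf <- runif(m, maf_range[1], maf_range[2])
    dosage <- matrix(rbinom(n_samples * m, 2, rep(maf, each = n_samples)),
                     n_samples, m,
                     dimnames = list(sprintf("s%04d", seq_len(n_samples)),
                                     snp_manifest$snp_id))
    structure(list(snp_manifest = snp_manifest, dosage = dosage,
                   maf = setNames(maf, snp_manifest$snp_id),
                   truth_meqtl = planted_meqtls),
              class = "genotype_set")
  })
}

#' Add planted meQTL genotype effects to an M-value matrix
#'
#' For every truth link of the genotype set, adds `effect * dosage` to the
#' target CpG's M-values (samples aligned by row order).
#'
#' @param m_matrix samples x CpGs M-value matrix.
#' @param genotypes a `genotype_set` with a `truth_meqtl` table.
#' @return the modified M-value matrix.
#' @export
plant_meqtl_effects <- function(m_matrix, genotypes) {
  tr <- genotypes$truth_meqtl
  if (is.null(tr) || !nrow(tr)) return(m_matrix)
  if (nrow(m_matrix) != nrow(genotypes$dosage))
    stopf("sample dimensions of M matrix and dosages differ")
  for (i in seq_len(nrow(tr))) {
    cpg <- tr$probe_id[i]
    if (!cpg %in% colnames(m_matrix))
      stopf("planted link targets CpG '%s' absent from the M matrix", cpg)
    m_matrix[, cpg] <- m_matrix[, cpg] +
      tr$effect[i] * genotypes$dosage[, tr$snp_id[i]]
  }
  m_matrix
}

#' Generate tissue open-chromatin interval collections
#'
#' Emits, per tissue, a set of 0-based half-open intervals placed over probe
#' positions.  Every tissue covers a random `base_rate` fraction of all
#' probes; the enriched tissue additionally covers `coverage_fraction` of
#' the designated probe set, creating a known tissue-specific enrichment
#' signal for overlap testing.
#'
#' @param manifest probe manifest.
#' @param tissues character vector of tissue labels.
#' @param enriched_tissue tissue receiving the planted signal (or NULL).
#' @param enriched_probe_set probe ids enriched in that tissue.
#' @param coverage_fraction fraction of the enriched set covered, in (0, 1].
#' @param base_rate background fraction of probes covered in every tissue.
#' @param halfwidth interval half-width (bp) around each covered probe.
#' @param seed RNG seed.
#' @return object of class `interval_collection`: named list (per tissue) of
#'   data.frames with chrom, start, end (0-based half-open).
#' @export
generate_hotspots <- function(manifest, tissues, enriched_tissue = NULL,
                              enriched_probe_set = NULL,
                              coverage_fraction = 0.5, base_rate = 0.1,
                              halfwidth = 100, seed = 1) {
  check_manifest(manifest)
  if (!is.null(enriched_tissue)) {
    if (!enriched_tissue %in% tissues) stopf("enriched tissue not in tissues")
    if (!length(enriched_probe_set)) stopf("enriched probe set is empty")
    if (coverage_fraction <= 0 || coverage_fraction > 1)
      stopf("coverage_fraction must lie in (0, 1]")
    bad <- setdiff(enriched_probe_set, manifest$probe_id)
    if (length(bad)) stopf("enriched probe(s) absent from manifest: %s",
                           paste(bad, collapse = ", "))
  }
  with_seed(seed, {
    mk_intervals <- function(ids) {
      rows <- manifest[match(ids, manifest$probe_id), , drop = FALSE]
      data.frame(chrom = rows$chrom,
                 start = pmax(rows$pos - 1 - halfwidth, 0),
                 end = rows$pos + halfwidth,
                 stringsAsFactors = FALSE)
    }
    out <- lapply(tissues, function(tis) {
      covered <- manifest$probe_id[runif(nrow(manifest)) < base_rate]
      if (!is.null(enriched_tissue) && tis == enriched_tissue) {
        extra <- sample(enriched_probe_set,
                        round(coverage_fraction * length(enriched_probe_set)))
        covered <- union(covered, extra)
      }
      mk_intervals(covered)
    })
    names(out) <- tissues
    structure(out, class = "interval_collection")
  })
}

#' @export
print.interval_collection <- function(x, ...) {
  cat(sprintf("Interval collection: %d tissues\n", length(x)))
  for (tis in names(x))
    cat(sprintf("  %-20s %6d intervals\n", tis, nrow(x[[tis]])))
  invisible(x)
}
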