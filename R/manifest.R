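#' Generate a synthetic CpG probe manifest
#'
#' Builds a manifest mimicking an Illumina-style array annotation: unique
#' probe ids, genomic position (1-based position of the interrogated
#' cytosine), relationship to CpG islands (island/shore/shelf/open_sea),
#' gene relationship (promoter/body/intergenic), and array membership flags.
#' The 450K content is a subset of the EPIC content, so per-probe sample
#' sizes can differ downstream when cohorts run different arrays.
#'
#' @param n_probes number of probes.
#' @param chroms chromosome labels to place probes on.
#' @param frac_450k fraction of probes also present on the 450K array.
#' @param island_prob,gene_prob category probabilities (named as the levels).
#' @param max_pos largest allowed position per chromosome.
#' @param seed RNG seed; identical arguments give an identical manifest.
#' @return data.frame with columns probe_id, chrom, pos, island_relation,
#'   gene_relation, on_450k, on_epic.
#' @export
generate_probe_manifest <- function(n_probes = 10000,
                                    chroms = paste0("chr", 1:22),
                                    frac_450k = 0.7,
                                    island_prob = c(island = 0.30, shore = 0.25,
                                                    shelf = 0.10, open_sea = 0.35),
                                    gene_prob = c(promoter = 0.30, body = 0.40,
                                                  intergenic = 0.30),
                                    max_pos = 5e7,
                                    seed = 1) {
  stopifnot(n_probes >= 1, frac_450k > 0, frac_450k <= 1)
  with_seed(seed, {
    chrom <- sample(chroms, n_probes, replace = TRUE)
    pos <- integer(n_probes)
    for (ch in unique(chrom)) {
      idx <- which(chrom == ch)
      pos[idx] <- sort(sample.int(max_pos, length(idx)))
    }
    manifest <- data.frame(
      probe_id = sprintf("cg%08d", seq_len(n_probes)),
      chrom = chrom,
      pos = pos,
      island_relation = sample(names(island_prob), n_probes, TRUE, prob = island_prob),
      gene_relation = sample(names(gene_prob), n_probes, TRUE, prob = gene_prob),
      on_450k = runif(n_probes) < frac_450k,
      on_epic = TRUE,
      stringsAsFactors = FALSE
    )
    ord <- order(match(manifest$chrom, chroms), manifest$pos)
    manifest <- manifest[ord, , drop = FALSE]
    rownames(manifest) <- NULL
    manifest
  })
}

# Validate the structural invariants of a manifest; returns it invisibly.
check_manifest <- function(manifest) {
  need <- c("probe_id", "chrom", "pos", "island_relation", "gene_relation")
  miss <- setdiff(need, names(manifest))
  if (length(miss)) stopf("manifest lacks column(s): %s", paste(miss, collapse = ", "))
  if (anyDuplicated(manifest$probe_id)) stopf("manifest probe_ids are not unique")
  if (any(manifest$pos < 1)) stopf("manifest positions must be >= 1")
  invisible(manifest)
}

#' Probes assayed on a given array
#'
#' @param manifest probe manifest.
#' @param array `"k450"` or `"epic"`.
#' @return the manifest rows assayed on that array.
#' @export
manifest_for_array <- function(manifest, array = c("epic", "k450")) {
  array <- match.arg(array)
  check_manifest(manifest)
  keep <- if (array == "k450") manifest$on_450k else manifest$on_epic
  out <- manifest[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
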