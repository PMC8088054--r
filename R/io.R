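# Readers and writers for the plain-text interchange formats the pipeline
# consumes and emits: METAL-style summary statistics, probe/SNP manifests,
# cohort matrices, and per-tissue BED interval files.

#' Write per-study summary statistics in METAL-style TSV
#'
#' Columns: MARKER, EFFECT, SE, PVAL, N, DIRECTION, STUDY, ETHNICITY.
#'
#' @param results EWAS results (`ewas` object or its `$results` data.frame).
#' @param path output file (plain TSV; use a `.gz` suffix for gzip).
#' @param study,ethnicity labels stamped on every row.
#' @export
write_metal_tsv <- function(results, path, study = "study1",
                            ethnicity = "EA") {
  if (inherits(results, "ewas")) results <- results$results
  out <- data.frame(MARKER = results$probe_id, EFFECT = results$effect,
                    SE = results$se, PVAL = results$p, N = results$n,
                    DIRECTION = results$direction, STUDY = study,
                    ETHNICITY = ethnicity)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read METAL-style summary statistics
#'
#' @param path TSV file written by [write_metal_tsv()] (or any file with the
#'   same columns).
#' @return data.frame with probe_id, effect, se, p, n, direction, study_id,
#'   ethnicity — the per-study input format of [ivw_meta()].
#' @export
read_metal_tsv <- function(path) {
  x <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  data.frame(probe_id = x$MARKER, effect = x$EFFECT, se = x$SE, p = x$PVAL,
             n = x$N, direction = x$DIRECTION, study_id = x$STUDY,
             ethnicity = x$ETHNICITY, stringsAsFactors = FALSE)
}

#' Write / read a probe manifest as TSV
#'
#' @param manifest probe manifest data.frame.
#' @param path TSV path.
#' @export
write_manifest_tsv <- function(manifest, path) {
  write.table(manifest, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest_tsv
#' @export
read_manifest_tsv <- function(path) {
  check_manifest(read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE))
}

#' Export a cohort dataset as gzipped TSV files
#'
#' Writes `beta.tsv.gz` (samples x probes), `covariates.tsv.gz`, and
#' `phenotype.tsv.gz` (creatinine, eGFR, family id) into `dir`.
#'
#' @param dataset a `cohort_dataset`.
#' @param dir output directory (created if needed).
#' @export
write_cohort_tsv <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(x, name, rn) {
    con <- gzfile(file.path(dir, name), "w")
    on.exit(close(con))
    write.table(x, con, sep = "\t", quote = FALSE, row.names = rn)
  }
  wr(dataset$beta, "beta.tsv.gz", TRUE)
  wr(dataset$covariates, "covariates.tsv.gz", FALSE)
  ph <- data.frame(creatinine = dataset$creatinine, egfr = dataset$egfr,
                   family_id = dataset$family_id %||% NA_character_)
  wr(ph, "phenotype.tsv.gz", FALSE)
  invisible(dir)
}

#' Write an interval collection as one BED3 file per tissue
#'
#' Files are named `<tissue>.bed` in 0-based half-open BED convention.
#'
#' @param intervals an `interval_collection`.
#' @param dir output directory.
#' @export
write_hotspot_beds <- function(intervals, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (tis in names(intervals)) {
    gr <- .interval_granges(intervals[[tis]])
    rtracklayer::export(gr, file.path(dir, paste0(tis, ".bed")),
                        format = "BED")
  }
  invisible(dir)
}

#' Read per-tissue BED files into an interval collection
#'
#' @param dir directory of `<tissue>.bed` files.
#' @return an `interval_collection` (0-based half-open data.frames).
#' @export
read_hotspot_beds <- function(dir) {
  files <- list.files(dir, pattern = "\\.bed$", full.names = TRUE)
  if (!length(files)) stopf("no .bed files under %s", dir)
  out <- lapply(files, function(f) {
    gr <- rtracklayer::import(f, format = "BED")
    data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
               start = GenomicRanges::start(gr) - 1L,
               end = GenomicRanges::end(gr), stringsAsFactors = FALSE)
  })
  names(out) <- sub("\\.bed$", "", basename(files))
  structure(out, class = "interval_collection")
}

#' Export genotype dosages and the SNP manifest as TSV
#'
#' @param genotypes a `genotype_set`.
#' @param dir output directory; writes `dosage.tsv.gz` and `snps.tsv`.
#' @export
write_genotypes_tsv <- function(genotypes, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  con <- gzfile(file.path(dir, "dosage.tsv.gz"), "w")
  write.table(genotypes$dosage, con, sep = "\t", quote = FALSE,
              row.names = TRUE)
  close(con)
  write.table(genotypes$snp_manifest, file.path(dir, "snps.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
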