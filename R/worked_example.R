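#' Published worked-example summary statistics
#'
#' Bundled table of discovery and replication summary statistics (effect in
#' eGFR mL/min/1.73 m^2 per unit beta, two-sided p) for the 13 replicated
#' trans-ethnic eGFR DMPs, together with the published combined-stage
#' values.  Standard errors are not printed in such tables; they are
#' reconstructed with [se_from_effect_p()], after which a two-entry
#' [ivw_meta()] of the discovery and replication rows reproduces the
#' combined column — the package's worked example.
#'
#' @return data.frame with columns probe_id, chrom, pos_hg38, gene,
#'   discovery_effect, discovery_p, replication_effect, replication_p,
#'   combined_effect, combined_p.
#' @export
replicated_dmps_table <- function() {
  path <- system.file("extdata", "replicated_dmps.tsv", package = "egfrewas",
                      mustWork = TRUE)
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
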