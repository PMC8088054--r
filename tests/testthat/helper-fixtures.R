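# Shared small fixtures, built in code at load time.

# Tiny deterministic manifest for geometry / QC tests.
tiny_manifest <- function() {
  data.frame(
    probe_id = sprintf("cg%02d", 1:10),
    chrom = rep(c("chr1", "chr2"), each = 5),
    pos = c(100, 250, 400, 900, 1500, 100, 300, 700, 1200, 5000),
    island_relation = rep(c("island", "open_sea"), 5),
    gene_relation = rep(c("promoter", "body"), length.out = 10),
    on_450k = TRUE, on_epic = TRUE,
    stringsAsFactors = FALSE
  )
}

# Fixed 12-observation regression fixture: outcome, one predictor of
# interest, one covariate.  Values are literal so the oracle comparison is
# reproducible to machine precision.
fixed_regression_fixture <- function() {
  list(
    y = c(85.2, 92.1, 70.4, 101.3, 88.8, 95.0, 76.2, 83.5, 99.1, 68.9,
          90.4, 81.7),
    beta = c(0.41, 0.35, 0.58, 0.22, 0.39, 0.30, 0.55, 0.47, 0.25, 0.61,
             0.33, 0.49),
    cov = c(52, 61, 70, 45, 58, 50, 66, 63, 48, 72, 55, 60)
  )
}

# Moderate synthetic cohort reused by several EWAS/meta tests.
shared_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      man <- generate_probe_manifest(n_probes = 120, seed = 7)
      sp <- cohort_spec("shared", "EA", n_samples = 400, array = "epic",
                        planted_dmps = data.frame(probe_id = man$probe_id[1],
                                                  effect = -30),
                        seed = 99)
      cache <<- list(manifest = man, dataset = generate_cohort(sp, man))
    }
    cache
  }
})
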