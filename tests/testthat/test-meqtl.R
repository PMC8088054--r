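toy_snps <- function() {
  data.frame(snp_id = paste0("rs", 1:3), chrom = c("chr1", "chr1", "chr2"),
             pos = c(1e6, 5e6, 2e6))
}
toy_cpgs <- function() {
  data.frame(probe_id = paste0("cg", 1:4), chrom = c("chr1", "chr1", "chr2", "chr2"),
              pos = c(2e6, 5.4e6, 2000001, 9e6),
              island_relation = "island", gene_relation = "body",
              on_450k = TRUE, on_epic = TRUE)
}

test_that("cis pairing respects the inclusive window boundary", {
  snps <- data.frame(snp_id = "rs1", chrom = "chr1", pos = 1e6)
  atb <- data.frame(probe_id = "cgA", chrom = "chr1", pos = 2e6,
                    island_relation = "x", gene_relation = "y")
  past <- data.frame(probe_id = "cgB", chrom = "chr1", pos = 2000001,
                     island_relation = "x", gene_relation = "y")
  expect_equal(nrow(cis_pairs(snps, atb, 1e6)), 1)       # exactly 1 Mb
  expect_equal(nrow(cis_pairs(snps, past, 1e6)), 0)      # 1 Mb + 1 bp
  expect_equal(cis_pairs(snps, atb, 1e6)$distance, 1e6)
})

test_that("cis pairing equals the all-pairs brute-force filter", {
  got <- cis_pairs(toy_snps(), toy_cpgs(), 1e6)
  orc <- brute_cis_oracle(toy_snps(), toy_cpgs(), 1e6)
  key <- function(d) d[order(d$snp_id, d$cpg_id), ]
  expect_equal(key(got)$snp_id, key(orc)$snp_id)
  expect_equal(key(got)$cpg_id, key(orc)$cpg_id)
  expect_equal(key(got)$distance, key(orc)$distance)
})

test_that("the scan recovers a planted per-allele effect", {
  est <- vapply(1:10, function(s) {
    set.seed(700 + s)
    n <- 500
    g <- rbinom(n, 2, 0.3)
    age <- runif(n, 40, 80)
    m <- 0.5 * g + 0.01 * age + rnorm(n, 0, 0.8)
    M <- cbind(cgT = m)
    gt <- list(dosage = cbind(rsT = g))
    pr <- data.frame(snp_id = "rsT", cpg_id = "cgT", distance = 1000)
    meqtl_scan(M, gt, cbind(age = age), pr)$effect
  }, numeric(1))
  expect_lt(abs(mean(est) - 0.5), 0.1)
})

test_that("null pairs give calibrated p-values and classical OLS inference", {
  set.seed(55)
  n <- 300
  g <- rbinom(n, 2, 0.4)
  covm <- cbind(age = runif(n, 40, 80))
  M <- matrix(rnorm(n * 400), n, dimnames = list(NULL, sprintf("cg%03d", 1:400)))
  pr <- data.frame(snp_id = "rs1", cpg_id = colnames(M), distance = 0)
  sc <- meqtl_scan(M, list(dosage = cbind(rs1 = g)), covm, pr)
  expect_true(mean(sc$p < 0.05) > 0.02 && mean(sc$p < 0.05) < 0.08)

  # classical-inference oracle on one pair via lm()
  ref <- summary(lm(M[, 7] ~ g + covm))$coefficients["g", ]
  row <- sc[sc$cpg_id == "cg007", ]
  expect_equal(row$effect, unname(ref["Estimate"]), tolerance = 1e-10)
  expect_equal(row$se, unname(ref["Std. Error"]), tolerance = 1e-10)
  expect_equal(row$p, unname(ref["Pr(>|t|)"]), tolerance = 1e-10)
})

test_that("monomorphic SNPs are skipped with a reason", {
  n <- 50
  M <- cbind(cgA = rnorm(n))
  gt <- list(dosage = cbind(rsA = rep(1, n)))
  pr <- data.frame(snp_id = "rsA", cpg_id = "cgA", distance = 0)
  sc <- meqtl_scan(M, gt, NULL, pr)
  expect_equal(nrow(sc), 0)
  expect_identical(attr(sc, "skipped")$reason, "monomorphic")
})

test_that("meQTL CpG classification uses the gap-region thresholds", {
  rec <- data.frame(snp_id = c("r1", "r2", "r3", "r3"),
                    cpg_id = c("cgA", "cgB", "cgC", "cgC"),
                    p = c(0.04, 0.96, 0.5, 0.97))
  cl <- classify_meqtl_cpgs(rec)
  expect_identical(cl$associated, "cgA")
  expect_identical(cl$non_associated, "cgB")   # cgC: min p = 0.5, neither
  expect_length(intersect(cl$associated, cl$non_associated), 0)
})

test_that("DMP overlap statistic counts distinct target CpGs", {
  rec <- data.frame(snp_id = c("s1", "s1", "s2", "s3"),
                    cpg_id = c("cgA", "cgB", "cgA", "cgC"),
                    p = c(0.01, 0.01, 0.01, 0.01))
  pool <- paste0("s", 1:6)
  # disjoint DMP set: observed 0, p = 1
  ot <- snp_meqtl_dmp_overlap_test(c("s1", "s2"), rec, dmp_cpgs = "cgZ",
                                   background_pool = pool, n_sims = 50, seed = 1)
  expect_equal(ot$observed, 0)
  expect_equal(ot$empirical_p, 1)

  # monotonicity: enlarging the DMP set never decreases the statistic
  grow <- c("cgA", "cgB", "cgC")
  prev <- -1
  for (k in seq_along(grow)) {
    ot <- snp_meqtl_dmp_overlap_test(c("s1", "s3"), rec, dmp_cpgs = grow[1:k],
                                     background_pool = pool, n_sims = 10, seed = 2)
    expect_gte(ot$observed, prev)
    prev <- ot$observed
  }
  expect_error(snp_meqtl_dmp_overlap_test(paste0("s", 1:7), rec, "cgA",
                                          background_pool = pool, n_sims = 5,
                                          seed = 1),
               "smaller")
})

test_that("empirical overlap p matches exhaustive enumeration on a toy pool", {
  # 6-SNP pool, 4 CpGs, hand-built incidence
  rec <- data.frame(snp_id = c("s1", "s1", "s2", "s3", "s4", "s5"),
                    cpg_id = c("cgA", "cgB", "cgB", "cgC", "cgD", "cgA"),
                    p = 0.01)
  dmp <- c("cgA", "cgB", "cgC")
  pool <- paste0("s", 1:6)
  query <- c("s1", "s3", "s6")
  sig <- rec[rec$cpg_id %in% dmp, ]
  hits <- split(sig$cpg_id, sig$snp_id)
  obs <- length(unique(unlist(hits[query])))
  exact <- enum_overlap_p_oracle(hits, 3, pool, obs)

  ot <- snp_meqtl_dmp_overlap_test(query, rec, dmp, pool,
                                   n_sims = 20000, seed = 3)
  expect_equal(ot$observed, obs)
  expect_lt(abs(ot$empirical_p - exact), 0.01)
  # determinism
  ot2 <- snp_meqtl_dmp_overlap_test(query, rec, dmp, pool,
                                    n_sims = 200, seed = 9)
  ot3 <- snp_meqtl_dmp_overlap_test(query, rec, dmp, pool,
                                    n_sims = 200, seed = 9)
  expect_identical(ot2$empirical_p, ot3$empirical_p)
})

test_that("hotspot overlap test counts targets inside tissue intervals", {
  cpgs <- toy_cpgs()
  rec <- data.frame(snp_id = c("s1", "s2", "s3"),
                    cpg_id = c("cg1", "cg2", "cg3"), p = 0.01)
  iv <- structure(list(kidney = data.frame(chrom = "chr1",
                                           start = c(2e6 - 1, 5.4e6 - 1),
                                           end = c(2e6, 5.4e6)),
                       none = data.frame(chrom = character(0),
                                         start = numeric(0),
                                         end = numeric(0))),
                  class = "interval_collection")
  ot <- meqtl_hotspot_overlap_test(c("s1", "s2"), rec, iv, "kidney", cpgs,
                                   background_pool = paste0("s", 1:3),
                                   n_sims = 100, seed = 4)
  expect_equal(ot$observed, 2)  # cg1 and cg2 sit inside kidney intervals
  empty <- meqtl_hotspot_overlap_test(c("s1", "s2"), rec, iv, "none", cpgs,
                                      background_pool = paste0("s", 1:3),
                                      n_sims = 100, seed = 4)
  expect_equal(empty$observed, 0)
  expect_equal(empty$empirical_p, 1)
})

test_that("blood-kidney overlap fraction reports one-decimal percentages", {
  expect_equal(blood_kidney_overlap_fraction(letters[1:5], letters), 100.0)
  expect_equal(blood_kidney_overlap_fraction(letters[1:5], LETTERS), 0.0)
  kidney <- paste0("cg", 1:12)
  blood <- c(paste0("cg", 1:7), "other")
  expect_equal(blood_kidney_overlap_fraction(kidney, blood), 58.3)
  expect_error(blood_kidney_overlap_fraction(character(0), "a"), "empty")
})
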