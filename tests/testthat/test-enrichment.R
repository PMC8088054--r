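test_that("top-probe selection orders by p with deterministic tie-breaks", {
  tab <- data.frame(probe_id = paste0("cg", 1:500), p = runif(500))
  expect_warning(ps <- top_probes(tab, k = 1000), "only 500")
  expect_equal(nrow(ps), 500)
  expect_identical(top_probes(tab, k = 1)$probe_id,
                   tab$probe_id[which.min(tab$p)])

  tie <- data.frame(probe_id = c("cgE", "cgB", "cgD", "cgA", "cgC"),
                    p = c(0.2, 0.1, 0.2, 0.2, 0.2))
  # rank-2 candidates all tie at p=0.2; lexicographic id wins
  expect_identical(top_probes(tie, k = 2)$probe_id, c("cgB", "cgA"))
})

test_that("ranked batches partition the top of the table", {
  set.seed(2)
  tab <- data.frame(probe_id = sprintf("cg%04d", 1:5000), p = runif(5000))
  batches <- ranked_probe_batches(tab, batch = 1000, n_batches = 5)
  expect_length(batches, 5)
  ids <- lapply(batches, function(b) b$probe_id)
  expect_equal(length(unique(unlist(ids))), 5000)
  expect_setequal(unlist(ids), top_probes(tab, 5000)$probe_id)
  # within- and between-batch p ordering
  expect_true(max(batches[[1]]$p) <= min(batches[[2]]$p))

  small <- data.frame(probe_id = letters[1:4], p = c(0.4, 0.1, 0.3, 0.2))
  b2 <- ranked_probe_batches(small, batch = 2, n_batches = 2)
  expect_identical(b2[[1]]$probe_id, c("b", "d"))
  expect_identical(b2[[2]]$probe_id, c("c", "a"))
})

test_that("overlap counting uses the single-base, half-open convention", {
  man <- data.frame(probe_id = "cgX", chrom = "chr1", pos = 100,
                    island_relation = "island", gene_relation = "body",
                    on_450k = TRUE, on_epic = TRUE)
  iv99 <- structure(list(t = data.frame(chrom = "chr1", start = 99, end = 100)),
                    class = "interval_collection")
  iv100 <- structure(list(t = data.frame(chrom = "chr1", start = 100, end = 200)),
                     class = "interval_collection")
  expect_equal(overlap_count("cgX", iv99, "t", man), 1L)   # covers base 100
  expect_equal(overlap_count("cgX", iv100, "t", man), 0L)  # covers 101..200
  expect_error(overlap_count("cgMissing", iv99, "t", man), "missing")
})

test_that("overlap counts match a brute-force interval scan", {
  man <- tiny_manifest()
  iv <- data.frame(chrom = c("chr1", "chr1", "chr2", "chr2"),
                   start = c(50, 890, 250, 4000),
                   end = c(260, 1000, 310, 5100))
  coll <- structure(list(kidney = iv), class = "interval_collection")
  got <- overlap_count(man$probe_id, coll, "kidney", man)
  expect_equal(got, brute_overlap_oracle(man$probe_id, iv, man))
  expect_equal(got, 5L)  # cg01 (100), cg02 (250), cg04 (900), cg07 (300), cg10 (5000)
})

test_that("matched backgrounds reproduce the query's stratum composition", {
  man <- generate_probe_manifest(n_probes = 3000, seed = 31)
  set.seed(5)
  query <- sample(man$probe_id, 80)
  bg <- matched_background(query, man, n_sets = 25, seed = 9)
  strat <- function(ids) {
    i <- match(ids, man$probe_id)
    sort(table(paste(man$island_relation[i], man$gene_relation[i])))
  }
  q <- strat(query)
  for (set in bg) {
    expect_equal(strat(set), q)
    expect_length(intersect(set, query), 0)
    expect_false(anyDuplicated(set) > 0)
  }
  expect_identical(matched_background(query, man, 5, seed = 3),
                   matched_background(query, man, 5, seed = 3))
})

test_that("an exhausted matching stratum raises a named error", {
  man <- tiny_manifest()  # only 5 island:promoter-ish strata, tiny
  # query occupies a stratum with too few remaining probes for 2x matching
  query <- man$probe_id[man$island_relation == "island" &
                        man$gene_relation == "promoter"]
  expect_error(matched_background(query, man, n_sets = 3, seed = 1),
               "exhausted")
})

test_that("empirical enrichment p follows the add-one estimator", {
  ee <- empirical_enrichment(10, rep(0:9, length.out = 999))
  expect_equal(ee$empirical_p, 1 / 1000)
  expect_equal(empirical_enrichment(5, rep(5, 100))$empirical_p, 1.0)
  expect_equal(empirical_enrichment(3, c(1, 2, 3, 4))$empirical_p, 3 / 5)
  expect_true(is.na(empirical_enrichment(3, rep(2, 10))$z))
  expect_error(empirical_enrichment(1, numeric(0)), "empty")
})

test_that("BY correction matches its step-up oracle and dominates BH", {
  expect_equal(by_correct(0.02), 0.02)
  expect_equal(by_correct(c(0.01, 0.5)), c(0.03, 0.75))
  set.seed(12)
  for (i in 1:50) {
    p <- runif(sample(2:30, 1))
    expect_equal(by_correct(p), by_q_oracle(p), tolerance = 1e-12)
    expect_true(all(by_correct(p) >= bh_fdr(p)$q_values - 1e-15))
  }
})

test_that("run_enrichment is deterministic and flags a planted tissue", {
  man <- generate_probe_manifest(n_probes = 2500, seed = 17)
  set.seed(21)
  query <- sample(man$probe_id, 120)
  hs <- generate_hotspots(man, tissues = paste0("t", 1:6),
                          enriched_tissue = "t2", enriched_probe_set = query,
                          coverage_fraction = 0.6, base_rate = 0.1, seed = 22)
  e1 <- run_enrichment(query, hs, man, n_sets = 200, seed = 30)
  e2 <- run_enrichment(query, hs, man, n_sets = 200, seed = 30)
  expect_identical(as.data.frame(e1), as.data.frame(e2))
  expect_identical(e1$tissue[1], "t2")
  expect_equal(e1$empirical_p[1], 1 / 201)
  expect_true(all(e1$by_q >= e1$empirical_p))
  expect_true(all(e1$empirical_p >= 1 / 201 & e1$empirical_p <= 1))
})

test_that("enrichment decays over ranked batches when signal tracks rank", {
  man <- generate_probe_manifest(n_probes = 6000, seed = 41)
  n_seeds <- 8
  lp <- matrix(NA_real_, n_seeds, 3)
  for (s in seq_len(n_seeds)) {
    set.seed(400 + s)
    # synthetic EWAS ranking: manifest order is the p-value order; hotspot
    # coverage probability decays with rank, so batch 1 is most enriched
    tab <- data.frame(probe_id = man$probe_id,
                      p = sort(runif(nrow(man))))
    rank_decay <- 0.05 + 0.45 * exp(-(seq_len(nrow(man))) / 800)
    covered <- man$probe_id[runif(nrow(man)) < rank_decay]
    hs <- structure(list(kidney = local({
      i <- match(covered, man$probe_id)
      data.frame(chrom = man$chrom[i], start = man$pos[i] - 1,
                 end = man$pos[i])
    })), class = "interval_collection")
    batches <- ranked_probe_batches(tab, batch = 1000, n_batches = 3)
    lp[s, ] <- vapply(seq_along(batches), function(b) {
      -log10(run_enrichment(batches[[b]], hs, man, n_sets = 200,
                            seed = 500 + s)$empirical_p[1])
    }, numeric(1))
  }
  avg <- colMeans(lp)
  expect_equal(which.max(avg), 1L)
  expect_true(all(diff(avg) <= 0))
})
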