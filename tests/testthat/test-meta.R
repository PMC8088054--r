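two_study <- function(b1, se1, b2, se2, probe = "cgA") {
  data.frame(probe_id = probe, study_id = c("s1", "s2"),
             effect = c(b1, b2), se = c(se1, se2))
}

test_that("equal-weight combination averages effects; Q and I2 match hand values", {
  m <- ivw_meta(two_study(1, 1, 3, 1))
  expect_equal(m$effect, 2.0)
  expect_equal(m$se, 1 / sqrt(2))
  expect_equal(m$q_cochran, 2)       # 1*(1-2)^2 + 1*(3-2)^2
  expect_equal(m$i_squared, 50)      # (2 - 1)/2 * 100
  expect_equal(m$direction, "++")
  orc <- cochran_oracle(c(1, 3), c(1, 1))
  expect_equal(m$q_cochran, orc$q)
  expect_equal(m$i_squared, orc$i2)
})

test_that("IVW agrees with an independent fixed-effect implementation", {
  skip_if_not_installed("metafor")
  set.seed(20)
  for (i in 1:5) {
    k <- sample(2:6, 1)
    b <- rnorm(k, -20, 10); se <- runif(k, 2, 8)
    mine <- ivw_meta(data.frame(probe_id = "x", study_id = paste0("s", 1:k),
                                effect = b, se = se))
    ref <- metafor::rma(yi = b, sei = se, method = "FE")
    expect_equal(mine$effect, as.numeric(ref$beta), tolerance = 1e-10)
    expect_equal(mine$se, ref$se, tolerance = 1e-10)
    expect_equal(mine$q_cochran, ref$QE, tolerance = 1e-10)
  }
})

test_that("IVW is order-invariant and at least as precise as any study", {
  set.seed(8)
  s <- data.frame(probe_id = "p", study_id = paste0("s", 1:5),
                  effect = rnorm(5), se = runif(5, 0.5, 3))
  m1 <- ivw_meta(s)
  m2 <- ivw_meta(s[sample(5), ])
  expect_equal(m1$effect, m2$effect, tolerance = 1e-12)
  expect_equal(m1$se, m2$se, tolerance = 1e-12)
  expect_lte(m1$se, min(s$se))
})

test_that("meta-analysis of sub-meta-analyses equals one-stage combination", {
  set.seed(15)
  for (rep in 1:10) {
    k <- sample(4:8, 1)
    s <- data.frame(probe_id = "p", study_id = sprintf("s%02d", 1:k),
                    effect = rnorm(k, -10, 5), se = runif(k, 1, 4))
    split_at <- if (k == 4) 2L else sample(2:(k - 2), 1)
    mA <- ivw_meta(s[1:split_at, ])
    mB <- ivw_meta(s[(split_at + 1):k, ])
    nested <- ivw_meta(data.frame(probe_id = "p", study_id = c("A", "B"),
                                  effect = c(mA$effect, mB$effect),
                                  se = c(mA$se, mB$se)))
    flat <- ivw_meta(s)
    expect_equal(nested$effect, flat$effect, tolerance = 1e-12)
    expect_equal(nested$se, flat$se, tolerance = 1e-12)
  }
})

test_that("probes with fewer than two studies are excluded with a record", {
  s <- data.frame(probe_id = c("a", "a", "b"), study_id = c("s1", "s2", "s1"),
                  effect = c(1, 2, 3), se = c(1, 1, 1))
  m <- ivw_meta(s)
  expect_identical(m$probe_id, "a")
  expect_identical(attr(m, "dropped"), "b")
  expect_equal(m$n_studies, 2)
  mp <- min_studies_filter(list(a = 1:2, b = 1), k = 2)
  expect_named(mp, "a")
  expect_equal(attr(mp, "n_dropped"), 1)
  expect_named(min_studies_filter(list(a = 1:2, b = 1), k = 1), c("a", "b"))
})

test_that("standard errors reconstructed from effect and p round-trip", {
  expect_equal(se_from_effect_p(1.96, 0.05), 1.0, tolerance = 1e-2)
  expect_equal(se_from_effect_p(-32.71, 1.41e-9), 5.40, tolerance = 0.01)
  set.seed(4)
  for (i in 1:20) {
    b <- rnorm(1, 0, 20); if (b == 0) b <- 1
    p <- runif(1, 1e-12, 0.99)
    se <- se_from_effect_p(b, p)
    expect_equal(2 * pnorm(-abs(b / se)), p, tolerance = 1e-12)
  }
  expect_error(se_from_effect_p(1, 1), "strictly")
  expect_error(se_from_effect_p(0, 0.5), "nonzero")
})

test_that("BH discovery matches the step-up enumeration oracle", {
  expect_equal(bh_fdr(0.03)$rejected, 1L)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04))$rejected, 1:4)
  expect_length(bh_fdr(c(0.04, 0.9, 0.9, 0.9))$rejected, 0)
  set.seed(99)
  for (i in 1:1000) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    got <- bh_fdr(p, alpha = 0.05)
    expect_identical(got$rejected, bh_reject_oracle(p, 0.05))
    expect_equal(got$q_values, bh_q_oracle(p), tolerance = 1e-12)
  }
})

test_that("Bonferroni threshold is alpha over m", {
  expect_equal(signif(bonferroni_threshold(0.05, 78), 2), 6.4e-4)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.01, 4), 0.0025)
  expect_error(bonferroni_threshold(0.05, 0), "m")
})

test_that("replication requires threshold p and concordant direction", {
  disc <- data.frame(probe_id = c("a", "b", "c"), effect = c(-30, -30, -25),
                     p = c(1e-8, 1e-8, 1e-7))
  repl <- data.frame(probe_id = c("a", "b"), effect = c(5, -16.34),
                     p = c(1e-6, 5.67e-7))
  calls <- call_replication(disc, repl, alpha = 0.05, m = 78)
  expect_false(calls$replicated[calls$probe_id == "a"])   # discordant
  expect_identical(calls$reason[calls$probe_id == "a"], "discordant")
  expect_true(calls$replicated[calls$probe_id == "b"])
  expect_identical(calls$reason[calls$probe_id == "c"], "untested")

  # boundary: replication p exactly at the threshold passes
  thr <- bonferroni_threshold(0.05, 2)
  calls <- call_replication(data.frame(probe_id = "a", effect = 1, p = 1e-9),
                            data.frame(probe_id = "a", effect = 2, p = thr),
                            m = 2)
  expect_true(calls$replicated)

  # concordance can be waived
  calls <- call_replication(disc[1, ], repl[1, ], m = 78,
                            require_concordance = FALSE)
  expect_true(calls$replicated)
})

test_that("combining identical stages halves the variance", {
  d <- list(probe_id = "x", effect = -10, se = 2)
  m <- combine_discovery_replication(d, d)
  expect_equal(m$effect, -10)
  expect_equal(m$se, 2 / sqrt(2))
  expect_error(combine_discovery_replication(d, NULL), "missing")
})

test_that("published combined-stage values are recovered from printed inputs", {
  tab <- replicated_dmps_table()
  expect_equal(nrow(tab), 13)
  for (i in seq_len(nrow(tab))) {
    m <- combine_discovery_replication(
      list(probe_id = tab$probe_id[i], effect = tab$discovery_effect[i],
           p = tab$discovery_p[i]),
      list(probe_id = tab$probe_id[i], effect = tab$replication_effect[i],
           p = tab$replication_p[i]))
    expect_lt(abs(m$effect - tab$combined_effect[i]), 0.05)
  }
})
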