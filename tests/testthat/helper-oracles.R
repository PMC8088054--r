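# Independent brute-force oracles used across the suite.  These deliberately
# form full matrices / enumerate exhaustively and never share code with the
# package internals they check.

# OLS coefficients and HC sandwich covariance from explicit matrix algebra:
# (X'X)^-1 X' diag(w e^2) X (X'X)^-1.
sandwich_oracle <- function(y, X, type = c("HC0", "HC1", "HC3", "const")) {
  type <- match.arg(type)
  XtXi <- solve(crossprod(X))
  bhat <- XtXi %*% crossprod(X, y)
  e <- drop(y - X %*% bhat)
  n <- nrow(X); k <- ncol(X)
  if (type == "const") {
    V <- XtXi * sum(e^2) / (n - k)
  } else {
    h <- diag(X %*% XtXi %*% t(X))
    w <- switch(type, HC0 = rep(1, n), HC1 = rep(n / (n - k), n),
                HC3 = 1 / (1 - h)^2)
    meat <- t(X) %*% (X * (w * e^2))
    V <- XtXi %*% meat %*% XtXi
  }
  list(coef = drop(bhat), vcov = V)
}

# Benjamini-Hochberg step-up by direct enumeration of the largest i with
# p_(i) <= i * alpha / m.
bh_reject_oracle <- function(p, alpha = 0.05) {
  m <- length(p)
  o <- order(p)
  ok <- which(p[o] <= alpha * seq_len(m) / m)
  if (!length(ok)) return(integer(0))
  sort(o[seq_len(max(ok))])
}

# BH q-values by the step-up minimum construction.
bh_q_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- rev(cummin(rev(pmin(1, m * p[o] / seq_len(m)))))
  q[order(o)]
}

# BY q-values: BH with the harmonic-sum inflation c(m).
by_q_oracle <- function(p) {
  m <- length(p)
  pmin(1, bh_q_oracle(p) * sum(1 / seq_len(m)))
}

# Cochran's Q and I^2 evaluated directly from the definitions.
cochran_oracle <- function(effects, ses) {
  w <- 1 / ses^2
  mu <- sum(w * effects) / sum(w)
  q <- sum(w * (effects - mu)^2)
  df <- length(effects) - 1
  list(q = q, i2 = if (q > 0) max(0, (q - df) / q) * 100 else 0)
}

# Brute-force interval overlap: loops every probe against every 0-based
# half-open interval and counts probes whose base (1-based) is covered.
brute_overlap_oracle <- function(ids, intervals_df, manifest) {
  n <- 0L
  for (id in unique(ids)) {
    row <- manifest[manifest$probe_id == id, ]
    hit <- FALSE
    for (i in seq_len(nrow(intervals_df))) {
      iv <- intervals_df[i, ]
      if (iv$chrom == row$chrom && iv$start < row$pos && row$pos <= iv$end) {
        hit <- TRUE
        break
      }
    }
    if (hit) n <- n + 1L
  }
  n
}

# Brute-force cis pairing over all SNP x CpG combinations.
brute_cis_oracle <- function(snps, cpgs, window) {
  out <- NULL
  for (i in seq_len(nrow(snps))) for (j in seq_len(nrow(cpgs))) {
    if (snps$chrom[i] == cpgs$chrom[j] &&
        abs(snps$pos[i] - cpgs$pos[j]) <= window) {
      out <- rbind(out, data.frame(snp_id = snps$snp_id[i],
                                   cpg_id = cpgs$probe_id[j],
                                   distance = abs(snps$pos[i] - cpgs$pos[j])))
    }
  }
  out
}

# Exhaustive enumeration of the SNP-resampling overlap statistic: exact
# probability that a uniform draw of k pool SNPs attains a count >= observed.
enum_overlap_p_oracle <- function(per_snp_hits, k, pool, observed) {
  draws <- utils::combn(pool, k)
  stats <- apply(draws, 2, function(snps)
    length(unique(unlist(per_snp_hits[snps], use.names = FALSE))))
  mean(stats >= observed)
}
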