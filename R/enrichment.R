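# Tissue-specific overlap enrichment of CpG sets against open-chromatin
# interval collections, with annotation-matched background resampling
# (eFORGE-style analysis).

#' Top-k probes of an EWAS table
#'
#' Returns the `k` probes with the smallest p-values (all probes, with a
#' warning, when fewer are available).  Ties at the boundary are broken by
#' lexicographic probe id so the selection is deterministic.
#'
#' @param ewas_table data.frame with `probe_id` and `p` (e.g. `$results` of
#'   [run_ewas()] or an [ivw_meta()] table).
#' @param k set size.
#' @param source optional label describing the originating analysis.
#' @return object of class `probe_set`: data.frame (probe_id, p) in
#'   ascending p order.
#' @export
top_probes <- function(ewas_table, k = 1000, source = NA_character_) {
  if (inherits(ewas_table, "ewas")) ewas_table <- ewas_table$results
  stopifnot(nrow(ewas_table) >= 1,
            all(c("probe_id", "p") %in% names(ewas_table)))
  ord <- order(ewas_table$p, ewas_table$probe_id)
  if (k > nrow(ewas_table)) {
    warnf("requested top %d probes but only %d available", k, nrow(ewas_table))
    k <- nrow(ewas_table)
  }
  out <- ewas_table[ord[seq_len(k)], c("probe_id", "p")]
  rownames(out) <- NULL
  structure(out, source = source, class = c("probe_set", "data.frame"))
}

#' Consecutive ranked probe batches
#'
#' Splits the p-value-ranked probes into consecutive non-overlapping rank
#' windows (1..batch, batch+1..2*batch, ...), as used to check whether a
#' tissue enrichment signal persists in probe sets below the top set.
#'
#' @inheritParams top_probes
#' @param batch probes per batch.
#' @param n_batches number of batches.
#' @return list of `probe_set` objects; fewer than `n_batches` (with a
#'   warning) when the table cannot fill them all.
#' @export
ranked_probe_batches <- function(ewas_table, batch = 1000, n_batches = 5) {
  if (inherits(ewas_table, "ewas")) ewas_table <- ewas_table$results
  stopifnot(nrow(ewas_table) >= batch)
  avail <- nrow(ewas_table) %/% batch
  if (avail < n_batches) {
    warnf("only %d full batches of %d available (%d requested)",
          avail, batch, n_batches)
    n_batches <- avail
  }
  ranked <- top_probes(ewas_table, k = batch * n_batches)
  lapply(seq_len(n_batches), function(i) {
    out <- ranked[((i - 1) * batch + 1):(i * batch), , drop = FALSE]
    rownames(out) <- NULL
    structure(out, source = sprintf("ranks %d-%d", (i - 1) * batch + 1,
                                    i * batch),
              class = c("probe_set", "data.frame"))
  })
}

# GRanges of single interrogated bases for a manifest.
.manifest_granges <- function(manifest) {
  GenomicRanges::GRanges(manifest$chrom,
                         IRanges::IRanges(manifest$pos, manifest$pos))
}

# GRanges covering the bases of 0-based half-open intervals: [start, end)
# covers 1-based bases start+1 .. end.
.interval_granges <- function(intervals) {
  if (!nrow(intervals))
    return(GenomicRanges::GRanges())
  GenomicRanges::GRanges(intervals$chrom,
                         IRanges::IRanges(intervals$start + 1, intervals$end))
}

# Logical matrix (manifest rows x tissues): does the probe's base fall in
# any interval of that tissue?
probe_overlap_indicator <- function(manifest, intervals) {
  gq <- .manifest_granges(manifest)
  out <- vapply(intervals, function(iv) {
    GenomicRanges::countOverlaps(gq, .interval_granges(iv)) > 0
  }, logical(nrow(manifest)))
  if (is.null(dim(out)))   # single-probe manifest: vapply collapses to vector
    out <- matrix(out, nrow = nrow(manifest),
                  dimnames = list(NULL, names(intervals)))
  rownames(out) <- manifest$probe_id
  out
}

#' Count probes overlapping a tissue's intervals
#'
#' A probe overlaps when its single interrogated base (1-based `pos`) falls
#' inside a 0-based half-open interval, i.e. `start < pos <= end`.  Each
#' probe is counted at most once.
#'
#' @param probes a `probe_set` or character vector of probe ids.
#' @param intervals an `interval_collection`.
#' @param tissue tissue label to count against.
#' @param manifest probe manifest giving probe positions.
#' @return integer overlap count.
#' @export
overlap_count <- function(probes, intervals, tissue, manifest) {
  ids <- if (is.data.frame(probes)) probes$probe_id else probes
  ids <- unique(ids)
  idx <- match(ids, manifest$probe_id)
  if (anyNA(idx))
    stopf("probe(s) missing from manifest: %s",
          paste(ids[is.na(idx)], collapse = ", "))
  if (!tissue %in% names(intervals)) stopf("unknown tissue '%s'", tissue)
  ind <- probe_overlap_indicator(manifest[idx, , drop = FALSE],
                                 intervals[tissue])
  sum(ind[, 1])
}

# Background sampling shared by matched_background() and run_enrichment():
# returns a (set size x n_sets) matrix of manifest row indices, each column
# reproducing the query's island x gene stratum composition exactly,
# excluding the query probes, sampled without replacement within a set.
matched_background_idx <- function(query_ids, manifest, n_sets, seed,
                                   strata_cols = c("island_relation",
                                                   "gene_relation")) {
  qidx <- match(query_ids, manifest$probe_id)
  if (anyNA(qidx))
    stopf("query probe(s) missing from manifest: %s",
          paste(query_ids[is.na(qidx)], collapse = ", "))
  strat <- interaction(manifest[strata_cols], drop = FALSE, sep = ":")
  q_strat <- strat[qidx]
  need <- table(droplevels(q_strat))
  pool <- setdiff(seq_len(nrow(manifest)), qidx)
  pool_strat <- strat[pool]
  with_seed(seed, {
    picks <- vector("list", length(need))
    names(picks) <- names(need)
    for (s in names(need)) {
      avail <- pool[pool_strat == s]
      if (length(avail) < 2 * need[[s]])
        stopf("stratum '%s' exhausted: %d needed, %d available (2x required)",
              s, need[[s]], length(avail))
      picks[[s]] <- vapply(seq_len(n_sets),
                           function(i) sample(avail, need[[s]]),
                           integer(need[[s]]))
      dim(picks[[s]]) <- c(need[[s]], n_sets)
    }
    do.call(rbind, picks)
  })
}

#' Annotation-matched background probe sets
#'
#' Draws `n_sets` random probe sets from the manifest, each with exactly the
#' query's composition over the island-relation x gene-relation strata,
#' never containing a query probe, sampled without replacement within a
#' set.  Deterministic under `seed`.
#'
#' @param query a `probe_set` or character vector of probe ids.
#' @param manifest probe manifest with the stratum annotation columns.
#' @param n_sets number of background sets.
#' @param seed RNG seed.
#' @param strata_cols manifest columns defining the matching strata.
#' @return list of `n_sets` character vectors of probe ids.
#' @export
matched_background <- function(query, manifest, n_sets = 1000, seed = 1,
                               strata_cols = c("island_relation",
                                               "gene_relation")) {
  ids <- if (is.data.frame(query)) query$probe_id else query
  idx <- matched_background_idx(ids, manifest, n_sets, seed, strata_cols)
  lapply(seq_len(ncol(idx)), function(i) manifest$probe_id[idx[, i]])
}

#' Empirical enrichment summary against background counts
#'
#' Empirical p uses the add-one resampling estimator
#' \eqn{(\#\{bg \ge obs\} + 1) / (B + 1)}, so the smallest attainable p at
#' B backgrounds is 1/(B+1); the z-score is (obs - mean)/sd of the
#' background counts (NA when the background is constant).
#'
#' @param observed observed overlap count.
#' @param background_counts vector of background overlap counts (B >= 1).
#' @return list with empirical_p, z, mean, sd, n_background_sets.
#' @export
empirical_enrichment <- function(observed, background_counts) {
  if (!length(background_counts)) stopf("empty background")
  b <- length(background_counts)
  mu <- mean(background_counts)
  sdev <- sd(background_counts)
  if (is.na(sdev)) sdev <- 0
  list(empirical_p = (sum(background_counts >= observed) + 1) / (b + 1),
       z = if (sdev > 0) (observed - mu) / sdev else NA_real_,
       mean = mu, sd = sdev, n_background_sets = b)
}

#' Tissue-specific overlap enrichment of a probe set
#'
#' For each tissue, counts the query probes overlapping the tissue's
#' open-chromatin intervals, builds the empirical null from
#' annotation-matched background sets (the same backgrounds are scored
#' against every tissue), and reports empirical p-values with
#' Benjamini-Yekutieli correction across tissues.
#'
#' @param probe_set a `probe_set` or character vector of probe ids.
#' @param intervals an `interval_collection`.
#' @param manifest probe manifest.
#' @param n_sets number of matched background sets.
#' @param seed RNG seed (resampling is deterministic under it).
#' @return object of class `enrichment_result`: data.frame with one row per
#'   tissue (tissue, observed, background_mean, background_sd, z,
#'   empirical_p, by_q, n_background_sets), sorted by empirical p.
#' @export
run_enrichment <- function(probe_set, intervals, manifest, n_sets = 1000,
                           seed = 1) {
  ids <- unique(if (is.data.frame(probe_set)) probe_set$probe_id else probe_set)
  qidx <- match(ids, manifest$probe_id)
  if (anyNA(qidx))
    stopf("probe(s) missing from manifest: %s",
          paste(ids[is.na(qidx)], collapse = ", "))
  ind <- probe_overlap_indicator(manifest, intervals)
  bg_idx <- matched_background_idx(ids, manifest, n_sets, seed)
  size <- nrow(bg_idx)

  rows <- lapply(names(intervals), function(tis) {
    v <- ind[, tis]
    obs <- sum(v[qidx])
    bg_counts <- colSums(matrix(v[bg_idx], size, n_sets))
    ee <- empirical_enrichment(obs, bg_counts)
    data.frame(tissue = tis, observed = obs, background_mean = ee$mean,
               background_sd = ee$sd, z = ee$z, empirical_p = ee$empirical_p,
               n_background_sets = ee$n_background_sets,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$by_q <- by_correct(out$empirical_p)
  out <- out[order(out$empirical_p, out$tissue),
             c("tissue", "observed", "background_mean", "background_sd",
               "z", "empirical_p", "by_q", "n_background_sets")]
  rownames(out) <- NULL
  structure(out, n_query = length(ids), class = c("enrichment_result",
                                                  "data.frame"))
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("Overlap enrichment: %d query probes, %d tissues, %d background sets\n",
              attr(x, "n_query"), nrow(x), x$n_background_sets[1]))
  NextMethod()
}
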