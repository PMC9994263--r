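# Brute-force oracles kept deliberately independent of the implementation:
# O(n^2) scans and per-bp arithmetic, no IRanges, no cumsums.

# Merge intervals on one chromosome when separated by a gap <= max_gap.
oracle_merge <- function(df, max_gap = 500) {
  out <- list()
  for (cn in sort(unique(df$chrom))) {
    d <- df[df$chrom == cn, , drop = FALSE]
    d <- d[order(d$start, d$end), , drop = FALSE]
    cur_s <- d$start[1]; cur_e <- d$end[1]
    for (i in seq_len(nrow(d))[-1]) {
      if (d$start[i] - cur_e <= max_gap) {
        cur_e <- max(cur_e, d$end[i])
      } else {
        out[[length(out) + 1]] <- data.frame(chrom = cn, start = cur_s,
                                             end = cur_e)
        cur_s <- d$start[i]; cur_e <- d$end[i]
      }
    }
    out[[length(out) + 1]] <- data.frame(chrom = cn, start = cur_s,
                                         end = cur_e)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

oracle_overlaps <- function(a, b) {
  vapply(seq_len(nrow(a)), function(i) {
    any(b$chrom == a$chrom[i] & b$start < a$end[i] & b$end > a$start[i])
  }, logical(1))
}

oracle_consensus <- function(replicates, blacklist = NULL, max_gap = 500) {
  pooled <- do.call(rbind, lapply(replicates,
                                  function(d) d[c("chrom", "start", "end")]))
  merged <- oracle_merge(pooled, max_gap)
  keep <- rep(TRUE, nrow(merged))
  for (r in replicates) keep <- keep & oracle_overlaps(merged, r)
  merged <- merged[keep, , drop = FALSE]
  if (!is.null(blacklist) && nrow(blacklist))
    merged <- merged[!oracle_overlaps(merged, blacklist), , drop = FALSE]
  rownames(merged) <- NULL
  merged
}

# Truncated moving average, plain loop.
oracle_blur <- function(v, hw) {
  n <- length(v)
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1, i - hw); hi <- min(n, i + hw)
    out[i] <- mean(v[lo:hi])
  }
  out
}

# Per-bp sum of density-valued windows over one interval.
oracle_aggregate <- function(track, iv, width_normalize = TRUE) {
  total <- 0
  for (j in seq_len(nrow(track))) {
    if (track$chrom[j] != iv$chrom) next
    ov <- min(iv$end, track$end[j]) - max(iv$start, track$start[j])
    if (ov > 0) total <- total + track$value[j] * ov
  }
  if (width_normalize) total / (iv$end - iv$start) else total
}

random_intervals <- function(n, chrom = "chr1", max_pos = 10000,
                             max_width = 500) {
  s <- sample.int(max_pos, n, replace = TRUE)
  data.frame(chrom = chrom, start = s,
             end = s + sample.int(max_width, n, replace = TRUE))
}

# Small default genome shared by the simulation-driven tests.
test_genome <- function(seed = 1, beta = 0.2, ...) {
  cfg <- sim_config(seed = seed, partition_truth = c(mark = beta))
  simulate_genome(cfg, ...)
}
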