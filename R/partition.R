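# SCAR-seq / OK-seq strand analysis: partition and RFD scores, smoothing,
# filtering, initiation-zone anchoring, meta-profiles and asymmetry tests.
#
# Sign conventions (every output sign depends on these):
#   * "upstream"/"downstream" of an initiation zone follow genomic
#     coordinate order (lower/higher coordinate).
#   * Partition = (F - R)/(F + R): positive = forward-strand enrichment.
#   * RFD = (R - F)/(F + R): rises from negative to positive through an
#     initiation zone.

stranded_cols <- function(track) {
  if (!all(c("F", "R") %in% names(track)))
    stop("expected a stranded track with F and R columns")
  invisible(track)
}

# Running mean with window halfwidth hw, truncated at the ends of each
# chromosome (the mean is over however many of the 2*hw+1 bins exist).
running_mean <- function(v, hw) {
  n <- length(v)
  cs <- cumsum(c(0, v))
  lo <- pmax(seq_len(n) - hw, 1L)
  hi <- pmin(seq_len(n) + hw, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Uniform-blur smoothing of a stranded track
#'
#' Replaces each strand's signal by the mean over a centered window of the
#' neighbouring `halfwidth` bins on each side (61 bins in total at the
#' default), truncated at chromosome ends. Strands are smoothed
#' independently; chromosomes never mix.
#'
#' @param track RPM-normalized stranded window track.
#' @param halfwidth Bins on each side of the center.
#' @return Smoothed track, state `"blurred"`.
#' @export
blur <- function(track, halfwidth = 30) {
  stranded_cols(track)
  if (norm_state(track) == "raw")
    stop("blur expects an RPM-normalized track")
  for (cn in unique(track$chrom)) {
    sel <- track$chrom == cn
    if (sum(sel) < 2 * halfwidth + 1)
      warning("chromosome ", cn, " shorter than the blur window; ",
              "means truncated")
    track$F[sel] <- running_mean(track$F[sel], halfwidth)
    track$R[sel] <- running_mean(track$R[sel], halfwidth)
  }
  norm_state(track) <- "blurred"
  track
}

#' Input correction of a stranded track
#'
#' Subtracts the matched input signal per window and strand; negative
#' values are floored at zero.
#'
#' @param track,input_track Stranded tracks on the same window grid and at
#'   the same normalization.
#' @return Corrected track, state `"input-corrected"`.
#' @export
input_correct <- function(track, input_track) {
  stranded_cols(track); stranded_cols(input_track)
  if (nrow(track) != nrow(input_track) ||
      !all(track$chrom == input_track$chrom) ||
      !all(track$start == input_track$start))
    stop("track and input are not on the same window grid")
  track$F <- pmax(0, track$F - input_track$F)
  track$R <- pmax(0, track$R - input_track$R)
  norm_state(track) <- "input-corrected"
  track
}

#' Low-coverage window mask
#'
#' Windows with signal below `min_rpm` on both strands are masked out of
#' all further analyses.
#'
#' @param track Input-corrected stranded track.
#' @param min_rpm RPM threshold.
#' @return Logical vector, `TRUE` where the window is masked (dropped).
#' @export
coverage_mask <- function(track, min_rpm = 0.3) {
  stranded_cols(track)
  track$F < min_rpm & track$R < min_rpm
}

score_track <- function(track, mask, numerator, clip_q) {
  stranded_cols(track)
  tot <- track$F + track$R
  zero <- !mask & tot == 0
  if (any(zero)) {
    warning(sum(zero), " unmasked window(s) with zero total signal; masked")
    mask <- mask | zero
  }
  score <- rep(NA_real_, nrow(track))
  score[!mask] <- numerator[!mask] / tot[!mask]
  if (!is.null(clip_q)) {
    qs <- stats::quantile(score[!mask], clip_q, na.rm = TRUE, names = FALSE)
    score[!mask] <- pmin(pmax(score[!mask], qs[1]), qs[2])
    attr(score, "clip_bounds") <- qs
  }
  out <- track[c("chrom", "start", "end")]
  out$score <- score
  out$masked <- mask
  attr(out, "clip_bounds") <- attr(score, "clip_bounds")
  out
}

#' Strand partition score
#'
#' Partition = (F - R)/(F + R) per unmasked window: the proportion of a
#' mark's nascent-strand signal segregating to the forward (positive) or
#' reverse (negative) daughter strand. Extreme values beyond the
#' genome-wide `clip_q` quantiles of the unmasked scores are set to the
#' quantile value.
#'
#' @param track Input-corrected stranded track.
#' @param mask Logical mask from [coverage_mask()]; computed at the
#'   default threshold when missing.
#' @param clip_q Lower/upper clipping quantiles, or `NULL` to skip.
#' @return Data frame with `chrom`, `start`, `end`, `score`, `masked`
#'   (score is `NA` where masked); clip bounds as attribute.
#' @export
partition_score <- function(track, mask = NULL,
                            clip_q = c(1e-4, 0.9999)) {
  if (is.null(mask)) mask <- coverage_mask(track)
  score_track(track, mask, track$F - track$R, clip_q)
}

#' Replication fork directionality score
#'
#' RFD = (R - F)/(F + R) from OK-seq counts: the partition score with the
#' strands exchanged in the numerator. OK-seq has no input correction.
#'
#' @inheritParams partition_score
#' @export
rfd_score <- function(track, mask = NULL, clip_q = NULL) {
  if (is.null(mask)) mask <- track$F + track$R == 0
  score_track(track, mask, track$R - track$F, clip_q)
}

#' Detect initiation-zone edges from RFD extrema
#'
#' For each zone, the upstream edge is placed at the RFD minimum within
#' `search` bp upstream of the center and the downstream edge at the RFD
#' maximum within `search` bp downstream. Ties are broken towards the
#' center. Zones whose search ranges are entirely masked are dropped with
#' a message.
#'
#' @param rfd RFD score track (from [rfd_score()]).
#' @param izs Data frame with `chrom` and `center`.
#' @param search Search radius in bp.
#' @return `izs` with `upstream_edge`, `downstream_edge` and `size`
#'   (edge-to-edge, bp) recomputed from the data.
#' @export
detect_iz_edges <- function(rfd, izs, search = 1e5) {
  pick <- function(sel, center, minimum) {
    cand <- which(sel & !rfd$masked)
    if (!length(cand)) return(NA_real_)
    v <- rfd$score[cand]
    best <- if (minimum) v == min(v) else v == max(v)
    mids <- (rfd$start[cand] + rfd$end[cand]) / 2
    cand_best <- cand[best]
    mids_best <- mids[best]
    mids_best[which.min(abs(mids_best - center))]
  }
  up <- dn <- rep(NA_real_, nrow(izs))
  mid <- (rfd$start + rfd$end) / 2
  for (i in seq_len(nrow(izs))) {
    onchr <- rfd$chrom == izs$chrom[i]
    ctr <- izs$center[i]
    up[i] <- pick(onchr & mid >= ctr - search & mid <= ctr, ctr, TRUE)
    dn[i] <- pick(onchr & mid >= ctr & mid <= ctr + search, ctr, FALSE)
  }
  drop <- is.na(up) | is.na(dn)
  if (any(drop))
    message(sum(drop), " zone(s) dropped: search range fully masked")
  out <- izs[!drop, , drop = FALSE]
  out$upstream_edge <- up[!drop]
  out$downstream_edge <- dn[!drop]
  out$size <- out$downstream_edge - out$upstream_edge
  rownames(out) <- NULL
  out
}

#' Filter initiation zones by peak proximity
#'
#' Keeps zones whose center lies within `within` bp of any peak of the
#' mark under study.
#'
#' @param izs Initiation-zone data frame with `chrom` and `center`.
#' @param peaks Peak interval data frame.
#' @param within Distance threshold in bp.
#' @export
filter_izs <- function(izs, peaks, within = 1e5) {
  if (!nrow(izs)) return(izs)
  centers <- new_intervals(izs$chrom, pmax(0, izs$center - within),
                           izs$center + within)
  izs[overlaps_any(centers, peaks), , drop = FALSE]
}

# Offset (bp, window-center to zone-center) and zone index for each track
# window relative to its nearest zone; ties go to the lower-coordinate
# zone (nearest_iz).
zone_offsets <- function(track, izs) {
  mid <- (track$start + track$end) / 2
  idx <- nearest_iz(track$chrom, mid, izs)
  list(offset = mid - izs$center[idx], zone = idx)
}

#' Meta-profile of partition around initiation zones
#'
#' Averages unmasked partition values at each offset in a `span`-bp window
#' centered on each zone (positive offsets downstream). When several
#' replicate tracks are supplied, per-replicate profiles are averaged.
#'
#' @param partition Partition score track, or list of replicate tracks.
#' @param izs Initiation zones (`chrom`, `center`).
#' @param span Total profile width in bp.
#' @return Data frame with `offset` (bp, bin midpoint relative to the
#'   center) and `score` (mean partition).
#' @export
metaprofile <- function(partition, izs, span = 2e5) {
  if (is.data.frame(partition)) partition <- list(partition)
  profs <- lapply(partition, function(p) {
    width <- p$end[1] - p$start[1]
    zo <- zone_offsets(p, izs)
    sel <- abs(zo$offset) <= span / 2 & !p$masked
    bin <- round(zo$offset[sel] / width) * width
    tapply(p$score[sel], bin, mean)
  })
  offs <- sort(unique(unlist(lapply(profs, function(p)
    as.numeric(names(p))))))
  score <- rowMeans(vapply(profs, function(p)
    unname(p[as.character(offs)]), numeric(length(offs))), na.rm = TRUE)
  data.frame(offset = offs, score = score)
}

#' Adjusted partition score
#'
#' Negates the partition value of every window upstream of its nearest
#' initiation-zone center and leaves downstream windows unchanged, so
#' that positive adjusted values uniformly indicate the leading strand on
#' both sides of the zone.
#'
#' @param partition Partition score track.
#' @param izs Initiation zones.
#' @return `partition` with extra columns `adjusted`, `zone` (index of the
#'   nearest zone) and `offset` (bp to its center).
#' @export
adjusted_partition <- function(partition, izs) {
  zo <- zone_offsets(partition, izs)
  partition$adjusted <- ifelse(zo$offset < 0, -partition$score,
                               partition$score)
  partition$zone <- zo$zone
  partition$offset <- zo$offset
  partition
}

#' Wilcoxon signed-rank asymmetry test between two samples
#'
#' Pairs the adjusted partition of two samples over the common set of
#' eligible windows - those between `band[1]` and `band[2]` bp from their
#' nearest initiation-zone center with total input-corrected coverage
#' above `min_rpm` in both samples - and applies a paired Wilcoxon
#' signed-rank test.
#'
#' @param sampleA,sampleB Adjusted-partition tracks (from
#'   [adjusted_partition()]) on the same grid, each with a `coverage`
#'   column (total RPM, F + R) or accompanied by `coverageA`/`coverageB`.
#' @param band Distance band (bp) from the zone center.
#' @param min_rpm Coverage threshold (applied to F + R).
#' @param eligible Optional extra logical filter per window (feature
#'   presence/absence stratification).
#' @param stratum Label stored in the result.
#' @param coverageA,coverageB Coverage vectors when the tracks carry none.
#' @return List of class `asymmetry_result`: `n`, `median_A`, `median_B`,
#'   `statistic`, `p_value`, `stratum`.
#' @export
asymmetry_test <- function(sampleA, sampleB, band = c(25000, 75000),
                           min_rpm = 0.6, eligible = NULL,
                           stratum = NA_character_,
                           coverageA = sampleA$coverage,
                           coverageB = sampleB$coverage) {
  if (nrow(sampleA) != nrow(sampleB) ||
      !all(sampleA$start == sampleB$start))
    stop("samples are not on the same window grid")
  if (is.null(coverageA) || is.null(coverageB))
    stop("coverage (F + R RPM) required for both samples")
  dist <- abs(sampleA$offset)
  ok <- dist >= band[1] & dist <= band[2] &
    coverageA > min_rpm & coverageB > min_rpm &
    !is.na(sampleA$adjusted) & !is.na(sampleB$adjusted)
  if (!is.null(eligible)) ok <- ok & eligible
  n <- sum(ok)
  if (n < 10)
    stop("only ", n, " eligible windows; need at least 10")
  a <- sampleA$adjusted[ok]; b <- sampleB$adjusted[ok]
  if (all(a == b)) {
    # identical pairs: no evidence of asymmetry whatsoever
    stat <- 0; p <- 1
  } else {
    wt <- suppressWarnings(stats::wilcox.test(a, b, paired = TRUE,
                                              exact = FALSE))
    stat <- unname(wt$statistic); p <- wt$p.value
  }
  structure(list(n = n, median_A = stats::median(a),
                 median_B = stats::median(b),
                 statistic = stat, p_value = p, stratum = stratum),
            class = "asymmetry_result")
}

#' @export
print.asymmetry_result <- function(x, ...) {
  cat(sprintf(paste0("Wilcoxon signed-rank asymmetry test%s\n",
                     "n = %d windows; median adjusted partition ",
                     "%.4f vs %.4f; V = %.1f, p = %.3g\n"),
              if (is.na(x$stratum)) "" else paste0(" [", x$stratum, "]"),
              x$n, x$median_A, x$median_B, x$statistic, x$p_value))
  invisible(x)
}
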