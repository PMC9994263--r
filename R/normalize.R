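# Spike-in (RRPM) normalization, RPM scaling, interval aggregation and the
# log2/z-score transforms used for quantitative comparisons.

norm_state <- function(track) {
  st <- attr(track, "norm_state")
  if (is.null(st)) "raw" else st
}

`norm_state<-` <- function(track, value) {
  attr(track, "norm_state") <- value
  track
}

#' Spike-in downsampling factors
#'
#' For each ChOR sample, the raw downsampling factor is
#' `(1 / spikein_reads) * (input_spikein_reads / input_target_reads)`,
#' with all read totals as uniquely mapped, deduplicated reads in millions
#' and the EdU-purified ("clicked") input serving as the reference for
#' relative spike-in abundance and labelling efficiency. Within a time
#' course, the largest factor is set to exactly 1 by a common alpha
#' coefficient and all others rescaled accordingly, so factors lie in
#' (0, 1]. Factors are invariant to any common rescaling of sequencing
#' depth.
#'
#' @param ledger Data frame with one row per sample and columns `sample`,
#'   `target_reads`, `spikein_reads`, `input_target_reads`,
#'   `input_spikein_reads` (all in millions of reads).
#' @param rescale If `TRUE` (default) apply the alpha rescaling; if
#'   `FALSE` return raw factors.
#' @return Named numeric vector of factors.
#' @examples
#' ledger <- data.frame(sample = c("T0", "T120"),
#'                      target_reads = c(10, 12),
#'                      spikein_reads = c(0.2, 0.5),
#'                      input_target_reads = c(5, 5),
#'                      input_spikein_reads = c(0.05, 0.05))
#' downsampling_factors(ledger)
#' @export
downsampling_factors <- function(ledger, rescale = TRUE) {
  req <- c("sample", "spikein_reads", "input_target_reads",
           "input_spikein_reads")
  if (!all(req %in% names(ledger)))
    stop("ledger must have columns: ", paste(req, collapse = ", "))
  bad <- ledger$spikein_reads <= 0 | ledger$input_spikein_reads <= 0 |
    ledger$input_target_reads <= 0
  if (any(bad))
    stop("zero or negative spike-in/input reads for sample(s): ",
         paste(ledger$sample[bad], collapse = ", "))
  raw <- (1 / ledger$spikein_reads) *
    (ledger$input_spikein_reads / ledger$input_target_reads)
  names(raw) <- ledger$sample
  if (!rescale) return(raw)
  raw / max(raw)
}

#' Global restoration level
#'
#' The genome-wide relative abundance of a mark in one sample: the raw
#' downsampling factor (without the alpha coefficient) multiplied by the
#' sample's uniquely mapped, deduplicated target-genome reads in millions.
#' Plotted over chase time this gives the global restoration curve.
#'
#' @inheritParams downsampling_factors
#' @return Named numeric vector, one level per sample.
#' @export
global_restoration_level <- function(ledger) {
  if (!"target_reads" %in% names(ledger))
    stop("ledger must have a target_reads column")
  downsampling_factors(ledger, rescale = FALSE) * ledger$target_reads
}

#' RPM normalization
#'
#' Scales raw counts to reads per million: `value * 1e6 / total_reads`.
#' Tracks carry a `norm_state` attribute and re-normalizing an
#' already-RPM track is an error.
#'
#' @param track Data frame with a `value` column (or stranded track with
#'   `F` and `R` columns), `norm_state` "raw".
#' @param total_reads Library size in reads.
#' @return Track with state `"RPM"`.
#' @export
rpm_normalize <- function(track, total_reads) {
  if (total_reads <= 0) stop("total_reads must be positive")
  if (norm_state(track) != "raw")
    stop("track is already normalized (state: ", norm_state(track), ")")
  for (col in intersect(c("value", "F", "R"), names(track)))
    track[[col]] <- track[[col]] * 1e6 / total_reads
  norm_state(track) <- "RPM"
  track
}

#' Apply a spike-in downsampling factor
#'
#' Multiplies an RPM-normalized track by its sample's downsampling factor,
#' yielding reference-adjusted RPM (RRPM).
#'
#' @param track RPM-state track.
#' @param factor Downsampling factor in (0, 1].
#' @return Track with state `"RRPM"`.
#' @export
rrpm_scale <- function(track, factor) {
  if (!(factor > 0 && factor <= 1)) stop("factor must lie in (0, 1]")
  if (norm_state(track) != "RPM")
    stop("rrpm_scale expects an RPM-normalized track")
  for (col in intersect(c("value", "F", "R"), names(track)))
    track[[col]] <- track[[col]] * factor
  norm_state(track) <- "RRPM"
  track
}

#' Aggregate a signal track over intervals
#'
#' Sums track signal over each query interval, optionally normalized by
#' interval width. Track values are interpreted as uniform per-bp densities
#' across their window (bedGraph semantics), so a window contributes
#' `value * overlap_bp` to the sum; width normalization divides by the
#' interval width, giving the mean per-bp density.
#'
#' @param track Data frame with `chrom`, `start`, `end`, `value`.
#' @param intervals Interval data frame.
#' @param width_normalize Divide by interval width (default `TRUE`).
#' @return Numeric vector, one value per interval; intervals with no
#'   overlapping track window get 0 with a warning.
#' @export
aggregate_over_intervals <- function(track, intervals,
                                     width_normalize = TRUE) {
  n <- nrow(intervals)
  if (!n) return(numeric())
  out <- numeric(n)
  # seqlevel mismatches are legitimate here (interval off the track) and
  # handled below; silence the GenomicRanges advisory
  ov <- suppressWarnings(
    GenomicRanges::findOverlaps(as_granges(intervals), as_granges(track)))
  qi <- S4Vectors::queryHits(ov); si <- S4Vectors::subjectHits(ov)
  if (length(qi)) {
    overlap <- pmin(intervals$end[qi], track$end[si]) -
      pmax(intervals$start[qi], track$start[si])
    contrib <- track$value[si] * overlap
    sums <- tapply(contrib, qi, sum)
    out[as.integer(names(sums))] <- sums
  }
  uncovered <- setdiff(seq_len(n), unique(qi))
  if (length(uncovered))
    warning(length(uncovered), " interval(s) outside track coverage; ",
            "signal set to 0")
  if (width_normalize) out <- out / (intervals$end - intervals$start)
  out
}

#' Signal transforms
#'
#' `log2p1` applies log2(x + 1); `zscore` centers and scales by the mean
#' and standard deviation of the supplied vector.
#'
#' @param values Finite numeric vector.
#' @param kind `"log2p1"` or `"zscore"`.
#' @return Transformed numeric vector.
#' @export
transform_signal <- function(values, kind = c("log2p1", "zscore")) {
  kind <- match.arg(kind)
  if (any(!is.finite(values))) stop("values must be finite")
  if (kind == "log2p1") return(log2(values + 1))
  s <- stats::sd(values)
  if (s == 0) stop("zero standard deviation; z-score undefined")
  (values - mean(values)) / s
}
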