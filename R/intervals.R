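# Interval algebra: consensus peaks, decorated genes, window parsing and
# feature stratification. Coordinates are 0-based half-open (BED) in every
# data frame; conversion to 1-based GRanges happens only inside helpers.

as_granges <- function(df) {
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(start = df$start + 1, end = df$end))
}

from_granges <- function(gr) {
  new_intervals(as.character(GenomicRanges::seqnames(gr)),
                GenomicRanges::start(gr) - 1, GenomicRanges::end(gr))
}

# TRUE for each row of `a` overlapping any row of `b` (>= 1 shared bp).
overlaps_any <- function(a, b) {
  if (is.null(b) || nrow(b) == 0) return(rep(FALSE, nrow(a)))
  suppressWarnings(IRanges::overlapsAny(as_granges(a), as_granges(b)))
}

#' Consensus peaks across replicates
#'
#' Reproduces the replicate-consensus construction used to define final
#' peak sets: all replicate peaks are concatenated and sorted, peaks within
#' `merge_distance` bp of one another are merged, and a merged interval is
#' retained only if it overlaps at least one peak of every individual
#' replicate. Intervals overlapping the blacklist are then removed.
#' "Within 500 bp" is gap distance (end-to-start), matching
#' `bedtools merge -d`; overlap means at least one shared bp.
#'
#' @param replicates List of interval data frames (`chrom`, `start`, `end`),
#'   one per replicate.
#' @param blacklist Optional interval data frame of regions to exclude.
#' @param merge_distance Maximum gap (bp) between peaks merged together.
#' @return Sorted, pairwise non-overlapping interval data frame.
#' @examples
#' a <- data.frame(chrom = "chr1", start = c(100, 300), end = c(200, 400))
#' b <- data.frame(chrom = "chr1", start = 150, end = 250)
#' consensus_peaks(list(a, b))
#' @export
consensus_peaks <- function(replicates, blacklist = NULL,
                            merge_distance = 500) {
  if (!length(replicates)) stop("no replicate peak sets supplied")
  for (i in seq_along(replicates)) {
    if (is.null(replicates[[i]]) || nrow(replicates[[i]]) == 0)
      stop("replicate ", i, " has an empty peak set")
  }
  pooled <- do.call(rbind, lapply(replicates,
                                  function(d) d[c("chrom", "start", "end")]))
  merged <- from_granges(
    GenomicRanges::reduce(as_granges(pooled),
                          min.gapwidth = merge_distance + 1))
  keep <- rep(TRUE, nrow(merged))
  for (rep_set in replicates)
    keep <- keep & overlaps_any(merged, rep_set)
  merged <- merged[keep, , drop = FALSE]
  if (!is.null(blacklist) && nrow(blacklist))
    merged <- merged[!overlaps_any(merged, blacklist), , drop = FALSE]
  rownames(merged) <- NULL
  merged[order(merged$chrom, merged$start), , drop = FALSE]
}

#' Parse peaks into fixed-width windows
#'
#' Tiles each peak into consecutive windows of `width` bp from its start.
#' A terminal window shorter than `width` is kept and flagged, so that
#' per-window signal can be width-normalized downstream and the tiling
#' conserves covered bases exactly.
#'
#' @param peaks Interval data frame.
#' @param width Window width in bp (1000 for most marks; 2000 for
#'   H2BK120ub1-style broad marks).
#' @return Interval data frame with `peak_id`, `window_id` and `full_width`
#'   (FALSE for truncated terminal windows).
#' @export
parse_into_windows <- function(peaks, width = 1000) {
  if (width <= 0) stop("width must be positive")
  if (!nrow(peaks)) return(cbind(peaks, peak_id = integer(),
                                 window_id = integer(),
                                 full_width = logical()))
  out <- lapply(seq_len(nrow(peaks)), function(i) {
    nw <- ceiling((peaks$end[i] - peaks$start[i]) / width)
    s <- peaks$start[i] + width * (seq_len(nw) - 1)
    e <- pmin(s + width, peaks$end[i])
    data.frame(chrom = peaks$chrom[i], start = s, end = e,
               peak_id = i, window_id = seq_along(s),
               full_width = (e - s) == width, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Select mark-decorated genes
#'
#' Genes are retained when longer than `min_length` bp (excluding short
#' pseudogenes), not overlapping the blacklist, and carrying at least one
#' peak in their transcribed region. The long subset additionally requires
#' length above `long_threshold`.
#'
#' @param genes Data frame with `chrom`, `start`, `end`, `strand` (and
#'   optionally `tss`/`tes`).
#' @param peaks Peak interval data frame.
#' @param blacklist Optional blacklist intervals.
#' @param min_length Minimum gene length in bp (exclusive).
#' @param long_threshold Length (bp) defining the long-gene subset.
#' @return List with `decorated` and `long` gene data frames.
#' @export
select_decorated_genes <- function(genes, peaks, blacklist = NULL,
                                   min_length = 3000,
                                   long_threshold = 50000) {
  len <- genes$end - genes$start
  keep <- len > min_length
  if (!is.null(blacklist) && nrow(blacklist))
    keep <- keep & !overlaps_any(genes, blacklist)
  keep <- keep & overlaps_any(genes, peaks)
  decorated <- genes[keep, , drop = FALSE]
  long <- decorated[(decorated$end - decorated$start) > long_threshold, ,
                    drop = FALSE]
  list(decorated = decorated, long = long)
}

#' Stratify windows by overlap with feature sets
#'
#' Labels each window with every named feature it overlaps. Interval
#' features use shared-bp overlap; point features (data frames with a
#' `pos` column, e.g. TSSs) match within `proximity` bp. The returned
#' logical matrix supports combinatorial definitions such as
#' presence/absence classes (e.g. variant-PRC1 sites: PCGF1/6-positive and
#' PCGF2-negative).
#'
#' @param windows Interval data frame.
#' @param feature_sets Named list of interval data frames, or point data
#'   frames with `chrom` and `pos`.
#' @param proximity Half-width (bp) of the match window for point features.
#' @return Data frame: one logical column per feature, plus `label`
#'   (comma-joined overlapping feature names, `"none"` when empty).
#' @export
stratify_by_overlap <- function(windows, feature_sets, proximity = 1000) {
  if (is.null(names(feature_sets)) || anyDuplicated(names(feature_sets)) ||
      any(!nzchar(names(feature_sets))))
    stop("feature sets must carry unique non-empty names")
  hits <- sapply(names(feature_sets), function(nm) {
    fs <- feature_sets[[nm]]
    if (!is.null(fs$pos) && is.null(fs$start))
      fs <- new_intervals(fs$chrom, pmax(0, fs$pos - proximity),
                          fs$pos + proximity)
    overlaps_any(windows, fs)
  })
  hits <- matrix(hits, nrow = nrow(windows),
                 dimnames = list(NULL, names(feature_sets)))
  label <- apply(hits, 1, function(z)
    if (any(z)) paste(names(feature_sets)[z], collapse = ",") else "none")
  out <- as.data.frame(hits)
  out$label <- label
  out
}

# Stable rank-based grouping shared by quartiles and deciles: ties broken
# by input order so assignments are deterministic.
rank_groups <- function(values, n_groups) {
  ok <- is.finite(values)
  grp <- rep(NA_integer_, length(values))
  v <- values[ok]
  r <- order(order(v, seq_along(v)))   # stable ranks 1..n
  grp[ok] <- ceiling(r / (length(v) / n_groups))
  grp[ok] <- pmin(grp[ok], n_groups)
  grp
}

#' Expression quartiles
#'
#' Ranks genes by expression and splits them at the 25/50/75 percentiles
#' into quartiles Q1 (lowest) to Q4 (highest). Ties are broken by stable
#' rank order; genes with missing values are excluded (label `NA`) with a
#' message.
#'
#' @param expression Numeric vector of per-gene expression values.
#' @return Factor with levels `Q1`-`Q4` (NA for missing input).
#' @export
expression_quartiles <- function(expression) {
  if (sum(is.finite(expression)) < 4)
    stop("need at least 4 genes with finite expression values")
  if (length(unique(expression[is.finite(expression)])) == 1L)
    warning("all expression values identical; quartiles are arbitrary")
  n_missing <- sum(!is.finite(expression))
  if (n_missing)
    message(n_missing, " gene(s) with missing expression excluded")
  grp <- rank_groups(expression, 4L)
  factor(ifelse(is.na(grp), NA, paste0("Q", grp)),
         levels = paste0("Q", 1:4))
}

#' Intensity deciles
#'
#' Splits windows into ten intensity groups D1-D10 with D1 the highest
#' intensity (the convention used when contrasting high/medium/low nascent
#' signal: D1 high, D5 medium, D10 low).
#'
#' @param signal Numeric vector of per-window intensities.
#' @return Factor with levels `D1`-`D10`.
#' @export
intensity_deciles <- function(signal) {
  if (sum(is.finite(signal)) < 10)
    stop("need at least 10 windows with finite signal for deciles")
  grp <- rank_groups(-signal, 10L)   # negate so group 1 = highest
  factor(ifelse(is.na(grp), NA, paste0("D", grp)),
         levels = paste0("D", 1:10))
}
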