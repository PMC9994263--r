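# Synthetic data generator: genomes, strand-biased read counts, spike-in
# ledgers and restoration time courses with the statistical structure the
# downstream analysis assumes.

#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generator with validation.
#' Defaults describe the study conditions the analysis was designed for:
#' a chase time course at 0/15/30/60/120/180/480 min, exogenous spike-in
#' chromatin at 0.05% of total, and three kinetic classes of peaks spanning
#' fast (t90 well under 2 h) to slow (t90 of 10-12 h) restoration.
#'
#' @param seed Integer seed; all randomness in the generator flows from it.
#' @param sequencing_depth Expected reads per sample.
#' @param spikein_fraction Proportion of spike-in chromatin in each sample.
#' @param partition_truth Named numeric vector of true leading-strand
#'   partition bias per mark, each in \[-1, 1\]. Positive values put the
#'   mark on the leading strand.
#' @param kinetics_truth Named list of kinetic classes, each a numeric
#'   vector with elements `ymax`, `b`, `k` (`k` per hour) of the
#'   first-order restoration curve y(t) = ymax - b * exp(-k * t).
#' @param noise_cv Coefficient of variation of the multiplicative
#'   log-normal noise applied to time-course signals.
#' @param timepoints_min Chase timepoints in minutes, strictly increasing,
#'   starting at 0 (nascent chromatin).
#' @param rfd_plateau Background magnitude of the replication fork
#'   directionality score outside initiation-zone ramps.
#' @return A list of class `sim_config`.
#' @examples
#' cfg <- sim_config(seed = 1)
#' cfg$spikein_fraction
#' @export
sim_config <- function(seed = 1L,
                       sequencing_depth = 2e7,
                       spikein_fraction = 5e-4,
                       partition_truth = c(mark = 0.2),
                       kinetics_truth = list(
                         fast   = c(ymax = 1, b = 0.7, k = 1.3),
                         medium = c(ymax = 1, b = 0.7, k = 0.5),
                         slow   = c(ymax = 1, b = 0.7, k = 0.18)
                       ),
                       noise_cv = 0.10,
                       timepoints_min = c(0, 15, 30, 60, 120, 180, 480),
                       rfd_plateau = 0.6) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  if (!(spikein_fraction > 0 && spikein_fraction < 1))
    stop("spikein_fraction must lie in (0, 1)")
  if (sequencing_depth <= 0) stop("sequencing_depth must be positive")
  if (is.unsorted(timepoints_min, strictly = TRUE))
    stop("timepoints_min must be strictly increasing")
  if (any(abs(partition_truth) > 1))
    stop("partition_truth values must lie in [-1, 1]")
  for (cls in names(kinetics_truth)) {
    p <- kinetics_truth[[cls]]
    if (!all(c("ymax", "b", "k") %in% names(p)))
      stop("kinetics_truth class '", cls, "' must name ymax, b, k")
    if (!(p[["k"]] > 0)) stop("k must be positive in class '", cls, "'")
    if (!(p[["b"]] > 0 && p[["b"]] <= p[["ymax"]]))
      stop("need 0 < b <= ymax in class '", cls, "'")
  }
  if (noise_cv < 0) stop("noise_cv must be non-negative")
  if (!(rfd_plateau > 0 && rfd_plateau <= 1))
    stop("rfd_plateau must lie in (0, 1]")
  structure(list(seed = as.integer(seed),
                 sequencing_depth = sequencing_depth,
                 spikein_fraction = spikein_fraction,
                 partition_truth = partition_truth,
                 kinetics_truth = kinetics_truth,
                 noise_cv = noise_cv,
                 timepoints_min = timepoints_min,
                 rfd_plateau = rfd_plateau),
            class = "sim_config")
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards so the generator never perturbs it.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  expr
}

new_intervals <- function(chrom = character(), start = integer(),
                          end = integer(), ...) {
  data.frame(chrom = chrom, start = as.numeric(start), end = as.numeric(end),
             ..., stringsAsFactors = FALSE)
}

# Sample n non-overlapping intervals with the given widths on one or more
# chromosomes; plain rejection sampling, errors out when the chromosomes
# cannot host the request.
sample_intervals <- function(chromosomes, n, width_range, min_gap = 1000) {
  sizes <- vapply(chromosomes, identity, numeric(1))
  need <- n * (mean(width_range) + min_gap)
  if (sum(sizes) < 2 * need)
    stop("chromosomes too short for ", n, " features of width ~",
         round(mean(width_range)))
  per <- pmax(1L, round(n * sizes / sum(sizes)))
  while (sum(per) > n) per[which.max(per)] <- per[which.max(per)] - 1L
  while (sum(per) < n) per[which.min(per)] <- per[which.min(per)] + 1L
  out <- list()
  for (i in seq_along(sizes)) {
    ni <- per[i]
    if (ni == 0L) next
    w <- round(exp(runif(ni, log(width_range[1]), log(width_range[2]))))
    # place on a jittered regular grid so non-overlap holds by construction
    slots <- floor(sizes[i] / (max(w) + min_gap))
    if (slots < ni)
      stop("chromosome ", names(sizes)[i], " too short for ", ni, " features")
    anchor <- sort(sample.int(slots, ni)) - 1L
    start <- anchor * (max(w) + min_gap) +
      floor(runif(ni, 0, min_gap))
    out[[i]] <- new_intervals(names(sizes)[i], start, start + w)
  }
  res <- do.call(rbind, out)
  res[order(res$chrom, res$start), , drop = FALSE]
}

#' Simulate a genome model
#'
#' Builds the deterministic scaffold every other simulator draws on:
#' chromosome sizes, per-mark peak sets with heterogeneous widths and
#' kinetic classes, gene annotations with TSS/TES and strand, CpG-island
#' and enhancer sets, replication initiation zones carrying a true fork
#' directionality profile, and a blacklist.
#'
#' Initiation zones are placed at least 200 kb from chromosome ends so that
#' 200 kb meta-profile windows always fit, and carry a piecewise-linear RFD
#' ramp rising from `-rfd_plateau` at the upstream edge to `+rfd_plateau`
#' at the downstream edge, crossing zero at the zone center.
#'
#' @param config A [sim_config()].
#' @param chromosomes Named numeric vector of chromosome lengths in bp.
#' @param n_peaks,n_genes,n_izs,n_cgi,n_enhancers,n_blacklist Feature counts.
#' @param iz_size_range Initiation-zone sizes (upstream to downstream edge),
#'   bp.
#' @return A list of class `genome_model` with elements `chromosomes`,
#'   `peaks` (interval data frame with `class` and `intensity`), `genes`,
#'   `cgis`, `enhancers`, `izs` (with `center`, `upstream_edge`,
#'   `downstream_edge`), `blacklist`, and `rfd_plateau`. All coordinates
#'   are 0-based half-open (BED convention).
#' @examples
#' g <- simulate_genome(sim_config(seed = 1))
#' nrow(g$peaks)
#' @export
simulate_genome <- function(config,
                            chromosomes = c(chr1 = 1e7, chr2 = 1e7),
                            n_peaks = 50, n_genes = 40, n_izs = 6,
                            n_cgi = 20, n_enhancers = 20, n_blacklist = 4,
                            iz_size_range = c(6e4, 1.6e5)) {
  stopifnot(inherits(config, "sim_config"))
  if (any(chromosomes < 4e5 + max(iz_size_range)) && n_izs > 0)
    stop("chromosome too short to host initiation zones 200 kb from ends")
  with_seed(config$seed, {
    peaks <- sample_intervals(chromosomes, n_peaks, c(1e3, 2e4))
    classes <- names(config$kinetics_truth)
    peaks$class <- sample(classes, nrow(peaks), replace = TRUE)
    peaks$intensity <- exp(rnorm(nrow(peaks), 0, 0.5))
    genes <- sample_intervals(chromosomes, n_genes, c(2e3, 8e4))
    genes$strand <- sample(c("+", "-"), nrow(genes), replace = TRUE)
    genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end)
    genes$tes <- ifelse(genes$strand == "+", genes$end, genes$start)
    genes$gene_id <- sprintf("gene%03d", seq_len(nrow(genes)))
    cgis <- sample_intervals(chromosomes, n_cgi, c(500, 3e3))
    enh <- sample_intervals(chromosomes, n_enhancers, c(300, 2e3))
    bl <- sample_intervals(chromosomes, n_blacklist, c(5e3, 2e4))
    izs <- NULL
    if (n_izs > 0) {
      per_chr <- table(factor(sample(names(chromosomes), n_izs,
                                     replace = TRUE,
                                     prob = chromosomes / sum(chromosomes)),
                              levels = names(chromosomes)))
      rows <- list()
      for (cn in names(chromosomes)) {
        ni <- per_chr[[cn]]
        if (ni == 0L) next
        lo <- 2e5 + max(iz_size_range) / 2
        hi <- chromosomes[[cn]] - lo
        # evenly spaced centers with jitter keep zones well separated
        centers <- round(lo + (seq_len(ni) - 0.5) / ni * (hi - lo) +
                           runif(ni, -2e4, 2e4))
        size <- round(runif(ni, iz_size_range[1], iz_size_range[2]))
        rows[[cn]] <- data.frame(chrom = cn, center = centers,
                                 upstream_edge = centers - size %/% 2,
                                 downstream_edge = centers + size %/% 2,
                                 size = size, stringsAsFactors = FALSE)
      }
      izs <- do.call(rbind, rows)
      rownames(izs) <- NULL
      if (any(izs$center < 2e5) ||
          any(izs$center > chromosomes[izs$chrom] - 2e5))
        stop("initiation zone center closer than 200 kb to a chromosome end")
    }
    structure(list(chromosomes = chromosomes, peaks = peaks, genes = genes,
                   cgis = cgis, enhancers = enh, izs = izs, blacklist = bl,
                   rfd_plateau = config$rfd_plateau,
                   partition_truth = config$partition_truth),
              class = "genome_model")
  })
}

#' Tile a genome into fixed-width windows
#'
#' @param genome A `genome_model` (or named vector of chromosome lengths).
#' @param width Window width in bp.
#' @return Interval data frame; the terminal window of each chromosome is
#'   truncated at the chromosome end.
#' @export
make_windows <- function(genome, width = 1000) {
  sizes <- if (inherits(genome, "genome_model")) genome$chromosomes else genome
  out <- lapply(names(sizes), function(cn) {
    start <- seq(0, sizes[[cn]] - 1, by = width)
    new_intervals(cn, start, pmin(start + width, sizes[[cn]]))
  })
  do.call(rbind, out)
}

# Index of the nearest initiation zone (by center) for each position;
# ties go to the lower-coordinate zone.
nearest_iz <- function(chrom, pos, izs) {
  idx <- rep(NA_integer_, length(pos))
  for (cn in unique(chrom)) {
    zi <- which(izs$chrom == cn)
    if (!length(zi)) next
    sel <- chrom == cn
    d <- abs(outer(pos[sel], izs$center[zi], "-"))
    idx[sel] <- zi[max.col(-d, ties.method = "first")]
  }
  idx
}

#' True replication fork directionality at genomic positions
#'
#' Piecewise-linear RFD profile implied by the genome model's initiation
#' zones: linear from `-rfd_plateau` at the upstream edge to `+rfd_plateau`
#' at the downstream edge, at the plateau magnitude outside the ramp, and
#' attributed to the nearest zone (so midway between zones the sign flips,
#' emulating a termination region).
#'
#' @param genome A `genome_model` with initiation zones.
#' @param chrom,pos Parallel vectors of chromosome names and positions (bp).
#' @return Numeric RFD values in `[-rfd_plateau, rfd_plateau]`.
#' @export
true_rfd <- function(genome, chrom, pos) {
  izs <- genome$izs
  if (is.null(izs)) stop("genome model has no initiation zones")
  p <- genome$rfd_plateau
  idx <- nearest_iz(chrom, pos, izs)
  up <- izs$upstream_edge[idx]
  dn <- izs$downstream_edge[idx]
  frac <- (pos - up) / (dn - up)
  p * pmax(-1, pmin(1, 2 * frac - 1))
}

#' True strand partition at genomic positions for a mark
#'
#' The partition score (F-R)/(F+R) a mark with leading-strand bias `beta`
#' would show: `beta` times the normalized RFD profile, so it plateaus at
#' `+beta` downstream and `-beta` upstream of each initiation zone and
#' crosses zero at the center.
#'
#' @inheritParams true_rfd
#' @param beta Leading-strand bias in `[-1, 1]`.
#' @export
true_partition <- function(genome, chrom, pos, beta) {
  beta * true_rfd(genome, chrom, pos) / genome$rfd_plateau
}

# Poisson strand-split counts on the 1 kb grid given per-window rates and
# forward fractions.
draw_stranded <- function(windows, lambda, f) {
  windows$F <- rpois(nrow(windows), lambda * f)
  windows$R <- rpois(nrow(windows), lambda * (1 - f))
  attr(windows, "norm_state") <- "raw"
  windows
}

#' Simulate SCAR-seq strand-specific window counts
#'
#' Draws Poisson read counts per 1 kb window on each strand. The expected
#' total per window mixes a flat background with peak enrichment for the
#' given mark; the forward-read fraction is (1 + partition)/2 where the
#' true partition comes from [true_partition()] at the window midpoint.
#' The matched input has no strand bias (forward fraction 0.5) and flat
#' coverage.
#'
#' @param genome A `genome_model`.
#' @param mark Name of a mark in `partition_truth`.
#' @param depth Expected total read count of the sample.
#' @param seed Integer seed.
#' @param beta Optional override of the mark's true bias.
#' @param width Window width (bp).
#' @param enrichment Peak-to-background rate ratio.
#' @param input_depth Expected reads in the matched input.
#' @return List with `sample` and `input` stranded window tracks (columns
#'   `chrom`, `start`, `end`, `F`, `R`; `norm_state` attribute "raw").
#' @export
simulate_scar_counts <- function(genome, mark, depth, seed,
                                 beta = NULL, width = 1000,
                                 enrichment = 3, input_depth = depth) {
  if (is.null(beta)) {
    pt <- genome$partition_truth
    if (is.null(pt) || !(mark %in% names(pt)))
      stop("no partition truth defined for mark '", mark, "'")
    beta <- pt[[mark]]
  }
  w <- make_windows(genome, width)
  mid <- (w$start + w$end) / 2
  in_peak <- overlaps_any(w, genome$peaks)
  rate <- ifelse(in_peak, enrichment, 1)
  part <- true_partition(genome, w$chrom, mid, beta)
  # one unit of unbiased input-like background everywhere; the mark-derived
  # (enriched) reads on top of it carry the strand bias, so the partition
  # of the mark's own signal is `part` while background windows are
  # symmetric, as in the assay
  extra <- rate - 1
  f <- (0.5 + (1 + part) / 2 * extra) / rate
  with_seed(seed, {
    smp <- draw_stranded(w, depth * rate / sum(rate), f)
    inp <- draw_stranded(w, input_depth / nrow(w), 0.5)
    list(sample = smp, input = inp)
  })
}

#' Simulate OK-seq strand-specific window counts
#'
#' As [simulate_scar_counts()] but coverage is flat and the reverse-read
#' fraction follows the initiation-zone RFD ramp, (1 + RFD)/2, so that
#' RFD = (R-F)/(F+R) computed from the counts recovers the configured
#' profile in expectation.
#'
#' @inheritParams simulate_scar_counts
#' @return A stranded window track.
#' @export
simulate_okseq <- function(genome, depth, seed, width = 1000) {
  w <- make_windows(genome, width)
  mid <- (w$start + w$end) / 2
  rfd <- true_rfd(genome, w$chrom, mid)
  rev_frac <- (1 + rfd) / 2
  with_seed(seed, draw_stranded(w, depth / nrow(w), 1 - rev_frac))
}

#' Simulate a ChOR-seq restoration time course with spike-in ledger
#'
#' For each peak of the genome model, the true signal at chase time t
#' (hours) follows the first-order restoration curve of its kinetic class,
#' y(t) = ymax - b exp(-k t), scaled by the peak's intensity. Observed
#' signals multiply the truth by mean-one log-normal noise with coefficient
#' of variation `noise_cv`. A spike-in read ledger is built alongside with
#' totals consistent with `spikein_fraction`, so the correct downsampling
#' factors are recoverable from it.
#'
#' @param genome A `genome_model`.
#' @param config A [sim_config()]; its `timepoints_min`, `kinetics_truth`,
#'   `noise_cv`, `sequencing_depth` and `spikein_fraction` define the
#'   course.
#' @param replicates Number of replicates.
#' @param kinetics Optional single kinetic parameter vector
#'   (`ymax`, `b`, `k`) applied to every peak, overriding per-class truth.
#' @return List with `signal` (long data frame: `region_id`, `replicate`,
#'   `timepoint_min`, `signal`, `truth`) and `ledger` (one row per
#'   sample: read totals in millions for the ChOR sample and its clicked
#'   input on the target and spike-in genomes). `signal` is on the raw
#'   per-library scale - each sample is inflated by the inverse of its
#'   true relative spike-in factor (library-size and IP-efficiency
#'   drift), so applying ledger-derived downsampling factors (as
#'   [run_restoration()] does) recovers comparable RRPM-scale values.
#'   With `noise_cv = 0` all drift is disabled and `signal` equals the
#'   analytic curve exactly.
#' @export
simulate_chor_timecourse <- function(genome, config, replicates = 2,
                                     kinetics = NULL) {
  stopifnot(inherits(config, "sim_config"))
  tp <- config$timepoints_min
  if (is.unsorted(tp, strictly = TRUE))
    stop("timepoints must be strictly increasing")
  peaks <- genome$peaks
  th <- tp / 60
  curve_for <- function(cls) {
    p <- if (is.null(kinetics)) config$kinetics_truth[[cls]] else kinetics
    p[["ymax"]] - p[["b"]] * exp(-p[["k"]] * th)
  }
  sdlog <- sqrt(log(1 + config$noise_cv^2))
  with_seed(config$seed + 7L, {
    rows <- list()
    for (r in seq_len(replicates)) {
      truth <- t(vapply(peaks$class, curve_for, numeric(length(th)))) *
        peaks$intensity
      noise <- matrix(rlnorm(length(truth), -sdlog^2 / 2, sdlog),
                      nrow = nrow(truth))
      obs <- truth * noise
      rows[[r]] <- data.frame(
        region_id = rep(sprintf("peak%03d", seq_len(nrow(peaks))),
                        times = length(tp)),
        replicate = r,
        timepoint_min = rep(tp, each = nrow(peaks)),
        signal = as.vector(obs), truth = as.vector(truth),
        stringsAsFactors = FALSE)
    }
    signal <- do.call(rbind, rows)
    # ledger: depth varies across samples (library-size drift), spike-in
    # totals Poisson around the configured proportion
    samples <- expand.grid(timepoint_min = tp,
                           replicate = seq_len(replicates))
    ns <- nrow(samples)
    # library size and IP efficiency drift across samples unless the run
    # is fully noiseless; together they set how many target reads each
    # library yields per unit of true signal, which is exactly what the
    # spike-in factor corrects
    drift <- if (config$noise_cv == 0) 0 else 1
    depth <- config$sequencing_depth * exp(rnorm(ns, 0, 0.2 * drift))
    input_depth <- config$sequencing_depth * exp(rnorm(ns, 0, 0.2 * drift))
    sf <- config$spikein_fraction
    ip_eff <- exp(rnorm(ns, 0, 0.15 * drift))
    ledger <- data.frame(
      sample = sprintf("T%d_rep%d", samples$timepoint_min,
                       samples$replicate),
      timepoint_min = samples$timepoint_min,
      replicate = samples$replicate,
      target_reads = rpois(ns, depth * ip_eff * (1 - sf)) / 1e6,
      spikein_reads = rpois(ns, depth * ip_eff * sf) / 1e6,
      input_target_reads = rpois(ns, input_depth * (1 - sf)) / 1e6,
      input_spikein_reads = rpois(ns, input_depth * sf) / 1e6,
      stringsAsFactors = FALSE)
    # raw (alpha-free) downsampling factor implied by the true rates;
    # observed per-peak signal scales inversely with it, so that applying
    # the ledger-derived factors makes samples comparable again
    true_raw <- 1e6 * (input_depth * sf / 1e6) /
      ((depth * ip_eff * sf) * (input_depth * (1 - sf) / 1e6))
    key <- paste(samples$timepoint_min, samples$replicate)
    idx <- match(paste(signal$timepoint_min, signal$replicate), key)
    signal$signal <- signal$signal / (true_raw[idx] / max(true_raw))
    list(signal = signal, ledger = ledger)
  })
}

#' Simulate modification dilution across DNA replication
#'
#' Models the passage of a modified-histone density profile through one
#' round of replication: a fraction `recycle_to_daughters` of parental
#' modified histones is recycled, split equally between the two daughter
#' strands, and newly deposited histones carry no modification. Each
#' daughter therefore receives density `parental * recycle_to_daughters/2`;
#' with full recycling the parental:per-daughter ratio is exactly 2 — the
#' two-fold dilution replication imposes on any fully recycled mark.
#'
#' @param genome A `genome_model`.
#' @param recycle_to_daughters Fraction of parental modified histones
#'   recycled, in `[0, 1]`.
#' @param seed Integer seed (used for the parental landscape draw).
#' @param width Window width (bp).
#' @return List with `parental` and `nascent` tracks (columns `chrom`,
#'   `start`, `end`, `density`), the nascent track being per daughter.
#' @export
simulate_replication_dilution <- function(genome, recycle_to_daughters,
                                          seed = 1L, width = 1000) {
  if (recycle_to_daughters < 0 || recycle_to_daughters > 1)
    stop("recycle_to_daughters must lie in [0, 1]")
  w <- make_windows(genome, width)
  in_peak <- overlaps_any(w, genome$peaks)
  parental <- w
  parental$density <- with_seed(seed, {
    base <- ifelse(in_peak, 8, 0.5)
    base * exp(rnorm(nrow(w), 0, 0.3))
  })
  nascent <- w
  nascent$density <- parental$density * recycle_to_daughters / 2
  list(parental = parental, nascent = nascent)
}
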