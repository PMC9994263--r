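# Orchestration: configuration, the two headline workflows (restoration
# and partition/asymmetry), the synthetic end-to-end demo, and file I/O
# for the standard formats (BED, bedGraph, TSV, YAML, JSON).

#' Workflow configuration defaults
#'
#' Collects every analysis threshold with its published default:
#' merge distance 500 bp, parse window 1000 bp (2000 for broad marks),
#' restoration fold 1.5, blur halfwidth 30 bins, coverage filter
#' RPM < 0.3, partition clipping at the 0.0001/0.9999 quantiles,
#' asymmetry band 25-75 kb with RPM > 0.6, initiation-zone search and
#' peak-proximity filter 100 kb, meta-profile span 200 kb.
#'
#' @param ... Overrides of any default.
#' @return Named list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(seed = 1L, merge_distance = 500, parse_window = 1000,
              fold = 1.5, exclude_timepoints = numeric(),
              blur_halfwidth = 30, min_rpm = 0.3,
              clip_q = c(1e-4, 0.9999), band = c(25000, 75000),
              asym_min_rpm = 0.6, iz_search = 1e5, iz_within = 1e5,
              span = 2e5, blur_input = TRUE, input_scale = "background")
  over <- list(...)
  stopifnot(all(names(over) %in% names(cfg)))
  cfg[names(over)] <- over
  for (nm in c("merge_distance", "parse_window", "fold", "blur_halfwidth",
               "iz_search", "iz_within", "span"))
    if (cfg[[nm]] <= 0) stop(nm, " must be positive")
  cfg
}

#' Read a workflow configuration from YAML
#'
#' @param path YAML file; keys override [pipeline_config()] defaults.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

# ---- I/O -------------------------------------------------------------------

#' Read/write BED and bedGraph files
#'
#' Thin wrappers around rtracklayer import/export keeping the package's
#' 0-based half-open data-frame convention at the surface.
#'
#' @param path File path.
#' @param df Interval data frame (`chrom`, `start`, `end`).
#' @param track Track data frame with a `value` column.
#' @name interval_io
NULL

#' @rdname interval_io
#' @export
read_bed <- function(path) {
  from_granges(rtracklayer::import(path, format = "BED"))
}

#' @rdname interval_io
#' @export
write_bed <- function(df, path) {
  rtracklayer::export(as_granges(df), path, format = "BED")
  invisible(path)
}

#' @rdname interval_io
#' @export
read_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  out <- from_granges(gr)
  out$value <- gr$score
  out
}

#' @rdname interval_io
#' @export
write_bedgraph <- function(track, path) {
  gr <- as_granges(track)
  gr$score <- track$value
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read a spike-in ledger or time-course table
#'
#' Ledgers are TSV with columns `sample`, `target_reads`, `spikein_reads`,
#' `input_target_reads`, `input_spikein_reads`; time courses are TSV with
#' `region_id`, `replicate`, `timepoint_min`, `signal`.
#'
#' @param path TSV file.
#' @export
read_ledger <- function(path) utils::read.delim(path)

#' @rdname read_ledger
#' @export
read_timecourse <- function(path) utils::read.delim(path)

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

write_report <- function(outdir, workflow, config, counts) {
  report <- list(workflow = workflow,
                 package_version = as.character(
                   utils::packageVersion("chorscar")),
                 r_version = R.version.string,
                 config = config, counts = counts,
                 timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  report
}

# ---- workflows -------------------------------------------------------------

#' Restoration analysis workflow
#'
#' Spike-in normalizes a per-peak chase time course (RRPM), fits the
#' first-order restoration model per region on replicate-averaged signal,
#' classifies restoration categories per replicate with the replicate-
#' agreement rule, and summarizes cumulative restoration. Emits TSV tables
#' and a JSON run report when `outdir` is given.
#'
#' @param timecourse Long data frame (`region_id`, `replicate`,
#'   `timepoint_min`, `signal`) or TSV path.
#' @param ledger Spike-in ledger data frame (one row per
#'   timepoint/replicate sample, see [downsampling_factors()]) or TSV
#'   path; `NULL` skips spike-in scaling (signal already normalized).
#' @param config [pipeline_config()] list.
#' @param strata Optional per-region stratum labels (named by region_id).
#' @param outdir Output directory, created if needed.
#' @return List with `fits` (per-region parameter table), `categories`,
#'   `summary`, `factors`, and `report`.
#' @export
run_restoration <- function(timecourse, ledger = NULL,
                            config = pipeline_config(), strata = NULL,
                            outdir = NULL) {
  if (is.character(timecourse)) {
    if (!file.exists(timecourse)) stop("missing input: ", timecourse)
    timecourse <- read_timecourse(timecourse)
  }
  if (is.character(ledger)) {
    if (!file.exists(ledger)) stop("missing input: ", ledger)
    ledger <- read_ledger(ledger)
  }
  req <- c("region_id", "replicate", "timepoint_min", "signal")
  if (!all(req %in% names(timecourse)))
    stop("time course must have columns: ", paste(req, collapse = ", "))
  if (!nrow(timecourse)) stop("empty time course")
  tp <- sort(unique(timecourse$timepoint_min))
  reps <- sort(unique(timecourse$replicate))
  regions <- unique(timecourse$region_id)
  factors <- NULL
  if (!is.null(ledger)) {
    factors <- downsampling_factors(ledger)
    key <- paste(ledger$timepoint_min, ledger$replicate)
    f <- factors[match(paste(timecourse$timepoint_min,
                             timecourse$replicate), key)]
    if (anyNA(f)) stop("ledger does not cover every timecourse sample")
    timecourse$signal <- timecourse$signal * f
  }
  # region x timepoint matrix per replicate
  mats <- lapply(reps, function(r) {
    d <- timecourse[timecourse$replicate == r, ]
    m <- matrix(NA_real_, length(regions), length(tp),
                dimnames = list(regions, tp))
    m[cbind(match(d$region_id, regions), match(d$timepoint_min, tp))] <-
      d$signal
    m
  })
  avg <- Reduce(`+`, mats) / length(mats)
  keep_tp <- !(tp %in% config$exclude_timepoints)
  fit_one <- function(yy) {
    f <- tryCatch(fit_first_order(tp[keep_tp] / 60, yy[keep_tp]),
                  error = function(e) NULL)
    if (is.null(f)) return(c(ymax = NA, b = NA, k = NA, t90 = NA,
                             recycled_fraction = NA, sse = NA))
    c(coef(f), t90 = f$t90, recycled_fraction = f$recycled_fraction,
      sse = f$sse)
  }
  fits <- as.data.frame(t(apply(avg, 1, fit_one)))
  fits <- cbind(region_id = regions, fits)
  rownames(fits) <- NULL
  categories <- classify_restoration(mats, tp, fold = config$fold)
  categories <- cbind(region_id = regions, categories)
  strat <- if (!is.null(strata)) strata[regions] else NULL
  summary_tab <- restoration_summary(categories, tp, strat)
  counts <- list(regions = length(regions), timepoints = length(tp),
                 replicates = length(reps),
                 excluded_timepoints = sum(!keep_tp),
                 fitted = sum(!is.na(fits$k)),
                 agreed = sum(!categories$label %in%
                                c("excluded", "excluded-zero")))
  report <- NULL
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_tsv(fits, file.path(outdir, "fits.tsv"))
    write_tsv(categories, file.path(outdir, "categories.tsv"))
    write_tsv(summary_tab, file.path(outdir, "restoration_summary.tsv"))
    report <- write_report(outdir, "restoration", config, counts)
  }
  list(fits = fits, categories = categories, summary = summary_tab,
       factors = factors, counts = counts, report = report)
}

# One SCAR sample through the fixed normalization chain:
# RPM -> blur -> input scaling -> subtraction (floor 0) -> coverage filter.
# With input_scale = "median" the RPM input is rescaled to the sample's
# background level (median ratio of per-window totals) before subtraction,
# so that subtraction removes the non-enriched background rather than
# over-subtracting it: IP enrichment compresses the background's share of
# an RPM-normalized library below the input's.
normalize_scar_sample <- function(sample, input, config) {
  s <- rpm_normalize(sample, sum(sample$F + sample$R))
  i <- rpm_normalize(input, sum(input$F + input$R))
  s <- blur(s, config$blur_halfwidth)
  if (config$blur_input) i <- blur(i, config$blur_halfwidth)
  if (identical(config$input_scale, "background")) {
    # lower-quartile totals sit in the undecorated background mass even
    # when smoothing has smeared peak signal across many windows
    ratio <- stats::quantile(s$F + s$R, 0.25, names = FALSE) /
      stats::quantile(i$F + i$R, 0.25, names = FALSE)
    i$F <- i$F * ratio
    i$R <- i$R * ratio
  }
  corrected <- input_correct(s, i)
  list(corrected = corrected, mask = coverage_mask(corrected,
                                                   config$min_rpm))
}

#' Partition / asymmetry analysis workflow
#'
#' Runs each SCAR sample through the fixed chain RPM normalization,
#' uniform blur, input subtraction with zero floor, and the both-strand
#' coverage filter; computes clipped partition scores, the OK-seq RFD
#' track, initiation-zone edges, the peak-proximity zone filter,
#' zone-anchored meta-profiles and adjusted partitions, and Wilcoxon
#' signed-rank asymmetry tests between consecutive sample pairs.
#'
#' @param samples Named list; each element a list with `sample` and
#'   `input` stranded count tracks (state `"raw"`).
#' @param okseq Stranded OK-seq count track.
#' @param izs Initiation zones (`chrom`, `center`), e.g. from the genome
#'   model or an external zone call.
#' @param peaks Peak set used to filter zones.
#' @param config [pipeline_config()] list.
#' @param outdir Optional output directory for TSV/bedGraph artifacts and
#'   the JSON report.
#' @return List with `partitions` (per sample), `adjusted`, `rfd`,
#'   `izs` (edges detected, peak-filtered), `metaprofiles`, `asymmetry`
#'   (pairwise test results), and `counts`.
#' @export
run_partition <- function(samples, okseq, izs, peaks,
                          config = pipeline_config(), outdir = NULL) {
  if (!length(samples)) stop("missing input: no SCAR samples supplied")
  if (is.null(names(samples)))
    names(samples) <- paste0("sample", seq_along(samples))
  counts <- list(windows = nrow(okseq))
  rfd <- rfd_score(rpm_normalize(okseq, sum(okseq$F + okseq$R)))
  zones <- detect_iz_edges(rfd, izs, config$iz_search)
  zones <- filter_izs(zones, peaks, config$iz_within)
  counts$zones_kept <- nrow(zones)
  if (!nrow(zones)) stop("no initiation zones survive the peak filter")
  partitions <- list(); adjusted <- list(); metas <- list()
  for (nm in names(samples)) {
    ns <- normalize_scar_sample(samples[[nm]]$sample,
                                samples[[nm]]$input, config)
    part <- partition_score(ns$corrected, ns$mask, config$clip_q)
    adj <- adjusted_partition(part, zones)
    adj$coverage <- ns$corrected$F + ns$corrected$R
    partitions[[nm]] <- part
    adjusted[[nm]] <- adj
    metas[[nm]] <- metaprofile(part, zones, config$span)
    counts[[paste0("unmasked_", nm)]] <- sum(!part$masked)
  }
  asym <- list()
  if (length(samples) >= 2) {
    pairs <- utils::combn(names(samples), 2, simplify = FALSE)
    for (pr in pairs) {
      asym[[paste(pr, collapse = "_vs_")]] <-
        asymmetry_test(adjusted[[pr[1]]], adjusted[[pr[2]]],
                       band = config$band, min_rpm = config$asym_min_rpm)
    }
  }
  report <- NULL
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_tsv(zones, file.path(outdir, "initiation_zones.tsv"))
    for (nm in names(partitions)) {
      p <- partitions[[nm]]
      p$value <- ifelse(is.na(p$score), 0, p$score)
      write_bedgraph(p[c("chrom", "start", "end", "value")],
                     file.path(outdir, paste0("partition_", nm,
                                              ".bedGraph")))
      write_tsv(adjusted[[nm]],
                file.path(outdir, paste0("adjusted_", nm, ".tsv")))
      write_tsv(metas[[nm]],
                file.path(outdir, paste0("metaprofile_", nm, ".tsv")))
    }
    if (length(asym)) {
      asym_tab <- do.call(rbind, lapply(names(asym), function(nm) {
        a <- asym[[nm]]
        data.frame(pair = nm, n = a$n, median_A = a$median_A,
                   median_B = a$median_B, statistic = a$statistic,
                   p_value = a$p_value)
      }))
      write_tsv(asym_tab, file.path(outdir, "asymmetry.tsv"))
    }
    report <- write_report(outdir, "partition", config, counts)
  }
  list(partitions = partitions, adjusted = adjusted, rfd = rfd,
       izs = zones, metaprofiles = metas, asymmetry = asym,
       counts = counts, report = report)
}

#' Synthetic end-to-end demo
#'
#' Simulates a genome model, a SCAR sample with matched input, an OK-seq
#' track and a ChOR chase time course with spike-in ledger, writing the
#' standard artifacts (BED, bedGraph, TSV, YAML config echo) to `outdir`.
#'
#' @param config A [sim_config()].
#' @param outdir Output directory.
#' @param mark Mark name (must appear in the config's `partition_truth`).
#' @return Invisible list of the simulated objects.
#' @export
run_simulation <- function(config, outdir, mark = "mark") {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  genome <- simulate_genome(config)
  scar <- simulate_scar_counts(genome, mark, config$sequencing_depth,
                               seed = config$seed + 1L)
  okseq <- simulate_okseq(genome, config$sequencing_depth,
                          seed = config$seed + 2L)
  chor <- simulate_chor_timecourse(genome, config)
  write_bed(genome$peaks, file.path(outdir, "peaks.bed"))
  write_bed(genome$blacklist, file.path(outdir, "blacklist.bed"))
  write_bed(genome$genes, file.path(outdir, "genes.bed"))
  write_tsv(genome$izs, file.path(outdir, "initiation_zones.tsv"))
  for (strand in c("F", "R")) {
    tr <- scar$sample[c("chrom", "start", "end")]
    tr$value <- scar$sample[[strand]]
    write_bedgraph(tr, file.path(outdir, paste0("scar_", strand,
                                                ".bedGraph")))
  }
  write_tsv(chor$signal, file.path(outdir, "timecourse.tsv"))
  write_tsv(chor$ledger, file.path(outdir, "ledger.tsv"))
  yaml::write_yaml(unclass(config)[c("seed", "sequencing_depth",
                                     "spikein_fraction", "noise_cv",
                                     "timepoints_min", "rfd_plateau")],
                   file.path(outdir, "config.yaml"))
  invisible(list(genome = genome, scar = scar, okseq = okseq,
                 chor = chor))
}
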