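make_track <- function(F, R, chrom = "chr1", width = 1000,
                       state = "RPM") {
  n <- length(F)
  tr <- data.frame(chrom = chrom, start = (seq_len(n) - 1) * width,
                   end = seq_len(n) * width, F = F, R = R)
  attr(tr, "norm_state") <- state
  tr
}

test_that("uniform blur equals the brute-force windowed mean", {
  # constant track unchanged; unit impulse spreads to 1/61
  cst <- blur(make_track(rep(2, 200), rep(3, 200)))
  expect_equal(cst$F, rep(2, 200))
  expect_equal(cst$R, rep(3, 200))
  imp <- make_track(c(rep(0, 100), 1, rep(0, 99)), rep(0, 200))
  bl <- blur(imp)
  expect_equal(sum(bl$F > 0), 61)
  expect_equal(max(bl$F), 1 / 61)
  # interior mass conservation
  expect_equal(sum(bl$F), 1)
  # random instances against the oracle, mixed lengths and halfwidths
  set.seed(33)
  for (i in 1:600) {
    n <- sample(5:80, 1)
    hw <- sample(1:10, 1)
    v <- rpois(n, 4) + runif(n)
    tr <- make_track(v, rev(v))
    got <- suppressWarnings(blur(tr, hw))
    expect_equal(got$F, oracle_blur(v, hw), info = paste("instance", i))
  }
  # chromosomes are smoothed independently
  two <- make_track(c(rep(0, 50), 10), rep(1, 51))
  two$chrom <- rep(c("chrA", "chrB"), c(50, 1))
  b2 <- suppressWarnings(blur(two, 5))
  expect_equal(b2$F[50], 0)      # chrA end sees nothing of chrB
  expect_equal(b2$F[51], 10)     # chrB is its own single-bin mean
  expect_error(blur(make_track(1:5, 1:5, state = "raw")), "RPM")
})

test_that("input correction subtracts with a zero floor", {
  tr <- make_track(c(2, 5, 1), c(0, 2, 4), state = "blurred")
  inp <- make_track(c(3, 2, 1), c(1, 1, 1), state = "blurred")
  out <- input_correct(tr, inp)
  expect_equal(out$F, c(0, 3, 0))
  expect_equal(out$R, c(0, 1, 3))
  # track equal to its input vanishes
  expect_true(all(input_correct(tr, tr)$F == 0))
  expect_error(input_correct(tr, inp[1:2, ]), "grid")
})

test_that("coverage mask drops windows weak on both strands only", {
  tr <- make_track(c(0.2, 0.5, 0.1, 0), c(0.2, 0, 0.5, 0.1),
                   state = "input-corrected")
  expect_equal(coverage_mask(tr, 0.3), c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(coverage_mask(tr, 0), rep(FALSE, 4))
})

test_that("partition score: formula, antisymmetry, clipping", {
  tr <- make_track(c(10, 3, 1, 0.1), c(10, 1, 3, 0.1),
                   state = "input-corrected")
  p <- partition_score(tr, mask = rep(FALSE, 4), clip_q = NULL)
  expect_equal(p$score, c(0, 0.5, -0.5, 0))
  # swapping strands negates every score
  sw <- make_track(tr$R, tr$F, state = "input-corrected")
  psw <- partition_score(sw, mask = rep(FALSE, 4), clip_q = NULL)
  expect_equal(psw$score, -p$score)
  # scores live in [-1, 1]; clipping only tightens
  set.seed(3)
  big <- make_track(rpois(5000, 2) + 0.1, rpois(5000, 2) + 0.1,
                    state = "input-corrected")
  pc <- partition_score(big, mask = rep(FALSE, 5000))
  pn <- partition_score(big, mask = rep(FALSE, 5000), clip_q = NULL)
  expect_true(all(abs(pn$score) <= 1))
  expect_true(all(pc$score >= min(pn$score) & pc$score <= max(pn$score)))
  bounds <- attr(pc, "clip_bounds")
  expect_true(all(pc$score >= bounds[1] & pc$score <= bounds[2]))
  # zero-total unmasked window is masked with a warning
  z <- make_track(c(1, 0), c(1, 0), state = "input-corrected")
  expect_warning(pz <- partition_score(z, mask = c(FALSE, FALSE),
                                       clip_q = NULL), "zero")
  expect_true(pz$masked[2])
})

test_that("RFD is the strand-swapped partition", {
  tr <- make_track(c(1, 3), c(3, 1), state = "RPM")
  r <- rfd_score(tr)
  expect_equal(r$score, c(0.5, -0.5))
  p <- partition_score(tr, mask = rep(FALSE, 2), clip_q = NULL)
  expect_equal(r$score, -p$score)
})

test_that("IZ edges are found at RFD extrema with center-proximal ties", {
  # synthetic monotone ramp: edges at the ramp endpoints
  n <- 300
  score <- c(rep(-0.6, 100), seq(-0.6, 0.6, length.out = 100),
             rep(0.6, 100))
  rfd <- data.frame(chrom = "chr1", start = (seq_len(n) - 1) * 1000,
                    end = seq_len(n) * 1000, score = score,
                    masked = rep(FALSE, n))
  izs <- data.frame(chrom = "chr1", center = 149500)
  ed <- detect_iz_edges(rfd, izs, search = 1e5)
  # the -0.6 plateau ends where the ramp starts (bin 101, midpoint
  # 100500); ties across the plateau break to the center-proximal bin
  expect_equal(ed$upstream_edge, 100500)
  expect_equal(ed$downstream_edge, 199500)
  # flat RFD: both edges collapse to the center-proximal position
  flat <- rfd
  flat$score <- 0
  ef <- detect_iz_edges(flat, izs, search = 1e4)
  expect_equal(ef$upstream_edge, 149500)
  expect_equal(ef$downstream_edge, 149500)
  # fully masked search range drops the zone
  msk <- rfd
  msk$masked <- TRUE
  expect_message(em <- detect_iz_edges(msk, izs), "dropped")
  expect_equal(nrow(em), 0L)
})

test_that("noiseless simulated zones are recovered at configured size", {
  g <- test_genome(seed = 8, n_peaks = 30)
  w <- make_windows(g, 1000)
  mid <- (w$start + w$end) / 2
  rfd <- data.frame(chrom = w$chrom, start = w$start, end = w$end,
                    score = true_rfd(g, w$chrom, mid),
                    masked = rep(FALSE, nrow(w)))
  ed <- detect_iz_edges(rfd, g$izs)
  expect_equal(nrow(ed), nrow(g$izs))
  # recovered size within one window of the configured size
  expect_true(all(abs(ed$size - g$izs$size) <= 2000))
})

test_that("zone filtering by peak proximity matches a distance scan", {
  peaks <- data.frame(chrom = "chr1", start = c(1e6, 5e6),
                      end = c(1e6 + 1e4, 5e6 + 1e4))
  izs <- data.frame(chrom = "chr1",
                    center = c(1.05e6, 1.2e6, 3e6, 5.15e6))
  kept <- filter_izs(izs, peaks, within = 1e5)
  # brute-force: distance from center to nearest peak edge
  dist <- vapply(izs$center, function(cc)
    min(pmax(0, pmax(peaks$start - cc, cc - peaks$end))), numeric(1))
  expect_equal(kept$center, izs$center[dist <= 1e5])
})

test_that("metaprofile averages zones with correct orientation", {
  # single zone: profile equals its own partition values
  n <- 400
  part <- data.frame(chrom = "chr1", start = (seq_len(n) - 1) * 1000,
                     end = seq_len(n) * 1000,
                     score = sin(seq_len(n) / 30),
                     masked = rep(FALSE, n))
  izs <- data.frame(chrom = "chr1", center = 200500)
  mp <- metaprofile(part, izs, span = 2e5)
  sel <- abs((part$start + part$end) / 2 - 200500) <= 1e5
  expect_equal(mp$score, part$score[sel])
  expect_equal(mp$offset[mp$score == part$score[sel][1]][1],
               (part$start + part$end)[which(sel)[1]] / 2 - 200500)
  # replicate averaging
  p2 <- part
  p2$score <- part$score + 0.2
  mp2 <- metaprofile(list(part, p2), izs, span = 2e5)
  expect_equal(mp2$score, mp$score + 0.1)
})

test_that("adjusted partition negates upstream windows only", {
  part <- data.frame(chrom = "chr1", start = c(0, 100000, 300000),
                     end = c(1000, 101000, 301000),
                     score = c(-0.2, 0.3, -0.4),
                     masked = rep(FALSE, 3))
  izs <- data.frame(chrom = "chr1", center = 150500)
  adj <- adjusted_partition(part, izs)
  expect_equal(adj$adjusted, c(0.2, -0.3, -0.4))
  expect_equal(adj$offset < 0, c(TRUE, TRUE, FALSE))
})

test_that("asymmetry test: identical samples, power, and counting", {
  n <- 2000
  base <- data.frame(chrom = "chr1", start = (seq_len(n) - 1) * 1000,
                     end = seq_len(n) * 1000)
  base$offset <- rep(c(-1, 1), n / 2) * round(runif(n, 0, 1e5))
  withr::with_seed(99, {
    base$adjusted <- rnorm(n, 0, 0.15)
    base$coverage <- runif(n, 0.2, 3)
    shifted <- base
    shifted$adjusted <- base$adjusted + 0.1
    # identical samples: maximal p
    same <- asymmetry_test(base, base)
    expect_equal(same$p_value, 1)
    # +0.1 shift at n ~ 2000: overwhelming rejection
    res <- asymmetry_test(base, shifted)
    expect_lt(res$p_value, 1e-6)
    expect_equal(res$median_B - res$median_A, 0.1, tolerance = 0.02)
    # eligible count equals the brute-force distance/coverage filter
    want <- sum(abs(base$offset) >= 25000 & abs(base$offset) <= 75000 &
                  base$coverage > 0.6 & shifted$coverage > 0.6)
    expect_equal(res$n, want)
    # stratum filter narrows the set
    strat <- asymmetry_test(base, shifted, eligible = base$start < 5e5)
    expect_lt(strat$n, res$n)
    expect_error(asymmetry_test(base[1:5, ], shifted[1:5, ]), "10")
  })
})

test_that("null asymmetry tests are calibrated at the window level", {
  # independent window noise, no shift: rejection at alpha = 0.01 must be
  # rare across seeded nulls
  n <- 800
  rejections <- 0
  for (s in 1:100) {
    withr::with_seed(1000 + s, {
      a <- data.frame(chrom = "chr1", start = (seq_len(n) - 1) * 1000,
                      end = seq_len(n) * 1000,
                      offset = rep(c(-1, 1), n / 2) *
                        round(runif(n, 25000, 75000)),
                      adjusted = rnorm(n, 0, 0.15),
                      coverage = rep(2, n))
      b <- a
      b$adjusted <- rnorm(n, 0, 0.15)
      if (asymmetry_test(a, b)$p_value < 0.01) rejections <- rejections + 1
    })
  }
  expect_lte(rejections, 5)
})

test_that("pipeline order is fixed: full chain recovers configured bias", {
  g <- test_genome(seed = 11, beta = 0.2,
                   chromosomes = c(chr1 = 1e7, chr2 = 1e7),
                   n_peaks = 80, n_izs = 10, iz_size_range = c(4e4, 6e4))
  sc <- simulate_scar_counts(g, "mark", 2e7, seed = 3)
  ns <- chorscar:::normalize_scar_sample(sc$sample, sc$input,
                                         pipeline_config())
  expect_identical(norm_state <- attr(ns$corrected, "norm_state"),
                   "input-corrected")
  part <- partition_score(ns$corrected, ns$mask)
  adj <- adjusted_partition(part, g$izs)
  cov <- ns$corrected$F + ns$corrected$R
  sel <- abs(adj$offset) >= 60000 & abs(adj$offset) <= 95000 &
    !is.na(adj$adjusted) & cov > 0.6
  zm <- tapply(adj$adjusted[sel], adj$zone[sel], mean)
  se <- stats::sd(zm) / sqrt(length(zm))
  expect_lt(abs(mean(zm) - 0.2), 3 * se)
})
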