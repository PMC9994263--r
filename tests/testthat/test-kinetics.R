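tc_hours <- c(0, 0.25, 0.5, 1, 2, 3, 8)

test_that("noiseless curves are refit to near machine precision", {
  for (p in list(c(1, 0.7, 0.5), c(2, 1.4, 1.3), c(0.8, 0.3, 0.18))) {
    y <- p[1] - p[2] * exp(-p[3] * tc_hours)
    fit <- fit_first_order(tc_hours, y)
    expect_equal(unname(coef(fit)), p, tolerance = 1e-6)
    expect_true(fit$converged)
    # derived quantities agree with closed forms
    expect_equal(fit$t90, log(0.1 * p[1] / p[2]) / (-p[3]),
                 tolerance = 1e-6)
    expect_equal(fit$recycled_fraction, (p[1] - p[2]) / p[1],
                 tolerance = 1e-6)
  }
})

test_that("t90 closed form matches hand arithmetic and scaling laws", {
  # ymax = 1, b = 0.75, k = ln(7.5)/2 -> exactly 2 h
  expect_equal(t90(1, b = 0.75, k = log(7.5) / 2), 2.0, tolerance = 1e-9)
  expect_equal(t90(1, b = 0.7, k = 0.5), log(0.1 / 0.7) / (-0.5),
               tolerance = 1e-12)
  # boundary: b = 0.1 * ymax means >= 90% restored at t = 0
  expect_equal(t90(1, b = 0.1, k = 1), 0)
  expect_message(out <- t90(structure(list(coefficients =
    c(ymax = 1, b = 0.05, k = 1)), class = "chor_fit")), "90%")
  expect_equal(out, 0)
  # doubling k halves t90
  expect_equal(t90(1, b = 0.7, k = 2), t90(1, b = 0.7, k = 1) / 2)
})

test_that("recycled fraction is scale invariant", {
  expect_equal(recycled_fraction(1, b = 0.7), 0.3)
  expect_equal(recycled_fraction(2, b = 1.4), 0.3)
  expect_equal(recycled_fraction(1, b = 1), 0)
  # joint rescale of (ymax, b) leaves t90 too
  expect_equal(t90(3, b = 2.1, k = 0.5), t90(1, b = 0.7, k = 0.5))
})

test_that("fit interface: formula method, exclusions, minutes, methods", {
  d <- data.frame(time = tc_hours * 60,
                  signal = 1 - 0.7 * exp(-0.5 * tc_hours))
  fit <- fit_first_order(signal ~ time, d, time_unit = "minutes")
  expect_equal(unname(coef(fit)), c(1, 0.7, 0.5), tolerance = 1e-6)
  # excluding a (corrupted) late timepoint restores the fit
  d2 <- d
  d2$signal[d2$time == 480] <- 0.2
  fit2 <- fit_first_order(signal ~ time, d2, time_unit = "minutes",
                          exclude = 480)
  expect_equal(unname(coef(fit2)), c(1, 0.7, 0.5), tolerance = 1e-6)
  # methods
  expect_equal(predict(fit, 0), 0.3, tolerance = 1e-6)
  expect_equal(fitted(fit) + residuals(fit), d$signal)
  expect_equal(deviance(fit), fit$sse)
  s <- summary(fit)
  expect_s3_class(s, "summary.chor_fit")
  expect_output(print(fit), "restoration")
  expect_output(print(s), "t90")
  sims <- simulate(fit, nsim = 3, seed = 1, cv = 0.1)
  expect_equal(dim(sims), c(7L, 3L))
  pdf(NULL); on.exit(dev.off())
  expect_invisible(plot(fit))
})

test_that("degenerate series are flagged, not silently fit", {
  expect_error(fit_first_order(tc_hours, c(7, 6, 5, 4, 3, 2, 1)),
               "unstable")
  flat <- fit_first_order(tc_hours, rep(3, 7))
  expect_equal(unname(coef(flat)[c("ymax", "b")]), c(3, 0))
  expect_equal(flat$recycled_fraction, 1)
  expect_true("degenerate-constant" %in% flat$flags)
  expect_error(fit_first_order(c(0, 1, 2), c(1, 2, 3)), "at least 4")
})

test_that("the fit is near the information bound under realistic noise", {
  # peaks spanning t90 in [0.5, 12] h, 10% multiplicative noise, curves
  # averaged over two replicates as in the assay protocol. The oracle is
  # the Cramer-Rao bound of the three-parameter model: for a Gaussian
  # efficient estimator the median |relative error| of k-hat is
  # 0.6745 * CRLB sd, so the fit must land within a modest factor of it.
  crlb_rel_k <- function(k, ymax = 1, b = 0.7, cv = 0.1) {
    y <- ymax - b * exp(-k * tc_hours)
    J <- cbind(1, -exp(-k * tc_hours), b * tc_hours * exp(-k * tc_hours))
    W <- diag(1 / (cv * y)^2)
    sqrt(solve(t(J) %*% W %*% J)[3, 3]) / k
  }
  set.seed(2024)
  n <- 200
  k_true <- log(7) / runif(n, 0.5, 12)
  rel_k <- numeric(n)
  err_rf <- numeric(n)
  sdlog <- sqrt(log(1 + 0.1^2))
  for (i in seq_len(n)) {
    mu <- 1 - 0.7 * exp(-k_true[i] * tc_hours)
    y <- (mu * rlnorm(length(tc_hours), -sdlog^2 / 2, sdlog) +
            mu * rlnorm(length(tc_hours), -sdlog^2 / 2, sdlog)) / 2
    fit <- fit_first_order(tc_hours, y)
    rel_k[i] <- abs(coef(fit)[["k"]] - k_true[i]) / k_true[i]
    err_rf[i] <- abs(fit$recycled_fraction - 0.3)
  }
  bound <- median(0.6745 * vapply(k_true, crlb_rel_k, numeric(1),
                                  cv = 0.1 / sqrt(2)))
  expect_lt(median(rel_k), 1.25 * bound)
  expect_lt(median(err_rf), 0.05)
})

test_that("restoration classifier reproduces the worked series", {
  tp <- c(0, 30, 180, 480)
  out <- classify_restoration(rbind(
    c(5, 5, 5, 5),        # flat: restored at the first timepoint
    c(1, 2, 3.5, 3.6),    # increases 1.5x until 180 min
    c(3, 2, 1.9, 1.8)),   # 3 -> 2 is a 1.5-fold decrease: unstable
    tp)
  expect_equal(out$label, c("R0", "R180", "unstable"))
  expect_equal(out$restored_at, c(0, 180, NA))
  # all-zero series excluded; zero at T(X) is not restored there
  z <- classify_restoration(rbind(c(0, 0, 0, 0), c(0, 1, 1.2, 1.3)), tp)
  expect_equal(z$label, c("excluded-zero", "R30"))
})

test_that("classifier is scale invariant and respects replicate agreement", {
  tp <- c(0, 30, 180, 480)
  set.seed(5)
  for (i in 1:1000) {
    s <- runif(4, 0.1, 10)
    c1 <- classify_restoration(rbind(s), tp)
    c2 <- classify_restoration(rbind(s * runif(1, 0.01, 100)), tp)
    expect_identical(c1$label, c2$label)
  }
  # replicate agreement on labels, not averaged signal
  r1 <- rbind(c(5, 5, 5, 5), c(1, 2, 3.5, 3.6))
  r2 <- rbind(c(5, 5, 5, 5), c(1, 1.2, 1.3, 1.4))
  cc <- classify_restoration(list(r1, r2), tp)
  expect_equal(cc$label, c("R0", "excluded"))
})

test_that("consecutive-only decrease option relaxes the unstable rule", {
  tp <- c(0, 30, 180, 480)
  s <- c(3, 2.5, 2.2, 1.9)  # only the 0 -> 480 pair is a 1.5x decrease
  expect_equal(classify_restoration(rbind(s), tp)$label, "unstable")
  expect_equal(classify_restoration(rbind(s), tp,
                                    decrease = "consecutive")$label, "R0")
})

test_that("cumulative restoration summary matches a counting oracle", {
  tp <- c(0, 60, 120)
  lab <- data.frame(
    label = c("R0", "R60", "R60", "R120", "unstable", "excluded-zero",
              "R0", "not-restored", "R120", "R60"),
    restored_at = c(0, 60, 60, 120, NA, NA, 0, NA, 120, 60))
  strat <- rep(c("a", "b"), 5)
  out <- restoration_summary(lab, tp, strat)
  # brute-force tally, denominator = classifiable regions per stratum
  for (s in c("a", "b")) {
    sel <- strat == s & !lab$label %in% c("excluded", "excluded-zero")
    for (tt in tp) {
      want <- sum(lab$restored_at[sel] <= tt, na.rm = TRUE) / sum(sel)
      got <- out$cum_fraction_restored[out$stratum == s &
                                         out$timepoint_min == tt]
      expect_equal(got, want)
    }
  }
  # non-decreasing in time
  for (s in unique(out$stratum))
    expect_true(!is.unsorted(out$cum_fraction_restored[out$stratum == s]))
  # global curve equals the single-stratum curve
  glob <- restoration_summary(lab, tp)
  one <- restoration_summary(lab, tp, rep("all", 10))
  expect_equal(glob, one)
})
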