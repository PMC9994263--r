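# First-order restoration kinetics: y(t) = ymax - b * exp(-k * t).
# fit_first_order() is the package's central model; it returns a classed
# object with the usual accessor methods. Internally the linear parameters
# (ymax, b) are profiled out by least squares for each candidate rate k
# (variable projection), leaving a 1-D deterministic search over k.

first_order_curve <- function(t, ymax, b, k) ymax - b * exp(-k * t)

# For fixed k, solve min over (ymax, b) of ||y - (ymax - b e^{-kt})||^2,
# subject to b >= 0 and b <= ymax; returns params and SSE.
profile_linear <- function(t, y, k) {
  x <- exp(-k * t)
  fit <- stats::lsfit(x, y, intercept = TRUE)
  ymax <- fit$coefficients[[1]]
  b <- -fit$coefficients[[2]]
  if (b < 0 || b > ymax || ymax <= 0) {
    # constrained fall-backs on the boundary of {0 <= b <= ymax}
    cand <- list()
    m <- mean(y)                               # b = 0
    cand[[1]] <- c(ymax = m, b = 0)
    a <- sum(y * (1 - x)) / sum((1 - x)^2)     # b = ymax
    cand[[2]] <- c(ymax = a, b = a)
    best <- NULL; best_sse <- Inf
    for (p in cand) {
      if (p[["ymax"]] <= 0) next
      sse <- sum((y - first_order_curve(t, p[["ymax"]], p[["b"]], k))^2)
      if (sse < best_sse) { best <- p; best_sse <- sse }
    }
    if (is.null(best)) return(list(ymax = NA, b = NA, sse = Inf))
    return(list(ymax = best[["ymax"]], b = best[["b"]], sse = best_sse))
  }
  list(ymax = ymax, b = b,
       sse = sum((y - first_order_curve(t, ymax, b, k))^2))
}

#' Fit the first-order restoration model
#'
#' Least-squares fit of y(t) = ymax - b * exp(-k * t) to a chase time
#' course, the model under which a histone mark on nascent chromatin
#' (signal ymax - b at t = 0) is restored towards its steady-state plateau
#' ymax at rate k. The derived quantities t90 (time to reach 90% of the
#' plateau) and the recycled fraction ((ymax - b)/ymax, the proportion of
#' steady state already present on nascent chromatin) are attached to the
#' fit.
#'
#' The fit profiles the linear parameters out and searches the rate on a
#' fixed logarithmic grid refined by golden-section optimization, so the
#' result is deterministic for given data. Constraints k > 0 and
#' 0 <= b <= ymax are enforced.
#'
#' @param x A formula `signal ~ time`, or a numeric vector of times.
#' @param ... Passed on to methods.
#' @return An object of class `chor_fit` with components `coefficients`
#'   (`ymax`, `b`, `k`), `t90`, `recycled_fraction`, `sse`, `fitted.values`,
#'   `residuals`, `data`, `converged` and `flags`.
#' @examples
#' t <- c(0, 0.25, 0.5, 1, 2, 3, 8)
#' y <- 1 - 0.7 * exp(-1.3 * t)
#' fit <- fit_first_order(t, y)
#' coef(fit)
#' t90(fit)
#' @export
fit_first_order <- function(x, ...) UseMethod("fit_first_order")

#' @rdname fit_first_order
#' @param data Data frame holding the formula's variables.
#' @param time_unit `"hours"` or `"minutes"`; minutes are converted to
#'   hours (rates are reported per hour).
#' @param exclude Timepoints (in `time_unit`) to omit from the regression,
#'   e.g. late timepoints confounded by mitotic removal of a mark.
#' @export
fit_first_order.formula <- function(x, data, time_unit = c("hours",
                                    "minutes"), exclude = NULL, ...) {
  mf <- stats::model.frame(x, data)
  fit_first_order.default(mf[[2L]], mf[[1L]], time_unit = time_unit,
                          exclude = exclude, ...)
  }

#' @rdname fit_first_order
#' @param y Numeric vector of signal values (same length as `x`).
#' @param k_grid Range of rates (per hour) scanned by the profile search.
#' @export
fit_first_order.default <- function(x, y, time_unit = c("hours", "minutes"),
                                    exclude = NULL,
                                    k_grid = c(1e-3, 50), ...) {
  time_unit <- match.arg(time_unit)
  cl <- match.call()
  t_in <- x
  keep <- !(t_in %in% exclude)
  t <- t_in[keep]
  y <- y[keep]
  if (time_unit == "minutes") t <- t / 60
  if (is.unsorted(t, strictly = TRUE))
    stop("timepoints must be strictly increasing")
  if (length(t) < 4)
    stop("need at least 4 non-excluded timepoints to fit 3 parameters")
  if (any(y < 0)) stop("signal values must be non-negative")
  flags <- character()
  if (all(diff(y) < 0))
    stop("signal decreases monotonically; no restoration to fit - ",
         "consider the unstable classification instead")
  if (stats::sd(y) == 0) {
    # flat series: plateau already reached at t = 0
    co <- c(ymax = y[1], b = 0, k = NA_real_)
    fitted <- rep(y[1], length(y))
    obj <- structure(list(coefficients = co, sse = 0,
                          fitted.values = fitted, residuals = y - fitted,
                          data = data.frame(time = t, signal = y),
                          t90 = 0, recycled_fraction = 1,
                          converged = TRUE,
                          flags = "degenerate-constant", call = cl),
                     class = "chor_fit")
    return(obj)
  }
  # deterministic 1-D search over log k
  ks <- exp(seq(log(k_grid[1]), log(k_grid[2]), length.out = 120))
  sses <- vapply(ks, function(k) profile_linear(t, y, k)$sse, numeric(1))
  i0 <- which.min(sses)
  lo <- ks[max(1L, i0 - 1L)]; hi <- ks[min(length(ks), i0 + 1L)]
  opt <- stats::optimize(function(lk) profile_linear(t, y, exp(lk))$sse,
                         interval = log(c(lo, hi)), tol = 1e-12)
  k <- exp(opt$minimum)
  pl <- profile_linear(t, y, k)
  converged <- is.finite(pl$sse)
  if (!converged) flags <- c(flags, "no-convergence")
  if (pl$b == 0) flags <- c(flags, "degenerate-constant")
  if (k <= k_grid[1] * 1.01 || k >= k_grid[2] * 0.99)
    flags <- c(flags, "rate-at-bound")
  co <- c(ymax = pl$ymax, b = pl$b, k = k)
  fitted <- first_order_curve(t, pl$ymax, pl$b, k)
  obj <- structure(list(coefficients = co, sse = pl$sse,
                        fitted.values = fitted, residuals = y - fitted,
                        data = data.frame(time = t, signal = y),
                        converged = converged, flags = flags, call = cl),
                   class = "chor_fit")
  obj$t90 <- t90(obj)
  obj$recycled_fraction <- recycled_fraction(obj)
  obj
}

#' Time to 90% restoration
#'
#' Closed form from the fitted curve: solving
#' y(t) = 0.9 * ymax gives t90 = ln(0.1 * ymax / b) / (-k). When
#' b <= 0.1 * ymax the signal is already at or above 90% of the plateau at
#' t = 0 and t90 is 0 (with a message).
#'
#' @param fit A `chor_fit`, or the plateau `ymax`.
#' @param b,k Amplitude and rate when `fit` is given as `ymax`.
#' @return Hours.
#' @examples
#' t90(1, b = 0.75, k = log(7.5) / 2)  # 2 hours
#' @export
t90 <- function(fit, b = NULL, k = NULL) {
  if (inherits(fit, "chor_fit")) {
    co <- fit$coefficients
    ymax <- co[["ymax"]]; b <- co[["b"]]; k <- co[["k"]]
  } else ymax <- fit
  if (is.na(k) || b <= 0.1 * ymax) {
    if (!is.na(k)) message("b <= 0.1 * ymax: >= 90% restored at t = 0")
    return(0)
  }
  log(0.1 * ymax / b) / (-k)
}

#' Recycled fraction
#'
#' The fitted signal at t = 0 relative to the plateau,
#' (ymax - b) / ymax: the proportion of the steady-state mark present on
#' nascent chromatin, i.e. transmitted by parental-histone recycling.
#'
#' @inheritParams t90
#' @return Fraction in `[0, 1]`.
#' @export
recycled_fraction <- function(fit, b = NULL) {
  if (inherits(fit, "chor_fit")) {
    co <- fit$coefficients
    ymax <- co[["ymax"]]; b <- co[["b"]]
  } else ymax <- fit
  (ymax - b) / ymax
}

#' @export
print.chor_fit <- function(x, digits = 4, ...) {
  cat("First-order restoration fit: y(t) = ymax - b * exp(-k * t)\n")
  print(round(x$coefficients, digits))
  cat(sprintf("t90: %.*g h   recycled fraction: %.*g\n",
              digits, x$t90, digits, x$recycled_fraction))
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.chor_fit <- function(object, ...) object$coefficients

#' @export
fitted.chor_fit <- function(object, ...) object$fitted.values

#' @export
residuals.chor_fit <- function(object, ...) object$residuals

#' @export
deviance.chor_fit <- function(object, ...) object$sse

#' @export
predict.chor_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$data$time
  else if (is.data.frame(newdata)) newdata$time else newdata
  co <- object$coefficients
  if (is.na(co[["k"]])) return(rep(co[["ymax"]], length(t)))
  first_order_curve(t, co[["ymax"]], co[["b"]], co[["k"]])
}

#' @export
summary.chor_fit <- function(object, ...) {
  n <- nrow(object$data)
  structure(list(coefficients = object$coefficients,
                 t90 = object$t90,
                 recycled_fraction = object$recycled_fraction,
                 sse = object$sse, n = n,
                 sigma = sqrt(object$sse / max(1, n - 3)),
                 converged = object$converged, flags = object$flags,
                 call = object$call),
            class = "summary.chor_fit")
}

#' @export
print.summary.chor_fit <- function(x, digits = 4, ...) {
  cat("First-order restoration fit\nCall: ")
  print(x$call)
  cat("\nParameters:\n")
  print(round(x$coefficients, digits))
  cat(sprintf("\nt90 (h):            %.*g\n", digits, x$t90))
  cat(sprintf("recycled fraction:  %.*g\n", digits, x$recycled_fraction))
  cat(sprintf("residual SE:        %.*g on %d timepoints\n",
              digits, x$sigma, x$n))
  if (!x$converged) cat("WARNING: fit did not converge\n")
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.chor_fit <- function(x, n_curve = 200, ...) {
  d <- x$data
  tt <- seq(0, max(d$time), length.out = n_curve)
  graphics::plot(d$time, d$signal, xlab = "chase time (h)",
                 ylab = "signal", pch = 19, ...)
  graphics::lines(tt, predict(x, tt))
  graphics::abline(h = 0.9 * x$coefficients[["ymax"]], lty = 3)
  if (x$t90 > 0) graphics::abline(v = x$t90, lty = 3)
  invisible(x)
}

#' Simulate time courses from a fitted restoration curve
#'
#' Draws `nsim` replicate series from the fitted curve under mean-one
#' multiplicative log-normal noise.
#'
#' @param object A `chor_fit`.
#' @param nsim Number of series.
#' @param seed Optional seed.
#' @param cv Coefficient of variation of the noise.
#' @param ... Unused.
#' @return Data frame with one column per simulated series, rows matching
#'   the fit's timepoints.
#' @export
simulate.chor_fit <- function(object, nsim = 1, seed = NULL, cv = 0.1,
                              ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- fitted(object)
  sdlog <- sqrt(log(1 + cv^2))
  out <- replicate(nsim, mu * stats::rlnorm(length(mu), -sdlog^2 / 2,
                                            sdlog))
  as.data.frame(out)
}

# ---- restoration categories -----------------------------------------------

# Classify one series: earliest timepoint X after which the signal never
# again increases >= `fold`; decreasing >= fold anywhere => unstable.
classify_series <- function(values, timepoints, fold = 1.5,
                            decrease = c("any", "consecutive")) {
  decrease <- match.arg(decrease)
  n <- length(values)
  stopifnot(n == length(timepoints))
  if (all(values == 0))
    return(list(label = "excluded-zero", restored_at = NA_real_))
  pairs <- if (decrease == "consecutive") {
    cbind(seq_len(n - 1), seq_len(n - 1) + 1L)
  } else {
    idx <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
    cbind(idx[, "row"], idx[, "col"])    # all i < j pairs
  }
  for (p in seq_len(nrow(pairs))) {
    i <- pairs[p, 1]; j <- pairs[p, 2]
    if (values[j] > 0 && values[i] / values[j] >= fold)
      return(list(label = "unstable", restored_at = NA_real_))
    if (values[j] == 0 && values[i] > 0)
      return(list(label = "unstable", restored_at = NA_real_))
  }
  for (i in seq_len(n)) {
    if (values[i] == 0) next            # ratio undefined: not restored here
    later <- values[seq_len(n) > i]
    if (!length(later) || all(later / values[i] < fold))
      return(list(label = paste0("R", timepoints[i]), restored_at = timepoints[i]))
  }
  list(label = "not-restored", restored_at = NA_real_)
}

#' Restoration categories from fold-change rules
#'
#' A region is restored at timepoint R(X) when its signal does not increase
#' by `fold` or more at any subsequent timepoint (T(X+n)/T(X) < fold). A
#' region whose signal decreases `fold`-fold is unstable; an all-zero
#' series is excluded. When several replicates are supplied, only regions
#' receiving the same label in every replicate are kept; disagreements are
#' labelled `"excluded"`.
#'
#' @param x Numeric matrix (regions x timepoints) for a single replicate,
#'   or a list of such matrices, one per replicate (identical timepoints).
#' @param timepoints Chase timepoints (minutes) naming the categories.
#' @param fold Fold-change threshold.
#' @param decrease Whether the unstable test compares `"any"` later-vs-
#'   earlier pair (default) or `"consecutive"` timepoints only.
#' @return Data frame with `label` (e.g. `"R60"`, `"unstable"`,
#'   `"not-restored"`, `"excluded-zero"`, `"excluded"`) and `restored_at`
#'   (minutes, NA unless restored).
#' @examples
#' classify_restoration(rbind(c(1, 2, 3.5, 3.6)), c(0, 30, 180, 480))
#' @export
classify_restoration <- function(x, timepoints, fold = 1.5,
                                 decrease = c("any", "consecutive")) {
  decrease <- match.arg(decrease)
  one_rep <- function(m) {
    m <- as.matrix(m)
    if (ncol(m) != length(timepoints))
      stop("series length does not match timepoints")
    res <- apply(m, 1, classify_series, timepoints = timepoints,
                 fold = fold, decrease = decrease)
    data.frame(label = vapply(res, `[[`, "", "label"),
               restored_at = vapply(res, `[[`, 0, "restored_at"),
               stringsAsFactors = FALSE)
  }
  if (!is.list(x) || is.data.frame(x)) return(one_rep(x))
  reps <- lapply(x, one_rep)
  lab <- reps[[1]]$label
  at <- reps[[1]]$restored_at
  for (r in reps[-1]) {
    disagree <- lab != r$label
    lab[disagree] <- "excluded"
    at[disagree] <- NA_real_
  }
  data.frame(label = lab, restored_at = at, stringsAsFactors = FALSE)
}

#' Cumulative fraction restored per stratum
#'
#' For each stratum, the fraction of classifiable regions restored at or
#' before each chase timepoint; unstable, not-restored and excluded
#' regions are tallied separately. Empty strata are omitted with a
#' message.
#'
#' @param categories Output of [classify_restoration()].
#' @param timepoints Chase timepoints (minutes).
#' @param strata Optional factor of stratum labels per region.
#' @return Data frame with `stratum`, `timepoint_min`,
#'   `cum_fraction_restored`, `n`, `n_unstable`, `n_excluded`.
#' @export
restoration_summary <- function(categories, timepoints, strata = NULL) {
  if (is.null(strata)) strata <- rep("all", nrow(categories))
  strata <- as.factor(strata)
  out <- list()
  for (s in levels(strata)) {
    sel <- which(strata == s & !is.na(strata))
    if (!length(sel)) { message("stratum '", s, "' is empty; omitted"); next }
    lab <- categories$label[sel]
    at <- categories$restored_at[sel]
    n_unstable <- sum(lab == "unstable")
    n_excluded <- sum(lab %in% c("excluded", "excluded-zero"))
    denom <- sum(!lab %in% c("excluded", "excluded-zero"))
    frac <- vapply(timepoints,
                   function(tt) sum(!is.na(at) & at <= tt) / max(1, denom),
                   numeric(1))
    out[[s]] <- data.frame(stratum = s, timepoint_min = timepoints,
                           cum_fraction_restored = frac, n = denom,
                           n_unstable = n_unstable,
                           n_excluded = n_excluded,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
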