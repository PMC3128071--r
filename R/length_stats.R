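## Distribution statistics for inter-CDS length samples: lower-limit
## estimation, Gaussian fits on log10 histograms with a nested F-test,
## stratified summaries, composition tests and cross-species summaries.

#' Estimate the lower limit (left edge) of a length distribution
#'
#' The left edge of the length distribution of promoter-containing regions
#' is read as the minimal space needed for transcription initiation and
#' regulation.  The default estimator is the empirical 1% quantile (linear
#' interpolation between order statistics, rounded to integer bp), which
#' is robust to a stray annotation error; `method = "min"` returns the
#' sample minimum.  Samples smaller than 20 fall back to the minimum with
#' a warning.
#'
#' @param lengths Positive integer lengths (bp).
#' @param method `"quantile"` (default) or `"min"`.
#' @param q Quantile in `[0, 0.05]` for `method = "quantile"`.
#' @return List with `value` (integer bp), `method`, `q`, `n`.
#' @export
estimate_lower_limit <- function(lengths, method = c("quantile", "min"),
                                 q = 0.01) {
  method <- match.arg(method)
  lengths <- as.numeric(lengths)
  if (length(lengths) == 0 || all(is.na(lengths))) {
    stop("cannot estimate a lower limit from an empty sample", call. = FALSE)
  }
  lengths <- lengths[!is.na(lengths)]
  if (method == "quantile" && (q < 0 || q > 0.05)) {
    stop("q must lie in [0, 0.05]", call. = FALSE)
  }
  if (method == "quantile" && length(lengths) < 20) {
    warning("fewer than 20 lengths; falling back to the sample minimum",
            call. = FALSE)
    method <- "min"
  }
  value <- if (method == "min") {
    min(lengths)
  } else {
    unname(stats::quantile(lengths, probs = q, type = 7))
  }
  list(value = as.integer(round(value)), method = method,
       q = if (method == "quantile") q else NA_real_, n = length(lengths))
}

## histogram of log10 lengths at a fixed bin width
.log10_hist <- function(lengths, bin_width) {
  x <- log10(lengths)
  lo <- floor(min(x) / bin_width) * bin_width
  hi <- ceiling(max(x) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  breaks <- seq(lo, hi + bin_width / 2, by = bin_width)
  h <- graphics::hist(x, breaks = breaks, plot = FALSE, right = FALSE)
  list(mids = h$mids, counts = h$counts, breaks = breaks)
}

.gauss_curve <- function(x, pars) {
  ## pars = c(a1, mu1, s1[, a2, mu2, s2]); amplitudes/sds on log scale-free
  k <- length(pars) / 3
  y <- 0
  for (j in seq_len(k)) {
    a <- pars[3 * j - 2]; mu <- pars[3 * j - 1]; s <- pars[3 * j]
    y <- y + a * exp(-(x - mu)^2 / (2 * s^2))
  }
  y
}

.fit_ls <- function(mids, counts, start, bin_width) {
  ## variance-weighted least squares (weights 1/max(count, 1), the usual
  ## Poisson-noise weighting for histogram fitting): Levenberg-Marquardt
  ## first, Nelder-Mead on log-transformed scale parameters as fallback
  k <- length(start) / 3
  w <- 1 / pmax(counts, 1)
  lower <- rep(c(1e-9, min(mids) - 1, bin_width / 10), k)
  upper <- rep(c(max(counts) * 10 + 10, max(mids) + 1, diff(range(mids)) + 1), k)
  df <- data.frame(x = mids, y = counts, w = w)
  form <- if (k == 1) {
    y ~ a1 * exp(-(x - mu1)^2 / (2 * s1^2))
  } else {
    y ~ a1 * exp(-(x - mu1)^2 / (2 * s1^2)) + a2 * exp(-(x - mu2)^2 / (2 * s2^2))
  }
  nm <- as.vector(t(outer(c("a", "mu", "s"), seq_len(k), paste0)))
  wrss <- function(pars) sum(w * (counts - .gauss_curve(mids, pars))^2)
  fit <- tryCatch({
    m <- suppressWarnings(minpack.lm::nlsLM(
      form, data = df, weights = w,
      start = stats::setNames(as.list(start), nm),
      lower = stats::setNames(lower, nm), upper = stats::setNames(upper, nm),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ))
    p <- unname(stats::coef(m)[nm])
    list(pars = p, rss = wrss(p))
  }, error = function(e) NULL)
  if (is.null(fit)) {
    obj <- function(theta) {
      pars <- theta
      pars[seq(1, 3 * k, 3)] <- exp(pars[seq(1, 3 * k, 3)])
      pars[seq(3, 3 * k, 3)] <- exp(pars[seq(3, 3 * k, 3)])
      wrss(pars)
    }
    theta0 <- start
    theta0[seq(1, 3 * k, 3)] <- log(pmax(start[seq(1, 3 * k, 3)], 1e-6))
    theta0[seq(3, 3 * k, 3)] <- log(pmax(start[seq(3, 3 * k, 3)], 1e-6))
    o <- stats::optim(theta0, obj, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-12))
    pars <- o$par
    pars[seq(1, 3 * k, 3)] <- exp(pars[seq(1, 3 * k, 3)])
    pars[seq(3, 3 * k, 3)] <- exp(pars[seq(3, 3 * k, 3)])
    fit <- list(pars = pars, rss = o$value)
  }
  fit
}

#' Fit one or two Gaussian components to a log10 length histogram
#'
#' Lengths are log10-transformed and binned at `bin_width_log10`; a sum of
#' `k` scaled Gaussian curves is fitted to the bin counts by least
#' squares, with the usual Poisson-noise weights for histogram data
#' (`1 / max(count, 1)`), so residuals are comparable across bins and the
#' nested F-test of [compare_fits()] is calibrated.  For `k = 2` a
#' multi-start strategy is used: component means
#' at the 25%/75% sample quantiles plus four seeded random perturbations
#' over the observed range; the fit with the smallest residual sum of
#' squares wins.  Components are reported in order of increasing mean.
#'
#' @param lengths Positive lengths (bp), `n >= 50`.
#' @param k Number of components, 1 or 2.
#' @param bin_width_log10 Histogram bin width on the log10 scale
#'   (default 0.1).
#' @param seed Seed for the random restarts (`k = 2`).
#' @param n_starts Number of starts for `k = 2` (>= 5 including the
#'   quantile start).
#' @return A `mixture_fit` object: `components` (data frame with `mean`,
#'   `sd`, `amplitude`, `weight` — weights are component areas normalized
#'   to 1), `rss`, `n_params` (`3k`), `bin_width`, `breaks`, `counts`,
#'   `n`.
#' @export
fit_gaussians <- function(lengths, k, bin_width_log10 = 0.1, seed = 1,
                          n_starts = 5) {
  stopifnot(k %in% c(1, 2))
  lengths <- as.numeric(lengths)
  lengths <- lengths[!is.na(lengths) & lengths > 0]
  if (length(lengths) < 50) {
    stop("need at least 50 lengths to fit", call. = FALSE)
  }
  h <- .log10_hist(lengths, bin_width_log10)
  x <- log10(lengths)
  amp0 <- max(h$counts)
  starts <- list()
  if (k == 1) {
    starts[[1]] <- c(amp0, mean(x), max(stats::sd(x), bin_width_log10 / 2))
  } else {
    qs <- stats::quantile(x, c(0.25, 0.75))
    s0 <- max(stats::sd(x) / 2, bin_width_log10 / 2)
    starts[[1]] <- c(amp0 / 2, qs[[1]], s0, amp0 / 2, qs[[2]], s0)
    extra <- with_seed(seed, {
      lapply(seq_len(max(n_starts - 1, 4)), function(i) {
        mus <- sort(stats::runif(2, min(x), max(x)))
        c(amp0 / 2, mus[1], s0, amp0 / 2, mus[2], s0)
      })
    })
    starts <- c(starts, extra)
  }
  fits <- lapply(starts, function(s) .fit_ls(h$mids, h$counts, s, bin_width_log10))
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok)) {
    stop(paste0("no start converged; starts tried:\n",
                paste(vapply(starts, function(s) paste(signif(s, 4), collapse = ", "),
                             character(1)), collapse = "\n")), call. = FALSE)
  }
  best <- fits[ok][[which.min(vapply(fits[ok], `[[`, numeric(1), "rss"))]]
  pars <- best$pars
  comp <- data.frame(
    amplitude = pars[seq(1, 3 * k, 3)],
    mean = pars[seq(2, 3 * k, 3)],
    sd = pars[seq(3, 3 * k, 3)]
  )
  comp <- comp[order(comp$mean), , drop = FALSE]
  area <- comp$amplitude * comp$sd
  comp$weight <- if (sum(area) > 0) area / sum(area) else rep(1 / k, k)
  rownames(comp) <- NULL
  structure(list(
    components = comp[, c("mean", "sd", "amplitude", "weight")],
    rss = best$rss, k = k, n_params = 3L * k,
    bin_width = bin_width_log10, breaks = h$breaks, mids = h$mids,
    counts = h$counts, n = length(lengths)
  ), class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("Gaussian fit (k = %d) on %d log10 bins (width %.3g), n = %d\n",
              x$k, length(x$counts), x$bin_width, x$n))
  print(round(x$components, 4))
  cat(sprintf("RSS = %.4g\n", x$rss))
  invisible(x)
}

#' Nested F-test comparing one- and two-component Gaussian fits
#'
#' Compares the residual sums of squares of two fits over identical bins:
#' `F = ((RSS1 - RSS2) / dp) / (RSS2 / (nbins - p2))`, with the p-value
#' from the upper tail of the F distribution.  The one-component model is
#' nested in the two-component model, so `RSS2 <= RSS1` must hold; a
#' violation indicates optimizer failure and is an error asking for a
#' refit.
#'
#' @param fit1 `mixture_fit` with `k = 1`.
#' @param fit2 `mixture_fit` with `k = 2` on the same bins.
#' @return List with `statistic` (F), `p_value`, `df1`, `df2`.
#' @export
compare_fits <- function(fit1, fit2) {
  stopifnot(inherits(fit1, "mixture_fit"), inherits(fit2, "mixture_fit"))
  if (fit1$k != 1 || fit2$k != 2) {
    stop("compare_fits expects fit1 with k = 1 and fit2 with k = 2",
         call. = FALSE)
  }
  if (!isTRUE(all.equal(fit1$breaks, fit2$breaks))) {
    stop("fits must be computed on identical bins", call. = FALSE)
  }
  tol <- 1e-8 * (1 + fit1$rss)
  if (fit2$rss > fit1$rss + tol) {
    stop("RSS(k = 2) exceeds RSS(k = 1); the two-component optimization failed, refit with more starts",
         call. = FALSE)
  }
  nbins <- length(fit1$counts)
  dp <- fit2$n_params - fit1$n_params
  df2 <- nbins - fit2$n_params
  if (df2 <= 0) stop("too few bins for the F-test", call. = FALSE)
  rss1 <- fit1$rss; rss2 <- min(fit2$rss, fit1$rss)
  if (rss2 <= 0) {
    f <- if (rss1 <= 0) 0 else Inf
  } else {
    f <- ((rss1 - rss2) / dp) / (rss2 / df2)
  }
  f <- max(f, 0)
  p <- stats::pf(f, dp, df2, lower.tail = FALSE)
  list(statistic = f, p_value = p, df1 = dp, df2 = df2)
}

#' Stratified summary of inter-CDS lengths
#'
#' For every `(species, age, orientation)` stratum of the retained regions
#' (tandem- and repeat-flagged regions excluded), reports the region
#' count, the arithmetic mean length in bp (rounded to integer) and the
#' [estimate_lower_limit()] value.  Strata with no regions are emitted
#' with `NA` markers so the table always covers species x {old, young} x
#' the three orientations.
#'
#' @param regions Region table with `age_label` assigned.
#' @param method,q Passed to [estimate_lower_limit()].
#' @return Data frame with columns `species`, `age`, `orientation`, `n`,
#'   `mean_bp`, `lower_limit`.
#' @export
summarize_lengths <- function(regions, method = "quantile", q = 0.01) {
  if (nrow(regions) && all(regions$age_label == "unassigned")) {
    stop("regions have no age labels; run conservation_profile first",
         call. = FALSE)
  }
  kept <- regions[!regions$tandem_flag & !regions$repeat_flag &
                    regions$age_label %in% c("old", "young"), , drop = FALSE]
  species <- sort(unique(regions$species))
  grid <- expand.grid(species = species, age = c("old", "young"),
                      orientation = .ORIENTATIONS,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    len <- kept$length[kept$species == g$species & kept$age_label == g$age &
                         kept$orientation == g$orientation]
    if (length(len) == 0) {
      data.frame(g, n = 0L, mean_bp = NA_integer_, lower_limit = NA_integer_)
    } else {
      ll <- suppressWarnings(estimate_lower_limit(len, method = method, q = q))
      data.frame(g, n = length(len), mean_bp = as.integer(round(mean(len))),
                 lower_limit = ll$value)
    }
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$species, out$age, match(out$orientation, .ORIENTATIONS)), ]
  rownames(out) <- NULL
  out
}

#' Coefficient of variation across species
#'
#' Sample standard deviation (n-1 denominator) divided by the arithmetic
#' mean, for one value per species.
#'
#' @param values Numeric vector, length >= 2.
#' @return The CV.
#' @export
cv_across_species <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2) stop("need at least 2 values", call. = FALSE)
  m <- mean(values)
  if (m == 0) stop("mean is zero; CV undefined", call. = FALSE)
  stats::sd(values) / m
}

#' Goodness-of-fit test of orientation composition in a length window
#'
#' Under random, independent gene orientations, 25% of adjacent pairs are
#' divergent, 50% co-oriented (unidirectional) and 25% convergent.  This
#' tests the observed composition of regions whose length falls in
#' `length_window` against those proportions (chi-square, df = 2); a
#' deficit of promoter-containing pairs at short lengths signals the
#' minimal regulatory space.
#'
#' @param regions Region table (flagged regions excluded internally).
#' @param length_window `c(lo, hi)` in bp, inclusive.
#' @return List with `statistic`, `p_value`, `observed` (named counts in
#'   order divergent, unidirectional, convergent), `expected`.
#' @export
orientation_composition_test <- function(regions, length_window) {
  stopifnot(length(length_window) == 2, length_window[1] <= length_window[2])
  kept <- regions[!regions$tandem_flag & !regions$repeat_flag, , drop = FALSE]
  kept <- kept[kept$length >= length_window[1] & kept$length <= length_window[2], ]
  obs <- c(
    divergent = sum(kept$orientation == "divergent"),
    unidirectional = sum(kept$orientation == "unidirectional"),
    convergent = sum(kept$orientation == "convergent")
  )
  if (sum(obs) < 1) stop("no regions in the length window", call. = FALSE)
  probs <- c(0.25, 0.50, 0.25)
  ct <- suppressWarnings(stats::chisq.test(obs, p = probs))
  list(statistic = unname(ct$statistic), p_value = ct$p.value,
       observed = obs, expected = stats::setNames(sum(obs) * probs, names(obs)))
}

#' Pearson correlation of two per-species quantities
#'
#' @param x,y Numeric vectors of equal length >= 3 with nonzero variance.
#' @return List with `r`, `p_value` (two-sided t-test, df = n - 2), `n`.
#' @export
correlate <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("need at least 3 paired values", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("values must be finite", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in x or y", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Optimized regulatory space of a divergent gene pair
#'
#' A canonical promoter plus one median 5'UTR for each of the two
#' divergently transcribed genes: `canonical_promoter_bp +
#' 2 * median_utr5_bp`.
#'
#' @param canonical_promoter_bp Canonical promoter length (bp, >= 0).
#' @param median_utr5_bp Median 5'UTR length (bp, >= 0).
#' @return Integer bp.
#' @examples
#' optimized_space(140, 68)  # 276
#' @export
optimized_space <- function(canonical_promoter_bp, median_utr5_bp) {
  if (canonical_promoter_bp < 0 || median_utr5_bp < 0) {
    stop("inputs must be non-negative", call. = FALSE)
  }
  canonical_promoter_bp + 2 * median_utr5_bp
}
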