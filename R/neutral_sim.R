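## Neutral distance-dependent rearrangement simulator.  The observed total
## (old + young) length distribution stands for the ancestor; N_young
## regions are removed with probability proportional to their (effective)
## length, and the survivors are compared with the observed old regions.

#' Simulator configuration
#'
#' Model A weights removal by the full region length; Model B assumes
#' rearrangements inside the promoter are strongly deleterious and weights
#' by the length minus a minimal promoter offset, clamped at zero (regions
#' at or below the offset can never be broken).
#'
#' @param model `"A"` or `"B"`.
#' @param n_young Number of regions removed per replicate.
#' @param promoter_offset Minimal promoter length subtracted once per
#'   region under Model B (bp, >= 0).
#' @param replicates Number of replicates (default 10); reported
#'   histograms are averaged over replicates.
#' @param seed Master seed; each replicate runs on an independently
#'   derived sub-seed.
#' @param removal_mode `"sequential"` (default): `n_young` rounds of
#'   weighted sampling without replacement.  `"bernoulli_sweep"`: repeated
#'   sweeps removing each region independently with probability
#'   `P = p x effective length` until exactly `n_old` survive, the last
#'   sweep truncated by weighted choice if it overshoots.
#' @param bin_width_log10 Bin width of the averaged survivor histogram.
#' @return A `sim_config` object.
#' @export
sim_config <- function(model = c("A", "B"), n_young, promoter_offset = 0,
                       replicates = 10, seed = 1,
                       removal_mode = c("sequential", "bernoulli_sweep"),
                       bin_width_log10 = 0.1) {
  model <- match.arg(model)
  removal_mode <- match.arg(removal_mode)
  stopifnot(n_young >= 0, promoter_offset >= 0, replicates >= 1)
  structure(list(model = model, n_young = as.integer(n_young),
                 promoter_offset = promoter_offset,
                 replicates = as.integer(replicates), seed = as.integer(seed),
                 removal_mode = removal_mode,
                 bin_width_log10 = bin_width_log10),
            class = "sim_config")
}

#' Effective length of a region under a rearrangement model
#'
#' @param length Region length(s), bp >= 1.
#' @param model `"A"` (full length) or `"B"` (length minus
#'   `promoter_offset`, clamped at 0).
#' @param promoter_offset Minimal promoter length (bp), Model B only.
#' @return Non-negative numeric vector.
#' @export
effective_length <- function(length, model = c("A", "B"), promoter_offset = 0) {
  model <- match.arg(model)
  stopifnot(all(length >= 1), promoter_offset >= 0)
  if (model == "A") as.numeric(length) else pmax(length - promoter_offset, 0)
}

#' Per-region break probability in one time step
#'
#' `P = p x effective_length`, where `p` is the per-nucleotide
#' rearrangement rate, canonically `N_young / sum(effective lengths)`.
#'
#' @param length Region length(s), bp.
#' @param p Per-nucleotide rate (>= 0).
#' @param model,promoter_offset See [effective_length()].
#' @return Probabilities in `[0, 1]`; an error if any product exceeds 1
#'   (choose a smaller time step).
#' @export
per_region_break_probability <- function(length, p, model = c("A", "B"),
                                         promoter_offset = 0) {
  stopifnot(p >= 0)
  pr <- p * effective_length(length, model, promoter_offset)
  if (any(pr > 1)) {
    stop("p x effective length exceeds 1 for some region; use a smaller time step (smaller p)",
         call. = FALSE)
  }
  pr
}

.one_replicate <- function(lengths, eff, config) {
  n_total <- length(lengths)
  n_young <- config$n_young
  if (n_young == 0) return(seq_len(n_total))
  if (config$removal_mode == "sequential") {
    removed <- sample.int(n_total, n_young, replace = FALSE, prob = eff)
    return(setdiff(seq_len(n_total), removed))
  }
  ## bernoulli_sweep: repeated sweeps at rate p until n_old survive
  p <- n_young / sum(eff)
  p <- min(p, 1 / max(eff))         # keep every P = p * eff below 1
  alive <- seq_len(n_total)
  removed_n <- 0L
  repeat {
    pr <- p * eff[alive]
    hit <- alive[stats::runif(length(alive)) < pr]   # break if r < P
    if (removed_n + length(hit) >= n_young) {
      need <- n_young - removed_n
      if (need < length(hit)) {
        hit <- if (need == 0) integer(0) else {
          hit[sample.int(length(hit), need, prob = eff[hit])]
        }
      }
      alive <- setdiff(alive, hit)
      break
    }
    alive <- setdiff(alive, hit)
    removed_n <- removed_n + length(hit)
  }
  alive
}

#' Simulate neutral removal of regions from the total distribution
#'
#' Starting from the total observed length distribution (standing in for
#' the ancestral one), removes `n_young` regions per replicate with
#' probability proportional to effective length, leaving exactly
#' `n_total - n_young` survivors.  Replicates differ only by their derived
#' sub-seed; the survivor histogram (log10 bins) is averaged over
#' replicates.
#'
#' @param lengths Total (old + young) region lengths, bp.
#' @param config A [sim_config()].
#' @return A `sim_result`: `survivors` (lengths per replicate),
#'   `survivor_idx` (indices into `lengths` per replicate), `histogram`
#'   (data frame `bin_left_log10`, `mean_count`), `config`.
#' @export
simulate_survivors <- function(lengths, config) {
  stopifnot(inherits(config, "sim_config"))
  lengths <- as.numeric(lengths)
  n_total <- length(lengths)
  if (config$n_young >= n_total) {
    stop("n_young must be smaller than the number of regions", call. = FALSE)
  }
  eff <- effective_length(lengths, config$model, config$promoter_offset)
  if (sum(eff > 0) < config$n_young) {
    stop("fewer removable regions (effective length > 0) than n_young",
         call. = FALSE)
  }
  seeds <- derive_seeds(config$seed, config$replicates)
  survivor_idx <- lapply(seq_len(config$replicates), function(r) {
    with_seed(seeds[r], .one_replicate(lengths, eff, config))
  })
  survivors <- lapply(survivor_idx, function(i) lengths[i])
  bw <- config$bin_width_log10
  h_all <- .log10_hist(lengths, bw)
  counts <- vapply(survivors, function(s) {
    graphics::hist(log10(s), breaks = h_all$breaks, plot = FALSE,
                   right = FALSE)$counts
  }, numeric(length(h_all$counts)))
  histogram <- data.frame(
    bin_left_log10 = h_all$breaks[-length(h_all$breaks)],
    mean_count = rowMeans(as.matrix(counts))
  )
  structure(list(survivors = survivors, survivor_idx = survivor_idx,
                 histogram = histogram, breaks = h_all$breaks,
                 config = config),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("neutral rearrangement simulation: model %s, %d replicates, %d survivors each\n",
              x$config$model, x$config$replicates, length(x$survivors[[1]])))
  invisible(x)
}

#' Compare simulated survivors with the observed old length distribution
#'
#' Pools the survivors of all replicates and computes the two-sample
#' Kolmogorov-Smirnov statistic against the observed old lengths, plus a
#' per-bin table of observed minus mean simulated counts — positive
#' right-tail entries expose an excess of long regions that the neutral
#' model does not capture.
#'
#' @param sim A `sim_result`.
#' @param observed_old_lengths Observed old region lengths, bp.
#' @return List with `ks_stat`, `bins` (data frame `bin_left_log10`,
#'   `observed`, `simulated_mean`, `excess`).
#' @export
compare_distributions <- function(sim, observed_old_lengths) {
  stopifnot(inherits(sim, "sim_result"), length(observed_old_lengths) > 0)
  pooled <- unlist(sim$survivors)
  ks <- suppressWarnings(stats::ks.test(pooled, observed_old_lengths))
  bw <- sim$config$bin_width_log10
  xs <- log10(observed_old_lengths)
  lo <- min(sim$breaks[1], floor(min(xs) / bw) * bw)
  hi <- max(sim$breaks[length(sim$breaks)], ceiling(max(xs) / bw) * bw)
  breaks <- seq(lo, hi + bw / 2, by = bw)
  obs_counts <- graphics::hist(xs, breaks = breaks, plot = FALSE,
                               right = FALSE)$counts
  sim_counts <- rowMeans(vapply(sim$survivors, function(s) {
    graphics::hist(log10(s), breaks = breaks, plot = FALSE, right = FALSE)$counts
  }, numeric(length(breaks) - 1)))
  list(
    ks_stat = unname(ks$statistic),
    bins = data.frame(bin_left_log10 = breaks[-length(breaks)],
                      observed = obs_counts, simulated_mean = sim_counts,
                      excess = obs_counts - sim_counts)
  )
}

#' Null distribution of the KS statistic under the neutral model
#'
#' Generates independent single-replicate survivor sets from the same
#' configuration and computes each one's KS statistic against the pooled
#' survivors of `sim`.  Under model correctness the observed old lengths
#' behave like one more realization, so the returned quantile calibrates
#' [compare_distributions()]'s `ks_stat`.
#'
#' @param lengths Total lengths the simulation ran on.
#' @param sim The `sim_result` being calibrated.
#' @param n_null Number of null realizations (default 40).
#' @param level Quantile level (default 0.95).
#' @return List with `quantile` and the vector of null `ks` values.
#' @export
simulate_ks_null <- function(lengths, sim, n_null = 40, level = 0.95) {
  stopifnot(inherits(sim, "sim_result"))
  pooled <- unlist(sim$survivors)
  cfg <- sim$config
  eff <- effective_length(lengths, cfg$model, cfg$promoter_offset)
  seeds <- derive_seeds(cfg$seed + 7919L, n_null)
  ks <- vapply(seq_len(n_null), function(i) {
    surv <- with_seed(seeds[i], lengths[.one_replicate(lengths, eff, cfg)])
    unname(suppressWarnings(stats::ks.test(surv, pooled))$statistic)
  }, numeric(1))
  list(quantile = unname(stats::quantile(ks, level)), ks = ks)
}
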