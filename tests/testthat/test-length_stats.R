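test_that("lower-limit estimation handles degenerate and small samples", {
  expect_equal(estimate_lower_limit(rep(100, 30))$value, 100L)
  expect_equal(estimate_lower_limit(rep(100, 30), method = "min")$value, 100L)

  expect_warning(small <- estimate_lower_limit(c(120, 150, 200, 90, 300)),
                 "fewer than 20")
  expect_equal(small$value, 90L)
  expect_equal(small$method, "min")

  expect_error(estimate_lower_limit(numeric(0)), "empty sample")
})

test_that("the quantile estimator recovers a planted truncation point", {
  # draws from a left-truncated log-normal; the generator truncation is
  # the oracle, the band allows for the 1%-quantile bias
  spec <- stratum_spec("unidirectional", 2.6, 0.2, 150)
  lens <- sample_lengths(spec, 5000, seed = 1)
  est <- estimate_lower_limit(lens)
  expect_gte(est$value, 150)
  expect_lte(est$value, 165)

  # monotone in q, and never above the median for q <= 0.05
  vals <- vapply(c(0, 0.01, 0.03, 0.05), function(q) {
    estimate_lower_limit(lens, q = q)$value
  }, integer(1))
  expect_true(all(diff(vals) >= 0))
  expect_lte(max(vals), stats::median(lens))
})

test_that("one-component fits recover generator parameters", {
  lens <- with(list(), {
    set.seed(7)
    round(10^stats::rnorm(2000, 2.5, 0.15))
  })
  fit <- fit_gaussians(lens, 1, seed = 1)
  expect_equal(fit$components$mean, 2.5, tolerance = 0.02)
  expect_equal(fit$components$sd, 0.15, tolerance = 0.02)
  expect_equal(fit$n_params, 3L)
  expect_error(fit_gaussians(lens[1:20], 1), "at least 50")
})

test_that("two-component fits separate well-separated masses and nest properly", {
  pm <- c(rep(round(10^2.2), 800), rep(round(10^2.8), 1200))
  f1 <- fit_gaussians(pm, 1, seed = 1)
  f2 <- fit_gaussians(pm, 2, seed = 1)
  expect_lt(f2$rss, f1$rss)
  # spike positions are only identifiable to about a bin width
  expect_equal(f2$components$mean[1], 2.2, tolerance = 0.2)
  expect_equal(f2$components$mean[2], 2.8, tolerance = 0.2)
  expect_equal(sum(f2$components$weight), 1)

  # nesting holds on generic unimodal samples too
  for (s in 1:5) {
    lens <- sample_lengths(stratum_spec("convergent", 2.4, 0.25), 800, seed = s)
    k1 <- fit_gaussians(lens, 1, seed = s)
    k2 <- fit_gaussians(lens, 2, seed = s)
    expect_lte(k2$rss, k1$rss * (1 + 1e-8))
    cmp <- compare_fits(k1, k2)
    expect_gte(cmp$statistic, 0)
  }
})

test_that("the nested F-test is exact at the boundaries and powerful on mixtures", {
  # equal RSS on identical bins: F = 0, p = 1
  base <- fit_gaussians(sample_lengths(stratum_spec("convergent", 2.4, 0.2),
                                       500, seed = 2), 1, seed = 2)
  fake2 <- base
  fake2$k <- 2L
  fake2$n_params <- 6L
  cmp <- compare_fits(base, fake2)
  expect_equal(cmp$statistic, 0)
  expect_equal(cmp$p_value, 1)

  # an inflated k=2 RSS is an optimizer failure, not a result
  worse <- fake2
  worse$rss <- base$rss * 2 + 1
  expect_error(compare_fits(base, worse), "refit")

  # strong bimodality is detected decisively
  lens <- with(list(), {
    set.seed(5)
    u <- stats::runif(2000) < 0.5
    round(10^ifelse(u, stats::rnorm(2000, 2.2, 0.12), stats::rnorm(2000, 2.8, 0.12)))
  })
  f1 <- fit_gaussians(lens, 1, seed = 1)
  f2 <- fit_gaussians(lens, 2, seed = 1)
  expect_lt(compare_fits(f1, f2)$p_value, 1e-6)
})

test_that("stratified summaries cover all strata and count every region", {
  regions <- data.frame(
    species = "spA", chromosome = "chr1",
    left_gene = paste0("l", 1:6), right_gene = paste0("r", 1:6),
    left_strand = "+", right_strand = "-",
    orientation = rep(c("convergent", "divergent"), each = 3),
    start = 1, end = 1, length = c(100L, 200L, 300L, 400L, 500L, 600L),
    tandem_flag = FALSE, repeat_flag = FALSE,
    age_label = c("old", "old", "old", "old", "young", "young"),
    age_class = NA_character_, conserved_in = "",
    stringsAsFactors = FALSE
  )
  tab <- suppressWarnings(summarize_lengths(regions))
  expect_equal(nrow(tab), 6)  # 1 species x 2 ages x 3 orientations
  expect_equal(tab$mean_bp[tab$age == "old" & tab$orientation == "convergent"],
               200L)
  expect_equal(sum(tab$n), nrow(regions))
  # empty stratum emitted with missing markers
  expect_true(is.na(tab$mean_bp[tab$age == "young" &
                                  tab$orientation == "convergent"]))
  expect_error(summarize_lengths(transform(regions, age_label = "unassigned")),
               "no age labels")
})

test_that("cross-species CV matches hand arithmetic and published summaries", {
  ref <- table1_reference()
  conv_means <- ref$mean_bp[ref$age == "old" & ref$orientation == "convergent"]
  expect_equal(length(conv_means), 11)
  expect_equal(round(cv_across_species(conv_means), 2), 0.35)

  expect_equal(cv_across_species(c(5, 5, 5)), 0)
  expect_equal(cv_across_species(c(1, 3)), sqrt(2) / 2, tolerance = 1e-12)
  expect_error(cv_across_species(7), "at least 2")
  expect_error(cv_across_species(c(-1, 1)), "mean is zero")
})

test_that("orientation composition test against the 25/50/25 null", {
  fake_regions <- function(div, uni, con) {
    n <- div + uni + con
    data.frame(orientation = rep(c("divergent", "unidirectional", "convergent"),
                                 c(div, uni, con)),
               length = 50L, tandem_flag = FALSE, repeat_flag = FALSE,
               stringsAsFactors = FALSE)
  }
  perfect <- orientation_composition_test(fake_regions(25, 50, 25), c(1, 100))
  expect_equal(perfect$statistic, 0)
  expect_equal(perfect$p_value, 1)

  skewed <- orientation_composition_test(fake_regions(0, 50, 50), c(1, 100))
  expect_equal(skewed$statistic, 50)  # 25^2/25 + 0 + 25^2/25

  # null calibration: multinomial draws at the null proportions
  set.seed(21)
  rej <- mean(replicate(1000, {
    counts <- as.vector(stats::rmultinom(1, 200, c(0.25, 0.50, 0.25)))
    orientation_composition_test(
      fake_regions(counts[1], counts[2], counts[3]), c(1, 100)
    )$p_value < 0.05
  }))
  expect_gte(rej, 0.03)
  expect_lte(rej, 0.07)
})

test_that("correlation returns exact R for linear data and is calibrated", {
  x <- c(1, 2, 4, 8, 9, 13)
  out <- correlate(x, 2 * x + 1)
  expect_equal(out$r, 1)

  expect_error(correlate(c(1, 2), c(3, 4)), "at least 3")
  expect_error(correlate(rep(1, 5), 1:5), "zero variance")

  set.seed(8)
  rs <- replicate(500, correlate(stats::rnorm(11), stats::rnorm(11))$r)
  expect_lt(abs(mean(rs)), 0.05)
  expect_lt(mean(abs(rs) > 0.6), 0.05)
})

test_that("optimized regulatory space is promoter plus two UTRs", {
  expect_equal(optimized_space(140, 68), 276)
  expect_equal(optimized_space(140, 0), 140)
  expect_equal(optimized_space(0, 0), 0)
  expect_error(optimized_space(-1, 10), "non-negative")
})
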