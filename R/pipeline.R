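## End-to-end orchestration: extraction -> filters -> conservation/age ->
## statistics -> neutral simulation, with deterministic, seeded outputs.

#' Published per-species summary statistics (reference fixture)
#'
#' The per-species means and lower-limit locations of the inter-CDS length
#' distributions of 11 yeast species (old/young x divergent/unidirectional/
#' convergent), shipped so that cross-species summary operations are
#' testable without the original genome annotations.
#'
#' @return Data frame with columns `species`, `age`, `orientation`,
#'   `mean_bp`, `lower_limit`.
#' @export
table1_reference <- function() {
  path <- system.file("extdata", "table1_reference.tsv", package = "intercds",
                      mustWork = TRUE)
  df <- .read_tsv_dialect(path, c("species", "age", "orientation",
                                  "mean_bp", "lower_limit"))
  df$mean_bp <- as.integer(df$mean_bp)
  df$lower_limit <- as.integer(df$lower_limit)
  attr(df, "line_numbers") <- NULL
  df
}

.load_input <- function(x, reader, ...) {
  if (is.character(x)) reader(x, ...) else x
}

.check_path <- function(x, what) {
  if (is.character(x) && !file.exists(x)) {
    stop(sprintf("%s file '%s' does not exist", what, x), call. = FALSE)
  }
  invisible(x)
}

#' Validate a pipeline run configuration
#'
#' @param genes Named list (by species) of gene-table paths or data
#'   frames.
#' @param orthologs Named list (`"a|b"`) of ortholog tables (paths or data
#'   frames), or one combined data frame.
#' @param tree Newick path or `phylo` (optional; needed for age classes).
#' @param homology Homology table path or data frame (optional).
#' @param repeats Named list (by species) of BED paths or repeat data
#'   frames (optional).
#' @param focal_species Species to profile (default: all).
#' @param n_age_classes,scheme_breaks Passed to [scheme_from_tree()] when
#'   a tree is given; `NULL` skips age classes.
#' @param lower_limit_method,q Passed to [summarize_lengths()].
#' @param bin_width_log10 Histogram bin width for fits and simulation.
#' @param sim_model,sim_replicates,removal_mode Simulator settings; under
#'   model B the per-stratum promoter offset is the stratum's estimated
#'   lower limit.
#' @param composition_window Length window (bp) for the orientation
#'   composition test.
#' @param min_fit_n Minimum stratum size for Gaussian fits (default 50).
#' @param seed Master seed (required: no silent nondeterminism).
#' @param out_dir Output directory.
#' @return A validated `run_config` object.
#' @export
run_config <- function(genes, orthologs = NULL, tree = NULL, homology = NULL,
                       repeats = NULL, focal_species = NULL,
                       n_age_classes = NULL, scheme_breaks = NULL,
                       lower_limit_method = "quantile", q = 0.01,
                       bin_width_log10 = 0.1, sim_model = "A",
                       sim_replicates = 10, removal_mode = "sequential",
                       composition_window = c(1, 120), min_fit_n = 50,
                       seed, out_dir) {
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  if (is.null(names(genes)) || any(!nzchar(names(genes)))) {
    stop("'genes' must be a named list (names = species codes)", call. = FALSE)
  }
  for (sp in names(genes)) .check_path(genes[[sp]], sprintf("gene table (%s)", sp))
  if (!is.null(orthologs) && is.list(orthologs) && !is.data.frame(orthologs)) {
    for (key in names(orthologs)) {
      .check_path(orthologs[[key]], sprintf("ortholog table (%s)", key))
    }
  }
  .check_path(tree, "tree")
  .check_path(homology, "homology")
  if (!is.null(repeats)) {
    for (sp in names(repeats)) .check_path(repeats[[sp]], sprintf("repeat BED (%s)", sp))
  }
  if (is.null(focal_species)) focal_species <- names(genes)
  structure(list(
    genes = genes, orthologs = orthologs, tree = tree, homology = homology,
    repeats = repeats, focal_species = focal_species,
    n_age_classes = n_age_classes, scheme_breaks = scheme_breaks,
    lower_limit_method = lower_limit_method, q = q,
    bin_width_log10 = bin_width_log10, sim_model = sim_model,
    sim_replicates = sim_replicates, removal_mode = removal_mode,
    composition_window = composition_window, min_fit_n = min_fit_n,
    seed = as.integer(seed), out_dir = out_dir
  ), class = "run_config")
}

.combined_orthologs <- function(orthologs) {
  if (is.null(orthologs)) return(NULL)
  if (is.data.frame(orthologs)) return(orthologs)
  tabs <- lapply(names(orthologs), function(key) {
    tab <- .load_input(orthologs[[key]], read_ortholog_table)
    tab[, c("species_a", "gene_a", "species_b", "gene_b", "confidence")]
  })
  do.call(rbind, tabs)
}

#' Run the full analysis pipeline
#'
#' Stages, in order: annotation reading, adjacent-pair extraction, tandem
#' and repeat filters, neighbourhood conservation and age labels for each
#' focal species, the stratified length summary, per-stratum Gaussian
#' fits with the nested F-test, the orientation composition test, and the
#' neutral rearrangement simulation of each stratum's old distribution.
#' All outputs are written to `config$out_dir` and are identical for
#' identical `(inputs, config, seed)`.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `regions` (per species), `replica`,
#'   `fits`, `composition`, `sim`, `correlations` and the output paths.
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  genes <- lapply(config$genes, .load_input, reader = read_annotation,
                  format = "tabular")
  tree <- if (!is.null(config$tree)) .load_input(config$tree, read_tree)
  homology <- if (!is.null(config$homology)) {
    .load_input(config$homology, read_homology_table)
  }
  ortho <- .combined_orthologs(config$orthologs)

  regions <- lapply(genes, build_neighbor_pairs)
  if (!is.null(homology)) {
    regions <- lapply(regions, filter_tandem, hits = homology)
  }
  if (!is.null(config$repeats)) {
    for (sp in names(config$repeats)) {
      reps <- .load_input(config$repeats[[sp]], read_repeat_bed, species = sp)
      regions[[sp]] <- filter_repeats(regions[[sp]], reps)
    }
  }

  for (sp in config$focal_species) {
    regions[[sp]] <- conservation_profile(regions[[sp]], regions, ortho, sp)
    if (!is.null(tree) && (!is.null(config$n_age_classes) ||
                           !is.null(config$scheme_breaks))) {
      scheme <- scheme_from_tree(tree, sp, n_classes = config$n_age_classes,
                                 breaks = config$scheme_breaks)
      cls <- assign_age_class(regions[[sp]]$conserved_in, scheme)
      regions[[sp]]$age_class <- ifelse(regions[[sp]]$age_label == "old",
                                        cls, "young")
    }
  }

  focal_regions <- do.call(rbind, regions[config$focal_species])
  replica <- summarize_lengths(focal_regions,
                               method = config$lower_limit_method, q = config$q)
  .write_tsv(replica, file.path(config$out_dir, "table1_replica.tsv"))

  ## per-stratum Gaussian fits on old lengths
  fit_seeds <- derive_seeds(config$seed, length(config$focal_species) * 3 + 3)
  fits <- list()
  i <- 0
  for (sp in config$focal_species) {
    for (ori in .ORIENTATIONS) {
      i <- i + 1
      lens <- focal_regions$length[
        focal_regions$species == sp & focal_regions$orientation == ori &
          focal_regions$age_label == "old" & !focal_regions$tandem_flag &
          !focal_regions$repeat_flag
      ]
      if (length(lens) < config$min_fit_n) next
      f1 <- fit_gaussians(lens, 1, config$bin_width_log10, seed = fit_seeds[i])
      f2 <- fit_gaussians(lens, 2, config$bin_width_log10, seed = fit_seeds[i])
      cmp <- compare_fits(f1, f2)
      fits[[paste(sp, ori, sep = ".")]] <- list(
        species = sp, orientation = ori, n = f1$n,
        k1 = list(components = f1$components, rss = f1$rss),
        k2 = list(components = f2$components, rss = f2$rss),
        f_statistic = cmp$statistic, p_value = cmp$p_value
      )
    }
  }
  jsonlite::write_json(fits, file.path(config$out_dir, "fits.json"),
                       auto_unbox = TRUE, digits = NA)

  composition <- do.call(rbind, lapply(config$focal_species, function(sp) {
    ct <- tryCatch(
      orientation_composition_test(regions[[sp]], config$composition_window),
      error = function(e) NULL
    )
    if (is.null(ct)) return(NULL)
    data.frame(species = sp, window_lo = config$composition_window[1],
               window_hi = config$composition_window[2],
               divergent = ct$observed[["divergent"]],
               unidirectional = ct$observed[["unidirectional"]],
               convergent = ct$observed[["convergent"]],
               chi_square = ct$statistic, p_value = ct$p_value,
               stringsAsFactors = FALSE)
  }))
  if (is.null(composition)) {
    composition <- data.frame(species = character(0), window_lo = integer(0),
                              window_hi = integer(0), divergent = integer(0),
                              unidirectional = integer(0), convergent = integer(0),
                              chi_square = numeric(0), p_value = numeric(0))
  }
  .write_tsv(composition, file.path(config$out_dir, "composition_test.tsv"))

  ## neutral simulation per focal species x orientation
  sim_seeds <- derive_seeds(config$seed + 1L, length(config$focal_species) * 3 + 3)
  sim_bins <- list(); sim_summary <- list()
  i <- 0
  for (sp in config$focal_species) {
    for (ori in .ORIENTATIONS) {
      i <- i + 1
      kept <- focal_regions[
        focal_regions$species == sp & focal_regions$orientation == ori &
          !focal_regions$tandem_flag & !focal_regions$repeat_flag &
          focal_regions$age_label %in% c("old", "young"), , drop = FALSE
      ]
      n_young <- sum(kept$age_label == "young")
      n_old <- sum(kept$age_label == "old")
      if (n_young < 1 || n_old < 5) next
      offset <- 0
      if (config$sim_model == "B") {
        row <- replica[replica$species == sp & replica$age == "old" &
                         replica$orientation == ori, ]
        if (nrow(row) == 1 && !is.na(row$lower_limit)) offset <- row$lower_limit
      }
      cfg <- sim_config(model = config$sim_model, n_young = n_young,
                        promoter_offset = offset,
                        replicates = config$sim_replicates,
                        seed = sim_seeds[i], removal_mode = config$removal_mode,
                        bin_width_log10 = config$bin_width_log10)
      sim <- simulate_survivors(kept$length, cfg)
      cmpd <- compare_distributions(sim, kept$length[kept$age_label == "old"])
      sim_bins[[paste(sp, ori)]] <- cbind(
        data.frame(species = sp, orientation = ori), cmpd$bins
      )
      sim_summary[[paste(sp, ori)]] <- data.frame(
        species = sp, orientation = ori, model = config$sim_model,
        n_total = nrow(kept), n_young = n_young, promoter_offset = offset,
        ks_stat = cmpd$ks_stat, stringsAsFactors = FALSE
      )
    }
  }
  sim_tab <- if (length(sim_bins)) do.call(rbind, sim_bins) else {
    data.frame(species = character(0), orientation = character(0),
               bin_left_log10 = numeric(0), observed = numeric(0),
               simulated_mean = numeric(0), excess = numeric(0))
  }
  rownames(sim_tab) <- NULL
  .write_tsv(sim_tab, file.path(config$out_dir, "sim_vs_observed.tsv"))
  sim_sum <- if (length(sim_summary)) do.call(rbind, sim_summary) else {
    data.frame(species = character(0), orientation = character(0),
               model = character(0), n_total = integer(0), n_young = integer(0),
               promoter_offset = numeric(0), ks_stat = numeric(0))
  }
  rownames(sim_sum) <- NULL
  .write_tsv(sim_sum, file.path(config$out_dir, "sim_summary.tsv"))

  ## cross-species correlation: total retained inter-CDS space vs the
  ## old-divergent lower limit (minimal promoter proxy)
  correlations <- data.frame(x = character(0), y = character(0), n = integer(0),
                             r = numeric(0), p_value = numeric(0))
  if (length(config$focal_species) >= 3) {
    sp_set <- config$focal_species
    space <- vapply(sp_set, function(sp) {
      r <- regions[[sp]]
      sum(r$length[!r$tandem_flag & !r$repeat_flag])
    }, numeric(1))
    lim <- vapply(sp_set, function(sp) {
      row <- replica[replica$species == sp & replica$age == "old" &
                       replica$orientation == "divergent", ]
      if (nrow(row) == 1) as.numeric(row$lower_limit) else NA_real_
    }, numeric(1))
    ok <- is.finite(space) & is.finite(lim)
    if (sum(ok) >= 3 && stats::sd(space[ok]) > 0 && stats::sd(lim[ok]) > 0) {
      ct <- correlate(space[ok], lim[ok])
      correlations <- data.frame(x = "total_intergenic_space",
                                 y = "old_divergent_lower_limit",
                                 n = ct$n, r = ct$r, p_value = ct$p_value,
                                 stringsAsFactors = FALSE)
    }
  }
  .write_tsv(correlations, file.path(config$out_dir, "correlations.tsv"))

  log_lines <- c(
    sprintf("intercds %s", as.character(utils::packageVersion("intercds"))),
    sprintf("seed: %d", config$seed),
    sprintf("species: %s", paste(names(config$genes), collapse = ", ")),
    sprintf("focal: %s", paste(config$focal_species, collapse = ", ")),
    sprintf("lower limit: %s (q = %g)", config$lower_limit_method, config$q),
    sprintf("fit bin width (log10): %g", config$bin_width_log10),
    sprintf("simulator: model %s, %d replicates, %s removal",
            config$sim_model, config$sim_replicates, config$removal_mode),
    sprintf("composition window: [%d, %d] bp", config$composition_window[1],
            config$composition_window[2])
  )
  writeLines(log_lines, file.path(config$out_dir, "run_log.txt"))

  invisible(list(regions = regions, replica = replica, fits = fits,
                 composition = composition, sim_bins = sim_tab,
                 sim_summary = sim_sum, correlations = correlations,
                 out_dir = config$out_dir))
}

#' Summarize minimal regulatory space from a stratified length table
#'
#' From a table in the layout of [summarize_lengths()] (or
#' [table1_reference()]), reports per promoter-containing orientation the
#' min and max of the old-region lower limits across species, and a
#' per-species minimal promoter-length estimate: the promoter-containing
#' class's lower limit minus the convergent (promoter-less) class's lower
#' limit.  Subtracting the convergent lower limit — rather than the
#' convergent mean — keeps the estimate a difference of like quantities
#' (two left edges); the function notes this convention when run.
#'
#' @param replica Data frame with columns `species`, `age`, `orientation`,
#'   `lower_limit` (old-age rows for at least one species).
#' @return List with `lower_limits` (per-orientation min/max across
#'   species), `promoter_estimates` (per species x promoter orientation),
#'   and `promoter_range` (`c(min, max)` over all estimates).
#' @export
report_minimal_space <- function(replica) {
  old <- replica[replica$age == "old" & !is.na(replica$lower_limit), ]
  if (nrow(old) == 0) stop("no old-age rows with lower limits", call. = FALSE)
  message("promoter-length estimates subtract the convergent lower limit (not the convergent mean)")
  promoter_cls <- c("divergent", "unidirectional")
  lower_limits <- do.call(rbind, lapply(promoter_cls, function(ori) {
    v <- old$lower_limit[old$orientation == ori]
    data.frame(orientation = ori, min = min(v), max = max(v),
               stringsAsFactors = FALSE)
  }))
  conv <- stats::setNames(old$lower_limit[old$orientation == "convergent"],
                          old$species[old$orientation == "convergent"])
  est <- old[old$orientation %in% promoter_cls, c("species", "orientation",
                                                  "lower_limit")]
  est <- est[est$species %in% names(conv), ]
  est$estimate <- est$lower_limit - conv[est$species]
  rownames(est) <- NULL
  list(
    lower_limits = lower_limits,
    promoter_estimates = est[, c("species", "orientation", "estimate")],
    promoter_range = c(min(est$estimate), max(est$estimate))
  )
}
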