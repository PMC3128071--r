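## Synthetic multi-species clade generator.  Emulates the statistical
## structure the analysis assumes: per-orientation inter-CDS length
## distributions (log-normal convergent; left-truncated log-normal
## unidirectional with an elevated right tail; left-truncated two-component
## mixture divergent), young regions created by rearrangements on tree
## branches (longer and more variable than old ones), and ortholog tables
## that follow identity by descent.

#' Specify the length distribution of one orientation stratum
#'
#' Lengths are drawn on the log10 scale from one or two Gaussian
#' components, rejection-sampled above a left-truncation point.
#'
#' @param orientation One of `"convergent"`, `"unidirectional"`,
#'   `"divergent"`.
#' @param mean_log10,sd_log10 First (lower) component, log10 bp.
#' @param truncation_bp Left truncation in bp (0 = none).
#' @param mean2,sd2,weight2 Optional second (upper) component and its
#'   mixture weight in (0, 1).
#' @return A `stratum_spec` object.
#' @export
stratum_spec <- function(orientation, mean_log10, sd_log10, truncation_bp = 0,
                         mean2 = NULL, sd2 = NULL, weight2 = NULL) {
  stopifnot(orientation %in% .ORIENTATIONS, sd_log10 > 0, truncation_bp >= 0)
  two <- !is.null(mean2)
  if (two) stopifnot(sd2 > 0, weight2 > 0, weight2 < 1)
  structure(list(
    orientation = orientation,
    means = if (two) c(mean_log10, mean2) else mean_log10,
    sds = if (two) c(sd_log10, sd2) else sd_log10,
    weights = if (two) c(1 - weight2, weight2) else 1,
    truncation_bp = truncation_bp
  ), class = "stratum_spec")
}

#' Default per-orientation strata
#'
#' Magnitudes typical of compact yeast genomes: log10 means around
#' 2.3-2.7, log10 sds 0.15-0.35, left truncation of promoter-containing
#' classes at 130-170 bp; the divergent class is a two-component mixture
#' (bi-directional vs independent promoters) and the unidirectional class
#' carries a 7% long-tail component emulating the elevated right tail of
#' promoter-containing regions.
#'
#' @return Named list of [stratum_spec()]s.
#' @export
default_strata <- function() {
  list(
    convergent = stratum_spec("convergent", 2.30, 0.35, 0),
    unidirectional = stratum_spec("unidirectional", 2.60, 0.30, 130,
                                  mean2 = 3.30, sd2 = 0.20, weight2 = 0.07),
    divergent = stratum_spec("divergent", 2.45, 0.12, 170,
                             mean2 = 2.85, sd2 = 0.12, weight2 = 0.40)
  )
}

## young regions: longer (mean shifted by log10(inflation)) and more
## variable (sd scaled) than the ancestral stratum
.inflate_spec <- function(spec, inflation, sd_factor) {
  spec$means <- spec$means + log10(inflation)
  spec$sds <- spec$sds * sd_factor
  spec
}

#' Draw integer lengths from a stratum specification
#'
#' @param spec A [stratum_spec()].
#' @param n Number of draws (>= 1).
#' @param seed Optional seed; with a seed the draw is a pure function of
#'   `(spec, n, seed)`.
#' @return Integer bp, all `>= max(1, truncation_bp)`.
#' @export
sample_lengths <- function(spec, n, seed = NULL) {
  if (is.null(seed)) {
    .sample_lengths_comp(spec, n)$length
  } else {
    with_seed(seed, .sample_lengths_comp(spec, n)$length)
  }
}

## draws plus the mixture component each draw came from (uses current RNG)
.sample_lengths_comp <- function(spec, n) {
  stopifnot(inherits(spec, "stratum_spec"), n >= 1)
  trunc_bp <- spec$truncation_bp
  accept <- if (trunc_bp <= 1) 1 else {
    sum(spec$weights *
          stats::pnorm(log10(trunc_bp), spec$means, spec$sds, lower.tail = FALSE))
  }
  if (accept < 1e-3) {
    stop(sprintf("truncation at %g bp leaves acceptance %.2g < 1e-3", trunc_bp,
                 accept), call. = FALSE)
  }
  out <- numeric(0)
  comp_out <- integer(0)
  while (length(out) < n) {
    m <- ceiling((n - length(out)) / accept * 1.3) + 10
    comp <- sample.int(length(spec$weights), m, replace = TRUE,
                       prob = spec$weights)
    len <- 10^stats::rnorm(m, spec$means[comp], spec$sds[comp])
    keep <- len >= trunc_bp
    out <- c(out, len[keep])
    comp_out <- c(comp_out, comp[keep])
  }
  list(length = pmax(as.integer(round(out[seq_len(n)])),
                     max(1L, as.integer(trunc_bp))),
       component = comp_out[seq_len(n)])
}

#' Specify a synthetic clade
#'
#' @param tree Newick string or `phylo`; leaf labels are the species.
#' @param genes_per_chromosome,chromosomes Genome layout per species.
#' @param strata Named list of ancestral [stratum_spec()]s (one per
#'   orientation); see [default_strata()].
#' @param rearrangements Named integer vector of rearrangement counts per
#'   branch.  Names are either a leaf label (terminal branch) or the
#'   sorted `+`-joined leaf set of an internal branch's clade (e.g.
#'   `"sba+sce"`).  Unnamed branches get 0.
#' @param inflation Young-region length inflation factor (>= 1): young
#'   junction lengths are drawn from the ancestral stratum with its log10
#'   mean shifted by `log10(inflation)`.
#' @param young_sd_factor Multiplier on the young strata's log10 sds.
#' @param cds_length Fixed CDS length in bp, so inter-CDS lengths equal
#'   the drawn gaps exactly.
#' @param tandem_pairs Number of adjacent pairs per species planted as
#'   tandem duplicates (homology bitscore 60) in the fixture bundle.
#' @param protect_tail Orientations whose upper-component draws are
#'   maintained by stabilising selection: such regions get rearrangement
#'   weight 0, so the extant old distribution keeps a long-region excess
#'   that a purely neutral removal of the total distribution cannot
#'   reproduce.  Default `"unidirectional"` (the elevated right tail of
#'   promoter-containing regions).
#' @param seed Master seed; generation is a pure function of the spec.
#' @return A `clade_spec` object.
#' @export
clade_spec <- function(tree, genes_per_chromosome = 200, chromosomes = 2,
                       strata = default_strata(), rearrangements = c(),
                       inflation = 1.8, young_sd_factor = 1.3,
                       cds_length = 500, tandem_pairs = 0,
                       protect_tail = "unidirectional", seed = 1) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  stopifnot(inherits(tree, "phylo"), inflation >= 1, young_sd_factor > 0,
            genes_per_chromosome >= 2, chromosomes >= 1, cds_length >= 1,
            all(rearrangements >= 0))
  stopifnot(all(.ORIENTATIONS %in% names(strata)))
  stopifnot(all(protect_tail %in% .ORIENTATIONS) || length(protect_tail) == 0)
  structure(list(tree = tree, genes_per_chromosome = genes_per_chromosome,
                 chromosomes = chromosomes, strata = strata,
                 rearrangements = rearrangements, inflation = inflation,
                 young_sd_factor = young_sd_factor, cds_length = cds_length,
                 tandem_pairs = tandem_pairs, protect_tail = protect_tail,
                 seed = as.integer(seed)),
            class = "clade_spec")
}

## ---- internal genome representation ---------------------------------------
## genome: list of chromosomes; each: genes (anc_id, strand, cds_len) and
## gaps (region_id, length, birth), gap i between genes i and i+1.

.counter <- function(prefix, start = 0L) {
  env <- new.env(parent = emptyenv())
  env$i <- start
  function(n) {
    ids <- sprintf("%s%06d", prefix, env$i + seq_len(n))
    env$i <- env$i + n
    ids
  }
}

.draw_gaps <- function(strands, strata, protect_tail) {
  n <- length(strands)
  ori <- classify_orientation(strands[-n], strands[-1])
  out <- integer(n - 1)
  protected <- logical(n - 1)
  for (o in unique(ori)) {
    idx <- which(ori == o)
    draw <- .sample_lengths_comp(strata[[o]], length(idx))
    out[idx] <- draw$length
    ## upper-component draws of protected orientations are maintained by
    ## stabilising selection and never rearranged
    protected[idx] <- (o %in% protect_tail) & draw$component == 2
  }
  data.frame(length = out, protected = protected)
}

.make_ancestor <- function(clade, next_gene, next_region) {
  chroms <- list()
  for (ci in seq_len(clade$chromosomes)) {
    g <- clade$genes_per_chromosome
    strands <- sample(.STRANDS, g, replace = TRUE)
    gaps <- .draw_gaps(strands, clade$strata, clade$protect_tail)
    chroms[[paste0("chr", ci)]] <- list(
      genes = data.frame(anc_id = next_gene(g), strand = strands,
                         cds_len = clade$cds_length, stringsAsFactors = FALSE),
      gaps = data.frame(region_id = next_region(nrow(gaps)),
                        length = gaps$length, birth = "root",
                        protected = gaps$protected,
                        stringsAsFactors = FALSE)
    )
  }
  chroms
}

.gap_index <- function(genome) {
  idx <- do.call(rbind, lapply(names(genome), function(cn) {
    ng <- nrow(genome[[cn]]$gaps)
    if (ng == 0) return(NULL)
    data.frame(chrom = cn, pos = seq_len(ng),
               length = genome[[cn]]$gaps$length,
               protected = genome[[cn]]$gaps$protected,
               stringsAsFactors = FALSE)
  }))
  if (is.null(idx)) data.frame(chrom = character(0), pos = integer(0),
                               length = numeric(0), protected = logical(0))
  else idx
}

## one relocation: cut at a length-weighted gap (selection-protected gaps
## have weight 0), move the tail block into a uniformly chosen other gap,
## drawing the two new junction lengths from the young strata
.one_rearrangement <- function(genome, young_strata, birth, next_region,
                               protect_tail) {
  idx <- .gap_index(genome)
  if (nrow(idx) < 2) {
    stop("rearrangement count exceeds the available regions", call. = FALSE)
  }
  w <- ifelse(idx$protected, 0, idx$length)
  if (sum(w) <= 0) {
    stop("no rearrangeable (unprotected) regions left", call. = FALSE)
  }
  pick <- idx[sample.int(nrow(idx), 1, prob = w), ]
  c1 <- pick$chrom; i <- pick$pos
  src <- genome[[c1]]
  block_genes <- src$genes[(i + 1):nrow(src$genes), , drop = FALSE]
  block_gaps <- if (i + 1 <= nrow(src$gaps)) {
    src$gaps[(i + 1):nrow(src$gaps), , drop = FALSE]
  } else {
    src$gaps[0, , drop = FALSE]
  }
  genome[[c1]]$genes <- src$genes[seq_len(i), , drop = FALSE]
  genome[[c1]]$gaps <- src$gaps[seq_len(i - 1), , drop = FALSE]

  idx2 <- .gap_index(genome)
  if (nrow(idx2) == 0) {
    stop("no insertion site left for rearrangement", call. = FALSE)
  }
  tgt <- idx2[sample.int(nrow(idx2), 1), ]
  c2 <- tgt$chrom; j <- tgt$pos
  dst <- genome[[c2]]
  left_strand <- dst$genes$strand[j]
  right_strand <- dst$genes$strand[j + 1]
  jun1_ori <- classify_orientation(left_strand, block_genes$strand[1])
  jun2_ori <- classify_orientation(block_genes$strand[nrow(block_genes)],
                                   right_strand)
  d1 <- .sample_lengths_comp(young_strata[[jun1_ori]], 1)
  d2 <- .sample_lengths_comp(young_strata[[jun2_ori]], 1)
  junctions <- data.frame(
    region_id = next_region(2),
    length = c(d1$length, d2$length),
    birth = birth,
    protected = c((jun1_ori %in% protect_tail) && d1$component == 2,
                  (jun2_ori %in% protect_tail) && d2$component == 2),
    stringsAsFactors = FALSE
  )
  genome[[c2]]$genes <- rbind(dst$genes[seq_len(j), , drop = FALSE],
                              block_genes,
                              dst$genes[(j + 1):nrow(dst$genes), , drop = FALSE])
  genome[[c2]]$gaps <- rbind(
    dst$gaps[seq_len(j - 1), , drop = FALSE],
    junctions[1, ], block_gaps, junctions[2, ],
    if (j + 1 <= nrow(dst$gaps)) dst$gaps[(j + 1):nrow(dst$gaps), , drop = FALSE]
  )
  genome
}

.apply_rearrangements <- function(genome, k, young_strata, birth, next_region,
                                  protect_tail) {
  for (t in seq_len(k)) {
    genome <- .one_rearrangement(genome, young_strata, birth, next_region,
                                 protect_tail)
  }
  genome
}

## lay a genome onto coordinates: gene records in the tabular dialect
.materialize <- function(genome, species) {
  pieces <- lapply(names(genome), function(cn) {
    ch <- genome[[cn]]
    n <- nrow(ch$genes)
    starts <- integer(n)
    pos <- 1L
    for (i in seq_len(n)) {
      starts[i] <- pos
      pos <- pos + ch$genes$cds_len[i]
      if (i <= nrow(ch$gaps)) pos <- pos + ch$gaps$length[i]
    }
    data.frame(
      gene_id = paste(species, ch$genes$anc_id, sep = "_"), species = species,
      chromosome = cn, strand = ch$genes$strand,
      cds_start = as.integer(starts),
      cds_end = as.integer(starts + ch$genes$cds_len - 1L),
      biotype = "protein_coding", stringsAsFactors = FALSE
    )
  })
  .sort_genes(do.call(rbind, pieces))
}

## per-species truth: one row per extant gap with its flanking genes
.genome_truth <- function(genome, species) {
  pieces <- lapply(names(genome), function(cn) {
    ch <- genome[[cn]]
    ng <- nrow(ch$gaps)
    if (ng == 0) return(NULL)
    i <- seq_len(ng)
    data.frame(
      species = species, chromosome = cn,
      region_id = ch$gaps$region_id, birth = ch$gaps$birth,
      length = ch$gaps$length, protected = ch$gaps$protected,
      left_gene = paste(species, ch$genes$anc_id[i], sep = "_"),
      right_gene = paste(species, ch$genes$anc_id[i + 1], sep = "_"),
      orientation = classify_orientation(ch$genes$strand[i],
                                         ch$genes$strand[i + 1]),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, pieces)
}

#' Generate a single species' genome with the ancestral length structure
#'
#' Lays `chromosomes x genes_per_chromosome` fixed-length CDSs
#' left-to-right with random strands, gap lengths drawn per orientation
#' from the clade's ancestral strata, so that [build_neighbor_pairs()]
#' recovers the drawn gaps exactly.
#'
#' @param clade A [clade_spec()].
#' @param species Species code for the gene ids.
#' @return Gene records ([read_annotation()] layout).
#' @export
generate_species_genome <- function(clade, species) {
  stopifnot(inherits(clade, "clade_spec"))
  with_seed(clade$seed, {
    genome <- .make_ancestor(clade, .counter("a"), .counter("r"))
    .materialize(genome, species)
  })
}

## branch label: leaf name, or sorted '+'-joined leaf set of the clade
.branch_label <- function(tree, node) {
  if (node <= length(tree$tip.label)) return(tree$tip.label[node])
  paste(sort(ape::extract.clade(tree, node)$tip.label), collapse = "+")
}

#' Evolve a clade: genomes, orthologs and a truth table by descent
#'
#' The ancestor genome is generated once at the root; along each branch
#' the specified number of rearrangements relocates a length-weighted
#' gene block, destroying two ancestral regions and creating two young
#' junction regions with lengths drawn from the inflated young strata.
#' Orthology is identity by descent with confidence 1.0.  The truth table
#' records every extant region's branch of origin and, via region-id
#' retention across species, the species set in which its neighbourhood
#' is conserved.
#'
#' @param clade A [clade_spec()].
#' @return List with `genes` (named list of gene-record data frames),
#'   `orthologs` (named list `"a|b"` of ortholog-pair data frames),
#'   `tree` (`phylo`), `truth` (data frame: `species`, `chromosome`,
#'   `region_id`, `birth`, `length`, `left_gene`, `right_gene`,
#'   `orientation`, `conserved_in`, `age_label`, `tandem`), `tandem_hits`
#'   (homology data frame), and the `clade` echo.
#' @export
evolve_clade <- function(clade) {
  stopifnot(inherits(clade, "clade_spec"))
  tree <- clade$tree
  young_strata <- lapply(clade$strata, .inflate_spec,
                         inflation = clade$inflation,
                         sd_factor = clade$young_sd_factor)
  with_seed(clade$seed, {
    next_gene <- .counter("a")
    next_region <- .counter("r")
    root <- length(tree$tip.label) + 1L
    genomes <- list()
    recurse <- function(node, genome) {
      kids <- tree$edge[tree$edge[, 1] == node, 2]
      if (length(kids) == 0) {
        genomes[[tree$tip.label[node]]] <<- genome
        return(invisible(NULL))
      }
      for (kid in kids) {
        label <- .branch_label(tree, kid)
        k <- if (label %in% names(clade$rearrangements)) {
          as.integer(clade$rearrangements[[label]])
        } else 0L
        child <- .apply_rearrangements(genome, k, young_strata, label,
                                       next_region, clade$protect_tail)
        recurse(kid, child)
      }
    }
    recurse(root, .make_ancestor(clade, next_gene, next_region))

    species <- tree$tip.label
    genes <- lapply(stats::setNames(species, species), function(sp) {
      .materialize(genomes[[sp]], sp)
    })
    truth <- do.call(rbind, lapply(species, function(sp) {
      .genome_truth(genomes[[sp]], sp)
    }))
    rownames(truth) <- NULL

    ## plant tandem duplicates: flag pairs by homology bitscore 60
    truth$tandem <- FALSE
    tandem_hits <- data.frame(query_id = character(0), subject_id = character(0),
                              bitscore = numeric(0), stringsAsFactors = FALSE)
    if (clade$tandem_pairs > 0) {
      for (sp in species) {
        rows <- which(truth$species == sp)
        pick <- sample(rows, min(clade$tandem_pairs, length(rows)))
        truth$tandem[pick] <- TRUE
        tandem_hits <- rbind(tandem_hits, data.frame(
          query_id = truth$left_gene[pick], subject_id = truth$right_gene[pick],
          bitscore = 60, stringsAsFactors = FALSE
        ))
      }
    }

    ## conservation by descent: species retaining the same region id,
    ## excluding copies masked by a planted tandem pair
    eligible <- truth[!truth$tandem, c("region_id", "species")]
    retained <- split(eligible$species, eligible$region_id)
    truth$conserved_in <- vapply(seq_len(nrow(truth)), function(i) {
      paste(sort(setdiff(retained[[truth$region_id[i]]], truth$species[i])),
            collapse = ",")
    }, character(1))
    truth$age_label <- ifelse(nzchar(truth$conserved_in), "old", "young")

    orthologs <- list()
    for (a_i in seq_along(species)) {
      for (b_i in seq_along(species)) {
        if (a_i >= b_i) next
        a <- species[a_i]; b <- species[b_i]
        shared <- intersect(sub(paste0("^", a, "_"), "", genes[[a]]$gene_id),
                            sub(paste0("^", b, "_"), "", genes[[b]]$gene_id))
        orthologs[[paste(a, b, sep = "|")]] <- data.frame(
          species_a = a, gene_a = paste(a, shared, sep = "_"),
          species_b = b, gene_b = paste(b, shared, sep = "_"),
          confidence = 1.0, stringsAsFactors = FALSE
        )
      }
    }
    list(genes = genes, orthologs = orthologs, tree = tree, truth = truth,
         tandem_hits = tandem_hits, clade = clade)
  })
}

#' Write a fixture bundle to disk in the package's file dialects
#'
#' Writes per-species gene tables, per-pair ortholog TSVs, the newick
#' tree, a homology TSV with the planted tandem pairs, and `truth.json`
#' (region ids, births, lengths, conservation sets and the stratum
#' parameters), so the bundle is fully self-describing.
#'
#' @param clade A [clade_spec()].
#' @param out_dir Writable output directory (created if needed).
#' @return Named list of file paths (plus the in-memory `bundle`),
#'   invisibly.
#' @export
make_fixture_bundle <- function(clade, out_dir) {
  bundle <- evolve_clade(clade)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  for (sp in names(bundle$genes)) {
    p <- file.path(out_dir, paste0("genes_", sp, ".tsv"))
    write_gene_table(bundle$genes[[sp]], p)
    paths$genes[[sp]] <- p
  }
  for (key in names(bundle$orthologs)) {
    ab <- strsplit(key, "|", fixed = TRUE)[[1]]
    p <- file.path(out_dir, paste0("orthologs_", ab[1], "__", ab[2], ".tsv"))
    write_ortholog_table(bundle$orthologs[[key]], p)
    paths$orthologs[[key]] <- p
  }
  paths$tree <- file.path(out_dir, "tree.nwk")
  ape::write.tree(bundle$tree, paths$tree)
  paths$homology <- file.path(out_dir, "homology.tsv")
  write_homology_table(bundle$tandem_hits, paths$homology)
  paths$truth <- file.path(out_dir, "truth.json")
  strata_json <- lapply(bundle$clade$strata, function(s) {
    list(orientation = s$orientation, means = s$means, sds = s$sds,
         weights = s$weights, truncation_bp = s$truncation_bp)
  })
  jsonlite::write_json(list(
    species = bundle$tree$tip.label,
    seed = bundle$clade$seed,
    inflation = bundle$clade$inflation,
    young_sd_factor = bundle$clade$young_sd_factor,
    rearrangements = as.list(bundle$clade$rearrangements),
    strata = strata_json,
    regions = bundle$truth
  ), paths$truth, auto_unbox = TRUE, digits = NA)
  paths$bundle <- bundle
  invisible(paths)
}
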