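# Shared fixture builders and independent oracles.

# quick gene-record data frame
genes_df <- function(gene_id, strand, cds_start, cds_end,
                     chromosome = "chr1", species = "spA",
                     biotype = "protein_coding") {
  data.frame(gene_id = gene_id, species = species, chromosome = chromosome,
             strand = strand, cds_start = as.integer(cds_start),
             cds_end = as.integer(cds_end), biotype = biotype,
             stringsAsFactors = FALSE)
}

write_lines_tmp <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

gene_header <- "#gene_id\tspecies\tchromosome\tstrand\tcds_start\tcds_end"

# a small two-species fixture: orthologous gene pairs adjacent in both
# species, with a configurable tweak applied to the second species
two_species_fixture <- function(flip_strand_of = NULL, insert_between = FALSE) {
  a <- genes_df(c("g1", "g2", "g3"), c("+", "+", "-"),
                c(100, 701, 1401), c(500, 1100, 1800), species = "spA")
  b_strand <- c("+", "+", "-")
  names(b_strand) <- c("h1", "h2", "h3")
  if (!is.null(flip_strand_of)) {
    b_strand[flip_strand_of] <- ifelse(b_strand[flip_strand_of] == "+", "-", "+")
  }
  if (insert_between) {
    b <- genes_df(c("h1", "hx", "h2", "h3"),
                  c(b_strand[["h1"]], "+", b_strand[["h2"]], b_strand[["h3"]]),
                  c(100, 650, 1301, 2001), c(500, 1200, 1700, 2400),
                  species = "spB")
  } else {
    b <- genes_df(c("h1", "h2", "h3"), unname(b_strand),
                  c(100, 701, 1401), c(500, 1100, 1800), species = "spB")
  }
  orth <- data.frame(species_a = "spA", gene_a = c("g1", "g2", "g3"),
                     species_b = "spB", gene_b = c("h1", "h2", "h3"),
                     confidence = 1, stringsAsFactors = FALSE)
  list(regions_a = build_neighbor_pairs(a),
       regions_b = build_neighbor_pairs(b),
       map = data.frame(gene_a = orth$gene_a, gene_b = orth$gene_b,
                        stringsAsFactors = FALSE),
       orth = orth)
}

# exact per-region removal probability under sequential weighted sampling
# without replacement (brute-force enumeration over removal orders)
oracle_removal_probs <- function(weights, n_remove) {
  n <- length(weights)
  probs <- numeric(n)
  recurse <- function(remaining, k_left, pr) {
    if (k_left == 0) return(invisible(NULL))
    tot <- sum(weights[remaining])
    for (i in remaining) {
      p_i <- pr * weights[i] / tot
      probs[i] <<- probs[i] + p_i
      recurse(setdiff(remaining, i), k_left - 1, p_i)
    }
  }
  recurse(seq_len(n), n_remove, 1)
  probs
}

# empirical per-region removal frequencies from many simulator replicates
removal_frequencies <- function(lengths, n_young, n_rep, seed, model = "A",
                                promoter_offset = 0,
                                removal_mode = "sequential") {
  cfg <- sim_config(model = model, n_young = n_young, replicates = n_rep,
                    promoter_offset = promoter_offset, seed = seed,
                    removal_mode = removal_mode)
  sim <- simulate_survivors(lengths, cfg)
  surv <- matrix(FALSE, nrow = n_rep, ncol = length(lengths))
  for (r in seq_len(n_rep)) surv[r, sim$survivor_idx[[r]]] <- TRUE
  colMeans(!surv)
}

# ladder topology for the 11-species clade with the classic age grouping
yeast11_newick <- paste0(
  "((((((sce,sba),sca),cgl),kpo),zro),",
  "((((kth,kwa),skl),ago),kla));"
)
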