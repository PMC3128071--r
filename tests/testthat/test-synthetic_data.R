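test_that("stratum sampling respects truncation, mixture weight and seed", {
  spec <- stratum_spec("divergent", 2.4, 0.2, 150)
  lens <- sample_lengths(spec, 2000, seed = 4)
  expect_gte(min(lens), 150)

  # bimodal: the fraction of draws nearer the lower component mean
  bim <- stratum_spec("divergent", 2.2, 0.1, 0, mean2 = 3.0, sd2 = 0.1,
                      weight2 = 0.5)
  draws <- sample_lengths(bim, 5000, seed = 5)
  frac_low <- mean(abs(log10(draws) - 2.2) < abs(log10(draws) - 3.0))
  se <- sqrt(0.25 / 5000)
  expect_lt(abs(frac_low - 0.5), 3 * se)

  expect_identical(sample_lengths(spec, 100, seed = 9),
                   sample_lengths(spec, 100, seed = 9))

  # truncation far above the distribution body is rejected
  extreme <- stratum_spec("convergent", 2.0, 0.1, 10000)
  expect_error(sample_lengths(extreme, 10, seed = 1), "acceptance")
})

test_that("generated genomes reproduce the drawn gaps and orientation null", {
  tiny <- clade_spec("(spA,spB);", genes_per_chromosome = 40, chromosomes = 2,
                     seed = 8)
  g1 <- generate_species_genome(tiny, "spA")
  expect_identical(g1, generate_species_genome(tiny, "spA"))

  # extraction round trip: inter-CDS lengths equal the generated gaps,
  # asserted via the identity clade's truth table
  b <- evolve_clade(tiny)
  for (sp in c("spA", "spB")) {
    regions <- build_neighbor_pairs(b$genes[[sp]])
    tr <- b$truth[b$truth$species == sp, ]
    m <- match(paste(regions$left_gene, regions$right_gene),
               paste(tr$left_gene, tr$right_gene))
    expect_false(anyNA(m))
    expect_equal(regions$length, tr$length[m])
    expect_equal(regions$orientation, tr$orientation[m])
  }

  # orientation proportions approach the 25/50/25 null
  big <- clade_spec("(spA,spB);", genes_per_chromosome = 5001, chromosomes = 2,
                    seed = 3)
  gb <- generate_species_genome(big, "spA")
  regions <- build_neighbor_pairs(gb)
  n <- nrow(regions)
  expect_gte(n, 9000)
  obs <- c(mean(regions$orientation == "divergent"),
           mean(regions$orientation == "unidirectional"),
           mean(regions$orientation == "convergent"))
  se <- sqrt(c(0.25 * 0.75, 0.5 * 0.5, 0.25 * 0.75) / n)
  expect_true(all(abs(obs - c(0.25, 0.5, 0.25)) < 3.5 * se))
})

test_that("an identity clade is conserved everywhere; rearranged branches age", {
  newick <- "((spA,spB),(spC,spD));"
  ident <- evolve_clade(clade_spec(newick, genes_per_chromosome = 30,
                                   chromosomes = 2, seed = 12))
  expect_true(all(ident$truth$age_label == "old"))
  expect_true(all(ident$truth$birth == "root"))
  # every region is conserved in all three other species
  expect_true(all(vapply(strsplit(ident$truth$conserved_in, ","),
                         length, integer(1)) == 3))

  # rearrangements on the focal terminal branch only: exactly the new
  # junctions are young
  cl <- clade_spec(newick, genes_per_chromosome = 40, chromosomes = 2,
                   rearrangements = c(spA = 6), seed = 13)
  b <- evolve_clade(cl)
  trA <- b$truth[b$truth$species == "spA", ]
  expect_equal(sort(unique(trA$birth)), c("root", "spA"))
  expect_true(all(trA$age_label[trA$birth == "spA"] == "young"))
  # regions destroyed by the relocation are missing from spA but still old
  # (witnessed among the other three) elsewhere
  others <- b$truth[b$truth$species != "spA", ]
  expect_true(all(others$age_label == "old"))

  # regions born on an internal branch carry that clade's age class
  cl2 <- clade_spec(newick, genes_per_chromosome = 40, chromosomes = 2,
                    rearrangements = c("spA+spB" = 5), seed = 14)
  b2 <- evolve_clade(cl2)
  trA2 <- b2$truth[b2$truth$species == "spA", ]
  born_internal <- trA2$birth == "spA+spB"
  expect_gt(sum(born_internal), 0)
  expect_true(all(trA2$conserved_in[born_internal] == "spB"))
  scheme <- scheme_from_tree(b2$tree, "spA", n_classes = 2)
  cls <- assign_age_class(trA2$conserved_in, scheme)
  expect_true(all(cls[born_internal] == "class1"))
  expect_true(all(cls[trA2$birth == "root"] == "class2"))
})

test_that("young regions are longer and more variable than old ones", {
  cl <- clade_spec("(spA,spB);", genes_per_chromosome = 250, chromosomes = 2,
                   rearrangements = c(spA = 40, spB = 40), inflation = 1.8,
                   seed = 15)
  b <- evolve_clade(cl)
  tr <- b$truth
  young <- tr$length[tr$age_label == "young"]
  old <- tr$length[tr$age_label == "old"]
  expect_gt(mean(young), mean(old))
  expect_gt(stats::sd(log10(young)), stats::sd(log10(old)))
})

test_that("fixture bundles round-trip through the file dialects", {
  cl <- clade_spec("((spA,spB),spC);", genes_per_chromosome = 40,
                   chromosomes = 2, rearrangements = c(spA = 4),
                   tandem_pairs = 2, seed = 16)
  out <- file.path(tempfile("bundle"))
  paths <- make_fixture_bundle(cl, out)
  b <- paths$bundle

  for (sp in names(b$genes)) {
    expect_identical(read_annotation(paths$genes[[sp]], "tabular"),
                     b$genes[[sp]])
  }
  for (key in names(b$orthologs)) {
    expect_identical(read_ortholog_table(paths$orthologs[[key]]),
                     b$orthologs[[key]])
  }
  tr <- read_tree(paths$tree)
  expect_setequal(tr$tip.label, b$tree$tip.label)

  # planted tandem pairs are flagged by the tandem filter
  hits <- read_homology_table(paths$homology)
  expect_equal(nrow(hits), 6)  # 2 per species
  regA <- filter_tandem(build_neighbor_pairs(b$genes$spA), hits)
  planted <- b$truth[b$truth$species == "spA" & b$truth$tandem, ]
  flagged <- regA[regA$tandem_flag, ]
  expect_setequal(paste(flagged$left_gene, flagged$right_gene),
                  paste(planted$left_gene, planted$right_gene))

  truth <- jsonlite::read_json(paths$truth, simplifyVector = TRUE)
  expect_setequal(truth$species, c("spA", "spB", "spC"))
  expect_equal(nrow(truth$regions), nrow(b$truth))
})

test_that("the planted divergent bimodality survives the full pipeline", {
  cl <- clade_spec("(spA,spB);", genes_per_chromosome = 900, chromosomes = 2,
                   rearrangements = c(spA = 30, spB = 30), seed = 18)
  b <- evolve_clade(cl)
  regions <- lapply(b$genes, build_neighbor_pairs)
  orth <- do.call(rbind, b$orthologs)
  profA <- conservation_profile(regions$spA, regions, orth, "spA")
  div_old <- profA$length[profA$orientation == "divergent" &
                            profA$age_label == "old"]
  expect_gt(length(div_old), 200)
  f1 <- fit_gaussians(div_old, 1, seed = 1)
  f2 <- fit_gaussians(div_old, 2, seed = 1)
  expect_lt(compare_fits(f1, f2)$p_value, 0.01)
})
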