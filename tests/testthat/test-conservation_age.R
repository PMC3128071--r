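test_that("neighbourhood conservation requires adjacency and matching geometry", {
  fx <- two_species_fixture()
  r1 <- fx$regions_a[1, ]  # g1 (+) .. g2 (+), unidirectional
  expect_true(is_region_conserved(r1, fx$regions_b, fx$map))

  # strand flip of one ortholog breaks the geometry match
  flipped <- two_species_fixture(flip_strand_of = "h2")
  expect_false(is_region_conserved(flipped$regions_a[1, ],
                                   flipped$regions_b, flipped$map))

  # a third gene between the orthologs breaks direct neighbourhood
  spaced <- two_species_fixture(insert_between = TRUE)
  expect_false(is_region_conserved(spaced$regions_a[1, ],
                                   spaced$regions_b, spaced$map))
  # the untouched g2..g3 neighbourhood is still conserved
  expect_true(is_region_conserved(spaced$regions_a[2, ],
                                  spaced$regions_b, spaced$map))

  # missing orthologs simply mean not conserved
  expect_false(is_region_conserved(r1, fx$regions_b,
                                   fx$map[fx$map$gene_a == "g3", ]))
})

test_that("conservation is invariant to reading the other chromosome backwards", {
  fx <- two_species_fixture()
  # reverse spB: mirror coordinates and flip strands; adjacency and the
  # gene ends facing each region are preserved
  b <- genes_df(c("h3", "h2", "h1"), c("+", "-", "-"),
                c(100, 801, 1401), c(500, 1200, 1800), species = "spB")
  regions_b_rev <- build_neighbor_pairs(b)
  for (i in 1:2) {
    expect_equal(
      is_region_conserved(fx$regions_a[i, ], regions_b_rev, fx$map),
      is_region_conserved(fx$regions_a[i, ], fx$regions_b, fx$map)
    )
  }
})

test_that("conservation is symmetric under a symmetric ortholog map", {
  fx <- two_species_fixture()
  rev_map <- data.frame(gene_a = fx$map$gene_b, gene_b = fx$map$gene_a)
  for (i in 1:2) {
    expect_equal(
      is_region_conserved(fx$regions_a[i, ], fx$regions_b, fx$map),
      is_region_conserved(fx$regions_b[i, ], fx$regions_a, rev_map)
    )
  }
})

test_that("tandem-flagged regions cannot witness conservation", {
  fx <- two_species_fixture()
  hits <- data.frame(query_id = "h1", subject_id = "h2", bitscore = 60)
  regions_b <- filter_tandem(fx$regions_b, hits)
  expect_false(is_region_conserved(fx$regions_a[1, ], regions_b, fx$map))
  expect_true(is_region_conserved(fx$regions_a[2, ], regions_b, fx$map))
})

test_that("conservation profiles set young/old labels", {
  fx <- two_species_fixture()
  all_regions <- list(spA = fx$regions_a, spB = fx$regions_b)
  prof <- conservation_profile(fx$regions_a, all_regions, fx$orth, "spA")
  expect_equal(prof$age_label, c("old", "old"))
  expect_equal(prof$conserved_in, c("spB", "spB"))

  # no orthologs at all: everything young, with a warning
  expect_warning(
    none <- conservation_profile(fx$regions_a, all_regions,
                                 fx$orth[0, ], "spA"),
    "no ortholog table"
  )
  expect_equal(none$age_label, c("young", "young"))
})

test_that("age classes pick the most distal conserved clade", {
  scheme <- age_class_scheme(
    c("PO", "VO", "XO"),
    list(c("sba", "sca"), c("cgl", "kpo", "zro"),
         c("kth", "kwa", "skl", "ago", "kla"))
  )
  expect_equal(assign_age_class("sba", scheme), "PO")
  expect_equal(assign_age_class("sba,kla", scheme), "XO")  # most distal wins
  expect_equal(assign_age_class("", scheme), "young")
  expect_equal(assign_age_class("cgl,zro", scheme), "VO")
  expect_error(assign_age_class("spo", scheme), "not covered")

  # monotonicity: adding a species never moves the class nearer
  set.seed(3)
  all_sp <- unlist(scheme$species_sets)
  rank_of <- function(lbl) match(lbl, c("young", scheme$labels))
  for (i in 1:25) {
    base <- sample(all_sp, sample(0:5, 1))
    extra <- sample(setdiff(all_sp, base), 1)
    r1 <- rank_of(assign_age_class(paste(base, collapse = ","), scheme))
    r2 <- rank_of(assign_age_class(paste(c(base, extra), collapse = ","), scheme))
    expect_gte(r2, r1)
  }
})

test_that("schemes derive from the rooted tree by attachment order", {
  tr <- ape::read.tree(text = "((sce,sba),sca);")
  s <- scheme_from_tree(tr, "sce", n_classes = 2)
  expect_equal(s$species_sets, list("sba", "sca"))

  # the classic 3-way grouping for the 11-species ladder
  tr11 <- ape::read.tree(text = yeast11_newick)
  s3 <- scheme_from_tree(tr11, "sce", breaks = c(2, 3, 1),
                         labels = c("PO", "VO", "XO"))
  expect_equal(s3$labels, c("PO", "VO", "XO"))
  expect_setequal(s3$species_sets[[1]], c("sba", "sca"))
  expect_setequal(s3$species_sets[[2]], c("cgl", "kpo", "zro"))
  expect_setequal(s3$species_sets[[3]], c("kth", "kwa", "skl", "ago", "kla"))

  # merge-farthest default covers all species with disjoint sets
  s2 <- scheme_from_tree(tr11, "sce", n_classes = 3)
  expect_equal(s2$species_sets[[1]], "sba")
  expect_setequal(unlist(s2$species_sets),
                  setdiff(tr11$tip.label, "sce"))

  expect_error(scheme_from_tree(tr, "nope", n_classes = 2), "not a leaf")
  expect_error(scheme_from_tree(tr, "sce", n_classes = 5), "exceeds")
})

test_that("ages recover perfectly on an evolved clade with complete orthologs", {
  cl <- clade_spec("((sceA,sceB),(outC,outD));", genes_per_chromosome = 60,
                   chromosomes = 2,
                   rearrangements = c(sceA = 8, "outC+outD" = 5),
                   seed = 101)
  b <- evolve_clade(cl)
  regions <- lapply(b$genes, build_neighbor_pairs)
  orth <- do.call(rbind, b$orthologs)
  prof <- conservation_profile(regions$sceA, regions, orth, "sceA")
  tr <- b$truth[b$truth$species == "sceA", ]
  m <- match(paste(prof$left_gene, prof$right_gene),
             paste(tr$left_gene, tr$right_gene))
  expect_false(anyNA(m))
  expect_equal(prof$age_label, tr$age_label[m])
  # conservation sets match identity-by-descent truth exactly
  split_set <- function(x) lapply(strsplit(x, ","), function(v) sort(v[nzchar(v)]))
  expect_equal(split_set(prof$conserved_in), split_set(tr$conserved_in[m]))
})
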