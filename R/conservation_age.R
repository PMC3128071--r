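## Gene-neighbourhood conservation across species and clade-based age
## classes against a rooted species tree.
##
## A region is conserved in another species iff both flanking genes have
## orthologs there, those orthologs are themselves direct neighbours of a
## retained region, and each gene presents the same end (5' or 3') to the
## region as its ortholog does.  Matching ends makes the test invariant to
## reading a rearranged chromosome from the other direction, and implies
## that the orientation class (convergent / unidirectional / divergent)
## matches too.

## which end of each flanking gene faces the region
.facing_ends <- function(left_strand, right_strand) {
  list(left = ifelse(left_strand == "+", "3p", "5p"),
       right = ifelse(right_strand == "+", "5p", "3p"))
}

## long form: one row per (region, flank); used to index regions by gene
.region_flanks <- function(regions) {
  if (nrow(regions) == 0) {
    return(data.frame(idx = integer(0), gene = character(0),
                      face = character(0), partner = character(0),
                      partner_face = character(0), stringsAsFactors = FALSE))
  }
  f <- .facing_ends(regions$left_strand, regions$right_strand)
  idx <- seq_len(nrow(regions))
  rbind(
    data.frame(idx = idx, gene = regions$left_gene, face = f$left,
               partner = regions$right_gene, partner_face = f$right,
               stringsAsFactors = FALSE),
    data.frame(idx = idx, gene = regions$right_gene, face = f$right,
               partner = regions$left_gene, partner_face = f$left,
               stringsAsFactors = FALSE)
  )
}

## Vectorized core: for each focal region, is it conserved in the other
## species?  `ortholog_map` has columns gene_a (focal) and gene_b (other);
## one-to-many maps are allowed — any witnessing combination counts.
.conserved_in_species <- function(regions, other_regions, ortholog_map) {
  out <- rep(FALSE, nrow(regions))
  if (nrow(regions) == 0 || is.null(other_regions) || nrow(other_regions) == 0 ||
      is.null(ortholog_map) || nrow(ortholog_map) == 0) {
    return(out)
  }
  ## regions removed by the tandem filter cannot witness conservation
  other <- other_regions[!other_regions$tandem_flag, , drop = FALSE]
  if (nrow(other) == 0) return(out)
  flanks <- .region_flanks(other)
  f <- .facing_ends(regions$left_strand, regions$right_strand)
  focal <- data.frame(idx = seq_len(nrow(regions)),
                      left_gene = regions$left_gene,
                      right_gene = regions$right_gene,
                      lface = f$left, rface = f$right,
                      stringsAsFactors = FALSE)
  om <- ortholog_map[, c("gene_a", "gene_b")]
  left_x <- merge(focal, om, by.x = "left_gene", by.y = "gene_a")
  if (nrow(left_x) == 0) return(out)
  names(left_x)[names(left_x) == "gene_b"] <- "left_orth"
  both <- merge(left_x, om, by.x = "right_gene", by.y = "gene_a")
  if (nrow(both) == 0) return(out)
  names(both)[names(both) == "gene_b"] <- "right_orth"
  cand <- merge(both, flanks, by.x = "left_orth", by.y = "gene")
  if (nrow(cand) == 0) return(out)
  ok <- cand$face == cand$lface &
    cand$partner == cand$right_orth &
    cand$partner_face == cand$rface
  out[unique(cand$idx.x[ok])] <- TRUE
  out
}

#' Is a region's neighbourhood conserved in another species?
#'
#' @param region A single region (1-row data frame from the region table).
#' @param other_species_regions Region table of the other species.
#' @param ortholog_map Data frame with columns `gene_a` (focal species
#'   gene ids) and `gene_b` (other species); one-to-many allowed.
#' @return `TRUE` iff both flanking genes have orthologs that are direct
#'   neighbours of a retained region in the other species, presenting the
#'   same gene ends to it.  Missing orthologs give `FALSE`.
#' @export
is_region_conserved <- function(region, other_species_regions, ortholog_map) {
  .conserved_in_species(region, other_species_regions, ortholog_map)[1]
}

## normalize an ortholog table to a focal->other two-column map
.ortholog_map_for <- function(pairs, focal, other) {
  a <- pairs[pairs$species_a == focal & pairs$species_b == other,
             c("gene_a", "gene_b")]
  b <- pairs[pairs$species_b == focal & pairs$species_a == other,
             c("gene_b", "gene_a")]
  names(b) <- c("gene_a", "gene_b")
  unique(rbind(a, b))
}

#' Conservation profiles and young/old labels for a species' regions
#'
#' For every region of the focal species, records the set of other species
#' in which its neighbourhood is conserved.  Regions conserved nowhere are
#' labelled `"young"`, all others `"old"`.
#'
#' @param regions Focal species' region table.
#' @param other_regions Named list (by species code) of the other species'
#'   region tables.
#' @param ortholog_pairs Either one combined ortholog-pair data frame
#'   (columns `species_a`, `gene_a`, `species_b`, `gene_b`) covering all
#'   pairs involving the focal species, or a named list (by other species)
#'   of `gene_a`/`gene_b` maps.  A species with no table available is
#'   treated as not conserving anything, with a warning.
#' @param focal Focal species code.
#' @return `regions` with `conserved_in` (comma-joined species codes) and
#'   `age_label` filled in.
#' @export
conservation_profile <- function(regions, other_regions, ortholog_pairs, focal) {
  others <- setdiff(names(other_regions), focal)
  conserved <- matrix(FALSE, nrow = nrow(regions), ncol = length(others),
                      dimnames = list(NULL, others))
  for (sp in others) {
    map <- if (is.data.frame(ortholog_pairs)) {
      .ortholog_map_for(ortholog_pairs, focal, sp)
    } else {
      ortholog_pairs[[sp]]
    }
    if (is.null(map) || nrow(map) == 0) {
      warning(sprintf("no ortholog table for species pair (%s, %s); treated as not conserved",
                      focal, sp), call. = FALSE)
      next
    }
    conserved[, sp] <- .conserved_in_species(regions, other_regions[[sp]], map)
  }
  regions$conserved_in <- apply(conserved, 1, function(row) {
    paste(others[row], collapse = ",")
  })
  if (nrow(regions)) {
    regions$age_label <- ifelse(nzchar(regions$conserved_in), "old", "young")
  }
  regions
}

#' Construct an age-class scheme explicitly
#'
#' @param labels Class labels ordered from the nearest to the farthest
#'   clade relative to the focal species.
#' @param species_sets List of character vectors of species codes, one per
#'   label; must be disjoint.
#' @return An `age_class_scheme` object.
#' @export
age_class_scheme <- function(labels, species_sets) {
  stopifnot(length(labels) == length(species_sets))
  all_sp <- unlist(species_sets)
  if (anyDuplicated(all_sp)) {
    stop("age-class species sets must be disjoint", call. = FALSE)
  }
  structure(list(labels = as.character(labels),
                 species_sets = lapply(species_sets, as.character)),
            class = "age_class_scheme")
}

#' Assign an age class from a conservation profile
#'
#' The class of the most distal clade intersected by the conservation
#' profile wins, even if intermediate clades show no conservation (losses
#' are ignored).  An empty profile is `"young"`.
#'
#' @param conserved_in Character vector of comma-joined species codes (as
#'   in the region table), or a list of character vectors.
#' @param scheme An [age_class_scheme()].
#' @return Character vector of class labels.
#' @export
assign_age_class <- function(conserved_in, scheme) {
  stopifnot(inherits(scheme, "age_class_scheme"))
  sets <- scheme$species_sets
  known <- unlist(sets)
  if (!is.list(conserved_in)) {
    conserved_in <- strsplit(as.character(conserved_in), ",", fixed = TRUE)
  }
  vapply(conserved_in, function(sp) {
    sp <- sp[nzchar(sp)]
    if (length(sp) == 0) return("young")
    missing <- setdiff(sp, known)
    if (length(missing)) {
      stop(sprintf("species '%s' not covered by the age-class scheme", missing[1]),
           call. = FALSE)
    }
    hit <- vapply(sets, function(s) any(sp %in% s), logical(1))
    scheme$labels[max(which(hit))]
  }, character(1))
}

## leaf sets of the sister clades attaching along the rootward path from a
## focal leaf, ordered nearest -> farthest
.attachment_levels <- function(tree, focal) {
  if (!(focal %in% tree$tip.label)) {
    stop(sprintf("focal species '%s' is not a leaf of the tree", focal),
         call. = FALSE)
  }
  node <- which(tree$tip.label == focal)
  parent <- tree$edge[, 1]
  child <- tree$edge[, 2]
  seen <- focal
  levels <- list()
  repeat {
    up <- parent[child == node]
    if (length(up) == 0) break
    leaves <- ape::extract.clade(tree, up)$tip.label
    new <- setdiff(leaves, seen)
    if (length(new)) levels[[length(levels) + 1]] <- new
    seen <- union(seen, leaves)
    node <- up
  }
  levels
}

#' Derive an age-class scheme from a rooted species tree
#'
#' Walks rootward from the focal leaf, collecting the leaf set of each
#' sister clade that attaches along the way (nearest first).  With only
#' `n_classes` given, the nearest `n_classes - 1` attachment levels each
#' form a class and all remaining levels are merged into the farthest
#' class.  `breaks` instead gives the number of consecutive attachment
#' levels per class (summing to the number of levels), which allows
#' groupings such as the classic three-way split used for
#' *S. cerevisiae*.
#'
#' @param tree Rooted `phylo` tree whose leaves are species codes.
#' @param focal Focal species (a leaf).
#' @param n_classes Number of age classes (>= 2 when `breaks` is `NULL`).
#' @param breaks Optional integer vector: attachment levels per class.
#' @param labels Optional class labels (default `class1..classK`).
#' @return An [age_class_scheme()], nearest class first.
#' @export
scheme_from_tree <- function(tree, focal, n_classes = NULL, breaks = NULL,
                             labels = NULL) {
  levels <- .attachment_levels(tree, focal)
  if (length(levels) == 0) stop("tree has no other species", call. = FALSE)
  if (is.null(breaks)) {
    if (is.null(n_classes) || n_classes < 2) {
      stop("n_classes must be >= 2 (or supply breaks)", call. = FALSE)
    }
    if (n_classes > length(levels)) {
      stop(sprintf("n_classes = %d exceeds the %d available sister clades",
                   n_classes, length(levels)), call. = FALSE)
    }
    breaks <- c(rep(1L, n_classes - 1), length(levels) - (n_classes - 1L))
    breaks <- breaks[breaks > 0]
  }
  if (sum(breaks) != length(levels)) {
    stop(sprintf("breaks must sum to the %d attachment levels", length(levels)),
         call. = FALSE)
  }
  idx <- rep(seq_along(breaks), breaks)
  sets <- lapply(seq_along(breaks), function(k) unlist(levels[idx == k]))
  if (is.null(labels)) labels <- paste0("class", seq_along(sets))
  age_class_scheme(labels, sets)
}
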