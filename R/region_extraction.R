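## Adjacent-gene-pair construction, orientation classification, inter-CDS
## lengths, and the tandem-duplicate and repeat filters.

#' Classify the orientation of an adjacent gene pair
#'
#' An inter-CDS region is classified by the strands of its flanking genes
#' (left = smaller coordinates): convergent (`+ -`, both 3' ends face the
#' region, no promoter inside), divergent (`- +`, both 5' ends face the
#' region, promoter(s) inside), unidirectional (equal strands, one
#' promoter inside).
#'
#' @param left_strand,right_strand `"+"` or `"-"`, vectorized.
#' @return Character vector in `c("convergent", "unidirectional", "divergent")`.
#' @examples
#' classify_orientation("+", "-")  # convergent
#' classify_orientation("-", "+")  # divergent
#' @export
classify_orientation <- function(left_strand, right_strand) {
  check_strand(left_strand)
  check_strand(right_strand)
  ifelse(left_strand == right_strand, "unidirectional",
         ifelse(left_strand == "+", "convergent", "divergent"))
}

#' Inter-CDS distance between two gene records
#'
#' Number of nucleotides strictly between the ORF boundaries of two genes
#' on the same chromosome: `right$cds_start - left$cds_end - 1`.  May be
#' zero (abutting ORFs) or negative (overlap); such pairs are excluded by
#' [build_neighbor_pairs()].
#'
#' @param left,right Single gene records (1-row data frames or lists) with
#'   `left$cds_start <= right$cds_start`.
#' @return Integer bp (may be `<= 0`).
#' @export
inter_cds_length <- function(left, right) {
  if (!identical(as.character(left$chromosome), as.character(right$chromosome))) {
    stop("genes lie on different chromosomes", call. = FALSE)
  }
  if (left$cds_start > right$cds_start) {
    stop("left gene must have the smaller start coordinate", call. = FALSE)
  }
  as.integer(right$cds_start - left$cds_end - 1L)
}

#' Build inter-CDS regions from adjacent gene pairs
#'
#' Genes of one species are sorted per chromosome by `(cds_start, cds_end,
#' gene_id)`; each pair of direct neighbours under the chosen adjacency
#' scope yields one candidate region.  Pairs with inter-CDS length `<= 0`
#' (overlapping or abutting ORFs) are dropped, and under
#' `"all_features"` a pair separated by any annotated feature (e.g. a
#' tRNA) is not adjacent, while `"protein_coding_only"` ignores
#' non-protein-coding records when deciding adjacency.  Regions flanked by
#' a non-protein-coding gene are never emitted.
#'
#' @param genes Gene records of a single species ([read_annotation()]).
#' @param adjacency_scope `"protein_coding_only"` (default) or
#'   `"all_features"`.
#' @return Region data frame with columns `species`, `chromosome`,
#'   `left_gene`, `right_gene`, `left_strand`, `right_strand`,
#'   `orientation`, `start`, `end` (1-based inclusive span of the region
#'   itself), `length`, `tandem_flag`, `repeat_flag`, `age_label`,
#'   `age_class`, `conserved_in`.
#' @export
build_neighbor_pairs <- function(genes,
                                 adjacency_scope = c("protein_coding_only",
                                                     "all_features")) {
  adjacency_scope <- match.arg(adjacency_scope)
  empty <- data.frame(
    species = character(0), chromosome = character(0),
    left_gene = character(0), right_gene = character(0),
    left_strand = character(0), right_strand = character(0),
    orientation = character(0), start = integer(0), end = integer(0),
    length = integer(0), tandem_flag = logical(0), repeat_flag = logical(0),
    age_label = character(0), age_class = character(0),
    conserved_in = character(0), stringsAsFactors = FALSE
  )
  if (is.null(genes) || nrow(genes) == 0) return(empty)
  if (length(unique(genes$species)) > 1) {
    stop("build_neighbor_pairs expects genes from a single species", call. = FALSE)
  }
  universe <- if (adjacency_scope == "protein_coding_only") {
    genes[genes$biotype == "protein_coding", , drop = FALSE]
  } else {
    genes
  }
  universe <- .sort_genes(universe)
  pieces <- lapply(split(universe, universe$chromosome), function(g) {
    n <- nrow(g)
    if (n < 2) return(NULL)
    i <- seq_len(n - 1)
    data.frame(
      species = g$species[i], chromosome = g$chromosome[i],
      left_gene = g$gene_id[i], right_gene = g$gene_id[i + 1],
      left_strand = g$strand[i], right_strand = g$strand[i + 1],
      left_pc = g$biotype[i] == "protein_coding",
      right_pc = g$biotype[i + 1] == "protein_coding",
      start = g$cds_end[i] + 1L, end = g$cds_start[i + 1] - 1L,
      length = as.integer(g$cds_start[i + 1] - g$cds_end[i] - 1L),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, pieces)
  if (is.null(out) || nrow(out) == 0) return(empty)
  out <- out[out$length >= 1L & out$left_pc & out$right_pc, , drop = FALSE]
  if (nrow(out) == 0) return(empty)
  out$left_pc <- out$right_pc <- NULL
  out$orientation <- classify_orientation(out$left_strand, out$right_strand)
  out$tandem_flag <- FALSE
  out$repeat_flag <- FALSE
  out$age_label <- "unassigned"
  out$age_class <- NA_character_
  out$conserved_in <- ""
  out <- out[order(out$chromosome, out$start), ]
  rownames(out) <- NULL
  out[, names(empty)]
}

#' Flag regions flanked by putative tandem duplicates
#'
#' A region is flagged when its two flanking genes hit each other with
#' `max(bitscore(left, right), bitscore(right, left)) >= bitscore_threshold`
#' (default 50, boundary inclusive).  Flagged regions are excluded from all
#' downstream statistics.
#'
#' @param regions Region data frame.
#' @param hits Homology hits ([read_homology_table()]).
#' @param bitscore_threshold Inclusive flagging threshold (default 50).
#' @return `regions` with `tandem_flag` set.
#' @export
filter_tandem <- function(regions, hits, bitscore_threshold = 50) {
  if (nrow(regions) == 0) return(regions)
  if (is.null(hits) || nrow(hits) == 0) {
    regions$tandem_flag <- FALSE
    return(regions)
  }
  score <- stats::setNames(hits$bitscore,
                           paste(hits$query_id, hits$subject_id, sep = "\r"))
  fwd <- score[paste(regions$left_gene, regions$right_gene, sep = "\r")]
  rev <- score[paste(regions$right_gene, regions$left_gene, sep = "\r")]
  best <- pmax(ifelse(is.na(fwd), -Inf, fwd), ifelse(is.na(rev), -Inf, rev))
  regions$tandem_flag <- best >= bitscore_threshold
  regions
}

#' Flag regions overlapped by repeat-mask intervals
#'
#' A region is flagged when any repeat interval overlaps the open interval
#' between its two ORFs by at least one bp.  Repeats confined to the
#' flanking CDSs do not flag.
#'
#' @param regions Region data frame (one species).
#' @param repeats Repeat intervals ([read_repeat_bed()]; 0-based half-open).
#' @return `regions` with `repeat_flag` set.
#' @export
filter_repeats <- function(regions, repeats) {
  if (nrow(regions) == 0) return(regions)
  if (is.null(repeats) || nrow(repeats) == 0) {
    regions$repeat_flag <- FALSE
    return(regions)
  }
  reg <- GenomicRanges::GRanges(
    regions$chromosome, IRanges::IRanges(regions$start, regions$end)
  )
  rep_gr <- GenomicRanges::GRanges(
    repeats$chromosome, IRanges::IRanges(repeats$start + 1L, repeats$end)
  )
  hits <- GenomicRanges::findOverlaps(reg, rep_gr, minoverlap = 1L)
  regions$repeat_flag <- seq_len(nrow(regions)) %in%
    S4Vectors::queryHits(hits)
  regions
}
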