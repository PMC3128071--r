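## Readers and writers for every external format the pipeline touches.
## All tabular dialects are TSV whose header line starts with '#'; readers
## also accept a bare header.  Validation errors name the offending line.

.read_lines_nonempty <- function(path) {
  if (!file.exists(path)) abort_validation("file does not exist", path = path)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  list(lines = lines[keep], numbers = which(keep))
}

## TSV with '#'-prefixed (or bare) header; returns df plus source line numbers
.read_tsv_dialect <- function(path, required_cols) {
  lr <- .read_lines_nonempty(path)
  if (length(lr$lines) == 0) {
    out <- as.data.frame(setNames(rep(list(character(0)), length(required_cols)),
                                  required_cols))
    attr(out, "line_numbers") <- integer(0)
    return(out)
  }
  header <- sub("^#\\s*", "", lr$lines[1])
  cols <- strsplit(header, "\t", fixed = TRUE)[[1]]
  if (!all(required_cols %in% cols)) {
    abort_validation(
      sprintf("header must name columns: %s", paste(required_cols, collapse = ", ")),
      path = path, line = lr$numbers[1]
    )
  }
  body <- lr$lines[-1]
  nums <- lr$numbers[-1]
  if (length(body) == 0) {
    out <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols))
  } else {
    out <- utils::read.delim(text = body, header = FALSE, col.names = cols,
                             colClasses = "character", quote = "",
                             stringsAsFactors = FALSE)
  }
  attr(out, "line_numbers") <- nums
  out
}

.as_coord <- function(x, what, path, lines) {
  v <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(v))
  if (length(bad)) {
    abort_validation(sprintf("non-numeric %s '%s'", what, x[bad[1]]),
                     path = path, line = lines[bad[1]])
  }
  as.integer(round(v))
}

.validate_genes <- function(df, path = NULL, lines = NULL) {
  check_strand(df$strand, path = path, lines = lines)
  bad <- which(df$cds_start < 1L)
  if (length(bad)) {
    abort_validation(sprintf("cds_start %d < 1", df$cds_start[bad[1]]),
                     path = path, line = if (!is.null(lines)) lines[bad[1]])
  }
  bad <- which(df$cds_end < df$cds_start)
  if (length(bad)) {
    abort_validation(
      sprintf("cds_end %d < cds_start %d for gene '%s'",
              df$cds_end[bad[1]], df$cds_start[bad[1]], df$gene_id[bad[1]]),
      path = path, line = if (!is.null(lines)) lines[bad[1]]
    )
  }
  dup <- df$gene_id[duplicated(df[, c("species", "gene_id")])]
  if (length(dup)) {
    abort_validation(sprintf("duplicate gene_id '%s' within a species", dup[1]),
                     path = path)
  }
  invisible(df)
}

.sort_genes <- function(df) {
  df <- df[order(df$species, df$chromosome, df$cds_start, df$cds_end, df$gene_id), ]
  rownames(df) <- NULL
  df
}

#' Read a gene annotation into gene records
#'
#' Parses either the package's tabular gene dialect (TSV with named columns
#' `gene_id`, `species`, `chromosome`, `strand`, `cds_start`, `cds_end` and
#' optional `biotype`) or a GFF3 file (features of type `gene` or `CDS`).
#' Multi-segment CDS entries sharing a gene id are collapsed to the union
#' span `min(start)..max(end)`, i.e. ORF boundaries.
#'
#' @param path Path to the annotation file.
#' @param format `"tabular"` or `"gff3"`.
#' @param species Species code stored in each record.  Required for GFF3
#'   (defaults to the file name without extension); for the tabular dialect
#'   the file's own `species` column is used.
#' @return A data frame of gene records (one row per gene), 1-based
#'   inclusive coordinates, sorted by `(chromosome, cds_start, cds_end,
#'   gene_id)`.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("#gene_id\tspecies\tchromosome\tstrand\tcds_start\tcds_end",
#'              "g1\tsce\tchr1\t+\t100\t500",
#'              "g2\tsce\tchr1\t-\t701\t900"), tf)
#' read_annotation(tf, "tabular")
#' @export
read_annotation <- function(path, format = c("tabular", "gff3"), species = NULL) {
  format <- match.arg(format)
  if (format == "tabular") {
    df <- .read_tsv_dialect(path, c("gene_id", "species", "chromosome",
                                    "strand", "cds_start", "cds_end"))
    lines <- attr(df, "line_numbers")
    if (nrow(df) == 0) {
      return(data.frame(gene_id = character(0), species = character(0),
                        chromosome = character(0), strand = character(0),
                        cds_start = integer(0), cds_end = integer(0),
                        biotype = character(0), stringsAsFactors = FALSE))
    }
    out <- data.frame(
      gene_id = df$gene_id, species = df$species, chromosome = df$chromosome,
      strand = df$strand,
      cds_start = .as_coord(df$cds_start, "cds_start", path, lines),
      cds_end = .as_coord(df$cds_end, "cds_end", path, lines),
      biotype = if ("biotype" %in% names(df)) df$biotype else "protein_coding",
      stringsAsFactors = FALSE
    )
    .validate_genes(out, path = path, lines = lines)
    return(.sort_genes(out))
  }
  .read_gff3(path, species = species)
}

.read_gff3 <- function(path, species = NULL) {
  if (is.null(species)) species <- sub("\\.[^.]*$", "", basename(path))
  ## cheap pre-scan so coordinate errors cite their line
  raw <- .read_lines_nonempty(path)
  dat <- raw$lines[!startsWith(raw$lines, "#")]
  nums <- raw$numbers[!startsWith(raw$lines, "#")]
  fields <- strsplit(dat, "\t", fixed = TRUE)
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) < 9) next
    s <- suppressWarnings(as.numeric(f[4])); e <- suppressWarnings(as.numeric(f[5]))
    if (!is.na(s) && !is.na(e) && e < s) {
      abort_validation(sprintf("cds_end %d < cds_start %d", e, s),
                       path = path, line = nums[i])
    }
  }
  gr <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  type <- as.character(gr$type)
  get_id <- function() {
    id <- rep(NA_character_, length(gr))
    for (col in c("ID", "gene_id", "Name")) {
      if (col %in% names(md)) id[is.na(id)] <- as.character(md[[col]])[is.na(id)]
    }
    id
  }
  ids <- get_id()
  parents <- if ("Parent" %in% names(md)) {
    vapply(md$Parent, function(p) if (length(p)) p[[1]] else NA_character_,
           character(1))
  } else {
    rep(NA_character_, length(gr))
  }
  ## CDS features group by gene: CDS -> Parent transcript -> Parent gene
  txn <- type %in% c("mRNA", "transcript")
  tx2gene <- stats::setNames(parents[txn], ids[txn])
  is_cds <- type == "CDS"
  is_gene <- type == "gene"
  if (!any(is_cds) && !any(is_gene)) {
    abort_validation("no 'gene' or 'CDS' features found", path = path)
  }
  cds_gene <- parents[is_cds]
  mapped <- cds_gene %in% names(tx2gene)
  cds_gene[mapped] <- unname(tx2gene[cds_gene[mapped]])
  cds_gene[is.na(cds_gene)] <- ids[is_cds][is.na(cds_gene)]
  if (anyNA(cds_gene)) {
    abort_validation("CDS feature without ID or Parent", path = path)
  }
  strand <- as.character(BiocGenerics::strand(gr))
  check_strand(strand[is_cds | is_gene], path = path)
  gene_biotype <- rep("protein_coding", sum(is_gene))
  for (col in c("biotype", "gene_biotype")) {
    if (col %in% names(md)) {
      v <- as.character(md[[col]])[is_gene]
      gene_biotype[!is.na(v)] <- v[!is.na(v)]
    }
  }
  parts <- rbind(
    data.frame(gene_id = ids[is_gene],
               chromosome = as.character(GenomeInfoDb::seqnames(gr))[is_gene],
               strand = strand[is_gene],
               start = BiocGenerics::start(gr)[is_gene],
               end = BiocGenerics::end(gr)[is_gene],
               biotype = gene_biotype, is_cds = FALSE, stringsAsFactors = FALSE),
    data.frame(gene_id = cds_gene,
               chromosome = as.character(GenomeInfoDb::seqnames(gr))[is_cds],
               strand = strand[is_cds],
               start = BiocGenerics::start(gr)[is_cds],
               end = BiocGenerics::end(gr)[is_cds],
               biotype = "protein_coding", is_cds = TRUE, stringsAsFactors = FALSE)
  )
  if (anyNA(parts$gene_id)) {
    abort_validation("feature without ID/Parent/gene_id", path = path)
  }
  ## union span per gene id; CDS segments define the ORF span when present
  out <- do.call(rbind, lapply(split(parts, parts$gene_id), function(g) {
    if (length(unique(g$chromosome)) != 1 || length(unique(g$strand)) != 1) {
      abort_validation(sprintf("gene '%s' spans chromosomes or strands",
                               g$gene_id[1]), path = path)
    }
    use <- if (any(g$is_cds)) g[g$is_cds, ] else g
    data.frame(gene_id = sub("^(gene|mRNA|transcript):", "", g$gene_id[1]),
               species = species,
               chromosome = g$chromosome[1], strand = g$strand[1],
               cds_start = min(use$start), cds_end = max(use$end),
               biotype = g$biotype[which.max(!g$is_cds)],
               stringsAsFactors = FALSE)
  }))
  .validate_genes(out, path = path)
  .sort_genes(out)
}

#' Read a tabular homology (BLAST-like) hit table
#'
#' Accepts the standard 12-column tabular hit dialect (query and subject ids
#' in columns 1-2, bitscore in column 12) or a minimal 3-column
#' `query subject bitscore` dialect, whitespace- or tab-delimited.
#' Duplicate `(query, subject)` rows are collapsed to their maximum
#' bitscore.  An empty file yields an empty table.
#'
#' @param path Path to the hit table.
#' @return Data frame with columns `query_id`, `subject_id`, `bitscore`.
#' @export
read_homology_table <- function(path) {
  empty <- data.frame(query_id = character(0), subject_id = character(0),
                      bitscore = numeric(0), stringsAsFactors = FALSE)
  if (!file.exists(path)) abort_validation("file does not exist", path = path)
  lr <- .read_lines_nonempty(path)
  keep <- !startsWith(lr$lines, "#")
  lines <- lr$lines[keep]; nums <- lr$numbers[keep]
  if (length(lines) == 0) return(empty)
  fields <- strsplit(trimws(lines), "[ \t]+")
  rows <- lapply(seq_along(fields), function(i) {
    f <- fields[[i]]
    if (length(f) >= 12) {
      c(f[1], f[2], f[12])
    } else if (length(f) == 3) {
      f
    } else {
      abort_validation(sprintf("expected 3 or >=12 columns, got %d", length(f)),
                       path = path, line = nums[i])
    }
  })
  m <- do.call(rbind, rows)
  bits <- suppressWarnings(as.numeric(m[, 3]))
  bad <- which(is.na(bits))
  if (length(bad)) {
    abort_validation(sprintf("non-numeric bitscore '%s'", m[bad[1], 3]),
                     path = path, line = nums[bad[1]])
  }
  if (any(bits < 0)) {
    abort_validation("negative bitscore", path = path,
                     line = nums[which(bits < 0)[1]])
  }
  df <- data.frame(query_id = m[, 1], subject_id = m[, 2], bitscore = bits,
                   stringsAsFactors = FALSE)
  ## duplicate (query, subject) rows collapse to the max bitscore
  key <- paste(df$query_id, df$subject_id, sep = "\r")
  agg <- tapply(df$bitscore, key, max)
  first <- !duplicated(key)
  out <- df[first, ]
  out$bitscore <- as.numeric(agg[paste(out$query_id, out$subject_id, sep = "\r")])
  rownames(out) <- NULL
  out
}

#' Read a pairwise ortholog table
#'
#' Five columns: `species_a`, `gene_a`, `species_b`, `gene_b`, `confidence`
#' (a score in \[0,1\]; pairs emulating fully supported orthologous groups
#' carry 1.0).  Only rows with `confidence >= min_confidence` are retained.
#'
#' @param path Path to the ortholog TSV.
#' @param min_confidence Minimum confidence retained (default 1.0, i.e.
#'   only fully supported pairs).
#' @return Data frame with the five columns, filtered.
#' @export
read_ortholog_table <- function(path, min_confidence = 1.0) {
  df <- .read_tsv_dialect(path, c("species_a", "gene_a", "species_b",
                                  "gene_b", "confidence"))
  lines <- attr(df, "line_numbers")
  conf <- suppressWarnings(as.numeric(df$confidence))
  bad <- which(is.na(conf) & nzchar(df$confidence))
  if (nrow(df) && length(bad)) {
    abort_validation(sprintf("non-numeric confidence '%s'", df$confidence[bad[1]]),
                     path = path, line = lines[bad[1]])
  }
  if (any(conf < 0 | conf > 1, na.rm = TRUE)) {
    abort_validation("confidence outside [0, 1]", path = path,
                     line = lines[which(conf < 0 | conf > 1)[1]])
  }
  same <- which(df$species_a == df$species_b)
  if (length(same)) {
    abort_validation(sprintf("species_a equals species_b ('%s')", df$species_a[same[1]]),
                     path = path, line = lines[same[1]])
  }
  out <- data.frame(species_a = df$species_a, gene_a = df$gene_a,
                    species_b = df$species_b, gene_b = df$gene_b,
                    confidence = conf, stringsAsFactors = FALSE)
  out <- out[!is.na(out$confidence) & out$confidence >= min_confidence, ]
  rownames(out) <- NULL
  out
}

#' Read a rooted species tree from a newick file
#'
#' @param path Path to a newick file with unique leaf labels.
#' @return An [ape::read.tree()] `phylo` object.  Duplicate leaf labels are
#'   an error; a basal multifurcation is accepted with a message.
#' @export
read_tree <- function(path) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) abort_validation("could not parse newick", path = path)
  if (anyDuplicated(tree$tip.label)) {
    abort_validation(
      sprintf("duplicate leaf label '%s'",
              tree$tip.label[duplicated(tree$tip.label)][1]),
      path = path
    )
  }
  if (!ape::is.rooted(tree)) {
    message("tree has a basal multifurcation; treating it as rooted as written")
  }
  tree
}

#' Read repeat-mask intervals from a BED file
#'
#' BED coordinates are 0-based, half-open; they are kept in that convention
#' (`length = end - start`).  Overlapping intervals are kept as-is.
#'
#' @param path Path to a BED3+ file.
#' @param species Species code attached to every interval.
#' @return Data frame with columns `chromosome`, `start` (0-based), `end`,
#'   `species`, sorted within chromosome.
#' @export
read_repeat_bed <- function(path, species) {
  lr <- .read_lines_nonempty(path)
  keep <- !startsWith(lr$lines, "#") & !startsWith(lr$lines, "track")
  dat <- lr$lines[keep]; nums <- lr$numbers[keep]
  if (length(dat) == 0) {
    return(data.frame(chromosome = character(0), start = integer(0),
                      end = integer(0), species = character(0),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(dat, "[ \t]+")
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) < 3) {
      abort_validation("BED line with fewer than 3 columns", path = path,
                       line = nums[i])
    }
    s <- suppressWarnings(as.numeric(f[2])); e <- suppressWarnings(as.numeric(f[3]))
    if (is.na(s) || is.na(e)) {
      abort_validation("non-numeric BED coordinate", path = path, line = nums[i])
    }
    if (s < 0 || s >= e) {
      abort_validation(sprintf("invalid BED interval [%s, %s)", f[2], f[3]),
                       path = path, line = nums[i])
    }
  }
  gr <- rtracklayer::import(path, format = "bed")
  out <- data.frame(
    chromosome = as.character(GenomeInfoDb::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,  # back to BED 0-based
    end = BiocGenerics::end(gr),
    species = species, stringsAsFactors = FALSE
  )
  out <- out[order(out$chromosome, out$start, out$end), ]
  rownames(out) <- NULL
  out
}

## ---- writers: TSV with a '#'-prefixed header line -------------------------

.write_tsv <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(names(df), collapse = "\t")), con)
  if (nrow(df)) {
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Write gene records to the tabular gene dialect
#' @param genes Data frame as returned by [read_annotation()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_table <- function(genes, path) {
  .write_tsv(genes[, c("gene_id", "species", "chromosome", "strand",
                       "cds_start", "cds_end", "biotype")], path)
}

#' Write an ortholog table
#' @param pairs Data frame as returned by [read_ortholog_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ortholog_table <- function(pairs, path) {
  .write_tsv(pairs[, c("species_a", "gene_a", "species_b", "gene_b",
                       "confidence")], path)
}

#' Write homology hits in the minimal 3-column dialect
#' @param hits Data frame as returned by [read_homology_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_homology_table <- function(hits, path) {
  .write_tsv(hits[, c("query_id", "subject_id", "bitscore")], path)
}

#' Write an inter-CDS region table
#' @param regions Region data frame (see [build_neighbor_pairs()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_region_table <- function(regions, path) {
  .write_tsv(regions, path)
}

#' Read an inter-CDS region table written by [write_region_table()]
#' @param path Path to the TSV.
#' @return Region data frame with typed columns.
#' @export
read_region_table <- function(path) {
  df <- .read_tsv_dialect(path, c("species", "chromosome", "left_gene",
                                  "right_gene", "orientation", "length"))
  lines <- attr(df, "line_numbers")
  for (col in c("start", "end", "length")) {
    if (col %in% names(df)) df[[col]] <- .as_coord(df[[col]], col, path, lines)
  }
  for (col in c("tandem_flag", "repeat_flag")) {
    if (col %in% names(df)) df[[col]] <- as.logical(df[[col]])
  }
  attr(df, "line_numbers") <- NULL
  df
}
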