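#' Raw RNA-seq counts with gene lengths
#'
#' Constructs the raw-count container used by all expression tools.
#' Counts must be raw non-negative integers; normalized values live in a
#' distinct type ([normalize_tpm()]) so normalization cannot be applied
#' twice.
#'
#' @param counts integer matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids).
#' @param gene_length_bp named positive integer vector covering every
#'   gene in `counts`.
#' @return an object of class `"counts_table"` with elements `counts`
#'   and `gene_length_bp`.
#' @export
counts_table <- function(counts, gene_length_bp) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts matrix must have gene rownames and sample colnames")
  }
  if (anyDuplicated(rownames(counts))) {
    stop("duplicate gene id in counts: ",
         rownames(counts)[duplicated(rownames(counts))][1])
  }
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  storage.mode(counts) <- "integer"
  missing <- setdiff(rownames(counts), names(gene_length_bp))
  if (length(missing)) {
    stop("gene(s) missing from lengths: ", paste(head(missing, 5), collapse = ", "))
  }
  len <- as.integer(gene_length_bp[rownames(counts)])
  if (any(is.na(len)) || any(len <= 0L)) stop("gene lengths must be positive integers")
  structure(list(counts = counts, gene_length_bp = setNames(len, rownames(counts))),
            class = "counts_table")
}

#' @export
print.counts_table <- function(x, ...) {
  cat(sprintf("<counts_table> %d genes x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  invisible(x)
}

#' Read a count matrix and gene lengths from TSV
#'
#' The counts file has a header row of sample ids and gene ids in the
#' first column; the lengths file has columns `gene_id` and `length_bp`.
#'
#' @param path counts TSV.
#' @param lengths_path gene-length TSV.
#' @return a [counts_table].
#' @export
read_counts <- function(path, lengths_path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("counts TSV '", path, "' needs gene ids plus >= 1 sample")
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) {
    stop("counts TSV '", path, "': duplicate gene id '", ids[duplicated(ids)][1], "'")
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  suppressWarnings(storage.mode(m) <- "double")
  if (any(is.na(m)) || any(m != round(m))) stop("counts TSV '", path, "': non-integer cell")
  if (any(m < 0)) stop("counts TSV '", path, "': negative count")
  rownames(m) <- ids
  lens <- read.delim(lengths_path, stringsAsFactors = FALSE)
  names(lens)[1:2] <- c("gene_id", "length_bp")
  counts_table(m, setNames(lens$length_bp, lens$gene_id))
}

#' Read sample metadata
#'
#' TSV with columns `sample_id`, `organ`, `cultivar`, `skin_color`
#' (black/white/unknown), `stage`, `project`.
#'
#' @param path metadata TSV.
#' @return data frame, one row per sample.
#' @export
read_sample_metadata <- function(path) {
  md <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "organ", "cultivar", "skin_color", "stage", "project")
  miss <- setdiff(need, names(md))
  if (length(miss)) stop("metadata '", path, "': missing column(s) ", paste(miss, collapse = ", "))
  if (anyDuplicated(md$sample_id)) stop("metadata '", path, "': duplicate sample_id")
  bad <- !md$skin_color %in% c("black", "white", "unknown")
  if (any(bad)) stop("metadata '", path, "': invalid skin_color '", md$skin_color[bad][1], "'")
  md
}

#' Read per-gene liftover mapping statistics
#' @param path TSV with columns `gene_id`, `coverage`, `identity`
#'   (fractions in \[0, 1\]).
#' @return data frame.
#' @export
read_mapping_stats <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "coverage", "identity")
  if (!all(need %in% names(df))) stop("mapping stats '", path, "': need columns ", paste(need, collapse = ", "))
  df
}

#' Read a protein-hit table
#' @param path TSV with columns `gene_id`, `has_protein_hit` (0/1 or
#'   TRUE/FALSE). Genes absent from the table are treated as no-hit.
#' @return named logical vector.
#' @export
read_hit_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "has_protein_hit") %in% names(df))) {
    stop("hit table '", path, "': need columns gene_id, has_protein_hit")
  }
  setNames(as.logical(df$has_protein_hit), df$gene_id)
}

.SV_TYPES <- c("INS", "DEL", "INV", "TRA", "DUP")

#' Structural-variant records
#'
#' The on-disk dialect is a TSV with columns `chrom_a`, `start_a`,
#' `end_a`, `chrom_b`, `start_b`, `end_b`, `type`, 0-based half-open on
#' both haplotype sides. Unlike gene intervals, SV intervals may be
#' zero-width (`end == start`): the haplotype-2 anchor of a deletion and
#' the haplotype-1 anchor of an insertion are points. `size` is computed
#' as the larger of the two interval widths.
#'
#' @param path SV TSV.
#' @return data frame of typed records with a `size` column.
#' @export
read_sv_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom_a", "start_a", "end_a", "chrom_b", "start_b", "end_b", "type")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("SV TSV '", path, "': missing column(s) ", paste(miss, collapse = ", "))
  bad <- !df$type %in% .SV_TYPES
  if (any(bad)) {
    stop("SV TSV '", path, "': unknown SV type code '", df$type[bad][1],
         "' (expected one of ", paste(.SV_TYPES, collapse = "/"), ")")
  }
  if (any(df$end_a < df$start_a) || any(df$end_b < df$start_b)) {
    stop("SV TSV '", path, "': interval end < start")
  }
  df$size <- pmax(df$end_a - df$start_a, df$end_b - df$start_b)
  df
}

#' @rdname read_sv_tsv
#' @param svs SV data frame in the internal dialect.
#' @export
write_sv_tsv <- function(svs, path) {
  cols <- c("chrom_a", "start_a", "end_a", "chrom_b", "start_b", "end_b", "type")
  write.table(svs[, cols], path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert SyRI native output to the internal SV dialect
#'
#' Accepts SyRI's whole-genome-comparison table (columns: reference
#' chrom/start/end, query chrom/start/end, annotation type), keeps the
#' insertion/deletion/inversion/translocation/duplication records, maps
#' SyRI's 1-based inclusive coordinates to 0-based half-open, and drops
#' syntenic and SNP-level records.
#'
#' @param path SyRI TSV (no header; columns 1-3 reference interval, 6-8
#'   query interval, 11 annotation code).
#' @return SV data frame in the [read_sv_tsv()] dialect.
#' @export
read_syri <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 11L) stop("SyRI table '", path, "': expected >= 11 columns")
  map <- c(INS = "INS", DEL = "DEL", INV = "INV", TRANS = "TRA", INVTR = "TRA",
           DUP = "DUP", INVDP = "DUP")
  code <- df[[11]]
  keep <- code %in% names(map)
  df <- df[keep, , drop = FALSE]
  num <- function(x) suppressWarnings(as.numeric(x))
  out <- data.frame(
    chrom_a = df[[1]], start_a = num(df[[2]]) - 1, end_a = num(df[[3]]),
    chrom_b = df[[6]], start_b = num(df[[7]]) - 1, end_b = num(df[[8]]),
    type = unname(map[df[[11]]]), stringsAsFactors = FALSE
  )
  # SyRI encodes point anchors as start == end on the unaffected side
  out$end_a <- pmax(out$end_a, out$start_a)
  out$end_b <- pmax(out$end_b, out$start_b)
  out$size <- pmax(out$end_a - out$start_a, out$end_b - out$start_b)
  out
}

#' Read a genotype panel
#'
#' TSV with marker ids in the first column and one column per accession;
#' cells are alternate-allele dosages 0/1/2 or NA for missing.
#'
#' @param path panel TSV.
#' @return numeric matrix markers x accessions with NA for missing.
#' @export
read_genotype_panel <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  suppressWarnings(storage.mode(m) <- "double")
  rownames(m) <- as.character(df[[1]])
  ok <- is.na(m) | m %in% c(0, 1, 2)
  if (!all(ok)) stop("genotype panel '", path, "': dosages must be 0/1/2/NA")
  m
}

#' @rdname read_genotype_panel
#' @param panel dosage matrix (markers x accessions).
#' @export
write_genotype_panel <- function(panel, path) {
  df <- data.frame(marker_id = rownames(panel), panel, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read SNP-marker definitions
#'
#' TSV with columns `marker_id`, `left_flank`, `right_flank`,
#' `allele_ref`, `allele_alt` (single nucleotides, distinct).
#'
#' @param path marker TSV.
#' @return data frame of marker definitions.
#' @export
read_marker_defs <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("marker_id", "left_flank", "right_flank", "allele_ref", "allele_alt")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("marker TSV '", path, "': missing column(s) ", paste(miss, collapse = ", "))
  if (any(df$allele_ref == df$allele_alt)) stop("marker TSV '", path, "': alleles must be distinct")
  df
}
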