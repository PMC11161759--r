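#' Transcript and gene models
#'
#' Lightweight S3 containers for stranded exon/CDS structures. All
#' coordinates are 0-based half-open; GFF3 serialization converts to
#' 1-based inclusive at the file boundary.
#'
#' @param tx_id transcript identifier.
#' @param chrom chromosome / contig name.
#' @param strand `"+"` or `"-"` (gene features do not admit `"."`).
#' @param exons two-column matrix or data frame of `start`, `end`
#'   (0-based half-open). Must be non-overlapping; sorted on input is not
#'   required, they are sorted by start.
#' @param cds optional CDS intervals in the same convention; must lie
#'   within the exon union.
#' @return `transcript_model()` returns an object of class
#'   `"transcript_model"`; `gene_model()` an object of class `"gene_model"`.
#' @examples
#' tx <- transcript_model("t1", "chr1", "+", exons = cbind(100, 200))
#' g  <- gene_model("Vv01g00010", list(tx))
#' gene_span(g)
#' @export
transcript_model <- function(tx_id, chrom, strand, exons, cds = NULL) {
  stopifnot(is.character(tx_id), length(tx_id) == 1L, nzchar(tx_id))
  if (!strand %in% c("+", "-")) {
    stop("transcript '", tx_id, "': strand must be '+' or '-', got '", strand, "'")
  }
  exons <- .as_interval_df(exons, sprintf("transcript '%s' exons", tx_id))
  exons <- exons[order(exons$start), , drop = FALSE]
  if (nrow(exons) > 1L && any(exons$start[-1L] < exons$end[-nrow(exons)])) {
    stop("transcript '", tx_id, "': exons overlap")
  }
  if (!is.null(cds) && NROW(cds) > 0L) {
    cds <- .as_interval_df(cds, sprintf("transcript '%s' CDS", tx_id))
    cds <- cds[order(cds$start), , drop = FALSE]
    ex_ir <- IRanges::IRanges(exons$start + 1L, exons$end)
    cds_ir <- IRanges::IRanges(cds$start + 1L, cds$end)
    if (sum(IRanges::width(IRanges::intersect(cds_ir, ex_ir))) !=
        sum(IRanges::width(cds_ir))) {
      stop("transcript '", tx_id, "': CDS not contained in exon union")
    }
  } else {
    cds <- data.frame(start = integer(0), end = integer(0))
  }
  structure(
    list(tx_id = tx_id, chrom = chrom, strand = strand,
         exons = exons, cds = cds),
    class = "transcript_model"
  )
}

.as_interval_df <- function(x, what) {
  x <- as.data.frame(x)
  if (ncol(x) < 2L) stop(what, ": need start and end columns")
  names(x)[1:2] <- c("start", "end")
  x <- x[, c("start", "end")]
  x$start <- as.integer(x$start); x$end <- as.integer(x$end)
  if (any(is.na(x$start)) || any(is.na(x$end))) stop(what, ": non-integer coordinates")
  if (any(x$start < 0L)) stop(what, ": negative start")
  if (any(x$end <= x$start)) stop(what, ": end must be > start (0-based half-open)")
  rownames(x) <- NULL
  x
}

#' @rdname transcript_model
#' @param gene_id gene identifier (unique within an annotation set; the
#'   output naming scheme uses the "Vv" prefix).
#' @param transcripts list of `transcript_model` objects sharing one
#'   chromosome and strand.
#' @param biotype feature biotype, default `"protein_coding"`.
#' @export
gene_model <- function(gene_id, transcripts, biotype = "protein_coding") {
  stopifnot(is.character(gene_id), length(gene_id) == 1L, nzchar(gene_id))
  if (!is.list(transcripts) || length(transcripts) == 0L ||
      !all(vapply(transcripts, inherits, logical(1), "transcript_model"))) {
    stop("gene '", gene_id, "': transcripts must be a non-empty list of transcript_model")
  }
  chrom <- unique(vapply(transcripts, `[[`, character(1), "chrom"))
  strand <- unique(vapply(transcripts, `[[`, character(1), "strand"))
  if (length(chrom) != 1L || length(strand) != 1L) {
    stop("gene '", gene_id, "': transcripts must share one chrom and strand")
  }
  starts <- vapply(transcripts, function(t) min(t$exons$start), integer(1))
  ends <- vapply(transcripts, function(t) max(t$exons$end), integer(1))
  structure(
    list(gene_id = gene_id, chrom = chrom, strand = strand,
         start = min(starts), end = max(ends),
         biotype = biotype, transcripts = transcripts),
    class = "gene_model"
  )
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s %s:%d-%d(%s) %s, %d transcript(s)\n",
              x$gene_id, x$chrom, x$start, x$end, x$strand, x$biotype,
              length(x$transcripts)))
  invisible(x)
}

#' Gene span and exonic union
#'
#' `gene_span()` returns the locus interval; `exonic_ranges()` the reduced
#' union of all transcript exons as an [IRanges::IRanges] (1-based, as
#' IRanges requires internally; widths equal exonic base counts).
#'
#' @param gene a `gene_model`.
#' @return `gene_span()`: a one-row data frame `chrom,start,end,strand`
#'   (0-based half-open). `exonic_ranges()`: an `IRanges`.
#' @export
gene_span <- function(gene) {
  data.frame(chrom = gene$chrom, start = gene$start, end = gene$end,
             strand = gene$strand, stringsAsFactors = FALSE)
}

#' @rdname gene_span
#' @export
exonic_ranges <- function(gene) {
  ex <- do.call(rbind, lapply(gene$transcripts, `[[`, "exons"))
  IRanges::reduce(IRanges::IRanges(ex$start + 1L, ex$end))
}

#' Exonic length of a gene in bases
#' @param gene a `gene_model`.
#' @return integer number of exonic bases (union over transcripts).
#' @export
exonic_length <- function(gene) sum(IRanges::width(exonic_ranges(gene)))

# ids of an annotation set (named or unnamed list of gene_model)
.gene_ids <- function(genes) vapply(genes, `[[`, character(1), "gene_id")

.check_unique_ids <- function(genes, label) {
  ids <- .gene_ids(genes)
  if (anyDuplicated(ids)) {
    stop("duplicate gene ids in ", label, " set: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  ids
}
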