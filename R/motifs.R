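.IUPAC <- c(A = "A", C = "C", G = "G", T = "T",
            R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
            B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT")

.check_iupac <- function(consensus, motif_id) {
  chars <- strsplit(toupper(consensus), "")[[1]]
  bad <- setdiff(chars, names(.IUPAC))
  if (length(bad)) {
    stop("motif '", motif_id, "': invalid IUPAC character(s) ",
         paste(unique(bad), collapse = ", "))
  }
  if (length(chars) == 0L) stop("motif '", motif_id, "': empty consensus")
  invisible(TRUE)
}

#' Extract the promoter window of a gene
#'
#' Returns the `window` bases immediately 5' of the transcription start
#' site: the upstream flank for `+` strand genes, the reverse complement
#' of the downstream flank for `-` strand genes, so position 0 of the
#' result is the window start and the TSS-proximal base is last. Windows
#' running off the contig edge are truncated with a warning.
#'
#' @param gene a [gene_model].
#' @param genome a [Biostrings::DNAStringSet].
#' @param window promoter length in bp (default 2000).
#' @return promoter sequence as a character string.
#' @export
extract_promoter <- function(gene, genome, window = 2000L) {
  if (!gene$chrom %in% names(genome)) {
    stop("chromosome '", gene$chrom, "' absent from genome")
  }
  chrseq <- as.character(genome[[gene$chrom]])
  clen <- nchar(chrseq)
  if (gene$strand == "+") {
    s0 <- gene$start - window
    if (s0 < 0L) {
      warning("promoter of '", gene$gene_id, "' truncated to ", gene$start,
              " bp at the contig edge")
      s0 <- 0L
    }
    .gsub_seq(chrseq, s0, gene$start)
  } else {
    e0 <- gene$end + window
    if (e0 > clen) {
      warning("promoter of '", gene$gene_id, "' truncated to ", clen - gene$end,
              " bp at the contig edge")
      e0 <- clen
    }
    .revcomp_chr(.gsub_seq(chrseq, gene$end, e0))
  }
}

#' Scan a promoter for IUPAC consensus motifs
#'
#' Reports every position, on both strands, where a degenerate IUPAC
#' consensus matches exactly (each code matching its degenerate base
#' set; matching uses [Biostrings::matchPattern()] with `fixed = FALSE`,
#' under which an `N` in the subject matches any pattern letter).
#' A hit's offset is the position of its first base relative to the TSS
#' (TSS at 0, upstream negative): in a window of length W a hit starting
#' at the 5' end has offset -W and a hit of length L ending at the TSS
#' has offset -L. Minus-strand hits report the offset of their
#' plus-strand footprint. Hits are sorted by offset, then strand, then
#' motif id.
#'
#' @param promoter promoter sequence (character, as returned by
#'   [extract_promoter()]).
#' @param patterns data frame with columns `motif_id`, `consensus`.
#' @return data frame with columns `motif_id`, `offset`, `strand`,
#'   `matched_seq` (always the plus-strand promoter substring).
#' @export
scan_motifs <- function(promoter, patterns) {
  W <- nchar(promoter)
  subj <- Biostrings::DNAString(toupper(promoter))
  rows <- list()
  for (i in seq_len(nrow(patterns))) {
    mid <- patterns$motif_id[i]
    consensus <- toupper(patterns$consensus[i])
    .check_iupac(consensus, mid)
    L <- nchar(consensus)
    if (L > W) next
    pat <- Biostrings::DNAString(consensus)
    for (strand in c("+", "-")) {
      p <- if (strand == "+") pat else Biostrings::reverseComplement(pat)
      hits <- Biostrings::matchPattern(p, subj, fixed = FALSE)
      if (length(hits) == 0L) next
      st <- Biostrings::start(hits)
      rows[[length(rows) + 1L]] <- data.frame(
        motif_id = mid, offset = st - 1L - W, strand = strand,
        matched_seq = substring(promoter, st, st + L - 1L),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(motif_id = character(0), offset = integer(0),
               strand = character(0), matched_seq = character(0))
  out <- out[order(out$offset, out$strand, out$motif_id, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scan gene promoters genome-wide
#'
#' Extracts each gene's promoter window and scans it for the given
#' motifs; a convenience wrapper combining [extract_promoter()] and
#' [scan_motifs()].
#'
#' @param genes named list of [gene_model].
#' @param genome a [Biostrings::DNAStringSet].
#' @param patterns motif data frame (`motif_id`, `consensus`).
#' @param window promoter window in bp.
#' @return data frame with a leading `gene_id` column.
#' @export
scan_gene_promoters <- function(genes, genome, patterns, window = 2000L) {
  out <- lapply(genes, function(g) {
    hits <- scan_motifs(extract_promoter(g, genome, window = window), patterns)
    if (nrow(hits)) cbind(gene_id = g$gene_id, hits, stringsAsFactors = FALSE) else NULL
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) {
    return(data.frame(gene_id = character(0), motif_id = character(0),
                      offset = integer(0), strand = character(0),
                      matched_seq = character(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Bundled Myb-family consensus motifs
#'
#' A small curated default set of Myb-binding-site consensus strings
#' (MBS core and AC-element variants commonly used for R2R3-Myb target
#' scans), shipped as plain text under `extdata/myb_motifs.tsv`. They
#' are defaults only and can be replaced by any user pattern table.
#'
#' @return data frame with columns `motif_id`, `consensus`.
#' @export
myb_motifs <- function() {
  path <- system.file("extdata", "myb_motifs.tsv", package = "vinekit",
                      mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE)
}
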