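# exons of a transcript in transcription order (5' -> 3')
.tx_exons_5to3 <- function(tx) {
  ex <- tx$exons
  if (tx$strand == "+") ex[order(ex$start), , drop = FALSE]
  else ex[order(-ex$start), , drop = FALSE]
}

.revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# 0-based half-open substring of a chromosome
.gsub_seq <- function(chrseq, start0, end0) substr(chrseq, start0 + 1L, end0)

# spliced 1-based position of a genomic base (0-based position p0) in a
# transcript; exons must be in transcription order
.spliced_pos <- function(exons53, strand, p0) {
  cum <- 0L
  for (i in seq_len(nrow(exons53))) {
    s <- exons53$start[i]; e <- exons53$end[i]
    if (p0 >= s && p0 < e) {
      off <- if (strand == "+") p0 - s + 1L else e - p0
      return(cum + off)
    }
    cum <- cum + (e - s)
  }
  stop("position not exonic")
}

#' Nonsense-mediated-decay flag
#'
#' Flags a transcript whose stop codon lies more than `nmd_rule_nt`
#' spliced nucleotides upstream of the final exon-exon junction (the
#' canonical 50-nt rule): such premature stop codons mark the transcript
#' as a likely decay target. Single-exon transcripts are never flagged.
#' A CDS whose length is not a multiple of 3 is an error; a CDS whose
#' final codon is not a stop is returned as `FALSE` with attribute
#' `invalid = TRUE` (an invalid model, not an NMD candidate).
#'
#' @param tx a [transcript_model] with a CDS.
#' @param genome a [Biostrings::DNAStringSet] covering the locus.
#' @param cfg a [reconcile_config()].
#' @return logical scalar (possibly with attribute `invalid`).
#' @export
nmd_flag <- function(tx, genome, cfg = reconcile_config()) {
  if (nrow(tx$cds) == 0L) stop("transcript '", tx$tx_id, "' has no CDS")
  if (!tx$chrom %in% names(genome)) stop("chromosome '", tx$chrom, "' absent from genome")
  cds_len <- sum(tx$cds$end - tx$cds$start)
  if (cds_len %% 3L != 0L) {
    stop("transcript '", tx$tx_id, "': CDS length ", cds_len, " is not a multiple of 3")
  }
  if (nrow(tx$exons) < 2L) return(FALSE)
  chrseq <- as.character(genome[[tx$chrom]])
  cds <- tx$cds[order(tx$cds$start), , drop = FALSE]
  pieces <- vapply(seq_len(nrow(cds)), function(i) {
    .gsub_seq(chrseq, cds$start[i], cds$end[i])
  }, character(1))
  cds_seq <- paste(pieces, collapse = "")
  if (tx$strand == "-") cds_seq <- .revcomp_chr(cds_seq)
  last_codon <- substr(cds_seq, cds_len - 2L, cds_len)
  if (!last_codon %in% c("TAA", "TAG", "TGA")) {
    return(structure(FALSE, invalid = TRUE))
  }
  ex53 <- .tx_exons_5to3(tx)
  widths <- ex53$end - ex53$start
  junction_pos <- sum(widths) - widths[length(widths)]
  stop_p0 <- if (tx$strand == "+") max(cds$end) - 1L else min(cds$start)
  stop_pos <- .spliced_pos(ex53, tx$strand, stop_p0)
  (junction_pos - stop_pos) > cfg$nmd_rule_nt
}

#' Reverse-transcriptase template-switch flag
#'
#' Detects the direct-repeat signature of RT template switching: for any
#' intron, the k-mer ending at the 5' exon/intron boundary (exonic side)
#' equals the k-mer ending at the intron/3'-exon boundary (intronic
#' side), with `k = rtswitch_repeat_len`. Both k-mers are taken in
#' transcription orientation, so the test is strand-aware. Boundaries
#' whose exon or intron is shorter than `k` are skipped.
#'
#' @param tx a [transcript_model] with at least 2 exons.
#' @param genome a [Biostrings::DNAStringSet].
#' @param cfg a [reconcile_config()].
#' @return logical scalar.
#' @export
rtswitch_flag <- function(tx, genome, cfg = reconcile_config()) {
  if (nrow(tx$exons) < 2L) stop("transcript '", tx$tx_id, "' has fewer than 2 exons")
  if (!tx$chrom %in% names(genome)) stop("chromosome '", tx$chrom, "' absent from genome")
  k <- cfg$rtswitch_repeat_len
  chrseq <- as.character(genome[[tx$chrom]])
  ex <- .tx_exons_5to3(tx)
  for (i in seq_len(nrow(ex) - 1L)) {
    if (tx$strand == "+") {
      donor_end <- ex$end[i]          # 5' exon/intron boundary
      acceptor_start <- ex$start[i + 1L]
      if (donor_end - ex$start[i] < k) next
      if (acceptor_start - donor_end < k) next
      exonic <- .gsub_seq(chrseq, donor_end - k, donor_end)
      intronic <- .gsub_seq(chrseq, acceptor_start - k, acceptor_start)
    } else {
      donor_start <- ex$start[i]      # genomic left edge of the 5' exon
      acceptor_end <- ex$end[i + 1L]  # genomic right edge of the 3' exon
      if (ex$end[i] - donor_start < k) next
      if (donor_start - acceptor_end < k) next
      exonic <- .revcomp_chr(.gsub_seq(chrseq, donor_start, donor_start + k))
      intronic <- .revcomp_chr(.gsub_seq(chrseq, acceptor_end, acceptor_end + k))
    }
    if (exonic == intronic) return(TRUE)
  }
  FALSE
}

#' Run the full reconciliation pipeline
#'
#' Applies, in order: the liftover acceptance filter (to genes present
#' in `stats` only - genes with no mapping record are treated as native,
#' transcript-sequencing-derived models and pass through), the
#' NMD / RT-switch / invalid-CDS transcript filters (a gene is dropped
#' when no transcript survives), the pseudogene filter, the
#' expression-support filter, and finally [classify_genes()] on the
#' survivors. Stages whose inputs are `NULL` are skipped, so the
#' classification can be run with all filters off.
#'
#' @param query,reference named lists of [gene_model] on one assembly.
#' @param stats liftover mapping statistics (see [read_mapping_stats()])
#'   or `NULL` to skip.
#' @param counts a [counts_table] or `NULL` to skip.
#' @param hits named logical protein-hit vector or `NULL` to skip.
#' @param genome a [Biostrings::DNAStringSet] or `NULL` to skip the
#'   transcript filters.
#' @param cfg a [reconcile_config()].
#' @return list with `report` (a `reconcile_report`), `retained` (the
#'   surviving query gene models) and `funnel` (named counts after each
#'   stage).
#' @export
reconcile_pipeline <- function(query, reference, stats = NULL, counts = NULL,
                               hits = NULL, genome = NULL,
                               cfg = reconcile_config()) {
  .check_unique_ids(query, "query")
  funnel <- c(input = length(query))
  keep <- query

  if (!is.null(stats)) {
    part <- acceptance_filter(stats, cfg)
    drop <- part$rejected
    keep <- keep[!.gene_ids(keep) %in% drop]
    funnel <- c(funnel, liftover_accepted = length(keep))
  }

  if (!is.null(genome)) {
    keep <- lapply(keep, function(g) {
      txs <- Filter(function(tx) {
        if (nrow(tx$cds)) {
          f <- nmd_flag(tx, genome, cfg)
          if (isTRUE(attr(f, "invalid")) || isTRUE(f)) return(FALSE)
        }
        if (nrow(tx$exons) >= 2L && rtswitch_flag(tx, genome, cfg)) return(FALSE)
        TRUE
      }, g$transcripts)
      if (length(txs) == 0L) return(NULL)
      gene_model(g$gene_id, txs, biotype = g$biotype)
    })
    keep <- keep[!vapply(keep, is.null, logical(1))]
    funnel <- c(funnel, transcript_filters = length(keep))
  }

  if (!is.null(hits)) {
    part <- pseudogene_filter(.gene_ids(keep), hits)
    keep <- keep[.gene_ids(keep) %in% part$coding]
    funnel <- c(funnel, protein_hit = length(keep))
  }

  if (!is.null(counts)) {
    part <- expression_support_filter(.gene_ids(keep), counts, cfg)
    keep <- keep[.gene_ids(keep) %in% part$supported]
    funnel <- c(funnel, expression_supported = length(keep))
  }

  report <- if (length(keep)) {
    classify_genes(keep, reference, cfg)
  } else {
    structure(list(per_gene = data.frame(gene_id = character(0), class = character(0),
                                         counterparts = character(0)),
                   split_reference = data.frame(ref_gene_id = character(0),
                                                members = character(0)),
                   summary = c(total = 0L, novel = 0L, covered = 0L, fused = 0L,
                               split = 0L, split_member = 0L, ambiguous = 0L)),
              class = "reconcile_report")
  }
  list(report = report, retained = keep, funnel = funnel)
}
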