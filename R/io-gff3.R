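#' Read a GFF3 annotation into gene models
#'
#' Parses a GFF3 file whose gene/mRNA/exon/CDS features are linked by
#' standard `ID`/`Parent` attributes and converts the 1-based inclusive
#' file coordinates to the internal 0-based half-open convention.
#' Orphan features (an mRNA whose `Parent` is not a gene `ID`, or an
#' exon/CDS whose `Parent` is not an mRNA `ID`) are rejected with an
#' error naming the offending feature. Models are returned in
#' deterministic (chrom, start, gene_id) order, so reading the same file
#' twice yields identical structures.
#'
#' @param path path to a GFF3 file.
#' @return named list of [gene_model] objects.
#' @seealso [write_gff3()]
#' @export
read_gff3 <- function(path) {
  gr <- tryCatch(
    rtracklayer::import(path, format = "gff3"),
    error = function(e) stop("failed to parse GFF3 '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(gr) == 0L) return(structure(list(), names = character(0)))
  type <- as.character(gr$type)
  id <- if ("ID" %in% names(S4Vectors::mcols(gr))) as.character(gr$ID) else rep(NA_character_, length(gr))
  parent <- if ("Parent" %in% names(S4Vectors::mcols(gr))) gr$Parent else S4Vectors::split(character(0), factor(integer(0)))

  first_parent <- function(i) {
    p <- tryCatch(as.character(parent[[i]]), error = function(e) character(0))
    if (length(p) == 0L) NA_character_ else p
  }

  is_gene <- type == "gene"
  is_tx <- type %in% c("mRNA", "transcript")
  is_exon <- type == "exon"
  is_cds <- type == "CDS"
  gene_idx <- which(is_gene)
  gene_ids <- id[gene_idx]
  if (any(is.na(gene_ids))) stop("GFF3 '", path, "': gene feature without ID attribute")
  names(gene_idx) <- gene_ids

  tx_idx <- which(is_tx)
  tx_ids <- id[tx_idx]
  if (any(is.na(tx_ids))) stop("GFF3 '", path, "': mRNA feature without ID attribute")
  tx_parent <- character(length(tx_idx))
  for (k in seq_along(tx_idx)) {
    p <- first_parent(tx_idx[k])
    bad <- is.na(p[1]) | !(p %in% gene_ids)
    if (any(bad)) {
      stop("GFF3 '", path, "': mRNA '", tx_ids[k],
           "' has Parent '", paste(p, collapse = ","),
           "' which is not a gene ID (orphan feature)")
    }
    tx_parent[k] <- p[1]
  }
  names(tx_parent) <- tx_ids

  # collect exon/CDS children per transcript
  ex_by_tx <- new.env(parent = emptyenv())
  cds_by_tx <- new.env(parent = emptyenv())
  for (i in which(is_exon | is_cds)) {
    p <- first_parent(i)
    if (any(is.na(p)) || !all(p %in% tx_ids)) {
      stop("GFF3 '", path, "': ", type[i], " at ",
           as.character(GenomicRanges::seqnames(gr)[i]), ":",
           GenomicRanges::start(gr)[i], "-", GenomicRanges::end(gr)[i],
           " has Parent '", paste(p, collapse = ","),
           "' which is not an mRNA ID (orphan feature)")
    }
    iv <- c(GenomicRanges::start(gr)[i] - 1L, GenomicRanges::end(gr)[i])
    env <- if (is_exon[i]) ex_by_tx else cds_by_tx
    for (pp in p) assign(pp, rbind(get0(pp, env), iv), envir = env)
  }

  biotype_col <- intersect(c("biotype", "gene_biotype"), names(S4Vectors::mcols(gr)))
  genes <- vector("list", length(gene_idx))
  for (k in seq_along(gene_idx)) {
    gid <- gene_ids[k]
    i <- gene_idx[k]
    strand <- as.character(GenomicRanges::strand(gr)[i])
    if (!strand %in% c("+", "-")) {
      stop("GFF3 '", path, "': gene '", gid, "' has strand '", strand,
           "'; gene features require + or -")
    }
    my_tx <- tx_ids[tx_parent == gid]
    if (length(my_tx) == 0L) stop("GFF3 '", path, "': gene '", gid, "' has no mRNA children")
    txs <- lapply(sort(my_tx), function(tid) {
      ex <- get0(tid, ex_by_tx)
      if (is.null(ex)) stop("GFF3 '", path, "': mRNA '", tid, "' has no exons")
      transcript_model(tid, as.character(GenomicRanges::seqnames(gr)[i]),
                       strand, ex, cds = get0(tid, cds_by_tx))
    })
    bt <- "protein_coding"
    if (length(biotype_col)) {
      v <- S4Vectors::mcols(gr)[[biotype_col[1]]][i]
      if (!is.na(v)) bt <- as.character(v)
    }
    genes[[k]] <- gene_model(gid, txs, biotype = bt)
  }
  names(genes) <- gene_ids
  ord <- order(vapply(genes, `[[`, character(1), "chrom"),
               vapply(genes, `[[`, integer(1), "start"),
               gene_ids, method = "radix")
  genes[ord]
}

#' Write gene models to GFF3
#'
#' Serializes models to 1-based inclusive GFF3 with a
#' gene -> mRNA -> exon/CDS hierarchy, sorted by (chrom, start, gene_id).
#' CDS phase is computed in transcription order. The writer is
#' deterministic: writing the same models twice yields byte-identical
#' files, and a read/write/read round trip preserves the models.
#'
#' @param models list of [gene_model] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(models, path) {
  lines <- "##gff-version 3"
  if (length(models)) {
    ids <- .gene_ids(models)
    ord <- order(vapply(models, `[[`, character(1), "chrom"),
                 vapply(models, `[[`, integer(1), "start"),
                 ids, method = "radix")
    models <- models[ord]
    fmt <- function(chrom, type, s0, e0, strand, phase, attrs) {
      sprintf("%s\tvinekit\t%s\t%d\t%d\t.\t%s\t%s\t%s",
              chrom, type, s0 + 1L, e0, strand, phase, attrs)
    }
    for (g in models) {
      lines <- c(lines, fmt(g$chrom, "gene", g$start, g$end, g$strand, ".",
                            sprintf("ID=%s;biotype=%s", g$gene_id, g$biotype)))
      for (tx in g$transcripts) {
        lines <- c(lines, fmt(g$chrom, "mRNA", min(tx$exons$start),
                              max(tx$exons$end), g$strand, ".",
                              sprintf("ID=%s;Parent=%s", tx$tx_id, g$gene_id)))
        for (j in seq_len(nrow(tx$exons))) {
          lines <- c(lines, fmt(g$chrom, "exon", tx$exons$start[j],
                                tx$exons$end[j], g$strand, ".",
                                sprintf("Parent=%s", tx$tx_id)))
        }
        if (nrow(tx$cds)) {
          cds <- tx$cds
          tx_order <- if (g$strand == "+") order(cds$start) else order(-cds$start)
          widths <- (cds$end - cds$start)[tx_order]
          phase <- integer(length(widths))
          cum <- 0L
          for (q in seq_along(widths)) {
            phase[q] <- (3L - (cum %% 3L)) %% 3L
            cum <- cum + widths[q]
          }
          for (q in seq_along(tx_order)) {
            j <- tx_order[q]
            lines <- c(lines, fmt(g$chrom, "CDS", cds$start[j], cds$end[j],
                                  g$strand, as.character(phase[q]),
                                  sprintf("Parent=%s", tx$tx_id)))
          }
        }
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}
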