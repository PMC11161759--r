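# builders and independent oracles used across the suite

single_exon_gene <- function(id, start, end, strand = "+", chrom = "chr1") {
  gene_model(id, list(transcript_model(paste0(id, ".1"), chrom, strand,
                                       cbind(start, end))))
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

dna_set <- function(...) Biostrings::DNAStringSet(c(...))

revcomp <- function(x) as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

# plant a string inside a random background at a 0-based position
plant <- function(background, at0, what) {
  paste0(substr(background, 1, at0), what,
         substr(background, at0 + nchar(what) + 1, nchar(background)))
}

# ---- brute-force per-base classification oracle -------------------------
# Independent of classify_genes(): exonic overlaps are enumerated base by
# base over logical masks, and the class rules are re-stated in
# straight-line code.

oracle_exonic_mask <- function(gene, glen) {
  m <- logical(glen)
  for (tx in gene$transcripts) {
    for (i in seq_len(nrow(tx$exons))) {
      m[(tx$exons$start[i] + 1):tx$exons$end[i]] <- TRUE
    }
  }
  m
}

oracle_classify <- function(query, reference, glen,
                            covered_frac = 0.8, member_frac = 0.5) {
  qm <- lapply(query, oracle_exonic_mask, glen = glen)
  rm_ <- lapply(reference, oracle_exonic_mask, glen = glen)
  qs <- vapply(query, `[[`, character(1), "strand")
  rs <- vapply(reference, `[[`, character(1), "strand")
  nq <- length(query); nr <- length(reference)
  bp <- matrix(0L, nq, nr)
  for (i in seq_len(nq)) {
    for (j in seq_len(nr)) {
      if (qs[i] == rs[j]) bp[i, j] <- sum(qm[[i]] & rm_[[j]])
    }
  }
  qlen <- vapply(qm, sum, integer(1)); rlen <- vapply(rm_, sum, integer(1))
  frac_q <- bp / qlen
  frac_r <- sweep(bp, 2, rlen, "/")
  qids <- vapply(query, `[[`, character(1), "gene_id")
  rids <- vapply(reference, `[[`, character(1), "gene_id")

  # split reference genes: >= 2 query members each covering member_frac
  split_refs <- which(colSums(frac_r >= member_frac & bp > 0) >= 2)
  split_members <- which(apply(
    (frac_r >= member_frac & bp > 0)[, split_refs, drop = FALSE], 1, any))

  best_ref <- function(i) {
    js <- which(bp[i, ] > 0)
    if (!length(js)) return(NA_integer_)
    js[order(-bp[i, js], rids[js], method = "radix")][1]
  }
  best_query <- function(j) {
    is <- which(bp[, j] > 0)
    if (!length(is)) return(NA_integer_)
    is[order(-bp[is, j], qids[is], method = "radix")][1]
  }
  cls <- character(nq)
  for (i in seq_len(nq)) {
    if (all(bp[i, ] == 0)) { cls[i] <- "novel"; next }
    if (sum(frac_r[i, ] >= member_frac & bp[i, ] > 0) >= 2) { cls[i] <- "fused"; next }
    j <- best_ref(i)
    if (!is.na(j) && best_query(j) == i &&
        frac_q[i, j] >= covered_frac && frac_r[i, j] >= covered_frac) {
      cls[i] <- "covered"; next
    }
    cls[i] <- if (i %in% split_members) "split_member" else "ambiguous"
  }
  list(class = setNames(cls, qids), split_refs = rids[split_refs])
}

# ---- sliding-window IUPAC motif oracle ----------------------------------

IUPAC_SETS <- list(A = "A", C = "C", G = "G", T = "T",
                   R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                   W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                   B = c("C", "G", "T"), D = c("A", "G", "T"),
                   H = c("A", "C", "T"), V = c("A", "C", "G"),
                   N = c("A", "C", "G", "T"))

oracle_scan <- function(promoter, consensus, motif_id = "m") {
  W <- nchar(promoter); L <- nchar(consensus)
  s_chars <- strsplit(promoter, "")[[1]]
  rows <- list()
  for (strand in c("+", "-")) {
    pat <- if (strand == "+") consensus else revcomp(consensus)
    pat_chars <- strsplit(pat, "")[[1]]
    ok <- rep(TRUE, W - L + 1)
    for (k in seq_len(L)) {            # slide the window one column at a time
      ok <- ok & s_chars[k:(W - L + k)] %in% IUPAC_SETS[[pat_chars[k]]]
    }
    for (p in which(ok)) {
      rows[[length(rows) + 1]] <- data.frame(
        motif_id = motif_id, offset = p - 1L - W, strand = strand,
        matched_seq = substr(promoter, p, p + L - 1),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(motif_id = character(0), offset = integer(0),
               strand = character(0), matched_seq = character(0))
  out[order(out$offset, out$strand, out$motif_id, method = "radix"), , drop = FALSE]
}
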