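#' Reconciliation configuration
#'
#' Thresholds for the multistep annotation-reconciliation procedure.
#' The liftover acceptance thresholds default to the 80% coverage and
#' identity rule, with closed (`>=`) boundaries. The remaining defaults
#' are package choices: a reciprocal 0.80 exonic-overlap fraction
#' declares a query gene "covered"; members of a fusion/split must cover
#' at least half of the reference gene; expression support means a raw
#' count of at least 5 in at least 2 samples; the nonsense-mediated-decay
#' rule uses the canonical 50-nt junction distance; the RT-switch
#' signature is an 8-bp direct repeat at intron boundaries.
#'
#' @param min_coverage,min_identity liftover acceptance fractions.
#' @param covered_reciprocal_fraction reciprocal exonic-overlap fraction
#'   for the "covered" class.
#' @param fusion_member_fraction minimum fraction of a reference gene
#'   covered by each member of a fusion (or each query member of a split).
#' @param min_support_count,min_support_samples expression-support rule.
#' @param nmd_rule_nt premature-stop distance from the last exon-exon
#'   junction, in spliced-transcript nucleotides.
#' @param rtswitch_repeat_len direct-repeat length for the RT-switch flag.
#' @return a list of class `"reconcile_config"`.
#' @export
reconcile_config <- function(min_coverage = 0.80, min_identity = 0.80,
                             covered_reciprocal_fraction = 0.80,
                             fusion_member_fraction = 0.50,
                             min_support_count = 5L, min_support_samples = 2L,
                             nmd_rule_nt = 50L, rtswitch_repeat_len = 8L) {
  fr <- c(min_coverage, min_identity, covered_reciprocal_fraction, fusion_member_fraction)
  if (any(fr <= 0) || any(fr > 1)) stop("fractions must lie in (0, 1]")
  ints <- c(min_support_count, min_support_samples, nmd_rule_nt, rtswitch_repeat_len)
  if (any(ints < 1)) stop("integer thresholds must be >= 1")
  structure(list(min_coverage = min_coverage, min_identity = min_identity,
                 covered_reciprocal_fraction = covered_reciprocal_fraction,
                 fusion_member_fraction = fusion_member_fraction,
                 min_support_count = as.integer(min_support_count),
                 min_support_samples = as.integer(min_support_samples),
                 nmd_rule_nt = as.integer(nmd_rule_nt),
                 rtswitch_repeat_len = as.integer(rtswitch_repeat_len)),
            class = "reconcile_config")
}

#' Liftover acceptance filter
#'
#' Partitions lifted genes by the acceptance rule: accepted iff
#' `coverage >= min_coverage` and `identity >= min_identity` (closed
#' boundaries, default 0.80/0.80).
#'
#' @param stats data frame with columns `gene_id`, `coverage`,
#'   `identity` (fractions in \[0, 1\]), one row per lifted gene.
#' @param cfg a [reconcile_config()].
#' @return list with character vectors `accepted` and `rejected`; the
#'   two are disjoint and exhaust the input gene ids.
#' @export
acceptance_filter <- function(stats, cfg = reconcile_config()) {
  if (any(stats$coverage < 0 | stats$coverage > 1 |
          stats$identity < 0 | stats$identity > 1, na.rm = FALSE)) {
    stop("coverage/identity fractions must lie in [0, 1]")
  }
  ok <- stats$coverage >= cfg$min_coverage & stats$identity >= cfg$min_identity
  list(accepted = stats$gene_id[ok], rejected = stats$gene_id[!ok])
}

#' Exonic overlap fractions between two genes
#'
#' Computes the shared exonic bases between two genes (union of
#' transcript exons each) as a fraction of each gene's exonic length.
#' Genes on different chromosomes or strands share nothing.
#'
#' @param a,b [gene_model] objects.
#' @return numeric vector `c(frac_a, frac_b)`.
#' @export
exonic_overlap_fraction <- function(a, b) {
  if (a$chrom != b$chrom || a$strand != b$strand) return(c(0, 0))
  ia <- exonic_ranges(a); ib <- exonic_ranges(b)
  ov <- sum(IRanges::width(IRanges::intersect(ia, ib)))
  c(ov / sum(IRanges::width(ia)), ov / sum(IRanges::width(ib)))
}

# pairwise exonic overlaps between two annotation sets; returns a data
# frame (qi, ri, bp) of same-strand overlaps > 0, computed via a single
# findOverlaps over the reduced exon unions
.overlap_table <- function(query, reference) {
  flat <- function(genes) {
    if (!length(genes)) {
      return(GenomicRanges::GRanges(seqnames = character(0),
                                    ranges = IRanges::IRanges(),
                                    strand = character(0), gene = integer(0)))
    }
    parts <- lapply(seq_along(genes), function(i) {
      g <- genes[[i]]
      ir <- exonic_ranges(g)
      GenomicRanges::GRanges(g$chrom, ir, strand = g$strand,
                             gene = rep(i, length(ir)))
    })
    do.call(c, parts)
  }
  gq <- flat(query); gr <- flat(reference)
  hits <- GenomicRanges::findOverlaps(gq, gr, ignore.strand = FALSE)
  if (!length(hits)) return(data.frame(qi = integer(0), ri = integer(0), bp = integer(0)))
  p <- IRanges::pintersect(gq[S4Vectors::queryHits(hits)],
                           gr[S4Vectors::subjectHits(hits)])
  df <- data.frame(qi = gq$gene[S4Vectors::queryHits(hits)],
                   ri = gr$gene[S4Vectors::subjectHits(hits)],
                   bp = GenomicRanges::width(p))
  agg <- stats::aggregate(bp ~ qi + ri, data = df, FUN = sum)
  agg[agg$bp > 0, , drop = FALSE]
}

#' Classify query genes against a reference annotation
#'
#' Assigns each query gene exactly one class from
#' novel / fused / covered / split_member / ambiguous, based on
#' same-strand exonic overlap:
#' * **novel** — no exonic overlap with any reference gene;
#' * **fused** — at least two reference genes each have at least
#'   `fusion_member_fraction` of their exonic bases covered by the query
#'   gene (one query gene standing for a fusion of two or more);
#' * **covered** — a unique reciprocal best partner with both overlap
#'   fractions at least `covered_reciprocal_fraction`;
#' * **split_member** — the query gene is one of >= 2 query genes that
#'   each cover at least `fusion_member_fraction` of one reference gene
#'   (that reference gene is reported as split);
#' * **ambiguous** — anything else.
#'
#' Best partners are ranked by overlap bases, ties broken by gene id, so
#' the classification is deterministic. The summary counts novel,
#' covered and fused on query genes and split on reference genes,
#' matching the direction each is defined in.
#'
#' @param query,reference named lists of [gene_model] on one assembly.
#' @param cfg a [reconcile_config()].
#' @return list of class `"reconcile_report"` with elements
#'   `per_gene` (data frame: gene_id, class, counterparts),
#'   `split_reference` (data frame: ref_gene_id, members) and
#'   `summary` (named counts).
#' @export
classify_genes <- function(query, reference, cfg = reconcile_config()) {
  qids <- .check_unique_ids(query, "query")
  rids <- .check_unique_ids(reference, "reference")
  ov <- .overlap_table(query, reference)
  qlen <- vapply(query, exonic_length, numeric(1))
  rlen <- vapply(reference, exonic_length, numeric(1))
  ov$frac_q <- ov$bp / qlen[ov$qi]   # fraction of the query gene covered
  ov$frac_r <- ov$bp / rlen[ov$ri]   # fraction of the reference gene covered

  cls <- rep("ambiguous", length(query))
  counterparts <- rep("", length(query))

  # split: reference genes with >= 2 query members each covering
  # fusion_member_fraction of the reference
  split_rows <- ov[ov$frac_r >= cfg$fusion_member_fraction, , drop = FALSE]
  split_tab <- split(split_rows$qi, split_rows$ri)
  split_tab <- split_tab[vapply(split_tab, length, integer(1)) >= 2L]
  split_ref_idx <- as.integer(names(split_tab))
  split_members_idx <- sort(unique(unlist(split_tab, use.names = FALSE)))

  # best reference partner per query gene and vice versa (bp desc, id asc)
  best_of <- function(rows, key, other, other_ids) {
    out <- integer(0)
    if (nrow(rows)) {
      ord <- order(rows[[key]], -rows$bp, other_ids[rows[[other]]], method = "radix")
      rows <- rows[ord, , drop = FALSE]
      first <- !duplicated(rows[[key]])
      out <- setNames(rows[[other]][first], rows[[key]][first])
    }
    out
  }
  best_r_for_q <- best_of(ov, "qi", "ri", rids)
  best_q_for_r <- best_of(ov, "ri", "qi", qids)

  has_ov <- unique(ov$qi)
  for (qi in seq_along(query)) {
    if (!(qi %in% has_ov)) { cls[qi] <- "novel"; next }
    rows <- ov[ov$qi == qi, , drop = FALSE]
    fused_refs <- rows$ri[rows$frac_r >= cfg$fusion_member_fraction]
    if (length(fused_refs) >= 2L) {
      cls[qi] <- "fused"
      counterparts[qi] <- paste(sort(rids[fused_refs]), collapse = ",")
      next
    }
    ri <- unname(best_r_for_q[as.character(qi)])
    reciprocal <- length(ri) == 1L && !is.na(ri) &&
      unname(best_q_for_r[as.character(ri)]) == qi
    if (reciprocal) {
      fr <- rows[rows$ri == ri, , drop = FALSE]
      if (fr$frac_q[1] >= cfg$covered_reciprocal_fraction &&
          fr$frac_r[1] >= cfg$covered_reciprocal_fraction) {
        cls[qi] <- "covered"
        counterparts[qi] <- rids[ri]
        next
      }
    }
    if (qi %in% split_members_idx) {
      cls[qi] <- "split_member"
      mem_of <- split_ref_idx[vapply(split_tab, function(m) qi %in% m, logical(1))]
      counterparts[qi] <- paste(sort(rids[mem_of]), collapse = ",")
    }
  }

  split_df <- data.frame(
    ref_gene_id = rids[split_ref_idx],
    members = vapply(split_tab, function(m) paste(sort(qids[m]), collapse = ","), character(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  per_gene <- data.frame(gene_id = qids, class = cls, counterparts = counterparts,
                         stringsAsFactors = FALSE, row.names = NULL)
  summary <- c(total = length(query),
               novel = sum(cls == "novel"),
               covered = sum(cls == "covered"),
               fused = sum(cls == "fused"),
               split = nrow(split_df),
               split_member = sum(cls == "split_member"),
               ambiguous = sum(cls == "ambiguous"))
  structure(list(per_gene = per_gene, split_reference = split_df, summary = summary),
            class = "reconcile_report")
}

#' @export
print.reconcile_report <- function(x, ...) {
  cat("<reconcile_report>\n")
  print(x$summary)
  invisible(x)
}

#' Expression-support filter
#'
#' A gene is supported by expression signals iff its raw count reaches
#' `min_support_count` in at least `min_support_samples` samples. A gene
#' with no counts row is unsupported.
#'
#' @param gene_ids character vector of gene ids.
#' @param counts a [counts_table].
#' @param cfg a [reconcile_config()].
#' @return list with character vectors `supported` and `unsupported`.
#' @export
expression_support_filter <- function(gene_ids, counts, cfg = reconcile_config()) {
  ok <- vapply(gene_ids, function(g) {
    if (!g %in% rownames(counts$counts)) return(FALSE)
    sum(counts$counts[g, ] >= cfg$min_support_count) >= cfg$min_support_samples
  }, logical(1))
  list(supported = gene_ids[ok], unsupported = gene_ids[!ok])
}

#' Pseudogene filter
#'
#' Discards genes with no hit in the protein databases; a gene absent
#' from the hit table counts as no-hit.
#'
#' @param gene_ids character vector.
#' @param hits named logical vector (`has_protein_hit` per gene).
#' @return list with character vectors `coding` and `discarded`.
#' @export
pseudogene_filter <- function(gene_ids, hits) {
  has <- !is.na(hits[gene_ids]) & hits[gene_ids]
  list(coding = gene_ids[has], discarded = gene_ids[!has])
}
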