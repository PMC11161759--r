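#' Call a SNP marker in an assembly
#'
#' Searches both strands of every contig for
#' `tail(left_flank, k) + allele + head(right_flank, k)` for each of the
#' two alleles, by exact matching. The call is the allele that matches
#' at exactly one locus while the other matches nowhere; anything else
#' (no match, both alleles matching, one allele at several loci) is
#' `"missing"`.
#'
#' @param assembly a [Biostrings::DNAStringSet].
#' @param marker one-row marker definition (see [read_marker_defs()]):
#'   fields `left_flank`, `right_flank`, `allele_ref`, `allele_alt`.
#' @param k flank match window; must not exceed the flank lengths.
#' @return `"ref"`, `"alt"` or `"missing"`.
#' @export
call_marker <- function(assembly, marker, k = 50L) {
  lf <- marker$left_flank; rf <- marker$right_flank
  if (nchar(lf) < k || nchar(rf) < k) {
    stop("marker '", marker$marker_id, "': flanks shorter than k = ", k)
  }
  lf <- substr(lf, nchar(lf) - k + 1L, nchar(lf))
  rf <- substr(rf, 1L, k)
  count_site <- function(allele) {
    pat <- Biostrings::DNAString(paste0(lf, allele, rf))
    sum(Biostrings::vcountPattern(pat, assembly)) +
      sum(Biostrings::vcountPattern(Biostrings::reverseComplement(pat), assembly))
  }
  n_ref <- count_site(marker$allele_ref)
  n_alt <- count_site(marker$allele_alt)
  if (n_ref == 1L && n_alt == 0L) "ref"
  else if (n_alt == 1L && n_ref == 0L) "alt"
  else "missing"
}

#' Genotype an assembly over a marker set
#'
#' Applies [call_marker()] to every marker and encodes the haploid calls
#' as alternate-allele dosages: ref = 0, alt = 2, missing = NA.
#'
#' @param assembly a [Biostrings::DNAStringSet].
#' @param markers marker-definition data frame.
#' @param k flank match window.
#' @return named numeric dosage vector (0/2/NA), one entry per marker.
#' @export
genotype_assembly <- function(assembly, markers, k = 50L) {
  calls <- vapply(seq_len(nrow(markers)), function(i) {
    call_marker(assembly, markers[i, ], k = k)
  }, character(1))
  setNames(c(ref = 0, alt = 2, missing = NA_real_)[calls], markers$marker_id)
}

#' Identity-by-state distance between dosage vectors
#'
#' `d = mean(|dose_x - dose_y| / 2)` over markers non-missing in both
#' vectors; identical genotypes are at distance 0 and opposite
#' homozygotes at 1. Returns `NA` when fewer than `min_shared` markers
#' are shared.
#'
#' @param x,y dosage vectors in the same marker order (0/1/2, NA
#'   missing; haploid calls use 0/2).
#' @param min_shared minimum number of jointly non-missing markers.
#' @return distance in \[0, 1\], or `NA`.
#' @export
ibs_distance <- function(x, y, min_shared = 100L) {
  if (length(x) != length(y)) stop("dosage vectors differ in length")
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) == 0L) return(NA_real_)
  if (sum(ok) < min_shared) return(NA_real_)
  mean(abs(x[ok] - y[ok]) / 2)
}

#' Rank panel accessions by distance to a query genotype
#'
#' Sorts accessions by [ibs_distance()] to the query, ascending, ties
#' broken by accession label, and returns the first `n` (the "closest
#' cultivars" selection, default 40).
#'
#' @param panel dosage matrix, markers x accessions (see
#'   [read_genotype_panel()]).
#' @param query dosage vector named by marker; matched to panel rows by
#'   name.
#' @param n number of accessions to return.
#' @param min_shared passed to [ibs_distance()].
#' @return data frame with columns `accession`, `distance`, ranked.
#' @export
closest_accessions <- function(panel, query, n = 40L, min_shared = 100L) {
  if (ncol(panel) == 0L) stop("panel is empty")
  q <- query[rownames(panel)]
  d <- vapply(colnames(panel), function(a) {
    ibs_distance(q, panel[, a], min_shared = min_shared)
  }, numeric(1))
  out <- data.frame(accession = colnames(panel), distance = unname(d),
                    stringsAsFactors = FALSE)
  out <- out[!is.na(out$distance), , drop = FALSE]
  out <- out[order(out$distance, out$accession, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  head(out, n)
}

#' Select a robust marker subset
#'
#' Keeps markers with unambiguous (non-missing) calls in every supplied
#' query genotype and a panel call rate of at least `min_call_rate`.
#'
#' @param panel dosage matrix markers x accessions.
#' @param query_calls list of query dosage vectors (named by marker).
#' @param min_call_rate minimum fraction of non-missing panel calls.
#' @return character vector of retained marker ids.
#' @export
robust_marker_subset <- function(panel, query_calls = list(), min_call_rate = 0.95) {
  rate <- rowMeans(!is.na(panel))
  keep <- rate >= min_call_rate
  for (q in query_calls) keep <- keep & !is.na(q[rownames(panel)])
  rownames(panel)[keep]
}

#' Pairwise identity-by-state distance matrix
#'
#' @param panel dosage matrix markers x accessions.
#' @param min_shared passed to [ibs_distance()].
#' @return symmetric numeric matrix with zero diagonal, labelled by
#'   accession.
#' @export
ibs_distance_matrix <- function(panel, min_shared = 100L) {
  acc <- colnames(panel)
  d <- matrix(0, length(acc), length(acc), dimnames = list(acc, acc))
  for (i in seq_along(acc)) {
    for (j in seq_len(i - 1L)) {
      d[i, j] <- d[j, i] <- ibs_distance(panel[, i], panel[, j], min_shared = min_shared)
    }
  }
  d
}
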