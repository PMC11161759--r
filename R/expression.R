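#' TPM normalization
#'
#' Normalizes raw counts for gene feature length and library size:
#' each count is divided by its gene length, and each sample column of
#' the resulting rates is rescaled to sum to one million (transcripts
#' per million). Doubling all counts of a sample therefore leaves its
#' column unchanged.
#'
#' @param counts a [counts_table].
#' @return an object of class `"tpm_matrix"`: list with `values`
#'   (numeric matrix, columns summing to 1e6) and `log_transformed`
#'   (`FALSE`).
#' @export
normalize_tpm <- function(counts) {
  stopifnot(inherits(counts, "counts_table"))
  rate <- counts$counts / counts$gene_length_bp
  colsum <- colSums(rate)
  zero <- colsum == 0
  if (any(zero)) {
    stop("sample(s) with all-zero counts cannot be normalized: ",
         paste(colnames(counts$counts)[zero], collapse = ", "))
  }
  values <- sweep(rate, 2, colsum, "/") * 1e6
  structure(list(values = values, log_transformed = FALSE), class = "tpm_matrix")
}

#' @export
print.tpm_matrix <- function(x, ...) {
  cat(sprintf("<tpm_matrix> %d genes x %d samples%s\n", nrow(x$values),
              ncol(x$values), if (x$log_transformed) " (log2(TPM+1))" else ""))
  invisible(x)
}

#' Log-transform a TPM matrix
#'
#' Applies `log2(x + 1)`. Transforming an already log-transformed matrix
#' is an error, so the transform cannot be applied twice.
#'
#' @param m a `"tpm_matrix"`.
#' @return the transformed `"tpm_matrix"` with `log_transformed = TRUE`.
#' @export
log_transform <- function(m) {
  stopifnot(inherits(m, "tpm_matrix"))
  if (m$log_transformed) stop("matrix is already log-transformed")
  structure(list(values = log2(m$values + 1), log_transformed = TRUE),
            class = "tpm_matrix")
}

# expression values for correlation work: log2(TPM+1) by default
.expr_values <- function(m, log2_input = TRUE) {
  stopifnot(inherits(m, "tpm_matrix"))
  if (log2_input && !m$log_transformed) m <- log_transform(m)
  m$values
}

#' Per-condition expression profile of a gene
#'
#' Computes mean, sample standard deviation (denominator n-1; reported
#' as 0 for single-sample groups) and sample count of a gene's
#' expression per condition group, in the order groups first appear in
#' the metadata. Declared groups with no samples are omitted with a
#' warning.
#'
#' @param m a `"tpm_matrix"`.
#' @param metadata sample metadata data frame (see
#'   [read_sample_metadata()]); rows are matched to columns of `m` by
#'   `sample_id`.
#' @param gene_id gene to profile.
#' @param group_by character vector of metadata column names; groups are
#'   their interaction, labels joined with "/".
#' @return data frame with columns `group`, `mean`, `sd`, `n`.
#' @export
expression_profile <- function(m, metadata, gene_id, group_by) {
  vals <- m$values
  if (!gene_id %in% rownames(vals)) stop("unknown gene '", gene_id, "'")
  md <- metadata[match(colnames(vals), metadata$sample_id), , drop = FALSE]
  if (any(is.na(md$sample_id))) stop("metadata is missing sample(s) present in the matrix")
  miss <- setdiff(group_by, names(md))
  if (length(miss)) stop("unknown metadata column(s): ", paste(miss, collapse = ", "))
  lab <- do.call(paste, c(md[group_by], sep = "/"))
  levels <- unique(lab)
  x <- vals[gene_id, ]
  out <- do.call(rbind, lapply(levels, function(l) {
    xi <- x[lab == l]
    data.frame(group = l, mean = mean(xi),
               sd = if (length(xi) > 1L) sd(xi) else 0,
               n = length(xi), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Aggregate replicate samples to condition means
#'
#' Collapses the columns of an expression matrix to per-condition means,
#' one column per distinct combination of the `group_by` metadata
#' columns (in order of first appearance). Correlation tools can then be
#' run on conditions rather than individual samples. Averaging preserves
#' the per-million column sums of a non-log matrix.
#'
#' @param m a `"tpm_matrix"`.
#' @param metadata sample metadata data frame.
#' @param group_by character vector of metadata columns defining a
#'   condition.
#' @return a `"tpm_matrix"` with one column per condition.
#' @export
aggregate_conditions <- function(m, metadata,
                                 group_by = c("organ", "cultivar", "stage")) {
  stopifnot(inherits(m, "tpm_matrix"))
  md <- metadata[match(colnames(m$values), metadata$sample_id), , drop = FALSE]
  if (any(is.na(md$sample_id))) stop("metadata is missing sample(s) present in the matrix")
  miss <- setdiff(group_by, names(md))
  if (length(miss)) stop("unknown metadata column(s): ", paste(miss, collapse = ", "))
  lab <- do.call(paste, c(md[group_by], sep = "/"))
  levels <- unique(lab)
  vals <- vapply(levels, function(l) {
    rowMeans(m$values[, lab == l, drop = FALSE])
  }, numeric(nrow(m$values)))
  colnames(vals) <- levels
  structure(list(values = vals, log_transformed = m$log_transformed),
            class = "tpm_matrix")
}

#' Pearson product-moment correlation
#'
#' Thin, validated wrapper over [stats::cor()]: requires equal lengths
#' of at least 3 and nonzero variance in both vectors (a zero-variance
#' vector has no defined correlation).
#'
#' @param x,y numeric vectors.
#' @return correlation coefficient in \[-1, 1\].
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (sd(x) == 0 || sd(y) == 0) stop("zero-variance vector: correlation undefined")
  cor(x, y)
}

#' Correlation gene finder
#'
#' Finds genes whose expression correlates with a target gene. In
#' `"threshold"` mode, returns genes with `r >= threshold`
#' (`direction = "positive"`), `r <= -threshold` (`"negative"`), or
#' `|r| >= threshold` (`"both"`). In `"topk"` mode, returns the `top_k`
#' genes ranked by `|r|`. The target itself is always excluded;
#' zero-variance genes are silently skipped (their correlation is
#' undefined). Correlations are computed on log2(TPM+1) unless
#' `log2_input = FALSE`. Results are sorted by `|r|` descending, ties by
#' gene id.
#'
#' @param m a `"tpm_matrix"` whose samples are already filtered to the
#'   conditions of interest.
#' @param target_gene gene id.
#' @param threshold correlation threshold in (0, 1\].
#' @param mode `"threshold"` or `"topk"`.
#' @param top_k number of genes in `"topk"` mode.
#' @param direction `"positive"`, `"negative"` or `"both"`.
#' @param log2_input correlate on log2(TPM+1) (default) or raw TPM.
#' @return data frame with columns `gene_id`, `r`, `n`, `sign`.
#' @export
correlation_gene_finder <- function(m, target_gene, threshold = 0.75,
                                    mode = c("threshold", "topk"), top_k = 10L,
                                    direction = c("positive", "negative", "both"),
                                    log2_input = TRUE) {
  mode <- match.arg(mode)
  direction <- match.arg(direction)
  if (threshold <= 0 || threshold > 1) stop("threshold must lie in (0, 1]")
  vals <- .expr_values(m, log2_input)
  if (!target_gene %in% rownames(vals)) stop("unknown gene '", target_gene, "'")
  x <- vals[target_gene, ]
  if (sd(x) == 0) stop("target gene '", target_gene, "' has zero variance")
  others <- vals[setdiff(rownames(vals), target_gene), , drop = FALSE]
  v <- apply(others, 1, sd)
  others <- others[v > 0, , drop = FALSE]
  r <- as.vector(cor(x, t(others)))
  res <- data.frame(gene_id = rownames(others), r = r, n = length(x),
                    sign = ifelse(r >= 0, "positive", "negative"),
                    stringsAsFactors = FALSE)
  res <- res[order(-abs(res$r), res$gene_id, method = "radix"), , drop = FALSE]
  if (mode == "threshold") {
    res <- switch(direction,
                  positive = res[res$r >= threshold, , drop = FALSE],
                  negative = res[res$r <= -threshold, , drop = FALSE],
                  both = res[abs(res$r) >= threshold, , drop = FALSE])
  } else {
    res <- head(res, top_k)
  }
  rownames(res) <- NULL
  res
}

#' Correlation-circle layout
#'
#' Places correlated genes on a circle around the target: the radius is
#' `1 - r` (clipped to \[0, 2\]), so the higher the correlation the
#' shorter the distance to the target; angles are assigned uniformly by
#' rank order starting at 0. The target sits at the origin.
#'
#' @param results finder output (data frame with `gene_id`, `r`).
#' @param target_gene target gene id.
#' @return data frame with columns `gene_id`, `radius`, `angle` (the
#'   target first, radius 0).
#' @export
correlation_circle_layout <- function(results, target_gene) {
  if (nrow(results) == 0L) stop("results must be nonempty")
  n <- nrow(results)
  radius <- pmin(pmax(1 - results$r, 0), 2)
  data.frame(gene_id = c(target_gene, results$gene_id),
             radius = c(0, radius),
             angle = c(0, 2 * pi * (seq_len(n) - 1L) / n),
             stringsAsFactors = FALSE)
}

#' Clustered expression heatmap
#'
#' Agglomerative hierarchical clustering of genes (rows) and samples
#' (columns) under Euclidean distance on the expression levels, or
#' Pearson distance (`1 - r`) for linear correlation. Returns the two
#' dendrograms and the matrix reordered by their leaf orders. The
#' procedure is deterministic. Under Pearson distance a zero-variance
#' row or column has no defined correlation and is an error naming the
#' offender.
#'
#' @param m a `"tpm_matrix"`.
#' @param genes,samples subsets to cluster (default: all).
#' @param distance `"euclidean"` or `"pearson"`.
#' @param linkage agglomeration method for [stats::hclust()] (default
#'   `"average"`).
#' @param log2_input cluster on log2(TPM+1) (default) or raw values.
#' @return list with `gene_hclust`, `sample_hclust` (both
#'   [stats::hclust] objects) and `matrix` (reordered values).
#' @export
cluster_heatmap <- function(m, genes = NULL, samples = NULL,
                            distance = c("euclidean", "pearson"),
                            linkage = "average", log2_input = TRUE) {
  distance <- match.arg(distance)
  vals <- .expr_values(m, log2_input)
  if (!is.null(genes)) {
    miss <- setdiff(genes, rownames(vals))
    if (length(miss)) stop("unknown gene(s): ", paste(head(miss, 5), collapse = ", "))
    vals <- vals[genes, , drop = FALSE]
  }
  if (!is.null(samples)) vals <- vals[, samples, drop = FALSE]
  if (nrow(vals) < 2L || ncol(vals) < 2L) stop("need at least 2 genes and 2 samples")
  dfun <- function(x, what) {
    if (distance == "euclidean") return(dist(x))
    v <- apply(x, 1, sd)
    if (any(v == 0)) {
      stop("zero-variance ", what, " under pearson distance: ",
           paste(head(rownames(x)[v == 0], 5), collapse = ", "))
    }
    stats::as.dist(1 - cor(t(x)))
  }
  gh <- hclust(dfun(vals, "gene(s)"), method = linkage)
  sh <- hclust(dfun(t(vals), "sample(s)"), method = linkage)
  list(gene_hclust = gh, sample_hclust = sh,
       matrix = vals[gh$order, sh$order, drop = FALSE])
}

#' Weighted correlation network around seed genes
#'
#' Builds the expression-based weighted correlation network for the
#' selected gene(s): edge weights are `|r|^beta` (soft threshold,
#' default `beta = 6`), nodes are the seeds plus every gene connected to
#' a seed with weight at least `min_weight`, and edges include both
#' seed-neighbor and neighbor-neighbor pairs above `min_weight`. The
#' network is undirected (each pair stored once) with no self-edges.
#'
#' @param m a `"tpm_matrix"`.
#' @param seed_genes character vector of seed gene ids.
#' @param beta soft-threshold exponent, `>= 1`.
#' @param min_weight minimum edge weight in \[0, 1\].
#' @param log2_input correlate on log2(TPM+1) (default) or raw values.
#' @return list of class `"correlation_network"` with `nodes`, `edges`
#'   (data frame `from`, `to`, `r`, `weight`), `beta`.
#' @export
correlation_network <- function(m, seed_genes, beta = 6, min_weight = 0.3,
                                log2_input = TRUE) {
  if (beta < 1) stop("beta must be >= 1")
  vals <- .expr_values(m, log2_input)
  miss <- setdiff(seed_genes, rownames(vals))
  if (length(miss)) stop("unknown seed gene(s): ", paste(miss, collapse = ", "))
  v <- apply(vals, 1, sd)
  vals <- vals[v > 0 | rownames(vals) %in% seed_genes, , drop = FALSE]
  r_seed <- cor(t(vals[seed_genes, , drop = FALSE]), t(vals))
  w_seed <- abs(r_seed)^beta
  neigh <- colnames(w_seed)[apply(w_seed >= min_weight, 2, any)]
  nodes <- sort(union(seed_genes, neigh))
  rmat <- cor(t(vals[nodes, , drop = FALSE]))
  idx <- which(upper.tri(rmat), arr.ind = TRUE)
  edges <- data.frame(from = nodes[idx[, 1]], to = nodes[idx[, 2]],
                      r = rmat[idx], stringsAsFactors = FALSE)
  edges$weight <- abs(edges$r)^beta
  edges <- edges[edges$weight >= min_weight, , drop = FALSE]
  edges <- edges[order(edges$from, edges$to, method = "radix"), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, beta = beta),
            class = "correlation_network")
}

#' @export
print.correlation_network <- function(x, ...) {
  cat(sprintf("<correlation_network> %d nodes, %d edges (beta = %g)\n",
              length(x$nodes), nrow(x$edges), x$beta))
  invisible(x)
}

#' A qPCR Ct record
#'
#' @param gene target gene name.
#' @param sample_group label of the biological group.
#' @param ct_replicates numeric vector of target-gene Ct values (>= 1
#'   replicate, positive).
#' @param reference_gene_cts named list of replicate Ct vectors, one per
#'   reference gene (e.g. ACT, EF1, UBQ).
#' @return object of class `"qpcr_record"`.
#' @export
qpcr_record <- function(gene, sample_group, ct_replicates, reference_gene_cts) {
  if (length(ct_replicates) < 1L) stop("need at least one Ct replicate")
  if (any(ct_replicates <= 0) || any(unlist(reference_gene_cts) <= 0)) {
    stop("Ct values must be positive")
  }
  if (length(reference_gene_cts) < 1L || is.null(names(reference_gene_cts))) {
    stop("reference_gene_cts must be a named list with >= 1 reference gene")
  }
  structure(list(gene = gene, sample_group = sample_group,
                 ct_replicates = as.numeric(ct_replicates),
                 reference_gene_cts = lapply(reference_gene_cts, as.numeric)),
            class = "qpcr_record")
}

.delta_ct <- function(rec) {
  ref_means <- vapply(rec$reference_gene_cts, mean, numeric(1))
  mean(rec$ct_replicates) - mean(ref_means)
}

#' 2^-ddCt relative expression
#'
#' The comparative Ct method: dCt is the mean target Ct minus the mean
#' of the per-reference-gene mean Cts; ddCt is the test dCt minus the
#' calibrator dCt; relative expression is `2^-ddCt`. A record compared
#' to itself yields exactly 1.
#'
#' @param test,calibrator [qpcr_record] objects for the same gene and
#'   the same set of reference genes.
#' @return relative expression (fold change) as a single number.
#' @export
ddct_relative_expression <- function(test, calibrator) {
  stopifnot(inherits(test, "qpcr_record"), inherits(calibrator, "qpcr_record"))
  if (test$gene != calibrator$gene) stop("records are for different genes")
  if (!setequal(names(test$reference_gene_cts), names(calibrator$reference_gene_cts))) {
    stop("records carry different reference-gene sets")
  }
  2^-(.delta_ct(test) - .delta_ct(calibrator))
}
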