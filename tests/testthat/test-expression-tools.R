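mk_counts <- function(m, lens = NULL) {
  if (is.null(lens)) lens <- setNames(rep(1000L, nrow(m)), rownames(m))
  counts_table(m, lens)
}

test_that("TPM normalization scales by length then library", {
  ct <- counts_table(matrix(c(10L, 20L), 2, 1, dimnames = list(c("g1", "g2"), "s1")),
                     c(g1 = 1000L, g2 = 2000L))
  tpm <- normalize_tpm(ct)
  expect_equal(unname(tpm$values[, 1]), c(5e5, 5e5))

  one <- counts_table(matrix(7L, 1, 1, dimnames = list("g1", "s1")), c(g1 = 123L))
  expect_equal(unname(normalize_tpm(one)$values[1, 1]), 1e6)

  # scale invariance: doubling a sample's counts leaves its column unchanged
  m <- matrix(c(3L, 9L, 1L, 6L, 2L, 18L), 3, 2,
              dimnames = list(paste0("g", 1:3), c("s1", "s2")))
  ct2 <- mk_counts(m)
  ct3 <- mk_counts(m * 2L)
  expect_equal(normalize_tpm(ct2)$values, normalize_tpm(ct3)$values)

  zero <- mk_counts(matrix(c(1L, 2L, 0L, 0L), 2, 2,
                           dimnames = list(c("g1", "g2"), c("good", "empty"))))
  expect_error(normalize_tpm(zero), "empty")
})

test_that("every normalized column sums to one million", {
  set.seed(44)
  for (i in 1:10) {
    n <- sample(5:40, 1); s <- sample(2:8, 1)
    m <- matrix(rnbinom(n * s, mu = 2, size = 0.5), n, s,
                dimnames = list(sprintf("g%02d", 1:n), sprintf("s%02d", 1:s)))
    m[, colSums(m) == 0][1] <- 1L  # keep columns normalizable
    tpm <- normalize_tpm(mk_counts(m, setNames(sample(200:5000, n), rownames(m))))
    expect_lt(max(abs(colSums(tpm$values) - 1e6)) / 1e6, 1e-6)
  }
})

test_that("log transform is log2(x+1) and refuses to run twice", {
  ct <- mk_counts(matrix(c(0L, 1L, 1023L), 3, 1,
                         dimnames = list(paste0("g", 1:3), "s1")))
  tpm <- normalize_tpm(ct)
  manual <- structure(list(values = matrix(c(0, 1, 1023), 3, 1,
                                           dimnames = dimnames(tpm$values)),
                           log_transformed = FALSE), class = "tpm_matrix")
  lg <- log_transform(manual)
  expect_equal(unname(lg$values[, 1]), c(0, 1, 10))  # log2(1024) = 10
  expect_error(log_transform(lg), "already")
})

test_that("expression profiles use sample sd with single-sample groups at 0", {
  vals <- matrix(c(2, 4, 9), 1, 3, dimnames = list("g1", c("s1", "s2", "s3")))
  m <- structure(list(values = vals, log_transformed = TRUE), class = "tpm_matrix")
  md <- data.frame(sample_id = c("s1", "s2", "s3"), organ = c("berry", "berry", "leaf"),
                   cultivar = "cv1", skin_color = "black", stage = "x", project = "p")
  prof <- expression_profile(m, md, "g1", "organ")
  expect_equal(prof$group, c("berry", "leaf"))
  expect_equal(prof$mean, c(3, 9))
  expect_equal(prof$sd, c(sd(c(2, 4)), 0))
  expect_equal(prof$n, c(2L, 1L))
  expect_error(expression_profile(m, md, "nope", "organ"), "unknown gene")
})

test_that("condition aggregation averages replicates and keeps column sums", {
  vals <- matrix(c(2, 4, 10, 6, 4, 0, 8, 2, 0), 3, 3,
                 dimnames = list(paste0("g", 1:3), c("s1", "s2", "s3")))
  vals <- sweep(vals, 2, colSums(vals), "/") * 1e6
  m <- structure(list(values = vals, log_transformed = FALSE), class = "tpm_matrix")
  md <- data.frame(sample_id = c("s1", "s2", "s3"),
                   organ = "berry", cultivar = c("a", "a", "b"),
                   skin_color = "black", stage = "x", project = "p")
  agg <- aggregate_conditions(m, md, group_by = c("organ", "cultivar"))
  expect_equal(colnames(agg$values), c("berry/a", "berry/b"))
  expect_equal(agg$values[, "berry/a"], rowMeans(vals[, c("s1", "s2")]))
  expect_equal(unname(colSums(agg$values)), c(1e6, 1e6))
})

test_that("pearson matches the product-moment formula and its guards", {
  expect_equal(pearson(c(1, 2, 3), c(2, 4, 6)), 1)
  expect_equal(pearson(c(1, 2, 3), c(6, 4, 2)), -1)
  expect_equal(pearson(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  # invariance to positive affine rescaling, symmetry, bounds
  set.seed(5)
  x <- rnorm(30); y <- rnorm(30)
  expect_equal(pearson(x, y), pearson(y, x))
  expect_equal(pearson(3 * x + 7, y), pearson(x, y))
  expect_lte(abs(pearson(x, y)), 1)
  expect_error(pearson(c(1, 1, 1), c(1, 2, 3)), "zero-variance")
  expect_error(pearson(1:2, 1:2), "at least 3")
})

test_that("the correlation gene finder ranks an exact copy first at r = 1", {
  set.seed(6)
  vals <- matrix(2^rnorm(50 * 12, 5), 50, 12,
                 dimnames = list(sprintf("g%02d", 1:50), sprintf("s%02d", 1:12)))
  vals["g02", ] <- vals["g01", ]
  m <- structure(list(values = vals, log_transformed = FALSE), class = "tpm_matrix")
  res <- correlation_gene_finder(m, "g01", threshold = 0.9)
  expect_equal(res$gene_id[1], "g02")
  expect_equal(res$r[1], 1)
  expect_false("g01" %in% res$gene_id)
  expect_error(correlation_gene_finder(m, "g01", threshold = 1.5), "threshold")
})

test_that("finder results are monotone in the threshold", {
  sim <- simulate_expression(simulation_config(seed = 77, n_black = 30, n_white = 10,
                                               n_noise_genes = 100))
  tpm <- normalize_tpm(sim$counts)
  prev <- NULL
  for (t in c(0.9, 0.8, 0.7, 0.5, 0.3)) {
    res <- correlation_gene_finder(tpm, sim$truth$seed_gene, threshold = t)
    if (!is.null(prev)) expect_true(all(prev %in% res$gene_id))
    prev <- res$gene_id
  }
})

test_that("finder recovers the planted module in threshold and top-k modes", {
  sim <- simulate_expression(simulation_config(seed = 90, n_black = 40, n_white = 20,
                                               n_noise_genes = 500))
  tpm <- normalize_tpm(sim$counts)
  others <- setdiff(sim$truth$module_genes, sim$truth$seed_gene)
  th <- correlation_gene_finder(tpm, sim$truth$seed_gene, threshold = 0.75)
  expect_true(all(others %in% th$gene_id))
  expect_lte(sum(!th$gene_id %in% others), 1)
  tk <- correlation_gene_finder(tpm, sim$truth$seed_gene, mode = "topk", top_k = 10)
  expect_equal(nrow(tk), 10L)
  expect_setequal(tk$gene_id[seq_along(others)], others)
})

test_that("correlation-circle radii are 1 - r with the target at the origin", {
  res <- data.frame(gene_id = c("a", "b", "c"), r = c(1, 0, -1))
  lay <- correlation_circle_layout(res, "seed")
  expect_equal(lay$gene_id[1], "seed")
  expect_equal(lay$radius, c(0, 0, 1, 2))
  expect_equal(lay$angle[2], 0)
  expect_error(correlation_circle_layout(res[0, ], "seed"), "nonempty")
})

test_that("heatmap clustering is deterministic, merges duplicates first and guards variance", {
  set.seed(7)
  vals <- matrix(2^rnorm(20 * 8, 6), 20, 8,
                 dimnames = list(sprintf("g%02d", 1:20), sprintf("s%02d", 1:8)))
  vals["g02", ] <- vals["g01", ]
  m <- structure(list(values = vals, log_transformed = FALSE), class = "tpm_matrix")
  hm <- cluster_heatmap(m, distance = "euclidean")
  first_merge <- hm$gene_hclust$merge[1, ]
  expect_setequal(hm$gene_hclust$labels[-first_merge], c("g01", "g02"))
  expect_equal(hm$gene_hclust$height[1], 0)
  hm2 <- cluster_heatmap(m, distance = "euclidean")
  expect_identical(hm$gene_hclust$order, hm2$gene_hclust$order)

  vals["g03", ] <- 5
  mz <- structure(list(values = vals, log_transformed = TRUE), class = "tpm_matrix")
  expect_error(cluster_heatmap(mz, distance = "pearson"), "g03")
})

test_that("samples with disjoint expressed gene sets split perfectly at k = 2", {
  vals <- matrix(0.01, 10, 6, dimnames = list(sprintf("g%02d", 1:10), sprintf("s%d", 1:6)))
  set.seed(8)
  vals[1:5, 1:3] <- 2^rnorm(15, 8)
  vals[6:10, 4:6] <- 2^rnorm(15, 8)
  m <- structure(list(values = vals, log_transformed = FALSE), class = "tpm_matrix")
  hm <- cluster_heatmap(m, distance = "euclidean")
  k2 <- cutree(hm$sample_hclust, 2)
  expect_equal(length(unique(k2[1:3])), 1L)
  expect_equal(length(unique(k2[4:6])), 1L)
  expect_true(k2[1] != k2[4])
})

test_that("network weights are soft-thresholded correlations on [0, 1]", {
  set.seed(9)
  vals <- matrix(2^rnorm(30 * 20, 6), 30, 20,
                 dimnames = list(sprintf("g%02d", 1:30), sprintf("s%02d", 1:20)))
  m <- structure(list(values = vals, log_transformed = FALSE), class = "tpm_matrix")
  nw1 <- correlation_network(m, "g01", beta = 1, min_weight = 0.2)
  expect_equal(nw1$edges$weight, abs(nw1$edges$r))
  expect_equal((0.5)^6, 0.015625)
  nw6 <- correlation_network(m, "g01", beta = 6, min_weight = 0)
  expect_true(all(nw6$edges$weight >= 0 & nw6$edges$weight <= 1))
  # raising beta never increases any weight
  shared <- merge(nw1$edges, nw6$edges, by = c("from", "to"))
  expect_true(all(shared$weight.y <= shared$weight.x + 1e-12))
  expect_false(any(nw6$edges$from == nw6$edges$to))
})

test_that("the planted module forms a connected component with the seed", {
  sim <- simulate_expression(simulation_config(seed = 91, n_black = 40, n_white = 20,
                                               n_noise_genes = 200))
  tpm <- normalize_tpm(sim$counts)
  nw <- correlation_network(tpm, sim$truth$seed_gene, beta = 6, min_weight = 0.3)
  expect_true(all(sim$truth$module_genes %in% nw$nodes))
  # BFS from the seed over the edge list
  adj <- rbind(nw$edges[, c("from", "to")],
               setNames(nw$edges[, c("to", "from")], c("from", "to")))
  seen <- sim$truth$seed_gene
  frontier <- seen
  while (length(frontier)) {
    nxt <- setdiff(adj$to[adj$from %in% frontier], seen)
    seen <- c(seen, nxt); frontier <- nxt
  }
  expect_true(all(sim$truth$module_genes %in% seen))
})

test_that("ddCt relative expression follows the comparative Ct worked cases", {
  refs <- list(ACT = c(15, 15), EF1 = c(15, 15), UBQ = c(15, 15))
  test <- qpcr_record("VvMYBA1", "red_callus", c(18, 18, 18), refs)
  cal <- qpcr_record("VvMYBA1", "white_callus", c(20, 20, 20), refs)
  expect_identical(ddct_relative_expression(test, cal), 4)       # dCt 3 vs 5
  expect_identical(ddct_relative_expression(cal, cal), 1)        # self-comparison
  single <- qpcr_record("g", "x", 18, list(ACT = 15))
  single_cal <- qpcr_record("g", "x", 20, list(ACT = 15))
  expect_identical(ddct_relative_expression(single, single_cal), 4)
  expect_error(qpcr_record("g", "x", numeric(0), list(ACT = 15)), "replicate")
  other <- qpcr_record("other_gene", "x", 18, list(ACT = 15))
  expect_error(ddct_relative_expression(test, other), "different genes")
})
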