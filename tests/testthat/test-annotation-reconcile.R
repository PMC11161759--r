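test_that("liftover acceptance uses closed 80/80 boundaries and partitions", {
  stats <- data.frame(
    gene_id = c("a", "b", "c", "d"),
    coverage = c(0.85, 0.79, 0.80, 0.99),
    identity = c(0.92, 0.99, 0.80, 0.60))
  part <- acceptance_filter(stats)
  expect_setequal(part$accepted, c("a", "c"))
  expect_setequal(part$rejected, c("b", "d"))
  expect_length(intersect(part$accepted, part$rejected), 0)
  expect_setequal(c(part$accepted, part$rejected), stats$gene_id)
  expect_error(acceptance_filter(data.frame(gene_id = "x", coverage = 1.2, identity = 0.9)),
               "\\[0, 1\\]")
})

test_that("raising the coverage threshold never admits more genes", {
  set.seed(31)
  stats <- data.frame(gene_id = sprintf("g%03d", 1:200),
                      coverage = runif(200), identity = runif(200))
  sizes <- vapply(seq(0.5, 0.95, by = 0.05), function(th) {
    length(acceptance_filter(stats, reconcile_config(min_coverage = th))$accepted)
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("exonic overlap fractions follow interval arithmetic", {
  a <- single_exon_gene("a", 0, 100)
  b <- single_exon_gene("b", 50, 150)
  expect_equal(exonic_overlap_fraction(a, a), c(1, 1))
  expect_equal(exonic_overlap_fraction(a, single_exon_gene("c", 500, 600)), c(0, 0))
  expect_equal(exonic_overlap_fraction(a, b), c(0.5, 0.5))
  # different strands share nothing
  expect_equal(exonic_overlap_fraction(a, single_exon_gene("d", 0, 100, "-")), c(0, 0))
})

test_that("classification archetypes: novel, fused, split", {
  ref <- list(r1 = single_exon_gene("r1", 0, 1000),
              r2 = single_exon_gene("r2", 1500, 2500),
              r3 = single_exon_gene("r3", 9000, 9500))
  qry <- list(qf = single_exon_gene("qf", 0, 2500),      # spans r1+r2 fully
              qn = single_exon_gene("qn", 5000, 5600),   # overlaps nothing
              qs1 = single_exon_gene("qs1", 9000, 9250), # half of r3
              qs2 = single_exon_gene("qs2", 9250, 9500)) # other half
  rep <- classify_genes(qry, ref)
  cls <- setNames(rep$per_gene$class, rep$per_gene$gene_id)
  expect_equal(unname(cls["qn"]), "novel")
  expect_equal(unname(cls["qf"]), "fused")
  expect_equal(rep$per_gene$counterparts[rep$per_gene$gene_id == "qf"], "r1,r2")
  expect_equal(rep$summary[["split"]], 1L)
  expect_equal(rep$split_reference$ref_gene_id, "r3")
  expect_equal(rep$split_reference$members, "qs1,qs2")
  expect_equal(unname(cls[c("qs1", "qs2")]), c("split_member", "split_member"))
})

test_that("classification is a total partition and identity maps to covered", {
  sim <- simulate_annotation_pair(simulation_config(seed = 42))
  rep <- classify_genes(sim$query, sim$reference)
  expect_equal(sum(rep$summary[c("novel", "covered", "fused", "split_member", "ambiguous")]),
               rep$summary[["total"]])
  selfrep <- classify_genes(sim$reference, sim$reference)
  expect_equal(selfrep$summary[["covered"]], selfrep$summary[["total"]])
  expect_equal(selfrep$summary[["novel"]], 0L)
  expect_equal(selfrep$summary[["fused"]], 0L)
  expect_equal(selfrep$summary[["split"]], 0L)
})

test_that("raising the reciprocal fraction never increases covered genes", {
  sim <- simulate_annotation_pair(simulation_config(
    seed = 13, n_genes = 60, jitter_prob = 0.5, jitter_bp = 300))
  counts <- vapply(c(0.5, 0.6, 0.7, 0.8, 0.9, 0.99), function(th) {
    classify_genes(sim$query, sim$reference,
                   reconcile_config(covered_reciprocal_fraction = th))$summary[["covered"]]
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("duplicate gene ids within one set are rejected", {
  g <- single_exon_gene("dup", 0, 100)
  expect_error(classify_genes(list(g, g), list(r = single_exon_gene("r", 0, 100))),
               "duplicate")
})

test_that("class assignments match the per-base brute-force oracle", {
  set.seed(99)
  for (rep_i in 1:5) {
    cfg <- simulation_config(seed = 100 + rep_i,
                             n_genes = sample(20:45, 1),
                             n_planted_novel = sample(0:4, 1),
                             n_planted_fused = sample(0:3, 1),
                             n_planted_split = sample(0:2, 1),
                             jitter_prob = 0.4, jitter_bp = 350)
    sim <- simulate_annotation_pair(cfg)
    glen <- Biostrings::width(sim$genome)[1]
    got <- classify_genes(sim$query, sim$reference)
    want <- oracle_classify(sim$query, sim$reference, glen)
    expect_equal(setNames(got$per_gene$class, got$per_gene$gene_id),
                 want$class[got$per_gene$gene_id])
    expect_setequal(got$split_reference$ref_gene_id, want$split_refs)
  }
})

test_that("expression support requires min count in min samples", {
  ct <- counts_table(
    matrix(c(0, 0, 0, 0,
             7, 9, 0, 0,
             100, 0, 0, 0), nrow = 3, byrow = TRUE,
           dimnames = list(c("gZero", "gTwo", "gOne"), paste0("s", 1:4))),
    c(gZero = 1000L, gTwo = 1000L, gOne = 1000L))
  part <- expression_support_filter(c("gZero", "gTwo", "gOne", "gMissing"), ct)
  expect_identical(part$supported, "gTwo")
  expect_setequal(part$unsupported, c("gZero", "gOne", "gMissing"))
})

test_that("pseudogene filter discards no-hit and unknown genes", {
  hits <- c(gA = TRUE, gB = FALSE)
  part <- pseudogene_filter(c("gA", "gB", "gC"), hits)
  expect_identical(part$coding, "gA")
  expect_setequal(part$discarded, c("gB", "gC"))
  empty <- pseudogene_filter(c("gA", "gB"), setNames(logical(0), character(0)))
  expect_length(empty$coding, 0)
})

test_that("pipeline recovers planted classes with filters off and funnels stages", {
  sim <- simulate_annotation_pair(simulation_config(seed = 8))
  res <- reconcile_pipeline(sim$query, sim$reference)
  expect_equal(res$report$summary[["novel"]], 5L)
  expect_equal(res$report$summary[["fused"]], 2L)
  expect_equal(res$report$summary[["split"]], 1L)
  expect_equal(res$funnel[["input"]], length(sim$query))

  # all genes failing expression support empties the retained set
  zero <- counts_table(
    matrix(0L, length(sim$query), 3,
           dimnames = list(names(sim$query), paste0("s", 1:3))),
    setNames(rep(1000L, length(sim$query)), names(sim$query)))
  res2 <- reconcile_pipeline(sim$query, sim$reference, counts = zero)
  expect_length(res2$retained, 0)
  expect_equal(res2$report$summary[["total"]], 0L)

  # query == reference: everything covered
  res3 <- reconcile_pipeline(sim$reference, sim$reference)
  expect_equal(res3$report$summary[["covered"]], length(sim$reference))
})
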