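mk_marker <- function(id = "M1", seed = 50) {
  set.seed(seed)
  data.frame(marker_id = id, left_flank = random_dna(60), right_flank = random_dna(60),
             allele_ref = "A", allele_alt = "G", stringsAsFactors = FALSE)
}

test_that("marker calling is exact, ambiguity-aware and strand-symmetric", {
  mk <- mk_marker()
  site <- function(allele) paste0(mk$left_flank, allele, mk$right_flank)
  set.seed(51)
  bg1 <- random_dna(300); bg2 <- random_dna(300)
  asm <- dna_set(c1 = paste0(bg1, site("A"), bg2))
  expect_identical(call_marker(asm, mk), "ref")
  asm_alt <- dna_set(c1 = paste0(bg1, site("G"), bg2))
  expect_identical(call_marker(asm_alt, mk), "alt")
  both <- dna_set(c1 = paste0(bg1, site("A"), bg2, site("G")))
  expect_identical(call_marker(both, mk), "missing")
  twice <- dna_set(c1 = paste0(site("A"), bg1, site("A")))
  expect_identical(call_marker(twice, mk), "missing")
  none <- dna_set(c1 = bg1)
  expect_identical(call_marker(none, mk), "missing")
  rc <- dna_set(c1 = revcomp(paste0(bg1, site("A"), bg2)))
  expect_identical(call_marker(rc, mk), "ref")
  expect_error(call_marker(asm, transform(mk, left_flank = "ACGT")), "shorter than k")
})

test_that("identity-by-state distance follows the dosage arithmetic", {
  expect_equal(ibs_distance(rep(2, 10), rep(2, 10), min_shared = 1), 0)
  x <- rep(0, 10); y <- c(rep(2, 2), rep(0, 8))
  expect_equal(ibs_distance(x, y, min_shared = 1), 0.2)
  expect_equal(ibs_distance(rep(2, 10), rep(1, 10), min_shared = 1), 0.5)
  with_na <- c(NA, rep(0, 9))
  expect_equal(ibs_distance(with_na, y, min_shared = 1), 1 / 9)  # one diff over 9 shared
  expect_true(is.na(ibs_distance(x, y, min_shared = 100)))
  expect_true(is.na(ibs_distance(rep(NA_real_, 5), rep(0, 5), min_shared = 1)))
})

test_that("closest-accession ranking is exact and order-invariant", {
  set.seed(52)
  panel <- matrix(sample(c(0, 2), 200 * 5, TRUE), 200, 5,
                  dimnames = list(sprintf("M%03d", 1:200), paste0("acc", 1:5)))
  q <- setNames(panel[, "acc3"], rownames(panel))
  top <- closest_accessions(panel, q, n = 3, min_shared = 10)
  expect_equal(top$accession[1], "acc3")
  expect_equal(top$distance[1], 0)
  all5 <- closest_accessions(panel, q, n = 99, min_shared = 10)
  expect_equal(nrow(all5), 5L)
  perm <- sample(nrow(panel))
  top_perm <- closest_accessions(panel[perm, ], q[rownames(panel)[perm]],
                                 n = 3, min_shared = 10)
  expect_equal(top, top_perm)
})

test_that("robust subset keeps well-called markers only", {
  panel <- matrix(c(0, 2, NA, 2, 0, 2, 0, 2, 2), 3, 3,
                  dimnames = list(c("M1", "M2", "M3"), c("a", "b", "c")))
  q <- c(M1 = 0, M2 = NA, M3 = 2)
  expect_identical(robust_marker_subset(panel, list(q), min_call_rate = 0.95), "M1")
  expect_setequal(robust_marker_subset(panel, min_call_rate = 0.6), c("M1", "M2", "M3"))
})

test_that("neighbor joining reproduces the three-point closed form", {
  d <- matrix(c(0, 3, 5, 3, 0, 6, 5, 6, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(d)
  expect_identical(newick_string(tr), "(A:1,B:2,C:4);")
  expect_error(neighbor_joining(matrix(c(0, 1, 2, 0), 2)), "at least 3")
  dbad <- d; dbad[1, 2] <- 9
  expect_error(neighbor_joining(dbad), "not symmetric")
})

test_that("neighbor joining recovers the four-taxon additive tree exactly", {
  # tree ((A:1,B:2):1,(C:3,D:4)) as pairwise path lengths
  labs <- c("A", "B", "C", "D")
  d <- matrix(0, 4, 4, dimnames = list(labs, labs))
  d["A", "B"] <- d["B", "A"] <- 3
  d["A", "C"] <- d["C", "A"] <- 5
  d["A", "D"] <- d["D", "A"] <- 6
  d["B", "C"] <- d["C", "B"] <- 6
  d["B", "D"] <- d["D", "B"] <- 7
  d["C", "D"] <- d["D", "C"] <- 7
  tr <- neighbor_joining(d)
  want <- ape::read.tree(text = "((A:1,B:2):1,C:3,D:4);")
  expect_equal(phangorn::RF.dist(tr, want), 0)
  expect_equal(tree_path_distances(tr, labs), d, tolerance = 1e-12)
})

test_that("additive matrices are recovered and match the independent NJ oracle", {
  set.seed(53)
  for (i in 1:20) {
    t0 <- ape::unroot(ape::rtree(8))
    t0$edge.length <- runif(nrow(t0$edge), 0.05, 2)
    D <- ape::cophenetic.phylo(t0)
    tr <- neighbor_joining(D)
    expect_equal(phangorn::RF.dist(tr, t0), 0)
    expect_lt(max(abs(tree_path_distances(tr, rownames(D)) - D)), 1e-9)
    expect_equal(phangorn::RF.dist(tr, ape::nj(D)), 0)  # cross-check vs ape
  }
})

test_that("negative branch estimates are clamped to zero with a message", {
  labs <- c("A", "B", "C", "D")
  set.seed(54)
  d <- matrix(0, 4, 4, dimnames = list(labs, labs))
  d[upper.tri(d)] <- c(10, 2, 3, 9, 10, 2)
  d <- d + t(d)
  expect_message(tr <- neighbor_joining(d), "clamped")
  expect_true(all(tr$edge.length >= 0))
})

test_that("tie-breaking on equidistant inputs is deterministic", {
  labs <- c("W", "X", "Y", "Z")
  d <- matrix(1, 4, 4, dimnames = list(labs, labs)); diag(d) <- 0
  t1 <- neighbor_joining(d)
  t2 <- neighbor_joining(d)
  expect_identical(newick_string(t1), newick_string(t2))
  # lowest label pair (W, X) is joined first
  expect_true(grepl("(W:0.5,X:0.5)", newick_string(t1), fixed = TRUE))
})
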