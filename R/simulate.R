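#' Simulation configuration
#'
#' One configuration object drives all four generators; each reads the
#' fields it needs. Identical configuration and seed give byte-identical
#' outputs. The defaults emulate the study designs the toolkit targets:
#' an annotation pair of 50 loci with 5 novel, 2 fused and 1 split
#' planted relationship; a berry expression matrix of 150 black and 63
#' white samples with a 7-gene regulator module at population
#' correlation 0.9 expressed in black but not white berries, over 500
#' independent background genes with negative-binomial counts; a
#' haplotype pair differing by typed structural variants; and a marker
#' panel evolved on a random binary tree.
#'
#' @param seed integer RNG seed.
#' @param n_genes loci in the annotation pair (and genes per haplotype).
#' @param n_planted_novel,n_planted_fused,n_planted_split planted
#'   relationship counts (fused consumes two adjacent loci each).
#' @param jitter_prob,jitter_bp probability and magnitude of a random
#'   coordinate shift of copied query genes (creates partial overlaps).
#' @param n_black,n_white berry sample counts.
#' @param module_size,module_r planted module size and target pairwise
#'   correlation (log2 scale, within black samples).
#' @param n_noise_genes independent background genes.
#' @param nb_dispersion negative-binomial dispersion (1/size).
#' @param library_size_range,gene_length_range uniform sampling ranges.
#' @param sv_spec data frame of planted SVs: columns `type`
#'   (INS/DEL/INV/TRA/DUP), `size` (bp), `in_gene` (logical: place the
#'   variant inside a gene body).
#' @param n_markers,tree_leaves,marker_flip_rate,flank_len marker-panel
#'   evolution parameters: markers, tree size, per-unit-branch-length
#'   allele flip probability, and flank length embedded around planted
#'   alleles.
#' @return a list of class `"sim_config"`.
#' @export
simulation_config <- function(seed = 1L,
                              n_genes = 50L,
                              n_planted_novel = 5L, n_planted_fused = 2L,
                              n_planted_split = 1L,
                              jitter_prob = 0, jitter_bp = 0L,
                              n_black = 150L, n_white = 63L,
                              module_size = 7L, module_r = 0.9,
                              n_noise_genes = 500L,
                              nb_dispersion = 0.05,
                              library_size_range = c(2e5, 5e5),
                              gene_length_range = c(500L, 5000L),
                              sv_spec = data.frame(
                                type = c("DEL", "DEL", "INS", "INV", "DUP", "TRA"),
                                size = c(1500L, 1000L, 1200L, 300L, 800L, 600L),
                                in_gene = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE),
                                stringsAsFactors = FALSE),
                              n_markers = 1000L, tree_leaves = 60L,
                              marker_flip_rate = 0.1, flank_len = 60L) {
  if (module_r <= 0 || module_r >= 1) stop("module_r must lie in (0, 1)")
  if (any(c(n_genes, n_black, n_white, module_size, n_noise_genes,
            n_markers, tree_leaves) < 0)) stop("counts must be >= 0")
  if (n_planted_novel + 2L * n_planted_fused + n_planted_split > n_genes) {
    stop("planted events exceed n_genes loci")
  }
  structure(as.list(environment()), class = "sim_config")
}

.random_genome <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

.rint <- function(n, range) {
  as.integer(round(runif(n, range[1], range[2])))
}

#' Simulate a reference/query annotation pair with planted relationships
#'
#' Lays out non-overlapping two-exon genes on a random genome and
#' derives a query annotation from the reference: copied genes
#' (covered), query-only genes (novel, absent from the reference),
#' single query genes spanning two adjacent reference genes (fused), and
#' reference genes bisected into two single-exon query genes (split,
#' with equal exon halves). With `jitter_prob > 0`, copied query genes
#' are randomly shifted to create partial overlaps. The truth table
#' lists every planted relationship.
#'
#' @param cfg a [simulation_config()].
#' @param dir optional directory: writes `reference.gff3`, `query.gff3`,
#'   `genome.fa` and `truth.tsv`.
#' @return list with `reference`, `query` (named [gene_model] lists),
#'   `genome` (a [Biostrings::DNAStringSet]) and `truth` (data frame
#'   `kind`, `query_ids`, `ref_ids`).
#' @export
simulate_annotation_pair <- function(cfg = simulation_config(), dir = NULL) {
  set.seed(cfg$seed)
  n_units <- cfg$n_genes - cfg$n_planted_fused
  units <- sample(c(rep("fused", cfg$n_planted_fused),
                    rep("split", cfg$n_planted_split),
                    rep("novel", cfg$n_planted_novel),
                    rep("covered", n_units - cfg$n_planted_fused -
                          cfg$n_planted_split - cfg$n_planted_novel)))
  ref <- list(); qry <- list(); truth <- list()
  rid <- 0L; qid <- 0L
  next_rid <- function() { rid <<- rid + 10L; sprintf("Vv01g%05d", rid) }
  next_qid <- function() { qid <<- qid + 10L; sprintf("Vv01g%05d", qid) }
  pos <- 1000L
  two_exons <- function(at, strand, equal = FALSE) {
    e1 <- .rint(1, c(200, 400)); e2 <- if (equal) e1 else .rint(1, c(200, 400))
    intr <- .rint(1, c(120, 250))
    rbind(c(at, at + e1), c(at + e1 + intr, at + e1 + intr + e2))
  }
  mk_gene <- function(id, exons, strand, cds = NULL) {
    gene_model(id, list(transcript_model(paste0(id, ".1"), "chr1", strand,
                                         exons, cds = cds)))
  }
  for (u in units) {
    strand <- sample(c("+", "-"), 1)
    if (u == "covered") {
      ex <- two_exons(pos, strand)
      r <- mk_gene(next_rid(), ex, strand)
      qex <- ex
      if (cfg$jitter_prob > 0 && runif(1) < cfg$jitter_prob && cfg$jitter_bp > 0) {
        shift <- sample(seq(-cfg$jitter_bp, cfg$jitter_bp), 1)
        qex <- pmax(qex + shift, 0L)
      }
      q <- mk_gene(next_qid(), qex, strand)
      ref[[r$gene_id]] <- r; qry[[q$gene_id]] <- q
      truth[[length(truth) + 1L]] <- data.frame(
        kind = "covered", query_ids = q$gene_id, ref_ids = r$gene_id)
      pos <- max(ex[, 2])
    } else if (u == "novel") {
      ex <- two_exons(pos, strand)
      q <- mk_gene(next_qid(), ex, strand)
      qry[[q$gene_id]] <- q
      truth[[length(truth) + 1L]] <- data.frame(
        kind = "novel", query_ids = q$gene_id, ref_ids = "")
      pos <- max(ex[, 2])
    } else if (u == "split") {
      ex <- two_exons(pos, strand, equal = TRUE)
      r <- mk_gene(next_rid(), ex, strand)
      q1 <- mk_gene(next_qid(), ex[1, , drop = FALSE], strand)
      q2 <- mk_gene(next_qid(), ex[2, , drop = FALSE], strand)
      ref[[r$gene_id]] <- r; qry[[q1$gene_id]] <- q1; qry[[q2$gene_id]] <- q2
      truth[[length(truth) + 1L]] <- data.frame(
        kind = "split", query_ids = paste(q1$gene_id, q2$gene_id, sep = ","),
        ref_ids = r$gene_id)
      pos <- max(ex[, 2])
    } else { # fused: two adjacent reference genes, one spanning query gene
      ex1 <- two_exons(pos, strand)
      gap <- .rint(1, c(150, 250))
      ex2 <- two_exons(max(ex1[, 2]) + gap, strand)
      r1 <- mk_gene(next_rid(), ex1, strand)
      r2 <- mk_gene(next_rid(), ex2, strand)
      q <- mk_gene(next_qid(), rbind(ex1, ex2), strand)
      ref[[r1$gene_id]] <- r1; ref[[r2$gene_id]] <- r2; qry[[q$gene_id]] <- q
      truth[[length(truth) + 1L]] <- data.frame(
        kind = "fused", query_ids = q$gene_id,
        ref_ids = paste(r1$gene_id, r2$gene_id, sep = ","))
      pos <- max(ex2[, 2])
    }
    pos <- pos + .rint(1, c(300, 800))
  }
  genome <- Biostrings::DNAStringSet(setNames(.random_genome(pos + 1000L), "chr1"))
  truth <- do.call(rbind, truth)
  out <- list(reference = ref, query = qry, genome = genome, truth = truth)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_gff3(ref, file.path(dir, "reference.gff3"))
    write_gff3(qry, file.path(dir, "query.gff3"))
    write_genome(genome, file.path(dir, "genome.fa"))
    write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  out
}

#' Simulate a berry expression matrix with a planted regulator module
#'
#' Emulates a black/white berry study: a latent anthocyanin-pathway
#' activity factor per black sample drives `module_size` genes whose
#' log2 expression is `baseline + slope * factor`, with the slope set
#' from the target pairwise correlation `module_r` (after a delta-method
#' allowance for negative-binomial counting noise on the log2 scale).
#' In white samples the module genes sit at a flat, near-zero level
#' (0.01 on the linear scale - essentially undetectable, and carrying no
#' echo of the black profile). Background genes vary independently of
#' berry color. Counts are negative binomial with per-sample library
#' sizes and per-gene lengths.
#'
#' @param cfg a [simulation_config()].
#' @param dir optional directory: writes `counts.tsv`, `lengths.tsv`,
#'   `metadata.tsv` and `truth.tsv`.
#' @return list with `counts` (a [counts_table]), `metadata` (data
#'   frame) and `truth` (list: `module_genes`, `seed_gene`, `colors`).
#' @export
simulate_expression <- function(cfg = simulation_config(), dir = NULL) {
  set.seed(cfg$seed)
  n_genes <- cfg$module_size + cfg$n_noise_genes
  if (cfg$module_size >= n_genes && cfg$n_noise_genes == 0 && cfg$module_size == 0) {
    stop("empty design")
  }
  gene_ids <- sprintf("Vv01g%05d", seq_len(n_genes) * 10L)
  module <- gene_ids[seq_len(cfg$module_size)]
  n_samp <- cfg$n_black + cfg$n_white
  sample_ids <- sprintf("S%03d", seq_len(n_samp))
  color <- c(rep("black", cfg$n_black), rep("white", cfg$n_white))
  lengths <- setNames(.rint(n_genes, cfg$gene_length_range), gene_ids)
  libsize <- .rint(n_samp, cfg$library_size_range)

  log2x <- matrix(0, n_genes, n_samp, dimnames = list(gene_ids, sample_ids))
  bg <- setdiff(gene_ids, module)
  base_bg <- runif(length(bg), 1, 9)
  log2x[bg, ] <- base_bg + matrix(rnorm(length(bg) * n_samp, 0, 0.5),
                                  length(bg), n_samp)
  if (cfg$module_size > 0) {
    # module baselines sit well above the background (log2 8-12 vs 1-9) so
    # even extreme latent draws leave the module visibly elevated; the
    # slope is the smallest achieving module_r once NB noise is accounted
    base_mod <- runif(cfg$module_size, 8, 12)
    slope <- 1.0
    nb_log2_var <- cfg$nb_dispersion / log(2)^2
    eps_var <- max(slope^2 * (1 - cfg$module_r) / cfg$module_r - nb_log2_var, 1e-3)
    f <- rnorm(cfg$n_black)
    black_idx <- which(color == "black")
    log2x[module, black_idx] <- base_mod +
      slope * matrix(f, cfg$module_size, cfg$n_black, byrow = TRUE) +
      matrix(rnorm(cfg$module_size * cfg$n_black, 0, sqrt(eps_var)),
             cfg$module_size, cfg$n_black)
    if (cfg$n_white > 0) {
      # flat, near-zero level: white berries do not express the module at
      # all, so their residual signal must not echo the black profile
      log2x[module, color == "white"] <- log2(0.01)
    }
  }
  x <- 2^log2x
  xl <- x * lengths
  mu <- sweep(sweep(xl, 2, colSums(xl), "/"), 2, libsize, "*")
  counts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / cfg$nb_dispersion),
                   n_genes, n_samp, dimnames = list(gene_ids, sample_ids))
  ct <- counts_table(counts, lengths)
  metadata <- data.frame(
    sample_id = sample_ids, organ = "berry",
    cultivar = sprintf("cv%02d", (seq_len(n_samp) - 1L) %% 20L + 1L),
    skin_color = color, stage = "ripening", project = "SIM1",
    stringsAsFactors = FALSE)
  truth <- list(module_genes = module, seed_gene = if (length(module)) module[1] else NA,
                colors = setNames(color, sample_ids))
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write.table(data.frame(gene_id = gene_ids, counts, check.names = FALSE),
                file.path(dir, "counts.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(data.frame(gene_id = gene_ids, length_bp = unname(lengths)),
                file.path(dir, "lengths.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(metadata, file.path(dir, "metadata.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(data.frame(gene_id = module, role = "module"),
                file.path(dir, "truth.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(counts = ct, metadata = metadata, truth = truth)
}

#' Simulate a haplotype pair differing by known structural variants
#'
#' Builds haplotype 1 as a random genome with large two-exon genes, then
#' derives haplotype 2 by applying the configured SVs: deletions remove
#' sequence, insertions add it, inversions reverse-complement a segment
#' in place, duplications are tandem, and translocations move a segment
#' to an intergenic acceptor site. Variants flagged `in_gene` are placed
#' wholly inside a distinct gene body (gene spans are sized to fit the
#' largest variant); others fall in intergenic gaps. Coordinates of
#' genes untouched by any SV are lifted to haplotype 2; genes
#' overlapping an SV (exactly the impacted ones) are omitted from the
#' haplotype-2 annotation. The truth lists, per planted SV, its target
#' gene and whether it qualifies as impacting under the
#' indel-size-exceeding-1-kb rule.
#'
#' @param cfg a [simulation_config()].
#' @param dir optional directory: writes `hap1.fa`, `hap1.gff3`,
#'   `hap2.fa`, `hap2.gff3` and `sv.tsv`.
#' @return list with `hap1`, `hap2` (each: `genome`, `genes`), `svs`
#'   (data frame in the [read_sv_tsv()] dialect with `size`), and
#'   `truth` (data frame `type`, `size`, `target_gene`; plus attributes
#'   via columns `indel_impact`, `inv_tra_impact`).
#' @export
simulate_haplotypes <- function(cfg = simulation_config(), dir = NULL) {
  set.seed(cfg$seed)
  spec <- cfg$sv_spec
  n_in_gene <- sum(spec$in_gene)
  n_genes <- max(cfg$n_genes, n_in_gene)
  max_sv <- if (nrow(spec)) max(spec$size) else 0L
  exon_len <- max(800L, as.integer(ceiling(max_sv / 2)) + 200L)
  intron_len <- 500L
  gap_len <- max(3000L, max_sv + 1000L)
  pos <- gap_len
  genes <- list()
  for (i in seq_len(n_genes)) {
    id <- sprintf("Vv01g%05d", i * 10L)
    strand <- sample(c("+", "-"), 1)
    ex <- rbind(c(pos, pos + exon_len),
                c(pos + exon_len + intron_len, pos + 2L * exon_len + intron_len))
    genes[[id]] <- gene_model(id, list(transcript_model(paste0(id, ".1"),
                                                        "chr1", strand, ex)))
    pos <- max(ex[, 2]) + gap_len
  }
  glen <- pos + gap_len
  hap1 <- .random_genome(glen)

  # place SVs: in-gene ones inside distinct gene bodies, others mid-gap
  target_idx <- sample(seq_len(n_genes), n_in_gene)
  svs <- data.frame(start = integer(0), end = integer(0), type = character(0),
                    size = integer(0), target = character(0),
                    stringsAsFactors = FALSE)
  ti <- 0L
  for (s in seq_len(nrow(spec))) {
    type <- spec$type[s]; size <- spec$size[s]
    if (spec$in_gene[s]) {
      ti <- ti + 1L
      g <- genes[[target_idx[ti]]]
      span <- g$end - g$start
      if (type == "INS") { start <- g$start + 100L; end <- start }
      else {
        if (size > span - 200L) stop("SV size ", size, " does not fit in gene span")
        start <- g$start + 100L; end <- start + size
      }
      target <- g$gene_id
    } else {
      # first gap is SV-free; use the gap after gene s (cycled)
      gi <- (s - 1L) %% n_genes + 1L
      gend <- genes[[gi]]$end
      start <- gend + 1000L
      end <- if (type == "INS") start else start + size
      target <- ""
    }
    svs <- rbind(svs, data.frame(start = start, end = end, type = type,
                                 size = size, target = target,
                                 stringsAsFactors = FALSE))
  }
  if (nrow(svs) > 1L) {
    o <- order(svs$start)
    svs <- svs[o, , drop = FALSE]
    if (any(svs$start[-1L] < pmax(svs$end, svs$start + 1L)[-nrow(svs)])) {
      stop("overlapping SV placements")
    }
  }

  # apply to hap2 left to right, tracking the coordinate offset
  ins_seq <- function(n) .random_genome(n)
  pieces <- character(0)
  cursor <- 0L
  delta <- integer(nrow(svs))  # cumulative length change after each SV
  b_start <- integer(nrow(svs)); b_end <- integer(nrow(svs))
  shift <- 0L
  tra_tail <- character(0)
  for (s in seq_len(nrow(svs))) {
    st <- svs$start[s]; en <- svs$end[s]; type <- svs$type[s]; size <- svs$size[s]
    pieces <- c(pieces, substr(hap1, cursor + 1L, st))
    seg <- substr(hap1, st + 1L, en)
    if (type == "DEL") {
      b_start[s] <- st + shift; b_end[s] <- st + shift
      shift <- shift - size
    } else if (type == "INS") {
      pieces <- c(pieces, ins_seq(size))
      b_start[s] <- st + shift; b_end[s] <- st + shift + size
      shift <- shift + size
    } else if (type == "INV") {
      pieces <- c(pieces, .revcomp_chr(seg))
      b_start[s] <- st + shift; b_end[s] <- en + shift
    } else if (type == "DUP") {
      pieces <- c(pieces, seg, seg)
      b_start[s] <- st + shift; b_end[s] <- en + shift + size
      shift <- shift + size
    } else if (type == "TRA") {
      # segment moves to the very end of the chromosome
      tra_tail <- c(tra_tail, seg)
      b_start[s] <- NA_integer_; b_end[s] <- NA_integer_
      shift <- shift - size
    }
    cursor <- en
    delta[s] <- shift
  }
  pieces <- c(pieces, substr(hap1, cursor + 1L, nchar(hap1)))
  hap2 <- paste(c(pieces, tra_tail), collapse = "")
  # destination coordinates of translocated segments (appended in order)
  tail_at <- nchar(hap2) - sum(nchar(tra_tail))
  for (s in which(svs$type == "TRA")) {
    b_start[s] <- tail_at; b_end[s] <- tail_at + svs$size[s]
    tail_at <- tail_at + svs$size[s]
  }

  lift <- function(p) {
    k <- which(svs$end <= p)
    p + if (length(k)) delta[max(k)] else 0L
  }
  touched <- svs$target[svs$target != ""]
  hap2_genes <- list()
  for (g in genes) {
    if (g$gene_id %in% touched) next
    tx <- g$transcripts[[1]]
    ex2 <- cbind(vapply(tx$exons$start, lift, integer(1)),
                 vapply(tx$exons$end, lift, integer(1)))
    hap2_genes[[g$gene_id]] <- gene_model(
      g$gene_id, list(transcript_model(tx$tx_id, "chr1", tx$strand, ex2)))
  }

  sv_out <- data.frame(chrom_a = rep("chr1", nrow(svs)), start_a = svs$start,
                       end_a = svs$end,
                       chrom_b = rep("chr1", nrow(svs)), start_b = b_start, end_b = b_end,
                       type = svs$type, size = svs$size,
                       stringsAsFactors = FALSE)
  truth <- data.frame(type = svs$type, size = svs$size, target_gene = svs$target,
                      indel_impact = svs$type %in% c("INS", "DEL") &
                        svs$size > 1000L & svs$target != "",
                      inv_tra_impact = svs$type %in% c("INV", "TRA") &
                        svs$target != "",
                      stringsAsFactors = FALSE)
  out <- list(
    hap1 = list(genome = Biostrings::DNAStringSet(setNames(hap1, "chr1")),
                genes = genes),
    hap2 = list(genome = Biostrings::DNAStringSet(setNames(hap2, "chr1")),
                genes = hap2_genes),
    svs = sv_out, truth = truth)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_genome(out$hap1$genome, file.path(dir, "hap1.fa"))
    write_genome(out$hap2$genome, file.path(dir, "hap2.fa"))
    write_gff3(genes, file.path(dir, "hap1.gff3"))
    write_gff3(hap2_genes, file.path(dir, "hap2.gff3"))
    write_sv_tsv(sv_out, file.path(dir, "sv.tsv"))
  }
  out
}

#' Simulate a genotype panel evolved on a known tree
#'
#' Draws a random binary tree, evolves biallelic markers along it by
#' independent per-branch allele flips (flip probability proportional to
#' branch length), emits the leaf genotypes as a haploid dosage panel
#' (0/2), and embeds one leaf's alleles into a synthetic two-contig
#' assembly as flank + allele + flank sites so the full
#' call-markers / distance / neighbor-joining chain can be scored
#' against the generating tree.
#'
#' @param cfg a [simulation_config()].
#' @param dir optional directory: writes `panel.tsv`, `markers.tsv`,
#'   `query.fa` and `true_tree.nwk`.
#' @return list with `panel` (dosage matrix), `markers` (definition data
#'   frame), `query_assembly` ([Biostrings::DNAStringSet]),
#'   `query_leaf` (the source accession) and `tree` (the generating
#'   `"phylo"`).
#' @export
simulate_marker_panel <- function(cfg = simulation_config(), dir = NULL) {
  set.seed(cfg$seed)
  if (cfg$tree_leaves < 4L) stop("tree_leaves must be >= 4")
  tree <- ape::rtree(cfg$tree_leaves,
                     tip.label = sprintf("ACC%03d", seq_len(cfg$tree_leaves)))
  tree <- stats::reorder(tree, "cladewise")
  n_node <- cfg$tree_leaves + tree$Nnode
  root <- cfg$tree_leaves + 1L
  states <- matrix(NA_integer_, cfg$n_markers, n_node)
  states[, root] <- 0L
  for (e in seq_len(nrow(tree$edge))) {
    par <- tree$edge[e, 1]; child <- tree$edge[e, 2]
    p <- min(0.4, cfg$marker_flip_rate * tree$edge.length[e])
    flip <- rbinom(cfg$n_markers, 1L, p)
    states[, child] <- (states[, par] + flip) %% 2L
  }
  marker_ids <- sprintf("M%05d", seq_len(cfg$n_markers))
  panel <- 2L * states[, seq_len(cfg$tree_leaves), drop = FALSE]
  dimnames(panel) <- list(marker_ids, tree$tip.label)

  fl <- cfg$flank_len
  markers <- data.frame(
    marker_id = marker_ids,
    left_flank = vapply(seq_len(cfg$n_markers), function(i) .random_genome(fl), ""),
    right_flank = vapply(seq_len(cfg$n_markers), function(i) .random_genome(fl), ""),
    allele_ref = sample(c("A", "C", "G", "T"), cfg$n_markers, replace = TRUE),
    stringsAsFactors = FALSE)
  markers$allele_alt <- vapply(markers$allele_ref, function(a) {
    sample(setdiff(c("A", "C", "G", "T"), a), 1)
  }, "")

  query_leaf <- sample(tree$tip.label, 1)
  q_state <- states[, match(query_leaf, tree$tip.label)]
  site <- paste0(markers$left_flank,
                 ifelse(q_state == 1L, markers$allele_alt, markers$allele_ref),
                 markers$right_flank)
  spacer <- vapply(seq_len(cfg$n_markers), function(i) .random_genome(20L), "")
  half <- ceiling(cfg$n_markers / 2)
  contig <- function(idx) paste(paste0(spacer[idx], site[idx]), collapse = "")
  query_assembly <- Biostrings::DNAStringSet(c(
    ctg1 = contig(seq_len(half)),
    ctg2 = contig(seq(half + 1L, cfg$n_markers))))

  out <- list(panel = panel, markers = markers, query_assembly = query_assembly,
              query_leaf = query_leaf, tree = tree)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_genotype_panel(panel, file.path(dir, "panel.tsv"))
    write.table(markers, file.path(dir, "markers.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write_genome(query_assembly, file.path(dir, "query.fa"))
    write_newick(tree, file.path(dir, "true_tree.nwk"))
  }
  out
}
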