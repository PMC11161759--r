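#' Write a phylogenetic tree to Newick
#'
#' Serializes an [ape::read.tree()]-style `"phylo"` object with branch
#' lengths at full double precision. Labels containing whitespace or
#' Newick metacharacters are single-quoted (embedded quotes doubled),
#' which [ape::read.tree()] parses back losslessly.
#'
#' @param tree a `"phylo"` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  writeLines(newick_string(tree), path)
  invisible(path)
}

#' @rdname write_newick
#' @return `newick_string()` returns the Newick string itself.
#' @export
newick_string <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  has_len <- !is.null(tree$edge.length)
  lab <- function(x) {
    if (grepl("[\\s()\\[\\]:;,']", x, perl = TRUE)) {
      paste0("'", gsub("'", "''", x), "'")
    } else x
  }
  fmt_len <- function(l) {
    if (!has_len || is.na(l)) "" else paste0(":", sprintf("%.17g", l))
  }
  rec <- function(node) {
    if (node <= ntip) return(lab(tree$tip.label[node]))
    rows <- kids[[as.character(node)]]
    parts <- vapply(rows, function(e) {
      paste0(rec(tree$edge[e, 2]),
             fmt_len(if (has_len) tree$edge.length[e] else NA_real_))
    }, character(1))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  paste0(rec(root), ";")
}

#' Read a Newick tree
#' @param path Newick file.
#' @return a `"phylo"` object.
#' @export
read_newick <- function(path) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("failed to parse Newick file '", path, "'")
  tr
}
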