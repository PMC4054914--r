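## Bootstrap neighbor-joining phylogeny of transposase proteins.

#' Pairwise identity distance matrix of proteins
#'
#' Distances are `1 - fractional identity` from global BLOSUM62 alignments
#' (identity over alignment columns, as in
#' [interfamily_protein_comparison()]).
#'
#' @param seqs named character vector of protein sequences (>= 2).
#' @return symmetric numeric matrix with zero diagonal, entries in [0, 1].
#' @export
protein_distance_matrix <- function(seqs) {
  n <- length(seqs)
  stopifnot(n >= 2L)
  labs <- names(seqs)
  if (is.null(labs)) labs <- paste0("s", seq_len(n))
  d <- matrix(0, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      cmp <- interfamily_protein_comparison(seqs[[i]], seqs[[j]])
      d[i, j] <- d[j, i] <- 1 - cmp$identity_pct / 100
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor joining (via \pkg{ape}); deterministic for a fixed
#' label order.
#'
#' @param dist symmetric distance matrix with labels.
#' @return an [ape::nj()] `phylo` tree (unrooted).
#' @export
nj_tree <- function(dist) {
  stopifnot(is.matrix(dist), nrow(dist) >= 3L,
            isTRUE(all.equal(dist, t(dist))))
  ape::nj(stats::as.dist(dist))
}

## Identity distances from rows of a (possibly column-resampled) alignment:
## identity over columns where neither sequence is gapped.
msa_identity_dist <- function(rows_mat) {
  n <- nrow(rows_mat)
  d <- matrix(0, n, n, dimnames = list(rownames(rows_mat), rownames(rows_mat)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- rows_mat[i, ] != "-" & rows_mat[j, ] != "-"
      id <- if (any(ok)) mean(rows_mat[i, ok] == rows_mat[j, ok]) else 0
      d[i, j] <- d[j, i] <- 1 - id
    }
  }
  d
}

#' Bootstrap-supported neighbor-joining tree of transposases
#'
#' Builds a center-star protein alignment, computes identity distances, the
#' NJ tree, and bootstrap support by resampling alignment columns with
#' replacement `n_replicates` times; support is the percentage of replicate
#' trees containing each internal bipartition.
#'
#' @param seqs named character vector of protein sequences (>= 4 for
#'   meaningful supports).
#' @param n_replicates number of bootstrap replicates (> 0); 1,000 is the
#'   conventional choice.
#' @param seed integer seed for resampling.
#' @param exemplar_index center sequence for the alignment.
#' @return list: `tree` (a `phylo` with `node.label` = support %),
#'   `distances`, `msa`, `support`.
#' @export
bootstrap_nj <- function(seqs, n_replicates = 1000L, seed = 1L,
                         exemplar_index = 1L) {
  if (n_replicates <= 0L) stop("n_replicates must be positive")
  msa <- build_msa(seqs, exemplar_index, type = "protein")
  rows_mat <- do.call(rbind, strsplit(msa$rows, "", fixed = TRUE))
  rownames(rows_mat) <- msa$ids
  d <- msa_identity_dist(rows_mat)
  tree <- nj_tree(d)
  ncol_aln <- ncol(rows_mat)
  boot <- with_seed(seed, {
    lapply(seq_len(n_replicates), function(b) {
      cols <- sample.int(ncol_aln, ncol_aln, replace = TRUE)
      nj_tree(msa_identity_dist(rows_mat[, cols, drop = FALSE]))
    })
  })
  counts <- ape::prop.clades(tree, boot, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  support <- round(100 * counts / n_replicates)
  tree$node.label <- support
  list(tree = tree, distances = d, msa = msa, support = support)
}

#' Write a tree with supports as Newick
#'
#' @param tree a `phylo` (node labels carry bootstrap support).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tree_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
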