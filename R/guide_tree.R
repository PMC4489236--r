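# Guide-tree machinery: pairwise distances, neighbor joining, column
# bootstrap of the reference MSA, and Newick I/O. Trees are ape "phylo"
# objects, rooted and strictly binary, with branch lengths.

#' Uncorrected p-distances between alignment rows
#'
#' Pairwise deletion: sites where either sequence has a gap are ignored;
#' the distance is the mismatch fraction over the remaining shared sites.
#' Pairs with zero shared sites get distance 1 by convention (with a
#' warning). No multiple-hit correction is applied; substitute a
#' corrected matrix if desired, [nj_tree()] only needs a distance matrix.
#'
#' @param msa an `msa` with at least 2 sequences.
#' @return symmetric numeric matrix with sequence ids as dimnames.
#' @export
p_distance <- function(msa) {
  if (length(msa) < 2L) stop("need at least 2 sequences")
  m <- msa_matrix(msa)
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(names(msa), names(msa)))
  none_shared <- FALSE
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      shared <- m[i, ] != 0L & m[j, ] != 0L
      ns <- sum(shared)
      if (ns == 0L) {
        d[i, j] <- d[j, i] <- 1
        none_shared <- TRUE
      } else {
        d[i, j] <- d[j, i] <- sum(m[i, shared] != m[j, shared]) / ns
      }
    }
  }
  if (none_shared) warning("sequence pair(s) share no ungapped sites; distance set to 1")
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Classic NJ (Q-criterion agglomeration) with deterministic tie-breaking
#' (lowest index pair) and negative branch-length estimates clamped to
#' zero, followed by midpoint rooting. The returned tree is rooted and
#' strictly binary, suitable as a progressive-alignment guide tree.
#'
#' @param d symmetric distance matrix with labels as dimnames.
#' @return rooted binary `phylo` object.
#' @export
nj_tree <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d)) stop("distance must be square")
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix must be symmetric")
  labels <- rownames(d)
  n <- nrow(d)
  if (n < 2L) stop("need at least 2 labels")
  if (n == 2L) {
    nwk <- sprintf("(%s:%.10g,%s:%.10g);", labels[1L], d[1, 2] / 2,
                   labels[2L], d[1, 2] / 2)
    return(finalize_tree(ape::read.tree(text = nwk)))
  }
  # active nodes carry a newick fragment for their subtree
  frag <- labels
  dm <- d
  while (nrow(dm) > 3L) {
    r <- nrow(dm)
    rs <- rowSums(dm)
    q <- (r - 2) * dm - outer(rs, rs, "+")
    diag(q) <- Inf
    k <- which(q == min(q), arr.ind = TRUE)
    k <- k[order(pmin(k[, 1], k[, 2]), pmax(k[, 1], k[, 2])), , drop = FALSE]
    i <- min(k[1L, ]); j <- max(k[1L, ])
    vi <- max(0, dm[i, j] / 2 + (rs[i] - rs[j]) / (2 * (r - 2)))
    vj <- max(0, dm[i, j] - vi)
    newfrag <- sprintf("(%s:%.10g,%s:%.10g)", frag[i], vi, frag[j], vj)
    dnew <- (dm[i, ] + dm[j, ] - dm[i, j]) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    dm2 <- rbind(cbind(dm[keep, keep, drop = FALSE], dnew[keep]),
                 c(dnew[keep], 0))
    dm <- dm2
    frag <- c(frag[keep], newfrag)
  }
  # final three nodes: unrooted star resolved by the three-point formulas
  a <- max(0, (dm[1, 2] + dm[1, 3] - dm[2, 3]) / 2)
  b <- max(0, (dm[1, 2] + dm[2, 3] - dm[1, 3]) / 2)
  c3 <- max(0, (dm[1, 3] + dm[2, 3] - dm[1, 2]) / 2)
  nwk <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                 frag[1L], a, frag[2L], b, frag[3L], c3)
  finalize_tree(phangorn::midpoint(ape::read.tree(text = nwk)))
}

# enforce: rooted, binary, branch lengths present and nonnegative
finalize_tree <- function(tree) {
  if (is.null(tree$edge.length)) tree$edge.length <- rep(0, nrow(tree$edge))
  tree$edge.length[is.na(tree$edge.length) | tree$edge.length < 0] <- 0
  if (!ape::is.rooted(tree)) tree <- phangorn::midpoint(tree)
  if (!ape::is.binary(tree)) tree <- ape::multi2di(tree, random = FALSE)
  tree$edge.length[is.na(tree$edge.length) | tree$edge.length < 0] <- 0
  tree
}

#' Column bootstrap of an alignment
#'
#' Resamples the alignment's columns uniformly with replacement (using
#' the current RNG state), for guide-tree re-estimation only — the
#' resampled object is never itself an alignment of the data.
#'
#' @param msa an `msa`.
#' @return an `msa` with the same rows over resampled columns.
#' @export
bootstrap_msa <- function(msa) {
  L <- msa_ncol(msa)
  idx <- sample.int(L, L, replace = TRUE)
  m <- msa_matrix(msa)[, idx, drop = FALSE]
  matrix_to_msa(m)
}

#' Read a guide tree from a Newick file
#'
#' The tree is validated against the dataset ids when given; unrooted or
#' multifurcating inputs are made rooted/binary (midpoint rooting,
#' deterministic resolution of polytomies with zero-length branches).
#'
#' @param path Newick file.
#' @param ids optional character vector of expected leaf labels.
#' @return rooted binary `phylo`.
#' @export
read_newick <- function(path, ids = NULL) {
  tree <- tryCatch(suppressWarnings(ape::read.tree(path)),
                   error = function(e) stop("failed to parse Newick: ",
                                            conditionMessage(e)))
  if (is.null(tree)) stop("failed to parse Newick file ", path)
  if (any(duplicated(tree$tip.label))) stop("duplicate leaf labels in tree")
  if (!is.null(ids)) {
    if (!setequal(tree$tip.label, ids)) {
      stop("tree leaves do not match dataset ids (missing: ",
           paste(setdiff(ids, tree$tip.label), collapse = ","),
           "; extra: ", paste(setdiff(tree$tip.label, ids), collapse = ","), ")")
    }
  }
  finalize_tree(tree)
}

#' Write a tree as Newick
#' @param tree a `phylo`.
#' @param path output path.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

# --- merge schedule ---------------------------------------------------
# Nested representation with deterministic child order (child containing
# the lexicographically smallest leaf id first). The post-order index of
# each internal node defines the orientation-bit indexing.

tree_to_nested <- function(tree) {
  n_tip <- length(tree$tip.label)
  kids <- vector("list", n_tip + tree$Nnode)
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
    kids[[p]] <- c(kids[[p]], ch)
  }
  len <- numeric(n_tip + tree$Nnode)
  len[tree$edge[, 2L]] <- tree$edge.length
  build <- function(node) {
    if (node <= n_tip) {
      return(list(leaf = TRUE, label = tree$tip.label[node],
                  len = len[node], min_leaf = tree$tip.label[node]))
    }
    ch <- lapply(kids[[node]], build)
    if (length(ch) != 2L) stop("tree is not binary")
    ord <- order(vapply(ch, `[[`, character(1), "min_leaf"))
    ch <- ch[ord]
    list(leaf = FALSE, left = ch[[1L]], right = ch[[2L]], len = len[node],
         min_leaf = min(ch[[1L]]$min_leaf, ch[[2L]]$min_leaf))
  }
  root <- setdiff(tree$edge[, 1L], tree$edge[, 2L])[1L]
  build(root)
}

# number of internal nodes = n_leaves - 1 for a rooted binary tree
n_merges <- function(tree) length(tree$tip.label) - 1L
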