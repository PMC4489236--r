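# Internal progressive aligner. Profiles are integer code matrices
# (rows = sequences) during alignment; the public surface speaks `msa`.
# The head/tail (HoT) device: a merge with orientation = TAIL reverses
# both profiles before the DP and un-reverses the merged result. Because
# the traceback tie-break is a fixed state preference, HEAD and TAIL are
# the two deterministic extremes of the co-optimal alignment set; their
# scores are always equal.

HEAD <- 0L
TAIL <- 1L

# merge two integer-code profile matrices; returns list(matrix, score)
merge_matrices <- function(Pa, Pb, scheme, reversed = FALSE) {
  wA <- mean(Pa != 0L)
  wB <- mean(Pb != 0L)
  if (reversed) {
    Pa <- Pa[, rev(seq_len(ncol(Pa))), drop = FALSE]
    Pb <- Pb[, rev(seq_len(ncol(Pb))), drop = FALSE]
  }
  res <- gotoh_profile_align(Pa, Pb, score_table(scheme),
                             raw_gap_open(scheme), raw_gap_extend(scheme),
                             wA, wB,
                             scheme$terminal_gap_policy == "free_ends")
  path <- res$path
  len <- length(path)
  Ma <- matrix(0L, nrow(Pa), len)
  Mb <- matrix(0L, nrow(Pb), len)
  Ma[, path != 3L] <- Pa
  Mb[, path != 2L] <- Pb
  merged <- rbind(Ma, Mb)
  rownames(merged) <- c(rownames(Pa), rownames(Pb))
  if (reversed) merged <- merged[, rev(seq_len(len)), drop = FALSE]
  list(matrix = merged, score = res$score)
}

#' Align two profiles (sub-alignments) globally with affine gaps
#'
#' Column-column substitution score is the mean of the substitution
#' scores over all cross pairs of rows (gap and X entries contribute 0);
#' gap open/extend penalties for a gap column inserted into a profile are
#' scaled by that profile's occupancy (fraction of non-gap cells).
#'
#' @param A,B `msa` objects (a single sequence is a one-row `msa`) over
#'   disjoint sequence sets.
#' @param scheme a [scoring_scheme()].
#' @param reversed if `TRUE`, align the character-reversed profiles and
#'   un-reverse the result (the "tail" co-optimum).
#' @return an `msa` containing all rows of `A` then `B`, with attribute
#'   `"score"` carrying the optimal alignment score.
#' @export
align_profiles <- function(A, B, scheme = scoring_scheme(), reversed = FALSE) {
  if (length(intersect(names(A), names(B)))) {
    stop("profiles share sequence ids: ",
         paste(intersect(names(A), names(B)), collapse = ","))
  }
  res <- merge_matrices(msa_matrix(A), msa_matrix(B), scheme, reversed)
  out <- matrix_to_msa(res$matrix)
  attr(out, "score") <- res$score
  out
}

#' Global pairwise alignment of two sequences
#'
#' @param a,b single named sequences (length-1 named character vectors).
#' @param scheme a [scoring_scheme()].
#' @param reversed tail orientation flag, see [align_profiles()].
#' @return list with `msa` (2-row alignment) and `score`.
#' @export
align_pair <- function(a, b, scheme = scoring_scheme(), reversed = FALSE) {
  Pa <- matrix(aa_code(strsplit(unname(a), "")[[1L]]), nrow = 1L,
               dimnames = list(names(a)))
  Pb <- matrix(aa_code(strsplit(unname(b), "")[[1L]]), nrow = 1L,
               dimnames = list(names(b)))
  res <- merge_matrices(Pa, Pb, scheme, reversed)
  list(msa = matrix_to_msa(res$matrix), score = res$score)
}

#' Progressive alignment along a guide tree
#'
#' Profiles are merged at the internal nodes of the rooted binary guide
#' tree in post-order; children are visited in a deterministic order
#' (subtree containing the lexicographically smallest leaf id first), so
#' the i-th entry of `orientation` addresses the i-th internal node met
#' in that post-order. Bit value 0 = HEAD (align as given), 1 = TAIL
#' (align reversed). Output row order follows the input sequence order.
#'
#' @param seqs named character vector of ungapped sequences.
#' @param tree rooted binary `phylo` whose leaves are `names(seqs)`.
#' @param scheme a [scoring_scheme()].
#' @param orientation integer vector of 0/1 of length `length(seqs) - 1`,
#'   or `NULL` for all-HEAD.
#' @return an `msa` over `seqs`, deterministic given all arguments.
#' @export
progressive_align <- function(seqs, tree, scheme = scoring_scheme(),
                              orientation = NULL) {
  seqs <- validate_seqs(seqs)
  if (!setequal(tree$tip.label, names(seqs))) {
    stop("tree leaves do not match sequence ids")
  }
  nb <- length(seqs) - 1L
  if (is.null(orientation)) orientation <- rep(HEAD, nb)
  orientation <- as.integer(orientation)
  if (length(orientation) != nb || any(!orientation %in% c(0L, 1L))) {
    stop("orientation must be ", nb, " bits (0 = HEAD, 1 = TAIL)")
  }
  if (length(seqs) == 1L) return(as_msa(seqs))
  nested <- tree_to_nested(tree)
  counter <- new.env(parent = emptyenv())
  counter$i <- 0L
  rec <- function(node) {
    if (node$leaf) {
      return(matrix(aa_code(strsplit(seqs[[node$label]], "")[[1L]]),
                    nrow = 1L, dimnames = list(node$label)))
    }
    left <- rec(node$left)
    right <- rec(node$right)
    counter$i <- counter$i + 1L
    merge_matrices(left, right, scheme,
                   reversed = orientation[counter$i] == TAIL)$matrix
  }
  m <- rec(nested)
  matrix_to_msa(m[names(seqs), , drop = FALSE])
}
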