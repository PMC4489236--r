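# Fixture generators and independent oracles. Oracles are deliberately
# naive (enumeration / all-against-all scans) and share no code with the
# implementation paths they check.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

random_seqs <- function(n, len_range = c(8L, 15L), alphabet = AA20,
                        ids = sprintf("s%02d", seq_len(n))) {
  lens <- sample(len_range[1L]:len_range[2L], n, replace = TRUE)
  setNames(vapply(lens, function(L) {
    paste(sample(alphabet, L, replace = TRUE), collapse = "")
  }, character(1)), ids)
}

# random valid MSA: residue matrix with random gaps, all-gap columns dropped
random_msa <- function(n = 5L, n_col = 12L, gap_prob = 0.2,
                       alphabet = AA20) {
  repeat {
    m <- matrix(sample(alphabet, n * n_col, replace = TRUE), n, n_col)
    m[matrix(runif(n * n_col) < gap_prob, n, n_col)] <- "-"
    keep <- colSums(m != "-") > 0L
    m <- m[, keep, drop = FALSE]
    if (ncol(m) >= 2L && all(rowSums(m != "-") > 0L)) break
  }
  rows <- apply(m, 1L, paste, collapse = "")
  as_msa(setNames(rows, sprintf("s%02d", seq_len(n))))
}

# random re-gapping of fixed sequences into n_col slots (order preserved):
# a valid alternative MSA over the same sequence set
random_alternative <- function(seqs, n_col) {
  n <- length(seqs)
  repeat {
    m <- matrix("-", n, n_col)
    for (i in seq_len(n)) {
      ch <- strsplit(seqs[[i]], "")[[1L]]
      m[i, sort(sample.int(n_col, length(ch)))] <- ch
    }
    keep <- colSums(m != "-") > 0L
    m <- m[, keep, drop = FALSE]
    if (ncol(m) >= 1L) break
  }
  as_msa(setNames(apply(m, 1L, paste, collapse = ""),
                  names(seqs)))
}

unit_scheme <- function(match = 1, mismatch = -1, open = 2, extend = 0.5) {
  m <- matrix(mismatch, 20, 20, dimnames = list(AA20, AA20))
  diag(m) <- match
  # scale of this matrix is `match`, so open/extend are raw units when match=1
  scoring_scheme(m, gap_open = open / match, gap_extend = extend / match)
}

# ORACLE: exhaustive enumeration of all global alignments with affine
# gaps (first gap column of a run costs `open`, later columns `extend`).
brute_force_pair_score <- function(s1, s2, match = 1, mismatch = -1,
                                   open = 2, extend = 0.5) {
  a <- strsplit(s1, "")[[1L]]
  b <- strsplit(s2, "")[[1L]]
  n1 <- length(a); n2 <- length(b)
  rec <- function(i, j, prev) {
    if (i > n1 && j > n2) return(0)
    best <- -Inf
    if (i <= n1 && j <= n2) {
      sub <- if (a[i] == b[j]) match else mismatch
      best <- max(best, sub + rec(i + 1L, j + 1L, 0L))
    }
    if (i <= n1) {
      best <- max(best, -(if (prev == 1L) extend else open) + rec(i + 1L, j, 1L))
    }
    if (j <= n2) {
      best <- max(best, -(if (prev == 2L) extend else open) + rec(i, j + 1L, 2L))
    }
    best
  }
  rec(1L, 1L, 0L)
}

# ORACLE: CS by comparing reference column j against every column of
# every alternative, entry by entry on raw key matrices (no hashing)
brute_force_cs <- function(ref, alt_list) {
  rk <- column_keys(ref)
  vapply(seq_len(ncol(rk)), function(j) {
    hit <- vapply(alt_list, function(alt) {
      ak <- column_keys(alt)[names(ref), , drop = FALSE]
      any(vapply(seq_len(ncol(ak)), function(q) all(ak[, q] == rk[, j]),
                 logical(1)))
    }, logical(1))
    mean(hit)
  }, numeric(1))
}

# ORACLE: pair score by scanning each alternative's columns for the two
# residues appearing together
brute_force_pair_score_table <- function(ref, alt_list) {
  rk <- column_keys(ref)
  out <- list()
  for (j in seq_len(ncol(rk))) {
    nz <- which(rk[, j] != 0L)
    if (length(nz) < 2L) next
    cmb <- combn(nz, 2L)
    for (p in seq_len(ncol(cmb))) {
      ia <- cmb[1L, p]; ib <- cmb[2L, p]
      oa <- rk[ia, j]; ob <- rk[ib, j]
      hit <- vapply(alt_list, function(alt) {
        ak <- column_keys(alt)[names(ref), , drop = FALSE]
        any(ak[ia, ] == oa & ak[ib, ] == ob)
      }, logical(1))
      out[[length(out) + 1L]] <- data.frame(ia = ia, oa = oa, ib = ib,
                                            ob = ob, col = j,
                                            score = mean(hit))
    }
  }
  do.call(rbind, out)
}

# ORACLE: AUC-ROC as the scaled Mann-Whitney U statistic (midpoint ties)
u_statistic_auc <- function(scores, labels) {
  r <- rank(scores)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# ORACLE (vectorized form): for each listed pair, scan every column of
# every alternative for the two ordinals appearing together
brute_force_pair_scores_fast <- function(ref, alt_list, pm) {
  if (!nrow(pm)) return(numeric(0))
  hits <- numeric(nrow(pm))
  for (alt in alt_list) {
    ak <- column_keys(alt)[names(ref), , drop = FALSE]
    A <- ak[pm[, "ia"], , drop = FALSE]
    B <- ak[pm[, "ib"], , drop = FALSE]
    hits <- hits + (rowSums(A == pm[, "oa"] & B == pm[, "ob"]) > 0)
  }
  unname(hits / length(alt_list))
}

# character matrix view of an msa, built independently of the package
msa_matrix_oracle <- function(msa) {
  do.call(rbind, strsplit(as.vector(unclass(msa)), ""))
}

# random additive distances: a random tree with known topology
random_additive <- function(n_taxa) {
  tr <- ape::rtree(n_taxa, tip.label = sprintf("t%02d", seq_len(n_taxa)))
  tr$edge.length <- runif(nrow(tr$edge), 0.1, 1)
  d <- ape::cophenetic.phylo(tr)
  d <- d[sort(rownames(d)), sort(rownames(d))]
  list(tree = tr, d = d)
}
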