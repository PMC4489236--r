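# Ensemble generation: joint perturbation of guide tree (column
# bootstrap + NJ), gap-opening penalty (one uniform draw per tree) and
# co-optimal head/tail orientations (per merge node). Each ensemble
# member is keyed by (seed, tree index, member index) through a small
# deterministic seed-derivation hash, so identical (seed, config, input)
# gives an identical ensemble regardless of execution order.

#' Ensemble recipe for alternative-alignment generation
#'
#' Defaults follow the published protocol: 100 bootstrap guide trees,
#' a gap-opening penalty drawn once per tree from Uniform(1, 3) (in
#' matrix-scale units, the MAFFT-like convention; use `c(4, 16)` for a
#' ClustalW-like preset), and 4 co-optimal head/tail samples per
#' tree-penalty combination, for a default ensemble of 400 alternatives.
#'
#' @param n_trees number of bootstrap guide trees (default 100).
#' @param n_cooptimal co-optimal orientation samples per tree (default 4).
#' @param gap_open_range length-2 numeric, uniform sampling interval for
#'   the gap-open penalty (default `c(1, 3)`).
#' @param components character subset of `c("TREE", "GAP", "HOT")`;
#'   components left out are pinned to the reference behaviour
#'   (base-MSA NJ tree / default gap-open / all-HEAD).
#' @param seed integer master seed.
#' @param scheme baseline [scoring_scheme()]; its `gap_open` is the
#'   pinned value when `"GAP"` is off; gap extension is never perturbed.
#' @return object of class `"perturb_config"`.
#' @export
perturb_config <- function(n_trees = 100L, n_cooptimal = 4L,
                           gap_open_range = c(1, 3),
                           components = c("TREE", "GAP", "HOT"),
                           seed = 1L, scheme = scoring_scheme()) {
  components <- match.arg(components, c("TREE", "GAP", "HOT"),
                          several.ok = TRUE)
  if (n_trees < 1L || n_cooptimal < 1L) stop("n_trees and n_cooptimal must be >= 1")
  if (length(gap_open_range) != 2L || gap_open_range[1L] > gap_open_range[2L]) {
    stop("gap_open_range must be an interval c(min, max)")
  }
  structure(list(n_trees = as.integer(n_trees),
                 n_cooptimal = as.integer(n_cooptimal),
                 gap_open_range = as.numeric(gap_open_range),
                 components = components, seed = as.integer(seed),
                 scheme = scheme),
            class = "perturb_config")
}

#' @export
print.perturb_config <- function(x, ...) {
  cat("perturb_config: ", x$n_trees, " trees x ", x$n_cooptimal,
      " co-optima = ", x$n_trees * x$n_cooptimal, " alternatives; ",
      "gap_open ~ U(", x$gap_open_range[1L], ",", x$gap_open_range[2L],
      "); components {", paste(x$components, collapse = ","),
      "}; seed ", x$seed, "\n", sep = "")
  invisible(x)
}

# deterministic 31-bit sub-seed from (seed, tree, member)
derive_seed <- function(seed, tree_idx, member_idx = 0L) {
  m <- 2147483647
  s <- (as.numeric(seed) %% m) * 48271 + as.numeric(tree_idx) * 69621 +
    as.numeric(member_idx) * 16807
  as.integer(s %% m) + 1L
}

# per-tree draws: bootstrap column indices and the gap-open penalty
draw_tree_params <- function(seed, tree_idx, n_col, range) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, tree_idx, 0L))
  list(cols = sample.int(n_col, n_col, replace = TRUE),
       gap_open = runif(1L, range[1L], range[2L]))
}

# per-member orientation draw; `avoid` = matrix of orientations already
# used for this tree (drawn distinct while 2^(n-1) allows)
draw_orientation <- function(seed, tree_idx, member_idx, n_bits, avoid) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, tree_idx, member_idx))
  can_be_distinct <- nrow(avoid) < 2^n_bits
  for (try in seq_len(200L)) {
    bits <- sample(c(0L, 1L), n_bits, replace = TRUE)
    if (!can_be_distinct) return(bits)
    dup <- nrow(avoid) > 0L &&
      any(colSums(t(avoid) != bits) == 0L)
    if (!dup) return(bits)
  }
  bits
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Build the reference alignment
#'
#' Distances for the reference guide tree come from global pairwise
#' alignments of all sequence pairs under the default scheme (p-distance
#' on each pairwise alignment); the tree is midpoint-rooted NJ, and the
#' progressive alignment uses the all-HEAD orientation. Deterministic.
#'
#' @param seqs named character vector of ungapped sequences (>= 2; a
#'   reliability analysis of only 2 sequences is near-trivial and warns).
#' @param scheme a [scoring_scheme()].
#' @return an `msa` with attribute `"guide_tree"` (the `phylo` used).
#' @export
build_reference <- function(seqs, scheme = scoring_scheme()) {
  seqs <- validate_seqs(seqs)
  n <- length(seqs)
  if (n < 2L) stop("need at least 2 sequences")
  if (n == 2L) warning("only 2 sequences: reliability scores are close to trivial")
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      pw <- align_pair(seqs[i], seqs[j], scheme)$msa
      d[i, j] <- d[j, i] <- p_distance(pw)[1L, 2L]
    }
  }
  tree <- nj_tree(d)
  ref <- progressive_align(seqs, tree, scheme)
  attr(ref, "guide_tree") <- tree
  ref
}

#' Generate the ensemble of perturbed alternative alignments
#'
#' For each tree index t: bootstrap the reference's columns, estimate
#' p-distances, build an NJ guide tree, and draw one gap-open penalty
#' from the configured uniform range; then produce `n_cooptimal` members
#' by progressive alignment under sampled head/tail orientations (the
#' first member of each tree is all-HEAD; further draws are distinct
#' while the orientation space allows). Switching a component off pins
#' it: `TREE` off reuses the reference NJ tree, `GAP` off uses the
#' scheme's default gap-open, `HOT` off forces all-HEAD.
#'
#' @param seqs named character vector of ungapped sequences.
#' @param base the reference `msa` over `seqs` (see [build_reference()]).
#' @param config a [perturb_config()].
#' @return object of class `"alternative_set"`: list with `base`,
#'   `alternatives` (list of `msa`) and `provenance` (data.frame with
#'   tree_idx, member_idx, gap_open, orientation, seed per member).
#' @export
generate_alternatives <- function(seqs, base, config = perturb_config()) {
  seqs <- validate_seqs(seqs)
  if (!setequal(names(base), names(seqs))) stop("base is not over seqs")
  base_seqs <- ungap(base)
  if (!identical(as.vector(base_seqs[names(seqs)]), as.vector(unclass(seqs)))) {
    stop("base does not ungap to the input sequences")
  }
  n <- length(seqs)
  n_bits <- n - 1L
  use_tree <- "TREE" %in% config$components
  use_gap <- "GAP" %in% config$components
  use_hot <- "HOT" %in% config$components
  base_tree <- attr(base, "guide_tree")
  if (!use_tree && is.null(base_tree)) base_tree <- nj_tree(p_distance(base))
  L <- msa_ncol(base)

  alts <- vector("list", config$n_trees * config$n_cooptimal)
  prov <- vector("list", length(alts))
  m <- 0L
  for (t in seq_len(config$n_trees)) {
    params <- draw_tree_params(config$seed, t, L, config$gap_open_range)
    if (use_tree) {
      boot <- matrix_to_msa(msa_matrix(base)[, params$cols, drop = FALSE])
      tree <- nj_tree(p_distance(boot))
    } else {
      tree <- base_tree
    }
    gap_open <- if (use_gap) params$gap_open else config$scheme$gap_open
    scheme_t <- config$scheme
    scheme_t$gap_open <- gap_open
    used <- matrix(integer(), 0L, n_bits)
    for (k in seq_len(config$n_cooptimal)) {
      if (!use_hot || k == 1L) {
        bits <- rep(HEAD, n_bits)
      } else {
        bits <- draw_orientation(config$seed, t, k, n_bits, avoid = used)
      }
      used <- rbind(used, bits)
      m <- m + 1L
      alts[[m]] <- progressive_align(seqs, tree, scheme_t, bits)
      prov[[m]] <- data.frame(tree_idx = t, member_idx = k,
                              gap_open = gap_open,
                              orientation = paste(bits, collapse = ""),
                              seed = derive_seed(config$seed, t, k),
                              stringsAsFactors = FALSE)
    }
  }
  structure(list(base = base, alternatives = alts,
                 provenance = do.call(rbind, prov), config = config),
            class = "alternative_set")
}

#' @export
print.alternative_set <- function(x, ...) {
  cat("alternative_set: ", length(x$alternatives), " perturbed alignments of ",
      length(x$base), " sequences (base: ", msa_ncol(x$base), " columns)\n",
      sep = "")
  invisible(x)
}

#' Write an alternative set to a directory
#'
#' Emits one gapped FASTA per member plus a provenance manifest
#' (`manifest.tsv`: tree_idx, member_idx, gap_open, orientation, seed,
#' file).
#'
#' @param alts an `alternative_set`.
#' @param dir output directory (created if needed).
#' @export
write_alternatives <- function(alts, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("alternative_%04d.fasta", seq_along(alts$alternatives))
  for (i in seq_along(alts$alternatives)) {
    write_msa(alts$alternatives[[i]], file.path(dir, files[i]))
  }
  manifest <- cbind(alts$provenance, file = files)
  write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}
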