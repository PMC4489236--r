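# Alignment scoring scheme: substitution matrix + affine gap penalties.
#
# Gap penalties are expressed in "matrix scale" units so that the
# published perturbation range (gap-open uniform on [1, 3] in MAFFT-like
# units) is meaningful: one unit equals the mean diagonal (exact-match)
# score of the substitution matrix. For BLOSUM62 the scale is 5.8, so the
# default open penalty 1.53 corresponds to a raw penalty of ~8.9.

#' Build an alignment scoring scheme
#'
#' @param matrix 20x20 symmetric substitution matrix with the standard
#'   amino-acid letters as dimnames (default BLOSUM62).
#' @param gap_open nonnegative gap-opening penalty, in matrix-scale units
#'   (1 unit = mean diagonal score of `matrix`).
#' @param gap_extend nonnegative gap-extension penalty, same units; must
#'   not exceed `gap_open`.
#' @param terminal_gap_policy `"penalized"` (global ends, default) or
#'   `"free_ends"` (terminal gaps cost nothing).
#' @return object of class `"scoring_scheme"`.
#' @export
scoring_scheme <- function(matrix = blosum62_matrix(),
                           gap_open = 1.53, gap_extend = 0.123,
                           terminal_gap_policy = c("penalized", "free_ends")) {
  terminal_gap_policy <- match.arg(terminal_gap_policy)
  if (!is.matrix(matrix) || !identical(dim(matrix), c(20L, 20L))) {
    stop("substitution matrix must be 20x20")
  }
  matrix <- matrix[AA_LETTERS, AA_LETTERS]
  if (max(abs(matrix - t(matrix))) > 1e-9) {
    stop("substitution matrix must be symmetric")
  }
  if (gap_open < 0 || gap_extend < 0 || gap_open < gap_extend) {
    stop("need gap_open >= gap_extend >= 0")
  }
  scale <- mean(diag(matrix))
  structure(list(matrix = matrix, gap_open = gap_open,
                 gap_extend = gap_extend, scale = scale,
                 terminal_gap_policy = terminal_gap_policy),
            class = "scoring_scheme")
}

#' @export
print.scoring_scheme <- function(x, ...) {
  cat("scoring_scheme: gap_open ", x$gap_open, ", gap_extend ", x$gap_extend,
      " (matrix scale ", round(x$scale, 2), "), ends ",
      x$terminal_gap_policy, "\n", sep = "")
  invisible(x)
}

# raw (matrix-unit) penalties used by the DP
raw_gap_open <- function(scheme) scheme$gap_open * scheme$scale
raw_gap_extend <- function(scheme) scheme$gap_extend * scheme$scale

# 21x21 score table indexed by residue code (code 21 = X scores 0)
score_table <- function(scheme) {
  s <- matrix(0, 21L, 21L)
  s[1:20, 1:20] <- scheme$matrix
  s
}

#' The BLOSUM62 substitution matrix (20 standard amino acids)
#' @return 20x20 symmetric numeric matrix.
#' @export
blosum62_matrix <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  m <- e$BLOSUM62[AA_LETTERS, AA_LETTERS]
  storage.mode(m) <- "double"
  m
}

#' Read a substitution matrix in NCBI text format
#'
#' Parses the whitespace-separated square matrix format used by NCBI
#' (`#` comments, one header line of residue letters, labeled rows).
#' Only the 20 standard amino acids are retained.
#'
#' @param path path to the matrix file.
#' @return 20x20 numeric matrix over [AA_LETTERS] order.
#' @export
read_score_matrix <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))])
  header <- strsplit(lines[1L], "\\s+")[[1L]]
  rows <- strsplit(lines[-1L], "\\s+")
  labels <- vapply(rows, `[`, character(1), 1L)
  vals <- t(vapply(rows, function(r) as.numeric(r[-1L]),
                   numeric(length(header))))
  dimnames(vals) <- list(labels, header)
  miss <- setdiff(AA_LETTERS, intersect(labels, header))
  if (length(miss)) stop("matrix lacks residues: ", paste(miss, collapse = ","))
  m <- vals[AA_LETTERS, AA_LETTERS]
  if (max(abs(m - t(m))) > 1e-9) stop("matrix is not symmetric")
  m
}
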