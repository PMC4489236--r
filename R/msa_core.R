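#' @useDynLib msarel, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats runif rgamma rpois ks.test cor sd setNames
#' @importFrom utils write.table read.table combn head tail
"_PACKAGE"

AA_LETTERS <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
GAP_CHAR <- "-"
# residue codes: 0 = gap, 1..20 = AA_LETTERS, 21 = X (unknown, scores 0)
X_CODE <- 21L

aa_code <- function(chars) {
  code <- match(chars, AA_LETTERS)
  code[chars == GAP_CHAR] <- 0L
  code[chars == "X"] <- X_CODE
  if (anyNA(code)) {
    stop("unsupported residue character(s): ",
         paste(unique(chars[is.na(code)]), collapse = ", "))
  }
  as.integer(code)
}

aa_decode <- function(code) {
  out <- character(length(code))
  out[code == 0L] <- GAP_CHAR
  out[code == X_CODE] <- "X"
  std <- code >= 1L & code <= 20L
  out[std] <- AA_LETTERS[code[std]]
  out
}

normalize_residues <- function(x) {
  x <- toupper(x)
  gsub(".", "-", x, fixed = TRUE)
}

#' Validate a set of ungapped protein sequences
#'
#' Sequences are represented as a named character vector: names are the
#' sequence identifiers, values the ungapped residue strings over the 20
#' amino-acid letters (plus `X` for unknown residues).
#'
#' @param seqs named character vector of residue strings.
#' @return the validated, upper-cased vector (invisibly classed `"seq_set"`).
#' @export
validate_seqs <- function(seqs) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    stop("all sequences must carry a non-empty id")
  }
  dup <- names(seqs)[duplicated(names(seqs))]
  if (length(dup)) stop("duplicate sequence id: ", dup[1L])
  seqs <- vapply(seqs, normalize_residues, character(1))
  if (any(!nzchar(seqs))) {
    stop("empty sequence: ", names(seqs)[!nzchar(seqs)][1L])
  }
  if (any(grepl("-", seqs, fixed = TRUE))) {
    stop("gap characters found in ungapped input (id ",
         names(seqs)[grepl("-", seqs, fixed = TRUE)][1L],
         "); use read_msa() for alignments")
  }
  for (i in seq_along(seqs)) {
    aa_code(strsplit(seqs[[i]], "")[[1L]])  # errors on bad letters
  }
  structure(seqs, class = "seq_set")
}

#' Read ungapped protein sequences from a FASTA file
#'
#' Ids are taken as the header up to the first whitespace; record order is
#' preserved. Gapped records are rejected (use [read_msa()]).
#'
#' @param path path to a FASTA file.
#' @return named character vector of class `"seq_set"`.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no FASTA records in ", path)
  ids <- sub("\\s.*$", "", names(set))
  validate_seqs(setNames(as.character(set), ids))
}

#' Write sequences to FASTA (60-column wrapped)
#'
#' @param seqs named character vector of sequences (gapped or ungapped).
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = 60L)
    writeLines(substring(s, starts, pmin(starts + 59L, nchar(s))), con)
  }
  invisible(path)
}

#' Construct a multiple sequence alignment object
#'
#' An `msa` is a named character vector of equal-length gapped rows
#' (`-` = gap) in a fixed sequence order; that order is the canonical
#' order for column keys across an ensemble.
#'
#' @param rows named character vector of gapped rows.
#' @param allow_all_gap keep all-gap columns instead of erroring.
#' @return object of class `"msa"`.
#' @export
as_msa <- function(rows, allow_all_gap = FALSE) {
  if (is.null(names(rows)) || any(!nzchar(names(rows)))) {
    stop("all alignment rows must carry a non-empty id")
  }
  dup <- names(rows)[duplicated(names(rows))]
  if (length(dup)) stop("duplicate sequence id: ", dup[1L])
  rows <- vapply(rows, normalize_residues, character(1))
  len <- unique(nchar(rows))
  if (length(len) != 1L) {
    bad <- names(rows)[nchar(rows) != nchar(rows)[1L]][1L]
    stop("ragged alignment: row '", bad, "' has a different length")
  }
  if (len == 0L) stop("alignment has zero columns")
  m <- msa_matrix_from_rows(rows)
  if (any(colSums(m != 0L) == 0L)) {
    if (!allow_all_gap) stop("alignment contains an all-gap column")
  }
  structure(rows, class = "msa")
}

msa_matrix_from_rows <- function(rows) {
  matrix(aa_code(unlist(strsplit(unname(rows), ""), use.names = FALSE)),
         nrow = length(rows), ncol = nchar(rows[[1L]]), byrow = TRUE)
}

# integer matrix (n_seq x n_col), rownames = ids; 0 gap, 1..20 aa, 21 X
msa_matrix <- function(msa) {
  m <- msa_matrix_from_rows(msa)
  rownames(m) <- names(msa)
  m
}

matrix_to_msa <- function(m, allow_all_gap = FALSE) {
  rows <- apply(m, 1L, function(code) paste(aa_decode(code), collapse = ""))
  as_msa(setNames(rows, rownames(m)), allow_all_gap = allow_all_gap)
}

#' @export
print.msa <- function(x, ...) {
  cat("msa: ", length(x), " sequences x ", msa_ncol(x), " columns\n", sep = "")
  show <- head(seq_along(x), 6L)
  for (i in show) {
    row <- x[[i]]
    if (nchar(row) > 60L) row <- paste0(substr(row, 1L, 57L), "...")
    cat(format(names(x)[i], width = 12L), row, "\n")
  }
  if (length(x) > 6L) cat("  ... ", length(x) - 6L, " more rows\n", sep = "")
  invisible(x)
}

#' Number of columns of an alignment
#' @param msa an `msa`.
#' @export
msa_ncol <- function(msa) nchar(msa[[1L]])

#' Remove gaps, recovering the input sequences
#' @param msa an `msa`.
#' @return `"seq_set"` named character vector in row order.
#' @export
ungap <- function(msa) {
  validate_seqs(setNames(gsub("-", "", unname(msa), fixed = TRUE), names(msa)))
}

#' Read a gapped FASTA alignment
#'
#' `.` and `-` are both accepted as gap characters and normalized to `-`;
#' residues are upper-cased.
#'
#' @param path path to a gapped FASTA file.
#' @param allow_all_gap tolerate all-gap columns (default errors).
#' @return an `msa`.
#' @export
read_msa <- function(path, allow_all_gap = FALSE) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no FASTA records in ", path)
  ids <- sub("\\s.*$", "", names(set))
  lens <- Biostrings::width(set)
  if (length(unique(lens)) != 1L) {
    stop("ragged alignment in ", path, ": row '",
         ids[lens != lens[1L]][1L], "' has a different length")
  }
  as_msa(setNames(as.character(set), ids), allow_all_gap = allow_all_gap)
}

#' Write an alignment as gapped FASTA (60-column wrapped)
#' @param msa an `msa`.
#' @param path output path.
#' @export
write_msa <- function(msa, path) write_fasta(msa, path)

#' Column keys: alignment-coordinate-free column identity
#'
#' Each column is identified by the vector of residue ordinals (1-based
#' position in the ungapped sequence) it aligns, with 0 marking a gap, in
#' the alignment's fixed sequence order. Two columns of any two
#' alignments over the same sequences are "the same column" iff their
#' keys are equal. This is the column-wise equivalent of the C-matrix
#' representation used for alignment comparison.
#'
#' @param msa an `msa`.
#' @return integer matrix, one row per sequence, one column per
#'   alignment column; 0 = gap.
#' @export
column_keys <- function(msa) {
  m <- msa_matrix(msa)
  keys <- m
  for (i in seq_len(nrow(m))) {
    nz <- m[i, ] != 0L
    keys[i, ] <- 0L
    keys[i, nz] <- seq_len(sum(nz))
  }
  keys
}

# canonical string form of each column key, for hashing/membership
key_strings <- function(msa) {
  keys <- column_keys(msa)
  apply(keys, 2L, paste, collapse = ",")
}

#' Residue pairs co-aligned in one column
#'
#' @param msa an `msa`.
#' @param col 1-based column index.
#' @return data.frame with columns `id_a`, `ord_a`, `id_b`, `ord_b`
#'   (canonical order: `id_a` earlier in the alignment's sequence order),
#'   one row per unordered pair of non-gap residues in the column.
#' @export
column_pairs <- function(msa, col) {
  if (col < 1L || col > msa_ncol(msa)) stop("column index out of range")
  keys <- column_keys(msa)
  nz <- which(keys[, col] != 0L)
  if (length(nz) < 2L) {
    return(data.frame(id_a = character(), ord_a = integer(),
                      id_b = character(), ord_b = integer()))
  }
  idx <- combn(nz, 2L)
  data.frame(id_a = names(msa)[idx[1L, ]], ord_a = keys[cbind(idx[1L, ], col)],
             id_b = names(msa)[idx[2L, ]], ord_b = keys[cbind(idx[2L, ], col)],
             stringsAsFactors = FALSE)
}

# all residue pairs of all columns: integer matrix with seq indices and
# ordinals plus the column they come from (used by scoring/evaluation)
all_column_pairs <- function(msa) {
  keys <- column_keys(msa)
  out <- vector("list", ncol(keys))
  for (j in seq_len(ncol(keys))) {
    nz <- which(keys[, j] != 0L)
    if (length(nz) < 2L) next
    idx <- combn(nz, 2L)
    out[[j]] <- cbind(ia = idx[1L, ], oa = keys[cbind(idx[1L, ], j)],
                      ib = idx[2L, ], ob = keys[cbind(idx[2L, ], j)],
                      col = j)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- matrix(integer(), ncol = 5L,
                  dimnames = list(NULL, c("ia", "oa", "ib", "ob", "col")))
  }
  res
}

# ordinal -> column lookup: matrix pos[i, o] = column of ordinal o of seq i
ordinal_positions <- function(msa) {
  keys <- column_keys(msa)
  lens <- vapply(seq_len(nrow(keys)), function(i) max(keys[i, ]), integer(1))
  pos <- matrix(NA_integer_, nrow = nrow(keys), ncol = max(lens))
  for (i in seq_len(nrow(keys))) {
    nz <- keys[i, ] != 0L
    pos[i, keys[i, nz]] <- which(nz)
  }
  rownames(pos) <- names(msa)
  pos
}
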