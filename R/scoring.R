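# Reliability scores of a reference MSA against its perturbed ensemble.
# Column identity is full column-key equality (gap pattern + residue
# ordinals): a reference column either reappears exactly in an
# alternative or it does not. Pair scores relax this to two residues
# sharing a column.

#' Column score (CS): ensemble frequency of each reference column
#'
#' `cs[j]` is the fraction of alternatives whose column-key set contains
#' the key of reference column `j`.
#'
#' @param ref the reference `msa`.
#' @param alts an `alternative_set` (or plain list of `msa`) over the
#'   same sequences.
#' @return numeric vector in `[0, 1]`, one value per reference column.
#' @export
column_score <- function(ref, alts) {
  alt_list <- alternatives_list(ref, alts)
  ref_keys <- key_strings(ref)
  hits <- numeric(length(ref_keys))
  for (alt in alt_list) {
    hits <- hits + (ref_keys %in% key_strings(alt))
  }
  hits / length(alt_list)
}

alternatives_list <- function(ref, alts) {
  alt_list <- if (inherits(alts, "alternative_set")) alts$alternatives else alts
  if (!length(alt_list)) stop("empty ensemble")
  for (alt in alt_list) {
    if (!identical(names(alt), names(ref))) {
      stop("ensemble member sequence set/order differs from reference")
    }
  }
  alt_list
}

#' Residue-pair scores and sum-of-pairs column score (SPC)
#'
#' A residue pair of the reference scores the fraction of alternatives
#' in which its two residues share a column; `spc[j]` is the mean pair
#' score over column `j`'s pairs. Columns with fewer than two residues
#' have no pair evidence and fall back to `spc = cs` (flagged via the
#' `no_pairs` attribute).
#'
#' @inheritParams column_score
#' @return list with `pairs` (data.frame id_a, ord_a, id_b, ord_b,
#'   score), `spc` (per-column numeric with attribute `no_pairs`), and
#'   `pair_matrix` (internal indexed form reused by downstream scores).
#' @export
pair_and_spc_scores <- function(ref, alts) {
  alt_list <- alternatives_list(ref, alts)
  pm <- all_column_pairs(ref)
  hits <- numeric(nrow(pm))
  for (alt in alt_list) {
    pos <- ordinal_positions(alt)
    hits <- hits + (pos[cbind(pm[, "ia"], pm[, "oa"])] ==
                      pos[cbind(pm[, "ib"], pm[, "ob"])])
  }
  score <- if (nrow(pm)) hits / length(alt_list) else numeric(0)
  cs <- column_score(ref, alt_list)
  spc <- cs  # fallback for columns without pairs
  if (nrow(pm)) {
    agg <- tapply(score, pm[, "col"], mean)
    spc[as.integer(names(agg))] <- as.numeric(agg)
  }
  no_pairs <- setdiff(seq_len(msa_ncol(ref)), unique(pm[, "col"]))
  attr(spc, "no_pairs") <- no_pairs
  pairs <- data.frame(id_a = names(ref)[pm[, "ia"]], ord_a = pm[, "oa"],
                      id_b = names(ref)[pm[, "ib"]], ord_b = pm[, "ob"],
                      col = pm[, "col"], score = score,
                      stringsAsFactors = FALSE)
  list(pairs = pairs, spc = spc,
       pair_matrix = cbind(pm, score = score), cs = cs)
}

#' Residue and sequence reliability scores
#'
#' A residue's score is the mean pair score over all pairs it
#' participates in; a residue whose column holds no other residue (no
#' pair evidence) falls back to the CS of its column and is flagged. A
#' sequence's score is the mean of its residue scores.
#'
#' @param pair_scores result of [pair_and_spc_scores()].
#' @param ref the reference `msa`.
#' @return list with `residues` (data.frame id, ordinal, score,
#'   no_pairs) and `sequences` (named numeric).
#' @export
residue_and_sequence_scores <- function(pair_scores, ref) {
  keys <- column_keys(ref)
  lens <- vapply(seq_len(nrow(keys)), function(i) max(keys[i, ]), integer(1))
  pm <- pair_scores$pair_matrix
  cs <- pair_scores$cs
  ids <- names(ref)
  res <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    sums <- numeric(lens[i]); cnts <- numeric(lens[i])
    a <- pm[, "ia"] == i
    if (any(a)) {
      sa <- tapply(pm[a, "score"], pm[a, "oa"], sum)
      ca <- tapply(rep(1, sum(a)), pm[a, "oa"], sum)
      sums[as.integer(names(sa))] <- sums[as.integer(names(sa))] + sa
      cnts[as.integer(names(ca))] <- cnts[as.integer(names(ca))] + ca
    }
    b <- pm[, "ib"] == i
    if (any(b)) {
      sb <- tapply(pm[b, "score"], pm[b, "ob"], sum)
      cb <- tapply(rep(1, sum(b)), pm[b, "ob"], sum)
      sums[as.integer(names(sb))] <- sums[as.integer(names(sb))] + sb
      cnts[as.integer(names(cb))] <- cnts[as.integer(names(cb))] + cb
    }
    score <- ifelse(cnts > 0, sums / pmax(cnts, 1), NA_real_)
    lonely <- which(cnts == 0)
    if (length(lonely)) {
      # fall back to the CS of the column holding that ordinal
      cols <- vapply(lonely, function(o) which(keys[i, ] == o), integer(1))
      score[lonely] <- cs[cols]
    }
    res[[i]] <- data.frame(id = ids[i], ordinal = seq_len(lens[i]),
                           score = score, no_pairs = cnts == 0,
                           stringsAsFactors = FALSE)
  }
  residues <- do.call(rbind, res)
  sequences <- vapply(split(residues$score, factor(residues$id, levels = ids)),
                      mean, numeric(1))
  list(residues = residues, sequences = sequences)
}

#' Full reliability report for a reference MSA
#'
#' @inheritParams column_score
#' @return object of class `"score_report"`: list with per-column `cs`
#'   and `spc`, `pairs`, `residues`, `sequences`, `n_alternatives`.
#' @export
score_msa <- function(ref, alts) {
  ps <- pair_and_spc_scores(ref, alts)
  rs <- residue_and_sequence_scores(ps, ref)
  structure(list(cs = ps$cs, spc = ps$spc, pairs = ps$pairs,
                 residues = rs$residues, sequences = rs$sequences,
                 n_alternatives = length(alternatives_list(ref, alts))),
            class = "score_report")
}

#' @export
print.score_report <- function(x, ...) {
  cat("score_report over ", x$n_alternatives, " alternatives\n",
      "  mean CS  ", round(mean(x$cs), 4),
      " | mean SPC ", round(mean(x$spc), 4), "\n",
      "  columns with CS < 0.93: ", sum(x$cs < 0.93), " of ", length(x$cs),
      "\n", sep = "")
  invisible(x)
}

#' Mask or filter an alignment by reliability
#'
#' `remove_columns` drops columns whose CS falls below `column_cutoff`;
#' `mask_residues` replaces residues whose residue score falls below
#' `residue_cutoff` with `X` (columns emptied to all-gap by either
#' operation are dropped, with a message).
#'
#' @param ref the scored `msa`.
#' @param report a [score_msa()] report for `ref`.
#' @param column_cutoff,residue_cutoff cutoffs in `[0, 1]`.
#' @param mode `"remove_columns"` or `"mask_residues"`.
#' @return filtered/masked `msa`.
#' @export
mask_msa <- function(ref, report, column_cutoff = 0.93, residue_cutoff = 0.6,
                     mode = c("remove_columns", "mask_residues")) {
  mode <- match.arg(mode)
  if (column_cutoff < 0 || column_cutoff > 1 ||
      residue_cutoff < 0 || residue_cutoff > 1) {
    stop("cutoffs must lie in [0, 1]")
  }
  m <- msa_matrix(ref)
  if (mode == "remove_columns") {
    keep <- report$cs >= column_cutoff
    m <- m[, keep, drop = FALSE]
  } else {
    keys <- column_keys(ref)
    bad <- report$residues[!is.na(report$residues$score) &
                             report$residues$score < residue_cutoff, ]
    for (r in seq_len(nrow(bad))) {
      i <- match(bad$id[r], names(ref))
      j <- which(keys[i, ] == bad$ordinal[r])
      m[i, j] <- X_CODE
    }
  }
  if (ncol(m) == 0L) stop("no columns survive the cutoff")
  empty <- colSums(m != 0L) == 0L
  if (any(empty)) {
    message(sum(empty), " column(s) emptied to all-gap were dropped")
    m <- m[, !empty, drop = FALSE]
  }
  matrix_to_msa(m)
}

#' Write a score report as TSV + JSON summary
#'
#' Emits `column_scores.tsv` (1-based column, cs, spc),
#' `residue_scores.tsv` (id, ordinal, score), `sequence_scores.tsv`, and
#' `summary.json` (means, n_alternatives).
#'
#' @param report a `score_report`.
#' @param dir output directory.
#' @export
write_score_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(data.frame(column = seq_along(report$cs), cs = report$cs,
                         spc = as.numeric(report$spc)),
              file.path(dir, "column_scores.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(report$residues[, c("id", "ordinal", "score")],
              file.path(dir, "residue_scores.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(data.frame(id = names(report$sequences),
                         score = as.numeric(report$sequences)),
              file.path(dir, "sequence_scores.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(mean_cs = mean(report$cs),
                            mean_spc = mean(as.numeric(report$spc)),
                            mean_sequence_score = mean(report$sequences),
                            n_alternatives = report$n_alternatives,
                            n_columns = length(report$cs)),
                       file.path(dir, "summary.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
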