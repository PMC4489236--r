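# Benchmarking reliability scores against a known true alignment:
# column labels by exact column-key matching, per-column fraction of
# correctly aligned residue pairs, ROC / precision-recall curves and
# their areas, and Pearson correlation of scores with pair fractions.

#' Label inferred columns against a true alignment
#'
#' A column of `inferred` is labeled correct (1) iff its column key
#' occurs among the keys of `truth` — i.e. the column is reproduced
#' exactly. The per-column fraction of correctly aligned pairs is also
#' returned (NA for columns with fewer than two residues, which carry no
#' pair evidence). With a `core_mask` (logical over truth columns), an
#' inferred column is evaluated only if at least two of its residues lie
#' in masked-in truth columns.
#'
#' @param inferred an `msa`.
#' @param truth an `msa` over the same sequences.
#' @param core_mask optional logical vector over the columns of `truth`.
#' @return data.frame with `column`, `label` (0/1), `fraction`
#'   (in `[0, 1]` or NA) and `evaluated` (logical, core-mask filter).
#' @export
label_columns <- function(inferred, truth, core_mask = NULL) {
  if (!setequal(names(inferred), names(truth))) {
    stop("inferred and truth are over different sequence sets")
  }
  truth <- as_msa(truth[names(inferred)])
  label <- as.integer(key_strings(inferred) %in% key_strings(truth))
  pm <- all_column_pairs(inferred)
  tpos <- ordinal_positions(truth)
  frac <- rep(NA_real_, msa_ncol(inferred))
  if (nrow(pm)) {
    ok <- tpos[cbind(pm[, "ia"], pm[, "oa"])] ==
      tpos[cbind(pm[, "ib"], pm[, "ob"])]
    agg <- tapply(ok, pm[, "col"], mean)
    frac[as.integer(names(agg))] <- as.numeric(agg)
  }
  evaluated <- rep(TRUE, msa_ncol(inferred))
  if (!is.null(core_mask)) {
    if (length(core_mask) != msa_ncol(truth)) {
      stop("core_mask length must equal the number of truth columns")
    }
    keys <- column_keys(inferred)
    core_cols <- which(core_mask)
    for (j in seq_len(ncol(keys))) {
      nz <- which(keys[, j] != 0L)
      in_core <- sum(tpos[cbind(nz, keys[nz, j])] %in% core_cols)
      evaluated[j] <- in_core >= 2L
    }
  }
  data.frame(column = seq_along(label), label = label, fraction = frac,
             evaluated = evaluated)
}

#' ROC curve and AUC for a column-level predictor
#'
#' Thresholds sweep the distinct score values (ties grouped); AUC is the
#' trapezoid area, equal to the Mann-Whitney U statistic divided by
#' `n_pos * n_neg` (midpoint tie handling).
#'
#' @param scores numeric predictor (higher = predicted correct).
#' @param labels 0/1 vector of the same length.
#' @return list with `points` (data.frame fpr, tpr from (0,0) to (1,1))
#'   and `auc`.
#' @export
roc_curve <- function(scores, labels) {
  chk <- check_binary(scores, labels)
  scores <- chk$scores; labels <- chk$labels
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  grp <- cumsum(!duplicated(s))
  tp <- tapply(y, grp, sum)
  fp <- tapply(1 - y, grp, sum)
  tpr <- c(0, cumsum(tp)) / sum(labels)
  fpr <- c(0, cumsum(fp)) / sum(1 - labels)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  list(points = data.frame(fpr = as.numeric(fpr), tpr = as.numeric(tpr)),
       auc = auc)
}

#' Precision-recall curve and AUC
#'
#' Threshold sweep over distinct score values (ties grouped); AUC-PR is
#' the trapezoid over recall (no interpolation).
#'
#' @inheritParams roc_curve
#' @return list with `points` (data.frame recall, precision) and `auc`.
#' @export
pr_curve <- function(scores, labels) {
  chk <- check_binary(scores, labels)
  scores <- chk$scores; labels <- chk$labels
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(tapply(y, grp, sum))
  n <- cumsum(tapply(rep(1, length(y)), grp, sum))
  recall <- as.numeric(tp / sum(labels))
  precision <- as.numeric(tp / n)
  recall <- c(0, recall)
  precision <- c(precision[1L], precision)
  auc <- sum(diff(recall) * (head(precision, -1) + tail(precision, -1)) / 2)
  list(points = data.frame(recall = recall, precision = precision), auc = auc)
}

check_binary <- function(scores, labels) {
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- as.integer(labels[keep])
  if (length(scores) != length(labels)) stop("scores/labels length mismatch")
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0/1")
  if (sum(labels) == 0L || sum(labels) == length(labels)) {
    stop("both classes must be present; AUC is undefined for single-class labels")
  }
  list(scores = scores, labels = labels)
}

#' Pearson correlation of scores with pair-correctness fractions
#'
#' @param scores per-column reliability scores.
#' @param fractions per-column fraction of correctly aligned pairs
#'   (NA entries dropped pairwise).
#' @return correlation coefficient, or NA (with a warning) when either
#'   vector is constant.
#' @export
pearson_to_pair_fraction <- function(scores, fractions) {
  keep <- !is.na(scores) & !is.na(fractions)
  s <- scores[keep]; f <- fractions[keep]
  if (length(s) < 2L) stop("need at least 2 complete pairs of values")
  if (sd(s) == 0 || sd(f) == 0) {
    warning("constant vector: Pearson correlation undefined")
    return(NA_real_)
  }
  cor(s, f)
}

#' Simulation benchmark of the ensemble reliability scores
#'
#' For each replicate: simulate a true alignment along a random
#' ultrametric tree, rebuild a reference alignment from the ungapped
#' leaf sequences, generate the perturbed ensemble under `config`,
#' compute the column score, and label the reference columns against the
#' truth. Per-replicate results are pooled for ROC/PR/correlation.
#'
#' @param n_replicates number of simulated datasets.
#' @param n_taxa,depth tree parameters (see [random_tree()]).
#' @param model an [evol_model()].
#' @param config a [perturb_config()]; its `seed` is combined with the
#'   replicate index.
#' @param seed master seed.
#' @return object of class `"benchmark_result"`: `per_replicate`
#'   (data.frame with replicate, auc_roc, auc_pr, pearson, n_columns),
#'   pooled `columns` (scores, labels, fractions) and pooled `auc_roc`,
#'   `auc_pr`, `pearson`.
#' @export
benchmark_scores <- function(n_replicates = 5L, n_taxa = 20L, depth = 1,
                             model = evol_model(), config = perturb_config(),
                             seed = 1L) {
  pooled <- vector("list", n_replicates)
  per <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    set.seed(derive_seed(seed, r, 0L))
    tree <- random_tree(n_taxa, depth)
    sim <- simulate_msa(tree, model)
    ref <- build_reference(sim$sequences, config$scheme)
    cfg <- config
    cfg$seed <- derive_seed(seed, r, 1L)
    alts <- generate_alternatives(sim$sequences, ref, cfg)
    cs <- column_score(ref, alts)
    lab <- label_columns(ref, sim$true_msa)
    pooled[[r]] <- data.frame(replicate = r, score = cs, label = lab$label,
                              fraction = lab$fraction)
    auc_roc <- tryCatch(roc_curve(cs, lab$label)$auc, error = function(e) NA_real_)
    auc_pr <- tryCatch(pr_curve(cs, lab$label)$auc, error = function(e) NA_real_)
    pears <- tryCatch(suppressWarnings(pearson_to_pair_fraction(cs, lab$fraction)),
                      error = function(e) NA_real_)
    per[[r]] <- data.frame(replicate = r, auc_roc = auc_roc, auc_pr = auc_pr,
                           pearson = pears, n_columns = length(cs))
  }
  cols <- do.call(rbind, pooled)
  structure(list(per_replicate = do.call(rbind, per), columns = cols,
                 auc_roc = roc_curve(cols$score, cols$label)$auc,
                 auc_pr = pr_curve(cols$score, cols$label)$auc,
                 pearson = suppressWarnings(
                   pearson_to_pair_fraction(cols$score, cols$fraction))),
            class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat("benchmark_result over ", nrow(x$per_replicate), " replicates (",
      nrow(x$columns), " pooled columns)\n",
      "  pooled AUC-ROC ", round(x$auc_roc, 4),
      " | AUC-PR ", round(x$auc_pr, 4),
      " | Pearson r ", round(x$pearson, 4), "\n", sep = "")
  invisible(x)
}
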