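test_that("column labels against truth follow exact key matching", {
  truth <- as_msa(c(a = "AC-DE", b = "ACCDE"))
  expect_true(all(label_columns(truth, truth)$label == 1))
  expect_true(all(label_columns(truth, truth)$fraction %in% c(1, NA)))

  # a mis-shifted block in a 2-sequence toy: hand-enumerated key sets
  truth2 <- as_msa(c(a = "AAC--", b = "--CAA"))
  inferred <- as_msa(c(a = "AAC--", b = "C--AA"))
  lab <- label_columns(inferred, truth2)
  # inferred keys (1,1) (2,0) (3,0) (0,2) (0,3) vs truth keys
  # (1,0) (2,0) (3,1) (0,2) (0,3): only columns 2, 4, 5 match
  expect_identical(lab$label, c(0L, 1L, 0L, 1L, 1L))
})

test_that("labels equal brute-force pair-set + residue-content comparison", {
  set.seed(101)
  for (rep in 1:10) {
    seqs <- random_seqs(4, len_range = c(5L, 8L))
    truth <- random_alternative(seqs, 10L)
    inferred <- random_alternative(seqs, 10L)
    lab <- label_columns(inferred, truth)
    ik <- column_keys(inferred)
    tk <- column_keys(truth)
    oracle <- vapply(seq_len(ncol(ik)), function(j) {
      any(vapply(seq_len(ncol(tk)),
                 function(q) all(tk[, q] == ik[, j]), logical(1)))
    }, logical(1))
    expect_identical(lab$label, as.integer(oracle))
    # a correct label forces a pair fraction of 1
    expect_true(all(lab$fraction[lab$label == 1L] == 1, na.rm = TRUE))
  }
})

test_that("core mask restricts evaluation to columns with >= 2 core residues", {
  truth <- as_msa(c(a = "ACDE", b = "ACDE"))
  inferred <- truth
  mask <- c(TRUE, TRUE, FALSE, FALSE)
  lab <- label_columns(inferred, truth, core_mask = mask)
  expect_identical(lab$evaluated, c(TRUE, TRUE, FALSE, FALSE))
  expect_error(label_columns(inferred, truth, core_mask = TRUE), "length")
})

test_that("ROC behaves: perfect separation, AUC = scaled U, invariance", {
  scores <- c(0.9, 0.8, 0.7, 0.3, 0.2)
  labels <- c(1, 1, 1, 0, 0)
  expect_equal(roc_curve(scores, labels)$auc, 1.0)
  expect_error(roc_curve(scores, rep(1, 5)), "single-class")

  set.seed(102)
  for (rep in 1:20) {
    n <- 60L
    scores <- round(runif(n), 2)  # ties on purpose
    labels <- rbinom(n, 1L, 0.4)
    if (sum(labels) %in% c(0L, n)) next
    r <- roc_curve(scores, labels)
    expect_equal(r$auc, u_statistic_auc(scores, labels), tolerance = 1e-12)
    # invariant under strictly monotone transforms
    expect_equal(roc_curve(exp(3 * scores), labels)$auc, r$auc,
                 tolerance = 1e-12)
    expect_equal(range(r$points$fpr), c(0, 1))
    expect_equal(range(r$points$tpr), c(0, 1))
  }
})

test_that("random scores give AUC 0.5 and PR AUC near prevalence", {
  set.seed(103)
  n <- 10000L
  scores <- runif(n)
  labels <- rbinom(n, 1L, 0.5)
  auc <- roc_curve(scores, labels)$auc
  se <- sqrt(1 / 12) / sqrt(n)  # conservative U-statistic scale
  expect_lt(abs(auc - 0.5), 3 * max(se, 1 / sqrt(n)))
  pr <- pr_curve(scores, labels)
  expect_lt(abs(pr$auc - mean(labels)), 0.05)
  expect_equal(pr_curve(c(1, 1, 0, 0), c(1, 1, 0, 0))$auc, 1.0)
})

test_that("Pearson correlation matches hand computation and flags constants", {
  f <- c(0.1, 0.4, 0.5, 0.8, 1.0)
  expect_equal(pearson_to_pair_fraction(f, f), 1)
  expect_equal(pearson_to_pair_fraction(1 - f, f), -1)
  s <- c(2, 4, 5, 4, 5)
  # textbook formula by hand
  hand <- sum((s - mean(s)) * (f - mean(f))) /
    sqrt(sum((s - mean(s))^2) * sum((f - mean(f))^2))
  expect_equal(pearson_to_pair_fraction(s, f), hand, tolerance = 1e-12)
  expect_warning(r <- pearson_to_pair_fraction(rep(1, 5), f), "constant")
  expect_true(is.na(r))
  expect_error(pearson_to_pair_fraction(1, 1), "at least 2")
})

test_that("benchmark harness runs end to end on a small configuration", {
  bench <- benchmark_scores(n_replicates = 2L, n_taxa = 6L, depth = 0.8,
                            model = evol_model(root_length = 60L),
                            config = perturb_config(n_trees = 5L,
                                                    n_cooptimal = 2L),
                            seed = 11L)
  expect_identical(nrow(bench$per_replicate), 2L)
  expect_true(all(c("auc_roc", "auc_pr", "pearson") %in%
                    names(bench$per_replicate)))
  expect_true(is.finite(bench$auc_roc) || is.na(bench$auc_roc))
  expect_identical(nrow(bench$columns),
                   as.integer(sum(bench$per_replicate$n_columns)))
})
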