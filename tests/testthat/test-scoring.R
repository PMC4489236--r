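make_ensemble <- function(n_seqs = 5L, seq_len = c(8L, 12L), n_alts = 10L,
                          n_col = 16L) {
  seqs <- random_seqs(n_seqs, len_range = seq_len)
  ref <- random_alternative(seqs, n_col)
  alts <- replicate(n_alts, random_alternative(seqs, n_col), simplify = FALSE)
  list(ref = ref, alts = alts)
}

test_that("CS and pair scores match the brute-force oracles", {
  set.seed(81)
  for (rep in 1:8) {
    e <- make_ensemble()
    expect_equal(column_score(e$ref, e$alts), brute_force_cs(e$ref, e$alts),
                 tolerance = 1e-12)
    ps <- pair_and_spc_scores(e$ref, e$alts)
    oracle <- brute_force_pair_score_table(e$ref, e$alts)
    got <- ps$pair_matrix
    expect_identical(nrow(got), nrow(oracle))
    ord_g <- order(got[, "col"], got[, "ia"], got[, "ib"])
    ord_o <- order(oracle$col, oracle$ia, oracle$ib)
    expect_equal(unname(got[ord_g, "score"]), oracle$score[ord_o],
                 tolerance = 1e-12)
  }
})

test_that("score laws hold: ranges, cs <= spc, ref-copy monotonicity", {
  set.seed(82)
  for (rep in 1:5) {
    e <- make_ensemble()
    rep1 <- score_msa(e$ref, e$alts)
    expect_true(all(rep1$cs >= 0 & rep1$cs <= 1))
    expect_true(all(rep1$spc >= 0 & rep1$spc <= 1))
    expect_true(all(rep1$residues$score >= 0 & rep1$residues$score <= 1))
    expect_true(all(rep1$sequences >= 0 & rep1$sequences <= 1))
    expect_true(all(rep1$cs <= as.numeric(rep1$spc) + 1e-12))
    # the report covers every column and every residue
    expect_length(rep1$cs, msa_ncol(e$ref))
    lens <- nchar(gsub("-", "", unclass(e$ref), fixed = TRUE))
    expect_identical(nrow(rep1$residues), as.integer(sum(lens)))

    # adding a copy of the reference never decreases any score
    rep2 <- score_msa(e$ref, c(e$alts, list(e$ref)))
    expect_true(all(rep2$cs >= rep1$cs - 1e-12))
    expect_true(all(as.numeric(rep2$spc) >= as.numeric(rep1$spc) - 1e-12))
    expect_true(all(rep2$residues$score >= rep1$residues$score - 1e-12))
    expect_true(all(rep2$sequences >= rep1$sequences - 1e-12))
    # and with ref present every column scores at least 1/n
    expect_true(all(rep2$cs >= 1 / (length(e$alts) + 1L) - 1e-12))
  }
})

test_that("ensemble of reference copies gives all scores 1", {
  set.seed(83)
  e <- make_ensemble(n_alts = 1L)
  rep1 <- score_msa(e$ref, list(e$ref, e$ref, e$ref))
  expect_true(all(rep1$cs == 1))
  expect_true(all(rep1$spc == 1))
  expect_true(all(rep1$residues$score == 1))
  expect_true(all(rep1$sequences == 1))
})

test_that("length-weighted sequence scores average to the residue mean", {
  set.seed(84)
  for (rep in 1:5) {
    e <- make_ensemble()
    rep1 <- score_msa(e$ref, e$alts)
    lens <- nchar(gsub("-", "", unclass(e$ref), fixed = TRUE))
    lhs <- sum(rep1$sequences * lens) / sum(lens)
    expect_equal(lhs, mean(rep1$residues$score), tolerance = 1e-12)
  }
})

test_that("residue scores average the pair scores they participate in", {
  # a residue in exactly 2 pairs scored 0.2 and 0.6 scores 0.4
  ref <- as_msa(c(a = "A", b = "A", c = "A"))
  alt1 <- as_msa(c(a = "A-", b = "A-", c = "-A"))  # only (a,b) aligned
  alts <- c(replicate(1, alt1, simplify = FALSE),
            replicate(4, ref, simplify = FALSE))
  ps <- pair_and_spc_scores(ref, alts)
  rs <- residue_and_sequence_scores(ps, ref)
  # pair (a,b) = 1.0, pairs (a,c) and (b,c) = 0.8
  expect_equal(sort(unique(ps$pairs$score)), c(0.8, 1.0))
  a_res <- rs$residues[rs$residues$id == "a", "score"]
  expect_equal(a_res, (1.0 + 0.8) / 2)
})

test_that("masking and filtering respect cutoffs and msa invariants", {
  set.seed(85)
  e <- make_ensemble()
  rep1 <- score_msa(e$ref, e$alts)
  expect_identical(as.vector(unclass(mask_msa(e$ref, rep1, column_cutoff = 0))),
                   as.vector(unclass(e$ref)))
  cut <- max(rep1$cs)  # guarantees at least one survivor
  filt <- mask_msa(e$ref, rep1, column_cutoff = cut)
  expect_identical(msa_ncol(filt), as.integer(sum(rep1$cs >= cut)))
  expect_error(mask_msa(e$ref, rep1, column_cutoff = 2), "cutoffs")
  masked <- mask_msa(e$ref, rep1, residue_cutoff = 0.8, mode = "mask_residues")
  n_masked <- sum(msa_matrix_oracle(masked) == "X") -
    sum(msa_matrix_oracle(e$ref) == "X")
  expect_identical(n_masked,
                   as.integer(sum(rep1$residues$score < 0.8, na.rm = TRUE)))
})

test_that("score report files round-trip the scores", {
  set.seed(86)
  e <- make_ensemble(n_alts = 5L)
  rep1 <- score_msa(e$ref, e$alts)
  dir <- withr::local_tempdir()
  write_score_report(rep1, dir)
  tab <- read.table(file.path(dir, "column_scores.tsv"), header = TRUE)
  expect_equal(tab$cs, rep1$cs, tolerance = 1e-12)
  expect_equal(tab$spc, as.numeric(rep1$spc), tolerance = 1e-12)
  js <- jsonlite::read_json(file.path(dir, "summary.json"))
  expect_equal(js$mean_cs, mean(rep1$cs), tolerance = 1e-12)
  expect_identical(js$n_alternatives, length(e$alts))
})
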