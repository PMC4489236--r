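test_that("degenerate regimes: zero branch lengths and zero indel rates", {
  tree <- random_tree(6, 1)
  zero <- tree; zero$edge.length[] <- 0
  model <- evol_model(root_length = 40L)
  sim <- simulate_msa(zero, model, seed = 1)
  expect_identical(msa_ncol(sim$true_msa), 40L)
  expect_false(any(grepl("-", unclass(sim$true_msa), fixed = TRUE)))
  expect_identical(length(unique(as.vector(unclass(sim$sequences)))), 1L)

  no_indel <- evol_model(ins_rate = 0, del_rate = 0, root_length = 55L)
  sim2 <- simulate_msa(tree, no_indel, seed = 2)
  expect_identical(msa_ncol(sim2$true_msa), 55L)
  expect_identical(nrow(sim2$events), 0L)
})

test_that("residue conservation and column accounting hold exactly", {
  set.seed(91)
  for (rep in 1:5) {
    tree <- random_tree(sample(5:12, 1), runif(1, 0.5, 1.5))
    model <- evol_model(root_length = sample(60:120, 1),
                        ins_rate = 0.05, del_rate = 0.05)
    sim <- simulate_msa(tree, model)
    expect_identical(as.vector(unclass(ungap(sim$true_msa))),
                     as.vector(unclass(sim$sequences)))
    ins_cols <- sum(sim$events$length[sim$events$type == "insertion"])
    expect_identical(sim$n_inserted, as.integer(ins_cols))
    expect_identical(msa_ncol(sim$true_msa),
                     model$root_length + sim$n_inserted - sim$n_extinct)
    m <- msa_matrix_oracle(sim$true_msa)
    expect_true(all(colSums(m != "-") > 0L))
  }
})

test_that("simulation is bit-reproducible under a fixed seed", {
  tree <- random_tree(8, 1)
  s1 <- simulate_msa(tree, evol_model(root_length = 80L), seed = 7)
  s2 <- simulate_msa(tree, evol_model(root_length = 80L), seed = 7)
  expect_identical(as.vector(unclass(s1$true_msa)),
                   as.vector(unclass(s2$true_msa)))
  expect_identical(s1$events, s2$events)
})

test_that("site rates have the stated mixture structure", {
  set.seed(92)
  expect_true(all(sample_site_rates(1, 0, 5000L) > 0))
  r <- sample_site_rates(1e6, 0, 2000L)
  expect_lt(max(abs(r - 1)), 0.01)  # gamma concentration at alpha -> Inf
  r2 <- sample_site_rates(0.8, 0.25, 1e5L)
  expect_lt(abs(mean(r2 == 0) - 0.25), 3 * sqrt(0.25 * 0.75 / 1e5))
  pos <- r2[r2 > 0]
  expect_lt(abs(mean(pos) - 1), 3 * sd(pos) / sqrt(length(pos)))
})

test_that("the substitution process is stationary and matches closed forms", {
  # two leaves at total divergence 2t under the Poisson model, fixed rate
  model <- evol_model("Poisson", alpha = 1e9, pinv = 0,
                      ins_rate = 0, del_rate = 0, root_length = 20000L)
  tree <- ape::read.tree(text = "(x:5,y:5);")
  sim <- simulate_msa(tree, model, seed = 93)
  counts <- table(factor(strsplit(sim$sequences[["x"]], "")[[1L]],
                         levels = AA20))
  chi <- suppressWarnings(chisq.test(as.vector(counts),
                                     p = rep(1 / 20, 20)))
  expect_gt(chi$p.value, 0.01)  # equilibrium frequencies at large t

  # small-t mismatch fraction: closed-form 20-state Poisson divergence
  t_tot <- 0.2
  tree2 <- ape::read.tree(text = sprintf("(x:%g,y:%g);", t_tot / 2, t_tot / 2))
  sim2 <- simulate_msa(tree2, model, seed = 94)
  a <- strsplit(sim2$sequences[["x"]], "")[[1L]]
  b <- strsplit(sim2$sequences[["y"]], "")[[1L]]
  phat <- mean(a != b)
  expected <- (19 / 20) * (1 - exp(-(20 / 19) * t_tot))
  se <- sqrt(expected * (1 - expected) / length(a))
  expect_lt(abs(phat - expected), 3 * se)
})

test_that("transition probabilities are proper and reversible", {
  for (model in list(evol_model("LG"), evol_model("Poisson"))) {
    P <- transition_probs(model, 0.5)
    expect_equal(rowSums(P), rep(1, 20), tolerance = 1e-9)
    expect_true(all(P >= 0))
    # detailed balance: pi_i P_ij = pi_j P_ji
    flux <- model$freqs * P
    expect_equal(flux, t(flux), tolerance = 1e-9)
    # branch length calibration: expected substitutions per unit time = 1
    expect_equal(-sum(model$freqs * diag(model$Q)), 1, tolerance = 1e-9)
  }
})

test_that("indel lengths respect the min(10% length, 25) cap", {
  set.seed(95)
  model <- evol_model(root_length = 400L, ins_rate = 0.15, del_rate = 0.15)
  tree <- random_tree(6, 2)
  sim <- simulate_msa(tree, model)
  expect_gt(nrow(sim$events), 0L)
  expect_true(all(sim$events$length <= 25L))
  small <- evol_model(root_length = 30L, ins_rate = 0.2, del_rate = 0.2)
  sim2 <- simulate_msa(tree, small, seed = 96)
  # sequence length never exceeds root_length + total insertions, so the
  # 10%-of-current-length cap bounds every event length
  cap <- max(1L, as.integer(ceiling(0.1 * (30L + sim2$n_inserted))))
  expect_true(all(sim2$events$length <= cap))
})
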