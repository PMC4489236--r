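# Indel-aware protein sequence evolution along a tree. Substitutions
# follow a reversible rate matrix (LG by default) with continuous gamma
# rate heterogeneity plus a proportion of invariant sites; indels occur
# as a Poisson process per branch with Zipf-distributed lengths capped
# at min(ceil(10% of the current sequence length), 25). Insertions
# create new columns of the true alignment; deletions create gaps. The
# true MSA and the ungapped leaf sequences are both returned, so
# reliability scores can be benchmarked against a known truth.

UPPER_TRI_20 <- upper.tri(diag(20), diag = TRUE) * 1

#' Evolution model for the simulator
#'
#' @param substitution `"LG"` (default; exchangeabilities and
#'   frequencies from the phangorn model table) or `"Poisson"` (all
#'   exchangeabilities and frequencies equal — used by closed-form
#'   oracles in the tests).
#' @param alpha gamma shape for among-site rate variation (mean-1 gamma).
#' @param pinv proportion of invariant sites (rate 0).
#' @param ins_rate,del_rate insertion/deletion events per substitution
#'   per site (default 0.03 each).
#' @param indel_exponent Zipf exponent of the indel length law
#'   (default 1.7); lengths are truncated at
#'   `min(ceiling(0.10 * current_length), 25)`.
#' @param root_length number of root sites.
#' @return object of class `"evol_model"` carrying the eigendecomposed
#'   rate matrix (unit expected substitutions per site per unit branch
#'   length at the equilibrium frequencies).
#' @export
evol_model <- function(substitution = c("LG", "Poisson"), alpha = 1,
                       pinv = 0.1, ins_rate = 0.03, del_rate = 0.03,
                       indel_exponent = 1.7, root_length = 200L) {
  substitution <- match.arg(substitution)
  if (alpha <= 0) stop("alpha must be positive")
  if (pinv < 0 || pinv >= 1) stop("pinv must lie in [0, 1)")
  if (ins_rate < 0 || del_rate < 0) stop("indel rates must be nonnegative")
  if (root_length < 1L) stop("root_length must be >= 1")
  if (substitution == "LG") {
    lg <- get(".LG", envir = asNamespace("phangorn"))
    exch <- matrix(0, 20, 20)
    exch[lower.tri(exch)] <- lg$Q
    exch <- exch + t(exch)
    freqs <- unname(lg$bf)
  } else {
    exch <- matrix(1, 20, 20); diag(exch) <- 0
    freqs <- rep(1 / 20, 20)
  }
  Q <- exch * rep(freqs, each = 20)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  mu <- -sum(freqs * diag(Q))
  Q <- Q / mu
  sq <- sqrt(freqs)
  B <- Q * outer(sq, 1 / sq)
  B <- (B + t(B)) / 2
  eig <- eigen(B, symmetric = TRUE)
  structure(list(substitution = substitution, alpha = alpha, pinv = pinv,
                 ins_rate = ins_rate, del_rate = del_rate,
                 indel_exponent = indel_exponent,
                 root_length = as.integer(root_length),
                 freqs = freqs, Q = Q, lambda = eig$values,
                 U1 = eig$vectors / sq, U2 = t(eig$vectors * sq)),
            class = "evol_model")
}

#' @export
print.evol_model <- function(x, ...) {
  cat("evol_model: ", x$substitution, ", alpha ", x$alpha, ", pinv ", x$pinv,
      ", indel rates ", x$ins_rate, "/", x$del_rate,
      ", root_length ", x$root_length, "\n", sep = "")
  invisible(x)
}

#' Transition probability matrix P(t) of the substitution model
#' @param model an [evol_model()].
#' @param t branch length (expected substitutions per site).
#' @return 20x20 stochastic matrix.
#' @export
transition_probs <- function(model, t) {
  P <- model$U1 %*% (exp(model$lambda * t) * model$U2)
  P[P < 0] <- 0
  P / rowSums(P)
}

#' Sample per-site rate multipliers
#'
#' A site is invariant (rate 0) with probability `pinv`; otherwise its
#' rate is Gamma(alpha, alpha) (mean 1). Uses the current RNG state.
#'
#' @param alpha gamma shape.
#' @param pinv proportion of invariant sites.
#' @param L number of sites.
#' @return numeric vector of length `L`.
#' @export
sample_site_rates <- function(alpha, pinv, L) {
  r <- rgamma(L, shape = alpha, rate = alpha)
  r[runif(L) < pinv] <- 0
  r
}

# truncated Zipf: P(len = k) proportional to k^-exponent, k = 1..max_len
rzipf_trunc <- function(n, exponent, max_len) {
  if (max_len <= 1L) return(rep(1L, n))
  w <- (1:max_len)^(-exponent)
  sample.int(max_len, n, replace = TRUE, prob = w)
}

# vectorized substitution of residues `res` with site rates `rs` over a
# branch of length t
evolve_residues <- function(res, rs, t, model) {
  if (t <= 0 || !length(res)) return(res)
  tau <- t * rs
  act <- which(tau > 0)
  if (!length(act)) return(res)
  E <- exp(outer(model$lambda, tau[act]))          # 20 x m
  probs <- (model$U1[res[act], , drop = FALSE] * t(E)) %*% model$U2
  probs[probs < 0] <- 0
  cp <- probs %*% UPPER_TRI_20
  u <- runif(length(act)) * cp[, 20L]
  res[act] <- pmin.int(1L + rowSums(cp < u), 20L)
  res
}

#' Simulate sequence evolution with indels along a tree
#'
#' @param tree rooted binary `phylo` with branch lengths in expected
#'   substitutions per site.
#' @param model an [evol_model()].
#' @param seed optional integer; when given, `set.seed(seed)` is called
#'   first so runs are bit-reproducible.
#' @return object of class `"sim_result"`: `true_msa` (the `msa` implied
#'   by the indel history, restricted to columns surviving in at least
#'   one leaf), `sequences` (ungapped leaf sequences), `site_rates`
#'   (root sites), `events` (data.frame: node, type, position, length),
#'   `n_inserted` and `n_extinct` column counts.
#' @export
simulate_msa <- function(tree, model = evol_model(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(tree$edge.length) || anyNA(tree$edge.length)) {
    stop("tree must have branch lengths")
  }
  tree <- finalize_tree(tree)
  n_tip <- length(tree$tip.label)
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1L])

  st <- new.env(parent = emptyenv())
  L0 <- model$root_length
  st$gcols <- seq_len(L0)          # global column order
  st$next_id <- L0 + 1L
  st$rates <- sample_site_rates(model$alpha, model$pinv, L0)
  st$events <- list()
  st$leaf_states <- vector("list", n_tip)
  root_rates <- st$rates

  root_state <- list(ids = seq_len(L0),
                     res = sample.int(20L, L0, replace = TRUE,
                                      prob = model$freqs))

  evolve_branch <- function(state, t, node_label) {
    ids <- state$ids; res <- state$res
    total_rate <- model$ins_rate + model$del_rate
    if (total_rate > 0 && t > 0 && length(ids) > 0L) {
      n_ev <- rpois(1L, total_rate * t * length(ids))
      for (e in seq_len(n_ev)) {
        L <- length(ids)
        if (L == 0L) break
        is_ins <- runif(1L) < model$ins_rate / total_rate
        max_len <- max(1L, min(ceiling(0.10 * L), 25L))
        len <- rzipf_trunc(1L, model$indel_exponent, max_len)
        if (is_ins) {
          p <- sample.int(L + 1L, 1L) - 1L   # insert after position p
          new_ids <- st$next_id + seq_len(len) - 1L
          st$next_id <- st$next_id + len
          st$rates[new_ids] <- sample_site_rates(model$alpha, model$pinv, len)
          new_res <- sample.int(20L, len, replace = TRUE, prob = model$freqs)
          gpos <- if (p == 0L) match(ids[1L], st$gcols) - 1L
                  else match(ids[p], st$gcols)
          st$gcols <- append(st$gcols, new_ids, after = gpos)
          ids <- append(ids, new_ids, after = p)
          res <- append(res, new_res, after = p)
          st$events[[length(st$events) + 1L]] <-
            data.frame(node = node_label, type = "insertion", position = p,
                       length = len, stringsAsFactors = FALSE)
        } else {
          start <- sample.int(L, 1L)
          drop <- start:min(L, start + len - 1L)
          ids <- ids[-drop]; res <- res[-drop]
          st$events[[length(st$events) + 1L]] <-
            data.frame(node = node_label, type = "deletion", position = start,
                       length = length(drop), stringsAsFactors = FALSE)
        }
      }
    }
    res <- evolve_residues(res, st$rates[ids], t, model)
    list(ids = ids, res = res)
  }

  node_name <- function(node) {
    if (node <= n_tip) tree$tip.label[node] else paste0("node", node)
  }
  rec <- function(node, state) {
    if (node <= n_tip) {
      st$leaf_states[[node]] <- state
      return(invisible())
    }
    for (e in kids[[as.character(node)]]) {
      child <- tree$edge[e, 2L]
      rec(child, evolve_branch(state, tree$edge.length[e], node_name(child)))
    }
  }
  root <- n_tip + 1L
  rec(root, root_state)

  leaf_ids <- lapply(st$leaf_states, `[[`, "ids")
  surv <- st$gcols[st$gcols %in% unique(unlist(leaf_ids))]
  if (!length(surv)) stop("all columns went extinct; increase root_length or lower del_rate")
  m <- matrix(0L, n_tip, length(surv), dimnames = list(tree$tip.label, NULL))
  for (i in seq_len(n_tip)) {
    pos <- match(leaf_ids[[i]], surv)
    m[i, pos] <- st$leaf_states[[i]]$res
  }
  empty_rows <- rowSums(m != 0L) == 0L
  if (any(empty_rows)) stop("a leaf lost all residues; lower del_rate")
  true_msa <- matrix_to_msa(m)
  events <- if (length(st$events)) do.call(rbind, st$events) else
    data.frame(node = character(), type = character(),
               position = integer(), length = integer())
  n_inserted <- st$next_id - 1L - L0
  structure(list(true_msa = true_msa, sequences = ungap(true_msa),
                 site_rates = root_rates, events = events,
                 n_inserted = n_inserted,
                 n_extinct = (L0 + n_inserted) - length(surv)),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat("sim_result: ", length(x$sequences), " leaves, true MSA ",
      msa_ncol(x$true_msa), " columns (", x$n_inserted, " inserted, ",
      x$n_extinct, " extinct), ", nrow(x$events), " indel events\n", sep = "")
  invisible(x)
}

#' Random ultrametric benchmark tree
#'
#' A coalescent topology rescaled so the root-to-tip path length equals
#' `depth` substitutions per site. Uses the current RNG state.
#'
#' @param n_taxa number of leaves.
#' @param depth root-to-tip height in expected substitutions per site.
#' @return rooted binary `phylo` with labels `t01`, `t02`, ...
#' @export
random_tree <- function(n_taxa, depth = 1) {
  tr <- ape::rcoal(n_taxa, tip.label = sprintf("t%02d", seq_len(n_taxa)))
  h <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length * depth / h
  finalize_tree(tr)
}
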