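# Shared fixtures: everything is generated in code at test time.

# Tiny simulated panel + design for fast sampler tests.
small_panel <- function(model = "M2", scale = 0.05, design_seed = 11,
                        sim_seed = 21) {
  design <- sim_design(scale = scale, seed = design_seed)
  truth <- default_truth(model)
  sim <- simulate_records(design, truth, seed = sim_seed)
  list(sim = sim, design = design, truth = truth)
}

quick_chain <- function(n_iter = 800, burn_in = 200, thin = 3, seed = 1,
                        ...) {
  chain_config(n_iter = n_iter, burn_in = burn_in, thin = thin, seed = seed,
               ...)
}

# Random acyclic structural matrix on `n` traits: strictly lower triangular
# under a random permutation, with N(0, 1) coefficients at density `p`.
random_acyclic_lambda <- function(n = 4, p = 0.5) {
  perm <- sample(n)
  L <- matrix(0, n, n)
  for (i in 2:n) {
    for (j in 1:(i - 1)) {
      if (stats::runif(1) < p) L[perm[i], perm[j]] <- stats::rnorm(1)
    }
  }
  L
}

random_pd_matrix <- function(n = 4) {
  Z <- matrix(stats::rnorm(n * (n + 2)), n + 2, n)
  crossprod(Z) / (n + 2) + diag(0.1, n)
}

# Independent pedigree oracle: assemble A^{-1} directly from the
# Henderson-style sire-MGS rules, with the needed ancestor diagonals
# computed by a standalone recursive kinship function (memoised), i.e. a
# construction independent of relationship_matrix()'s tabular sweep.
henderson_sire_mgs_ainv <- function(ped) {
  ids <- ped$id
  n <- length(ids)
  sidx <- match(ped$sire, ids)
  midx <- match(ped$mgs, ids)
  memo <- new.env(parent = emptyenv())
  rel <- function(i, j) {
    if (is.na(i) || is.na(j)) return(0)
    if (i > j) { tmp <- i; i <- j; j <- tmp }
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    val <- if (i == j) {
      1 + 0.25 * rel(sidx[i], midx[i])
    } else {
      # j is later in topological order, so recurse through j's parents
      0.5 * rel(i, sidx[j]) + 0.25 * rel(i, midx[j])
    }
    memo[[key]] <- val
    val
  }
  Ainv <- matrix(0, n, n, dimnames = list(ids, ids))
  for (q in seq_len(n)) {
    s <- sidx[q]; m <- midx[q]
    d <- 1 -
      (if (!is.na(s)) 0.25 * rel(s, s) else 0) -
      (if (!is.na(m)) 0.0625 * rel(m, m) else 0)
    w <- numeric(n)
    w[q] <- 1
    if (!is.na(s)) w[s] <- w[s] - 0.5
    if (!is.na(m)) w[m] <- w[m] - 0.25
    Ainv <- Ainv + tcrossprod(w) / d
  }
  Ainv
}

# Random sire-MGS pedigree as a plain tibble (rows in random order).
random_pedigree_table <- function(n = 30, seed = 1) {
  set.seed(seed)
  ids <- sprintf("X%03d", seq_len(n))
  sire <- rep(NA_character_, n)
  mgs <- rep(NA_character_, n)
  for (k in 3:n) {
    if (stats::runif(1) < 0.8) sire[k] <- ids[sample(k - 1, 1)]
    if (stats::runif(1) < 0.6) mgs[k] <- ids[sample(k - 1, 1)]
  }
  tbl <- tibble::tibble(id = ids, sire = sire, mgs = mgs)
  tbl[sample(n), ]
}
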