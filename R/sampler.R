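#' Prior specification for the Bayesian SEM / MTM fit
#'
#' Defaults follow the analysis protocol: structural coefficients get
#' independent normal priors `N(lambda0, tau2)` with `lambda0 = 0` and
#' `tau2 = 10000`; fixed effects `N(0, 10000)`; the sire (G), herd (H) and
#' permanent-environment (P) covariance matrices get inverse-Wishart priors
#' with `nu = 6` degrees of freedom; the residual covariance R gets an
#' inverse-Wishart in the MTM and independent per-trait scaled inverse
#' chi-square priors (same `nu`) in the SEM, where R is forced diagonal for
#' identifiability.
#'
#' Scale matrices are not part of the protocol and default to weakly
#' informative values derived from the data at fit time: with `nt` traits
#' and `nc` random components plus the residual, each component's prior is
#' centred at half an equal share of the observed phenotypic variance,
#' i.e. `S = diag(0.5 * var_obs / ncomp) * (nu - nt - 1)` for the Wishart
#' priors and `S_t = 0.5 * (var_obs_t / ncomp) * (nu - 2)` for the
#' inverse chi-square residual scales.
#'
#' @param nu Inverse-Wishart / inverse chi-square degrees of freedom.
#' @param tau2 Prior variance of structural coefficients.
#' @param lambda0 Prior mean of structural coefficients.
#' @param b_var Prior variance of fixed effects.
#' @param S_G,S_P,S_H,S_R Optional explicit scale matrices (traits x
#'   traits) overriding the data-derived defaults.
#' @param r_scale Optional explicit per-trait inverse chi-square scales for
#'   the SEM residual.
#' @return Object of class `prior_spec`.
#' @export
prior_spec <- function(nu = 6, tau2 = 10000, lambda0 = 0, b_var = 10000,
                       S_G = NULL, S_P = NULL, S_H = NULL, S_R = NULL,
                       r_scale = NULL) {
  stopifnot(tau2 > 0, b_var > 0, nu > 0)
  structure(list(nu = nu, tau2 = tau2, lambda0 = lambda0, b_var = b_var,
                 S_G = S_G, S_P = S_P, S_H = S_H, S_R = S_R,
                 r_scale = r_scale),
            class = "prior_spec")
}

#' Chain configuration
#'
#' Defaults reproduce the analysis protocol: 120 000 iterations, the first
#' 20 000 discarded as burn-in, every 10th retained thereafter, leaving
#' 10 000 samples for inference.
#'
#' @param n_iter Total iterations.
#' @param burn_in Burn-in iterations (discarded).
#' @param thin Thinning interval.
#' @param seed Integer RNG seed.
#' @param step_init Initial Metropolis-Hastings random-walk SD per
#'   structural coefficient (recycled); adapted during burn-in only
#'   (Robbins-Monro toward `target_accept`), frozen afterwards.
#' @param adapt_every Adaptation batch length in iterations.
#' @param target_accept Target MH acceptance rate.
#' @param lambda_init Starting value(s) for the structural coefficients
#'   (recycled over edges); default 0. Useful for dispersed-start
#'   convergence checks.
#' @return Object of class `chain_config` with derived `n_retained`.
#' @export
chain_config <- function(n_iter = 120000, burn_in = 20000, thin = 10,
                         seed = 1, step_init = 0.1, adapt_every = 50,
                         target_accept = 0.30, lambda_init = 0) {
  stopifnot(burn_in < n_iter, thin >= 1)
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), seed = as.integer(seed),
                 step_init = step_init, adapt_every = as.integer(adapt_every),
                 target_accept = target_accept, lambda_init = lambda_init,
                 n_retained = (as.integer(n_iter) - as.integer(burn_in)) %/%
                   as.integer(thin)),
            class = "chain_config")
}

#' Transform records to the structural scale
#'
#' Applies `y* = (I - Lambda) y` per record, removing the causal
#' contributions so that `y*` follows the multiple-trait likelihood with
#' independent (diagonal-R) residuals.
#'
#' @param records Records tibble (or data frame) with the trait columns.
#' @param Lambda Structural coefficient matrix.
#' @param traits Trait column names; default [milk_traits()].
#' @return The records tibble with trait columns replaced by their
#'   structural-scale values.
#' @export
#' @examples
#' L <- lambda_matrix(model_preset("M2"), c("RCT->a30" = -1.901))
#' df <- tibble::tibble(SCS = 2, CAS = 2.4, RCT = 18.9, a30 = 23.0)
#' reduce_records(df, L)$a30 # 23.0 - (-1.901) * 18.9 = 58.9289
reduce_records <- function(records, Lambda, traits = milk_traits()) {
  Y <- as.matrix(records[traits])
  Ystar <- Y %*% t(diag(ncol(Y)) - Lambda)
  out <- records
  out[traits] <- tibble::as_tibble(Ystar, .name_repair = ~traits)
  out
}

#' Fit a recursive SEM or baseline MTM by MCMC
#'
#' Samples all model unknowns by Gibbs updates (fixed effects, herd, cow
#' permanent-environment and sire effect blocks from their multivariate
#' normal full conditionals; covariance matrices from inverse-Wishart /
#' inverse chi-square full conditionals) with scalar random-walk
#' Metropolis-Hastings updates for the structural coefficients. An empty
#' structure gives the baseline multiple-trait model with a full residual
#' covariance; any structure with edges forces the residual diagonal.
#'
#' @param records Tibble of phenotype records with columns `cow`, `herd`,
#'   `sire`, `dim_class` and the trait columns.
#' @param pedigree Optional `sire_mgs_pedigree` (see [read_pedigree()]);
#'   all `sire` values in `records` must appear in it. `NULL` treats the
#'   sires as unrelated.
#' @param structure A [causal_structure()] or preset name (see
#'   [model_preset()]); default `"M0"`.
#' @param priors A [prior_spec()].
#' @param chain A [chain_config()].
#' @param traits Trait column names; default [milk_traits()].
#' @param verbose Print progress every 1000 iterations.
#' @return Object of class `sem_fit` with elements `draws` (tibble, one
#'   row per retained sample), `structure`, `traits`, `trait_sd` (observed
#'   phenotypic SDs, used for SD-unit transforms), `acceptance` (tibble
#'   per edge), `effect_means` (posterior means of herd/cow/sire effect
#'   matrices), `priors`, `chain`, `n_records` and level counts.
#' @export
fit_sem <- function(records, pedigree = NULL, structure = "M0",
                    priors = prior_spec(), chain = chain_config(),
                    traits = milk_traits(), verbose = FALSE) {
  if (is.character(structure)) structure <- model_preset(structure)
  stopifnot(inherits(structure, "causal_structure"),
            inherits(priors, "prior_spec"), inherits(chain, "chain_config"))
  if (!identical(structure$traits, traits)) {
    stop("structure traits do not match the requested trait columns",
         call. = FALSE)
  }
  miss <- setdiff(c("cow", "herd", "sire", "dim_class", traits),
                  names(records))
  if (length(miss)) stop("records lack column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  Y <- as.matrix(records[traits])
  if (anyNA(Y)) stop("records contain missing trait values", call. = FALSE)
  nt <- length(traits)
  n <- nrow(Y)

  herd_lev <- sort(unique(records$herd))
  cow_lev <- sort(unique(records$cow))
  herd_idx <- match(records$herd, herd_lev) - 1L
  cow_idx <- match(records$cow, cow_lev) - 1L

  if (is.null(pedigree)) {
    sire_lev <- sort(unique(records$sire))
    Ainv <- diag(length(sire_lev))
    sire_ids <- sire_lev
  } else {
    rel <- relationship_matrix(pedigree)
    sire_ids <- rel$ids
    missing_sires <- setdiff(unique(records$sire), sire_ids)
    if (length(missing_sires)) {
      stop("sire(s) absent from pedigree: ",
           paste(utils::head(missing_sires, 5), collapse = ", "),
           call. = FALSE)
    }
    Ainv <- rel$A_inv
  }
  sire_idx <- match(records$sire, sire_ids) - 1L

  X <- cbind(1, outer(records$dim_class, seq_len(3), `==`) * 1)
  colnames(X) <- c("intercept", paste0("dim", 1:3))

  # data-derived weakly informative prior scales
  var_obs <- apply(Y, 2, stats::var)
  ncomp <- 1 + 2 + 1 # herd + cow + sire + residual
  share <- var_obs / ncomp
  wish_factor <- max(priors$nu - nt - 1, 1)
  S_G <- priors$S_G %||% diag(0.5 * share * wish_factor, nt)
  S_P <- priors$S_P %||% diag(0.5 * share * wish_factor, nt)
  S_H <- priors$S_H %||% diag(0.5 * share * wish_factor, nt)
  S_R <- priors$S_R %||% diag(0.5 * share * wish_factor, nt)
  r_scale <- priors$r_scale %||% (0.5 * share * max(priors$nu - 2, 1))

  edges <- structure$edges
  edge_mat <- if (nrow(edges)) {
    cbind(edges$to_idx - 1L, edges$from_idx - 1L)
  } else {
    matrix(0L, 0, 2)
  }
  lambda0_vec <- rep_len(chain$lambda_init %||% 0,
                         max(nrow(edges), 1))[seq_len(nrow(edges))]
  step0 <- rep_len(chain$step_init, max(nrow(edges), 1))[
    seq_len(nrow(edges))]

  set.seed(chain$seed)
  raw <- sem_mcmc_cpp(
    Y, X, herd_idx, cow_idx, sire_idx,
    use_herd = TRUE, use_cow = TRUE, use_sire = TRUE,
    Ainv = Ainv, edges = edge_mat,
    nu = priors$nu, Sg = S_G, Sp = S_P, Sh = S_H, Sr = S_R,
    r_scale = r_scale, tau2 = priors$tau2, lambda0 = priors$lambda0,
    b_var = priors$b_var, lambda = lambda0_vec, step = step0,
    n_iter = chain$n_iter, burn_in = chain$burn_in, thin = chain$thin,
    adapt_every = chain$adapt_every, target_accept = chain$target_accept,
    verbose = verbose
  )

  draws <- assemble_draws(raw, traits, colnames(X), structure)
  acceptance <- if (nrow(edges)) {
    tibble::tibble(edge = edge_keys(structure),
                   accept_rate = as.numeric(raw$accept_rate),
                   step_final = as.numeric(raw$step_final))
  } else {
    tibble::tibble(edge = character(), accept_rate = numeric(),
                   step_final = numeric())
  }
  effect_means <- list(
    herd = name_effects(raw$herd_mean, herd_lev, traits),
    cow = name_effects(raw$cow_mean, cow_lev, traits),
    sire = name_effects(raw$sire_mean, sire_ids, traits)
  )
  structure(
    list(draws = draws, structure = structure, traits = traits,
         trait_sd = apply(Y, 2, stats::sd), trait_mean = colMeans(Y),
         acceptance = acceptance, effect_means = effect_means,
         priors = priors, chain = chain, n_records = n,
         n_herds = length(herd_lev), n_cows = length(cow_lev),
         n_pedigree = nrow(Ainv)),
    class = "sem_fit"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

name_effects <- function(M, levels, traits) {
  M <- as.matrix(M)
  dimnames(M) <- list(levels, traits)
  M
}

cov_names <- function(prefix, traits) {
  as.vector(outer(traits, traits,
                  function(a, b) paste0(prefix, "[", a, ",", b, "]")))
}

assemble_draws <- function(raw, traits, terms, structure) {
  nt <- length(traits)
  b_names <- as.vector(outer(terms, traits,
                             function(t, tr) paste0("b[", tr, ",", t, "]")))
  cols <- list(
    stats::setNames(as.data.frame(raw$B), b_names),
    stats::setNames(as.data.frame(raw$G), cov_names("G", traits)),
    stats::setNames(as.data.frame(raw$P), cov_names("P", traits)),
    stats::setNames(as.data.frame(raw$H), cov_names("H", traits)),
    stats::setNames(as.data.frame(raw$R), cov_names("R", traits))
  )
  if (nrow(structure$edges)) {
    cols <- c(cols, list(stats::setNames(
      as.data.frame(raw$lambda),
      paste0("lambda[", edge_keys(structure), "]"))))
  }
  out <- dplyr::bind_cols(cols)
  # drop duplicated symmetric entries: keep lower-left redundant copies out
  keep <- !duplicated_cov_cols(names(out), traits)
  out <- out[keep]
  tibble::as_tibble(dplyr::bind_cols(
    tibble::tibble(iteration = seq_len(nrow(out))), out))
}

duplicated_cov_cols <- function(nms, traits) {
  nt <- length(traits)
  dup <- rep(FALSE, length(nms))
  for (prefix in c("G", "P", "H", "R")) {
    idx <- matrix(match(cov_names(prefix, traits), nms), nt, nt)
    for (i in seq_len(nt)) {
      for (j in seq_len(nt)) {
        if (i > j && !is.na(idx[i, j])) dup[idx[i, j]] <- TRUE
      }
    }
  }
  dup
}

#' Extract a trait-by-trait covariance matrix from one stored draw
#'
#' @param fit A `sem_fit`.
#' @param which One of `"G"`, `"P"`, `"H"`, `"R"`.
#' @param draw Row index of the retained sample.
#' @return Symmetric matrix with trait dimnames.
#' @export
draw_matrix <- function(fit, which = c("G", "P", "H", "R"), draw = 1L) {
  which <- match.arg(which)
  tr <- fit$traits
  nt <- length(tr)
  M <- matrix(NA_real_, nt, nt, dimnames = list(tr, tr))
  for (i in seq_len(nt)) {
    for (j in i:nt) {
      col <- paste0(which, "[", tr[i], ",", tr[j], "]")
      M[i, j] <- M[j, i] <- fit$draws[[col]][draw]
    }
  }
  M
}

#' Lambda matrix from one stored draw
#'
#' @param fit A `sem_fit`.
#' @param draw Row index of the retained sample.
#' @return Structural coefficient matrix for that draw.
#' @export
draw_lambda <- function(fit, draw = 1L) {
  L <- lambda_matrix(fit$structure,
                     stats::setNames(rep(0, nrow(fit$structure$edges)),
                                     edge_keys(fit$structure)))
  for (k in edge_keys(fit$structure)) {
    e <- fit$structure$edges[match(k, edge_keys(fit$structure)), ]
    L[e$to_idx, e$from_idx] <- fit$draws[[paste0("lambda[", k, "]")]][draw]
  }
  L
}

#' @export
print.sem_fit <- function(x, ...) {
  cat("<sem_fit> ", x$n_records, " records, ", x$n_cows, " cows, ",
      x$n_herds, " herds, ", x$n_pedigree, " pedigree individuals\n",
      sep = "")
  cat("  structure:", if (nrow(x$structure$edges))
    paste(edge_keys(x$structure), collapse = ", ") else
      "none (multiple-trait model)", "\n")
  cat("  retained samples:", nrow(x$draws), "\n")
  if (nrow(x$acceptance)) {
    cat("  MH acceptance:",
        paste(sprintf("%s %.2f", x$acceptance$edge,
                      x$acceptance$accept_rate), collapse = "; "), "\n")
  }
  invisible(x)
}
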