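#' Reference estimates for the emulated study conditions
#'
#' Point estimates (posterior means and 95% HPD bounds) for Italian
#' Holstein first-lactation test-day records on the four-trait panel, used
#' to calibrate the synthetic-data generator's default truth and as worked-
#' example inputs for the desk-scale transforms ([sd_units()],
#' [heritability()], [variance_loss()]).
#'
#' @return A named list of tibbles:
#' \describe{
#'   \item{trait_stats}{observed per-trait mean and SD of the records.}
#'   \item{causal_effects}{per model (M1, M2, M3) and edge: posterior mean,
#'     95% HPD bounds, and the SD-unit transform.}
#'   \item{heritability_m0}{baseline MTM heritabilities per trait.}
#'   \item{a30_variance}{per model: sire and phenotypic variance of curd
#'     firmness (MTM scale for M0; structural scale for M1-M3) and the
#'     associated heritability.}
#'   \item{genetic_correlations_m0, phenotypic_correlations_m0}{baseline
#'     MTM correlation matrices.}
#' }
#' @export
reference_estimates <- function() {
  tr <- milk_traits()
  trait_stats <- tibble::tibble(
    trait = tr,
    mean = c(2.35, 2.46, 18.9, 23.0),
    sd   = c(1.66, 0.23, 3.80, 8.53)
  )
  causal_effects <- tibble::tribble(
    ~model, ~from, ~to, ~mean, ~hpd_lower, ~hpd_upper,
    "M1", "SCS", "RCT",   0.242,  0.196,  0.288,
    "M1", "CAS", "RCT",  -3.043, -3.372, -2.705,
    "M1", "SCS", "a30",  -0.730, -0.824, -0.625,
    "M1", "CAS", "a30",  18.823, 18.128, 19.595,
    "M2", "RCT", "a30",  -1.901, -1.931, -1.869,
    "M3", "SCS", "a30",  -0.267, -0.327, -0.207,
    "M3", "CAS", "a30",  12.845, 12.443, 13.232,
    "M3", "RCT", "a30",  -1.792, -1.819, -1.764
  )
  sds <- stats::setNames(trait_stats$sd, trait_stats$trait)
  causal_effects$sd_units <- unname(sd_units(
    causal_effects$mean,
    sd_x = sds[causal_effects$from],
    sd_y = sds[causal_effects$to]
  ))
  heritability_m0 <- tibble::tibble(
    trait = tr, h2 = c(0.030, 0.157, 0.167, 0.187)
  )
  a30_variance <- tibble::tibble(
    model = c("M0", "M1", "M2", "M3"),
    sigma2_s = c(3.829, 3.135, 0.536, 0.128),
    sigma2_y = c(81.998, 70.192, 22.108, 11.902),
    h2 = c(0.187, 0.179, 0.097, 0.043)
  )
  gc <- diag(4)
  gc[upper.tri(gc)] <- c(-0.096, -0.081, -0.157, -0.072, 0.374, -0.918)
  gc <- gc + t(gc) - diag(4)
  pc <- diag(4)
  pc[upper.tri(pc)] <- c(0.042, 0.182, -0.046, -0.192, 0.291, -0.851)
  pc <- pc + t(pc) - diag(4)
  dimnames(gc) <- dimnames(pc) <- list(tr, tr)
  list(
    trait_stats = trait_stats,
    causal_effects = causal_effects,
    heritability_m0 = heritability_m0,
    a30_variance = a30_variance,
    genetic_correlations_m0 = gc,
    phenotypic_correlations_m0 = pc
  )
}

#' Project a symmetric matrix to the nearest positive semi-definite matrix
#' (eigenvalue clipping) with a small ridge for strict positive
#' definiteness.
#' @noRd
nearest_pd <- function(M, ridge = 1e-8, label = "matrix") {
  M <- (M + t(M)) / 2
  e <- eigen(M, symmetric = TRUE)
  if (min(e$values) > 0) return(M)
  warning(label, " is not positive definite; projected to nearest PSD",
          call. = FALSE)
  v <- pmax(e$values, ridge * mean(abs(e$values)))
  out <- e$vectors %*% (v * t(e$vectors))
  dimnames(out) <- dimnames(M)
  (out + t(out)) / 2
}

#' Default generator truth calibrated to the emulated study
#'
#' Constructs the true parameters used by [simulate_records()] so the
#' simulated panels carry the dispersion structure of the emulated Italian
#' Holstein study conditions. The construction works on the MTM scale
#' first: total phenotypic variances come from the observed trait SDs
#' (81.998 for a30, the model-based value), sire variances from the
#' baseline heritabilities (3.829 for a30), and covariances from the
#' baseline genetic and phenotypic correlation matrices. These are then
#' congruence-transformed to the SEM scale by `(I - Lambda)`, where
#' `Lambda` holds the reference posterior means of the requested model
#' preset. The SEM-scale residual is diagonal (identifiability); all
#' environmental off-diagonals are carried by the herd and permanent-
#' environment components, so the implied MTM-scale totals are preserved
#' exactly. Defaults: residual takes 50% of the SEM-scale environmental
#' variance per trait; the remainder splits 30% herd / 70% permanent
#' environment.
#'
#' @param model Preset name for the true causal structure (default
#'   `"M3"`); `"M0"` gives a causality-free truth.
#' @param residual_frac,herd_frac Fraction of the SEM-scale environmental
#'   variance assigned to the residual, and fraction of the non-residual
#'   remainder assigned to the herd component.
#' @return Object of class `sem_truth`: list with `structure`, `Lambda`,
#'   SEM-scale `G`, `P`, `H`, `R` (diagonal), fixed effects `b`
#'   (rows: intercept + days-in-milk classes 1-3 against class 4), and
#'   `trait_stats`.
#' @export
#' @examples
#' tp <- default_truth("M2")
#' tp$Lambda["a30", "RCT"] # -1.901
default_truth <- function(model = "M3", residual_frac = 0.5,
                          herd_frac = 0.3) {
  ref <- reference_estimates()
  tr <- milk_traits()
  structure_ <- model_preset(model)
  ce <- dplyr::filter(ref$causal_effects, .data$model == !!model)
  vals <- if (nrow(ce)) {
    stats::setNames(ce$mean, paste0(ce$from, "->", ce$to))
  } else {
    numeric()
  }
  Lambda <- lambda_matrix(structure_, vals)

  sd_obs <- stats::setNames(ref$trait_stats$sd, tr)
  v_tot <- sd_obs^2
  v_tot["a30"] <- ref$a30_variance$sigma2_y[ref$a30_variance$model == "M0"]
  v_sire <- ref$heritability_m0$h2 * v_tot / 4
  v_sire["a30"] <- ref$a30_variance$sigma2_s[ref$a30_variance$model == "M0"]

  ss <- sqrt(v_sire)
  st <- sqrt(v_tot)
  G_mtm <- nearest_pd(diag(ss) %*% ref$genetic_correlations_m0 %*% diag(ss),
                      label = "MTM-scale genetic covariance")
  T_mtm <- nearest_pd(diag(st) %*% ref$phenotypic_correlations_m0 %*%
                        diag(st),
                      label = "MTM-scale total covariance")
  dimnames(G_mtm) <- dimnames(T_mtm) <- list(tr, tr)
  E_mtm <- nearest_pd(T_mtm - G_mtm, label = "MTM-scale environmental "
                      %+% "covariance")

  G <- from_mtm_scale(G_mtm, Lambda)
  E <- from_mtm_scale(E_mtm, Lambda)
  R <- diag(residual_frac * diag(E), nrow = 4)
  M <- nearest_pd(E - R, label = "SEM-scale herd+PE covariance")
  H <- herd_frac * M
  P <- (1 - herd_frac) * M
  dimnames(G) <- dimnames(R) <- dimnames(H) <- dimnames(P) <- list(tr, tr)

  mu <- stats::setNames(ref$trait_stats$mean, tr)
  B <- diag(4) - Lambda
  intercept <- drop(B %*% mu)
  # Modest early-lactation trends per days-in-milk class (1-3 vs class 4),
  # a generator choice: the emulated conditions report no fixed-effect
  # solutions.
  dim_fx <- rbind(
    SCS = c(0.25, 0.00, -0.05),
    CAS = c(0.08, -0.02, -0.01),
    RCT = c(-0.40, -0.20, -0.10),
    a30 = c(1.00, 0.50, 0.20)
  )
  b <- rbind(intercept = intercept, dim1 = dim_fx[, 1], dim2 = dim_fx[, 2],
             dim3 = dim_fx[, 3])
  colnames(b) <- tr

  structure(
    list(structure = structure_, Lambda = Lambda, G = G, P = P, H = H,
         R = R, b = b, trait_stats = ref$trait_stats, model = model),
    class = "sem_truth"
  )
}

`%+%` <- function(a, b) paste0(a, b)

#' Implied MTM-scale dispersion of a generator truth
#'
#' @param truth A `sem_truth` object.
#' @return List with MTM-scale `G`, `P`, `H`, `R`, `total`, per-trait
#'   heritability and the genetic/phenotypic correlation matrices.
#' @export
implied_mtm <- function(truth) {
  stopifnot(inherits(truth, "sem_truth"))
  m <- to_mtm_scale(truth$G, truth$P, truth$H, truth$R, truth$Lambda)
  total <- m$G + m$P + m$H + m$R
  list(G = m$G, P = m$P, H = m$H, R = m$R, total = total,
       h2 = heritability(diag(m$G), diag(m$P), diag(m$H), diag(m$R)),
       correlations = trait_correlations(m))
}

# deterministic per-source substream seed derived from the global seed
substream <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 1009 + h * 97) %% 2147483629)
}

#' Generate a study design emulating the reference recording scheme
#'
#' Lays out cows, herds, sires and a sire-MGS pedigree with the structure
#' of the emulated conditions: 3266 cows in 309 herds sired by 128 AI
#' bulls inside a 1254-individual sire-MGS pedigree, about 2.7 records per
#' cow (zero-truncated Poisson), days-in-milk classes assigned
#' sequentially per cow to mimic monthly recording. A single `scale`
#' factor shrinks every dimension proportionally.
#'
#' @param scale Proportional size of the design (1 = full study size).
#' @param seed Integer seed; every random source uses a named substream
#'   derived from it.
#' @param mean_records Target mean records per cow (default 8783/3266).
#' @param sires_per_herd Optional cap on the number of sires represented
#'   in any one herd; `NULL` (default) leaves sire usage unrestricted
#'   across herds, which keeps herd and sire effects well separated.
#' @return Object of class `study_design`: list with counts, a `cows`
#'   tibble (cow, herd, sire, n_records), and `pedigree`.
#' @export
sim_design <- function(scale = 1, seed = 1, mean_records = 8783 / 3266,
                       sires_per_herd = NULL) {
  stopifnot(scale > 0)
  n_cows  <- max(2L, round(3266 * scale))
  n_herds <- max(2L, round(309 * scale))
  n_sires <- max(2L, round(128 * scale))
  n_ped   <- max(n_sires + 2L, round(1254 * scale))

  ped <- sim_pedigree(n_ped, n_sires, seed = substream(seed, "pedigree"))

  withr_seed(substream(seed, "design"), {
    # zero-truncated Poisson: solve lambda/(1 - exp(-lambda)) = mean_records
    lam <- stats::uniroot(function(l) l / (1 - exp(-l)) - mean_records,
                          c(1e-6, 50))$root
    n_rec <- stats::qpois(stats::runif(n_cows, stats::dpois(0, lam), 1), lam)
    herd <- sample(rep_len(seq_len(n_herds), n_cows))
    # heterogeneous sire usage (popular bulls), shared across herds
    w <- stats::rgamma(n_sires, shape = 0.7)
    sire_pool <- attr(ped, "study_sires")
    if (is.null(sires_per_herd)) {
      sire <- sample(sire_pool, n_cows, replace = TRUE, prob = w)
    } else {
      sire <- character(n_cows)
      for (hh in seq_len(n_herds)) {
        idx <- which(herd == hh)
        ok <- sample(seq_len(n_sires), min(sires_per_herd, n_sires),
                     prob = w)
        sire[idx] <- sample(sire_pool[ok], length(idx), replace = TRUE)
      }
    }
    start_class <- sample(1:4, n_cows, replace = TRUE,
                          prob = c(0.4, 0.3, 0.2, 0.1))
  })

  cows <- tibble::tibble(
    cow = sprintf("C%05d", seq_len(n_cows)),
    herd = sprintf("H%04d", herd),
    sire = sire,
    n_records = pmax(1L, as.integer(n_rec)),
    start_class = as.integer(start_class)
  )
  structure(
    list(n_cows = n_cows, n_herds = n_herds, n_sires = n_sires,
         cows = cows, pedigree = ped, scale = scale, seed = seed),
    class = "study_design"
  )
}

# evaluate expr under a local RNG seed, restoring the caller's RNG state
withr_seed <- function(seed, expr) {
  env <- parent.frame()
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  eval(substitute(expr), env)
}

#' Simulate a sire-MGS pedigree linking the study sires
#'
#' Sequential generative scheme: an initial founder fraction has unknown
#' parents; each later bull draws a sire (known with probability 0.9) and
#' a maternal grandsire (known with probability 0.7) among earlier bulls,
#' with popularity weights so that large paternal half-sib families occur.
#' The study sires are the final `n_sires` individuals.
#'
#' @param n_ped Total pedigree size.
#' @param n_sires Number of study sires (must be < `n_ped`).
#' @param seed Integer seed.
#' @param founder_frac Fraction of founders (default 0.35).
#' @return A `sire_mgs_pedigree`; attribute `"study_sires"` holds the ids
#'   of the study sires.
#' @export
sim_pedigree <- function(n_ped, n_sires, seed = 1, founder_frac = 0.35) {
  stopifnot(n_ped > n_sires)
  n_found <- max(2L, round(founder_frac * n_ped))
  ids <- sprintf("B%05d", seq_len(n_ped))
  sire <- rep(NA_character_, n_ped)
  mgs <- rep(NA_character_, n_ped)
  withr_seed(seed, {
    pop <- stats::rgamma(n_ped, shape = 0.5) # popularity weights
    for (k in seq.int(n_found + 1L, n_ped)) {
      prev <- seq_len(k - 1L)
      if (stats::runif(1) < 0.9) {
        sire[k] <- ids[sample(prev, 1, prob = pop[prev])]
      }
      if (stats::runif(1) < 0.7) {
        mgs[k] <- ids[sample(prev, 1, prob = pop[prev])]
      }
    }
  })
  ped <- as_pedigree(tibble::tibble(id = ids, sire = sire, mgs = mgs))
  attr(ped, "study_sires") <- ids[seq.int(n_ped - n_sires + 1L, n_ped)]
  ped
}

#' Simulate phenotype records under a recursive structural model
#'
#' Draws sire effects jointly from `N(0, G (x) A)` over the pedigree, herd
#' and cow permanent-environment effects i.i.d. across levels from `H` and
#' `P`, and record residuals from diagonal `R`, then forms each record's
#' four-trait phenotype through the reduced form
#' `y = (I - Lambda)^-1 (Xb + h + p + s + e)`. All realized effects are
#' returned for audit, so tests can check the systematic part exactly.
#'
#' @param design A [sim_design()] object.
#' @param truth A [default_truth()] object (or compatible list).
#' @param seed Integer seed (named substreams per random source).
#' @return Object of class `sem_sim`: list with `records` (tibble: record,
#'   cow, herd, sire, dim_class, SCS, CAS, RCT, a30), `effects` (realized
#'   s, h, p, e, and the structural linear predictor `eta`), `design`,
#'   `truth`, `seed`.
#' @export
simulate_records <- function(design, truth, seed = 1) {
  stopifnot(inherits(design, "study_design"), inherits(truth, "sem_truth") ||
              is.list(truth))
  tr <- milk_traits()
  for (nm in c("G", "P", "H", "R", "Lambda", "b")) {
    if (is.null(truth[[nm]])) stop("truth lacks component ", nm,
                                   call. = FALSE)
  }
  check_pd <- function(M, nm) {
    ev <- min(eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)$values)
    if (ev < -1e-10) stop("truth component ", nm, " is not positive ",
                          "semi-definite", call. = FALSE)
  }
  check_pd(truth$G, "G"); check_pd(truth$P, "P")
  check_pd(truth$H, "H"); check_pd(truth$R, "R")

  ped <- design$pedigree
  rel <- relationship_matrix(ped)
  n_ped <- nrow(rel$A)
  cows <- design$cows
  n_rec_total <- sum(cows$n_records)

  L_A <- t(chol(rel$A))
  U_G <- chol(truth$G)
  s_mat <- withr_seed(substream(seed, "sire-effects"), {
    L_A %*% matrix(stats::rnorm(n_ped * 4), n_ped, 4) %*% U_G
  })
  rownames(s_mat) <- rel$ids

  herds <- sort(unique(cows$herd))
  h_mat <- withr_seed(substream(seed, "herd-effects"), {
    matrix(stats::rnorm(length(herds) * 4), ncol = 4) %*% chol(truth$H)
  })
  rownames(h_mat) <- herds
  p_mat <- withr_seed(substream(seed, "pe-effects"), {
    matrix(stats::rnorm(nrow(cows) * 4), ncol = 4) %*% chol(truth$P)
  })
  rownames(p_mat) <- cows$cow
  e_mat <- withr_seed(substream(seed, "residuals"), {
    matrix(stats::rnorm(n_rec_total * 4), ncol = 4) %*% chol(truth$R)
  })

  rec <- tibble::tibble(
    cow = rep(cows$cow, cows$n_records),
    herd = rep(cows$herd, cows$n_records),
    sire = rep(cows$sire, cows$n_records),
    visit = unlist(lapply(cows$n_records, seq_len)),
    dim_class = pmin(rep(cows$start_class, cows$n_records) +
                       unlist(lapply(cows$n_records, seq_len)) - 1L, 4L)
  )
  rec$record <- sprintf("R%06d", seq_len(nrow(rec)))

  X <- cbind(1, outer(rec$dim_class, 1:3, `==`) * 1)
  eta <- X %*% truth$b +
    h_mat[rec$herd, , drop = FALSE] +
    p_mat[rec$cow, , drop = FALSE] +
    s_mat[rec$sire, , drop = FALSE] +
    e_mat
  W <- solve(diag(4) - truth$Lambda)
  Y <- eta %*% t(W)
  colnames(Y) <- tr

  records <- dplyr::bind_cols(
    rec[c("record", "cow", "herd", "sire", "dim_class")],
    tibble::as_tibble(Y)
  )
  structure(
    list(records = records,
         effects = list(s = s_mat, h = h_mat, p = p_mat, e = e_mat,
                        eta = eta, X = X),
         design = design, truth = truth, seed = seed),
    class = "sem_sim"
  )
}

#' Write simulated records to delimited text
#'
#' @param x A `sem_sim` object or a records tibble.
#' @param path Output path (tab-separated with header).
#' @return `path`, invisibly.
#' @export
write_records <- function(x, path) {
  records <- if (inherits(x, "sem_sim")) x$records else x
  readr::write_tsv(records, path)
  invisible(path)
}

#' Read phenotype records from delimited text
#'
#' Expects the columns written by [write_records()]: record, cow, herd,
#' sire, dim_class and the four trait columns.
#'
#' @param path Input path (any delimiter readr can guess; default TSV).
#' @return A tibble of records.
#' @export
read_records <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           record = "c", cow = "c", herd = "c", sire = "c",
                           dim_class = "i", .default = "d"))
  need <- c("record", "cow", "herd", "sire", "dim_class", milk_traits())
  miss <- setdiff(need, names(out))
  if (length(miss)) stop("records file lacks column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  out
}
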