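#' Transform SEM-scale covariance matrices to the MTM scale
#'
#' Dispersion parameters of a recursive structural equation model describe
#' variation on the structural scale, after causal paths among phenotypes
#' are removed. To compare them with a standard multiple-trait model they
#' are mapped through the reduced form: each matrix `M` becomes
#' `(I - Lambda)^-1 M (I - Lambda)'^-1`. With no causal paths
#' (`Lambda = 0`) the transform is the identity.
#'
#' @param G,P,H,R Sire genetic, permanent-environment, herd and residual
#'   covariance matrices on the SEM scale (R may be diagonal).
#' @param Lambda Structural coefficient matrix (acyclic).
#' @return List with elements `G`, `P`, `H`, `R` on the MTM scale.
#' @export
#' @examples
#' L <- lambda_matrix(model_preset("M2"), c("RCT->a30" = -1.9))
#' to_mtm_scale(diag(4), diag(4), diag(4), diag(4), L)
to_mtm_scale <- function(G, P, H, R, Lambda) {
  n <- nrow(Lambda)
  W <- solve(diag(n) - Lambda)
  tf <- function(M) {
    out <- W %*% M %*% t(W)
    (out + t(out)) / 2
  }
  list(G = tf(G), P = tf(P), H = tf(H), R = tf(R))
}

#' Map MTM-scale matrices back to the SEM scale
#'
#' Inverse of [to_mtm_scale()]: `M -> (I - Lambda) M (I - Lambda)'`.
#'
#' @inheritParams to_mtm_scale
#' @param M A covariance matrix on the MTM scale.
#' @return The SEM-scale matrix.
#' @export
from_mtm_scale <- function(M, Lambda) {
  B <- diag(nrow(Lambda)) - Lambda
  out <- B %*% M %*% t(B)
  (out + t(out)) / 2
}

#' Sire-model heritability
#'
#' `h2 = 4 * sigma2_s / (sigma2_s + sigma2_p + sigma2_h + sigma2_e)`:
#' under a sire model the sire variance is a quarter of the additive genetic
#' variance, and the phenotypic variance is the sum of the sire, cow
#' permanent-environment, herd and residual components.
#'
#' @param sigma2_s,sigma2_p,sigma2_h,sigma2_e Variance components (either
#'   scalars or vectors over posterior draws).
#' @return Heritability value(s).
#' @export
#' @examples
#' heritability(3.829, 81.998 - 3.829 - 0, 0, 0) # via explicit components
heritability <- function(sigma2_s, sigma2_p, sigma2_h, sigma2_e) {
  4 * sigma2_s / (sigma2_s + sigma2_p + sigma2_h + sigma2_e)
}

#' Genetic and phenotypic correlation matrices from one draw
#'
#' Genetic correlations come from the MTM-scale sire covariance matrix
#' alone; phenotypic correlations from the elementwise sum
#' `G + P + H + R` (herd component included in the phenotypic variance).
#'
#' @param draw A list with MTM-scale `G`, `P`, `H`, `R` (see
#'   [to_mtm_scale()]).
#' @return List with `genetic` and `phenotypic` correlation matrices.
#' @export
trait_correlations <- function(draw) {
  total <- draw$G + draw$P + draw$H + draw$R
  list(genetic = stats::cov2cor(draw$G),
       phenotypic = stats::cov2cor(total))
}

#' Structural coefficient in standard-deviation units
#'
#' `lambda' = lambda * sd(x) / sd(y)`: the expected change in y, in y
#' standard deviations, per one standard deviation change in x. The
#' standard deviations are the observed phenotypic SDs of the analysed
#' records.
#'
#' @param lambda Posterior mean (or draws) of the causal effect of x on y.
#' @param sd_x,sd_y Observed standard deviations of x and y.
#' @return Transformed coefficient(s).
#' @export
#' @examples
#' sd_units(-1.901, sd_x = 3.80, sd_y = 8.53)
sd_units <- function(lambda, sd_x, sd_y) {
  if (any(sd_y <= 0)) stop("sd_y must be positive", call. = FALSE)
  lambda * sd_x / sd_y
}

#' Percent variance lost relative to the baseline model
#'
#' `100 * (v_M0 - v_Mk) / v_M0`: the share of a baseline (MTM) variance
#' component absorbed by the causal paths of model Mk, i.e. the variance
#' that would disappear if the causing phenotypes were held constant.
#'
#' @param value_m0 Baseline (M0) variance component; must be positive.
#' @param value_mk The same component under the structural model.
#' @return Percentage (positive when the structural model has less
#'   variance).
#' @export
#' @examples
#' variance_loss(3.829, 0.536) # sire variance of a30 absorbed by RCT
variance_loss <- function(value_m0, value_mk) {
  if (any(value_m0 <= 0)) stop("baseline variance must be positive",
                               call. = FALSE)
  100 * (value_m0 - value_mk) / value_m0
}

#' Highest posterior density interval
#'
#' Shortest contiguous interval containing the requested posterior mass,
#' computed by the sorted-sample method: among all windows of
#' `ceiling(mass * n)` consecutive order statistics, the narrowest is
#' returned (ties broken toward the lower start).
#'
#' @param samples Numeric vector of posterior draws.
#' @param mass Probability mass, default 0.95.
#' @return Named numeric vector `c(lower, upper)`.
#' @export
#' @examples
#' hpd_interval(rnorm(10000)) # close to c(-1.96, 1.96)
hpd_interval <- function(samples, mass = 0.95) {
  stopifnot(is.numeric(samples), length(samples) >= 2,
            mass > 0, mass < 1)
  x <- sort(samples)
  n <- length(x)
  k <- ceiling(mass * n)
  if (k >= n) k <- n - 1L
  width <- x[(k + 1):n] - x[1:(n - k)]
  i <- which.min(width) # which.min returns the first (lowest start) on ties
  c(lower = x[i], upper = x[i + k])
}

#' Effective sample size of an MCMC chain
#'
#' `ESS = n / (1 + 2 * sum(rho_k))`, truncating the autocorrelation sum by
#' Geyer's initial positive-sequence rule (sums of adjacent autocorrelation
#' pairs are kept while positive). Constant chains are degenerate and
#' return `NA` with a warning.
#'
#' @param x Numeric vector of draws.
#' @param max_lag Largest lag to consider; defaults to `length(x) - 1`.
#' @return Effective sample size (scalar).
#' @export
ess <- function(x, max_lag = NULL) {
  n <- length(x)
  stopifnot(n >= 2)
  if (stats::var(x) == 0) {
    warning("constant chain: effective sample size is undefined")
    return(NA_real_)
  }
  if (is.null(max_lag)) max_lag <- n - 1L
  ac <- stats::acf(x, lag.max = max_lag, plot = FALSE,
                   demean = TRUE)$acf[, 1, 1]
  # Geyer initial positive sequence on pairs (rho_{2t} + rho_{2t+1})
  rho_sum <- 0
  t <- 1L
  K <- length(ac) - 1L # ac[1] is lag 0
  while (t <= K) {
    r1 <- ac[t + 1L]
    r2 <- if (t + 1L <= K) ac[t + 2L] else 0
    if (r1 + r2 <= 0) break
    rho_sum <- rho_sum + r1 + r2
    t <- t + 2L
  }
  max(1, n / (1 + 2 * rho_sum))
}

#' Per-parameter convergence diagnostics
#'
#' Effective sample size, lag-k autocorrelations, and plot-ready trace and
#' running-mean series for each column of a draws table.
#'
#' @param draws A data frame of posterior draws (one column per parameter)
#'   or a `sem_fit` object.
#' @param lags Integer vector of autocorrelation lags to report.
#' @return A tibble with one row per parameter: `parameter`, `n`, `ess`,
#'   and one `acf_<k>` column per requested lag. The trace/running-mean
#'   series are available through [autoplot.sem_fit()].
#' @export
chain_diagnostics <- function(draws, lags = c(1, 5, 10, 50)) {
  if (inherits(draws, "sem_fit")) draws <- draws$draws
  draws <- dplyr::select(tibble::as_tibble(draws),
                         -dplyr::any_of("iteration"))
  purrr::map_dfr(names(draws), function(p) {
    x <- draws[[p]]
    constant <- stats::var(x) == 0
    e <- if (constant) NA_real_ else suppressWarnings(ess(x))
    acs <- if (constant) rep(NA_real_, length(lags)) else {
      stats::acf(x, lag.max = max(lags), plot = FALSE)$acf[lags + 1, 1, 1]
    }
    out <- tibble::tibble(parameter = p, n = length(x), ess = e)
    out[paste0("acf_", lags)] <- as.list(acs)
    out
  })
}

#' Posterior mean and HPD summary of a draws table
#'
#' @param draws Data frame of draws, one column per parameter.
#' @param mass HPD mass, default 0.95.
#' @return Tibble with `parameter`, `mean`, `sd`, `hpd_lower`, `hpd_upper`.
#' @export
posterior_summary <- function(draws, mass = 0.95) {
  draws <- dplyr::select(tibble::as_tibble(draws),
                         -dplyr::any_of("iteration"))
  purrr::map_dfr(names(draws), function(p) {
    x <- draws[[p]]
    h <- hpd_interval(x, mass)
    tibble::tibble(parameter = p, mean = mean(x), sd = stats::sd(x),
                   hpd_lower = h[["lower"]], hpd_upper = h[["upper"]])
  })
}
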