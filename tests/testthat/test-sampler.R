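test_that("reduce_records applies (I - Lambda) exactly and round-trips", {
  L0 <- lambda_matrix(model_preset("M0"))
  df <- tibble::tibble(SCS = 1.2, CAS = 2.4, RCT = 18.9, a30 = 23.0)
  expect_equal(reduce_records(df, L0), df)

  L2 <- lambda_matrix(model_preset("M2"), c("RCT->a30" = -1.901))
  red <- reduce_records(df, L2)
  expect_equal(red$a30, 23.0 - (-1.901) * 18.9) # 58.9289
  expect_equal(red$a30, 58.9289)
  expect_equal(red$RCT, df$RCT)

  # multiply back by (I - Lambda)^{-1}: original records to 1e-12
  W <- solve(diag(4) - L2)
  back <- as.matrix(red[milk_traits()]) %*% t(W)
  expect_equal(unname(back), unname(as.matrix(df[milk_traits()])),
               tolerance = 1e-12)
})

test_that("retained-sample bookkeeping and determinism hold", {
  cc <- chain_config(n_iter = 320, burn_in = 120, thin = 4, seed = 5)
  expect_equal(cc$n_retained, 50)

  panel <- small_panel("M2", scale = 0.04)
  fit1 <- fit_sem(panel$sim$records, panel$design$pedigree, "M2",
                  chain = cc)
  expect_equal(nrow(fit1$draws), 50)
  fit2 <- fit_sem(panel$sim$records, panel$design$pedigree, "M2",
                  chain = cc)
  expect_identical(fit1$draws, fit2$draws)
  expect_identical(fit1$acceptance, fit2$acceptance)

  fit3 <- fit_sem(panel$sim$records, panel$design$pedigree, "M2",
                  chain = chain_config(n_iter = 320, burn_in = 120,
                                       thin = 4, seed = 6))
  expect_false(identical(fit1$draws, fit3$draws))
})

test_that("SEM residual covariance draws are exactly diagonal", {
  panel <- small_panel("M2", scale = 0.04)
  fit <- fit_sem(panel$sim$records, panel$design$pedigree, "M2",
                 chain = quick_chain())
  expect_true(all(fit$draws[["R[SCS,CAS]"]] == 0))
  expect_true(all(fit$draws[["R[RCT,a30]"]] == 0))
  expect_true(all(fit$draws[["R[a30,a30]"]] > 0))
  # MTM keeps a full residual covariance
  fit0 <- fit_sem(panel$sim$records, panel$design$pedigree, "M0",
                  chain = quick_chain(n_iter = 300, burn_in = 100))
  expect_true(var(fit0$draws[["R[RCT,a30]"]]) > 0)
})

test_that("degenerate structural prior pins the coefficient at its mean", {
  panel <- small_panel("M2", scale = 0.04)
  fit <- fit_sem(panel$sim$records, panel$design$pedigree, "M2",
                 priors = prior_spec(tau2 = 1e-12),
                 chain = quick_chain(n_iter = 400, burn_in = 100))
  expect_lt(max(abs(fit$draws[["lambda[RCT->a30]"]])), 1e-4)
})

test_that("vanishing proposal step makes every MH proposal accepted", {
  panel <- small_panel("M2", scale = 0.04)
  fit <- fit_sem(panel$sim$records, panel$design$pedigree, "M2",
                 chain = quick_chain(n_iter = 400, burn_in = 100,
                                     step_init = 1e-12,
                                     adapt_every = 10000))
  expect_gt(fit$acceptance$accept_rate, 0.999)
})

test_that("MH structural sampling matches an independent conjugate-Gibbs
          oracle on the same data", {
  # Recursive-SEM lambda has a closed-form normal full conditional
  # (conjugacy of the reduced-residual likelihood with the normal prior).
  # An all-Gibbs reference sampler written here independently must give
  # the same posterior as the package's MH-within-Gibbs on a model with
  # fixed effects + structural coefficient only.
  set.seed(99)
  n <- 80
  y1 <- rnorm(n, 10, 2)
  lam_true <- 1.4
  y2 <- lam_true * y1 + 3 + rnorm(n, 0, 1)
  df <- tibble::tibble(
    record = as.character(1:n), cow = as.character(1:n),
    herd = rep("h1", n), sire = rep("s1", n), dim_class = 4L,
    SCS = y1, CAS = 0, RCT = 0, a30 = y2)
  # package fit: structure SCS -> a30 (other traits constant-free noise
  # cannot be used, so give them independent noise instead of constants)
  df$CAS <- rnorm(n); df$RCT <- rnorm(n)
  fit <- fit_sem(df, pedigree = NULL,
                 structure = causal_structure(list(c("SCS", "a30"))),
                 chain = chain_config(n_iter = 30000, burn_in = 10000,
                                      thin = 2, seed = 4))
  lam_draws <- fit$draws[["lambda[SCS->a30]"]]

  # oracle: scalar Gibbs on y2 = lam*y1 + b + e, flat-ish priors matching
  # prior_spec defaults (tau2 = b_var = 1e4, invChisq(nu=6) residual)
  nu <- 6; tau2 <- 1e4; b_var <- 1e4
  s_r <- 0.5 * (var(y2) / 4) * (nu - 2)
  lam <- 0; b <- 0; r <- 1
  keep <- numeric(10000)
  set.seed(42)
  for (it in 1:22000) {
    # b | .
    prec_b <- n / r + 1 / b_var
    b <- rnorm(1, sum(y2 - lam * y1) / r / prec_b, sqrt(1 / prec_b))
    # lam | . (conjugate normal)
    prec_l <- sum(y1^2) / r + 1 / tau2
    lam <- rnorm(1, sum((y2 - b) * y1) / r / prec_l, sqrt(1 / prec_l))
    # r | . (scaled inverse chi-square)
    sse <- sum((y2 - b - lam * y1)^2)
    r <- (s_r + sse) / rchisq(1, nu + n)
    if (it > 2000) keep[it - 2000] <- lam
  }
  oracle <- keep[seq(1, length(keep), by = 2)]
  # The package fit has extra herd/cow/sire nuisance blocks with proper
  # priors; on this single-herd single-sire layout they only widen the
  # intercept, not the slope. Compare location and spread.
  se <- sd(oracle) / sqrt(ess(oracle))
  expect_lt(abs(mean(lam_draws) - mean(oracle)),
            4 * (se + sd(lam_draws) / sqrt(ess(lam_draws))))
  expect_equal(sd(lam_draws), sd(oracle), tolerance = 0.25)
  expect_lt(abs(mean(lam_draws) - lam_true), 4 * sd(lam_draws))
})

test_that("dispersed starts converge to the same posterior (split-Rhat)", {
  panel <- small_panel("M2", scale = 0.05)
  fits <- lapply(c(-4, 1), function(l0) {
    fit_sem(panel$sim$records, panel$design$pedigree, "M2",
            chain = chain_config(n_iter = 6000, burn_in = 3000, thin = 3,
                                 seed = 8, step_init = 0.2,
                                 lambda_init = l0))
  })
  chains <- vapply(fits, function(f) f$draws[["lambda[RCT->a30]"]],
                   numeric(1000))
  m <- colMeans(chains)
  w <- mean(apply(chains, 2, var))
  b <- nrow(chains) * var(m)
  rhat <- sqrt(((nrow(chains) - 1) / nrow(chains) * w + b / nrow(chains)) / w)
  expect_lt(rhat, 1.05)
})

test_that("missing sires and malformed records are rejected", {
  panel <- small_panel(scale = 0.03)
  rec <- panel$sim$records
  rec$sire[1] <- "NOPE"
  expect_error(fit_sem(rec, panel$design$pedigree, "M2",
                       chain = quick_chain()),
               "absent from pedigree")
  rec2 <- panel$sim$records
  rec2$a30[3] <- NA
  expect_error(fit_sem(rec2, panel$design$pedigree, "M2",
                       chain = quick_chain()),
               "missing trait values")
  expect_error(fit_sem(panel$sim$records[, -3], panel$design$pedigree,
                       "M2", chain = quick_chain()),
               "lack column")
})
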