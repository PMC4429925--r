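test_that("MTM-scale transform: identity, hand algebra, PSD, round trip", {
  tr <- milk_traits()
  G <- random_pd_matrix(); P <- random_pd_matrix(); H <- random_pd_matrix()
  R <- diag(c(1.1, 0.3, 2.2, 4.4))
  L0 <- matrix(0, 4, 4)
  out <- to_mtm_scale(G, P, H, R, L0)
  expect_equal(out$G, (G + t(G)) / 2)
  expect_equal(out$R, R)

  # single-path structure: R*[4,4] = r4 + c^2 r3 and R*[3,4] = c * r3
  c43 <- -1.901
  L2 <- lambda_matrix(model_preset("M2"), c("RCT->a30" = c43))
  r <- c(1.5, 0.2, 3.1, 7.2)
  outR <- to_mtm_scale(diag(4), diag(4), diag(4), diag(r), L2)$R
  expect_equal(outR[4, 4], r[4] + c43^2 * r[3])
  expect_equal(outR[3, 4], c43 * r[3])
  expect_equal(outR[1, 1], r[1])

  set.seed(314)
  for (i in 1:20) {
    L <- random_acyclic_lambda(4, 0.5)
    M <- random_pd_matrix()
    tf <- to_mtm_scale(M, M, M, M, L)$G
    expect_gte(min(eigen(tf, symmetric = TRUE, only.values = TRUE)$values),
               -1e-10)
    expect_equal(from_mtm_scale(tf, L), (M + t(M)) / 2, tolerance = 1e-10)
  }
})

test_that("heritability follows the 4-sigma2s sire-model formula", {
  expect_equal(round(heritability(3.829, 81.998 - 3.829, 0, 0), 3), 0.187)
  expect_equal(round(heritability(0.536, 10, 5, 22.108 - 0.536 - 15), 3),
               0.097)
  expect_equal(heritability(0, 1, 1, 1), 0)
  # vectorised over draws
  expect_equal(heritability(c(1, 2), c(1, 2), c(1, 2), c(1, 2)),
               c(1, 1))
})

test_that("correlations come from G* alone vs the full component sum", {
  draw <- list(G = diag(c(1, 2, 3, 4)), P = random_pd_matrix(),
               H = random_pd_matrix(), R = random_pd_matrix())
  cors <- trait_correlations(draw)
  expect_equal(cors$genetic, diag(4), ignore_attr = TRUE)
  expect_equal(diag(cors$phenotypic), rep(1, 4))
  expect_equal(cors$phenotypic, t(cors$phenotypic))
  expect_true(all(abs(cors$phenotypic) <= 1 + 1e-12))
})

test_that("SD-unit transform matches the worked examples and invariances", {
  expect_equal(round(sd_units(-1.901, 3.80, 8.53), 4), -0.8469)
  expect_equal(round(sd_units(0.242, 1.66, 3.80), 4), 0.1057)
  expect_equal(sd_units(0, 2, 3), 0)
  expect_error(sd_units(1, 1, 0), "positive")
  # rescaling x by a and lambda by 1/a leaves lambda' unchanged
  a <- 2.7
  expect_equal(sd_units(1.3 / a, a * 1.66, 8.53), sd_units(1.3, 1.66, 8.53))
})

test_that("variance loss is the percent drop from the baseline", {
  expect_equal(round(variance_loss(3.829, 0.536), 1), 86.0)
  expect_equal(variance_loss(3.829, 3.829), 0)
  expect_equal(round(variance_loss(81.998, 11.902), 1), 85.5)
  expect_error(variance_loss(0, 1), "positive")
})

test_that("HPD interval is the shortest mass-covering interval", {
  set.seed(7)
  x <- rnorm(10000)
  h <- hpd_interval(x)
  expect_equal(unname(h), c(-1.96, 1.96), tolerance = 0.04)

  expect_equal(unname(hpd_interval(rep(3.3, 200))), c(3.3, 3.3))

  y <- rchisq(10000, df = 3)
  h_hpd <- hpd_interval(y)
  h_et <- quantile(y, c(0.025, 0.975))
  expect_lte(diff(unname(h_hpd)), unname(h_et[2] - h_et[1]))
  # skewed draws: HPD hugs the mode near zero
  expect_lt(h_hpd[["lower"]], h_et[[1]])
})

test_that("ESS matches closed forms for iid and AR(1) chains", {
  set.seed(12)
  x <- rnorm(20000)
  expect_equal(ess(x), length(x), tolerance = 0.1)

  rho <- 0.9
  n <- 20000
  ar <- as.numeric(arima.sim(list(ar = rho), n))
  expect_equal(ess(ar), n * (1 - rho) / (1 + rho), tolerance = 0.25)

  expect_warning(e <- ess(rep(1, 100)), "constant")
  expect_true(is.na(e))

  # independent cross-check against coda's spectral estimator
  expect_equal(ess(ar), unname(coda::effectiveSize(ar)), tolerance = 0.3)
})

test_that("fit summaries expose coherent derived quantities", {
  panel <- small_panel("M2", scale = 0.06)
  fit <- fit_sem(panel$sim$records, panel$design$pedigree, "M2",
                 chain = quick_chain(n_iter = 1200, burn_in = 400, thin = 4))
  s <- mtm_summary(fit)
  expect_s3_class(s, "sem_summary")
  expect_equal(nrow(s$heritability), 4)
  expect_true(all(s$heritability$mean > 0 & s$heritability$mean < 1))
  expect_true(all(abs(s$genetic_correlations$mean) <= 1))

  # summation identity: total equals the component sum per trait
  v <- tidyr::pivot_wider(s$variances[c("trait", "component", "mean")],
                          names_from = "component", values_from = "mean")
  expect_equal(v$total, v$sire + v$pe + v$herd + v$residual,
               tolerance = 1e-10)

  # recovered genetic correlation between RCT and a30 is strongly negative
  gc <- dplyr::filter(s$genetic_correlations,
                      trait_x == "RCT", trait_y == "a30")
  expect_lt(gc$mean, 0)

  # M0 fit: SEM scale and MTM scale coincide (empty Lambda)
  fit0 <- fit_sem(panel$sim$records, panel$design$pedigree, "M0",
                  chain = quick_chain(n_iter = 600, burn_in = 200))
  s0 <- mtm_summary(fit0)
  g_draws <- fit0$draws[["G[a30,a30]"]]
  sire_row <- dplyr::filter(s0$variances, trait == "a30",
                            component == "sire")
  expect_equal(sire_row$mean, mean(g_draws), tolerance = 1e-10)

  td <- tidy(fit)
  expect_true(all(c("parameter", "mean", "hpd_lower") %in% names(td)))
  g <- glance(fit)
  expect_equal(g$n_retained, nrow(fit$draws))
  expect_s3_class(autoplot(fit), "ggplot")
  expect_true(all(c("quantity", "term") %in% names(tidy(s))))
})

test_that("variance-loss summary reports point and per-draw views", {
  panel <- small_panel("M2", scale = 0.06)
  cc <- quick_chain(n_iter = 1000, burn_in = 400, thin = 3)
  fit0 <- fit_sem(panel$sim$records, panel$design$pedigree, "M0", chain = cc)
  fit2 <- fit_sem(panel$sim$records, panel$design$pedigree, "M2", chain = cc)
  vl <- variance_loss_summary(fit0, fit2)
  expect_equal(vl$component, c("sire", "phenotypic"))
  # the RCT->a30 path absorbs most of the curd-firmness variance
  expect_gt(vl$loss_point[vl$component == "phenotypic"], 40)
  expect_equal(vl$loss_point,
               variance_loss(vl$baseline_mean, vl$model_mean))
  expect_error(variance_loss_summary(fit2, fit0), "baseline")
})

test_that("chain diagnostics flag degenerate parameters", {
  d <- tibble::tibble(iteration = 1:500, a = rnorm(500), b = rep(2, 500))
  out <- chain_diagnostics(d, lags = c(1, 5))
  expect_equal(out$parameter, c("a", "b"))
  expect_true(is.na(out$ess[out$parameter == "b"]))
  expect_gt(out$ess[out$parameter == "a"], 300)
})
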