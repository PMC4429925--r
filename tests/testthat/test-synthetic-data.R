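test_that("default truth reproduces the calibration targets", {
  tp3 <- default_truth("M3")
  expect_equal(tp3$Lambda["a30", "RCT"], -1.792)
  expect_equal(tp3$Lambda["a30", "CAS"], 12.845)
  expect_equal(default_truth("M2")$Lambda["a30", "RCT"], -1.901)

  im <- implied_mtm(tp3)
  expect_equal(unname(im$total["a30", "a30"]), 81.998, tolerance = 1e-6)
  expect_equal(unname(im$h2[["a30"]]), 0.187, tolerance = 0.002)
  expect_equal(unname(im$h2[c("SCS", "CAS", "RCT")]),
               c(0.030, 0.157, 0.167), tolerance = 1e-6)
  expect_equal(unname(im$correlations$genetic["RCT", "a30"]), -0.918,
               tolerance = 1e-6)
  expect_equal(unname(im$correlations$phenotypic["RCT", "a30"]), -0.851,
               tolerance = 1e-6)

  # SEM-scale residual is exactly diagonal; all matrices are PD
  expect_true(all(tp3$R[upper.tri(tp3$R)] == 0))
  for (M in list(tp3$G, tp3$P, tp3$H, tp3$R)) {
    expect_gt(min(eigen(M, symmetric = TRUE, only.values = TRUE)$values), 0)
  }
})

test_that("study design scales proportionally and is seed-deterministic", {
  d1 <- sim_design(scale = 1, seed = 9)
  expect_equal(d1$n_cows, 3266)
  expect_equal(d1$n_herds, 309)
  expect_equal(d1$n_sires, 128)
  expect_equal(nrow(d1$pedigree), 1254)
  expect_equal(mean(d1$cows$n_records), 8783 / 3266, tolerance = 0.05)
  expect_true(all(d1$cows$sire %in% d1$pedigree$id))

  d01 <- sim_design(scale = 0.1, seed = 9)
  expect_equal(d01$n_cows, 327)
  expect_equal(d01$n_herds, 31)
  expect_equal(d01$n_sires, 13)

  d01b <- sim_design(scale = 0.1, seed = 9)
  expect_identical(d01$cows, d01b$cows)
  expect_identical(tibble::as_tibble(d01$pedigree),
                   tibble::as_tibble(d01b$pedigree))
})

test_that("independence case: trait variances add across components", {
  design <- sim_design(scale = 0.3, seed = 5)
  tr <- milk_traits()
  dg <- function(v) matrix(diag(v), 4, 4, dimnames = list(tr, tr))
  truth <- structure(list(
    structure = model_preset("M0"),
    Lambda = dg(rep(0, 4)) * 0,
    G = dg(c(0.5, 0.1, 1.0, 2.0)), P = dg(c(1.0, 0.2, 2.0, 4.0)),
    H = dg(c(0.5, 0.1, 1.0, 2.0)), R = dg(c(2.0, 0.4, 4.0, 8.0)),
    b = matrix(0, 4, 4, dimnames = list(NULL, tr)),
    trait_stats = reference_estimates()$trait_stats, model = "M0"),
    class = "sem_truth")
  sim <- simulate_records(design, truth, seed = 31)
  v_expect <- c(4, 0.8, 8, 16)
  v_obs <- apply(as.matrix(sim$records[tr]), 2, var)
  expect_equal(unname(v_obs), v_expect, tolerance = 0.15)
})

test_that("reduced form is exact on the audit trail", {
  panel <- small_panel("M2", scale = 0.08)
  sim <- panel$sim
  W <- solve(diag(4) - panel$truth$Lambda)
  Y <- as.matrix(sim$records[milk_traits()])
  expect_equal(Y, sim$effects$eta %*% t(W), tolerance = 1e-10,
               ignore_attr = TRUE)

  # residual-free systematic part recovers lambda43 exactly:
  # y4' - (eta4 - e4) = lambda43 * y3' for y' = reduced form without e
  y_sys <- (sim$effects$eta - sim$effects$e) %*% t(W)
  lhs <- y_sys[, 4] - (sim$effects$eta[, 4] - sim$effects$e[, 4])
  expect_equal(lhs, panel$truth$Lambda["a30", "RCT"] * y_sys[, 3],
               tolerance = 1e-10)
})

test_that("empty edge set and zero coefficients give identical panels", {
  design <- sim_design(scale = 0.05, seed = 2)
  # the causality-free completion clips the herd+PE remainder to PSD
  expect_warning(t0 <- default_truth("M0"), "nearest PSD")
  tz <- t0
  tz$structure <- model_preset("M2")
  tz$Lambda <- lambda_matrix(model_preset("M2"), c("RCT->a30" = 0))
  s0 <- simulate_records(design, t0, seed = 13)
  sz <- simulate_records(design, tz, seed = 13)
  expect_identical(s0$records, sz$records)

  # and the whole generator is bit-reproducible for a fixed seed
  s0b <- simulate_records(design, t0, seed = 13)
  expect_identical(s0$records, s0b$records)
})

test_that("simulated covariance matches the model-implied reduced form", {
  design <- sim_design(scale = 0.4, seed = 8)
  truth <- default_truth("M2")
  sim <- simulate_records(design, truth, seed = 3)
  W <- solve(diag(4) - truth$Lambda)
  implied <- W %*% (truth$G + truth$P + truth$H + truth$R) %*% t(W)
  emp <- cov(as.matrix(sim$records[milk_traits()]))
  expect_lt(norm(emp - implied, "F") / norm(implied, "F"), 0.15)
})

test_that("pedigree structure shows up in sire-effect dispersion", {
  # 1 founder with 19 half-sib sons vs 20 unrelated bulls: with A structure
  # the sons' effects are positively correlated through the shared sire.
  tr <- milk_traits()
  half_sib <- as_pedigree(tibble::tibble(
    id = c("F", sprintf("K%02d", 1:19)),
    sire = c(NA, rep("F", 19)), mgs = NA))
  unrelated <- as_pedigree(tibble::tibble(
    id = sprintf("U%02d", 1:20), sire = NA, mgs = NA))
  G <- diag(4)
  pull_sons <- function(ped, rows, seed) {
    A <- relationship_matrix(ped)$A
    L <- t(chol(A))
    set.seed(seed)
    vapply(1:200, function(i) {
      s <- L %*% matrix(rnorm(nrow(A) * 4), ncol = 4) %*% chol(G)
      mean(s[rows, 1]) # family mean of trait-1 effects
    }, numeric(1))
  }
  fam_mean_hs <- pull_sons(half_sib, 2:20, seed = 77)
  fam_mean_un <- pull_sons(unrelated, 1:19, seed = 77)
  # shared ancestry inflates the variance of the family mean
  expect_gt(var(fam_mean_hs) / var(fam_mean_un), 2)
})

test_that("records round-trip through the delimited writers", {
  panel <- small_panel(scale = 0.03)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_records(panel$sim, f)
  back <- read_records(f)
  expect_equal(back, panel$sim$records, tolerance = 1e-12)

  fp <- withr::local_tempfile(fileext = ".tsv")
  write_pedigree(panel$design$pedigree, fp)
  ped_back <- read_pedigree(fp)
  expect_equal(tibble::as_tibble(ped_back)[c("id", "sire", "mgs")],
               tibble::as_tibble(panel$design$pedigree)[c("id", "sire",
                                                          "mgs")],
               ignore_attr = TRUE)
})
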