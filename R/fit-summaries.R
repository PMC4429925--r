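#' Genetic summary of a fitted model on the MTM scale
#'
#' Transforms every retained draw to the MTM scale via [to_mtm_scale()]
#' and computes the derived quantities per draw before summarising
#' (posterior mean and 95% HPD): per-trait variance components and
#' heritabilities, genetic and phenotypic correlations, and the structural
#' coefficients with their SD-unit transforms (using the observed
#' phenotypic SDs of the fitted records).
#'
#' @param fit A [fit_sem()] result.
#' @param mass HPD mass, default 0.95.
#' @return Object of class `sem_summary`: list of tibbles `heritability`,
#'   `variances` (per trait and component, including the total),
#'   `genetic_correlations`, `phenotypic_correlations`, `causal_effects`,
#'   plus `mass` and bookkeeping fields.
#' @export
mtm_summary <- function(fit, mass = 0.95) {
  stopifnot(inherits(fit, "sem_fit"))
  tr <- fit$traits
  nt <- length(tr)
  nd <- nrow(fit$draws)
  comp_names <- c("sire", "pe", "herd", "residual")

  h2 <- matrix(NA_real_, nd, nt, dimnames = list(NULL, tr))
  vars <- array(NA_real_, c(nd, nt, 5),
                dimnames = list(NULL, tr, c(comp_names, "total")))
  npair <- nt * (nt - 1) / 2
  pair_idx <- which(upper.tri(diag(nt)), arr.ind = TRUE)
  pair_names <- paste0(tr[pair_idx[, 1]], ":", tr[pair_idx[, 2]])
  gcor <- matrix(NA_real_, nd, npair, dimnames = list(NULL, pair_names))
  pcor <- matrix(NA_real_, nd, npair, dimnames = list(NULL, pair_names))

  for (d in seq_len(nd)) {
    L <- draw_lambda(fit, d)
    m <- to_mtm_scale(draw_matrix(fit, "G", d), draw_matrix(fit, "P", d),
                      draw_matrix(fit, "H", d), draw_matrix(fit, "R", d), L)
    total <- m$G + m$P + m$H + m$R
    vars[d, , ] <- cbind(diag(m$G), diag(m$P), diag(m$H), diag(m$R),
                         diag(total))
    h2[d, ] <- heritability(diag(m$G), diag(m$P), diag(m$H), diag(m$R))
    cors <- trait_correlations(m)
    gcor[d, ] <- cors$genetic[upper.tri(cors$genetic)]
    pcor[d, ] <- cors$phenotypic[upper.tri(cors$phenotypic)]
  }

  summ_mat <- function(M) {
    purrr::map_dfr(colnames(M), function(cn) {
      h <- hpd_interval(M[, cn], mass)
      tibble::tibble(name = cn, mean = mean(M[, cn]),
                     hpd_lower = h[["lower"]], hpd_upper = h[["upper"]])
    })
  }

  heritability_tbl <- dplyr::rename(summ_mat(h2), trait = "name")
  variances <- purrr::map_dfr(c(comp_names, "total"), function(cc) {
    out <- summ_mat(vars[, , cc, drop = TRUE])
    out$component <- cc
    dplyr::rename(out, trait = "name")
  })
  gc_tbl <- tidyr::separate(summ_mat(gcor), "name", c("trait_x", "trait_y"),
                            sep = ":")
  pc_tbl <- tidyr::separate(summ_mat(pcor), "name", c("trait_x", "trait_y"),
                            sep = ":")

  causal <- NULL
  if (nrow(fit$structure$edges)) {
    keys <- edge_keys(fit$structure)
    causal <- purrr::map_dfr(seq_along(keys), function(k) {
      e <- fit$structure$edges[k, ]
      x <- fit$draws[[paste0("lambda[", keys[k], "]")]]
      h <- hpd_interval(x, mass)
      tibble::tibble(
        edge = keys[k], from = e$from, to = e$to,
        mean = mean(x), hpd_lower = h[["lower"]], hpd_upper = h[["upper"]],
        sd_units = sd_units(mean(x), fit$trait_sd[[e$from]],
                            fit$trait_sd[[e$to]])
      )
    })
  } else {
    causal <- tibble::tibble(edge = character(), from = character(),
                             to = character(), mean = numeric(),
                             hpd_lower = numeric(), hpd_upper = numeric(),
                             sd_units = numeric())
  }

  structure(
    list(heritability = heritability_tbl,
         variances = dplyr::select(variances, "trait", "component",
                                   "mean", "hpd_lower", "hpd_upper"),
         genetic_correlations = gc_tbl,
         phenotypic_correlations = pc_tbl,
         causal_effects = causal,
         mass = mass, traits = tr, n_draws = nd,
         model_edges = edge_keys(fit$structure)),
    class = "sem_summary"
  )
}

#' Variance-loss comparison against a baseline fit
#'
#' For one trait (default curd firmness a30), the percentage of the
#' baseline (M0) MTM-scale sire and phenotypic variance absorbed by the
#' structural model's causal paths, where the structural model's variance
#' components are taken on the SEM (structural) scale, i.e. before
#' transformation. Reported both ways: point arithmetic on the posterior
#' means (`loss_point`), and summarised per paired draw (`loss_mean`,
#' HPD), pairing draws by retained-sample index.
#'
#' @param fit0 Baseline [fit_sem()] (no causal paths).
#' @param fitk Structural-model fit to compare.
#' @param trait Trait to compare (default `"a30"`).
#' @param mass HPD mass.
#' @return Tibble with one row per component (`sire`, `phenotypic`).
#' @export
variance_loss_summary <- function(fit0, fitk, trait = "a30", mass = 0.95) {
  stopifnot(inherits(fit0, "sem_fit"), inherits(fitk, "sem_fit"))
  if (nrow(fit0$structure$edges) > 0) {
    stop("fit0 must be the baseline fit (no causal paths)", call. = FALSE)
  }
  comp_draws <- function(fit, mtm) {
    nd <- nrow(fit$draws)
    s <- tot <- numeric(nd)
    for (d in seq_len(nd)) {
      G <- draw_matrix(fit, "G", d); P <- draw_matrix(fit, "P", d)
      H <- draw_matrix(fit, "H", d); R <- draw_matrix(fit, "R", d)
      if (mtm) {
        m <- to_mtm_scale(G, P, H, R, draw_lambda(fit, d))
        G <- m$G; P <- m$P; H <- m$H; R <- m$R
      }
      s[d] <- G[trait, trait]
      tot[d] <- G[trait, trait] + P[trait, trait] + H[trait, trait] +
        R[trait, trait]
    }
    list(s = s, tot = tot)
  }
  base <- comp_draws(fit0, mtm = TRUE)   # identity transform for M0
  mod <- comp_draws(fitk, mtm = FALSE)   # structural-scale components
  nd <- min(length(base$s), length(mod$s))
  per_draw_s <- variance_loss(base$s[seq_len(nd)], mod$s[seq_len(nd)])
  per_draw_t <- variance_loss(base$tot[seq_len(nd)], mod$tot[seq_len(nd)])
  hs <- hpd_interval(per_draw_s, mass)
  ht <- hpd_interval(per_draw_t, mass)
  tibble::tibble(
    component = c("sire", "phenotypic"),
    baseline_mean = c(mean(base$s), mean(base$tot)),
    model_mean = c(mean(mod$s), mean(mod$tot)),
    loss_point = c(variance_loss(mean(base$s), mean(mod$s)),
                   variance_loss(mean(base$tot), mean(mod$tot))),
    loss_mean = c(mean(per_draw_s), mean(per_draw_t)),
    loss_hpd_lower = c(hs[["lower"]], ht[["lower"]]),
    loss_hpd_upper = c(hs[["upper"]], ht[["upper"]])
  )
}

#' @export
print.sem_summary <- function(x, ...) {
  cat("<sem_summary> (", x$n_draws, " draws, ", 100 * x$mass,
      "% HPD)\n", sep = "")
  cat("heritabilities:\n")
  print(x$heritability, n = Inf)
  if (nrow(x$causal_effects)) {
    cat("causal effects:\n")
    print(x$causal_effects, n = Inf)
  }
  invisible(x)
}

#' Tidy posterior summary of a fitted model
#'
#' One row per sampled parameter with posterior mean, SD and HPD bounds.
#'
#' @param x A `sem_fit`.
#' @param mass HPD mass, default 0.95.
#' @param ... Unused.
#' @return A tibble with `parameter`, `mean`, `sd`, `hpd_lower`,
#'   `hpd_upper`.
#' @export
tidy.sem_fit <- function(x, mass = 0.95, ...) {
  posterior_summary(x$draws, mass)
}

#' One-row fit overview
#'
#' @param x A `sem_fit`.
#' @param ... Unused.
#' @return Tibble with chain sizes, record counts, minimum effective
#'   sample size across dispersion parameters and mean MH acceptance.
#' @export
glance.sem_fit <- function(x, ...) {
  diag_cols <- grep("^(G|P|H|R|lambda)\\[", names(x$draws), value = TRUE)
  ess_vals <- vapply(diag_cols, function(cn) {
    v <- x$draws[[cn]]
    if (stats::var(v) == 0) NA_real_ else suppressWarnings(ess(v))
  }, numeric(1))
  tibble::tibble(
    n_records = x$n_records, n_cows = x$n_cows, n_herds = x$n_herds,
    n_pedigree = x$n_pedigree, n_retained = nrow(x$draws),
    n_iter = x$chain$n_iter, burn_in = x$chain$burn_in,
    thin = x$chain$thin, n_edges = nrow(x$structure$edges),
    min_ess = min(ess_vals, na.rm = TRUE),
    mean_accept = if (nrow(x$acceptance))
      mean(x$acceptance$accept_rate) else NA_real_
  )
}

#' Trace and running-mean plots for a fitted chain
#'
#' @param object A `sem_fit`.
#' @param parameters Character vector of draw column names; defaults to
#'   the structural coefficients if any, else the four sire variances.
#' @param ... Unused.
#' @return A ggplot object (facets: parameter; lines: trace and running
#'   mean).
#' @export
autoplot.sem_fit <- function(object, parameters = NULL, ...) {
  draws <- object$draws
  if (is.null(parameters)) {
    lam <- grep("^lambda\\[", names(draws), value = TRUE)
    parameters <- if (length(lam)) lam else
      paste0("G[", object$traits, ",", object$traits, "]")
  }
  long <- tidyr::pivot_longer(draws[c("iteration", parameters)],
                              -"iteration", names_to = "parameter")
  long <- dplyr::mutate(
    dplyr::group_by(long, .data$parameter),
    running_mean = cumsum(.data$value) / seq_along(.data$value))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$iteration)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$value), alpha = 0.4) +
    ggplot2::geom_line(ggplot2::aes(y = .data$running_mean),
                       colour = "firebrick") +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "retained sample", y = "value") +
    ggplot2::theme_minimal()
}

#' Tidy method for genetic summaries
#'
#' Stacks every summarised quantity into one long tibble.
#'
#' @param x A `sem_summary`.
#' @param ... Unused.
#' @return Tibble with `quantity`, `term`, `mean`, `hpd_lower`,
#'   `hpd_upper`.
#' @export
tidy.sem_summary <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(dplyr::select(x$heritability, term = "trait", "mean",
                                "hpd_lower", "hpd_upper"),
                  quantity = "heritability"),
    dplyr::mutate(
      dplyr::transmute(x$variances,
                       term = paste0(.data$trait, ":", .data$component),
                       mean = .data$mean, hpd_lower = .data$hpd_lower,
                       hpd_upper = .data$hpd_upper),
      quantity = "variance"),
    dplyr::mutate(
      dplyr::transmute(x$genetic_correlations,
                       term = paste0(.data$trait_x, ":", .data$trait_y),
                       mean = .data$mean, hpd_lower = .data$hpd_lower,
                       hpd_upper = .data$hpd_upper),
      quantity = "genetic_correlation"),
    dplyr::mutate(
      dplyr::transmute(x$phenotypic_correlations,
                       term = paste0(.data$trait_x, ":", .data$trait_y),
                       mean = .data$mean, hpd_lower = .data$hpd_lower,
                       hpd_upper = .data$hpd_upper),
      quantity = "phenotypic_correlation"),
    dplyr::mutate(dplyr::select(x$causal_effects, term = "edge", "mean",
                                "hpd_lower", "hpd_upper"),
                  quantity = "causal_effect")
  )[c("quantity", "term", "mean", "hpd_lower", "hpd_upper")]
}
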