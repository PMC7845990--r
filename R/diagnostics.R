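#' Empirical cumulative distribution function over counts
#'
#' Right-continuous ECDF evaluated on the integer support `0..max(counts)`.
#'
#' @param counts Nonempty vector of nonnegative integer counts.
#' @return Data frame with columns `m` and `ecdf`.
#' @export
ecdf_counts <- function(counts) {
  if (length(counts) == 0) stop("empty count vector")
  stopifnot(all(counts >= 0))
  m <- 0:max(counts)
  data.frame(m = m, ecdf = stats::ecdf(counts)(m))
}

#' Posterior predictive ECDF band
#'
#' For each of `n_rep` posterior draws, generates `n_cells` counts from the
#' tagged observation model and records the replicate ECDF; the band is the
#' pointwise median and `level` envelope over replicates at each count value.
#' Replicates use the observed condition size so the band width reflects the
#' actual sampling noise. Bands are pointwise, not simultaneous.
#'
#' @param s A `posterior_samples` object whose parameters include those of
#'   the tagged model (`k_i` for `"poisson"` — the Poisson rate is `k_i * b`
#'   if `b` is present, else `k_i`; `k_i`, `b` for `"neg_binom"`;
#'   additionally `k_on`, `k_off` — or the named `k_on_<level>`,
#'   `k_off_<operator>` pair via `condition` — for `"bursty_repressed"`).
#' @param model One of `"poisson"`, `"neg_binom"`, `"bursty_repressed"`.
#' @param n_cells Cells per replicate (use the observed condition size).
#' @param observed Optional observed counts; when given, the observed ECDF is
#'   attached and the band support covers it.
#' @param condition Length-2 character vector `c(operator, level)` selecting
#'   the rate parameters by name for the repressed model.
#' @param n_rep Number of posterior predictive replicates (default 200).
#' @param level Envelope probability (default 0.95).
#' @param seed Integer seed.
#' @param override Proceed despite failed convergence diagnostics?
#' @return An object of class `ecdf_band`: data frame with columns `m`,
#'   `lower`, `median`, `upper` and, if supplied, `observed`.
#' @export
posterior_predictive_band <- function(s, model = c("neg_binom", "poisson",
                                                   "bursty_repressed"),
                                      n_cells, observed = NULL,
                                      condition = NULL, n_rep = 200,
                                      level = 0.95, seed = 1,
                                      override = FALSE) {
  model <- match.arg(model)
  check_converged(s, override)
  stopifnot(n_cells >= 1, n_rep >= 2, level > 0, level < 1)
  x <- draws_matrix(s, natural = TRUE)
  set.seed(seed)
  idx <- sample.int(nrow(x), n_rep, replace = n_rep > nrow(x))
  reps <- vector("list", n_rep)
  for (r in seq_len(n_rep)) {
    th <- x[idx[r], ]
    reps[[r]] <- switch(model,
      poisson = stats::rpois(n_cells, if ("b" %in% s$params)
        th[["k_i"]] * th[["b"]] else th[["k_i"]]),
      neg_binom = stats::rnbinom(n_cells, size = th[["k_i"]],
                                 prob = 1 / (1 + th[["b"]])),
      bursty_repressed = {
        if (!is.null(condition)) {
          kon <- th[[paste0("k_on_", condition[2])]]
          koff <- th[[paste0("k_off_", condition[1])]]
        } else {
          kon <- th[["k_on"]]; koff <- th[["k_off"]]
        }
        sample_pmf(repressed_pmf_adaptive(kon, koff, th[["k_i"]],
                                          th[["b"]], tail_tol = 1e-8),
                   n_cells)
      })
  }
  m_top <- max(vapply(reps, max, numeric(1)),
               if (!is.null(observed)) max(observed) else 0)
  m <- 0:m_top
  emat <- vapply(reps, function(cc) stats::ecdf(cc)(m),
                 numeric(length(m)))
  qs <- apply(emat, 1, stats::quantile,
              probs = c((1 - level) / 2, 0.5, (1 + level) / 2))
  band <- data.frame(m = m, lower = qs[1, ], median = qs[2, ],
                     upper = qs[3, ])
  if (!is.null(observed)) band$observed <- stats::ecdf(observed)(m)
  structure(band, class = c("ecdf_band", "data.frame"), level = level)
}

#' Fraction of support points where the observed ECDF lies inside the band
#'
#' @param band An `ecdf_band` with an `observed` column.
#' @return Fraction in `[0, 1]`.
#' @export
band_coverage <- function(band) {
  stopifnot(inherits(band, "ecdf_band"), "observed" %in% names(band))
  mean(band$observed >= band$lower & band$observed <= band$upper)
}

#' Plot an ECDF band
#'
#' @param x An `ecdf_band`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.ecdf_band <- function(x, ...) {
  graphics::plot(x$m, x$median, type = "s", ylim = c(0, 1),
                 xlab = "mRNA count", ylab = "ECDF", ...)
  graphics::lines(x$m, x$lower, type = "s", lty = 2, col = "grey50")
  graphics::lines(x$m, x$upper, type = "s", lty = 2, col = "grey50")
  if ("observed" %in% names(x)) {
    graphics::lines(x$m, x$observed, type = "s", col = "black", lwd = 2)
  }
  invisible(x)
}

#' Per-condition mean and Fano factor of a count dataset
#'
#' @param dataset Count data frame in the [generate_study()] schema.
#' @return Data frame with one row per condition: `condition_type`,
#'   `promoter_or_operator`, `repressor_level`, `n_cells`, `mean`, `fano`.
#'   Conditions with zero mean have `NA` Fano (flagged, not dropped).
#' @export
fano_mean_table <- function(dataset) {
  key <- interaction(dataset$condition_type, dataset$promoter_or_operator,
                     ifelse(is.na(dataset$repressor_level), "",
                            dataset$repressor_level), drop = TRUE)
  out <- do.call(rbind, lapply(split(dataset, key), function(dd) {
    if (nrow(dd) < 2) stop("condition with fewer than 2 cells")
    mu <- mean(dd$mrna_count)
    data.frame(condition_type = dd$condition_type[1],
               promoter_or_operator = dd$promoter_or_operator[1],
               repressor_level = dd$repressor_level[1],
               n_cells = nrow(dd), mean = mu,
               fano = if (mu > 0) stats::var(dd$mrna_count) / mu
                      else NA_real_)
  }))
  rownames(out) <- NULL
  out
}

#' Posterior of the binding-energy difference between two operators
#'
#' Under the master-curve correspondence, the difference in repressor binding
#' energy between two operators measured at the same repressor copy number
#' depends only on the unbinding rates:
#' \deqn{\Delta\epsilon_a - \Delta\epsilon_b = \log(k^-_a / k^-_b),}
#' the binding rates canceling. Computed per posterior draw and summarized
#' with the median and a central credible interval.
#'
#' @param s A `posterior_samples` object containing `k_off_<op_a>` and
#'   `k_off_<op_b>`.
#' @param op_a,op_b Operator labels; the result is the energy of `op_a`
#'   minus that of `op_b` in kT units.
#' @param level Credible level (default 0.95).
#' @param override Proceed despite failed convergence diagnostics?
#' @return List with `draws`, `median`, `lower`, `upper`, and the labels.
#' @export
energy_difference_posterior <- function(s, op_a, op_b, level = 0.95,
                                        override = FALSE) {
  pa <- paste0("k_off_", op_a); pb <- paste0("k_off_", op_b)
  if (!all(c(pa, pb) %in% s$params)) {
    stop("posterior does not contain unbinding rates for both operators")
  }
  check_converged(s, override)
  x <- draws_matrix(s, natural = TRUE)
  dr <- log(x[, pa] / x[, pb])
  qs <- stats::quantile(dr, c((1 - level) / 2, 0.5, (1 + level) / 2))
  list(op_a = op_a, op_b = op_b, draws = dr,
       median = unname(qs[2]), lower = unname(qs[1]), upper = unname(qs[3]),
       level = level)
}

#' Map burst parameters onto three-state thermodynamic parameters
#'
#' Equating the mean mRNA of the bursty model, `k_i b`, with the weak-promoter
#' limit of the three-state occupancy model identifies
#' \deqn{k_i/\gamma = (P/N_{NS}) e^{-\epsilon_P}, \qquad b = r/\gamma,}
#' giving the RNAP binding energy implied by a burst rate at an assumed
#' polymerase copy number.
#'
#' @param k_i Burst initiation rate (units of the degradation rate).
#' @param b Mean burst size.
#' @param P Assumed RNAP copy number (default 5000).
#' @param N_NS Non-specific site count (default 4.6e6).
#' @return List with `eps_P` (kT units) and `r_over_gamma`.
#' @export
thermo_kinetic_map <- function(k_i, b, P = 5000, N_NS = 4.6e6) {
  stopifnot(k_i > 0, b > 0, P > 0, N_NS > 0)
  list(eps_P = -log(k_i * N_NS / P), r_over_gamma = b)
}

#' Convert a nondimensional unbinding rate to physical units
#'
#' Rates in this package are in units of the mRNA degradation rate; to report
#' a repressor dissociation rate in per-second units an mRNA lifetime must be
#' assumed.
#'
#' @param k_off_over_gamma Unbinding rate in units of the degradation rate.
#' @param mrna_lifetime_minutes Assumed mRNA lifetime 1/gamma in minutes.
#' @return The unbinding rate in s^-1.
#' @export
dissociation_rate_to_physical <- function(k_off_over_gamma,
                                          mrna_lifetime_minutes) {
  if (any(mrna_lifetime_minutes <= 0)) stop("lifetime must be positive")
  k_off_over_gamma / (mrna_lifetime_minutes * 60)
}
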