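#' Log-normal prior specification
#'
#' All rates in the package are positive and plausibly span orders of
#' magnitude, so sampling is done on the natural-log scale where a log-normal
#' prior on a rate is a normal density on its log. The default (location 0,
#' scale 2 natural-log units) is weakly informative, spanning roughly four
#' orders of magnitude around 1 (rates are in units of the mRNA degradation
#' rate).
#'
#' @param params Character vector of parameter names.
#' @param location Prior location(s) on the log scale (recycled).
#' @param scale Prior scale(s) on the log scale (> 0, recycled).
#' @return Data frame with columns `param`, `location`, `scale`.
#' @export
prior_spec <- function(params, location = 0, scale = 2) {
  stopifnot(all(scale > 0))
  data.frame(param = params,
             location = rep_len(location, length(params)),
             scale = rep_len(scale, length(params)))
}

# normal log-density on the log-parameters, truncated at 3.5 prior sd; the
# truncation removes a negligible 5e-4 of mass while keeping samplers out of
# extreme regions where likelihood evaluation cost blows up
log_prior <- function(theta, prior) {
  z <- (theta - prior$location) / prior$scale
  if (any(abs(z) > 3.5)) return(-Inf)
  sum(stats::dnorm(theta, prior$location, prior$scale, log = TRUE))
}

#' Log-likelihood of constitutive counts under the bursty model
#'
#' Sum over cells of the log negative binomial probability; the likelihood of
#' the one-state bursty promoter model. Computed from tabulated counts so the
#' cost is set by the number of distinct count values, not cells.
#'
#' @param counts Nonnegative integer mRNA counts (one per cell).
#' @param k_i Burst initiation rate (> 0).
#' @param b Mean burst size (> 0).
#' @return The log-likelihood (0 for an empty count vector).
#' @export
loglike_constitutive <- function(counts, k_i, b) {
  if (length(counts) == 0) return(0)
  stopifnot(all(counts >= 0), all(counts == floor(counts)))
  tab <- table(counts)
  m <- as.integer(names(tab))
  sum(as.integer(tab) * neg_binom_pmf(m, k_i, b, log = TRUE))
}

#' Log-likelihood of counts under an arbitrary promoter CME model
#'
#' Evaluates the model's steady-state mRNA distribution numerically and sums
#' log-probabilities of the observed counts. This is the brute-force
#' likelihood used, e.g., to exhibit the ridge-shaped (nonidentifiable)
#' likelihood surface of the telegraph model, where single-cell counts
#' constrain the burst size `r / k_inact` but not `r` and `k_inact`
#' separately.
#'
#' @param counts Nonnegative integer mRNA counts.
#' @param model A [promoter_cme()] model.
#' @param tail_tol Steady-state tail tolerance.
#' @return The log-likelihood.
#' @export
loglike_cme <- function(counts, model, tail_tol = 1e-10) {
  if (length(counts) == 0) return(0)
  pmf <- marginal_mrna(steady_state_joint(model, tail_tol,
                                          m_max = max(counts, 10)))
  if (max(counts) + 1 > length(pmf)) {
    pmf <- c(pmf, rep(0, max(counts) + 1 - length(pmf)))
  }
  lp <- log(pmax(pmf, 1e-300))
  tab <- table(counts)
  sum(as.integer(tab) * lp[as.integer(names(tab)) + 1])
}

# --- regulated model -------------------------------------------------------

#' Specify the regulated (joint) inference model
#'
#' Maps every condition of a count dataset onto its parameters: one repressor
#' unbinding rate per operator, one binding rate per induction level, and a
#' shared `(k_i, b)` for the reference promoter. With the default
#' `fix_burst = FALSE` the burst parameters are co-inferred together with the
#' rates using the reference promoter's constitutive counts (the full
#' nine-dimensional posterior for three operators and four levels);
#' `fix_burst = TRUE` conditions on supplied burst parameters instead and
#' infers only the rates.
#'
#' @param dataset Count data frame in the [generate_study()] schema.
#' @param reference Constitutive promoter whose data (and burst parameters)
#'   anchor the fit.
#' @param fix_burst If `TRUE`, hold `(k_i, b)` fixed at `burst`.
#' @param burst Named vector `c(k_i =, b =)` used when `fix_burst = TRUE`.
#' @return An object of class `regulated_model_spec` with the parameter
#'   naming and per-condition count tabulations.
#' @export
regulated_model_spec <- function(dataset, reference = "prom09",
                                 fix_burst = FALSE, burst = NULL) {
  reg <- dataset[dataset$condition_type == "regulated", , drop = FALSE]
  if (!nrow(reg)) stop("dataset has no regulated conditions")
  ref <- dataset$condition_type == "constitutive" &
    dataset$promoter_or_operator == reference
  if (!fix_burst && !any(ref)) {
    stop("co-inference of (k_i, b) requested but the dataset has no ",
         "constitutive reference condition '", reference, "'")
  }
  if (fix_burst &&
      (is.null(burst) || !all(c("k_i", "b") %in% names(burst)))) {
    stop("fix_burst = TRUE requires burst = c(k_i =, b =)")
  }
  operators <- sort(unique(reg$promoter_or_operator))
  levels <- unique(reg$repressor_level)
  levels <- levels[order(suppressWarnings(as.numeric(levels)), levels)]
  conds <- unique(reg[c("promoter_or_operator", "repressor_level")])
  cond_tabs <- lapply(seq_len(nrow(conds)), function(i) {
    m <- reg$mrna_count[
      reg$promoter_or_operator == conds$promoter_or_operator[i] &
        reg$repressor_level == conds$repressor_level[i]]
    tab <- table(m)
    list(operator = conds$promoter_or_operator[i],
         level = conds$repressor_level[i],
         m = as.integer(names(tab)), n = as.integer(tab),
         m_max = max(m))
  })
  params <- c(paste0("k_off_", operators), paste0("k_on_", levels))
  if (!fix_burst) params <- c(params, "k_i", "b")
  structure(
    list(operators = operators, levels = levels, params = params,
         fix_burst = fix_burst, burst = burst,
         cond_tabs = cond_tabs,
         ref_counts = if (any(ref)) dataset$mrna_count[ref] else integer(0),
         ref_tab = if (any(ref)) {
           tb <- table(dataset$mrna_count[ref])
           list(m = as.integer(names(tb)), n = as.integer(tb))
         }),
    class = "regulated_model_spec")
}

#' Log-likelihood of the joint regulated model
#'
#' Product over cells of the repressed bursty probability, factorized by
#' condition: the steady-state pmf depends only on the condition's
#' `(k_on, k_off, k_i, b)`, so it is evaluated once per condition per call
#' and applied to the tabulated counts. When the spec co-infers the burst
#' parameters, the reference promoter's constitutive counts contribute their
#' negative binomial log-likelihood.
#'
#' @param spec A [regulated_model_spec()].
#' @param k_vec Named vector of rates covering `k_off_<operator>` and
#'   `k_on_<level>` for every condition in the spec.
#' @param k_i,b Burst parameters (ignored if the spec fixes them).
#' @return The log-likelihood.
#' @export
loglike_regulated <- function(spec, k_vec, k_i = NULL, b = NULL) {
  stopifnot(inherits(spec, "regulated_model_spec"))
  if (spec$fix_burst) {
    k_i <- spec$burst[["k_i"]]; b <- spec$burst[["b"]]
  }
  stopifnot(!is.null(k_i), !is.null(b))
  kv <- as.list(k_vec)
  ll <- 0
  for (ct in spec$cond_tabs) {
    kon <- kv[[paste0("k_on_", ct$level)]]
    koff <- kv[[paste0("k_off_", ct$operator)]]
    if (is.null(kon) || is.null(koff)) {
      stop("condition (", ct$operator, ", ", ct$level,
           ") not mapped by k_vec")
    }
    lp <- log_drepressed_vec(ct$m_max, kon, koff, k_i, b, rtol = 1e-11,
                             max_terms = 30000L, on_max = "na")
    if (anyNA(lp)) return(-Inf)          # series budget exceeded: reject
    ll <- ll + sum(ct$n * lp[ct$m + 1])
  }
  if (!spec$fix_burst && length(spec$ref_counts)) {
    ll <- ll + sum(spec$ref_tab$n * neg_binom_pmf(spec$ref_tab$m, k_i, b,
                                                  log = TRUE))
  }
  ll
}

#' Log-posterior builders
#'
#' `constitutive_log_posterior()` and `regulated_log_posterior()` return
#' functions of the log-scale parameter vector suitable for [run_mcmc()]:
#' log-likelihood plus a normal prior density on the log parameters
#' (equivalently a log-normal prior on the natural-scale rates).
#'
#' @param counts Constitutive mRNA counts.
#' @param prior A [prior_spec()]; defaults to location 0, scale 2 for every
#'   parameter.
#' @return A function `theta -> log posterior` with a `params` attribute.
#' @export
constitutive_log_posterior <- function(counts,
                                       prior = prior_spec(c("k_i", "b"))) {
  force(prior)
  tab <- table(counts)                   # tabulate once, not per evaluation
  m <- as.integer(names(tab))
  n <- as.integer(tab)
  f <- function(theta) {
    sum(n * stats::dnbinom(m, size = exp(theta[1]),
                           prob = 1 / (1 + exp(theta[2])), log = TRUE)) +
      log_prior(theta, prior)
  }
  attr(f, "params") <- prior$param
  f
}

#' @rdname constitutive_log_posterior
#' @param spec A [regulated_model_spec()].
#' @export
regulated_log_posterior <- function(spec,
                                    prior = prior_spec(spec$params)) {
  stopifnot(identical(prior$param, spec$params))
  force(spec); force(prior)
  f <- function(theta) {
    lp <- log_prior(theta, prior)
    if (!is.finite(lp)) return(-Inf)
    names(theta) <- spec$params
    x <- exp(theta)
    ll <- if (spec$fix_burst) {
      loglike_regulated(spec, x)
    } else {
      loglike_regulated(spec, x, k_i = x[["k_i"]], b = x[["b"]])
    }
    ll + lp
  }
  attr(f, "params") <- spec$params
  f
}

# --- ensemble sampler ------------------------------------------------------

#' Affine-invariant ensemble MCMC on log-scale parameters
#'
#' Samples a log-posterior with the stretch-move ensemble sampler: each
#' walker proposes along the line through a randomly chosen companion walker
#' with a scale drawn from the standard \eqn{g(z) \propto 1/\sqrt z} density
#' on `[1/a, a]`. The move is gradient-free and invariant under affine
#' reparameterizations, which suits the strong pairwise correlations of the
#' joint repressor-rate posterior. The first `warmup_frac` of iterations is
#' discarded. Walkers are initialized overdispersed from the central 50% of
#' the prior unless an `init` matrix is given.
#'
#' @param log_post Function `theta -> log posterior` on the log scale,
#'   ideally from [constitutive_log_posterior()] or
#'   [regulated_log_posterior()].
#' @param params Parameter names; defaults to `attr(log_post, "params")`.
#' @param prior A [prior_spec()] used for default initialization.
#' @param n_walkers Number of ensemble walkers; defaults to
#'   `max(2 * d + 2, 10)` for dimension `d`.
#' @param n_steps Total ensemble iterations (default 1500).
#' @param warmup_frac Fraction of iterations discarded (default 0.5).
#' @param stretch_a Stretch scale `a` (default 2).
#' @param seed Integer seed; the full output is reproducible given it.
#' @param init Optional `n_walkers x d` matrix of starting log-parameters,
#'   or one of `"map"` (default: walkers start in a tight ball around a
#'   posterior mode located by Nelder-Mead from the prior center, the
#'   standard practice for ensemble samplers) and `"prior"` (walkers drawn
#'   from the central 50% of the prior; robust but slow to collapse when the
#'   posterior is much narrower than the prior).
#' @return An object of class `posterior_samples`: post-warmup draws
#'   (iterations x walkers x parameters, log scale), seed, settings, and
#'   convergence diagnostics (split R-hat and effective sample size per
#'   parameter).
#' @export
run_mcmc <- function(log_post, params = attr(log_post, "params"),
                     prior = prior_spec(params), n_walkers = NULL,
                     n_steps = 1500, warmup_frac = 0.5, stretch_a = 2,
                     seed = 1, init = "map") {
  d <- length(params)
  stopifnot(d >= 1, n_steps >= 10, warmup_frac > 0, warmup_frac < 1)
  if (is.null(n_walkers)) n_walkers <- max(2L * d + 2L, 10L)
  if (n_walkers < max(d + 2, 4)) stop("too few walkers for the dimension")
  set.seed(seed)
  if (is.character(init)) {
    init <- match.arg(init, c("map", "prior"))
    init <- switch(init,
      prior = matrix(
        stats::qnorm(stats::runif(n_walkers * d, 0.25, 0.75),
                     mean = rep(prior$location, each = n_walkers),
                     sd = rep(prior$scale, each = n_walkers)),
        n_walkers, d),
      map = {
        par <- if (d == 1) {
          stats::optimize(function(th) -log_post(th),
                          prior$location + c(-3, 3) * prior$scale)$minimum
        } else {
          stats::optim(prior$location, function(th) -log_post(th),
                       method = "Nelder-Mead",
                       control = list(maxit = 5000))$par
        }
        matrix(rep(par, each = n_walkers), n_walkers, d) +
          matrix(stats::rnorm(n_walkers * d, 0, 0.1), n_walkers, d)
      })
  }
  stopifnot(nrow(init) == n_walkers, ncol(init) == d)
  lp <- apply(init, 1, log_post)
  if (any(!is.finite(lp))) {
    bad <- which(!is.finite(lp))[1]
    stop("non-finite log-posterior at initialization; offending values: ",
         paste(signif(exp(init[bad, ]), 4), collapse = ", "))
  }
  x <- init
  a <- stretch_a
  n_keep <- n_steps - floor(n_steps * warmup_frac)
  draws <- array(NA_real_, c(n_keep, n_walkers, d),
                 dimnames = list(NULL, NULL, params))
  accept <- 0L
  for (it in seq_len(n_steps)) {
    for (k in seq_len(n_walkers)) {
      j <- sample((seq_len(n_walkers))[-k], 1)
      z <- (((a - 1) * stats::runif(1) + 1)^2) / a
      y <- x[j, ] + z * (x[k, ] - x[j, ])
      lpy <- log_post(y)
      if (is.finite(lpy) &&
          log(stats::runif(1)) < (d - 1) * log(z) + lpy - lp[k]) {
        x[k, ] <- y
        lp[k] <- lpy
        accept <- accept + 1L
      }
    }
    if (it > n_steps - n_keep) draws[it - (n_steps - n_keep), , ] <- x
  }
  out <- structure(
    list(draws = draws, params = params, seed = seed,
         n_steps = n_steps, n_walkers = n_walkers,
         warmup = n_steps - n_keep,
         accept_rate = accept / (n_steps * n_walkers)),
    class = "posterior_samples")
  out$diagnostics <- mcmc_diagnostics(out)
  out
}

# split R-hat and effective sample size, walkers treated as chains
mcmc_diagnostics <- function(s) {
  dr <- s$draws
  n <- dim(dr)[1]; K <- dim(dr)[2]; d <- dim(dr)[3]
  half <- floor(n / 2)
  rhat <- ess <- numeric(d)
  for (p in seq_len(d)) {
    # split each walker chain in half
    ch <- cbind(dr[seq_len(half), , p], dr[(n - half + 1):n, , p])
    mns <- colMeans(ch)
    vrs <- apply(ch, 2, stats::var)
    W <- mean(vrs)
    B <- half * stats::var(mns)
    rhat[p] <- if (W > 0) sqrt(((half - 1) / half * W + B / half) / W) else 1
    ess[p] <- sum(vapply(seq_len(K), function(k) {
      unname(coda::effectiveSize(coda::mcmc(dr[, k, p])))
    }, numeric(1)))
  }
  data.frame(param = s$params, rhat = rhat, ess = ess)
}

#' @export
print.posterior_samples <- function(x, ...) {
  cat(sprintf(
    "<posterior_samples> %d parameter(s), %d walkers x %d kept iterations\n",
    length(x$params), x$n_walkers, dim(x$draws)[1]))
  cat(sprintf("  acceptance rate %.2f; max split R-hat %.4f; min ESS %.0f\n",
              x$accept_rate, max(x$diagnostics$rhat),
              min(x$diagnostics$ess)))
  invisible(x)
}

#' Flatten posterior draws to a matrix
#'
#' @param s A `posterior_samples` object.
#' @param natural Return natural-scale (exponentiated) draws? Default `TRUE`.
#' @return Matrix with one column per parameter.
#' @export
draws_matrix <- function(s, natural = TRUE) {
  stopifnot(inherits(s, "posterior_samples"))
  d <- dim(s$draws)[3]
  m <- matrix(aperm(s$draws, c(1, 2, 3)), ncol = d,
              dimnames = list(NULL, s$params))
  if (natural) exp(m) else m
}

check_converged <- function(s, override = FALSE,
                            rhat_max = 1.01, ess_min = 400) {
  bad <- s$diagnostics$rhat > rhat_max | s$diagnostics$ess < ess_min
  if (any(bad) && !override) {
    stop("MCMC has not converged (R-hat > ", rhat_max, " or ESS < ", ess_min,
         ") for: ", paste(s$diagnostics$param[bad], collapse = ", "),
         ". Re-run longer or pass override = TRUE.")
  }
  invisible(!any(bad))
}

#' Posterior summaries on the natural scale
#'
#' Mean, standard deviation, coefficient of variation (percent) and quantiles
#' per parameter, computed on the natural (rate) scale. Refuses to summarize
#' an unconverged sample (split R-hat above 1.01 or effective sample size
#' below 400 on any parameter) unless `override = TRUE`.
#'
#' @param s A `posterior_samples` object.
#' @param probs Quantile levels.
#' @param override Summarize despite failed convergence diagnostics?
#' @return Data frame with one row per parameter.
#' @export
posterior_summary <- function(s, probs = c(0.025, 0.25, 0.5, 0.75, 0.975),
                              override = FALSE) {
  check_converged(s, override)
  x <- draws_matrix(s, natural = TRUE)
  qs <- t(apply(x, 2, stats::quantile, probs = probs))
  colnames(qs) <- paste0("q", probs * 100)
  mu <- colMeans(x)
  sd <- apply(x, 2, stats::sd)
  cbind(data.frame(param = s$params, mean = mu, sd = sd,
                   cv_pct = 100 * sd / mu, row.names = NULL),
        as.data.frame(qs), s$diagnostics[c("rhat", "ess")])
}

#' Highest posterior density region
#'
#' In one dimension, the shortest interval containing `level` of the draws.
#' In two dimensions, the level set of a bivariate kernel density estimate
#' (on the log scale, mapped back) chosen so that approximately `level` of
#' the draws have density above the threshold; returned as the contour
#' polygon(s).
#'
#' @param s A `posterior_samples` object.
#' @param params One or two parameter names.
#' @param level Probability content (default 0.95).
#' @param override Proceed despite failed convergence diagnostics?
#' @param n_grid Kernel density grid size for the 2-D case.
#' @return For one parameter, a named vector `c(lower, upper)`; for two, a
#'   list with the enclosed `fraction` of draws and `polygons` (list of
#'   data frames with the contour coordinates on the natural scale).
#' @export
hpd_region <- function(s, params, level = 0.95, override = FALSE,
                       n_grid = 101) {
  stopifnot(level > 0, level < 1, length(params) %in% 1:2,
            all(params %in% s$params))
  check_converged(s, override)
  x <- draws_matrix(s, natural = TRUE)[, params, drop = FALSE]
  if (length(params) == 1) {
    v <- sort(x[, 1])
    n <- length(v)
    k <- max(1L, floor(level * n))
    starts <- seq_len(n - k)
    widths <- v[starts + k] - v[starts]
    i <- starts[which.min(widths)]
    return(c(lower = v[i], upper = v[i + k]))
  }
  lx <- log(x)
  kd <- MASS::kde2d(lx[, 1], lx[, 2], n = n_grid,
                    lims = c(range(lx[, 1]) + c(-1, 1) * stats::sd(lx[, 1]),
                             range(lx[, 2]) + c(-1, 1) * stats::sd(lx[, 2])))
  # density at each draw via bilinear interpolation
  di <- findInterval(lx[, 1], kd$x, all.inside = TRUE)
  dj <- findInterval(lx[, 2], kd$y, all.inside = TRUE)
  tx <- (lx[, 1] - kd$x[di]) / diff(kd$x[1:2])
  ty <- (lx[, 2] - kd$y[dj]) / diff(kd$y[1:2])
  dens <- kd$z[cbind(di, dj)] * (1 - tx) * (1 - ty) +
    kd$z[cbind(di + 1, dj)] * tx * (1 - ty) +
    kd$z[cbind(di, dj + 1)] * (1 - tx) * ty +
    kd$z[cbind(di + 1, dj + 1)] * tx * ty
  thr <- stats::quantile(dens, 1 - level)
  cl <- grDevices::contourLines(kd$x, kd$y, kd$z, levels = thr)
  polys <- lapply(cl, function(p) {
    out <- data.frame(exp(p$x), exp(p$y))
    names(out) <- params
    out
  })
  list(level = level, fraction = mean(dens >= thr), polygons = polys)
}

#' Fit the bursty model to one constitutive promoter's counts
#'
#' Convenience wrapper: builds the negative binomial log-posterior with
#' log-normal priors and runs the ensemble sampler.
#'
#' @param counts Nonnegative integer mRNA counts.
#' @param prior A [prior_spec()] for `k_i` and `b`.
#' @param n_steps,n_walkers,seed Sampler settings (see [run_mcmc()]).
#' @return A `posterior_samples` object with parameters `k_i` and `b`.
#' @export
fit_constitutive <- function(counts, prior = prior_spec(c("k_i", "b")),
                             n_steps = 8000, n_walkers = 6, seed = 1) {
  if (length(counts) == 0) stop("empty count vector")
  run_mcmc(constitutive_log_posterior(counts, prior), prior = prior,
           n_walkers = n_walkers, n_steps = n_steps, seed = seed)
}

#' Fit the joint regulated model
#'
#' Builds the [regulated_model_spec()] for a dataset and samples the joint
#' posterior of repressor rates (and, unless `fix_burst`, the burst
#' parameters) with the ensemble sampler.
#'
#' @inheritParams regulated_model_spec
#' @param dataset Count data frame in the [generate_study()] schema.
#' @param prior Optional [prior_spec()] over the model's parameters.
#' @param n_steps,n_walkers,seed Sampler settings (see [run_mcmc()]).
#' @return A `posterior_samples` object.
#' @export
fit_regulated <- function(dataset, reference = "prom09", fix_burst = FALSE,
                          burst = NULL, prior = NULL, n_steps = 1200,
                          n_walkers = NULL, seed = 1) {
  spec <- regulated_model_spec(dataset, reference, fix_burst, burst)
  if (is.null(prior)) prior <- prior_spec(spec$params)
  run_mcmc(regulated_log_posterior(spec, prior), params = spec$params,
           prior = prior, n_walkers = n_walkers, n_steps = n_steps,
           seed = seed)
}
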