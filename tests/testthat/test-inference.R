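test_that("constitutive log-likelihood: edge cases and shape", {
  expect_equal(loglike_constitutive(integer(0), 2, 3), 0)
  expect_equal(loglike_constitutive(0L, k_i = 2, b = 3), -2 * log(1 + 3))
  # likelihood at the generating truth beats a wrong parameter on average
  diffs <- vapply(1:20, function(sd) {
    set.seed(sd)
    x <- rnbinom(100, size = 2, prob = 0.25)
    loglike_constitutive(x, 2, 3) - loglike_constitutive(x, 4, 6)
  }, numeric(1))
  expect_gt(mean(diffs), 0)
})

test_that("regulated likelihood factorizes and reduces to the constitutive one", {
  ds <- generate_study(tiny_study_config(cells = 150))
  spec <- regulated_model_spec(ds, reference = "ref")
  expect_setequal(spec$params,
                  c("k_off_opA", "k_off_opB", "k_on_1", "k_i", "b"))
  ref_counts <- ds$mrna_count[ds$condition_type == "constitutive"]
  reg_counts <- split(
    ds$mrna_count[ds$condition_type == "regulated"],
    ds$promoter_or_operator[ds$condition_type == "regulated"])
  # k_on -> 0: every condition reverts to the unregulated negative binomial
  k0 <- c(k_off_opA = 1, k_off_opB = 4, k_on_1 = 1e-12)
  ll0 <- loglike_regulated(spec, k0, k_i = 4.5, b = 4.5)
  ll_nb <- loglike_constitutive(ds$mrna_count, 4.5, 4.5)
  expect_equal(ll0, ll_nb, tolerance = 1e-6)
  # duplicated condition contributes exactly twice the single-condition value
  ds2 <- ds[ds$condition_type == "regulated" &
              ds$promoter_or_operator == "opA", ]
  dsc <- rbind(ds[ds$condition_type == "constitutive", ], ds2)
  spec1 <- regulated_model_spec(dsc, reference = "ref")
  dsb <- ds2; dsb$promoter_or_operator <- "opB"
  spec2 <- regulated_model_spec(rbind(dsc, dsb), reference = "ref")
  kk <- c(k_off_opA = 2, k_off_opB = 2, k_on_1 = 1.5)
  ll1 <- loglike_regulated(spec1, kk[c(1, 3)], k_i = 4, b = 4)
  llref <- sum(spec1$ref_tab$n * neg_binom_pmf(spec1$ref_tab$m, 4, 4,
                                               log = TRUE))
  ll2 <- loglike_regulated(spec2, kk, k_i = 4, b = 4)
  expect_equal(ll2 - llref, 2 * (ll1 - llref), tolerance = 1e-8)
  # unmapped condition is a configuration error
  expect_error(loglike_regulated(spec, c(k_off_opA = 1, k_on_1 = 1),
                                 k_i = 4, b = 4), "not mapped")
  expect_error(regulated_model_spec(ds[ds$condition_type == "regulated", ],
                                    reference = "ref"),
               "no constitutive reference")
  expect_error(
    regulated_model_spec(ds, reference = "ref", fix_burst = TRUE),
    "burst")
})

test_that("posterior equals prior on empty data; flat priors leave likelihood", {
  pr <- prior_spec(c("k_i", "b"), location = c(0.3, -0.2), scale = 1.4)
  lp <- constitutive_log_posterior(integer(0), pr)
  th <- c(0.4, 0.8)
  expect_equal(lp(th), sum(dnorm(th, pr$location, pr$scale, log = TRUE)))
  # very weak prior: log-posterior differences equal log-likelihood differences
  x <- c(0L, 3L, 5L, 9L)
  lpw <- constitutive_log_posterior(x, prior_spec(c("k_i", "b"),
                                                  scale = 1e6))
  d_post <- lpw(log(c(2, 3))) - lpw(log(c(4, 6)))
  d_lik <- loglike_constitutive(x, 2, 3) - loglike_constitutive(x, 4, 6)
  expect_equal(d_post, d_lik, tolerance = 1e-4)
})

test_that("posterior mode lies near the generating truth on rich data", {
  set.seed(31)
  x <- rnbinom(2500, size = 4.5, prob = 1 / 5.5)
  lp <- constitutive_log_posterior(x)
  opt <- optim(c(0, 0), function(th) -lp(th), method = "Nelder-Mead")
  expect_lt(max(abs(exp(opt$par) / c(4.5, 4.5) - 1)), 0.10)
})

test_that("ensemble sampler recovers a known prior and is seed-deterministic", {
  lp0 <- function(theta) sum(dnorm(theta, 0, 2, log = TRUE))
  attr(lp0, "params") <- c("p1", "p2")
  s <- run_mcmc(lp0, prior = prior_spec(c("p1", "p2")), n_steps = 8000,
                seed = 2, init = "prior")
  dm <- draws_matrix(s, natural = FALSE)
  expect_lt(max(abs(colMeans(dm))), 0.15)
  expect_lt(max(abs(apply(dm, 2, sd) - 2)), 0.15)
  s2 <- run_mcmc(lp0, prior = prior_spec(c("p1", "p2")), n_steps = 8000,
                 seed = 2, init = "prior")
  expect_identical(s$draws, s2$draws)
  # non-finite log-posterior at explicit init is an initialization error
  bad <- function(theta) -Inf
  attr(bad, "params") <- "p"
  expect_error(run_mcmc(bad, prior = prior_spec("p"),
                        init = matrix(1, 10, 1)),
               "non-finite log-posterior at initialization")
})

test_that("posterior summaries: gating, degenerate draws, quantile monotonicity", {
  dm <- matrix(log(3), nrow = 400, ncol = 1, dimnames = list(NULL, "k"))
  s <- fake_posterior(dm)
  s$diagnostics$ess <- 0                  # constant draws: no information
  expect_error(posterior_summary(s), "not converged")
  sm <- posterior_summary(s, override = TRUE)
  expect_equal(sm$mean, 3)
  expect_equal(sm$sd, 0)
  expect_equal(sm$cv_pct, 0)
  set.seed(1)
  dm2 <- matrix(rnorm(4000), ncol = 1, dimnames = list(NULL, "k"))
  sm2 <- posterior_summary(fake_posterior(dm2))
  qs <- as.numeric(sm2[1, c("q2.5", "q25", "q50", "q75", "q97.5")])
  expect_true(all(diff(qs) > 0))
})

test_that("highest-density regions enclose the right mass", {
  set.seed(8)
  u <- matrix(log(runif(40000)), ncol = 1, dimnames = list(NULL, "p"))
  s <- fake_posterior(u)                  # natural-scale draws ~ U(0,1)
  hp <- hpd_region(s, "p", level = 0.95)
  expect_lt(abs((hp["upper"] - hp["lower"]) - 0.95), 0.02)
  # symmetric unimodal (on the natural scale): HPD ~ equal-tailed interval
  z <- matrix(log(rnorm(40000, 10, 1)), ncol = 1,
              dimnames = list(NULL, "p"))
  sz <- fake_posterior(z)
  hz <- hpd_region(sz, "p")
  et <- quantile(exp(z), c(0.025, 0.975))
  expect_lt(abs(hz["lower"] - et[1]), 0.05)
  expect_lt(abs(hz["upper"] - et[2]), 0.05)
  # 2-D region encloses ~95% of draws
  xy <- cbind(a = rnorm(20000), b = rnorm(20000, 0, 0.5))
  sxy <- fake_posterior(xy)
  h2 <- hpd_region(sxy, c("a", "b"), level = 0.95)
  expect_gt(h2$fraction, 0.94)
  expect_lt(h2$fraction, 0.96)
  expect_error(hpd_region(s, "p", level = 1.2), "level")
})

test_that("constitutive fits recover truth across the burst-parameter regime", {
  set.seed(99)
  truths <- cbind(k_i = exp(runif(20, log(0.5), log(10))),
                  b = exp(runif(20, log(0.5), log(8))))
  covered <- logical(20)
  for (i in 1:20) {
    x <- rnbinom(2500, size = truths[i, 1],
                 prob = 1 / (1 + truths[i, 2]))
    s <- fit_constitutive(x, n_steps = 9000, seed = 1000 + i)
    sm <- posterior_summary(s, override = TRUE)
    covered[i] <- all(sm$q2.5 <= truths[i, ] & truths[i, ] <= sm$q97.5)
  }
  expect_gte(sum(covered), 16)
})

test_that("telegraph likelihood has a ridge: only the burst size is identified", {
  set.seed(11)
  x <- rnbinom(1000, size = 2, prob = 0.25)   # bursty data, k_i = 2, b = 3
  ll <- function(r, kin) {
    loglike_cme(x, promoter_model("telegraph", r = r, k_act = 2,
                                  k_inact = kin))
  }
  # along r/k_inact = 3 the likelihood is nearly flat at large rates ...
  expect_lt(abs(ll(80, 80 / 3) - ll(40, 40 / 3)), 30)
  # ... but moving off the ridge at fixed r collapses it
  expect_gt(ll(80, 80 / 3) - ll(80, 80 / 1.5), 200)
  # in contrast the bursty model's parameters are individually constrained
  expect_gt(loglike_constitutive(x, 2, 3) - loglike_constitutive(x, 4, 1.5),
            20)
})
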