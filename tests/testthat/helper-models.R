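# shared fixtures: all synthetic, built in code

# total-variation distance between two pmfs on 0..max support
tv_dist <- function(p, q) {
  L <- max(length(p), length(q))
  p <- c(p, rep(0, L - length(p)))
  q <- c(q, rep(0, L - length(q)))
  0.5 * sum(abs(p - q))
}

# KS distance between empirical counts and a pmf over 0..length(pmf)-1
ks_to_pmf <- function(counts, pmf) {
  m <- 0:(length(pmf) - 1)
  max(abs(stats::ecdf(counts)(m) - cumsum(pmf)))
}

# small regulated study used by pipeline/inference tests (2 operators x 1
# level over a single reference promoter; cheap to fit)
tiny_study_config <- function(cells = 200, seed = 402) {
  study_config(
    constitutive = list(ref = c(k_i = 4.5, b = 4.5)),
    reference = "ref",
    operators = c(opA = 1, opB = 4),
    repressor_levels = c(`1` = 2),
    conditions = data.frame(operator = c("opA", "opB"), level = "1"),
    cells_per_condition = cells, seed = seed)
}

# hand-rolled posterior_samples with known draws (for summary/ecdf tests)
fake_posterior <- function(draws_mat, n_walkers = 4) {
  d <- ncol(draws_mat)
  n <- nrow(draws_mat) / n_walkers
  s <- structure(
    list(draws = array(draws_mat, c(n, n_walkers, d),
                       dimnames = list(NULL, NULL, colnames(draws_mat))),
         params = colnames(draws_mat), seed = 0, n_steps = n * 2,
         n_walkers = n_walkers, warmup = n, accept_rate = 0.5),
    class = "posterior_samples")
  s$diagnostics <- data.frame(param = s$params, rhat = 1,
                              ess = nrow(draws_mat))
  s
}
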