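#' Burst-size distribution of a promoter escaping an active state
#'
#' While a promoter dwells in its transcriptionally active state (exponential
#' dwell, rate `k_minus` to leave) it initiates transcripts at rate `r`.
#' Marginalizing the dwell time yields a geometric number of transcripts per
#' activity window with parameter \eqn{\theta = k^-/(k^- + r)} on
#' \{0, 1, 2, ...\} and mean \eqn{b = r / k^-}: the burst-size law behind the
#' bursty one-state model.
#'
#' @param n Nonnegative integer burst sizes.
#' @param r Initiation rate while active (units of the degradation rate).
#' @param k_minus Rate of leaving the active state.
#' @param log Return log-probabilities?
#' @return Probabilities (or log-probabilities) of the burst sizes.
#' @export
#' @examples
#' burst_size_pmf(0:5, r = 3, k_minus = 1)
burst_size_pmf <- function(n, r, k_minus, log = FALSE) {
  if (r <= 0 || k_minus <= 0) stop("rates must be strictly positive")
  stopifnot(all(n == floor(n)), all(n >= 0))
  stats::dgeom(n, prob = k_minus / (k_minus + r), log = log)
}

#' Negative binomial steady state of the one-state bursty promoter
#'
#' The steady-state mRNA distribution when geometric bursts of mean size `b`
#' arrive as a Poisson process of rate `k_i` (units of the degradation rate):
#' \deqn{p(m) = \frac{\Gamma(m + k_i)}{\Gamma(m+1)\Gamma(k_i)}
#'   \left(\frac{1}{1+b}\right)^{k_i} \left(\frac{b}{1+b}\right)^m,}
#' i.e. negative binomial with size `k_i` and success probability
#' `1/(1+b)`; mean `k_i b`, Fano factor `1 + b`. Evaluated in log-space via
#' log-gamma (through [stats::dnbinom()]).
#'
#' @param m Nonnegative integer mRNA counts.
#' @param k_i Burst initiation rate (> 0).
#' @param b Mean burst size (> 0).
#' @param log Return log-probabilities?
#' @return Probabilities (or log-probabilities).
#' @export
neg_binom_pmf <- function(m, k_i, b, log = FALSE) {
  if (k_i <= 0 || b <= 0) stop("k_i and b must be strictly positive")
  stats::dnbinom(m, size = k_i, prob = 1 / (1 + b), log = log)
}

#' Hypergeometric shape parameters of the repressed bursty distribution
#'
#' The repressed bursty steady state is governed by the two roots
#' \deqn{\alpha, \beta = \tfrac12\left(k_i + k_{off} + k_{on} \pm
#'   \sqrt{(k_i + k_{off} + k_{on})^2 - 4 k_i k_{off}}\right),}
#' computed here in a cancellation-free form (the smaller root via the
#' product identity \eqn{\alpha\beta = k_i k_{off}}). The discriminant is
#' bounded below by \eqn{(k_i - k_{off})^2} and the roots are always real,
#' with \eqn{\beta < \min(k_i, k_{off}) \le \max(k_i, k_{off}) < \alpha} and
#' \eqn{\alpha + \beta = k_i + k_{on} + k_{off}}.
#'
#' @param k_i Burst initiation rate (> 0).
#' @param k_on,k_off Repressor binding/unbinding rates (> 0).
#' @return Named numeric vector `c(alpha, beta)`.
#' @export
alpha_beta <- function(k_i, k_on, k_off) {
  if (k_i <= 0 || k_on <= 0 || k_off <= 0) {
    stop("all rates must be strictly positive")
  }
  s <- k_i + k_on + k_off
  disc <- sqrt(s^2 - 4 * k_i * k_off)
  alpha <- (s + disc) / 2
  c(alpha = alpha, beta = k_i * k_off / alpha)
}

#' Log Gauss hypergeometric function at negative argument
#'
#' Evaluates \eqn{\log {}_2F_1(a, b; c; -z)} for positive parameters and
#' `z > 0` via the Pfaff transformation
#' \deqn{{}_2F_1(a, b; c; -z) = (1+z)^{-a}\, {}_2F_1(a, c - b; c; z/(1+z)),}
#' which maps the argument into (0, 1) where the series converges. For the
#' parameter family arising in the repressed bursty distribution the
#' transformed series has strictly positive terms (there `c - b > 0`), so a
#' log-space accumulation is free of cancellation; the series is truncated
#' when the geometric tail bound falls below `rtol`.
#'
#' @param a,b_arg,c_arg Hypergeometric parameters, `a >= 0`,
#'   `c_arg >= b_arg > 0` (so that the Pfaff-transformed series has
#'   nonnegative terms).
#' @param z Positive magnitude of the (negative) argument.
#' @param rtol Relative truncation tolerance (default 1e-12).
#' @param max_terms Series length cap; exceeding it with an unsatisfied tail
#'   bound raises an error carrying the achieved bound.
#' @return `log(2F1(a, b_arg; c_arg; -z))`, a finite negative-or-zero number.
#' @export
#' @examples
#' # closed form when c equals an upper parameter: (1+z)^(-a)
#' log_gauss_2f1_neg_arg(2, 1.5, 1.5, 3) # -2 log 4
log_gauss_2f1_neg_arg <- function(a, b_arg, c_arg, z,
                                  rtol = 1e-12, max_terms = 1e5) {
  stopifnot(a >= 0, b_arg > 0, c_arg > 0, z > 0)
  if (c_arg < b_arg - 1e-12) {
    stop("requires c_arg >= b_arg for a positive-term Pfaff series")
  }
  if (a == 0) return(0)
  x <- z / (1 + z)
  e <- c_arg - b_arg                      # second upper parameter after Pfaff
  if (e <= 0) return(-a * log1p(z))       # c == b: 2F1(a, 0; c; x) = 1
  # series sum_n t_n, t_0 = 1, t_{n+1}/t_n = (a+n)(e+n) x / ((c+n)(n+1))
  block <- 256L
  logsum <- 0                             # log of accumulated sum
  logt <- 0                               # log t_0
  n0 <- 0L
  repeat {
    n <- n0 + seq_len(block) - 1L
    logr <- log(a + n) + log(e + n) + log(x) - log(c_arg + n) - log1p(n)
    logt_next <- logt + cumsum(logr)
    mx <- max(logsum, logt_next)
    logsum <- mx + log(exp(logsum - mx) + sum(exp(logt_next - mx)))
    logt <- logt_next[block]
    n0 <- n0 + block
    ratio <- exp(logr[block])
    if (ratio < 1) {
      tail_bound <- exp(logt - logsum) * ratio / (1 - ratio)
      if (tail_bound < rtol) break
    }
    if (n0 >= max_terms) {
      stop(sprintf(
        "2F1 series did not meet rtol = %.1e within %d terms (a=%g, b=%g, c=%g, z=%g)",
        rtol, max_terms, a, b_arg, c_arg, z))
    }
  }
  -a * log1p(z) + logsum
}

# vectorized-over-m core used by drepressed(): returns log p(m) for
# m = 0..m_max; with on_max = "na" an excessive series length (deep in
# negligible-posterior parameter regions) yields a single NA instead of an
# error, letting likelihood callers reject the region
log_drepressed_vec <- function(m_max, k_on, k_off, k_i, b, rtol = 1e-12,
                               max_terms = 200000L,
                               on_max = c("error", "na")) {
  on_max <- match.arg(on_max)
  ab <- alpha_beta(k_i, k_on, k_off)
  alpha <- ab[["alpha"]]; beta <- ab[["beta"]]
  ksum <- k_on + k_off
  m <- 0:m_max
  e <- ksum - beta                        # c - b_arg, independent of m
  # Pfaff-transformed positive-term series, evaluated in compiled code
  log2f1 <- log2f1_pfaff_vec(m_max, alpha, e, ksum, b, rtol, max_terms,
                             error_on_max = on_max == "error")
  if (anyNA(log2f1)) return(NA_real_)
  lgamma(alpha + m) - lgamma(alpha) +
    lgamma(beta + m) - lgamma(beta) +
    lgamma(ksum) - lgamma(ksum + m) +
    m * log(b) - lgamma(m + 1) + log2f1
}

#' Steady-state mRNA distribution of the repressed bursty promoter
#'
#' The bursty one-state promoter with a repressor-bound silent state
#' (binding rate `k_on`, unbinding rate `k_off`, both in units of the mRNA
#' degradation rate) has steady state
#' \deqn{p(m) = \frac{\Gamma(\alpha+m)\Gamma(\beta+m)\Gamma(k_{on}+k_{off})}
#'   {\Gamma(\alpha)\Gamma(\beta)\Gamma(k_{on}+k_{off}+m)}\frac{b^m}{m!}
#'   \; {}_2F_1(\alpha+m, \beta+m; k_{on}+k_{off}+m; -b),}
#' with \eqn{\alpha,\beta} from [alpha_beta()]. All gamma ratios are taken as
#' log-gamma differences and the hypergeometric factor is evaluated through
#' [log_gauss_2f1_neg_arg()]'s Pfaff-transformed positive-term series. As
#' `k_on -> 0` the distribution reduces to the negative binomial
#' [neg_binom_pmf()]; its mean is `k_i b / (1 + k_on/k_off)` (the fold-change
#' relation) and its Fano factor exceeds `1 + b` at intermediate repressor
#' rates.
#'
#' @param m Nonnegative integer mRNA counts.
#' @param k_on,k_off Repressor binding/unbinding rates (> 0).
#' @param k_i Burst initiation rate (> 0).
#' @param b Mean burst size (> 0).
#' @param log Return log-probabilities?
#' @return Probabilities (or log-probabilities) at `m`.
#' @export
#' @examples
#' bursty_repressed_pmf(0:10, k_on = 1, k_off = 1, k_i = 2, b = 3)
bursty_repressed_pmf <- function(m, k_on, k_off, k_i, b, log = FALSE) {
  stopifnot(all(m == floor(m)), all(m >= 0))
  if (b <= 0) stop("b must be strictly positive")
  lp_all <- log_drepressed_vec(max(m), k_on, k_off, k_i, b)
  lp <- lp_all[m + 1]
  if (log) lp else exp(lp)
}

#' Repressed bursty pmf on an adaptively extended support
#'
#' Evaluates [bursty_repressed_pmf()] on `0..M`, extending `M` until the
#' cumulative mass reaches `1 - tail_tol`, and verifies normalization.
#'
#' @inheritParams bursty_repressed_pmf
#' @param tail_tol Mass allowed beyond the returned support (default 1e-10).
#' @return Numeric pmf vector over `0..M`.
#' @export
repressed_pmf_adaptive <- function(k_on, k_off, k_i, b, tail_tol = 1e-10) {
  mean_ub <- k_i * b
  M <- ceiling(mean_ub + 10 * sqrt(max(mean_ub, 1) * (1 + b))) + 20
  repeat {
    pmf <- exp(log_drepressed_vec(M, k_on, k_off, k_i, b))
    miss <- 1 - sum(pmf)
    if (miss < tail_tol) break
    if (M > 2^15) {
      stop(sprintf("repressed pmf not normalized (missing mass %.3e): %s",
                   miss, "hypergeometric instability or truncation failure"))
    }
    M <- 2 * M
  }
  if (abs(sum(pmf) - 1) > 1e-8) {
    stop(sprintf("repressed pmf normalization failure: sum = %.12f", sum(pmf)))
  }
  pmf
}

#' Fano factor of a pmf over counts 0, 1, 2, ...
#'
#' Convenience wrapper around [pmf_moments()].
#'
#' @inheritParams pmf_moments
#' @return The Fano factor (variance/mean).
#' @export
fano_of_pmf <- function(pmf) {
  pmf_moments(pmf)$fano
}
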