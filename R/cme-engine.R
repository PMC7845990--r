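#' Construct a finite promoter-state chemical master equation model
#'
#' A promoter is modeled as a finite, irreducible Markov chain over discrete
#' microstates (empty, RNAP-bound, repressor-bound, active, inactive, ...)
#' coupled to mRNA copy number through per-state transcript production and
#' first-order degradation. All rates are nondimensionalized by the mRNA
#' degradation rate, which is fixed to 1 internally.
#'
#' Production from a state is one of:
#' \itemize{
#'   \item `list(type = "single", rate = r)` — one transcript at a time at
#'     rate `r`; an optional `to` field names the promoter state reached when
#'     the transcript is made (used for irreversible RNAP escape, where
#'     initiation returns the promoter to the empty state).
#'   \item `list(type = "burst", rate = k_i, b = b)` — instantaneous bursts
#'     arriving at rate `k_i`, each of geometric size with mean `b` on
#'     \{0, 1, 2, ...\} (zero-size bursts are no-ops).
#'   \item `NULL` — the state does not transcribe.
#' }
#'
#' @param states Character vector of promoter microstate names.
#' @param switch_rates Square matrix of promoter switching rates; entry
#'   `[i, j]` is the rate of the transition i -> j (diagonal ignored).
#' @param production Named list (by state) of production specifications as
#'   described above; states may be omitted (no production).
#' @param repressor_state Optional name of the repressor-bound state (set by
#'   [add_repressor()]).
#' @return An object of class `promoter_cme`.
#' @seealso [promoter_model()] for named presets, [steady_state_joint()].
#' @export
promoter_cme <- function(states, switch_rates, production = list(),
                         repressor_state = NULL) {
  states <- as.character(states)
  S <- length(states)
  stopifnot(S >= 1, !anyDuplicated(states))
  switch_rates <- as.matrix(switch_rates)
  stopifnot(nrow(switch_rates) == S, ncol(switch_rates) == S)
  diag(switch_rates) <- 0
  if (any(switch_rates < 0)) stop("switching rates must be nonnegative")
  dimnames(switch_rates) <- list(states, states)
  prod_full <- vector("list", S)
  names(prod_full) <- states
  for (nm in names(production)) {
    if (!nm %in% states) stop("production refers to unknown state: ", nm)
    p <- production[[nm]]
    if (is.null(p)) next
    if (!p$type %in% c("single", "burst")) {
      stop("production type must be 'single' or 'burst'")
    }
    if (is.null(p$rate) || p$rate < 0) stop("production rate must be >= 0")
    if (p$type == "burst" && (is.null(p$b) || p$b <= 0)) {
      stop("burst production requires mean burst size b > 0")
    }
    if (p$type == "single") {
      if (is.null(p$to)) p$to <- nm
      if (!p$to %in% states) stop("production destination unknown: ", p$to)
    }
    prod_full[[nm]] <- p
  }
  if (!is.null(repressor_state) && !repressor_state %in% states) {
    stop("repressor_state must name one of the promoter states")
  }
  model <- structure(
    list(states = states, switch_rates = switch_rates,
         production = prod_full, repressor_state = repressor_state),
    class = "promoter_cme")
  check_irreducible(model)
  model
}

# promoter-state graph must be strongly connected (production-coupled state
# changes count as edges) so the stationary distribution is unique
check_irreducible <- function(model) {
  S <- length(model$states)
  if (S == 1L) return(invisible(TRUE))
  A <- (model$switch_rates > 0) * 1
  for (s in seq_len(S)) {
    p <- model$production[[s]]
    if (!is.null(p) && p$type == "single" && p$rate > 0) {
      A[s, match(p$to, model$states)] <- 1
    }
  }
  reach <- A
  diag(reach) <- 1
  for (k in seq_len(S)) reach <- pmin(reach %*% reach, 1)
  if (any(reach == 0)) {
    stop("promoter-state graph is not irreducible; no unique steady state")
  }
  invisible(TRUE)
}

#' @export
print.promoter_cme <- function(x, ...) {
  cat("<promoter_cme> ", length(x$states), " state(s): ",
      paste(x$states, collapse = ", "), "\n", sep = "")
  for (s in x$states) {
    p <- x$production[[s]]
    if (is.null(p)) next
    if (p$type == "single") {
      cat("  ", s, ": single transcripts at rate ", p$rate,
          if (p$to != s) paste0(" (-> ", p$to, ")"), "\n", sep = "")
    } else {
      cat("  ", s, ": bursts at rate ", p$rate, ", mean size ", p$b,
          "\n", sep = "")
    }
  }
  if (!is.null(x$repressor_state)) {
    cat("  repressor-bound state: ", x$repressor_state, "\n", sep = "")
  }
  invisible(x)
}

#' Named presets for the constitutive promoter models
#'
#' Builds the five constitutive promoter architectures commonly contrasted in
#' the gene-expression-noise literature:
#' \describe{
#'   \item{`poisson`}{Model 1: one state, transcripts in a Poisson process at
#'     rate `r`.}
#'   \item{`rnap_escape`}{Model 2: empty <-> RNAP-bound (rates `kP_on`,
#'     `kP_off`), with irreversible escape producing one transcript at rate
#'     `r` and returning the promoter to empty.}
#'   \item{`multistep_escape`}{Model 3: as model 2 but initiation proceeds
#'     through a closed -> open complex step at rate `k_O` before escape.}
#'   \item{`telegraph`}{Model 4: inactive <-> active two-state promoter
#'     (rates `k_act` for inactive -> active, `k_inact` for the reverse) with
#'     Poisson initiation at rate `r` while active.}
#'   \item{`bursty`}{Model 5: one state producing instantaneous geometric
#'     bursts, initiation rate `k_i`, mean size `b` — the limit of the
#'     telegraph model at fast switching with `b = r / k_inact`.}
#' }
#' All rates are in units of the mRNA degradation rate.
#'
#' @param name One of `"poisson"`, `"rnap_escape"`, `"multistep_escape"`,
#'   `"telegraph"`, `"bursty"`.
#' @param r,kP_on,kP_off,k_O,k_act,k_inact,k_i,b Rate parameters as described
#'   above; only those relevant to the chosen preset are used.
#' @return A [promoter_cme()] model.
#' @export
#' @examples
#' promoter_model("bursty", k_i = 2, b = 3)
promoter_model <- function(name = c("poisson", "rnap_escape",
                                    "multistep_escape", "telegraph", "bursty"),
                           r = 1, kP_on = 1, kP_off = 1, k_O = 1,
                           k_act = 1, k_inact = 1, k_i = 1, b = 1) {
  name <- match.arg(name)
  switch(name,
    poisson = promoter_cme(
      "promoter", matrix(0, 1, 1),
      list(promoter = list(type = "single", rate = r))),
    rnap_escape = promoter_cme(
      c("empty", "rnap"),
      matrix(c(0, kP_off, kP_on, 0), 2, 2,
             dimnames = list(c("empty", "rnap"), c("empty", "rnap"))),
      list(rnap = list(type = "single", rate = r, to = "empty"))),
    multistep_escape = promoter_cme(
      c("empty", "closed", "open"),
      matrix(c(0, kP_on, 0,
               kP_off, 0, k_O,
               0, 0, 0), 3, 3, byrow = TRUE,
             dimnames = rep(list(c("empty", "closed", "open")), 2)),
      list(open = list(type = "single", rate = r, to = "empty"))),
    telegraph = promoter_cme(
      c("inactive", "active"),
      matrix(c(0, k_inact, k_act, 0), 2, 2,
             dimnames = rep(list(c("inactive", "active")), 2)),
      list(active = list(type = "single", rate = r))),
    bursty = promoter_cme(
      "promoter", matrix(0, 1, 1),
      list(promoter = list(type = "burst", rate = k_i, b = b)))
  )
}

#' Add a repressor-bound state to a promoter model
#'
#' Appends a transcriptionally silent repressor-bound state exchanging with a
#' single repressor-free state at rates `k_on` (binding) and `k_off`
#' (unbinding), the structure shared by every simple-repression model here.
#'
#' @param model A [promoter_cme()] model without a repressor state.
#' @param k_on,k_off Repressor binding and unbinding rates (units of the mRNA
#'   degradation rate), both > 0.
#' @param from Name of the repressor-free state the repressor binds from;
#'   defaults to the first state (the empty/only state in the presets).
#' @return A [promoter_cme()] model with `repressor_state` flagged.
#' @export
#' @examples
#' add_repressor(promoter_model("bursty", k_i = 2, b = 3), k_on = 2, k_off = 1)
add_repressor <- function(model, k_on, k_off, from = model$states[1]) {
  stopifnot(inherits(model, "promoter_cme"), k_on > 0, k_off > 0)
  if (!is.null(model$repressor_state)) {
    stop("model already has a repressor-bound state")
  }
  if (!from %in% model$states) stop("unknown state: ", from)
  states <- c(model$states, "repressed")
  S <- length(states)
  Q <- matrix(0, S, S, dimnames = list(states, states))
  Q[seq_len(S - 1), seq_len(S - 1)] <- model$switch_rates
  Q[from, "repressed"] <- k_on
  Q["repressed", from] <- k_off
  prod <- model$production
  prod$repressed <- NULL
  promoter_cme(states, Q, prod, repressor_state = "repressed")
}

# remove one promoter state (used to form the unregulated counterpart)
drop_state <- function(model, state) {
  idx <- if (is.character(state)) match(state, model$states) else state
  stopifnot(!is.na(idx), length(model$states) > 1)
  keep <- setdiff(seq_along(model$states), idx)
  promoter_cme(model$states[keep],
               model$switch_rates[keep, keep, drop = FALSE],
               model$production[keep])
}

#' Build the truncated CME generator
#'
#' Assembles the infinitesimal generator of the joint (promoter state, mRNA
#' count) Markov chain on counts `0..m_max` as a sparse matrix `G` with
#' `G[i, j]` the rate of the transition i -> j and `diag(G) = -rowSums`.
#' Burst production enters as jump terms weighted by the geometric burst-size
#' distribution; bursts that would exceed `m_max` are suppressed (together
#' with their diagonal contribution), so the truncated generator is a proper
#' conservative rate matrix and truncation error is surfaced through the tail
#' mass of the solved steady state rather than through probability leakage.
#'
#' @param model A [promoter_cme()] model.
#' @param m_max Largest mRNA copy number retained (>= 1).
#' @return A sparse `dgCMatrix` of dimension `S * (m_max + 1)` where `S` is
#'   the number of promoter states; row/column order is state-major within
#'   each count level (state varies fastest).
#' @export
build_generator <- function(model, m_max) {
  stopifnot(inherits(model, "promoter_cme"), m_max >= 1)
  S <- length(model$states)
  M <- m_max + 1L                        # count levels 0..m_max
  idx <- function(s, m) s + S * m        # m is 0-based
  ii <- list(); jj <- list(); xx <- list()
  push <- function(i, j, x) {
    k <- length(ii) + 1L
    ii[[k]] <<- i; jj[[k]] <<- j; xx[[k]] <<- x
  }
  ms <- 0:m_max
  # degradation: (s, m) -> (s, m-1) at rate m
  for (s in seq_len(S)) {
    m <- 1:m_max
    push(idx(s, m), idx(s, m - 1), m)
  }
  # promoter switching at fixed m
  sw <- which(model$switch_rates > 0, arr.ind = TRUE)
  if (nrow(sw)) {
    for (k in seq_len(nrow(sw))) {
      push(idx(sw[k, 1], ms), idx(sw[k, 2], ms),
           rep(model$switch_rates[sw[k, 1], sw[k, 2]], M))
    }
  }
  # production
  for (s in seq_len(S)) {
    p <- model$production[[s]]
    if (is.null(p) || p$rate == 0) next
    if (p$type == "single") {
      to <- match(p$to, model$states)
      m <- 0:(m_max - 1)
      push(idx(s, m), idx(to, m + 1), rep(p$rate, m_max))
    } else {
      prob <- 1 / (1 + p$b)
      n_cut <- stats::qgeom(1e-16, prob, lower.tail = FALSE) + 1L
      for (m in 0:(m_max - 1)) {
        n <- 1:min(m_max - m, n_cut)
        push(rep(idx(s, m), length(n)), idx(s, m + n),
             p$rate * stats::dgeom(n, prob))
      }
    }
  }
  G <- Matrix::sparseMatrix(
    i = unlist(ii), j = unlist(jj), x = unlist(xx),
    dims = c(S * M, S * M))
  Matrix::diag(G) <- Matrix::diag(G) - Matrix::rowSums(G)
  G
}

#' Steady state of the joint (promoter state, mRNA count) distribution
#'
#' Solves the stationary linear system of the truncated generator, enlarging
#' the truncation until the probability mass in the top 5% of retained count
#' levels falls below `tail_tol`. The solve is a deterministic sparse LU
#' factorization with the normalization constraint appended; no iterative
#' randomness is involved.
#'
#' @param model A [promoter_cme()] model.
#' @param tail_tol Tolerance on the tail mass (default 1e-10).
#' @param m_max Optional starting truncation; by default a moment-based
#'   pre-estimate (mean + 10 sd of the most productive state) is used.
#' @param m_max_limit Hard cap on the truncation (default 2^14); exceeding it
#'   raises an error reporting the achieved tail mass.
#' @return An object of class `cme_steady_state`: a list with `joint` (matrix
#'   of probabilities, states x counts), `marginal` (mRNA pmf), `m_max`, and
#'   `tail_mass`.
#' @export
#' @examples
#' ss <- steady_state_joint(promoter_model("poisson", r = 10))
#' pmf_moments(marginal_mrna(ss))
steady_state_joint <- function(model, tail_tol = 1e-10, m_max = NULL,
                               m_max_limit = 2^14) {
  stopifnot(inherits(model, "promoter_cme"))
  if (is.null(m_max)) {
    mu <- 1; bmax <- 1
    for (p in model$production) {
      if (is.null(p)) next
      if (p$type == "single") mu <- max(mu, p$rate)
      else { mu <- max(mu, p$rate * p$b); bmax <- max(bmax, p$b) }
    }
    m_max <- ceiling(mu + 10 * sqrt(mu * (1 + bmax))) + 20
  }
  S <- length(model$states)
  repeat {
    G <- build_generator(model, m_max)
    n <- nrow(G)
    A <- Matrix::t(G)
    A[n, ] <- 1                          # normalization row
    rhs <- c(rep(0, n - 1), 1)
    pi_vec <- as.numeric(Matrix::solve(A, rhs))
    pi_vec[pi_vec < 0] <- 0
    pi_vec <- pi_vec / sum(pi_vec)
    joint <- matrix(pi_vec, nrow = S,
                    dimnames = list(model$states, NULL))
    marginal <- colSums(joint)
    tail_n <- max(2L, ceiling(0.05 * (m_max + 1)))
    tail_mass <- sum(marginal[(m_max + 2 - tail_n):(m_max + 1)])
    if (tail_mass < tail_tol) {
      return(structure(
        list(joint = joint, marginal = marginal, m_max = m_max,
             tail_mass = tail_mass, model = model),
        class = "cme_steady_state"))
    }
    if (2 * m_max > m_max_limit) {
      stop(sprintf(
        "steady state not resolved within m_max = %d (tail mass %.3e > %.1e)",
        m_max, tail_mass, tail_tol))
    }
    m_max <- 2 * m_max
  }
}

#' @export
print.cme_steady_state <- function(x, ...) {
  mom <- pmf_moments(x$marginal)
  cat(sprintf(
    "<cme_steady_state> %d state(s), m_max = %d, tail mass %.2e\n",
    nrow(x$joint), x$m_max, x$tail_mass))
  cat(sprintf("  mRNA mean %.4g, Fano %.4g\n", mom$mean, mom$fano))
  invisible(x)
}

#' Marginal mRNA distribution of a joint steady state
#'
#' @param joint A `cme_steady_state` object from [steady_state_joint()].
#' @return Numeric pmf over counts `0..m_max`, normalized to 1.
#' @export
marginal_mrna <- function(joint) {
  stopifnot(inherits(joint, "cme_steady_state"))
  m <- joint$marginal
  m / sum(m)
}

#' Moments of a discrete pmf over counts 0, 1, 2, ...
#'
#' @param pmf Numeric vector of probabilities for counts `0..length(pmf)-1`;
#'   must be nonnegative and sum to 1 (within 1e-6).
#' @return List with `mean`, `variance` and `fano` (variance/mean). The Fano
#'   factor of a distribution with zero mean is undefined and returned as
#'   `NA` with a warning.
#' @export
pmf_moments <- function(pmf) {
  stopifnot(all(pmf >= 0))
  if (abs(sum(pmf) - 1) > 1e-6) stop("pmf is not normalized")
  m <- seq_along(pmf) - 1
  mu <- sum(m * pmf)
  v <- sum((m - mu)^2 * pmf)
  if (mu == 0) {
    warning("zero-mean distribution: Fano factor undefined")
    return(list(mean = 0, variance = v, fano = NA_real_))
  }
  list(mean = mu, variance = v, fano = v / mu)
}

#' Closed-form Fano factor of the telegraph (two-state) promoter
#'
#' For the active/inactive two-state promoter with activation rate `k_act`
#' (inactive -> active), inactivation rate `k_inact`, initiation rate `r`
#' while active, and unit degradation rate:
#' \deqn{\nu = 1 + \frac{r\,k^-}{(k^+ + k^- + 1)(k^+ + k^-)},}
#' which is strictly greater than 1 — the two-state promoter is always
#' super-Poissonian. In the bursty limit (`k_inact`, `r` large at fixed
#' `b = r / k_inact`) it tends to `1 + b`.
#'
#' @param r Initiation rate while active (units of degradation rate).
#' @param k_act Activation rate k+ (inactive -> active).
#' @param k_inact Inactivation rate k- (active -> inactive).
#' @return The Fano factor (> 1).
#' @export
fano_two_state_closed_form <- function(r, k_act, k_inact) {
  if (any(r <= 0) || any(k_act <= 0) || any(k_inact <= 0)) {
    stop("all rates must be strictly positive")
  }
  ks <- k_act + k_inact
  1 + r * k_inact / ((ks + 1) * ks)
}
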