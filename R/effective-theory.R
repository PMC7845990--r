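#' Effective repressor free energy from thermodynamic parameters
#'
#' For a promoter regulated by a repressor present at `R` copies that can also
#' bind any of `N_NS` non-specific genomic sites with relative binding energy
#' `eps_R` (in units of kT; favorable binding is negative), the repressor's
#' contribution to the fold-change collapses into a single effective free
#' energy \deqn{\Delta F_R = \epsilon_R - \log(R / N_{NS}).}
#'
#' All energies in this package are carried in kT units, so the inverse
#' temperature never appears as a runtime quantity.
#'
#' @param R Repressor copy number per cell (must be > 0; an unregulated
#'   promoter has no defined repressor free energy).
#' @param eps_R Repressor-operator binding energy in kT units.
#' @param N_NS Number of non-specific binding sites (default the E. coli
#'   genome length, 4.6e6).
#' @return The effective repressor free energy in kT units.
#' @seealso [delta_F_from_rates()], [master_fold_change()]
#' @export
#' @examples
#' delta_F_from_thermo(R = 100, eps_R = -13.9)
delta_F_from_thermo <- function(R, eps_R, N_NS = 4.6e6) {
  stopifnot(is.finite(eps_R), N_NS > 0, R >= 0)
  if (any(R == 0)) {
    stop(structure(
      class = c("burstrep_unregulated", "error", "condition"),
      list(message = paste(
        "R = 0: promoter is unregulated; fold-change is 1 by definition",
        "and the repressor free energy diverges."),
        call = sys.call(-1))))
  }
  eps_R - log(R / N_NS)
}

#' Effective repressor free energy from kinetic rates
#'
#' In the kinetic picture the same effective free energy is minus the log
#' ratio of the repressor binding and unbinding rates:
#' \deqn{\Delta F_R = -\log(k_{on} / k_{off}).}
#' Both rates are nondimensionalized by the mRNA degradation rate.
#'
#' @param k_on Repressor binding rate (units of the mRNA degradation rate).
#' @param k_off Repressor unbinding rate (same units).
#' @return Effective repressor free energy in kT units.
#' @export
#' @examples
#' delta_F_from_rates(k_on = 9, k_off = 1)
delta_F_from_rates <- function(k_on, k_off) {
  if (any(k_on <= 0) || any(k_off <= 0)) {
    stop("repressor rates must be strictly positive")
  }
  -log(k_on / k_off)
}

#' Master fold-change curve
#'
#' Every simple-repression model considered in this package, thermodynamic or
#' kinetic, predicts a fold-change in mean expression of Fermi-function form
#' \deqn{FC = (1 + \exp(-\Delta F_R + \log\rho))^{-1},}
#' where `delta_F_R` captures the repressor and `rho` coarse-grains every
#' repressor-free promoter state.
#'
#' @param delta_F_R Effective repressor free energy (kT units).
#' @param rho Coarse-graining factor, strictly positive; 1 when the model has
#'   a single repressor-free state.
#' @return Fold-change in (0, 1).
#' @export
#' @examples
#' master_fold_change(delta_F_R = 0, rho = 1) # 0.5
master_fold_change <- function(delta_F_R, rho = 1) {
  if (any(rho <= 0)) stop("rho must be strictly positive")
  1 / (1 + exp(-delta_F_R + log(rho)))
}

#' Fold-change of the two-state thermodynamic model
#'
#' The simplest occupancy model: the operator is either empty (transcribing)
#' or repressor-bound. \deqn{FC = (1 + (R/N_{NS}) e^{-\epsilon_R})^{-1}.}
#' `R = 0` returns 1 (unregulated).
#'
#' @inheritParams delta_F_from_thermo
#' @return Fold-change in (0, 1].
#' @export
fold_change_thermo_two_state <- function(R, eps_R, N_NS = 4.6e6) {
  stopifnot(R >= 0, N_NS > 0, is.finite(eps_R))
  1 / (1 + (R / N_NS) * exp(-eps_R))
}

#' Fold-change of the three-state thermodynamic model
#'
#' Adds an explicit RNAP-bound state with `P` polymerases binding at energy
#' `eps_P`, which enters only through the coarse-graining factor
#' \deqn{\rho = 1 + (P/N_{NS}) e^{-\epsilon_P}.}
#' With `P = 0` this reduces to the two-state model.
#'
#' @inheritParams delta_F_from_thermo
#' @param P RNAP copy number per cell (>= 0).
#' @param eps_P RNAP-promoter binding energy in kT units.
#' @return Fold-change in (0, 1].
#' @export
fold_change_thermo_three_state <- function(R, eps_R, P, eps_P, N_NS = 4.6e6) {
  stopifnot(R >= 0, P >= 0, N_NS > 0, is.finite(eps_R), is.finite(eps_P))
  rho <- 1 + (P / N_NS) * exp(-eps_P)
  if (any(R == 0)) {
    fc <- rep_len(1, max(length(R), length(rho)))
    reg <- R > 0
    fc[reg] <- master_fold_change(delta_F_from_thermo(R[reg], eps_R, N_NS), rho)
    return(fc)
  }
  master_fold_change(delta_F_from_thermo(R, eps_R, N_NS), rho)
}

#' Coarse-graining factor of the three-state thermodynamic model
#'
#' @inheritParams fold_change_thermo_three_state
#' @return rho >= 1.
#' @export
rho_thermo_three_state <- function(P, eps_P, N_NS = 4.6e6) {
  stopifnot(P >= 0, N_NS > 0)
  1 + (P / N_NS) * exp(-eps_P)
}

#' Fold-change from repressor kinetic rates
#'
#' \deqn{FC = (1 + (k_{on}/k_{off})\,\rho)^{-1}.}
#'
#' @inheritParams delta_F_from_rates
#' @param rho Coarse-graining factor of the repressor-free promoter states.
#' @return Fold-change in (0, 1).
#' @export
fold_change_from_rates <- function(k_on, k_off, rho = 1) {
  master_fold_change(delta_F_from_rates(k_on, k_off), rho)
}

#' Recover the coarse-graining factor rho numerically from a kinetic model
#'
#' Computes the fold-change of a promoter model carrying a repressor-bound
#' state by solving the chemical master equation for mean mRNA with and
#' without the repressor, then inverts the master curve
#' \eqn{FC = (1 + (k_{on}/k_{off})\rho)^{-1}} for rho. The detailed-balance
#' argument behind the master curve guarantees that the recovered rho does not
#' depend on the repressor rates; this function is the numerical embodiment of
#' that statement and is validated as such in the test-suite.
#'
#' @param model A [promoter_cme()] model that contains a repressor-bound
#'   state (see [add_repressor()]). The repressor state must exchange with
#'   exactly one repressor-free state.
#' @param tail_tol Tail-mass tolerance passed to [steady_state_joint()].
#' @return The scalar coarse-graining factor rho.
#' @export
effective_rho_numeric <- function(model, tail_tol = 1e-12) {
  stopifnot(inherits(model, "promoter_cme"))
  rs <- model$repressor_state
  if (is.null(rs)) {
    stop("model has no repressor-bound state flagged; see add_repressor()")
  }
  Q <- model$switch_rates
  into <- which(Q[, rs] > 0)
  outof <- which(Q[rs, ] > 0)
  if (length(into) != 1L || length(outof) != 1L || into != outof) {
    stop(paste("repressor-bound state must exchange with exactly one",
               "repressor-free state; model violates the single-path",
               "structural assumption"))
  }
  k_on <- Q[into, rs]
  k_off <- Q[rs, into]
  free <- drop_state(model, rs)
  m_reg <- pmf_moments(marginal_mrna(steady_state_joint(model, tail_tol)))$mean
  m_con <- pmf_moments(marginal_mrna(steady_state_joint(free, tail_tol)))$mean
  fc <- m_reg / m_con
  (1 / fc - 1) * k_off / k_on
}
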