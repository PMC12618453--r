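# The free energy is a sum over 8 invariant rows; within each row the four
# nodes act on the corrected invariant u (I1-3, I2-3, I4*-1, I8 raw):
#   lin * u   +  exp1_out*[exp(exp1_in*u) - 1]
# + quad * u^2 + exp2_out*[exp(exp2_in*u^2) - 1]
# Directional rows (I4f, I4s, I4n) are gated by the tension-compression
# switch evaluated on the UNdispersed squared stretch.

.EXP_GUARD <- 50

#' Tension-compression switch
#'
#' Directional energy rows are active only when the corresponding structural
#' direction is under tension, i.e. when the undispersed squared stretch
#' satisfies \code{I4i >= 1} (inclusive at the boundary, where the row's
#' contribution is zero anyway). The switch prevents non-physiological
#' compressive stiffening.
#'
#' @param inv An \code{\link{compute_invariants}} result.
#' @return Named logical vector \code{c(f=, s=, n=)}.
#' @export
tension_switch <- function(inv) {
  c(f = inv$I4f >= 1, s = inv$I4s >= 1, n = inv$I4n >= 1)
}

# corrected network inputs u_k for the 8 rows, from an invariant_set + kappas
.corrected_inputs <- function(inv, kappas) {
  st <- disperse_invariants(inv, kappas)
  c(I1 = inv$I1 - 3, I2 = inv$I2 - 3,
    I4f = unname(st["I4f_star"]) - 1, I4s = unname(st["I4s_star"]) - 1,
    I4n = unname(st["I4n_star"]) - 1,
    I8fs = inv$I8fs, I8fn = inv$I8fn, I8sn = inv$I8sn)
}

.row_gate <- function(flags) {
  c(1, 1, as.numeric(flags[["f"]]), as.numeric(flags[["s"]]),
    as.numeric(flags[["n"]]), 1, 1, 1)
}

.check_exp_guard <- function(W, u) {
  a1 <- W[, "exp1_in"] * u
  a2 <- W[, "exp2_in"] * u^2
  bad <- which(a1 > .EXP_GUARD | a2 > .EXP_GUARD)
  if (length(bad))
    stop("exponent overflow guard (argument > ", .EXP_GUARD,
         ") in invariant row(s): ", paste(INVARIANT_NAMES[bad], collapse = ", "))
}

#' Free energy of the 32-term dispersed orthotropic model
#'
#' Evaluates \eqn{\psi} (kPa) at a deformation state. The energy vanishes
#' identically at \code{F = I} for any admissible weights because every term
#' is built from corrected invariants that are zero at rest.
#'
#' @param inv An \code{\link{compute_invariants}} result.
#' @param weights A \code{\link{cann_weights}} object.
#' @param kappas A \code{\link{dispersion_params}} triple.
#' @return Scalar energy in kPa.
#' @export
free_energy <- function(inv, weights, kappas = dispersion_params()) {
  W <- unclass(weights)
  u <- .corrected_inputs(inv, kappas)
  gate <- .row_gate(tension_switch(inv))
  .check_exp_guard(W, u)
  terms <- W[, "lin"] * u +
    W[, "exp1_out"] * expm1(W[, "exp1_in"] * u) +
    W[, "quad"] * u^2 +
    W[, "exp2_out"] * expm1(W[, "exp2_in"] * u^2)
  sum(gate * terms)
}

#' Analytic energy gradients with respect to the eight input invariants
#'
#' Closed-form partial derivatives \eqn{\partial\psi/\partial I_k} of every
#' active term; switched-off directional rows return zero. These are the
#' quantities that enter all protocol stress formulas.
#'
#' @inheritParams free_energy
#' @return Named numeric vector over
#'   \code{c("I1","I2","I4f","I4s","I4n","I8fs","I8fn","I8sn")}, where the
#'   directional entries are derivatives with respect to the dispersed
#'   invariants \code{I4i*}.
#' @export
energy_gradients <- function(inv, weights, kappas = dispersion_params()) {
  W <- unclass(weights)
  u <- .corrected_inputs(inv, kappas)
  gate <- .row_gate(tension_switch(inv))
  .check_exp_guard(W, u)
  d <- W[, "lin"] +
    W[, "exp1_in"] * W[, "exp1_out"] * exp(W[, "exp1_in"] * u) +
    2 * W[, "quad"] * u +
    2 * W[, "exp2_in"] * W[, "exp2_out"] * u * exp(W[, "exp2_in"] * u^2)
  stats::setNames(gate * d, INVARIANT_NAMES)
}

#' Per-term energy contributions
#'
#' Energy of each of the 32 nodes separately (kPa), in node order; used by
#' the active-term reporting layer.
#'
#' @inheritParams free_energy
#' @return Numeric vector of length 32 named by node labels.
#' @keywords internal
.term_energies <- function(inv, weights, kappas = dispersion_params()) {
  W <- unclass(weights)
  u <- .corrected_inputs(inv, kappas)
  gate <- .row_gate(tension_switch(inv))
  .check_exp_guard(W, u)
  out <- numeric(32)
  labs <- character(32)
  for (m in 1:8) {
    node <- 4L * (m - 1L)
    vals <- c(W[m, "lin"] * u[m],
              W[m, "exp1_out"] * expm1(W[m, "exp1_in"] * u[m]),
              W[m, "quad"] * u[m]^2,
              W[m, "exp2_out"] * expm1(W[m, "exp2_in"] * u[m]^2))
    out[node + 1:4] <- gate[m] * vals
    labs[node + 1:4] <- paste0("node", node + 1:4)
  }
  stats::setNames(out, labs)
}
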