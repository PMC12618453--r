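# Training design arrays.
#
# Every protocol stress channel is linear in the eight energy gradients
# dpsi/dI_k with deformation-dependent coefficients, and both those
# coefficients and the corrected network inputs u_k are affine in the
# dispersion parameters:
#   sigma(point) = sum_k C_k(point; kappa) * dpsi/dI_k(u_k(point; kappa))
#   C = C0 + kappa_f Cf + kappa_s Cs + kappa_n Cn   (n x 8 each)
#   U = U0 + kappa_f Uf + kappa_s Us + kappa_n Un
# Tension-compression switch flags (evaluated on the undispersed I4, hence
# kappa-independent) are folded into the C arrays. Precomputing these eight
# arrays makes every loss/gradient evaluation a handful of elementwise
# matrix operations, for fixed as well as trainable kappa.

.I4_COLS <- 3:5

.build_design <- function(dataset) {
  n <- nrow(dataset)
  zero <- function() matrix(0, n, 8, dimnames = list(NULL, INVARIANT_NAMES))
  C0 <- zero(); Cf <- zero(); Cs <- zero(); Cn <- zero()
  U0 <- zero(); Uf <- zero(); Us <- zero(); Un <- zero()
  for (r in seq_len(n)) {
    row <- dataset[r, ]
    if (startsWith(row$protocol, "shear_")) {
      mode <- row$mode_or_ratio
      g <- row$strain_or_stretch_f
      inv <- .shear_invariants(mode, g)
      ax <- .mode_axes(mode)
      m <- setdiff(1:3, ax)
      C0[r, c("I1", "I2")] <- 2 * g
      C0[r, .I4_COLS[ax[["i"]]]] <- 2 * g
      i8col <- paste0("I8", c(fs = "fs", sf = "fs", fn = "fn", nf = "fn",
                              sn = "sn", ns = "sn")[[mode]])
      C0[r, i8col] <- 1
      dC <- c(0, 0, 0)
      dC[ax[["i"]]] <- -4 * g
      dC[ax[["j"]]] <- 2 * g
      dC[m] <- 2 * g
      Cf[r, .I4_COLS[1]] <- dC[1]
      Cs[r, .I4_COLS[2]] <- dC[2]
      Cn[r, .I4_COLS[3]] <- dC[3]
    } else {
      lf <- row$strain_or_stretch_f; ln <- row$stretch_n; ls <- 1 / (lf * ln)
      inv <- .biaxial_invariants(lf, ln)
      fl <- tension_switch(inv)
      ff <- identical(row$channel, "sigma_ff")
      la <- if (ff) lf else ln   # stretch of the measured direction
      lo <- if (ff) ln else lf   # the other in-plane stretch
      C0[r, "I1"] <- 2 * (la^2 - ls^2)
      C0[r, "I2"] <- 2 * (la^2 - ls^2) * lo^2
      acol <- if (ff) "I4f" else "I4n"   # measured direction
      ocol <- if (ff) "I4n" else "I4f"
      afl <- if (ff) fl[["f"]] else fl[["n"]]
      ofl <- if (ff) fl[["n"]] else fl[["f"]]
      C0[r, acol] <- 2 * la^2 * afl
      C0[r, "I4s"] <- -2 * ls^2 * fl[["s"]]
      aC <- (-4 * la^2 - 2 * ls^2) * afl       # d/dkappa of measured dir col
      oC <- 2 * (la^2 - ls^2) * ofl            # d/dkappa of other dir col
      sC <- (2 * la^2 + 4 * ls^2) * fl[["s"]]
      if (ff) {
        Cf[r, "I4f"] <- aC; Cn[r, "I4n"] <- oC
      } else {
        Cn[r, "I4n"] <- aC; Cf[r, "I4f"] <- oC
      }
      Cs[r, "I4s"] <- sC
    }
    U0[r, ] <- c(inv$I1 - 3, inv$I2 - 3, inv$I4f - 1, inv$I4s - 1,
                 inv$I4n - 1, inv$I8fs, inv$I8fn, inv$I8sn)
    Uf[r, "I4f"] <- inv$I1 - 3 * inv$I4f
    Us[r, "I4s"] <- inv$I1 - 3 * inv$I4s
    Un[r, "I4n"] <- inv$I1 - 3 * inv$I4n
  }
  # each row is one measured stress value; a shear state's single row stands
  # for both symmetric tensor components (weight 2), a biaxial state owns
  # two rows (sigma_ff, sigma_nn) of weight 1. n_states counts deformation
  # states, the unit the loss averages over.
  shear <- startsWith(dataset$protocol, "shear_")
  rowW <- ifelse(shear, 2, 1)
  n_states <- sum(shear) + sum(!shear) / 2
  list(C0 = C0, Cf = Cf, Cs = Cs, Cn = Cn,
       U0 = U0, Uf = Uf, Us = Us, Un = Un,
       y = dataset$stress_kPa, rowW = rowW, n_states = n_states,
       channel = .channel_id(dataset))
}

.design_CU <- function(design, kappas) {
  k <- unclass(kappas)
  list(C = design$C0 + k[["f"]] * design$Cf + k[["s"]] * design$Cs +
         k[["n"]] * design$Cn,
       U = design$U0 + k[["f"]] * design$Uf + k[["s"]] * design$Us +
         k[["n"]] * design$Un)
}

# dpsi/dI_k per point (n x 8) from corrected inputs U and weights
.design_dpsi <- function(U, W) {
  lin <- W[, "lin"]; a1 <- W[, "exp1_in"]; b1 <- W[, "exp1_out"]
  quad <- W[, "quad"]; a2 <- W[, "exp2_in"]; b2 <- W[, "exp2_out"]
  E1 <- exp(sweep(U, 2, a1, "*"))
  E2 <- exp(sweep(U^2, 2, a2, "*"))
  sweep(E1, 2, a1 * b1, "*") +
    sweep(U * E2, 2, 2 * a2 * b2, "*") +
    sweep(2 * U, 2, quad, "*") +
    matrix(lin, nrow(U), 8, byrow = TRUE)
}

# model-predicted stresses for all rows of a design, pure R (test oracle for
# the compiled trainer and the closed-form route)
.design_predict <- function(design, weights, kappas) {
  cu <- .design_CU(design, kappas)
  rowSums(cu$C * .design_dpsi(cu$U, unclass(weights)))
}

#' Training loss
#'
#' \deqn{L = \frac{1}{n_{data}} \sum_i \|\sigma_{model}(F_i) -
#'   \hat\sigma_i\|_2^2 + \alpha \|w\|_1.}
#' Each data point \code{i} is one deformation state and the norm runs over
#' its measured Cauchy stress components: a shear state contributes both
#' symmetric components \code{sigma_ij = sigma_ji} (its residual counts
#' twice), a biaxial state contributes \code{sigma_ff} and \code{sigma_nn}.
#' The L1 penalty acts on the stiffness-carrying weights: the collapsed
#' effective weights of the identity nodes and the outer weights of the
#' exponential nodes. The inner exponents are dimensionless shape
#' parameters and are not penalized, and neither are the dispersion
#' parameters.
#'
#' @param weights A \code{\link{cann_weights}} object.
#' @param kappas A \code{\link{dispersion_params}} triple.
#' @param dataset A \code{cann_dataset}.
#' @param alpha L1 regularization weight (default 0.01).
#' @return Scalar loss (kPa^2).
#' @export
loss <- function(weights, kappas, dataset, alpha = 0.01) {
  if (nrow(dataset) == 0L) stop("empty dataset")
  design <- .build_design(dataset)
  pred <- .design_predict(design, weights, kappas)
  W <- unclass(weights)
  sum(design$rowW * (pred - design$y)^2) / design$n_states +
    alpha * sum(W[, c("lin", "exp1_out", "quad", "exp2_out")])
}

#' Predicted stresses for every row of a dataset
#'
#' @param weights,kappas Model.
#' @param dataset A \code{cann_dataset}.
#' @return Numeric vector of model stresses (kPa), aligned with the rows.
#' @export
predict_stresses <- function(weights, kappas, dataset) {
  .design_predict(.build_design(dataset), weights, kappas)
}
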