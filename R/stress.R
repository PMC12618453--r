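#' General Cauchy stress of the incompressible dispersed model
#'
#' \deqn{\sigma = \sum_k \frac{\partial\psi}{\partial I_k}
#'   \frac{\partial I_k}{\partial F} F^T - p I,}
#' with the invariant derivatives
#' \code{dI1/dF = 2F}, \code{dI2/dF = 2(I1 F - F C)},
#' \code{dI4i*/dF = 2 F H_i} (generalized structure tensor push-forward),
#' \code{dI8ij/dF = F (i0 \%o\% j0 + j0 \%o\% i0)}.
#'
#' @param F 3x3 deformation gradient with \code{det(F) = 1}.
#' @param weights A \code{\link{cann_weights}} object.
#' @param kappas A \code{\link{dispersion_params}} triple.
#' @param p Hydrostatic pressure (kPa). The incompressibility multiplier is
#'   not determined by F; supply the value implied by the boundary
#'   conditions of the protocol at hand (e.g. from a plane-stress
#'   condition).
#' @param frame A \code{\link{material_frame}}.
#' @return Symmetric 3x3 Cauchy stress matrix (kPa), with rows/columns in
#'   frame coordinates (f, s, n).
#' @export
cauchy_stress_general <- function(F, weights, kappas = dispersion_params(),
                                  p = 0, frame = material_frame()) {
  inv <- compute_invariants(F, frame)
  d <- energy_gradients(inv, weights, kappas)
  M <- unclass(frame)
  f0 <- M[, 1]; s0 <- M[, 2]; n0 <- M[, 3]
  b <- tcrossprod(F)                     # F F^T
  Hf <- structure_tensor(kappas[["f"]], f0)
  Hs <- structure_tensor(kappas[["s"]], s0)
  Hn <- structure_tensor(kappas[["n"]], n0)
  push <- function(A) F %*% A %*% t(F)
  sig <- 2 * d[["I1"]] * b +
    2 * d[["I2"]] * (inv$I1 * b - b %*% b) +
    2 * d[["I4f"]] * push(Hf) +
    2 * d[["I4s"]] * push(Hs) +
    2 * d[["I4n"]] * push(Hn) +
    d[["I8fs"]] * push(f0 %o% s0 + s0 %o% f0) +
    d[["I8fn"]] * push(f0 %o% n0 + n0 %o% f0) +
    d[["I8sn"]] * push(s0 %o% n0 + n0 %o% s0)
  # express in frame coordinates so [1,1] is the ff component
  sig <- t(M) %*% sig %*% M - p * diag(3)
  dimnames(sig) <- list(c("f", "s", "n"), c("f", "s", "n"))
  sig
}

.shear_invariants <- function(mode, gamma) {
  ax <- .mode_axes(mode)
  I4 <- c(1, 1, 1)
  I4[ax[["i"]]] <- 1 + gamma^2
  I8 <- c(fs = 0, fn = 0, sn = 0)
  # canonical pair order: fs, fn, sn
  key <- c(fs = "fs", sf = "fs", fn = "fn", nf = "fn",
           sn = "sn", ns = "sn")[[mode]]
  I8[key] <- gamma
  structure(list(I1 = 3 + gamma^2, I2 = 3 + gamma^2, I3 = 1,
                 I4f = I4[1], I4s = I4[2], I4n = I4[3],
                 I8fs = unname(I8["fs"]), I8fn = unname(I8["fn"]),
                 I8sn = unname(I8["sn"])),
            class = "invariant_set")
}

#' Closed-form shear stress for the six triaxial shear modes
#'
#' For simple shear in the ij-plane along j at strain gamma, the only
#' measured stress component is
#' \deqn{\sigma_{ij} = 2\gamma\Big[\frac{\partial\psi}{\partial I_1} +
#'   \frac{\partial\psi}{\partial I_2} +
#'   (1-2\kappa_i)\frac{\partial\psi}{\partial I_{4i}^*} +
#'   \kappa_j\frac{\partial\psi}{\partial I_{4j}^*} +
#'   \kappa_m\frac{\partial\psi}{\partial I_{4m}^*}\Big] +
#'   \frac{\partial\psi}{\partial I_{8ij}},}
#' where m is the remaining third direction. The form follows from the
#' general stress and needs no pressure (it is an off-diagonal component);
#' it is validated against \code{\link{cauchy_stress_general}} and a
#' finite-difference oracle in the test suite. With all kappas zero only the
#' stretched direction i contributes among the fourth invariants.
#'
#' @param mode One of \code{"fs","fn","sf","sn","nf","ns"}.
#' @param gamma Shear strain(s), vectorized.
#' @param weights A \code{\link{cann_weights}} object.
#' @param kappas A \code{\link{dispersion_params}} triple.
#' @return Numeric vector \code{sigma_ij} (kPa), one per gamma.
#' @export
shear_stress <- function(mode, gamma, weights, kappas = dispersion_params()) {
  ax <- .mode_axes(mode)
  ki <- kappas[[ax[["i"]]]]
  kj <- kappas[[ax[["j"]]]]
  m <- setdiff(1:3, ax)
  km <- kappas[[m]]
  d4names <- c("I4f", "I4s", "I4n")
  i8name <- paste0("I8", c(fs = "fs", sf = "fs", fn = "fn", nf = "fn",
                           sn = "sn", ns = "sn")[[mode]])
  vapply(gamma, function(g) {
    inv <- .shear_invariants(mode, g)
    d <- energy_gradients(inv, weights, kappas)
    2 * g * (d[["I1"]] + d[["I2"]] + (1 - 2 * ki) * d[[d4names[ax[["i"]]]]] +
               kj * d[[d4names[ax[["j"]]]]] + km * d[[d4names[m]]]) +
      d[[i8name]]
  }, numeric(1))
}

.biaxial_invariants <- function(lf, ln) {
  ls <- 1 / (lf * ln)
  structure(list(I1 = lf^2 + ls^2 + ln^2,
                 I2 = lf^2 * ls^2 + lf^2 * ln^2 + ls^2 * ln^2,
                 I3 = 1, I4f = lf^2, I4s = ls^2, I4n = ln^2,
                 I8fs = 0, I8fn = 0, I8sn = 0),
            class = "invariant_set")
}

#' Closed-form biaxial extension stresses under plane stress
#'
#' Biaxial stretching along fiber (f) and normal (n) with through-thickness
#' (sheet) plane stress \code{sigma_ss = 0}. With \code{pressure = "exact"}
#' (default) the hydrostatic pressure is solved from the full ss-component
#' of the general stress, including the dispersed anisotropic
#' contributions, so the plane-stress condition holds exactly:
#' \deqn{p = 2\lambda_s^2\frac{\partial\psi}{\partial I_1} +
#'   2\lambda_s^2(\lambda_f^2+\lambda_n^2)\frac{\partial\psi}{\partial I_2}
#'   + 2\lambda_s^2\big[\kappa_f \partial_{4f}\psi +
#'   (1-2\kappa_s)\partial_{4s}\psi + \kappa_n \partial_{4n}\psi\big].}
#' \code{pressure = "truncated"} reproduces a commonly printed truncation
#' that keeps only the isotropic pressure terms and drops the
#' sheet/pressure dispersion couplings; it is provided for comparison
#' studies only.
#'
#' @param lambda_f,lambda_n Stretch vectors (>= 1 in protocols; equal
#'   length or length 1, recycled).
#' @param weights A \code{\link{cann_weights}} object.
#' @param kappas A \code{\link{dispersion_params}} triple.
#' @param pressure \code{"exact"} or \code{"truncated"}.
#' @return Two-column matrix \code{cbind(sigma_ff, sigma_nn)} in kPa.
#' @export
biaxial_stresses <- function(lambda_f, lambda_n, weights,
                             kappas = dispersion_params(),
                             pressure = c("exact", "truncated")) {
  pressure <- match.arg(pressure)
  nl <- max(length(lambda_f), length(lambda_n))
  lambda_f <- rep_len(lambda_f, nl)
  lambda_n <- rep_len(lambda_n, nl)
  kf <- kappas[["f"]]; ks <- kappas[["s"]]; kn <- kappas[["n"]]
  out <- matrix(NA_real_, nl, 2, dimnames = list(NULL, c("sigma_ff", "sigma_nn")))
  for (r in seq_len(nl)) {
    lf <- lambda_f[r]; ln <- lambda_n[r]; ls <- 1 / (lf * ln)
    inv <- .biaxial_invariants(lf, ln)
    d <- energy_gradients(inv, weights, kappas)
    if (pressure == "exact") {
      sff <- 2 * d[["I1"]] * (lf^2 - ls^2) +
        2 * d[["I2"]] * (lf^2 - ls^2) * ln^2 +
        2 * d[["I4f"]] * (lf^2 * (1 - 2 * kf) - ls^2 * kf) +
        2 * d[["I4s"]] * (lf^2 * ks - ls^2 * (1 - 2 * ks)) +
        2 * d[["I4n"]] * (lf^2 - ls^2) * kn
      snn <- 2 * d[["I1"]] * (ln^2 - ls^2) +
        2 * d[["I2"]] * (ln^2 - ls^2) * lf^2 +
        2 * d[["I4f"]] * (ln^2 - ls^2) * kf +
        2 * d[["I4s"]] * (ln^2 * ks - ls^2 * (1 - 2 * ks)) +
        2 * d[["I4n"]] * (ln^2 * (1 - 2 * kn) - ls^2 * kn)
    } else {
      sff <- 2 * d[["I1"]] * (lf^2 - ls^2) +
        2 * d[["I2"]] * (lf^2 - ls^2) * ln^2 +
        2 * lf^2 * (d[["I4f"]] * (1 - 2 * kf) + d[["I4n"]] * kn)
      snn <- 2 * d[["I1"]] * (ln^2 - ls^2) +
        2 * d[["I2"]] * (ln^2 - ls^2) * ln^2 +
        2 * ln^2 * (d[["I4n"]] * (1 - 2 * kn) + d[["I4f"]] * kf)
    }
    out[r, ] <- c(sff, snn)
  }
  out
}
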