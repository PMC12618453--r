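# Shared oracles and fixture builders. Everything is generated in code; the
# finite-difference machinery here is deliberately independent of the
# package's analytic derivative paths.

# random admissible weight matrix; exclude_linear_aniso drops first-power
# I4/I8 nodes, whose derivative does not vanish at rest
random_weights <- function(seed, exclude_linear_aniso = FALSE) {
  set.seed(seed)
  W <- matrix(runif(48, 0.01, 0.8), 8, 6)
  W[, c(2, 5)] <- runif(16, 0.1, 2)  # inner exponents
  if (exclude_linear_aniso) {
    W[3:8, 1] <- 0          # lin nodes of I4/I8 rows
    W[3:8, 2:3] <- 0        # exp-linear pairs of I4/I8 rows
  }
  cann_weights(W)
}

random_kappas <- function(seed) {
  set.seed(seed)
  k <- runif(3, 0, 1 / 3)
  dispersion_params(k[1], k[2], k[3])
}

# psi as a plain function of F (via the package energy), used to build
# finite-difference stress oracles sigma = dpsi/dF . F^T - p I
psi_of_F <- function(F, weights, kappas, frame = material_frame()) {
  free_energy(compute_invariants(F, frame), weights, kappas)
}

fd_cauchy_stress <- function(F, weights, kappas, h = 1e-6,
                             frame = material_frame()) {
  P <- matrix(0, 3, 3)
  for (i in 1:3) {
    for (j in 1:3) {
      Fp <- F; Fp[i, j] <- Fp[i, j] + h
      Fm <- F; Fm[i, j] <- Fm[i, j] - h
      P[i, j] <- (psi_of_F(Fp, weights, kappas, frame) -
                    psi_of_F(Fm, weights, kappas, frame)) / (2 * h)
    }
  }
  M <- unclass(frame)
  t(M) %*% (P %*% t(F)) %*% M
}

# uniformly random rotation matrix (QR of a Gaussian matrix, sign-fixed)
random_rotation <- function(seed) {
  set.seed(seed)
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  Q * sign(diag(qr.R(qr_)))[col(Q)]
}

# protocol deformations used to randomize stress tests
random_protocol_F <- function(seed) {
  set.seed(seed)
  if (runif(1) < 0.5) {
    shear_deformation_gradient(sample(SHEAR_MODES, 1), runif(1, 0.05, 0.5))
  } else {
    biaxial_deformation_gradient(runif(1, 1.01, 1.1), runif(1, 1.01, 1.1))
  }
}

# deformation with every raw I4 strictly away from the switch boundary
# I4 = 1: finite differences across F are only meaningful where the
# tension-compression switch cannot flip (with dispersion the energy jumps
# by kappa*(I1-3) worth of row energy at the boundary)
random_offboundary_F <- function(seed) {
  set.seed(seed)
  repeat {
    F <- biaxial_deformation_gradient(runif(1, 1.02, 1.08),
                                      runif(1, 1.02, 1.08)) %*%
      shear_deformation_gradient(sample(SHEAR_MODES, 1), runif(1, 0.05, 0.4))
    inv <- compute_invariants(F)
    if (min(abs(c(inv$I4f, inv$I4s, inv$I4n) - 1)) > 1e-3) return(F)
  }
}

# quick training configuration for smoke-level discovery tests
quick_config <- function(seed, epochs = 2000, restarts = 1, ...) {
  training_config(seed = seed, max_epochs = epochs,
                  patience = min(epochs - 1L, max(200L, epochs %/% 4L)),
                  restarts = restarts, ...)
}

four_term_generator <- function() myocardium_models()$sheet_normal[["0"]]
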