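#' Log of the imaginary error function
#'
#' \code{erfi(x) = -i * erf(i x) = 2/sqrt(pi) * integral_0^x exp(t^2) dt}.
#' Evaluated on the log scale so that the von Mises normalizer stays finite
#' for concentrations up to b ~ 1e3. For moderate arguments this wraps
#' \code{pracma::erfi}; beyond the overflow point (x ~ 26.6) it switches to
#' the asymptotic expansion
#' \code{erfi(x) ~ exp(x^2) / (x sqrt(pi)) * (1 + 1/(2x^2) + 3/(4x^4) + ...)}.
#'
#' @param x Positive numeric vector.
#' @return \code{log(erfi(x))}.
#' @keywords internal
log_erfi <- function(x) {
  stopifnot(all(x > 0))
  out <- numeric(length(x))
  small <- x <= 25
  if (any(small)) out[small] <- log(pracma::erfi(x[small]))
  if (any(!small)) {
    xl <- x[!small]
    x2 <- xl^2
    series <- 1 + 1 / (2 * x2) + 3 / (4 * x2^2) + 15 / (8 * x2^3)
    out[!small] <- x2 - log(xl * sqrt(pi)) + log(series)
  }
  out
}

#' Pi-periodic von Mises orientation density
#'
#' Axisymmetric orientation density on the unit sphere, centered at polar
#' angle \code{Theta = 0},
#' \deqn{\rho(\Theta) = 4 \sqrt{b/2\pi}\; \exp\{b[\cos(2\Theta)+1]\} /
#'   \mathrm{erfi}(\sqrt{2b}),}
#' normalized so that \code{(1/4pi) * integral_sphere rho domega = 1}. It is
#' antipodally symmetric, \code{rho(Theta) = rho(pi - Theta)}, as required of
#' a fiber orientation density.
#'
#' @param theta Polar angle(s) in \code{[0, pi]}.
#' @param b Concentration parameter (> 0). Large \code{b} concentrates the
#'   density at the mean direction; \code{b -> 0} approaches the isotropic
#'   density \code{rho = 1}.
#' @return Density value(s).
#' @examples
#' von_mises_density(c(0, pi / 4, pi / 2), b = 2)
#' @export
von_mises_density <- function(theta, b) {
  if (!is.numeric(b) || length(b) != 1L || !is.finite(b) || b <= 0)
    stop("concentration b must be a positive finite scalar")
  logrho <- log(4) + 0.5 * log(b / (2 * pi)) +
    b * (cos(2 * theta) + 1) - log_erfi(sqrt(2 * b))
  exp(logrho)
}

#' Dispersion parameter kappa from concentration b
#'
#' \deqn{\kappa(b) = \tfrac14 \int_0^\pi \rho(\Theta) \sin^3\Theta \,
#'   d\Theta,}
#' evaluated by adaptive quadrature. \code{kappa} is the single scalar that
#' the generalized structure tensor retains from the orientation density:
#' \code{kappa -> 1/3} as \code{b -> 0} (isotropic dispersion) and
#' \code{kappa -> 0} as \code{b -> Inf} (perfect alignment); it is strictly
#' decreasing in \code{b}.
#'
#' @param b Concentration parameter(s) (> 0).
#' @param abs.tol Absolute quadrature tolerance.
#' @return Value(s) of kappa in (0, 1/3).
#' @examples
#' kappa_from_b(c(0.01, 1, 100))
#' @export
kappa_from_b <- function(b, abs.tol = 1e-10) {
  vapply(b, function(bi) {
    # integrand is symmetric about pi/2; integrate half and double to keep
    # the concentration peak at an interval endpoint for the subdivision
    q <- stats::integrate(function(th) von_mises_density(th, bi) * sin(th)^3,
                          0, pi / 2, abs.tol = abs.tol / 2,
                          rel.tol = .Machine$double.eps^0.5,
                          subdivisions = 400L)
    if (q$message != "OK")
      stop("kappa quadrature failed for b = ", bi, ": ", q$message)
    2 * q$value / 4
  }, numeric(1))
}

#' Dispersion parameter triple
#'
#' Bundles the fiber, sheet, and normal dispersion parameters. Each must lie
#' in \code{[0, 1/3]}: 0 is perfect alignment, 1/3 isotropic dispersion.
#'
#' @param kappa_f,kappa_s,kappa_n Dispersion parameters.
#' @return Named numeric vector of class \code{dispersion_params}.
#' @examples
#' dispersion_params(0, 1 / 15, 1 / 3)
#' @export
dispersion_params <- function(kappa_f = 0, kappa_s = 0, kappa_n = 0) {
  k <- c(f = as.numeric(kappa_f), s = as.numeric(kappa_s),
         n = as.numeric(kappa_n))
  if (any(!is.finite(k)) || any(k < 0) || any(k > 1 / 3 + 1e-12))
    stop("each kappa must lie in [0, 1/3]")
  k <- pmin(k, 1 / 3)
  structure(k, class = "dispersion_params")
}

#' Generalized structure tensor
#'
#' Second-moment tensor of an axisymmetric orientation density with mean
#' direction \code{direction}:
#' \code{H = kappa * I + (1 - 3 kappa) * (dir %o% dir)}. It has unit trace,
#' eigenvalues \code{(kappa, kappa, 1 - 2 kappa)}, and is positive
#' semi-definite on \code{kappa} in \code{[0, 1/3]}.
#'
#' @param kappa Dispersion parameter in \code{[0, 1/3]}.
#' @param direction Unit 3-vector (mean direction).
#' @return Symmetric 3x3 matrix.
#' @examples
#' structure_tensor(1 / 3, c(1, 0, 0)) # isotropic: I/3
#' @export
structure_tensor <- function(kappa, direction) {
  if (!is.finite(kappa) || kappa < 0 || kappa > 1 / 3 + 1e-12)
    stop("kappa must lie in [0, 1/3]")
  d <- as.numeric(direction)
  if (abs(sum(d^2) - 1) > 1e-10) stop("direction must be a unit vector")
  kappa * diag(3) + (1 - 3 * kappa) * (d %o% d)
}

#' Dispersed fourth invariants
#'
#' Replaces each squared structural stretch by its generalized-structure-
#' tensor average, \code{I4i* = C : H_i = kappa_i * I1 + (1 - 3 kappa_i) *
#' I4i}. At \code{F = I}, \code{I4i* = 1} for every kappa, so energy terms
#' in \code{(I4i* - 1)} vanish at rest.
#'
#' @param inv An \code{\link{compute_invariants}} result.
#' @param kappas A \code{\link{dispersion_params}} triple.
#' @return Named numeric vector \code{c(I4f_star, I4s_star, I4n_star)}.
#' @export
disperse_invariants <- function(inv, kappas = dispersion_params()) {
  k <- unclass(kappas)
  c(I4f_star = k[["f"]] * inv$I1 + (1 - 3 * k[["f"]]) * inv$I4f,
    I4s_star = k[["s"]] * inv$I1 + (1 - 3 * k[["s"]]) * inv$I4s,
    I4n_star = k[["n"]] * inv$I1 + (1 - 3 * k[["n"]]) * inv$I4n)
}

#' Tabulate kappa against concentration b
#'
#' Utility behind the \code{kappa-table} command-line helper.
#'
#' @param b_min,b_max Range of concentrations (> 0).
#' @param n Number of log-spaced values.
#' @return \code{data.frame} with columns \code{b} and \code{kappa}.
#' @export
kappa_table <- function(b_min = 1e-2, b_max = 1e2, n = 25) {
  stopifnot(b_min > 0, b_max > b_min, n >= 2)
  b <- exp(seq(log(b_min), log(b_max), length.out = n))
  data.frame(b = b, kappa = kappa_from_b(b))
}
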