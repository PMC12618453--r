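#' Orthonormal material frame
#'
#' Constructs the triad of mean structural directions of orthotropic
#' myocardium: fiber \code{f0} (myocyte axis), sheet \code{s0} (laminar
#' sheet), and normal \code{n0} (sheet-normal). The default frame is the
#' Cartesian basis.
#'
#' @param f0,s0,n0 Unit 3-vectors. Must be pairwise orthogonal and of unit
#'   norm to within \code{1e-12}.
#' @return An object of class \code{material_frame}: a 3x3 matrix whose
#'   columns are \code{f0}, \code{s0}, \code{n0}.
#' @examples
#' material_frame()
#' @export
material_frame <- function(f0 = c(1, 0, 0), s0 = c(0, 1, 0), n0 = c(0, 0, 1)) {
  M <- cbind(f0 = as.numeric(f0), s0 = as.numeric(s0), n0 = as.numeric(n0))
  if (nrow(M) != 3L) stop("frame directions must be 3-vectors")
  G <- crossprod(M)
  if (max(abs(G - diag(3))) > 1e-12)
    stop("frame directions must be orthonormal (tolerance 1e-12)")
  structure(M, class = "material_frame")
}

#' @export
print.material_frame <- function(x, ...) {
  cat("material frame (columns f0, s0, n0):\n")
  print(unclass(x))
  invisible(x)
}

#' Triaxial shear modes
#'
#' The six simple-shear modes \code{ij}: shear in the ij-plane along the
#' j-direction, so that material lines along i are stretched.
#' @export
SHEAR_MODES <- c("fs", "fn", "sf", "sn", "nf", "ns")

.axis_index <- c(f = 1L, s = 2L, n = 3L)

.mode_axes <- function(mode) {
  mode <- as.character(mode)
  if (!(mode %in% SHEAR_MODES)) stop("unknown shear mode: ", mode)
  c(i = .axis_index[[substr(mode, 1, 1)]], j = .axis_index[[substr(mode, 2, 2)]])
}

#' Deformation gradient of a triaxial simple-shear test
#'
#' For mode \code{ij}, \code{F = I + gamma * (e_j %o% e_i)}: the displacement
#' is along the j-axis and varies with the i-coordinate, so material lines
#' along i are stretched (\code{I4i = 1 + gamma^2}) while \code{I4j = 1}.
#' \code{det(F) = 1} for every gamma.
#'
#' @param mode One of \code{"fs","fn","sf","sn","nf","ns"}.
#' @param gamma Shear strain (dimensionless, finite).
#' @param frame A \code{\link{material_frame}}.
#' @return 3x3 deformation gradient matrix.
#' @examples
#' shear_deformation_gradient("fs", 0.2)
#' @export
shear_deformation_gradient <- function(mode, gamma, frame = material_frame()) {
  if (!is.finite(gamma)) stop("gamma must be finite")
  ax <- .mode_axes(mode)
  ei <- unclass(frame)[, ax[["i"]]]
  ej <- unclass(frame)[, ax[["j"]]]
  diag(3) + gamma * (ej %o% ei)
}

#' Deformation gradient of a biaxial extension test
#'
#' Stretches \code{lambda_f} along the fiber axis and \code{lambda_n} along
#' the normal axis; the sheet stretch follows from incompressibility,
#' \code{lambda_s = 1 / (lambda_f * lambda_n)}, so \code{det(F) = 1}.
#'
#' @param lambda_f,lambda_n Stretches (> 0; protocols use values >= 1).
#' @param frame A \code{\link{material_frame}}.
#' @return 3x3 deformation gradient matrix.
#' @export
biaxial_deformation_gradient <- function(lambda_f, lambda_n,
                                         frame = material_frame()) {
  if (!is.finite(lambda_f) || !is.finite(lambda_n) ||
      lambda_f <= 0 || lambda_n <= 0)
    stop("stretches must be positive and finite")
  lambda_s <- 1 / (lambda_f * lambda_n)
  M <- unclass(frame)
  M %*% diag(c(lambda_f, lambda_s, lambda_n)) %*% t(M)
}

#' Nine deformation invariants of an orthotropic material
#'
#' Evaluates, from \code{C = t(F) \%*\% F}, the isotropic invariants
#' \code{I1 = tr(C)}, \code{I2 = (I1^2 - C:C)/2}, \code{I3 = det(C)}, the
#' squared structural stretches \code{I4f, I4s, I4n}, and the coupling
#' invariants \code{I8fs, I8fn, I8sn = C : sym(i0 %o% j0)}.
#'
#' @param F 3x3 deformation gradient.
#' @param frame A \code{\link{material_frame}}.
#' @return Named list of class \code{invariant_set} with components
#'   \code{I1, I2, I3, I4f, I4s, I4n, I8fs, I8fn, I8sn}.
#' @examples
#' compute_invariants(diag(3))
#' @export
compute_invariants <- function(F, frame = material_frame()) {
  stopifnot(is.matrix(F), all(dim(F) == 3L))
  M <- unclass(frame)
  C <- crossprod(F)
  f0 <- M[, 1]; s0 <- M[, 2]; n0 <- M[, 3]
  I1 <- sum(diag(C))
  out <- list(
    I1 = I1,
    I2 = 0.5 * (I1^2 - sum(C * C)),
    I3 = det(C),
    I4f = drop(crossprod(f0, C %*% f0)),
    I4s = drop(crossprod(s0, C %*% s0)),
    I4n = drop(crossprod(n0, C %*% n0)),
    I8fs = drop(crossprod(f0, C %*% s0)),
    I8fn = drop(crossprod(f0, C %*% n0)),
    I8sn = drop(crossprod(s0, C %*% n0))
  )
  structure(out, class = "invariant_set")
}
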