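#' @keywords internal
INVARIANT_NAMES <- c("I1", "I2", "I4f", "I4s", "I4n", "I8fs", "I8fn", "I8sn")

#' @keywords internal
TERM_TYPES <- c("lin", "exp1_in", "exp1_out", "quad", "exp2_in", "exp2_out")

# Node numbering of the 32-term energy: invariant block m (1..8, in the order
# of INVARIANT_NAMES) occupies nodes 4m-3 .. 4m:
#   4m-3  identity  of u      -> collapsed product weight  "lin"
#   4m-2  exp       of u      -> pair ("exp1_in", "exp1_out")
#   4m-1  identity  of u^2    -> collapsed product weight  "quad"
#   4m    exp       of u^2    -> pair ("exp2_in", "exp2_out")
# where u is the corrected invariant (I1-3, I2-3, I4*-1, I8 raw). Identity
# nodes carry a single effective weight w1*w2 (the 64 -> 48 reduction);
# exponential nodes keep the (inner, outer) pair because the inner weight
# sits inside the nonlinearity.

#' Model weights of the 32-term orthotropic free energy
#'
#' The trainable material parameters: 48 non-negative scalars arranged as an
#' 8 x 6 matrix with one row per input invariant (\code{I1, I2, I4f, I4s,
#' I4n, I8fs, I8fn, I8sn}) and one column per term type. Identity-activation
#' nodes are stored as single effective weights (\code{lin}, \code{quad};
#' units kPa); exponential nodes as inner/outer pairs (\code{exp1_in},
#' \code{exp2_in} unitless; \code{exp1_out}, \code{exp2_out} kPa).
#'
#' @param x An 8 x 6 numeric matrix (rows in invariant order, columns in term
#'   order), or a named numeric vector of node weights using labels such as
#'   \code{"w1w2_7"} (effective weight of node 7), \code{"w1_12"},
#'   \code{"w2_12"} (inner/outer pair of node 12); omitted entries are zero.
#' @return Object of class \code{cann_weights}.
#' @examples
#' cann_weights(c(w1w2_7 = 5.153, w1_12 = 21.062, w2_12 = 0.081))
#' @export
cann_weights <- function(x = NULL) {
  W <- matrix(0, 8, 6, dimnames = list(INVARIANT_NAMES, TERM_TYPES))
  if (is.matrix(x)) {
    stopifnot(all(dim(x) == c(8L, 6L)))
    W[] <- as.numeric(x)
  } else if (!is.null(x)) {
    if (is.null(names(x)) || any(names(x) == ""))
      stop("vector input must be fully named with node labels")
    for (lab in names(x)) {
      idx <- .parse_node_label(lab)
      W[idx[1], idx[2]] <- as.numeric(x[[lab]])
    }
  }
  if (any(!is.finite(W)) || any(W < 0))
    stop("all weights must be finite and non-negative")
  structure(W, class = "cann_weights")
}

# "w1w2_7" -> (row, col) in the 8 x 6 layout; "w1_12"/"w2_12" -> exp pair slot
.parse_node_label <- function(lab) {
  m <- regmatches(lab, regexec("^(w1w2|w1|w2)_([0-9]+)$", lab))[[1]]
  if (length(m) == 0L) stop("unparseable weight label: ", lab)
  node <- as.integer(m[3])
  if (node < 1L || node > 32L) stop("node index out of 1..32: ", lab)
  row <- (node - 1L) %/% 4L + 1L
  slot <- (node - 1L) %% 4L + 1L  # 1 lin, 2 exp(u), 3 quad, 4 exp(u^2)
  if (slot %in% c(1L, 3L)) {
    if (m[2] != "w1w2")
      stop("identity node ", node, " takes a collapsed 'w1w2_' weight")
    col <- if (slot == 1L) 1L else 4L
  } else {
    if (m[2] == "w1w2")
      stop("exponential node ", node, " takes separate 'w1_'/'w2_' weights")
    col <- if (slot == 2L) {
      if (m[2] == "w1") 2L else 3L
    } else {
      if (m[2] == "w1") 5L else 6L
    }
  }
  c(row, col)
}

#' Flatten model weights to labelled node weights
#'
#' Inverse view of \code{\link{cann_weights}}: a named vector keyed by the
#' node labels \code{w1w2_j} (identity nodes, effective weight) and
#' \code{w1_j}/\code{w2_j} (exponential nodes), dropping exact zeros if
#' requested.
#'
#' @param weights A \code{cann_weights} object.
#' @param drop_zero Drop zero entries?
#' @return Named numeric vector.
#' @export
weight_labels <- function(weights, drop_zero = TRUE) {
  W <- unclass(weights)
  out <- c()
  for (m in 1:8) {
    node <- 4L * (m - 1L)
    v <- c(W[m, "lin"], W[m, "exp1_in"], W[m, "exp1_out"],
           W[m, "quad"], W[m, "exp2_in"], W[m, "exp2_out"])
    names(v) <- c(paste0("w1w2_", node + 1L),
                  paste0("w1_", node + 2L), paste0("w2_", node + 2L),
                  paste0("w1w2_", node + 3L),
                  paste0("w1_", node + 4L), paste0("w2_", node + 4L))
    out <- c(out, v)
  }
  if (drop_zero) out <- out[out != 0]
  out
}

#' @export
print.cann_weights <- function(x, ...) {
  cat("cann_weights (48 non-negative parameters; kPa outer, unitless inner)\n")
  act <- weight_labels(x)
  if (length(act) == 0L) cat("  all zero\n") else print(round(act, 4))
  invisible(x)
}

#' Write / read a discovered model as JSON
#'
#' Serializes the labelled weights, the dispersion parameters, and optional
#' metadata. The round trip is bit-exact (full double precision).
#'
#' @param weights A \code{\link{cann_weights}} object.
#' @param kappas A \code{\link{dispersion_params}} triple.
#' @param path File path.
#' @param metadata Optional named list stored verbatim.
#' @return \code{read_model} returns \code{list(weights, kappas, metadata)}.
#' @export
write_model <- function(weights, kappas, path, metadata = list()) {
  obj <- list(
    weights = as.list(weight_labels(weights, drop_zero = FALSE)),
    kappas = list(f = unname(kappas[["f"]]), s = unname(kappas[["s"]]),
                  n = unname(kappas[["n"]])),
    metadata = metadata
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  list(weights = cann_weights(unlist(obj$weights)),
       kappas = dispersion_params(obj$kappas$f, obj$kappas$s, obj$kappas$n),
       metadata = obj$metadata)
}

.ref_model <- function(kappas, r2, ...) {
  list(weights = cann_weights(c(...)), kappas = kappas, R2 = r2)
}

#' Bundled discovered myocardium parameter sets
#'
#' Representative sparse parameter sets discovered for passive human
#' myocardium from combined triaxial-shear and biaxial-extension data, at
#' varying levels of structural dispersion. Three families are provided,
#' each keyed by the dispersion level \code{c("0","1/15","2/15","1/5",
#' "4/15","1/3")}:
#' \describe{
#'   \item{sheet_normal}{\code{kappa_s = kappa_n} varied, \code{kappa_f = 0}.}
#'   \item{fiber}{\code{kappa_f} varied, \code{kappa_s = kappa_n = 0}.}
#'   \item{equal}{\code{kappa_f = kappa_s = kappa_n} varied.}
#' }
#' Each entry is \code{list(weights, kappas, R2)} where \code{R2} is the mean
#' goodness of fit reported for that fit to the experimental data. These sets
#' serve as ground-truth generators for the synthetic-data workflow and as
#' worked examples for the reporting layer.
#'
#' @return Nested list as described.
#' @examples
#' m <- myocardium_models()$sheet_normal[["0"]]
#' weight_labels(m$weights)
#' @export
myocardium_models <- function() {
  kap <- c(`0` = 0, `1/15` = 1 / 15, `2/15` = 2 / 15, `1/5` = 1 / 5,
           `4/15` = 4 / 15, `1/3` = 1 / 3)
  sn <- list(
    `0`    = .ref_model(dispersion_params(0, 0, 0), 0.890,
                        w1w2_7 = 5.153, w1_12 = 21.062, w2_12 = 0.081,
                        w1_20 = 4.132, w2_20 = 0.340,
                        w1_24 = 0.511, w2_24 = 0.485),
    `1/15` = .ref_model(dispersion_params(0, kap[2], kap[2]), 0.898,
                        w1w2_7 = 5.108, w1_12 = 23.844, w2_12 = 0.063,
                        w1_20 = 4.683, w2_20 = 0.380, w1w2_23 = 0.257),
    `2/15` = .ref_model(dispersion_params(0, kap[3], kap[3]), 0.905,
                        w1_8 = 1.075, w2_8 = 4.520,
                        w1_12 = 23.331, w2_12 = 0.065,
                        w1_20 = 3.565, w2_20 = 0.705,
                        w1_24 = 0.517, w2_24 = 0.532),
    `1/5`  = .ref_model(dispersion_params(0, kap[4], kap[4]), 0.914,
                        w1w2_7 = 5.144, w1_12 = 23.925, w2_12 = 0.059,
                        w1_20 = 2.598, w2_20 = 1.358,
                        w1_24 = 0.537, w2_24 = 0.514),
    `4/15` = .ref_model(dispersion_params(0, kap[5], kap[5]), 0.922,
                        w1_8 = 1.215, w2_8 = 3.813,
                        w1_12 = 24.687, w2_12 = 0.055,
                        w1_20 = 2.759, w2_20 = 2.228,
                        w1_24 = 0.605, w2_24 = 0.607),
    `1/3`  = .ref_model(dispersion_params(0, kap[6], kap[6]), 0.920,
                        w1_8 = 1.401, w2_8 = 2.572,
                        w1_12 = 24.214, w2_12 = 0.055,
                        w1_20 = 4.044, w2_20 = 4.202,
                        w1_24 = 1.696, w2_24 = 0.351)
  )
  fib <- list(
    `0`    = sn[["0"]],
    `1/15` = .ref_model(dispersion_params(kap[2], 0, 0), 0.905,
                        w1w2_7 = 5.121, w1_12 = 25.558, w2_12 = 0.105,
                        w1_20 = 5.517, w2_20 = 0.214, w1w2_23 = 0.222),
    `2/15` = .ref_model(dispersion_params(kap[3], 0, 0), 0.904,
                        w1w2_7 = 5.290, w1_12 = 24.893, w2_12 = 0.199,
                        w1_20 = 5.644, w2_20 = 0.161, w1w2_21 = 0.104),
    `1/5`  = .ref_model(dispersion_params(kap[4], 0, 0), 0.885,
                        w1w2_7 = 5.527, w1_12 = 23.176, w2_12 = 0.406,
                        w1w2_19 = 0.608, w1w2_21 = 0.035),
    `4/15` = .ref_model(dispersion_params(kap[5], 0, 0), 0.852,
                        w1w2_7 = 5.308, w1_12 = 14.619, w2_12 = 1.438),
    `1/3`  = .ref_model(dispersion_params(kap[6], 0, 0), 0.720,
                        w1_6 = 0.629, w2_6 = 0.721,
                        w1w2_7 = 3.080, w1_12 = 5.059, w2_12 = 9.141)
  )
  eq <- list(
    `0`    = sn[["0"]],
    `1/15` = .ref_model(dispersion_params(kap[2], kap[2], kap[2]), 0.910,
                        w1_8 = 1.112, w2_8 = 4.333,
                        w1_12 = 25.315, w2_12 = 0.105,
                        w1_20 = 5.532, w2_20 = 0.286, w1w2_23 = 0.270),
    `2/15` = .ref_model(dispersion_params(kap[3], kap[3], kap[3]), 0.904,
                        w1_8 = 1.222, w2_8 = 4.179,
                        w1_12 = 25.442, w2_12 = 0.187, w1w2_19 = 1.755),
    `1/5`  = .ref_model(dispersion_params(kap[4], kap[4], kap[4]), 0.888,
                        w1w2_7 = 5.579, w1_12 = 24.149, w2_12 = 0.370,
                        w1_20 = 1.393, w2_20 = 1.030),
    `4/15` = .ref_model(dispersion_params(kap[5], kap[5], kap[5]), 0.854,
                        w1w2_7 = 5.303, w1_12 = 14.439, w2_12 = 1.459),
    `1/3`  = .ref_model(dispersion_params(kap[6], kap[6], kap[6]), 0.722,
                        w1_6 = 0.642, w2_6 = 0.740,
                        w1w2_7 = 3.026, w1_12 = 5.359, w2_12 = 8.582)
  )
  list(sheet_normal = sn, fiber = fib, equal = eq)
}
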