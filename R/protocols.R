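#' Standard loading protocols
#'
#' The eleven protocols used for training: six triaxial simple-shear modes
#' with a common shear-strain grid, and five biaxial extension protocols
#' with stretch-increment ratios \code{1:1, 1:0.5, 1:0.75, 0.5:1, 0.75:1}.
#' A ratio \code{r:q} scales the stretch increments,
#' \code{lambda_f = 1 + r t (lambda_max - 1)},
#' \code{lambda_n = 1 + q t (lambda_max - 1)}, \code{t in [0, 1]}, so both
#' stretches stay >= 1. All grids start at the rest state.
#'
#' @param gamma_max Maximum shear strain (default 0.5).
#' @param lambda_max Maximum stretch of the leading biaxial direction
#'   (default 1.1).
#' @param n_points Grid points per protocol curve (default 17).
#' @return List of 11 protocol descriptors (class \code{cann_protocol}).
#' @export
default_protocols <- function(gamma_max = 0.5, lambda_max = 1.1,
                              n_points = 17) {
  stopifnot(gamma_max > 0, lambda_max > 1, n_points >= 2)
  t <- seq(0, 1, length.out = n_points)
  shear <- lapply(SHEAR_MODES, function(m)
    structure(list(kind = "shear", mode = m, gamma = gamma_max * t),
              class = "cann_protocol"))
  ratios <- list(`1:1` = c(1, 1), `1:0.5` = c(1, 0.5), `1:0.75` = c(1, 0.75),
                 `0.5:1` = c(0.5, 1), `0.75:1` = c(0.75, 1))
  biax <- lapply(names(ratios), function(lab) {
    rq <- ratios[[lab]]
    structure(list(kind = "biaxial", ratio = lab,
                   lambda_f = 1 + rq[1] * t * (lambda_max - 1),
                   lambda_n = 1 + rq[2] * t * (lambda_max - 1)),
              class = "cann_protocol")
  })
  c(shear, biax)
}

.new_dataset <- function(df) {
  rownames(df) <- NULL
  structure(df, class = c("cann_dataset", "data.frame"))
}

#' Forward-simulate a stress dataset from a model
#'
#' Evaluates the closed-form protocol stresses of a given model on every
#' grid point: one \code{sigma_ij} channel per shear mode, and both
#' \code{sigma_ff} and \code{sigma_nn} channels per biaxial protocol.
#'
#' @param weights A \code{\link{cann_weights}} object (generator model).
#' @param kappas A \code{\link{dispersion_params}} triple of the generator.
#' @param protocols List from \code{\link{default_protocols}}.
#' @return A \code{cann_dataset}: a long data frame with columns
#'   \code{protocol, mode_or_ratio, strain_or_stretch_f, stretch_n, channel,
#'   stress_kPa}.
#' @examples
#' m <- myocardium_models()$sheet_normal[["0"]]
#' d <- simulate_dataset(m$weights, m$kappas, default_protocols(n_points = 5))
#' head(d)
#' @export
simulate_dataset <- function(weights, kappas = dispersion_params(),
                             protocols = default_protocols()) {
  rows <- lapply(protocols, function(p) {
    if (p$kind == "shear") {
      data.frame(protocol = paste0("shear_", p$mode), mode_or_ratio = p$mode,
                 strain_or_stretch_f = p$gamma, stretch_n = NA_real_,
                 channel = paste0("sigma_", p$mode),
                 stress_kPa = shear_stress(p$mode, p$gamma, weights, kappas))
    } else {
      sig <- biaxial_stresses(p$lambda_f, p$lambda_n, weights, kappas)
      id <- paste0("biaxial_", p$ratio)
      rbind(
        data.frame(protocol = id, mode_or_ratio = p$ratio,
                   strain_or_stretch_f = p$lambda_f, stretch_n = p$lambda_n,
                   channel = "sigma_ff", stress_kPa = sig[, "sigma_ff"]),
        data.frame(protocol = id, mode_or_ratio = p$ratio,
                   strain_or_stretch_f = p$lambda_f, stretch_n = p$lambda_n,
                   channel = "sigma_nn", stress_kPa = sig[, "sigma_nn"])
      )
    }
  })
  .new_dataset(do.call(rbind, rows))
}

#' Channel identifiers of a dataset
#'
#' A channel is one measured stress component of one protocol (one curve).
#' @param dataset A \code{cann_dataset}.
#' @return Character vector, one entry per data row.
#' @keywords internal
.channel_id <- function(dataset) paste(dataset$protocol, dataset$channel)

#' Add Gaussian measurement noise to a stress dataset
#'
#' Perturbs each stress value once by \code{epsilon ~ k * N(0, std_sigma)},
#' where \code{std_sigma} is the standard deviation of the (pre-noise)
#' stresses of that channel, emulating proportional measurement noise in a
#' deformation mode. \code{k = 0} returns the dataset unchanged. Standard
#' noise levels used in robustness sweeps are
#' \code{c(0.03, 0.05, 0.07, 0.1)}.
#'
#' @param dataset A \code{cann_dataset}.
#' @param k Noise level (non-negative scalar).
#' @param seed Integer seed making the perturbation reproducible.
#' @return The perturbed \code{cann_dataset}.
#' @export
add_noise <- function(dataset, k, seed = 1L) {
  stopifnot(is.numeric(k), length(k) == 1L, k >= 0)
  if (k == 0) return(dataset)
  ch <- .channel_id(dataset)
  std <- tapply(dataset$stress_kPa, ch, stats::sd)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  eps <- stats::rnorm(nrow(dataset), mean = 0, sd = k * std[ch])
  dataset$stress_kPa <- dataset$stress_kPa + eps
  dataset
}

#' Read and write stress datasets as CSV
#'
#' Plain-text round trip of the long dataset format with columns
#' \code{protocol, mode_or_ratio, strain_or_stretch_f, stretch_n, channel,
#' stress_kPa}.
#'
#' @param dataset A \code{cann_dataset}.
#' @param path File path.
#' @return \code{read_dataset} returns a \code{cann_dataset}.
#' @export
write_dataset <- function(dataset, path) {
  utils::write.csv(as.data.frame(dataset), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("protocol", "mode_or_ratio", "strain_or_stretch_f", "stretch_n",
            "channel", "stress_kPa")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("dataset file ", path, " is missing column(s): ",
         paste(miss, collapse = ", "))
  bad <- which(!is.finite(df$stress_kPa))
  if (length(bad))
    stop("non-numeric stress_kPa at data line(s): ",
         paste(utils::head(bad + 1L, 5), collapse = ", "))
  .new_dataset(df[, need])
}
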