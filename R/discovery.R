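#' Training configuration
#'
#' Bundles the hyperparameters of the sparse discovery optimization. The
#' defaults are the discovery protocol used throughout: L1 weight
#' \code{alpha = 0.01}, Adam with learning rate 0.001, up to 30000 epochs
#' with batch size 32, early stopping after 1000 epochs without improvement
#' of the monitored quantity (absolute improvement threshold \code{1e-8}),
#' and 3 random restarts of which the best monitored value wins.
#'
#' @param alpha L1 regularization weight (>= 0).
#' @param max_epochs Maximum training epochs.
#' @param batch_size Minibatch size.
#' @param patience Early-stopping patience in epochs (< max_epochs).
#' @param learning_rate Adam step size.
#' @param seed Integer seed controlling initialization and batching.
#' @param kappa_mode \code{"fixed"} (dispersion supplied) or
#'   \code{"trainable"} (dispersion learned jointly, projected onto the
#'   interval 0..1/3 after every step).
#' @param restarts Number of random restarts (>= 1).
#' @param improve_tol Minimum absolute improvement of the monitored
#'   quantity that resets the patience counter.
#' @param monitor Quantity watched by early stopping and restored as the
#'   returned state: \code{"fit"} (default) watches the unregularized mean
#'   squared stress error, so the returned model is the best fit reached
#'   before the L1 term erodes it; \code{"loss"} watches the full
#'   regularized objective and therefore runs to the L1 equilibrium (used
#'   to study the regularization path).
#' @return List of class \code{training_config}.
#' @export
training_config <- function(alpha = 0.01, max_epochs = 30000L,
                            batch_size = 32L, patience = 1000L,
                            learning_rate = 0.001, seed = 1L,
                            kappa_mode = c("fixed", "trainable"),
                            restarts = 3L, improve_tol = 1e-8,
                            monitor = c("fit", "loss")) {
  kappa_mode <- match.arg(kappa_mode)
  monitor <- match.arg(monitor)
  stopifnot(alpha >= 0, patience < max_epochs, restarts >= 1,
            learning_rate > 0, batch_size >= 1)
  structure(list(alpha = alpha, max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size),
                 patience = as.integer(patience),
                 learning_rate = learning_rate, seed = as.integer(seed),
                 kappa_mode = kappa_mode, restarts = as.integer(restarts),
                 improve_tol = improve_tol, monitor = monitor),
            class = "training_config")
}

#' Random weight initialization
#'
#' Identity-activation effective weights are drawn from a Glorot normal
#' distribution and clamped non-negative; exponential-node pairs are drawn
#' uniformly on \code{[0, 0.1]}. Reproducible for a fixed seed.
#'
#' @param seed Integer seed.
#' @return A \code{\link{cann_weights}} object.
#' @export
init_weights <- function(seed = 1L) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  W <- matrix(0, 8, 6, dimnames = list(INVARIANT_NAMES, TERM_TYPES))
  # Glorot normal for 1-in/1-out nodes: sd = sqrt(2/(fan_in+fan_out)) = 1
  W[, c("lin", "quad")] <- pmax(stats::rnorm(16, 0, 1), 0)
  W[, c("exp1_in", "exp1_out", "exp2_in", "exp2_out")] <-
    stats::runif(32, 0, 0.1)
  cann_weights(W)
}

.restart_seed <- function(seed, restart) {
  as.integer((as.numeric(seed) * 1009 + restart * 9973) %% 2147483629)
}

#' Coefficient of determination per stress channel
#'
#' Per channel (one measured stress curve), \code{R^2 = 1 - SS_res/SS_tot}
#' with total sums of squares about the channel mean; the reported "mean
#' R^2" is the unweighted mean over channels. Channels with zero variance
#' are excluded with a warning.
#'
#' @param model A \code{discovered_model}, or any
#'   \code{list(weights=, kappas=)}.
#' @param dataset A \code{cann_dataset}.
#' @return List with \code{per_channel} (named numeric) and \code{mean}.
#' @export
r_squared <- function(model, dataset) {
  pred <- predict_stresses(model$weights, model$kappas, dataset)
  ch <- .channel_id(dataset)
  vals <- vapply(split(seq_along(ch), ch), function(ix) {
    sst <- sum((dataset$stress_kPa[ix] - mean(dataset$stress_kPa[ix]))^2)
    if (sst == 0) return(NA_real_)
    1 - sum((pred[ix] - dataset$stress_kPa[ix])^2) / sst
  }, numeric(1))
  if (anyNA(vals)) {
    warning("excluding zero-variance channel(s): ",
            paste(names(vals)[is.na(vals)], collapse = ", "))
    vals <- vals[!is.na(vals)]
  }
  list(per_channel = vals, mean = mean(vals))
}

# per-node stress contributions (n x 32) on a dataset
.node_contributions <- function(weights, kappas, dataset) {
  design <- .build_design(dataset)
  cu <- .design_CU(design, kappas)
  W <- unclass(weights)
  out <- matrix(0, nrow(dataset), 32)
  for (m in 1:8) {
    u <- cu$U[, m]; cc <- cu$C[, m]
    node <- 4L * (m - 1L)
    out[, node + 1L] <- cc * W[m, "lin"]
    out[, node + 2L] <- cc * W[m, "exp1_in"] * W[m, "exp1_out"] *
      exp(W[m, "exp1_in"] * u)
    out[, node + 3L] <- cc * 2 * W[m, "quad"] * u
    out[, node + 4L] <- cc * 2 * W[m, "exp2_in"] * W[m, "exp2_out"] * u *
      exp(W[m, "exp2_in"] * u^2)
  }
  colnames(out) <- paste0("node", 1:32)
  out
}

#' Active terms of a model on a dataset
#'
#' A node is reported active when its peak absolute stress contribution
#' across the training protocols exceeds \code{threshold} (default 0.5%) of
#' the peak absolute total stress. This reporting cutoff mirrors how sparse
#' discovered models are tabulated with near-zero weights omitted.
#'
#' @param weights,kappas Model.
#' @param dataset A \code{cann_dataset} (typically the training data).
#' @param threshold Relative contribution cutoff.
#' @return Integer vector of active node indices (1..32).
#' @export
active_terms <- function(weights, kappas, dataset, threshold = 0.005) {
  contrib <- .node_contributions(weights, kappas, dataset)
  peak <- max(abs(dataset$stress_kPa))
  if (peak == 0) return(integer(0))
  which(apply(abs(contrib), 2, max) > threshold * peak)
}

.NODE_BASES <- c("[I1-3]", "[I2-3]", "[I4f*-1]", "[I4s*-1]", "[I4n*-1]",
                 "[I8fs]", "[I8fn]", "[I8sn]")

.node_description <- function(node) {
  m <- (node - 1L) %/% 4L + 1L
  slot <- (node - 1L) %% 4L + 1L
  base <- .NODE_BASES[m]
  switch(slot, base, paste0("exp(", base, ")-1"), paste0(base, "^2"),
         paste0("exp(", base, "^2)-1"))
}

#' Tabulate the active terms of a discovered model
#'
#' One row per active node with its paired network-weight labels, the
#' values, the combined magnitude (product of the pair for exponential
#' nodes, the effective weight itself for identity nodes; kPa), and the
#' peak stress contribution. The mean R-squared on the dataset is attached
#' as attribute \code{"mean_R2"}.
#'
#' @param model A \code{discovered_model} or \code{list(weights=, kappas=)}.
#' @param dataset A \code{cann_dataset}.
#' @param threshold Passed to \code{\link{active_terms}}.
#' @return \code{data.frame} with columns \code{node, term, label, w1, w2,
#'   magnitude_kPa, peak_contribution_kPa}.
#' @examples
#' m <- myocardium_models()$sheet_normal[["4/15"]]
#' d <- simulate_dataset(m$weights, m$kappas, default_protocols(n_points = 9))
#' report_active_terms(m, d)
#' @export
report_active_terms <- function(model, dataset, threshold = 0.005) {
  W <- unclass(model$weights)
  act <- active_terms(model$weights, model$kappas, dataset, threshold)
  contrib <- .node_contributions(model$weights, model$kappas, dataset)
  rows <- lapply(act, function(node) {
    m <- (node - 1L) %/% 4L + 1L
    slot <- (node - 1L) %% 4L + 1L
    if (slot %in% c(1L, 3L)) {
      w1 <- NA_real_; w2 <- NA_real_
      mag <- W[m, if (slot == 1L) "lin" else "quad"]
      lab <- paste0("w1w2_", node)
    } else {
      w1 <- W[m, if (slot == 2L) "exp1_in" else "exp2_in"]
      w2 <- W[m, if (slot == 2L) "exp1_out" else "exp2_out"]
      mag <- w1 * w2
      lab <- paste0("w1_", node, ",w2_", node)
    }
    data.frame(node = node, term = .node_description(node), label = lab,
               w1 = w1, w2 = w2, magnitude_kPa = mag,
               peak_contribution_kPa = max(abs(contrib[, node])))
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(node = integer(0), term = character(0), label = character(0),
               w1 = numeric(0), w2 = numeric(0), magnitude_kPa = numeric(0),
               peak_contribution_kPa = numeric(0))
  attr(out, "mean_R2") <- r_squared(model, dataset)$mean
  out
}

#' Train the dispersed constitutive network on a stress dataset
#'
#' Minimizes the L1-regularized mean squared stress error (see
#' \code{\link{loss}}) with projected minibatch Adam: data points from all
#' protocols are pooled and reshuffled every epoch, weights are clipped at
#' zero after every step, and training stops early when the full training
#' loss has not improved for \code{patience} consecutive epochs. With
#' \code{kappa_mode = "trainable"} the three dispersion parameters are
#' learned jointly, constrained to the interval 0..1/3. The best final loss over
#' \code{restarts} random initializations is returned; a restart whose loss
#' turns non-finite is abandoned with a warning.
#'
#' @param dataset A \code{cann_dataset} covering at least one protocol.
#' @param config A \code{\link{training_config}}.
#' @param kappas Dispersion parameters: fixed values for
#'   \code{kappa_mode = "fixed"}, the starting point otherwise.
#' @return Object of class \code{discovered_model}:
#'   \code{list(weights, kappas, loss, r2, active, epochs, history,
#'   config)}.
#' @export
train_cann <- function(dataset, config = training_config(),
                       kappas = dispersion_params()) {
  if (nrow(dataset) == 0L) stop("empty dataset")
  design <- .build_design(dataset)
  best <- NULL
  for (rs in seq_len(config$restarts)) {
    rseed <- .restart_seed(config$seed, rs)
    w0 <- init_weights(rseed)
    kap0 <- kappas
    if (config$kappa_mode == "trainable" && rs > 1L) {
      # joint (weights, kappa) optimization is multi-modal: dispersion can be
      # partially absorbed into the weights; restarts explore kappa space
      old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
      set.seed(rseed + 1L)
      kap0 <- dispersion_params(stats::runif(1, 0, 1 / 3),
                                stats::runif(1, 0, 1 / 3),
                                stats::runif(1, 0, 1 / 3))
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    }
    fit <- .adam_fit_cpp(design$C0, design$Cf, design$Cs, design$Cn,
                         design$U0, design$Uf, design$Us, design$Un,
                         design$y, design$rowW, design$n_states,
                         unclass(w0), unclass(kap0),
                         config$kappa_mode == "trainable",
                         config$alpha, config$learning_rate,
                         config$max_epochs, config$batch_size,
                         config$patience, config$improve_tol,
                         identical(config$monitor, "loss"), rseed)
    if (isTRUE(fit$diverged)) {
      warning("restart ", rs, " diverged (non-finite loss); discarded")
      next
    }
    if (is.null(best) || fit$loss < best$loss) best <- fit
  }
  if (is.null(best)) stop("all restarts diverged")
  weights <- cann_weights(best$weights)
  kap <- dispersion_params(best$kappas[1], best$kappas[2], best$kappas[3])
  model <- list(weights = weights, kappas = kap, loss = best$loss,
                epochs = best$epochs, history = best$history,
                config = config)
  model$r2 <- r_squared(model, dataset)
  model$active <- active_terms(weights, kap, dataset)
  structure(model, class = "discovered_model")
}

#' @rdname train_cann
#' @details \code{discover_kappa} is \code{train_cann} with
#'   \code{kappa_mode = "trainable"}: the dispersion parameters become part
#'   of the optimization, starting from \code{kappas}.
#' @export
discover_kappa <- function(dataset, config = training_config(),
                           kappas = dispersion_params(1 / 6, 1 / 6, 1 / 6)) {
  config$kappa_mode <- "trainable"
  train_cann(dataset, config, kappas)
}

#' @export
print.discovered_model <- function(x, ...) {
  cat("discovered_model:", length(x$active), "active terms,",
      "mean R2 =", round(x$r2$mean, 4), "\n")
  cat("kappas: f =", round(x$kappas[["f"]], 4),
      " s =", round(x$kappas[["s"]], 4),
      " n =", round(x$kappas[["n"]], 4), "\n")
  cat("fit =", signif(x$loss, 6), "kPa^2 after", x$epochs, "epochs\n")
  W <- unclass(x$weights)
  for (node in x$active) {
    m <- (node - 1L) %/% 4L + 1L
    slot <- (node - 1L) %% 4L + 1L
    desc <- .node_description(node)
    if (slot %in% c(1L, 3L)) {
      w <- W[m, if (slot == 1L) "lin" else "quad"]
      cat(sprintf("  %-18s w1w2_%-2d = %.4f kPa\n", desc, node, w))
    } else {
      w1 <- W[m, if (slot == 2L) "exp1_in" else "exp2_in"]
      w2 <- W[m, if (slot == 2L) "exp1_out" else "exp2_out"]
      cat(sprintf("  %-18s w1_%-2d = %.4f, w2_%-2d = %.4f kPa\n",
                  desc, node, w1, node, w2))
    }
  }
  invisible(x)
}
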