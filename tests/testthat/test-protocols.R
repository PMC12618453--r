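test_that("default protocols: eleven curves with increment-ratio biaxial grids", {
  pr <- default_protocols()
  expect_length(pr, 11)
  kinds <- vapply(pr, `[[`, "", "kind")
  expect_equal(sum(kinds == "shear"), 6)
  expect_equal(sum(kinds == "biaxial"), 5)
  expect_setequal(vapply(pr[kinds == "shear"], `[[`, "", "mode"), SHEAR_MODES)
  half <- pr[[which(vapply(pr, function(p)
    identical(p$ratio, "1:0.5"), logical(1)))]]
  expect_equal(max(half$lambda_f), 1.1)
  expect_equal(max(half$lambda_n), 1.05)
  # every grid starts at the rest state
  for (p in pr) {
    if (p$kind == "shear") expect_equal(p$gamma[1], 0)
    else expect_equal(c(p$lambda_f[1], p$lambda_n[1]), c(1, 1))
  }
})

test_that("simulated datasets: channels, zero model, and dispersion symmetry", {
  pr <- default_protocols(n_points = 7)
  d0 <- simulate_dataset(cann_weights(), dispersion_params(), pr)
  expect_equal(nrow(d0), 6 * 7 + 5 * 7 * 2)
  expect_true(all(d0$stress_kPa == 0))

  gen <- four_term_generator()
  d <- simulate_dataset(gen$weights, gen$kappas, pr)
  fs <- d$stress_kPa[d$protocol == "shear_fs"]
  expect_true(all(diff(fs) > 0))  # monotone stiffening in fs shear
  # rest rows carry zero stress
  expect_true(all(abs(d$stress_kPa[d$strain_or_stretch_f == 1 |
                                     (startsWith(d$protocol, "shear") &
                                        d$strain_or_stretch_f == 0)]) < 1e-12))
  # isotropic dispersion: equal-biaxial ff and nn channels coincide
  k3 <- dispersion_params(1 / 3, 1 / 3, 1 / 3)
  d3 <- simulate_dataset(gen$weights, k3, pr)
  b11 <- d3[d3$protocol == "biaxial_1:1", ]
  expect_equal(b11$stress_kPa[b11$channel == "sigma_ff"],
               b11$stress_kPa[b11$channel == "sigma_nn"], tolerance = 1e-12)
})

test_that("design-matrix predictions equal the closed-form protocol stresses", {
  for (s in 1:4) {
    w <- random_weights(s + 200)
    kap <- random_kappas(s + 220)
    d <- simulate_dataset(w, kap, default_protocols(n_points = 6))
    expect_equal(predict_stresses(w, kap, d), d$stress_kPa, tolerance = 1e-10)
  }
})

test_that("noise injection is reproducible, proportional, and centered", {
  gen <- four_term_generator()
  d <- simulate_dataset(gen$weights, gen$kappas, default_protocols(n_points = 9))
  expect_identical(add_noise(d, 0), d)
  n1 <- add_noise(d, 0.05, seed = 42)
  expect_identical(add_noise(d, 0.05, seed = 42), n1)
  expect_false(identical(n1, add_noise(d, 0.05, seed = 43)))

  # Monte-Carlo over one channel: sd(eps) ~ k * sd(channel) within 3%,
  # mean shift below 1% of the channel sd
  fs <- d$protocol == "shear_fs"
  std_fs <- sd(d$stress_kPa[fs])
  eps <- unlist(lapply(1:2000, function(s)
    add_noise(d, 0.05, seed = s)$stress_kPa[fs] - d$stress_kPa[fs]))
  expect_equal(sd(eps), 0.05 * std_fs, tolerance = 0.03)
  expect_lt(abs(mean(eps)), 0.01 * std_fs)
})

test_that("dataset CSV round trip and malformed-file errors", {
  gen <- four_term_generator()
  d <- simulate_dataset(gen$weights, gen$kappas, default_protocols(n_points = 5))
  path <- withr::local_tempfile(fileext = ".csv")
  write_dataset(d, path)
  back <- read_dataset(path)
  expect_equal(as.data.frame(back), as.data.frame(d), tolerance = 1e-12)

  bad <- read.csv(path)
  bad$channel <- NULL
  path2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(bad, path2, row.names = FALSE)
  expect_error(read_dataset(path2), "channel")

  fixture <- system.file("extdata", "simulated_shear_biaxial_kappa0.csv",
                         package = "dispcann")
  expect_true(nzchar(fixture))
  df <- read_dataset(fixture)
  expect_s3_class(df, "cann_dataset")
  expect_equal(sort(unique(df$protocol)),
               sort(unique(d$protocol)))
})

test_that("loss: exact model, zero model, and a hand-computed toy dataset", {
  gen <- four_term_generator()
  d <- simulate_dataset(gen$weights, gen$kappas, default_protocols(n_points = 5))
  expect_equal(loss(gen$weights, gen$kappas, d, alpha = 0), 0, tolerance = 1e-20)
  expect_error(loss(gen$weights, gen$kappas, d[0, ], 0.01), "empty")

  # zero model, alpha = 0: state-weighted mean of squared measured stresses
  sh <- startsWith(d$protocol, "shear_")
  n_states <- sum(sh) + sum(!sh) / 2
  expect_equal(loss(cann_weights(), dispersion_params(), d, alpha = 0),
               sum(ifelse(sh, 2, 1) * d$stress_kPa^2) / n_states)

  # two-state toy set against spreadsheet arithmetic: lin-I1 model
  toy <- data.frame(
    protocol = c("shear_fs", "biaxial_1:1", "biaxial_1:1"),
    mode_or_ratio = c("fs", "1:1", "1:1"),
    strain_or_stretch_f = c(0.3, 1.05, 1.05),
    stretch_n = c(NA, 1.05, 1.05),
    channel = c("sigma_fs", "sigma_ff", "sigma_nn"),
    stress_kPa = c(1.0, 2.0, 1.5))
  class(toy) <- c("cann_dataset", "data.frame")
  cval <- 0.8
  w <- cann_weights(c(w1w2_1 = cval))
  ls2 <- (1 / 1.05^2)^2
  pred_sh <- 2 * 0.3 * cval
  pred_bi <- 2 * cval * (1.05^2 - ls2)
  hand <- (2 * (pred_sh - 1)^2 + (pred_bi - 2)^2 + (pred_bi - 1.5)^2) / 2 +
    0.01 * cval
  expect_equal(loss(w, dispersion_params(), toy, alpha = 0.01), hand,
               tolerance = 1e-12)
})

test_that("R-squared per channel: perfect fit, mean prediction, hand arithmetic", {
  gen <- four_term_generator()
  d <- simulate_dataset(gen$weights, gen$kappas, default_protocols(n_points = 5))
  r2 <- r_squared(gen, d)
  expect_equal(r2$mean, 1)
  expect_length(r2$per_channel, 16)

  # zero model on a zero-mean channel is exactly the channel-mean predictor
  toy <- data.frame(
    protocol = "shear_fs", mode_or_ratio = "fs",
    strain_or_stretch_f = c(0.1, 0.2, 0.3), stretch_n = NA,
    channel = "sigma_fs", stress_kPa = c(-1, 0, 1))
  class(toy) <- c("cann_dataset", "data.frame")
  zero <- list(weights = cann_weights(), kappas = dispersion_params())
  expect_equal(r_squared(zero, toy)$mean, 0)
  # same data shifted: R2 = 1 - SSres/SStot = 1 - (1+4+9)/2
  toy$stress_kPa <- c(1, 2, 3)
  expect_equal(r_squared(zero, toy)$mean, 1 - 14 / 2)
  # zero-variance channel excluded with a warning
  toy2 <- toy
  toy2$stress_kPa <- c(2, 2, 2)
  expect_warning(r_squared(zero, toy2), "zero-variance")
})

test_that("active-term report: labels, magnitudes, and empty models", {
  gen <- myocardium_models()$sheet_normal[["4/15"]]
  d <- simulate_dataset(gen$weights, gen$kappas, default_protocols(n_points = 7))
  rep <- report_active_terms(gen, d)
  expect_setequal(rep$node, c(8, 12, 20, 24))
  i2 <- rep[rep$node == 8, ]
  expect_equal(i2$magnitude_kPa, 1.215 * 3.813)
  expect_equal(attr(rep, "mean_R2"), 1)
  empty <- report_active_terms(
    list(weights = cann_weights(), kappas = dispersion_params()), d)
  expect_equal(nrow(empty), 0)
})
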