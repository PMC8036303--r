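test_that("parameter count follows K(2D+1) - 1", {
  expect_identical(num_params(3, 5), 32L)
  expect_identical(num_params(1, 2), 4L)
  expect_identical(num_params(2, 3), 13L)
})

test_that("lattice constants take their analytic values", {
  kc <- mml_lattice_constants()
  expect_equal(round(kc[["k1"]], 3), 0.083)
  expect_equal(signif(kc[["asymptotic"]], 4), 0.05855)
})

test_that("log prior assembles its four blocks correctly", {
  # K=1, D=2, ||alpha_hat|| = 1:
  # lgamma(1) + lgamma(2) + log(0.1) + 2*(-6 - log 1)
  m <- ssd_mixture(1, list(ssd_params(c(0.6, 0.8), c(0.5, 0.5), 1)))
  expect_equal(log_prior(m), log(0.1) - 12, tolerance = 1e-12)

  # doubling the shape norm lowers the prior by D log 2 per component
  m2 <- ssd_mixture(1, list(ssd_params(c(1.2, 1.6), c(0.5, 0.5), 1)))
  expect_equal(log_prior(m) - log_prior(m2), 2 * log(2), tolerance = 1e-12)

  # three-component mixing-weight block adds log Gamma(3) = log 2 relative
  # to the same single component counted three times
  m3 <- ssd_mixture(rep(1 / 3, 3), rep(list(ssd_params(c(0.6, 0.8))), 3))
  expect_equal(log_prior(m3), lgamma(3) + 3 * (lgamma(2) + log(0.1) - 12),
               tolerance = 1e-12)
})

test_that("mixing-weight Fisher block follows the chosen convention", {
  # K = 1: no free weight, contributes 0
  expect_equal(ssdmix:::fisher_pi_logdet(1, 100), 0)
  # pi = (0.5, 0.5), N = 100 -> log(100) - 2 log(0.5) = log 400
  expect_equal(ssdmix:::fisher_pi_logdet(c(0.5, 0.5), 100), log(400))
  # printed variant: log(N * prod pi)
  expect_equal(ssdmix:::fisher_pi_logdet(c(0.5, 0.5), 100, "as_printed"),
               log(25))
})

test_that("component Hessian log-determinant matches an independent FD oracle", {
  Y <- rssd(400, ssd_params(c(4, 2), c(0.4, 0.6), 1.2), seed = 21)
  fit <- fit_em(Y, 1, seed = 22)
  fld <- fisher_info_logdet(fit$model, Y)
  # oracle: own central-difference Hessian with a different (absolute) step
  par <- ssdmix:::theta_to_par(fit$model$components[[1]])
  lY <- log(Y)
  f <- function(p) ssdmix:::weighted_nll(p, lY, rep(1, 400))
  p <- length(par); h <- 5e-5
  H <- matrix(0, p, p)
  for (i in 1:p) for (j in i:p) {
    ei <- ej <- rep(0, p); ei[i] <- h; ej[j] <- h
    H[i, j] <- H[j, i] <-
      (f(par + ei + ej) - f(par + ei - ej) - f(par - ei + ej) + f(par - ei - ej)) /
      (4 * h * h)
  }
  expect_equal(as.numeric(fld), determinant(H)$modulus[1], tolerance = 1e-3)
})

test_that("message length shifts one-for-one with the log-likelihood term", {
  Y <- rssd(150, ssd_params(c(3, 2, 4)), seed = 23)
  fit <- fit_em(Y, 1, seed = 24)
  ml <- message_length(fit$model, Y)
  br <- attr(ml, "breakdown")
  expect_equal(as.numeric(ml),
               -br$log_prior - br$loglik + 0.5 * br$fisher_logdet +
                 br$Np / 2 + (br$Np / 2) * log(1 / 12),
               tolerance = 1e-10)
})

test_that("message length prefers the true single component over K = 3", {
  Y <- rssd(1000, ssd_params(c(5, 3, 4), c(0.3, 0.3, 0.4), 1.2), seed = 25)
  f1 <- fit_em(Y, 1, seed = 26)
  f3 <- fit_em(Y, 3, seed = 26)
  ml1 <- message_length(f1$model, Y)
  ml3 <- message_length(f3$model, Y)
  expect_lt(as.numeric(ml1), as.numeric(ml3))
})

test_that("select_k reports consistent records and trivial cases", {
  Y <- rssd_mixture(300, ssdmix:::separated_k3_truth(), seed = 27)
  rep2 <- select_k(Y, 2, seed = 28)
  expect_equal(rep2$best_K, 2L)

  rep_ <- select_k(Y, 1:4, seed = 28)
  expect_true(all(rep_$records$Np ==
                    num_params(rep_$records$K, 3)))
  expect_equal(rep_$records$K[which.min(rep_$records$message_length)],
               rep_$best_K)
  expect_true(all(is.finite(rep_$records$message_length)))
  expect_error(select_k(Y, 301, seed = 1), "exceeds")
})
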