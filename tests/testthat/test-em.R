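test_that("K-means initialisation covers the edge cases", {
  set.seed(1)
  Y <- rssd(60, ssd_params(c(4, 2, 3)), seed = 1)
  m1 <- init_kmeans(Y, 1, seed = 2)
  expect_equal(m1$weights, 1)
  gm <- colMeans(Y)
  expect_equal(m1$components[[1]]$beta, gm / sum(gm), tolerance = 1e-12)
  expect_equal(m1$components[[1]]$b, 1)

  # every point its own cluster: must not fail on empty clusters
  Ys <- Y[1:8, ]
  m8 <- init_kmeans(Ys, 8, seed = 3)
  expect_equal(m8$K, 8L)
  expect_equal(sum(m8$weights), 1)

  expect_error(init_kmeans(Ys, 9, seed = 1), "exceed")
})

test_that("K-means initialisation recovers fractions of well-separated blobs", {
  mix <- ssd_mixture(c(0.7, 0.3), list(
    ssd_params(c(30, 3, 3)), ssd_params(c(3, 3, 30))))
  Y <- rssd_mixture(1000, mix, seed = 4)
  m <- init_kmeans(Y, 2, seed = 5)
  expect_lt(min(abs(sort(m$weights) - c(0.3, 0.7))), 0.05)
  expect_lt(max(abs(sort(m$weights) - c(0.3, 0.7))), 0.05)
})

test_that("E-step posteriors: trivial structure and row normalization", {
  th <- ssd_params(c(4, 2, 3), c(0.3, 0.3, 0.4), 1.2)
  Y <- rssd(40, th, seed = 6)
  expect_equal(e_step(Y, ssd_mixture(1, list(th))), matrix(1, 40, 1))

  m_same <- ssd_mixture(c(0.5, 0.5), list(th, th))
  expect_equal(e_step(Y, m_same), matrix(0.5, 40, 2), tolerance = 1e-12)

  m_skew <- ssd_mixture(c(0.9, 0.1), list(th, th))
  Z <- e_step(Y, m_skew)
  expect_equal(Z[, 1], rep(0.9, 40), tolerance = 1e-12)
  expect_equal(rowSums(Z), rep(1, 40), tolerance = 1e-9)

  # hard assignment: argmax with low-index tie-break
  expect_equal(hard_assign(matrix(c(0.5, 0.3, 0.5, 0.7), 2, 2)), c(1L, 2L))
})

test_that("M-step weight update is the closed-form responsibility mean", {
  set.seed(7)
  Y <- rssd(100, ssd_params(c(3, 2, 4)), seed = 7)
  Z <- cbind(rep(0.3, 100), rep(0.7, 100))
  model <- ssd_mixture(c(0.5, 0.5), list(
    ssd_params(c(3, 2, 4)), ssd_params(c(2, 3, 4))))
  up <- m_step(Y, Z, model, optim_maxit = 2)
  expect_equal(up$weights, c(0.3, 0.7), tolerance = 1e-12)
})

test_that("analytic gradient of the weighted log-likelihood matches finite differences", {
  set.seed(8)
  Y <- rssd(200, ssd_params(c(5, 2, 3), c(0.3, 0.3, 0.4), 1.5), seed = 8)
  lY <- log(Y)
  w <- runif(200)
  for (rep in 1:10) {
    par <- c(log(runif(3, 0.5, 6)), rnorm(2, 0, 0.5), log(runif(1, 0.5, 2)))
    g <- ssdmix:::weighted_nll_grad(par, lY, w)
    gn <- numeric(length(par))
    for (i in seq_along(par)) {
      e <- rep(0, length(par)); e[i] <- 1e-6
      gn[i] <- (ssdmix:::weighted_nll(par + e, lY, w) -
                  ssdmix:::weighted_nll(par - e, lY, w)) / 2e-6
    }
    expect_lt(max(abs(g - gn) / (abs(gn) + 1e-8)), 1e-5)
  }
})

test_that("single-component M-step agrees with an independent direct optimizer", {
  Y <- rssd(600, ssd_params(c(5, 2, 3), c(0.3, 0.3, 0.4), 1.5), seed = 9)
  fit <- fit_em(Y, 1, seed = 10)
  est <- fit$model$components[[1]]
  # oracle: Nelder-Mead from a different start, no gradients, own objective
  lY <- log(Y)
  obj <- function(p) {
    a <- exp(p[1:3]); e <- c(exp(p[4:5]), 1); be <- e / sum(e); b <- exp(p[6])
    if (b < 0.05 || b > 20) return(1e10)
    ap <- sum(a)
    lp <- lgamma(ap) - sum(lgamma(a)) - 2 * log(b) - sum((a / b) * log(be)) +
      drop(lY %*% (a / b - 1)) -
      ap * log(rowSums(sweep(Y, 2, be, "/")^(1 / b)))
    -sum(lp)
  }
  o <- optim(c(log(c(2, 2, 2)), 0, 0, 0), obj,
             control = list(maxit = 5000, reltol = 1e-12))
  o <- optim(o$par, obj, control = list(maxit = 5000, reltol = 1e-12))
  a_or <- exp(o$par[1:3])
  expect_equal(est$alpha, a_or, tolerance = 0.05)
  expect_equal(-obj(c(log(est$alpha),
                      log(est$beta[-3] / est$beta[3]), log(est$b))),
               -o$value, tolerance = 1e-3)
})

test_that("EM log-likelihood is monotone and the fit is deterministic", {
  mk <- test_mixture_k2()
  Y <- rssd_mixture(400, mk, seed = 12)
  f1 <- fit_em(Y, 2, seed = 13)
  f2 <- fit_em(Y, 2, seed = 13)
  expect_identical(f1$loglik_trace, f2$loglik_trace)
  expect_true(all(diff(f1$loglik_trace) > -1e-8))
})

test_that("EM recovers weights of a separated two-component mixture", {
  mix <- ssd_mixture(c(0.6, 0.4), list(
    ssd_params(c(20, 2, 2)), ssd_params(c(2, 2, 20))))
  Y <- rssd_mixture(2000, mix, seed = 14)
  f <- fit_em(Y, 2, seed = 15)
  expect_equal(sort(f$model$weights), c(0.4, 0.6), tolerance = 0.05)
})

test_that("EM refuses degenerate data", {
  Y <- matrix(rep(c(0.3, 0.3, 0.4), 20), ncol = 3, byrow = TRUE)
  expect_error(fit_em(Y, 2), "degenerate")
})

test_that("shape-estimation error shrinks with sample size (median over seeds)", {
  truth <- ssd_params(c(5, 2, 3), c(0.3, 0.3, 0.4), 1.5)
  err_at <- function(n, s) {
    Y <- rssd(n, truth, seed = s)
    est <- fit_em(Y, 1, seed = s + 100)$model$components[[1]]
    max(abs(est$alpha - truth$alpha) / truth$alpha)
  }
  e500 <- vapply(1:10, function(s) err_at(500, s), numeric(1))
  e5000 <- vapply(1:10, function(s) err_at(5000, s), numeric(1))
  expect_lt(median(e5000), median(e500))
})
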