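test_that("Fisher score vanishes at the single-component MLE", {
  Y <- rssd(500, ssd_params(c(5, 2, 3), c(0.3, 0.3, 0.4), 1.3), seed = 31)
  fit <- fit_em(Y, 1, seed = 32)
  fs <- fisher_score(feature_bag("a", Y), fit$model)
  expect_length(fs$grad_pi, 0)
  expect_lt(max(abs(fs$grad_alpha)), 0.05)
})

test_that("Fisher shape-gradient matches finite differences of the bag likelihood", {
  expect_lt(experiment_fisher_fd(seed = 33), 1e-5)
})

test_that("Fisher weight-gradient matches finite differences along the weight constraint", {
  mk <- test_mixture_k2()
  Y <- rssd_mixture(30, mk, seed = 34)
  fs <- fisher_score(feature_bag("a", Y), mk)
  # independent check: perturb (pi_1, pi_2) -> (pi_1 - d, pi_2 + d)
  d <- 1e-6
  ll <- function(w) {
    sum(dssd_mixture(Y, ssd_mixture(w, mk$components), log = TRUE))
  }
  fd <- (ll(mk$weights + c(-d, d)) - ll(mk$weights + c(d, -d))) / (2 * d)
  expect_equal(fs$grad_pi[1] * 30, fd, tolerance = 1e-4 * abs(fd))
})

test_that("Fisher kernel matrix is symmetric with non-negative diagonal", {
  mk <- test_mixture_k2()
  bags <- lapply(1:5, function(i) {
    feature_bag(paste0("b", i), rssd_mixture(20, mk, seed = 40 + i))
  })
  bags[[5]] <- feature_bag("b5", bags[[4]]$vectors)   # duplicate content
  Km <- fisher_kernel_matrix(bags, mk)
  expect_true(isSymmetric(unname(Km), tol = 1e-9))
  expect_true(all(diag(Km) >= 0))
  # identical bags give identical rows
  expect_equal(unname(Km[4, ]), unname(Km[5, ]), tolerance = 1e-9)
})

test_that("symmetrized KL estimator: self-divergence, non-negativity, oracle", {
  p <- ssd_mixture(1, list(ssd_params(c(3, 2, 4), b = 1)))
  q <- ssd_mixture(1, list(ssd_params(c(2, 5, 3), b = 1)))
  expect_identical(as.numeric(skl_divergence_mc(p, p, L = 100, seed = 1)), 0)

  est <- skl_divergence_mc(p, q, L = 10000, seed = 2)
  truth <- ssdmix:::dirichlet_kl(c(3, 2, 4), c(2, 5, 3)) +
    ssdmix:::dirichlet_kl(c(2, 5, 3), c(3, 2, 4))
  expect_lt(abs(as.numeric(est) - truth), 3 * attr(est, "se"))

  set.seed(3)
  for (i in 1:5) {
    a1 <- runif(3, 0.5, 6); a2 <- runif(3, 0.5, 6)
    m1 <- ssd_mixture(1, list(ssd_params(a1, b = 1)))
    m2 <- ssd_mixture(1, list(ssd_params(a2, b = 1)))
    d <- skl_divergence_mc(m1, m2, L = 1000, seed = 50 + i)
    expect_gt(as.numeric(d), -3 * attr(d, "se"))
  }
})

test_that("Monte Carlo standard error shrinks like 1/sqrt(L)", {
  p <- ssd_mixture(1, list(ssd_params(c(3, 2, 4), b = 1)))
  q <- ssd_mixture(1, list(ssd_params(c(2, 5, 3), b = 1)))
  Ls <- c(100, 1000, 10000)
  ses <- vapply(Ls, function(L) {
    attr(skl_divergence_mc(p, q, L = L, seed = 7), "se")
  }, numeric(1))
  slope <- coef(lm(log(ses) ~ log(Ls)))[2]
  expect_lt(abs(slope + 0.5), 0.1)
})

test_that("Bhattacharyya estimator: self-affinity, bound, oracle", {
  p <- ssd_mixture(1, list(ssd_params(c(3, 2, 4), b = 1)))
  q <- ssd_mixture(1, list(ssd_params(c(2, 5, 3), b = 1)))
  expect_identical(as.numeric(bhattacharyya_mc(p, p, L = 100, seed = 1)), 1)

  est <- bhattacharyya_mc(p, q, L = 10000, seed = 2)
  truth <- ssdmix:::dirichlet_bhattacharyya(c(3, 2, 4), c(2, 5, 3))
  expect_lt(abs(as.numeric(est) - truth), 3 * attr(est, "se"))
  expect_lte(as.numeric(est), 1 + 3 * attr(est, "se"))
})

test_that("divergence kernel matrices have unit diagonal, symmetry, and exp(-B) scaling", {
  mk <- test_mixture_k2()
  models <- lapply(1:4, function(i) {
    fit_em(rssd_mixture(60, mk, seed = 60 + i), 1, seed = i)$model
  })
  names(models) <- paste0("m", 1:4)
  K1 <- skk_kernel_matrix(models, B = 1, L = 400, seed = 5, psd_repair = FALSE)
  expect_equal(unname(diag(K1)), rep(1, 4))
  expect_true(isSymmetric(unname(K1)))
  expect_true(all(K1 > 0 & K1 <= 1))
  K2 <- skk_kernel_matrix(models, B = 2, L = 400, seed = 5, psd_repair = FALSE)
  off <- upper.tri(K1)
  expect_equal(K2[off], K1[off]^2, tolerance = 1e-10)

  Kb <- bk_kernel_matrix(models, L = 400, seed = 5, psd_repair = FALSE)
  expect_equal(unname(diag(Kb)), rep(1, 4))
  expect_true(isSymmetric(unname(Kb)))
})

test_that("PSD repair clips negative eigenvalues and preserves PSD inputs", {
  A <- matrix(c(1, 2, 2, 1), 2, 2)           # eigenvalues 3 and -1
  R <- ensure_psd(A, jitter = 0)
  expect_equal(R, matrix(1.5, 2, 2), tolerance = 1e-10)

  B <- diag(2) + 0.3
  expect_equal(ensure_psd(B, jitter = 0), B, tolerance = 1e-10)
  expect_gte(min(eigen(ensure_psd(A), symmetric = TRUE)$values), -1e-8)
  expect_error(ensure_psd(matrix(c(1, 2, 3, 1), 2, 2)), "symmetric")
})
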