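# Mixture-derived SVM kernels: Fisher scores/kernel under a shared background
# model, and Monte Carlo symmetrized-KL and Bhattacharyya kernels between
# per-image mixtures.

# ---- generic mixture interface ---------------------------------------------
# The MC kernels only need a log-density and a sampler, so they work for any
# mixture family implementing these generics (the Gaussian baseline in the
# classification pipeline provides its own methods).

#' Log-density / sampler generics for mixture families
#'
#' The Monte Carlo kernels are generic over mixture families: any class
#' implementing these two generics can be compared.
#'
#' @param model a mixture model object.
#' @param x matrix of points (one per row).
#' @param n number of draws.
#' @param seed optional integer seed.
#' @return `mixture_log_density()`: numeric vector of log-densities;
#'   `mixture_sample()`: matrix of draws.
#' @export
mixture_log_density <- function(model, x) UseMethod("mixture_log_density")

#' @rdname mixture_log_density
#' @export
mixture_sample <- function(model, n, seed = NULL) UseMethod("mixture_sample")

#' @export
mixture_log_density.ssd_mixture <- function(model, x) dssd_mixture(x, model, log = TRUE)

#' @export
mixture_sample.ssd_mixture <- function(model, n, seed = NULL) {
  rssd_mixture(n, model, seed = seed)
}

mixture_dim <- function(model) UseMethod("mixture_dim")
#' @export
mixture_dim.ssd_mixture <- function(model) model$dim
#' @export
mixture_dim.default <- function(model) model$dim

# ---- Fisher scores and kernel ----------------------------------------------

#' Fisher score of a feature bag under a background SSD mixture
#'
#' The gradient of the bag's log-likelihood with respect to the background
#' model's mixing weights and shape parameters, normalised by bag size.
#' With responsibilities `Z` from [e_step()] of the bag under the model:
#' the weight block (component 1 is the sum-constraint reference, leaving
#' `K - 1` free entries) is `sum_i (Z_ij / pi_j - Z_i1 / pi_1)`; the shape
#' block, row `j` coordinate `d`, is
#' `sum_i Z_ij * (psi(alpha_j+) - psi(alpha_jd) +
#' (log y_id - log beta_jd) / b_j - log sum_d (y_id / beta_jd)^(1/b_j))`.
#'
#' @param bag a [feature_bag()] (or an `N x D` matrix).
#' @param ref_model the background [ssd_mixture()] fitted on pooled training
#'   descriptors.
#' @return an object of class `"fisher_score"`: list with `grad_pi`
#'   (length `K - 1`), `grad_alpha` (`K x D`), and `concatenated`.
#' @export
fisher_score <- function(bag, ref_model) {
  stopifnot(inherits(ref_model, "ssd_mixture"))
  Y <- if (inherits(bag, "feature_bag")) bag$vectors else as.matrix(bag)
  if (nrow(Y) < 1L) stop("empty bag", call. = FALSE)
  Y <- as_simplex_matrix(Y, ref_model$dim)
  N <- nrow(Y); K <- ref_model$K; D <- ref_model$dim
  lY <- base::log(Y)
  Z <- e_step(Y, ref_model)
  pi_ <- ref_model$weights
  grad_pi <- if (K > 1L) {
    s <- colSums(Z) / pi_            # sum_i Z_ij / pi_j, per component
    s[-1L] - s[1L]
  } else numeric(0)
  grad_alpha <- matrix(0, K, D)
  for (j in seq_len(K)) {
    th <- ref_model$components[[j]]
    ap <- sum(th$alpha)
    U <- sweep(lY, 2L, base::log(th$beta), "-") / th$b
    lS <- row_logsumexp(U)
    G <- sweep(U - lS, 2L, digamma(ap) - digamma(th$alpha), "+")
    grad_alpha[j, ] <- drop(crossprod(Z[, j], G))
  }
  grad_pi <- grad_pi / N
  grad_alpha <- grad_alpha / N
  structure(list(grad_pi = grad_pi, grad_alpha = grad_alpha,
                 concatenated = c(grad_pi, as.vector(t(grad_alpha)))),
            class = "fisher_score")
}

#' Stack Fisher scores of several bags into a matrix
#'
#' @param bags list of [feature_bag()] objects.
#' @inheritParams fisher_score
#' @return `M x ((K-1) + K*D)` matrix, row names = image ids.
#' @export
fisher_scores_matrix <- function(bags, ref_model) {
  S <- t(vapply(bags, function(b) fisher_score(b, ref_model)$concatenated,
                numeric((ref_model$K - 1L) + ref_model$K * ref_model$dim)))
  rownames(S) <- vapply(bags, function(b) b$image_id, character(1))
  S
}

#' Fisher kernel matrix between feature bags
#'
#' Inner products of Fisher scores under an approximation of the inverse
#' Fisher information: `"identity"` (default) standardises each score
#' coordinate (centre and scale) across the reference bags and uses the
#' identity metric; `"diagonal"` scales by the empirical second moment
#' without centring. The standardisation statistics are computed from
#' `stats_from` (default: the bags themselves) so a training set can fix
#' them for held-out bags.
#'
#' @param bags list of [feature_bag()] objects.
#' @param ref_model background [ssd_mixture()].
#' @param info `"identity"` or `"diagonal"`.
#' @param stats_from optional list of bags from which to compute the
#'   standardisation statistics (defaults to `bags`).
#' @return symmetric `M x M` kernel matrix with image-id dimnames.
#' @export
fisher_kernel_matrix <- function(bags, ref_model, info = c("identity", "diagonal"),
                                 stats_from = NULL) {
  info <- match.arg(info)
  S <- fisher_scores_matrix(bags, ref_model)
  S0 <- if (is.null(stats_from)) S else fisher_scores_matrix(stats_from, ref_model)
  if (info == "identity") {
    ctr <- colMeans(S0)
    scl <- apply(S0, 2L, stats::sd)
  } else {
    ctr <- rep(0, ncol(S0))
    scl <- sqrt(colMeans(S0^2))
  }
  scl[!is.finite(scl) | scl < 1e-12] <- 1
  Z <- sweep(sweep(S, 2L, ctr, "-"), 2L, scl, "/")
  Km <- tcrossprod(Z)
  Km <- (Km + t(Km)) / 2
  dimnames(Km) <- list(rownames(S), rownames(S))
  Km
}

# ---- Monte Carlo divergences ------------------------------------------------

#' Symmetrized Kullback-Leibler divergence between mixtures, by Monte Carlo
#'
#' Estimates `KL(p1 || p2) + KL(p2 || p1)` by ancestral sampling:
#' `mean(log p1(x) - log p2(x))` over `L` draws `x ~ p1` plus the mirrored
#' term over `L` draws from `p2`. With `one_sided = TRUE` only the first
#' term is returned.
#'
#' @param p1,p2 mixture models implementing [mixture_log_density()] and
#'   [mixture_sample()] (e.g. [ssd_mixture()]).
#' @param L Monte Carlo sample count per side.
#' @param seed optional integer seed (deterministic estimate when given).
#' @param one_sided if `TRUE`, return only `KL(p1 || p2)`.
#' @return the divergence estimate, with attribute `se` (Monte Carlo
#'   standard error).
#' @export
skl_divergence_mc <- function(p1, p2, L = 5000L, seed = NULL, one_sided = FALSE) {
  stopifnot(L >= 1)
  if (mixture_dim(p1) != mixture_dim(p2)) stop_dim("mixture dimensions differ")
  if (!is.null(seed)) set.seed(seed)
  x <- mixture_sample(p1, L)
  l1 <- mixture_log_density(p1, x) - mixture_log_density(p2, x)
  if (one_sided) {
    est <- mean(l1)
    se <- stats::sd(l1) / sqrt(L)
  } else {
    z <- mixture_sample(p2, L)
    l2 <- mixture_log_density(p2, z) - mixture_log_density(p1, z)
    est <- mean(l1) + mean(l2)
    se <- sqrt(stats::var(l1) / L + stats::var(l2) / L)
  }
  structure(est, se = se)
}

#' Bhattacharyya affinity between mixtures, by Monte Carlo
#'
#' Two-sided importance-sampling estimate of
#' `integral sqrt(p(y) q(y)) dy`:
#' `w * mean(sqrt(q(x)/p(x)))` over draws `x ~ p` plus
#' `(1-w) * mean(sqrt(p(z)/q(z)))` over draws `z ~ q`, with mixing weight
#' `w = mc_mix_weight` (default 0.5). Equals 1 exactly when `p` and `q`
#' coincide.
#'
#' @inheritParams skl_divergence_mc
#' @param p,q mixture models.
#' @param mc_mix_weight weight of the `p`-side term, in `[0, 1]`.
#' @return affinity estimate in `(0, 1]` up to MC noise, with attribute `se`.
#' @export
bhattacharyya_mc <- function(p, q, L = 5000L, seed = NULL, mc_mix_weight = 0.5) {
  stopifnot(L >= 1, mc_mix_weight >= 0, mc_mix_weight <= 1)
  if (mixture_dim(p) != mixture_dim(q)) stop_dim("mixture dimensions differ")
  if (!is.null(seed)) set.seed(seed)
  w <- mc_mix_weight
  x <- mixture_sample(p, L)
  t1 <- exp(0.5 * (mixture_log_density(q, x) - mixture_log_density(p, x)))
  z <- mixture_sample(q, L)
  t2 <- exp(0.5 * (mixture_log_density(p, z) - mixture_log_density(q, z)))
  est <- w * mean(t1) + (1 - w) * mean(t2)
  se <- sqrt(w^2 * stats::var(t1) / L + (1 - w)^2 * stats::var(t2) / L)
  structure(est, se = se)
}

# ---- kernel matrices from per-image mixtures --------------------------------

pair_models_matrix <- function(models, pair_fun, diag_value = 1) {
  M <- length(models)
  ids <- names(models) %||% as.character(seq_len(M))
  Km <- diag(diag_value, M)
  if (M > 1L) for (i in 1:(M - 1L)) for (j in (i + 1L):M) {
    Km[i, j] <- Km[j, i] <- pair_fun(i, j)
  }
  dimnames(Km) <- list(ids, ids)
  Km
}

#' Symmetrized-KL kernel matrix between per-image mixtures
#'
#' Entry `(a, b)` is `exp(-B * D_sym(model_a, model_b))` with `D_sym` the
#' Monte Carlo symmetrized KL divergence; the diagonal is 1. Each unordered
#' pair uses a seed derived from `seed` and the pair indices, so the matrix
#' is symmetric by construction.
#'
#' @param models named list of mixture models (one per image).
#' @param B positive scale factor inside the exponential.
#' @param L Monte Carlo samples per side per pair.
#' @param seed master integer seed.
#' @param psd_repair if `TRUE` (default) pass the result through
#'   [ensure_psd()].
#' @param one_sided see [skl_divergence_mc()].
#' @return symmetric kernel matrix with image-id dimnames.
#' @export
skk_kernel_matrix <- function(models, B = 1, L = 5000L, seed = 0L,
                              psd_repair = TRUE, one_sided = FALSE) {
  stopifnot(B > 0)
  Km <- pair_models_matrix(models, function(i, j) {
    d <- skl_divergence_mc(models[[i]], models[[j]], L = L,
                           seed = derive_seed(seed, i, j), one_sided = one_sided)
    exp(-B * max(as.numeric(d), 0))
  })
  if (psd_repair) Km <- ensure_psd(Km)
  Km
}

#' Bhattacharyya kernel matrix between per-image mixtures
#'
#' Entry `(a, b)` is the Monte Carlo Bhattacharyya affinity; the diagonal is
#' forced to 1 (the affinity of a density with itself).
#'
#' @inheritParams skk_kernel_matrix
#' @param mc_mix_weight see [bhattacharyya_mc()].
#' @return symmetric kernel matrix with image-id dimnames.
#' @export
bk_kernel_matrix <- function(models, L = 5000L, seed = 0L, psd_repair = TRUE,
                             mc_mix_weight = 0.5) {
  Km <- pair_models_matrix(models, function(i, j) {
    as.numeric(bhattacharyya_mc(models[[i]], models[[j]], L = L,
                                seed = derive_seed(seed, i, j),
                                mc_mix_weight = mc_mix_weight))
  })
  if (psd_repair) Km <- ensure_psd(Km)
  Km
}

#' Repair a symmetric matrix to positive semidefiniteness
#'
#' Eigendecomposes, clips negative eigenvalues to zero, reconstructs, and
#' adds `jitter` to the diagonal. Monte Carlo kernel estimates (and
#' `exp(-B * divergence)` matrices generally) are not guaranteed PSD, and
#' the SVM solver needs a valid Gram matrix.
#'
#' @param K symmetric numeric matrix.
#' @param jitter small ridge added to the diagonal (default `1e-8`).
#' @return repaired symmetric matrix, smallest eigenvalue `>= -1e-8`.
#' @export
ensure_psd <- function(K, jitter = 1e-8) {
  if (!is.matrix(K) || !isSymmetric(unname(K), tol = 1e-9)) {
    stop("input must be a symmetric matrix", call. = FALSE)
  }
  dn <- dimnames(K)
  eg <- eigen((K + t(K)) / 2, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  out <- eg$vectors %*% (ev * t(eg$vectors))
  out <- (out + t(out)) / 2 + jitter * diag(nrow(K))
  dimnames(out) <- dn
  out
}
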