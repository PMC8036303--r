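# EM for finite SSD mixtures: K-means initialisation, soft E-step via
# log-sum-exp, numerical M-step (bounded quasi-Newton on transformed
# coordinates with analytic gradients).

# ---- parameter transforms ---------------------------------------------------
# Unconstrained coordinates per component, length 2D:
#   log(alpha) (D), additive-log-ratio of beta (D-1, last coord is reference),
#   log(b) (1). This gives exactly 2D free parameters per component, matching
#   the K(2D+1)-1 total parameter count with the K-1 free mixing weights.

theta_to_par <- function(theta) {
  D <- length(theta$alpha)
  c(base::log(theta$alpha),
    base::log(theta$beta[-D]) - base::log(theta$beta[D]),
    base::log(theta$b))
}

par_to_theta <- function(par, D) {
  la <- par[seq_len(D)]
  cc <- par[D + seq_len(D - 1)]
  lb <- par[2 * D]
  e <- c(exp(cc), 1)
  ssd_params(alpha = exp(la), beta = e / sum(e), b = exp(lb))
}

par_bounds <- function(D) {
  bb <- ssd_b_bounds()
  list(lower = c(rep(base::log(1e-3), D), rep(-30, D - 1), base::log(bb[1])),
       upper = c(rep(base::log(1e4), D), rep(30, D - 1), base::log(bb[2])))
}

# Weighted negative log-likelihood and its analytic gradient in the
# transformed coordinates. `lY` is log of the N x D data matrix, `w` the
# responsibility weights.
weighted_nll <- function(par, lY, w) {
  D <- ncol(lY)
  a <- exp(par[seq_len(D)])
  cc <- par[D + seq_len(D - 1)]
  b <- exp(par[2 * D])
  e <- c(exp(cc), 1); be <- e / sum(e)
  ap <- sum(a)
  U <- sweep(lY, 2L, base::log(be), "-")
  lS <- row_logsumexp(U / b)
  logc <- lgamma(ap) - sum(lgamma(a)) - (D - 1) * base::log(b) -
    sum((a / b) * base::log(be))
  lp <- logc + drop(lY %*% (a / b - 1)) - ap * lS
  -sum(w * lp)
}

weighted_nll_grad <- function(par, lY, w) {
  D <- ncol(lY)
  a <- exp(par[seq_len(D)])
  cc <- par[D + seq_len(D - 1)]
  b <- exp(par[2 * D])
  e <- c(exp(cc), 1); be <- e / sum(e)
  ap <- sum(a); sw <- sum(w)
  U <- sweep(lY, 2L, base::log(be), "-")       # u_id = log y_id - log beta_d
  lS <- row_logsumexp(U / b)
  R <- exp(U / b - lS)                          # softmax rows: r_id

  # d/d alpha_d of sum_i w_i log p_i  (Fisher-score structure)
  ga <- sw * (digamma(ap) - digamma(a)) +
    drop(crossprod(w, U)) / b - sum(w * lS)
  # d/d beta_d (natural coordinates, full D)
  gbe <- (-a * sw + ap * drop(crossprod(w, R))) / (b * be)
  # d/d b
  wu_a <- drop((w %*% U) %*% a)                # sum_i w_i sum_d a_d u_id
  wu_r <- sum(w * rowSums(R * U))              # sum_i w_i sum_d r_id u_id
  gb <- -(D - 1) * sw / b - wu_a / b^2 + ap * wu_r / b^2

  # chain rules: log-alpha, alr-beta (softmax with fixed reference), log-b
  g_la <- ga * a
  g_cc <- (be * (gbe - sum(be * gbe)))[-D]
  g_lb <- gb * b
  -c(g_la, g_cc, g_lb)
}

# ---- initialisation ---------------------------------------------------------

#' K-means initialisation of an SSD mixture
#'
#' Clusters the compositions with K-means; each cluster seeds one component:
#' mixing weight = cluster fraction, location `beta` = renormalised cluster
#' mean, scale `b = 1`, and shape `alpha` by Dirichlet moment matching (the
#' method-of-moments precision from the first coordinate's mean and variance,
#' clipped to `[0.1, 500]`, spread along the cluster mean). Empty clusters
#' are re-seeded from a randomly chosen data point.
#'
#' @param data `N x D` matrix of compositions.
#' @param K number of components, `1 <= K <= N`.
#' @param seed integer seed (K-means uses random restarts).
#' @return an [ssd_mixture()].
#' @export
init_kmeans <- function(data, K, seed = 0L) {
  Y <- as_simplex_matrix(data, ncol(as.matrix(data)))
  N <- nrow(Y)
  if (K > N) stop("K cannot exceed the number of data points", call. = FALSE)
  set.seed(seed)
  if (K == 1L) {
    cl <- rep(1L, N)
  } else {
    km <- tryCatch(
      stats::kmeans(Y, centers = K, nstart = 5, iter.max = 50),
      error = function(e) NULL, warning = function(w) NULL)
    if (is.null(km)) {
      set.seed(seed)
      km <- tryCatch(stats::kmeans(Y, centers = K, nstart = 5, iter.max = 50),
                     error = function(e) NULL)
    }
    if (!is.null(km) && length(unique(km$cluster)) == K) {
      cl <- km$cluster
    } else {
      # fallback (e.g. K close to N with ties): nearest of K sampled points
      ctr <- Y[sample.int(N, K), , drop = FALSE]
      d2 <- outer(rowSums(Y^2), rep(1, K)) - 2 * Y %*% t(ctr) +
        outer(rep(1, N), rowSums(ctr^2))
      cl <- max.col(-d2, ties.method = "first")
      cl[sample.int(N, K)] <- seq_len(K)   # guarantee no empty cluster
    }
  }
  comps <- vector("list", K)
  wts <- numeric(K)
  for (k in seq_len(K)) {
    idx <- which(cl == k)
    if (!length(idx)) idx <- sample.int(N, 1L)   # re-seed empty cluster
    wts[k] <- length(idx) / N
    Yk <- Y[idx, , drop = FALSE]
    mu <- colMeans(Yk); mu <- mu / sum(mu)
    m1 <- mean(Yk[, 1]); v1 <- stats::var(Yk[, 1])
    s <- if (length(idx) > 1 && is.finite(v1) && v1 > 0) m1 * (1 - m1) / v1 - 1 else 10
    s <- min(max(s, 0.1), 500)
    comps[[k]] <- ssd_params(alpha = pmax(s * mu, 1e-3), beta = mu, b = 1)
  }
  wts <- wts / sum(wts)
  ssd_mixture(weights = wts, components = comps)
}

# ---- E / M steps ------------------------------------------------------------

#' E-step: posterior responsibilities
#'
#' Row `i`, column `j` is `pi_j p(y_i | theta_j) / sum_l pi_l p(y_i | theta_l)`,
#' computed with log-sum-exp; every row sums to 1.
#'
#' @param data `N x D` matrix of compositions.
#' @param model an [ssd_mixture()].
#' @return `N x K` responsibility matrix.
#' @export
e_step <- function(data, model) {
  W <- component_log_weighted(data, model)
  Z <- exp(W - row_logsumexp(W))
  Z / rowSums(Z)
}

#' Hard component assignment
#'
#' Argmax of each responsibility row, ties broken toward the lowest index.
#'
#' @param Z responsibility matrix from [e_step()].
#' @return integer vector of component labels.
#' @export
hard_assign <- function(Z) max.col(Z, ties.method = "first")

#' M-step: update mixture parameters given responsibilities
#'
#' Mixing weights have the closed form `pi_j = mean(Z[, j])`. Each
#' component's `(alpha, beta, b)` is updated by bounded quasi-Newton
#' (L-BFGS-B) on unconstrained coordinates (log alpha, additive-log-ratio
#' beta, log b) with analytic gradients, warm-started from the current
#' parameters; an update that would lower that component's weighted
#' log-likelihood is rejected in favour of the current parameters.
#'
#' @param data `N x D` matrix of compositions.
#' @param Z `N x K` responsibility matrix.
#' @param model current [ssd_mixture()].
#' @param optim_maxit iteration cap for the inner optimizer.
#' @return updated [ssd_mixture()].
#' @export
m_step <- function(data, Z, model, optim_maxit = 50L) {
  Y <- as_simplex_matrix(data, model$dim)
  if (nrow(Z) != nrow(Y) || ncol(Z) != model$K) stop_dim("Z does not match data/model")
  lY <- base::log(Y)
  D <- model$dim
  bounds <- par_bounds(D)
  wts <- colMeans(Z)
  wts <- pmax(wts, 1e-12); wts <- wts / sum(wts)
  comps <- model$components
  for (j in seq_len(model$K)) {
    w <- Z[, j]
    if (sum(w) < 1e-10) next
    p0 <- theta_to_par(comps[[j]])
    f0 <- weighted_nll(p0, lY, w)
    res <- tryCatch(
      stats::optim(p0, fn = weighted_nll, gr = weighted_nll_grad,
                   lY = lY, w = w, method = "L-BFGS-B",
                   lower = bounds$lower, upper = bounds$upper,
                   control = list(maxit = optim_maxit)),
      error = function(e) NULL)
    if (!is.null(res) && is.finite(res$value) && res$value <= f0) {
      comps[[j]] <- par_to_theta(res$par, D)
    }
  }
  ssd_mixture(weights = wts, components = comps)
}

# ---- full EM ----------------------------------------------------------------

#' Fit an SSD mixture by expectation-maximisation
#'
#' Initialises with [init_kmeans()], then alternates [e_step()] and
#' [m_step()] until the relative change in total log-likelihood falls below
#' `tol` or `max_iter` is reached. The log-likelihood trace is
#' non-decreasing (up to a small numerical slack), and the whole fit is
#' deterministic for a fixed seed.
#'
#' Components whose weight collapses below `1/(2N)` are re-initialised once
#' from the worst-fit data point; if they collapse again they are dropped
#' with a warning.
#'
#' @param data `N x D` matrix of compositions, or a [feature_bag()].
#' @param K number of components.
#' @param max_iter maximum EM iterations (default 200).
#' @param tol relative log-likelihood convergence tolerance (default 1e-6).
#' @param seed integer seed for the initialisation.
#' @param optim_maxit inner optimizer iteration cap per component per M-step.
#' @return an object of class `"ssd_fit"`: list with `model`
#'   ([ssd_mixture()]), `loglik_trace`, `n_iter`, `converged`.
#' @export
fit_em <- function(data, K, max_iter = 200L, tol = 1e-6, seed = 0L,
                   optim_maxit = 50L) {
  if (inherits(data, "feature_bag")) data <- data$vectors
  Y <- as_simplex_matrix(data, ncol(as.matrix(data)))
  N <- nrow(Y)
  if (N < K) stop("need at least K data points", call. = FALSE)
  if (all(abs(sweep(Y, 2L, Y[1, ], "-")) < 1e-12)) {
    stop("degenerate data: all points identical", call. = FALSE)
  }
  model <- init_kmeans(Y, K, seed = seed)
  trace <- numeric(0)
  converged <- FALSE
  it <- 0L
  repeat {
    it <- it + 1L
    W <- component_log_weighted(Y, model)
    ll <- sum(row_logsumexp(W))
    trace <- c(trace, ll)
    if (it > 1L) {
      rel <- abs(ll - trace[it - 1L]) / (abs(trace[it - 1L]) + 1e-12)
      if (rel < tol) { converged <- TRUE; break }
    }
    if (it >= max_iter) break
    Z <- exp(W - row_logsumexp(W)); Z <- Z / rowSums(Z)
    model <- m_step(Y, Z, model, optim_maxit = optim_maxit)
    # component death handling
    dead <- which(model$weights < 1 / (2 * N))
    if (length(dead) && model$K > 1L) {
      lls <- dssd_mixture(Y, model, log = TRUE)
      worst <- order(lls)
      comps <- model$components; wts <- model$weights
      reseeded <- attr(model, "reseeded") %||% integer(0)
      keep <- rep(TRUE, model$K)
      for (d in dead) {
        if (d %in% reseeded) {
          keep[d] <- FALSE
          warning(sprintf("dropping collapsed component %d", d), call. = FALSE)
        } else {
          y0 <- Y[worst[1L], ]
          comps[[d]] <- ssd_params(alpha = pmax(10 * y0, 1e-3),
                                   beta = y0 / sum(y0), b = 1)
          wts[d] <- 1 / N
          reseeded <- c(reseeded, d)
        }
      }
      wts <- wts[keep] / sum(wts[keep])
      model <- ssd_mixture(wts, comps[keep])
      attr(model, "reseeded") <- reseeded[reseeded %in% which(keep)]
    }
  }
  attr(model, "reseeded") <- NULL
  structure(list(model = model, loglik_trace = trace, n_iter = it,
                 converged = converged, N = N),
            class = "ssd_fit")
}

#' @export
print.ssd_fit <- function(x, ...) {
  cat(sprintf("SSD mixture fit: K = %d, N = %d, logLik = %.4f, %s after %d iterations\n",
              x$model$K, x$N, utils::tail(x$loglik_trace, 1),
              if (x$converged) "converged" else "not converged", x$n_iter))
  invisible(x)
}

#' @export
logLik.ssd_fit <- function(object, ...) {
  val <- utils::tail(object$loglik_trace, 1)
  attr(val, "df") <- num_params(object$model$K, object$model$dim)
  class(val) <- "logLik"
  val
}
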