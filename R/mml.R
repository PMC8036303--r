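# Minimum Message Length scoring of fitted SSD mixtures and selection of the
# number of components K. The message length trades data fit (log-likelihood)
# against the code length of the parameters (prior + Fisher information +
# quantisation lattice term).

#' Number of free parameters of a K-component SSD mixture
#'
#' Each component carries `2D` free parameters (`D` shapes, `D - 1` free
#' location coordinates, one scale) and the mixing weights add `K - 1`,
#' giving `K(2D+1) - 1`.
#'
#' @param K number of components (`K >= 1`).
#' @param D dimension of the simplex (`D >= 2`).
#' @return integer parameter count.
#' @export
num_params <- function(K, D) {
  stopifnot(K >= 1, D >= 2)
  as.integer(K * (2 * D + 1) - 1)
}

#' Quantisation lattice constants used by the message-length criterion
#'
#' The optimal quantisation lattice constant is `1/12` in one dimension and
#' tends to `1/(2*pi*e)` as the dimension grows; the criterion approximates
#' it by `1/12` for all parameter counts.
#'
#' @return named numeric vector with elements `k1` (= 1/12) and
#'   `asymptotic` (= 1/(2*pi*e)).
#' @export
mml_lattice_constants <- function() {
  c(k1 = 1 / 12, asymptotic = 1 / (2 * pi * exp(1)))
}

#' Log prior of an SSD mixture's parameters
#'
#' The prior factorises over parameter blocks:
#' uniform Dirichlet(1) on the mixing weights (contributes `log Gamma(K)`),
#' uniform Dirichlet(1) on each component's location `beta`
#' (`log Gamma(D)` each), a constant `log(1/10)` per component for the
#' scale `b`, and a uniform box of width `e^6 * ||alpha_hat_j||` per shape
#' coordinate (`-6 - log ||alpha_hat_j||` each, Euclidean norm of the
#' component's estimated shape vector).
#'
#' @param model an [ssd_mixture()].
#' @param alpha_hat optional list of shape estimates, one per component;
#'   defaults to the model's own shape vectors.
#' @return log prior density (scalar).
#' @export
log_prior <- function(model, alpha_hat = NULL) {
  stopifnot(inherits(model, "ssd_mixture"))
  K <- model$K; D <- model$dim
  if (is.null(alpha_hat)) alpha_hat <- lapply(model$components, `[[`, "alpha")
  norms <- vapply(alpha_hat, function(a) sqrt(sum(a^2)), numeric(1))
  if (any(norms <= 0)) stop("alpha_hat has zero norm", call. = FALSE)
  lgamma(K) +                       # Dirichlet(1) prior on pi
    K * lgamma(D) +                 # Dirichlet(1) prior on each beta
    K * base::log(0.1) +            # p(b) = 1/10 per component
    sum(-D * (6 + base::log(norms)))  # uniform box on each alpha coordinate
}

# log |F(pi)| for the mixing-weight block. "standard" is N^(K-1) / prod(pi_j)
# (K-1 free weights); "as_printed" is N * prod(pi_j). K = 1 contributes 0.
fisher_pi_logdet <- function(weights, N, form = "standard") {
  K <- length(weights)
  if (K == 1L) return(0)
  if (form == "standard") {
    (K - 1) * base::log(N) - sum(base::log(weights))
  } else {
    base::log(N) + sum(base::log(weights))
  }
}

# Central finite-difference Hessian of f at x, relative step h*(1+|x_i|).
fd_hessian <- function(f, x, h = 1e-4) {
  p <- length(x)
  hh <- h * (1 + abs(x))
  H <- matrix(0, p, p)
  f0 <- f(x)
  for (i in seq_len(p)) {
    ei <- rep(0, p); ei[i] <- hh[i]
    H[i, i] <- (f(x + ei) + f(x - ei) - 2 * f0) / hh[i]^2
    if (i < p) for (j in (i + 1):p) {
      ej <- rep(0, p); ej[j] <- hh[j]
      H[i, j] <- H[j, i] <-
        (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
        (4 * hh[i] * hh[j])
    }
  }
  H
}

#' Log-determinant of the (approximate) Fisher information of a fitted mixture
#'
#' Block approximation: the mixing-weight block contributes
#' `(K-1) log N - sum_j log pi_j` (the standard mixture result; the
#' alternative form `log N + sum_j log pi_j`, as sometimes printed, is
#' available via `fisher_pi_form = "as_printed"`), and each component block
#' is the log-determinant of the central-finite-difference Hessian of the
#' negative responsibility-weighted log-likelihood at that component's
#' parameters (transformed coordinates). Non-positive-definite Hessians are
#' regularised by `1e-6 I` and flagged via the `"regularized"` attribute.
#'
#' @param model a fitted [ssd_mixture()].
#' @param data `N x D` matrix of compositions the model was fitted to.
#' @param fisher_pi_form `"standard"` (default) or `"as_printed"`.
#' @param h finite-difference step scale.
#' @return scalar `log |F(Theta)|`, with attribute `regularized`: integer
#'   vector of component indices whose Hessian needed regularisation.
#' @export
fisher_info_logdet <- function(model, data, fisher_pi_form = c("standard", "as_printed"),
                               h = 1e-4) {
  fisher_pi_form <- match.arg(fisher_pi_form)
  Y <- as_simplex_matrix(data, model$dim)
  N <- nrow(Y); K <- model$K
  lY <- base::log(Y)
  lf_pi <- fisher_pi_logdet(model$weights, N, fisher_pi_form)
  Z <- e_step(Y, model)
  regularized <- integer(0)
  lf_comp <- 0
  for (j in seq_len(K)) {
    w <- Z[, j]
    par <- theta_to_par(model$components[[j]])
    H <- fd_hessian(function(p) weighted_nll(p, lY, w), par, h = h)
    ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
    if (any(ev <= 0)) {
      regularized <- c(regularized, j)
      ev <- eigen(H + 1e-6 * diag(nrow(H)), symmetric = TRUE,
                  only.values = TRUE)$values
    }
    if (any(ev <= 0)) {
      stop(sprintf("component %d: Hessian singular after regularisation (min eig %.3g)",
                   j, min(ev)), call. = FALSE)
    }
    lf_comp <- lf_comp + sum(base::log(ev))
  }
  structure(lf_pi + lf_comp, regularized = regularized)
}

#' Message length of a fitted mixture
#'
#' `MML = -log p(Theta) - L(Theta, Y) + 0.5 log |F(Theta)| + Np/2 +
#' (Np/2) log(1/12)`, with `Np` from [num_params()] and the lattice
#' constant approximated by `1/12`.
#'
#' @param model a fitted [ssd_mixture()].
#' @param data `N x D` matrix of compositions.
#' @inheritParams fisher_info_logdet
#' @return scalar message length (nats), with attribute `breakdown`: a list
#'   with `loglik`, `log_prior`, `fisher_logdet`, `Np`.
#' @export
message_length <- function(model, data, fisher_pi_form = c("standard", "as_printed"),
                           h = 1e-4) {
  fisher_pi_form <- match.arg(fisher_pi_form)
  Y <- as_simplex_matrix(data, model$dim)
  ll <- sum(dssd_mixture(Y, model, log = TRUE))
  lp <- log_prior(model)
  fld <- fisher_info_logdet(model, Y, fisher_pi_form = fisher_pi_form, h = h)
  Np <- num_params(model$K, model$dim)
  ml <- -lp - ll + 0.5 * as.numeric(fld) + Np / 2 + (Np / 2) * base::log(1 / 12)
  structure(ml, breakdown = list(loglik = ll, log_prior = lp,
                                 fisher_logdet = as.numeric(fld), Np = Np,
                                 regularized = attr(fld, "regularized")))
}

#' Select the number of mixture components by Minimum Message Length
#'
#' Fits each candidate `K` with [fit_em()] (one shared seed policy) and
#' scores it with [message_length()]; the best `K` minimises the message
#' length, ties broken toward smaller `K`.
#'
#' @param data `N x D` matrix of compositions.
#' @param k_range integer vector of candidate component counts.
#' @param seed integer seed shared by all fits.
#' @param fisher_pi_form see [fisher_info_logdet()].
#' @param ... further arguments passed to [fit_em()].
#' @return an object of class `"mml_report"`: list with `records` (a
#'   data.frame with columns `K`, `message_length`, `loglik`, `log_prior`,
#'   `fisher_logdet`, `Np`), `best_K`, and `fits` (the fitted models).
#' @export
select_k <- function(data, k_range, seed = 0L,
                     fisher_pi_form = c("standard", "as_printed"), ...) {
  fisher_pi_form <- match.arg(fisher_pi_form)
  stopifnot(length(k_range) >= 1)
  k_range <- sort(unique(as.integer(k_range)))
  Y <- as_simplex_matrix(data, ncol(as.matrix(data)))
  if (max(k_range) > nrow(Y)) stop("max K exceeds N", call. = FALSE)
  recs <- list(); fits <- list()
  for (K in k_range) {
    row <- tryCatch({
      fit <- fit_em(Y, K, seed = seed, ...)
      ml <- message_length(fit$model, Y, fisher_pi_form = fisher_pi_form)
      br <- attr(ml, "breakdown")
      fits[[as.character(K)]] <- fit
      data.frame(K = fit$model$K, message_length = as.numeric(ml),
                 loglik = br$loglik, log_prior = br$log_prior,
                 fisher_logdet = br$fisher_logdet, Np = br$Np)
    }, error = function(e) NULL)
    if (!is.null(row)) recs[[as.character(K)]] <- row
  }
  if (!length(recs)) stop("all candidate fits failed", call. = FALSE)
  records <- do.call(rbind, recs)
  rownames(records) <- NULL
  best_K <- records$K[which.min(records$message_length)]
  structure(list(records = records, best_K = best_K, fits = fits),
            class = "mml_report")
}

#' @export
print.mml_report <- function(x, ...) {
  cat("MML component-selection report\n")
  print(x$records, row.names = FALSE)
  cat("best K:", x$best_K, "\n")
  invisible(x)
}
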