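#' Shifted-scaled Dirichlet distribution
#'
#' The shifted-scaled Dirichlet (SSD) is a three-parameter family on the unit
#' simplex generalising the Dirichlet: a shape vector `alpha` (as in the
#' Dirichlet), a location composition `beta` that perturbs the density inside
#' the simplex, and a positive scale scalar `b` that powers it. With `b = 1`
#' the SSD reduces to the scaled Dirichlet; with `b = 1` and uniform `beta`
#' (all `1/D`) it reduces to the ordinary Dirichlet(`alpha`).
#'
#' All density computations are carried out in log space (log-Gamma and
#' log-sum-exp); raw products of Gamma functions are never formed, so large
#' `sum(alpha)` is safe.
#'
#' @param alpha positive shape vector of length `D >= 2`.
#' @param beta location parameter: strictly positive vector of length `D`
#'   summing to 1 (a composition). Defaults to the uniform composition.
#' @param b positive scale scalar, constrained to `[0.05, 20]`; the density
#'   degenerates as `b` grows without bound (the `1/b^(D-1)` factor), so
#'   estimation keeps it in this box.
#' @return `ssd_params()` returns an object of class `"ssd_params"` with
#'   fields `alpha`, `beta`, `b`.
#' @examples
#' th <- ssd_params(alpha = c(3, 2, 4), beta = c(0.2, 0.3, 0.5), b = 1.5)
#' y <- rssd(5, th, seed = 1)
#' dssd(y, th, log = TRUE)
#' @export
ssd_params <- function(alpha, beta = NULL, b = 1) {
  alpha <- as.numeric(alpha)
  D <- length(alpha)
  if (D < 2) stop_dim("alpha must have length D >= 2")
  if (any(!is.finite(alpha)) || any(alpha <= 0)) {
    stop("all entries of alpha must be positive and finite", call. = FALSE)
  }
  if (is.null(beta)) beta <- rep(1 / D, D)
  beta <- as.numeric(beta)
  check_composition(beta, D, what = "beta")
  b <- as.numeric(b)
  if (length(b) != 1L || !is.finite(b) || b < ssd_b_bounds()[1] || b > ssd_b_bounds()[2]) {
    stop(sprintf("b must be a scalar in [%g, %g]", ssd_b_bounds()[1], ssd_b_bounds()[2]),
         call. = FALSE)
  }
  structure(list(alpha = alpha, beta = beta, b = b), class = "ssd_params")
}

#' Bounds within which the SSD scale parameter is kept during estimation
#' @return numeric length-2 vector `c(b_min, b_max)`.
#' @export
ssd_b_bounds <- function() c(0.05, 20)

# Validate a composition vector (strictly positive, sums to 1).
check_composition <- function(x, D = length(x), what = "composition") {
  if (length(x) != D) stop_dim(sprintf("%s must have length %d", what, D))
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop(sprintf("%s must be strictly positive", what), call. = FALSE)
  }
  if (abs(sum(x) - 1) > 1e-9) {
    stop(sprintf("%s must sum to 1 (got %.12g)", what, sum(x)), call. = FALSE)
  }
  invisible(x)
}

#' @export
print.ssd_params <- function(x, ...) {
  cat(sprintf("Shifted-scaled Dirichlet (D = %d)\n", length(x$alpha)))
  cat("  alpha:", format(x$alpha, digits = 4), "\n")
  cat("  beta :", format(x$beta, digits = 4), "\n")
  cat("  b    :", format(x$b, digits = 4), "\n")
  invisible(x)
}

# Coerce density input to an N x D matrix of interior simplex points.
as_simplex_matrix <- function(x, D, clip = 1e-12) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  x <- as.matrix(x)
  if (ncol(x) != D) stop_dim(sprintf("points have %d columns, model dimension is %d",
                                     ncol(x), D))
  if (any(x <= 0)) stop("simplex points must be strictly positive", call. = FALSE)
  if (any(abs(rowSums(x) - 1) > 1e-6)) {
    stop("simplex points must sum to 1", call. = FALSE)
  }
  pmax(x, clip)
}

#' Density of the shifted-scaled Dirichlet
#'
#' Evaluates the SSD density
#' \deqn{p(y \mid \alpha, \beta, b) = \frac{\Gamma(\alpha_+)}{\prod_d \Gamma(\alpha_d)}
#'   \frac{1}{b^{D-1}} \frac{\prod_d \beta_d^{-\alpha_d/b} y_d^{\alpha_d/b - 1}}
#'        {\left(\sum_d (y_d/\beta_d)^{1/b}\right)^{\alpha_+}}}
#' with \eqn{\alpha_+ = \sum_d \alpha_d}, entirely in log space.
#'
#' @param x a composition vector of length `D`, or an `N x D` matrix of
#'   compositions (one per row). Entries are clipped below at `1e-12`
#'   before logs.
#' @param theta an [ssd_params()] object.
#' @param log if `TRUE` return log-density.
#' @return numeric vector of (log-)densities, one per row of `x`.
#' @export
dssd <- function(x, theta, log = FALSE) {
  stopifnot(inherits(theta, "ssd_params"))
  a <- theta$alpha; be <- theta$beta; b <- theta$b
  D <- length(a); ap <- sum(a)
  Y <- as_simplex_matrix(x, D)
  lY <- base::log(Y)
  logc <- lgamma(ap) - sum(lgamma(a)) - (D - 1) * base::log(b) -
    sum((a / b) * base::log(be))
  # log sum_d (y_d / beta_d)^(1/b), stabilised row-wise
  U <- sweep(lY, 2L, base::log(be), "-") / b
  lS <- row_logsumexp(U)
  ld <- logc + drop(lY %*% (a / b - 1)) - ap * lS
  if (log) ld else exp(ld)
}

#' Sample from the shifted-scaled Dirichlet
#'
#' Draws `x ~ Dirichlet(alpha)` and applies the perturbation-powering map
#' `y = C(beta * x^b)` where `C` is closure (renormalisation to sum 1). This
#' construction has the SSD density; the test-suite verifies the
#' change of variables against the density by a Kolmogorov-Smirnov check.
#'
#' @param n number of draws (`n = 0` gives an empty matrix).
#' @param theta an [ssd_params()] object.
#' @param seed optional integer; when given the draw is deterministic.
#' @return `n x D` matrix of compositions (rows sum to 1, entries > 0).
#' @export
rssd <- function(n, theta, seed = NULL) {
  stopifnot(inherits(theta, "ssd_params"), n >= 0)
  if (!is.null(seed)) set.seed(seed)
  D <- length(theta$alpha)
  if (n == 0) return(matrix(numeric(0), nrow = 0L, ncol = D))
  G <- matrix(stats::rgamma(n * D, shape = rep(theta$alpha, each = n)),
              nrow = n, ncol = D)
  X <- G / rowSums(G)
  # power then perturb, in log space to avoid underflow for large b
  L <- theta$b * base::log(pmax(X, 1e-300))
  L <- sweep(L, 2L, base::log(theta$beta), "+")
  m <- row_max(L)
  W <- exp(L - m)
  Y <- W / rowSums(W)
  # keep strictly interior
  Y <- pmax(Y, 1e-300)
  Y / rowSums(Y)
}

#' Finite mixture of shifted-scaled Dirichlet components
#'
#' @param weights positive mixing proportions summing to 1 (length `K`).
#' @param components list of `K` [ssd_params()] objects sharing dimension.
#' @return an object of class `"ssd_mixture"` with fields `weights`,
#'   `components`, `dim`, `K`.
#' @export
ssd_mixture <- function(weights, components) {
  weights <- as.numeric(weights)
  K <- length(weights)
  if (K < 1 || length(components) != K) {
    stop_dim("weights and components must have the same length K >= 1")
  }
  if (any(weights <= 0) || abs(sum(weights) - 1) > 1e-9) {
    stop("mixing weights must be positive and sum to 1", call. = FALSE)
  }
  ok <- vapply(components, inherits, logical(1), what = "ssd_params")
  if (!all(ok)) stop("components must be ssd_params objects", call. = FALSE)
  Ds <- vapply(components, function(th) length(th$alpha), integer(1))
  if (length(unique(Ds)) != 1L) stop_dim("all components must share dimension D")
  structure(list(weights = weights, components = components,
                 dim = Ds[1], K = K),
            class = "ssd_mixture")
}

#' @export
print.ssd_mixture <- function(x, ...) {
  cat(sprintf("SSD mixture: K = %d components, D = %d\n", x$K, x$dim))
  cat("  weights:", format(x$weights, digits = 4), "\n")
  for (k in seq_len(x$K)) {
    th <- x$components[[k]]
    cat(sprintf("  [%d] alpha = (%s), beta = (%s), b = %.4g\n", k,
                paste(format(th$alpha, digits = 4), collapse = ", "),
                paste(format(th$beta, digits = 4), collapse = ", "), th$b))
  }
  invisible(x)
}

# N x K matrix of per-component log densities log pi_k + log p(y | theta_k).
component_log_weighted <- function(x, model) {
  Y <- as_simplex_matrix(x, model$dim)
  out <- matrix(0, nrow(Y), model$K)
  for (k in seq_len(model$K)) {
    out[, k] <- base::log(model$weights[k]) + dssd(Y, model$components[[k]], log = TRUE)
  }
  out
}

#' Mixture density of an SSD mixture
#'
#' Log-sum-exp of `log pi_k + dssd(x, theta_k, log = TRUE)` over components.
#'
#' @inheritParams dssd
#' @param model an [ssd_mixture()].
#' @return numeric vector of (log-)densities.
#' @export
dssd_mixture <- function(x, model, log = FALSE) {
  stopifnot(inherits(model, "ssd_mixture"))
  W <- component_log_weighted(x, model)
  ld <- row_logsumexp(W)
  if (log) ld else exp(ld)
}

#' Sample from an SSD mixture (ancestral sampling)
#'
#' @param n number of draws.
#' @param model an [ssd_mixture()].
#' @param seed optional integer seed.
#' @return `n x D` matrix of compositions.
#' @export
rssd_mixture <- function(n, model, seed = NULL) {
  stopifnot(inherits(model, "ssd_mixture"), n >= 0)
  if (!is.null(seed)) set.seed(seed)
  D <- model$dim
  if (n == 0) return(matrix(numeric(0), 0L, D))
  z <- sample.int(model$K, size = n, replace = TRUE, prob = model$weights)
  Y <- matrix(NA_real_, n, D)
  for (k in seq_len(model$K)) {
    idx <- which(z == k)
    if (length(idx)) Y[idx, ] <- rssd(length(idx), model$components[[k]])
  }
  Y
}

#' Project an arbitrary real vector onto the interior of the simplex
#'
#' Shifts the vector by `-min(v)` when any entry is non-positive, adds
#' `epsilon` to every entry, and renormalises to sum 1. This is the bridge
#' from raw feature descriptors (Haralick statistics, keypoint descriptors)
#' to the simplex support the mixture model assumes.
#'
#' @param v numeric vector of length `D >= 2`, or a matrix (rows projected
#'   independently).
#' @param epsilon small positive constant added to every entry (default
#'   `1e-6`); guards against zeros after shifting.
#' @return a composition vector (or matrix of compositions).
#' @export
project_to_simplex <- function(v, epsilon = 1e-6) {
  if (is.matrix(v)) {
    out <- t(apply(v, 1L, project_to_simplex, epsilon = epsilon))
    dimnames(out) <- dimnames(v)
    return(out)
  }
  v <- as.numeric(v)
  if (length(v) < 2) stop_dim("vector must have length D >= 2")
  if (any(!is.finite(v))) stop("non-finite entries", call. = FALSE)
  if (max(v) == min(v) && epsilon == 0) {
    stop("degenerate vector: all entries equal with epsilon = 0", call. = FALSE)
  }
  if (any(v <= 0)) v <- v - min(v)
  v <- v + epsilon
  v / sum(v)
}
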