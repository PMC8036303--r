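# Internal numerical helpers shared across modules.

#' @keywords internal
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Row-wise log-sum-exp of a matrix (column-wise pmax: avoids apply()'s
# per-row overhead, which dominates on tall matrices).
row_max <- function(X) {
  m <- X[, 1L]
  if (ncol(X) > 1L) for (j in 2:ncol(X)) m <- pmax(m, X[, j])
  m
}

row_logsumexp <- function(X) {
  m <- row_max(X)
  finite <- is.finite(m)
  out <- m
  if (any(finite)) {
    out[finite] <- m[finite] + log(rowSums(exp(X[finite, , drop = FALSE] - m[finite])))
  }
  out
}

# Deterministic sub-seed derivation: keeps every derived seed a valid
# 32-bit integer and symmetric in (i, j) when callers sort the pair.
derive_seed <- function(master, i, j = 0L) {
  s <- (as.double(master) * 48271 + as.double(i) * 1000003 + as.double(j) * 997) %%
    2147483647
  as.integer(s)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_dim <- function(msg) stop(msg, call. = FALSE)
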