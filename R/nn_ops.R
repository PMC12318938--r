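# Elementary network operations with matched forward/backward pairs. The whole
# network and its backpropagation are written in base R; correctness of every
# hand-derived gradient is guarded by finite-difference checks in the tests.

add_bias <- function(M, b) M + rep(b, each = nrow(M))

# Activations (value and derivative). GELU is the exact Gaussian form.
act_fun <- function(name) {
  switch(name,
    gelu = list(f = function(x) x * stats::pnorm(x),
                df = function(x) stats::pnorm(x) + x * stats::dnorm(x)),
    relu = list(f = function(x) pmax(x, 0),
                df = function(x) (x > 0) * 1),
    silu = list(f = function(x) x * stats::plogis(x),
                df = function(x) { s <- stats::plogis(x); s + x * s * (1 - s) }),
    tanh = list(f = tanh, df = function(x) 1 - tanh(x)^2),
    abort(sprintf("unknown activation %s", name), "wheatmoe_config_error"))
}

gelu <- function(x) x * stats::pnorm(x)
silu <- function(x) x * stats::plogis(x)

softmax_rows <- function(M) {
  mx <- M[cbind(seq_len(nrow(M)), max.col(M, ties.method = "first"))]
  E <- exp(M - mx)
  E / rowSums(E)
}

# GELU with the standard-normal CDF cached for reuse in the backward pass
gelu_fwd <- function(x) {
  phi <- stats::pnorm(x)
  list(Y = x * phi, phi = phi, x = x)
}
gelu_bwd <- function(dY, cache) dY * (cache$phi + cache$x * stats::dnorm(cache$x))

# d(softmax)/dlogits given upstream dP and probabilities P (rowwise)
softmax_rows_bwd <- function(dP, P) P * (dP - rowSums(dP * P))

#' Sinusoidal positional encoding
#'
#' `PE[pos, 2i] = sin(pos / 10000^(2i/d))`, `PE[pos, 2i+1] = cos(...)` with
#' zero-based position and dimension indices; returned as a `t x d` matrix for
#' one-based R rows 1..t (positions 0..t-1).
#'
#' @param t sequence length.
#' @param d model dimension (even).
#' @return `t x d` matrix.
#' @export
positional_encoding <- function(t, d) {
  pos <- 0:(t - 1)
  j <- 0:(d - 1)
  angle_rate <- 1 / 10000^((j - j %% 2) / d)
  A <- outer(pos, angle_rate)
  PE <- matrix(0, t, d)
  even <- which(j %% 2 == 0)      # zero-based even dims -> sin
  PE[, even] <- sin(A[, even, drop = FALSE])
  PE[, -even] <- cos(A[, -even, drop = FALSE])
  PE
}

glorot <- function(m, n) {
  lim <- sqrt(6 / (m + n))
  matrix(stats::runif(m * n, -lim, lim), m, n)
}

# -- linear ------------------------------------------------------------------
linear_fwd <- function(X, W, b) list(Y = add_bias(X %*% W, b), X = X)
linear_bwd <- function(dY, cache, W) {
  list(dX = dY %*% t(W), dW = crossprod(cache$X, dY), db = colSums(dY))
}

# -- dropout (inverted) ------------------------------------------------------
dropout_fwd <- function(X, p, training) {
  if (!training || p <= 0) return(list(Y = X, mask = NULL))
  mask <- (stats::runif(length(X)) >= p) / (1 - p)
  dim(mask) <- dim(X)
  list(Y = X * mask, mask = mask)
}
dropout_bwd <- function(dY, cache) if (is.null(cache$mask)) dY else dY * cache$mask

# -- row-wise layer normalization -------------------------------------------
layernorm_fwd <- function(X, g, b, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc^2)
  istd <- 1 / sqrt(v + eps)
  xhat <- xc * istd
  list(Y = add_bias(xhat * rep(g, each = nrow(X)), b), xhat = xhat, istd = istd)
}
layernorm_bwd <- function(dY, cache, g) {
  xhat <- cache$xhat
  dxhat <- dY * rep(g, each = nrow(dY))
  dX <- cache$istd * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(dX = dX, dg = colSums(dY * xhat), db = colSums(dY))
}
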