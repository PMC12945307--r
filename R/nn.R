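# Minimal dense-network machinery for the offline RL agents: fully-connected
# ReLU networks with an optional tanh output, hand-derived backpropagation
# and Adam.  Batches are rows; weights W[[l]] are (d_in x d_out).

mlp_new <- function(sizes, out_act = c("linear", "tanh")) {
  out_act <- match.arg(out_act)
  L <- length(sizes) - 1L
  W <- vector("list", L); b <- vector("list", L)
  for (l in seq_len(L)) {
    bound <- 1 / sqrt(sizes[l])
    W[[l]] <- matrix(runif(sizes[l] * sizes[l + 1L], -bound, bound),
                     sizes[l], sizes[l + 1L])
    b[[l]] <- runif(sizes[l + 1L], -bound, bound)
  }
  list(W = W, b = b, sizes = sizes, out_act = out_act)
}

mlp_forward <- function(net, X, keep_cache = FALSE) {
  L <- length(net$W)
  H <- list(X)
  A <- X
  n <- nrow(X)
  for (l in seq_len(L)) {
    Z <- A %*% net$W[[l]]
    Z <- Z + rep(net$b[[l]], each = n)
    A <- if (l < L) Z * (Z > 0) else if (net$out_act == "tanh") tanh(Z) else Z
    if (keep_cache) H[[l + 1L]] <- A
  }
  if (keep_cache) list(out = A, H = H) else A
}

# dOut: gradient of the scalar loss w.r.t. the network output (n x d_out).
# Returns weight/bias gradients and the gradient w.r.t. the input rows.
mlp_backward <- function(net, cache, dOut) {
  L <- length(net$W)
  H <- cache$H
  gW <- vector("list", L); gb <- vector("list", L)
  delta <- if (net$out_act == "tanh") dOut * (1 - H[[L + 1L]]^2) else dOut
  for (l in rev(seq_len(L))) {
    gW[[l]] <- crossprod(H[[l]], delta)
    gb[[l]] <- colSums(delta)
    if (l > 1L) {
      delta <- (delta %*% t(net$W[[l]])) * (H[[l]] > 0)
    } else {
      delta <- delta %*% t(net$W[[l]])
    }
  }
  list(gW = gW, gb = gb, dX = delta)
}

adam_new <- function(net) {
  zeros <- function(x) if (is.matrix(x)) matrix(0, nrow(x), ncol(x))
                       else numeric(length(x))
  list(mW = lapply(net$W, zeros), vW = lapply(net$W, zeros),
       mb = lapply(net$b, zeros), vb = lapply(net$b, zeros), t = 0L)
}

adam_step <- function(net, grads, st, lr = 3e-4, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1L
  c1 <- 1 - beta1^st$t; c2 <- 1 - beta2^st$t
  for (l in seq_along(net$W)) {
    st$mW[[l]] <- beta1 * st$mW[[l]] + (1 - beta1) * grads$gW[[l]]
    st$vW[[l]] <- beta2 * st$vW[[l]] + (1 - beta2) * grads$gW[[l]]^2
    net$W[[l]] <- net$W[[l]] -
      lr * (st$mW[[l]] / c1) / (sqrt(st$vW[[l]] / c2) + eps)
    st$mb[[l]] <- beta1 * st$mb[[l]] + (1 - beta1) * grads$gb[[l]]
    st$vb[[l]] <- beta2 * st$vb[[l]] + (1 - beta2) * grads$gb[[l]]^2
    net$b[[l]] <- net$b[[l]] -
      lr * (st$mb[[l]] / c1) / (sqrt(st$vb[[l]] / c2) + eps)
  }
  list(net = net, st = st)
}

soft_update <- function(target, src, tau) {
  for (l in seq_along(src$W)) {
    target$W[[l]] <- (1 - tau) * target$W[[l]] + tau * src$W[[l]]
    target$b[[l]] <- (1 - tau) * target$b[[l]] + tau * src$b[[l]]
  }
  target
}
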