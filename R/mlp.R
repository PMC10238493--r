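# Minimal dense multilayer perceptron with tanh hidden activations, manual
# backpropagation and an Adam optimizer. Deliberately small: the policy and
# value networks here are two hidden layers on an 8-dimensional observation,
# which plain BLAS-backed matrix algebra handles comfortably.

mlp_init <- function(in_dim, hidden, out_dim, out_scale = 1) {
  sizes <- c(in_dim, hidden, out_dim)
  L <- length(sizes) - 1L
  W <- vector("list", L); b <- vector("list", L)
  for (i in seq_len(L)) {
    sd <- sqrt(2 / (sizes[i] + sizes[i + 1]))   # Xavier/Glorot for tanh
    W[[i]] <- matrix(stats::rnorm(sizes[i] * sizes[i + 1], 0, sd),
                     sizes[i], sizes[i + 1])
    b[[i]] <- numeric(sizes[i + 1])
  }
  W[[L]] <- W[[L]] * out_scale
  list(W = W, b = b, L = L)
}

# Forward pass; returns output and per-layer activations for backprop.
mlp_forward <- function(net, X) {
  A <- vector("list", net$L + 1L)
  A[[1L]] <- X
  for (i in seq_len(net$L)) {
    Z <- A[[i]] %*% net$W[[i]]
    Z <- sweep(Z, 2, net$b[[i]], "+")
    A[[i + 1L]] <- if (i < net$L) tanh(Z) else Z
  }
  list(out = A[[net$L + 1L]], A = A)
}

# Backward pass given d(loss)/d(output); returns gradients matching net$W/b.
mlp_backward <- function(net, fw, dout) {
  L <- net$L
  gW <- vector("list", L); gb <- vector("list", L)
  delta <- dout
  for (i in rev(seq_len(L))) {
    gW[[i]] <- crossprod(fw$A[[i]], delta)
    gb[[i]] <- colSums(delta)
    if (i > 1L) {
      delta <- tcrossprod(delta, net$W[[i]]) * (1 - fw$A[[i]]^2)
    }
  }
  list(W = gW, b = gb)
}

adam_init <- function(net) {
  zero <- function(p) lapply(p, function(x) x * 0)
  list(mW = zero(net$W), vW = zero(net$W),
       mb = zero(net$b), vb = zero(net$b), t = 0L)
}

# One Adam step; optional global-norm gradient clipping. Returns updated
# net and optimizer state.
adam_step <- function(net, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, grad_clip = Inf) {
  if (is.finite(grad_clip)) {
    gn <- sqrt(sum(vapply(grads$W, function(g) sum(g^2), numeric(1))) +
                 sum(vapply(grads$b, function(g) sum(g^2), numeric(1))))
    if (gn > grad_clip) {
      sc <- grad_clip / gn
      grads$W <- lapply(grads$W, "*", sc)
      grads$b <- lapply(grads$b, "*", sc)
    }
  }
  opt$t <- opt$t + 1L
  c1 <- 1 - beta1^opt$t; c2 <- 1 - beta2^opt$t
  for (i in seq_along(net$W)) {
    opt$mW[[i]] <- beta1 * opt$mW[[i]] + (1 - beta1) * grads$W[[i]]
    opt$vW[[i]] <- beta2 * opt$vW[[i]] + (1 - beta2) * grads$W[[i]]^2
    net$W[[i]] <- net$W[[i]] - lr * (opt$mW[[i]] / c1) /
      (sqrt(opt$vW[[i]] / c2) + eps)
    opt$mb[[i]] <- beta1 * opt$mb[[i]] + (1 - beta1) * grads$b[[i]]
    opt$vb[[i]] <- beta2 * opt$vb[[i]] + (1 - beta2) * grads$b[[i]]^2
    net$b[[i]] <- net$b[[i]] - lr * (opt$mb[[i]] / c1) /
      (sqrt(opt$vb[[i]] / c2) + eps)
  }
  list(net = net, opt = opt)
}
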