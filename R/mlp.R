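# Minimal dense feed-forward network (ReLU hidden layers, linear output)
# with Adam, written in base R matrix algebra. The training objective is the
# configuration-level mean absolute error of the *sum* of per-pair outputs,
# which no off-the-shelf regression interface expresses; see
# train_interaction_model().

mlp_init <- function(d_in, hidden, d_out) {
  dims <- c(d_in, hidden, d_out)
  W <- list(); b <- list()
  for (l in seq_len(length(dims) - 1)) {
    W[[l]] <- matrix(stats::rnorm(dims[l] * dims[l + 1],
                                  sd = sqrt(2 / dims[l])),
                     dims[l], dims[l + 1])
    b[[l]] <- rep(0, dims[l + 1])
  }
  # near-zero output layer: per-pair contributions start at ~0 so that
  # configuration-level sums (over a variable number of pairs) begin on the
  # scale of the labels rather than the pair count
  W[[length(W)]] <- W[[length(W)]] * 0.01
  list(W = W, b = b, n_layers = length(W))
}

mlp_forward <- function(net, X, keep = FALSE) {
  A <- list(X)
  Z <- list()
  for (l in seq_len(net$n_layers)) {
    Z[[l]] <- sweep(A[[l]] %*% net$W[[l]], 2, net$b[[l]], "+")
    A[[l + 1]] <- if (l < net$n_layers) pmax(Z[[l]], 0) else Z[[l]]
  }
  if (keep) list(out = A[[net$n_layers + 1]], A = A, Z = Z)
  else A[[net$n_layers + 1]]
}

adam_init <- function(net) {
  list(m_W = lapply(net$W, function(w) w * 0),
       v_W = lapply(net$W, function(w) w * 0),
       m_b = lapply(net$b, function(b) b * 0),
       v_b = lapply(net$b, function(b) b * 0),
       t = 0)
}

adam_update <- function(net, opt, gW, gb, lr, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8) {
  opt$t <- opt$t + 1
  c1 <- 1 - beta1^opt$t
  c2 <- 1 - beta2^opt$t
  for (l in seq_len(net$n_layers)) {
    opt$m_W[[l]] <- beta1 * opt$m_W[[l]] + (1 - beta1) * gW[[l]]
    opt$v_W[[l]] <- beta2 * opt$v_W[[l]] + (1 - beta2) * gW[[l]]^2
    net$W[[l]] <- net$W[[l]] -
      lr * (opt$m_W[[l]] / c1) / (sqrt(opt$v_W[[l]] / c2) + eps)
    opt$m_b[[l]] <- beta1 * opt$m_b[[l]] + (1 - beta1) * gb[[l]]
    opt$v_b[[l]] <- beta2 * opt$v_b[[l]] + (1 - beta2) * gb[[l]]^2
    net$b[[l]] <- net$b[[l]] -
      lr * (opt$m_b[[l]] / c1) / (sqrt(opt$v_b[[l]] / c2) + eps)
  }
  list(net = net, opt = opt)
}

# Backpropagate a gradient dOut (rows x d_out) through the network.
mlp_backward <- function(net, fw, dOut) {
  L <- net$n_layers
  gW <- vector("list", L)
  gb <- vector("list", L)
  dZ <- dOut
  for (l in L:1) {
    gW[[l]] <- crossprod(fw$A[[l]], dZ)
    gb[[l]] <- colSums(dZ)
    if (l > 1) {
      dA <- tcrossprod(dZ, net$W[[l]])
      dZ <- dA * (fw$Z[[l - 1]] > 0)
    }
  }
  list(gW = gW, gb = gb)
}

# One fold of sum-aggregated training.
# X: scaled pair features; cfg: integer configuration index per row;
# Y: scaled per-configuration labels (n_cfg x 2); cfg_train: configuration
# indices to train on.
train_fold <- function(X, cfg, Y, cfg_train, hidden, epochs, lr,
                       batch_size, verbose = FALSE) {
  net <- mlp_init(ncol(X), hidden, 2)
  opt <- adam_init(net)
  history <- numeric(epochs)
  y_sum <- rowSums(Y)
  for (ep in seq_len(epochs)) {
    order_cfg <- sample(cfg_train)
    nb <- ceiling(length(order_cfg) / batch_size)
    ep_loss <- 0
    for (bi in seq_len(nb)) {
      bc <- order_cfg[((bi - 1) * batch_size + 1):min(bi * batch_size,
                                                      length(order_cfg))]
      rows <- which(cfg %in% bc)
      B <- length(bc)
      pred <- stats::setNames(rep(0, B), bc)
      if (length(rows) > 0) {
        fw <- mlp_forward(net, X[rows, , drop = FALSE], keep = TRUE)
        rs <- rowsum(fw$out[, 1] + fw$out[, 2], group = cfg[rows])
        pred[rownames(rs)] <- rs[, 1]
      }
      resid <- pred - y_sum[bc]
      ep_loss <- ep_loss + sum(abs(resid))
      if (length(rows) > 0) {
        g_cfg <- stats::setNames(sign(resid) / B, bc)
        drow <- g_cfg[as.character(cfg[rows])]
        grads <- mlp_backward(net, fw, cbind(drow, drow))
        upd <- adam_update(net, opt, grads$gW, grads$gb, lr)
        net <- upd$net
        opt <- upd$opt
      }
    }
    history[ep] <- ep_loss / length(cfg_train)
    if (verbose && ep %% 25 == 0)
      message(sprintf("  epoch %d  MAE(scaled sum) %.4f", ep, history[ep]))
  }
  list(net = net, history = history)
}
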