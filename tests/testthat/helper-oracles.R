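# Independent oracles used across the suite. These deliberately use
# plain nested loops / closed forms so they share no code with the
# vectorized implementations they check.

# single-level Haar analysis by explicit 2x2 patch dot products
brute_dwt2 <- function(xm, f) {
  H <- nrow(xm) / 2
  W <- ncol(xm) / 2
  out <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W))
    out[i, j] <- sum(xm[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j)] * f)
  out
}

# one-vs-rest metrics recomputed from label vectors with scalar loops
brute_ovr_metrics <- function(y_true, y_pred, K) {
  out <- matrix(NA_real_, K, 4,
                dimnames = list(NULL, c("accuracy", "precision",
                                        "recall", "specificity")))
  n <- length(y_true)
  for (c in seq_len(K) - 1L) {
    tp <- fp <- fn <- tn <- 0L
    for (i in seq_len(n)) {
      p <- y_pred[i] == c
      t <- y_true[i] == c
      if (p && t) tp <- tp + 1L
      else if (p && !t) fp <- fp + 1L
      else if (!p && t) fn <- fn + 1L
      else tn <- tn + 1L
    }
    out[c + 1L, ] <- c(
      (tp + tn) / n,
      if (tp + fp > 0) tp / (tp + fp) else NA_real_,
      if (tp + fn > 0) tp / (tp + fn) else NA_real_,
      if (tn + fp > 0) tn / (tn + fp) else NA_real_
    )
  }
  out
}

# nested-loop evaluation of multi-head agent attention
# (two softmax stages through pooled agents, biases, DWC residual)
brute_agent_attention <- function(x, l, grid) {
  N <- nrow(x); d <- ncol(x); heads <- l$heads; dh <- d / heads
  ga <- pmin(l$agent_grid, grid); na <- prod(ga)
  lin <- function(w, m) sweep(m %*% w$params$W, 2, w$params$b, "+")
  Q <- lin(l$children$wq, x)
  K <- lin(l$children$wk, x)
  V <- lin(l$children$wv, x)
  P <- whanet:::adaptive_pool_matrix(grid[1], grid[2], ga[1], ga[2])
  La <- whanet:::bilinear_interp_matrix(l$agent_grid[1], l$agent_grid[2],
                                        ga[1], ga[2])
  Rn <- t(whanet:::bilinear_interp_matrix(l$base_grid[1], l$base_grid[2],
                                          grid[1], grid[2]))
  sm_row <- function(r) exp(r - max(r)) / sum(exp(r - max(r)))
  out <- matrix(0, N, d)
  for (h in seq_len(heads)) {
    cols <- (h - 1) * dh + seq_len(dh)
    Qh <- Q[, cols, drop = FALSE]
    Kh <- K[, cols, drop = FALSE]
    Vh <- V[, cols, drop = FALSE]
    A <- matrix(0, na, dh)
    for (a in seq_len(na)) for (c in seq_len(dh))
      A[a, c] <- sum(P[a, ] * Qh[, c])
    B1 <- La %*% matrix(l$params$B1[h, , ], dim(l$params$B1)[2]) %*% Rn
    B2 <- t(Rn) %*% matrix(l$params$B2[h, , ], dim(l$params$B2)[2]) %*% t(La)
    S1 <- matrix(0, na, N)
    for (a in seq_len(na)) for (j in seq_len(N))
      S1[a, j] <- sum(A[a, ] * Kh[j, ]) / sqrt(dh) + B1[a, j]
    P1 <- t(apply(S1, 1, sm_row))
    VA <- P1 %*% Vh
    S2 <- matrix(0, N, na)
    for (i in seq_len(N)) for (a in seq_len(na))
      S2[i, a] <- sum(Qh[i, ] * A[a, ]) / sqrt(dh) + B2[i, a]
    P2 <- t(apply(S2, 1, sm_row))
    out[, cols] <- P2 %*% VA
  }
  if (l$use_dwc) {
    W <- l$children$dwc$params$W
    b <- l$children$dwc$params$b
    vg <- array(V, c(grid[1], grid[2], d))
    dres <- array(0, dim(vg))
    for (c in seq_len(d)) for (i in seq_len(grid[1]))
      for (j in seq_len(grid[2])) {
        s <- b[c]
        for (di in -1:1) for (dj in -1:1) {
          ii <- i + di; jj <- j + dj
          if (ii >= 1 && ii <= grid[1] && jj >= 1 && jj <= grid[2])
            s <- s + vg[ii, jj, c] * W[di + 2, dj + 2, 1, c]
        }
        dres[i, j, c] <- s
      }
    out <- out + matrix(dres, N, d)
  }
  sweep(out %*% l$children$wo$params$W, 2, l$children$wo$params$b, "+")
}

# finite-difference gradient check; returns worst relative error over a
# sample of parameters and input coordinates
num_grad_check <- function(layer, x, n_params = 4L, n_inputs = 8L,
                           seed = 7L) {
  whanet:::zero_grads(layer)
  y <- layer_forward(layer, x, training = TRUE)
  set.seed(seed)
  dy <- array(rnorm(length(y)), dim = dim(y))
  dx <- layer_backward(layer, dy)
  loss <- function(xx) {
    attr(xx, "token_grid") <- attr(x, "token_grid")
    sum(layer_forward(layer, xx, training = TRUE) * dy)
  }
  eps <- 1e-5
  worst <- 0
  for (r in whanet:::param_refs(layer)) {
    p <- r$layer$params[[r$name]]
    for (i in sample(length(p), min(n_params, length(p)))) {
      p0 <- p[i]
      r$layer$params[[r$name]][i] <- p0 + eps; lp <- loss(x)
      r$layer$params[[r$name]][i] <- p0 - eps; lm <- loss(x)
      r$layer$params[[r$name]][i] <- p0
      g <- (lp - lm) / (2 * eps)
      worst <- max(worst, abs(g - r$layer$grads[[r$name]][i]) / max(1, abs(g)))
    }
  }
  for (i in sample(length(x), min(n_inputs, length(x)))) {
    x0 <- x[i]
    x[i] <- x0 + eps; lp <- loss(x)
    x[i] <- x0 - eps; lm <- loss(x)
    x[i] <- x0
    g <- (lp - lm) / (2 * eps)
    worst <- max(worst, abs(g - dx[i]) / max(1, abs(g)))
  }
  worst
}
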