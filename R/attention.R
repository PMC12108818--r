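# Attention mechanisms: scSE channel/spatial gating, the softmax
# attention reference, and agent attention (two-stage softmax attention
# through a small set of pooled agent tokens, linear in sequence length).

row_softmax <- function(m) {
  mx <- m[cbind(seq_len(nrow(m)), max.col(m, ties.method = "first"))]
  e <- exp(m - mx)
  e / rowSums(e)
}

softmax_bwd <- function(dp, p) (dp - rowSums(dp * p)) * p

# ---- scSE ----------------------------------------------------------------

#' Concurrent spatial and channel squeeze-and-excitation (scSE) layer
#'
#' Two parallel gates: cSE pools the map globally, passes the channel
#' vector through a two-layer bottleneck (SiLU in between) and produces
#' per-channel Hard-Sigmoid gates; sSE projects channels to a single map
#' and produces per-position Hard-Sigmoid gates. The branch outputs are
#' summed, so with all weights and biases zero each gate is 1/2 and the
#' module is exactly the identity -- safe to insert anywhere.
#'
#' @param ch input channel count
#' @param r channel reduction ratio of the cSE bottleneck (default 4)
#' @param zero_init initialize all weights/biases to zero (identity map)
#' @return a `wha_layer` of class `scse`
#' @export
scse_layer <- function(ch, r = 4L, zero_init = FALSE) {
  if (ch %/% r < 1) stop("ch/r must be >= 1")
  l <- new_layer("scse", ch = ch, r = as.integer(r))
  mid <- ch %/% r
  l$children$fc1 <- linear_layer(ch, mid, zero_init = zero_init)
  l$children$fc2 <- linear_layer(mid, ch, zero_init = zero_init)
  l$children$sse <- conv2d(ch, 1L, k = 1, bias = TRUE)
  if (zero_init) l$children$sse$params$W[] <- 0
  l
}

# channel gate g: (N, C) matrix -> factor array matching (H,W,C,N)
bcast_gate_cn <- function(x, g) {
  d <- dim(x)
  x * rep(as.vector(t(g)), each = d[1] * d[2])
}

cse_path <- function(layer, x, training) {
  d <- dim(x)
  hw <- d[1] * d[2]
  pooled <- t(matrix(colSums(matrix(x, hw, d[3] * d[4])) / hw, d[3], d[4]))
  z1 <- layer_forward(layer$children$fc1, pooled, training)
  a1 <- silu(z1)
  z2 <- layer_forward(layer$children$fc2, a1, training)
  g <- hard_sigmoid(z2)
  if (training)
    layer$cache$cse <- list(x = x, z1 = z1, z2 = z2, g = g)
  bcast_gate_cn(x, g)
}

sse_path <- function(layer, x, training) {
  m <- layer_forward(layer$children$sse, x, training)  # (H,W,1,N)
  s <- hard_sigmoid(m)
  if (training) layer$cache$sse <- list(x = x, m = m, s = s)
  x * s[, , rep(1L, dim(x)[3]), , drop = FALSE]
}

#' Channel squeeze-and-excitation gate
#' @param x feature map `(H,W,C,N)` (or `(H,W,C)`)
#' @param p an [scse_layer()] with matching channels
#' @return `x` rescaled channel-wise by gates in `[0,1]`
#' @export
cse_forward <- function(x, p) {
  cc <- as_hwcn(x)
  if (dim(cc$x)[3] != p$ch) stop("channel mismatch")
  restore_dim(cse_path(p, cc$x, FALSE), cc$orig)
}

#' Spatial squeeze-and-excitation gate
#' @inheritParams cse_forward
#' @return `x` rescaled position-wise by gates in `[0,1]`
#' @export
sse_forward <- function(x, p) {
  cc <- as_hwcn(x)
  if (dim(cc$x)[3] != p$ch) stop("channel mismatch")
  restore_dim(sse_path(p, cc$x, FALSE), cc$orig)
}

#' scSE hybrid attention
#'
#' Elementwise sum of [cse_forward()] and [sse_forward()].
#' @inheritParams cse_forward
#' @return gated feature map, same shape as `x`
#' @export
scse_forward <- function(x, p) {
  cc <- as_hwcn(x)
  if (dim(cc$x)[3] != p$ch) stop("channel mismatch")
  restore_dim(cse_path(p, cc$x, FALSE) + sse_path(p, cc$x, FALSE), cc$orig)
}

#' @export
layer_forward.scse <- function(layer, x, training = FALSE) {
  if (dim(x)[3] != layer$ch) stop("channel mismatch")
  cse_path(layer, x, training) + sse_path(layer, x, training)
}

#' @export
layer_backward.scse <- function(layer, dy) {
  d <- dim(dy)
  hw <- d[1] * d[2]
  # cSE branch
  cc <- layer$cache$cse
  dx <- bcast_gate_cn(dy, cc$g)
  dg <- t(matrix(colSums(matrix(dy * cc$x, hw, d[3] * d[4])), d[3], d[4]))
  dz2 <- dg * hard_sigmoid_grad(cc$z2)
  da1 <- layer_backward(layer$children$fc2, dz2)
  dz1 <- da1 * silu_grad(cc$z1)
  dpooled <- layer_backward(layer$children$fc1, dz1)
  dx <- dx + rep(as.vector(t(dpooled)), each = hw) / hw
  # sSE branch
  ss <- layer$cache$sse
  dx <- dx + dy * ss$s[, , rep(1L, d[3]), , drop = FALSE]
  dsgate <- dy * ss$x
  dm <- array(rowSums(matrix(aperm(dsgate, c(1, 2, 4, 3)), hw * d[4], d[3])),
              c(d[1], d[2], 1, d[4])) * hard_sigmoid_grad(ss$m)
  dx + layer_backward(layer$children$sse, dm)
}

#' @export
layer_macs.scse <- function(layer, shp) {
  mid <- layer$ch %/% layer$r
  m <- layer$ch * mid + mid * layer$ch +      # cSE bottleneck linears
    layer$ch * shp[1] * shp[2]                # sSE pointwise conv
  list(macs = m, shp = shp)
}

# ---- softmax attention (reference) ---------------------------------------

#' Scaled dot-product softmax attention
#'
#' The quadratic-cost reference mechanism:
#' `softmax(Q K' / sqrt(d_k)) V`, row-stochastic weights.
#'
#' @param q,k query/key matrices, `N x d_k`
#' @param v value matrix, `N x d_v`
#' @param d_k scaling dimension (default `ncol(q)`)
#' @return `N x d_v` output matrix
#' @export
softmax_attention <- function(q, k, v, d_k = ncol(q)) {
  if (ncol(q) != ncol(k) || nrow(k) != nrow(v))
    stop("shape mismatch between q, k, v")
  row_softmax(q %*% t(k) / sqrt(d_k)) %*% v
}

#' Multiply-accumulate count of softmax attention
#'
#' Counts the two attention matmuls (`QK'` and the weighted sum with
#' `V`); quadratic in sequence length.
#'
#' @param N sequence length
#' @param d_k key/query dimension
#' @param d_v value dimension (default `d_k`)
#' @return MAC count
#' @export
softmax_attention_macs <- function(N, d_k, d_v = d_k) {
  N^2 * d_k + N^2 * d_v
}

#' Multiply-accumulate count of agent attention
#'
#' Counts the four attention matmuls of the two-stage mechanism
#' (`A K'`, aggregation with `V`, `Q A'`, broadcasting) plus the
#' depthwise diversity convolution; linear in sequence length at fixed
#' agent count.
#'
#' @param N sequence length
#' @param d token dimension (split across heads)
#' @param n agent token count
#' @param dwc include the 3x3 depthwise convolution on V
#' @return MAC count
#' @export
agent_attention_macs <- function(N, d, n, dwc = TRUE) {
  m <- 4 * N * n * d
  if (dwc) m <- m + 9 * N * d
  m
}

# ---- adaptive average pooling / bilinear interpolation matrices ----------

# pooling matrix P (gh*gw x h*w), column-major token order (row fastest)
adaptive_pool_matrix <- function(h, w, gh, gw) {
  P <- matrix(0, gh * gw, h * w)
  for (gc in seq_len(gw)) {
    c0 <- floor((gc - 1) * w / gw) + 1
    c1 <- ceiling(gc * w / gw)
    for (gr in seq_len(gh)) {
      r0 <- floor((gr - 1) * h / gh) + 1
      r1 <- ceiling(gr * h / gh)
      cells <- as.vector(outer(r0:r1, (c0:c1 - 1) * h, "+"))
      P[gr + (gc - 1) * gh, cells] <- 1 / length(cells)
    }
  }
  P
}

# bilinear interpolation matrix (dst_N x src_N), align_corners = FALSE
bilinear_interp_matrix <- function(sh, sw, dh, dw) {
  M <- matrix(0, dh * dw, sh * sw)
  pos <- function(i, dst, src) {
    p <- (i - 0.5) * src / dst - 0.5
    min(max(p, 0), src - 1)
  }
  for (dc in seq_len(dw)) {
    pc <- pos(dc, dw, sw)
    c0 <- floor(pc); wc <- pc - c0
    for (dr in seq_len(dh)) {
      pr <- pos(dr, dh, sh)
      r0 <- floor(pr); wr <- pr - r0
      for (dcc in 0:1) for (drr in 0:1) {
        r <- min(r0 + drr, sh - 1); c <- min(c0 + dcc, sw - 1)
        wgt <- (if (drr == 1) wr else 1 - wr) *
               (if (dcc == 1) wc else 1 - wc)
        idx <- (r + 1) + c * sh
        M[dr + (dc - 1) * dh, idx] <- M[dr + (dc - 1) * dh, idx] + wgt
      }
    }
  }
  M
}

# ---- agent attention layer ----------------------------------------------

#' Multi-head agent attention layer
#'
#' Two-stage softmax attention through `n` agent tokens obtained by
#' adaptive average pooling of the queries on their spatial grid:
#' aggregation `softmax(A K'/sqrt(d_h) + B1) V` followed by broadcasting
#' `softmax(Q A'/sqrt(d_h) + B2) (.)`, per head, plus a depthwise 3x3
#' convolution of `V` as a feature-diversity residual. Learnable agent
#' biases are stored on a base token grid and bilinearly interpolated
#' when the runtime grid differs. Cost is linear in sequence length.
#'
#' @param d token dimension (must be divisible by `heads`)
#' @param heads number of attention heads (default 4)
#' @param n agent token count (default 16, pooled on a square grid;
#'   clipped when the sequence is shorter)
#' @param base_grid integer `c(h, w)` token grid at which the agent
#'   biases are stored
#' @param dwc enable the depthwise-convolution diversity term
#' @return a `wha_layer` of class `agent_attn`
#' @export
agent_attention_layer <- function(d, heads = 4L, n = 16L,
                                  base_grid = c(8L, 8L), dwc = TRUE) {
  if (d %% heads != 0) stop("d must be divisible by heads")
  l <- new_layer("agent_attn", d = d, heads = as.integer(heads),
                 n = as.integer(n), base_grid = as.integer(base_grid),
                 use_dwc = dwc)
  l$children$wq <- linear_layer(d, d)
  l$children$wk <- linear_layer(d, d)
  l$children$wv <- linear_layer(d, d)
  l$children$wo <- linear_layer(d, d)
  ga <- max(1L, as.integer(round(sqrt(n))))
  nb <- ga * ga
  Nb <- prod(base_grid)
  l$agent_grid <- c(ga, ga)
  l$params$B1 <- array(0, c(heads, nb, Nb))
  l$params$B2 <- array(0, c(heads, Nb, nb))
  if (dwc) l$children$dwc <- conv2d(d, d, k = 3, groups = d, bias = TRUE)
  l
}

# x: (N, d, S) token array with attr "token_grid" = c(h, w); N = h*w
#' @export
layer_forward.agent_attn <- function(layer, x, training = FALSE) {
  d3 <- dim(x)
  N <- d3[1]; d <- d3[2]; S <- d3[3]
  grid <- attr(x, "token_grid")
  if (is.null(grid)) {
    if (layer$use_dwc) stop("token grid required when DWC is enabled")
    grid <- c(N, 1L)
  }
  heads <- layer$heads; dh <- d %/% heads
  ga <- pmin(layer$agent_grid, grid)
  na <- prod(ga)
  xm <- matrix(aperm(x, c(1, 3, 2)), N * S, d)   # rows: token-within-seq
  Q <- layer_forward(layer$children$wq, xm, training)
  K <- layer_forward(layer$children$wk, xm, training)
  V <- layer_forward(layer$children$wv, xm, training)
  P <- adaptive_pool_matrix(grid[1], grid[2], ga[1], ga[2])
  # interpolate biases to the runtime grids if they differ
  B1 <- layer$params$B1; B2 <- layer$params$B2
  ident_bias <- identical(dim(B1)[2:3], c(na, N)) &&
    identical(layer$base_grid, as.integer(grid)) &&
    identical(layer$agent_grid, as.integer(ga))
  if (!ident_bias) {
    La <- bilinear_interp_matrix(layer$agent_grid[1], layer$agent_grid[2],
                                 ga[1], ga[2])
    Rn <- t(bilinear_interp_matrix(layer$base_grid[1], layer$base_grid[2],
                                   grid[1], grid[2]))
    B1r <- array(0, c(heads, na, N))
    B2r <- array(0, c(heads, N, na))
    for (h in seq_len(heads)) {
      B1r[h, , ] <- La %*% matrix(B1[h, , ], dim(B1)[2]) %*% Rn
      B2r[h, , ] <- t(Rn) %*% matrix(B2[h, , ], dim(B2)[2]) %*% t(La)
    }
  } else {
    La <- NULL; Rn <- NULL; B1r <- B1; B2r <- B2
  }
  out <- matrix(0, N * S, d)
  cache <- if (training)
    list(N = N, d = d, S = S, grid = grid, ga = ga, na = na, P = P,
         Q = Q, K = K, V = V, La = La, Rn = Rn, ident = ident_bias,
         heads = heads, dh = dh, A = vector("list", heads * S),
         P1 = vector("list", heads * S), P2 = vector("list", heads * S),
         VA = vector("list", heads * S))
  scl <- 1 / sqrt(dh)
  for (s in seq_len(S)) {
    rows <- (s - 1) * N + seq_len(N)
    for (h in seq_len(heads)) {
      cols <- (h - 1) * dh + seq_len(dh)
      Qh <- Q[rows, cols, drop = FALSE]
      Kh <- K[rows, cols, drop = FALSE]
      Vh <- V[rows, cols, drop = FALSE]
      A <- P %*% Qh                                   # (na, dh)
      P1 <- row_softmax(tcrossprod(A, Kh) * scl + B1r[h, , ])
      VA <- P1 %*% Vh                                 # (na, dh)
      P2 <- row_softmax(tcrossprod(Qh, A) * scl + B2r[h, , ])
      out[rows, cols] <- P2 %*% VA
      if (training) {
        i <- (s - 1) * heads + h
        cache$A[[i]] <- A; cache$P1[[i]] <- P1
        cache$P2[[i]] <- P2; cache$VA[[i]] <- VA
      }
    }
  }
  if (layer$use_dwc) {
    vmap <- array(aperm(array(V, c(N, S, d)), c(1, 3, 2)), c(N, d, S))
    vgrid <- array(vmap, c(grid[1], grid[2], d, S))
    dres <- layer_forward(layer$children$dwc, vgrid, training)
    out <- out + matrix(aperm(array(dres, c(N, d, S)), c(1, 3, 2)), N * S, d)
  }
  y <- layer_forward(layer$children$wo, out, training)
  if (training) layer$cache <- cache
  y <- array(aperm(array(y, c(N, S, d)), c(1, 3, 2)), c(N, d, S))
  attr(y, "token_grid") <- grid
  y
}

#' @export
layer_backward.agent_attn <- function(layer, dy) {
  ca <- layer$cache
  N <- ca$N; d <- ca$d; S <- ca$S
  heads <- ca$heads; dh <- ca$dh
  scl <- 1 / sqrt(dh)
  dym <- matrix(aperm(dy, c(1, 3, 2)), N * S, d)
  dout <- layer_backward(layer$children$wo, dym)
  dQ <- matrix(0, N * S, d)
  dK <- matrix(0, N * S, d)
  dV <- matrix(0, N * S, d)
  dB1r <- array(0, c(heads, ca$na, N))
  dB2r <- array(0, c(heads, N, ca$na))
  if (layer$use_dwc) {
    dgrid <- array(aperm(array(dout, c(N, S, d)), c(1, 3, 2)),
                   c(ca$grid[1], ca$grid[2], d, S))
    dvg <- layer_backward(layer$children$dwc, dgrid)
    dV <- dV + matrix(aperm(array(dvg, c(N, d, S)), c(1, 3, 2)), N * S, d)
  }
  for (s in seq_len(S)) {
    rows <- (s - 1) * N + seq_len(N)
    for (h in seq_len(heads)) {
      cols <- (h - 1) * dh + seq_len(dh)
      i <- (s - 1) * heads + h
      A <- ca$A[[i]]; P1 <- ca$P1[[i]]; P2 <- ca$P2[[i]]; VA <- ca$VA[[i]]
      Qh <- ca$Q[rows, cols, drop = FALSE]
      Kh <- ca$K[rows, cols, drop = FALSE]
      Vh <- ca$V[rows, cols, drop = FALSE]
      dZ <- dout[rows, cols, drop = FALSE]
      dP2 <- tcrossprod(dZ, VA)
      dVA <- crossprod(P2, dZ)
      dS2 <- softmax_bwd(dP2, P2)
      dB2r[h, , ] <- dB2r[h, , ] + dS2
      dQh <- dS2 %*% A * scl
      dA <- crossprod(dS2, Qh) * scl
      dP1 <- tcrossprod(dVA, Vh)
      dVh <- crossprod(P1, dVA)
      dS1 <- softmax_bwd(dP1, P1)
      dB1r[h, , ] <- dB1r[h, , ] + dS1
      dA <- dA + dS1 %*% Kh * scl
      dKh <- crossprod(dS1, A) * scl
      dQh <- dQh + crossprod(ca$P, dA)
      dQ[rows, cols] <- dQ[rows, cols] + dQh
      dK[rows, cols] <- dK[rows, cols] + dKh
      dV[rows, cols] <- dV[rows, cols] + dVh
    }
  }
  if (ca$ident) {
    acc_grad(layer, "B1", dB1r)
    acc_grad(layer, "B2", dB2r)
  } else {
    gB1 <- array(0, dim(layer$params$B1))
    gB2 <- array(0, dim(layer$params$B2))
    for (h in seq_len(heads)) {
      gB1[h, , ] <- crossprod(ca$La, matrix(dB1r[h, , ], ca$na)) %*% t(ca$Rn)
      gB2[h, , ] <- ca$Rn %*% matrix(dB2r[h, , ], ca$N) %*% ca$La
    }
    acc_grad(layer, "B1", gB1)
    acc_grad(layer, "B2", gB2)
  }
  dxm <- layer_backward(layer$children$wq, dQ) +
    layer_backward(layer$children$wk, dK) +
    layer_backward(layer$children$wv, dV)
  array(aperm(array(dxm, c(N, S, d)), c(1, 3, 2)), c(N, d, S))
}

#' Apply agent attention to a token batch
#'
#' Functional wrapper: `x` is an `N x d` token matrix (a single
#' sequence) or an `(N, d, S)` array; a `token_grid` attribute (or the
#' `grid` argument) supplies the `h x w` arrangement needed by the
#' pooling and the DWC term.
#'
#' @param x tokens, `N x d` matrix or `(N, d, S)` array
#' @param p an [agent_attention_layer()]
#' @param grid optional integer `c(h, w)` with `h * w == N`
#' @return array/matrix of the same shape as `x`
#' @export
agent_attention <- function(x, p, grid = NULL) {
  was_mat <- is.matrix(x)
  if (was_mat) {
    xm <- array(x, c(nrow(x), ncol(x), 1L))
  } else xm <- x
  if (!is.null(grid)) attr(xm, "token_grid") <- as.integer(grid)
  if (is.null(attr(xm, "token_grid"))) {
    n <- dim(xm)[1]
    rt <- as.integer(round(sqrt(n)))
    if (rt * rt == n) attr(xm, "token_grid") <- c(rt, rt)
    else if (p$use_dwc) stop("non-square token count: supply grid")
  }
  g <- attr(xm, "token_grid")
  if (!is.null(g) && prod(g) != dim(xm)[1]) stop("grid does not match N")
  if (prod(pmin(p$agent_grid, g %||% c(dim(xm)[1], 1L))) > dim(xm)[1])
    stop("more agent tokens than tokens")
  y <- layer_forward(p, xm, training = FALSE)
  if (was_mat) matrix(y[, , 1], dim(y)[1], dim(y)[2]) else y
}

#' @export
layer_macs.agent_attn <- function(layer, shp) {
  # shp here is c(N_total_tokens, d); used by the enclosing block
  N <- shp[1]; d <- shp[2]
  m <- 4 * N * d * d                      # q,k,v and output projections
  m <- m + agent_attention_macs(N, d, prod(layer$agent_grid),
                                dwc = layer$use_dwc)
  list(macs = m, shp = shp)
}
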