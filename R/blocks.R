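# Composite blocks: MobileViT-style unfold/fold, inverted residual (IR),
# hybrid attention inverted residual (HAIR), Agent-Transformer and the
# Agent-MViT block.

# ---- unfold / fold -------------------------------------------------------

#' Rearrange a feature map into patch-token sequences
#'
#' Non-overlapping `p x p` patches are rearranged pixel-position-major:
#' the `p^2` positions within a patch index independent token sequences,
#' each of length `H*W/p^2` (tokens ordered along the patch grid,
#' row-fastest). The inverse is [fold_patches()].
#'
#' @param x feature map, `(H,W,C)` or `(H,W,C,N)` array with `H`, `W`
#'   divisible by `p`
#' @param p patch size
#' @return `(HW/p^2, C, p^2 * N)` token array with attributes
#'   `token_grid` (`c(H/p, W/p)`) and `fold_shape`
#' @export
unfold_patches <- function(x, p) {
  cc <- as_hwcn(x)
  d <- dim(cc$x)
  if (d[1] %% p != 0 || d[2] %% p != 0)
    stop("H and W must be divisible by the patch size")
  hh <- d[1] %/% p; ww <- d[2] %/% p
  out <- array(0, c(hh * ww, d[3], p * p * d[4]))
  g <- 0L
  for (dj in seq_len(p)) for (di in seq_len(p)) {
    g <- g + 1L
    sub <- cc$x[seq(di, d[1], p), seq(dj, d[2], p), , , drop = FALSE]
    out[, , seq(g, by = p * p, length.out = d[4])] <-
      array(sub, c(hh * ww, d[3], d[4]))
  }
  attr(out, "token_grid") <- c(hh, ww)
  attr(out, "fold_shape") <- c(d, p)
  out
}

#' Restore a feature map from patch-token sequences
#'
#' Exact inverse of [unfold_patches()].
#'
#' @param t token array produced by [unfold_patches()]
#' @param shape optional `(H,W,C,N,p)` vector overriding the stored
#'   `fold_shape` attribute
#' @return feature map of the original shape
#' @export
fold_patches <- function(t, shape = attr(t, "fold_shape")) {
  if (is.null(shape)) stop("fold target shape unknown")
  d <- shape[1:4]; p <- shape[5]
  hh <- d[1] %/% p; ww <- d[2] %/% p
  if (dim(t)[1] != hh * ww || dim(t)[3] != p * p * d[4] ||
      dim(t)[2] != d[3])
    stop("token array inconsistent with target shape")
  x <- array(0, d)
  g <- 0L
  for (dj in seq_len(p)) for (di in seq_len(p)) {
    g <- g + 1L
    x[seq(di, d[1], p), seq(dj, d[2], p), , ] <-
      array(t[, , seq(g, by = p * p, length.out = d[4])],
            c(hh, ww, d[3], d[4]))
  }
  x
}

# ---- inverted residual / HAIR -------------------------------------------

#' Inverted residual block, optionally with scSE hybrid attention (HAIR)
#'
#' Pointwise expansion to `t * in_ch` (+BN+activation), 3x3 depthwise
#' convolution at the given stride (+BN+activation), then pointwise
#' projection (+BN, no activation), with a residual connection when
#' `stride == 1` and `in_ch == out_ch`. With `use_scse = TRUE` an scSE
#' module sits immediately after the depthwise stage (the HAIR block).
#'
#' @param in_ch,out_ch channel counts
#' @param stride 1 or 2
#' @param t expansion factor (default 4)
#' @param act activation name, `"silu"` or `"hard_swish"`
#' @param use_scse insert scSE after the depthwise stage
#' @param scse_r scSE reduction ratio
#' @return a `wha_layer` of class `ir`
#' @export
ir_block <- function(in_ch, out_ch, stride = 1L, t = 4L, act = "silu",
                     use_scse = FALSE, scse_r = 4L) {
  if (!stride %in% c(1L, 2L)) stop("stride must be 1 or 2")
  e <- t * in_ch
  body <- list(
    exp = conv2d(in_ch, e, k = 1, bias = FALSE),
    bn1 = bnact_layer(e, act),
    dw = conv2d(e, e, k = 3, stride = stride, groups = e, bias = FALSE),
    bn2 = bnact_layer(e, act)
  )
  if (use_scse) body$scse <- scse_layer(e, r = scse_r)
  body$proj <- conv2d(e, out_ch, k = 1, bias = FALSE)
  # residual blocks start as (near-)identity: zero-gamma on the last BN
  residual <- (stride == 1L && in_ch == out_ch)
  body$bn3 <- batchnorm2d(out_ch, gamma_init = if (residual) 0 else 1)
  l <- new_layer("ir", in_ch = in_ch, out_ch = out_ch,
                 stride = as.integer(stride), t = as.integer(t),
                 use_scse = use_scse, residual = residual)
  l$children$body <- sequential(body)
  l
}

#' @export
layer_forward.ir <- function(layer, x, training = FALSE) {
  y <- layer_forward(layer$children$body, x, training)
  if (layer$residual) y + x else y
}

#' @export
layer_backward.ir <- function(layer, dy) {
  dx <- layer_backward(layer$children$body, dy)
  if (layer$residual) dx + dy else dx
}

#' @export
layer_macs.ir <- function(layer, shp) {
  layer_macs(layer$children$body, shp)
}

#' Forward pass of an IR/HAIR block
#' @param x feature map `(H,W,C)` or `(H,W,C,N)`
#' @param block an [ir_block()]
#' @return output feature map
#' @export
ir_forward <- function(x, block) {
  cc <- as_hwcn(x)
  if (dim(cc$x)[3] != block$in_ch) stop("channel mismatch")
  y <- layer_forward(block, cc$x, training = FALSE)
  restore_dim(y, cc$orig)
}

#' @rdname ir_forward
#' @export
hair_forward <- function(x, block) {
  if (!isTRUE(block$use_scse)) stop("block has no scSE module")
  ir_forward(x, block)
}

# ---- agent transformer ---------------------------------------------------

tok_to_mat <- function(x) {
  d <- dim(x)
  matrix(aperm(x, c(1, 3, 2)), d[1] * d[3], d[2])
}

mat_to_tok <- function(m, d3) {
  array(aperm(array(m, c(d3[1], d3[3], d3[2])), c(1, 3, 2)), d3)
}

#' Agent-Transformer block
#'
#' Pre-norm transformer layer with multi-head agent attention:
#' `t + AgentAttn(LN(t))` followed by `(.) + MLP(LN(.))`, where the MLP
#' is `linear(d, rho*d) -> SiLU -> linear(rho*d, d)`.
#'
#' @param d token dimension
#' @param heads attention heads
#' @param n agent token count
#' @param rho MLP expansion ratio (default 2)
#' @param base_grid base token grid for the agent biases
#' @return a `wha_layer` of class `agent_tx`
#' @export
agent_transformer <- function(d, heads = 4L, n = 16L, rho = 2,
                              base_grid = c(8L, 8L)) {
  l <- new_layer("agent_tx", d = d, rho = rho)
  l$children$ln1 <- layernorm(d)
  l$children$attn <- agent_attention_layer(d, heads, n, base_grid)
  l$children$ln2 <- layernorm(d)
  l$children$fc1 <- linear_layer(d, as.integer(rho * d))
  l$children$fc2 <- linear_layer(as.integer(rho * d), d)
  l
}

#' @export
layer_forward.agent_tx <- function(layer, x, training = FALSE) {
  d3 <- dim(x)
  grid <- attr(x, "token_grid")
  h1 <- mat_to_tok(layer_forward(layer$children$ln1, tok_to_mat(x),
                                 training), d3)
  attr(h1, "token_grid") <- grid
  x1 <- x + layer_forward(layer$children$attn, h1, training)
  m <- layer_forward(layer$children$ln2, tok_to_mat(x1), training)
  z1 <- layer_forward(layer$children$fc1, m, training)
  if (training) layer$cache <- list(d3 = d3, z1 = z1)
  h2 <- layer_forward(layer$children$fc2, silu(z1), training)
  y <- x1 + mat_to_tok(h2, d3)
  attr(y, "token_grid") <- grid
  y
}

#' @export
layer_backward.agent_tx <- function(layer, dy) {
  d3 <- layer$cache$d3
  dm2 <- layer_backward(layer$children$fc2, tok_to_mat(dy))
  dz1 <- dm2 * silu_grad(layer$cache$z1)
  dm <- layer_backward(layer$children$fc1, dz1)
  dx1 <- dy + mat_to_tok(layer_backward(layer$children$ln2, dm), d3)
  dh1 <- layer_backward(layer$children$attn, dx1)
  dx <- dx1 + mat_to_tok(layer_backward(layer$children$ln1,
                                        tok_to_mat(dh1)), d3)
  dx
}

#' Forward pass of an Agent-Transformer on a token batch
#' @param t `(N, d, S)` token array (or `N x d` matrix) with a
#'   `token_grid` attribute
#' @param params an [agent_transformer()]
#' @return same shape as `t`
#' @export
agent_transformer_forward <- function(t, params) {
  was_mat <- is.matrix(t)
  if (was_mat) {
    g <- attr(t, "token_grid")
    n <- nrow(t)
    t <- array(t, c(n, ncol(t), 1L))
    rt <- as.integer(round(sqrt(n)))
    attr(t, "token_grid") <- g %||% c(rt, max(1L, n %/% rt))
  }
  y <- layer_forward(params, t, training = FALSE)
  if (was_mat) matrix(y[, , 1], dim(y)[1], dim(y)[2]) else y
}

macs_agent_tx <- function(layer, n_tokens) {
  d <- layer$d
  na <- prod(layer$children$attn$agent_grid)
  m <- layer_macs(layer$children$attn, c(n_tokens, d))$macs
  m + 2 * layer$rho * d * d * n_tokens
}

# ---- Agent-MViT ----------------------------------------------------------

#' Agent-MViT block
#'
#' Local representation via depthwise 3x3 (+BN+SiLU) and pointwise
#' projection to the token dimension; global modeling via `L` stacked
#' Agent-Transformers on unfolded patch tokens (patch size `p`), a final
#' layer norm, folding back, and pointwise reversion to the block
#' channels; fusion concatenates the local representation with the
#' globalized one, projects `2C -> C` pointwise, and adds the block
#' input (MobileViTv3-style residual). Output shape equals input shape.
#'
#' @param ch block channel count
#' @param d token dimension
#' @param L number of stacked transformers
#' @param p patch size (default 2)
#' @param heads attention heads
#' @param n agent token count
#' @param base_grid base token grid for agent biases (defaults to the
#'   grid this block sees at 256x256 network input)
#' @param rho MLP expansion ratio
#' @return a `wha_layer` of class `agent_mvit`
#' @export
agent_mvit <- function(ch, d, L, p = 2L, heads = 4L, n = 16L,
                       base_grid = c(8L, 8L), rho = 2) {
  l <- new_layer("agent_mvit", ch = ch, d = d, L = as.integer(L),
                 p = as.integer(p))
  l$children$dw <- conv2d(ch, ch, k = 3, groups = ch, bias = FALSE)
  l$children$bn_dw <- bnact_layer(ch, "silu")
  l$children$pw <- conv2d(ch, d, k = 1, bias = FALSE)
  for (i in seq_len(L))
    l$children[[paste0("tx", i)]] <-
      agent_transformer(d, heads, n, rho, base_grid)
  l$children$ln <- layernorm(d)
  l$children$proj <- conv2d(d, ch, k = 1, bias = FALSE)
  l$children$bn_proj <- batchnorm2d(ch)
  l$children$fuse <- conv2d(2L * ch, ch, k = 1, bias = FALSE)
  l$children$bn_fuse <- batchnorm2d(ch, gamma_init = 0)
  l
}

#' @export
layer_forward.agent_mvit <- function(layer, x, training = FALSE) {
  d4 <- dim(x)
  p <- layer$p
  local <- layer_forward(layer$children$bn_dw,
             layer_forward(layer$children$dw, x, training), training)
  z <- layer_forward(layer$children$pw, local, training)
  pp <- reflect_pad(z, p)
  t <- unfold_patches(pp$x, p)
  fold_shape <- attr(t, "fold_shape")
  for (i in seq_len(layer$L))
    t <- layer_forward(layer$children[[paste0("tx", i)]], t, training)
  d3 <- dim(t)
  tm <- layer_forward(layer$children$ln, tok_to_mat(t), training)
  t2 <- mat_to_tok(tm, d3)
  zf <- fold_patches(t2, fold_shape)
  if (pp$ph > 0 || pp$pw > 0)
    zf <- zf[seq_len(d4[1]), seq_len(d4[2]), , , drop = FALSE]
  g <- layer_forward(layer$children$bn_proj,
         layer_forward(layer$children$proj, zf, training), training)
  cat2 <- array(0, c(d4[1], d4[2], 2L * layer$ch, d4[4]))
  cat2[, , seq_len(layer$ch), ] <- local
  cat2[, , layer$ch + seq_len(layer$ch), ] <- g
  fus <- layer_forward(layer$children$bn_fuse,
           layer_forward(layer$children$fuse, cat2, training), training)
  if (training)
    layer$cache <- list(d4 = d4, d3 = d3, ph = pp$ph, pw = pp$pw,
                        fold_shape = fold_shape)
  fus + x
}

#' @export
layer_backward.agent_mvit <- function(layer, dy) {
  ca <- layer$cache
  d4 <- ca$d4
  dfus <- layer_backward(layer$children$fuse,
            layer_backward(layer$children$bn_fuse, dy))
  dlocal <- dfus[, , seq_len(layer$ch), , drop = FALSE]
  dg <- dfus[, , layer$ch + seq_len(layer$ch), , drop = FALSE]
  dzf <- layer_backward(layer$children$proj,
           layer_backward(layer$children$bn_proj, dg))
  if (ca$ph > 0 || ca$pw > 0) {
    z <- array(0, c(d4[1] + ca$ph, d4[2] + ca$pw, layer$d, d4[4]))
    z[seq_len(d4[1]), seq_len(d4[2]), , ] <- dzf
    dzf <- z
  }
  dt2 <- unfold_patches(dzf, layer$p)   # adjoint of fold = unfold
  dtm <- layer_backward(layer$children$ln, tok_to_mat(dt2))
  dt <- mat_to_tok(dtm, ca$d3)
  for (i in rev(seq_len(layer$L)))
    dt <- layer_backward(layer$children[[paste0("tx", i)]], dt)
  dz <- fold_patches(dt, ca$fold_shape) # adjoint of unfold = fold
  if (ca$ph > 0 || ca$pw > 0)
    dz <- reflect_pad_adjoint(dz, d4[1], d4[2], ca$ph, ca$pw)
  dlocal <- dlocal + layer_backward(layer$children$pw, dz)
  dx <- layer_backward(layer$children$dw,
          layer_backward(layer$children$bn_dw, dlocal))
  dx + dy
}

#' Forward pass of an Agent-MViT block
#' @param x feature map `(H,W,C)` or `(H,W,C,N)`
#' @param block an [agent_mvit()]
#' @return output feature map, same shape as `x`
#' @export
agent_mvit_forward <- function(x, block) {
  cc <- as_hwcn(x)
  if (dim(cc$x)[3] != block$ch) stop("channel mismatch")
  restore_dim(layer_forward(block, cc$x, training = FALSE), cc$orig)
}

#' @export
layer_macs.agent_mvit <- function(layer, shp) {
  hw <- shp[1] * shp[2]
  ch <- layer$ch; d <- layer$d
  m <- 9 * ch * hw + ch * d * hw            # local rep
  for (i in seq_len(layer$L))
    m <- m + macs_agent_tx(layer$children[[paste0("tx", i)]], hw)
  m <- m + d * ch * hw + 2 * ch * ch * hw   # proj + fusion
  list(macs = m, shp = shp)
}
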