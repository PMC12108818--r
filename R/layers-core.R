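# Core building-block layers. Feature maps are (H, W, C, N) arrays.

# broadcast a per-channel vector over (H,W,C,N); relies on R recycling:
# rep(g, each = H*W) has length H*W*C which divides the array length.
bcast_channel <- function(x, g) {
  d <- dim(x)
  x * rep(g, each = d[1] * d[2])
}

channel_sum <- function(x) {
  d <- dim(x)
  m <- matrix(x, d[1] * d[2], d[3] * d[4])
  rowSums(matrix(colSums(m), d[3], d[4]))
}

conv_out_hw <- function(hw, k, stride, pad) (hw + 2 * pad - k) %/% stride + 1

# ---- conv2d -------------------------------------------------------------

conv2d <- function(in_ch, out_ch, k = 3, stride = 1,
                   pad = (k - 1) %/% 2, groups = 1, bias = TRUE) {
  stopifnot(in_ch %% groups == 0, out_ch %% groups == 0)
  l <- new_layer("conv2d", in_ch = in_ch, out_ch = out_ch, k = k,
                 stride = stride, pad = pad, groups = groups)
  fan_in <- k * k * in_ch / groups
  l$params$W <- kaiming_init(c(k, k, in_ch %/% groups, out_ch), fan_in)
  if (bias) l$params$b <- numeric(out_ch)
  l
}

is_depthwise <- function(layer) {
  layer$groups == layer$in_ch && layer$in_ch == layer$out_ch
}

#' @export
layer_forward.conv2d <- function(layer, x, training = FALSE) {
  if (training) layer$cache$x <- x
  if (is_depthwise(layer))
    dwconv_fwd_cpp(x, layer$params$W, layer$params$b,
                   layer$stride, layer$pad)
  else
    conv2d_fwd_cpp(x, layer$params$W, layer$params$b,
                   layer$stride, layer$pad, layer$groups)
}

#' @export
layer_backward.conv2d <- function(layer, dy) {
  if (is_depthwise(layer)) {
    r <- dwconv_bwd_cpp(layer$cache$x, layer$params$W, dy,
                        layer$stride, layer$pad,
                        !is.null(layer$params$b))
  } else {
    r <- conv2d_bwd_cpp(layer$cache$x, layer$params$W, dy,
                        layer$stride, layer$pad, layer$groups,
                        TRUE, !is.null(layer$params$b))
  }
  acc_grad(layer, "W", r$dw)
  if (!is.null(layer$params$b)) acc_grad(layer, "b", r$db)
  r$dx
}

# ---- batch normalization ------------------------------------------------

batchnorm2d <- function(ch, eps = 1e-5, momentum = 0.1,
                        gamma_init = 1) {
  l <- new_layer("bn2d", ch = ch, eps = eps, momentum = momentum)
  l$params$gamma <- rep(gamma_init, ch)
  l$params$beta <- numeric(ch)
  l$buffers$running_mean <- numeric(ch)
  l$buffers$running_var <- rep(1, ch)
  l
}

#' @export
layer_forward.bn2d <- function(layer, x, training = FALSE) {
  if (training && !isTRUE(layer$frozen_stats)) {
    m <- dim(x)[1] * dim(x)[2] * dim(x)[4]
    r <- bn_fwd_train_cpp(x, layer$params$gamma, layer$params$beta,
                          layer$eps)
    mom <- layer$momentum
    layer$buffers$running_mean <-
      (1 - mom) * layer$buffers$running_mean + mom * r$mu
    layer$buffers$running_var <-
      (1 - mom) * layer$buffers$running_var + mom * r$var * m / max(m - 1, 1)
    layer$cache <- list(xhat = r$xhat, invstd = r$invstd)
    r$y
  } else {
    invstd <- 1 / sqrt(layer$buffers$running_var + layer$eps)
    scale <- layer$params$gamma * invstd
    shift <- layer$params$beta - layer$buffers$running_mean * scale
    layer$cache <- list(scale = scale)
    bn_fwd_eval_cpp(x, scale, shift)
  }
}

#' @export
layer_backward.bn2d <- function(layer, dy) {
  if (!is.null(layer$cache$scale)) {   # eval-mode (used by Grad-CAM)
    return(bcast_channel(dy, layer$cache$scale))
  }
  r <- bn_bwd_cpp(dy, layer$cache$xhat, layer$params$gamma,
                  layer$cache$invstd)
  acc_grad(layer, "gamma", r$dgamma)
  acc_grad(layer, "beta", r$dbeta)
  r$dx
}

# ---- fused batch norm + activation --------------------------------------

bnact_layer <- function(ch, act = "silu", eps = 1e-5, momentum = 0.1,
                        gamma_init = 1) {
  l <- new_layer("bnact", ch = ch, eps = eps, momentum = momentum,
                 act_name = act,
                 act_code = switch(act, silu = 1L, hard_swish = 3L, 0L))
  l$params$gamma <- rep(gamma_init, ch)
  l$params$beta <- numeric(ch)
  l$buffers$running_mean <- numeric(ch)
  l$buffers$running_var <- rep(1, ch)
  l
}

#' @export
layer_forward.bnact <- function(layer, x, training = FALSE) {
  if (training && !isTRUE(layer$frozen_stats)) {
    m <- dim(x)[1] * dim(x)[2] * dim(x)[4]
    r <- bnact_fwd_train_cpp(x, layer$params$gamma, layer$params$beta,
                             layer$eps, layer$act_code)
    mom <- layer$momentum
    layer$buffers$running_mean <-
      (1 - mom) * layer$buffers$running_mean + mom * r$mu
    layer$buffers$running_var <-
      (1 - mom) * layer$buffers$running_var + mom * r$var * m / max(m - 1, 1)
    layer$cache <- list(xhat = r$xhat, invstd = r$invstd)
    r$y
  } else {
    invstd <- 1 / sqrt(layer$buffers$running_var + layer$eps)
    scale <- layer$params$gamma * invstd
    shift <- layer$params$beta - layer$buffers$running_mean * scale
    layer$cache <- list(scale = scale, x = if (training) x)
    bnact_fwd_eval_cpp(x, scale, shift, layer$act_code)
  }
}

#' @export
layer_backward.bnact <- function(layer, dy) {
  if (!is.null(layer$cache$scale)) {  # frozen-stats path (Grad-CAM)
    d <- dim(dy)
    scale <- layer$cache$scale
    shift <- layer$params$beta - layer$buffers$running_mean * scale
    z <- bcast_channel(layer$cache$x, scale) + rep(shift, each = d[1] * d[2])
    g <- if (layer$act_code == 1L) silu_grad(z)
      else if (layer$act_code == 3L) hard_swish_grad(z)
      else array(1, d)
    return(bcast_channel(dy * g, scale))
  }
  r <- bnact_bwd_cpp(dy, layer$cache$xhat, layer$params$gamma,
                     layer$params$beta, layer$cache$invstd,
                     layer$act_code)
  acc_grad(layer, "gamma", r$dgamma)
  acc_grad(layer, "beta", r$dbeta)
  r$dx
}

# ---- linear (on row-major sample matrices) ------------------------------

linear_layer <- function(d_in, d_out, bias = TRUE, zero_init = FALSE,
                         init_sd = NULL) {
  l <- new_layer("linear", d_in = d_in, d_out = d_out)
  l$params$W <- if (zero_init) array(0, c(d_in, d_out))
    else if (!is.null(init_sd))
      array(stats::rnorm(d_in * d_out, sd = init_sd), c(d_in, d_out))
    else kaiming_init(c(d_in, d_out), d_in)
  if (bias) l$params$b <- numeric(d_out)
  l
}

#' @export
layer_forward.linear <- function(layer, x, training = FALSE) {
  if (training) layer$cache$x <- x
  y <- x %*% layer$params$W
  if (!is.null(layer$params$b)) y <- sweep(y, 2, layer$params$b, "+")
  y
}

#' @export
layer_backward.linear <- function(layer, dy) {
  acc_grad(layer, "W", crossprod(layer$cache$x, dy))
  if (!is.null(layer$params$b)) acc_grad(layer, "b", colSums(dy))
  tcrossprod(dy, layer$params$W)
}

# ---- layer normalization (rows of a matrix, across columns) -------------

layernorm <- function(d, eps = 1e-5) {
  l <- new_layer("layernorm", d = d, eps = eps)
  l$params$gamma <- rep(1, d)
  l$params$beta <- numeric(d)
  l
}

#' @export
layer_forward.layernorm <- function(layer, x, training = FALSE) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc * xc)
  invstd <- 1 / sqrt(v + layer$eps)
  xhat <- xc * invstd
  if (training) layer$cache <- list(xhat = xhat, invstd = invstd)
  sweep(xhat, 2, layer$params$gamma, "*") +
    rep(layer$params$beta, each = nrow(x))
}

#' @export
layer_backward.layernorm <- function(layer, dy) {
  xhat <- layer$cache$xhat
  acc_grad(layer, "gamma", colSums(dy * xhat))
  acc_grad(layer, "beta", colSums(dy))
  dxhat <- sweep(dy, 2, layer$params$gamma, "*")
  (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) *
    layer$cache$invstd
}

# ---- global average pooling --------------------------------------------

gap_layer <- function() new_layer("gap")

#' @export
layer_forward.gap <- function(layer, x, training = FALSE) {
  d <- dim(x)
  if (training) layer$cache$dim <- d
  matrix(colSums(matrix(x, d[1] * d[2], d[3] * d[4])) / (d[1] * d[2]),
         d[3], d[4])
}

#' @export
layer_backward.gap <- function(layer, dy) {
  d <- layer$cache$dim
  array(rep(as.vector(dy), each = d[1] * d[2]) / (d[1] * d[2]), dim = d)
}

# ---- sequential ---------------------------------------------------------

sequential <- function(...) {
  ch <- list(...)
  if (length(ch) == 1 && is.list(ch[[1]]) && !inherits(ch[[1]], "wha_layer"))
    ch <- ch[[1]]
  if (is.null(names(ch)) || any(names(ch) == ""))
    names(ch) <- sprintf("l%02d", seq_along(ch))
  l <- new_layer("sequential")
  l$children <- ch
  l
}

#' @export
layer_forward.sequential <- function(layer, x, training = FALSE) {
  for (ch in layer$children) x <- layer_forward(ch, x, training)
  x
}

#' @export
layer_backward.sequential <- function(layer, dy) {
  for (ch in rev(layer$children)) dy <- layer_backward(ch, dy)
  dy
}

# ---- analytic MAC accounting -------------------------------------------
# layer_macs(layer, shp) with shp = c(H, W, C) returns list(macs, shp).
# Convolutions count k^2 * Cin * Cout * Ho * Wo / groups; linears count
# rows * d_in * d_out; normalizations, activations and pooling count zero.

layer_macs <- function(layer, shp) UseMethod("layer_macs")

#' @export
layer_macs.conv2d <- function(layer, shp) {
  ho <- conv_out_hw(shp[1], layer$k, layer$stride, layer$pad)
  wo <- conv_out_hw(shp[2], layer$k, layer$stride, layer$pad)
  m <- layer$k^2 * layer$in_ch * layer$out_ch * ho * wo / layer$groups
  list(macs = m, shp = c(ho, wo, layer$out_ch))
}

#' @export
layer_macs.bn2d <- function(layer, shp) list(macs = 0, shp = shp)

#' @export
layer_macs.bnact <- function(layer, shp) list(macs = 0, shp = shp)

#' @export
layer_macs.act <- function(layer, shp) list(macs = 0, shp = shp)

#' @export
layer_macs.gap <- function(layer, shp) list(macs = 0, shp = c(1, 1, shp[3]))

#' @export
layer_macs.linear <- function(layer, shp) {
  # applied to pooled features: one row per sample
  list(macs = layer$d_in * layer$d_out, shp = c(1, 1, layer$d_out))
}

#' @export
layer_macs.sequential <- function(layer, shp) {
  total <- 0
  for (ch in layer$children) {
    r <- layer_macs(ch, shp)
    total <- total + r$macs
    shp <- r$shp
  }
  list(macs = total, shp = shp)
}
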