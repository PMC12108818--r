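# Haar wavelet convolution (WTC) block.
#
# A fixed orthonormal 2x2 Haar filter bank decomposes each channel into
# four half-resolution subbands (LL/LH/HL/HH); decomposition recurses on
# the *unconvolved* LL. Learnable 3x3 depthwise kernels filter every
# subband at every level plus the original scale; reconstruction runs
# bottom-up through the exact inverse transform, adding each level's
# output to the convolved LL of the level above. The whole block is
# linear in its input for fixed kernels.
#
# Convention: cross-correlation (no kernel flip); subband names follow
# the usual wavelet-CNN ordering in which "LH" denotes the filter
# [[1/2,1/2],[-1/2,-1/2]] (responding to vertical intensity variation).

#' The fixed 2x2 Haar filter bank
#'
#' Returns the four orthonormal analysis filters with entries +-1/2:
#' one low-pass (`f_LL`) and three high-pass (`f_LH`, `f_HL`, `f_HH`)
#' kernels. Each has unit L2 norm and the four are mutually orthogonal,
#' so the induced transform conserves energy exactly.
#'
#' @return an object of class `haar_filter_bank`: a named list of four
#'   2x2 matrices
#' @examples
#' fb <- haar_filter_bank()
#' sum(fb$f_LL^2)            # 1
#' sum(fb$f_LL * fb$f_HH)    # 0
#' @export
haar_filter_bank <- function() {
  h <- 1 / 2
  fb <- list(
    f_LL = matrix(c(h, h, h, h), 2, 2),
    f_LH = matrix(c(h, -h, h, -h), 2, 2),
    f_HL = matrix(c(h, h, -h, -h), 2, 2),
    f_HH = matrix(c(h, -h, -h, h), 2, 2)
  )
  structure(fb, class = "haar_filter_bank")
}

# coerce input to (H, W, C, N), remembering the original shape
as_hwcn <- function(x) {
  d <- dim(x)
  if (is.null(d)) stop("input must be a matrix or array")
  orig <- d
  if (length(d) == 2) dim(x) <- c(d, 1L, 1L)
  else if (length(d) == 3) dim(x) <- c(d, 1L)
  else if (length(d) != 4) stop("input must have 2-4 dimensions")
  list(x = x, orig = orig)
}

restore_dim <- function(x, orig, half = FALSE, double = FALSE) {
  d <- dim(x)
  if (length(orig) == 2) dim(x) <- d[1:2]
  if (length(orig) == 3) dim(x) <- d[1:3]
  x
}

#' Single-level 2-D Haar decomposition
#'
#' Stride-2 per-channel cross-correlation of a feature map with the fixed
#' Haar filter bank. Each subband has half the spatial resolution (a
#' quarter of the area) and the same channel count as the input; the
#' transform is orthonormal, so total sum of squares is conserved.
#'
#' @param x matrix, `(H,W,C)` or `(H,W,C,N)` array with even `H` and `W`
#' @return an object of class `subband_set`: list with `level` and the
#'   four subbands `LL`, `LH`, `HL`, `HH` shaped like `x` at half
#'   resolution
#' @examples
#' s <- dwt2(matrix(c(1, 3, 2, 4), 2, 2))  # [[1,2],[3,4]]
#' c(s$LL, s$LH, s$HL, s$HH)               # 5, -2, -1, 0
#' @export
dwt2 <- function(x) {
  cc <- as_hwcn(x)
  d <- dim(cc$x)
  if (any(d[1:2] == 0)) stop("empty feature map")
  if (d[1] %% 2 != 0 || d[2] %% 2 != 0)
    stop("spatial dimensions must be even; pad first")
  xa <- cc$x
  ro <- seq(1, d[1], 2); re <- seq(2, d[1], 2)
  co <- seq(1, d[2], 2); ce <- seq(2, d[2], 2)
  a <- xa[ro, co, , , drop = FALSE]  # top-left of each 2x2 patch
  b <- xa[ro, ce, , , drop = FALSE]  # top-right
  cc_ <- xa[re, co, , , drop = FALSE] # bottom-left
  dd <- xa[re, ce, , , drop = FALSE] # bottom-right
  s <- list(
    level = 1L,
    LL = (a + b + cc_ + dd) / 2,
    LH = (a + b - cc_ - dd) / 2,
    HL = (a - b + cc_ - dd) / 2,
    HH = (a - b - cc_ + dd) / 2
  )
  if (length(cc$orig) < 4)
    for (nm in c("LL", "LH", "HL", "HH"))
      s[[nm]] <- restore_dim(s[[nm]], cc$orig)
  structure(s, class = "subband_set")
}

#' Inverse 2-D Haar transform
#'
#' Stride-2 transposed convolution with the same fixed filter bank,
#' summed over the four subbands; the exact inverse of [dwt2()].
#'
#' @param s a `subband_set` (or plain list with `LL`, `LH`, `HL`, `HH`)
#' @return feature map at twice the subband resolution
#' @examples
#' x <- matrix(rnorm(16), 4, 4)
#' max(abs(idwt2(dwt2(x)) - x))   # ~1e-16
#' @export
idwt2 <- function(s) {
  bands <- lapply(s[c("LL", "LH", "HL", "HH")], function(b) as_hwcn(b)$x)
  dims <- lapply(bands, dim)
  if (!all(vapply(dims, identical, TRUE, dims[[1]])))
    stop("subband shapes differ")
  d <- dims[[1]]
  y <- array(0, c(2 * d[1], 2 * d[2], d[3], d[4]))
  ro <- seq(1, 2 * d[1], 2); re <- seq(2, 2 * d[1], 2)
  co <- seq(1, 2 * d[2], 2); ce <- seq(2, 2 * d[2], 2)
  LL <- bands$LL; LH <- bands$LH; HL <- bands$HL; HH <- bands$HH
  y[ro, co, , ] <- (LL + LH + HL + HH) / 2
  y[ro, ce, , ] <- (LL + LH - HL - HH) / 2
  y[re, co, , ] <- (LL - LH + HL - HH) / 2
  y[re, ce, , ] <- (LL - LH - HL + HH) / 2
  orig <- dim(s$LL)
  if (is.null(orig)) dim(y) <- dim(y)[1:2]
  else if (length(orig) == 2) dim(y) <- dim(y)[1:2]
  else if (length(orig) == 3) dim(y) <- dim(y)[1:3]
  y
}

# stack a subband_set into a (H, W, 4C, N) array ordered LL,LH,HL,HH
stack_subbands <- function(s) {
  d <- dim(s$LL)
  out <- array(0, c(d[1], d[2], 4 * d[3], d[4]))
  ch <- d[3]
  out[, , 1:ch, ] <- s$LL
  out[, , ch + 1:ch, ] <- s$LH
  out[, , 2 * ch + 1:ch, ] <- s$HL
  out[, , 3 * ch + 1:ch, ] <- s$HH
  out
}

unstack_subbands <- function(a) {
  d <- dim(a)
  ch <- d[3] %/% 4L
  list(LL = a[, , 1:ch, , drop = FALSE],
       LH = a[, , ch + 1:ch, , drop = FALSE],
       HL = a[, , 2 * ch + 1:ch, , drop = FALSE],
       HH = a[, , 3 * ch + 1:ch, , drop = FALSE])
}

# reflect-pad right/bottom to multiples of `mult` (and its adjoint)
reflect_pad <- function(x, mult) {
  d <- dim(x)
  ph <- (mult - d[1] %% mult) %% mult
  pw <- (mult - d[2] %% mult) %% mult
  if (ph == 0 && pw == 0) return(list(x = x, ph = 0L, pw = 0L))
  if (ph > 0) {
    idx <- d[1] - seq_len(ph)           # reflect without repeating the edge
    x2 <- array(0, c(d[1] + ph, d[2], d[3], d[4]))
    x2[seq_len(d[1]), , , ] <- x
    x2[d[1] + seq_len(ph), , , ] <- x[idx, , , , drop = FALSE]
    x <- x2; d <- dim(x)
  }
  if (pw > 0) {
    idx <- d[2] - seq_len(pw)
    x2 <- array(0, c(d[1], d[2] + pw, d[3], d[4]))
    x2[, seq_len(d[2]), , ] <- x
    x2[, d[2] + seq_len(pw), , ] <- x[, idx, , , drop = FALSE]
    x <- x2
  }
  list(x = x, ph = ph, pw = pw)
}

reflect_pad_adjoint <- function(dxp, orig_h, orig_w, ph, pw) {
  if (pw > 0) {
    d <- dim(dxp)
    body_w <- d[2] - pw
    idx <- body_w - seq_len(pw)
    extra <- dxp[, body_w + seq_len(pw), , , drop = FALSE]
    dxp <- dxp[, seq_len(body_w), , , drop = FALSE]
    dxp[, idx, , ] <- dxp[, idx, , , drop = FALSE] + extra
  }
  if (ph > 0) {
    d <- dim(dxp)
    body_h <- d[1] - ph
    idx <- body_h - seq_len(ph)
    extra <- dxp[body_h + seq_len(ph), , , , drop = FALSE]
    dxp <- dxp[seq_len(body_h), , , , drop = FALSE]
    dxp[idx, , , ] <- dxp[idx, , , , drop = FALSE] + extra
  }
  dxp
}

#' Wavelet convolution (WTC) layer
#'
#' Two-branch wavelet convolution: an original-scale depthwise
#' convolution of the input, plus a recursive Haar decomposition with
#' learnable per-subband depthwise 3x3 kernels and inverse-transform
#' aggregation. The Haar filters themselves are fixed (non-learnable).
#' Output shape equals input shape; inputs whose spatial dimensions are
#' not divisible by `2^levels` are reflect-padded and cropped back.
#' The block contains no bias, normalization or nonlinearity.
#'
#' @param ch number of input (= output) channels
#' @param levels decomposition depth (default 2)
#' @param orig_branch_kernel kernel size of the original-scale branch,
#'   1 or 3 (default 3)
#' @return a `wha_layer` of class `wtc`
#' @export
wtc_layer <- function(ch, levels = 2L, orig_branch_kernel = 3L) {
  if (levels < 1) stop("levels must be >= 1")
  if (!orig_branch_kernel %in% c(1L, 3L))
    stop("orig_branch_kernel must be 1 or 3")
  l <- new_layer("wtc", ch = ch, levels = as.integer(levels))
  l$children$conv0 <- conv2d(ch, ch, k = orig_branch_kernel,
                             groups = ch, bias = FALSE)
  for (i in seq_len(levels))
    l$children[[paste0("conv", i)]] <-
      conv2d(4 * ch, 4 * ch, k = 3, groups = 4 * ch, bias = FALSE)
  l
}

#' @export
layer_forward.wtc <- function(layer, x, training = FALSE) {
  cc <- as_hwcn(x)
  d0 <- dim(cc$x)
  pp <- reflect_pad(cc$x, 2^layer$levels)
  xp <- pp$x
  # analysis chain on unconvolved LL
  stacks <- vector("list", layer$levels)
  xi <- xp
  for (i in seq_len(layer$levels)) {
    s <- dwt2(xi)
    stacks[[i]] <- stack_subbands(s)
    xi <- s$LL
  }
  # per-subband convolutions
  ys <- vector("list", layer$levels)
  for (i in seq_len(layer$levels))
    ys[[i]] <- layer_forward(layer$children[[paste0("conv", i)]],
                             stacks[[i]], training)
  # bottom-up reconstruction
  z <- 0
  for (i in rev(seq_len(layer$levels))) {
    s <- unstack_subbands(ys[[i]])
    s$LL <- s$LL + z
    z <- idwt2(s)
  }
  out <- layer_forward(layer$children$conv0, xp, training) + z
  if (pp$ph > 0 || pp$pw > 0)
    out <- out[seq_len(d0[1]), seq_len(d0[2]), , , drop = FALSE]
  if (training)
    layer$cache <- list(d0 = d0, ph = pp$ph, pw = pp$pw, orig = cc$orig)
  if (length(cc$orig) < 4) out <- restore_dim(out, cc$orig)
  out
}

#' @export
layer_backward.wtc <- function(layer, dy) {
  ca <- layer$cache
  dyc <- as_hwcn(dy)$x
  d0 <- ca$d0
  if (ca$ph > 0 || ca$pw > 0) {
    dyp <- array(0, c(d0[1] + ca$ph, d0[2] + ca$pw, d0[3], d0[4]))
    dyp[seq_len(d0[1]), seq_len(d0[2]), , ] <- dyc
  } else dyp <- dyc
  # adjoint of reconstruction: dwt2 (adjoint of idwt2) peels level by level
  dA <- vector("list", layer$levels)
  dz <- dyp
  for (i in seq_len(layer$levels)) {
    a <- dwt2(dz)
    dA[[i]] <- a
    dz <- a$LL
  }
  # adjoint of convs and of the analysis chain, bottom-up
  carry <- 0
  for (i in rev(seq_len(layer$levels))) {
    dstack <- layer_backward(layer$children[[paste0("conv", i)]],
                             stack_subbands(dA[[i]]))
    ds <- unstack_subbands(dstack)
    ds$LL <- ds$LL + carry
    carry <- idwt2(ds)
  }
  dxp <- carry + layer_backward(layer$children$conv0, dyp)
  dx <- reflect_pad_adjoint(dxp, d0[1], d0[2], ca$ph, ca$pw)
  if (length(ca$orig) < 4) dim(dx) <- ca$orig
  dx
}

#' Apply a WTC layer to a feature map
#'
#' Functional wrapper around [layer_forward()] for a [wtc_layer()].
#'
#' @param x feature map (matrix, `(H,W,C)` or `(H,W,C,N)` array)
#' @param layer a `wtc` layer whose channel count matches `x`
#' @return filtered feature map, same shape as `x`
#' @export
wtc_forward <- function(x, layer) {
  stopifnot(inherits(layer, "wtc"))
  layer_forward(layer, x, training = FALSE)
}

#' @export
layer_macs.wtc <- function(layer, shp) {
  ch <- layer$ch
  k0 <- layer$children$conv0$k
  m <- k0^2 * ch * shp[1] * shp[2]
  h <- shp[1]; w <- shp[2]
  for (i in seq_len(layer$levels)) {
    h <- h / 2; w <- w / 2
    m <- m + 16 * ch * h * w     # analysis filter bank (4 filters, 2x2)
    m <- m + 9 * 4 * ch * h * w  # per-subband depthwise 3x3
    m <- m + 16 * ch * h * w     # synthesis (transposed) filter bank
  }
  list(macs = m, shp = shp)
}
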