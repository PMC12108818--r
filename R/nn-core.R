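#' @useDynLib whanet, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif
NULL

# ------------------------------------------------------------------------
# Minimal neural-network layer framework.
#
# Every layer is an environment with class c("<kind>", "wha_layer") holding
#   params   named list of numeric arrays (learnable)
#   grads    named list, same shapes, accumulated by layer_backward()
#   buffers  named list of non-learnable state (e.g. BN running stats)
#   children named list of sub-layers (composites)
#   cache    forward-pass intermediates consumed by the matching backward
# Feature maps are (H, W, C, N) arrays; token batches are (N, d, S) arrays.
# ------------------------------------------------------------------------

new_layer <- function(.kind, ...) {
  e <- new.env(parent = emptyenv())
  e$params <- list()
  e$grads <- list()
  e$buffers <- list()
  e$children <- list()
  e$cache <- list()
  e$training <- FALSE
  dots <- list(...)
  for (nm in names(dots)) assign(nm, dots[[nm]], envir = e)
  class(e) <- c(.kind, "wha_layer")
  e
}

#' Run a layer forward
#'
#' Generic dispatch for the forward pass of any network layer. When
#' `training = TRUE` layers cache the intermediates needed by
#' [layer_backward()] and batch-norm layers use batch statistics.
#'
#' @param layer a `wha_layer` object
#' @param x input array (feature map `(H,W,C,N)` or token batch `(N,d,S)`)
#' @param training logical; enable training behaviour and caching
#' @return the layer output array
#' @export
layer_forward <- function(layer, x, training = FALSE) {
  UseMethod("layer_forward")
}

#' Backpropagate through a layer
#'
#' Consumes the cache left by the last `layer_forward(..., training = TRUE)`
#' call, accumulates parameter gradients into `layer$grads`, and returns the
#' gradient with respect to the layer input.
#'
#' @param layer a `wha_layer` object
#' @param dy gradient of the loss w.r.t. the layer output
#' @return gradient w.r.t. the layer input
#' @export
layer_backward <- function(layer, dy) {
  UseMethod("layer_backward")
}

set_training <- function(layer, mode) {
  layer$training <- mode
  for (ch in layer$children) set_training(ch, mode)
  invisible(layer)
}

# Depth-first list of list(layer=, name=) references to every learnable array.
param_refs <- function(layer, prefix = "") {
  out <- list()
  for (nm in names(layer$params)) {
    out[[length(out) + 1L]] <-
      list(layer = layer, name = nm, path = paste0(prefix, nm))
  }
  for (cn in names(layer$children)) {
    out <- c(out, param_refs(layer$children[[cn]],
                             paste0(prefix, cn, ".")))
  }
  out
}

zero_grads <- function(layer) {
  for (nm in names(layer$params)) {
    g <- layer$params[[nm]]
    g[] <- 0
    layer$grads[[nm]] <- g
  }
  for (ch in layer$children) zero_grads(ch)
  invisible(layer)
}

acc_grad <- function(layer, name, g) {
  cur <- layer$grads[[name]]
  if (is.null(cur)) layer$grads[[name]] <- g else layer$grads[[name]] <- cur + g
  invisible(NULL)
}

n_params <- function(layer) {
  n <- sum(vapply(layer$params, length, 0L))
  for (ch in layer$children) n <- n + n_params(ch)
  n
}

# Serialize / restore all parameters and buffers (used for checkpoints and
# best-epoch selection).
state_dict <- function(layer, prefix = "") {
  out <- list()
  for (nm in names(layer$params))
    out[[paste0(prefix, nm)]] <- layer$params[[nm]]
  for (nm in names(layer$buffers))
    out[[paste0(prefix, "buf:", nm)]] <- layer$buffers[[nm]]
  for (cn in names(layer$children))
    out <- c(out, state_dict(layer$children[[cn]], paste0(prefix, cn, ".")))
  out
}

load_state_dict <- function(layer, sd, prefix = "") {
  for (nm in names(layer$params)) {
    key <- paste0(prefix, nm)
    if (!is.null(sd[[key]])) layer$params[[nm]] <- sd[[key]]
  }
  for (nm in names(layer$buffers)) {
    key <- paste0(prefix, "buf:", nm)
    if (!is.null(sd[[key]])) layer$buffers[[nm]] <- sd[[key]]
  }
  for (cn in names(layer$children))
    load_state_dict(layer$children[[cn]], sd, paste0(prefix, cn, "."))
  invisible(layer)
}

# ---- initializers -------------------------------------------------------

# scaled uniform initialization, U(+-sqrt(1/fan_in)) -- the standard
# convolution/linear default of mainstream deep-learning frameworks;
# with scale-free adaptive optimizers the weight scale sets how fast a
# fixed-size step rotates the function, so matching it matters in
# short schedules
kaiming_init <- function(dim, fan_in) {
  b <- sqrt(1 / fan_in)
  array(stats::runif(prod(dim), -b, b), dim = dim)
}

# ---- AdamW --------------------------------------------------------------

#' Create an AdamW optimizer
#'
#' Decoupled weight-decay Adam over every learnable parameter of a model,
#' matching the training recipe used for WHA-Net (weight decay 0.02).
#'
#' @param model root `wha_layer`
#' @param lr initial learning rate
#' @param betas length-2 numeric, exponential decay rates
#' @param eps numerical stabilizer
#' @param weight_decay decoupled weight-decay coefficient
#' @return an optimizer object with `$step()` semantics via [optim_step()]
#' @export
optim_adamw <- function(model, lr = 5e-4, betas = c(0.9, 0.999),
                        eps = 1e-8, weight_decay = 0.02) {
  refs <- param_refs(model)
  st <- lapply(refs, function(r) {
    p <- r$layer$params[[r$name]]
    list(m = array(0, dim = dim(p) %||% length(p)),
         v = array(0, dim = dim(p) %||% length(p)))
  })
  structure(list(refs = refs, state = st, lr = lr, betas = betas,
                 eps = eps, wd = weight_decay, t = 0L),
            class = "wha_optim")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Apply one AdamW update
#'
#' @param opt optimizer from [optim_adamw()]
#' @param lr learning rate for this step (overrides the stored one so a
#'   schedule can drive it)
#' @return the updated optimizer (its moment estimates are mutated by value)
#' @export
optim_step <- function(opt, lr = opt$lr) {
  opt$t <- opt$t + 1L
  b1 <- opt$betas[1]; b2 <- opt$betas[2]
  bc1 <- 1 - b1^opt$t; bc2 <- 1 - b2^opt$t
  for (i in seq_along(opt$refs)) {
    r <- opt$refs[[i]]
    g <- r$layer$grads[[r$name]]
    if (is.null(g)) next
    s <- opt$state[[i]]
    s$m <- b1 * s$m + (1 - b1) * g
    s$v <- b2 * s$v + (1 - b2) * g * g
    p <- r$layer$params[[r$name]]
    p <- p - lr * opt$wd * p
    p <- p - lr * (s$m / bc1) / (sqrt(s$v / bc2) + opt$eps)
    r$layer$params[[r$name]] <- p
    opt$state[[i]] <- s
  }
  opt
}
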