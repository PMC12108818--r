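# Activation functions used across the network. SiLU in shallow stages,
# Hard-Swish where channel counts are large; Hard-Sigmoid gates the
# attention modules.

#' Sigmoid-weighted linear unit
#' @param x numeric array
#' @return `x * plogis(x)`
#' @export
silu <- function(x) x * stats::plogis(x)

#' Piecewise-linear sigmoid approximation
#'
#' `clip((x + 3) / 6, 0, 1)`; saturates at -3 and +3.
#' @param x numeric array
#' @return values in `[0, 1]`
#' @export
hard_sigmoid <- function(x) pmin(pmax((x + 3) / 6, 0), 1)

#' Piecewise-linear Swish approximation
#' @param x numeric array
#' @return `x * hard_sigmoid(x)`
#' @export
hard_swish <- function(x) x * hard_sigmoid(x)

silu_grad <- function(x) {
  s <- stats::plogis(x)
  s * (1 + x * (1 - s))
}

hard_sigmoid_grad <- function(x) {
  g <- x
  g[] <- ifelse(x > -3 & x < 3, 1 / 6, 0)
  g
}

hard_swish_grad <- function(x) {
  hard_sigmoid(x) + x * hard_sigmoid_grad(x)
}

act_fun <- function(name) {
  switch(name,
    silu = silu,
    hard_swish = hard_swish,
    hard_sigmoid = hard_sigmoid,
    identity = identity,
    stop("unknown activation: ", name)
  )
}

act_grad_fun <- function(name) {
  switch(name,
    silu = silu_grad,
    hard_swish = hard_swish_grad,
    hard_sigmoid = hard_sigmoid_grad,
    identity = function(x) {x[] <- 1; x},
    stop("unknown activation: ", name)
  )
}

# activation as a layer ----------------------------------------------------

act_type_code <- function(name) {
  switch(name, silu = 1L, hard_sigmoid = 2L, hard_swish = 3L, 0L)
}

activation_layer <- function(name) {
  new_layer("act", act_name = name, type_code = act_type_code(name))
}

#' @export
layer_forward.act <- function(layer, x, training = FALSE) {
  if (training) layer$cache$x <- x
  if (layer$type_code > 0L) act_fwd_cpp(x, layer$type_code)
  else act_fun(layer$act_name)(x)
}

#' @export
layer_backward.act <- function(layer, dy) {
  if (layer$type_code > 0L)
    act_bwd_cpp(layer$cache$x, dy, layer$type_code)
  else dy * act_grad_fun(layer$act_name)(layer$cache$x)
}
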