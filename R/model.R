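# WHA-Net assembly: declarative configuration, network construction,
# analytic parameter and MAC budgets, ablation variants.
#
# Default stage table (a reconstruction of the published architecture,
# constrained to the printed complexity budget; see the methods
# vignette): stem 3->16 s2; 2-level WTC on 16 channels (+BN+SiLU);
# HAIR 16->32 s1; HAIR 32->48 s2; IR 48->48 x2; IR 48->64 s2 +
# Agent-MViT(d=96, L=2); IR 64->80 s2 + Agent-MViT(d=112, L=4);
# IR 80->96 s2 + Agent-MViT(d=216, L=3); pointwise 96->384, global
# average pool, linear 384->classes. Cumulative stride 32.

make_divisible <- function(v, div = 4L) {
  as.integer(pmax(div, round(v / div) * div))
}

#' Default WHA-Net model configuration
#'
#' @param input_size square input resolution (default 256)
#' @param classes number of output classes (default 3:
#'   Normal / ODE / PPE)
#' @param width_mult channel width multiplier; channels round to
#'   multiples of 4, token dims to multiples of `heads`
#' @param use_wtc include the wavelet convolution block
#' @param use_hair use scSE hybrid attention in the first two inverted
#'   residual stages (HAIR); otherwise plain IR
#' @param channels six stage channel counts
#' @param dims token dimensions of the three Agent-MViT stages
#' @param repeats Agent-Transformer stack depths (L) per stage
#' @param head_width channel count of the pre-pooling pointwise head
#' @param heads,n_agents,patch,expansion,scse_r,rho,wtc_levels
#'   architecture hyperparameters (attention heads, agent tokens, patch
#'   size, IR expansion, scSE reduction, MLP ratio, wavelet levels)
#' @param orig_branch_kernel WTC original-scale branch kernel, 1 or 3
#' @return an object of class `wha_config`
#' @export
wha_config <- function(input_size = 256L, classes = 3L, width_mult = 1,
                       use_wtc = TRUE, use_hair = TRUE,
                       channels = c(16L, 32L, 48L, 64L, 80L, 96L),
                       dims = c(96L, 112L, 216L),
                       repeats = c(2L, 4L, 3L),
                       head_width = 384L,
                       heads = 4L, n_agents = 16L, patch = 2L,
                       expansion = 4L, scse_r = 4L, rho = 2,
                       wtc_levels = 2L, orig_branch_kernel = 3L) {
  if (input_size %% 32 != 0)
    stop("input_size must be a multiple of the cumulative stride (32)")
  if (width_mult != 1) {
    channels <- make_divisible(channels * width_mult, 4L)
    dims <- make_divisible(dims * width_mult, as.integer(heads))
    head_width <- make_divisible(head_width * width_mult, 8L)
  }
  cfg <- list(input_size = as.integer(input_size),
              classes = as.integer(classes), width_mult = width_mult,
              use_wtc = use_wtc, use_hair = use_hair,
              channels = as.integer(channels), dims = as.integer(dims),
              repeats = as.integer(repeats),
              head_width = as.integer(head_width),
              heads = as.integer(heads), n_agents = as.integer(n_agents),
              patch = as.integer(patch), expansion = as.integer(expansion),
              scse_r = as.integer(scse_r), rho = rho,
              wtc_levels = as.integer(wtc_levels),
              orig_branch_kernel = as.integer(orig_branch_kernel),
              class_names = c("Normal", "ODE", "PPE")[seq_len(min(classes, 3))])
  if (classes > 3) cfg$class_names <- paste0("class", seq_len(classes))
  structure(cfg, class = "wha_config")
}

#' Derive an ablation variant of a configuration
#'
#' `use_wtc = FALSE` removes the wavelet convolution block;
#' `use_hair = FALSE` replaces every HAIR block with the plain IR block
#' of identical channels and stride. With both off, the model is the
#' plain agent-attention baseline.
#'
#' @param cfg a [wha_config()]
#' @param use_wtc,use_hair ablation flags
#' @return a modified `wha_config`
#' @export
ablation_variant <- function(cfg, use_wtc = cfg$use_wtc,
                             use_hair = cfg$use_hair) {
  cfg$use_wtc <- use_wtc
  cfg$use_hair <- use_hair
  cfg
}

# activation per stage: SiLU while the expanded width stays below 256,
# Hard-Swish for the high-channel stages
stage_act <- function(expanded) if (expanded < 256) "silu" else "hard_swish"

#' Build a WHA-Net model from a configuration
#'
#' @param cfg a [wha_config()]
#' @param seed optional integer seed for weight initialization
#' @return an object of class `wha_model`
#' @export
build_model <- function(cfg = wha_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ch <- cfg$channels; dm <- cfg$dims; L <- cfg$repeats
  t <- cfg$expansion
  # base grids: token geometry of each Agent-MViT stage at 256 input
  bg <- lapply(c(16L, 8L, 4L), function(g) c(g, g))
  feats <- list(
    stem_conv = conv2d(3L, ch[1], k = 3, stride = 2, bias = FALSE),
    stem_bn = bnact_layer(ch[1], "silu")
  )
  if (cfg$use_wtc) {
    feats$wtc <- wtc_layer(ch[1], cfg$wtc_levels, cfg$orig_branch_kernel)
    feats$wtc_bn <- bnact_layer(ch[1], "silu")
  }
  mk_ir <- function(ci, co, s, hair) {
    ir_block(ci, co, s, t, act = stage_act(t * ci),
             use_scse = hair, scse_r = cfg$scse_r)
  }
  feats$s1 <- mk_ir(ch[1], ch[2], 1L, cfg$use_hair)
  feats$s2 <- mk_ir(ch[2], ch[3], 2L, cfg$use_hair)
  feats$s3a <- mk_ir(ch[3], ch[3], 1L, FALSE)
  feats$s3b <- mk_ir(ch[3], ch[3], 1L, FALSE)
  feats$s4_ir <- mk_ir(ch[3], ch[4], 2L, FALSE)
  feats$s4_amv <- agent_mvit(ch[4], dm[1], L[1], cfg$patch, cfg$heads,
                             cfg$n_agents, bg[[1]], cfg$rho)
  feats$s5_ir <- mk_ir(ch[4], ch[5], 2L, FALSE)
  feats$s5_amv <- agent_mvit(ch[5], dm[2], L[2], cfg$patch, cfg$heads,
                             cfg$n_agents, bg[[2]], cfg$rho)
  feats$s6_ir <- mk_ir(ch[5], ch[6], 2L, FALSE)
  feats$s6_amv <- agent_mvit(ch[6], dm[3], L[3], cfg$patch, cfg$heads,
                             cfg$n_agents, bg[[3]], cfg$rho)
  m <- new_layer("wha_model", cfg = cfg)
  m$children$features <- sequential(feats)
  m$children$head_conv <- conv2d(ch[6], cfg$head_width, k = 1, bias = FALSE)
  m$children$head_bn <- bnact_layer(cfg$head_width, "hard_swish")
  m$children$gap <- gap_layer()
  m$children$classifier <- linear_layer(cfg$head_width, cfg$classes)
  # stride audit: stem + four downsampling stages
  strides <- c(2L, vapply(feats[grep("^s", names(feats))],
                          function(l) if (inherits(l, "ir"))
                            l$stride else 1L, 0L))
  if (prod(strides) != 32L) stop("cumulative stride must be 32")
  m
}

# fixed input standardization constants (fundus channel statistics)
INPUT_MEAN <- c(0.48, 0.19, 0.11)
INPUT_SD <- c(0.125, 0.15, 0.095)

whanet_standardize <- function(x) {
  d <- dim(x)
  sweep_arr <- rep(INPUT_MEAN, each = d[1] * d[2])
  scale_arr <- rep(1 / INPUT_SD, each = d[1] * d[2])
  (x - sweep_arr) * scale_arr
}

#' @export
layer_forward.wha_model <- function(layer, x, training = FALSE) {
  x <- whanet_standardize(x)
  f <- layer_forward(layer$children$features, x, training)
  h <- layer_forward(layer$children$head_bn,
         layer_forward(layer$children$head_conv, f, training), training)
  pooled <- t(layer_forward(layer$children$gap, h, training))
  layer_forward(layer$children$classifier, pooled, training)
}

#' @export
layer_backward.wha_model <- function(layer, dy) {
  dpool <- t(layer_backward(layer$children$classifier, dy))
  dh <- layer_backward(layer$children$gap, dpool)
  df <- layer_backward(layer$children$head_conv,
          layer_backward(layer$children$head_bn, dh))
  dx <- layer_backward(layer$children$features, df)
  dx * rep(1 / INPUT_SD, each = dim(dx)[1] * dim(dx)[2])
}

#' Class probabilities for a batch of images
#'
#' Deterministic inference (eval-mode batch norm, no augmentation).
#'
#' @param model a `wha_model`
#' @param x `(H,W,3)` or `(H,W,3,N)` image array in `[0,1]`
#' @return `N x K` matrix of softmax probabilities, columns named by
#'   class
#' @export
predict_proba <- function(model, x) {
  cc <- as_hwcn(x)
  logits <- layer_forward(model, cc$x, training = FALSE)
  p <- row_softmax(logits)
  colnames(p) <- model$cfg$class_names
  p
}

# ---- complexity reports --------------------------------------------------

top_components <- function(model) {
  c(model$children$features$children,
    list(head_conv = model$children$head_conv,
         head_bn = model$children$head_bn,
         classifier = model$children$classifier))
}

#' Count learnable parameters
#'
#' Exact count of learnable scalars (the fixed Haar filters are not
#' parameters and are excluded by construction), with a per-component
#' breakdown.
#'
#' @param model a `wha_model`
#' @return an object of class `wha_complexity`: list with `total`,
#'   `total_m` (millions, 3 dp) and a `breakdown` tibble
#' @export
count_params <- function(model) {
  comp <- top_components(model)
  n <- vapply(comp, n_params, 0)
  structure(list(
    quantity = "params",
    total = sum(n),
    total_m = round(sum(n) / 1e6, 3),
    breakdown = tibble::tibble(component = names(comp), value = n)
  ), class = "wha_complexity")
}

#' Analytic multiply-accumulate count
#'
#' Counts one MAC per multiply-accumulate (reported FLOPs = MACs):
#' convolutions `k^2 Cin Cout Ho Wo / groups`, linears `d_in d_out` per
#' row, attention matmuls by their Eq-shapes; normalizations,
#' activations and pooling are excluded.
#'
#' @param model a `wha_model`
#' @param input_size square input resolution (defaults to the config)
#' @return a `wha_complexity` with totals in MACs and millions (2 dp)
#' @export
count_macs <- function(model, input_size = model$cfg$input_size) {
  comp <- top_components(model)
  shp <- c(input_size, input_size, 3)
  vals <- numeric(length(comp))
  for (i in seq_along(comp)) {
    r <- layer_macs(comp[[i]], shp)
    vals[i] <- r$macs
    shp <- r$shp
  }
  structure(list(
    quantity = "macs",
    total = sum(vals),
    total_m = round(sum(vals) / 1e6, 2),
    breakdown = tibble::tibble(component = names(comp), value = vals)
  ), class = "wha_complexity")
}

#' @export
print.wha_complexity <- function(x, ...) {
  unit <- if (x$quantity == "params") "parameters" else "MACs"
  cat(sprintf("%s: %s total (%.3f M)\n", unit,
              format(x$total, big.mark = ","), x$total / 1e6))
  df <- x$breakdown
  df$value_m <- round(df$value / 1e6, 3)
  print(as.data.frame(df), row.names = FALSE)
  invisible(x)
}

#' One-line model summary
#' @param object a `wha_model`
#' @param ... unused
#' @return tibble with parameter and MAC totals
#' @export
glance.wha_model <- function(object, ...) {
  p <- count_params(object)
  m <- count_macs(object)
  tibble::tibble(
    input_size = object$cfg$input_size,
    classes = object$cfg$classes,
    width_mult = object$cfg$width_mult,
    use_wtc = object$cfg$use_wtc,
    use_hair = object$cfg$use_hair,
    params = p$total, params_m = p$total_m,
    macs = m$total, macs_m = m$total_m
  )
}

#' @export
glance <- function(object, ...) UseMethod("glance")

# ---- config serialization -----------------------------------------------

#' Write / read a model configuration as YAML
#' @param cfg a `wha_config`
#' @param path file path
#' @return `read_config` returns a `wha_config`
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$class_names <- NULL
  do.call(wha_config, raw[setdiff(names(raw), "width_mult")] |>
            (\(x) {x$width_mult <- 1; x})())
}

# ---- checkpoints ---------------------------------------------------------

#' Save / load model weights
#'
#' Weights go to `<path>` (RDS of the full state dictionary) with a JSON
#' sidecar `<path>.json` recording the configuration, class names and
#' seed.
#'
#' @param model a `wha_model`
#' @param path checkpoint file path
#' @param seed optional seed to record
#' @export
save_checkpoint <- function(model, path, seed = NULL) {
  saveRDS(state_dict(model), path)
  meta <- list(config = unclass(model$cfg),
               class_names = model$cfg$class_names, seed = seed)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_checkpoint
#' @return `load_checkpoint` returns a rebuilt `wha_model`
#' @export
load_checkpoint <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  raw <- meta$config
  raw$class_names <- NULL
  raw$channels <- as.integer(raw$channels)
  raw$dims <- as.integer(raw$dims)
  raw$repeats <- as.integer(raw$repeats)
  raw$width_mult <- 1   # stored channels are already scaled
  cfg <- do.call(wha_config, raw)
  m <- build_model(cfg)
  load_state_dict(m, readRDS(path))
  m
}
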