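# Unfold/fold, inverted residual blocks, Agent-Transformer, Agent-MViT.

test_that("unfold and fold are an exact inverse pair", {
  set.seed(21)
  x <- array(rnorm(8 * 6 * 3 * 2), c(8, 6, 3, 2))
  t <- unfold_patches(x, 2)
  # p^2 sequences per sample, each of length HW / p^2
  expect_equal(dim(t), c(12L, 3L, 8L))
  expect_equal(attr(t, "token_grid"), c(4L, 3L))
  expect_equal(fold_patches(t), x)
  # a constant map yields constant tokens
  expect_true(all(unfold_patches(array(2, c(4, 4, 1, 1)), 2) == 2))
  # 4x4 map, p = 2: four tokens per pixel-position group
  expect_equal(dim(unfold_patches(array(0, c(4, 4, 1, 1)), 2))[1], 4L)
  expect_error(unfold_patches(x, 5), "divisible")
  expect_error(fold_patches(t, shape = c(8, 6, 4, 2, 2)), "inconsistent")
})

test_that("inverted residual blocks honor their shape and identity
           contracts", {
  set.seed(22)
  x <- array(rnorm(8 * 8 * 6 * 2), c(8, 8, 6, 2))
  # zero projection + residual: exact identity in eval mode
  b <- ir_block(6, 6, stride = 1)
  b$children$body$children$proj$params$W[] <- 0
  expect_lt(max(abs(ir_forward(x, b) - x)), 1e-10)
  # stride-2 halves spatial dims (ceiling)
  b2 <- ir_block(6, 8, stride = 2)
  expect_equal(dim(layer_forward(b2, x)), c(4L, 4L, 8L, 2L))
  # expansion stage has t * C_in channels
  expect_equal(b2$children$body$children$exp$out_ch, 24L)
  expect_error(ir_block(6, 6, stride = 3), "stride")
})

test_that("HAIR equals IR at scSE zero-init and adds exactly the scSE
           parameters", {
  set.seed(23)
  bh <- ir_block(16, 24, stride = 1, t = 4, use_scse = TRUE, scse_r = 4)
  bi <- ir_block(16, 24, stride = 1, t = 4)
  for (nm in names(bi$children$body$children)) {
    bi$children$body$children[[nm]]$params <-
      bh$children$body$children[[nm]]$params
  }
  sc <- bh$children$body$children$scse
  for (r in whanet:::param_refs(sc)) r$layer$params[[r$name]][] <- 0
  x <- array(rnorm(8 * 8 * 16 * 2), c(8, 8, 16, 2))
  expect_lt(max(abs(hair_forward(x, bh) - ir_forward(x, bi))), 1e-12)
  # parameter surplus equals the closed-form scSE count at E = t*C_in:
  # 2 * E * (E/r) + E/r + E (cSE) + E + 1 (sSE)
  E <- 64
  scse_formula <- (E * (E / 4) + E / 4) + ((E / 4) * E + E) + (E + 1)
  expect_equal(whanet:::n_params(bh) - whanet:::n_params(bi),
               scse_formula)
  expect_error(hair_forward(x, bi), "scSE")
})

test_that("the Agent-Transformer reduces to the identity when its
           residual branches are zeroed", {
  set.seed(24)
  tx <- agent_transformer(8, heads = 2, n = 4, base_grid = c(3, 3))
  tx$children$attn$children$wo$params$W[] <- 0
  tx$children$attn$children$wo$params$b[] <- 0
  tx$children$fc2$params$W[] <- 0
  tx$children$fc2$params$b[] <- 0
  x <- array(rnorm(9 * 8 * 2), c(9, 8, 2))
  attr(x, "token_grid") <- c(3L, 3L)
  y <- agent_transformer_forward(x, tx)
  expect_lt(max(abs(y - x)), 1e-12)
  expect_equal(dim(y), dim(x))
})

test_that("Agent-MViT preserves shape and reduces to the input residual
           with a zeroed fusion", {
  set.seed(25)
  x <- array(rnorm(8 * 8 * 6 * 2), c(8, 8, 6, 2))
  am <- agent_mvit(6, 8, L = 1, p = 2, heads = 2, n = 4,
                   base_grid = c(4, 4))
  am$children$fuse$params$W[] <- 0
  expect_lt(max(abs(agent_mvit_forward(x, am) - x)), 1e-10)
  am2 <- agent_mvit(6, 8, L = 2, p = 2, heads = 2, n = 4,
                    base_grid = c(4, 4))
  expect_equal(dim(agent_mvit_forward(x, am2)), dim(x))
  # odd spatial dims go through the internal pad-and-crop path
  xo <- array(rnorm(6 * 6 * 6 * 1), c(6, 6, 6, 1))
  expect_equal(dim(agent_mvit_forward(xo, am2)), dim(xo))
  # attention-stage MACs scale linearly with token count
  m8 <- layer_macs(am2, c(8, 8, 6))$macs
  m16 <- layer_macs(am2, c(16, 16, 6))$macs
  expect_equal(m16 / m8, 4)
})

test_that("every block type backpropagates finite gradients", {
  set.seed(26)
  blocks <- list(
    ir = ir_block(4, 6, stride = 2),
    hair = ir_block(4, 4, stride = 1, use_scse = TRUE),
    wtc = wtc_layer(4),
    amv = agent_mvit(4, 8, L = 1, p = 2, heads = 2, n = 4,
                     base_grid = c(4, 4))
  )
  for (nm in names(blocks)) {
    b <- blocks[[nm]]
    x <- array(rnorm(8 * 8 * 4 * 2), c(8, 8, 4, 2))
    whanet:::zero_grads(b)
    y <- layer_forward(b, x, training = TRUE)
    dx <- layer_backward(b, array(rnorm(length(y)), dim(y)))
    expect_true(all(is.finite(dx)), info = nm)
    for (r in whanet:::param_refs(b))
      expect_true(all(is.finite(r$layer$grads[[r$name]])), info = nm)
  }
})

test_that("composite blocks backpropagate exactly (finite differences)", {
  set.seed(27)
  w <- num_grad_check(ir_block(4, 6, stride = 2, use_scse = TRUE),
                      array(rnorm(6 * 6 * 4 * 2), c(6, 6, 4, 2)))
  expect_lt(w, 1e-5)
  w <- num_grad_check(agent_mvit(4, 8, L = 1, p = 2, heads = 2, n = 4,
                                 base_grid = c(4, 4)),
                      array(rnorm(6 * 6 * 4 * 2), c(6, 6, 4, 2)))
  expect_lt(w, 1e-4)
})
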