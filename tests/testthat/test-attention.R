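# Activations, scSE gates, softmax attention reference and agent attention.

test_that("piecewise activations hit their breakpoints", {
  expect_equal(hard_sigmoid(c(-3, 0, 3)), c(0, 0.5, 1))
  expect_equal(silu(0), 0)
  expect_equal(hard_swish(c(0, 6)), c(0, 6))
  expect_equal(hard_swish(-5), 0)
  # silu approaches identity for large x
  expect_equal(silu(20), 20, tolerance = 1e-6)
})

test_that("scSE gates bound and rescale the map, identity at zero-init", {
  set.seed(11)
  x <- array(rnorm(6 * 5 * 8 * 2), c(6, 5, 8, 2))
  pz <- scse_layer(8, zero_init = TRUE)
  # both half-gates are exactly 1/2 with zero weights
  expect_equal(cse_forward(x, pz), x / 2)
  expect_equal(sse_forward(x, pz), x / 2)
  expect_equal(scse_forward(x, pz), x)
  # random weights: |output| <= |x| elementwise per branch, shape kept
  p <- scse_layer(8)
  yc <- cse_forward(x, p)
  ys <- sse_forward(x, p)
  expect_true(all(abs(yc) <= abs(x) + 1e-12))
  expect_true(all(abs(ys) <= abs(x) + 1e-12))
  expect_equal(dim(scse_forward(x, p)), dim(x))
  expect_equal(scse_forward(array(0, dim(x)), p), array(0, dim(x)))
  expect_error(cse_forward(array(0, c(4, 4, 3, 1)), p), "channel")
})

test_that("softmax attention matches closed-form cases", {
  q <- diag(2)
  out <- softmax_attention(q, q, q, d_k = 2)
  w <- exp(1 / sqrt(2)) / (exp(1 / sqrt(2)) + 1)
  expect_equal(out[1, ], c(w, 1 - w), tolerance = 1e-12)
  expect_equal(round(out[1, ], 4), c(0.6698, 0.3302))
  # single token: output is v itself
  v <- matrix(rnorm(3), 1, 3)
  expect_equal(softmax_attention(matrix(1, 1, 2), matrix(-2, 1, 2), v), v)
  # zero queries: uniform weights, every row the column mean of v
  v4 <- matrix(rnorm(8), 4, 2)
  out <- softmax_attention(matrix(0, 4, 3), matrix(rnorm(12), 4, 3), v4)
  expect_equal(out, matrix(colMeans(v4), 4, 2, byrow = TRUE))
  expect_error(softmax_attention(matrix(0, 4, 3), matrix(0, 4, 2), v4),
               "shape")
})

test_that("agent attention equals the nested-loop evaluation of its
           two-stage softmax formula", {
  set.seed(12)
  worst <- 0
  for (k in 1:20) {
    grid <- sample(2:5, 2, replace = TRUE)
    d <- sample(c(4, 8), 1)
    l <- agent_attention_layer(d, heads = 2, n = 4, base_grid = c(6, 6))
    l$params$B1[] <- rnorm(length(l$params$B1), sd = 0.3)
    l$params$B2[] <- rnorm(length(l$params$B2), sd = 0.3)
    x <- matrix(rnorm(prod(grid) * d), prod(grid), d)
    worst <- max(worst, max(abs(agent_attention(x, l, grid = grid) -
                                  brute_agent_attention(x, l, grid))))
  }
  expect_lt(worst, 1e-5)
})

test_that("both attention stages are row-stochastic", {
  set.seed(13)
  l <- agent_attention_layer(8, heads = 2, n = 4, base_grid = c(4, 4))
  l$params$B1[] <- rnorm(length(l$params$B1))
  l$params$B2[] <- rnorm(length(l$params$B2))
  x <- array(rnorm(16 * 8 * 2), c(16, 8, 2))
  attr(x, "token_grid") <- c(4L, 4L)
  layer_forward(l, x, training = TRUE)
  for (p in c(l$cache$P1, l$cache$P2)) {
    expect_true(all(p >= 0))
    expect_lt(max(abs(rowSums(p) - 1)), 1e-6)
  }
})

test_that("without the DWC term outputs stay inside the V hull", {
  set.seed(14)
  l <- agent_attention_layer(8, heads = 2, n = 4, base_grid = c(4, 4),
                             dwc = FALSE)
  # identity value/output projections expose the double convex combination
  l$children$wv$params$W <- diag(8); l$children$wv$params$b[] <- 0
  l$children$wo$params$W <- diag(8); l$children$wo$params$b[] <- 0
  x <- matrix(rnorm(16 * 8), 16, 8)
  y <- agent_attention(x, l, grid = c(4, 4))
  for (j in 1:8) {
    expect_gte(min(y[, j]), min(x[, j]) - 1e-10)
    expect_lte(max(y[, j]), max(x[, j]) + 1e-10)
  }
  # constant V is preserved exactly
  xc <- matrix(rep(rnorm(8), each = 16), 16, 8)
  expect_lt(max(abs(agent_attention(xc, l, grid = c(4, 4)) - xc)), 1e-10)
  # a single agent broadcasts one aggregated vector to every token
  l1 <- agent_attention_layer(8, heads = 2, n = 1, base_grid = c(4, 4),
                              dwc = FALSE)
  y1 <- agent_attention(matrix(rnorm(16 * 8), 16, 8), l1, grid = c(4, 4))
  expect_lt(max(abs(sweep(y1, 2, y1[1, ]))), 1e-12)
})

test_that("agent attention cost is linear in sequence length while
           softmax attention is quadratic", {
  d <- 96; n <- 16
  Ns <- c(64, 256, 1024)
  agent <- sapply(Ns, function(N) agent_attention_macs(N, d, n))
  soft <- sapply(Ns, function(N) softmax_attention_macs(N, d))
  # quadrupling N quadruples the agent cost (linear) ...
  expect_equal(agent[2] / agent[1], 4)
  expect_equal(agent[3] / agent[2], 4)
  # ... but multiplies the softmax cost by 16 (quadratic)
  expect_equal(soft[2] / soft[1], 16)
  expect_equal(soft[3] / soft[2], 16)
})

test_that("token grids are validated", {
  l <- agent_attention_layer(8, heads = 2, n = 4, base_grid = c(4, 4))
  x <- matrix(rnorm(12 * 8), 12, 8)   # 12 tokens: not a square count
  expect_error(agent_attention(x, l), "grid")
  expect_error(agent_attention(x, l, grid = c(5, 2)), "grid")
})

test_that("attention layers backpropagate correctly", {
  set.seed(15)
  x <- array(rnorm(9 * 8 * 2), c(9, 8, 2))
  attr(x, "token_grid") <- c(3L, 3L)
  w <- num_grad_check(agent_transformer(8, heads = 2, n = 4,
                                        base_grid = c(4, 4)), x)
  expect_lt(w, 1e-5)
  w <- num_grad_check(scse_layer(8),
                      array(rnorm(5 * 5 * 8 * 2), c(5, 5, 8, 2)))
  expect_lt(w, 1e-5)
})
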