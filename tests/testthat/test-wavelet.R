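# Haar filter bank, 2-D transform pair and the wavelet convolution block.

test_that("the Haar filter bank is the fixed orthonormal 2x2 quadruple", {
  fb <- haar_filter_bank()
  expect_equal(fb$f_LL, matrix(0.5, 2, 2))
  # unit L2 norm and zero-sum high-pass filters
  for (nm in c("f_LL", "f_LH", "f_HL", "f_HH"))
    expect_equal(sum(fb[[nm]]^2), 1)
  for (nm in c("f_LH", "f_HL", "f_HH"))
    expect_equal(sum(fb[[nm]]), 0)
  # pairwise orthogonality
  prs <- combn(names(fb), 2)
  for (k in seq_len(ncol(prs)))
    expect_equal(sum(fb[[prs[1, k]]] * fb[[prs[2, k]]]), 0)
})

test_that("dwt2 reproduces direct patch dot products", {
  # the 2x2 worked example
  s <- dwt2(matrix(c(1, 3, 2, 4), 2, 2))  # [[1,2],[3,4]] row-major
  expect_equal(c(s$LL, s$LH, s$HL, s$HH), c(5, -2, -1, 0))
  # against the nested-loop oracle on random matrices
  fb <- haar_filter_bank()
  set.seed(42)
  for (k in 1:5) {
    xm <- matrix(rnorm(8 * 12), 8, 12)
    s <- dwt2(xm)
    expect_equal(s$LL, brute_dwt2(xm, fb$f_LL))
    expect_equal(s$LH, brute_dwt2(xm, fb$f_LH))
    expect_equal(s$HL, brute_dwt2(xm, fb$f_HL))
    expect_equal(s$HH, brute_dwt2(xm, fb$f_HH))
  }
})

test_that("dwt2 of a constant map concentrates everything in LL", {
  s <- dwt2(array(3, c(6, 6, 2, 1)))
  expect_equal(max(abs(s$LL - 6)), 0)
  expect_equal(max(abs(c(s$LH, s$HL, s$HH))), 0)
})

test_that("the transform pair conserves energy and reconstructs exactly", {
  set.seed(1)
  for (k in 1:8) {
    h <- 2 * sample(1:32, 1)
    w <- 2 * sample(1:32, 1)
    ch <- sample(1:8, 1)
    x <- array(rnorm(h * w * ch), c(h, w, ch, 1))
    s <- dwt2(x)
    expect_equal(dim(s$LL), c(h / 2, w / 2, ch, 1))
    expect_equal(sum(x^2), sum(s$LL^2 + s$LH^2 + s$HL^2 + s$HH^2),
                 tolerance = 1e-10)
    expect_lt(max(abs(idwt2(s) - x)), 1e-5)
  }
})

test_that("idwt2 inverts the worked example and rejects bad subbands", {
  y <- idwt2(list(LL = matrix(5), LH = matrix(-2),
                  HL = matrix(-1), HH = matrix(0)))
  expect_equal(y, matrix(c(1, 3, 2, 4), 2, 2))
  expect_equal(idwt2(list(LL = matrix(0, 2, 2), LH = matrix(0, 2, 2),
                          HL = matrix(0, 2, 2), HH = matrix(0, 2, 2))),
               matrix(0, 4, 4))
  expect_error(idwt2(list(LL = matrix(0, 2, 2), LH = matrix(0, 2, 3),
                          HL = matrix(0, 2, 2), HH = matrix(0, 2, 2))),
               "shapes")
})

test_that("degenerate and odd-sized inputs are handled", {
  expect_error(dwt2(matrix(numeric(0), 0, 4)), "empty")
  expect_error(dwt2(matrix(rnorm(15), 3, 5)), "even")
  # the WTC block pads odd sizes internally and crops back
  l <- wtc_layer(2)
  x <- array(rnorm(7 * 9 * 2), c(7, 9, 2, 1))
  expect_equal(dim(layer_forward(l, x)), dim(x))
})

test_that("the WTC block is linear and matches its symbolic traces", {
  expect_error(wtc_layer(4, levels = 0), "levels")
  # zero input -> zero output
  l <- wtc_layer(2)
  expect_true(all(layer_forward(l, array(0, c(8, 8, 2, 1))) == 0))
  # homogeneity
  set.seed(3)
  x <- array(rnorm(8 * 8 * 2 * 2), c(8, 8, 2, 2))
  expect_lt(max(abs(layer_forward(l, 5 * x) - 5 * layer_forward(l, x))),
            1e-10)
  # identity (centered delta) kernels: constant c -> 3c, because the
  # level-2 reconstruction adds a second copy of the level-1 low-pass
  ld <- wtc_layer(2, levels = 2)
  for (nm in names(ld$children)) {
    W <- ld$children[[nm]]$params$W
    W[] <- 0
    W[2, 2, 1, ] <- 1
    ld$children[[nm]]$params$W <- W
  }
  y <- layer_forward(ld, array(7, c(4, 4, 2, 1)))
  expect_lt(max(abs(y - 21)), 1e-10)
  # output shape equals input shape across sizes
  for (hw in list(c(4, 4), c(16, 8), c(10, 6))) {
    x <- array(rnorm(hw[1] * hw[2] * 2), c(hw[1], hw[2], 2, 1))
    expect_equal(dim(wtc_forward(x, l)), dim(x))
  }
})

test_that("WTC gradients agree with finite differences", {
  set.seed(5)
  w <- num_grad_check(wtc_layer(2), array(rnorm(8 * 8 * 2 * 2), c(8, 8, 2, 2)))
  expect_lt(w, 1e-6)
})

test_that("the level-2 branch sees at least a 12x12 input neighbourhood", {
  # gradient-sparsity probe: backpropagate a delta from one output pixel
  # and measure the support of the input gradient
  set.seed(8)
  l <- wtc_layer(1, levels = 2)
  l$children$conv0$params$W[] <- 0      # isolate the wavelet branch
  x <- array(rnorm(32 * 32), c(32, 32, 1, 1))
  whanet:::zero_grads(l)
  y <- layer_forward(l, x, training = TRUE)
  dy <- array(0, dim(y))
  dy[16, 16, 1, 1] <- 1
  dx <- layer_backward(l, dy)
  nz <- which(abs(dx[, , 1, 1]) > 1e-12, arr.ind = TRUE)
  expect_gte(diff(range(nz[, 1])) + 1, 12)
  expect_gte(diff(range(nz[, 2])) + 1, 12)
})
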