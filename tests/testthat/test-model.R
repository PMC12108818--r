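# Model assembly, parameter counting, analytic MAC budgets, ablations.

test_that("single-layer counters match closed forms", {
  # conv 3->16, 3x3, with bias: 3*16*9 + 16
  cv <- whanet:::conv2d(3, 16, k = 3, bias = TRUE)
  expect_equal(whanet:::n_params(cv), 448)
  # linear 384 -> 3 with bias
  li <- whanet:::linear_layer(384, 3)
  expect_equal(whanet:::n_params(li), 384 * 3 + 3)
  # 3x3 conv 3->16 stride 2 on 256x256: 9 * 3 * 16 * 128^2 MACs
  cv2 <- whanet:::conv2d(3, 16, k = 3, stride = 2, bias = FALSE)
  expect_equal(layer_macs(cv2, c(256, 256, 3))$macs, 7077888)
  # agent attention MAC closed form at N=256, n=16, d=96
  expect_equal(agent_attention_macs(256, 96, 16),
               4 * 256 * 16 * 96 + 9 * 256 * 96)
})

test_that("the default model meets its published complexity budget", {
  m <- build_model(wha_config(), seed = 1)
  p <- count_params(m)
  mc <- count_macs(m)
  expect_lt(abs(p$total / 1e6 - 2.147) / 2.147, 0.03)
  expect_lt(abs(mc$total / 1e6 - 809.81) / 809.81, 0.03)
  # breakdown sums to the totals
  expect_equal(sum(p$breakdown$value), p$total)
  expect_equal(sum(mc$breakdown$value), mc$total)
  # reported rounding conventions
  expect_equal(p$total_m, round(p$total / 1e6, 3))
  expect_equal(mc$total_m, round(mc$total / 1e6, 2))
})

test_that("parameter counting agrees with an independent traversal of
           the serialized weights", {
  m <- build_model(wha_config(width_mult = 0.25, input_size = 64), seed = 2)
  sd <- whanet:::state_dict(m)
  learnable <- sd[!grepl("buf:", names(sd))]
  expect_equal(count_params(m)$total,
               sum(vapply(learnable, length, 0L)))
})

test_that("ablation flags change the architecture monotonically and
           reversibly", {
  base <- wha_config()
  cfg0 <- ablation_variant(base, use_wtc = FALSE, use_hair = FALSE)
  p0 <- count_params(build_model(cfg0, seed = 1))$total
  pw <- count_params(build_model(ablation_variant(base, use_hair = FALSE),
                                 seed = 1))$total
  ph <- count_params(build_model(ablation_variant(base, use_wtc = FALSE),
                                 seed = 1))$total
  pf <- count_params(build_model(base, seed = 1))$total
  expect_gt(pw, p0)   # +WTC adds parameters
  expect_gt(ph, p0)   # +HAIR adds parameters
  expect_gt(pf, pw)
  expect_gt(pf, ph)
  # toggling twice restores the original counts
  cfg_back <- ablation_variant(cfg0, use_wtc = TRUE, use_hair = TRUE)
  expect_equal(count_params(build_model(cfg_back, seed = 1))$total, pf)
  # same monotonicity for MACs
  expect_gt(count_macs(build_model(base, seed = 1))$total,
            count_macs(build_model(cfg0, seed = 1))$total)
})

test_that("a forward pass through the assembled network is deterministic
           and shape-correct", {
  set.seed(31)
  m <- build_model(wha_config(input_size = 64, width_mult = 0.25), seed = 5)
  x <- array(runif(64 * 64 * 3 * 2), c(64, 64, 3, 2))
  l1 <- layer_forward(m, x)
  l2 <- layer_forward(m, x)
  expect_identical(l1, l2)
  expect_equal(dim(l1), c(2L, 3L))
  expect_true(all(is.finite(l1)))
  # final feature map is input_size / 32 on a side
  f <- layer_forward(m$children$features, x)
  expect_equal(dim(f)[1:2], c(2L, 2L))
  p <- predict_proba(m, x)
  expect_lt(max(abs(rowSums(p) - 1)), 1e-6)
  expect_equal(colnames(p), c("Normal", "ODE", "PPE"))
})

test_that("configurations validate and round-trip through YAML", {
  expect_error(wha_config(input_size = 100), "multiple")
  cfg <- wha_config(width_mult = 0.25)
  expect_equal(cfg$channels, c(4L, 8L, 12L, 16L, 20L, 24L))
  expect_true(all(cfg$dims %% 4 == 0))
  path <- tempfile(fileext = ".yaml")
  write_config(cfg, path)
  cfg2 <- read_config(path)
  expect_equal(cfg2$channels, cfg$channels)
  expect_equal(cfg2$dims, cfg$dims)
  expect_equal(cfg2$use_wtc, cfg$use_wtc)
})

test_that("checkpoints restore weights and predictions exactly", {
  set.seed(32)
  m <- build_model(wha_config(input_size = 64, width_mult = 0.25), seed = 7)
  x <- array(runif(64 * 64 * 3 * 1), c(64, 64, 3, 1))
  p1 <- predict_proba(m, x)
  ck <- tempfile(fileext = ".rds")
  save_checkpoint(m, ck, seed = 7)
  m2 <- load_checkpoint(ck)
  expect_equal(predict_proba(m2, x), p1)
  expect_true(file.exists(paste0(ck, ".json")))
})
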