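# Synthetic fundus generator, augmentation stack, disc localizer.

test_that("generation is deterministic and respects the geometry
           invariants", {
  s1 <- generate_fundus("ODE", seed = 5, size = 96)
  s2 <- generate_fundus("ODE", seed = 5, size = 96)
  expect_identical(s1$image, s2$image)
  expect_false(identical(s1$image,
                         generate_fundus("ODE", seed = 6, size = 96)$image))
  expect_gte(min(s1$image), 0)
  expect_lte(max(s1$image), 1)
  expect_equal(dim(s1$image), c(96, 96, 3))
  for (i in 1:5) {
    s <- generate_fundus(sample(c("Normal", "ODE", "PPE"), 1),
                         seed = i, size = 96)
    expect_gte(s$radius, 0.12 * 96)
    expect_lte(s$radius, 0.22 * 96)
    expect_true(all(s$center >= 0.2 * 96 & s$center <= 0.8 * 96))
  }
  expect_error(generate_fundus("Glaucoma", seed = 1), "arg")
})

test_that("rim gradient energy orders the classes as designed", {
  ge <- sapply(1:30, function(i)
    sapply(c("Normal", "PPE", "ODE"), function(l)
      rim_gradient_energy(generate_fundus(l, seed = i, size = 96))))
  m <- rowMeans(ge)
  expect_gt(m["Normal"], m["PPE"])
  expect_gt(m["PPE"], m["ODE"])
})

test_that("the brightest pixels cluster at the stored disc center", {
  errs <- sapply(1:30, function(i) {
    s <- generate_fundus(c("Normal", "PPE", "ODE")[(i %% 3) + 1],
                         seed = i + 50, size = 96)
    g <- s$image[, , 2]
    idx <- which(g >= stats::quantile(g, 0.99), arr.ind = TRUE)
    sqrt(sum((colMeans(idx) - s$center)^2)) / s$radius
  })
  expect_lt(stats::median(errs), 0.1)
})

test_that("dataset builds are deterministic with the requested counts
           and banker's rounding", {
  counts <- default_split_counts(0.02)
  d1 <- file.path(tempdir(), "wds1")
  man <- build_dataset(d1, counts, seed = 3, size = 48)
  expect_equal(nrow(man), sum(counts$n))
  expect_true(all(file.exists(man$path)))
  got <- as.data.frame(table(split = man$split, label = man$label),
                       stringsAsFactors = FALSE)
  want <- merge(got, as.data.frame(counts), by = c("split", "label"))
  expect_equal(want$Freq, want$n)
  # decodable PNGs
  img <- png::readPNG(man$path[1])
  expect_equal(dim(img)[1:2], c(48, 48))
  # same seed, fresh directory: identical per-image seeds
  man2 <- build_dataset(file.path(tempdir(), "wds2"), counts,
                        seed = 3, size = 48)
  expect_identical(man$seed, man2$seed)
  # Table-1 proportions at scale 0.1 round to 62/33/26 training images
  sc <- default_split_counts(0.1)
  expect_equal(sc$n[sc$split == "train"], c(62L, 33L, 26L))
  expect_error(build_dataset(tempdir(), default_split_counts(0), seed = 1),
               "positive")
})

test_that("offline augmentation quadruples the training split and only
           the training split", {
  counts <- tibble::tibble(split = c("train", "val"),
                           label = c("Normal", "ODE"), n = c(4L, 2L))
  man <- build_dataset(file.path(tempdir(), "wds3"), counts,
                       seed = 5, size = 48)
  aug <- augment_offline(man, seed = 6)
  expect_equal(sum(aug$split == "train"), 16)
  expect_equal(sum(aug$split == "val"), 2)
  expect_true(all(aug$label[aug$split == "train"] == "Normal"))
  expect_true(all(file.exists(aug$path)))
  expect_error(augment_offline(man, split = "val"), "training")
  # per-source bookkeeping: 3 new variants per image
  expect_equal(nrow(aug) - nrow(man), 3 * 4)
})

test_that("online augmentation is seeded and the evaluation path is a
           plain resize", {
  img <- generate_fundus("Normal", seed = 9, size = 96)$image
  a1 <- augment_online(img, seed = 4, out_size = 64)
  a2 <- augment_online(img, seed = 4, out_size = 64)
  expect_identical(a1, a2)
  expect_equal(dim(a1), c(64L, 64L, 3L))
  expect_gte(min(a1), 0); expect_lte(max(a1), 1)
  ev1 <- augment_online(img, out_size = 64, train = FALSE)
  ev2 <- augment_online(img, seed = 99, out_size = 64, train = FALSE)
  expect_identical(ev1, ev2)   # no randomness on the evaluation path
  expect_error(augment_online(array(0, c(1, 1, 3)), 1), "degenerate")
})

test_that("the disc localizer finds the disc and crops around it", {
  errs <- sapply(1:30, function(i) {
    s <- generate_fundus(c("Normal", "PPE", "ODE")[(i %% 3) + 1],
                         seed = i + 300, size = 96)
    cd <- crop_disc(s$image, out_size = 64)
    expect_equal(dim(cd$image), c(64, 64, 3))
    sqrt(sum((cd$center - s$center)^2)) / s$radius
  })
  expect_lt(max(errs), 0.15)
  # idempotence: re-cropping an already disc-centered crop re-selects
  # (nearly) the full frame
  for (i in 1:5) {
    s <- generate_fundus("Normal", seed = i, size = 128)
    c1 <- crop_disc(s$image, out_size = 96)
    c2 <- crop_disc(c1$image, out_size = 96)
    expect_lte(c2$box[1], 3)
    expect_lte(c2$box[2], 3)
    expect_gte(c2$box[3], 96 - 4)
  }
  expect_error(crop_disc(array(0, c(32, 32, 3))), "localization")
})

test_that("a rim-gradient threshold rule separates the synthetic classes
           well above chance", {
  # learn two cutpoints on a small calibration batch, then classify a
  # fresh 300-image test split
  classes <- c("ODE", "PPE", "Normal")   # increasing rim sharpness
  cal <- sapply(1:20, function(i)
    sapply(classes, function(l)
      rim_gradient_peak(generate_fundus(l, seed = 7000 + i, size = 96))))
  mu <- rowMeans(cal)
  cut1 <- mean(mu[c("ODE", "PPE")])
  cut2 <- mean(mu[c("PPE", "Normal")])
  labs <- rep(classes, each = 100)
  correct <- 0
  for (j in seq_along(labs)) {
    s <- generate_fundus(labs[j], seed = 8000 + j, size = 96)
    g <- rim_gradient_peak(s)
    pred <- if (g < cut1) "ODE" else if (g < cut2) "PPE" else "Normal"
    correct <- correct + (pred == labs[j])
  }
  expect_gte(correct / length(labs), 0.8)
})

test_that("ODE carries hemorrhages while Normal and PPE do not", {
  for (i in 1:8) {
    so <- generate_fundus("ODE", seed = i, size = 96)
    expect_gte(nrow(so$hemorrhage), 1)
    expect_lte(nrow(so$hemorrhage), 3)
    # a paired blob-free render differs exactly where the blobs are,
    # and the blobs darken the red channel there
    s0 <- generate_fundus("ODE", seed = i, size = 96, hemorrhages = FALSE)
    diff <- s0$image[, , 1] - so$image[, , 1]
    expect_gte(min(diff), -1e-12)       # blobs only ever darken
    expect_gt(max(diff), 0.05)          # and do so substantially
    expect_identical(nrow(generate_fundus("Normal", seed = i,
                                          size = 96)$hemorrhage), 0L)
    expect_identical(nrow(generate_fundus("PPE", seed = i,
                                          size = 96)$hemorrhage), 0L)
  }
})
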