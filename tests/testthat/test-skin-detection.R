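test_that("asymmetric loss is zero for exact predictions", {
  m <- matrix(runif(64), 8, 8)
  truth <- m >= 0.5
  expect_equal(asymmetric_loss(ifelse(truth, 1, 0), truth), 0)
})

test_that("a single false positive costs 1 - alpha", {
  expect_equal(asymmetric_loss(matrix(1), matrix(0), alpha = 0.4), 0.6)
  expect_equal(asymmetric_loss(matrix(0), matrix(1), alpha = 0.4), 0.4)
})

test_that("asymmetric loss matches a naive per-pixel double loop", {
  set.seed(11)
  for (rep in 1:5) {
    pred <- matrix(runif(64), 8, 8)
    truth <- matrix(runif(64) > 0.6, 8, 8)
    alpha <- runif(1, 0.05, 0.45)
    ref <- 0
    for (i in 1:8) for (j in 1:8) {
      y <- as.numeric(truth[i, j]); p <- pred[i, j]
      ref <- ref + (y - p)^2 * (alpha * y + (1 - alpha) * (1 - y))
    }
    expect_equal(asymmetric_loss(pred, truth, alpha), ref, tolerance = 1e-12)
  }
})

test_that("alpha = 0.5 reduces the loss to half the sum of squares", {
  set.seed(12)
  pred <- matrix(runif(64), 8, 8)
  truth <- matrix(runif(64) > 0.5, 8, 8)
  expect_equal(asymmetric_loss(pred, truth, 0.5),
               0.5 * sum((as.numeric(truth) - pred)^2), tolerance = 1e-12)
})

test_that("alpha < 0.5 penalizes false positives more than false negatives", {
  fp <- asymmetric_loss(matrix(c(1, 0), 1), matrix(c(0, 0), 1), 0.4)
  fn <- asymmetric_loss(matrix(c(0, 1), 1), matrix(c(1, 1), 1), 0.4)
  expect_gt(fp, fn)
})

test_that("loss rejects mismatched shapes and bad alpha", {
  expect_error(asymmetric_loss(matrix(0, 2, 2), matrix(0, 3, 3)), "mismatch")
  expect_error(asymmetric_loss(matrix(0), matrix(0), alpha = 1.5), "alpha")
})

test_that("binarization is inclusive at the threshold and counts correctly", {
  expect_true(all(binarize(matrix(0.9, 4, 4), 0.5)))
  expect_true(all(binarize(matrix(0.5, 4, 4), 0.5)))
  set.seed(13)
  m <- matrix(runif(200), 10, 20)
  b <- binarize(m, 0.37)
  expect_equal(attr(b, "n_skin"), sum(m >= 0.37))
  expect_equal(n_skin(b), sum(m >= 0.37))
})

test_that("raising the binarization threshold never grows the mask", {
  set.seed(14)
  m <- matrix(runif(200), 10, 20)
  counts <- sapply(seq(0.1, 0.9, 0.1), function(th) n_skin(binarize(m, th)))
  expect_true(all(diff(counts) <= 0))
})

test_that("morphology behaves on an elliptical mask", {
  sc <- scene_params()
  mask <- spadppg:::ellipse_mask_at(sc, 0)
  expect_identical(geometric_mask_provider(
    structure(list(true_masks = list(mask)), class = "ground_truth"))[[1]],
    mask)
  expect_lt(n_skin(erode_mask(mask)), n_skin(mask))
  closed <- erode_mask(dilate_mask(mask), 1)
  expect_true(all(closed[mask]))  # closing a convex mask keeps every pixel
  # oracle: erosion equals the naive neighbourhood minimum
  naive <- mask
  for (i in seq_len(nrow(mask))) for (j in seq_len(ncol(mask))) {
    nb <- mask[max(1, i - 1):min(nrow(mask), i + 1),
               max(1, j - 1):min(ncol(mask), j + 1)]
    full <- (min(nrow(mask), i + 1) - max(1, i - 1) + 1) *
            (min(ncol(mask), j + 1) - max(1, j - 1) + 1) == 9
    naive[i, j] <- all(nb) && full
  }
  expect_identical(erode_mask(mask), naive)
})

test_that("network respects the output shape/range contract", {
  cfg <- skin_net_config(encoder_channels = c(2, 2, 3, 3, 3, 3, 4, 4),
                         decoder_channels = c(3, 3, 2, 2, 2, 1))
  model <- build_network(cfg, 32, 64)
  set.seed(15)
  frame <- matrix(rpois(2048, 100), 32, 64)
  p <- predict(model, frame)
  expect_equal(dim(p), c(32, 64))
  expect_true(all(p >= 0 & p <= 1))
  expect_identical(p, predict(model, frame))  # deterministic
  expect_error(build_network(cfg, 30, 64), "divisible by 8")
})

test_that("parameter count matches the layer-by-layer sum", {
  cfg <- skin_net_config()
  model <- build_network(cfg)
  enc <- cfg$encoder_channels; dec <- cfg$decoder_channels
  cins <- c(1, enc[-8], enc[8], dec[-6])
  couts <- c(enc, dec)
  expect_equal(n_parameters(model), sum(9 * cins * couts + couts))
})

test_that("backpropagation matches numeric gradients", {
  cfg <- skin_net_config(encoder_channels = c(2, 2, 3, 3, 3, 3, 4, 4),
                         decoder_channels = c(3, 3, 2, 2, 2, 1), seed = 9)
  model <- build_network(cfg, 8, 16)
  set.seed(16)
  N <- 8 * 16
  X <- matrix(runif(N), N, 1)
  Y <- matrix(rbinom(N, 1, 0.3), N, 1)
  alpha <- 0.4
  lossfun <- function(m) {
    p <- spadppg:::net_forward(m, X, 1L)$out
    sum((Y - p)^2 * (alpha * Y + (1 - alpha) * (1 - Y)))
  }
  fw <- spadppg:::net_forward(model, X, 1L, keep = TRUE)
  dOut <- -2 * (Y - fw$out) * (alpha * Y + (1 - alpha) * (1 - Y))
  gr <- spadppg:::net_backward(model, fw$cache, dOut, 1L)
  eps <- 1e-5
  for (li in which(sapply(model$layers, function(l) l$type == "conv"))) {
    for (i in sample(length(model$layers[[li]]$W), 3)) {
      m2 <- model; m2$layers[[li]]$W[i] <- m2$layers[[li]]$W[i] + eps
      m3 <- model; m3$layers[[li]]$W[i] <- m3$layers[[li]]$W[i] - eps
      num <- (lossfun(m2) - lossfun(m3)) / (2 * eps)
      expect_equal(gr[[li]]$dW[i], num, tolerance = 1e-4)
    }
  }
})

test_that("a short training run descends and an empty set errors", {
  expect_error(train_skin_network(list()), "empty")
  pairs <- simulate_training_pairs(30, seed = 31)
  cfg <- skin_net_config(epochs = 3)
  model <- train_skin_network(pairs, cfg)
  expect_lt(tail(model$loss_history, 1), model$loss_history[1])
  expect_true(model$trained)
})

test_that("training on empty-mask targets drives predictions to zero", {
  pairs <- simulate_training_pairs(30, seed = 32)
  pairs <- lapply(pairs, function(p) {
    p$mask <- p$mask & FALSE
    p
  })
  model <- train_skin_network(pairs, skin_net_config(epochs = 10))
  p <- predict(model, pairs[[1]]$frame)
  expect_lt(mean(p), 0.1)
})

test_that("checkpoints round-trip through disk", {
  cfg <- skin_net_config(encoder_channels = c(2, 2, 3, 3, 3, 3, 4, 4),
                         decoder_channels = c(3, 3, 2, 2, 2, 1))
  model <- build_network(cfg)
  path <- tempfile(fileext = ".rds")
  save_skin_net(model, path)
  back <- load_skin_net(path)
  set.seed(17)
  frame <- matrix(rpois(2048, 50), 32, 64)
  expect_identical(predict(model, frame), predict(back, frame))
})
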