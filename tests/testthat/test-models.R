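test_that("inverse-frequency class weights follow N / (2 Nc)", {
  labels <- c(rep(0L, 917), rep(1L, 42))
  w <- class_weights(labels)
  expect_equal(unname(w["pos"] / w["neg"]), 917 / 42, tolerance = 1e-12)
  expect_equal(mean(w[labels + 1]), 1)        # weighted average is 1
  expect_equal(unname(class_weights(c(0, 1, 0, 1))), c(1, 1))
  expect_equal(unname(class_weights(c(0, 0, 0, 1))), c(2 / 3, 2))
  expect_error(class_weights(c(0, 0)), "both classes")
})

test_that("tile subsampling takes max(1, round(fraction * n)) deterministically", {
  tiles <- as.list(letters[1:20])
  expect_length(subsample_tiles(rep(tiles, 2), 0.10, seed = 1), 4)
  expect_length(subsample_tiles(tiles[1:3], 0.10, seed = 1), 1)
  a <- subsample_tiles(tiles, 0.25, seed = 9)
  b <- subsample_tiles(tiles, 0.25, seed = 9)
  expect_identical(a, b)
  expect_length(a, 5)
  expect_error(subsample_tiles(list(), 0.1, 1), "at least one tile")
})

test_that("image augmentation is an exact dihedral action on pixels", {
  set.seed(5)
  a <- random_tile(8)
  expect_identical(augment_image(a, rotation = 0, flip = FALSE), a)
  f <- augment_image(a, rotation = 0, flip = TRUE)
  expect_identical(augment_image(f, rotation = 0, flip = TRUE), a)
  r <- a
  for (i in 1:4) r <- augment_image(r, rotation = 1, flip = FALSE)
  expect_equal(r, a)
  # pixel multiset is always preserved
  for (k in 0:3) for (fl in c(TRUE, FALSE)) {
    out <- augment_image(a, rotation = k, flip = fl)
    expect_equal(sort(as.vector(out)), sort(as.vector(a)))
  }
})

test_that("built models emit probabilities with the right branch structure", {
  widths <- list(ge = 30, drug = 12, image = 20)
  n <- 7
  inputs <- list(ge = matrix(stats::rnorm(n * 30), n),
                 drug1 = matrix(stats::rnorm(n * 12), n),
                 drug2 = matrix(stats::rnorm(n * 12), n),
                 image = matrix(stats::rnorm(n * 20), n))
  for (kind in c("mmnet", "ume", "umh")) {
    cfg <- model_config(kind, ge_encoder_dim = 8, drug_encoder_dim = 4,
                        image_head_dims = c(6), seed = 3)
    m <- build_model(cfg, widths)
    p <- predict(m, inputs)
    expect_length(p, n)
    expect_true(all(p >= 0 & p <= 1))
  }
  mm <- build_model(model_config("mmnet", ge_encoder_dim = 8,
                                 drug_encoder_dim = 4,
                                 image_head_dims = c(6)), widths)
  expect_named(mm$branches, c("ge", "drug1", "drug2", "image"))
  # drug branches share shapes but not weights
  expect_equal(dim(mm$branches$drug1[[1]]$W), dim(mm$branches$drug2[[1]]$W))
  expect_false(identical(mm$branches$drug1[[1]]$W, mm$branches$drug2[[1]]$W))
  expect_error(build_model(model_config("mmnet"), list(ge = 30)),
               "missing feature widths")
})

test_that("tying the two drug branches makes outputs swap-symmetric", {
  cfg <- model_config("ume", ge_encoder_dim = 8, drug_encoder_dim = 4, seed = 3)
  m <- build_model(cfg, list(ge = 10, drug = 6))
  # tied-weight configuration: equal drug encoders AND equal head blocks
  # for the two drug positions (branch widths: ge 8, drug1 4, drug2 4)
  m$branches$drug2 <- m$branches$drug1
  m$head[[1]]$W[13:16, ] <- m$head[[1]]$W[9:12, ]
  ge <- matrix(stats::rnorm(50), 5)
  d1 <- matrix(stats::rnorm(30), 5)
  d2 <- matrix(stats::rnorm(30), 5)
  p_ab <- predict(m, list(ge = ge, drug1 = d1, drug2 = d2))
  p_ba <- predict(m, list(ge = ge, drug1 = d2, drug2 = d1))
  expect_equal(p_ab, p_ba, tolerance = 1e-12)
})

test_that("analytic gradients match finite differences on a toy batch", {
  set.seed(6)
  cfg <- model_config("ume", ge_encoder_dim = 3, drug_encoder_dim = 2, seed = 8)
  net <- build_model(cfg, list(ge = 4, drug = 3))
  x <- list(ge = matrix(stats::rnorm(20), 5),
            drug1 = matrix(stats::rnorm(15), 5),
            drug2 = matrix(stats::rnorm(15), 5))
  y <- c(1, 0, 1, 0, 0)
  w <- unname(class_weights(y)[y + 1])
  loss_at <- function(net) {
    p <- pdxmm:::nn_forward(net, x)$prob
    weighted_bce(p, y, w)
  }
  fw <- pdxmm:::nn_forward(net, x)
  grads <- pdxmm:::nn_backward(net, fw, y, w)
  eps <- 1e-6
  check <- function(get, set, g) {
    for (idx in seq_len(min(5, length(get(net))))) {
      net_p <- net; v <- get(net_p); v[idx] <- v[idx] + eps
      net_p <- set(net_p, v)
      net_m <- net; v <- get(net_m); v[idx] <- v[idx] - eps
      net_m <- set(net_m, v)
      num <- (loss_at(net_p) - loss_at(net_m)) / (2 * eps)
      expect_equal(g[idx], num, tolerance = 1e-5)
    }
  }
  check(function(n) n$branches$ge[[1]]$W,
        function(n, v) { n$branches$ge[[1]]$W[] <- v; n },
        grads$branches$ge[[1]]$W)
  check(function(n) n$branches$drug2[[1]]$W,
        function(n, v) { n$branches$drug2[[1]]$W[] <- v; n },
        grads$branches$drug2[[1]]$W)
  check(function(n) n$head[[1]]$W,
        function(n, v) { n$head[[1]]$W[] <- v; n },
        grads$head[[1]]$W)
})

test_that("class weighting reproduces positive-oversampling gradients", {
  # weighted loss with w_pos = 2 must match unweighted loss on a batch in
  # which every positive appears twice (up to the changed normalization)
  set.seed(7)
  cfg <- model_config("ume", ge_encoder_dim = 3, drug_encoder_dim = 2, seed = 8)
  net <- build_model(cfg, list(ge = 4, drug = 3))
  x <- list(ge = matrix(stats::rnorm(16), 4),
            drug1 = matrix(stats::rnorm(12), 4),
            drug2 = matrix(stats::rnorm(12), 4))
  y <- c(1, 0, 0, 0)
  dup <- c(1, 1, 2, 3, 4)
  x_dup <- lapply(x, function(m) m[dup, , drop = FALSE])
  fw <- pdxmm:::nn_forward(net, x)
  g_w <- pdxmm:::nn_backward(net, fw, y, w = c(2, 1, 1, 1) * (4 / 5))
  fw_dup <- pdxmm:::nn_forward(net, x_dup)
  g_dup <- pdxmm:::nn_backward(net, fw_dup, y[dup], w = rep(1, 5))
  expect_equal(g_w$branches$ge[[1]]$W, g_dup$branches$ge[[1]]$W,
               tolerance = 1e-6)
  expect_equal(g_w$head[[1]]$W, g_dup$head[[1]]$W, tolerance = 1e-6)
})

test_that("early stopping halts after `patience` flat epochs and never later", {
  fx <- smoke_dataset(smoke_config(seed = 33))
  plans <- generate_splits(fx$manifest, k = 4, repeats = 1, seed = 3)
  # zero learning rate freezes the weights: validation loss is constant,
  # so training stops exactly `patience` epochs after the first
  cfg0 <- model_config("ume", ge_encoder_dim = 4, drug_encoder_dim = 4,
                       learning_rate = 1e-30, max_epochs = 50,
                       early_stop_patience = 5, seed = 5)
  fit0 <- train_model(fx$dataset, plans[[1]], fx$cohort$expression,
                      fx$cohort$descriptors, fx$cohort$landmark_genes, cfg0)
  expect_equal(nrow(fit0$history), 1 + 5)
  expect_equal(fit0$best_epoch, 1)
  # a learning model never runs past best_epoch + patience
  cfg1 <- model_config("ume", ge_encoder_dim = 8, drug_encoder_dim = 4,
                       learning_rate = 1e-3, max_epochs = 60,
                       early_stop_patience = 6, seed = 5)
  fit1 <- train_model(fx$dataset, plans[[1]], fx$cohort$expression,
                      fx$cohort$descriptors, fx$cohort$landmark_genes, cfg1)
  expect_lte(nrow(fit1$history), fit1$best_epoch + 6)
  # restored weights correspond to the best validation epoch
  expect_equal(fit1$history$val_loss[fit1$best_epoch],
               min(fit1$history$val_loss))
})

test_that("training is deterministic under the config seed", {
  fx <- smoke_dataset(smoke_config(seed = 37))
  plans <- generate_splits(fx$manifest, k = 4, repeats = 1, seed = 3)
  cfg <- model_config("ume", ge_encoder_dim = 8, drug_encoder_dim = 4,
                      learning_rate = 1e-3, max_epochs = 15, seed = 11)
  run <- function() {
    fit <- train_model(fx$dataset, plans[[1]], fx$cohort$expression,
                       fx$cohort$descriptors, fx$cohort$landmark_genes, cfg)
    predict(fit)$probability
  }
  expect_identical(run(), run())
})

test_that("tile-level instances inherit their sample's label and features", {
  tf <- list(features = matrix(stats::rnorm(12), 6),
             specimen_id = c("S01", "S01", "S01", "S01", "S02", "S02"))
  ss <- toy_samples(c("dA", "dB"), c("dB", "dA"), response = c(1L, 0L))
  inst <- pdxmm:::tile_instances(ss, tf)
  expect_equal(inst$sample_row, c(rep(1, 4), rep(2, 2)))
  expect_equal(inst$tile_row, 1:6)
  # training subsample takes 10% with the one-tile floor guard
  inst2 <- pdxmm:::tile_instances(ss, tf, fraction = 0.1, subsample = TRUE,
                                  seed = 4)
  expect_equal(as.integer(table(inst2$sample_row)), c(1L, 1L))
})

test_that("the unregistered pretrained backbone fails with guidance", {
  expect_error(backbone_features(list(random_tile(8)), "pretrained-large"),
               "register_backbone")
  f <- backbone_features(list(random_tile(16), random_tile(16)))
  expect_equal(nrow(f), 2)
  expect_true(all(is.finite(f)))
})
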