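# Light-weight training checks (sanity and reproducibility); the full
# trained-stage performance floors live in test-acceptance.R.

tiny_view_data <- function(n_per_class = 6, px = 32) {
  # two synthetic "views": bright disk vs bright ring
  set.seed(404)
  out <- list()
  rr <- matrix(0:(px - 1), px, px); cc <- t(rr)
  r <- sqrt((rr - px / 2)^2 + (cc - px / 2)^2)
  for (i in seq_len(n_per_class)) {
    disk <- 100 * (r < px / 4) + matrix(rnorm(px^2, 0, 5), px)
    ring <- 100 * (r < px / 3 & r > px / 5) + matrix(rnorm(px^2, 0, 5), px)
    out[[length(out) + 1]] <- list(image = disk, label = "SAx")
    out[[length(out) + 1]] <- list(image = ring, label = "4Ch")
  }
  out
}

test_that("classifier training reduces the loss and is seed-reproducible", {
  ds <- tiny_view_data()
  cfg <- train_config("view", epochs = 6, input_px = 32, seed = 5,
                      augmentation = NULL)
  m1 <- train_stage("view", ds, cfg)
  expect_lt(m1$loss_log[6], m1$loss_log[1])
  m2 <- train_stage("view", ds, cfg)
  expect_identical(m1$loss_log, m2$loss_log)
  expect_identical(m1$net, m2$net)
  # learns the toy distinction
  pred <- vapply(ds, function(ex) predict(m1, ex$image)$label, "")
  expect_gt(mean(pred == vapply(ds, `[[`, "", "label")), 0.9)
})

test_that("training rejects datasets that violate the stage contract", {
  expect_error(train_stage("view", list(list(image = 1:3, label = "SAx"))),
               "contract")
  expect_error(train_stage("segment", list(list(image = matrix(0, 4, 4)))),
               "contract")
})

test_that("phase decoding of oracle curves gives AAFD 0", {
  # sanity mode: feed the label codec's own curves through the decoder
  es_true <- c(8L, 11L, 13L)
  dec <- vapply(es_true, function(es)
    decode_es_phase(encode_phase_curve(es, 30)), 0L)
  expect_equal(aafd(dec, es_true), 0)
})

test_that("stage models save to and load from JSON unchanged", {
  ds <- tiny_view_data(2)
  cfg <- train_config("view", epochs = 1, input_px = 32, seed = 5,
                      augmentation = NULL)
  m <- train_stage("view", ds, cfg)
  path <- file.path(withr::local_tempdir(), "view.json")
  save_stage_model(m, path)
  back <- load_stage_model(path)
  img <- ds[[1]]$image
  expect_equal(predict(back, img)$probs, predict(m, img)$probs,
               tolerance = 1e-12)
})

test_that("zero-magnitude augmentation is the identity", {
  img <- matrix(runif(64 * 64), 64)
  out <- augment(img, spec = list(), seed = 3)
  expect_identical(out$image, img)
  out2 <- augment(img, list(type = "points", points = rbind(c(10, 20))),
                  spec = list(rotation = 0, zoom = 0, translation = 0), seed = 3)
  expect_equal(out2$image, img, tolerance = 1e-12)
  expect_equal(out2$label$points, rbind(c(10, 20)))
})

test_that("time-roll shifts the cine and its ES label jointly", {
  cine <- array(0, c(10, 8, 8))
  for (t in 1:10) cine[t, , ] <- t
  for (seed in 1:10) {
    out <- augment(cine, list(type = "es", es = 4), list(time_roll = TRUE),
                   seed = seed)
    # the frame that held value 5 (index 4, 0-based) moved with the label
    expect_equal(out$image[out$label$es + 1, 1, 1], 5)
  }
})

test_that("rotation moves point labels with the image content", {
  px <- 64
  pt <- c(20, 40)
  hm <- encode_landmark_heatmap(rbind(pt), c(px, px), sigma = 3)
  img <- hm[, , 1]
  for (seed in 1:5) {
    out <- augment(img, list(type = "points", points = rbind(pt)),
                   spec = list(rotation = 25), seed = seed)
    dec <- decode_heatmap(pmax(out$image, 0))
    expect_lt(sqrt(sum((dec$point - out$label$points)^2)), 0.5)
  }
})

test_that("unknown augmentations are rejected", {
  expect_error(augment(matrix(0, 4, 4), spec = list(warp9 = 1)), "unknown")
})

test_that("stage predictions are invariant to input intensity scaling", {
  ds <- tiny_view_data(2)
  cfg <- train_config("view", epochs = 2, input_px = 32, seed = 6,
                      augmentation = NULL)
  m <- train_stage("view", ds, cfg)
  img <- ds[[1]]$image
  expect_equal(predict(m, img)$probs, predict(m, img * 7.3)$probs,
               tolerance = 1e-9)
})
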