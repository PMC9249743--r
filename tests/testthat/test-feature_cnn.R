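test_that("partition_subsets yields a balanced stratified partition", {
  ids <- sprintf("s%03d", 1:100)
  labs <- rep(c(0L, 1L), each = 50L)
  subs <- partition_subsets(ids, labs, 10L, rng_seed = 3L)
  expect_length(subs, 10L)
  expect_true(all(lengths(subs) == 10L))
  expect_setequal(unlist(subs), ids)
  expect_identical(anyDuplicated(unlist(subs)), 0L)

  # 101 samples: sizes 10 or 11, sum exact
  ids2 <- sprintf("t%03d", 1:101)
  labs2 <- c(rep(0L, 51L), rep(1L, 50L))
  subs2 <- partition_subsets(ids2, labs2, 10L, rng_seed = 4L)
  expect_true(all(lengths(subs2) %in% c(10L, 11L)))
  expect_identical(sum(lengths(subs2)), 101L)

  # stratification: per-subset positive count is floor or ceil of share
  for (n in c(3L, 5L, 7L)) {
    subs3 <- partition_subsets(ids, labs, n, rng_seed = n)
    pos <- vapply(subs3, function(s) sum(labs[match(s, ids)] == 1L),
                  integer(1))
    expect_true(all(pos %in% c(floor(50 / n), ceiling(50 / n))))
  }

  expect_error(partition_subsets(ids, labs, 1L), "at least 2")
  expect_error(partition_subsets(ids[1:3], labs[1:3], 5L), "exceeds")
})

test_that("train_cnn validates its inputs", {
  ds <- tiny_cohort()
  spec <- cnn_spec(input_shape = c(16L, 16L), epochs = 1L, batch_size = 4L)
  one_class <- ds$sample_id[ds$label == 0L][1:8]
  expect_error(train_cnn(one_class, ds$sample_id[70:72], ds, spec),
               "both classes")
  expect_error(train_cnn(ds$sample_id[1:8], ds$sample_id[8:10], ds, spec),
               "disjoint")
})

test_that("training reduces hinge loss on a separable cohort", {
  fx <- tiny_extractor()
  e <- fx$extractor
  expect_identical(nrow(e$training_log), e$spec$epochs)
  final <- e$training_log$train_loss[e$spec$epochs]
  expect_lt(final, e$initial_loss[["train"]])
})

test_that("training run is reproducible under fixed seeds", {
  ds <- tiny_cohort()
  spec <- cnn_spec(input_shape = c(16L, 16L), epochs = 1L, batch_size = 4L)
  ids <- ds$sample_id
  tr <- ids[c(1:20, 41:60)]; va <- ids[c(21:28, 61:68)]
  a <- train_cnn(tr, va, ds, spec, rng_seed = 9L)
  b <- train_cnn(tr, va, ds, spec, rng_seed = 9L)
  expect_identical(a$training_log, b$training_log)
  expect_identical(a$params, b$params)
})

test_that("an uninformative cohort trains to chance-level validation", {
  ds <- tiny_cohort(lesion = 0, seed = 3L)
  spec <- cnn_spec(input_shape = c(16L, 16L), epochs = 2L, batch_size = 4L)
  ids <- ds$sample_id
  set.seed(21)
  val <- sample(ids, 20L)
  e <- train_cnn(setdiff(ids, val), val, ds, spec, rng_seed = 5L)
  Xv <- cnnforest:::dataset_matrix(ds, val, c(16L, 16L))
  pred <- as.integer(cnnforest:::cnn_score_batch(e, Xv) > 0)
  truth <- ds$label[match(val, ds$sample_id)]
  acc <- mean(pred == truth)
  p0 <- max(mean(truth == 1L), mean(truth == 0L))  # majority-class rate
  ci <- 1.96 * sqrt(p0 * (1 - p0) / length(val))
  expect_lte(acc, p0 + ci)
})

test_that("cnn_score is deterministic, shape-checked, and zero for a
           zeroed output head", {
  fx <- tiny_extractor()
  e <- fx$extractor
  img <- fx$ds$images[[1]]
  expect_identical(cnn_score(e, img), cnn_score(e, img))
  expect_error(cnn_score(e, matrix(0, 8, 8)), "shape")
  ez <- e
  ez$params$Wo[] <- 0; ez$params$bo <- 0
  expect_identical(cnn_score(ez, img), 0)
  expect_identical(cnn_score(ez, fx$ds$images[[30]]), 0)
})

test_that("a trained extractor separates the classes in mean score", {
  fx <- tiny_extractor()
  ds <- fx$ds
  X <- cnnforest:::dataset_matrix(ds, ds$sample_id, c(16L, 16L))
  s <- cnnforest:::cnn_score_batch(fx$extractor, X)
  expect_gt(mean(s[ds$label == 1L]), mean(s[ds$label == 0L]))
})

test_that("build_feature_matrix equals the per-sample scoring oracle", {
  fx <- tiny_extractor()
  ds <- fx$ds
  ids <- ds$sample_id[1:8]
  # constant extractors: zero weights, bias c_j
  consts <- lapply(c(-0.5, 0.25, 2), function(cj) {
    e <- fx$extractor
    e$params$Wo[] <- 0; e$params$bo <- cj
    e
  })
  P <- build_feature_matrix(consts, ids, ds)
  expect_identical(dim(P), c(8L, 3L))
  for (j in 1:3) expect_true(all(P[, j] == consts[[j]]$params$bo))

  # exact floating-point identity with looping cnn_score
  exts <- list(fx$extractor, consts[[1]])
  P2 <- build_feature_matrix(exts, ids, ds)
  for (i in seq_along(ids)) for (j in seq_along(exts))
    expect_identical(P2[i, j],
                     cnn_score(exts[[j]], ds$images[[match(ids[i],
                                                   ds$sample_id)]]))
  expect_error(build_feature_matrix(list(), ids, ds), "empty")
})

test_that("extractors survive a save/load round trip", {
  fx <- tiny_extractor()
  dir <- withr::local_tempdir()
  save_extractor(fx$extractor, dir)
  back <- load_extractor(dir)
  img <- fx$ds$images[[5]]
  expect_identical(cnn_score(back, img), cnn_score(fx$extractor, img))
  expect_identical(back$spec$optimizer, fx$extractor$spec$optimizer)
})

test_that("cnn_spec validates and all three optimizers take steps", {
  expect_error(cnn_spec(filters = c(8L)), "one entry per")
  expect_error(cnn_spec(optimizer = "sgd"), "optimizer")
  expect_error(cnn_spec(loss = "mse"), "hinge")
  ds <- tiny_cohort()
  ids <- ds$sample_id
  for (opt in c("adagrad", "rmsprop", "adam")) {
    spec <- cnn_spec(input_shape = c(16L, 16L), epochs = 1L,
                     batch_size = 8L, optimizer = opt)
    e <- train_cnn(ids[c(1:12, 41:52)], ids[c(13:16, 53:56)], ds, spec,
                   rng_seed = 2L)
    expect_false(is.na(e$training_log$train_loss[1]))
    # parameters moved away from the seeded initialisation
    e0 <- cnnforest:::with_seed(2L, cnnforest:::cnn_init_params(
      e$plans, spec$dense_units, e$plans[[2]]$npix_out))
    expect_false(identical(e$params$Wd, e0$Wd))
  }
})
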