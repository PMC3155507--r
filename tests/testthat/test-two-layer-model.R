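test_that("K-means recovers well separated blobs and is deterministic", {
  set.seed(11)
  blob1 <- cbind(rnorm(20, 0, 0.5), rnorm(20, 0, 0.5))
  blob2 <- cbind(rnorm(20, 5, 0.5), rnorm(20, 5, 0.5))
  x <- rbind(blob1, blob2)
  cl <- cluster_positives(x, k = 2, seed = 3)
  expect_length(unique(cl$assignments[1:20]), 1L)
  expect_length(unique(cl$assignments[21:40]), 1L)
  expect_false(cl$assignments[1] == cl$assignments[21])

  cl2 <- cluster_positives(x, k = 2, seed = 3)
  expect_identical(cl, cl2)

  one <- cluster_positives(x, k = 1, seed = 3)
  expect_equal(unname(one$centers[1, ]), unname(colMeans(x)))

  # cluster 1 is the larger
  skew <- rbind(blob1, blob2[1:5, , drop = FALSE])
  cs <- cluster_positives(skew, k = 2, seed = 3)
  expect_gte(sum(cs$assignments == 1), sum(cs$assignments == 2))

  expect_error(cluster_positives(x[1, , drop = FALSE], k = 2), "at least 2")
})

test_that("negative sampling honours the 1:3 ratio and the seed", {
  pool <- matrix(seq_len(200), ncol = 2)
  s <- sample_negatives(pool, n_positive = 10, ratio = 3, seed = 5)
  expect_equal(nrow(s), 30L)
  expect_identical(s, sample_negatives(pool, 10, 3, seed = 5))
  expect_false(identical(s, sample_negatives(pool, 10, 3, seed = 6)))

  # ratio 1 with a pool of exactly n -> the whole pool
  small <- matrix(seq_len(20), ncol = 2)
  expect_identical(sample_negatives(small, 10, ratio = 1, seed = 1), small)
  expect_warning(sample_negatives(small, 10, ratio = 3, seed = 1),
                 "whole pool")
  expect_error(sample_negatives(small[0, , drop = FALSE], 10), "empty")
})

test_that("clustered models separate a toy problem and calibrate", {
  fx <- separable_fixture()
  m <- train_clustered_model(fx$pos, fx$neg, C = 1, gamma = 0.5, seed = 1)
  pr <- betaturn:::clustered_proba(m, rbind(fx$pos, fx$neg))
  expect_equal(unname(rowSums(pr)), rep(1, 40))
  expect_true(all(pr[1:20, "pos"] > 0.5))
  expect_true(all(pr[21:40, "pos"] < 0.5))

  set.seed(2)
  probes <- matrix(runif(100), ncol = 2)
  prq <- betaturn:::clustered_proba(m, probes)
  expect_true(all(prq >= 0 & prq <= 1))
  expect_equal(unname(rowSums(prq)), rep(1, 50))

  # duplicating every training point leaves predictions stable
  m2 <- train_clustered_model(rbind(fx$pos, fx$pos), rbind(fx$neg, fx$neg),
                              C = 1, gamma = 0.5, seed = 1)
  p1 <- betaturn:::clustered_proba(m, probes)[, "pos"] > 0.5
  p2 <- betaturn:::clustered_proba(m2, probes)[, "pos"] > 0.5
  expect_equal(p1, p2)

  expect_error(train_clustered_model(fx$pos, fx$neg[0, , drop = FALSE]),
               "non-empty")
})

test_that("meta features are paired probabilities in a fixed order", {
  fx <- separable_fixture()
  m1 <- train_clustered_model(fx$pos, fx$neg, C = 1, gamma = 0.5, seed = 1)
  m2 <- train_clustered_model(fx$pos + 1, fx$neg, C = 1, gamma = 0.5, seed = 2)
  meta <- meta_features(rbind(fx$pos, fx$neg), m1, m2)
  expect_equal(colnames(meta), c("p1_pos", "p1_neg", "p2_pos", "p2_neg"))
  expect_true(all(meta >= 0 & meta <= 1))
  expect_equal(unname(meta[, 1] + meta[, 2]), rep(1, 40))
  expect_equal(unname(meta[, 3] + meta[, 4]), rep(1, 40))
  expect_gt(meta[1, "p1_pos"], 0.5)  # a strong positive of model 1
})

test_that("the two-layer pipeline learns the planted structure", {
  w <- small_world()
  idx <- seq_len(nrow(w$samples))
  train <- w$samples[idx %% 4 != 0, ]
  test <- w$samples[idx %% 4 == 0, ]
  model <- train_two_layer(train, training_config(seed = 7))
  pred <- predict(model, test)
  expect_gte(mean(pred$label == test$label), 0.95)
  expect_true(all(pred$score >= 0 & pred$score <= 1))
  expect_equal(pred$label, pred$score >= 0.5)

  # threshold flips the label exactly at the cut
  thr <- sort(pred$score)[5]
  pred2 <- predict(model, test, threshold = thr)
  expect_equal(pred2$label, pred2$score >= thr)

  # defaults recorded in the fitted model
  expect_equal(model$config$first_layer_C, 0.5)
  expect_equal(model$config$first_layer_gamma, 0.0078125)
  expect_equal(model$config$second_layer_C, 32)
  expect_equal(model$config$second_layer_gamma, 8)

  expect_error(predict(model, matrix(0.5, 2, 10)), "expects")
})

test_that("training is deterministic and first-layer models stay frozen", {
  w <- small_world(n_samples = 240L, seed = 13L)
  cfg <- training_config(seed = 21)
  m1 <- train_two_layer(w$samples, cfg)
  m2 <- train_two_layer(w$samples, cfg)
  expect_identical(predict(m1, w$samples)$score, predict(m2, w$samples)$score)

  # rebuild the first layer exactly as train_two_layer does; fitting the
  # second layer must not have touched the clustered models
  x <- as.matrix(w$samples$features)
  pos <- x[w$samples$label, , drop = FALSE]
  neg <- x[!w$samples$label, , drop = FALSE]
  cl <- cluster_positives(pos, k = 2, seed = cfg$seed)
  for (j in 1:2) {
    pos_j <- pos[cl$assignments == j, , drop = FALSE]
    neg_j <- sample_negatives(neg, nrow(pos_j), ratio = cfg$neg_ratio,
                              seed = cfg$seed + 100L * j)
    standalone <- train_clustered_model(pos_j, neg_j, C = cfg$first_layer_C,
                                        gamma = cfg$first_layer_gamma,
                                        seed = cfg$seed + 200L + j,
                                        cluster_index = j)
    expect_identical(serialize(m1$cluster_models[[j]], NULL),
                     serialize(standalone, NULL))
  }

  smoke <- w$samples[c(which(w$samples$label)[1:8],
                       which(!w$samples$label)[1:12]), ]
  expect_warning(
    expect_s3_class(train_two_layer(smoke, training_config(seed = 2)),
                    "two_layer_model"),
    "whole pool")
  expect_error(train_two_layer(w$samples[!w$samples$label, ],
                               training_config()), "both classes")
})

test_that("model archives round-trip and refuse foreign formats", {
  w <- small_world(n_samples = 160L, seed = 3L)
  model <- train_two_layer(w$samples, training_config(seed = 4))
  path <- tempfile(fileext = ".rds")
  write_model(model, path)
  back <- read_model(path)
  expect_identical(predict(back, w$samples)$score,
                   predict(model, w$samples)$score)
  expect_equal(back$config$second_layer_C, 32)

  saveRDS(list(format = "something-else"), path)
  expect_error(read_model(path), "unrecognised")
})

test_that("grid search is exhaustive with deterministic tie-breaks", {
  w <- small_world(n_samples = 160L, seed = 17L)
  one <- grid_search_svm(w$samples, C_grid = 2, gamma_grid = 0.5,
                         inner_folds = 3, seed = 1)
  expect_equal(one$C, 2)
  expect_equal(one$gamma, 0.5)

  g <- grid_search_svm(w$samples, C_grid = c(0.5, 8), gamma_grid = c(0.01, 1),
                       inner_folds = 3, seed = 1)
  expect_equal(nrow(g$results), 4L)
  best <- g$results[order(-g$results$accuracy, g$results$C, g$results$gamma), ][1, ]
  expect_equal(g$C, best$C)
  expect_equal(g$gamma, best$gamma)
  g2 <- grid_search_svm(w$samples, C_grid = c(0.5, 8), gamma_grid = c(0.01, 1),
                        inner_folds = 3, seed = 1)
  expect_identical(g, g2)
})
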