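test_that("build_tensor lays out values, mask, and padding as documented", {
  adm <- data.frame(
    hadm_id = c(11L, 12L),
    subject_id = c(1L, 2L),
    admit_time = c("2120-01-01 07:00:00", "2120-02-01 07:00:00"),
    discharge_time = c("2120-01-03 20:00:00", "2120-02-01 20:00:00"),
    stringsAsFactors = FALSE)
  rec <- data.frame(
    hadm_id = c(11L, 11L, 11L, 12L),
    timestamp = c("2120-01-01 12:00:00", "2120-01-03 12:00:00",
                  "2120-01-03 13:00:00", "2120-02-01 12:00:00"),
    event_id = c(5L, 5L, 7L, 7L),
    event_value = c(1, 1, 2, 1), stringsAsFactors = FALSE)
  tensor <- build_tensor(rec, adm, max_len = 15L)
  expect_equal(dim(tensor$values), c(2L, 15L, 2L))
  # 3-day stay: mask 1,1,1 then 12 padded days
  expect_equal(tensor$mask[1, ], c(1, 1, 1, rep(0, 12)))
  expect_equal(tensor$mask[2, ], c(1, rep(0, 14)))
  f5 <- tensor$feature_index[["5"]]; f7 <- tensor$feature_index[["7"]]
  expect_equal(tensor$values[1, 1, f5], 1)
  expect_equal(tensor$values[1, 3, f5], 1)
  expect_equal(tensor$values[1, 3, f7], 2)   # summed event values per day
  expect_equal(tensor$values[2, 1, f7], 1)
  expect_true(all(tensor$values[1, 4:15, ] == 0))
})

test_that("overflow drops or truncates long stays as configured", {
  adm <- data.frame(
    hadm_id = c(1L, 2L), subject_id = 1:2,
    admit_time = "2120-01-01 07:00:00",
    discharge_time = c("2120-01-25 20:00:00", "2120-01-02 20:00:00"),
    stringsAsFactors = FALSE)
  rec <- data.frame(hadm_id = c(1L, 1L, 2L),
                    timestamp = c("2120-01-01 12:00:00", "2120-01-20 12:00:00",
                                  "2120-01-02 12:00:00"),
                    event_id = 3L, event_value = 1, stringsAsFactors = FALSE)
  dropped <- build_tensor(rec, adm, max_len = 15L, overflow = "drop")
  expect_equal(dropped$keys, "2")               # the 25-day stay is absent
  trunc <- build_tensor(rec, adm, max_len = 15L, overflow = "truncate")
  expect_equal(trunc$keys, c("1", "2"))
  expect_equal(sum(trunc$mask[1, ]), 15)        # truncated to max_len days
  expect_equal(sum(trunc$values[1, , ]), 1)     # day-20 event fell off
})

test_that("the feature cap is enforced as a configuration error", {
  adm <- data.frame(hadm_id = 1L, subject_id = 1L,
                    admit_time = "2120-01-01 00:00:00",
                    discharge_time = "2120-01-02 00:00:00",
                    stringsAsFactors = FALSE)
  rec <- data.frame(hadm_id = 1L, timestamp = "2120-01-01 10:00:00",
                    event_id = 1L, event_value = 1, stringsAsFactors = FALSE)
  expect_error(build_tensor(rec, adm, feature_ids = 1:300,
                            max_features = 251L), "251")
})

test_that("split sizes follow the fractions with stratified class balance", {
  dat <- strong_signal_data(400L, n_patients = 100L)
  tensor <- dat$tensor
  sp <- split_dataset(tensor, c(0.7, 0.15, 0.15), seed = 9L)
  expect_equal(length(sp$train$labels), 70L)
  expect_equal(length(sp$val$labels), 15L)
  expect_equal(length(sp$test$labels), 15L)
  # disjoint and exhaustive
  keys <- c(sp$train$keys, sp$val$keys, sp$test$keys)
  expect_setequal(keys, tensor$keys)
  expect_equal(anyDuplicated(keys), 0L)
  # class ratio within one sample of overall in every split
  overall <- mean(tensor$labels)
  for (part in sp) {
    n <- length(part$labels)
    expect_lte(abs(sum(part$labels) - overall * n), 1 + 1e-9)
  }
  # determinism per seed
  sp2 <- split_dataset(tensor, c(0.7, 0.15, 0.15), seed = 9L)
  expect_identical(sp$train$keys, sp2$train$keys)
  expect_false(identical(
    sp$train$keys, split_dataset(tensor, seed = 10L)$train$keys))
})

test_that("a 40/60 class mix splits with ratios within one sample", {
  tensor <- strong_signal_data(401L, n_patients = 60L)$tensor
  n <- length(tensor$labels)
  labels <- rep(c(0L, 1L), length.out = n)
  labels[seq_len(floor(n * 0.4))] <- 0L
  tensor$labels <- as.integer(labels)
  sp <- split_dataset(tensor, seed = 2L)
  overall <- mean(tensor$labels)
  for (part in sp)
    expect_lte(abs(sum(part$labels) - overall * length(part$labels)), 1 + 1e-9)
})

test_that("AUROC equals brute-force pairwise concordance on fixtures", {
  concordance <- function(scores, labels) {
    pos <- scores[labels == 1]; neg <- scores[labels == 0]
    tot <- 0
    for (p in pos) for (q in neg)
      tot <- tot + (p > q) + 0.5 * (p == q)
    tot / (length(pos) * length(neg))
  }
  # perfect separation
  expect_equal(auroc_score(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0)), 1.0)
  expect_equal(f1_score(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0)), 1.0)
  # all ties
  expect_equal(auroc_score(rep(0.4, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  # one inversion in six samples: 8/9 concordant pairs
  s <- c(0.9, 0.7, 0.45, 0.5, 0.3, 0.1); l <- c(1, 1, 1, 0, 0, 0)
  expect_equal(auroc_score(s, l), 8 / 9)
  expect_equal(auroc_score(s, l), concordance(s, l))
  # random fixtures with ties
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(6:14, 1)
    l <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    s <- round(runif(n), 1)
    expect_equal(auroc_score(s, l), concordance(s, l))
  }
  expect_error(auroc_score(1:3 / 3, c(1, 1, 1)), "both classes")
})

test_that("training records one history entry per epoch and needs two classes", {
  dat <- strong_signal_data(402L, n_patients = 120L)
  cfg <- model_config(lstm_units = 4L, max_len = 10L, epochs = 4L,
                      batch_size = 32L, seed = 1L)
  m <- train_model(dat$splits$train, dat$splits$val, cfg)
  expect_equal(nrow(m$history), 4L)
  expect_equal(m$history$epoch, 1:4)
  expect_true(all(is.finite(m$history$train_loss)))
  expect_true(all(is.finite(m$history$val_loss)))
  single <- dat$splits$train
  single$labels <- rep(1L, length(single$labels))
  expect_error(train_model(single, config = cfg), "both classes")
})

test_that("training is deterministic for a fixed seed", {
  dat <- strong_signal_data(403L, n_patients = 80L)
  cfg <- model_config(lstm_units = 4L, max_len = 10L, epochs = 2L,
                      batch_size = 16L, seed = 7L)
  m1 <- train_model(dat$splits$train, config = cfg)
  m2 <- train_model(dat$splits$train, config = cfg)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$history, m2$history)
})

test_that("predictions are probabilities, per-sample, and ignore padded days", {
  tm <- tiny_trained_model()
  model <- tm$model; test <- tm$data$splits$test
  p <- predict(model, test)
  expect_true(all(p >= 0 & p <= 1))
  # permuting samples permutes outputs identically
  idx <- rev(seq_along(p))
  expect_equal(predict(model, pathminer:::subset_tensor(test, idx)), p[idx])
  # perturbing padded days never changes predictions
  noisy <- test
  pad <- noisy$mask == 0
  for (f in seq_len(noisy$F)) {
    slab <- noisy$values[, , f]
    slab[pad] <- slab[pad] + 100
    noisy$values[, , f] <- slab
  }
  expect_equal(predict(model, noisy), p)
  # feature mismatch is a shape error
  bad <- test
  bad$values <- bad$values[, , 1:5]; bad$F <- 5L
  bad$feature_index <- bad$feature_index[1:5]
  expect_error(predict(model, bad), "feature")
})

test_that("all-zero features give chance-level discrimination", {
  dat <- strong_signal_data(404L, n_patients = 150L)
  zero <- dat$splits$train
  zero$values[] <- 0
  zero$mask[] <- 1  # equal-length stays: no signal left anywhere
  cfg <- model_config(lstm_units = 4L, max_len = 10L, epochs = 3L,
                      batch_size = 32L, seed = 3L)
  m <- train_model(zero, config = cfg)
  zval <- dat$splits$val
  zval$values[] <- 0
  zval$mask[] <- 1
  ev <- evaluate_model(m, zval)
  expect_equal(ev$auroc, 0.5)  # constant scores: all ties
  oneclass <- zval
  oneclass$labels <- rep(0L, length(oneclass$labels))
  expect_error(evaluate_model(m, oneclass), "single-class")
})

test_that("analytic gradients match finite differences in all configurations", {
  set.seed(1)
  B <- 5L; T_ <- 4L; F_ <- 3L; H <- 4L
  X <- array(rnorm(B * T_ * F_), dim = c(B, T_, F_))
  M <- matrix(1, B, T_); M[1, 3:4] <- 0; M[2, 4] <- 0
  for (t in seq_len(T_)) for (f in seq_len(F_)) X[, t, f] <- X[, t, f] * M[, t]
  y <- c(1, 0, 1, 0, 1)
  loss_of <- function(params, cfg) {
    p <- pathminer:::net_forward(X, M, params, cfg, cache = FALSE)$p
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -mean(y * log(p) + (1 - y) * log(1 - p))
  }
  eps <- 1e-6
  for (cell in c("lstm", "rnn")) for (sharing in c("per-timestep", "shared")) {
    cfg <- model_config(lstm_units = H, max_len = T_, cell = cell,
                        attention_weight_sharing = sharing)
    set.seed(2)
    params <- pathminer:::init_params(T_, F_, H, cfg)
    fw <- pathminer:::net_forward(X, M, params, cfg, cache = TRUE)
    gr <- pathminer:::net_backward(fw, y, params, cfg)
    for (nm in c("Wa", "Wx", "Wh", "b", "wo", "bo")) {
      ks <- if (is.list(params[[nm]])) seq_along(params[[nm]]) else NA
      for (k in ks) {
        obj <- if (is.na(k)) params[[nm]] else params[[nm]][[k]]
        for (idx in sample(length(obj), min(3L, length(obj)))) {
          bump <- function(d) {
            p2 <- params
            if (is.na(k)) p2[[nm]][idx] <- p2[[nm]][idx] + d
            else p2[[nm]][[k]][idx] <- p2[[nm]][[k]][idx] + d
            loss_of(p2, cfg)
          }
          num <- (bump(eps) - bump(-eps)) / (2 * eps)
          ana <- if (is.na(k)) gr[[nm]][idx] else gr[[nm]][[k]][idx]
          expect_lt(abs(num - ana), 1e-4 * max(1, abs(num)),
                    label = sprintf("%s %s %s grad", cell, sharing, nm))
        }
      }
    }
  }
})

test_that("a plain recurrence does not beat the LSTM beyond noise on the planted task", {
  dat <- strong_signal_data(505L)
  cfg <- model_config(lstm_units = 32L, max_len = 10L, epochs = 20L,
                      batch_size = 64L, seed = 506L, standardize = FALSE)
  lstm <- train_model(dat$splits$train, dat$splits$val, cfg)
  cfg_rnn <- cfg; cfg_rnn$cell <- "rnn"
  rnn <- train_model(dat$splits$train, dat$splits$val, cfg_rnn)
  a_lstm <- evaluate_model(lstm, dat$splits$test)$auroc
  a_rnn <- evaluate_model(rnn, dat$splits$test)$auroc
  expect_gt(a_lstm, 0.85)
  expect_lte(a_rnn, a_lstm + 0.05)
})

test_that("attention maps are normalized over features and zero when masked", {
  tm <- tiny_trained_model()
  am <- extract_attention(tm$model, tm$data$splits$test)
  rows <- apply(am$weights, c(1, 2), sum)
  expect_true(all(abs(rows[am$mask == 1] - 1) < 1e-6))
  expect_true(all(rows[am$mask == 0] == 0))
  expect_true(all(am$weights >= 0))
})

test_that("a trained model round-trips through its checkpoint file", {
  tm <- tiny_trained_model()
  path <- withr::local_tempfile(fileext = ".json")
  save_model(tm$model, path)
  back <- load_model(path)
  test <- tm$data$splits$test
  expect_equal(predict(back, test), predict(tm$model, test), tolerance = 1e-12)
  expect_equal(back$config$lstm_units, tm$model$config$lstm_units)
})
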