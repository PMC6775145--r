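# closed-form parameter count, written independently of weight_shapes
params_arith <- function(L, H, D = 132, P = 32, Pd = 32, K = 4) {
  dense_in <- D * P + P
  bilstm1 <- 2 * 4 * ((P + H) * H + H)
  bilstm_rest <- 2 * 4 * ((2 * H + H) * H + H)
  dense_in + bilstm1 + max(0, L - 1) * bilstm_rest +
    2 * H * Pd + Pd + Pd * K + K
}

test_that("parameter count matches the per-layer arithmetic on the grid", {
  expect_equal(count_parameters(model_config()), 255812)
  expect_equal(count_parameters(model_config()),
               4256 + 49664 + 98816 + 98816 + 4128 + 132)
  expect_equal(signif(count_parameters(model_config()), 2), 2.6e5)
  for (L in 1:6) for (H in c(32L, 64L, 128L)) {
    cfg <- model_config(n_lstm_layers = L, lstm_units_per_direction = H)
    expect_equal(count_parameters(cfg), params_arith(L, H))
  }
  expect_error(model_config(n_lstm_layers = 0))
})

test_that("forward pass yields normalized posteriors and is deterministic", {
  cfg <- model_config(input_dim = 132, n_lstm_layers = 1,
                      lstm_units_per_direction = 16, seed = 9)
  m <- build_model(cfg)
  X <- matrix(rnorm(7 * 132), 7, 132)
  P <- hrvstager:::lstm_forward_cpp(m$weights, X, 1, 16)
  expect_equal(dim(P), c(7, 4))
  expect_equal(rowSums(P), rep(1, 7), tolerance = 1e-6)
  expect_true(all(P > 0 & P < 1))
  # same seed -> identical initial weights; inference has no dropout
  m2 <- build_model(cfg)
  expect_identical(m$weights, m2$weights)
  expect_identical(P, hrvstager:::lstm_forward_cpp(m2$weights, X, 1, 16))
})

test_that("soft cross-entropy matches closed forms and the Gibbs bound", {
  one_hot <- matrix(c(1, 0, 0, 0), 1, 4)
  expect_equal(soft_cross_entropy(one_hot, one_hot), 0)
  expect_equal(soft_cross_entropy(one_hot, matrix(0.25, 1, 4)), log(4))
  expect_error(soft_cross_entropy(one_hot, matrix(c(0, 1, 0, 0), 1, 4)),
               "positive")
  set.seed(43)
  for (i in 1:20) {
    P <- t(apply(matrix(runif(12), 3, 4), 1, function(r) r / sum(r)))
    Q <- t(apply(matrix(runif(12), 3, 4), 1, function(r) r / sum(r)))
    expect_gte(soft_cross_entropy(P, Q), soft_cross_entropy(P, P) - 1e-12)
  }
})

test_that("BPTT gradients match central finite differences", {
  set.seed(44)
  cfg <- model_config(input_dim = 5, pre_dense_units = 4, n_lstm_layers = 2,
                      lstm_units_per_direction = 16, post_dense_units = 3,
                      seed = 44)
  m <- build_model(cfg)
  X <- matrix(rnorm(6 * 5), 6, 5)
  Y <- t(apply(matrix(runif(24), 6, 4), 1, function(r) r / sum(r)))
  lg <- hrvstager:::lstm_lossgrad_cpp(m$weights, X, Y, 2, 16)
  eps <- 1e-5
  for (nm in names(m$weights)) {
    ks <- sample(length(m$weights[[nm]]), min(4, length(m$weights[[nm]])))
    for (k in ks) {
      wp <- m$weights; wp[[nm]][k] <- wp[[nm]][k] + eps
      wm <- m$weights; wm[[nm]][k] <- wm[[nm]][k] - eps
      num <- (hrvstager:::lstm_lossgrad_cpp(wp, X, Y, 2, 16)$loss -
                hrvstager:::lstm_lossgrad_cpp(wm, X, Y, 2, 16)$loss) /
        (2 * eps)
      expect_equal(lg$grad[[nm]][k], num, tolerance = 1e-5)
    }
  }
})

test_that("fold assignment shuffles participants, never splits them", {
  meta <- data.frame(recording_id = paste0("r", 1:4),
                     participant_id = c("A", "A", "B", "B"))
  f <- assign_folds(meta, k = 2, seed = 1)
  expect_equal(f[1], f[2])
  expect_equal(f[3], f[4])
  expect_identical(f, assign_folds(meta, k = 2, seed = 1))
  expect_error(assign_folds(meta, k = 3), "fewer participants")

  big <- data.frame(recording_id = paste0("r", 1:584),
                    participant_id = rep(sprintf("P%03d", 1:292), each = 2))
  f4 <- assign_folds(big, k = 4, seed = 7)
  per_part <- tapply(f4, big$participant_id, function(x) length(unique(x)))
  expect_true(all(per_part == 1))
  expect_equal(unname(table(f4[!duplicated(big$participant_id)])),
               rep(73L, 4), ignore_attr = TRUE)
})

test_that("training beats the class-prior baseline on separable sequences", {
  set.seed(45)
  # two latent stages with well-separated feature means
  mk_night <- function(T) {
    z <- rep(sample(1:2, max(1, T / 10), replace = TRUE), each = 10)[1:T]
    X <- matrix(rnorm(T * 132, mean = 0, sd = 1), T, 132)
    X[, 1] <- X[, 1] + ifelse(z == 1, 3, -3)
    Y <- matrix(0, T, 4); Y[cbind(1:T, z)] <- 1
    list(X = X, Y = Y)
  }
  nights <- lapply(rep(40, 12), mk_night)
  tabs <- lapply(nights, `[[`, "X")
  labs <- lapply(nights, `[[`, "Y")
  pid <- sprintf("P%02d", rep(1:6, each = 2))
  cfg <- model_config(n_lstm_layers = 1, lstm_units_per_direction = 16,
                      seed = 45)
  tcfg <- train_config(patience = 15, max_passes = 60, batch_nights = 4,
                       seed = 45)
  m <- train_stager(build_model(cfg), tabs, labs, pid, tcfg)
  allY <- do.call(rbind, labs)
  prior <- colMeans(allY)
  keep <- prior > 0
  prior_loss <- -sum(prior[keep] * log(prior[keep]))
  expect_lt(min(m$history$train_loss), prior_loss)
  # patience semantics: stops within patience passes of the best pass
  expect_lte(nrow(m$history) - attr(m$history, "best_pass"), 15)
  # determinism: identical run with the same seed
  m2 <- train_stager(build_model(cfg), tabs, labs, pid, tcfg)
  expect_identical(m$history, m2$history)
  expect_identical(m$weights, m2$weights)
})

test_that("prediction standardizes with stored statistics and labels rows", {
  set.seed(46)
  T <- 30
  tabs <- lapply(1:4, function(i) matrix(rnorm(T * 132), T, 132))
  labs <- lapply(1:4, function(i) {
    Y <- matrix(0, T, 4); Y[cbind(1:T, sample(1:4, T, TRUE))] <- 1; Y
  })
  cfg <- model_config(n_lstm_layers = 1, lstm_units_per_direction = 16,
                      seed = 46)
  m <- train_stager(build_model(cfg), tabs, labs, c("a", "a", "b", "c"),
                    train_config(patience = 3, max_passes = 5))
  pr <- predict(m, tabs[[1]])
  expect_equal(rowSums(pr$posteriors), rep(1, T), tolerance = 1e-6)
  expect_length(pr$stages, T)
  expect_true(all(pr$stages %in% STAGES))
  expect_error(predict(m, tabs[[1]][, 1:10]), "mismatch")
  # constant input (the stored medians) varies only with sequence position
  Xc <- matrix(rep(m$impute_medians, each = T), T, 132)
  p1 <- predict(m, Xc)$posteriors
  p2 <- predict(m, Xc)$posteriors
  expect_identical(p1, p2)
})

test_that("cross-validation predicts every night once without leakage", {
  set.seed(47)
  T <- 20
  n_nights <- 16
  tabs <- lapply(1:n_nights, function(i) matrix(rnorm(T * 132), T, 132))
  labs <- lapply(1:n_nights, function(i) {
    Y <- matrix(0, T, 4); Y[cbind(1:T, sample(1:4, T, TRUE))] <- 1; Y
  })
  meta <- data.frame(recording_id = paste0("r", 1:n_nights),
                     participant_id = rep(sprintf("P%d", 1:8), each = 2))
  cv <- cross_validate(tabs, labs, meta,
                       model_config(n_lstm_layers = 1,
                                    lstm_units_per_direction = 16, seed = 47),
                       train_config(k_folds = 4, patience = 2, max_passes = 3,
                                    seed = 47))
  expect_length(cv$models, 4)
  expect_true(all(!vapply(cv$predictions, is.null, logical(1))))
  # each fold's test participants are absent from its imputation statistics:
  # fold models differ because their training portions differ
  expect_false(identical(cv$models[[1]]$impute_medians,
                         cv$models[[2]]$impute_medians))
  # partition property
  expect_equal(sort(unname(unlist(tapply(seq_len(n_nights), cv$fold, c)))),
               seq_len(n_nights))
})

test_that("model checkpoints round-trip weights and statistics", {
  set.seed(48)
  T <- 20
  tabs <- lapply(1:3, function(i) matrix(rnorm(T * 132), T, 132))
  labs <- lapply(1:3, function(i) {
    Y <- matrix(0, T, 4); Y[cbind(1:T, sample(1:4, T, TRUE))] <- 1; Y
  })
  m <- train_stager(build_model(model_config(n_lstm_layers = 1,
                                             lstm_units_per_direction = 16,
                                             seed = 48)),
                    tabs, labs, c("a", "b", "c"),
                    train_config(patience = 2, max_passes = 3))
  p <- withr::local_tempfile(fileext = ".rds")
  save_stager(m, p)
  m2 <- load_stager(p)
  expect_identical(m2$weights, m$weights)
  expect_identical(predict(m2, tabs[[1]]), predict(m, tabs[[1]]))
})
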