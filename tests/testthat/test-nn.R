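ns <- asNamespace("gaitcascade")

test_that("cross_entropy matches hand values and a brute-force oracle", {
  expect_lte(cross_entropy(1, 1.0), 1.2e-7)  # perfect prediction, clipped
  expect_equal(cross_entropy(c(1, 0), c(0.5, 0.5)), log(2),
               tolerance = 1e-12)
  brute <- function(y, p, eps = 1e-7) {
    acc <- 0
    for (i in seq_along(y)) {
      pi <- min(max(p[i], eps), 1 - eps)
      acc <- acc + y[i] * log(pi) + (1 - y[i]) * log(1 - pi)
    }
    -acc / length(y)
  }
  set.seed(1)
  for (rep in 1:100) {
    y <- stats::rbinom(50, 1, 0.5)
    p <- stats::runif(50)
    expect_equal(cross_entropy(y, p), brute(y, p), tolerance = 1e-12)
  }
  expect_error(cross_entropy(c(1, 0), 0.5), class = "gait_schema_error")
})

test_that("network output is a probability for arbitrary finite inputs", {
  cfg <- model_config(n_dense_layers = 1, units = 1, window_length = 4,
                      channels = c("p0", "p1"))
  net <- build_network(cfg, seed = 3)
  set.seed(2)
  for (scale in c(1, 1e3, 1e6)) {
    x <- array(stats::rnorm(5 * 4 * 2, sd = scale), dim = c(5, 4, 2))
    p <- ns$sigmoid(ns$nn_forward(net, x)$logit)
    expect_true(all(p >= 0 & p <= 1))
  }
})

test_that("analytic gradients match numerical differentiation per layer type", {
  check <- function(config, tol = 1e-5) {
    net <- build_network(config, seed = 2, clamp_conv = TRUE)
    set.seed(9)
    n <- 4
    x <- array(stats::rnorm(n * config$window_length *
                              length(config$channels)),
               dim = c(n, config$window_length, length(config$channels)))
    y <- stats::rbinom(n, 1, 0.5)
    loss_fn <- function(net) {
      cross_entropy(y, ns$sigmoid(ns$nn_forward(net, x)$logit))
    }
    fw <- ns$nn_forward(net, x)
    p <- ns$sigmoid(fw$logit)
    grads <- ns$nn_backward(net, fw$caches, (p - y) / n)
    for (i in seq_along(net$layers)) {
      for (pn in names(net$layers[[i]]$params)) {
        P <- net$layers[[i]]$params[[pn]]
        for (j in sample(length(P), min(5, length(P)))) {
          eps <- 1e-5
          up <- net; up$layers[[i]]$params[[pn]][j] <- P[j] + eps
          dn <- net; dn$layers[[i]]$params[[pn]][j] <- P[j] - eps
          num <- (loss_fn(up) - loss_fn(dn)) / (2 * eps)
          expect_equal(grads[[i]][[pn]][j], num, tolerance = tol)
        }
      }
    }
  }
  check(model_config(n_dense_layers = 2, units = c(5, 3),
                     activations = c("tanh", "selu"), window_length = 6,
                     channels = c("p0", "p1", "p2"), dropout = 0))
  check(model_config(n_dense_layers = 1, units = 4, use_conv = TRUE,
                     conv_filters = 3, conv_window = 3,
                     conv_activation = "sigmoid", use_pooling = TRUE,
                     window_length = 8, channels = c("p0", "p1", "ax"),
                     dropout = 0))
  check(model_config(n_dense_layers = 1, units = 4, use_lstm = TRUE,
                     lstm_units = 3, window_length = 5,
                     channels = c("p0", "p1"), dropout = 0), tol = 1e-4)
})

test_that("build_network shapes follow the configuration", {
  # single hidden unit forward pass on zeros
  cfg <- model_config(n_dense_layers = 1, units = 1, window_length = 4,
                      channels = "p0")
  net <- build_network(cfg, seed = 1)
  p <- ns$sigmoid(ns$nn_forward(net, array(0, dim = c(1, 4, 1)))$logit)
  expect_true(p >= 0 && p <= 1)
  expect_equal(net$input_shape, c(4, 1))
  # conv window longer than the input window errors unless clamped
  bad <- model_config(n_dense_layers = 1, units = 2, use_conv = TRUE,
                      conv_filters = 2, conv_window = 10,
                      conv_activation = "selu", window_length = 4,
                      channels = c("p0", "p1"))
  expect_error(build_network(bad, seed = 1), "conv_window",
               class = "gait_config_error")
  clamped <- build_network(bad, seed = 1, clamp_conv = TRUE)
  expect_true(attr(clamped, "conv_clamped"))
})

test_that("model_config validates the search-space ranges", {
  expect_error(model_config(n_dense_layers = 12, units = rep(2, 12)),
               class = "gait_config_error")
  expect_error(model_config(units = 65), class = "gait_config_error")
  expect_error(model_config(learning_rate = 0.05),
               class = "gait_config_error")
  expect_error(model_config(optimizer = "adagrad"),
               class = "gait_config_error")
  expect_error(model_config(window_length = 33), class = "gait_config_error")
  expect_error(model_config(channels = character(0)),
               class = "gait_config_error")
})

test_that("training learns separable gait data and respects max_epochs", {
  recs <- simulate_dataset(gait_sim_config(seed = 51, duration = 30),
                           c(walking = 3, running = 3))
  win <- stratified_split(build_windows(recs, window = 16), seed = 1)
  lab <- relabel_binary(win, "running_vs_walking")
  cfg <- model_config(window_length = 16)
  fit <- train_node(lab, cfg, patience = 5, max_epochs = 20, seed = 1)
  expect_gte(fit$validation_auc, 0.9)
  # loss trend decreases on separable data
  h <- fit$history
  expect_lt(mean(utils::tail(h$train_loss, 3)),
            mean(utils::head(h$train_loss, 3)))
  # single epoch budget -> single-epoch history
  one <- train_node(lab, cfg, patience = 5, max_epochs = 1, seed = 1)
  expect_equal(nrow(one$history), 1)
  # reproducibility given (seed, config, data)
  fit2 <- train_node(lab, cfg, patience = 5, max_epochs = 20, seed = 1)
  expect_identical(fit$net$layers, fit2$net$layers)
  expect_identical(fit$validation_auc, fit2$validation_auc)
})

test_that("single-class training data is rejected, naming the node", {
  recs <- simulate_dataset(gait_sim_config(seed = 52, duration = 20),
                           c(walking = 3))
  win <- stratified_split(build_windows(recs, window = 8), seed = 1)
  lab <- relabel_binary(win, "running_vs_walking")
  expect_error(train_node(lab, model_config(window_length = 8)),
               "running_vs_walking", class = "gait_schema_error")
})

test_that("tidiers summarise trained models", {
  recs <- simulate_dataset(gait_sim_config(seed = 53, duration = 20),
                           c(sitting = 3, walking = 3))
  win <- stratified_split(build_windows(recs, window = 8), seed = 1)
  lab <- relabel_binary(win, "standing_vs_seated")
  fit <- train_node(lab, model_config(window_length = 8), max_epochs = 5)
  expect_equal(names(tidy(fit)), c("epoch", "train_loss", "val_loss"))
  g <- glance(fit)
  expect_equal(g$node, "standing_vs_seated")
  expect_equal(g$epochs, nrow(fit$history))
  expect_s3_class(autoplot(fit), "ggplot")
})
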