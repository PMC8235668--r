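ns <- asNamespace("gaitcascade")

test_that("random configuration sampling stays inside the space", {
  sp <- search_space()
  ns$with_seed(1, {
    for (i in 1:50) {
      cfg <- ns$sample_config(sp)
      expect_true(cfg$n_dense_layers >= 1 && cfg$n_dense_layers <= 11)
      expect_true(all(cfg$units >= 1 & cfg$units <= 64))
      expect_true(all(cfg$activations %in% c("tanh", "selu")))
      expect_true(cfg$window_length >= 4 && cfg$window_length <= 32)
      if (cfg$use_conv) {
        expect_lte(cfg$conv_window, cfg$window_length)
      }
      expect_true(cfg$optimizer %in% c("sgd", "adam", "rmsprop"))
      expect_gte(length(cfg$channels), 1)
    }
  })
  # space can be narrowed
  narrow <- search_space(n_dense_layers = c(1L, 1L), use_conv = FALSE,
                         use_lstm = FALSE, window_length = c(8L, 8L))
  cfg <- ns$with_seed(2, ns$sample_config(narrow))
  expect_equal(cfg$n_dense_layers, 1L)
  expect_equal(cfg$window_length, 8L)
  expect_false(cfg$use_conv)
})

test_that("registry ranks models by validation AUC with stable ties", {
  reg <- new_registry()
  mk <- function(auc, ch, id) {
    m <- function_model(function(w) 0.5, window_length = 4, channels = ch,
                        node = "standing_vs_seated", validation_auc = auc)
    m$id <- id
    m
  }
  reg <- registry_insert(reg, mk(0.7, c("p0"), "a"))
  reg <- registry_insert(reg, mk(0.9, c("p1"), "b"))
  reg <- registry_insert(reg, mk(0.9, c("p2"), "c"))  # tie: b stays ahead
  reg <- registry_insert(reg, mk(0.8, c("p3"), "d"))
  expect_equal(vapply(reg$model[order(reg$rank)], function(m) m$id,
                      character(1)),
               c("b", "c", "d", "a"))
  # no model lost or duplicated
  expect_setequal(vapply(reg$model, function(m) m$id, character(1)),
                  c("a", "b", "c", "d"))
})

test_that("fallback returns the best model disjoint from the failed set", {
  reg <- new_registry()
  m1 <- function_model(function(w) 1, channels = c("p0", "p1", "ax"),
                       node = "moving_vs_still", validation_auc = 0.95)
  m2 <- function_model(function(w) 1, channels = c("p3", "az"),
                       node = "moving_vs_still", validation_auc = 0.85)
  reg <- registry_insert(reg, m1)
  reg <- registry_insert(reg, m2)
  expect_identical(best_without(reg, "moving_vs_still"), m1)
  expect_identical(best_without(reg, "moving_vs_still", "p0"), m2)
  expect_identical(best_without(reg, "moving_vs_still", c("P0", "A0")), m2)
  expect_error(best_without(reg, "moving_vs_still", c("p0", "p3")),
               "moving_vs_still", class = "gait_node_unavailable")
  expect_error(best_without(reg, "running_vs_walking"),
               class = "gait_node_unavailable")
})

test_that("fallback equals filter-then-take-first on random registries", {
  set.seed(10)
  for (rep in 1:30) {
    n_models <- sample(2:6, 1)
    entries <- purrr::map(seq_len(n_models), function(i) {
      ch <- sample(gait_channels(), sample(1:6, 1))
      function_model(function(w) 0.5, channels = ch,
                     node = "stumbling_vs_not",
                     validation_auc = stats::runif(1))
    })
    reg <- new_registry()
    for (m in entries) reg <- registry_insert(reg, m)
    failed <- sample(gait_channels(), sample(0:4, 1))
    ordered <- entries[order(-vapply(entries, function(m)
      m$validation_auc, numeric(1)))]
    eligible <- purrr::keep(ordered, function(m)
      length(intersect(m$channels, failed)) == 0)
    if (length(eligible) == 0) {
      expect_error(best_without(reg, "stumbling_vs_not", failed),
                   class = "gait_node_unavailable")
    } else {
      got <- best_without(reg, "stumbling_vs_not", failed)
      expect_no_intersect(got$channels, failed)
      expect_equal(got$validation_auc, eligible[[1]]$validation_auc)
    }
  }
})

test_that("search trains, ranks and reproduces under a fixed seed", {
  recs <- simulate_dataset(gait_sim_config(seed = 61, duration = 20),
                           c(sitting = 3, walking = 3))
  narrow <- search_space(n_dense_layers = c(1L, 3L), units = c(2L, 8L),
                         use_conv = FALSE, use_lstm = FALSE,
                         window_length = c(6L, 10L),
                         batch_size = c(16L, 32L), channel_prob = 0.8)
  one <- run_search(recs, "standing_vs_seated", n_trials = 1,
                    sampler = "random", seed = 3, space = narrow,
                    max_epochs = 2, patience = 2)
  expect_equal(nrow(one$registry), 1)
  expect_equal(one$registry$node, "standing_vs_seated")

  six <- run_search(recs, "standing_vs_seated", n_trials = 6,
                    sampler = "random", seed = 3, space = narrow,
                    max_epochs = 3, patience = 2)
  # best-ranked model dominates every other trial's AUC
  best <- six$registry$validation_auc[six$registry$rank == 1]
  expect_true(all(six$registry$validation_auc <= best))
  expect_equal(sort(six$registry$rank), 1:6)

  again <- run_search(recs, "standing_vs_seated", n_trials = 6,
                      sampler = "random", seed = 3, space = narrow,
                      max_epochs = 3, patience = 2)
  expect_identical(six$trials, again$trials)  # same trial sequence
})

test_that("TPE suggestions stay in the space and improve on history", {
  sp <- search_space(use_conv = FALSE, use_lstm = FALSE)
  # synthetic history: larger windows score better
  hist <- dplyr::bind_rows(purrr::map(1:20, function(i) {
    cfg <- ns$with_seed(i, ns$sample_config(sp))
    feat <- ns$config_features(cfg)
    feat$value <- cfg$window_length / 32
    feat$trial <- i
    tibble::as_tibble(feat)
  }))
  ns$with_seed(99, {
    sugg <- purrr::map(1:10, function(i) ns$tpe_suggest(hist, sp))
  })
  ws <- vapply(sugg, function(cfg) cfg$window_length, integer(1))
  expect_true(all(ws >= 4 & ws <= 32))
  # guided suggestions should concentrate above the space midpoint
  expect_gt(mean(ws), 18)
})

test_that("registry persistence round-trips trained models", {
  recs <- simulate_dataset(gait_sim_config(seed = 62, duration = 20),
                           c(sitting = 3, walking = 3))
  win <- stratified_split(build_windows(recs, window = 8), seed = 1)
  lab <- relabel_binary(win, "standing_vs_seated")
  fit <- train_node(lab, model_config(window_length = 8,
                                      channels = c("p0", "p5", "az")),
                    max_epochs = 3)
  reg <- registry_insert(new_registry(), fit)
  dir <- withr::local_tempdir()
  save_registry(reg, dir)
  back <- load_registry(dir)
  expect_equal(nrow(back), 1)
  m <- back$model[[1]]
  expect_equal(m$validation_auc, fit$validation_auc)
  te <- lab[lab$split == "test", ]
  expect_equal(predict(m, te), predict(fit, te), tolerance = 1e-12)
})
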