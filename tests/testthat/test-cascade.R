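test_that("the decision tree's leaves cover exactly the six events", {
  leaves <- cascade_leaves()
  expect_equal(nrow(leaves), 6)
  expect_setequal(leaves$event, gait_events())
  # expected routing, leaf by leaf
  lookup <- function(dec) {
    hit <- purrr::detect_index(leaves$decisions, function(d)
      identical(d, as.integer(dec)))
    leaves$event[hit]
  }
  expect_equal(lookup(0), "sitting")
  expect_equal(lookup(c(1, 0, 0)), "standing_still")
  expect_equal(lookup(c(1, 0, 1)), "standing_imbalance")
  expect_equal(lookup(c(1, 1, 1)), "stumbling")
  expect_equal(lookup(c(1, 1, 0, 0)), "walking")
  expect_equal(lookup(c(1, 1, 0, 1)), "running")
  # paths are bounded by four decisions
  expect_true(all(lengths(leaves$decisions) %in% 1:4))
  # the five nodes partition their domains consistently
  nodes <- cascade_nodes()
  for (i in seq_len(nrow(nodes))) {
    expect_no_intersect(nodes$class0_events[[i]], nodes$class1_events[[i]])
  }
})

test_that("fixed node probabilities route and multiply as hand-traced", {
  probs <- c(standing_vs_seated = 0.9, moving_vs_still = 0.8,
             stumbling_vs_not = 0.2, running_vs_walking = 0.9,
             unbalanced_vs_stable = 0.5)
  models <- purrr::imap(probs, function(p, nm) {
    function_model(function(w) p, node = nm, validation_auc = 1)
  })
  tree <- cascade_tree(models)
  frames <- make_frames(8)
  res <- predict_cascade(tree, frames)
  expect_equal(res$event, "running")
  # 0.9 (standing) * 0.8 (moving) * 0.8 (not stumbling) * 0.9 (running)
  expect_equal(res$path_probability, 0.9 * 0.8 * 0.8 * 0.9)
  expect_equal(nrow(res$path), 4)
  expect_false(res$risk_flag)

  # root below threshold ends at sitting in one step
  models$standing_vs_seated <-
    function_model(function(w) 0.1, node = "standing_vs_seated")
  res0 <- predict_cascade(cascade_tree(models), frames)
  expect_equal(res0$event, "sitting")
  expect_equal(nrow(res0$path), 1)
  expect_equal(res0$path_probability, 0.9)
})

test_that("flipping the root decision always changes the terminal event", {
  frames <- make_frames(8)
  for (p_rest in list(c(0.9, 0.9, 0.9, 0.9), c(0.1, 0.1, 0.1, 0.1))) {
    mk_tree <- function(root_p) {
      nodes <- cascade_nodes()$name
      probs <- stats::setNames(c(root_p, p_rest), nodes)
      cascade_tree(purrr::imap(probs, function(p, nm)
        function_model(function(w) p, node = nm)))
    }
    lo <- predict_cascade(mk_tree(0.2), frames)$event
    hi <- predict_cascade(mk_tree(0.8), frames)$event
    expect_equal(lo, "sitting")
    expect_false(hi == "sitting")
  }
})

test_that("perfect-oracle nodes give six-class accuracy 1.0", {
  recs <- simulate_dataset(gait_sim_config(seed = 71, duration = 10),
                           stats::setNames(rep(2L, 6), gait_events()))
  tree <- cascade_tree(oracle_registry())
  cm <- evaluate_cascade(tree, recs, stride = 3)
  expect_equal(cm$accuracy, 1.0)
  expect_gt(cm$n, 0)
  # oracle scores put probability 1 on the true leaf
  expect_equal(cm$macro_auc, 1.0)
  # risk flags mark exactly the imbalance and stumbling predictions
  res <- attr(cm, "results")
  expect_equal(res$risk_flag,
               res$event_pred %in% c("standing_imbalance", "stumbling"))
})

test_that("cascade falls back per node when sensors fail", {
  reg <- oracle_registry()
  # a better-but-fragile model for the root that uses p0 and always says 1
  fragile <- function_model(function(w) 1, channels = c("p0"),
                            node = "standing_vs_seated",
                            validation_auc = 1)
  reg <- registry_insert(reg, fragile, node = "standing_vs_seated")
  tree <- cascade_tree(reg)
  sit <- simulate_recording(gait_sim_config(seed = 72, duration = 5),
                            "sitting", "s1")
  frames <- sit$frames[[1]]
  frames$event <- "sitting"
  # fragile model ties at AUC 1 but oracle was inserted first: oracle wins
  expect_equal(predict_cascade(tree, frames)$event, "sitting")
  # fail every oracle channel except what fragile needs: fragile selected
  fails <- setdiff(gait_channels(), "p0")
  # oracles use all channels, so they are knocked out entirely
  expect_error(predict_cascade(tree, frames, failed_channels = fails),
               class = "gait_node_unavailable")
})

test_that("prediction reports a warm-up condition on short history", {
  models <- purrr::map(
    stats::setNames(cascade_nodes()$name, cascade_nodes()$name),
    function(nm) function_model(function(w) 0.1, window_length = 8,
                                node = nm))
  tree <- cascade_tree(models)
  expect_error(predict_cascade(tree, make_frames(5)), "Warming up",
               class = "gait_warmup")
})

test_that("streaming emits after warm-up and alerts exactly once per risk", {
  # deterministic router: everything is standing imbalance (a risk event)
  probs <- c(standing_vs_seated = 0.9, moving_vs_still = 0.1,
             unbalanced_vs_stable = 0.9, stumbling_vs_not = 0.1,
             running_vs_walking = 0.1)
  tree <- cascade_tree(purrr::imap(probs, function(p, nm)
    function_model(function(w) p, window_length = 6, node = nm)))
  collector <- alert_collector()
  frames <- make_frames(20)
  out <- predict_stream(tree, frames, alert_sink = collector$sink,
                        stride = 2)
  expect_equal(nrow(out), length(seq(6, 20, by = 2)))
  expect_true(all(out$event_pred == "standing_imbalance"))
  expect_true(all(out$risk_flag))
  expect_equal(nrow(collector$alerts()), sum(out$risk_flag))

  # stream shorter than warm-up emits nothing
  short <- predict_stream(tree, make_frames(5), alert_sink = collector$sink)
  expect_equal(nrow(short), 0)
})

test_that("NDJSON streams with malformed lines are skipped, not fatal", {
  rec <- simulate_recording(gait_sim_config(seed = 73, duration = 5),
                            "walking", "w1")
  frames <- rec$frames[[1]]
  lines <- vapply(seq_len(nrow(frames)), function(i)
    as.character(serialize_message(frames[i, c("timestamp",
                                               paste0("p", 0:15))])),
    character(1))
  lines <- append(lines, "{not json}", after = 3)
  aux <- frames[, c("timestamp", "temp", "ax", "ay", "az")]
  tree <- cascade_tree(purrr::map(
    stats::setNames(cascade_nodes()$name, cascade_nodes()$name),
    function(nm) function_model(function(w) 0.1, window_length = 4,
                                node = nm)))
  out <- suppressMessages(predict_stream(tree, lines, aux = aux))
  expect_equal(nrow(out), nrow(frames) - 4 + 1)
  expect_true(all(out$event_pred == "sitting"))
})

test_that("end-to-end: trained cascade flags a stumbling stream", {
  fit <- train_cascade(small_dataset(), seed = 2, max_epochs = 25,
                       patience = 5)
  tree <- cascade_tree(fit$registry)
  stream_rec <- simulate_recording(gait_sim_config(seed = 74, duration = 30),
                                   "stumbling", "st_live")
  collector <- alert_collector()
  out <- predict_stream(tree, stream_rec$frames[[1]],
                        alert_sink = collector$sink)
  expect_gt(nrow(out), 0)
  alerts <- collector$alerts()
  expect_gt(nrow(alerts), 0)  # at least one risk alert delivered
  expect_equal(nrow(alerts), sum(out$risk_flag))
})
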