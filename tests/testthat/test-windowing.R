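test_that("window counts and boundary cases match enumeration", {
  rec32 <- make_recording(32)
  w <- build_windows(rec32, window = 32)
  expect_equal(nrow(w), 1)
  expect_equal(dim(w$values[[1]]), c(32, 20))

  rec40 <- make_recording(40)
  expect_equal(nrow(build_windows(rec40, window = 32)), 9)  # n - w + 1

  # the published stumbling-node geometry: w = 4, 9 channels, 10 frames
  ch9 <- c("P0", "P1", "P4", "P7", "P10", "P11", "P12", "P14", "A1")
  w49 <- build_windows(make_recording(10), channels = ch9, window = 4)
  expect_equal(nrow(w49), 7)
  expect_equal(dim(w49$values[[1]]), c(4, 9))

  # too-short recordings yield no windows, without error
  expect_equal(nrow(suppressMessages(
    build_windows(make_recording(10), window = 16))), 0)
})

test_that("window contents equal exhaustive slicing for every start offset", {
  rec <- make_recording(40, fill = function(i, ch) i * 1000 + ch)
  mat <- as.matrix(rec$frames[[1]][, gait_channels()])
  for (w in c(4, 16, 32)) {
    for (stride in c(1, 2, 4)) {
      got <- build_windows(rec, window = w, stride = stride)
      starts <- seq.int(1, 40 - w + 1, by = stride)
      expect_equal(nrow(got), length(starts))
      for (k in seq_along(starts)) {
        expect_equal(unname(got$values[[k]]),
                     unname(mat[starts[k]:(starts[k] + w - 1), ]))
        expect_equal(got$t_index[k], starts[k] + w - 1)
      }
    }
  }
})

test_that("windows never cross interleaved recording boundaries", {
  a <- make_recording(12, id = "a", fill = function(i, ch) 1)
  b <- make_recording(12, id = "b", start = "2021-01-01 00:00:01.1",
                      fill = function(i, ch) 2)
  w <- build_windows(dplyr::bind_rows(a, b), window = 8)
  expect_equal(nrow(w), 2 * (12 - 8 + 1))
  for (i in seq_len(nrow(w))) {
    vals <- unique(as.numeric(w$values[[i]]))
    expect_length(vals, 1)  # all-1 or all-2, never mixed
  }
})

test_that("stratified split honours per-class 60/20/20 within one sample", {
  win <- dplyr::bind_rows(
    build_windows(make_recording(103, event = "walking", id = "w"),
                  window = 4),
    build_windows(make_recording(53, event = "running", id = "r"),
                  window = 4))
  # 100 class-A + 50 class-B windows
  split <- stratified_split(win, seed = 5)
  tab <- table(split$event, split$split)
  expect_equal(unname(tab["walking", ]), c(60, 20, 20), ignore_attr = TRUE)
  expect_equal(unname(tab["running", ]), c(30, 10, 10), ignore_attr = TRUE)
  expect_equal(sum(tab), nrow(win))

  # 10 samples of one class -> 6/2/2 (remainder to train)
  w10 <- build_windows(make_recording(13, event = "sitting"), window = 4)
  s10 <- stratified_split(w10, seed = 1)
  expect_equal(unname(table(s10$split)), c(6L, 2L, 2L), ignore_attr = TRUE)
})

test_that("split is seed-deterministic and proportional on random mixes", {
  set.seed(77)
  for (rep in 1:50) {
    sizes <- sample(3:40, sample(2:4, 1))
    win <- dplyr::bind_rows(purrr::imap(sizes, function(n, i) {
      build_windows(make_recording(n + 3, event = gait_events()[i],
                                   id = paste0("r", i)), window = 4)
    }))
    s1 <- stratified_split(win, seed = rep)
    s2 <- stratified_split(win, seed = rep)
    expect_identical(s1$split, s2$split)
    for (ev in unique(win$event)) {
      n <- sum(win$event == ev)
      cnt <- table(s1$split[s1$event == ev])
      expect_lte(abs(cnt[["validation"]] - 0.2 * n), 1)
      expect_lte(abs(cnt[["test"]] - 0.2 * n), 1)
      expect_lte(abs(cnt[["train"]] - 0.6 * n), 1)
    }
  }
  # different seeds give different memberships on a non-trivial input
  win <- build_windows(make_recording(60), window = 4)
  expect_false(identical(stratified_split(win, seed = 1)$split,
                         stratified_split(win, seed = 2)$split))
})

test_that("split refuses classes too small to partition", {
  win <- build_windows(make_recording(5, event = "stumbling"), window = 4)
  expect_error(stratified_split(win, seed = 1), "stumbling",
               class = "gait_split_error")
})

test_that("recording-level split keeps whole recordings together", {
  recs <- dplyr::bind_rows(purrr::map(1:6, function(i) {
    make_recording(10, event = "walking", id = paste0("w", i))
  }))
  win <- build_windows(recs, window = 4)
  s <- stratified_split(win, seed = 3, by = "recording")
  mix <- tapply(as.character(s$split), s$recording_id,
                function(x) length(unique(x)))
  expect_true(all(mix == 1))
})

test_that("relabel_binary applies node polarity and domain", {
  recs <- dplyr::bind_rows(purrr::imap(gait_events(), function(ev, i) {
    make_recording(6, event = ev, id = paste0("r", i))
  }))
  win <- build_windows(recs, window = 4)
  # root: sitting is class 0, everything else class 1, nothing excluded
  root <- relabel_binary(win, "standing_vs_seated")
  expect_equal(nrow(root), nrow(win))
  expect_true(all(root$label[root$event == "sitting"] == 0))
  expect_true(all(root$label[root$event != "sitting"] == 1))
  # unbalanced node keeps only the two standing events
  ub <- relabel_binary(win, "unbalanced_vs_stable")
  expect_setequal(unique(ub$event), c("standing_still", "standing_imbalance"))
  expect_true(all(ub$label[ub$event == "standing_imbalance"] == 1))
  # a node applied outside its domain yields an empty set
  sit_only <- win[win$event == "sitting", ]
  expect_equal(nrow(relabel_binary(sit_only, "running_vs_walking")), 0)
})

test_that("window persistence round-trips values and metadata", {
  dir <- withr::local_tempdir()
  win <- stratified_split(
    build_windows(make_recording(20), window = 8,
                  channels = c("p0", "p3", "az")), seed = 2)
  write_windows(win, dir)
  back <- read_windows(dir)
  expect_equal(back$values, win$values)
  expect_equal(back$split, win$split)
  expect_equal(attr(back, "channels"), c("p0", "p3", "az"))
})
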