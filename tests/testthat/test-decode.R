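grid_axes <- list(freqs = 10:40, frames = seq(0, 0.5, by = 0.01))

test_that("searchlight grid tiles, counts neighbors and excludes margins", {
  g <- searchlight_grid(10:52, grid_axes$frames)
  expect_s3_class(g, "searchlight_grid")
  ## interior bins have the full two-bin Chebyshev neighborhood (24)
  expect_equal(max(g$n_neighbors), 24)
  ## corner bins have 8 neighbors and are excluded under the default rule
  expect_true(any(g$n_neighbors == 8))
  expect_true(all(g$n_neighbors[g$retained] >= 10))
  expect_false(all(g$retained))
  ## cells rule keeps bins by member-cell count instead
  g2 <- searchlight_grid(10:52, grid_axes$frames,
                         neighbor_rule = "cells")
  expect_true(all(vapply(g2$bins[g2$retained], function(b)
    length(b$cells), 0L) >= 10))
  expect_error(searchlight_grid(1:5, c(0, 0.01)), "smaller than")
})

test_that("constant coherence decodes at exact chance", {
  mkc <- function() structure(list(
    coh = matrix(0.4, length(grid_axes$freqs), length(grid_axes$frames)),
    freqs = grid_axes$freqs, frames = grid_axes$frames, n_trials = 10),
    class = "coherence_map")
  feats <- build_features(lapply(1:6, function(p) list(low = mkc(), high = mkc())))
  acc <- loo_decode(feats)
  expect_true(all(acc[feats$grid$retained, "accuracy"] == 0.5))
})

test_that("label-independent features decode at chance; a class offset in one
           bin separates only there", {
  set.seed(20)
  coh0 <- lapply(1:8, function(p)
    synthetic_coh_pair(grid_axes$freqs, grid_axes$frames))
  feats0 <- build_features(coh0)
  acc0 <- loo_decode(feats0)
  m <- mean(acc0[feats0$grid$retained, "accuracy"])
  expect_lt(abs(m - 0.5), 0.12)  # binomial CI at 16 examples x bins
  ## large offset restricted to one region
  cells <- which(outer(grid_axes$freqs >= 22 & grid_axes$freqs <= 30,
                       grid_axes$frames >= 0.2 & grid_axes$frames < 0.3, "&"))
  set.seed(21)
  coh1 <- lapply(1:8, function(p)
    synthetic_coh_pair(grid_axes$freqs, grid_axes$frames,
                       offset_cells = cells, offset = 0.4))
  feats1 <- build_features(coh1)
  acc1 <- loo_decode(feats1)
  hit <- vapply(feats1$grid$bins, function(b)
    length(intersect(b$cells, cells)) > 20, TRUE)
  far <- vapply(feats1$grid$bins, function(b)
    length(intersect(b$cells, cells)) == 0, TRUE)
  expect_gt(min(acc1[hit & feats1$grid$retained, "accuracy"]), 0.9)
  expect_lt(mean(acc1[far & feats1$grid$retained, "accuracy"]), 0.65)
})

test_that("participants missing a class are excluded with a log entry", {
  set.seed(22)
  coh <- lapply(1:6, function(p)
    synthetic_coh_pair(grid_axes$freqs, grid_axes$frames))
  coh[[3]]$high <- NULL
  expect_message(feats <- build_features(coh), "excluded")
  expect_equal(length(unique(feats$participant)), 5)
})

test_that("leave-one-out requires 5 participants and two-class folds", {
  set.seed(23)
  coh <- lapply(1:4, function(p)
    synthetic_coh_pair(grid_axes$freqs, grid_axes$frames))
  feats <- build_features(coh)
  expect_error(loo_decode(feats), "5 participants")
})

test_that("shuffle null test is deterministic under seed and respects the
           p floor", {
  set.seed(24)
  coh <- lapply(1:6, function(p)
    synthetic_coh_pair(10:24, seq(0, 0.25, by = 0.01)))
  feats <- build_features(coh, searchlight_grid(10:24, seq(0, 0.25, by = 0.01),
                                                neighbor_rule = "cells"))
  expect_warning(dm <- shuffle_null_test(feats, n_shuffles = 60, seed = 5),
                 "60 shuffles|fewer than 100")
  dm2 <- suppressWarnings(shuffle_null_test(feats, n_shuffles = 60, seed = 5))
  expect_identical(dm$null_acc, dm2$null_acc)
  expect_true(all(dm$p_bin >= 1 / 61, na.rm = TRUE))
})

test_that("an injected class offset yields a significant corrected cluster", {
  freqs <- 10:24; frames <- seq(0, 0.25, by = 0.01)
  cells <- which(outer(freqs >= 14 & freqs <= 22,
                       frames >= 0.05 & frames < 0.2, "&"))
  set.seed(25)
  coh <- lapply(1:8, function(p)
    synthetic_coh_pair(freqs, frames, offset_cells = cells, offset = 0.35))
  feats <- build_features(coh, searchlight_grid(freqs, frames,
                                                neighbor_rule = "cells"))
  dm <- shuffle_null_test(feats, n_shuffles = 150, seed = 6)
  expect_gt(length(dm$clusters), 0)
  expect_lt(dm$clusters[[1]]$p_corrected, 0.05)
})
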