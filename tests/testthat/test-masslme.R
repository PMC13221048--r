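behav_random <- function(n_p, n_t, seed = 1) {
  set.seed(seed)
  data.frame(participant = rep(sprintf("P%02d", seq_len(n_p)), each = n_t),
             intensity = runif(n_p * n_t, 0, 10),
             valence = rnorm(n_p * n_t, 5),
             sniff_amplitude = exp(rnorm(n_p * n_t, 0, 0.25)),
             sniff_auc = exp(rnorm(n_p * n_t, 0, 0.25)))
}

test_that("rank inverse normal transform matches Blom scores", {
  x <- c(2.3, -1, 0.5, 9, 4)
  got <- rank_inverse_normal(x)
  expected <- qnorm((rank(x) - 3 / 8) / (5 + 1 / 4))
  expect_equal(got, expected)
  ## symmetric for a symmetric rank pattern, mean zero
  expect_equal(mean(rank_inverse_normal(c(1, 2, 3))), 0)
  ## invariant under monotone rescaling
  expect_equal(rank_inverse_normal(exp(x / 2)), got)
  expect_error(rank_inverse_normal(rep(1, 5)), "all-equal")
  expect_error(rank_inverse_normal(c(1, 2)), ">= 3")
})

test_that("fast profiled-REML engine reproduces lmerTest t statistics", {
  b <- behav_random(8, 30, seed = 42)
  n <- nrow(b)
  group <- factor(b$participant)
  set.seed(43)
  Y <- sapply(c(0, 0.3, 1, 3), function(tau)
    0.02 * b$intensity + rnorm(8, 0, tau)[as.integer(group)] + rnorm(n))
  pow <- array(Y, dim = c(n, 2, 2))
  m_gls <- fit_lme_map(pow, b, engine = "gls")
  m_lmer <- suppressMessages(fit_lme_map(pow, b, engine = "lmer"))
  expect_equal(as.vector(m_gls$t), as.vector(m_lmer$t), tolerance = 0.02)
  expect_equal(as.vector(m_gls$beta), as.vector(m_lmer$beta),
               tolerance = 0.02)
})

test_that("degenerate designs are rejected", {
  b <- behav_random(4, 10)
  pow <- array(rnorm(40 * 2 * 2), c(40, 2, 2))
  b$intensity <- 5
  expect_error(fit_lme_map(pow, b), "zero variance")
  b1 <- behav_random(1, 10)
  expect_error(fit_lme_map(array(rnorm(10 * 4), c(10, 2, 2)), b1),
               "2 participants")
})

test_that("voxel p-values are calibrated under a within-participant null", {
  b <- behav_random(6, 40, seed = 7)
  set.seed(8)
  pow <- array(abs(rnorm(240 * 6 * 10, 2)), c(240, 6, 10))
  sm <- fit_lme_map(pow, b, engine = "gls")
  frac <- mean(sm$p < 0.05)
  ## 60 weakly dependent cells; generous binomial-style margin
  expect_lt(frac, 0.15)
  expect_gte(frac, 0)
})

test_that("wcm_test obeys the permutation p floor and warns when coarse", {
  mk_map <- function(t) structure(list(
    t = t, p = 2 * pnorm(-abs(t)), df = 100,
    freqs = seq_len(nrow(t)), frames = seq_len(ncol(t))), class = "stat_map")
  set.seed(1)
  obs <- mk_map(matrix(rnorm(20, 0, 1) + 5, 4, 5))  # one huge blob
  perms <- replicate(150, mk_map(matrix(rnorm(20), 4, 5)), simplify = FALSE)
  expect_warning(cr <- wcm_test(obs, perms[1:99]), "100 permutations")
  cr <- wcm_test(obs, perms)
  expect_equal(cr$clusters[[1]]$p_corrected, 1 / 151)
  expect_true(all(vapply(cr$clusters, `[[`, 0, "p_corrected") >= 1 / 151))
  expect_error(wcm_test(obs, list()), "at least one permutation")
})

test_that("permuting within participant preserves participant marginals", {
  b <- behav_random(5, 12)
  g <- factor(b$participant)
  set.seed(3)
  perm <- olfosc:::permute_within(b$intensity, g)
  for (p in levels(g))
    expect_equal(sort(perm[g == p]), sort(b$intensity[g == p]))
  expect_false(identical(perm, b$intensity))
})

test_that("larger injected effects never shrink the top cluster mass", {
  freqs <- seq(8, 30, by = 3)
  masses <- sapply(c(0.6, 1.2, 2.4), function(amp) {
    cfg <- sim_config(n_participants = 5, n_trials = 30, fs = 64,
                      epoch = c(-0.5, 2.5), seed = 77,
                      effect_spec = list(power_effect("OB", c(12, 25),
                                                      c(0.6, 1.6), amp, 0.25)))
    d <- generate_dataset(cfg)
    pow <- do.call(olfosc:::abind3, lapply(d$trials, function(ts)
      superlet_transform(ts, freqs, region = "OB", frame_rate = 4)$power))
    sm <- fit_lme_map(pow, d$behavior, engine = "gls")
    cl <- olfosc:::find_clusters(sm$t, sm$p)
    if (length(cl)) cl[[1]]$mass else 0
  })
  expect_true(all(diff(masses) >= 0))
})

test_that("restricted-window rerun masks frames without changing machinery", {
  b <- behav_random(4, 20, seed = 9)
  set.seed(10)
  pow <- array(abs(rnorm(80 * 3 * 8, 2)), c(80, 3, 8))
  cr <- suppressWarnings(
    lme_cluster_test(pow, b, n_perm = 30, seed = 1, freqs = 1:3,
                     frames = seq(0, 0.7, by = 0.1),
                     frame_mask = c(rep(TRUE, 4), rep(FALSE, 4))))
  expect_equal(length(cr$observed$frames), 4)
  expect_equal(dim(cr$observed$t), c(3, 4))
})
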