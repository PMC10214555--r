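test_that("model assembly fixes the reference and counts basic parameters", {
  net <- load_gtps_fixture()
  model <- build_model(net)
  expect_equal(model$K, 5L)
  expect_equal(model$reference, "CSI-U")
  expect_false("CSI-U" %in% model$free)

  # automatic outcome scale: the widest contrast bound (Begkas 2020)
  expect_equal(model$prior$scale, 5.46 + 1.96 * sqrt(0.505^2 / 12 + 0.691^2 / 12))
  expect_equal(model$prior$sigma_d, 15 * model$prior$scale)
  expect_equal(model$prior$tau_max, 5 * model$prior$scale)

  single <- build_model(build_network(
    two_arm_study("S1", "A", 1, 0.5, 10, "B", 2, 0.5, 10), reference = "A"))
  expect_equal(single$K, 1L)
  expect_equal(length(single$studies), 1L)
  expect_equal(single$studies[["S1"]]$y, 1)
})

test_that("a three-arm study yields correlated baseline contrasts", {
  arms <- rbind(arm("S1", "A", 20, 5.0, 2.0), arm("S1", "B", 20, 4.0, 1.5),
                arm("S1", "C", 20, 3.0, 1.0),
                two_arm_study("S2", "A", 5, 2, 30, "B", 4, 2, 30))
  model <- build_model(build_network(arms, reference = "A"))
  s1 <- model$studies[["S1"]]
  expect_equal(length(s1$y), 2L)
  expect_equal(s1$y, c(-1, -2))
  # likelihood covariance: shared baseline arm variance off the diagonal
  expect_equal(s1$V[1L, 2L], 2.0^2 / 20)
  expect_equal(diag(s1$V), c(1.5^2 / 20 + 2^2 / 20, 1^2 / 20 + 2^2 / 20))
  # random-effects structure: unit-tau covariance (I + J)/2 -> off-diag 1/2
  prep <- vasnma:::prepare_sampler(model)
  expect_equal(length(prep$multi), 1L)
  expect_equal(prep$multi[[1L]]$P, matrix(c(1, 0.5, 0.5, 1), 2L))
  expect_equal(prep$nu, 3L)
})

test_that("retained-draw bookkeeping matches the settings", {
  s <- mcmc_settings()
  expect_equal(s$retained, 3000L)
  expect_equal(s$n_chains * s$retained, 12000L)
  expect_equal(desk_settings()$retained, 1000L)
  expect_error(mcmc_settings(n_iter = 100, burn_in = 100), "burn_in")
})

test_that("sampling is bit-reproducible under a fixed seed", {
  net <- build_network(rbind(
    two_arm_study("S1", "A", 1.0, 1.0, 20, "B", 2.0, 1.0, 20),
    two_arm_study("S2", "A", 1.2, 1.0, 20, "B", 1.9, 1.1, 20)), reference = "A")
  model <- build_model(net)
  s1 <- sample_posterior(model, tiny_settings(seed = 99))
  s2 <- sample_posterior(model, tiny_settings(seed = 99))
  expect_identical(s1$chains, s2$chains)
  s3 <- sample_posterior(model, tiny_settings(seed = 100))
  expect_false(identical(s1$chains, s3$chains))
  expect_equal(nrow(s1$chains[[1L]]), tiny_settings()$retained)
  expect_true(all(vapply(s1$chains, function(ch) all(ch[, "tau"] >= 0), TRUE)))
})

test_that("posterior recovers the truth on a simulated two-treatment network", {
  design <- simulation_design(
    treatments = c("A", "B"), d_star = c(A = 0, B = 1), tau_star = 0.5,
    studies = replicate(20, list(arms = c("A", "B"), n = 50), simplify = FALSE),
    seed = 31)
  arms <- simulate_network(design)
  samples <- sample_posterior(build_model(build_network(arms, reference = "A")),
                              tiny_settings(seed = 8))
  d <- relative_effect_draws(samples, "B", "A")
  expect_lt(abs(mean(d) - 1) / stats::sd(d), 3)
})

test_that("the league table summarizes per-draw contrasts", {
  eff <- matrix(c(1, 2, 3, 4), ncol = 1)
  lg <- league_table(fake_samples(eff, c("A", "B"), "A"))
  # hand-computed order statistics of the 4 draws
  expect_equal(lg$median["A", "B"], 2.5)
  expect_equal(lg$lower["A", "B"], 1.075)
  expect_equal(lg$upper["A", "B"], 3.925)
  expect_equal(lg$median["B", "A"], -2.5)
  expect_equal(diag(lg$median), c(0, 0), ignore_attr = TRUE)
})

test_that("league antisymmetry and draw-wise consistency hold on the fixture", {
  net <- load_gtps_fixture()
  samples <- sample_posterior(build_model(net), tiny_settings(seed = 2))
  lg <- league_table(samples)
  expect_equal(lg$median, -t(lg$median), tolerance = 1e-12)
  expect_equal(lg$lower, -t(lg$upper), tolerance = 1e-12)
  expect_equal(max(abs(diag(lg$median))), 0)

  # consistency identity: d(A->C) = d(A->B) + d(B->C) per draw
  trts <- samples$treatments
  for (trio in list(c("CSI-B", "ESWT", "PRP-U"), c("EX", "CSI-U", "UC"))) {
    ab <- relative_effect_draws(samples, trio[2L], trio[1L])
    bc <- relative_effect_draws(samples, trio[3L], trio[2L])
    ac <- relative_effect_draws(samples, trio[3L], trio[1L])
    expect_equal(ac, ab + bc, tolerance = 1e-12)
  }
})

test_that("tau_summary reports equal-tail quantiles", {
  s <- fake_samples(matrix(0, 5, 1), c("A", "B"), "A")
  s$chains[[1L]][, "tau"] <- c(0.1, 0.2, 0.3, 0.4, 0.5)
  expect_equal(tau_summary(s),
               c(median = 0.3, lower = 0.11, upper = 0.49))
  s$chains[[1L]][, "tau"] <- rep(0.7, 5)
  expect_equal(tau_summary(s), c(median = 0.7, lower = 0.7, upper = 0.7))
})

test_that("with essentially no data the heterogeneity posterior follows its prior", {
  # one tiny study with enormous within-arm SD: the likelihood is flat
  arms <- two_arm_study("S1", "A", 0, 1000, 2, "B", 0, 1000, 2)
  model <- build_model(build_network(arms, reference = "A"))
  samples <- sample_posterior(model, mcmc_settings(n_chains = 2, n_iter = 6000,
                                                   burn_in = 1000, thin = 5,
                                                   seed = 4))
  tau <- unlist(lapply(samples$chains, function(ch) ch[, "tau"]))
  u <- model$prior$tau_max
  expect_gt(mean(tau) / u, 0.3)
  expect_lt(mean(tau) / u, 0.7)
})

test_that("the fitted MD is reference-invariant up to Monte Carlo error", {
  net <- load_gtps_fixture()
  settings <- mcmc_settings(n_chains = 4, n_iter = 3000, burn_in = 500,
                            thin = 2, seed = 5)
  fit_ref <- sample_posterior(build_model(net), settings)
  net2 <- load_gtps_fixture(reference = "EX")
  fit_alt <- sample_posterior(build_model(net2), settings)
  md_ref <- stats::median(relative_effect_draws(fit_ref, "ESWT", "EX"))
  md_alt <- stats::median(relative_effect_draws(fit_alt, "ESWT", "EX"))
  expect_lt(abs(md_ref - md_alt), 0.25)
})

test_that("two-treatment networks reduce to the pairwise estimate", {
  design <- simulation_design(
    treatments = c("A", "B"), d_star = c(A = 0, B = -2), tau_star = 0.3,
    studies = replicate(20, list(arms = c("A", "B"), n = 100), simplify = FALSE),
    seed = 12)
  arms <- simulate_network(design)
  net <- build_network(arms, reference = "A")
  dl <- pairwise_meta(net, c("B", "A"))
  samples <- sample_posterior(build_model(net), tiny_settings(seed = 3))
  nma_md <- stats::median(relative_effect_draws(samples, "B", "A"))
  expect_lt(abs(nma_md - dl$pooled_md), 0.15)
})
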