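test_that("compute_contrast gives the mean difference and its variance", {
  st <- two_arm_study("Heaver2021", "ESWT", 4.0, 2.5, 52, "CSI-U", 4.82, 2.65, 52)
  ct <- compute_contrast(st[1L, ], st[2L, ])
  expect_equal(ct$y, -0.82)
  expect_equal(ct$v, 2.5^2 / 52 + 2.65^2 / 52)
  expect_equal(ct$pair, c("ESWT", "CSI-U"))

  # identical arms: null contrast with v = 2 sd^2 / n
  same <- two_arm_study("S", "A", 3, 1.2, 30, "B", 3, 1.2, 30)
  ct0 <- compute_contrast(same[1L, ], same[2L, ])
  expect_equal(ct0$y, 0)
  expect_equal(ct0$v, 2 * 1.2^2 / 30)

  # transcribed two-arm trial, direct arithmetic
  bg <- two_arm_study("Begkas2020", "PRP-U", 1.52, 0.505, 12, "CSI-U", 6.98, 0.691, 12)
  ctb <- compute_contrast(bg[1L, ], bg[2L, ])
  expect_equal(ctb$y, -5.46)
  expect_equal(ctb$v, 0.0610, tolerance = 1e-3)

  expect_error(compute_contrast(st[1L, ], bg[2L, ]), "different studies")
  mixed <- rbind(arm("S", "A", 10, 1, 0.5, "rest"),
                 arm("S", "B", 10, 2, 0.5, "activity"))
  expect_error(compute_contrast(mixed[1L, ], mixed[2L, ]),
               "outcome conditions")
})

test_that("reversing a contrast negates y and preserves v", {
  ct <- new_contrast("S", c("A", "B"), 1.3, 0.4)
  rev <- reverse_contrast(ct)
  expect_equal(rev$y, -1.3)
  expect_equal(rev$v, 0.4)
  expect_equal(rev$pair, c("B", "A"))
})

test_that("within-study merging is fixed-effect inverse-variance", {
  rest <- new_contrast("Brinks2011", c("CSI-U", "UC"), -0.2, 0.1923)
  act <- new_contrast("Brinks2011", c("CSI-U", "UC"), -0.4, 0.2708)
  merged <- pool_within_study(list(rest, act))
  expect_equal(merged$y, -0.28, tolerance = 0.02)
  expect_equal(merged$v, 1 / (1 / 0.1923 + 1 / 0.2708))

  expect_identical(pool_within_study(list(rest)), rest)
  twin <- pool_within_study(list(rest, rest))
  expect_equal(twin$y, rest$y)
  expect_equal(twin$v, rest$v / 2)
  expect_error(pool_within_study(list()), "no contrasts")
  expect_error(pool_within_study(list(rest, new_contrast("Other", c("CSI-U", "UC"), 0, 1))),
               "one study")
})

test_that("DL pooling agrees with brute-force evaluation for k <= 3", {
  set.seed(11)
  for (k in 1:3) {
    for (rep in 1:25) {
      y <- stats::rnorm(k, sd = 3)
      v <- stats::runif(k, 0.05, 2)
      cts <- lapply(seq_len(k), function(i)
        new_contrast(paste0("S", i), c("A", "B"), y[i], v[i]))
      got <- pool_dersimonian_laird(cts)
      want <- dl_oracle(y, v)
      for (f in names(want)) {
        expect_equal(got[[f]], want[[f]], tolerance = 1e-12, label = f)
      }
    }
  }
})

test_that("DL pooling agrees with metafor's DL estimator", {
  set.seed(23)
  for (k in c(2, 3, 6)) {
    y <- stats::rnorm(k, sd = 2)
    v <- stats::runif(k, 0.05, 1.5)
    got <- pool_dersimonian_laird(lapply(seq_len(k), function(i)
      new_contrast(paste0("S", i), c("A", "B"), y[i], v[i])))
    ref <- metafor::rma(yi = y, vi = v, method = "DL")
    expect_equal(got$pooled_md, as.numeric(ref$b), tolerance = 1e-10)
    expect_equal(got$se, ref$se, tolerance = 1e-10)
    expect_equal(got$tau2, ref$tau2, tolerance = 1e-10)
    expect_equal(got$Q, ref$QE, tolerance = 1e-10)
    expect_equal(100 * got$i2, ref$I2, tolerance = 1e-8)
  }
})

test_that("single-study pooling degenerates to the study estimate", {
  ct <- new_contrast("S", c("A", "B"), -0.9, 0.6573)
  res <- pool_dersimonian_laird(list(ct))
  expect_equal(res$pooled_md, -0.9)
  expect_equal(res$se, sqrt(0.6573))
  expect_equal(res$tau2, 0)
  expect_equal(res$Q, 0)
  expect_equal(res$df, 0L)
})

test_that("identical studies pool without heterogeneity", {
  cts <- lapply(1:4, function(i) new_contrast(paste0("S", i), c("A", "B"), 1.7, 0.3))
  res <- pool_dersimonian_laird(cts)
  expect_equal(res$Q, 0)
  expect_equal(res$tau2, 0)
  expect_equal(res$i2, 0)
  expect_equal(res$pooled_md, 1.7)
})

test_that("pooling is antisymmetric under pair reversal", {
  set.seed(5)
  cts <- lapply(1:4, function(i)
    new_contrast(paste0("S", i), c("A", "B"), stats::rnorm(1), stats::runif(1, 0.1, 1)))
  fwd <- pool_dersimonian_laird(cts)
  bwd <- pool_dersimonian_laird(lapply(cts, reverse_contrast))
  expect_equal(bwd$pooled_md, -fwd$pooled_md)
  expect_equal(bwd$ci_low, -fwd$ci_high)
  expect_equal(bwd$ci_high, -fwd$ci_low)
  expect_equal(bwd$Q, fwd$Q)
  expect_equal(bwd$tau2, fwd$tau2)
  expect_equal(bwd$i2, fwd$i2)
})

test_that("extra evidence tightens the pooled SE unless it adds heterogeneity", {
  # Duplicating a contrast adds information but can also inflate the
  # moment estimate of tau^2 (it perturbs Q); the SE is guaranteed not to
  # increase whenever tau^2 does not.
  set.seed(9)
  saw_tau_drop <- FALSE
  for (rep in 1:40) {
    k <- sample(2:5, 1)
    cts <- lapply(seq_len(k), function(i)
      new_contrast(paste0("S", i), c("A", "B"), stats::rnorm(1, sd = 2),
                   stats::runif(1, 0.05, 1)))
    base <- pool_dersimonian_laird(cts)
    dup <- pool_dersimonian_laird(c(cts, list(
      new_contrast("Sdup", c("A", "B"), cts[[1L]]$y, cts[[1L]]$v))))
    if (dup$tau2 <= base$tau2) {
      saw_tau_drop <- TRUE
      expect_lte(dup$se, base$se + 1e-12)
    }
    expect_true(base$i2 >= 0 && base$i2 < 1)
    expect_true(dup$i2 >= 0 && dup$i2 < 1)
  }
  expect_true(saw_tau_drop)
})

test_that("homogeneous pooling reduces to the fixed-effect closed form", {
  # k = 2 with Q below its degrees of freedom: tau^2 truncates to 0 and
  # the estimate is the inverse-variance fixed-effect combination.
  ct1 <- new_contrast("S1", c("A", "B"), 1.00, 0.50)
  ct2 <- new_contrast("S2", c("A", "B"), 1.20, 0.40)
  res <- pool_dersimonian_laird(list(ct1, ct2))
  w <- c(1 / 0.5, 1 / 0.4)
  expect_lte(res$Q, 1)
  expect_equal(res$tau2, 0)
  expect_equal(res$pooled_md, sum(w * c(1.0, 1.2)) / sum(w))
  expect_equal(res$se, 1 / sqrt(sum(w)))
})

test_that("fixture pairwise analyses reproduce the published estimates", {
  net <- load_gtps_fixture()

  heaver <- pairwise_meta(net, c("ESWT", "CSI-U"))
  expect_equal(round(c(heaver$pooled_md, heaver$ci_low, heaver$ci_high), 2),
               c(-0.82, -1.81, 0.17))

  mitchell <- pairwise_meta(net, c("CSI-U", "CSI-B"))
  expect_equal(round(c(mitchell$pooled_md, mitchell$ci_low, mitchell$ci_high), 2),
               c(-0.90, -2.49, 0.69))

  brinks <- pairwise_meta(net, c("CSI-U", "UC"))
  expect_equal(brinks$k, 1L)  # the two outcome rows merge into one contrast
  expect_equal(round(c(brinks$pooled_md, brinks$ci_low, brinks$ci_high), 2),
               c(-0.28, -0.94, 0.37))

  eswt <- pairwise_meta(net, c("ESWT", "EX"))
  expect_equal(eswt$k, 3L)
  expect_lt(abs(eswt$pooled_md - (-3.16)), 0.03)
  expect_equal(eswt$df, 2L)
})

test_that("pairwise_all orients edges as in the source trials", {
  net <- load_gtps_fixture()
  pw <- pairwise_all(net)
  expect_setequal(names(pw),
                  c("PRP-U vs CSI-U", "ESWT vs EX", "ESWT vs CSI-U",
                    "CSI-U vs CSI-B", "CSI-U vs UC"))
  expect_error(pairwise_meta(net, c("PRP-U", "EX")), "no study")
})
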