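# pairwise mismatch rate, degree classification, sex call, sex-bias Z

test_that("pairwise mismatch rate counts mismatches over the joint overlap", {
  gm <- make_gm(rbind(c(0L, 1L, 0L, 1L), c(0L, 1L, 1L, 1L)))
  est <- pairwise_mismatch_rate(gm, "I1", "I2", min_overlap = 1)
  expect_equal(est$rate, 0.25)
  expect_equal(est$n_overlap, 4)

  est0 <- pairwise_mismatch_rate(gm, "I1", "I1", min_overlap = 1)
  expect_equal(est0$rate, 0)

  # symmetry
  est_ba <- pairwise_mismatch_rate(gm, "I2", "I1", min_overlap = 1)
  expect_equal(est_ba$rate, est$rate)
  expect_equal(est_ba$pair, est$pair)

  # missing sites drop out of the overlap
  gm2 <- make_gm(rbind(c(0L, NA, 0L, 1L), c(0L, 1L, NA, 1L)))
  expect_equal(pairwise_mismatch_rate(gm2, "I1", "I2", min_overlap = 1)$n_overlap, 2)
  expect_error(pairwise_mismatch_rate(gm2, "I1", "I2", min_overlap = 10),
               class = "dk_insufficient_data_error")
})

test_that("unrelated-pair PMR matches the 2p(1-p) expectation", {
  set.seed(7)
  n <- 10000
  a <- rbinom(n, 1, 0.5)
  b <- rbinom(n, 1, 0.5)
  gm <- make_gm(rbind(a, b), ids = c("A", "B"))
  est <- pairwise_mismatch_rate(gm, "A", "B", min_overlap = 100)
  expect_within_3se(est$rate, 0.5, sqrt(0.25 / n), "unrelated PMR at p = 0.5")
})

test_that("baseline_rate is a robust median over unrelated pairs", {
  mk <- function(r, n = 5e4) structure(
    list(pair = paste0("p", r), ids = c("x", "y"), rate = r, n_overlap = n,
         se = sqrt(r * (1 - r) / n)), class = "mismatch_estimate")
  ests <- lapply(c(0.24, 0.25, 0.26), mk)
  expect_equal(baseline_rate(ests)$p0, 0.25)

  # one clearly related (near-identical) pair among ten unrelated
  ests <- c(lapply(seq(0.245, 0.254, by = 0.001), mk), list(mk(0.13)))
  b <- baseline_rate(ests)
  expect_equal(b$p0, stats::median(seq(0.245, 0.254, by = 0.001)))
  expect_equal(b$n_pairs, 10)

  expect_error(baseline_rate(ests[1:2]), class = "dk_insufficient_data_error")
})

test_that("degree posterior concentrates on the nearest class mean", {
  p0 <- 0.25
  mk <- function(r, se) structure(
    list(pair = "A|B", ids = c("A", "B"), rate = r, n_overlap = 1e5, se = se),
    class = "mismatch_estimate")
  # tiny SE at each class mean -> certainty for that class
  for (cls in seq_len(nrow(relatedness_classes()))) {
    mult <- relatedness_classes()$multiplier[cls]
    post <- degree_posterior(mk(p0 * mult, 1e-5), p0)
    expect_equal(unname(post[cls]), 1, tolerance = 1e-6)
    expect_equal(sum(post), 1)
  }
  # exact zero SE at a class mean
  post <- degree_posterior(mk(p0 / 2, 0), p0)
  expect_equal(unname(post["identical"]), 1)
  expect_error(degree_posterior(mk(0.2, 0), p0), class = "dk_degenerate_error")
  # posterior sums to 1 everywhere, including far tails
  for (r in c(0.01, 0.1, 0.22, 0.3, 0.9)) {
    expect_equal(sum(degree_posterior(mk(r, 0.003), p0)), 1)
  }
})

test_that("sex calls follow the coverage decision boxes", {
  # rates are relative to autosomal per-site coverage; construct read counts
  # that land exactly on the expectations
  call_for <- function(x_rate, y_rate) {
    cov_a <- 1000 / 1150639
    determine_sex(round(x_rate * cov_a * 49704), round(y_rate * cov_a * 2547),
                  1000)$call
  }
  expect_equal(call_for(1.0, 0.0), "XX")
  expect_equal(call_for(0.5, 0.5), "XY")
  expect_equal(call_for(0.75, 0.25), "unknown")
  expect_error(determine_sex(10, 10, 0), class = "dk_input_error")
  sc <- determine_sex(43, 1, 1000)
  expect_gt(sc$x_se, 0)
})

test_that("sex-bias Z reproduces the printed examples and is antisymmetric", {
  expect_equal(round(sex_bias_z(0.55, 0.011, 0.835, 0.099)$Z, 2), -2.86)
  expect_equal(sex_bias_z(0.4, 0.01, 0.4, 0.02)$Z, 0)
  expect_equal(round(sex_bias_z(0.49, 0.006, 0.436, 0.057)$Z, 2), 0.94)
  z1 <- sex_bias_z(0.55, 0.011, 0.835, 0.099)$Z
  z2 <- sex_bias_z(0.835, 0.099, 0.55, 0.011)$Z
  expect_equal(z1, -z2)
  expect_error(sex_bias_z(0.5, 0, 0.5, 0), class = "dk_degenerate_error")
})
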