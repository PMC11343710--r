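# chronological engine: joint density, marginal likelihoods, MCMC, evidence

models <- enumerate_candidate_pedigrees("HOC001", "APG001")
priors <- headline_priors()

test_that("joint density is the product of its terms and 0 when infeasible", {
  m1 <- models[[1]]
  state <- c("b:M" = -600, "b:HOC001" = -572, "b:S" = -570,
             "b:APG001" = -535, "a:HOC001" = 45, "a:APG001" = 30)
  d <- joint_density(m1, state, priors)
  # term-by-term recomputation oracle
  dt <- function(x, p) dnorm(x, p$mean, p$sd) /
    (pnorm(p$hi, p$mean, p$sd) - pnorm(p$lo, p$mean, p$sd))
  w <- priors$root_window
  expected <- 1 / (w[2] - w[1]) *
    dt(28, priors$maternal) * dt(30, priors$maternal) * dt(35, priors$maternal) *
    (1 / 10) * (1 / 10)
  expect_equal(d, expected)

  # burial outside its interval -> 0
  bad <- state; bad["a:HOC001"] <- 41  # burial -531 < -539? no: -572+41=-531 ok
  bad["b:HOC001"] <- -585              # burial -544 outside [-539,-519]
  expect_lt(joint_density(m1, bad, priors), d)
  expect_equal(joint_density(m1, bad, priors), 0)
  # maternal age outside support -> 0
  bad2 <- state; bad2["b:S"] <- -590   # mother's age 10 at S's birth
  expect_equal(joint_density(m1, bad2, priors), 0)
})

test_that("an impossible topology has zero marginal likelihood", {
  # father model with the son buried far later than the father can allow
  far <- chrono_priors(list(
    individual("HOC001", burial_lo = -650, burial_hi = -640, age_lo = 40, age_hi = 50),
    individual("APG001", burial_lo = -450, burial_hi = -440, age_lo = 25, age_hi = 35)))
  m6 <- models[[6]]
  expect_warning(ml <- marginal_likelihood(m6, far, n_draws = 1e4, seed = 1),
                 "no feasible draw")
  expect_equal(ml$M, 0)
})

test_that("marginal likelihood tends to 1 as intervals widen", {
  wide <- chrono_priors(list(
    individual("HOC001", burial_lo = -2000, burial_hi = 1500, age_lo = 0, age_hi = 110),
    individual("APG001", burial_lo = -2000, burial_hi = 1500, age_lo = 0, age_hi = 110)),
    root_window = c(-700, -500))
  ml <- marginal_likelihood(models[[1]], wide, n_draws = 1e4, seed = 2)
  expect_equal(ml$M, 1)
})

test_that("marginal likelihood is Monte-Carlo consistent across seeds", {
  m1 <- models[[1]]
  a <- marginal_likelihood(m1, priors, n_draws = 1e5, seed = 11)
  b <- marginal_likelihood(m1, priors, n_draws = 1e5, seed = 97)
  expect_within_3se(a$M, b$M, sqrt(a$mc_se^2 + b$mc_se^2) * 4 / 3,
                    "two-seed ML agreement")  # 4 combined SEs
  # determinism under a fixed seed
  expect_identical(a, marginal_likelihood(m1, priors, n_draws = 1e5, seed = 11))
})

test_that("the posterior collapses as the priors tend to point masses", {
  eps <- 0.01
  pt <- chrono_priors(list(
    individual("HOC001", burial_lo = -525 - eps, burial_hi = -525 + eps,
               age_lo = 45, age_hi = 45),
    individual("APG001", burial_lo = -495 - eps, burial_hi = -495 + eps,
               age_lo = 30, age_hi = 30)))
  # R-hat is meaningless on a near-degenerate box; silence its warning
  s <- suppressWarnings(
    sample_posterior(models[[6]], pt, n_chains = 2, n_iter = 500, seed = 5))
  # ages pinned exactly; birth years implied up to the vanishing width
  expect_equal(unique(s$draws[, "a:HOC001"]), 45)
  expect_lt(max(abs(s$draws[, "burial:APG001"] - (-495))), 2 * eps)
  expect_lt(max(abs(s$draws[, "b:HOC001"] - (-570))), 2 * eps)
})

test_that("posterior means respect their observation intervals", {
  s <- sample_posterior(models[[1]], priors, n_chains = 2, n_iter = 2000,
                        seed = 6)
  for (id in c("HOC001", "APG001")) {
    mu <- mean(s$draws[, paste0("burial:", id)])
    iv <- priors$individuals[[id]]$burial_interval
    expect_gte(mu, iv[["lo"]]); expect_lte(mu, iv[["hi"]])
  }
})

test_that("MCMC marginals agree with the rejection-sampling oracle", {
  # smaller-n version of the acceptance check, on a different model
  m2 <- models[[2]]
  s <- sample_posterior(m2, priors, n_chains = 2, n_iter = 4000, seed = 8, thin = 2)
  r <- rejection_sample(m2, priors, n = 4000, seed = 9)
  for (cn in colnames(r)) {
    D <- suppressWarnings(stats::ks.test(s$draws[, cn], r[, cn]))$statistic
    expect_lt(D, 0.08, label = sprintf("KS distance for %s", cn))
  }
})

test_that("mtDNA evidence follows matrilineal connectivity", {
  expect_equal(mtdna_evidence(models[[1]], TRUE, 0.01), 1)
  expect_equal(mtdna_evidence(models[[2]], TRUE, 0.01), 0.01)
  expect_equal(mtdna_evidence(models[[2]], FALSE, 0.01), 0.99)
  expect_equal(mtdna_evidence(models[[1]], FALSE, 0.01), 0)
  # f = 1 is uninformative: identical for all models
  evs <- vapply(models, mtdna_evidence, 0, observed_match = TRUE,
                f_background = 1)
  expect_equal(unique(evs), 1)
})

test_that("kinship evidence is the closed-form Normal likelihood", {
  est <- structure(list(pair = "A|B", ids = c("A", "B"), rate = 0.21875,
                        se = 0.005, n_overlap = 1e5),
                   class = "mismatch_estimate")
  p0 <- 0.25
  g1 <- kinship_evidence(models[[6]], est, p0)  # first degree: mean 0.1875
  g2 <- kinship_evidence(models[[1]], est, p0)  # second degree: mean 0.21875
  expect_equal(g2, dnorm(0.21875, 0.21875, 0.005))
  expect_equal(g1 / g2, dnorm(0.21875, 0.1875, 0.005) / dnorm(0.21875, 0.21875, 0.005))
  expect_gt(g2, g1)
})

test_that("evidence combination normalizes, renormalizes and ranks", {
  n <- length(models)
  flat <- lapply(seq_len(n), function(i) list(M = 0.5, mc_se = 0.01))
  post <- combine_evidence(models, flat, rep(2, n), rep(1, n))
  expect_equal(post$weight, rep(1 / n, n))
  expect_equal(sum(post$weight), 1)

  # zero one model out; others renormalize
  m0 <- flat; m0[[4]] <- list(M = 0, mc_se = 0)
  post <- combine_evidence(models, m0, rep(2, n), rep(1, n))
  expect_equal(post$weight[post$model_id == 4], 0)
  expect_equal(sum(post$weight), 1)
  expect_equal(max(post$bayes_factor), 1)

  # invariance under rescaling all evidences
  pa <- combine_evidence(models, flat, rep(2, n), rep(0.3, n))
  pb <- combine_evidence(models, flat, rep(200, n), rep(0.003, n))
  expect_equal(pa$weight, pb$weight)

  expect_error(combine_evidence(models, m0, rep(0, n), rep(1, n)),
               class = "dk_no_feasible_model_error")
})

test_that("with flat kinship/mtDNA evidence the ranking is pure chronology", {
  n <- length(models)
  marg <- lapply(models, function(m) suppressWarnings(
    marginal_likelihood(m, priors, n_draws = 2e4, seed = 30 + m$model_id)))
  post <- combine_evidence(models, marg, rep(1, n), rep(1, n))
  # the forward father/grandfather direction must beat the reversed one,
  # because APG001 is buried decades after HOC001
  w <- function(id) post$weight[post$model_id == id]
  expect_gt(w(6), w(9))
  expect_gt(w(2) + w(4), w(10) + w(11))
})

test_that("latent summaries nest credible intervals and handle point masses", {
  s <- sample_posterior(models[[1]], priors, n_chains = 2, n_iter = 1500, seed = 10)
  lat <- predict_latents(s, levels = c(0.5, 0.9))
  expect_true(all(lat$lo90 <= lat$lo50 & lat$lo50 <= lat$median &
                    lat$median <= lat$hi50 & lat$hi50 <= lat$hi90))
  # degenerate input: medians equal the point values
  s$draws <- matrix(rep(c(-600, 42), each = 10), ncol = 2,
                    dimnames = list(NULL, c("b:X", "a:X")))
  s$chain <- rep(1:2, each = 5)
  lat <- predict_latents(s)
  expect_equal(lat$median, c(-600, 42))
  expect_equal(lat$lo90, lat$hi90)
})
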