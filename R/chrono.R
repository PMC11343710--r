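# Chronological priors, per-model marginal likelihoods by Monte Carlo,
# random-walk Metropolis sampling of latent birth dates, and combination of
# chronological, autosomal-kinship and mitochondrial evidence into posterior
# model weights and Bayes factors.
#
# The generative model per pedigree: the chain root's birth year is uniform
# on a broad window shared by all models; every other dated node's birth is
# its chain parent's birth plus a maternal or paternal age-at-birth drawn
# from a truncated normal prior; each observed individual's age at death is
# uniform on their osteological interval; the burial year (birth + age) must
# fall in the archaeological interval (a pure indicator -- the interval-width
# constant is shared by all models and cancels in the posterior weights).

# truncated normal helpers ---------------------------------------------------

dtnorm <- function(x, mean, sd, lo, hi, log = FALSE) {
  z <- stats::pnorm(hi, mean, sd) - stats::pnorm(lo, mean, sd)
  d <- ifelse(x >= lo & x <= hi, stats::dnorm(x, mean, sd) / z, 0)
  if (log) log(d) else d
}

rtnorm <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

age_density <- function(x, link, priors, log = FALSE) {
  p <- if (link == "maternal") priors$maternal else priors$paternal
  dtnorm(x, p$mean, p$sd, p$lo, p$hi, log = log)
}

age_draw <- function(n, link, priors) {
  p <- if (link == "maternal") priors$maternal else priors$paternal
  rtnorm(n, p$mean, p$sd, p$lo, p$hi)
}

#' Chronological priors for a focal-pair analysis
#'
#' Bundles the parental age-at-birth priors with the per-individual burial
#' and age-at-death intervals, and fixes the shared root-birth window: it
#' spans from `min(burial lo) - 110 - 2 * 60` (the oldest any chain root two
#' paternal generations above an observed node could be born) to
#' `max(burial hi)`, and is identical for every model so that its width
#' cancels in the posterior weights.
#'
#' @param individuals list of [individual()] records for the observed nodes
#'   (the two focal individuals).
#' @param maternal,paternal truncated-normal age-at-birth parameters (lists
#'   with `mean`, `sd`, `lo`, `hi`, in years).
#' @param root_window optional explicit `c(lo, hi)` override.
#' @return object of class `chrono_priors`.
#' @export
chrono_priors <- function(individuals,
                          maternal = list(mean = 26, sd = 7, lo = 13, hi = 50),
                          paternal = list(mean = 32, sd = 9, lo = 15, hi = 60),
                          root_window = NULL) {
  dk_assert(length(individuals) >= 1, "at least one observed individual required")
  for (p in list(maternal, paternal)) {
    dk_assert(all(c("mean", "sd", "lo", "hi") %in% names(p)) &&
                p$lo > 0 && p$hi > p$lo && p$sd > 0,
              "age priors need positive, bounded support and positive spread")
  }
  blo <- vapply(individuals, function(x) x$burial_interval[["lo"]], 0)
  bhi <- vapply(individuals, function(x) x$burial_interval[["hi"]], 0)
  dk_assert(all(is.finite(blo)) && all(is.finite(bhi)),
            "burial intervals must be finite to anchor the root window")
  if (is.null(root_window)) {
    root_window <- c(min(blo) - 110 - 2 * paternal$hi, max(bhi))
  }
  dk_assert(root_window[2] > root_window[1], "root window must be non-empty")
  names(individuals) <- vapply(individuals, `[[`, "", "id")
  structure(list(maternal = maternal, paternal = paternal,
                 individuals = individuals, root_window = root_window),
            class = "chrono_priors")
}

# parameter layout for one model: birth year per chain node, age at death
# per observed node.  Returns character vector of names.
state_names <- function(model) {
  obs <- model$nodes$id[model$nodes$observed]
  c(paste0("b:", model$chain$node), paste0("a:", obs))
}

# precompiled index-based density over an unnamed state vector (sampler
# hot path); agrees with joint_density() on named states by construction
make_density <- function(model, priors) {
  nm <- state_names(model)
  chain <- model$chain
  root_i <- which(is.na(chain$parent))
  w <- priors$root_window
  link_rows <- which(!is.na(chain$parent))
  ci <- match(chain$node[link_rows], chain$node)
  pi <- match(chain$parent[link_rows], chain$node)
  lp <- lapply(chain$link[link_rows], function(l)
    if (l == "maternal") priors$maternal else priors$paternal)
  lz <- vapply(lp, function(p)
    stats::pnorm(p$hi, p$mean, p$sd) - stats::pnorm(p$lo, p$mean, p$sd), 0)
  obs <- model$nodes$id[model$nodes$observed]
  nb <- nrow(chain)
  ob <- match(obs, chain$node)
  oa <- nb + seq_along(obs)
  ints <- lapply(obs, function(id) {
    ind <- priors$individuals[[id]]
    c(ind$age_interval[["lo"]], ind$age_interval[["hi"]],
      ind$burial_interval[["lo"]], ind$burial_interval[["hi"]])
  })
  function(x) {
    if (x[root_i] < w[1] || x[root_i] > w[2]) return(0)
    dens <- 1 / (w[2] - w[1])
    for (k in seq_along(link_rows)) {
      age <- x[ci[k]] - x[pi[k]]
      p <- lp[[k]]
      if (age < p$lo || age > p$hi) return(0)
      dens <- dens * stats::dnorm(age, p$mean, p$sd) / lz[k]
    }
    for (k in seq_along(obs)) {
      a <- x[oa[k]]
      iv <- ints[[k]]
      if (a < iv[1] || a > iv[2]) return(0)
      if (iv[2] > iv[1]) dens <- dens / (iv[2] - iv[1])
      burial <- x[ob[k]] + a
      if (burial < iv[3] || burial > iv[4]) return(0)
    }
    dens
  }
}

#' Joint density of a latent chronological state
#'
#' Product of the root-window uniform density, the truncated-normal age
#' density of every chain link, the uniform age-at-death density of every
#' observed node, and the indicator that each observed node's burial year
#' (birth + age at death) falls inside its archaeological interval. Returns
#' 0 for any violated constraint.
#'
#' @param model a `pedigree_model`.
#' @param state named numeric vector: `b:<node>` birth years for every chain
#'   node and `a:<id>` ages at death for every observed node.
#' @param priors a [chrono_priors()].
#' @return a non-negative density value.
#' @export
joint_density <- function(model, state, priors) {
  nm <- state_names(model)
  dk_assert(all(nm %in% names(state)),
            "state does not match the model's parameter layout")
  dens <- 1
  w <- priors$root_window
  root <- model$chain$node[is.na(model$chain$parent)]
  b_root <- state[[paste0("b:", root)]]
  if (b_root < w[1] || b_root > w[2]) return(0)
  dens <- dens / (w[2] - w[1])
  for (i in seq_len(nrow(model$chain))) {
    if (is.na(model$chain$parent[i])) next
    b_child <- state[[paste0("b:", model$chain$node[i])]]
    b_parent <- state[[paste0("b:", model$chain$parent[i])]]
    d <- age_density(b_child - b_parent, model$chain$link[i], priors)
    if (d == 0) return(0)
    dens <- dens * d
  }
  for (id in model$nodes$id[model$nodes$observed]) {
    ind <- priors$individuals[[id]]
    dk_assert(!is.null(ind), sprintf("no priors for observed individual %s", id))
    a <- state[[paste0("a:", id)]]
    ai <- ind$age_interval
    if (a < ai[["lo"]] || a > ai[["hi"]]) return(0)
    if (ai[["hi"]] > ai[["lo"]]) dens <- dens / (ai[["hi"]] - ai[["lo"]])
    burial <- state[[paste0("b:", id)]] + a
    bi <- ind$burial_interval
    if (burial < bi[["lo"]] || burial > bi[["hi"]]) return(0)
  }
  dens
}

# vectorized generative prior draw: list of matrices (n x params) of birth
# years and ages, plus the burial-indicator vector
prior_predictive_draw <- function(model, priors, n) {
  chain <- model$chain
  b <- matrix(NA_real_, nrow = n, ncol = nrow(chain),
              dimnames = list(NULL, chain$node))
  w <- priors$root_window
  for (i in seq_len(nrow(chain))) {
    if (is.na(chain$parent[i])) {
      b[, i] <- stats::runif(n, w[1], w[2])
    } else {
      b[, i] <- b[, chain$parent[i]] + age_draw(n, chain$link[i], priors)
    }
  }
  obs <- model$nodes$id[model$nodes$observed]
  a <- matrix(NA_real_, nrow = n, ncol = length(obs),
              dimnames = list(NULL, obs))
  ok <- rep(TRUE, n)
  for (id in obs) {
    ind <- priors$individuals[[id]]
    ai <- ind$age_interval
    a[, id] <- if (ai[["hi"]] > ai[["lo"]])
      stats::runif(n, ai[["lo"]], ai[["hi"]]) else rep(ai[["lo"]], n)
    burial <- b[, id] + a[, id]
    bi <- ind$burial_interval
    ok <- ok & burial >= bi[["lo"]] & burial <= bi[["hi"]]
  }
  list(b = b, a = a, ok = ok)
}

#' Monte-Carlo marginal likelihood of one pedigree model
#'
#' Direct Monte-Carlo integration of the burial-date indicators over the
#' bounded generative prior: the estimate is the fraction of prior-predictive
#' draws whose implied burial years all fall in their archaeological
#' intervals. Unbiased, with a binomial Monte-Carlo standard error, and
#' tends to 1 as the observation intervals widen to cover the whole prior
#' predictive range.
#'
#' @param model a `pedigree_model`.
#' @param priors a [chrono_priors()].
#' @param n_draws number of draws (at least 1e4).
#' @param seed RNG seed.
#' @return list with `M` (estimate), `mc_se`, and `n_draws`. If no draw is
#'   feasible, `M = 0` with a warning.
#' @export
marginal_likelihood <- function(model, priors, n_draws = 1e5, seed = 1L) {
  dk_assert(n_draws >= 1e4, "n_draws must be at least 1e4")
  set.seed(seed)
  draw <- prior_predictive_draw(model, priors, n_draws)
  M <- mean(draw$ok)
  if (M == 0) {
    warning(sprintf("model %d ('%s'): no feasible draw among %g; M = 0",
                    model$model_id, model$label, n_draws))
    return(list(M = 0, mc_se = 0, n_draws = n_draws))
  }
  list(M = M, mc_se = sqrt(M * (1 - M) / n_draws), n_draws = n_draws)
}

#' Rejection sampler for the chronological posterior
#'
#' Draws from the generative prior and keeps states whose burial years land
#' inside the archaeological intervals — exact independent posterior draws,
#' used as the oracle the MCMC sampler is checked against.
#'
#' @param model a `pedigree_model`.
#' @param priors a [chrono_priors()].
#' @param n number of accepted draws wanted.
#' @param seed RNG seed.
#' @param max_batches give up after this many prior batches.
#' @return matrix of accepted states (columns per [state_names()]).
#' @export
rejection_sample <- function(model, priors, n = 1e4, seed = 1L,
                             max_batches = 2000) {
  set.seed(seed)
  out <- NULL
  batch <- max(1e4, n)
  for (i in seq_len(max_batches)) {
    d <- prior_predictive_draw(model, priors, batch)
    if (any(d$ok)) {
      acc <- cbind(d$b[d$ok, , drop = FALSE], d$a[d$ok, , drop = FALSE])
      out <- rbind(out, acc)
    }
    if (!is.null(out) && nrow(out) >= n) break
  }
  dk_assert(!is.null(out) && nrow(out) >= n,
            "rejection sampler could not reach the requested sample size",
            "dk_sampler_error")
  out <- out[seq_len(n), , drop = FALSE]
  colnames(out) <- c(paste0("b:", model$chain$node),
                     paste0("a:", model$nodes$id[model$nodes$observed]))
  out
}

# deterministic feasible starting state: walk the chain placing each birth
# as close as the link supports allow to the value implied by the midpoint
# of the node's burial/age intervals (latent nodes aim at the link mean).
# Falls back to prior rejection if the greedy state is infeasible.
feasible_init <- function(model, priors, dens, seed) {
  chain <- model$chain
  obs <- model$nodes$id[model$nodes$observed]
  w <- priors$root_window
  target <- function(id) {
    ind <- priors$individuals[[id]]
    mean(ind$burial_interval) - mean(ind$age_interval)
  }
  b <- stats::setNames(numeric(nrow(chain)), chain$node)
  for (i in seq_len(nrow(chain))) {
    nd <- chain$node[i]
    if (is.na(chain$parent[i])) {
      ideal <- if (nd %in% obs) target(nd) else mean(w)
      b[[nd]] <- min(max(ideal, w[1]), w[2])
    } else {
      p <- if (chain$link[i] == "maternal") priors$maternal else priors$paternal
      ideal <- if (nd %in% obs) target(nd) else b[[chain$parent[i]]] + p$mean
      b[[nd]] <- min(max(ideal, b[[chain$parent[i]]] + p$lo),
                     b[[chain$parent[i]]] + p$hi)
    }
  }
  a <- vapply(obs, function(id) {
    ind <- priors$individuals[[id]]
    min(max(mean(ind$burial_interval) - b[[id]], ind$age_interval[["lo"]]),
        ind$age_interval[["hi"]])
  }, 0)
  x <- c(unname(b), unname(a))
  if (dens(x) > 0) return(x)
  init <- rejection_sample(model, priors, n = 1, seed = seed)
  as.numeric(init[1, ])
}

#' Posterior sampling of latent birth dates by random-walk Metropolis
#'
#' Samples the latent state (birth years of the focal individuals and their
#' connecting relatives, ages at death) from the joint density, with
#' per-parameter proposal scales adapted during burn-in toward a 20-40%
#' acceptance rate. Split-chain R-hat is reported per parameter; values
#' above 1.05 trigger a warning, not an error.
#'
#' @param model a `pedigree_model` with positive marginal likelihood.
#' @param priors a [chrono_priors()].
#' @param n_chains number of chains (at least 2).
#' @param n_iter iterations per chain after burn-in.
#' @param seed RNG seed.
#' @param burn_frac burn-in fraction (of `n_iter`) prepended and discarded.
#' @param thin keep every `thin`-th iteration.
#' @return object of class `posterior_samples`: list with `draws` (matrix,
#'   including derived burial years `burial:<id>`), `chain` index vector,
#'   `rhat`, `accept_rate`, `seed`.
#' @export
sample_posterior <- function(model, priors, n_chains = 4L, n_iter = 2e4L,
                             seed = 1L, burn_frac = 0.25, thin = 1L) {
  dk_assert(n_chains >= 2, "at least 2 chains required")
  nm <- state_names(model)
  npar <- length(nm)
  nb <- nrow(model$chain)  # leading nb parameters are birth years
  dens <- make_density(model, priors)
  n_burn <- ceiling(n_iter * burn_frac)
  all_draws <- vector("list", n_chains)
  acc_rates <- numeric(n_chains)
  for (ch in seq_len(n_chains)) {
    set.seed(seed + 1000L * ch)
    x <- feasible_init(model, priors, dens, seed = seed + 1000L * ch)
    set.seed(seed + 1000L * ch + 1L)
    fx <- dens(x)
    dk_assert(fx > 0, "infeasible initial state", "dk_sampler_error")
    scale <- rep(5, npar)
    shift_scale <- 5
    shift_acc <- 0L
    keep <- matrix(NA_real_, nrow = floor(n_iter / thin), ncol = npar,
                   dimnames = list(NULL, nm))
    n_acc <- 0L; n_try <- 0L
    batch_acc <- integer(npar); batch_try <- 0L
    ki <- 0L
    for (it in seq_len(n_burn + n_iter)) {
      # one iteration = a Metropolis-within-Gibbs sweep over coordinates,
      # plus one joint translation of all birth years (the slow mode when
      # burial intervals are wide)
      for (j in seq_len(npar)) {
        prop <- x
        prop[j] <- prop[j] + stats::rnorm(1, 0, scale[j])
        fp <- dens(prop)
        if (fp > 0 && stats::runif(1) < fp / fx) {
          x <- prop; fx <- fp
          if (it > n_burn) n_acc <- n_acc + 1L
          batch_acc[j] <- batch_acc[j] + 1L
        }
      }
      prop <- x
      prop[seq_len(nb)] <- prop[seq_len(nb)] + stats::rnorm(1, 0, shift_scale)
      fp <- dens(prop)
      if (fp > 0 && stats::runif(1) < fp / fx) {
        x <- prop; fx <- fp
        if (it > n_burn) n_acc <- n_acc + 1L
        shift_acc <- shift_acc + 1L
      }
      batch_try <- batch_try + 1L
      if (it <= n_burn && batch_try == 25L) {
        rate <- batch_acc / batch_try
        scale[rate < 0.20] <- scale[rate < 0.20] * 0.7
        scale[rate > 0.40] <- scale[rate > 0.40] * 1.4
        if (shift_acc / batch_try < 0.20) shift_scale <- shift_scale * 0.7
        if (shift_acc / batch_try > 0.40) shift_scale <- shift_scale * 1.4
        batch_acc <- integer(npar); batch_try <- 0L; shift_acc <- 0L
      }
      if (it > n_burn) {
        n_try <- n_try + npar + 1L
        if ((it - n_burn) %% thin == 0) {
          ki <- ki + 1L
          keep[ki, ] <- x
        }
      }
    }
    all_draws[[ch]] <- keep[seq_len(ki), , drop = FALSE]
    acc_rates[ch] <- n_acc / n_try
  }
  if (all(acc_rates == 0)) {
    dk_error("zero acceptance after adaptation in every chain", "dk_sampler_error")
  }
  draws <- do.call(rbind, all_draws)
  chain <- rep(seq_len(n_chains), vapply(all_draws, nrow, 0L))
  # derived burial years for observed nodes
  for (id in model$nodes$id[model$nodes$observed]) {
    draws <- cbind(draws, draws[, paste0("b:", id)] + draws[, paste0("a:", id)])
    colnames(draws)[ncol(draws)] <- paste0("burial:", id)
  }
  rh <- apply(draws, 2, function(v) split_rhat(v, chain))
  if (any(rh > 1.05, na.rm = TRUE)) {
    warning(sprintf("R-hat above 1.05 for: %s",
                    paste(names(rh)[rh > 1.05], collapse = ", ")))
  }
  structure(list(draws = draws, chain = chain, rhat = rh,
                 accept_rate = acc_rates, seed = seed, model_id = model$model_id),
            class = "posterior_samples")
}

# split-chain potential scale reduction factor
split_rhat <- function(v, chain) {
  pieces <- list()
  for (ch in unique(chain)) {
    x <- v[chain == ch]
    h <- floor(length(x) / 2)
    pieces <- c(pieces, list(x[seq_len(h)], x[h + seq_len(h)]))
  }
  m <- length(pieces); n <- min(lengths(pieces))
  pieces <- lapply(pieces, function(x) x[seq_len(n)])
  means <- vapply(pieces, mean, 0)
  vars <- vapply(pieces, stats::var, 0)
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W == 0) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Posterior summaries for latent family members
#'
#' Per-parameter posterior median and central credible intervals — the
#' birth dates of the focal pair and of their unobserved relatives (e.g.
#' the latent mothers), their burial dates, and the implied maternal ages.
#'
#' @param samples a `posterior_samples` object.
#' @param levels credible-interval levels (default 50% and 90%).
#' @return data frame with one row per parameter: `median` and interval
#'   bounds per level.
#' @export
predict_latents <- function(samples, levels = c(0.5, 0.9)) {
  qs <- sort(unique(c(0.5, (1 - levels) / 2, 1 - (1 - levels) / 2)))
  out <- t(apply(samples$draws, 2, stats::quantile, probs = qs))
  df <- data.frame(parameter = rownames(out), median = out[, "50%"],
                   row.names = NULL, stringsAsFactors = FALSE)
  for (lv in levels) {
    df[[sprintf("lo%g", 100 * lv)]] <- out[, sprintf("%g%%", 100 * (1 - lv) / 2)]
    df[[sprintf("hi%g", 100 * lv)]] <- out[, sprintf("%g%%", 100 * (1 + lv) / 2)]
  }
  df
}

#' Mitochondrial haplotype evidence for one model
#'
#' If the pedigree joins the focal pair through an unbroken female line, a
#' haplotype match is certain; otherwise a match occurs only through cryptic
#' background sharing, with probability `f_background`.
#'
#' @param model a `pedigree_model`.
#' @param observed_match logical; do the two mtDNA labels match?
#' @param f_background background haplotype frequency in (0, 1].
#' @return the probability of the observation under the model.
#' @export
mtdna_evidence <- function(model, observed_match, f_background = 0.01) {
  dk_assert(f_background > 0 && f_background <= 1, "f_background must be in (0, 1]")
  p_match <- if (model$matrilineal_connected) 1 else f_background
  if (isTRUE(observed_match)) p_match else 1 - p_match
}

#' Autosomal kinship evidence for one model
#'
#' Normal density of the observed pairwise mismatch rate at the model's
#' expected rate `p0 * (1 - r/2)`, with the estimate's binomial SE.
#'
#' @param model a `pedigree_model`.
#' @param pmr_estimate a `mismatch_estimate` for the focal pair.
#' @param p0 unrelated baseline mismatch rate.
#' @return a density value.
#' @export
kinship_evidence <- function(model, pmr_estimate, p0) {
  stats::dnorm(pmr_estimate$rate, mean = p0 * (1 - model$r / 2),
               sd = pmr_estimate$se)
}

#' Combine chronological, kinship and mtDNA evidence into model weights
#'
#' Posterior weight `w_m` proportional to
#' `prior_m * M_m * G_m * T_m`, normalized over the catalogue; evidence
#' (Bayes) factors are reported relative to the maximum-weight model, whose
#' factor is 1.
#'
#' @param models list of `pedigree_model`s.
#' @param marginals list of [marginal_likelihood()] results (same order).
#' @param kinship_evs,mt_evs numeric vectors of [kinship_evidence()] and
#'   [mtdna_evidence()] values.
#' @param prior model prior vector (`NULL` for uniform); must sum to 1.
#' @return object of class `model_posterior`: a data frame with one row per
#'   model (`model_id`, `label`, `degree`, `matrilineal`, `prior`, `M`,
#'   `mc_se`, `G`, `T`, `weight`, `bayes_factor`), sorted by weight.
#' @export
combine_evidence <- function(models, marginals, kinship_evs, mt_evs,
                             prior = NULL) {
  n <- length(models)
  dk_assert(length(marginals) == n && length(kinship_evs) == n &&
              length(mt_evs) == n, "evidence vectors must match the model list")
  if (is.null(prior)) prior <- rep(1 / n, n)
  dk_assert(length(prior) == n && abs(sum(prior) - 1) < 1e-8,
            "model priors must sum to 1")
  M <- vapply(marginals, `[[`, 0, "M")
  mc_se <- vapply(marginals, `[[`, 0, "mc_se")
  ev <- M * kinship_evs * mt_evs
  w_un <- prior * ev
  if (all(w_un == 0)) {
    dk_error("no model has positive combined evidence", "dk_no_feasible_model_error")
  }
  w <- w_un / sum(w_un)
  top <- which.max(w)
  bf <- ev / ev[top]
  out <- data.frame(
    model_id = vapply(models, `[[`, 0, "model_id"),
    label = vapply(models, `[[`, "", "label"),
    degree = vapply(models, `[[`, 0L, "degree"),
    matrilineal = vapply(models, `[[`, NA, "matrilineal_connected"),
    prior = prior, M = M, mc_se = mc_se, G = kinship_evs, T = mt_evs,
    weight = w, bayes_factor = bf, stringsAsFactors = FALSE)
  out <- out[order(-out$weight), ]
  rownames(out) <- NULL
  class(out) <- c("model_posterior", "data.frame")
  out
}

#' @export
print.model_posterior <- function(x, ...) {
  cat("<model_posterior>\n")
  df <- as.data.frame(x)
  df$weight <- sprintf("%.4f", df$weight)
  df$bayes_factor <- sprintf("%.3g", df$bayes_factor)
  print(df[, c("model_id", "label", "degree", "matrilineal", "weight",
               "bayes_factor")], right = FALSE)
  invisible(x)
}
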