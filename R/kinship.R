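# Genotype-level kinship: pairwise mismatch rate on pseudo-haploid calls,
# Bayesian relatedness-degree classification, chromosomal sex determination,
# and the sex-biased-admixture Z statistic.

#' Relatedness classes
#'
#' The five classes used for pseudo-haploid kinship classification, their
#' relatedness coefficients r and expected mismatch multipliers `1 - r/2`:
#' an identical pair mismatches at half the unrelated baseline, a
#' first-degree pair at 3/4 of it, second degree 7/8, third degree 15/16.
#'
#' @return data frame with columns `class`, `r`, `multiplier`.
#' @export
relatedness_classes <- function() {
  data.frame(class = c("identical", "first", "second", "third", "unrelated"),
             r = c(1, 1/2, 1/4, 1/8, 0),
             multiplier = c(1/2, 3/4, 7/8, 15/16, 1),
             stringsAsFactors = FALSE)
}

#' Pairwise mismatch rate
#'
#' Fraction of SNPs, among those called in both individuals, at which the two
#' pseudo-haploid calls differ. Unrelated individuals mismatch at a baseline
#' p0 set by the panel's heterozygosity; relatives at `p0 * (1 - r/2)`.
#'
#' @param gm a [genotype_matrix()].
#' @param idA,idB individual ids present in `gm`.
#' @param min_overlap minimum number of jointly called SNPs.
#' @return object of class `mismatch_estimate`: list with `pair` (canonical
#'   id), `ids`, `rate`, `n_overlap` and binomial `se`.
#' @export
pairwise_mismatch_rate <- function(gm, idA, idB, min_overlap = 15000) {
  for (id in c(idA, idB)) {
    dk_assert(id %in% gm$individuals, sprintf("individual %s not in matrix", id),
              "dk_input_error")
  }
  a <- gm$calls[idA, ]
  b <- gm$calls[idB, ]
  ok <- !is.na(a) & !is.na(b)
  n <- sum(ok)
  if (n < min_overlap) {
    dk_error(sprintf("pair %s: only %d overlapping SNPs (< %d required)",
                     pair_id(idA, idB), n, min_overlap),
             "dk_insufficient_data_error")
  }
  r <- sum(a[ok] != b[ok]) / n
  structure(list(pair = pair_id(idA, idB), ids = c(idA, idB),
                 rate = r, n_overlap = n, se = sqrt(r * (1 - r) / n)),
            class = "mismatch_estimate")
}

#' @export
print.mismatch_estimate <- function(x, ...) {
  cat(sprintf("<mismatch_estimate> %s: r = %.4f +/- %.4f (n = %d)\n",
              x$pair, x$rate, x$se, x$n_overlap))
  invisible(x)
}

#' All pairwise mismatch rates of a cohort
#'
#' @param gm a [genotype_matrix()].
#' @param min_overlap minimum joint SNP count; pairs below it are dropped
#'   with a message rather than an error.
#' @return list of `mismatch_estimate` objects.
#' @export
all_pairwise_rates <- function(gm, min_overlap = 15000) {
  ids <- gm$individuals
  out <- list()
  for (i in seq_along(ids)[-length(ids)]) {
    for (j in (i + 1):length(ids)) {
      est <- tryCatch(pairwise_mismatch_rate(gm, ids[i], ids[j], min_overlap),
                      dk_insufficient_data_error = function(e) {
                        dk_log(conditionMessage(e)); NULL
                      })
      if (!is.null(est)) out[[est$pair]] <- est
    }
  }
  out
}

#' Unrelated-pair baseline mismatch rate
#'
#' Two-pass estimate of the cohort baseline p0: a provisional p0 (the median
#' rate over all pairs) is used to classify every pair with
#' [degree_posterior()]; p0 is then the median over pairs classified
#' unrelated. The median makes a handful of related pairs harmless.
#'
#' @param estimates list of `mismatch_estimate` objects (at least 3).
#' @return list with `p0` and `se` (median standard error, 1.2533 * mean-SE
#'   scaled by the retained pair count).
#' @export
baseline_rate <- function(estimates) {
  dk_assert(length(estimates) >= 3, "need at least 3 pairs to calibrate a baseline",
            "dk_insufficient_data_error")
  rates <- vapply(estimates, `[[`, 0, "rate")
  prov <- stats::median(rates)
  # first pass: drop only pairs that classify as second degree or closer —
  # third-degree vs unrelated is within the natural spread of cohort
  # baselines, and excluding it would bias the median upward
  unrel <- vapply(estimates, function(e) {
    post <- degree_posterior(e, prov)
    !(names(which.max(post)) %in% c("identical", "first", "second"))
  }, NA)
  if (!any(unrel)) {
    dk_error("every pair classifies as related; cannot calibrate a baseline",
             "dk_calibration_error")
  }
  kept <- rates[unrel]
  p0 <- stats::median(kept)
  se <- 1.2533 * stats::median(vapply(estimates[unrel], `[[`, 0, "se")) /
    sqrt(length(kept))
  list(p0 = p0, se = se, n_pairs = length(kept))
}

#' Bayesian relatedness-degree posterior
#'
#' Posterior probability of each relatedness class for one pair: a Normal
#' likelihood for the observed mismatch rate centred on each class mean
#' `p0 * (1 - r/2)` with the estimate's binomial SE, times a class prior
#' (uniform by default), normalized.
#'
#' @param est a `mismatch_estimate` from [pairwise_mismatch_rate()].
#' @param p0 unrelated baseline rate, in (0, 1).
#' @param prior optional vector of 5 prior weights (identical, first,
#'   second, third, unrelated).
#' @return named numeric vector of 5 posterior probabilities summing to 1.
#' @export
degree_posterior <- function(est, p0, prior = NULL) {
  dk_assert(p0 > 0 && p0 < 1, "p0 must lie in (0, 1)")
  cls <- relatedness_classes()
  if (is.null(prior)) prior <- rep(1 / nrow(cls), nrow(cls))
  dk_assert(length(prior) == nrow(cls) && all(prior >= 0),
            "prior must be 5 non-negative weights")
  mu <- p0 * cls$multiplier
  if (est$se <= 0) {
    hit <- abs(est$rate - mu) < 1e-12
    if (!any(hit)) {
      dk_error("zero SE with a rate off every class mean: degenerate likelihood",
               "dk_degenerate_error")
    }
    lik <- as.numeric(hit)
  } else {
    lik <- stats::dnorm(est$rate, mean = mu, sd = est$se)
    if (all(lik == 0)) {
      # far tails underflow; work on log scale
      ll <- stats::dnorm(est$rate, mean = mu, sd = est$se, log = TRUE)
      lik <- exp(ll - max(ll))
    }
  }
  w <- lik * prior
  p <- w / sum(w)
  names(p) <- cls$class
  p
}

#' Chromosomal sex determination from relative coverage
#'
#' Normalizes X- and Y-chromosome coverage by autosomal coverage. Females are
#' expected at rates (x, y) = (1, 0), males at (0.5, 0.5). The call uses
#' symmetric acceptance boxes around those expectations: XX iff
#' `x > 0.8 & y < 0.1`; XY iff `0.35 < x < 0.65 & y > 0.3`; otherwise
#' `unknown`. Error bars are delta-method SEs for the Poisson read-count
#' ratios.
#'
#' @param reads_x,reads_y,reads_autosomal read counts on X, Y, autosomes.
#' @param snps_x,snps_y,snps_autosomal target site counts used to convert
#'   reads to per-site coverage.
#' @return object of class `sex_call`: list with `x_rate`, `y_rate`,
#'   `x_se`, `y_se` and `call`.
#' @export
determine_sex <- function(reads_x, reads_y, reads_autosomal,
                          snps_x = 49704, snps_y = 2547,
                          snps_autosomal = 1150639) {
  if (reads_autosomal <= 0) {
    dk_error("zero autosomal reads: relative coverage undefined", "dk_input_error")
  }
  cov_a <- reads_autosomal / snps_autosomal
  x_rate <- (reads_x / snps_x) / cov_a
  y_rate <- (reads_y / snps_y) / cov_a
  x_se <- if (reads_x > 0) x_rate * sqrt(1 / reads_x + 1 / reads_autosomal) else
    (1 / snps_x) / cov_a
  y_se <- if (reads_y > 0) y_rate * sqrt(1 / reads_y + 1 / reads_autosomal) else
    (1 / snps_y) / cov_a
  call <- if (x_rate > 0.8 && y_rate < 0.1) "XX"
  else if (x_rate > 0.35 && x_rate < 0.65 && y_rate > 0.3) "XY"
  else "unknown"
  structure(list(x_rate = x_rate, y_rate = y_rate, x_se = x_se, y_se = y_se,
                 call = call),
            class = "sex_call")
}

#' @export
print.sex_call <- function(x, ...) {
  cat(sprintf("<sex_call> x = %.3f +/- %.3f, y = %.3f +/- %.3f -> %s\n",
              x$x_rate, x$x_se, x$y_rate, x$y_se, x$call))
  invisible(x)
}

#' Sex-biased-admixture Z score
#'
#' Compares an ancestry proportion estimated on the autosomes with the same
#' proportion on the X chromosome:
#' `Z = (p_A - p_X) / sqrt(sigma_A^2 + sigma_X^2)`.
#' A negative Z means more of the tested ancestry on the X than on the
#' autosomes — female-biased admixture, since females carry two thirds of
#' the population's X chromosomes.
#'
#' @param p_A,sigma_A autosomal proportion and its jackknife SD.
#' @param p_X,sigma_X X-chromosome proportion and its jackknife SD.
#' @return object of class `sex_bias_result`: the four inputs plus `Z`.
#' @export
sex_bias_z <- function(p_A, sigma_A, p_X, sigma_X) {
  dk_assert(sigma_A^2 + sigma_X^2 > 0, "both SDs zero: Z undefined",
            "dk_degenerate_error")
  z <- (p_A - p_X) / sqrt(sigma_A^2 + sigma_X^2)
  structure(list(p_A = p_A, sigma_A = sigma_A, p_X = p_X, sigma_X = sigma_X,
                 Z = z),
            class = "sex_bias_result")
}

#' @export
print.sex_bias_result <- function(x, ...) {
  cat(sprintf("<sex_bias> p_A = %.3f +/- %.3f, p_X = %.3f +/- %.3f, Z = %.2f\n",
              x$p_A, x$sigma_A, x$p_X, x$sigma_X, x$Z))
  invisible(x)
}
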