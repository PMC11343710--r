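# Shared fixture builders.  Everything is generated in code at test time.

# tiny pseudo-haploid matrix from explicit call vectors (rows = individuals)
make_gm <- function(calls, ids = paste0("I", seq_len(nrow(calls)))) {
  n <- ncol(calls)
  snps <- data.frame(id = paste0("rs", seq_len(n)), chrom = 1L,
                     pos = seq_len(n), ref = "A", alt = "G",
                     stringsAsFactors = FALSE)
  genotype_matrix(calls, snps, individuals = ids)
}

# the focal-pair priors used throughout: the package's stated defaults for
# the two princely burials
headline_individuals <- function() {
  list(
    individual("HOC001", sex = "XY", burial_lo = -539, burial_hi = -519,
               age_lo = 40, age_hi = 50, mt_haplotype = "J1b1a1"),
    individual("APG001", sex = "XY", burial_lo = -509, burial_hi = -479,
               age_lo = 25, age_hi = 35, mt_haplotype = "J1b1a1"))
}

headline_priors <- function() chrono_priors(headline_individuals())

# a focal-pair mismatch estimate sitting exactly on the second-degree
# expectation for baseline p0
headline_pmr <- function(p0 = 0.24, se = 0.003) {
  structure(list(pair = pair_id("HOC001", "APG001"),
                 ids = c("HOC001", "APG001"),
                 rate = 0.875 * p0, se = se, n_overlap = 1e5),
            class = "mismatch_estimate")
}

# write a 31-row roster-style metadata TSV (20 XY, 11 XX), returns the path
write_roster_fixture <- function(path) {
  set.seed(42)
  n <- 31
  sexes <- c(rep("XY", 20), rep("XX", 11))
  df <- data.frame(
    id = sprintf("IND%03d", seq_len(n)),
    site = sample(c("EH", "AG", "MBG", "DS"), n, replace = TRUE),
    sex = sexes,
    burial_lo = round(runif(n, -620, -500)),
    mt_haplotype = sample(c("J1b1a1", "H1", "U5a", "K1a"), n, replace = TRUE),
    stringsAsFactors = FALSE)
  df$burial_hi <- df$burial_lo + 30
  df$age_lo <- round(runif(n, 18, 50))
  df$age_hi <- df$age_lo + 10
  df <- df[, c("id", "site", "sex", "burial_lo", "burial_hi",
               "age_lo", "age_hi", "mt_haplotype")]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# pedigree whose focal child has first-cousin parents
first_cousin_child_pedigree <- function() {
  sim_pedigree(
    id     = c("Gm", "Gf", "S1", "S2", "sp1", "sp2", "C1", "C2", "sp0", "X"),
    sex    = c("XX", "XY", "XY", "XX", "XX", "XY", "XX", "XY", "XX", "XY"),
    mother = c(NA, NA, "Gm", "Gm", NA, NA, "sp1", "S2", NA, "C1"),
    father = c(NA, NA, "Gf", "Gf", NA, NA, "S1", "sp2", NA, "C2"),
    focal = c("X", "X"))
}

expect_within_3se <- function(est, target, se, label = "estimate") {
  expect_lt(abs(est - target), 3 * se + 1e-12,
            label = sprintf("%s = %.5g vs target %.5g (3se = %.2g)",
                            label, est, target, 3 * se))
}
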