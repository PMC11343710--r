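# synthetic-data generators: gene dropping, pseudo-haploidization,
# recombination segments, mtDNA transmission, chronology

test_that("sim_pedigree validates structure and topologically sorts", {
  ped <- sim_pedigree(id = c("C", "M", "F"), sex = c("XY", "XX", "XY"),
                      mother = c("M", NA, NA), father = c("F", NA, NA))
  expect_equal(ped$id[3], "C")  # child after parents
  expect_error(sim_pedigree(id = c("C", "M"), sex = c("XY", "XX"),
                            mother = c("M", NA), father = c(NA, NA)),
               class = "dk_validation_error")  # one parent only
})

test_that("gene_drop founders follow Hardy-Weinberg and children Mendel", {
  ped <- sim_pedigree(id = c("M", "F", "C"), sex = c("XX", "XY", "XY"),
                      mother = c(NA, NA, "M"), father = c(NA, NA, "F"))
  n <- 1e5
  cfg <- sim_config(n_snps = n, freqs = rep(0.3, n), seed = 11)
  gd <- gene_drop(ped, cfg)
  g <- rowSums(gd$alleles$M)  # diploid dosage
  # HWE at p = 0.3: P(het) = 2 * 0.3 * 0.7
  expect_within_3se(mean(g == 1), 0.42, sqrt(0.42 * 0.58 / n), "het freq")
  expect_within_3se(mean(g == 2), 0.09, sqrt(0.09 * 0.91 / n), "hom-alt freq")
  # a child is never opposite-homozygous to a parent
  gc <- rowSums(gd$alleles$C)
  gm <- rowSums(gd$alleles$M)
  expect_equal(sum(gc == 2 & gm == 0), 0)
  expect_equal(sum(gc == 0 & gm == 2), 0)
  # parent-offspring realized sharing: k1 = 1
  expect_equal(unname(realized_k(gd, "M", "C")), c(0, 1, 0))
  # unrelated founders share nothing
  expect_equal(unname(realized_k(gd, "M", "F")), c(1, 0, 0))
})

test_that("identical seeds reproduce bit-identically; different seeds differ", {
  ped <- sim_pedigree(id = c("M", "F", "C"), sex = c("XX", "XY", "XY"),
                      mother = c(NA, NA, "M"), father = c(NA, NA, "F"))
  a <- gene_drop(ped, sim_config(n_snps = 1000, seed = 5))
  b <- gene_drop(ped, sim_config(n_snps = 1000, seed = 5))
  c <- gene_drop(ped, sim_config(n_snps = 1000, seed = 6))
  expect_identical(a$alleles, b$alleles)
  expect_false(identical(a$alleles, c$alleles))
})

test_that("pseudo-haploidization samples one allele with error and missingness", {
  ped <- sim_pedigree(id = "X", sex = "XY", mother = NA, father = NA)
  n <- 1e5
  # all-heterozygous individual
  gd <- list(alleles = list(X = cbind(rep(0L, n), rep(1L, n))))
  cfg <- sim_config(n_snps = n, seed = 3)
  gm <- pseudo_haploidize(gd, cfg, ids = "X")
  expect_within_3se(mean(gm$calls["X", ] == 1), 0.5, sqrt(0.25 / n), "het call")

  # homozygous input, no error: calls equal the allele
  gd0 <- list(alleles = list(X = cbind(rep(1L, n), rep(1L, n))))
  gm0 <- pseudo_haploidize(gd0, cfg, ids = "X")
  expect_true(all(gm0$calls == 1L))

  # full missingness
  cfg1 <- sim_config(n_snps = n, missing_rate = 1, seed = 4)
  expect_true(all(is.na(pseudo_haploidize(gd0, cfg1, ids = "X")$calls)))

  # error rate flips homozygous calls at the configured rate
  cfge <- sim_config(n_snps = n, error_rate = 0.01, seed = 5)
  gme <- pseudo_haploidize(gd0, cfge, ids = "X")
  expect_within_3se(mean(gme$calls["X", ] == 0), 0.01, sqrt(0.0099 / n), "error rate")
})

test_that("recombination simulator has the right crossover intensity", {
  # crossovers per meiosis on a 100 cM chromosome are Poisson(1): count the
  # mosaic pieces a single meiosis produces
  set.seed(12)
  hap1 <- data.frame(start = 0, end = 100, label = "a")
  hap2 <- data.frame(start = 0, end = 100, label = "b")
  ncx <- vapply(1:300, function(i) nrow(dynastikin:::meiose(hap1, hap2, 100)) - 1L,
                0L)
  expect_within_3se(mean(ncx), 1, sd(ncx) / sqrt(300), "crossovers per 100 cM")

  ped <- sim_pedigree(id = c("M", "F", "C"), sex = c("XX", "XY", "XY"),
                      mother = c(NA, NA, "M"), father = c(NA, NA, "F"))
  map <- genetic_map(lengths_cM = rep(100, 22))
  # a parent and child share one allele everywhere: IBD total = L exactly
  s1 <- simulate_recombination(ped, map, seed = 8, roh_ids = character(),
                               ibd_pairs = list(c("M", "C")))
  expect_equal(sum(s1$end_cM - s1$start_cM), map$L)
  # unrelated founders share no segments
  s2 <- simulate_recombination(ped, map, seed = 9, roh_ids = character(),
                               ibd_pairs = list(c("M", "F")))
  expect_equal(nrow(s2), 0)
  # outbred individuals have no RoH
  s3 <- simulate_recombination(ped, map, seed = 10, roh_ids = "C")
  expect_equal(nrow(s3), 0)

  # grandparent-grandchild sharing halves: E[total] = L/2, now with variance
  ped2 <- sim_pedigree(
    id = c("M", "F", "C", "S", "G"), sex = c("XX", "XY", "XX", "XY", "XY"),
    mother = c(NA, NA, "M", NA, "C"), father = c(NA, NA, "F", NA, "S"))
  tot <- vapply(1:30, function(i) {
    s <- simulate_recombination(ped2, map, seed = 200 + i,
                                roh_ids = character(),
                                ibd_pairs = list(c("M", "G")))
    sum(s$end_cM - s$start_cM)
  }, 0)
  expect_within_3se(mean(tot), map$L / 2, sd(tot) / sqrt(30),
                    "grandparent IBD total")
})

test_that("mtDNA follows the mother and collides at pool homozygosity", {
  models <- enumerate_candidate_pedigrees("A", "B")
  ped_mat <- as_sim_pedigree(models[[1]])  # matrilineal uncle
  ped_pat <- as_sim_pedigree(models[[4]])  # paternal grandfather
  pool <- c(H1 = 0.6, H2 = 0.3, H3 = 0.1)
  hom <- sum(pool^2)
  match_mat <- vapply(1:50, function(i)
    simulate_mtdna(ped_mat, pool, seed = i)[["A"]] ==
      simulate_mtdna(ped_mat, pool, seed = i)[["B"]], NA)
  expect_true(all(match_mat))
  match_pat <- vapply(1:400, function(i) {
    lab <- simulate_mtdna(ped_pat, pool, seed = 1000 + i)
    lab[["A"]] == lab[["B"]]
  }, NA)
  expect_within_3se(mean(match_pat), hom, sqrt(hom * (1 - hom) / 400),
                    "mt collision rate")
  # single-haplotype pool: everyone matches
  lab <- simulate_mtdna(ped_pat, c(H = 1), seed = 1)
  expect_equal(length(unique(lab)), 1L)
})

test_that("simulated chronology is self-consistent with the generating model", {
  models <- enumerate_candidate_pedigrees("A", "B")
  priors0 <- chrono_priors(list(
    individual("A", burial_lo = -600, burial_hi = -400),
    individual("B", burial_lo = -600, burial_hi = -400)),
    root_window = c(-700, -450))
  for (i in c(1, 2, 6)) {
    sim <- simulate_chronology(models[[i]], priors0, seed = 20 + i)
    pr <- chrono_priors(sim$individuals,
                        root_window = priors0$root_window)
    state <- sim$truth[c(paste0("b:", models[[i]]$chain$node),
                         paste0("a:", models[[i]]$nodes$id[models[[i]]$nodes$observed]))]
    expect_gt(joint_density(models[[i]], state, pr), 0)
  }
  # zero interval widths reproduce the truth exactly
  sim <- simulate_chronology(models[[1]], priors0, burial_width = 0,
                             age_width = 0, seed = 31)
  ind <- sim$individuals$A
  expect_equal(unname(ind$burial_interval[["lo"]]),
               unname(sim$truth[["burial:A"]]))
  expect_equal(unname(diff(ind$age_interval)), 0)
  # matrilineal generating model forces an mtDNA match
  expect_true(sim$mt_match)
})
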