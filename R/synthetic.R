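# Synthetic-data generators: pedigree-structured diploid genotypes by gene
# dropping at unlinked sites, random-read pseudo-haploidization, Poisson
# recombination for linked RoH/IBD segments, matrilineal mtDNA transmission,
# and chronological observation intervals from the priors.

#' Construct a simulation pedigree
#'
#' @param id node ids.
#' @param sex `"XX"`/`"XY"` per node.
#' @param mother,father parent ids (`NA` for founders; non-founders need
#'   both).
#' @param focal optional length-2 vector designating the focal pair.
#' @return a data frame of class `sim_pedigree`, topologically ordered.
#' @export
sim_pedigree <- function(id, sex, mother = NA, father = NA, focal = NULL) {
  ped <- data.frame(id = as.character(id), sex = as.character(sex),
                    mother = as.character(rep_len(mother, length(id))),
                    father = as.character(rep_len(father, length(id))),
                    stringsAsFactors = FALSE)
  dk_assert(!anyDuplicated(ped$id), "duplicate node ids")
  both <- is.na(ped$mother) == is.na(ped$father)
  dk_assert(all(both), "every non-founder needs both parents in the pedigree")
  known <- ped$id
  for (p in c(ped$mother, ped$father)) {
    dk_assert(is.na(p) || p %in% known, sprintf("unknown parent id: %s", p))
  }
  ped <- topo_sort_pedigree(ped)
  if (!is.null(focal)) {
    dk_assert(all(focal %in% ped$id), "focal ids must be pedigree members")
    attr(ped, "focal") <- focal
  }
  class(ped) <- c("sim_pedigree", "data.frame")
  ped
}

topo_sort_pedigree <- function(ped) {
  placed <- character()
  remaining <- ped$id
  while (length(remaining)) {
    ready <- remaining[vapply(remaining, function(i) {
      r <- ped[ped$id == i, ]
      (is.na(r$mother) || r$mother %in% placed) &&
        (is.na(r$father) || r$father %in% placed)
    }, NA)]
    dk_assert(length(ready) > 0, "pedigree contains a cycle")
    placed <- c(placed, ready)
    remaining <- setdiff(remaining, ready)
  }
  ped[match(placed, ped$id), , drop = FALSE]
}

#' Convert a catalogue pedigree model to a simulation pedigree
#'
#' Adds anonymous founder spouses wherever a catalogued node has only one
#' recorded parent, so that every non-founder has both parents.
#'
#' @param model a `pedigree_model`.
#' @return a [sim_pedigree()] with the focal pair designated.
#' @export
as_sim_pedigree <- function(model) {
  nodes <- model$nodes
  mother <- stats::setNames(rep(NA_character_, nrow(nodes)), nodes$id)
  father <- stats::setNames(rep(NA_character_, nrow(nodes)), nodes$id)
  for (i in seq_len(nrow(model$links))) {
    l <- model$links[i, ]
    if (l$type == "mother") mother[[l$child]] <- l$parent else father[[l$child]] <- l$parent
  }
  extra_id <- character(); extra_sex <- character()
  for (id in nodes$id) {
    if (is.na(mother[[id]]) != is.na(father[[id]])) {
      new <- paste0("anon_", id, if (is.na(mother[[id]])) "_m" else "_f")
      extra_id <- c(extra_id, new)
      extra_sex <- c(extra_sex, if (is.na(mother[[id]])) "XX" else "XY")
      if (is.na(mother[[id]])) mother[[id]] <- new else father[[id]] <- new
    }
  }
  sim_pedigree(id = c(nodes$id, extra_id),
               sex = c(nodes$sex, extra_sex),
               mother = c(unname(mother), rep(NA_character_, length(extra_id))),
               father = c(unname(father), rep(NA_character_, length(extra_id))),
               focal = c(model$focalA, model$focalB))
}

#' Simulation configuration
#'
#' @param n_snps number of unlinked biallelic sites.
#' @param freq_range allele frequencies drawn per site from
#'   `Uniform(freq_range[1], freq_range[2])` (mimics an ascertained panel);
#'   or supply `freqs` directly.
#' @param freqs optional explicit per-site alt-allele frequencies.
#' @param missing_rate per-call probability of a missing pseudo-haploid call.
#' @param error_rate per-call probability that the sampled allele is flipped.
#' @param map a [genetic_map()] (used by the segment simulator).
#' @param seed RNG seed (mandatory).
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_snps = 1e5, freq_range = c(0.05, 0.5), freqs = NULL,
                       missing_rate = 0, error_rate = 0,
                       map = genetic_map(), seed) {
  dk_assert(!missing(seed), "a seed is mandatory")
  dk_assert(missing_rate >= 0 && missing_rate <= 1 &&
              error_rate >= 0 && error_rate <= 1, "rates must lie in [0, 1]")
  structure(list(n_snps = n_snps, freq_range = freq_range, freqs = freqs,
                 missing_rate = missing_rate, error_rate = error_rate,
                 map = map, seed = as.integer(seed)),
            class = "sim_config")
}

#' Gene-drop diploid genotypes through a pedigree
#'
#' Founders draw two alleles per site binomially from the per-site allele
#' frequency (Hardy-Weinberg); every child inherits one allele per parent
#' per site, independently across sites (unlinked-site model). Each founder
#' allele carries a distinct descent label, so realized identity-by-descent
#' sharing is available exactly.
#'
#' @param ped a [sim_pedigree()].
#' @param cfg a [sim_config()].
#' @return list of class `gene_drop_result` with `alleles` (per node, a
#'   two-column 0/1 matrix of allele states), `labels` (per node, the
#'   founder-allele descent labels), `freqs`, and `ped`.
#' @export
gene_drop <- function(ped, cfg) {
  set.seed(cfg$seed)
  n <- cfg$n_snps
  freqs <- if (!is.null(cfg$freqs)) cfg$freqs else
    stats::runif(n, cfg$freq_range[1], cfg$freq_range[2])
  alleles <- list(); labels <- list()
  lab_next <- 1L
  for (i in seq_len(nrow(ped))) {
    id <- ped$id[i]
    if (is.na(ped$mother[i])) {
      a <- cbind(stats::rbinom(n, 1, freqs), stats::rbinom(n, 1, freqs))
      l <- cbind(rep(lab_next, n), rep(lab_next + 1L, n))
      lab_next <- lab_next + 2L
    } else {
      pick_m <- stats::rbinom(n, 1, 0.5) + 1L
      pick_f <- stats::rbinom(n, 1, 0.5) + 1L
      im <- cbind(seq_len(n), pick_m); iff <- cbind(seq_len(n), pick_f)
      a <- cbind(alleles[[ped$mother[i]]][im], alleles[[ped$father[i]]][iff])
      l <- cbind(labels[[ped$mother[i]]][im], labels[[ped$father[i]]][iff])
    }
    alleles[[id]] <- a
    labels[[id]] <- l
  }
  structure(list(alleles = alleles, labels = labels, freqs = freqs, ped = ped),
            class = "gene_drop_result")
}

#' Realized IBD-sharing fractions of a pair
#'
#' Fraction of sites at which the two individuals share 0, 1 or 2 alleles
#' identical by descent (by founder-allele label) — the long-run oracle for
#' a pedigree's (k0, k1, k2).
#'
#' @param gd a [gene_drop()] result.
#' @param idA,idB pair of node ids.
#' @return named numeric vector `(k0, k1, k2)`.
#' @export
realized_k <- function(gd, idA, idB) {
  la <- gd$labels[[idA]]; lb <- gd$labels[[idB]]
  shared1 <- (la[, 1] == lb[, 1]) | (la[, 1] == lb[, 2])
  shared2 <- (la[, 2] == lb[, 1]) | (la[, 2] == lb[, 2])
  s <- shared1 + shared2
  c(k0 = mean(s == 0), k1 = mean(s == 1), k2 = mean(s == 2))
}

#' Pseudo-haploidize diploid genotypes
#'
#' Emulates random-read genotyping of low-coverage ancient DNA: per site one
#' allele of the diploid genotype is drawn at random, flipped with the error
#' rate, and dropped with the missing rate.
#'
#' @param gd a [gene_drop()] result (or any list of two-column allele
#'   matrices under `$alleles`).
#' @param cfg a [sim_config()]; its `missing_rate`/`error_rate` apply.
#' @param ids which individuals to emit (default: all).
#' @param seed optional seed override (default `cfg$seed + 1`).
#' @return a [genotype_matrix()] with calls in {0, 1, NA}.
#' @export
pseudo_haploidize <- function(gd, cfg, ids = names(gd$alleles), seed = NULL) {
  set.seed(if (is.null(seed)) cfg$seed + 1L else seed)
  n <- nrow(gd$alleles[[ids[1]]])
  calls <- matrix(NA_integer_, nrow = length(ids), ncol = n)
  for (i in seq_along(ids)) {
    a <- gd$alleles[[ids[i]]]
    pick <- stats::rbinom(n, 1, 0.5) + 1L
    call <- a[cbind(seq_len(n), pick)]
    if (cfg$error_rate > 0) {
      flip <- stats::runif(n) < cfg$error_rate
      call[flip] <- 1L - call[flip]
    }
    if (cfg$missing_rate > 0) {
      call[stats::runif(n) < cfg$missing_rate] <- NA_integer_
    }
    calls[i, ] <- call
  }
  snps <- data.frame(id = paste0("snp", seq_len(n)), chrom = 1L,
                     pos = seq_len(n), ref = "A", alt = "G",
                     stringsAsFactors = FALSE)
  genotype_matrix(calls, snps, individuals = ids)
}

# one meiosis: recombine a parent's two haplotypes on one chromosome.
# haplotypes are data.frames (start, end, label) over [0, len), cM.
meiose <- function(hap1, hap2, len) {
  ncx <- stats::rpois(1, len / 100)
  cuts <- sort(stats::runif(ncx, 0, len))
  bounds <- c(0, cuts, len)
  phase <- stats::rbinom(1, 1, 0.5)
  pieces <- vector("list", length(bounds) - 1)
  for (i in seq_len(length(bounds) - 1)) {
    src <- if ((i + phase) %% 2 == 0) hap1 else hap2
    pieces[[i]] <- hap_window(src, bounds[i], bounds[i + 1])
  }
  do.call(rbind, pieces)
}

hap_window <- function(hap, a, b) {
  keep <- hap$end > a & hap$start < b
  h <- hap[keep, , drop = FALSE]
  h$start <- pmax(h$start, a)
  h$end <- pmin(h$end, b)
  h
}

# intersect two label mosaics: regions where labels coincide
hap_match <- function(h1, h2) {
  out <- list()
  for (i in seq_len(nrow(h1))) {
    o <- h2[h2$label == h1$label[i] & h2$end > h1$start[i] &
              h2$start < h1$end[i], , drop = FALSE]
    if (nrow(o)) {
      o$start <- pmax(o$start, h1$start[i])
      o$end <- pmin(o$end, h1$end[i])
      out[[length(out) + 1]] <- o
    }
  }
  if (length(out)) do.call(rbind, out) else h1[0, , drop = FALSE]
}

#' Simulate linked inheritance and emit RoH/IBD segments
#'
#' Per meiosis, crossovers fall as a Poisson process at 1 per 100 cM per
#' chromosome (no interference); founder-chromosome origin is tracked along
#' each autosome. Emits runs of homozygosity (regions where an individual's
#' two haplotypes descend from the same founder chromosome) for the
#' requested individuals, and IBD segments for requested pairs.
#'
#' @param ped a [sim_pedigree()].
#' @param map a [genetic_map()].
#' @param seed RNG seed.
#' @param roh_ids individuals whose RoH to emit (default: all).
#' @param ibd_pairs list of id pairs whose IBD to emit (default: none).
#' @param min_cM drop segments shorter than this (default 0: keep all).
#' @return a [segment_table()] with individual carriers for RoH rows and
#'   `pair_id()` carriers for IBD rows.
#' @export
simulate_recombination <- function(ped, map, seed, roh_ids = ped$id,
                                   ibd_pairs = list(), min_cM = 0) {
  set.seed(seed)
  rows <- list()
  for (chrom in seq_along(map$lengths_cM)) {
    len <- map$lengths_cM[chrom]
    haps <- list()
    for (i in seq_len(nrow(ped))) {
      id <- ped$id[i]
      if (is.na(ped$mother[i])) {
        haps[[id]] <- list(
          data.frame(start = 0, end = len, label = paste0(id, ".1")),
          data.frame(start = 0, end = len, label = paste0(id, ".2")))
      } else {
        haps[[id]] <- list(
          meiose(haps[[ped$mother[i]]][[1]], haps[[ped$mother[i]]][[2]], len),
          meiose(haps[[ped$father[i]]][[1]], haps[[ped$father[i]]][[2]], len))
      }
    }
    for (id in roh_ids) {
      m <- hap_match(haps[[id]][[1]], haps[[id]][[2]])
      if (nrow(m)) rows[[length(rows) + 1]] <-
          data.frame(carrier = id, chrom = chrom, start_cM = m$start,
                     end_cM = m$end)
    }
    for (pr in ibd_pairs) {
      segs <- list()
      for (i in 1:2) for (j in 1:2) {
        m <- hap_match(haps[[pr[1]]][[i]], haps[[pr[2]]][[j]])
        if (nrow(m)) segs[[length(segs) + 1]] <- m
      }
      if (length(segs)) {
        m <- do.call(rbind, segs)
        rows[[length(rows) + 1]] <-
          data.frame(carrier = pair_id(pr[1], pr[2]), chrom = chrom,
                     start_cM = m$start, end_cM = m$end)
      }
    }
  }
  if (!length(rows)) return(segment_table())
  df <- do.call(rbind, rows)
  df <- df[df$end_cM - df$start_cM > 0, , drop = FALSE]
  seg <- segment_table(df$carrier, df$chrom, df$start_cM, df$end_cM)
  if (min_cM > 0) {
    seg <- seg[seg$end_cM - seg$start_cM >= min_cM, , drop = FALSE]
    class(seg) <- c("segment_table", "data.frame")
  }
  seg
}

#' Matrilineal mtDNA haplotype transmission
#'
#' Founders draw a haplotype label from a frequency pool; every non-founder
#' inherits the mother's label exactly.
#'
#' @param ped a [sim_pedigree()].
#' @param pool named numeric vector of haplotype frequencies (sums to 1).
#' @param seed RNG seed.
#' @return named character vector: haplotype label per node.
#' @export
simulate_mtdna <- function(ped, pool, seed) {
  dk_assert(abs(sum(pool) - 1) < 1e-8, "haplotype pool frequencies must sum to 1")
  set.seed(seed)
  lab <- stats::setNames(rep(NA_character_, nrow(ped)), ped$id)
  for (i in seq_len(nrow(ped))) {
    lab[[ped$id[i]]] <- if (is.na(ped$mother[i])) {
      sample(names(pool), 1, prob = pool)
    } else {
      lab[[ped$mother[i]]]
    }
  }
  lab
}

#' Simulate chronological observations under a pedigree model
#'
#' Prior-predictive generator for parameter-recovery studies: latent birth
#' years follow the model's generative chain (root uniform on a window, link
#' ages from the maternal/paternal priors), true ages at death are uniform
#' on `age_range`, and the emitted burial/age observation intervals have the
#' requested widths, centred with a uniform random offset around the truth.
#'
#' @param model a `pedigree_model`.
#' @param priors a [chrono_priors()] providing the age-at-birth priors (its
#'   individuals' intervals are ignored; `root_window` is reused if finite).
#' @param burial_width,age_width interval widths (years).
#' @param age_range range of true ages at death.
#' @param seed RNG seed.
#' @param mt_pool optional haplotype pool for mtDNA observation (default: a
#'   20-haplotype uniform pool).
#' @return list with `truth` (named vector of latent values), `individuals`
#'   (observed [individual()] records for the focal pair), and `mt_match`
#'   (logical).
#' @export
simulate_chronology <- function(model, priors, burial_width = 30,
                                age_width = 10, age_range = c(18, 70),
                                seed = 1L, mt_pool = NULL) {
  set.seed(seed)
  chain <- model$chain
  b <- stats::setNames(numeric(nrow(chain)), chain$node)
  w <- priors$root_window
  for (i in seq_len(nrow(chain))) {
    b[[chain$node[i]]] <- if (is.na(chain$parent[i])) {
      stats::runif(1, w[1], w[2])
    } else {
      b[[chain$parent[i]]] + age_draw(1, chain$link[i], priors)
    }
  }
  obs <- model$nodes$id[model$nodes$observed]
  sex_of <- stats::setNames(model$nodes$sex, model$nodes$id)
  if (is.null(mt_pool)) {
    mt_pool <- stats::setNames(rep(0.05, 20), paste0("H", 1:20))
  }
  mt <- simulate_mtdna(as_sim_pedigree(model), mt_pool, seed = seed + 7L)
  individuals <- list()
  truth <- c()
  for (id in obs) {
    a <- stats::runif(1, age_range[1], age_range[2])
    burial <- b[[id]] + a
    boff <- stats::runif(1) * burial_width
    aoff <- stats::runif(1) * age_width
    age_lo <- max(0, a - aoff)
    individuals[[id]] <- individual(
      id = id, sex = sex_of[[id]],
      burial_lo = burial - boff, burial_hi = burial - boff + burial_width,
      age_lo = age_lo, age_hi = age_lo + age_width,
      mt_haplotype = mt[[id]])
    truth[paste0("b:", id)] <- b[[id]]
    truth[paste0("a:", id)] <- a
    truth[paste0("burial:", id)] <- burial
  }
  for (nd in chain$node[!chain$node %in% obs]) truth[paste0("b:", nd)] <- b[[nd]]
  list(truth = truth, individuals = individuals,
       mt_match = mt[[model$focalA]] == mt[[model$focalB]])
}
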