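# Runs-of-homozygosity consanguinity summaries and IBD-sharing summaries
# with simulation-based degree envelopes for distant relatives.

#' Runs-of-homozygosity profile and consanguinity class
#'
#' Sums and counts an individual's RoH segments above the standard minimum
#' lengths (4, 8, 12, 20 cM). The parents are called close kin when the
#' total above 4 cM exceeds the configured cut (default 150 cM, roughly the
#' level expected under first-cousin parents after segment-length
#' filtering); any smaller non-zero total is background relatedness.
#'
#' @param segments a [segment_table()] of RoH rows.
#' @param id carrier id.
#' @param map a [genetic_map()] (bounds check and total length).
#' @param thresholds_cM minimum segment lengths to sum over.
#' @param consanguinity_cM total-RoH cut for the close-kin-parents call.
#' @return object of class `roh_profile`: list with `id`, `sums` (named by
#'   threshold), `counts`, `class`.
#' @export
roh_profile <- function(segments, id, map = genetic_map(),
                        thresholds_cM = c(4, 8, 12, 20),
                        consanguinity_cM = 150) {
  seg <- segments[segments$carrier == id, , drop = FALSE]
  if (nrow(seg)) {
    too_long <- seg$end_cM > map$lengths_cM[seg$chrom] + 1e-9
    dk_assert(!any(too_long),
              sprintf("segment beyond chromosome length (row %d)", which(too_long)[1]))
  }
  len <- seg$end_cM - seg$start_cM
  sums <- vapply(thresholds_cM, function(t) sum(len[len >= t]), 0)
  counts <- vapply(thresholds_cM, function(t) sum(len >= t), 0L)
  names(sums) <- names(counts) <- paste0(">=", thresholds_cM)
  total <- sums[[1]]
  cls <- if (total > consanguinity_cM) "close-kin parents"
  else if (total > 0) "background"
  else "none detected"
  structure(list(id = id, sums = sums, counts = counts, class = cls,
                 consanguinity_cM = consanguinity_cM),
            class = "roh_profile")
}

#' @export
print.roh_profile <- function(x, ...) {
  cat(sprintf("<roh_profile> %s: %s  [%s]\n", x$id,
              paste(sprintf("%s: %.1f cM (n=%d)", names(x$sums), x$sums,
                            x$counts), collapse = ", "),
              x$class))
  invisible(x)
}

#' Expected total autozygosity under parental kinship
#'
#' The expected summed RoH of an individual whose parents have kinship
#' coefficient f is `f * L` (first-cousin parents: f = 1/16).
#'
#' @param parental_kinship_f kinship coefficient of the parents, in
#'   \[0, 1/4\].
#' @param map a [genetic_map()].
#' @return expected total RoH in cM.
#' @export
expected_autozygosity <- function(parental_kinship_f, map = genetic_map()) {
  dk_assert(parental_kinship_f >= 0 && parental_kinship_f <= 0.25,
            "parental kinship must lie in [0, 1/4]")
  parental_kinship_f * map$L
}

#' IBD-sharing summary for a pair
#'
#' Summed length and count of IBD segments in the standard bins (at least
#' 8, 12, 16 and 20 cM).
#'
#' @param segments a [segment_table()] whose carriers are [pair_id()]s.
#' @param pair length-2 vector of ids (order-free).
#' @param bins_cM bin minima.
#' @return object of class `ibd_summary`: list with `pair`, `sums`,
#'   `counts`.
#' @export
ibd_summary <- function(segments, pair, bins_cM = c(8, 12, 16, 20)) {
  pid <- pair_id(pair[1], pair[2])
  seg <- segments[segments$carrier == pid, , drop = FALSE]
  len <- seg$end_cM - seg$start_cM
  sums <- vapply(bins_cM, function(t) sum(len[len >= t]), 0)
  counts <- vapply(bins_cM, function(t) sum(len >= t), 0L)
  names(sums) <- names(counts) <- paste0(">=", bins_cM)
  structure(list(pair = pid, sums = sums, counts = counts),
            class = "ibd_summary")
}

#' Simulated reference distributions of IBD sharing by degree
#'
#' For each relationship degree d, simulates pairs separated by d meioses
#' from a common ancestral couple (relatedness `r = 2^-d`) with the Poisson
#' recombination model and records the summed IBD at or above `min_cM`.
#'
#' @param degrees degrees to simulate (default 4:10).
#' @param n_rep replicates per degree.
#' @param map a [genetic_map()].
#' @param seed RNG seed.
#' @param min_cM IBD bin minimum backing the envelopes (default 8 cM).
#' @return list of class `ibd_reference`: per degree, the vector of summed
#'   sharing; attributes record `min_cM`.
#' @export
ibd_reference <- function(degrees = 4:10, n_rep = 200, map = genetic_map(),
                          seed = 1L, min_cM = 8) {
  refs <- list()
  for (d in degrees) {
    # chain: ancestral couple -> two siblings (degree 1), then d-1 further
    # meioses split as evenly as possible between the two descents
    extra <- d - 1
    la <- ceiling(extra / 2); lb <- extra - la
    ids <- c("anc_m", "anc_f", "sib_a0", "sib_b0")
    sexes <- c("XX", "XY", "XY", "XY")
    mothers <- c(NA, NA, "anc_m", "anc_m")
    fathers <- c(NA, NA, "anc_f", "anc_f")
    mk_chain <- function(side, nlink) {
      prev <- paste0("sib_", side, 0)
      for (g in seq_len(nlink)) {
        sp <- paste0("sp_", side, g); ch <- paste0("sib_", side, g)
        ids <<- c(ids, sp, ch); sexes <<- c(sexes, "XX", "XY")
        mothers <<- c(mothers, NA, sp); fathers <<- c(fathers, NA, prev)
        prev <- ch
      }
      prev
    }
    ta <- mk_chain("a", la); tb <- mk_chain("b", lb)
    ped <- sim_pedigree(ids, sexes, mothers, fathers, focal = c(ta, tb))
    sums <- numeric(n_rep)
    for (r in seq_len(n_rep)) {
      seg <- simulate_recombination(ped, map, seed = seed + 1000L * d + r,
                                    roh_ids = character(),
                                    ibd_pairs = list(c(ta, tb)))
      s <- ibd_summary(seg, c(ta, tb), bins_cM = min_cM)
      sums[r] <- s$sums[[1]]
    }
    refs[[as.character(d)]] <- sums
  }
  structure(refs, class = "ibd_reference", min_cM = min_cM, degrees = degrees)
}

#' Degree interval consistent with observed IBD sharing
#'
#' Returns the degrees whose simulated central 90% envelope of summed IBD
#' contains the observed sum; an observed sum below every envelope is
#' reported as consistent with being unrelated or beyond the simulated
#' range.
#'
#' @param summary an [ibd_summary()].
#' @param reference an [ibd_reference()].
#' @param level envelope coverage (default 0.9).
#' @return list with `degrees` (integer vector, possibly empty),
#'   `interval` (e.g. `"6-8"`, or `"unrelated/beyond simulated range"`),
#'   `observed` (the sum used).
#' @export
degree_from_ibd <- function(summary, reference, level = 0.9) {
  dk_assert(length(reference) > 0, "empty reference set", "dk_config_error")
  min_cM <- attr(reference, "min_cM")
  obs <- summary$sums[[paste0(">=", min_cM)]]
  dk_assert(!is.null(obs), "summary lacks the reference's bin")
  if (obs <= 0) {
    return(list(degrees = integer(),
                interval = "unrelated/beyond simulated range", observed = obs))
  }
  lo <- (1 - level) / 2
  hits <- integer()
  for (d in names(reference)) {
    q <- stats::quantile(reference[[d]], c(lo, 1 - lo))
    if (obs >= q[1] && obs <= q[2]) hits <- c(hits, as.integer(d))
  }
  interval <- if (length(hits)) {
    if (length(hits) == 1) as.character(hits) else
      paste0(min(hits), "-", max(hits))
  } else "unrelated/beyond simulated range"
  list(degrees = hits, interval = interval, observed = obs)
}
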