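# End-to-end orchestration: kinship estimation -> evidence construction ->
# pedigree model selection -> latent prediction -> JSON report and figures.

#' Run the full focal-pair analysis from one config file
#'
#' Stages: (1) read genotypes and metadata; (2) pairwise mismatch rates and
#' baseline; (3) degree posteriors; (4) enumerate the candidate pedigrees
#' for the focal pair; (5) chronological marginal likelihoods, kinship and
#' mtDNA evidence; (6) posterior model weights and Bayes factors; (7) MCMC
#' on the top model; (8) latent summaries; (9) JSON report (and figures
#' unless disabled). Deterministic given the config seed.
#'
#' Config keys beyond [analysis_config()]: `genotypes` (EIGENSTRAT prefix),
#' `metadata` (TSV path), `focal` (two ids), `out_dir`, optional `figures`
#' (logical), `pmr` (list `rate`, `se`, `n_overlap` to bypass genotypes),
#' `mt_match` (logical override; default: compare metadata labels).
#'
#' @param config_path path to a YAML (or JSON) config file.
#' @return object of class `run_report` (also serialized to
#'   `<out_dir>/report.json`).
#' @export
run_full_analysis <- function(config_path) {
  cfg <- read_config(config_path)
  dk_assert(!is.null(cfg$focal) && length(cfg$focal) == 2,
            "config must name the two focal individuals", "dk_config_error")
  dk_assert(!is.null(cfg$metadata), "config must point at a metadata table",
            "dk_config_error")
  stage <- function(name, expr) {
    dk_log("stage: ", name)
    tryCatch(expr, error = function(e) {
      dk_error(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
               "dk_stage_error")
    })
  }
  meta <- stage("metadata", read_metadata(cfg$metadata))
  focal <- as.character(cfg$focal)
  dk_assert(all(focal %in% names(meta)),
            "focal individuals missing from metadata", "dk_config_error")

  pair_table <- NULL
  if (!is.null(cfg$genotypes)) {
    gm <- stage("genotypes", read_eigenstrat(cfg$genotypes))
    ests <- stage("pmr", all_pairwise_rates(gm, cfg$min_overlap))
    p0 <- if (!is.null(cfg$p0)) list(p0 = cfg$p0, se = NA) else
      stage("baseline", baseline_rate(ests))
    pair_table <- do.call(rbind, lapply(ests, function(e) {
      post <- degree_posterior(e, p0$p0)
      data.frame(pair = e$pair, rate = e$rate, se = e$se,
                 n_overlap = e$n_overlap,
                 class = names(which.max(post)),
                 posterior = max(post), stringsAsFactors = FALSE)
    }))
    rownames(pair_table) <- NULL
    focal_est <- ests[[pair_id(focal[1], focal[2])]]
    dk_assert(!is.null(focal_est), "no mismatch estimate for the focal pair",
              "dk_insufficient_data_error")
  } else {
    dk_assert(!is.null(cfg$pmr),
              "config needs either 'genotypes' or a direct 'pmr' entry",
              "dk_config_error")
    p0 <- list(p0 = cfg$p0, se = NA)
    dk_assert(!is.null(cfg$p0), "a direct 'pmr' entry requires 'p0'",
              "dk_config_error")
    focal_est <- structure(list(pair = pair_id(focal[1], focal[2]),
                                ids = focal, rate = cfg$pmr$rate,
                                se = cfg$pmr$se,
                                n_overlap = cfg$pmr$n_overlap),
                           class = "mismatch_estimate")
  }

  models <- stage("catalogue", enumerate_candidate_pedigrees(focal[1], focal[2]))
  priors <- stage("priors", chrono_priors(
    meta[focal], maternal = cfg$maternal, paternal = cfg$paternal))

  mt_match <- if (!is.null(cfg$mt_match)) isTRUE(cfg$mt_match) else {
    la <- meta[[focal[1]]]$mt_haplotype
    lb <- meta[[focal[2]]]$mt_haplotype
    !is.na(la) && !is.na(lb) && la == lb
  }

  marginals <- stage("marginal likelihoods", lapply(models, function(m) {
    suppressWarnings(marginal_likelihood(m, priors, n_draws = cfg$n_draws,
                                         seed = cfg$seed + m$model_id))
  }))
  G <- vapply(models, kinship_evidence, 0, pmr_estimate = focal_est, p0 = p0$p0)
  Tv <- vapply(models, mtdna_evidence, 0, observed_match = mt_match,
               f_background = cfg$f_background)
  posterior <- stage("combine", combine_evidence(models, marginals, G, Tv,
                                                 prior = cfg$model_prior))

  top <- models[[which(vapply(models, `[[`, 0, "model_id") ==
                         posterior$model_id[1])]]
  samples <- stage("mcmc", sample_posterior(top, priors,
                                            n_chains = cfg$n_chains,
                                            n_iter = cfg$n_iter,
                                            seed = cfg$seed))
  latents <- stage("latents", predict_latents(samples))

  report <- structure(list(
    version = as.character(utils::packageVersion("dynastikin")),
    seed = cfg$seed,
    config_path = config_path,
    inputs = list(metadata = unname(tools::md5sum(cfg$metadata)),
                  genotypes = if (!is.null(cfg$genotypes)) cfg$genotypes),
    parameters = list(n_draws = cfg$n_draws, n_chains = cfg$n_chains,
                      n_iter = cfg$n_iter, p0 = p0$p0,
                      f_background = cfg$f_background,
                      maternal = cfg$maternal, paternal = cfg$paternal,
                      root_window = priors$root_window),
    focal = focal, mt_match = mt_match,
    pairwise = pair_table,
    focal_pmr = list(rate = focal_est$rate, se = focal_est$se,
                     n_overlap = focal_est$n_overlap),
    model_posterior = as.data.frame(posterior),
    top_model = list(model_id = top$model_id, label = top$label,
                     rhat = as.list(samples$rhat)),
    latents = latents), class = "run_report")
  report$samples <- samples

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    ser <- report; ser$samples <- NULL  # draws are large; keep report light
    jsonlite::write_json(ser, file.path(cfg$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
    if (!identical(cfg$figures, FALSE)) {
      render_figures(report, cfg$out_dir)
    }
  }
  report
}

#' Render pipeline figures
#'
#' A posterior-weight bar chart over the candidate pedigrees, and
#' kernel-density marginals of the burial dates, birth dates and latent
#' mothers' birth dates from the MCMC samples.
#'
#' @param report a `run_report` from [run_full_analysis()].
#' @param out_dir output directory; PDF files are written there.
#' @return character vector of created file paths, invisibly.
#' @export
render_figures <- function(report, out_dir = ".") {
  if (is.null(report$samples) || nrow(report$samples$draws) == 0) {
    warning("no posterior samples in report; figures skipped")
    return(invisible(character()))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()

  f1 <- file.path(out_dir, "model_weights.pdf")
  grDevices::pdf(f1, width = 7, height = 4.5)
  mp <- report$model_posterior[order(report$model_posterior$model_id), ]
  graphics::barplot(mp$weight, names.arg = mp$model_id,
                    xlab = "pedigree model", ylab = "posterior weight",
                    main = "Candidate pedigree posterior weights")
  grDevices::dev.off()
  files <- c(files, f1)

  f2 <- file.path(out_dir, "posterior_marginals.pdf")
  draws <- report$samples$draws
  keep <- grep("^(b:|burial:)", colnames(draws), value = TRUE)
  grDevices::pdf(f2, width = 7, height = 2.5 * length(keep))
  graphics::par(mfrow = c(length(keep), 1), mar = c(4, 4, 2, 1))
  for (cn in keep) {
    v <- draws[, cn]
    if (stats::sd(v) == 0) {
      graphics::plot(v[1], 1, type = "h", xlab = "year (astronomical)",
                     ylab = "density", main = cn,
                     xlim = v[1] + c(-1, 1))
    } else {
      d <- stats::density(v)
      graphics::plot(d, xlim = range(v), xlab = "year (astronomical)",
                     main = cn)
    }
  }
  grDevices::dev.off()
  files <- c(files, f2)
  invisible(files)
}

#' Write a simulated dataset to disk
#'
#' Gene-drops genotypes under a catalogued pedigree model, pseudo-haploidizes
#' them, simulates segments and chronology, and writes the EIGENSTRAT trio,
#' a metadata TSV and a segment TSV — the `simulate pedigree` CLI
#' subcommand.
#'
#' @param model_id catalogue model (1-11).
#' @param n_snps number of sites.
#' @param seed RNG seed.
#' @param out_prefix output path prefix.
#' @param focal ids for the focal pair.
#' @param missing_rate,error_rate pseudo-haploid observation parameters.
#' @return list of written paths, invisibly.
#' @export
simulate_dataset <- function(model_id, n_snps = 2e5, seed = 7L,
                             out_prefix = "sim", focal = c("A", "B"),
                             missing_rate = 0.3, error_rate = 0.005) {
  models <- enumerate_candidate_pedigrees(focal[1], focal[2])
  model <- models[[model_id]]
  ped <- as_sim_pedigree(model)
  cfg <- sim_config(n_snps = n_snps, missing_rate = missing_rate,
                    error_rate = error_rate, seed = seed)
  gd <- gene_drop(ped, cfg)
  gm <- pseudo_haploidize(gd, cfg)
  write_eigenstrat(gm, out_prefix)
  priors <- chrono_priors(list(
    individual(focal[1], burial_lo = -600, burial_hi = -400),
    individual(focal[2], burial_lo = -600, burial_hi = -400)),
    root_window = c(-700, -400))
  sim <- simulate_chronology(model, priors, seed = seed)
  write_metadata(sim$individuals, paste0(out_prefix, "_metadata.tsv"))
  seg <- simulate_recombination(ped, genetic_map(), seed = seed,
                                roh_ids = ped$id,
                                ibd_pairs = list(focal), min_cM = 4)
  write_segments(seg, paste0(out_prefix, "_segments.tsv"))
  invisible(list(eigenstrat = out_prefix,
                 metadata = paste0(out_prefix, "_metadata.tsv"),
                 segments = paste0(out_prefix, "_segments.tsv")))
}
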