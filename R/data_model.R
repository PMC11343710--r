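# Domain types and file I/O: individuals, pseudo-haploid genotype matrices
# (EIGENSTRAT dialect), RoH/IBD segment tables, genetic maps, analysis config.

#' Construct an Individual record
#'
#' One sampled person with the observed quantities the pedigree model uses:
#' a chromosomal sex call, an archaeological burial-date interval, an
#' osteological age-at-death interval, and optional uniparental haplotype
#' labels.
#'
#' Calendar years use astronomical numbering (1 BCE = year 0, so 616 BCE is
#' -615); strings like `"616 BCE"` are converted at construction and never
#' again.
#'
#' @param id sample identifier.
#' @param sex `"XX"`, `"XY"` or `"unknown"`.
#' @param burial_lo,burial_hi burial-date interval bounds (years, astronomical
#'   numbering or `"N BCE"` strings), `burial_lo <= burial_hi`.
#' @param age_lo,age_hi osteological age-at-death interval, within \[0, 110\].
#' @param site site label.
#' @param mt_haplotype,y_haplogroup optional haplotype labels; `NA` when the
#'   sample is too poorly covered to call.
#' @return an object of class `individual` (a named list).
#' @export
individual <- function(id, sex = c("unknown", "XX", "XY"),
                       burial_lo = -Inf, burial_hi = Inf,
                       age_lo = 0, age_hi = 110,
                       site = NA_character_,
                       mt_haplotype = NA_character_,
                       y_haplogroup = NA_character_) {
  sex <- match.arg(sex, c("unknown", "XX", "XY"))
  burial_lo <- parse_year(burial_lo)
  burial_hi <- parse_year(burial_hi)
  age_lo <- as.numeric(age_lo); age_hi <- as.numeric(age_hi)
  dk_assert(burial_lo <= burial_hi,
            sprintf("individual %s: burial interval inverted [%s, %s]",
                    id, burial_lo, burial_hi))
  dk_assert(age_lo >= 0 && age_lo <= age_hi && age_hi <= 110,
            sprintf("individual %s: age-at-death interval must satisfy 0 <= lo <= hi <= 110", id))
  structure(list(id = as.character(id), site = as.character(site), sex = sex,
                 burial_interval = c(lo = burial_lo, hi = burial_hi),
                 age_interval = c(lo = age_lo, hi = age_hi),
                 mt_haplotype = as.character(mt_haplotype),
                 y_haplogroup = as.character(y_haplogroup)),
            class = "individual")
}

#' @export
print.individual <- function(x, ...) {
  cat(sprintf("<individual> %s (%s, %s)  burial [%g, %g]  age [%g, %g]  mt=%s\n",
              x$id, x$site, x$sex,
              x$burial_interval[["lo"]], x$burial_interval[["hi"]],
              x$age_interval[["lo"]], x$age_interval[["hi"]],
              ifelse(is.na(x$mt_haplotype), "-", x$mt_haplotype)))
  invisible(x)
}

#' Read per-individual metadata
#'
#' Expects a delimited table (TSV or CSV, sniffed from the extension) with
#' columns `id`, `sex`, `burial_lo`, `burial_hi`, `age_lo`, `age_hi`,
#' `mt_haplotype`; optional `site` and `y_haplogroup`. Years may be numeric
#' (astronomical) or `"N BCE"` strings.
#'
#' @param path path to the table.
#' @return a list of [individual()] records, named by id.
#' @export
read_metadata <- function(path) {
  dk_assert(file.exists(path), sprintf("metadata file not found: %s", path),
            "dk_input_error")
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, na.strings = c("NA", ""),
                           comment.char = "#", quote = "\"")
  need <- c("id", "sex", "burial_lo", "burial_hi", "age_lo", "age_hi", "mt_haplotype")
  miss <- setdiff(need, names(tab))
  dk_assert(length(miss) == 0,
            sprintf("metadata missing required column(s): %s", paste(miss, collapse = ", ")),
            "dk_format_error")
  out <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    r <- tab[i, ]
    out[[i]] <- tryCatch(
      individual(id = r$id, sex = as.character(r$sex),
                 burial_lo = r$burial_lo, burial_hi = r$burial_hi,
                 age_lo = r$age_lo, age_hi = r$age_hi,
                 site = if ("site" %in% names(tab)) r$site else NA,
                 mt_haplotype = r$mt_haplotype,
                 y_haplogroup = if ("y_haplogroup" %in% names(tab)) r$y_haplogroup else NA),
      dynastikin_error = function(e)
        dk_error(sprintf("metadata row %d: %s", i, conditionMessage(e)),
                 "dk_validation_error"))
  }
  names(out) <- vapply(out, `[[`, "", "id")
  out
}

#' Write per-individual metadata
#'
#' @param individuals a list of [individual()] records.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(individuals, path) {
  tab <- do.call(rbind, lapply(individuals, function(x) {
    data.frame(id = x$id, site = x$site, sex = x$sex,
               burial_lo = x$burial_interval[["lo"]],
               burial_hi = x$burial_interval[["hi"]],
               age_lo = x$age_interval[["lo"]], age_hi = x$age_interval[["hi"]],
               mt_haplotype = x$mt_haplotype, y_haplogroup = x$y_haplogroup,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a pseudo-haploid genotype matrix
#'
#' Calls are 0 (reference allele), 1 (alternative allele) or `NA` (missing) —
#' never heterozygous: each call is a single randomly sampled allele, the
#' standard representation for low-coverage ancient DNA.
#'
#' @param calls integer matrix, individuals in rows, SNPs in columns; values
#'   in `{0, 1, NA}`.
#' @param snps data frame with columns `id`, `chrom`, `pos`, `ref`, `alt`;
#'   positions must be strictly increasing within a chromosome.
#' @param individuals character vector of row ids.
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls, snps, individuals = rownames(calls)) {
  calls <- as.matrix(calls)
  dk_assert(!is.null(individuals) && length(individuals) == nrow(calls),
            "individual ids must match the call matrix rows")
  dk_assert(nrow(snps) == ncol(calls),
            sprintf("snp table has %d rows but call matrix has %d columns",
                    nrow(snps), ncol(calls)), "dk_format_error")
  vals <- calls[!is.na(calls)]
  dk_assert(all(vals %in% c(0L, 1L)),
            "pseudo-haploid calls must be 0, 1 or NA (no heterozygotes)")
  for (ch in unique(snps$chrom)) {
    p <- snps$pos[snps$chrom == ch]
    dk_assert(all(diff(p) > 0),
              sprintf("positions not strictly increasing on chromosome %s", ch))
  }
  rownames(calls) <- individuals
  structure(list(calls = calls, snps = snps,
                 individuals = as.character(individuals)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d individuals x %d SNPs, %.1f%% missing\n",
              nrow(x$calls), ncol(x$calls),
              100 * mean(is.na(x$calls))))
  invisible(x)
}

#' Read an EIGENSTRAT genotype trio
#'
#' Reads the `.geno`/`.snp`/`.ind` plain-text trio used by the 1240k-capture
#' ecosystem. Genotype symbols count reference alleles: for pseudo-haploid
#' data rows contain only `0` (alt call), `2` (ref call) and `9` (missing).
#' A diploid heterozygote `1` is rejected by default or down-coded to missing
#' with `het = "missing"`.
#'
#' @param prefix path prefix, so `<prefix>.geno` etc. exist; alternatively
#'   pass the three paths explicitly.
#' @param geno_path,snp_path,ind_path explicit file paths (override `prefix`).
#' @param het `"error"` (default) or `"missing"`.
#' @return a [genotype_matrix()].
#' @export
read_eigenstrat <- function(prefix = NULL, geno_path = NULL, snp_path = NULL,
                            ind_path = NULL, het = c("error", "missing")) {
  het <- match.arg(het)
  if (!is.null(prefix)) {
    if (is.null(geno_path)) geno_path <- paste0(prefix, ".geno")
    if (is.null(snp_path)) snp_path <- paste0(prefix, ".snp")
    if (is.null(ind_path)) ind_path <- paste0(prefix, ".ind")
  }
  for (p in c(geno_path, snp_path, ind_path)) {
    dk_assert(file.exists(p), sprintf("file not found: %s", p), "dk_input_error")
  }
  ind <- utils::read.table(ind_path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("id", "sex", "group"))
  snp <- utils::read.table(snp_path, header = FALSE, stringsAsFactors = FALSE)
  dk_assert(ncol(snp) >= 6, "snp file must have 6 columns (id chrom genpos pos ref alt)",
            "dk_format_error")
  snp <- snp[, 1:6]
  names(snp) <- c("id", "chrom", "genpos", "pos", "ref", "alt")
  lines <- readLines(geno_path)
  dk_assert(length(lines) > 0, sprintf("empty geno file: %s", geno_path),
            "dk_format_error")
  dk_assert(length(lines) == nrow(snp),
            sprintf("geno file has %d rows but snp file has %d",
                    length(lines), nrow(snp)), "dk_format_error")
  widths <- nchar(lines)
  dk_assert(all(widths == nrow(ind)),
            sprintf("geno row width mismatch (first bad line %d: %d chars, expected %d individuals)",
                    which(widths != nrow(ind))[1],
                    widths[which(widths != nrow(ind))[1]], nrow(ind)),
            "dk_format_error")
  # one char per individual per SNP row; columns are individuals
  mat <- matrix(unlist(strsplit(lines, "", fixed = TRUE), use.names = FALSE),
                nrow = nrow(ind), ncol = nrow(snp))
  bad <- matrix(!(mat %in% c("0", "1", "2", "9")), nrow = nrow(mat))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    dk_error(sprintf("unknown genotype symbol '%s' at geno line %d, individual %d",
                     mat[bad][1], idx[2], idx[1]), "dk_parse_error")
  }
  if (any(mat == "1")) {
    if (het == "error") {
      ln <- which(apply(mat == "1", 2, any))[1]
      dk_error(sprintf("diploid heterozygote in pseudo-haploid input at geno line %d (use het = 'missing' to down-code)", ln),
               "dk_format_error")
    }
    mat[mat == "1"] <- "9"
  }
  calls <- matrix(NA_integer_, nrow = nrow(ind), ncol = nrow(snp))
  calls[mat == "2"] <- 0L  # two reference alleles -> ref call
  calls[mat == "0"] <- 1L  # zero reference alleles -> alt call
  genotype_matrix(calls, snp, individuals = ind$id)
}

#' Write an EIGENSTRAT genotype trio
#'
#' Inverse of [read_eigenstrat()]: ref calls become `2`, alt calls `0`,
#' missing `9`.
#'
#' @param gm a [genotype_matrix()].
#' @param prefix output path prefix.
#' @param sexes optional character vector of sex codes for the `.ind` file
#'   (`M`/`F`/`U`), recycled to the number of individuals.
#' @return `prefix`, invisibly.
#' @export
write_eigenstrat <- function(gm, prefix, sexes = "U") {
  sym <- matrix("9", nrow = nrow(gm$calls), ncol = ncol(gm$calls))
  sym[!is.na(gm$calls) & gm$calls == 0L] <- "2"
  sym[!is.na(gm$calls) & gm$calls == 1L] <- "0"
  writeLines(apply(sym, 2, paste, collapse = ""), paste0(prefix, ".geno"))
  snp <- gm$snps
  utils::write.table(
    data.frame(snp$id, snp$chrom,
               if ("genpos" %in% names(snp)) snp$genpos else 0,
               snp$pos, snp$ref, snp$alt),
    paste0(prefix, ".snp"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(
    data.frame(gm$individuals, rep_len(sexes, length(gm$individuals)), "sample"),
    paste0(prefix, ".ind"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Construct a segment table
#'
#' RoH or IBD segments in centimorgan coordinates, half-open `[start, end)`
#' so that lengths add without end corrections. Overlapping or abutting
#' segments of one carrier on one chromosome are merged on construction.
#'
#' @param carrier carrier id (an individual, or a pair encoded as
#'   `"A|B"` — see [pair_id()]).
#' @param chrom chromosome (1-22).
#' @param start_cM,end_cM segment bounds in cM, `end_cM > start_cM`.
#' @return a data frame of class `segment_table`, sorted and normalized.
#' @export
segment_table <- function(carrier = character(), chrom = integer(),
                          start_cM = numeric(), end_cM = numeric()) {
  df <- data.frame(carrier = as.character(carrier),
                   chrom = as.integer(chrom),
                   start_cM = as.numeric(start_cM),
                   end_cM = as.numeric(end_cM),
                   stringsAsFactors = FALSE)
  if (nrow(df)) {
    bad <- df$end_cM <= df$start_cM
    dk_assert(!any(bad),
              sprintf("segment with non-positive length at row %d", which(bad)[1]))
    df <- df[order(df$carrier, df$chrom, df$start_cM), , drop = FALSE]
    df <- do.call(rbind, lapply(split(df, list(df$carrier, df$chrom), drop = TRUE),
                                merge_segments_one))
    df <- df[order(df$carrier, df$chrom, df$start_cM), , drop = FALSE]
    rownames(df) <- NULL
  }
  class(df) <- c("segment_table", "data.frame")
  df
}

# merge sorted, same-carrier same-chromosome half-open segments
merge_segments_one <- function(df) {
  if (nrow(df) <= 1) return(df)
  keep_start <- df$start_cM[1]; out <- df[0, ]
  cur_end <- df$end_cM[1]
  for (i in seq_len(nrow(df))[-1]) {
    if (df$start_cM[i] <= cur_end) {
      cur_end <- max(cur_end, df$end_cM[i])
    } else {
      out <- rbind(out, data.frame(carrier = df$carrier[1], chrom = df$chrom[1],
                                   start_cM = keep_start, end_cM = cur_end))
      keep_start <- df$start_cM[i]; cur_end <- df$end_cM[i]
    }
  }
  rbind(out, data.frame(carrier = df$carrier[1], chrom = df$chrom[1],
                        start_cM = keep_start, end_cM = cur_end))
}

#' Canonical id for an unordered pair
#'
#' @param a,b individual ids.
#' @return `"A|B"` with the two ids sorted, so the pair id is order-free.
#' @export
pair_id <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")

#' Read a segment table
#'
#' @param path TSV/CSV with columns `carrier`, `chrom`, `start_cM`, `end_cM`.
#' @return a [segment_table()]; an empty file yields an empty table.
#' @export
read_segments <- function(path) {
  dk_assert(file.exists(path), sprintf("segment file not found: %s", path),
            "dk_input_error")
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  first <- readLines(path, n = 1L)
  if (length(first) == 0) return(segment_table())
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  if (nrow(tab) == 0) return(segment_table())
  need <- c("carrier", "chrom", "start_cM", "end_cM")
  dk_assert(all(need %in% names(tab)),
            sprintf("segment table must have columns: %s", paste(need, collapse = ", ")),
            "dk_format_error")
  segment_table(tab$carrier, tab$chrom, tab$start_cM, tab$end_cM)
}

#' Write a segment table
#' @param seg a [segment_table()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_segments <- function(seg, path) {
  utils::write.table(as.data.frame(seg), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# relative sex-averaged autosome lengths (chr1..chr22), rescaled to total L
.AUTOSOME_REL <- c(284.2, 269.4, 223.4, 214.2, 204.1, 192.5, 187.3, 168.9,
                   166.4, 181.1, 158.2, 174.7, 125.9, 120.2, 141.8, 134.0,
                   128.5, 117.5, 107.9, 108.3, 62.8, 74.1)

#' Construct a genetic map
#'
#' Per-autosome genetic lengths in cM. The default rescales a standard
#' sex-averaged map shape to a total autosomal length of 3545 cM.
#'
#' @param lengths_cM numeric vector of 22 positive autosome lengths, or
#'   `NULL` to use the default shape rescaled to `total_cM`.
#' @param total_cM total genome length used when `lengths_cM` is `NULL`.
#' @return object of class `genetic_map` with fields `lengths_cM` and
#'   `L` (the total).
#' @export
genetic_map <- function(lengths_cM = NULL, total_cM = 3545) {
  if (is.null(lengths_cM)) {
    lengths_cM <- .AUTOSOME_REL * (total_cM / sum(.AUTOSOME_REL))
  }
  dk_assert(length(lengths_cM) == 22, "a genetic map needs 22 autosome lengths")
  dk_assert(all(lengths_cM > 0), "all map lengths must be positive")
  structure(list(lengths_cM = as.numeric(lengths_cM), L = sum(lengths_cM)),
            class = "genetic_map")
}

#' Analysis configuration defaults
#'
#' Central bag of tunables shared by the pipeline stages. Every stochastic
#' stage takes its seed from here; all counts must be positive.
#'
#' @param seed integer RNG seed.
#' @param n_draws Monte-Carlo draws per model for the marginal likelihood.
#' @param n_chains,n_iter MCMC chain count and per-chain length.
#' @param min_overlap minimum number of jointly called SNPs for a pairwise
#'   mismatch rate (default 15000 keeps the binomial SE below ~0.004 at
#'   typical baselines).
#' @param p0 unrelated-pair baseline mismatch rate; `NULL` means estimate it
#'   from the cohort with [baseline_rate()].
#' @param f_background population frequency of the shared mtDNA haplotype,
#'   in (0, 1]; 1 makes the mtDNA evidence uninformative.
#' @param model_prior prior weight vector over candidate pedigrees (`NULL`
#'   for uniform); must sum to 1.
#' @param maternal,paternal age-at-birth prior parameters: lists with
#'   `mean`, `sd`, `lo`, `hi` (truncated normal, years).
#' @param roh_consanguinity_cM total-RoH cut above which parents are called
#'   close kin (default 150 cM).
#' @return a named list of class `analysis_config`.
#' @export
analysis_config <- function(seed = 1L, n_draws = 1e5, n_chains = 4L,
                            n_iter = 2e4L, min_overlap = 15000,
                            p0 = NULL, f_background = 0.01,
                            model_prior = NULL,
                            maternal = list(mean = 26, sd = 7, lo = 13, hi = 50),
                            paternal = list(mean = 32, sd = 9, lo = 15, hi = 60),
                            roh_consanguinity_cM = 150) {
  dk_assert(n_draws > 0 && n_chains > 0 && n_iter > 0 && min_overlap > 0,
            "all counts must be positive")
  dk_assert(f_background > 0 && f_background <= 1, "f_background must lie in (0, 1]")
  if (!is.null(model_prior)) {
    dk_assert(abs(sum(model_prior) - 1) < 1e-8, "model priors must sum to 1")
  }
  structure(list(seed = as.integer(seed), n_draws = n_draws,
                 n_chains = as.integer(n_chains), n_iter = as.integer(n_iter),
                 min_overlap = min_overlap, p0 = p0,
                 f_background = f_background, model_prior = model_prior,
                 maternal = maternal, paternal = paternal,
                 roh_consanguinity_cM = roh_consanguinity_cM),
            class = "analysis_config")
}

#' Read an analysis configuration file
#'
#' YAML (or JSON) file whose top-level keys override [analysis_config()]
#' defaults; unknown keys are kept for pipeline use (input paths etc.).
#'
#' @param path config file path.
#' @return a list: validated `analysis_config` entries plus any extra keys.
#' @export
read_config <- function(path) {
  dk_assert(file.exists(path), sprintf("config file not found: %s", path),
            "dk_input_error")
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- names(formals(analysis_config))
  cfg <- do.call(analysis_config, raw[intersect(names(raw), known)])
  extra <- raw[setdiff(names(raw), known)]
  c(cfg, extra)
}
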