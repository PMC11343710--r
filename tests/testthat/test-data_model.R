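# data model: individuals, EIGENSTRAT I/O, metadata, segment tables

test_that("year parsing applies the astronomical convention exactly once", {
  expect_equal(parse_year("616 BCE"), -615)
  expect_equal(parse_year("1 BCE"), 0)
  expect_equal(parse_year("45 CE"), 45)
  expect_equal(parse_year(-539), -539)
  expect_error(parse_year("sometime"), class = "dk_parse_error")
})

test_that("individual validates its intervals", {
  x <- individual("HOC001", sex = "XY", burial_lo = -539, burial_hi = -521,
                  age_lo = 30, age_hi = 40, mt_haplotype = "J1b1a1")
  expect_equal(unname(x$burial_interval), c(-539, -521))
  expect_error(individual("bad", burial_lo = -500, burial_hi = -510),
               class = "dk_validation_error")
  expect_error(individual("bad", age_lo = 50, age_hi = 40),
               class = "dk_validation_error")
  expect_error(individual("bad", age_lo = 90, age_hi = 120),
               class = "dk_validation_error")
})

test_that("EIGENSTRAT symbols map per convention and round-trip", {
  d <- withr::local_tempdir()
  writeLines(c("02", "29", "90"), file.path(d, "t.geno"))
  writeLines(c("rs1\t1\t0\t100\tA\tG", "rs2\t1\t0\t200\tA\tG",
               "rs3\t1\t0\t300\tA\tG"), file.path(d, "t.snp"))
  writeLines(c("I1\tU\tpop", "I2\tU\tpop"), file.path(d, "t.ind"))
  gm <- read_eigenstrat(file.path(d, "t"))
  # 0 -> alt (1), 2 -> ref (0), 9 -> missing
  expect_equal(unname(gm$calls["I1", ]), c(1L, 0L, NA))
  expect_equal(unname(gm$calls["I2", ]), c(0L, NA, 1L))

  write_eigenstrat(gm, file.path(d, "rt"))
  gm2 <- read_eigenstrat(file.path(d, "rt"))
  expect_equal(gm2$calls, gm$calls)
  expect_equal(gm2$individuals, gm$individuals)
  expect_equal(gm2$snps$pos, gm$snps$pos)
})

test_that("EIGENSTRAT reader rejects malformed input", {
  d <- withr::local_tempdir()
  writeLines(character(), file.path(d, "e.geno"))
  writeLines("rs1\t1\t0\t100\tA\tG", file.path(d, "e.snp"))
  writeLines("I1\tU\tpop", file.path(d, "e.ind"))
  expect_error(read_eigenstrat(file.path(d, "e")), class = "dk_format_error")

  writeLines(c("00", "0"), file.path(d, "w.geno"))
  writeLines(c("rs1\t1\t0\t100\tA\tG", "rs2\t1\t0\t200\tA\tG"),
             file.path(d, "w.snp"))
  writeLines(c("I1\tU\tpop", "I2\tU\tpop"), file.path(d, "w.ind"))
  expect_error(read_eigenstrat(file.path(d, "w")), class = "dk_format_error")

  writeLines(c("0X"), file.path(d, "x.geno"))
  writeLines("rs1\t1\t0\t100\tA\tG", file.path(d, "x.snp"))
  writeLines(c("I1\tU\tpop", "I2\tU\tpop"), file.path(d, "x.ind"))
  expect_error(read_eigenstrat(file.path(d, "x")), class = "dk_parse_error")

  # heterozygote: rejected by default, down-coded on request
  writeLines(c("01"), file.path(d, "h.geno"))
  writeLines("rs1\t1\t0\t100\tA\tG", file.path(d, "h.snp"))
  writeLines(c("I1\tU\tpop", "I2\tU\tpop"), file.path(d, "h.ind"))
  expect_error(read_eigenstrat(file.path(d, "h")), class = "dk_format_error")
  gm <- read_eigenstrat(file.path(d, "h"), het = "missing")
  expect_true(is.na(gm$calls["I2", 1]))
})

test_that("metadata reader parses, validates and counts a roster", {
  d <- withr::local_tempdir()
  p <- file.path(d, "meta.tsv")
  writeLines(paste(
    c("id\tsite\tsex\tburial_lo\tburial_hi\tage_lo\tage_hi\tmt_haplotype",
      "HOC001\tEH\tXY\t-539\t-521\t30\t40\tJ1b1a1",
      "APG001\tAG\tXY\t510 BCE\t480 BCE\t25\t35\tJ1b1a1")), p)
  meta <- read_metadata(p)
  expect_equal(unname(meta$HOC001$burial_interval), c(-539, -521))
  expect_equal(unname(meta$APG001$burial_interval), c(-509, -479))
  expect_equal(meta$HOC001$mt_haplotype, "J1b1a1")

  writeLines(c("id\tsex\tburial_lo\tburial_hi\tage_lo\tage_hi\tmt_haplotype",
               "B1\tXY\t-500\t-490\t45\t35\tH1"), p)
  err <- tryCatch(read_metadata(p), error = identity)
  expect_s3_class(err, "dk_validation_error")
  expect_match(conditionMessage(err), "row 1")

  roster <- read_metadata(write_roster_fixture(file.path(d, "roster.tsv")))
  expect_length(roster, 31)
  sexes <- vapply(roster, `[[`, "", "sex")
  expect_equal(sum(sexes == "XY"), 20)
  expect_equal(sum(sexes == "XX"), 11)

  # round-trip
  write_metadata(roster, file.path(d, "rt.tsv"))
  roster2 <- read_metadata(file.path(d, "rt.tsv"))
  expect_equal(roster2, roster)
})

test_that("segment tables merge, validate and round-trip", {
  seg <- segment_table(c("A", "A"), c(1, 1), c(10, 15), c(20, 30))
  expect_equal(nrow(seg), 1)
  expect_equal(seg$start_cM, 10)
  expect_equal(seg$end_cM, 30)

  expect_error(segment_table("A", 1, 20, 10), class = "dk_validation_error")

  d <- withr::local_tempdir()
  p <- file.path(d, "seg.tsv")
  writeLines("carrier\tchrom\tstart_cM\tend_cM", p)
  expect_equal(nrow(read_segments(p)), 0)

  seg <- segment_table(rep("A", 3), c(1, 1, 2), c(0, 50, 5), c(10, 70, 10))
  expect_equal(sum(seg$end_cM - seg$start_cM), 35)
  write_segments(seg, p)
  seg2 <- read_segments(p)
  expect_equal(as.data.frame(seg2), as.data.frame(seg))
})

test_that("genetic map and analysis config validate", {
  map <- genetic_map()
  expect_length(map$lengths_cM, 22)
  expect_equal(map$L, 3545)
  expect_error(genetic_map(lengths_cM = rep(100, 21)), class = "dk_validation_error")
  expect_error(analysis_config(f_background = 0), class = "dk_validation_error")
  expect_error(analysis_config(n_draws = -1), class = "dk_validation_error")

  d <- withr::local_tempdir()
  p <- file.path(d, "cfg.yaml")
  writeLines(c("seed: 7", "f_background: 0.05", "focal: [A, B]"), p)
  cfg <- read_config(p)
  expect_equal(cfg$seed, 7L)
  expect_equal(cfg$f_background, 0.05)
  expect_equal(cfg$focal, c("A", "B"))
  expect_equal(cfg$n_chains, 4L)  # default preserved
})
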