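test_that("embryo read simulation is a pure function of config and seed", {
  spec <- make_toy_spec()
  s1 <- simulate_embryo_reads(spec, depth = 300, seed = 4)
  s2 <- simulate_embryo_reads(spec, depth = 300, seed = 4)
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$manifest$per_read, s2$manifest$per_read)
  s3 <- simulate_embryo_reads(spec, depth = 300, seed = 5)
  expect_false(identical(s1$reads$bases, s3$reads$bases))
  # FASTQ output is byte-identical across repeated runs
  p1 <- tempfile(); p2 <- tempfile()
  write_fastq(s1$reads, p1); write_fastq(s2$reads, p2)
  expect_identical(readLines(p1), readLines(p2))
  # the generator leaves the caller's RNG stream untouched
  set.seed(123); before <- runif(3)
  set.seed(123); invisible(simulate_embryo_reads(spec, depth = 10,
                                                 seed = 99))
  expect_identical(runif(3), before)
})

test_that("simulation config is validated", {
  spec <- make_toy_spec()
  expect_error(simulate_embryo_reads(spec, mix = c(wt = 0.6,
                                                   precise = 0.6)),
               "sum to 1")
  expect_error(simulate_embryo_reads(spec, subst_error_rate = 0.2),
               "subst_error_rate")
  amp <- random_seq(240)
  no_sec <- target_spec("x", amp, nick_pos = 110, edit_offset = 5,
                        edit_alt = chartr("ACGT", "GTAC",
                                          substr(amp, 115, 115)))
  expect_error(simulate_embryo_reads(no_sec,
                                     mix = c(wt = 0.5, precise = 0,
                                             internick_del = 0.5,
                                             combined = 0,
                                             small_indel = 0)),
               "secondary")
})

test_that("noise-free reads classify exactly as their true molecules", {
  spec <- make_toy_spec()
  sim <- simulate_embryo_reads(spec, depth = 500, subst_error_rate = 0,
                               p_lowq = 0, seed = 21,
                               mix = c(wt = 0.4, precise = 0.4,
                                       internick_del = 0.1,
                                       combined = 0.07,
                                       small_indel = 0.03))
  cls <- classify_reads(sim$reads, spec, method = 1)
  expect_equal(cls, sim$manifest$per_read$true_class)
  s <- summarize_embryo(cls, "e", method = 1)
  expect_equal(s$frac_precise,
               unname(sim$manifest$true_class_fractions["PRECISE"]))
  expect_equal(s$frac_error,
               unname(sim$manifest$true_class_fractions["ERROR"]))
})

test_that("control cohort reports the closed-form error expectation", {
  spec <- make_toy_spec()
  cohort <- simulate_control_cohort(spec, n_embryos = 2, depth = 50,
                                    subst_error_rate = 5e-4, seed = 3)
  expect_equal(cohort$window_length, 40L)
  expect_equal(cohort$expected_error_fraction, 1 - 0.9995^40)
  expect_equal(round(cohort$expected_error_fraction, 4), 0.0198)
  zero <- simulate_control_cohort(spec, n_embryos = 2, depth = 50,
                                  subst_error_rate = 0, band = NULL,
                                  seed = 3)
  expect_equal(zero$expected_error_fraction, 0)
  # a rate outside the requested band is refused
  expect_error(simulate_control_cohort(spec, n_embryos = 2,
                                       subst_error_rate = 1e-5,
                                       band = c(0.01, 0.06)), "band")
  # same seed, identical cohort
  c2 <- simulate_control_cohort(spec, n_embryos = 2, depth = 50,
                                subst_error_rate = 5e-4, seed = 3)
  expect_identical(lapply(cohort$embryos, `[[`, "reads"),
                   lapply(c2$embryos, `[[`, "reads"))
})

test_that("family simulation is deterministic and internally consistent", {
  f1 <- simulate_family(autosome_length = 30000L, sex_length = 10000L,
                        shared_variant_count = 30L, unique_snv_rate = 15,
                        unique_indel_rate_control = 10, seed = 8)
  f2 <- simulate_family(autosome_length = 30000L, sex_length = 10000L,
                        shared_variant_count = 30L, unique_snv_rate = 15,
                        unique_indel_rate_control = 10, seed = 8)
  expect_identical(f1$table$variants, f2$table$variants)
  expect_identical(f1$truth, f2$truth)
  # VCF bytes reproduce
  p1 <- tempfile(); p2 <- tempfile()
  write_family_vcf(f1$table, p1, f1$reference)
  write_family_vcf(f2$table, p2, f2$reference)
  expect_identical(readLines(p1), readLines(p2))
  # truth table covers every variant row
  expect_equal(nrow(f1$truth), nrow(f1$table$variants))
})

test_that("planted passing variants are exactly what the filter recovers", {
  fam <- simulate_family(autosome_length = 40000L, sex_length = 15000L,
                         shared_variant_count = 40L, unique_snv_rate = 20,
                         unique_indel_rate_control = 12, seed = 31)
  u <- find_unique_variants(fam$table)
  tr <- fam$truth[fam$truth$pass_filters, ]
  expect_equal(nrow(u), nrow(tr))
  expect_setequal(paste(u$chrom, u$pos, u$ref, u$alt, u$carrier_sample),
                  paste(tr$chrom, tr$pos, tr$ref, tr$alt, tr$carrier))
  expect_true(all(u$vaf >= 0.2))
})

test_that("simulated VCF round-trips through load_family unchanged", {
  fam <- simulate_family(autosome_length = 30000L, sex_length = 10000L,
                         shared_variant_count = 20L, unique_snv_rate = 10,
                         unique_indel_rate_control = 8, seed = 12)
  dir <- tempfile(); dir.create(dir)
  vcf <- file.path(dir, "family.vcf")
  write_family_vcf(fam$table, vcf, fam$reference)
  ped <- file.path(dir, "pedigree.tsv")
  write_pedigree(fam$table$samples, ped)
  back <- load_family(vcf, ped, reference = fam$reference)
  expect_equal(back$variants, fam$table$variants)
  expect_equal(unname(back$gt), unname(fam$table$gt))
  expect_equal(unname(back$dp), unname(fam$table$dp))
  expect_equal(unname(back$ad), unname(fam$table$ad))
})

test_that("off-target regions are planted clear of variants at 100 bp", {
  fam <- simulate_family(autosome_length = 40000L, sex_length = 15000L,
                         shared_variant_count = 30L, unique_snv_rate = 15,
                         unique_indel_rate_control = 10, n_offtargets = 10L,
                         seed = 77)
  counts <- count_region_variants(fam$table$variants,
                                  fam$regions$offtargets, pad_bp = 100L)
  expect_true(all(counts$count == 0L))
  expect_equal(nrow(fam$regions$microsatellites), 12L)
})
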