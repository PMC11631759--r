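bc <- c(s1 = "AAAAAAAAAA", s2 = "TTTTTTTTTT", s3 = "GGGGGGGGGG")

test_that("demultiplexing assigns within Hamming distance 1, never on ties", {
  body <- random_seq(60)
  rd <- reads_df(c(
    paste0("AAAAAAAAAA", body),   # exact match -> s1
    paste0("AAAAAAAAAT", body),   # distance 1 from s1, >= 2 from others
    paste0("CCCCCCCCCC", body),   # distance 10 from everything
    paste0("TTTTTTTTTG", body)))  # distance 1 from s2 only
  dm <- demultiplex(rd, bc)
  expect_equal(unname(dm$counts),
               c(2L, 1L, 0L, 1L))
  expect_equal(dm$samples$s1$read_id, c("r1", "r2"))
  expect_equal(dm$samples$s2$read_id, "r4")
  # barcode stripped: assigned reads start at amplicon position 0
  expect_equal(dm$samples$s1$bases, c(body, body))

  # a barcode within distance 1 of two references stays unassigned
  tie_bc <- c(a = "AAAA", b = "AATT")
  tie <- demultiplex(reads_df(paste0("AATA", body)), tie_bc)
  expect_equal(nrow(tie$unassigned), 1L)
  expect_equal(sum(vapply(tie$samples, nrow, 0L)), 0L)
})

test_that("demultiplexing rejects misconfigured barcode sets", {
  expect_error(demultiplex(reads_df("ACGT"), c(a = "AAAA", b = "AAAA")),
               "duplicate")
  expect_error(demultiplex(reads_df("ACGT"), c(a = "AAAA", b = "AAAAA")),
               "length")
  expect_error(demultiplex(reads_df("ACG"), c(a = "AAAA", b = "TTTT")),
               "shorter")
})

test_that("assignment bins partition the input reads", {
  set.seed(31)
  rd <- reads_df(vapply(1:200, function(i)
    paste0(sample(c(bc, "CACACACACA"), 1L),
           random_seq(40)), ""))
  dm <- demultiplex(rd, bc)
  expect_equal(sum(dm$counts), nrow(rd))
})

test_that("quality masking replaces exactly the sub-threshold calls", {
  rd <- reads_df("ACGTACGT",
                 quals = phred_encode(c(29, 30, 31, 2, 40, 29, 30, 40)))
  m <- mask_low_quality(rd)
  expect_equal(m$bases, "NCGNANGT")  # 29 masked, 30 kept (strict <)
  expect_true(m$masked)
  expect_equal(m$quals, rd$quals)    # qualities retained
  # idempotent
  expect_equal(mask_low_quality(m)$bases, m$bases)
  # all high-quality reads pass untouched
  hi <- reads_df("ACGT", quals = phred_encode(rep(30, 4)))
  expect_equal(mask_low_quality(hi)$bases, "ACGT")
})

test_that("ambiguity filter applies the strict >10% rule in the window", {
  spec <- make_toy_spec()
  # window [edit_pos - 40, edit_pos + 40] has 81 positions, all covered
  mk <- function(n_N) {
    b <- spec$amplicon
    pos <- spec$edit_pos + 1L - 40L + seq_len(n_N) - 1L
    for (p in pos) substr(b, p, p) <- "N"
    reads_df(b)
  }
  expect_true(filter_ambiguity(mk(0), spec)$keep)
  f9 <- filter_ambiguity(mk(9), spec)   # 9/81 = 11.1% > 10%
  expect_false(f9$keep)
  expect_equal(f9$n_frac, 9 / 81)
  expect_equal(f9$reason, "ambiguity")
  f8 <- filter_ambiguity(mk(8), spec)   # 8/81 = 9.9% <= 10%
  expect_true(f8$keep)
  expect_equal(f8$n_frac, 8 / 81)
  # too short to cover the interval
  short <- reads_df(substr(spec$amplicon, 1, spec$edit_pos))
  fs <- filter_ambiguity(short, spec)
  expect_false(fs$keep)
  expect_equal(fs$reason, "no_coverage")
})

test_that("seed filter removes reads below 90% seed identity", {
  spec <- make_toy_spec()
  mutate_seed <- function(n_mm, n_N = 0L) {
    b <- strsplit(spec$amplicon, "")[[1]]
    if (n_mm > 0L)
      for (p in seq_len(n_mm)) b[p] <- chartr("ACGT", "GTAC", b[p])
    if (n_N > 0L) b[n_mm + seq_len(n_N)] <- "N"
    reads_df(paste(b, collapse = ""))
  }
  expect_true(seed_filter(mutate_seed(0), spec)$keep)
  f5 <- seed_filter(mutate_seed(5), spec)   # 35/40 = 87.5% < 90%
  expect_false(f5$keep)
  expect_equal(f5$identity, 35 / 40)
  f4 <- seed_filter(mutate_seed(4), spec)   # 36/40 = 90%, boundary kept
  expect_true(f4$keep)
  expect_equal(f4$identity, 36 / 40)
  # masked bases are non-informative: 4 mismatches in 40 informative is
  # exactly 90% even with Ns present elsewhere... but >50% N discards
  fN <- seed_filter(mutate_seed(0, n_N = 21L), spec)
  expect_false(fN$keep)
  expect_equal(fN$reason, "seed_uninformative")
  fhalf <- seed_filter(mutate_seed(0, n_N = 20L), spec)
  expect_true(fhalf$keep)
  fshort <- seed_filter(reads_df("ACGT"), spec)
  expect_equal(fshort$reason, "short_read")
  # N positions drop out of numerator and denominator
  fmix <- seed_filter(mutate_seed(2, n_N = 10L), spec)
  expect_equal(fmix$identity, 28 / 30)
})

test_that("seed region overlapping nick/edit sites is a config error", {
  amp <- random_seq(120)
  spec <- target_spec("near", amp, nick_pos = 30, edit_offset = 2,
                      edit_alt = chartr("ACGT", "GTAC", substr(amp, 32, 32)))
  expect_error(seed_filter(reads_df(amp), spec), "seed")
})

test_that("noise-free wild-type reads all pass the full pipeline", {
  spec <- make_toy_spec(barcodes = c(e1 = strrep("ACGTA", 4),
                                     e2 = strrep("TGCAT", 4)))
  sim1 <- simulate_embryo_reads(spec, depth = 300, subst_error_rate = 0,
                                p_lowq = 0,
                                mix = c(wt = 1, precise = 0,
                                        internick_del = 0, combined = 0,
                                        small_indel = 0),
                                barcode = spec$barcode_map[["e1"]],
                                seed = 5)
  pp <- preprocess_reads(sim1$reads, spec)
  expect_equal(pp$report$n_kept[pp$report$sample_id == "e1"], 300L)
  expect_equal(pp$n_unassigned, 0L)
  # conservation across bins
  expect_equal(sum(pp$report$n_kept) + pp$n_unassigned +
                 sum(pp$report$n_input - pp$report$n_kept),
               300L)
})

test_that("preprocessing report accounts for every read", {
  spec <- make_toy_spec()
  sim <- simulate_embryo_reads(spec, depth = 500, subst_error_rate = 0.004,
                               p_lowq = 0.05, seed = 9,
                               mix = c(wt = 0.5, precise = 0.4,
                                       internick_del = 0.05,
                                       combined = 0.04,
                                       small_indel = 0.01))
  pp <- preprocess_reads(sim$reads, spec, demultiplex = FALSE)
  r <- pp$report
  expect_equal(r$n_input, 500L)
  expect_equal(r$n_kept + r$n_no_coverage + r$n_ambiguity +
                 r$n_short_read + r$n_seed_uninformative +
                 r$n_seed_identity, 500L)
})
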