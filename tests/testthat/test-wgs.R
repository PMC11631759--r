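simple_table <- function(gt_row, dp_row = rep(50L, 6L),
                         ad_row = c(20L, 0L, 0L, 0L, 0L, 0L),
                         chrom = "chr1") {
  family_variant_table(
    data.frame(chrom = chrom, pos = 1000L, ref = "A", alt = "G",
               stringsAsFactors = FALSE),
    gt = matrix(gt_row, 1L), dp = matrix(dp_row, 1L),
    ad = matrix(ad_row, 1L),
    samples = data.frame(sample_id = sprintf("s%d", 1:6),
                         role = c("parent", "parent", "control_offspring",
                                  "control_offspring", "treated_offspring",
                                  "treated_offspring"),
                         stringsAsFactors = FALSE))
}

test_that("each unique-variant rule admits or rejects as defined", {
  base_gt <- c("0/1", "0/0", "0/0", "0/0", "0/0", "0/0")
  u <- find_unique_variants(simple_table(base_gt))
  expect_equal(nrow(u), 1L)
  expect_equal(u$carrier_sample, "s1")
  expect_equal(u$vaf, 0.4)
  expect_equal(u$var_class, "SNV")
  # depth rule: one sample below 30 kills the site
  expect_equal(nrow(find_unique_variants(
    simple_table(base_gt, dp_row = c(50L, 29L, 50L, 50L, 50L, 50L)))), 0L)
  # two carriers
  expect_equal(nrow(find_unique_variants(
    simple_table(c("0/1", "0/1", "0/0", "0/0", "0/0", "0/0")))), 0L)
  # carrier VAF below 0.2
  expect_equal(nrow(find_unique_variants(
    simple_table(base_gt, ad_row = c(9L, 0L, 0L, 0L, 0L, 0L)))), 0L)
  expect_equal(nrow(find_unique_variants(
    simple_table(base_gt, ad_row = c(10L, 0L, 0L, 0L, 0L, 0L)))), 1L)
  # sex chromosomes excluded (including RefSeq-style names)
  expect_equal(nrow(find_unique_variants(simple_table(base_gt,
                                                      chrom = "chrX"))), 0L)
  expect_equal(nrow(find_unique_variants(
    simple_table(base_gt, chrom = "NC_000086.8"))), 0L)
  # a missing genotype in any sample drops the site (detection undefined)
  expect_equal(nrow(find_unique_variants(
    simple_table(c("0/1", "./.", "0/0", "0/0", "0/0", "0/0")))), 0L)
})

test_that("unique-variant filtering equals the brute-force oracle", {
  set.seed(23)
  for (k in 1:60) {
    tab <- random_family_table()
    got <- find_unique_variants(tab, excluded_chroms = c("chrX", "chrY"))
    want <- brute_unique_variants(tab)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want) > 0L) {
      key_got <- paste(got$chrom, got$pos, got$alt, got$carrier_sample)
      key_want <- paste(tab$variants$chrom[want$row],
                        tab$variants$pos[want$row],
                        tab$variants$alt[want$row], want$carrier)
      expect_setequal(key_got, key_want)
    }
  }
})

test_that("indel typing uses alt minus ref length", {
  u <- data.frame(chrom = "chr1", pos = c(1, 2, 3, 4), ref = c("AA", "A",
                                                               "A", "ACG"),
                  alt = c("A", "ACG", "G", "A"),
                  carrier_sample = c("s1", "s1", "s2", "s1"),
                  vaf = 0.4, stringsAsFactors = FALSE)
  u$size <- nchar(u$alt) - nchar(u$ref)
  cc <- classify_indels(u)
  expect_equal(cc$count[cc$sample_id == "s1" & cc$class == "del_1"], 1L)
  expect_equal(cc$count[cc$sample_id == "s1" & cc$class == "ins_2"], 1L)
  expect_equal(cc$count[cc$sample_id == "s1" & cc$class == "del_2"], 1L)
  expect_equal(cc$count[cc$sample_id == "s2" & cc$class == "SNV"], 1L)
  expect_equal(cc$count[cc$sample_id == "s2" & cc$class == "del_1"], 0L)
})

test_that("homopolymer adjacency flags tract deletions only", {
  #              0123456789012345678
  ref <- c(chr1 = "GCTAAAAGCGTCACGTGCA")
  del_at <- function(pos0) {
    # anchored -1 bp deletion of the base at pos0
    data.frame(chrom = "chr1", pos = pos0 - 1L,
               ref = substr(ref, pos0, pos0 + 1L),
               alt = substr(ref, pos0, pos0),
               carrier_sample = "s1", vaf = 0.5,
               size = -1L, stringsAsFactors = FALSE)
  }
  # deletion of the first A of the AAAA run (0-based 3)
  run_del <- del_at(3L)
  # deletion of the C at 0-based 11, flanked by T and A: no tract
  lone_del <- del_at(11L)
  # deletion of the G at 0-based 7, directly right of the AAAA run
  abut_del <- del_at(7L)
  res <- homopolymer_adjacent_fraction(rbind(run_del, lone_del, abut_del),
                                       ref)
  expect_equal(res$per_variant$homopolymer_adjacent, c(TRUE, FALSE, TRUE))
  expect_equal(res$per_sample$fraction, 2 / 3)
  # a sample with no -1 bp deletions reports NA, not zero
  snv_only <- data.frame(chrom = "chr1", pos = 1L, ref = "C", alt = "T",
                         carrier_sample = "s2", vaf = 0.5, size = 0L,
                         stringsAsFactors = FALSE)
  res2 <- homopolymer_adjacent_fraction(snv_only, ref)
  expect_true(is.na(res2$per_sample$fraction))
  outside <- del_at(3L); outside$pos <- 500L
  expect_error(homopolymer_adjacent_fraction(outside, ref), "reference")
})

test_that("region counting honors the pad and half-open bounds", {
  regions <- data.frame(chrom = "chr1", start = 1000L, end = 1100L,
                        name = "site1", stringsAsFactors = FALSE)
  v <- function(pos) data.frame(chrom = rep("chr1", length(pos)),
                                pos = pos, stringsAsFactors = FALSE)
  expect_equal(count_region_variants(v(950L), regions, pad_bp = 100L)$count,
               1L)  # 50 bp upstream
  expect_equal(count_region_variants(v(850L), regions, pad_bp = 100L)$count,
               0L)  # 150 bp upstream
  expect_equal(count_region_variants(v(1199L), regions,
                                     pad_bp = 100L)$count, 1L)
  expect_equal(count_region_variants(v(1200L), regions,
                                     pad_bp = 100L)$count, 0L)
  expect_equal(count_region_variants(v(999L), regions)$count, 0L)
  expect_equal(count_region_variants(v(1000L), regions)$count, 1L)
  none <- count_region_variants(v(integer(0)), regions, pad_bp = 100L)
  expect_equal(none$count, 0L)
})

test_that("fold change relates treated counts to the control mean", {
  mk_uniques <- function(counts) {
    do.call(rbind, lapply(names(counts), function(s) {
      n <- counts[[s]]
      if (n == 0L) return(NULL)
      data.frame(chrom = "chr1", pos = seq_len(n), ref = "AT", alt = "A",
                 carrier_sample = s, vaf = 0.4, size = -1L,
                 stringsAsFactors = FALSE)
    }))
  }
  samples <- data.frame(
    sample_id = c("p1", "p2", "c1", "c2", "t1", "t2", "t3"),
    role = c("parent", "parent", "control_offspring", "control_offspring",
             rep("treated_offspring", 3)), stringsAsFactors = FALSE)
  fc <- suppressWarnings(
    indel_fold_change(mk_uniques(c(p1 = 4L, p2 = 4L, c1 = 4L, c2 = 4L,
                                   t1 = 10L, t2 = 10L, t3 = 10L)),
                      samples))
  expect_equal(fc$per_treated$fold, rep(2.5, 3))
  expect_false(fc$undefined)
  expect_lt(fc$p_welch, 0.05)
  eq <- suppressWarnings(
    indel_fold_change(mk_uniques(c(p1 = 5L, p2 = 5L, c1 = 5L, c2 = 5L,
                                   t1 = 5L, t2 = 5L, t3 = 5L)),
                      samples))
  expect_equal(eq$per_treated$fold, rep(1, 3))
  zero <- suppressWarnings(
    indel_fold_change(mk_uniques(c(p1 = 0L, p2 = 0L, c1 = 0L,
                                   c2 = 0L, t1 = 3L, t2 = 3L,
                                   t3 = 3L)), samples))
  expect_true(zero$undefined)
  expect_true(all(is.na(zero$per_treated$fold)))
})

test_that("multiallelic decomposition and left-alignment on VCF load", {
  ref <- c(chr1 = paste0("GATTACAGATTACA", strrep("T", 8), "GCGCGC"))
  dir <- tempfile(); dir.create(dir)
  vcf <- file.path(dir, "fam.vcf")
  samples <- c("mom", "dad", "kid")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=28>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"a\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"d\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", samples), collapse = "\t"),
    # multiallelic SNV: A -> C,T at POS 5
    paste(c("chr1", "5", ".", "A", "C,T", ".", "PASS", ".", "GT:AD:DP",
            "0/1:30,20,0:50", "0/2:30,0,18:48", "0/0:50,0,0:50"),
          collapse = "\t"),
    # deletion inside the T homopolymer (not left-aligned: POS 18 TT>T;
    # run starts at POS 15)
    paste(c("chr1", "18", ".", "TT", "T", ".", "PASS", ".", "GT:AD:DP",
            "0/0:50,0:50", "0/0:49,0:49", "0/1:25,22:47"),
          collapse = "\t")), vcf)
  ped <- data.frame(sample_id = samples,
                    role = c("parent", "parent", "treated_offspring"),
                    stringsAsFactors = FALSE)
  tab <- load_family(vcf, ped, reference = ref)
  expect_equal(nrow(tab$variants), 3L)  # 2 from the multiallelic + 1
  first <- tab$variants[tab$variants$alt == "C", ]
  expect_equal(first$pos, 4L)           # 0-based
  expect_equal(tab$gt[tab$variants$alt == "C", ],
               c(mom = "0/1", dad = "0/0", kid = "0/0"))
  expect_equal(tab$gt[tab$variants$alt == "T" &
                        tab$variants$ref == "A", ],
               c(mom = "0/0", dad = "0/1", kid = "0/0"))
  expect_equal(unname(tab$ad[tab$variants$alt == "C", "dad"]), 0L)
  # the deletion left-aligns to the run start: anchor A at 0-based 13
  del <- tab$variants[nchar(tab$variants$ref) == 2L, ]
  expect_equal(del$pos, 13L)
  expect_equal(del$ref, "AT")
  expect_equal(del$alt, "A")
  expect_error(load_family(vcf, rbind(ped, data.frame(
    sample_id = "ghost", role = "parent"))), "missing")
})

test_that("allele normalization is idempotent", {
  ref <- c(chr1 = "GATTACAGATTACATTTTTTTTGC")
  n1 <- primeout:::normalize_allele("chr1", 17L, "TT", "T", ref)
  n2 <- primeout:::normalize_allele(n1$chrom, n1$pos, n1$ref, n1$alt, ref)
  expect_equal(n1, n2)
  expect_equal(n1$pos, 13L)
  # SNV and already-normalized indel pass through unchanged
  s <- primeout:::normalize_allele("chr1", 4L, "A", "G", ref)
  expect_equal(s$pos, 4L)
  expect_equal(s$ref, "A")
})
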