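# Independent oracles used to validate the package's own implementations.

# Exhaustive affine-gap global alignment score by path enumeration.
# Walks alignment columns right-to-left; `prev` is the move emitted at the
# column to the right, so a gap move is an extension iff prev continues the
# same gap. Tractable for sequences up to ~6 bases.
oracle_align_score <- function(a, b, match = 1, mismatch = 0,
                               gap_open = -3, gap_extend = -1) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  rec <- function(i, j, prev) {
    if (i == 0L && j == 0L) return(0)
    best <- -Inf
    if (i > 0L && j > 0L) {
      s <- if (av[i] == bv[j]) match else mismatch
      best <- max(best, rec(i - 1L, j - 1L, "M") + s)
    }
    if (i > 0L) {
      g <- if (identical(prev, "X")) gap_extend else gap_open
      best <- max(best, rec(i - 1L, j, "X") + g)
    }
    if (j > 0L) {
      g <- if (identical(prev, "Y")) gap_extend else gap_open
      best <- max(best, rec(i, j - 1L, "Y") + g)
    }
    best
  }
  rec(length(av), length(bv), "none")
}

random_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# Plain-loop re-implementation of the four unique-variant rules, written
# directly from their definitions (all-sample depth, single non-reference
# carrier with all others homozygous reference, carrier VAF, autosomes).
brute_unique_variants <- function(tab, min_depth = 30L, min_vaf = 0.2,
                                  excluded = c("chrX", "chrY", "X", "Y")) {
  hits <- list()
  for (v in seq_len(nrow(tab$variants))) {
    if (tab$variants$chrom[v] %in% excluded) next
    dps <- tab$dp[v, ]
    if (any(is.na(dps)) || any(dps < min_depth)) next
    carriers <- c()
    ok <- TRUE
    for (s in seq_len(nrow(tab$samples))) {
      g <- tab$gt[v, s]
      if (is.na(g)) { ok <- FALSE; break }
      alleles <- strsplit(g, "[/|]")[[1]]
      if (any(alleles == ".")) { ok <- FALSE; break }
      if (any(alleles == "1")) carriers <- c(carriers, s)
      else if (!all(alleles == "0")) { ok <- FALSE; break }
    }
    if (!ok || length(carriers) != 1L) next
    vaf <- tab$ad[v, carriers] / tab$dp[v, carriers]
    if (is.na(vaf) || vaf < min_vaf) next
    hits[[length(hits) + 1L]] <-
      data.frame(row = v, carrier = tab$samples$sample_id[carriers],
                 vaf = vaf, stringsAsFactors = FALSE)
  }
  if (length(hits) == 0L)
    return(data.frame(row = integer(0), carrier = character(0),
                      vaf = numeric(0)))
  do.call(rbind, hits)
}

# random small family tables exercising every filter rule
random_family_table <- function(n_var = 50L, n_samp = 6L) {
  sample_ids <- sprintf("s%d", seq_len(n_samp))
  roles <- c("parent", "parent",
             sample(c("control_offspring", "treated_offspring"),
                    n_samp - 2L, replace = TRUE))
  chrom <- sample(c("chr1", "chr2", "chrX"), n_var, replace = TRUE,
                  prob = c(0.45, 0.45, 0.1))
  pos <- sample.int(99999L, n_var)
  ref <- sample(c("A", "C", "G", "T", "AT", "GCC"), n_var, replace = TRUE)
  alt <- vapply(ref, function(r) {
    if (nchar(r) == 1L) sample(setdiff(c("A", "C", "G", "T"), r), 1L)
    else substr(r, 1L, 1L)
  }, "", USE.NAMES = FALSE)
  gt <- matrix(sample(c("0/0", "0/1", "1/1", "./.", "0|1"),
                      n_var * n_samp, replace = TRUE,
                      prob = c(0.72, 0.12, 0.06, 0.05, 0.05)),
               n_var, n_samp)
  dp <- matrix(sample(10:60, n_var * n_samp, replace = TRUE),
               n_var, n_samp)
  ad <- matrix(rbinom(n_var * n_samp, as.vector(dp), 0.35), n_var, n_samp)
  family_variant_table(
    data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
               stringsAsFactors = FALSE),
    gt = gt, dp = dp, ad = ad,
    samples = data.frame(sample_id = sample_ids, role = roles,
                         stringsAsFactors = FALSE))
}

# shared toy target: 240-nt amplicon with nick and edit sites well past a
# 40-nt seed, plus a secondary nick for double-nick analyses
make_toy_spec <- function(barcodes = NULL, seed = 20L) {
  amp <- local({
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(seed)
    paste(sample(c("A", "C", "G", "T"), 240, replace = TRUE), collapse = "")
  })
  alt <- chartr("ACGT", "GTAC", substr(amp, 115, 115))
  target_spec("toy", amp, nick_pos = 110L, edit_kind = "substitution",
              edit_offset = 5L, edit_alt = alt,
              secondary_nick_pos = 160L, barcode_map = barcodes)
}

perfect_quals <- function(seqs, q = 40L) {
  vapply(nchar(seqs), function(n) phred_encode(rep(q, n)), "")
}

reads_df <- function(seqs, quals = perfect_quals(seqs),
                     ids = sprintf("r%d", seq_along(seqs))) {
  data.frame(read_id = ids, bases = seqs, quals = quals,
             stringsAsFactors = FALSE)
}
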