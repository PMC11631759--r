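# Family-based unique-variant filtering and mismatch-repair signature
# analysis from joint-genotyped multi-sample VCFs.
#
# Internal container ("family_variant_table"):
#   variants  data.frame(chrom, pos, ref, alt)  -- pos 0-based; biallelic
#   gt, dp, ad  matrices (variants x samples): genotype string, total depth,
#               alt-supporting depth
#   samples   data.frame(sample_id, role), role in
#             {parent, control_offspring, treated_offspring}

SEX_CHROM_DEFAULT <- c("X", "Y", "chrX", "chrY",
                       "NC_000086.8", "NC_000087.8")

#' Construct a family variant table
#'
#' Usually produced by [load_family()]; the constructor is exported so that
#' variant tables can also be built programmatically (e.g. by the family
#' simulator or in tests).
#'
#' @param variants data.frame with columns `chrom`, `pos` (0-based), `ref`,
#'   `alt` (one alternate allele per row).
#' @param gt,dp,ad matrices (rows = variants, columns = samples) of
#'   genotype strings (e.g. `"0/1"`), total read depth and alt-supporting
#'   read depth.
#' @param samples data.frame with columns `sample_id` and `role`
#'   (`parent`, `control_offspring` or `treated_offspring`).
#' @return an object of class `family_variant_table`.
#' @export
family_variant_table <- function(variants, gt, dp, ad, samples) {
  stopifnot(is.data.frame(variants),
            all(c("chrom", "pos", "ref", "alt") %in% names(variants)),
            all(c("sample_id", "role") %in% names(samples)))
  n <- nrow(variants); m <- nrow(samples)
  for (mat in list(gt, dp, ad))
    if (!all(dim(mat) == c(n, m)))
      stop("gt/dp/ad must be variants x samples matrices")
  if (!all(samples$role %in% c("parent", "control_offspring",
                               "treated_offspring")))
    stop("unknown sample role")
  colnames(gt) <- colnames(dp) <- colnames(ad) <- samples$sample_id
  structure(list(variants = variants, gt = gt, dp = dp, ad = ad,
                 samples = samples), class = "family_variant_table")
}

#' @export
print.family_variant_table <- function(x, ...) {
  cat("Family variant table:", nrow(x$variants), "biallelic variants x",
      nrow(x$samples), "samples\n")
  print(table(x$samples$role))
  invisible(x)
}

#' Load a joint-genotyped family VCF
#'
#' Reads a multi-sample VCF with per-sample GT, DP and AD fields,
#' decomposes multiallelic records into biallelic rows, and (when a
#' reference is supplied) left-aligns and trims indel representations so
#' that the uniqueness and homopolymer-adjacency rules operate on
#' normalized alleles.
#'
#' @param vcf_path path to a VCF file (plain or bgzipped).
#' @param pedigree a data.frame with columns `sample_id` and `role`, or
#'   the path to a tab-separated file with those columns.
#' @param reference optional named character vector of contig sequences
#'   (see [read_reference()]); required for left-alignment.
#' @return a [family_variant_table()].
#' @export
load_family <- function(vcf_path, pedigree, reference = NULL) {
  if (is.character(pedigree))
    pedigree <- read.table(pedigree, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  stopifnot(all(c("sample_id", "role") %in% names(pedigree)))
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  vcf_samples <- colnames(v@gt)[-1]
  missing <- setdiff(pedigree$sample_id, vcf_samples)
  if (length(missing) > 0L)
    stop("pedigree samples missing from the VCF: ",
         paste(missing, collapse = ", "))
  gt_raw <- vcfR::extract.gt(v, element = "GT")
  dp_raw <- vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)
  ad_raw <- vcfR::extract.gt(v, element = "AD")
  if (is.null(gt_raw) || is.null(dp_raw) || is.null(ad_raw))
    stop("VCF must carry per-sample GT, DP and AD fields")
  ord <- match(pedigree$sample_id, vcf_samples)
  fix <- as.data.frame(v@fix[, c("CHROM", "POS", "REF", "ALT"),
                             drop = FALSE], stringsAsFactors = FALSE)

  out_var <- list(); out_gt <- list(); out_dp <- list(); out_ad <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    ads <- strsplit(ad_raw[i, ord], ",", fixed = TRUE)
    for (a in seq_along(alts)) {
      rec <- normalize_allele(fix$CHROM[i], as.integer(fix$POS[i]) - 1L,
                              fix$REF[i], alts[a], reference)
      out_var[[length(out_var) + 1L]] <- rec
      gts <- gt_raw[i, ord]
      # re-index genotypes against the decomposed biallelic row: the
      # chosen alt becomes allele 1, any other alt collapses to ref
      out_gt[[length(out_gt) + 1L]] <- vapply(gts, function(g) {
        if (is.na(g)) return(NA_character_)
        sep <- if (grepl("|", g, fixed = TRUE)) "|" else "/"
        al <- strsplit(g, sep, fixed = TRUE)[[1]]
        al <- ifelse(al == ".", ".", ifelse(al == as.character(a), "1", "0"))
        paste(al, collapse = "/")
      }, "", USE.NAMES = FALSE)
      out_dp[[length(out_dp) + 1L]] <- as.integer(dp_raw[i, ord])
      out_ad[[length(out_ad) + 1L]] <- vapply(ads, function(x) {
        if (length(x) >= a + 1L) suppressWarnings(as.integer(x[a + 1L]))
        else NA_integer_
      }, 0L, USE.NAMES = FALSE)
    }
  }
  variants <- do.call(rbind, out_var)
  rownames(variants) <- NULL
  family_variant_table(variants,
                       gt = do.call(rbind, out_gt),
                       dp = do.call(rbind, out_dp),
                       ad = do.call(rbind, out_ad),
                       samples = pedigree)
}

# Normalize one biallelic record: trim shared flanking bases and left-shift
# indels, keeping the VCF anchor-base convention. `pos` is 0-based.
normalize_allele <- function(chrom, pos, ref, alt, reference = NULL) {
  refseq <- if (!is.null(reference) && chrom %in% names(reference))
    reference[[chrom]] else NULL
  repeat {
    nr <- nchar(ref); na <- nchar(alt)
    if (nr > 0L && na > 0L &&
        substr(ref, nr, nr) == substr(alt, na, na)) {
      if (nr == 1L || na == 1L) {
        # need to extend left to keep trimming (pure left-shift)
        if (is.null(refseq) || pos == 0L) break
        prev <- substr(refseq, pos, pos)  # base at 0-based pos-1
        ref <- paste0(prev, substr(ref, 1L, nr - 1L))
        alt <- paste0(prev, substr(alt, 1L, na - 1L))
        pos <- pos - 1L
      } else {
        ref <- substr(ref, 1L, nr - 1L)
        alt <- substr(alt, 1L, na - 1L)
      }
    } else break
  }
  # trim shared leading bases (keep one anchor for indels)
  while (nchar(ref) >= 2L && nchar(alt) >= 2L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substr(ref, 2L, nchar(ref))
    alt <- substr(alt, 2L, nchar(alt))
    pos <- pos + 1L
  }
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
             stringsAsFactors = FALSE)
}

#' Find variants unique to one family member
#'
#' A variant is retained iff (a) every sample in the family has depth of
#' at least `min_depth` at the site, (b) exactly one sample carries a
#' non-reference genotype while all others are called homozygous
#' reference, (c) the carrier's variant allele frequency (alt depth /
#' total depth) is at least `min_vaf`, and (d) the chromosome is
#' autosomal (sex chromosomes excluded by name).
#'
#' @param table a [family_variant_table()].
#' @param min_depth minimum depth in every sample (default 30).
#' @param min_vaf minimum carrier variant allele frequency (default 0.2).
#' @param excluded_chroms chromosome names to exclude (defaults cover
#'   common X/Y aliases and the mouse RefSeq sex-chromosome accessions).
#' @return data.frame with one row per unique variant: `chrom`, `pos`,
#'   `ref`, `alt`, `carrier_sample`, `vaf`, `var_class` (`SNV`,
#'   `insertion`, `deletion`), `size` (alt length minus ref length).
#' @export
find_unique_variants <- function(table, min_depth = 30L, min_vaf = 0.2,
                                 excluded_chroms = SEX_CHROM_DEFAULT) {
  stopifnot(inherits(table, "family_variant_table"))
  v <- table$variants
  n <- nrow(v)
  empty <- data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      carrier_sample = character(0), vaf = numeric(0),
                      var_class = character(0), size = integer(0),
                      stringsAsFactors = FALSE)
  if (n == 0L) return(empty)
  det <- !is.na(table$gt) & grepl("1", table$gt, fixed = TRUE)
  is_ref <- !is.na(table$gt) & !grepl("[^0/|]", table$gt)
  depth_ok <- !is.na(table$dp) & table$dp >= min_depth
  rows <- which(rowSums(det) == 1L &
                rowSums(det | is_ref) == ncol(det) &
                rowSums(depth_ok) == ncol(det) &
                !(v$chrom %in% excluded_chroms))
  if (length(rows) == 0L) return(empty)
  carrier_idx <- apply(det[rows, , drop = FALSE], 1L, which)
  carrier <- table$samples$sample_id[carrier_idx]
  idx <- cbind(rows, carrier_idx)
  vaf <- table$ad[idx] / table$dp[idx]
  ok <- !is.na(vaf) & vaf >= min_vaf
  rows <- rows[ok]; carrier <- carrier[ok]; vaf <- vaf[ok]
  size <- nchar(v$alt[rows]) - nchar(v$ref[rows])
  out <- data.frame(chrom = v$chrom[rows], pos = v$pos[rows],
                    ref = v$ref[rows], alt = v$alt[rows],
                    carrier_sample = carrier, vaf = vaf,
                    var_class = ifelse(size == 0L, "SNV",
                                       ifelse(size > 0L, "insertion",
                                              "deletion")),
                    size = as.integer(size), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Tabulate unique variants by class and size
#'
#' Indel size is alt length minus ref length: negative for deletions,
#' positive for insertions, zero for SNVs (multi-nucleotide substitutions
#' count in the SNV class).
#'
#' @param uniques a [find_unique_variants()] result.
#' @param samples optional character vector of sample ids to report (so
#'   that samples with zero unique variants appear with count 0).
#' @return data.frame with columns `sample_id`, `class` (e.g. `SNV`,
#'   `del_1`, `ins_2`), `count`.
#' @export
classify_indels <- function(uniques, samples = NULL) {
  cls <- ifelse(uniques$size == 0L, "SNV",
                ifelse(uniques$size > 0L, paste0("ins_", uniques$size),
                       paste0("del_", -uniques$size)))
  samples <- samples %||% sort(unique(uniques$carrier_sample))
  levels_cls <- unique(c("SNV", sort(unique(cls))))
  tab <- table(factor(uniques$carrier_sample, levels = samples),
               factor(cls, levels = levels_cls))
  out <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(out) <- c("sample_id", "class", "count")
  out$count <- as.integer(out$count)
  out[order(out$sample_id, out$class), , drop = FALSE]
}

# run-length homopolymer annotation around one 0-based position
.tract_near <- function(refseq, d, min_tract) {
  base_at <- function(i) substr(refseq, i + 1L, i + 1L)
  run_len <- function(i) {
    b <- base_at(i)
    l <- i; r <- i
    while (l > 0L && base_at(l - 1L) == b) l <- l - 1L
    while (r < nchar(refseq) - 1L && base_at(r + 1L) == b) r <- r + 1L
    c(len = r - l + 1L, base = b)
  }
  for (i in c(d, d - 1L, d + 1L)) {
    if (i < 0L || i >= nchar(refseq)) next
    rl <- run_len(i)
    if (rl[["base"]] %in% c("A", "T") &&
        as.integer(rl[["len"]]) >= min_tract) {
      # the run must contain d or immediately abut it; runs looked up at
      # d-1 / d+1 qualify only if they do not span d without containing it
      return(list(adjacent = TRUE, base = rl[["base"]]))
    }
  }
  list(adjacent = FALSE, base = NA_character_)
}

#' Fraction of unique -1 bp deletions adjacent to poly(A/T) tracts
#'
#' Replication slippage under impaired mismatch repair produces single-base
#' deletions at homopolymer runs. For every unique -1 bp deletion, the
#' deleted base's reference context is scanned for a run of at least
#' `min_tract` identical A or T bases containing or immediately abutting
#' the deleted position (deletions are left-aligned, so a deletion inside
#' a tract always registers). Samples with no -1 bp deletions report `NA`,
#' not zero.
#'
#' @param uniques a [find_unique_variants()] result.
#' @param reference named character vector of contig sequences.
#' @param min_tract minimum homopolymer run length (default 4).
#' @param samples optional sample ids to report.
#' @return list with `per_variant` (the -1 bp deletions with a
#'   `homopolymer_adjacent` flag and `tract_base`) and `per_sample`
#'   (columns `sample_id`, `n_del1`, `n_adjacent`, `fraction`).
#' @export
homopolymer_adjacent_fraction <- function(uniques, reference,
                                          min_tract = 4L, samples = NULL) {
  del1 <- uniques[uniques$size == -1L, , drop = FALSE]
  flags <- logical(nrow(del1)); tract_base <- rep(NA_character_, nrow(del1))
  for (k in seq_len(nrow(del1))) {
    chrom <- del1$chrom[k]
    if (!chrom %in% names(reference))
      stop("variant locus on contig absent from the reference: ", chrom)
    refseq <- reference[[chrom]]
    if (del1$pos[k] + nchar(del1$ref[k]) > nchar(refseq))
      stop("variant locus outside the reference sequence")
    # anchored representation: deleted base sits one past the anchor
    d <- del1$pos[k] + 1L
    res <- .tract_near(refseq, d, min_tract)
    flags[k] <- res$adjacent
    tract_base[k] <- res$base
  }
  del1$homopolymer_adjacent <- flags
  del1$tract_base <- tract_base
  samples <- samples %||% sort(unique(uniques$carrier_sample))
  per_sample <- do.call(rbind, lapply(samples, function(s) {
    sel <- del1$carrier_sample == s
    n <- sum(sel)
    data.frame(sample_id = s, n_del1 = n, n_adjacent = sum(flags[sel]),
               fraction = if (n > 0L) sum(flags[sel]) / n else NA_real_,
               stringsAsFactors = FALSE)
  }))
  list(per_variant = del1, per_sample = per_sample)
}

#' Count variants in (padded) genomic regions
#'
#' A variant counts toward a region iff its position lies within
#' `[start - pad_bp, end + pad_bp)`. Off-target checks use a 100-bp pad
#' around each predicted site; microsatellite region counts use no pad.
#'
#' @param variants a data.frame with `chrom` and `pos` (0-based) columns,
#'   e.g. a [find_unique_variants()] result (per-carrier counts) or the
#'   `variants` slot of a family table (total counts).
#' @param regions data.frame with columns `chrom`, `start`, `end`
#'   (0-based half-open) and optionally `name`.
#' @param pad_bp symmetric padding in bases (default 0).
#' @return data.frame with one row per region (crossed with carrier
#'   sample when `variants` has a `carrier_sample` column) and a `count`
#'   column.
#' @export
count_region_variants <- function(variants, regions, pad_bp = 0L) {
  stopifnot(all(c("chrom", "start", "end") %in% names(regions)))
  if (is.null(regions$name))
    regions$name <- paste0("region_", seq_len(nrow(regions)))
  by_sample <- "carrier_sample" %in% names(variants)
  groups <- if (by_sample) sort(unique(variants$carrier_sample)) else "all"
  out <- list()
  for (r in seq_len(nrow(regions))) {
    lo <- regions$start[r] - pad_bp
    hi <- regions$end[r] + pad_bp
    hit <- variants$chrom == regions$chrom[r] &
      variants$pos >= lo & variants$pos < hi
    for (g in groups) {
      sel <- if (by_sample) hit & variants$carrier_sample == g else hit
      out[[length(out) + 1L]] <-
        data.frame(region = regions$name[r], sample_id = g,
                   count = sum(sel), stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  if (!by_sample) res$sample_id <- NULL
  res
}

#' Unique-indel fold change in treated versus control samples
#'
#' The number of unique indels in each treated sample relative to the mean
#' count across control samples (parents and control offspring), with a
#' two-sided Welch's t-test comparing treated and control counts.
#'
#' @param uniques a [find_unique_variants()] result.
#' @param samples data.frame with `sample_id` and `role` (the family's
#'   sample sheet); treated = `treated_offspring`, controls = all others.
#' @return list with `per_treated` (data.frame: `sample_id`, `n_indels`,
#'   `fold`), `control_mean`, `p_welch` (NA when either group is too
#'   small) and `undefined` (TRUE when the control mean is zero).
#' @export
indel_fold_change <- function(uniques, samples) {
  stopifnot(all(c("sample_id", "role") %in% names(samples)))
  indels <- uniques[uniques$size != 0L, , drop = FALSE]
  counts <- vapply(samples$sample_id,
                   function(s) sum(indels$carrier_sample == s), 0L)
  treated <- samples$role == "treated_offspring"
  if (!any(treated) || sum(!treated) < 2L)
    stop("need >= 1 treated and >= 2 control samples")
  ctrl_mean <- mean(counts[!treated])
  undefined <- ctrl_mean == 0
  per_treated <- data.frame(sample_id = samples$sample_id[treated],
                            n_indels = as.integer(counts[treated]),
                            fold = if (undefined) NA_real_
                                   else counts[treated] / ctrl_mean,
                            stringsAsFactors = FALSE)
  rownames(per_treated) <- NULL
  p <- if (sum(treated) >= 2L)
    compare_groups(counts[treated], counts[!treated], "welch")$p
  else NA_real_
  list(per_treated = per_treated, control_mean = ctrl_mean,
       p_welch = p, undefined = undefined)
}

#' Read genomic regions from a BED file
#'
#' @param path path to a 3+ column BED file (0-based half-open, as BED is
#'   defined).
#' @return data.frame with columns `chrom`, `start`, `end` and `name`.
#' @export
read_bed <- function(path) {
  df <- read.table(path, header = FALSE, sep = "\t",
                   stringsAsFactors = FALSE)
  out <- data.frame(chrom = df[[1]], start = as.integer(df[[2]]),
                    end = as.integer(df[[3]]),
                    name = if (ncol(df) >= 4L) df[[4]]
                           else paste0("region_", seq_len(nrow(df))),
                    stringsAsFactors = FALSE)
  out
}
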