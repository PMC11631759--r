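# Family WGS simulator: a toy reference with planted poly(A/T) tracts, a
# joint-genotyped multi-sample variant table with known shared and unique
# variants, and an elevated unique-indel burden in treated offspring.

# does a run of >= min_tract identical A/T bases contain or abut 0-based
# position d? (generator-side check, used to guarantee planted truth)
.at_run_near <- function(refseq, d, min_tract) {
  n <- nchar(refseq)
  run_at <- function(i) {
    b <- substr(refseq, i + 1L, i + 1L)
    l <- i
    while (l > 0L && substr(refseq, l, l) == b) l <- l - 1L
    r <- i
    while (r < n - 1L && substr(refseq, r + 2L, r + 2L) == b) r <- r + 1L
    list(base = b, len = r - l + 1L)
  }
  for (i in c(d, d - 1L, d + 1L)) {
    if (i < 0L || i >= n) next
    ra <- run_at(i)
    if (ra$base %in% c("A", "T") && ra$len >= min_tract) return(TRUE)
  }
  FALSE
}

# sample() without the length-1 surprise
sample_one <- function(x) x[sample.int(length(x), 1L)]

#' Simulate a joint-genotyped mouse-family variant table
#'
#' Builds a toy reference (two autosome-like contigs and one sex-like
#' contig, so the sex-chromosome exclusion is exercised) seeded with
#' poly(A/T) homopolymer tracts, then plants: variants shared by two or
#' more family members; per-sample unique SNVs at a common rate; and
#' per-sample unique indels, where treated offspring receive
#' `treated_indel_fold` times the control rate and the excess consists
#' predominantly of -1 bp deletions abutting A/T tracts — the replication
#' slippage signature of impaired mismatch repair. Per-sample genotype,
#' depth and allele-depth fields are drawn from a simple depth model with
#' carrier allele frequencies comfortably above the 0.2 filter, and a
#' small labelled fraction of planted variants deliberately violates the
#' depth or chromosome rules.
#'
#' @param n_parents,n_controls,n_treated family composition (default two
#'   parents, two control and three treated offspring).
#' @param autosome_length,sex_length contig lengths in bp.
#' @param tract_density planted A/T tracts per kb of autosome.
#' @param shared_variant_count variants carried by >= 2 members.
#' @param unique_snv_rate Poisson mean of unique SNVs per sample.
#' @param unique_indel_rate_control Poisson mean of unique indels per
#'   control sample.
#' @param treated_indel_fold unique-indel enrichment in treated offspring
#'   (>= 1).
#' @param frac_tract_del fraction of the treated excess placed as -1 bp
#'   deletions abutting A/T tracts.
#' @param mean_dp,sd_dp per-sample depth model (normal, rounded).
#' @param low_depth_frac fraction of planted unique variants given one
#'   sample below the depth-30 filter (labelled as failing in the truth
#'   table).
#' @param sex_frac fraction of unique SNVs placed on the sex-like contig
#'   (labelled as failing).
#' @param min_tract tract length used when planting (matches the
#'   detector's default).
#' @param seed RNG seed.
#' @return list with `table` (a [family_variant_table()]), `reference`
#'   (named character vector), `truth` (one row per planted variant:
#'   position, alleles, carrier, kind, size, `tract_adjacent`,
#'   `pass_filters`), `regions` (list of `offtargets` — sites with no
#'   variant within 100 bp — and `microsatellites` — tract intervals),
#'   and `config`.
#' @export
simulate_family <- function(n_parents = 2L, n_controls = 2L,
                            n_treated = 3L,
                            autosome_length = 100000L,
                            sex_length = 50000L, tract_density = 5,
                            shared_variant_count = 150L,
                            unique_snv_rate = 60,
                            unique_indel_rate_control = 40,
                            treated_indel_fold = 2.5,
                            frac_tract_del = 0.7,
                            mean_dp = 100, sd_dp = 12,
                            low_depth_frac = 0.02, sex_frac = 0.05,
                            min_tract = 4L, n_offtargets = 38L,
                            n_microsats = 12L, seed = 1L) {
  stopifnot(n_controls + n_parents >= 2L, n_treated >= 1L,
            treated_indel_fold >= 1)
  samples <- data.frame(
    sample_id = c(sprintf("parent%d", seq_len(n_parents)),
                  sprintf("control%d", seq_len(n_controls)),
                  sprintf("treated%d", seq_len(n_treated))),
    role = c(rep("parent", n_parents),
             rep("control_offspring", n_controls),
             rep("treated_offspring", n_treated)),
    stringsAsFactors = FALSE)
  n_samp <- nrow(samples)

  with_seed(seed, {
    chroms <- c(chr1 = autosome_length, chr2 = autosome_length,
                chrX = sex_length)
    reference <- vapply(chroms, random_dna, "")

    # plant A/T tracts on the autosomes, flanked by a different base so
    # each tract is a maximal run
    n_tracts <- round(tract_density * autosome_length / 1000)
    tracts <- list()
    for (chrom in c("chr1", "chr2")) {
      starts <- sort(sample(seq(50L, autosome_length - 50L, by = 40L),
                            n_tracts))
      lens <- sample(min_tract:(min_tract + 6L), n_tracts, replace = TRUE)
      bases <- sample(c("A", "T"), n_tracts, replace = TRUE)
      s <- reference[[chrom]]
      for (k in seq_len(n_tracts)) {
        run <- strrep(bases[k], lens[k])
        flank <- sample(setdiff(.BASES, bases[k]), 2L, replace = TRUE)
        s <- paste0(substr(s, 1L, starts[k] - 1L), flank[1], run, flank[2],
                    substr(s, starts[k] + lens[k] + 2L, nchar(s)))
      }
      reference[[chrom]] <- s
      tracts[[chrom]] <- data.frame(chrom = chrom, start = starts,
                                    len = lens, base = bases,
                                    stringsAsFactors = FALSE)
    }
    tracts <- do.call(rbind, tracts)
    rownames(tracts) <- NULL

    # non-overlapping variant sites: sample 30-bp bins without
    # replacement, keep a small offset inside each bin
    bin_pool <- expand.grid(
      chrom = c("chr1", "chr2"),
      bin = seq(3L, floor(autosome_length / 30L) - 3L),
      stringsAsFactors = FALSE)
    bin_pool <- bin_pool[sample.int(nrow(bin_pool)), ]
    pool_next <- 0L
    next_site <- function() {
      pool_next <<- pool_next + 1L
      b <- bin_pool[pool_next, ]
      list(chrom = b$chrom, pos = b$bin * 30L + sample.int(10L, 1L))
    }
    used_tracts <- logical(nrow(tracts))

    truth <- list()
    add_truth <- function(chrom, pos, ref, alt, carrier, kind,
                          tract_adjacent, pass_filters, fail_reason) {
      truth[[length(truth) + 1L]] <<- data.frame(
        chrom = chrom, pos = pos, ref = ref, alt = alt,
        carrier = carrier, kind = kind,
        size = nchar(alt) - nchar(ref),
        tract_adjacent = tract_adjacent, pass_filters = pass_filters,
        fail_reason = fail_reason, stringsAsFactors = FALSE)
    }
    base_at <- function(chrom, pos0) substr(reference[[chrom]], pos0 + 1L,
                                            pos0 + 1L)

    snv_at <- function(chrom, pos) {
      ref <- base_at(chrom, pos)
      alt <- sample(setdiff(.BASES, ref), 1L)
      list(ref = ref, alt = alt)
    }
    # a -1 bp deletion of the first base of tract k, left-aligned and
    # anchored on the distinct flanking base
    tract_del <- function(k) {
      tr <- tracts[k, ]
      pos <- tr$start - 1L  # 0-based anchor = flank before the run
      list(chrom = tr$chrom, pos = pos,
           ref = paste0(base_at(tr$chrom, pos), tr$base),
           alt = base_at(tr$chrom, pos))
    }
    # indel at a generic site, rejected until already left-normalized and
    # (for -1 bp deletions) clear of A/T runs
    plain_indel <- function(size) {
      repeat {
        st <- next_site()
        anchor <- base_at(st$chrom, st$pos)
        if (size < 0L) {
          del <- substr(reference[[st$chrom]], st$pos + 2L,
                        st$pos + 1L - size)
          # left-normalized iff the last deleted base differs from the
          # anchor (otherwise the deletion interval can shift left)
          if (substr(del, -size, -size) == anchor) next
          if (size == -1L && .at_run_near(reference[[st$chrom]],
                                          st$pos + 1L, min_tract)) next
          return(list(chrom = st$chrom, pos = st$pos,
                      ref = paste0(anchor, del), alt = anchor))
        } else {
          ins <- random_dna(size)
          if (substr(ins, size, size) == anchor) next
          return(list(chrom = st$chrom, pos = st$pos, ref = anchor,
                      alt = paste0(anchor, ins)))
        }
      }
    }
    draw_control_indel <- function() {
      type <- sample(c("del1_tract", "del1_plain", "del2", "ins1", "ins2"),
                     1L, prob = c(0.2, 0.3, 0.2, 0.2, 0.1))
      if (type == "del1_tract") {
        k <- sample_one(which(!used_tracts))
        used_tracts[k] <<- TRUE
        c(tract_del(k), list(tract_adjacent = TRUE))
      } else if (type == "del1_plain") {
        c(plain_indel(-1L), list(tract_adjacent = FALSE))
      } else {
        sz <- switch(type, del2 = -2L, ins1 = 1L, ins2 = 2L)
        c(plain_indel(sz), list(tract_adjacent = NA))
      }
    }

    # shared variants (>= 2 carriers) -- excluded by the uniqueness rule
    shared_carriers <- matrix(FALSE, shared_variant_count, n_samp)
    shared_rec <- list()
    for (v in seq_len(shared_variant_count)) {
      st <- next_site()
      al <- snv_at(st$chrom, st$pos)
      carriers <- sample.int(n_samp, sample(2:n_samp, 1L))
      shared_carriers[v, carriers] <- TRUE
      shared_rec[[v]] <- data.frame(chrom = st$chrom, pos = st$pos,
                                    ref = al$ref, alt = al$alt,
                                    stringsAsFactors = FALSE)
      add_truth(st$chrom, st$pos, al$ref, al$alt, "shared", "shared",
                NA, FALSE, "multi_carrier")
    }

    # unique variants per sample
    uniq_rec <- list(); uniq_carrier <- character(0)
    for (si in seq_len(n_samp)) {
      sid <- samples$sample_id[si]
      treated <- samples$role[si] == "treated_offspring"
      n_snv <- rpois(1L, unique_snv_rate)
      for (k in seq_len(n_snv)) {
        on_sex <- runif(1) < sex_frac
        if (on_sex) {
          pos <- sample.int(sex_length - 100L, 1L) + 50L
          al <- snv_at("chrX", pos)
          uniq_rec[[length(uniq_rec) + 1L]] <-
            data.frame(chrom = "chrX", pos = pos, ref = al$ref,
                       alt = al$alt, stringsAsFactors = FALSE)
          add_truth("chrX", pos, al$ref, al$alt, sid, "unique_snv", NA,
                    FALSE, "sex_chromosome")
        } else {
          st <- next_site()
          al <- snv_at(st$chrom, st$pos)
          uniq_rec[[length(uniq_rec) + 1L]] <-
            data.frame(chrom = st$chrom, pos = st$pos, ref = al$ref,
                       alt = al$alt, stringsAsFactors = FALSE)
          add_truth(st$chrom, st$pos, al$ref, al$alt, sid, "unique_snv",
                    NA, TRUE, NA_character_)
        }
        uniq_carrier <- c(uniq_carrier, sid)
      }
      n_base <- rpois(1L, unique_indel_rate_control)
      n_extra <- if (treated)
        rpois(1L, unique_indel_rate_control * (treated_indel_fold - 1))
      else 0L
      for (k in seq_len(n_base + n_extra)) {
        rec <- if (k > n_base && runif(1) < frac_tract_del) {
          j <- sample_one(which(!used_tracts))
          used_tracts[j] <- TRUE
          c(tract_del(j), list(tract_adjacent = TRUE))
        } else draw_control_indel()
        uniq_rec[[length(uniq_rec) + 1L]] <-
          data.frame(chrom = rec$chrom, pos = rec$pos, ref = rec$ref,
                     alt = rec$alt, stringsAsFactors = FALSE)
        add_truth(rec$chrom, rec$pos, rec$ref, rec$alt, sid,
                  "unique_indel", rec$tract_adjacent, TRUE, NA_character_)
        uniq_carrier <- c(uniq_carrier, sid)
      }
    }

    variants <- do.call(rbind, c(shared_rec, uniq_rec))
    truth <- do.call(rbind, truth)
    n_var <- nrow(variants)

    # depth / genotype / allele-depth model
    dp <- matrix(pmax(31L, as.integer(round(rnorm(n_var * n_samp, mean_dp,
                                                  sd_dp)))),
                 n_var, n_samp)
    gt <- matrix("0/0", n_var, n_samp)
    ad <- matrix(0L, n_var, n_samp)
    is_shared <- truth$kind == "shared"
    for (v in which(is_shared)) {
      for (s in which(shared_carriers[v, ])) {
        gt[v, s] <- "0/1"
        ad[v, s] <- max(1L, rbinom(1L, dp[v, s], 0.5))
      }
    }
    uniq_rows <- which(!is_shared)
    carrier_idx <- match(truth$carrier[uniq_rows], samples$sample_id)
    for (j in seq_along(uniq_rows)) {
      v <- uniq_rows[j]; s <- carrier_idx[j]
      gt[v, s] <- "0/1"
      # mosaic / heterozygous allele fractions, clear of the 0.2 gate
      ad[v, s] <- max(ceiling(0.25 * dp[v, s]),
                      rbinom(1L, dp[v, s], runif(1L, 0.3, 0.6)))
    }
    # violate the depth filter for a labelled fraction of passing uniques
    passing <- which(truth$pass_filters)
    n_low <- round(low_depth_frac * length(passing))
    if (n_low > 0L) {
      low <- sample(passing, n_low)
      for (v in low) {
        s <- sample.int(n_samp, 1L)
        dp[v, s] <- sample(10:29, 1L)
        ad[v, s] <- min(ad[v, s], dp[v, s])
        truth$pass_filters[v] <- FALSE
        truth$fail_reason[v] <- "low_depth"
      }
    }

    # sort by genomic coordinate for VCF-style output
    ord <- order(match(variants$chrom, names(chroms)), variants$pos)
    variants <- variants[ord, , drop = FALSE]
    truth <- truth[ord, , drop = FALSE]
    dp <- dp[ord, , drop = FALSE]
    gt <- gt[ord, , drop = FALSE]
    ad <- ad[ord, , drop = FALSE]
    rownames(variants) <- rownames(truth) <- NULL

    table <- family_variant_table(variants, gt, dp, ad, samples)

    # predicted off-target sites: no variant within 100 bp
    offt <- list()
    while (length(offt) < n_offtargets) {
      chrom <- sample(c("chr1", "chr2"), 1L)
      start <- sample.int(autosome_length - 400L, 1L) + 150L
      sel <- variants$chrom == chrom &
        variants$pos >= start - 110L & variants$pos < start + 133L
      if (!any(sel))
        offt[[length(offt) + 1L]] <-
          data.frame(chrom = chrom, start = start, end = start + 23L,
                     name = sprintf("offtarget_%02d", length(offt) + 1L),
                     stringsAsFactors = FALSE)
    }
    msel <- sample.int(nrow(tracts), n_microsats)
    microsat <- data.frame(chrom = tracts$chrom[msel],
                           start = tracts$start[msel] - 1L,
                           end = tracts$start[msel] + tracts$len[msel] + 1L,
                           name = sprintf("microsat_%02d",
                                          seq_len(n_microsats)),
                           stringsAsFactors = FALSE)

    list(table = table, reference = reference, truth = truth,
         regions = list(offtargets = do.call(rbind, offt),
                        microsatellites = microsat),
         tracts = tracts,
         config = list(n_parents = n_parents, n_controls = n_controls,
                       n_treated = n_treated,
                       unique_snv_rate = unique_snv_rate,
                       unique_indel_rate_control = unique_indel_rate_control,
                       treated_indel_fold = treated_indel_fold,
                       frac_tract_del = frac_tract_del,
                       min_tract = min_tract, seed = seed))
  })
}

#' Write a family variant table as a multi-sample VCF
#'
#' Emits a minimal VCFv4.2 file with per-sample GT, AD and DP fields,
#' byte-deterministic for a given table.
#'
#' @param table a [family_variant_table()].
#' @param path output path.
#' @param reference optional named character vector used to emit contig
#'   header lines.
#' @return `path`, invisibly.
#' @export
write_family_vcf <- function(table, path, reference = NULL) {
  stopifnot(inherits(table, "family_variant_table"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=primeout_family_simulator"), con)
  if (!is.null(reference))
    writeLines(sprintf("##contig=<ID=%s,length=%d>", names(reference),
                       nchar(reference)), con)
  writeLines(c(
    paste0("##FORMAT=<ID=GT,Number=1,Type=String,",
           "Description=\"Genotype\">"),
    paste0("##FORMAT=<ID=AD,Number=R,Type=Integer,",
           "Description=\"Allelic depths\">"),
    paste0("##FORMAT=<ID=DP,Number=1,Type=Integer,",
           "Description=\"Read depth\">")), con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                     "FILTER", "INFO", "FORMAT",
                     table$samples$sample_id), collapse = "\t"), con)
  v <- table$variants
  for (i in seq_len(nrow(v))) {
    cells <- sprintf("%s:%d,%d:%d", table$gt[i, ],
                     table$dp[i, ] - table$ad[i, ], table$ad[i, ],
                     table$dp[i, ])
    writeLines(paste(c(v$chrom[i], v$pos[i] + 1L, ".", v$ref[i],
                       v$alt[i], ".", "PASS", ".", "GT:AD:DP", cells),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Write a pedigree/treatment sample sheet as TSV
#'
#' @param samples data.frame with `sample_id` and `role`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(samples, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(c("sample_id", "role"), collapse = "\t"), con)
  writeLines(paste(samples$sample_id, samples$role, sep = "\t"), con)
  invisible(path)
}

#' Write genomic regions as a BED file
#'
#' @param regions data.frame with `chrom`, `start`, `end` and optionally
#'   `name` (0-based half-open, as BED is defined).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  nm <- regions$name %||% paste0("region_", seq_len(nrow(regions)))
  writeLines(paste(regions$chrom, regions$start, regions$end, nm,
                   sep = "\t"), con)
  invisible(path)
}
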