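#' Demultiplex reads by sample barcode
#'
#' Assigns each read to the unique sample whose barcode lies within Hamming
#' distance 1 of the read's barcode. Reads matching no barcode at distance
#' <= 1, or two or more barcodes at distance <= 1, are left unassigned:
#' sample identity is never guessed on a tie. Barcodes are taken from the
#' first `nchar(barcode)` bases of each read and stripped on assignment, so
#' assigned reads start at amplicon position 0.
#'
#' @param reads a read-set data.frame (`read_id`, `bases`, `quals`).
#' @param spec a [target_spec()] with a `barcode_map`, or a named character
#'   vector of barcodes (sample_id -> barcode).
#' @param strip_barcode drop the barcode prefix (and its qualities) from
#'   assigned reads. Default `TRUE`.
#' @return list with `samples` (named list of read-set data.frames),
#'   `unassigned` (read-set data.frame) and `counts` (named integer vector
#'   of assignments, including `"unassigned"`).
#' @export
demultiplex <- function(reads, spec, strip_barcode = TRUE) {
  barcodes <- if (inherits(spec, "target_spec")) spec$barcode_map else spec
  if (is.null(barcodes))
    stop("no barcode_map in the target specification")
  if (anyDuplicated(barcodes)) stop("duplicate barcodes")
  blen <- unique(nchar(barcodes))
  if (length(blen) != 1L) stop("barcodes differ in length")
  if (nrow(reads) > 0L && any(nchar(reads$bases) < blen))
    stop("reads shorter than the barcode length")

  bc <- substr(reads$bases, 1L, blen)
  bsplit <- strsplit(barcodes, "")
  bcu <- unique(bc)
  # distance of each observed barcode to every reference barcode
  assign_of <- vapply(bcu, function(b) {
    xs <- strsplit(b, "")[[1]]
    d <- vapply(bsplit, function(ys) sum(xs != ys), 0L)
    hits <- which(d <= 1L)
    if (length(hits) == 1L) names(barcodes)[hits] else NA_character_
  }, "")
  sample_of <- assign_of[match(bc, bcu)]

  strip <- function(df) {
    if (strip_barcode && nrow(df) > 0L) {
      df$bases <- substr(df$bases, blen + 1L, nchar(df$bases))
      df$quals <- substr(df$quals, blen + 1L, nchar(df$quals))
    }
    df
  }
  samples <- lapply(setNames(names(barcodes), names(barcodes)), function(s) {
    df <- reads[!is.na(sample_of) & sample_of == s, , drop = FALSE]
    df <- strip(df)
    if (nrow(df) > 0L) df$sample_id <- s
    rownames(df) <- NULL
    df
  })
  unassigned <- reads[is.na(sample_of), , drop = FALSE]
  rownames(unassigned) <- NULL
  counts <- c(vapply(samples, nrow, 0L), unassigned = nrow(unassigned))
  list(samples = samples, unassigned = unassigned, counts = counts)
}

#' Mask low-quality base calls
#'
#' Replaces every base whose Phred quality is strictly below `q_threshold`
#' with 'N'. Qualities are retained; masking is idempotent.
#'
#' @param reads a read-set data.frame.
#' @param q_threshold minimum quality for a base call to be kept (default
#'   30; a call with quality 29 is masked, one with 30 is not).
#' @return the read set with masked `bases` and a `masked = TRUE` column.
#' @export
mask_low_quality <- function(reads, q_threshold = 30L) {
  n <- nrow(reads)
  if (n > 0L) {
    lens <- nchar(reads$bases)
    if (!all(nchar(reads$quals) == lens))
      stop("bases and quals differ in length")
    # one pass over the concatenated read set: cheap even at depth 10,000
    bigq <- utf8ToInt(paste(reads$quals, collapse = "")) - 33L
    low <- bigq < q_threshold
    if (any(low)) {
      bigb <- strsplit(paste(reads$bases, collapse = ""), "")[[1]]
      bigb[low] <- "N"
      big <- paste(bigb, collapse = "")
      ends <- cumsum(lens)
      reads$bases <- substring(big, ends - lens + 1L, ends)
    }
  }
  reads$masked <- rep(TRUE, n)
  reads
}

#' Ambiguity filter around the edit site
#'
#' Discards reads with more than `max_n_frac` ambiguous ('N') calls among
#' the read positions mapping (ungapped, reads anchored at amplicon
#' position 0) to the reference interval
#' `[edit_pos - radius_bp, edit_pos + radius_bp]` (clipped to the
#' amplicon). Reads too short to cover the interval are discarded with
#' reason `"no_coverage"`.
#'
#' @param reads a masked read-set data.frame.
#' @param spec a [target_spec()].
#' @param radius_bp window radius around the edit site (default 40).
#' @param max_n_frac maximum tolerated 'N' fraction (default 0.10; the
#'   discard rule is strictly greater).
#' @return data.frame with columns `keep`, `n_frac`, `reason`.
#' @export
filter_ambiguity <- function(reads, spec, radius_bp = 40L,
                             max_n_frac = 0.10) {
  stopifnot(inherits(spec, "target_spec"))
  lo <- max(0L, spec$edit_pos - radius_bp)
  hi <- min(nchar(spec$amplicon) - 1L, spec$edit_pos + radius_bp)
  keep <- logical(nrow(reads)); n_frac <- rep(NA_real_, nrow(reads))
  reason <- rep(NA_character_, nrow(reads))
  covered <- nchar(reads$bases) >= hi + 1L
  if (any(!covered)) {
    keep[!covered] <- FALSE
    reason[!covered] <- "no_coverage"
  }
  if (any(covered)) {
    win <- substr(reads$bases[covered], lo + 1L, hi + 1L)
    nf <- nchar(win) - nchar(gsub("N", "", win, fixed = TRUE))
    frac <- nf / nchar(win)
    n_frac[covered] <- frac
    keep[covered] <- frac <= max_n_frac
    reason[covered][frac > max_n_frac] <- "ambiguity"
  }
  data.frame(keep = keep, n_frac = n_frac, reason = reason,
             stringsAsFactors = FALSE)
}

#' Seed-region filter
#'
#' Compares the first `seed_len` read bases to the first `seed_len`
#' amplicon bases, ungapped. Identity is computed over non-'N' positions;
#' a read is discarded when identity falls strictly below `min_identity`,
#' when more than half the seed is 'N' (masked bases are non-informative,
#' not mismatches, but an uninformative seed cannot validate a read), or
#' when the read is shorter than the seed (reason `"short_read"`). The
#' seed region must not overlap the edit or nick sites; amplicon designs
#' place these at least 75 bases from the read start.
#'
#' @param reads a masked read-set data.frame.
#' @param spec a [target_spec()].
#' @param seed_len seed length in bases (default 40).
#' @param min_identity minimum seed identity (default 0.90; a seed at
#'   exactly 90% identity is kept).
#' @return data.frame with columns `keep`, `identity`, `reason`.
#' @export
seed_filter <- function(reads, spec, seed_len = 40L, min_identity = 0.90) {
  stopifnot(inherits(spec, "target_spec"))
  first_site <- min(spec$edit_pos, spec$nick_pos,
                    spec$secondary_nick_pos %||% .Machine$integer.max)
  if (seed_len > first_site)
    stop("seed region overlaps the edit/nick sites; shorten seed_len or ",
         "redesign the amplicon")
  n <- nrow(reads)
  keep <- logical(n); ident <- rep(NA_real_, n)
  reason <- rep(NA_character_, n)
  short <- nchar(reads$bases) < seed_len
  reason[short] <- "short_read"
  idx <- which(!short)
  if (length(idx) > 0L) {
    sc <- utf8ToInt(paste(substr(reads$bases[idx], 1L, seed_len),
                          collapse = ""))
    refv <- rep.int(utf8ToInt(substr(spec$amplicon, 1L, seed_len)),
                    length(idx))
    informative <- sc != utf8ToInt("N")
    grp <- rep(seq_along(idx), each = seed_len)
    n_inf <- as.vector(rowsum(as.integer(informative), grp))
    n_match <- as.vector(rowsum(as.integer(informative & sc == refv), grp))
    id <- ifelse(n_inf > 0L, n_match / n_inf, 0)
    uninf <- n_inf < seed_len / 2
    ident[idx] <- id
    keep[idx] <- !uninf & id >= min_identity
    reason[idx][uninf] <- "seed_uninformative"
    reason[idx][!uninf & id < min_identity] <- "seed_identity"
  }
  data.frame(keep = keep, identity = ident, reason = reason,
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full read-preprocessing pipeline
#'
#' Fixed order: demultiplex (optional) -> quality masking -> ambiguity
#' filter -> seed filter. Every input read ends in exactly one bin
#' (assigned-and-kept, discarded with a reason, or unassigned) and the
#' per-bin counts sum to the input count.
#'
#' @param reads a read-set data.frame.
#' @param spec a [target_spec()].
#' @param demultiplex demultiplex by barcode first (`TRUE` whenever the
#'   spec carries a `barcode_map`).
#' @param q_threshold,radius_bp,max_n_frac,seed_len,min_identity filter
#'   parameters; see the individual filter functions.
#' @return an object of class `preprocess_result`: list with `samples`
#'   (named list of kept, masked read sets), `report` (per-sample counts
#'   by fate) and `n_unassigned`.
#' @export
preprocess_reads <- function(reads, spec,
                             demultiplex = !is.null(spec$barcode_map),
                             q_threshold = 30L, radius_bp = 40L,
                             max_n_frac = 0.10, seed_len = 40L,
                             min_identity = 0.90) {
  stopifnot(inherits(spec, "target_spec"))
  if (demultiplex) {
    dm <- primeout::demultiplex(reads, spec)
    per_sample <- dm$samples
    n_unassigned <- nrow(dm$unassigned)
  } else {
    per_sample <- list(sample = reads)
    n_unassigned <- 0L
  }
  samples <- list()
  rows <- list()
  for (s in names(per_sample)) {
    rd <- mask_low_quality(per_sample[[s]], q_threshold)
    amb <- filter_ambiguity(rd, spec, radius_bp, max_n_frac)
    sd_ <- seed_filter(rd, spec, seed_len, min_identity)
    keep <- amb$keep & sd_$keep
    reason <- ifelse(!amb$keep, amb$reason, ifelse(!sd_$keep, sd_$reason, NA))
    kept <- rd[keep, , drop = FALSE]
    rownames(kept) <- NULL
    samples[[s]] <- kept
    tab <- table(factor(reason[!keep],
                        levels = c("no_coverage", "ambiguity", "short_read",
                                   "seed_uninformative", "seed_identity")))
    rows[[s]] <- data.frame(sample_id = s, n_input = nrow(rd),
                            n_kept = nrow(kept),
                            n_no_coverage = as.integer(tab[["no_coverage"]]),
                            n_ambiguity = as.integer(tab[["ambiguity"]]),
                            n_short_read = as.integer(tab[["short_read"]]),
                            n_seed_uninformative =
                              as.integer(tab[["seed_uninformative"]]),
                            n_seed_identity =
                              as.integer(tab[["seed_identity"]]),
                            stringsAsFactors = FALSE)
  }
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  structure(list(samples = samples, report = report,
                 n_unassigned = n_unassigned),
            class = "preprocess_result")
}

#' @export
print.preprocess_result <- function(x, ...) {
  cat("Preprocessed reads:", sum(x$report$n_input), "assigned,",
      x$n_unassigned, "unassigned\n")
  print(x$report, row.names = FALSE)
  invisible(x)
}
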