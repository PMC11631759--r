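#' Alignment scoring parameters
#'
#' Scores used by the affine-gap global aligner. The defaults — match +1,
#' mismatch 0, gap opening -3, gap extension -1 — are the standard scoring
#' for read-to-amplicon alignment in prime-editing outcome quantification;
#' a gap of length L costs `gap_open + (L - 1) * gap_extend`.
#'
#' @param match score for an identical aligned pair.
#' @param mismatch score for a mismatched pair (also used for 'N' columns).
#' @param gap_open score charged to the first position of a gap.
#' @param gap_extend score charged to each additional gapped position.
#' @return an object of class `align_scoring`.
#' @export
align_scoring <- function(match = 1, mismatch = 0, gap_open = -3,
                          gap_extend = -1) {
  if (!(gap_open <= gap_extend && gap_extend <= 0 && 0 <= match &&
        mismatch <= match))
    stop("require gap_open <= gap_extend <= 0 <= match and mismatch <= match")
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend), class = "align_scoring")
}

#' Global affine-gap alignment of a read to the reference amplicon
#'
#' Needleman-Wunsch global alignment with Gotoh's affine-gap recursion.
#' End gaps are penalized (true global mode). Traceback ties are broken
#' with fixed priority diagonal > vertical > horizontal so the reported
#' alignment is deterministic. A read 'N' scores as a mismatch during
#' dynamic programming but never generates a substitution event: masked
#' base calls are non-informative for classification.
#'
#' @param read_seq read sequence (A/C/G/T/N).
#' @param ref_seq reference (amplicon) sequence.
#' @param scoring an [align_scoring()] object.
#' @return an object of class `alignment`: list with `ref_aligned`,
#'   `read_aligned` (equal-length gapped strings), `score`, and `events`
#'   (see Details). Events are the substitutions, insertions and deletions
#'   observed in the traceback, sorted by reference coordinate; indel
#'   coordinates are as placed by the traceback (use the classification
#'   layer for left-aligned comparisons).
#' @examples
#' aln <- global_align("ACGTCGT", "ACGTAACGT")
#' aln$score  # 7 matches - (3 + 1) for a length-2 deletion = 3
#' @export
global_align <- function(read_seq, ref_seq, scoring = align_scoring()) {
  stopifnot(inherits(scoring, "align_scoring"))
  if (!nzchar(read_seq) || !nzchar(ref_seq))
    stop("sequences must be non-empty")
  res <- gotoh_align_cpp(ref_seq, read_seq, scoring$match, scoring$mismatch,
                         scoring$gap_open, scoring$gap_extend)
  structure(list(ref_aligned = res$ref_aligned,
                 read_aligned = res$read_aligned,
                 score = res$score,
                 events = alignment_events(res$ref_aligned,
                                           res$read_aligned),
                 ref = ref_seq, read = read_seq, scoring = scoring),
            class = "alignment")
}

#' @export
print.alignment <- function(x, width = 60L, ...) {
  cat("Global alignment, score ", x$score, " (", nrow(x$events),
      " event", if (nrow(x$events) != 1L) "s", ")\n", sep = "")
  n <- nchar(x$ref_aligned)
  for (s in seq(1L, n, by = width)) {
    e <- min(s + width - 1L, n)
    r <- substr(x$ref_aligned, s, e)
    q <- substr(x$read_aligned, s, e)
    rc <- strsplit(r, "")[[1]]; qc <- strsplit(q, "")[[1]]
    mid <- paste(ifelse(rc == qc & rc != "-", "|", " "), collapse = "")
    cat("ref  ", r, "\n     ", mid, "\nread ", q, "\n\n", sep = "")
  }
  invisible(x)
}

#' Project an alignment onto a reference window
#'
#' Returns the alignment columns whose reference coordinate lies in the
#' half-open interval `[ref_start, ref_end)`, plus insertion events whose
#' left-flanking reference base lies in `[ref_start, ref_end - 1]`.
#'
#' @param aln an [global_align()] result.
#' @param ref_start,ref_end 0-based half-open reference interval.
#' @return list with `ref_slice` and `read_slice` (gapped column strings)
#'   and `events` (the contained events).
#' @export
project_window <- function(aln, ref_start, ref_end) {
  stopifnot(inherits(aln, "alignment"))
  n_ref <- nchar(aln$ref)
  if (!(ref_start >= 0 && ref_start < ref_end && ref_end <= n_ref))
    stop("window outside the reference")
  rs <- strsplit(aln$ref_aligned, "")[[1]]
  # reference coordinate of each column; insertion columns take the
  # coordinate of their left-flanking reference base
  coord <- cumsum(rs != "-") - 1L
  keep <- coord >= ref_start & coord < ref_end
  # leading insertion columns (coord -1) belong to no window start > 0
  ev <- aln$events
  in_win <- logical(nrow(ev))
  for (k in seq_len(nrow(ev))) {
    if (ev$type[k] == "ins") {
      in_win[k] <- ev$ref_start[k] >= ref_start &&
        ev$ref_start[k] <= ref_end - 1L
    } else {
      in_win[k] <- ev$ref_start[k] < ref_end && ev$ref_end[k] > ref_start
    }
  }
  list(ref_slice = paste(rs[keep], collapse = ""),
       read_slice = paste(strsplit(aln$read_aligned, "")[[1]][keep],
                          collapse = ""),
       events = ev[in_win, , drop = FALSE])
}
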