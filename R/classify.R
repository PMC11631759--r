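#' Build nick-anchored classification windows
#'
#' Method 1 considers a 40-nt window around the pegRNA nick (18 nt in the
#' 5' direction, 22 nt in the 3' direction) together with a 34-nt window
#' around the secondary nick (17 nt each side); method 2 considers only
#' the 40-nt pegRNA-nick window. Intervals are 0-based half-open.
#'
#' @param spec a [target_spec()].
#' @param method 1 (double-nick strategies) or 2 (pegRNA nick only).
#' @return an object of class `class_windows`: list with `method`,
#'   `primary` = `c(start, end)` and `secondary` (or `NULL`).
#' @export
build_windows <- function(spec, method = 2L) {
  stopifnot(inherits(spec, "target_spec"))
  method <- as.integer(method)
  if (!method %in% c(1L, 2L)) stop("method must be 1 or 2")
  len <- nchar(spec$amplicon)
  primary <- c(spec$nick_pos - 18L, spec$nick_pos + 22L)
  if (primary[1] < 0L || primary[2] > len)
    stop("primary window extends past the amplicon")
  secondary <- NULL
  if (method == 1L) {
    if (is.null(spec$secondary_nick_pos))
      stop("method 1 requires a secondary nick position")
    secondary <- c(spec$secondary_nick_pos - 17L,
                   spec$secondary_nick_pos + 17L)
    if (secondary[1] < 0L || secondary[2] > len)
      stop("secondary window extends past the amplicon")
  }
  if (!(spec$edit_pos >= primary[1] && spec$edit_pos < primary[2]))
    stop("intended edit lies outside the primary window")
  structure(list(method = method, primary = primary, secondary = secondary),
            class = "class_windows")
}

# events overlapping any considered window (union semantics for method 1)
events_in_windows <- function(events, windows) {
  if (nrow(events) == 0L) return(events)
  wins <- list(windows$primary)
  if (!is.null(windows$secondary)) wins <- c(wins, list(windows$secondary))
  inside <- logical(nrow(events))
  for (w in wins) {
    for (k in seq_len(nrow(events))) {
      if (events$type[k] == "ins") {
        hit <- events$ref_start[k] >= w[1] && events$ref_start[k] <= w[2] - 1L
      } else {
        hit <- events$ref_start[k] < w[2] && events$ref_end[k] > w[1]
      }
      inside[k] <- inside[k] || hit
    }
  }
  events[inside, , drop = FALSE]
}

#' Classify one aligned read as WT, PRECISE or ERROR
#'
#' Collects the informative variant events inside the considered
#' window(s): no events means the read exactly matches the reference there
#' (WT); events exactly equal to the intended edit and nothing else make a
#' PRECISE call; any other non-empty event set is an ERROR. Events are
#' compared after left-aligning indels against the reference, so
#' equivalent placements of the same molecule match the intended edit
#' consistently. Changes strictly outside all considered windows are
#' ignored, and masked ('N') read columns never produce events.
#'
#' @param aln an [global_align()] result against the wild-type amplicon.
#' @param windows a [build_windows()] result from the same spec.
#' @param spec the [target_spec()].
#' @return one of `"WT"`, `"PRECISE"`, `"ERROR"`.
#' @export
classify_read <- function(aln, windows, spec) {
  stopifnot(inherits(aln, "alignment"), inherits(windows, "class_windows"))
  ev <- normalize_events(aln$events, spec$amplicon)
  ev <- events_in_windows(ev, windows)
  if (nrow(ev) == 0L) return("WT")
  if (identical(sort(event_keys(ev)),
                sort(event_keys(intended_event(spec)))))
    return("PRECISE")
  "ERROR"
}

#' Classify a set of kept reads against the amplicon
#'
#' Aligns each distinct read sequence to the wild-type amplicon and
#' classifies it within the considered windows. Duplicate sequences are
#' aligned once and the call reused, which makes deep amplicon data cheap
#' to process.
#'
#' @param reads a kept, masked read-set data.frame (or character vector of
#'   sequences).
#' @param spec a [target_spec()].
#' @param method classification method, 1 or 2.
#' @param scoring an [align_scoring()].
#' @return character vector of classes (`"WT"`, `"PRECISE"`, `"ERROR"`),
#'   one per read.
#' @export
classify_reads <- function(reads, spec, method = 2L,
                           scoring = align_scoring()) {
  seqs <- if (is.data.frame(reads)) reads$bases else reads
  windows <- build_windows(spec, method)
  uniq <- unique(seqs)
  target_keys <- sort(event_keys(intended_event(spec)))
  amp <- spec$amplicon
  refv <- utf8ToInt(amp)
  n_char <- utf8ToInt("N")
  # Exact shortcut under the standard scoring for reads of amplicon
  # length: any gapped global alignment of equal-length sequences needs
  # g >= 1 insertion and g deletion columns, scoring at most
  # L - 3g - 4 < L - m whenever m < 3g + 4; so with m <= 6 informative
  # mismatches the ungapped alignment is strictly optimal and its
  # substitution events are exactly the aligner's events.
  fast_ok <- scoring$match == 1 && scoring$mismatch == 0 &&
    scoring$gap_open == -3 && scoring$gap_extend == -1
  cls <- vapply(uniq, function(s) {
    if (fast_ok && nchar(s) == nchar(amp)) {
      sv <- utf8ToInt(s)
      mm <- which(sv != refv & sv != n_char)
      if (length(mm) <= 6L) {
        if (length(mm) == 0L) return("WT")
        ev <- data.frame(type = "sub", ref_start = mm - 1L, ref_end = mm,
                         ref = substring(amp, mm, mm),
                         alt = substring(s, mm, mm),
                         stringsAsFactors = FALSE)
        ev <- events_in_windows(ev, windows)
        if (nrow(ev) == 0L) return("WT")
        if (identical(sort(event_keys(ev)), target_keys)) return("PRECISE")
        return("ERROR")
      }
    }
    classify_read(global_align(s, amp, scoring), windows, spec)
  }, "", USE.NAMES = FALSE)
  cls[match(seqs, uniq)]
}

#' Summarize read classes for one embryo
#'
#' Counts and fractions are computed over kept reads only; reads discarded
#' by the preprocessing filters are excluded from the denominator. The
#' adjusted error fraction is `NA` until [adjust_errors()] subtracts a
#' control background.
#'
#' @param classes character vector of per-read classes.
#' @param embryo_id embryo label.
#' @param method classification method used (1 or 2).
#' @param n_discarded number of reads discarded during preprocessing.
#' @param target target-locus label (carried for background matching).
#' @return a one-row data.frame of class `embryo_summary`.
#' @export
summarize_embryo <- function(classes, embryo_id, method = 2L,
                             n_discarded = 0L, target = NA_character_) {
  if (length(classes) == 0L) {
    out <- data.frame(embryo_id = embryo_id, target = target,
                      method = as.integer(method), n_total_kept = 0L,
                      n_wt = 0L, n_precise = 0L, n_error = 0L,
                      frac_wt = NA_real_, frac_precise = NA_real_,
                      frac_error = NA_real_, frac_error_adjusted = NA_real_,
                      n_discarded = as.integer(n_discarded),
                      no_data = TRUE, stringsAsFactors = FALSE)
    class(out) <- c("embryo_summary", "data.frame")
    return(out)
  }
  stopifnot(all(classes %in% c("WT", "PRECISE", "ERROR")))
  n <- length(classes)
  n_wt <- sum(classes == "WT")
  n_precise <- sum(classes == "PRECISE")
  n_error <- sum(classes == "ERROR")
  out <- data.frame(embryo_id = embryo_id, target = target,
                    method = as.integer(method), n_total_kept = n,
                    n_wt = n_wt, n_precise = n_precise, n_error = n_error,
                    frac_wt = n_wt / n, frac_precise = n_precise / n,
                    frac_error = n_error / n,
                    frac_error_adjusted = NA_real_,
                    n_discarded = as.integer(n_discarded), no_data = FALSE,
                    stringsAsFactors = FALSE)
  class(out) <- c("embryo_summary", "data.frame")
  out
}

#' Subtract the control background from error fractions
#'
#' Reported ("adjusted") error rates subtract the mean error-read fraction
#' of unedited control embryos for the same target site and analysis
#' method, clipping at zero.
#'
#' @param summary an [summarize_embryo()] row (or several rbind-ed rows).
#' @param background a [fit_background()] model for the same target and
#'   method.
#' @return the summary with `frac_error_adjusted` filled in.
#' @export
adjust_errors <- function(summary, background) {
  stopifnot(inherits(background, "background_model"))
  check_background_match(summary, background)
  summary$frac_error_adjusted <- pmax(0, summary$frac_error -
                                        background$mean)
  summary
}

check_background_match <- function(summary, background) {
  if (any(!is.na(summary$target) & !is.na(background$target) &
          summary$target != background$target))
    stop("background model fitted on a different target site")
  if (any(summary$method != background$method))
    stop("background model fitted with a different analysis method")
  invisible(TRUE)
}

#' Analyze one embryo's reads end to end
#'
#' Convenience wrapper: quality masking and filtering, alignment, window
#' classification and per-embryo summary for a single (already
#' demultiplexed) read set.
#'
#' @param reads a read-set data.frame for one embryo.
#' @param spec a [target_spec()].
#' @param embryo_id embryo label.
#' @param method classification method, 1 or 2.
#' @param ... passed to [preprocess_reads()].
#' @return list with `summary` (an `embryo_summary` row), `classes`
#'   (per-kept-read calls) and `report` (the preprocessing report row).
#' @export
analyze_embryo <- function(reads, spec, embryo_id, method = 2L, ...) {
  pp <- preprocess_reads(reads, spec, demultiplex = FALSE, ...)
  kept <- pp$samples[[1]]
  classes <- classify_reads(kept, spec, method)
  list(summary = summarize_embryo(classes, embryo_id, method,
                                  n_discarded =
                                    pp$report$n_input - pp$report$n_kept,
                                  target = spec$name),
       classes = classes, report = pp$report)
}
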