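#' Describe one prime-editing target locus
#'
#' A target specification ties together the wild-type amplicon sequence, the
#' pegRNA nick position, the programmed edit, the optional complementary
#' (secondary) nick used by double-nick strategies, and the sample barcode
#' map used for demultiplexing. All coordinates are 0-based indices into the
#' amplicon; `nick_pos` is the first reference base 3' of the pegRNA nick,
#' so an edit at "+k" sits at reference index `nick_pos + k - 1`.
#'
#' @param name locus label.
#' @param amplicon wild-type amplicon sequence (A/C/G/T).
#' @param nick_pos 0-based index of the first base 3' of the pegRNA nick.
#' @param edit_kind one of `"substitution"`, `"deletion"`, `"insertion"`.
#' @param edit_offset 1-based offset of the edit from the nick (+1 is the
#'   first base 3' of the nick). Ignored when `edit_pos` is given.
#' @param edit_pos 0-based reference index of the edit; for insertions, the
#'   index of the reference base immediately 5' of the inserted sequence.
#' @param edit_ref reference allele (`""` for insertions).
#' @param edit_alt alternate allele (`""` for deletions).
#' @param secondary_nick_pos optional 0-based index for the secondary nick.
#' @param barcode_map optional named character vector, sample_id -> barcode;
#'   barcodes must share one length and be pairwise Hamming distance >= 3 so
#'   that distance-<=1 demultiplexing is unambiguous.
#' @return an object of class `target_spec`.
#' @examples
#' amp <- paste(rep("ACGT", 60), collapse = "")
#' spec <- target_spec("demo", amp, nick_pos = 100,
#'                     edit_kind = "substitution", edit_offset = 5,
#'                     edit_alt = "A")
#' @export
target_spec <- function(name, amplicon, nick_pos,
                        edit_kind = c("substitution", "deletion", "insertion"),
                        edit_offset = NULL, edit_pos = NULL,
                        edit_ref = NULL, edit_alt = NULL,
                        secondary_nick_pos = NULL, barcode_map = NULL) {
  edit_kind <- match.arg(edit_kind)
  amplicon <- toupper(amplicon)
  stopifnot(is.character(amplicon), length(amplicon) == 1L)
  if (grepl("[^ACGT]", amplicon))
    stop("amplicon must contain only A/C/G/T")
  len <- nchar(amplicon)
  if (nick_pos < 0 || nick_pos >= len)
    stop("nick_pos outside amplicon")
  if (is.null(edit_pos)) {
    if (is.null(edit_offset))
      stop("give either edit_pos or edit_offset")
    edit_pos <- nick_pos + edit_offset - 1L
  }
  edit_pos <- as.integer(edit_pos)
  if (edit_pos < 0 || edit_pos >= len)
    stop("edit_pos outside amplicon")

  if (edit_kind == "substitution") {
    if (is.null(edit_alt) || nchar(edit_alt) < 1L)
      stop("substitution needs edit_alt")
    if (is.null(edit_ref))
      edit_ref <- substr(amplicon, edit_pos + 1L, edit_pos + nchar(edit_alt))
    if (nchar(edit_ref) != nchar(edit_alt))
      stop("substitution ref/alt lengths differ")
  } else if (edit_kind == "deletion") {
    if (is.null(edit_ref)) edit_ref <- substr(amplicon, edit_pos + 1L,
                                              edit_pos + 1L)
    edit_alt <- ""
  } else {
    if (is.null(edit_alt) || nchar(edit_alt) < 1L)
      stop("insertion needs edit_alt")
    edit_ref <- ""
  }
  edit_ref <- toupper(edit_ref); edit_alt <- toupper(edit_alt)
  if (edit_kind != "insertion") {
    have <- substr(amplicon, edit_pos + 1L, edit_pos + nchar(edit_ref))
    if (have != edit_ref)
      stop("edit_ref does not match the amplicon at edit_pos (found '",
           have, "')")
  }

  if (!is.null(barcode_map)) {
    barcode_map <- toupper(unlist(barcode_map))
    if (is.null(names(barcode_map)) || any(names(barcode_map) == ""))
      stop("barcode_map must be named by sample_id")
    if (anyDuplicated(barcode_map))
      stop("duplicate barcodes in barcode_map")
    if (length(unique(nchar(barcode_map))) != 1L)
      stop("all barcodes must have the same length")
    if (length(barcode_map) > 1L) {
      for (i in seq_len(length(barcode_map) - 1L)) {
        d <- hamming(barcode_map[i], barcode_map[-seq_len(i)])
        if (any(d < 3L))
          stop("barcodes must be pairwise Hamming distance >= 3")
      }
    }
  }

  spec <- structure(list(
    name = name, amplicon = amplicon, nick_pos = as.integer(nick_pos),
    intended_edit = list(kind = edit_kind, ref = edit_ref, alt = edit_alt),
    edit_pos = edit_pos,
    secondary_nick_pos = if (is.null(secondary_nick_pos)) NULL
                         else as.integer(secondary_nick_pos),
    barcode_map = barcode_map), class = "target_spec")
  if (!is.null(spec$secondary_nick_pos) &&
      (spec$secondary_nick_pos < 0 || spec$secondary_nick_pos >= len))
    stop("secondary_nick_pos outside amplicon")
  if (apply_edit(spec) == amplicon)
    stop("intended edit leaves the amplicon unchanged")
  spec
}

#' Apply the intended edit to the wild-type amplicon
#'
#' @param spec a [target_spec()].
#' @return the edited amplicon sequence.
#' @export
apply_edit <- function(spec) {
  stopifnot(inherits(spec, "target_spec"))
  amp <- spec$amplicon
  p <- spec$edit_pos
  e <- spec$intended_edit
  switch(e$kind,
    substitution = paste0(substr(amp, 1L, p), e$alt,
                          substr(amp, p + nchar(e$alt) + 1L, nchar(amp))),
    deletion = paste0(substr(amp, 1L, p),
                      substr(amp, p + nchar(e$ref) + 1L, nchar(amp))),
    insertion = paste0(substr(amp, 1L, p + 1L), e$alt,
                       substr(amp, p + 2L, nchar(amp))))
}

# The intended edit as a normalized alignment event (see events.R), used to
# decide PRECISE calls. Indels are left-aligned against the amplicon so the
# comparison is robust to equivalent alignment placements.
intended_event <- function(spec) {
  e <- spec$intended_edit
  p <- spec$edit_pos
  ev <- switch(e$kind,
    substitution = data.frame(type = "sub", ref_start = p,
                              ref_end = p + nchar(e$ref),
                              ref = e$ref, alt = e$alt,
                              stringsAsFactors = FALSE),
    deletion = data.frame(type = "del", ref_start = p,
                          ref_end = p + nchar(e$ref),
                          ref = e$ref, alt = "", stringsAsFactors = FALSE),
    # insertion after reference base p (left flank = p)
    insertion = data.frame(type = "ins", ref_start = p, ref_end = p,
                           ref = "", alt = e$alt, stringsAsFactors = FALSE))
  normalize_events(ev, spec$amplicon)
}

#' @export
print.target_spec <- function(x, ...) {
  e <- x$intended_edit
  cat("Target locus '", x$name, "': ", nchar(x$amplicon), " nt amplicon\n",
      sep = "")
  cat("  pegRNA nick at ", x$nick_pos, " (0-based)",
      if (!is.null(x$secondary_nick_pos))
        paste0("; secondary nick at ", x$secondary_nick_pos), "\n", sep = "")
  cat("  intended edit: ", e$kind, " at ", x$edit_pos, " (",
      ifelse(e$ref == "", "-", e$ref), " > ",
      ifelse(e$alt == "", "-", e$alt), ")\n", sep = "")
  if (!is.null(x$barcode_map))
    cat("  barcodes: ", length(x$barcode_map), " samples, ",
        nchar(x$barcode_map[1]), " nt\n", sep = "")
  invisible(x)
}

#' Read a target specification from a YAML or JSON config file
#'
#' Field names mirror the [target_spec()] arguments; `barcode_map` is a
#' mapping of sample ids to barcode sequences.
#'
#' @param path path to a YAML (or JSON, a YAML subset) file.
#' @return a [target_spec()].
#' @export
read_target_spec <- function(path) {
  cfg <- yaml::read_yaml(path)
  target_spec(name = cfg$name, amplicon = cfg$amplicon,
              nick_pos = cfg$nick_pos,
              edit_kind = cfg$edit_kind,
              edit_offset = cfg$edit_offset, edit_pos = cfg$edit_pos,
              edit_ref = cfg$edit_ref, edit_alt = cfg$edit_alt,
              secondary_nick_pos = cfg$secondary_nick_pos,
              barcode_map = cfg$barcode_map)
}
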