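# Read-set container: a data.frame with columns read_id, bases, quals
# (Phred+33 encoded string, same length as bases) and, once processed,
# sample_id / masked columns. Kept deliberately plain so that standard
# data.frame tooling applies.

#' Decode a Phred+33 quality string to integer scores
#'
#' @param qual character vector of quality strings.
#' @return a list of integer vectors, one per input string.
#' @export
phred_decode <- function(qual) {
  lapply(qual, function(q) utf8ToInt(q) - 33L)
}

#' Encode integer Phred scores as a Phred+33 string
#'
#' @param scores integer vector of Phred scores (0-93).
#' @return a single character string.
#' @export
phred_encode <- function(scores) {
  stopifnot(all(scores >= 0L), all(scores <= 93L))
  intToUtf8(as.integer(scores) + 33L)
}

# Highest quality character expected under Phred+33 ('K' = Q42); anything
# above strongly suggests a Phred+64 file, which is rejected outright.
.PHRED33_MAX_CHAR <- 75L

#' Read single-end amplicon reads from a FASTQ file
#'
#' Reads a (optionally gzipped) FASTQ file with Phred+33 qualities. Files
#' whose quality strings contain characters outside the Phred+33 range are
#' rejected rather than silently misdecoded.
#'
#' @param path path to a FASTQ (or FASTQ.gz) file.
#' @return a data.frame with columns `read_id`, `bases`, `quals`.
#' @export
read_fastq <- function(path) {
  # Biostrings warns that FASTQ metadata columns are dropped; harmless here
  x <- withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(path),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  bases <- as.character(x)
  quals <- as.character(Biostrings::quality(x))
  if (length(quals) > 0L) {
    rng <- range(utf8ToInt(paste(quals, collapse = "")))
    if (rng[1] < 33L || rng[2] > .PHRED33_MAX_CHAR)
      stop("quality strings outside the Phred+33 range; ",
           "only Phred+33 FASTQ is supported")
  }
  data.frame(read_id = names(x), bases = unname(bases),
             quals = unname(quals), stringsAsFactors = FALSE)
}

#' Write reads to a FASTQ file
#'
#' @param reads a read-set data.frame (`read_id`, `bases`, `quals`).
#' @param path output path; written as plain text, byte-deterministic.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(is.data.frame(reads),
            all(c("read_id", "bases", "quals") %in% names(reads)))
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (nrow(reads) > 0L) {
    out <- paste0("@", reads$read_id, "\n", reads$bases, "\n+\n", reads$quals)
    writeLines(out, con, sep = "\n")
  }
  invisible(path)
}

#' Read a reference FASTA into a named character vector
#'
#' @param path path to a FASTA file.
#' @return named character vector of uppercase sequences, one per contig.
#' @export
read_reference <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(x))
  # FASTA descriptions may carry annotations after the first word
  names(out) <- vapply(strsplit(names(x), "\\s+"), `[`, "", 1L)
  out
}

#' Write named sequences to a FASTA file
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @param width line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (nm in names(seqs)) {
    writeLines(paste0(">", nm), con)
    s <- seqs[[nm]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

# hamming distance between equal-length strings (vectorized over `y`)
hamming <- function(x, y) {
  xs <- strsplit(x, "")[[1]]
  vapply(strsplit(y, ""), function(ys) sum(xs != ys), 0L)
}
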