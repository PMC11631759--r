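# Variant events extracted from a gapped pairwise alignment.
#
# An event table is a data.frame with columns:
#   type      "sub", "del" or "ins"
#   ref_start 0-based reference coordinate (for "ins": the left-flanking
#             reference base; -1 for an insertion before the first base)
#   ref_end   half-open end on the reference ("ins": equal to ref_start)
#   ref, alt  alleles ("" where empty)
# Events are non-overlapping and sorted by ref_start.

# Walk the aligned columns and emit events. Substitution columns where the
# read base is 'N' are non-informative (masked base calls must not create
# spurious errors) and are skipped.
alignment_events <- function(ref_aligned, read_aligned) {
  rs <- strsplit(ref_aligned, "")[[1]]
  qs <- strsplit(read_aligned, "")[[1]]
  stopifnot(length(rs) == length(qs))
  n <- length(rs)
  type <- character(0); ref_start <- integer(0); ref_end <- integer(0)
  refs <- character(0); alts <- character(0)
  ri <- 0L  # reference bases consumed so far
  i <- 1L
  while (i <= n) {
    if (rs[i] != "-" && qs[i] != "-") {
      if (rs[i] != qs[i] && qs[i] != "N") {
        type <- c(type, "sub"); ref_start <- c(ref_start, ri)
        ref_end <- c(ref_end, ri + 1L)
        refs <- c(refs, rs[i]); alts <- c(alts, qs[i])
      }
      ri <- ri + 1L
      i <- i + 1L
    } else if (qs[i] == "-") {  # deletion from the read: ref bases consumed
      j <- i
      while (j <= n && qs[j] == "-") j <- j + 1L
      L <- j - i
      type <- c(type, "del"); ref_start <- c(ref_start, ri)
      ref_end <- c(ref_end, ri + L)
      refs <- c(refs, paste(rs[i:(j - 1L)], collapse = ""))
      alts <- c(alts, "")
      ri <- ri + L
      i <- j
    } else {  # insertion in the read: left flank is the last ref base
      j <- i
      while (j <= n && rs[j] == "-") j <- j + 1L
      type <- c(type, "ins"); ref_start <- c(ref_start, ri - 1L)
      ref_end <- c(ref_end, ri - 1L)
      refs <- c(refs, "")
      alts <- c(alts, paste(qs[i:(j - 1L)], collapse = ""))
      i <- j
    }
  }
  data.frame(type = type, ref_start = ref_start, ref_end = ref_end,
             ref = refs, alt = alts, stringsAsFactors = FALSE)
}

# Left-align indel events against the reference so that equivalent gap
# placements of the same molecule compare equal. Substitutions are returned
# unchanged. `ref` is the ungapped reference sequence.
normalize_events <- function(events, ref) {
  if (nrow(events) == 0L) return(events)
  refc <- strsplit(ref, "")[[1]]
  for (k in seq_len(nrow(events))) {
    if (events$type[k] == "del") {
      s <- events$ref_start[k]
      L <- events$ref_end[k] - s
      # shift left while the base preceding the gap equals its last base
      while (s > 0L && refc[s] == refc[s + L]) s <- s - 1L
      events$ref_start[k] <- s
      events$ref_end[k] <- s + L
      events$ref[k] <- paste(refc[(s + 1L):(s + L)], collapse = "")
    } else if (events$type[k] == "ins") {
      p <- events$ref_start[k]  # left flank (0-based), -1 allowed
      ins <- strsplit(events$alt[k], "")[[1]]
      # rotate the inserted string left past matching flanking bases
      while (p >= 0L && ins[length(ins)] == refc[p + 1L]) {
        ins <- c(ins[length(ins)], ins[-length(ins)])
        p <- p - 1L
      }
      events$ref_start[k] <- p
      events$ref_end[k] <- p
      events$alt[k] <- paste(ins, collapse = "")
    }
  }
  events[order(events$ref_start, events$type), , drop = FALSE]
}

# Canonical string keys for set comparison of events.
event_keys <- function(events) {
  if (nrow(events) == 0L) return(character(0))
  paste(events$type, events$ref_start, events$ref_end,
        events$ref, events$alt, sep = ":")
}
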