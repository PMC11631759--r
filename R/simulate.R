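# Synthetic-data generators with ground-truth manifests. Both generators
# are pure functions of (configuration, seed): they save and restore the
# caller's RNG state and the same seed reproduces identical output bytes.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  code
}

.BASES <- c("A", "C", "G", "T")

random_dna <- function(n) {
  paste(sample(.BASES, n, replace = TRUE), collapse = "")
}

# substitute `k` random positions of `seq` with a different base
add_substitutions <- function(seq, k) {
  x <- utf8ToInt(seq)
  pos <- sample.int(length(x), k)
  for (p in pos) {
    cur <- intToUtf8(x[p])
    x[p] <- utf8ToInt(sample(setdiff(.BASES, cur), 1L))
  }
  intToUtf8(x)
}

#' Simulate one embryo's amplicon read set with known outcome mixture
#'
#' Draws each read's true molecule from a mixture over the outcome classes
#' seen in prime-edited embryos: unedited wild type, the precise edit,
#' deletions removing sequence between the two nicks (double-nick
#' byproduct), "combined" molecules carrying the intended edit plus a 3'
#' deletion, and small (1-3 nt) indels at the pegRNA nick. Reads then
#' receive i.i.d. substitution noise (emulating PCR/sequencing error and
#' somatic variation) and two-valued qualities; low-quality positions are
#' later masked by preprocessing.
#'
#' @param spec a [target_spec()]; a secondary nick is required when the
#'   mixture puts mass on inter-nick deletions.
#' @param embryo_id label used in read names and the manifest.
#' @param depth number of reads (default 10,000, the targeted per-sample
#'   sequencing depth).
#' @param mix named probabilities over
#'   `c(wt, precise, internick_del, combined, small_indel)`; must sum
#'   to 1. The default is a well-edited single-nick embryo.
#' @param subst_error_rate per-base substitution noise probability
#'   (default 5e-4, which puts the background error-read fraction near 2%
#'   for a 40-nt window, inside the 1-6% band seen in unedited controls).
#' @param q_high,q_low the two quality values; `q_low` falls below the
#'   masking threshold of 30.
#' @param p_lowq probability that a base call gets `q_low` (default 5e-4:
#'   masking is exercised on roughly one call per thousand while leaving
#'   outcome fractions essentially undistorted; a read whose edit-site
#'   call is masked cannot demonstrate the edit and bins as WT).
#' @param barcode optional barcode sequence prepended to every read (with
#'   high quality), for demultiplexing exercises.
#' @param seed RNG seed; identical seeds give byte-identical output.
#' @return list with `reads` (a read-set data.frame) and `manifest`
#'   (list: `per_read` truth table, `true_fractions` of molecule classes,
#'   `true_class_fractions` over WT/PRECISE/ERROR, and the configuration
#'   including the seed).
#' @export
simulate_embryo_reads <- function(spec, embryo_id = "embryo1",
                                  depth = 10000L,
                                  mix = c(wt = 0.37, precise = 0.60,
                                          internick_del = 0,
                                          combined = 0.02,
                                          small_indel = 0.01),
                                  subst_error_rate = 5e-4,
                                  q_high = 37L, q_low = 11L,
                                  p_lowq = 5e-4, barcode = NULL,
                                  seed = 1L) {
  stopifnot(inherits(spec, "target_spec"), depth >= 1L)
  classes <- c("wt", "precise", "internick_del", "combined", "small_indel")
  mix <- mix[classes]
  mix[is.na(mix)] <- 0
  names(mix) <- classes
  if (abs(sum(mix) - 1) > 1e-12) stop("mix probabilities must sum to 1")
  if (!(subst_error_rate >= 0 && subst_error_rate < 0.05))
    stop("subst_error_rate must lie in [0, 0.05)")
  if (mix[["internick_del"]] > 0 && is.null(spec$secondary_nick_pos))
    stop("inter-nick deletions require a secondary nick in the spec")

  amp <- spec$amplicon
  edited <- apply_edit(spec)
  with_seed(seed, {
    molecule <- sample(classes, depth, replace = TRUE, prob = mix)
    seqs <- character(depth)
    seqs[molecule == "wt"] <- amp
    seqs[molecule == "precise"] <- edited
    for (i in which(molecule == "internick_del")) {
      # excision between the two nicks: anchored at the pegRNA nick and
      # extending toward the secondary nick, removing 1..distance bases
      dist <- spec$secondary_nick_pos - spec$nick_pos
      L <- sample.int(abs(dist), 1L)
      s <- if (dist > 0L) spec$nick_pos else spec$nick_pos - L
      seqs[i] <- paste0(substr(amp, 1L, s), substr(amp, s + L + 1L,
                                                   nchar(amp)))
    }
    for (i in which(molecule == "combined")) {
      # intended edit plus a 3' deletion inside the nick window
      L <- sample(3:10, 1L)
      s <- spec$edit_pos + 1L + sample.int(4L, 1L)
      seqs[i] <- paste0(substr(edited, 1L, s), substr(edited, s + L + 1L,
                                                      nchar(edited)))
    }
    for (i in which(molecule == "small_indel")) {
      L <- sample.int(3L, 1L)
      if (runif(1) < 0.5) {
        seqs[i] <- paste0(substr(amp, 1L, spec$nick_pos),
                          substr(amp, spec$nick_pos + L + 1L, nchar(amp)))
      } else {
        seqs[i] <- paste0(substr(amp, 1L, spec$nick_pos), random_dna(L),
                          substr(amp, spec$nick_pos + 1L, nchar(amp)))
      }
    }
    lens <- nchar(seqs)
    nhit <- rbinom(depth, lens, subst_error_rate)
    for (i in which(nhit > 0L)) seqs[i] <- add_substitutions(seqs[i],
                                                             nhit[i])
    if (!is.null(barcode)) {
      seqs <- paste0(barcode, seqs)
      lens <- nchar(seqs)
    }
    # two-valued qualities drawn per base; barcode bases included
    qc <- c(intToUtf8(q_high + 33L), intToUtf8(q_low + 33L))
    draws <- runif(sum(lens)) < p_lowq
    bigq <- paste(qc[draws + 1L], collapse = "")
    ends <- cumsum(lens)
    quals <- substring(bigq, ends - lens + 1L, ends)

    reads <- data.frame(read_id = sprintf("%s:%d", embryo_id,
                                          seq_len(depth)),
                        bases = seqs, quals = quals,
                        stringsAsFactors = FALSE)
    true_class <- ifelse(molecule == "wt", "WT",
                         ifelse(molecule == "precise", "PRECISE", "ERROR"))
    manifest <- list(
      per_read = data.frame(read_id = reads$read_id, molecule = molecule,
                            true_class = true_class,
                            stringsAsFactors = FALSE),
      true_fractions = as.numeric(table(factor(molecule,
                                               levels = classes))) / depth,
      true_class_fractions = c(
        WT = mean(true_class == "WT"),
        PRECISE = mean(true_class == "PRECISE"),
        ERROR = mean(true_class == "ERROR")),
      config = list(embryo_id = embryo_id, depth = depth, mix = mix,
                    subst_error_rate = subst_error_rate, q_high = q_high,
                    q_low = q_low, p_lowq = p_lowq, barcode = barcode,
                    seed = seed))
    names(manifest$true_fractions) <- classes
    list(reads = reads, manifest = manifest)
  })
}

#' Simulate a cohort of unedited control embryos
#'
#' All reads are wild-type molecules; substitution noise alone produces
#' the background of error-classified reads observed in unedited
#' controls. The closed-form expected error-read fraction implied by the
#' noise rate and the classification window,
#' `1 - (1 - subst_error_rate)^window_length`, is reported alongside and
#' checked against the requested band.
#'
#' @param spec a [target_spec()].
#' @param n_embryos number of control embryos (>= 2).
#' @param method classification method whose window length sets the
#'   expectation (2 = the 40-nt pegRNA-nick window).
#' @param band acceptable range for the expected error-read fraction
#'   (default the 1-6% band observed in unedited controls).
#' @param depth,subst_error_rate,q_high,q_low,p_lowq,seed as in
#'   [simulate_embryo_reads()]; embryo `i` uses seed `seed + i - 1`.
#' @return list with `embryos` (list of [simulate_embryo_reads()]
#'   results), `expected_error_fraction` and `window_length`.
#' @export
simulate_control_cohort <- function(spec, n_embryos = 10L, depth = 10000L,
                                    subst_error_rate = 5e-4, method = 2L,
                                    band = c(0.01, 0.06), q_high = 37L,
                                    q_low = 11L, p_lowq = 5e-4, seed = 1L) {
  stopifnot(n_embryos >= 2L)
  w <- build_windows(spec, method)
  win_len <- (w$primary[2] - w$primary[1]) +
    if (is.null(w$secondary)) 0L else w$secondary[2] - w$secondary[1]
  expected <- 1 - (1 - subst_error_rate)^win_len
  if (!is.null(band) && (expected < band[1] || expected > band[2]))
    stop(sprintf(paste0("expected error-read fraction %.4f outside the ",
                        "requested band [%g, %g]"),
                 expected, band[1], band[2]))
  mix <- c(wt = 1, precise = 0, internick_del = 0, combined = 0,
           small_indel = 0)
  embryos <- lapply(seq_len(n_embryos), function(i) {
    simulate_embryo_reads(spec, embryo_id = sprintf("control%02d", i),
                          depth = depth, mix = mix,
                          subst_error_rate = subst_error_rate,
                          q_high = q_high, q_low = q_low, p_lowq = p_lowq,
                          seed = seed + i - 1L)
  })
  list(embryos = embryos, expected_error_fraction = expected,
       window_length = win_len)
}
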