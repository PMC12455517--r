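# Design and in-silico validation of a 3'-C3-spacer blocking
# oligonucleotide (PCR clamp) against the recurrent off-target 5'
# consensus. The blocker anneals to the host genome immediately
# downstream of the primer-like region; its C3 spacer prevents extension,
# so bound templates do not amplify.

#' Design parameters for the blocking oligo
#'
#' @param length_range Candidate lengths in nt (min >= 15).
#' @param tm_window Acceptable |Tm - mean primer Tm| in degrees C.
#' @param anchor_len 3' anchor used when cross-screening the oligo as if
#'   it were a primer.
#' @param max_mismatch Mismatch allowance for the cross-screen.
#' @param explicit_length Fixed oligo length overriding Tm selection.
#' @return A list of class `design_params`.
#' @export
design_params <- function(length_range = c(20L, 26L), tm_window = 5,
                          anchor_len = 5L, max_mismatch = 3L,
                          explicit_length = NULL) {
  if (length(length_range) != 2L || length_range[1L] > length_range[2L])
    stop("length_range must be c(min, max)")
  if (length_range[1L] < 15L)
    stop("minimum inhibitor length is 15 nt (got ", length_range[1L], ")")
  if (!is.null(explicit_length) && explicit_length < 15L)
    stop("explicit_length below the 15 nt minimum")
  structure(list(length_range = as.integer(length_range),
                 tm_window = tm_window, anchor_len = as.integer(anchor_len),
                 max_mismatch = as.integer(max_mismatch),
                 explicit_length = if (is.null(explicit_length)) NULL
                                   else as.integer(explicit_length)),
            class = "design_params")
}

#' Design a 3'-C3-spacer blocking oligo from the off-target consensus
#'
#' The candidate is a 5'-anchored prefix of the reduced consensus (which
#' by construction begins immediately downstream of the primer-like
#' region, so the blocker sits exactly where extension would start).
#' With `explicit_length` the prefix of that length is returned; otherwise
#' the shortest length in `length_range` whose Tm falls within
#' `tm_window` of the mean primer Tm is selected. The design is
#' `accepted` iff it meets the Tm window, forms no hairpin, and (when
#' `microbial_refs` is given) shows no cross-reactive priming site.
#'
#' @param consensus A `consensus_motif` (reduced form used) or a
#'   consensus string.
#' @param primers List of primer [oligo]s the Tm must be comparable to.
#' @param params A [design_params] object.
#' @param microbial_refs Optional named microbial reference sequences to
#'   screen for cross-reactivity.
#' @param min_stem,min_loop Hairpin-scan settings.
#' @return An `inhibitor_design`: the C3-annotated [oligo], `tm`,
#'   `delta_tm`, `hairpin`, `cross_hits`, `accepted`.
#' @export
design_inhibitor <- function(consensus,
                             primers = list(primer_341F(), primer_805R()),
                             params = design_params(),
                             microbial_refs = NULL,
                             min_stem = 4L, min_loop = 3L) {
  cons <- if (inherits(consensus, "consensus_motif")) consensus$iupac_reduced
          else nuc_sequence(consensus, what = "consensus")
  min_needed <- if (is.null(params$explicit_length)) params$length_range[1L]
                else params$explicit_length
  if (nchar(cons) < min_needed)
    stop("consensus (", nchar(cons), " nt) shorter than the requested ",
         "inhibitor length (", min_needed, ")")
  primer_tms <- vapply(primers, function(p) as.numeric(melting_temperature(p)),
                       numeric(1L))
  tm_ref <- mean(primer_tms)

  eval_len <- function(len) {
    seq <- substr(cons, 1L, len)
    tm <- as.numeric(melting_temperature(seq))
    list(len = len, seq = seq, tm = tm, delta = tm - tm_ref)
  }

  if (!is.null(params$explicit_length)) {
    cand <- eval_len(params$explicit_length)
  } else {
    lens <- seq.int(params$length_range[1L],
                    min(params$length_range[2L], nchar(cons)))
    cands <- lapply(lens, eval_len)
    ok <- vapply(cands, function(x) abs(x$delta) <= params$tm_window, logical(1L))
    if (!any(ok)) {
      best <- cands[[which.min(vapply(cands, function(x) abs(x$delta), numeric(1L)))]]
      stop(sprintf(paste0("no length in [%d, %d] meets the Tm window of +/-%.1f C; ",
                          "best candidate: %d nt '%s' with delta Tm %+.2f C"),
                   params$length_range[1L], params$length_range[2L],
                   params$tm_window, best$len, best$seq, best$delta))
    }
    cand <- cands[[which(ok)[1L]]]
  }

  olig <- oligo("offtarget_inhibitor", cand$seq, role = "inhibitor",
                three_prime_mod = "C3_spacer")
  hp <- hairpin_scan(olig, min_stem = min_stem, min_loop = min_loop)
  cross <- if (is.null(microbial_refs)) {
    data.frame(chrom = character(0L), pos = integer(0L),
               strand = character(0L), n_mismatches = integer(0L),
               stringsAsFactors = FALSE)
  } else {
    screen_cross_reactivity(olig, microbial_refs,
                            max_mismatch = params$max_mismatch,
                            anchor_len = params$anchor_len)
  }
  accepted <- abs(cand$delta) <= params$tm_window && !hp$has_hairpin &&
    nrow(cross) == 0L
  structure(
    list(oligo = olig, length = cand$len, tm = cand$tm,
         tm_primer_mean = tm_ref, delta_tm = cand$delta,
         hairpin = hp, cross_hits = cross, accepted = accepted,
         params = params),
    class = "inhibitor_design")
}

#' @export
print.inhibitor_design <- function(x, ...) {
  cat(sprintf("<inhibitor_design> 5'-%s-3' /3SpC3/ (%d nt)\n",
              x$oligo$seq, x$length))
  cat(sprintf("  Tm %.2f C (primer mean %.2f C, delta %+.2f C)\n",
              x$tm, x$tm_primer_mean, x$delta_tm))
  cat(sprintf("  hairpin: %s | cross-reactive sites: %d | %s\n",
              if (x$hairpin$has_hairpin) "YES" else "none",
              nrow(x$cross_hits),
              if (x$accepted) "ACCEPTED" else "not accepted"))
  invisible(x)
}

#' Screen a blocking oligo for cross-reactive priming sites
#'
#' Treats the oligo as if it could prime (perfect 3' anchor, limited
#' mismatches elsewhere, both strands) and scans the given references
#' with the mis-priming scanner. An empty result means the oligo is
#' specific to its intended target.
#'
#' @param x The [oligo] to screen.
#' @param references Named reference sequences (non-empty).
#' @param max_mismatch,anchor_len Scan settings (defaults 3 and 5).
#' @return Hits as a data frame (`chrom`, `pos` 1-based, `strand`,
#'   `n_mismatches`).
#' @export
screen_cross_reactivity <- function(x, references, max_mismatch = 3L,
                                    anchor_len = 5L) {
  references <- .as_named_seqs(references, what = "references")
  if (any(!nzchar(references)))
    stop("references contain an empty sequence")
  params <- scan_params(anchor_len = anchor_len, max_mismatches = max_mismatch)
  attr(params, "as_blocker") <- TRUE  # allow scanning a C3-spacer oligo
  sites <- scan_priming_sites(references, x, params)
  data.frame(chrom = sites$chrom, pos = sites$start + 1L,
             strand = sites$strand, n_mismatches = sites$n_mismatches,
             stringsAsFactors = FALSE)
}
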