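# Genome scan for primer-like landing sites under a 3'-anchored mismatch
# model, and pairing of convergent sites into predicted off-target
# amplicons. Mis-priming tolerates mismatches in the 5'/central part of a
# primer but requires a perfect 3' end for polymerase extension; the
# scanner encodes exactly that geometry.

.as_named_seqs <- function(genome, what = "genome") {
  if (inherits(genome, "DNAStringSet") || inherits(genome, "BStringSet"))
    genome <- as.character(genome)
  if (is.list(genome)) genome <- unlist(genome)
  if (!is.character(genome) || length(genome) == 0L)
    stop(what, " must be a non-empty named character vector of sequences")
  if (is.null(names(genome)) || anyNA(names(genome)) || any(!nzchar(names(genome))))
    stop(what, " sequences must all be named")
  if (anyDuplicated(names(genome)))
    stop("duplicate sequence ids in ", what)
  toupper(genome)
}

# Subject-side bitmasks: N in a genome is an unknown base and never
# matches any primer base (conservative call).
.subject_bits <- function(seq) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  bits <- .IUPAC_BITS[chars]
  if (anyNA(bits))
    stop(sprintf("invalid character '%s' in subject sequence",
                 chars[which(is.na(bits))[1L]]))
  bits <- unname(bits)
  bits[chars == "N"] <- 0L
  bits
}

.pattern_bits <- function(seq) {
  unname(.IUPAC_BITS[strsplit(seq, "", fixed = TRUE)[[1L]]])
}

# Ungapped scan of one strand. Returns 1-based start positions and
# non-anchor mismatch counts of all windows passing the anchor + mismatch
# contract. Vectorized over window positions, looping only over the
# pattern length.
.scan_strand <- function(subj_bits, pat_bits, anchor_len, max_mm) {
  P <- length(pat_bits)
  npos <- length(subj_bits) - P + 1L
  if (npos < 1L) return(list(start = integer(0L), n_mm = integer(0L)))
  anchor_from <- P - anchor_len + 1L
  mm <- integer(npos)
  ok <- rep(TRUE, npos)
  for (j in seq_len(P)) {
    mismatch <- bitwAnd(pat_bits[j], subj_bits[j:(j + npos - 1L)]) == 0L
    if (anchor_len > 0L && j >= anchor_from) {
      ok <- ok & !mismatch
    } else {
      mm <- mm + mismatch
    }
  }
  hit <- which(ok & mm <= max_mm)
  list(start = hit, n_mm = mm[hit])
}

# 3'-relative offsets (0 = terminal base) of the mismatching positions of
# one window.
.window_mismatch_offsets <- function(subj_bits, pat_bits, start) {
  P <- length(pat_bits)
  seg <- subj_bits[start:(start + P - 1L)]
  j <- which(bitwAnd(pat_bits, seg) == 0L)
  sort(P - j)
}

.empty_sites <- function() {
  data.frame(chrom = character(0L), start = integer(0L), strand = character(0L),
             primer_name = character(0L), primer_len = integer(0L),
             n_mismatches = integer(0L),
             mismatch_offsets = I(list()),
             anchor_intact = logical(0L),
             stringsAsFactors = FALSE)
}

#' Scan parameters for the mis-priming site search
#'
#' @param anchor_len Number of 3'-terminal primer bases that must match
#'   the genome perfectly (IUPAC-aware). Default 5.
#' @param max_mismatches Mismatches tolerated outside the anchor.
#'   Default 4.
#' @param allow_indels Must be `FALSE`; gapped priming is not modeled.
#' @return A list of class `scan_params`.
#' @export
scan_params <- function(anchor_len = 5L, max_mismatches = 4L,
                        allow_indels = FALSE) {
  anchor_len <- as.integer(anchor_len)
  max_mismatches <- as.integer(max_mismatches)
  if (anchor_len < 1L) stop("anchor_len must be positive")
  if (max_mismatches < 0L) stop("max_mismatches must be >= 0")
  if (isTRUE(allow_indels)) stop("gapped (indel) priming is not supported")
  structure(list(anchor_len = anchor_len, max_mismatches = max_mismatches,
                 allow_indels = FALSE),
            class = "scan_params")
}

#' Scan a genome for primer-like landing sites
#'
#' Finds every position, on both strands, where the primer aligns
#' ungapped with a perfect IUPAC match over its `anchor_len` 3'-terminal
#' bases and at most `max_mismatches` mismatches elsewhere. `N` in the
#' genome never matches. Coordinates are 0-based half-open on the forward
#' strand; for a minus-strand site `start` is the leftmost genomic
#' coordinate of the landing.
#'
#' @param genome Named character vector (or `DNAStringSet`) of A/C/G/T/N
#'   sequences.
#' @param primer An [oligo] or primer sequence string.
#' @param params A [scan_params] object.
#' @return A data frame of priming sites with columns `chrom`, `start`,
#'   `strand`, `primer_name`, `primer_len`, `n_mismatches`,
#'   `mismatch_offsets` (list column of 3'-relative offsets, 0 = terminal
#'   base) and `anchor_intact`, sorted by (chrom, start, strand).
#' @export
scan_priming_sites <- function(genome, primer, params = scan_params()) {
  genome <- .as_named_seqs(genome)
  pseq <- .oligo_seq(primer)
  pname <- if (inherits(primer, "oligo")) primer$name else "primer"
  if (inherits(primer, "oligo") && primer$three_prime_mod == "C3_spacer" &&
      !identical(attr(params, "as_blocker"), TRUE))
    stop("a 3'-C3-spacer oligo cannot act as an extensible primer; ",
         "use screen_cross_reactivity() to look for its binding sites")
  P <- nchar(pseq)
  if (P < params$anchor_len)
    stop("primer (", P, " nt) shorter than anchor_len (", params$anchor_len, ")")
  pat <- .pattern_bits(pseq)

  out <- vector("list", 2L * length(genome))
  k <- 0L
  for (chrom in names(genome)) {
    cs <- genome[[chrom]]
    L <- nchar(cs)
    fwd_bits <- .subject_bits(cs)
    rev_bits <- .subject_bits(reverse_complement(cs))
    for (strand in c("+", "-")) {
      bits <- if (strand == "+") fwd_bits else rev_bits
      h <- .scan_strand(bits, pat, params$anchor_len, params$max_mismatches)
      if (!length(h$start)) next
      start0 <- if (strand == "+") h$start - 1L else L - (h$start - 1L) - P
      offs <- lapply(h$start, .window_mismatch_offsets,
                     subj_bits = bits, pat_bits = pat)
      k <- k + 1L
      out[[k]] <- data.frame(
        chrom = chrom, start = start0, strand = strand,
        primer_name = pname, primer_len = P,
        n_mismatches = h$n_mm,
        mismatch_offsets = I(offs),
        anchor_intact = TRUE,
        stringsAsFactors = FALSE)
    }
  }
  if (k == 0L) return(.empty_sites())
  sites <- do.call(rbind, out[seq_len(k)])
  sites <- sites[!duplicated(sites[c("chrom", "start", "strand", "primer_name")]), ]
  sites <- sites[order(sites$chrom, sites$start, sites$strand), ]
  rownames(sites) <- NULL
  sites
}

#' Pair convergent priming sites into predicted amplicons
#'
#' A PCR product forms when a forward-primer landing and a reverse-primer
#' landing sit on opposite strands with their 3' ends facing each other.
#' All such convergent pairs on the same chromosome whose primer-to-primer
#' span lies inside `[min_len, max_len]` are reported, with the insert
#' sequence (between the two landings) extracted from the forward strand.
#'
#' @param fwd_sites,rev_sites Site data frames from [scan_priming_sites]
#'   for the forward and reverse primer respectively.
#' @param min_len,max_len Product length window in bp (defaults 100-600,
#'   covering both the roughly 300 bp host off-target and the roughly
#'   460 bp V3-V4 product).
#' @param genome The genome the sites were scanned on.
#' @return A data frame sorted by (chrom, product_start) with the product
#'   interval (0-based half-open), its length, both landings and the
#'   insert sequence.
#' @export
predict_amplicons <- function(fwd_sites, rev_sites, min_len = 100L,
                              max_len = 600L, genome = NULL) {
  if (min_len > max_len) stop("min_len must be <= max_len")
  if (!NROW(fwd_sites) || !NROW(rev_sites)) return(.empty_amplicons())
  if (!is.null(genome)) genome <- .as_named_seqs(genome)
  out <- list()
  k <- 0L
  for (chrom in intersect(unique(fwd_sites$chrom), unique(rev_sites$chrom))) {
    f <- fwd_sites[fwd_sites$chrom == chrom, ]
    r <- rev_sites[rev_sites$chrom == chrom, ]
    for (i in seq_len(nrow(f))) {
      for (j in seq_len(nrow(r))) {
        a <- f[i, ]; b <- r[j, ]
        if (a$strand == b$strand) next
        left  <- if (a$strand == "+") a else b
        right <- if (a$strand == "+") b else a
        # convergent: plus-strand landing upstream, 3' ends facing inward,
        # landings non-overlapping
        if (left$start + left$primer_len > right$start) next
        p_start <- left$start
        p_end <- right$start + right$primer_len
        p_len <- p_end - p_start
        if (p_len < min_len || p_len > max_len) next
        insert <- NA_character_
        if (!is.null(genome)) {
          insert <- substr(genome[[chrom]], left$start + left$primer_len + 1L,
                           right$start)
        }
        k <- k + 1L
        out[[k]] <- data.frame(
          chrom = chrom,
          product_start = p_start, product_end = p_end, product_len = p_len,
          fwd_primer = a$primer_name, fwd_start = a$start, fwd_strand = a$strand,
          rev_primer = b$primer_name, rev_start = b$start, rev_strand = b$strand,
          insert_len = right$start - (left$start + left$primer_len),
          insert_seq = insert,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (k == 0L) return(.empty_amplicons())
  amp <- do.call(rbind, out)
  amp <- amp[order(amp$chrom, amp$product_start), ]
  rownames(amp) <- NULL
  amp
}

.empty_amplicons <- function() {
  data.frame(chrom = character(0L), product_start = integer(0L),
             product_end = integer(0L), product_len = integer(0L),
             fwd_primer = character(0L), fwd_start = integer(0L),
             fwd_strand = character(0L), rev_primer = character(0L),
             rev_start = integer(0L), rev_strand = character(0L),
             insert_len = integer(0L), insert_seq = character(0L),
             stringsAsFactors = FALSE)
}

#' Textual alignment of a priming site against its primer
#'
#' Produces a primer-over-genome alignment for one emitted site, with
#' per-position match flags. Minus-strand windows are reverse-complemented
#' so the primer always reads 5' to 3'.
#'
#' @param site One row of a [scan_priming_sites] data frame.
#' @param primer The primer the site was emitted for.
#' @param genome The genome it was scanned on.
#' @return A list with `primer`, `window`, `match` (logical vector) and a
#'   preformatted `text` alignment.
#' @export
annotate_mispriming <- function(site, primer, genome) {
  genome <- .as_named_seqs(genome)
  if (NROW(site) != 1L) stop("site must be a single priming-site row")
  pseq <- .oligo_seq(primer)
  P <- nchar(pseq)
  if (!site$chrom %in% names(genome))
    stop("site chromosome '", site$chrom, "' absent from genome")
  chrom_seq <- genome[[site$chrom]]
  if (site$start + P > nchar(chrom_seq) || site$start < 0L)
    stop("site does not fit on chromosome '", site$chrom, "'")
  window <- substr(chrom_seq, site$start + 1L, site$start + P)
  if (site$strand == "-") window <- reverse_complement(window)
  pb <- .pattern_bits(pseq)
  wb <- .subject_bits(window)
  match_flags <- bitwAnd(pb, wb) > 0L
  if (sum(!match_flags) != site$n_mismatches)
    stop("site/genome mismatch: observed ", sum(!match_flags),
         " mismatches, site records ", site$n_mismatches)
  bars <- paste(ifelse(match_flags, "|", " "), collapse = "")
  text <- paste0(
    sprintf("%-8s 5'-%s-3'\n", site$primer_name, pseq),
    sprintf("%-8s    %s\n", "", bars),
    sprintf("%-8s 5'-%s-3' (%s:%d %s)\n", "genome", window,
            site$chrom, site$start + 1L, site$strand))
  list(primer_name = site$primer_name, primer = pseq, window = window,
       match = match_flags, text = text)
}
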