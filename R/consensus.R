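# IUPAC consensus motifs from off-target sequence sets: end-anchored
# gapless alignment, position frequency matrix, consensus calling in a
# full and a reduced (low-frequency degeneracies collapsed) form, and
# motif localization on reference sequences.
#
# Off-target reads share an exact primer-defined start, so end-anchoring
# replaces a general multiple alignment: no gaps can arise between reads
# born from the same priming event.

#' End-anchor and truncate sequences into a gapless aligned block
#'
#' @param seqs Character vector of (primer-trimmed) sequences.
#' @param end `"five_prime"`: keep the first `window` bases.
#'   `"three_prime"`: reverse-complement first, then keep the first
#'   `window` bases, so columns read 5' to 3' of the 3'-end motif.
#' @param window Block width in bp.
#' @return Character vector of equal-length sequences.
#' @export
anchor_align <- function(seqs, end = c("five_prime", "three_prime"),
                         window = 32L) {
  end <- match.arg(end)
  seqs <- vapply(seqs, nuc_sequence, character(1L), USE.NAMES = FALSE)
  short <- which(nchar(seqs) < window)
  if (length(short))
    stop("sequence ", short[1L], " (", nchar(seqs[short[1L]]),
         " nt) shorter than the ", window, " bp window")
  if (end == "three_prime")
    seqs <- vapply(seqs, reverse_complement, character(1L), USE.NAMES = FALSE)
  substr(seqs, 1L, window)
}

#' Build a position frequency matrix from an aligned block
#'
#' Ambiguous residues distribute fractionally across their expansion set
#' (an `S` adds 0.5 to C and 0.5 to G in its column).
#'
#' @param block Equal-length character vector (from [anchor_align]).
#' @return A `consensus_motif` with the 4 x width `pfm` (rows A, C, G, T)
#'   and `n_seqs`; consensus strings are filled in by
#'   [call_iupac_consensus].
#' @export
build_pfm <- function(block) {
  if (!length(block)) stop("empty block")
  w <- unique(nchar(block))
  if (length(w) != 1L) stop("ragged block: sequence lengths ",
                            paste(w, collapse = ", "))
  mat <- matrix(0, nrow = 4L, ncol = w,
                dimnames = list(c("A", "C", "G", "T"), NULL))
  chars <- do.call(rbind, strsplit(block, "", fixed = TRUE))
  for (j in seq_len(w)) {
    for (ch in unique(chars[, j])) {
      set <- .IUPAC_EXPANSION[[ch]]
      n_ch <- sum(chars[, j] == ch)
      mat[set, j] <- mat[set, j] + n_ch / length(set)
    }
  }
  structure(list(pfm = mat, n_seqs = length(block),
                 iupac_full = NULL, iupac_reduced = NULL,
                 include_freq = NULL, drop_freq = NULL, min_coverage = NULL),
            class = "consensus_motif")
}

.set_to_iupac <- function(bases) {
  .BITS_TO_IUPAC[sum(.IUPAC_BITS[bases])]
}

#' Call full and reduced IUPAC consensus strings from a PFM
#'
#' Per column, every base whose frequency (relative to the column's
#' observations) reaches `include_freq` enters the IUPAC code of the full
#' consensus. The reduced consensus additionally collapses a column to
#' its majority base when all its minor included bases fall below
#' `drop_freq` -- the "exclude degenerations with extremely low
#' frequency" rule -- and trims trailing columns observed in fewer than
#' `min_coverage` of the sequences.
#'
#' @param motif A `consensus_motif` from [build_pfm].
#' @param include_freq Minimum base frequency to enter the full code
#'   (default 0.25).
#' @param drop_freq Minor bases below this frequency are collapsed in the
#'   reduced form (default 0.10).
#' @param min_coverage Trailing-column coverage threshold for the reduced
#'   form (default 0.50).
#' @return The motif with `iupac_full` and `iupac_reduced` filled in.
#' @export
call_iupac_consensus <- function(motif, include_freq = 0.25,
                                 drop_freq = 0.10, min_coverage = 0.50) {
  if (!inherits(motif, "consensus_motif")) stop("motif must be a consensus_motif")
  if (include_freq <= 0 || include_freq > 1)
    stop("include_freq must be in (0, 1]")
  pfm <- motif$pfm
  w <- ncol(pfm)
  cov <- colSums(pfm)
  full <- reduced <- character(w)
  for (j in seq_len(w)) {
    if (cov[j] == 0) { full[j] <- "N"; reduced[j] <- "N"; next }
    freq <- pfm[, j] / cov[j]
    inc <- names(freq)[freq >= include_freq]
    major <- names(freq)[which.max(freq)]
    if (!length(inc)) inc <- major
    full[j] <- .set_to_iupac(inc)
    minor <- setdiff(inc, major)
    reduced[j] <- if (length(minor) && all(freq[minor] < drop_freq))
      major else full[j]
  }
  keep <- w
  while (keep > 0L && cov[keep] < min_coverage * motif$n_seqs) keep <- keep - 1L
  motif$iupac_full <- paste(full, collapse = "")
  motif$iupac_reduced <- paste(reduced[seq_len(keep)], collapse = "")
  motif$include_freq <- include_freq
  motif$drop_freq <- drop_freq
  motif$min_coverage <- min_coverage
  motif
}

#' @export
print.consensus_motif <- function(x, ...) {
  cat(sprintf("<consensus_motif> %d columns from %d sequences\n",
              ncol(x$pfm), x$n_seqs))
  if (!is.null(x$iupac_full))
    cat("  full:    ", x$iupac_full, "\n  reduced: ", x$iupac_reduced, "\n",
        sep = "")
  invisible(x)
}

#' Per-column base frequencies of a motif (logo data)
#' @param motif A `consensus_motif`.
#' @return A data frame with `position`, `base`, `count`, `freq`.
#' @export
motif_logo_data <- function(motif) {
  pfm <- motif$pfm
  cov <- colSums(pfm)
  data.frame(
    position = rep(seq_len(ncol(pfm)), each = 4L),
    base = rep(rownames(pfm), ncol(pfm)),
    count = as.vector(pfm),
    freq = as.vector(sweep(pfm, 2L, pmax(cov, 1), "/")),
    stringsAsFactors = FALSE)
}

#' Locate a (possibly degenerate) motif on reference sequences
#'
#' IUPAC-aware ungapped search on both strands, with up to `max_mismatch`
#' mismatches anywhere in the motif. This fills the role a BLASTn search
#' of a short consensus plays: short, near-exact, ungapped hits.
#'
#' @param motif Motif string or `consensus_motif` (reduced form used);
#'   at least 12 nt.
#' @param reference Named reference sequences.
#' @param max_mismatch Mismatch allowance (default 0).
#' @return Data frame (`chrom`, `pos` 1-based, `strand`, `n_mismatches`)
#'   sorted by (chrom, pos).
#' @export
locate_motif <- function(motif, reference, max_mismatch = 0L) {
  mseq <- if (inherits(motif, "consensus_motif")) motif$iupac_reduced
          else nuc_sequence(motif, what = "motif")
  if (nchar(mseq) < 12L)
    stop("motif too short (", nchar(mseq), " nt, need >= 12)")
  reference <- .as_named_seqs(reference, what = "reference")
  pat <- .pattern_bits(mseq)
  P <- length(pat)
  out <- list()
  for (chrom in names(reference)) {
    cs <- reference[[chrom]]
    L <- nchar(cs)
    for (strand in c("+", "-")) {
      s <- if (strand == "+") cs else reverse_complement(cs)
      h <- .scan_strand(.subject_bits(s), pat, anchor_len = 0L,
                        max_mm = max_mismatch)
      if (!length(h$start)) next
      pos1 <- if (strand == "+") h$start else L - (h$start - 1L) - P + 1L
      out[[length(out) + 1L]] <- data.frame(
        chrom = chrom, pos = pos1, strand = strand,
        n_mismatches = h$n_mm, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(0L), pos = integer(0L),
                      strand = character(0L), n_mismatches = integer(0L),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$pos, res$strand), ]
  rownames(res) <- NULL
  res
}

#' Outer-end span of a convergent 5'/3' consensus pair
#'
#' Given the 1-based positions of the 5'-end consensus and the 3'-end
#' consensus on a chromosome (as reported by [locate_motif]) and their
#' lengths, returns the span between the outermost ends of the two
#' motifs, i.e. the off-target product size measured on the consensus
#' coordinates (primer landings excluded).
#'
#' @param five_pos,three_pos 1-based leftmost positions of the two motif
#'   occurrences.
#' @param five_len,three_len Motif lengths (defaults 32 and 29 nt).
#' @return Span in bp.
#' @export
consensus_product_span <- function(five_pos, three_pos, five_len = 32L,
                                   three_len = 29L) {
  left <- min(five_pos, three_pos)
  right <- max(five_pos + five_len - 1L, three_pos + three_len - 1L)
  as.integer(right - left + 1L)
}
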