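# IUPAC-aware sequence primitives shared by every stage: validation,
# matching, complementation, degenerate expansion.

# Bitmask encoding of the 15 IUPAC nucleotide codes: A=1, C=2, G=4, T=8.
# Two codes are compatible iff their base sets intersect (bitwAnd > 0).
.IUPAC_BITS <- c(
  A = 1L, C = 2L, G = 4L, T = 8L,
  M = 3L, R = 5L, W = 9L, S = 6L, Y = 10L, K = 12L,
  V = 7L, H = 11L, D = 13L, B = 14L, N = 15L
)

.BITS_TO_IUPAC <- {
  x <- character(15L)
  x[.IUPAC_BITS] <- names(.IUPAC_BITS)
  x
}

.IUPAC_EXPANSION <- list(
  A = "A", C = "C", G = "G", T = "T",
  M = c("A", "C"), R = c("A", "G"), W = c("A", "T"),
  S = c("C", "G"), Y = c("C", "T"), K = c("G", "T"),
  V = c("A", "C", "G"), H = c("A", "C", "T"),
  D = c("A", "G", "T"), B = c("C", "G", "T"),
  N = c("A", "C", "G", "T")
)

# chartr maps for IUPAC complementation (W<->W, S<->S, R<->Y, M<->K, B<->V, ...)
.COMP_FROM <- "ACGTMRWSYKVHDBN"
.COMP_TO   <- "TGCAKYWSRMBDHVN"

#' Validate and normalize a nucleotide sequence
#'
#' Accepts upper or lower case, normalizes `U` to `T`, and rejects any
#' character outside the 15 IUPAC nucleotide codes, naming the offending
#' character and its position.
#'
#' @param x A single character string.
#' @param what Label used in error messages.
#' @return The normalized (uppercase, DNA-alphabet) string.
#' @export
nuc_sequence <- function(x, what = "sequence") {
  if (length(x) != 1L || !is.character(x) || is.na(x))
    stop(what, " must be a single character string")
  x <- chartr("u", "t", x)
  x <- toupper(x)
  x <- chartr("U", "T", x)
  if (nzchar(x)) {
    chars <- strsplit(x, "", fixed = TRUE)[[1L]]
    bad <- which(!(chars %in% names(.IUPAC_BITS)))
    if (length(bad))
      stop(sprintf("invalid IUPAC character '%s' at position %d in %s",
                   chars[bad[1L]], bad[1L], what))
  }
  x
}

#' Test whether two IUPAC codes are compatible
#'
#' Two codes match iff their base expansion sets intersect, e.g. `N`
#' matches everything, `W` = \{A,T\} does not match `C`. Vectorized over
#' equal-length inputs; symmetric in its arguments.
#'
#' @param pattern_base,target_base Character vectors of single IUPAC codes.
#' @return Logical vector.
#' @examples
#' iupac_match("N", "A")  # TRUE
#' iupac_match("W", "C")  # FALSE
#' @export
iupac_match <- function(pattern_base, target_base) {
  a <- .IUPAC_BITS[toupper(pattern_base)]
  b <- .IUPAC_BITS[toupper(target_base)]
  if (anyNA(a))
    stop("invalid IUPAC code '", pattern_base[which(is.na(a))[1L]], "'")
  if (anyNA(b))
    stop("invalid IUPAC code '", target_base[which(is.na(b))[1L]], "'")
  bitwAnd(unname(a), unname(b)) > 0L
}

#' IUPAC-aware reverse complement
#'
#' Degenerate codes map to their complementary sets (R to Y, M to K,
#' B to V, W and S to themselves, N to N). Applying the function twice
#' returns the input.
#'
#' @param seq Nucleotide sequence (IUPAC alphabet).
#' @return The reverse complement as a character string.
#' @export
reverse_complement <- function(seq) {
  seq <- nuc_sequence(seq)
  if (!nzchar(seq)) return(seq)
  comp <- chartr(.COMP_FROM, .COMP_TO, seq)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1L]]), collapse = "")
}

#' Enumerate the concrete A/C/G/T expansions of a degenerate sequence
#'
#' @param seq Nucleotide sequence.
#' @param limit Refuse expansion when the number of concrete sequences
#'   (product of per-position degeneracies) exceeds this.
#' @return Character vector of expansions in lexicographic order.
#' @export
expand_degenerate <- function(seq, limit = 64L) {
  seq <- nuc_sequence(seq)
  if (!nzchar(seq)) return("")
  sets <- .IUPAC_EXPANSION[strsplit(seq, "", fixed = TRUE)[[1L]]]
  count <- prod(vapply(sets, length, integer(1L)))
  if (count > limit)
    stop(sprintf("degenerate expansion of '%s' yields %d sequences, above the limit of %d",
                 seq, count, as.integer(limit)))
  Reduce(function(acc, opts) as.vector(t(outer(acc, opts, paste0))), sets, "")
}

#' Number of concrete expansions of a degenerate sequence
#' @inheritParams expand_degenerate
#' @return Integer count (product of per-position set sizes).
#' @export
degeneracy <- function(seq) {
  seq <- nuc_sequence(seq)
  if (!nzchar(seq)) return(1)
  prod(vapply(.IUPAC_EXPANSION[strsplit(seq, "", fixed = TRUE)[[1L]]],
              length, integer(1L)))
}

#' Construct an oligonucleotide
#'
#' An oligo couples a sequence with its PCR role and an optional 3'
#' modification. Oligos carrying a 3' C3 spacer cannot be extended by a
#' polymerase: downstream stages treat them as blockers, never as primers.
#'
#' @param name Label.
#' @param seq Nucleotide sequence (IUPAC codes allowed).
#' @param role One of `"forward_primer"`, `"reverse_primer"`,
#'   `"inhibitor"`, `"probe"`.
#' @param three_prime_mod `"none"` or `"C3_spacer"`.
#' @return An object of class `oligo`.
#' @export
oligo <- function(name, seq,
                  role = c("forward_primer", "reverse_primer", "inhibitor", "probe"),
                  three_prime_mod = c("none", "C3_spacer")) {
  role <- match.arg(role)
  three_prime_mod <- match.arg(three_prime_mod)
  structure(
    list(name = as.character(name),
         seq = nuc_sequence(seq, what = paste0("oligo '", name, "'")),
         role = role,
         three_prime_mod = three_prime_mod),
    class = "oligo"
  )
}

#' @export
print.oligo <- function(x, ...) {
  mod <- if (x$three_prime_mod == "C3_spacer") " [3'-C3 spacer]" else ""
  cat(sprintf("<oligo> %s (%s)%s\n  5'-%s-3'  (%d nt)\n",
              x$name, x$role, mod, x$seq, nchar(x$seq)))
  invisible(x)
}

.oligo_seq <- function(x) {
  if (inherits(x, "oligo")) x$seq else nuc_sequence(x)
}

# The universal V3-V4 primers and the off-target blocking oligo used
# throughout the package as defaults.
#' Standard primers and blocking oligo
#'
#' `primer_341F()` and `primer_805R()` return the universal 16S V3-V4
#' primer pair; `primer_338F()` the alternate forward primer;
#' `default_inhibitor()` the 24-mer 3'-C3-spacer blocking oligo directed
#' against the recurrent human off-target 5' consensus.
#' @return An [oligo].
#' @export
primer_341F <- function() oligo("341F", "CCTACGGGNGGCWGCAG", "forward_primer")

#' @rdname primer_341F
#' @export
primer_805R <- function() oligo("805R", "GACTACNVGGGTWTCTAATCC", "reverse_primer")

#' @rdname primer_341F
#' @export
primer_338F <- function() oligo("338F", "ACTCCTACGGGAGGCAGCAG", "forward_primer")

#' @rdname primer_341F
#' @export
default_inhibitor <- function()
  oligo("offtarget_inhibitor", "TGATAAACCTTTAGCAATAAACSA", "inhibitor",
        three_prime_mod = "C3_spacer")
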