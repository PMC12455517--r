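# Nearest-neighbor melting temperature and hairpin detection.

# SantaLucia (1998) unified nearest-neighbor parameters.
# dH in kcal/mol, dS in cal/(mol K).
.NN_DH <- c(
  AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
  CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
  CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
  CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0
)
.NN_DS <- c(
  AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
  CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
  CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
  CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9
)
# Duplex initiation with a terminal A/T vs terminal G/C.
.NN_INIT_DH <- c(AT = 2.3, GC = 0.1)
.NN_INIT_DS <- c(AT = 4.1, GC = -2.8)
.GAS_CONSTANT <- 1.987  # cal/(mol K)

.tm_concrete <- function(seq, na_molar, ct_molar) {
  n <- nchar(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  steps <- paste0(chars[-n], chars[-1L])
  dh <- sum(.NN_DH[steps])
  ds <- sum(.NN_DS[steps])
  for (term in chars[c(1L, n)]) {
    key <- if (term %in% c("A", "T")) "AT" else "GC"
    dh <- dh + .NN_INIT_DH[[key]]
    ds <- ds + .NN_INIT_DS[[key]]
  }
  # Entropy salt correction, 0.368 * (N-1) * ln[Na+]
  ds <- ds + 0.368 * (n - 1L) * log(na_molar)
  dh * 1000 / (ds + .GAS_CONSTANT * log(ct_molar / 4)) - 273.15
}

#' Nearest-neighbor melting temperature
#'
#' Computes the duplex melting temperature from SantaLucia (1998) unified
#' nearest-neighbor thermodynamics with a monovalent-salt entropy
#' correction, at a total oligo concentration `oligo_conc` (CT/4 term,
#' non-self-complementary duplex assumed). For a degenerate oligo every
#' concrete expansion is evaluated and the arithmetic mean returned; the
#' min and max over expansions are attached as attributes `tm_min` and
#' `tm_max`.
#'
#' @param x An [oligo] or a nucleotide sequence string, length >= 8 nt.
#' @param monovalent_salt Monovalent cation concentration in mol/L
#'   (default 0.05, i.e. 50 mM Na+).
#' @param oligo_conc Total oligo concentration in mol/L (default 0.25 uM).
#' @param expansion_limit Maximum number of degenerate expansions.
#' @return Melting temperature in degrees Celsius (mean over expansions),
#'   with attributes `tm_min`, `tm_max` and `n_expansions`.
#' @export
melting_temperature <- function(x, monovalent_salt = 0.05,
                                oligo_conc = 0.25e-6,
                                expansion_limit = 64L) {
  seq <- .oligo_seq(x)
  if (nchar(seq) < 8L)
    stop("oligo too short for nearest-neighbor Tm (", nchar(seq), " nt, need >= 8)")
  exps <- expand_degenerate(seq, limit = expansion_limit)
  tms <- vapply(exps, .tm_concrete, numeric(1L),
                na_molar = monovalent_salt, ct_molar = oligo_conc)
  structure(mean(tms),
            tm_min = min(tms), tm_max = max(tms),
            n_expansions = length(tms))
}

#' Scan an oligo for hairpin-forming self-complementarity
#'
#' Exhaustive search for an intramolecular stem: two antiparallel windows
#' whose bases pair under IUPAC intersection (a degenerate code pairs with
#' another code iff their expansion sets contain a complementary pair),
#' separated by a loop of at least `min_loop` unpaired bases. Stems held
#' together exclusively by A:T pairs are too weak to fold at PCR
#' annealing temperatures, so a stem only qualifies when it contains at
#' least `min_gc` G:C pairs (degenerate positions count optimistically).
#' The longest qualifying stem is reported; ties resolve to the 5'-most.
#'
#' @param x An [oligo] or sequence string.
#' @param min_stem Minimum stem length in bp to call a hairpin (>= 3).
#' @param min_loop Minimum loop length in bases (>= 3).
#' @param min_gc Minimum number of G:C pairs a stem must contain
#'   (default 1).
#' @return A list of class `hairpin_report` with elements `has_hairpin`,
#'   `best_stem_len`, `best_loop_len` and `stem_positions` (1-based start
#'   offsets of the two stem arms), the latter two `NA`/`NULL` when no
#'   qualifying stem exists.
#' @export
hairpin_scan <- function(x, min_stem = 4L, min_loop = 3L, min_gc = 1L) {
  if (min_stem < 3L || min_loop < 3L)
    stop("min_stem and min_loop must both be >= 3")
  seq <- .oligo_seq(x)
  n <- nchar(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  bits <- unname(.IUPAC_BITS[chars])
  comp_bits <- unname(.IUPAC_BITS[chartr(.COMP_FROM, .COMP_TO, chars)])
  G <- .IUPAC_BITS[["G"]]; C <- .IUPAC_BITS[["C"]]

  best_len <- 0L
  best_loop <- NA_integer_
  best_pos <- NULL
  if (n >= 2L * min_stem + min_loop) {
    # anchor at the innermost base pair (p, q), extend outward
    for (p in seq_len(n - min_loop - 1L)) {
      for (q in seq.int(p + min_loop + 1L, n)) {
        len <- 0L
        gc <- 0L
        while (p - len >= 1L && q + len <= n &&
               bitwAnd(bits[p - len], comp_bits[q + len]) > 0L) {
          i <- p - len; j <- q + len
          if ((bitwAnd(bits[i], G) > 0L && bitwAnd(bits[j], C) > 0L) ||
              (bitwAnd(bits[i], C) > 0L && bitwAnd(bits[j], G) > 0L))
            gc <- gc + 1L
          len <- len + 1L
        }
        if (gc >= min_gc && len > best_len) {
          best_len <- len
          best_loop <- q - p - 1L
          best_pos <- c(p - len + 1L, q)
        }
      }
    }
  }
  structure(
    list(has_hairpin = best_len >= min_stem,
         best_stem_len = best_len,
         best_loop_len = best_loop,
         stem_positions = best_pos,
         min_stem = as.integer(min_stem),
         min_loop = as.integer(min_loop),
         min_gc = as.integer(min_gc)),
    class = "hairpin_report"
  )
}

#' @export
print.hairpin_report <- function(x, ...) {
  if (x$has_hairpin) {
    cat(sprintf("hairpin: stem %d bp, loop %d nt (arms at %d and %d)\n",
                x$best_stem_len, x$best_loop_len,
                x$stem_positions[1L], x$stem_positions[2L]))
  } else {
    cat(sprintf("no hairpin (longest stem %d bp, required >= %d with loop >= %d)\n",
                x$best_stem_len, x$min_stem, x$min_loop))
  }
  invisible(x)
}
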