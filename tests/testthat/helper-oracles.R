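# Independent oracles used to cross-check the package's hand-authored
# algorithms. These deliberately take different routes from the
# implementation: Biostrings for pattern matching and complementation,
# direct set arithmetic for IUPAC semantics, naive enumeration for
# hairpins and subsampling for rarefaction.

# IUPAC expansion sets written out independently of the package tables.
ORACLE_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
  D = c("A", "G", "T"), H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

oracle_base_match <- function(a, b) {
  length(intersect(ORACLE_SETS[[a]], ORACLE_SETS[[b]])) > 0L
}

oracle_revcomp <- function(seq) {
  if (!nchar(seq)) return(seq)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

random_dna_string <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Brute-force priming-site oracle: candidate windows from Biostrings
# matchPattern (IUPAC-aware, both strands), then per-window anchor and
# mismatch accounting by direct character comparison. Genomes must be
# A/C/G/T (no N) for this oracle.
oracle_scan <- function(genome, primer_seq, anchor_len, max_mm,
                        primer_name = "primer") {
  P <- nchar(primer_seq)
  pchars <- strsplit(primer_seq, "", fixed = TRUE)[[1L]]
  pat <- Biostrings::DNAString(primer_seq)
  rows <- list()
  for (chrom in names(genome)) {
    L <- nchar(genome[[chrom]])
    for (strand in c("+", "-")) {
      subj_seq <- if (strand == "+") genome[[chrom]]
                  else oracle_revcomp(genome[[chrom]])
      m <- Biostrings::matchPattern(pat, Biostrings::DNAString(subj_seq),
                                    max.mismatch = max_mm, fixed = FALSE)
      for (st in Biostrings::start(m)) {
        win <- strsplit(substr(subj_seq, st, st + P - 1L), "", fixed = TRUE)[[1L]]
        mism_at <- which(!mapply(oracle_base_match, pchars, win))
        anchor_ok <- !any(mism_at > P - anchor_len)
        if (!anchor_ok || length(mism_at) > max_mm) next
        start0 <- if (strand == "+") st - 1L else L - st + 1L - P
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = chrom, start = start0, strand = strand,
          primer_name = primer_name, n_mismatches = length(mism_at),
          offsets = paste(sort(P - mism_at), collapse = ","),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows))
    return(data.frame(chrom = character(0L), start = integer(0L),
                      strand = character(0L), primer_name = character(0L),
                      n_mismatches = integer(0L), offsets = character(0L),
                      stringsAsFactors = FALSE))
  out <- unique(do.call(rbind, rows))
  out[order(out$chrom, out$start, out$strand), , drop = FALSE]
}

# Flatten a scan_priming_sites result into the oracle's comparable shape.
sites_for_comparison <- function(sites) {
  out <- data.frame(chrom = sites$chrom, start = sites$start,
                    strand = sites$strand, primer_name = sites$primer_name,
                    n_mismatches = sites$n_mismatches,
                    offsets = vapply(sites$mismatch_offsets, paste,
                                     character(1L), collapse = ","),
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Naive hairpin oracle: enumerate every (arm1, arm2, stem length) triple
# explicitly and test all base pairs.
oracle_hairpin <- function(seq, min_stem, min_loop, min_gc = 1L) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  comp <- c(A = "T", C = "G", G = "C", T = "A",
            R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
            B = "V", V = "B", D = "H", H = "D", N = "N")
  pairs_with <- function(a, b) oracle_base_match(a, comp[[b]])
  is_gc <- function(a, b) {
    ("G" %in% ORACLE_SETS[[a]] && "C" %in% ORACLE_SETS[[b]]) ||
      ("C" %in% ORACLE_SETS[[a]] && "G" %in% ORACLE_SETS[[b]])
  }
  for (L in seq.int(min_stem, max(min_stem, (n - min_loop) %/% 2L))) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i + L - 1L > n || j + L - 1L > n) next
        if (j < i + L + min_loop) next  # loop between arm1 end and arm2 start
        ok <- TRUE; gc <- 0L
        for (t in 0:(L - 1L)) {
          a <- chars[i + t]; b <- chars[j + L - 1L - t]
          if (!pairs_with(a, b)) { ok <- FALSE; break }
          if (is_gc(a, b)) gc <- gc + 1L
        }
        if (ok && gc >= min_gc) return(TRUE)
      }
    }
  }
  FALSE
}

# Exact-match motif oracle: expand degeneracies and search every
# concrete string with fixed-string matching on both strands.
oracle_locate_exact <- function(motif, genome) {
  hits <- list()
  for (m in amplihijack::expand_degenerate(motif, limit = 1024L)) {
    for (chrom in names(genome)) {
      L <- nchar(genome[[chrom]])
      for (strand in c("+", "-")) {
        s <- if (strand == "+") genome[[chrom]] else oracle_revcomp(genome[[chrom]])
        found <- gregexpr(m, s, fixed = TRUE)[[1L]]
        if (found[1L] == -1L) next
        pos <- if (strand == "+") as.integer(found)
               else L - as.integer(found) + 1L - nchar(m) + 1L
        hits[[length(hits) + 1L]] <- data.frame(
          chrom = chrom, pos = pos, strand = strand, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(hits))
    return(data.frame(chrom = character(0L), pos = integer(0L),
                      strand = character(0L), stringsAsFactors = FALSE))
  out <- unique(do.call(rbind, hits))
  out[order(out$chrom, out$pos, out$strand), , drop = FALSE]
}

# Hypergeometric expected richness written directly from the formula.
oracle_expected_richness <- function(counts, n) {
  N <- sum(counts)
  sum(1 - exp(lchoose(N - counts, n) - lchoose(N, n)))
}

# The planted 5' consensus and chromosome-specific 3' consensi.
PLANTED_5P <- "TGATAAACCTTTAGCAATAAACSAAAGTTTAA"
PLANTED_3P <- c(chr5  = "CAGTTTGGGTCTTAGCTATTGTGTGTTCA",
                chr11 = "CAGTTTGGGTCTTAGTTATTCTGTGTTCA",
                chr17 = "CAGTTTGAATCTTCGCTATTGTGTATTCA")

# A small, fast simulation fixture shared by several test files.
small_sim_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    cfg <- sim_config(seed = 202, chrom_len = 15000L, n_taxa = 10L,
                      depth = 8000L)
    host <- make_host_genome(cfg)
    com <- make_16s_community(cfg)
    kit <- make_16s_community(cfg, n_taxa = cfg$n_kitome, prefix = "Kitome",
                              copies_total = cfg$kitome_template_copies,
                              seed = cfg$seed + 7L)
    sim <- simulate_pcr_reads(host, com, kit, cfg)
    ft <- make_feature_tables(list(s1 = sim))
    cache <<- list(cfg = cfg, host = host, com = com, kit = kit,
                   sim = sim, ft = ft)
    cache
  }
})
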