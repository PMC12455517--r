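# Partition amplicon features (ASVs) into host off-targets vs putative
# microbial sequences, then localize the off-targets: per-chromosome
# read-weighted counts and clustering of recurrent 5' mapping positions.

.empty_classified <- function() {
  data.frame(feature_id = character(0L), label = character(0L),
             chrom = character(0L), start = integer(0L),
             strand = character(0L), aligned_len = integer(0L),
             identity = numeric(0L), coverage = numeric(0L),
             read_weight = numeric(0L), stringsAsFactors = FALSE)
}

# Positional k-mer index of a reference: kmer string -> integer positions
# (1-based). Desk-scale references only.
.kmer_index <- function(ref, k) {
  idx <- new.env(parent = emptyenv(), hash = TRUE)
  for (chrom in names(ref)) {
    s <- ref[[chrom]]
    n <- nchar(s)
    if (n < k) next
    starts <- seq_len(n - k + 1L)
    kmers <- substring(s, starts, starts + k - 1L)
    sp <- split(starts, kmers)
    for (km in names(sp)) {
      prev <- idx[[km]]
      entry <- cbind(match(chrom, names(ref)), sp[[km]])
      idx[[km]] <- if (is.null(prev)) entry else rbind(prev, entry)
    }
  }
  idx
}

.ungapped_hit <- function(q, ref, chrom, offset) {
  # offset: implied 1-based reference start of query position 1 (may be < 1)
  s <- ref[[chrom]]
  L <- nchar(s)
  n <- nchar(q)
  r_from <- max(1L, offset)
  r_to <- min(L, offset + n - 1L)
  if (r_to < r_from) return(NULL)
  q_from <- r_from - offset + 1L
  q_to <- r_to - offset + 1L
  qc <- strsplit(substr(q, q_from, q_to), "", fixed = TRUE)[[1L]]
  rc <- strsplit(substr(s, r_from, r_to), "", fixed = TRUE)[[1L]]
  aligned <- length(qc)
  ident <- sum(qc == rc & rc != "N") / aligned
  list(chrom = chrom, start = r_from - 1L, aligned_len = aligned,
       identity = ident, coverage = aligned / n)
}

#' Align one feature sequence against a host reference
#'
#' K-mer seeded, ungapped extension alignment on both strands. Every seed
#' occurrence proposes a diagonal; the query is laid on the reference at
#' that diagonal (clipped at contig ends) and scored by exact identity.
#' The best hit by (identity, aligned_len) is returned, ties broken by
#' reference name, then lowest start, then plus strand. Intended for
#' desk-scale references, not whole-genome alignment.
#'
#' @param seq Feature sequence.
#' @param host_ref Named sequences of the host reference.
#' @param seed_len Exact seed k-mer length (default 16).
#' @param max_mismatch_rate Hits with identity below
#'   `1 - max_mismatch_rate` are discarded (default 0.25).
#' @param index Optional prebuilt k-mer index (internal reuse).
#' @return A one-row data frame (`chrom`, `start` 0-based, `strand`,
#'   `aligned_len`, `identity`, `coverage`) or `NULL` when no seed
#'   matches.
#' @export
align_feature <- function(seq, host_ref, seed_len = 16L,
                          max_mismatch_rate = 0.25, index = NULL) {
  host_ref <- .as_named_seqs(host_ref, what = "host_ref")
  seq <- nuc_sequence(seq, what = "feature")
  n <- nchar(seq)
  if (n < seed_len)
    stop("feature (", n, " nt) shorter than seed_len (", seed_len, ")")
  if (is.null(index)) index <- .kmer_index(host_ref, seed_len)
  chrom_names <- names(host_ref)

  best <- NULL
  for (strand in c("+", "-")) {
    q <- if (strand == "+") seq else reverse_complement(seq)
    seed_starts <- unique(c(seq(1L, n - seed_len + 1L, by = seed_len),
                            n - seed_len + 1L))
    diags <- NULL
    for (qs in seed_starts) {
      hitpos <- index[[substr(q, qs, qs + seed_len - 1L)]]
      if (is.null(hitpos)) next
      diags <- rbind(diags, cbind(hitpos[, 1L], hitpos[, 2L] - qs + 1L))
    }
    if (is.null(diags)) next
    diags <- unique(diags)
    for (i in seq_len(nrow(diags))) {
      chrom <- chrom_names[diags[i, 1L]]
      h <- .ungapped_hit(q, host_ref, chrom, diags[i, 2L])
      if (is.null(h) || h$identity < 1 - max_mismatch_rate) next
      h$strand <- strand
      if (is.null(best) || .hit_better(h, best)) best <- h
    }
  }
  if (is.null(best)) return(NULL)
  data.frame(chrom = best$chrom, start = best$start, strand = best$strand,
             aligned_len = best$aligned_len, identity = best$identity,
             coverage = best$coverage, stringsAsFactors = FALSE)
}

.hit_better <- function(a, b) {
  if (a$identity != b$identity) return(a$identity > b$identity)
  if (a$aligned_len != b$aligned_len) return(a$aligned_len > b$aligned_len)
  if (a$chrom != b$chrom) return(a$chrom < b$chrom)
  if (a$start != b$start) return(a$start < b$start)
  a$strand == "+" && b$strand == "-"
}

#' Partition features into host off-targets and putative microbial reads
#'
#' Each feature is aligned against the host reference; a feature is
#' labelled `host_offtarget` iff its best hit reaches both the identity
#' and query-coverage thresholds, otherwise `non_host`. Read weights are
#' the feature's total counts across samples.
#'
#' @param features Named character vector (or `DNAStringSet`) of feature
#'   sequences; names are feature ids.
#' @param table A [feature_table] (or a counts matrix with feature row
#'   names). Every tabulated feature must have a sequence.
#' @param host_ref Host reference sequences.
#' @param identity_min,coverage_min Classification thresholds
#'   (defaults 0.95 and 0.90).
#' @param seed_len Seed k-mer length for the aligner.
#' @return A data frame with one row per feature: `feature_id`, `label`,
#'   best-hit columns (`NA` for `non_host`), and `read_weight`.
#' @export
classify_features <- function(features, table, host_ref,
                              identity_min = 0.95, coverage_min = 0.90,
                              seed_len = 16L) {
  host_ref <- .as_named_seqs(host_ref, what = "host_ref")
  features <- .as_named_seqs(features, what = "features")
  counts <- if (inherits(table, "feature_table")) table$counts else as.matrix(table)
  missing <- setdiff(rownames(counts), names(features))
  if (length(missing))
    stop("no sequence for tabulated feature(s): ",
         paste(utils::head(missing, 5L), collapse = ", "))
  idx <- .kmer_index(host_ref, seed_len)
  weights <- rowSums(counts)

  rows <- lapply(rownames(counts), function(id) {
    hit <- align_feature(features[[id]], host_ref, seed_len = seed_len,
                         index = idx)
    if (!is.null(hit) && hit$identity >= identity_min &&
        hit$coverage >= coverage_min) {
      cbind(data.frame(feature_id = id, label = "host_offtarget",
                       stringsAsFactors = FALSE),
            hit, read_weight = unname(weights[id]))
    } else {
      data.frame(feature_id = id, label = "non_host",
                 chrom = NA_character_, start = NA_integer_,
                 strand = NA_character_, aligned_len = NA_integer_,
                 identity = NA_real_, coverage = NA_real_,
                 read_weight = unname(weights[id]), stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.cigar_ref_len <- function(cigar) {
  if (cigar == "*") return(NA_integer_)
  ops <- gregexpr("(\\d+)([MIDNSHP=X])", cigar, perl = TRUE)[[1L]]
  if (ops[1L] == -1L) stop("unparseable CIGAR '", cigar, "'")
  lens <- regmatches(cigar, gregexpr("\\d+", cigar))[[1L]]
  kinds <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))[[1L]]
  sum(as.integer(lens)[kinds %in% c("M", "D", "N", "=", "X")])
}

#' Ingest ASV-vs-host alignments from a SAM file
#'
#' Accepts the SAM produced by an external aligner (e.g. Bowtie2) in
#' place of the internal aligner. Mapped primary records become
#' `host_offtarget` (chrom = RNAME, `start` = POS-1, strand from FLAG
#' 0x10, aligned length from the CIGAR reference span); unmapped records
#' become `non_host`. Secondary (0x100) and supplementary (0x800) records
#' are ignored. Records whose QNAME is absent from the table are skipped
#' with a warning.
#'
#' @param path Path to a SAM file.
#' @param table A [feature_table] (or counts matrix) giving read weights.
#' @return A classified-feature data frame as from [classify_features]
#'   (identity/coverage are `NA`: the SAM route does not rescore).
#' @export
ingest_sam <- function(path, table) {
  counts <- if (inherits(table, "feature_table")) table$counts else as.matrix(table)
  weights <- rowSums(counts)
  lines <- readLines(path)
  body_idx <- which(!startsWith(lines, "@"))
  rows <- list()
  skipped <- 0L
  for (i in body_idx) {
    if (!nzchar(lines[i])) next
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 11L)
      stop("malformed SAM record at line ", i, ": expected >= 11 fields, got ",
           length(f))
    flag <- suppressWarnings(as.integer(f[2L]))
    if (is.na(flag)) stop("malformed SAM record at line ", i, ": bad FLAG '", f[2L], "'")
    if (bitwAnd(flag, 256L) > 0L || bitwAnd(flag, 2048L) > 0L) next
    qname <- f[1L]
    if (!qname %in% rownames(counts)) { skipped <- skipped + 1L; next }
    if (bitwAnd(flag, 4L) > 0L) {
      rows[[length(rows) + 1L]] <- data.frame(
        feature_id = qname, label = "non_host", chrom = NA_character_,
        start = NA_integer_, strand = NA_character_, aligned_len = NA_integer_,
        identity = NA_real_, coverage = NA_real_,
        read_weight = unname(weights[qname]), stringsAsFactors = FALSE)
    } else {
      pos <- suppressWarnings(as.integer(f[4L]))
      if (is.na(pos) || pos < 1L)
        stop("malformed SAM record at line ", i, ": bad POS '", f[4L], "'")
      alen <- .cigar_ref_len(f[6L])
      if (is.na(alen)) alen <- nchar(f[10L])
      rows[[length(rows) + 1L]] <- data.frame(
        feature_id = qname, label = "host_offtarget", chrom = f[3L],
        start = pos - 1L,
        strand = if (bitwAnd(flag, 16L) > 0L) "-" else "+",
        aligned_len = alen, identity = NA_real_, coverage = NA_real_,
        read_weight = unname(weights[qname]), stringsAsFactors = FALSE)
    }
  }
  if (skipped > 0L)
    warning(skipped, " SAM record(s) referenced feature ids absent from the table and were skipped")
  if (!length(rows)) return(.empty_classified())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Biological 5' end of a hit, 1-based: leftmost coordinate on '+',
# rightmost on '-'.
.five_prime_pos <- function(classified) {
  ifelse(classified$strand == "-",
         classified$start + classified$aligned_len,
         classified$start + 1L)
}

#' Cluster off-target 5' mapping positions into recurrent loci
#'
#' Off-target reads from one mis-priming locus all start at the same
#' genomic 5' coordinate; clustering the 5' positions per (chromosome,
#' strand) by single linkage with a small gap tolerance exposes those
#' recurrent loci. Clusters are ranked by total read weight.
#'
#' @param classified Output of [classify_features] or [ingest_sam].
#' @param tolerance Maximum gap in bp between neighbouring positions of
#'   one cluster (default 5).
#' @return A data frame with `chrom`, `strand`, `mode_start` (1-based
#'   position carrying the most reads), `total_reads`, `n_features` and a
#'   `member_positions` list column, ordered by decreasing `total_reads`.
#' @export
cluster_positions <- function(classified, tolerance = 5L) {
  host <- classified[classified$label == "host_offtarget", , drop = FALSE]
  if (!nrow(host))
    return(data.frame(chrom = character(0L), strand = character(0L),
                      mode_start = integer(0L), total_reads = numeric(0L),
                      n_features = integer(0L), member_positions = I(list()),
                      stringsAsFactors = FALSE))
  host$pos5 <- .five_prime_pos(host)
  out <- list()
  for (key in unique(paste(host$chrom, host$strand))) {
    grp <- host[paste(host$chrom, host$strand) == key, ]
    grp <- grp[order(grp$pos5), ]
    brk <- cumsum(c(1L, diff(grp$pos5) > tolerance))
    for (b in unique(brk)) {
      cl <- grp[brk == b, ]
      upos <- sort(unique(cl$pos5))
      w <- vapply(upos, function(p) sum(cl$read_weight[cl$pos5 == p]),
                  numeric(1L))
      mode_start <- as.integer(upos[which.max(w)])  # ties: lowest position
      out[[length(out) + 1L]] <- data.frame(
        chrom = cl$chrom[1L], strand = cl$strand[1L],
        mode_start = mode_start,
        total_reads = sum(cl$read_weight),
        n_features = nrow(cl),
        member_positions = I(list(sort(unique(cl$pos5)))),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, out)
  out <- out[order(-out$total_reads, out$chrom, out$mode_start), ]
  rownames(out) <- NULL
  out
}

#' Read-weighted off-target counts per chromosome
#'
#' @param classified Output of [classify_features] or [ingest_sam].
#' @return A data frame (`chrom`, `offtarget_reads`) in decreasing count
#'   order; counts sum to the total read weight of host off-targets.
#' @export
chromosome_report <- function(classified) {
  host <- classified[classified$label == "host_offtarget", , drop = FALSE]
  if (!nrow(host))
    return(data.frame(chrom = character(0L), offtarget_reads = numeric(0L),
                      stringsAsFactors = FALSE))
  agg <- tapply(host$read_weight, host$chrom, sum)
  out <- data.frame(chrom = names(agg), offtarget_reads = as.numeric(agg),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$offtarget_reads, out$chrom), ]
  rownames(out) <- NULL
  out
}
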