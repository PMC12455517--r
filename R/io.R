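# Readers and writers for the standard formats the pipeline touches:
# FASTA, FASTQ, BED6, TSV tables and a flat key = value config file.

#' Read a FASTA file into a named character vector
#'
#' Multi-line and gzip-compressed FASTA are accepted. Sequences are
#' validated against the IUPAC alphabet (offending record and position
#' reported) and returned uppercase. An empty file yields an empty set.
#'
#' @param path FASTA path (optionally .gz).
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- tryCatch(readLines(gzfile(path), n = 1L), error = function(e) character(0L))
  if (!length(first)) return(stats::setNames(character(0L), character(0L)))
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    stop("duplicate record id '", ids[duplicated(ids)][1L], "' in ", path)
  seqs <- as.character(set)
  names(seqs) <- ids
  for (i in seq_along(seqs))
    seqs[[i]] <- nuc_sequence(seqs[[i]], what = paste0("record '", ids[i], "'"))
  seqs
}

#' Write sequences as 80-column wrapped FASTA
#' @param seqs Named character vector (or `DNAStringSet`).
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  if (!inherits(seqs, "XStringSet")) {
    seqs <- Biostrings::BStringSet(unlist(as.list(seqs)))
  }
  Biostrings::writeXStringSet(seqs, filepath = path, width = 80L)
  invisible(path)
}

#' Read a FASTQ file (4-line records, Phred+33)
#'
#' @param path FASTQ path (optionally .gz).
#' @return Data frame with `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(gzfile(path))
  if (!length(lines)) return(data.frame(id = character(0L), seq = character(0L),
                                        qual = character(0L),
                                        stringsAsFactors = FALSE))
  if (length(lines) %% 4L != 0L)
    stop("truncated FASTQ: ", length(lines), " lines is not a multiple of 4 (",
         "record ", length(lines) %/% 4L + 1L, " incomplete)")
  n <- length(lines) %/% 4L
  hdr <- lines[seq(1L, by = 4L, length.out = n)]
  seq <- lines[seq(2L, by = 4L, length.out = n)]
  qual <- lines[seq(4L, by = 4L, length.out = n)]
  bad <- which(!startsWith(hdr, "@"))
  if (length(bad)) stop("FASTQ record ", bad[1L], " does not start with '@'")
  mism <- which(nchar(seq) != nchar(qual))
  if (length(mism))
    stop("FASTQ record ", mism[1L], ": sequence length ", nchar(seq[mism[1L]]),
         " != quality length ", nchar(qual[mism[1L]]))
  data.frame(id = sub("^@", "", sub("\\s.*$", "", hdr)), seq = toupper(seq),
             qual = qual, stringsAsFactors = FALSE)
}

#' Write simulated reads as FASTQ
#' @param reads Data frame with `id`, `seq`, `qual` (as produced by
#'   [simulate_pcr_reads]).
#' @param path Output path.
#' @export
write_fastq <- function(reads, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", reads$id, "\n", reads$seq, "\n+\n", reads$qual), con,
             sep = "\n")
  invisible(path)
}

#' Write priming sites as BED6
#'
#' BED uses 0-based half-open coordinates; name carries the primer,
#' score the mismatch count.
#' @param sites Data frame from [scan_priming_sites].
#' @param path Output path.
#' @export
write_bed6 <- function(sites, path) {
  bed <- data.frame(chrom = sites$chrom, start = sites$start,
                    end = sites$start + sites$primer_len,
                    name = sites$primer_name, score = sites$n_mismatches,
                    strand = sites$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write priming sites as TSV (1-based positions, mismatch offsets)
#' @param sites Data frame from [scan_priming_sites].
#' @param path Output path.
#' @export
write_sites_tsv <- function(sites, path) {
  out <- data.frame(
    chrom = sites$chrom,
    start0 = sites$start,                       # 0-based half-open
    pos1 = sites$start + 1L,                    # 1-based, SAM-style
    strand = sites$strand, primer = sites$primer_name,
    primer_len = sites$primer_len, n_mismatches = sites$n_mismatches,
    mismatch_offsets_3p = vapply(sites$mismatch_offsets, paste,
                                 character(1L), collapse = ","),
    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write/read a feature-by-sample count table as TSV
#'
#' The TSV carries feature ids in the first column (`feature_id`) and
#' one column per sample; taxonomy travels in a separate TSV
#' (`feature_id`, `phylum`, `genus`, `organelle`).
#'
#' @param table A [feature_table].
#' @param path Counts TSV path.
#' @param taxonomy_path Optional taxonomy TSV path.
#' @export
write_feature_table <- function(table, path, taxonomy_path = NULL) {
  df <- data.frame(feature_id = rownames(table$counts), table$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(taxonomy_path) && !is.null(table$taxonomy))
    utils::write.table(table$taxonomy, taxonomy_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @param taxonomy_path Optional taxonomy TSV to attach on read.
#' @return `read_feature_table` returns a [feature_table].
#' @export
read_feature_table <- function(path, taxonomy_path = NULL) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1L] != "feature_id")
    stop("first column of ", path, " must be 'feature_id'")
  counts <- as.matrix(df[, -1L, drop = FALSE])
  rownames(counts) <- df$feature_id
  storage.mode(counts) <- "integer"
  tax <- if (!is.null(taxonomy_path))
    utils::read.delim(taxonomy_path, stringsAsFactors = FALSE) else NULL
  feature_table(counts, tax)
}

#' Flat key = value run configuration files
#'
#' One `key = value` pair per line; `#` starts a comment; values are
#' parsed as numbers where possible. Used to capture every effective
#' simulation/analysis parameter including the seed.
#'
#' @param path File path.
#' @return `read_config` returns a named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    if (length(kv) < 2L) stop("unparseable config line: '", ln, "'")
    key <- trimws(kv[1L])
    val <- trimws(paste(kv[-1L], collapse = "="))
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num
                  else if (val %in% c("TRUE", "FALSE")) as.logical(val)
                  else val
  }
  out
}

#' @rdname read_config
#' @param config Named list of scalar values.
#' @export
write_config <- function(config, path) {
  flat <- unlist(config)
  writeLines(paste(names(flat), "=", as.character(flat)), path)
  invisible(path)
}
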