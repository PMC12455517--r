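# Quantify how retaining vs removing host off-targets changes community
# summaries: genus-level abundance/prevalence filtering, relative
# abundances in both modes, analytic rarefaction saturation, and
# Hellinger-distance principal coordinate analysis.

#' Construct a feature-by-sample count table
#'
#' @param counts Non-negative integer matrix, features in rows, samples
#'   in columns, with unique dimnames.
#' @param taxonomy Optional data frame with columns `feature_id`,
#'   `phylum`, `genus` and logical `organelle`, covering a subset of the
#'   features.
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(counts, taxonomy = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry feature (row) and sample (column) names")
  if (anyDuplicated(rownames(counts))) stop("duplicate feature ids")
  if (anyDuplicated(colnames(counts))) stop("duplicate sample ids")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (!is.null(taxonomy)) {
    need <- c("feature_id", "phylum", "genus")
    if (!all(need %in% names(taxonomy)))
      stop("taxonomy must have columns feature_id, phylum, genus")
    if (is.null(taxonomy$organelle)) taxonomy$organelle <- FALSE
    extra <- setdiff(taxonomy$feature_id, rownames(counts))
    if (length(extra))
      stop("taxonomy references unknown feature(s): ",
           paste(utils::head(extra, 5L), collapse = ", "))
  }
  structure(list(counts = counts, taxonomy = taxonomy),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d features x %d samples (%s taxonomy)\n",
              nrow(x$counts), ncol(x$counts),
              if (is.null(x$taxonomy)) "no" else "with"))
  invisible(x)
}

.genus_of <- function(ids, taxonomy = NULL) {
  genus <- ids  # unlabelled features aggregate as their own singletons
  if (!is.null(taxonomy)) {
    m <- match(ids, taxonomy$feature_id)
    lab <- taxonomy$genus[m]
    has <- !is.na(m) & !is.na(lab) & nzchar(lab)
    genus[has] <- lab[has]
  }
  genus
}

.genus_counts <- function(counts, genus) {
  rowsum(counts, group = genus)
}

#' Filtering parameters
#'
#' Defaults follow the standard contaminant/noise filter for amplicon
#' surveys: a genus is kept only if its highest per-sample relative
#' abundance reaches 0.01% and it occurs in at least 1% of the samples;
#' organelle (mitochondria/chloroplast) reads and reads unassigned at the
#' phylum level are discarded.
#'
#' @param max_abund_cutoff Minimum of the per-genus maximum relative
#'   abundance (fraction; default 1e-4 = 0.01%).
#' @param prevalence_cutoff Minimum fraction of samples the genus occurs
#'   in (default 0.01 = 1%).
#' @param drop_unassigned_phylum,drop_organelles Taxonomy-based removals.
#' @return A list of class `filter_params`.
#' @export
filter_params <- function(max_abund_cutoff = 1e-4, prevalence_cutoff = 0.01,
                          drop_unassigned_phylum = TRUE,
                          drop_organelles = TRUE) {
  stopifnot(max_abund_cutoff > 0, max_abund_cutoff < 1,
            prevalence_cutoff > 0, prevalence_cutoff < 1)
  structure(list(max_abund_cutoff = max_abund_cutoff,
                 prevalence_cutoff = prevalence_cutoff,
                 drop_unassigned_phylum = isTRUE(drop_unassigned_phylum),
                 drop_organelles = isTRUE(drop_organelles)),
            class = "filter_params")
}

#' Abundance/prevalence filtering at the genus level
#'
#' Removals happen in three passes, each logged with its reason:
#' organelle features, features unassigned at the phylum level, then
#' genera failing the maximum-abundance or prevalence rule (all ASVs of a
#' failing genus are removed). The filter log is attached as attribute
#' `"filter_log"` of the returned table. The operation is idempotent.
#'
#' @param table A [feature_table].
#' @param params A [filter_params] object.
#' @return The filtered [feature_table].
#' @export
filter_features <- function(table, params = filter_params()) {
  if (!inherits(table, "feature_table")) stop("table must be a feature_table")
  if ((params$drop_unassigned_phylum || params$drop_organelles) &&
      is.null(table$taxonomy))
    stop("taxonomy-based filtering requested but the table has no taxonomy")
  counts <- table$counts
  log <- data.frame(feature_id = character(0L), reason = character(0L),
                    stringsAsFactors = FALSE)
  drop <- function(ids, reason) {
    if (!length(ids)) return()
    log <<- rbind(log, data.frame(feature_id = ids, reason = reason,
                                  stringsAsFactors = FALSE))
    counts <<- counts[setdiff(rownames(counts), ids), , drop = FALSE]
  }

  tax <- table$taxonomy
  if (params$drop_organelles && !is.null(tax))
    drop(intersect(tax$feature_id[isTRUE_vec(tax$organelle)], rownames(counts)),
         "organelle")
  if (params$drop_unassigned_phylum && !is.null(tax)) {
    unass <- tax$feature_id[is.na(tax$phylum) | !nzchar(trimws(tax$phylum))]
    no_tax <- setdiff(rownames(counts), tax$feature_id)
    drop(intersect(union(unass, no_tax), rownames(counts)), "unassigned_phylum")
  }

  if (nrow(counts)) {
    ids <- rownames(counts)
    genus <- .genus_of(ids, tax)
    g <- .genus_counts(counts, genus)
    totals <- colSums(counts)
    relab <- sweep(g, 2L, pmax(totals, 1), "/")
    max_relab <- apply(relab, 1L, max)
    prevalence <- rowMeans(g > 0)
    fail_ab <- rownames(g)[max_relab < params$max_abund_cutoff]
    fail_prev <- setdiff(rownames(g)[prevalence < params$prevalence_cutoff],
                         fail_ab)
    drop(ids[genus %in% fail_ab], "max_abundance")
    drop(ids[genus %in% fail_prev], "prevalence")
  }
  if (!nrow(counts))
    stop("no features left after filtering")
  out <- feature_table(counts,
                       if (is.null(tax)) NULL
                       else tax[tax$feature_id %in% rownames(counts), ,
                                drop = FALSE])
  attr(out, "filter_log") <- log
  out
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

#' Per-taxon relative abundance with off-targets retained vs removed
#'
#' The two summaries differ only in whether host off-target features
#' enter the per-sample denominators; host features never appear as taxa
#' rows. Removing host reads can only shrink denominators, so
#' removed-mode abundances are always >= retained-mode abundances, with
#' strict increase in samples carrying host reads.
#'
#' @param table A [feature_table].
#' @param host_ids Feature ids classified as host off-targets (subset of
#'   the table's features; may be empty).
#' @return Data frame per microbial taxon: `taxon`, `mean_relab_with`
#'   (off-targets retained), `mean_relab_without` (off-targets removed),
#'   `delta` (without - with); abundances are fractions of sample totals,
#'   averaged over samples.
#' @export
compare_with_without <- function(table, host_ids) {
  if (!inherits(table, "feature_table")) stop("table must be a feature_table")
  counts <- table$counts
  unknown <- setdiff(host_ids, rownames(counts))
  if (length(unknown))
    stop("host_ids not in table: ", paste(utils::head(unknown, 5L), collapse = ", "))
  microbial <- setdiff(rownames(counts), host_ids)
  if (!length(microbial))
    stop("host_ids cover every feature; nothing microbial remains")
  mic <- counts[microbial, , drop = FALSE]
  genus <- .genus_of(rownames(mic), table$taxonomy)
  g <- .genus_counts(mic, genus)

  tot_with <- colSums(counts)           # denominators include host reads
  tot_without <- colSums(mic)           # host reads removed
  if (any(tot_without == 0))
    stop("sample(s) with no microbial reads: ",
         paste(colnames(counts)[tot_without == 0], collapse = ", "))
  relab_with <- sweep(g, 2L, pmax(tot_with, 1), "/")
  relab_without <- sweep(g, 2L, tot_without, "/")
  out <- data.frame(
    taxon = rownames(g),
    mean_relab_with = rowMeans(relab_with),
    mean_relab_without = rowMeans(relab_without),
    stringsAsFactors = FALSE)
  out$delta <- out$mean_relab_without - out$mean_relab_with
  out <- out[order(-out$mean_relab_without), ]
  rownames(out) <- NULL
  out
}

#' Analytic rarefaction curve and saturation call for one sample
#'
#' Expected genus richness at depth n under hypergeometric subsampling,
#' E\[S(n)\] = sum over genera of (1 - choose(N - N_g, n)/choose(N, n)),
#' evaluated at multiples of `step` up to the sample total N. The final
#' slope is the one-step increment (E\[S(N)\] - E\[S(N - step)\]) / step;
#' the sample is saturated when that slope drops below `threshold`
#' (default 1e-4 genera per read).
#'
#' @param sample_counts Named vector of per-genus counts for one sample.
#' @param step Depth step in reads (default 100).
#' @param threshold Saturation threshold in genera per read.
#' @return A `rarefaction_result`: `curve` (data frame of depth,
#'   richness), `final_slope`, `saturated`, `evaluable` (FALSE when the
#'   sample has fewer than `2 * step` reads; such samples are reported,
#'   not dropped).
#' @export
rarefaction_curve <- function(sample_counts, step = 100L, threshold = 1e-4) {
  x <- sample_counts[sample_counts > 0]
  N <- sum(x)
  if (N < 2L * step) {
    return(structure(list(curve = NULL, final_slope = NA_real_,
                          saturated = NA, evaluable = FALSE, total = N,
                          step = step, threshold = threshold),
                     class = "rarefaction_result"))
  }
  depths <- sort(unique(c(seq(step, N, by = step), N - step, N)))
  # vegan warns when the smallest genus count exceeds 1; spurious for
  # aggregated genus tables
  richness <- as.numeric(withCallingHandlers(
    vegan::rarefy(matrix(x, nrow = 1L), sample = depths),
    warning = function(w) {
      if (grepl("smallest count", conditionMessage(w)))
        invokeRestart("muffleWarning")
    }))
  final_slope <- (richness[length(depths)] -
                    richness[match(N - step, depths)]) / step
  structure(list(curve = data.frame(depth = depths, richness = richness),
                 final_slope = final_slope,
                 saturated = final_slope < threshold,
                 evaluable = TRUE, total = N, step = step,
                 threshold = threshold),
            class = "rarefaction_result")
}

#' @export
print.rarefaction_result <- function(x, ...) {
  if (!x$evaluable) {
    cat(sprintf("<rarefaction> unevaluable: %d reads < 2 * step (%d)\n",
                x$total, x$step))
  } else {
    cat(sprintf("<rarefaction> %d reads, final slope %.3g genera/read -> %s\n",
                x$total, x$final_slope,
                if (x$saturated) "saturated" else "NOT saturated"))
  }
  invisible(x)
}

#' Hellinger-distance principal coordinate analysis
#'
#' Hellinger transform (square root of per-sample relative abundances),
#' pairwise Euclidean distances, then classical metric scaling (Gower
#' double-centering and eigendecomposition). Hellinger distances are
#' Euclidean-embeddable, so meaningfully negative eigenvalues should not
#' arise; their appearance triggers a warning and those axes are excluded
#' from the coordinates.
#'
#' @param table A [feature_table] (or counts matrix), typically
#'   genus-aggregated.
#' @param k Number of ordination axes to return (default 2).
#' @return An `ordination_result`: `distances` (samples x samples
#'   matrix), `coordinates` (samples x k), `eigenvalues` (descending),
#'   `prop_explained` (relative to the sum of positive eigenvalues).
#' @export
hellinger_pcoa <- function(table, k = 2L) {
  counts <- if (inherits(table, "feature_table")) table$counts else as.matrix(table)
  if (ncol(counts) < 2L) stop("need at least 2 samples")
  zero <- colnames(counts)[colSums(counts) == 0]
  if (length(zero))
    stop("sample(s) with zero total counts: ", paste(zero, collapse = ", "))
  H <- vegan::decostand(t(counts), method = "hellinger")
  d <- stats::dist(H)
  k_eff <- min(k, ncol(counts) - 1L)
  fit <- stats::cmdscale(d, k = k_eff, eig = TRUE)
  eig <- sort(fit$eig, decreasing = TRUE)
  tol <- max(abs(eig)) * 1e-8
  if (any(eig < -tol))
    warning("negative PCoA eigenvalue(s) beyond numerical tolerance; ",
            "excluded from the coordinates")
  pos <- eig[eig > tol]
  coords <- fit$points
  colnames(coords) <- paste0("PCo", seq_len(ncol(coords)))
  structure(list(distances = as.matrix(d), coordinates = coords,
                 eigenvalues = eig,
                 prop_explained = pos / sum(pos),
                 k = ncol(coords)),
            class = "ordination_result")
}

#' @export
print.ordination_result <- function(x, ...) {
  cat(sprintf("<hellinger_pcoa> %d samples, %d axes (%.1f%%, %.1f%% explained)\n",
              nrow(x$coordinates), x$k,
              100 * x$prop_explained[1L],
              if (length(x$prop_explained) > 1L) 100 * x$prop_explained[2L] else 0))
  invisible(x)
}

#' Mean Hellinger distance of samples to their centroid
#'
#' A scalar dispersion summary used to compare community scatter with
#' and without host off-targets retained.
#'
#' @param table A [feature_table] or counts matrix.
#' @return Mean Euclidean distance of Hellinger-transformed samples to
#'   their centroid.
#' @export
hellinger_dispersion <- function(table) {
  counts <- if (inherits(table, "feature_table")) table$counts else as.matrix(table)
  H <- as.matrix(vegan::decostand(t(counts), method = "hellinger"))
  centroid <- colMeans(H)
  mean(sqrt(rowSums(sweep(H, 2L, centroid)^2)))
}
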