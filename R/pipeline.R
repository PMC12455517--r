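# End-to-end driver: scan -> predict -> classify -> cluster -> consensus
# -> design-inhibitor -> bias, over either real inputs (genome FASTA,
# feature FASTA + count TSV, optional SAM) or the synthetic generator.

#' Pipeline run configuration
#'
#' Bundles the per-stage parameters (each defaulting to its module's
#' defaults) with input paths. When `genome_path` is `NULL` the
#' synthetic generator supplies all inputs: `n_samples` simulated
#' samples whose host template pools vary log-normally
#' (`host_copy_log_sd`) around the configured copy number, so the host
#' off-target burden differs between samples as it does between real
#' biopsies.
#'
#' @param seed Master seed; every stage derives its draws from it.
#' @param genome_path,features_path,table_path,taxonomy_path,sam_path
#'   Real-mode input paths (all `NULL` for synthetic mode).
#' @param n_samples,host_copy_log_sd Synthetic-mode sample layout.
#' @param sim A [sim_config] (synthetic mode).
#' @param scan A [scan_params].
#' @param filter A [filter_params].
#' @param design A [design_params].
#' @param identity_min,coverage_min Host-classification thresholds.
#' @param min_len,max_len Amplicon window in bp.
#' @param cluster_tolerance Position-cluster gap in bp.
#' @param consensus_window_5p,consensus_window_3p Consensus block widths.
#' @param include_freq,drop_freq,min_coverage Consensus-calling
#'   thresholds.
#' @param rarefaction_step,slope_threshold Saturation rule.
#' @param max_consensus_reads Cap on reads entering the consensus block.
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 1L,
                       genome_path = NULL, features_path = NULL,
                       table_path = NULL, taxonomy_path = NULL,
                       sam_path = NULL,
                       n_samples = 4L, host_copy_log_sd = 0.8,
                       sim = sim_config(seed = seed, depth = 20000L),
                       scan = scan_params(),
                       filter = filter_params(),
                       design = design_params(),
                       identity_min = 0.95, coverage_min = 0.90,
                       min_len = 100L, max_len = 600L,
                       cluster_tolerance = 5L,
                       consensus_window_5p = 32L, consensus_window_3p = 29L,
                       include_freq = 0.25, drop_freq = 0.10,
                       min_coverage = 0.50,
                       rarefaction_step = 100L, slope_threshold = 1e-4,
                       max_consensus_reads = 2000L) {
  cfg <- list(seed = as.integer(seed), genome_path = genome_path,
              features_path = features_path, table_path = table_path,
              taxonomy_path = taxonomy_path, sam_path = sam_path,
              n_samples = as.integer(n_samples),
              host_copy_log_sd = host_copy_log_sd,
              sim = sim, scan = scan, filter = filter, design = design,
              identity_min = identity_min, coverage_min = coverage_min,
              min_len = min_len, max_len = max_len,
              cluster_tolerance = cluster_tolerance,
              consensus_window_5p = as.integer(consensus_window_5p),
              consensus_window_3p = as.integer(consensus_window_3p),
              include_freq = include_freq, drop_freq = drop_freq,
              min_coverage = min_coverage,
              rarefaction_step = as.integer(rarefaction_step),
              slope_threshold = slope_threshold,
              max_consensus_reads = as.integer(max_consensus_reads))
  for (p in c("genome_path", "features_path", "table_path", "taxonomy_path",
              "sam_path")) {
    if (!is.null(cfg[[p]]) && !file.exists(cfg[[p]]))
      stop("configured ", p, " does not exist: ", cfg[[p]])
  }
  structure(cfg, class = "run_config")
}

.log_stage <- function(stage, ...) {
  message(format(Sys.time(), "%H:%M:%S"), " [", stage, "] ", ...)
}

.run_stage <- function(stage, out_dir, expr) {
  tryCatch(expr, error = function(e) {
    if (!is.null(out_dir))
      writeLines(paste0("stage '", stage, "' failed: ", conditionMessage(e)),
                 file.path(out_dir, "FAILED"))
    stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full off-target forensics pipeline
#'
#' Executes scan, amplicon prediction, host/microbial classification,
#' position clustering, 5' consensus recovery, blocking-oligo design and
#' community-bias assessment, writing every stage output plus a JSON run
#' manifest (seed, effective parameters, per-stage record counts) to
#' `out_dir`.
#'
#' @param config A [run_config].
#' @param out_dir Output directory (created); `NULL` skips file output.
#' @return (Invisibly) a list with every stage result and the manifest.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  if (!inherits(config, "run_config")) stop("config must be a run_config")
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  emit <- function(fn, ...) if (!is.null(out_dir)) fn(...)
  counts_log <- list()
  synthetic <- is.null(config$genome_path)

  # --- inputs -------------------------------------------------------
  inputs <- .run_stage("input", out_dir, {
    if (synthetic) {
      .log_stage("input", "synthetic mode: generating genome, community, reads")
      host <- make_host_genome(config$sim, scan = config$scan)
      community <- make_16s_community(config$sim)
      kitome <- make_16s_community(config$sim, n_taxa = config$sim$n_kitome,
                                   prefix = "Kitome",
                                   copies_total = config$sim$kitome_template_copies,
                                   seed = config$sim$seed + 7L)
      scales <- .with_seed(config$seed + 99L,
                           exp(stats::rnorm(config$n_samples, 0,
                                            config$host_copy_log_sd)))
      sims <- lapply(seq_len(config$n_samples), function(s) {
        cfg_s <- config$sim
        cfg_s$host_template_copies <- cfg_s$host_template_copies * scales[s]
        simulate_pcr_reads(host, community, kitome, cfg_s,
                           seed = config$seed + 1000L + s)
      })
      names(sims) <- paste0("sample", seq_len(config$n_samples))
      ft <- make_feature_tables(sims)
      emit(write_fasta, host$genome, file.path(out_dir, "genome.fa"))
      emit(write_fastq, do.call(rbind, lapply(sims, `[[`, "reads")),
           file.path(out_dir, "reads.fastq"))
      list(genome = host$genome, host = host, sims = sims,
           features = ft$features, table = ft$table, host_truth = ft$host_ids,
           microbial_refs = community$templates)
    } else {
      .log_stage("input", "reading ", config$genome_path)
      genome <- read_fasta(config$genome_path)
      features <- if (!is.null(config$features_path))
        read_fasta(config$features_path) else NULL
      table <- if (!is.null(config$table_path))
        read_feature_table(config$table_path, config$taxonomy_path) else NULL
      list(genome = genome, host = NULL, sims = NULL, features = features,
           table = table, host_truth = NULL, microbial_refs = NULL)
    }
  })

  # --- scan ---------------------------------------------------------
  fwd <- primer_341F(); rev <- primer_805R()
  sites <- .run_stage("scan", out_dir, {
    s <- rbind(scan_priming_sites(inputs$genome, fwd, config$scan),
               scan_priming_sites(inputs$genome, rev, config$scan))
    .log_stage("scan", nrow(s), " priming site(s)")
    emit(write_bed6, s, file.path(out_dir, "priming_sites.bed"))
    emit(write_sites_tsv, s, file.path(out_dir, "priming_sites.tsv"))
    s
  })
  counts_log$priming_sites <- nrow(sites)

  # --- predict ------------------------------------------------------
  amplicons <- .run_stage("predict", out_dir, {
    a <- predict_amplicons(sites[sites$primer_name == fwd$name, ],
                           sites[sites$primer_name == rev$name, ],
                           min_len = config$min_len, max_len = config$max_len,
                           genome = inputs$genome)
    .log_stage("predict", nrow(a), " predicted amplicon(s)")
    if (!is.null(out_dir)) {
      utils::write.table(a[, setdiff(names(a), "insert_seq")],
                         file.path(out_dir, "amplicons.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      if (nrow(a))
        write_fasta(stats::setNames(a$insert_seq,
                                    sprintf("amplicon_%s_%d", a$chrom,
                                            a$product_start + 1L)),
                    file.path(out_dir, "amplicon_inserts.fa"))
    }
    a
  })
  counts_log$predicted_amplicons <- nrow(amplicons)

  # --- classify -----------------------------------------------------
  classified <- .run_stage("classify", out_dir, {
    cl <- if (!is.null(config$sam_path)) {
      ingest_sam(config$sam_path, inputs$table)
    } else {
      classify_features(inputs$features, inputs$table, inputs$genome,
                        identity_min = config$identity_min,
                        coverage_min = config$coverage_min)
    }
    .log_stage("classify", sum(cl$label == "host_offtarget"), " host / ",
               sum(cl$label == "non_host"), " non-host feature(s)")
    emit(function(x, p) utils::write.table(x, p, sep = "\t", quote = FALSE,
                                           row.names = FALSE),
         cl, file.path(out_dir, "classified_features.tsv"))
    cl
  })
  counts_log$host_offtargets <- sum(classified$label == "host_offtarget")

  # --- cluster ------------------------------------------------------
  clusters <- .run_stage("cluster", out_dir, {
    cp <- cluster_positions(classified, tolerance = config$cluster_tolerance)
    cr <- chromosome_report(classified)
    .log_stage("cluster", nrow(cp), " position cluster(s) on ",
               nrow(cr), " chromosome(s)")
    if (!is.null(out_dir)) {
      cp_out <- cp
      cp_out$member_positions <- vapply(cp$member_positions, paste,
                                        character(1L), collapse = ",")
      utils::write.table(cp_out, file.path(out_dir, "position_clusters.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(cr, file.path(out_dir, "chromosome_report.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    list(positions = cp, chromosomes = cr)
  })

  # --- consensus ----------------------------------------------------
  consensus <- .run_stage("consensus", out_dir, {
    host_ids <- classified$feature_id[classified$label == "host_offtarget"]
    if (!length(host_ids)) {
      .log_stage("consensus", "no host off-targets; skipping motif recovery")
      NULL
    } else {
      seqs <- if (!is.null(inputs$sims)) {
        # primer-trimmed off-target reads (errors retained)
        rd <- do.call(rbind, lapply(inputs$sims, `[[`, "reads"))
        rd <- rd$seq[rd$class == "host"]
        if (length(rd) > config$max_consensus_reads) {
          # evenly spaced subsample so every locus keeps its share
          # (reads arrive grouped by template)
          keep <- unique(round(seq(1L, length(rd),
                                   length.out = config$max_consensus_reads)))
          rd <- rd[keep]
        }
        substr(rd, nchar(.FWD_LANDING$seq) + 1L,
               nchar(rd) - nchar(.REV_LANDING$seq))
      } else {
        inputs$features[host_ids]
      }
      block <- anchor_align(seqs, "five_prime", config$consensus_window_5p)
      motif <- call_iupac_consensus(build_pfm(block),
                                    include_freq = config$include_freq,
                                    drop_freq = config$drop_freq,
                                    min_coverage = config$min_coverage)
      .log_stage("consensus", "reduced 5' consensus: ", motif$iupac_reduced)
      if (!is.null(out_dir)) {
        write_fasta(c(consensus_full = motif$iupac_full,
                      consensus_reduced = motif$iupac_reduced),
                    file.path(out_dir, "consensus.fa"))
        utils::write.table(motif_logo_data(motif),
                           file.path(out_dir, "consensus_logo.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
      motif
    }
  })

  # --- design-inhibitor ---------------------------------------------
  design <- .run_stage("design-inhibitor", out_dir, {
    if (is.null(consensus)) NULL else {
      d <- design_inhibitor(consensus, primers = list(fwd, rev),
                            params = config$design,
                            microbial_refs = inputs$microbial_refs)
      .log_stage("design-inhibitor", d$oligo$seq, " (",
                 if (d$accepted) "accepted" else "not accepted", ")")
      if (!is.null(out_dir)) {
        write_fasta(stats::setNames(
          d$oligo$seq, paste0(d$oligo$name, " /3SpC3/ Tm=",
                              sprintf("%.2f", d$tm))),
          file.path(out_dir, "inhibitor.fa"))
        utils::write.table(
          data.frame(length = d$length, tm = d$tm,
                     tm_primer_mean = d$tm_primer_mean, delta_tm = d$delta_tm,
                     hairpin = d$hairpin$has_hairpin,
                     cross_hits = nrow(d$cross_hits), accepted = d$accepted),
          file.path(out_dir, "inhibitor_design.tsv"), sep = "\t",
          quote = FALSE, row.names = FALSE)
      }
      d
    }
  })

  # --- bias ---------------------------------------------------------
  bias <- .run_stage("bias", out_dir, {
    if (is.null(inputs$table)) {
      .log_stage("bias", "no feature table; skipping")
      NULL
    } else {
      host_ids <- classified$feature_id[classified$label == "host_offtarget"]
      comparison <- compare_with_without(inputs$table, host_ids)
      counts <- inputs$table$counts
      genus <- .genus_of(rownames(counts), inputs$table$taxonomy)
      gcounts <- .genus_counts(counts, genus)
      rare <- lapply(colnames(gcounts), function(s)
        rarefaction_curve(gcounts[, s], step = config$rarefaction_step,
                          threshold = config$slope_threshold))
      names(rare) <- colnames(gcounts)
      mic <- counts[setdiff(rownames(counts), host_ids), , drop = FALSE]
      ord <- NULL
      disp <- NULL
      if (ncol(counts) >= 2L) {
        g_with <- gcounts
        g_without <- .genus_counts(mic, .genus_of(rownames(mic),
                                                  inputs$table$taxonomy))
        ord <- list(with_offtargets = hellinger_pcoa(g_with),
                    without_offtargets = hellinger_pcoa(g_without))
        disp <- c(with_offtargets = hellinger_dispersion(g_with),
                  without_offtargets = hellinger_dispersion(g_without))
      }
      tax_mic <- inputs$table$taxonomy
      if (!is.null(tax_mic))
        tax_mic <- tax_mic[tax_mic$feature_id %in% rownames(mic), , drop = FALSE]
      filtered <- tryCatch(
        filter_features(feature_table(mic, tax_mic), config$filter),
        error = function(e) NULL)
      .log_stage("bias", sum(vapply(rare, function(r) isTRUE(r$saturated),
                                    logical(1L))),
                 "/", length(rare), " sample(s) saturated")
      if (!is.null(out_dir)) {
        utils::write.table(comparison, file.path(out_dir, "bias_comparison.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        if (!is.null(ord))
          utils::write.table(
            data.frame(sample = rownames(ord$without_offtargets$coordinates),
                       ord$without_offtargets$coordinates),
            file.path(out_dir, "pcoa_coordinates.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
        if (!is.null(filtered)) {
          write_feature_table(filtered,
                              file.path(out_dir, "filtered_counts.tsv"),
                              file.path(out_dir, "filtered_taxonomy.tsv"))
          utils::write.table(attr(filtered, "filter_log"),
                             file.path(out_dir, "filter_log.tsv"), sep = "\t",
                             quote = FALSE, row.names = FALSE)
        }
      }
      list(comparison = comparison, rarefaction = rare, ordination = ord,
           dispersion = disp, filtered = filtered)
    }
  })

  manifest <- list(
    package = "amplihijack",
    version = as.character(utils::packageVersion("amplihijack")),
    r_version = as.character(getRversion()),
    seed = config$seed,
    mode = if (synthetic) "synthetic" else "real",
    parameters = .flatten_config(config),
    stage_counts = c(counts_log,
                     position_clusters = nrow(clusters$positions),
                     consensus_reduced = if (is.null(consensus)) NA_character_
                                         else consensus$iupac_reduced,
                     inhibitor_accepted = if (is.null(design)) NA
                                          else design$accepted))
  if (!is.null(out_dir))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         force = TRUE)

  invisible(list(inputs = inputs, sites = sites, amplicons = amplicons,
                 classified = classified, clusters = clusters,
                 consensus = consensus, design = design, bias = bias,
                 manifest = manifest))
}

.flatten_config <- function(config) {
  keep <- config[!vapply(config, is.null, logical(1L))]
  lapply(keep, function(x) {
    if (inherits(x, c("scan_params", "filter_params", "design_params",
                      "sim_config"))) {
      unclass(x[!vapply(x, is.null, logical(1L))])
    } else x
  })
}
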