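# Synthetic-data generator with known truth: host genomes carrying
# planted mis-priming loci, mock 16S communities, kitome contaminant
# templates, and PCR-simulated reads with mismatch-dependent efficiency
# and optional inhibitor suppression. Every random draw is reproducible
# from the configured seed.

# The recurrent off-target motifs: the shared 5'-end consensus (reduced
# form, 32 nt, one degenerate S column) and the three chromosome-specific
# 3'-end consensi (29 nt each).
.OFFTARGET_5P_CONSENSUS <- "TGATAAACCTTTAGCAATAAACSAAAGTTTAA"
.OFFTARGET_3P_CONSENSI <- c(
  chr5  = "CAGTTTGGGTCTTAGCTATTGTGTGTTCA",
  chr11 = "CAGTTTGGGTCTTAGTTATTCTGTGTTCA",
  chr17 = "CAGTTTGAATCTTCGCTATTGTGTATTCA"
)

.with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.mutate_seq <- function(seq, n_sub) {
  if (n_sub == 0L) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  pos <- sample.int(length(chars), n_sub)
  for (p in pos) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
  }
  paste(chars, collapse = "")
}

#' Simulation configuration
#'
#' The defaults define the standard study conditions: a three-chromosome
#' host genome (50 kb each) carrying one mis-priming locus per
#' chromosome (chr5/chr11/chr17 analogues, printed 3'-consensus
#' variants, product 248 bp spanning both primer landings), a 20-taxon
#' mock community, 3 kitome taxa at trace copy number, 25 PCR cycles
#' with base efficiency 0.95 and per-mismatch efficiency multiplier 0.6,
#' 0.5% substitution sequencing error, 50,000 reads. The host pool is
#' 2e8 template copies against 1e3 microbial pool copies -- the extreme
#' host:bacteria template ratio of a tissue biopsy. A 35-cycle,
#' contaminant-enhancing PCR is obtained with `cycles = 35`.
#'
#' @param seed Integer seed driving every random draw.
#' @param n_chrom,chrom_len Host genome shape.
#' @param loci Optional list of planted-locus specs (see
#'   [default_planted_loci]); `NULL` uses the defaults (first
#'   `n_chrom` loci).
#' @param n_taxa,dirichlet_alpha Mock community size and Dirichlet
#'   concentration for its abundances.
#' @param n_kitome Number of kitome taxa.
#' @param host_template_copies,microbial_template_copies,kitome_template_copies
#'   Template pool sizes (relative copy numbers).
#' @param cycles PCR cycles (25 standard, 35 for the second-PCR preset).
#' @param base_efficiency Per-cycle amplification efficiency of a
#'   perfectly primed template (e0, in \[0,1\]).
#' @param mismatch_penalty Per-mismatch efficiency multiplier (rho).
#' @param inhibitor_binding Probability that a bound blocking oligo
#'   suppresses a template's amplification in a cycle (0 = no inhibitor).
#' @param error_rate Per-base substitution error applied to reads.
#' @param depth Total reads drawn per sample.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_chrom = 3L, chrom_len = 50000L,
                       loci = NULL,
                       n_taxa = 20L, dirichlet_alpha = 1,
                       n_kitome = 3L,
                       host_template_copies = 2e8,
                       microbial_template_copies = 1e3,
                       kitome_template_copies = 1,
                       cycles = 25L, base_efficiency = 0.95,
                       mismatch_penalty = 0.6,
                       inhibitor_binding = 0,
                       error_rate = 0.005, depth = 50000L) {
  stopifnot(cycles >= 1L, depth >= 1L, n_taxa >= 1L,
            base_efficiency >= 0, base_efficiency <= 1,
            mismatch_penalty >= 0, mismatch_penalty <= 1,
            inhibitor_binding >= 0, inhibitor_binding <= 1,
            error_rate >= 0, error_rate < 1)
  if (is.null(loci)) loci <- default_planted_loci(n_chrom)
  structure(list(seed = as.integer(seed), n_chrom = as.integer(n_chrom),
                 chrom_len = as.integer(chrom_len), loci = loci,
                 n_taxa = as.integer(n_taxa),
                 dirichlet_alpha = dirichlet_alpha,
                 n_kitome = as.integer(n_kitome),
                 host_template_copies = host_template_copies,
                 microbial_template_copies = microbial_template_copies,
                 kitome_template_copies = kitome_template_copies,
                 cycles = as.integer(cycles),
                 base_efficiency = base_efficiency,
                 mismatch_penalty = mismatch_penalty,
                 inhibitor_binding = inhibitor_binding,
                 error_rate = error_rate, depth = as.integer(depth)),
            class = "sim_config")
}

#' Default planted mis-priming loci
#'
#' Three convergent loci mirroring the recurrent human off-target
#' geometry: a 341F-like landing with two mismatches outside the 3'
#' anchor (3'-relative offsets 13 and 15), the shared 32-nt 5' consensus
#' immediately downstream, a 149-bp spacer, the chromosome-specific
#' 29-nt 3' consensus (reverse-complemented on the forward strand), and
#' an 805R-like landing with two non-anchor mismatches (offsets 8 and
#' 12) -- a 248-bp product spanning both landings. The chr5 and chr11
#' analogues are planted in reverse orientation, chr17 forward, matching
#' the strands on which the 5' consensus recurs.
#'
#' @param n Number of loci (up to 3).
#' @return List of locus specifications.
#' @export
default_planted_loci <- function(n = 3L) {
  specs <- list(
    list(chrom = "chr5",  orientation = "-", s_base = "C",
         three_prime_motif = .OFFTARGET_3P_CONSENSI[["chr5"]],  spacer_len = 149L),
    list(chrom = "chr11", orientation = "-", s_base = "G",
         three_prime_motif = .OFFTARGET_3P_CONSENSI[["chr11"]], spacer_len = 149L),
    list(chrom = "chr17", orientation = "+", s_base = "C",
         three_prime_motif = .OFFTARGET_3P_CONSENSI[["chr17"]], spacer_len = 149L)
  )
  if (n > length(specs)) stop("at most ", length(specs), " default loci available")
  specs[seq_len(n)]
}

# Concrete primer-like landings planted at every locus. Mismatch
# positions are fixed design constants: they must stay outside the
# scanner's default 5-base 3' anchor.
.FWD_LANDING <- list(primer = "341F",
                     seq = "CATCCGGGAGGCAGCAG",   # 341F expansion, mm at 5' pos 2 and 4
                     offsets = c(13L, 15L))
.REV_LANDING <- list(primer = "805R",
                     seq = "GACTACCAAGGTGTCTAATCC", # 805R expansion, mm at pos 9 and 13
                     offsets = c(8L, 12L))

.locus_cassette <- function(spec, spacer) {
  motif <- sub("S", spec$s_base, .OFFTARGET_5P_CONSENSUS, fixed = TRUE)
  insert <- paste0(motif, spacer, reverse_complement(spec$three_prime_motif))
  cassette <- paste0(.FWD_LANDING$seq, insert,
                     reverse_complement(.REV_LANDING$seq))
  list(cassette = cassette, insert = insert, motif = motif)
}

.locus_truth_sites <- function(spec, start0, product_len) {
  fwd_len <- nchar(.FWD_LANDING$seq)
  rev_len <- nchar(.REV_LANDING$seq)
  if (spec$orientation == "+") {
    data.frame(
      chrom = spec$chrom,
      start = c(start0, start0 + product_len - rev_len),
      strand = c("+", "-"),
      primer_name = c(.FWD_LANDING$primer, .REV_LANDING$primer),
      primer_len = c(fwd_len, rev_len),
      n_mismatches = c(length(.FWD_LANDING$offsets), length(.REV_LANDING$offsets)),
      mismatch_offsets = I(list(.FWD_LANDING$offsets, .REV_LANDING$offsets)),
      anchor_intact = TRUE, stringsAsFactors = FALSE)
  } else {
    data.frame(
      chrom = spec$chrom,
      start = c(start0 + product_len - fwd_len, start0),
      strand = c("-", "+"),
      primer_name = c(.FWD_LANDING$primer, .REV_LANDING$primer),
      primer_len = c(fwd_len, rev_len),
      n_mismatches = c(length(.FWD_LANDING$offsets), length(.REV_LANDING$offsets)),
      mismatch_offsets = I(list(.FWD_LANDING$offsets, .REV_LANDING$offsets)),
      anchor_intact = TRUE, stringsAsFactors = FALSE)
  }
}

.patch_base_against <- function(code) {
  banned <- union(.IUPAC_EXPANSION[[code]],
                  .IUPAC_EXPANSION[[chartr(.COMP_FROM, .COMP_TO, code)]])
  choice <- setdiff(c("A", "C", "G", "T"), banned)
  if (!length(choice)) stop("cannot patch against code ", code)
  choice[1L]
}

.site_key <- function(df) {
  if (!NROW(df)) return(character(0L))
  paste(df$chrom, df$start, df$strand, df$primer_name, sep = ":")
}

#' Generate a host genome with planted mis-priming loci
#'
#' Builds a seeded uniform-random background and plants the configured
#' convergent loci. The background is screened with the mis-priming
#' scanner itself: any accidental anchor-perfect landing of 341F, 805R
#' or the blocking oligo outside the planted loci is ablated by a
#' single-base anchor patch (spacers spawning accidental sites are
#' redrawn), so the emitted truth is exhaustive.
#'
#' @param config A [sim_config].
#' @param scan A [scan_params] used for the screening scan (defaults).
#' @param max_attempts Screening iteration limit.
#' @return A list: `genome` (named sequences), `loci` (data frame with
#'   coordinates, orientation, product and primer-trimmed insert
#'   sequences), `sites` (truth priming sites as from
#'   [scan_priming_sites]), `config`.
#' @export
make_host_genome <- function(config = sim_config(), scan = scan_params(),
                             max_attempts = 100L) {
  specs <- config$loci
  if (length(specs) > config$n_chrom)
    stop("more loci than chromosomes")
  .with_seed(config$seed, {
    chrom_names <- vapply(seq_len(config$n_chrom), function(i) {
      if (i <= length(specs)) specs[[i]]$chrom else paste0("chr_bg", i)
    }, character(1L))
    background <- vapply(chrom_names, function(ch) .random_dna(config$chrom_len),
                         character(1L))
    positions <- integer(length(specs))
    spacers <- character(length(specs))
    for (i in seq_along(specs)) {
      margin <- min(5000L, config$chrom_len %/% 10L)
      room <- config$chrom_len - 2L * margin - 300L
      if (room < 1L) stop("chromosomes too short to hold a locus")
      positions[i] <- margin + sample.int(room, 1L)
      spacers[i] <- .random_dna(specs[[i]]$spacer_len)
    }

    fwd_primer <- primer_341F()
    rev_primer <- primer_805R()
    inhib <- default_inhibitor()
    blocker_params <- scan_params(anchor_len = 5L, max_mismatches = 3L)
    attr(blocker_params, "as_blocker") <- TRUE

    build <- function() {
      genome <- background
      loci <- list()
      sites <- list()
      for (i in seq_along(specs)) {
        spec <- specs[[i]]
        cass <- .locus_cassette(spec, spacers[i])
        product_len <- nchar(cass$cassette)
        planted <- if (spec$orientation == "+") cass$cassette
                   else reverse_complement(cass$cassette)
        start0 <- positions[i] - 1L
        s <- genome[[spec$chrom]]
        substr(s, start0 + 1L, start0 + product_len) <- planted
        genome[[spec$chrom]] <- s
        loci[[i]] <- data.frame(
          locus_id = paste0("locus_", spec$chrom),
          chrom = spec$chrom, start = start0, end = start0 + product_len,
          orientation = spec$orientation, s_base = spec$s_base,
          product_len = product_len,
          n_mismatches = length(.FWD_LANDING$offsets) + length(.REV_LANDING$offsets),
          product_seq = if (spec$orientation == "+") cass$cassette
                        else cass$cassette,  # product read off the amplifying strand
          insert_seq = cass$insert,
          stringsAsFactors = FALSE)
        sites[[i]] <- .locus_truth_sites(spec, start0, product_len)
      }
      list(genome = genome, loci = do.call(rbind, loci),
           sites = do.call(rbind, sites))
    }

    g <- build()
    expected <- .site_key(g$sites)
    in_locus <- function(chrom, pos0) {
      any(g$loci$chrom == chrom & pos0 >= g$loci$start & pos0 < g$loci$end)
    }

    for (attempt in seq_len(max_attempts)) {
      found <- rbind(scan_priming_sites(g$genome, fwd_primer, scan),
                     scan_priming_sites(g$genome, rev_primer, scan))
      extra <- found[!.site_key(found) %in% expected, , drop = FALSE]
      binding <- scan_priming_sites(g$genome, inhib, blocker_params)
      if (NROW(binding)) {
        inside <- mapply(in_locus, binding$chrom, binding$start) &
          mapply(in_locus, binding$chrom,
                 binding$start + binding$primer_len - 1L)
        extra_b <- binding[!inside, , drop = FALSE]
      } else extra_b <- binding
      missing <- setdiff(expected, .site_key(found))
      if (length(missing))
        stop("internal error: planted site not recovered (", missing[1L], ")")
      if (!NROW(extra) && !NROW(extra_b)) {
        return(list(genome = g$genome, loci = g$loci, sites = g$sites,
                    config = config))
      }
      redraw <- FALSE
      for (df in list(extra, extra_b)) {
        if (!NROW(df)) next
        for (r in seq_len(nrow(df))) {
          pseq <- switch(df$primer_name[r],
                         "341F" = fwd_primer$seq, "805R" = rev_primer$seq,
                         inhib$seq)
          anchor0 <- if (df$strand[r] == "+")
            df$start[r] + nchar(pseq) - 1L else df$start[r]
          if (in_locus(df$chrom[r], anchor0)) {
            # accidental site inside a planted locus: redraw that spacer
            hitl <- which(g$loci$chrom == df$chrom[r] &
                          anchor0 >= g$loci$start & anchor0 < g$loci$end)
            spacers[hitl[1L]] <- .random_dna(specs[[hitl[1L]]]$spacer_len)
            redraw <- TRUE
          } else {
            term <- substr(pseq, nchar(pseq), nchar(pseq))
            s <- g$genome[[df$chrom[r]]]
            substr(s, anchor0 + 1L, anchor0 + 1L) <- .patch_base_against(term)
            g$genome[[df$chrom[r]]] <- s
            background[[df$chrom[r]]] <- g$genome[[df$chrom[r]]]
          }
        }
      }
      if (redraw) g <- build()
    }
    stop("could not screen a clean background in ", max_attempts, " attempts")
  })
}

#' Generate a mock 16S-like template set
#'
#' Each template is a concrete 341F expansion, a random insert (420-435
#' bp, giving the typical V3-V4 product of about 460 bp) and the reverse
#' complement of an 805R expansion; abundances are Dirichlet-distributed.
#' Templates are screened at generation time to exclude the off-target
#' consensus and any site the blocking oligo could bind.
#'
#' @param config A [sim_config].
#' @param n_taxa Number of templates (defaults to `config$n_taxa`).
#' @param prefix Template id prefix.
#' @param copies_total Pool copy number split by abundance (defaults to
#'   `config$microbial_template_copies`).
#' @param seed Seed (defaults to `config$seed + 1`).
#' @return A list: `templates` (named sequences), `abundances`, `copies`.
#' @export
make_16s_community <- function(config = sim_config(),
                               n_taxa = config$n_taxa,
                               prefix = "Taxon",
                               copies_total = config$microbial_template_copies,
                               seed = config$seed + 1L) {
  stopifnot(n_taxa >= 1L)
  inhib <- default_inhibitor()
  blocker_params <- scan_params(anchor_len = 5L, max_mismatches = 3L)
  attr(blocker_params, "as_blocker") <- TRUE
  .with_seed(seed, {
    fwd_exp <- expand_degenerate(primer_341F()$seq)
    rev_exp <- expand_degenerate(primer_805R()$seq)
    templates <- character(n_taxa)
    for (i in seq_len(n_taxa)) {
      for (try in seq_len(100L)) {
        insert <- .random_dna(sample(420:435, 1L))
        tmpl <- paste0(sample(fwd_exp, 1L), insert,
                       reverse_complement(sample(rev_exp, 1L)))
        ref <- stats::setNames(tmpl, "t")
        clean <- NROW(locate_motif(.OFFTARGET_5P_CONSENSUS, ref,
                                   max_mismatch = 3L)) == 0L &&
          NROW(scan_priming_sites(ref, inhib, blocker_params)) == 0L
        if (clean) break
        if (try == 100L) stop("could not generate a clean template")
      }
      templates[i] <- tmpl
    }
    names(templates) <- paste0(prefix, "_", seq_len(n_taxa))
    ab <- stats::rgamma(n_taxa, shape = config$dirichlet_alpha)
    ab <- ab / sum(ab)
    names(ab) <- names(templates)
    list(templates = templates, abundances = ab,
         copies = copies_total * ab)
  })
}

# Assemble the template panel (host amplicons + microbial + kitome) with
# copies, mismatch counts and inhibitor-binding indicators.
.template_panel <- function(host, community, kitome, config) {
  inhib <- default_inhibitor()
  blocker_params <- scan_params(anchor_len = 5L, max_mismatches = 3L)
  attr(blocker_params, "as_blocker") <- TRUE
  rows <- list()
  if (!is.null(host)) {
    nl <- nrow(host$loci)
    for (i in seq_len(nl)) {
      tmpl <- host$loci$product_seq[i]
      bound <- NROW(scan_priming_sites(stats::setNames(tmpl, "t"), inhib,
                                       blocker_params)) > 0L
      rows[[length(rows) + 1L]] <- data.frame(
        template_id = host$loci$locus_id[i], class = "host",
        seq = tmpl, copies = config$host_template_copies / nl,
        mismatches = host$loci$n_mismatches[i],
        inhibited = bound, stringsAsFactors = FALSE)
    }
  }
  add_pool <- function(pool, class) {
    for (id in names(pool$templates)) {
      rows[[length(rows) + 1L]] <<- data.frame(
        template_id = id, class = class, seq = pool$templates[[id]],
        copies = pool$copies[[id]], mismatches = 0L,
        inhibited = FALSE, stringsAsFactors = FALSE)
    }
  }
  if (!is.null(community)) add_pool(community, "microbial")
  if (!is.null(kitome)) add_pool(kitome, "kitome")
  panel <- do.call(rbind, rows)
  rownames(panel) <- NULL
  panel
}

#' Closed-form expected read fractions of the PCR model
#'
#' Template t with initial copies T and per-cycle efficiency
#' e = e0 * rho^m * (1 - b * I) reaches weight W = T * (1 + e)^cycles
#' after the configured cycles (m = planted non-anchor mismatch count of
#' its priming sites, I = 1 if the blocking oligo binds the template,
#' b = `inhibitor_binding`). Read fractions are W / sum(W).
#'
#' @param panel Template panel from [simulate_pcr_reads] (or internal).
#' @param config A [sim_config].
#' @return The panel with `efficiency`, `weight` and `exp_fraction`.
#' @export
pcr_expected_fractions <- function(panel, config) {
  e <- config$base_efficiency * config$mismatch_penalty^panel$mismatches *
    (1 - config$inhibitor_binding * as.numeric(panel$inhibited))
  w <- panel$copies * (1 + e)^config$cycles
  if (all(w == 0)) stop("all template weights are zero")
  panel$efficiency <- e
  panel$weight <- w
  panel$exp_fraction <- w / sum(w)
  panel
}

#' Simulate PCR-amplified sequencing reads
#'
#' Deterministic exponential amplification weights (see
#' [pcr_expected_fractions]) followed by a multinomial read draw at the
#' configured depth; substitution errors are applied per base at
#' `error_rate`, and constant Phred-35 qualities attached.
#'
#' @param host Output of [make_host_genome] (or `NULL`).
#' @param community Output of [make_16s_community] (or `NULL`).
#' @param kitome Optional kitome pool (same shape as `community`).
#' @param config A [sim_config].
#' @param seed Seed for the read draw (defaults to `config$seed + 2`).
#' @return A list: `reads` (data frame id, seq, qual, template_id,
#'   class), `panel` (with expected fractions), `config`.
#' @export
simulate_pcr_reads <- function(host, community, kitome = NULL,
                               config = sim_config(),
                               seed = config$seed + 2L) {
  panel <- .template_panel(host, community, kitome, config)
  panel <- pcr_expected_fractions(panel, config)
  .with_seed(seed, {
    n_per <- as.integer(stats::rmultinom(1L, config$depth, panel$weight))
    reads <- vector("list", nrow(panel))
    for (i in seq_len(nrow(panel))) {
      n_t <- n_per[i]
      if (n_t == 0L) next
      tmpl <- panel$seq[i]
      len <- nchar(tmpl)
      k <- stats::rbinom(n_t, len, config$error_rate)
      seqs <- rep.int(tmpl, n_t)
      for (r in which(k > 0L)) seqs[r] <- .mutate_seq(tmpl, k[r])
      reads[[i]] <- data.frame(
        id = sprintf("%s_read%05d", panel$template_id[i], seq_len(n_t)),
        seq = seqs, qual = strrep(rawToChar(as.raw(35L + 33L)), len),
        template_id = panel$template_id[i], class = panel$class[i],
        stringsAsFactors = FALSE)
    }
    reads <- do.call(rbind, reads)
    rownames(reads) <- NULL
    list(reads = reads, panel = panel, config = config)
  })
}

#' Observed and expected host off-target read fraction of a simulation
#' @param sim Output of [simulate_pcr_reads].
#' @return Named numeric: `observed` (fraction of reads from host
#'   templates) and `expected` (closed-form weight fraction).
#' @export
offtarget_fraction <- function(sim) {
  obs <- if (is.null(sim$reads) || !nrow(sim$reads)) 0
         else mean(sim$reads$class == "host")
  c(observed = obs,
    expected = sum(sim$panel$exp_fraction[sim$panel$class == "host"]))
}

#' Build feature tables from simulated samples
#'
#' Denoised features (ASVs) are the error-free, primer-trimmed template
#' inserts; counts per sample are the per-template read counts of each
#' simulation. Microbial and kitome features receive synthetic
#' genus/phylum labels; host off-target features remain unassigned at
#' the phylum level, as real off-targets do.
#'
#' @param sims Named list of [simulate_pcr_reads] outputs, one per
#'   sample.
#' @return A list: `table` ([feature_table] with taxonomy), `features`
#'   (named feature sequences), `host_ids`, `truth` (long data frame of
#'   per-sample template read counts and expected fractions).
#' @export
make_feature_tables <- function(sims) {
  if (is.null(names(sims)) || any(!nzchar(names(sims))))
    names(sims) <- paste0("sample", seq_along(sims))
  panel <- sims[[1L]]$panel
  fwd_len <- nchar(.FWD_LANDING$seq)
  rev_len <- nchar(.REV_LANDING$seq)
  feat_seq <- vapply(seq_len(nrow(panel)), function(i) {
    s <- panel$seq[i]
    substr(s, fwd_len + 1L, nchar(s) - rev_len)  # trim the primer landings
  }, character(1L))
  feature_ids <- paste0("ASV_", seq_len(nrow(panel)))
  names(feat_seq) <- feature_ids

  counts <- sapply(sims, function(sim) {
    tab <- table(factor(sim$reads$template_id, levels = panel$template_id))
    as.integer(tab)
  })
  if (is.null(dim(counts))) counts <- matrix(counts, ncol = length(sims))
  dimnames(counts) <- list(feature_ids, names(sims))

  phyla <- c("Bacillota", "Bacteroidota", "Pseudomonadota", "Actinomycetota")
  taxonomy <- data.frame(
    feature_id = feature_ids,
    phylum = ifelse(panel$class == "host", NA_character_,
                    phyla[(seq_len(nrow(panel)) - 1L) %% length(phyla) + 1L]),
    genus = ifelse(panel$class == "host", NA_character_,
                   paste0(ifelse(panel$class == "kitome", "Kitome", "Genus"),
                          "_", panel$template_id)),
    organelle = FALSE, stringsAsFactors = FALSE)

  truth <- do.call(rbind, lapply(names(sims), function(s) {
    p <- sims[[s]]$panel
    tab <- table(factor(sims[[s]]$reads$template_id, levels = p$template_id))
    data.frame(sample = s, template_id = p$template_id, class = p$class,
               reads = as.integer(tab), exp_fraction = p$exp_fraction,
               stringsAsFactors = FALSE)
  }))

  list(table = feature_table(counts, taxonomy),
       features = feat_seq,
       host_ids = feature_ids[panel$class == "host"],
       truth = truth)
}

#' Simulate primer-trimmed off-target reads for consensus recovery
#'
#' Draws reads from the three planted locus variants in equal
#' proportion: the shared 5' consensus with its degenerate S column
#' drawn C/G equiprobably per read, the locus spacer, and the
#' chromosome-specific 3' consensus (reverse-complemented), with
#' substitution noise applied.
#'
#' @param n Number of reads (default 120).
#' @param error_rate Per-base substitution rate (default 0.01).
#' @param seed Seed.
#' @param loci Optional locus specs; defaults to [default_planted_loci].
#' @return Character vector of reads.
#' @export
simulate_offtarget_reads <- function(n = 120L, error_rate = 0.01, seed = 1L,
                                     loci = default_planted_loci()) {
  .with_seed(seed, {
    tails <- vapply(loci, function(spec) {
      paste0(.random_dna(spec$spacer_len),
             reverse_complement(spec$three_prime_motif))
    }, character(1L))
    variant <- rep_len(seq_along(loci), n)
    reads <- character(n)
    for (r in seq_len(n)) {
      s <- sample(c("C", "G"), 1L)
      body <- paste0(sub("S", s, .OFFTARGET_5P_CONSENSUS, fixed = TRUE),
                     tails[variant[r]])
      k <- stats::rbinom(1L, nchar(body), error_rate)
      reads[r] <- .mutate_seq(body, k)
    }
    reads
  })
}
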