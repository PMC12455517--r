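# The generator: planted truth, screening, determinism, and the PCR
# weight model.

test_that("generation is byte-identical under a fixed seed", {
  cfg <- sim_config(seed = 61, chrom_len = 12000, n_taxa = 5, depth = 2000)
  a <- make_host_genome(cfg)
  b <- make_host_genome(cfg)
  expect_identical(a$genome, b$genome)
  expect_identical(a$sites, b$sites)
  ca <- make_16s_community(cfg)
  cb <- make_16s_community(cfg)
  expect_identical(ca$templates, cb$templates)
  expect_identical(ca$abundances, cb$abundances)
  sa <- simulate_pcr_reads(a, ca, NULL, cfg)
  sb <- simulate_pcr_reads(b, cb, NULL, cfg)
  expect_identical(sa$reads, sb$reads)
})

test_that("a zero-locus genome is screened clean of primer sites", {
  cfg <- sim_config(seed = 62, n_chrom = 2, chrom_len = 10000, loci = list())
  g <- make_host_genome(cfg)
  expect_identical(nrow(scan_priming_sites(g$genome, primer_341F())), 0L)
  expect_identical(nrow(scan_priming_sites(g$genome, primer_805R())), 0L)
})

test_that("planted loci are recovered with exact coordinates and offsets", {
  fx <- small_sim_fixture()
  found <- rbind(scan_priming_sites(fx$host$genome, primer_341F()),
                 scan_priming_sites(fx$host$genome, primer_805R()))
  expect_identical(sites_for_comparison(found),
                   sites_for_comparison(fx$host$sites))
  amp <- predict_amplicons(found[found$primer_name == "341F", ],
                           found[found$primer_name == "805R", ],
                           genome = fx$host$genome)
  expect_identical(nrow(amp), 3L)
  expect_true(all(amp$product_len == 248L))
  expect_setequal(paste(amp$chrom, amp$product_start),
                  paste(fx$host$loci$chrom, fx$host$loci$start))
})

test_that("planted mismatch offsets avoid the scanner's default anchor", {
  for (spec in default_planted_loci()) {
    sites <- small_sim_fixture()$host$sites
    expect_true(all(unlist(sites$mismatch_offsets) >= 5L))
  }
})

test_that("mock community templates have primer-flanked structure", {
  fx <- small_sim_fixture()
  tpl <- fx$com$templates
  expect_equal(sum(fx$com$abundances), 1)
  lens <- nchar(tpl)
  expect_true(all(lens >= 17 + 420 + 21 & lens <= 17 + 435 + 21))
  for (t in tpl) {
    expect_true(all(iupac_match(strsplit(primer_341F()$seq, "")[[1]],
                                strsplit(substr(t, 1, 17), "")[[1]])))
    tail21 <- substr(t, nchar(t) - 20, nchar(t))
    expect_true(all(iupac_match(strsplit(primer_805R()$seq, "")[[1]],
                                strsplit(reverse_complement(tail21), "")[[1]])))
  }
  expect_identical(nrow(screen_cross_reactivity(default_inhibitor(), tpl)), 0L)
})

test_that("symmetric templates yield read fractions near the copy share", {
  # equal copies, no mismatch penalty, no inhibitor: the off-target
  # fraction equals the host copy share up to multinomial noise
  cfg <- sim_config(seed = 63, chrom_len = 12000, n_taxa = 5,
                    mismatch_penalty = 1, host_template_copies = 1000,
                    microbial_template_copies = 1000,
                    error_rate = 0, depth = 20000)
  host <- make_host_genome(cfg)
  com <- make_16s_community(cfg)
  sim <- simulate_pcr_reads(host, com, NULL, cfg)
  # mismatch_penalty 1 makes every efficiency e0: fractions = copy shares
  expect_equal(unname(offtarget_fraction(sim)["expected"]), 0.5)
  p <- 0.5
  sd3 <- 3 * sqrt(p * (1 - p) / cfg$depth)
  expect_lt(abs(offtarget_fraction(sim)["observed"] - p), sd3)
})

test_that("full inhibitor binding freezes host weights at the template count", {
  cfg <- sim_config(seed = 64, cycles = 35, inhibitor_binding = 1)
  panel <- data.frame(
    template_id = c("locus", "taxon"), class = c("host", "microbial"),
    seq = NA, copies = c(2e8, 1e3), mismatches = c(4L, 0L),
    inhibited = c(TRUE, FALSE), stringsAsFactors = FALSE)
  p <- pcr_expected_fractions(panel, cfg)
  expect_equal(p$weight[1], 2e8)                 # T * 1^cycles
  expect_lt(p$exp_fraction[1], 1e-3)             # vanishing off-target share
})

test_that("expected off-target fraction is monotone in the model knobs", {
  base <- function(...) sim_config(seed = 65, ...)
  frac <- function(cfg) {
    panel <- data.frame(
      template_id = c("locus", "taxon"), class = c("host", "microbial"),
      seq = NA, copies = c(cfg$host_template_copies, 1e3),
      mismatches = c(4L, 0L), inhibited = c(TRUE, FALSE),
      stringsAsFactors = FALSE)
    p <- pcr_expected_fractions(panel, cfg)
    sum(p$exp_fraction[p$class == "host"])
  }
  by_inhib <- vapply(c(0, 0.3, 0.6, 1), function(b)
    frac(base(inhibitor_binding = b)), numeric(1))
  expect_true(all(diff(by_inhib) <= 0))
  by_copies <- vapply(c(1e6, 1e7, 1e8, 1e9), function(h)
    frac(base(host_template_copies = h)), numeric(1))
  expect_true(all(diff(by_copies) >= 0))
  # more cycles favour the efficient microbial templates, so the host
  # share shrinks; with the host efficiency advantage inverted it grows
  by_cycles <- vapply(c(10L, 25L, 35L), function(cy)
    frac(base(cycles = cy)), numeric(1))
  expect_true(all(diff(by_cycles) <= 0))
})

test_that("the model spans the observed off-target range across configs", {
  frac_for <- function(host_copies) {
    cfg <- sim_config(seed = 66, host_template_copies = host_copies)
    panel <- data.frame(
      template_id = c("locus", "taxon"), class = c("host", "microbial"),
      seq = NA, copies = c(host_copies, 1e3), mismatches = c(4L, 0L),
      inhibited = c(TRUE, FALSE), stringsAsFactors = FALSE)
    p <- pcr_expected_fractions(panel, cfg)
    sum(p$exp_fraction[p$class == "host"])
  }
  expect_lt(frac_for(1e4), 0.001)   # below 0.1%
  expect_gt(frac_for(1e9), 0.25)    # tens of percent
})

test_that("feature tables conserve depth and share a feature universe", {
  fx <- small_sim_fixture()
  sim2 <- simulate_pcr_reads(fx$host, fx$com, fx$kit, fx$cfg,
                             seed = fx$cfg$seed + 50)
  ft <- make_feature_tables(list(s1 = fx$sim, s2 = sim2))
  expect_equal(unname(colSums(ft$table$counts)),
               rep(fx$cfg$depth, 2))
  expect_identical(rownames(ft$table$counts),
                   paste0("ASV_", seq_len(nrow(fx$sim$panel))))
  expect_false(identical(ft$table$counts[, 1], ft$table$counts[, 2]))
  expect_identical(length(ft$host_ids), 3L)
  # per-sample truth fractions sum to one
  for (s in unique(ft$truth$sample))
    expect_equal(sum(ft$truth$exp_fraction[ft$truth$sample == s]), 1)
})

test_that("simulated read fractions converge to the closed form", {
  fx <- small_sim_fixture()
  f <- offtarget_fraction(fx$sim)
  p <- f["expected"]
  expect_lt(abs(f["observed"] - p),
            3 * sqrt(p * (1 - p) / fx$cfg$depth))
})

test_that("off-target read simulation honours its locus structure", {
  reads <- simulate_offtarget_reads(n = 30, error_rate = 0, seed = 67)
  expect_length(reads, 30)
  expect_true(all(nchar(reads) == 32 + 149 + 29))
  first32 <- substr(reads, 1, 32)
  s_col <- substr(first32, 23, 23)
  expect_true(all(s_col %in% c("C", "G")))
  expect_true(all(substr(first32, 1, 22) == substr(PLANTED_5P, 1, 22)))
})
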