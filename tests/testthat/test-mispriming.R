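# The scanner's contract: perfect IUPAC match over the 3' anchor,
# bounded mismatches elsewhere, both strands, exact coordinates.

plant <- function(background, seq, offset0) {
  # offset0 is 0-based
  substr(background, offset0 + 1, offset0 + nchar(seq)) <- seq
  background
}

test_that("an exact planted 341F expansion is found at its coordinates", {
  g <- c(chr1 = plant(strrep("T", 200), "CCTACGGGAGGCAGCAG", 50))
  s <- scan_priming_sites(g, primer_341F())
  expect_identical(nrow(s), 1L)
  expect_identical(s$start, 50L)
  expect_identical(s$strand, "+")
  expect_identical(s$n_mismatches, 0L)
  expect_true(s$anchor_intact)
})

test_that("substitutions outside the anchor are reported as 3'-relative offsets", {
  exp341 <- "CCTACGGGAGGCAGCAG"
  mutated <- exp341
  substr(mutated, 2, 2) <- "A"  # 5' offset 1 -> 3' offset 15
  substr(mutated, 4, 4) <- "C"  # 5' offset 3 -> 3' offset 13
  g <- c(chr1 = plant(strrep("T", 200), mutated, 50))
  params <- scan_params(anchor_len = 5, max_mismatches = 3)
  s <- scan_priming_sites(g, primer_341F(), params)
  expect_identical(nrow(s), 1L)
  expect_identical(s$start, 50L)
  expect_identical(sort(s$mismatch_offsets[[1]]), c(13L, 15L))
  # cross-check against the independent matcher
  orc <- oracle_scan(g, primer_341F()$seq, 5, 3, "341F")
  expect_identical(sites_for_comparison(s), orc)
})

test_that("a mismatch inside the 3' anchor suppresses the site", {
  exp341 <- "CCTACGGGAGGCAGCAG"
  substr(exp341, 16, 16) <- "T"  # 3' offset 1, inside the 5-base anchor
  g <- c(chr1 = plant(strrep("T", 200), exp341, 50))
  s <- scan_priming_sites(g, primer_341F(),
                          scan_params(anchor_len = 5, max_mismatches = 4))
  expect_identical(nrow(s), 0L)
})

test_that("minus-strand landings are found with mapped coordinates", {
  exp341 <- "CCTACGGGAGGCAGCAG"
  g <- c(chr1 = plant(strrep("T", 200), reverse_complement(exp341), 80))
  s <- scan_priming_sites(g, primer_341F())
  expect_identical(nrow(s), 1L)
  expect_identical(s$strand, "-")
  expect_identical(s$start, 80L)
})

test_that("genome N never matches a primer base", {
  exp341 <- "CCTACGGGAGGCAGCAG"
  withN <- exp341
  substr(withN, 17, 17) <- "N"   # anchor base unknown
  g <- c(chr1 = plant(strrep("T", 200), withN, 50))
  expect_identical(nrow(scan_priming_sites(g, primer_341F())), 0L)
  # N outside the anchor counts as a mismatch
  withN2 <- exp341
  substr(withN2, 3, 3) <- "N"
  g2 <- c(chr1 = plant(strrep("T", 200), withN2, 50))
  s2 <- scan_priming_sites(g2, primer_341F())
  expect_identical(s2$n_mismatches, 1L)
})

test_that("scanner equals the brute-force matcher on random genomes", {
  set.seed(21)
  for (i in 1:20) {
    g <- c(chrA = random_dna_string(sample(2000:6000, 1)))
    for (p in list(primer_341F(), primer_805R())) {
      s <- scan_priming_sites(g, p, scan_params(5, 4))
      orc <- oracle_scan(g, p$seq, 5, 4, p$name)
      expect_identical(sites_for_comparison(s), orc,
                       info = paste("genome", i, p$name))
    }
  }
})

test_that("minus-strand scan equals plus-strand scan of the reverse complement", {
  set.seed(22)
  g <- c(chr1 = random_dna_string(5000))
  rc <- c(chr1 = reverse_complement(g[["chr1"]]))
  p <- primer_341F()
  s <- scan_priming_sites(g, p)
  s_rc <- scan_priming_sites(rc, p)
  minus <- s[s$strand == "-", ]
  plus_rc <- s_rc[s_rc$strand == "+", ]
  L <- nchar(g[["chr1"]])
  expect_setequal(minus$start, L - plus_rc$start - plus_rc$primer_len)
  expect_identical(sort(minus$n_mismatches), sort(plus_rc$n_mismatches))
})

test_that("errors: empty genome, primer shorter than anchor, indels refused", {
  expect_error(scan_priming_sites(character(0), primer_341F()), "non-empty")
  expect_error(scan_priming_sites(c(chr1 = "ACGTACGT"), "ACG",
                                  scan_params(anchor_len = 5)), "shorter than")
  expect_error(scan_params(allow_indels = TRUE), "not supported")
})

test_that("convergent site pairs become amplicons with exact intervals", {
  exp341 <- "CCTACGGGAGGCAGCAG"
  exp805 <- "GACTACCAGGGTTTCTAATCC"
  g <- strrep("T", 500)
  g <- plant(g, exp341, 100)
  g <- plant(g, reverse_complement(exp805), 353)
  genome <- c(chr1 = g)
  fwd <- scan_priming_sites(genome, primer_341F())
  rev <- scan_priming_sites(genome, primer_805R())
  amp <- predict_amplicons(fwd, rev, min_len = 100, max_len = 600,
                           genome = genome)
  expect_identical(nrow(amp), 1L)
  expect_identical(amp$product_start, 100L)
  expect_identical(amp$product_end, 374L)
  expect_identical(amp$product_len, 274L)
  expect_identical(nchar(amp$insert_seq), amp$insert_len)
  expect_identical(amp$insert_seq,
                   substr(genome[["chr1"]], 100 + 17 + 1, 353))
})

test_that("same-strand pairs and out-of-window spans yield no amplicon", {
  exp341 <- "CCTACGGGAGGCAGCAG"
  exp805 <- "GACTACCAGGGTTTCTAATCC"
  # both on plus strand
  g1 <- c(chr1 = plant(plant(strrep("T", 500), exp341, 100), exp805, 300))
  fwd1 <- scan_priming_sites(g1, primer_341F())
  rev1 <- scan_priming_sites(g1, primer_805R())
  expect_identical(nrow(predict_amplicons(fwd1, rev1, genome = g1)), 0L)
  # convergent but 800 bp product vs max 600
  g2 <- c(chr1 = plant(plant(strrep("T", 1000), exp341, 100),
                       reverse_complement(exp805), 879))
  fwd2 <- scan_priming_sites(g2, primer_341F())
  rev2 <- scan_priming_sites(g2, primer_805R())
  expect_identical(nrow(predict_amplicons(fwd2, rev2, max_len = 600,
                                          genome = g2)), 0L)
  expect_identical(nrow(predict_amplicons(fwd2, rev2, max_len = 900,
                                          genome = g2)), 1L)
})

test_that("mispriming annotation flags exactly the planted mismatches", {
  exp341 <- "CCTACGGGAGGCAGCAG"
  mutated <- exp341
  substr(mutated, 2, 2) <- "A"
  substr(mutated, 4, 4) <- "C"
  g <- c(chr1 = plant(strrep("T", 200), mutated, 50))
  s <- scan_priming_sites(g, primer_341F(), scan_params(5, 3))
  ann <- annotate_mispriming(s[1, ], primer_341F(), g)
  expect_identical(which(!ann$match), c(2L, 4L))
  expect_identical(sum(!ann$match), s$n_mismatches[1])

  # minus strand: reported window is the reverse complement of the slice
  g2 <- c(chr1 = plant(strrep("T", 200), reverse_complement(exp341), 80))
  s2 <- scan_priming_sites(g2, primer_341F())
  ann2 <- annotate_mispriming(s2[1, ], primer_341F(), g2)
  expect_identical(ann2$window,
                   reverse_complement(substr(g2[["chr1"]], 81, 97)))
  expect_true(all(ann2$match))
})
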