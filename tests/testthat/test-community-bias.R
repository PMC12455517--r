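# Filtering, with/without off-target comparison, rarefaction and
# Hellinger-PCoA.

make_table <- function(counts, genera = NULL, phyla = NULL,
                       organelle = NULL) {
  tax <- NULL
  if (!is.null(genera)) {
    tax <- data.frame(
      feature_id = rownames(counts), phylum = phyla %||% "Bacillota",
      genus = genera,
      organelle = organelle %||% FALSE, stringsAsFactors = FALSE)
  }
  feature_table(counts, tax)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("feature tables validate counts and ids", {
  m <- matrix(1:4, 2, dimnames = list(c("f1", "f2"), c("s1", "s2")))
  expect_s3_class(feature_table(m), "feature_table")
  bad <- m; bad[1] <- -1L
  expect_error(feature_table(bad), "non-negative")
  expect_error(feature_table(matrix(1:4, 2)), "names")
})

test_that("genus filtering applies the abundance, prevalence and taxonomy rules", {
  # 200 samples; rare genus below 0.01% everywhere, sparse genus in 1 sample
  n_s <- 200
  counts <- rbind(
    common  = rep(20000L, n_s),
    rare    = rep(1L, n_s),                        # max relab 1/20051 < 1e-4
    sparse  = c(5000L, rep(0L, n_s - 1L)),         # prevalence 0.5% < 1%
    organ   = rep(50L, n_s))
  colnames(counts) <- paste0("s", 1:n_s)
  tab <- make_table(counts,
                    genera = c("Common", "Rare", "Sparse", "Mito"),
                    phyla = c("Bacillota", "Bacillota", "Bacillota", NA),
                    organelle = c(FALSE, FALSE, FALSE, TRUE))
  out <- filter_features(tab)
  log <- attr(out, "filter_log")
  expect_identical(rownames(out$counts), "common")
  expect_identical(log$reason[log$feature_id == "rare"], "max_abundance")
  expect_identical(log$reason[log$feature_id == "sparse"], "prevalence")
  expect_identical(log$reason[log$feature_id == "organ"], "organelle")
})

test_that("features without taxonomy rows are dropped as unassigned", {
  counts <- rbind(known = c(100L, 100L), mystery = c(50L, 50L))
  colnames(counts) <- c("s1", "s2")
  tax <- data.frame(feature_id = "known", phylum = "Bacillota",
                    genus = "G1", organelle = FALSE)
  out <- filter_features(feature_table(counts, tax))
  expect_identical(rownames(out$counts), "known")
  log <- attr(out, "filter_log")
  expect_identical(log$reason[log$feature_id == "mystery"], "unassigned_phylum")
})

test_that("filtering is idempotent and errors when nothing survives", {
  set.seed(51)
  counts <- matrix(rpois(200, 30), nrow = 20,
                   dimnames = list(paste0("f", 1:20), paste0("s", 1:10)))
  genera <- paste0("G", rep(1:5, each = 4))
  tab <- make_table(counts, genera = genera)
  once <- filter_features(tab)
  twice <- filter_features(once)
  expect_identical(once$counts, twice$counts)

  tiny <- make_table(matrix(c(1L, 0L), 1, 2,
                            dimnames = list("f1", c("s1", "s2"))),
                     genera = "G1")
  expect_error(suppressWarnings(filter_features(
    tiny, filter_params(prevalence_cutoff = 0.9))), "no features left")
})

test_that("with/without comparison follows denominator arithmetic", {
  counts <- matrix(c(50L, 30L, 20L), ncol = 1,
                   dimnames = list(c("taxA", "taxB", "host1"), "s1"))
  tab <- feature_table(counts)
  out <- compare_with_without(tab, "host1")
  expect_equal(out$mean_relab_with[out$taxon == "taxA"], 50 / 100)
  expect_equal(out$mean_relab_without[out$taxon == "taxA"], 50 / 80)
  # empty host set: the two summaries coincide
  out0 <- compare_with_without(tab, character(0))
  expect_equal(out0$mean_relab_with, out0$mean_relab_without)
  expect_error(compare_with_without(tab, c("taxA", "taxB", "host1")),
               "nothing microbial")
  expect_error(compare_with_without(tab, "nope"), "not in table")
})

test_that("removal never decreases microbial relative abundance (property)", {
  set.seed(52)
  for (i in 1:20) {
    n_f <- sample(5:15, 1); n_s <- sample(3:8, 1)
    counts <- matrix(rpois(n_f * n_s, 20), n_f,
                     dimnames = list(paste0("f", 1:n_f), paste0("s", 1:n_s)))
    host <- paste0("f", sample(n_f, sample(1:2, 1)))
    counts[host, ] <- counts[host, , drop = FALSE] + 1L  # host reads present
    out <- compare_with_without(feature_table(counts), host)
    expect_true(all(out$delta >= -1e-12))
    nonzero <- out$mean_relab_with > 0
    expect_true(all(out$delta[nonzero] > 0))
  }
})

test_that("relative abundances sum to one per sample in both modes", {
  set.seed(53)
  counts <- matrix(rpois(40, 50) + 1L, 8,
                   dimnames = list(paste0("f", 1:8), paste0("s", 1:5)))
  host <- c("f1", "f2")
  mic <- counts[setdiff(rownames(counts), host), ]
  expect_equal(colSums(sweep(mic, 2, colSums(mic), "/")), rep(1, 5),
               ignore_attr = TRUE)
  with_host <- sweep(counts, 2, colSums(counts), "/")
  expect_equal(colSums(with_host), rep(1, 5), ignore_attr = TRUE)
})

test_that("rarefaction handles degenerate one-genus and all-singleton samples", {
  r1 <- rarefaction_curve(c(g1 = 1000), step = 100)
  expect_true(all(r1$curve$richness == 1))
  expect_equal(r1$final_slope, 0)
  expect_true(r1$saturated)

  r2 <- rarefaction_curve(setNames(rep(1, 1000), paste0("g", 1:1000)),
                          step = 100)
  expect_equal(r2$curve$richness, r2$curve$depth)  # E[S(n)] = n
  expect_equal(r2$final_slope, 1)
  expect_false(r2$saturated)

  r3 <- rarefaction_curve(c(g1 = 50), step = 100)
  expect_false(r3$evaluable)
})

test_that("analytic rarefaction equals the hypergeometric formula", {
  counts <- c(a = 3, b = 2, c = 1)
  r <- rarefaction_curve(counts, step = 2)
  for (k in seq_len(nrow(r$curve))) {
    expect_equal(r$curve$richness[k],
                 oracle_expected_richness(counts, r$curve$depth[k]))
  }
})

test_that("Hellinger PCoA maps identical samples together and disjoint apart", {
  counts <- cbind(s1 = c(10L, 5L, 0L), s2 = c(10L, 5L, 0L),
                  s3 = c(0L, 0L, 7L))
  rownames(counts) <- paste0("f", 1:3)
  ord <- hellinger_pcoa(counts, k = 2)
  expect_equal(ord$distances["s1", "s2"], 0)
  expect_equal(ord$distances["s1", "s3"], sqrt(2))  # the metric's maximum
  expect_equal(ord$coordinates["s1", ], ord$coordinates["s2", ])
  expect_true(all(abs(ord$distances - t(ord$distances)) < 1e-12))
  expect_true(all(diag(ord$distances) == 0))
  expect_false(is.unsorted(rev(ord$eigenvalues)))
})

test_that("distances are reconstructed from full-rank coordinates", {
  set.seed(54)
  counts <- matrix(rpois(60, 30) + 1L, 10,
                   dimnames = list(paste0("f", 1:10), paste0("s", 1:6)))
  ord <- hellinger_pcoa(counts, k = 5)
  rec <- as.matrix(dist(ord$coordinates))
  expect_lt(max(abs(rec - ord$distances)) / max(ord$distances), 1e-10)
})

test_that("Hellinger distance satisfies the metric axioms on random tables", {
  set.seed(55)
  for (i in 1:10) {
    counts <- matrix(rpois(50, 10) + 1L, 10,
                     dimnames = list(paste0("f", 1:10), paste0("s", 1:5)))
    d <- hellinger_pcoa(counts, k = 2)$distances
    expect_true(all(d >= 0))
    expect_equal(d, t(d))
    for (a in 1:5) for (b in 1:5) for (cc in 1:5)
      expect_lte(d[a, b], d[a, cc] + d[cc, b] + 1e-12)
  }
})

test_that("zero-total samples are rejected by name", {
  counts <- cbind(s1 = c(1L, 2L), dead = c(0L, 0L))
  rownames(counts) <- c("f1", "f2")
  expect_error(hellinger_pcoa(counts), "dead")
})
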