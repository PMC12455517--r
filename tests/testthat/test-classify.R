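# Host/microbial partitioning: the seeded aligner, SAM ingestion,
# position clustering and per-chromosome accounting.

make_ref <- function(n = 10000, seed = 31) {
  set.seed(seed)
  c(ref1 = random_dna_string(n))
}

test_that("an exact reference slice aligns with full identity and coverage", {
  ref <- make_ref()
  q <- substr(ref[["ref1"]], 2001, 2300)
  hit <- align_feature(q, ref)
  expect_identical(hit$chrom, "ref1")
  expect_identical(hit$start, 2000L)
  expect_identical(hit$strand, "+")
  expect_equal(hit$identity, 1.0)
  expect_equal(hit$coverage, 1.0)
  # reverse-complemented query maps to the same locus on the minus strand
  hit_rc <- align_feature(reverse_complement(q), ref)
  expect_identical(hit_rc$start, 2000L)
  expect_identical(hit_rc$strand, "-")
})

test_that("a 3% mutated slice still aligns at the same start", {
  ref <- make_ref()
  q <- substr(ref[["ref1"]], 2001, 2300)
  set.seed(32)
  chars <- strsplit(q, "")[[1]]
  pos <- sample(300, 9)
  for (p in pos) chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
  hit <- align_feature(paste(chars, collapse = ""), ref)
  expect_identical(hit$start, 2000L)
  expect_gte(hit$identity, 0.95)
})

test_that("a foreign sequence yields no hit", {
  ref <- make_ref(10000, seed = 33)
  set.seed(34)
  q <- random_dna_string(300)
  # construction check: no shared 16-mer diagonal reaches 75% identity;
  # the aligner must agree
  expect_null(align_feature(q, ref))
})

test_that("classification separates planted host amplicons from mock 16S", {
  fx <- small_sim_fixture()
  cl <- classify_features(fx$ft$features, fx$ft$table, fx$host$genome)
  truth_host <- fx$ft$host_ids
  called_host <- cl$feature_id[cl$label == "host_offtarget"]
  expect_setequal(called_host, truth_host)          # sensitivity & specificity 1
  expect_identical(nrow(cl), nrow(fx$ft$table$counts))
  # read weights partition exactly
  expect_equal(sum(cl$read_weight), sum(fx$ft$table$counts))
})

test_that("a half-host chimera below the coverage threshold stays non-host", {
  fx <- small_sim_fixture()
  host_seq <- fx$ft$features[[fx$ft$host_ids[1]]]
  set.seed(35)
  chimera <- paste0(substr(host_seq, 1, 105), random_dna_string(150))
  feats <- c(fx$ft$features, chimera_1 = chimera)
  counts <- rbind(fx$ft$table$counts,
                  chimera_1 = rep(5L, ncol(fx$ft$table$counts)))
  cl <- classify_features(feats, counts, fx$host$genome)
  expect_identical(cl$label[cl$feature_id == "chimera_1"], "non_host")
})

sam_header <- "@HD\tVN:1.6\n@SQ\tSN:chr9\tLN:100000"
sam_line <- function(qname, flag, rname = "chr9", pos = 0, cigar = "*",
                     seq = "ACGT") {
  paste(qname, flag, rname, pos, 255, cigar, "*", 0, 0, seq, "IIII",
        sep = "\t")
}

test_that("SAM ingestion honours FLAG semantics and CIGAR reference spans", {
  counts <- matrix(c(10L, 20L, 7L), ncol = 1,
                   dimnames = list(c("f1", "f2", "f3"), "s1"))
  sam <- tempfile(fileext = ".sam")
  writeLines(c(sam_header,
               sam_line("f1", 0, pos = 101, cigar = "100M"),
               sam_line("f2", 4),
               sam_line("f3", 16, pos = 501, cigar = "50M10D40M")),
             sam)
  cl <- ingest_sam(sam, counts)
  expect_identical(cl$label, c("host_offtarget", "non_host", "host_offtarget"))
  expect_identical(cl$start[1], 100L)
  expect_identical(cl$strand[c(1, 3)], c("+", "-"))
  expect_identical(cl$aligned_len[3], 100L)  # 50M + 10D + 40M on the reference
  expect_identical(cl$read_weight, c(10, 20, 7))
})

test_that("SAM ingestion skips secondary records and unknown ids, rejects bad lines", {
  counts <- matrix(5L, dimnames = list("f1", "s1"))
  sam <- tempfile(fileext = ".sam")
  writeLines(c(sam_header,
               sam_line("f1", 0, pos = 11, cigar = "4M"),
               sam_line("f1", 256, pos = 900, cigar = "4M"),  # secondary
               sam_line("ghost", 0, pos = 5, cigar = "4M")),
             sam)
  expect_warning(cl <- ingest_sam(sam, counts), "1 SAM record")
  expect_identical(nrow(cl), 1L)
  expect_identical(cl$start, 10L)

  bad <- tempfile(fileext = ".sam")
  writeLines(c(sam_header, "f1\t0\tchr9"), bad)
  expect_error(ingest_sam(bad, counts), "line 3")
})

test_that("SAM round-trip reproduces the internal aligner's partition", {
  fx <- small_sim_fixture()
  cl <- classify_features(fx$ft$features, fx$ft$table, fx$host$genome)
  sam <- tempfile(fileext = ".sam")
  lines <- "@HD\tVN:1.6"
  for (i in seq_len(nrow(cl))) {
    lines <- c(lines, if (cl$label[i] == "host_offtarget") {
      sam_line(cl$feature_id[i], if (cl$strand[i] == "-") 16 else 0,
               cl$chrom[i], cl$start[i] + 1,
               paste0(cl$aligned_len[i], "M"))
    } else {
      sam_line(cl$feature_id[i], 4)
    })
  }
  writeLines(lines, sam)
  cl2 <- ingest_sam(sam, fx$ft$table)
  m <- match(cl$feature_id, cl2$feature_id)
  expect_identical(cl$label, cl2$label[m])
  expect_identical(cl$start, cl2$start[m])
  expect_identical(cl$strand, cl2$strand[m])
})

test_that("position clustering groups nearby 5' coordinates by read weight", {
  cl <- data.frame(
    feature_id = c("a", "b"), label = "host_offtarget", chrom = "chr17",
    start = c(23210488L, 23210489L), strand = "+",
    aligned_len = c(210L, 210L), identity = 1, coverage = 1,
    read_weight = c(100, 2), stringsAsFactors = FALSE)
  out <- cluster_positions(cl, tolerance = 5)
  expect_identical(nrow(out), 1L)
  expect_identical(out$mode_start, 23210489L)
  expect_equal(out$total_reads, 102)
  expect_identical(out$n_features, 2L)

  cl2 <- cl
  cl2$start <- c(1000L, 2000L)
  expect_identical(nrow(cluster_positions(cl2, tolerance = 5)), 2L)

  none <- cl[0, ]
  expect_identical(nrow(cluster_positions(none)), 0L)
})

test_that("minus-strand 5' ends use the rightmost alignment coordinate", {
  cl <- data.frame(
    feature_id = "a", label = "host_offtarget", chrom = "chr5",
    start = 1000L, strand = "-", aligned_len = 210L, identity = 1,
    coverage = 1, read_weight = 50, stringsAsFactors = FALSE)
  out <- cluster_positions(cl)
  expect_identical(out$mode_start, 1210L)
})

test_that("chromosome report conserves read weight", {
  fx <- small_sim_fixture()
  cl <- classify_features(fx$ft$features, fx$ft$table, fx$host$genome)
  rep <- chromosome_report(cl)
  expect_setequal(rep$chrom, c("chr5", "chr11", "chr17"))
  expect_equal(sum(rep$offtarget_reads),
               sum(cl$read_weight[cl$label == "host_offtarget"]))
  expect_identical(nrow(chromosome_report(cl[cl$label == "non_host", ])), 0L)
})
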