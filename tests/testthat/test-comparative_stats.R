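test_that("Fisher p-values match the hypergeometric oracle", {
  set.seed(17)
  worst <- 0
  for (r in 1:100) {
    tab <- matrix(rpois(4, 20), 2)
    p_pkg <- fisher.test(tab)$p.value
    p_orc <- oracle_fisher2x2(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
    worst <- max(worst, abs(p_pkg - p_orc))
  }
  expect_lt(worst, 1e-12)
})

test_that("k-mer enrichment scans presence against background", {
  set.seed(23)
  seqs <- vapply(1:12, function(i) {
    paste(sample(c("A", "C", "G", "T"), 150, TRUE), collapse = "")
  }, character(1))
  # identical sets: everything null
  km0 <- kmer_enrichment(seqs, seqs)
  expect_true(all(km0$p_value > 1 - 1e-7))
  expect_true(all(abs(km0$log2_enrichment) < 1e-12))

  # spec'd 2x2: 8/10 targets vs 10/100 background carrying GTGTG
  with_m <- function(s) paste0(substr(s, 1, 70), "GTGTG",
                               substr(s, 76, 150))
  tgt <- c(vapply(1:8, function(i) with_m(seqs[i]), character(1)),
           seqs[9:10])
  set.seed(31)
  bg_raw <- vapply(1:100, function(i) {
    paste(sample(c("A", "C"), 150, TRUE), collapse = "")
  }, character(1))
  bg <- c(vapply(1:10, function(i) with_m(bg_raw[i]), character(1)),
          bg_raw[11:100])
  km <- kmer_enrichment(tgt, bg)
  row <- km[km$kmer == "GTGTG", ]
  expect_identical(row$n_target_with + row$n_target_without, 10L)
  expect_gte(row$n_target_with, 8L)   # planted (chance extras possible)
  expect_equal(row$p_value,
               oracle_fisher2x2(row$n_target_with, row$n_target_without,
                                row$n_bg_with, row$n_bg_without),
               tolerance = 1e-12)
  expect_gt(row$log2_enrichment, 0)
  expect_error(kmer_enrichment(tgt, bg, k = 0), "k must be")
})

test_that("planted GU-repeat targets rank canonical motifs on top", {
  cfg <- sim_config(seed = 2)
  u <- gen_utr_set(cfg)
  km <- kmer_enrichment(u$utrs[u$truth_genes$is_target],
                        u$utrs[!u$truth_genes$is_target])
  expect_true(all(c("GTGTG", "TGTGT") %in% head(km$kmer, 3)))
})

test_that("rank-sum comparisons use the exact distribution when possible", {
  gc <- group_compare(c(1, 2, 3, 4, 5, 6),
                      rep(c("a", "b"), each = 3))
  expect_equal(gc$p_value, 0.1)   # exact two-sided p for {1,2,3} vs {4,5,6}
  expect_equal(gc$median1, 2)
  expect_equal(gc$median2, 5)

  # identical groups
  same <- group_compare(rep(c(1, 2, 3), 2), rep(c("a", "b"), each = 3))
  expect_equal(same$p_value, 1)

  # exact branch equals full enumeration for all group sizes <= 8
  set.seed(41)
  for (r in 1:20) {
    n1 <- sample(2:8, 1); n2 <- sample(2:8, 1)
    x <- sample(seq_len(100), n1)
    y <- sample(setdiff(seq_len(100), x), n2)
    p_pkg <- group_compare(c(x, y),
                           c(rep("a", n1), rep("b", n2)))$p_value
    expect_equal(p_pkg, oracle_wilcoxon(x, y), tolerance = 1e-12)
  }

  # exact and approximate branches agree at the boundary
  set.seed(43)
  x <- rnorm(25); y <- rnorm(25) + 0.3
  p_exact <- wilcox.test(x, y, exact = TRUE)$p.value
  p_approx <- suppressWarnings(
    wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value)
  expect_lt(abs(p_exact - p_approx), 0.02)
  # the dispatcher picks the exact branch there
  expect_equal(group_compare(c(x, y), rep(c("a", "b"), each = 25))$p_value,
               p_exact)
})

test_that("peak overlap and read density statistics are exact", {
  utrs <- data.frame(gene_id = c("g1", "g2"), length = c(1000L, 500L),
                     group = c("up", "other"), stringsAsFactors = FALSE)
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer())
  st0 <- clip_overlap_stats(utrs, empty, empty)
  expect_true(all(!st0$per_utr$has_peak))
  expect_true(all(st0$groups$frac_with_peak == 0))

  reads <- data.frame(chrom = "g1", start = seq(0, 900, by = 100),
                      end = seq(30, 930, by = 100))
  peaks <- data.frame(chrom = "g1", start = 100L, end = 200L)
  st <- clip_overlap_stats(utrs, peaks, reads, control_group = "other")
  g1 <- st$per_utr[st$per_utr$gene_id == "g1", ]
  expect_true(g1$has_peak)
  expect_equal(g1$density, 10)   # 10 fully contained reads per kb
  expect_equal(st$groups$fold_peak[st$groups$group == "up"], Inf)

  # malformed BED rejected with a line number
  bad <- tempfile(fileext = ".bed")
  writeLines(c("g1\t0\t100", "g1\t50\t20"), bad)
  expect_error(read_bed(bad), "line 2")
})

test_that("motif/CLIP classes partition non-mutant oligos with half-open overlap", {
  manifest <- data.frame(
    oligo_id = c("a", "b", "c", "d", "e"),
    gene_id = "g1",
    start = c(0L, 0L, 40L, 100L, 0L),
    variable_seq = "x", full_seq = "x",
    motif_hits = c("", "GTGTG:10-15", "GTGTG:10-15", "GTGTG:0-5",
                   "GTGTG:10-15"),
    is_mutant = c(FALSE, FALSE, FALSE, FALSE, TRUE),
    companion_id = c(NA, NA, NA, NA, "b"), stringsAsFactors = FALSE)
  peaks <- data.frame(chrom = "g1", start = 15L, end = 60L)
  cls <- motif_class_assign(manifest, peaks)
  expect_identical(unname(cls["a"]), "no_motif")
  # motif at gene coords [10,15) adjacent to peak [15,60): zero overlap
  expect_identical(unname(cls["b"]), "motif_no_clip")
  # motif at [50,55) inside the peak
  expect_identical(unname(cls["c"]), "motif_clip")
  # motif at [100,105) beyond the peak
  expect_identical(unname(cls["d"]), "motif_no_clip")
  expect_identical(unname(cls["e"]), "mutant")
  # partition: every non-mutant labelled with exactly one class
  expect_setequal(unique(cls[manifest$oligo_id[!manifest$is_mutant]]),
                  c("no_motif", "motif_no_clip", "motif_clip"))
})

test_that("motif count correlates with stability change as constructed", {
  ids <- paste0("r", 1:500)
  mc <- setNames(sample(0:6, 500, TRUE), ids)
  flat <- motifcount_stability_correlation(mc, setNames(rep(1, 500), ids))
  expect_equal(flat$rho, 0)

  set.seed(3)
  sc <- setNames(mc + rnorm(500, 0, 0.1), ids)
  cor_up <- motifcount_stability_correlation(mc, sc)
  expect_gt(cor_up$rho, 0.9)
  expect_lt(cor_up$p_value, 1e-6)
  expect_identical(cor_up$bins$bin, c("0", "1", "2", "3", "4+"))
  # counting convention: overlapping occurrences all count
  expect_identical(nrow(find_motifs("TGTGTGT")), 3L)
})

test_that("the master join runs contrasts and flags disjoint inputs", {
  manifest <- data.frame(
    oligo_id = paste0("o", 1:40),
    gene_id = "g1", start = seq(0, 234, by = 6),
    variable_seq = "x", full_seq = "x",
    motif_hits = rep(c("", "GTGTG:0-5"), each = 20),
    is_mutant = FALSE, companion_id = NA_character_,
    stringsAsFactors = FALSE)
  peaks <- data.frame(chrom = "g1", start = 0L, end = 500L)
  dlr <- data.frame(feature_id = manifest$oligo_id,
                    delta_lr = c(rnorm(20, 0, 0.1), rnorm(20, 2, 0.1)),
                    fdr = 0.01)
  out <- build_master(manifest, dlr, peaks = peaks)
  expect_identical(nrow(out$master), 40L)
  row <- out$contrasts[out$contrasts$contrast ==
                         "delta_lr:motif_clip_vs_no_motif", ]
  expect_lt(row$p_value, 0.01)
  expect_gt(row$median2, row$median1)

  dlr_bad <- dlr; dlr_bad$feature_id <- paste0("zz", 1:40)
  expect_warning(build_master(manifest, dlr_bad, peaks = peaks),
                 "no shared")
})
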