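make_records <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, as.data.frame, stringsAsFactors = FALSE))
}

test_that("UTR filtering applies tag, length and polyA rules in order", {
  recs <- make_records(
    list(gene_id = "g1", transcript_id = "t1",
         sequence = strrep("A", 100), tags = "cds_end_NF",
         polya_conserved = TRUE),
    list(gene_id = "g1", transcript_id = "t2",
         sequence = strrep("A", 100), tags = "mRNA_end_NF",
         polya_conserved = TRUE),
    list(gene_id = "g2", transcript_id = "t3",
         sequence = strrep("A", 10001), tags = "",
         polya_conserved = TRUE),
    list(gene_id = "g3", transcript_id = "t4",
         sequence = strrep("A", 10000), tags = "",
         polya_conserved = TRUE),
    list(gene_id = "g4", transcript_id = "t5",
         sequence = strrep("A", 100), tags = "",
         polya_conserved = FALSE),
    list(gene_id = "g5", transcript_id = "t6",
         sequence = strrep("A", 10001), tags = "cds_end_NF",
         polya_conserved = FALSE))
  out <- filter_utrs(recs)
  expect_identical(out$retained$transcript_id, "t4")  # 10 kb inclusive
  rej <- setNames(out$rejected$reason, out$rejected$transcript_id)
  expect_identical(rej[["t1"]], "tag")
  expect_identical(rej[["t2"]], "tag")
  expect_identical(rej[["t3"]], "length")
  expect_identical(rej[["t5"]], "polya")
  expect_identical(rej[["t6"]], "tag")   # first failed rule wins
})

test_that("meta-UTR merging unions isoform intervals", {
  single <- data.frame(gene_id = "g", transcript_id = "t1",
                       sequence = "ACGTACGT", utr_start = 0L,
                       utr_end = 8L, stringsAsFactors = FALSE)
  m <- merge_meta_utr(single)
  expect_identical(m$sequence, "ACGTACGT")
  expect_identical(m$intervals, data.frame(start = 0L, end = 8L))

  set.seed(1)
  gene_seq <- paste(sample(c("A", "C", "G", "T"), 200, TRUE),
                    collapse = "")
  two <- data.frame(
    gene_id = "g", transcript_id = c("t1", "t2"),
    sequence = c(substr(gene_seq, 1, 100), substr(gene_seq, 51, 200)),
    utr_start = c(0L, 50L), utr_end = c(100L, 200L),
    stringsAsFactors = FALSE)
  m2 <- merge_meta_utr(two)
  expect_identical(m2$intervals, data.frame(start = 0L, end = 200L))
  expect_identical(m2$sequence, gene_seq)

  disjoint <- data.frame(
    gene_id = "g", transcript_id = c("t1", "t2"),
    sequence = c(strrep("A", 100), strrep("C", 100)),
    utr_start = c(0L, 300L), utr_end = c(100L, 400L),
    stringsAsFactors = FALSE)
  m3 <- merge_meta_utr(disjoint)
  expect_equal(nrow(m3$intervals), 2)
  expect_identical(nchar(m3$sequence), 200L)
  expect_identical(m3$sequence, paste0(strrep("A", 100), strrep("C", 100)))

  expect_error(merge_meta_utr(single[0, , drop = FALSE]), "no filter")
})

test_that("tiling geometry follows the closed form", {
  starts <- tile_meta_utr(600, tile_len = 260, step = 6, flank = 260)
  expect_length(starts, 144)   # floor((600 + 520 - 260) / 6) + 1
  expect_identical(starts[1], -260L)
  expect_true(all(diff(starts) == 6))
  expect_true(all(starts + 260 <= 600 + 260))

  expect_identical(tile_meta_utr(266, flank = 0), c(0L, 6L))
  expect_error(tile_meta_utr(100, flank = 0), "shorter than tile")
})

test_that("motif scanning finds all overlapping occurrences", {
  h <- find_motifs("TGTGTGT")
  expect_identical(h$motif, c("TGTGT", "GTGTG", "TGTGT"))
  expect_identical(h$start, c(0L, 1L, 2L))
  expect_identical(h$end, c(5L, 6L, 7L))

  expect_identical(nrow(find_motifs(strrep("A", 50))), 0L)
  h2 <- find_motifs("GTATG")
  expect_identical(h2$motif, "GTATG")
  expect_identical(h2$start, 0L)
  # U alphabet is normalised to T
  expect_identical(find_motifs("GUAUG")$motif, "GTATG")
})

test_that("motif mutation complements exactly the canonical substitutions", {
  expect_identical(mutate_motifs("GTGTG", find_motifs("GTGTG")), "CACAC")
  expect_identical(mutate_motifs("TGTGT", find_motifs("TGTGT")), "ACACA")
  expect_identical(mutate_motifs("GTATG", find_motifs("GTATG")), "CATAC")
  # overlap: union span complemented
  expect_identical(mutate_motifs("TGTGTG", find_motifs("TGTGTG")),
                   "ACACAC")
  # idempotent on motif-free sequence
  s <- "AAACCCGGG"
  expect_identical(mutate_motifs(s, find_motifs(s)), s)
  # context outside hits untouched, rescan finds nothing
  s2 <- "AATGTGTAA"
  mut <- mutate_motifs(s2, find_motifs(s2))
  expect_identical(mut, "AAACACAAA")
  expect_identical(nrow(find_motifs(mut)), 0L)
  expect_error(mutate_motifs("GTGTG",
                             data.frame(motif = "GTGTG", start = 2L,
                                        end = 7L)),
               "out of")
})

test_that("pool assembly emits handles, companions and a valid manifest", {
  set.seed(5)
  body <- paste(sample(c("A", "C"), 300, TRUE), collapse = "")
  substr(body, 101, 105) <- "GTGTG"
  metas <- list(list(gene_id = "gA", sequence = body))
  flanks <- data.frame(gene_id = "gA",
                       upstream_flank = strrep("A", 260),
                       downstream_flank = strrep("C", 260),
                       stringsAsFactors = FALSE)
  pool <- assemble_pool(metas, flanks)
  man <- pool$manifest
  expect_true(all(nchar(man$variable_seq) == 260))
  expect_true(all(nchar(man$full_seq) == 300))   # 260 + 2 x 20
  expect_false(any(duplicated(man$oligo_id)))

  wt <- man[!man$is_mutant, ]
  expect_true(all(diff(wt$start) == 6))
  # coverage: every meta position covered by >= 1 tile
  covered <- rep(FALSE, 300)
  for (s in wt$start) {
    idx <- intersect(seq_len(300), (s + 1):(s + 260))
    covered[idx] <- TRUE
  }
  expect_true(all(covered))

  mut <- man[man$is_mutant, ]
  expect_identical(nrow(mut), sum(wt$motif_hits != ""))
  # companions differ from partners only inside motif spans
  for (i in seq_len(nrow(mut))) {
    partner <- man[man$oligo_id == mut$companion_id[i], ]
    hits <- decode_hits(partner$motif_hits)[[1]]
    a <- strsplit(partner$variable_seq, "")[[1]]
    b <- strsplit(mut$variable_seq[i], "")[[1]]
    inside <- unique(unlist(mapply(function(s, e) (s + 1):e, hits$start,
                                   hits$end, SIMPLIFY = FALSE)))
    expect_true(all(a[inside] != b[inside]))
    expect_identical(a[-inside], b[-inside])
    expect_identical(nrow(find_motifs(mut$variable_seq[i])), 0L)
  }
  # motif-free tiles have no companion
  expect_true(all(is.na(wt$companion_id[wt$motif_hits == ""])))

  # manifest + FASTA round trip
  tmp <- tempfile(fileext = ".fa")
  write_fasta(pool$sequences, tmp)
  expect_identical(read_fasta(tmp), pool$sequences)
})
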