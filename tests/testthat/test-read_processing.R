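test_that("adapter trimming removes prefixes within the mismatch budget", {
  fa <- mpra_fwd_adapter(); ra <- mpra_rev_adapter()
  payload <- "ACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGT"
  # exact, 2 mismatches (kept), 3 mismatches (rejected), short read
  f1 <- paste0(fa, payload)
  f2 <- paste0(sub("^GGC", "TTC", fa), payload)       # 2 mismatches
  f3 <- paste0(sub("^GGCG", "TTTT", fa), payload)     # 4 mismatches
  f4 <- substr(fa, 1, 10)
  rv <- paste0(ra, payload)
  out <- trim_adapters(c(f1, f2, f3, f4), rep(rv, 4))
  expect_identical(out$keep, c(TRUE, TRUE, FALSE, FALSE))
  expect_identical(out$fwd, rep(payload, 2))
  expect_identical(out$rev, rep(payload, 2))
  expect_identical(out$n_rejected, 2L)
})

test_that("UMI extraction takes the leading bases of the reverse read", {
  out <- extract_umi(c("ACGTACGTNNNGGG", "ACGTACGTA"), umi_len = 8)
  expect_identical(out$umi, c("ACGTACGT", "ACGTACGT"))
  expect_identical(out$remainder, c("NNNGGG", "A"))
  # N kept as a literal symbol
  outN <- extract_umi("ACGTNCGTAAA", umi_len = 8)
  expect_identical(outN$umi, "ACGTNCGT")
  # degenerate zero-length UMI -> read counting
  out0 <- extract_umi("ACGT", umi_len = 0)
  expect_identical(out0$umi, "")
  expect_identical(out0$remainder, "ACGT")
  # too-short reads flagged
  expect_identical(extract_umi("ACGT", umi_len = 8)$keep, FALSE)
})

test_that("assignment returns the unique best oligo and refuses ties", {
  pool <- tiny_pool(4)
  v <- pool$variable_seq
  fwd <- substr(v, 1, 100)
  rev <- substr(revcomp(v), 1, 100)
  index <- oligo_index(pool)
  expect_identical(assign_to_oligo(fwd, rev, index), pool$oligo_id)

  # a read matching two references equally well is unassigned:
  # duplicate reference sequences create a forced tie
  pool2 <- pool
  pool2$variable_seq[2] <- pool2$variable_seq[1]
  idx2 <- oligo_index(pool2)
  hit <- assign_to_oligo(fwd[1], rev[1], idx2)
  expect_true(is.na(hit))
  # other oligos unaffected
  expect_identical(assign_to_oligo(fwd[3], rev[3], idx2), pool$oligo_id[3])

  # discordant mates (fwd from one oligo, rev from another) -> unassigned
  expect_true(is.na(assign_to_oligo(fwd[1], rev[2], index)))

  # empty index errors
  expect_error(oligo_index(pool[0, ]), "empty")
})

test_that("wild-type/mutant companions are distinguished when the motif is sequenced", {
  set.seed(21)
  # A/C body: no chance motif occurrences outside the planted one
  var <- paste(sample(c("A", "C"), 260, TRUE), collapse = "")
  substr(var, 21, 25) <- "GTGTG"   # motif near 5' end: covered by fwd mate
  hits <- find_motifs(var)
  mut <- mutate_motifs(var, hits)
  pool <- data.frame(oligo_id = c("wt", "mut"), gene_id = "g", start = 0L,
                     variable_seq = c(var, mut),
                     full_seq = "", motif_hits = "", is_mutant = c(FALSE, TRUE),
                     companion_id = c("mut", "wt"), stringsAsFactors = FALSE)
  index <- oligo_index(pool)
  fwd <- substr(pool$variable_seq, 1, 105)
  rev <- substr(revcomp(pool$variable_seq), 1, 107)
  expect_identical(assign_to_oligo(fwd, rev, index), c("wt", "mut"))

  # motif outside both sequenced ends -> the mates cannot distinguish the
  # pair and the tie rule leaves the read unassigned
  var2 <- var
  substr(var2, 21, 25) <- "AAAAA"
  substr(var2, 131, 135) <- "GTGTG"  # inside the unsequenced middle
  mut2 <- mutate_motifs(var2, find_motifs(var2))
  pool2 <- pool
  pool2$variable_seq <- c(var2, mut2)
  idx2 <- oligo_index(pool2)
  fwd2 <- substr(pool2$variable_seq, 1, 105)
  rev2 <- substr(revcomp(pool2$variable_seq), 1, 107)
  expect_true(all(is.na(assign_to_oligo(fwd2, rev2, idx2))))
})

test_that("UMI counting deduplicates exactly and keeps explicit zeros", {
  a <- data.frame(
    oligo_id = c(rep("o1", 5), "o2"),
    umi = c("AAAAAAAA", "AAAAAAAA", "CCCCCCCC", "CCCCCCCC", "GGGGGGGG",
            "TTTTTTTT"),
    sample = "s1", stringsAsFactors = FALSE)
  counts <- count_umis(a, c("o1", "o2", "o3"), c("s1", "s2"))
  expect_identical(counts["o1", "s1"], 3L)
  expect_identical(counts["o2", "s1"], 1L)
  expect_identical(counts["o3", "s1"], 0L)   # zero row kept
  expect_true(all(counts[, "s2"] == 0L))

  # saturation: distinct UMIs cannot exceed 4^umi_len
  many <- data.frame(oligo_id = "o1",
                     umi = sample(c("A", "C", "G", "T"), 500, TRUE),
                     sample = "s1", stringsAsFactors = FALSE)
  expect_lte(count_umis(many, "o1", "s1")[1, 1], 4L)
})

test_that("processing bookkeeping partitions every input pair", {
  cfg <- sim_config(seed = 31, read_depth = 5000, seq_error_rate = 0.01,
                    replicates = 1)
  pool <- tiny_pool(5)
  ot <- data.frame(oligo_id = pool$oligo_id, planted_delta_lr = 0,
                   planted_affinity = 1, planted_halflife_wt = 12,
                   planted_halflife_ko = 12)
  od <- withr::local_tempdir()
  sheet <- gen_mpra_reads(pool, ot, cfg, od)
  index <- oligo_index(pool)
  pr <- process_fastq_pair(sheet$fastq1[1], sheet$fastq2[1], index, "s")
  lg <- pr$log
  expect_identical(lg$n_total, 5000L)
  expect_identical(lg$n_rejected + lg$n_unassigned + lg$n_assigned,
                   lg$n_total)
  expect_identical(nrow(pr$assignments), lg$n_assigned)
})

test_that("assignment accuracy is total without errors and >=95% at 0.5% error", {
  pool <- tiny_pool(40)   # companion-free pool: pure error-tolerance check
  ot <- data.frame(oligo_id = pool$oligo_id, planted_delta_lr = 0,
                   planted_affinity = 1, planted_halflife_wt = 12,
                   planted_halflife_ko = 12)
  od <- withr::local_tempdir()

  cfg0 <- sim_config(seed = 17, read_depth = 4000, seq_error_rate = 0,
                     replicates = 1)
  sheet <- gen_mpra_reads(pool, ot, cfg0, od)
  q0 <- quantify_samples(sheet[1, ], pool)
  expect_identical(q0$log$n_assigned, 4000L)   # 100% on clean reads

  cfg5 <- sim_config(seed = 17, read_depth = 20000,
                     seq_error_rate = 0.005, replicates = 1)
  sheet5 <- gen_mpra_reads(pool, ot, cfg5, od)
  q5 <- quantify_samples(sheet5[1, ], pool)
  retained <- q5$log$n_total - q5$log$n_rejected
  expect_gte(q5$log$n_assigned / retained, 0.95)
})
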