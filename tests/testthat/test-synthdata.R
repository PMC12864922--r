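test_that("config validation catches bad probabilities, counts and rates", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(frac_occupied = 1.5), "frac_occupied")
  expect_error(sim_config(seq_error_rate = -0.1), "seq_error_rate")
  expect_error(sim_config(read_depth = -5), "read_depth")
  expect_error(sim_config(read_depth = 10.5), "read_depth")
  expect_error(sim_config(halflife_wt_h = 0), "half-lives")
  expect_error(sim_config(replicates = -1), "replicates")
})

test_that("UTR generation plants verifiable motifs and is deterministic", {
  cfg <- sim_config(seed = 11, n_target_utrs = 6, n_background_utrs = 4)
  u1 <- gen_utr_set(cfg)
  u2 <- gen_utr_set(cfg)
  expect_identical(u1, u2)   # same seed, byte-identical outputs

  targets <- u1$truth_genes$gene_id[u1$truth_genes$is_target]
  for (g in targets) {
    hits <- find_motifs(u1$utrs[[g]])
    expect_gte(nrow(hits), 3)   # motifs_per_target planted occurrences
    tm <- u1$truth_motifs[u1$truth_motifs$gene_id == g, ]
    # every recorded position matches an independent string scan
    expect_true(all(paste(tm$motif, tm$start) %in%
                      paste(hits$motif, hits$start)))
    # and every scanned occurrence is recorded
    expect_true(all(paste(hits$motif, hits$start) %in%
                      paste(tm$motif, tm$start)))
  }
  pl <- u1$truth_motifs[u1$truth_motifs$planted, ]
  expect_setequal(unique(pl$structural_context[pl$occupied]),
                  "single_stranded")
  expect_setequal(unique(pl$structural_context[!pl$occupied]), "paired")

  # empty target case
  u0 <- gen_utr_set(sim_config(seed = 2, n_target_utrs = 0,
                               n_background_utrs = 5))
  expect_true(all(grepl("^bg", names(u0$utrs))))
  expect_false(any(u0$truth_motifs$planted))

  # sizing error
  expect_error(gen_utr_set(sim_config(utr_length = 150,
                                      motifs_per_target = 3)),
               "too short")
})

test_that("fractionation counts follow the planted localization model", {
  cfg <- sim_config(seed = 3, n_target_utrs = 10, n_background_utrs = 40)
  u <- gen_utr_set(cfg)
  fr <- gen_fractionation_counts(cfg, u$truth_genes)
  expect_identical(dim(fr$counts), c(50L, 12L))
  expect_true(all(fr$counts >= 0))

  # null case: no planted effect anywhere -> mean delta within 3 SE of 0
  tg0 <- u$truth_genes
  tg0$planted_delta_lr <- 0
  fr0 <- gen_fractionation_counts(cfg, tg0)
  dlr0 <- delta_lr_test(compute_lr(normalize_counts(fr0$counts),
                                   fr0$samples))
  se <- sd(dlr0$delta_lr) / sqrt(nrow(dlr0))
  expect_lt(abs(mean(dlr0$delta_lr)), 3 * se + 1e-6)

  # single replicate: table valid, downstream p flagged NA
  cfg1 <- sim_config(seed = 3, n_target_utrs = 2, n_background_utrs = 2,
                     replicates = 1)
  u1 <- gen_utr_set(cfg1)
  fr1 <- gen_fractionation_counts(cfg1, u1$truth_genes)
  dlr1 <- delta_lr_test(compute_lr(normalize_counts(fr1$counts),
                                   fr1$samples))
  expect_true(all(is.na(dlr1$p_value)))
  expect_true(all(is.finite(dlr1$delta_lr)))
})

test_that("planted gene-level delta-LR is recovered by the pipeline", {
  # sparse-effect recovery design: 10 affected genes out of 100,
  # 3 replicates, NB dispersion 0.1, ~1e6 reads per library
  ests <- vapply(1:10, function(sd) {
    cfg <- sim_config(seed = sd, n_target_utrs = 10,
                      n_background_utrs = 90)
    u <- gen_utr_set(cfg)
    fr <- gen_fractionation_counts(cfg, u$truth_genes)
    dlr <- delta_lr_test(compute_lr(normalize_counts(fr$counts),
                                    fr$samples))
    tgt <- dlr$feature_id %in%
      u$truth_genes$gene_id[u$truth_genes$is_target]
    mean(dlr$delta_lr[tgt])
  }, numeric(1))
  expect_true(all(ests > 3.5 & ests < 4.5))
  expect_lt(abs(mean(ests) - 4), 0.3)
})

test_that("MPRA read simulation writes valid, assignable FASTQ pairs", {
  cfg <- sim_config(seed = 8, n_target_utrs = 2, n_background_utrs = 1,
                    read_depth = 4000, seq_error_rate = 0,
                    replicates = 1)
  u <- gen_utr_set(cfg)
  pool <- tiny_pool(6)
  ot <- data.frame(oligo_id = pool$oligo_id, n_occupied = 0, n_paired = 0,
                   planted_delta_lr = 0, planted_affinity = 1,
                   planted_halflife_wt = 12, planted_halflife_ko = 12,
                   stringsAsFactors = FALSE)
  od <- withr::local_tempdir()
  sheet <- gen_mpra_reads(pool, ot, cfg, od)
  expect_identical(nrow(sheet), 4L)   # 2 compartments x 2 genotypes x 1 rep

  r1 <- read_fastq(sheet$fastq1[1])
  r2 <- read_fastq(sheet$fastq2[1])
  expect_identical(nrow(r1), 4000L)   # multinomial conserves depth exactly
  expect_identical(r1$id, r2$id)      # mate ids match
  expect_true(all(nchar(r1$seq) == cfg$read_len))
  expect_true(all(startsWith(r1$seq, mpra_fwd_adapter())))
  expect_true(all(startsWith(r2$seq, mpra_rev_adapter())))

  # error-free reads reconstruct their source oligo exactly
  tr <- trim_adapters(r1$seq, r2$seq)
  um <- extract_umi(tr$rev, cfg$umi_length)
  expect_true(all(tr$keep))
  prefixes <- substr(pool$variable_seq, 1, nchar(tr$fwd[1]))
  expect_true(all(tr$fwd %in% prefixes))
  rc_suffix <- substr(revcomp(pool$variable_seq), 1,
                      nchar(um$remainder[1]))
  expect_true(all(um$remainder %in% rc_suffix))

  # read_depth 0 -> empty files; empty pool -> error
  cfg0 <- sim_config(seed = 8, read_depth = 0, replicates = 1)
  sheet0 <- gen_mpra_reads(pool, ot, cfg0, od)
  expect_identical(nrow(read_fastq(sheet0$fastq1[1])), 0L)
  expect_error(gen_mpra_reads(pool[0, ], ot[0, ], cfg, od), "empty")
})

test_that("binding assay emits input plus one bound file per concentration and replicate", {
  cfg <- sim_config(seed = 9, rbns_depth = 2000, replicates = 2,
                    seq_error_rate = 0)
  pool <- tiny_pool(3)
  ot <- data.frame(oligo_id = pool$oligo_id, planted_affinity = c(1, 2, 4))
  od <- withr::local_tempdir()
  sheet <- gen_rbns_reads(pool, ot, cfg, od)
  # 3 concentrations -> 3 bound + 1 input, per replicate (duplicate)
  expect_identical(sum(sheet$role == "input"), 2L)
  expect_identical(sum(sheet$role == "bound"), 6L)
  expect_setequal(unique(sheet$concentration[sheet$role == "bound"]),
                  c(500, 50, 5))
  expect_identical(nrow(read_fastq(sheet$fastq1[1])), 2000L)
})

test_that("labeling simulation controls conversions as configured", {
  pool <- tiny_pool(2)
  ot <- data.frame(oligo_id = pool$oligo_id, planted_affinity = 1,
                   planted_halflife_wt = c(12, 1e9),
                   planted_halflife_ko = c(12, 1e9))
  od <- withr::local_tempdir()

  # zero conversion rates -> zero T>C mismatches anywhere
  cfg0 <- sim_config(seed = 4, conversion_rate_labeled = 0,
                     background_conversion_rate = 0, seq_error_rate = 0,
                     slam_depth_per_oligo = 50)
  sheet <- gen_slam_reads(pool, ot, cfg0, od)
  index <- oligo_index(pool)
  for (s in seq_len(nrow(sheet))) {
    pr <- process_fastq_pair(sheet$fastq1[s], sheet$fastq2[s], index,
                             sheet$sample[s], tc_aware = TRUE,
                             keep_seqs = TRUE)
    cc <- count_conversions(pr, pool)
    expect_true(all(cc$n_TC == 0))
    expect_true(all(cc$n_T > 0))
  }

  # infinite half-life -> stability ratio ~ 1
  cfg1 <- sim_config(seed = 4, seq_error_rate = 0,
                     slam_depth_per_oligo = 400)
  sheet1 <- gen_slam_reads(pool, ot, cfg1, od)
  conv <- lapply(seq_len(nrow(sheet1)), function(s) {
    pr <- process_fastq_pair(sheet1$fastq1[s], sheet1$fastq2[s], index,
                             sheet1$sample[s], max_mismatch = 10,
                             tc_aware = TRUE, keep_seqs = TRUE)
    count_conversions(pr, pool)
  })
  names(conv) <- sheet1$sample
  st <- stability_ratio(conv[["slam_WT_t0"]], conv[["slam_WT_t12"]])
  expect_lt(abs(st$stability_ratio[2] - 1), 0.1)   # halflife -> Inf
  expect_lt(abs(st$stability_ratio[1] - 0.5), 0.1) # halflife 12 at t=12
})

test_that("CLIP features pile reads over occupied motifs", {
  cfg <- sim_config(seed = 6, n_target_utrs = 10, n_background_utrs = 10)
  u <- gen_utr_set(cfg)
  clip <- gen_clip_features(u$truth_motifs, nchar(u$utrs), cfg)
  occ <- u$truth_motifs[u$truth_motifs$planted & u$truth_motifs$occupied, ]
  expect_identical(nrow(clip$peaks), nrow(occ))
  # every occupied motif lies inside >= 1 peak
  for (i in seq_len(nrow(occ))) {
    pk <- clip$peaks[clip$peaks$chrom == occ$gene_id[i], ]
    expect_true(any(pk$start <= occ$start[i] & pk$end >= occ$end[i]))
  }
  expect_true(all(clip$peaks$start < clip$peaks$end))
  expect_true(all(clip$reads$start < clip$reads$end))

  # read density (reads/kb) inside peaks well above outside
  n_in <- n_out <- len_in <- len_out <- 0
  for (g in names(u$utrs)) {
    pk <- clip$peaks[clip$peaks$chrom == g, ]
    rd <- clip$reads[clip$reads$chrom == g, ]
    L <- nchar(u$utrs[[g]])
    hit <- if (nrow(pk) == 0) rep(FALSE, nrow(rd)) else {
      vapply(seq_len(nrow(rd)), function(i) {
        any(pk$start < rd$end[i] & pk$end > rd$start[i])
      }, logical(1))
    }
    pl <- sum(pk$end - pk$start)
    n_in <- n_in + sum(hit); n_out <- n_out + sum(!hit)
    len_in <- len_in + pl; len_out <- len_out + (L - pl)
  }
  fold <- (n_in / len_in) / (n_out / len_out)
  expect_gt(fold, 4)   # configured 13-fold, generous sampling margin
  # frac_occupied = 0 -> no peaks at all
  u0 <- gen_utr_set(sim_config(seed = 6, frac_occupied = 0,
                               n_target_utrs = 5, n_background_utrs = 0))
  clip0 <- gen_clip_features(u0$truth_motifs, nchar(u0$utrs), cfg)
  expect_identical(nrow(clip0$peaks), 0L)
})
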