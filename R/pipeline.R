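#' Default pipeline configuration
#'
#' Nested parameter blocks for every stage, all defaults as documented in
#' the stage functions. The pool block selects how many simulated target
#' and background UTRs enter the reporter pool (the full UTR set is used
#' for the gene-level analyses).
#'
#' @param seed master seed forwarded to the simulation block.
#' @return validated config of class `pipeline_config`.
#' @export
default_config <- function(seed = 1) {
  validate_config(list(
    sim = list(seed = seed),
    pool = list(n_target = 9, n_background = 6, tile_len = 260, step = 6,
                flank = 260),
    quantify = list(umi_len = 8, max_mismatch = 2),
    localize = list(pseudocount = 0.5, window = 5, method = "welch",
                    fdr_threshold = 0.05),
    fold = list(window = 80, slide = 10),
    rbns = list(min_input = 10),
    slam = list(min_T = 200, max_mismatch = 10)))
}

#' Validate a raw configuration list
#'
#' Fills defaults, rejects unknown keys, and reports every violation at
#' once. The `sim` block is validated by [sim_config()].
#'
#' @param raw a (possibly partial) nested list.
#' @return config of class `pipeline_config`.
#' @export
validate_config <- function(raw) {
  if (is.null(raw)) raw <- list()
  stopifnot(is.list(raw))
  defaults <- list(
    sim = list(),
    pool = list(n_target = 9, n_background = 6, tile_len = 260, step = 6,
                flank = 260),
    quantify = list(umi_len = 8, max_mismatch = 2),
    localize = list(pseudocount = 0.5, window = 5, method = "welch",
                    fdr_threshold = 0.05),
    fold = list(window = 80, slide = 10),
    rbns = list(min_input = 10),
    slam = list(min_T = 200, max_mismatch = 10))
  errs <- character(0)
  unknown_blocks <- setdiff(names(raw), names(defaults))
  if (length(unknown_blocks) > 0) {
    errs <- c(errs, paste0("unknown config block(s): ",
                           paste(unknown_blocks, collapse = ", ")))
  }
  cfg <- defaults
  for (b in intersect(names(raw), names(defaults))) {
    if (b == "sim") {
      bad <- setdiff(names(raw$sim), names(formals(sim_config)))
      if (length(bad) > 0) {
        errs <- c(errs, paste0("unknown sim key(s): ",
                               paste(bad, collapse = ", ")))
      } else {
        cfg$sim <- raw$sim
      }
      next
    }
    bad <- setdiff(names(raw[[b]]), names(defaults[[b]]))
    if (length(bad) > 0) {
      errs <- c(errs, paste0("unknown ", b, " key(s): ",
                             paste(bad, collapse = ", ")))
    }
    for (k in intersect(names(raw[[b]]), names(defaults[[b]]))) {
      cfg[[b]][[k]] <- raw[[b]][[k]]
    }
  }
  sim <- tryCatch(do.call(sim_config, cfg$sim),
                  error = function(e) {
                    errs <<- c(errs, conditionMessage(e))
                    NULL
                  })
  for (k in c("n_target", "n_background", "tile_len", "step", "flank")) {
    if (!is.numeric(cfg$pool[[k]]) || cfg$pool[[k]] < 0) {
      errs <- c(errs, paste0("pool$", k, " must be a non-negative number"))
    }
  }
  if (length(errs) > 0) {
    stop("invalid configuration:\n  ", paste(errs, collapse = "\n  "))
  }
  cfg$sim_config <- sim
  structure(cfg, class = "pipeline_config")
}

#' Write / read a pipeline configuration
#' @param config a `pipeline_config`.
#' @param path file path (human-readable R expression text).
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  x$sim_config <- NULL
  dput(x, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("missing config file: ", path)
  validate_config(dget(path))
}

.load_tsv <- function(outdir, name) {
  path <- file.path(outdir, name)
  if (!file.exists(path)) {
    stop("missing pipeline input: ", path,
         " (run the earlier stages first)")
  }
  read_tsv(path)
}

.load_counts <- function(outdir, name) {
  df <- .load_tsv(outdir, name)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

.save_counts <- function(m, outdir, name) {
  df <- data.frame(feature_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, file.path(outdir, name))
}

#' Pipeline stage: simulate all raw inputs
#'
#' Emits the UTR set (FASTA + metadata + ground truth), fractionation
#' counts, and CLIP peak/read intervals into `outdir`.
#'
#' @param config a `pipeline_config`.
#' @param outdir output directory (created).
#' @return invisibly, the list of generated objects.
#' @export
stage_simulate <- function(config, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  cfg <- config$sim_config
  u <- gen_utr_set(cfg)
  write_fasta(u$utrs, file.path(outdir, "utrs.fa"))
  write_tsv(u$metadata, file.path(outdir, "utr_metadata.tsv"))
  write_tsv(u$truth_genes, file.path(outdir, "truth_genes.tsv"))
  write_tsv(u$truth_motifs, file.path(outdir, "truth_motifs.tsv"))
  fr <- gen_fractionation_counts(cfg, u$truth_genes)
  .save_counts(fr$counts, outdir, "fractionation_counts.tsv")
  write_tsv(fr$samples, file.path(outdir, "fractionation_samples.tsv"))
  clip <- gen_clip_features(u$truth_motifs, nchar(u$utrs), cfg)
  write_bed(clip$peaks, file.path(outdir, "clip_peaks.bed"))
  write_bed(clip$reads, file.path(outdir, "clip_reads.bed"))
  invisible(list(utrs = u, fractionation = fr, clip = clip))
}

#' Pipeline stage: gene-level localization, 5-mer and CLIP analyses
#'
#' Computes gene localization ratios and genotype differences from the
#' fractionation counts, then asks what distinguishes the UTRs of genes
#' that become more neurite-enriched on knockout: 5-mer enrichment
#' against insensitive UTRs and CLIP peak/read-density comparisons.
#'
#' @inheritParams stage_simulate
#' @return invisibly, list(gene_dlr, kmers, clip_groups).
#' @export
stage_gene_level <- function(config, outdir) {
  counts <- .load_counts(outdir, "fractionation_counts.tsv")
  samples <- .load_tsv(outdir, "fractionation_samples.tsv")
  meta <- .load_tsv(outdir, "utr_metadata.tsv")
  loc <- config$localize
  rel <- normalize_counts(counts, loc$pseudocount)
  lr <- compute_lr(rel, samples)
  dlr <- delta_lr_test(lr, method = loc$method)
  write_tsv(dlr, file.path(outdir, "gene_delta_lr.tsv"))
  up <- dlr$feature_id[!is.na(dlr$fdr) & dlr$fdr < loc$fdr_threshold &
                         dlr$delta_lr > 0]
  meta1 <- meta[!duplicated(meta$gene_id), , drop = FALSE]
  seqs <- setNames(meta1$sequence, meta1$gene_id)
  kmers <- NULL
  if (length(up) > 0 && length(up) < length(seqs)) {
    kmers <- kmer_enrichment(seqs[names(seqs) %in% up],
                             seqs[!names(seqs) %in% up])
    write_tsv(kmers, file.path(outdir, "kmer_enrichment.tsv"))
  }
  peaks <- read_bed(file.path(outdir, "clip_peaks.bed"))
  reads <- read_bed(file.path(outdir, "clip_reads.bed"))
  utrs <- data.frame(gene_id = names(seqs), length = nchar(seqs),
                     group = ifelse(names(seqs) %in% up, "lr_up", "other"),
                     stringsAsFactors = FALSE)
  clip_groups <- clip_overlap_stats(utrs, peaks, reads,
                                    control_group = "other")
  write_tsv(clip_groups$groups, file.path(outdir, "clip_group_stats.tsv"))
  invisible(list(gene_dlr = dlr, kmers = kmers,
                 clip_groups = clip_groups))
}

#' Pipeline stage: design the tiling reporter pool
#'
#' Filters the UTR records, merges isoforms per gene into meta-UTRs, and
#' tiles a subset of genes (`pool$n_target` targets, `pool$n_background`
#' backgrounds) into the oligo pool with mutant companions and handles.
#'
#' @inheritParams stage_simulate
#' @return invisibly, the pool list from [assemble_pool()].
#' @export
stage_design <- function(config, outdir) {
  meta <- .load_tsv(outdir, "utr_metadata.tsv")
  meta$tags[is.na(meta$tags)] <- ""
  p <- config$pool
  flt <- filter_utrs(meta)
  write_tsv(flt$rejected, file.path(outdir, "design_rejections.tsv"))
  keep <- flt$retained
  genes <- unique(keep$gene_id)
  pick <- c(head(grep("^tgt", genes, value = TRUE), p$n_target),
            head(grep("^bg", genes, value = TRUE), p$n_background))
  metas <- lapply(pick, function(g) {
    merge_meta_utr(keep[keep$gene_id == g, , drop = FALSE])
  })
  flanks <- keep[!duplicated(keep$gene_id),
                 c("gene_id", "upstream_flank", "downstream_flank")]
  pool <- assemble_pool(metas, flanks, tile_len = p$tile_len,
                        step = p$step, flank = p$flank)
  write_tsv(pool$manifest, file.path(outdir, "pool_manifest.tsv"))
  write_fasta(pool$sequences, file.path(outdir, "pool.fa"))
  invisible(pool)
}

.read_manifest <- function(outdir) {
  m <- .load_tsv(outdir, "pool_manifest.tsv")
  m$motif_hits[is.na(m$motif_hits)] <- ""
  m$companion_id[is.na(m$companion_id)] <- NA_character_
  m
}

#' Pipeline stage: simulate and quantify the MPRA
#'
#' Generates reporter amplicon reads per compartment/genotype/replicate,
#' quantifies unique-UMI counts per oligo, and computes oligo-level
#' localization ratios, genotype differences and the positional rolling
#' profile of the first target gene.
#'
#' @inheritParams stage_simulate
#' @return invisibly, list(counts, log, oligo_dlr, profile).
#' @export
stage_mpra <- function(config, outdir) {
  manifest <- .read_manifest(outdir)
  truth_motifs <- .load_tsv(outdir, "truth_motifs.tsv")
  cfg <- config$sim_config
  otruth <- oligo_truth(manifest, truth_motifs, cfg)
  write_tsv(otruth, file.path(outdir, "oligo_truth.tsv"))
  sheet <- gen_mpra_reads(manifest, otruth, cfg,
                          file.path(outdir, "fastq_mpra"))
  q <- quantify_samples(sheet, manifest, config$quantify$umi_len,
                        config$quantify$max_mismatch)
  .save_counts(q$counts, outdir, "mpra_counts.tsv")
  write_tsv(q$log, file.path(outdir, "mpra_log.tsv"))
  write_tsv(q$samples, file.path(outdir, "mpra_samples.tsv"))
  loc <- config$localize
  rel <- normalize_counts(q$counts, loc$pseudocount)
  lr <- compute_lr(rel, q$samples)
  dlr <- delta_lr_test(lr, method = loc$method)
  write_tsv(dlr, file.path(outdir, "oligo_delta_lr.tsv"))
  g1 <- grep("^tgt", manifest$gene_id, value = TRUE)[1]
  wt <- manifest[manifest$gene_id == g1 & !manifest$is_mutant, ,
                 drop = FALSE]
  prof <- rolling_profile(wt$start,
                          dlr$delta_lr[match(wt$oligo_id,
                                             dlr$feature_id)],
                          loc$window)
  write_tsv(prof, file.path(outdir, paste0("profile_", g1, ".tsv")))
  invisible(list(counts = q$counts, log = q$log, oligo_dlr = dlr,
                 profile = prof))
}

#' Structure scores for a pool's motif-containing oligos
#'
#' Positional profiles via sliding-window folding, with folding memoised
#' on window sequence (tiles of one gene overlap heavily, so most windows
#' recur across neighbouring oligos). Returns one score per oligo: the
#' mean pairing probability over all its motif positions, plus the
#' motif-level table.
#'
#' @param manifest pool manifest (rows to score; callers usually pass
#'   non-mutant motif-containing oligos).
#' @param window,slide folding geometry (nt).
#' @param backend see [fold_window()].
#' @return list with `scores` (named vector per oligo) and `motifs`
#'   (per-motif table from [motif_pair_prob()] with oligo_id).
#' @export
pool_structure_scores <- function(manifest, window = 80, slide = 10,
                                  backend = mccaskill_backend()) {
  cache <- new.env(parent = emptyenv())
  fold_sums <- function(wseq) {
    v <- cache[[wseq]]
    if (is.null(v)) {
      v <- rowSums(fold_window(wseq, backend))
      cache[[wseq]] <- v
    }
    v
  }
  hits_list <- decode_hits(manifest$motif_hits)
  scores <- rep(NA_real_, nrow(manifest))
  motif_rows <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    hits <- hits_list[[i]]
    if (nrow(hits) == 0) next
    seq <- manifest$variable_seq[i]
    n <- nchar(seq)
    starts <- seq.int(0, n - window, by = slide)
    if (starts[length(starts)] + window < n) starts <- c(starts, n - window)
    acc <- numeric(n); cov <- numeric(n)
    for (s0 in starts) {
      v <- fold_sums(substr(seq, s0 + 1, s0 + window))
      idx <- (s0 + 1):(s0 + window)
      acc[idx] <- acc[idx] + v
      cov[idx] <- cov[idx] + 1
    }
    prof <- acc / cov
    mp <- motif_pair_prob(prof, hits)
    mp <- cbind(data.frame(oligo_id = manifest$oligo_id[i],
                           stringsAsFactors = FALSE), mp)
    motif_rows[[i]] <- mp
    scores[i] <- mean(mp$mean_pair_prob)
  }
  keep <- !vapply(motif_rows, is.null, logical(1))
  list(scores = setNames(scores, manifest$oligo_id)[keep],
       motifs = if (any(keep)) do.call(rbind, motif_rows[keep]) else NULL)
}

#' Pipeline stage: fold the pool and score motif structural context
#'
#' @inheritParams stage_simulate
#' @return invisibly, the [pool_structure_scores()] result.
#' @export
stage_structure <- function(config, outdir) {
  manifest <- .read_manifest(outdir)
  sel <- manifest[!manifest$is_mutant & manifest$motif_hits != "", ,
                  drop = FALSE]
  res <- pool_structure_scores(sel, config$fold$window, config$fold$slide)
  write_tsv(data.frame(oligo_id = names(res$scores),
                       motif_pair_prob = unname(res$scores),
                       stringsAsFactors = FALSE),
            file.path(outdir, "structure_scores.tsv"))
  write_tsv(res$motifs, file.path(outdir, "structure_motifs.tsv"))
  invisible(res)
}

#' Pipeline stage: simulate and quantify the binding assay
#'
#' @inheritParams stage_simulate
#' @return invisibly, list(r, concordance, trend).
#' @export
stage_rbns <- function(config, outdir) {
  manifest <- .read_manifest(outdir)
  truth_motifs <- .load_tsv(outdir, "truth_motifs.tsv")
  cfg <- config$sim_config
  otruth <- oligo_truth(manifest, truth_motifs, cfg)
  sheet <- gen_rbns_reads(manifest, otruth, cfg,
                          file.path(outdir, "fastq_rbns"))
  q <- quantify_samples(sheet, manifest, config$quantify$umi_len,
                        config$quantify$max_mismatch)
  .save_counts(q$counts, outdir, "rbns_counts.tsv")
  write_tsv(q$log, file.path(outdir, "rbns_log.tsv"))
  rr <- compute_r(q$counts, q$samples, config$rbns$min_input)
  .save_counts(rr$r, outdir, "rbns_r.tsv")
  write_tsv(data.frame(oligo_id = names(rr$mean_r),
                       mean_r = unname(rr$mean_r),
                       stringsAsFactors = FALSE),
            file.path(outdir, "rbns_mean_r.tsv"))
  conc <- concentration_concordance(rr$r)
  .save_counts(conc$rho, outdir, "rbns_concordance.tsv")
  mc <- setNames(vapply(decode_hits(manifest$motif_hits), nrow,
                        integer(1)), manifest$oligo_id)
  mc[manifest$is_mutant] <- 0L
  trend <- r_by_motif_count(rr$mean_r, mc)
  write_tsv(trend$bins, file.path(outdir, "rbns_motif_trend.tsv"))
  invisible(list(r = rr, concordance = conc, trend = trend))
}

#' Pipeline stage: simulate and quantify RNA stability
#'
#' @inheritParams stage_simulate
#' @return invisibly, list(conversions, stability, delta).
#' @export
stage_slam <- function(config, outdir) {
  manifest <- .read_manifest(outdir)
  truth_motifs <- .load_tsv(outdir, "truth_motifs.tsv")
  cfg <- config$sim_config
  otruth <- oligo_truth(manifest, truth_motifs, cfg)
  sheet <- gen_slam_reads(manifest, otruth, cfg,
                          file.path(outdir, "fastq_slam"))
  index <- oligo_index(manifest)
  conv <- lapply(seq_len(nrow(sheet)), function(s) {
    pr <- process_fastq_pair(sheet$fastq1[s], sheet$fastq2[s], index,
                             sheet$sample[s],
                             umi_len = config$quantify$umi_len,
                             max_mismatch = config$slam$max_mismatch,
                             tc_aware = TRUE, keep_seqs = TRUE)
    count_conversions(pr, manifest)
  })
  names(conv) <- sheet$sample
  write_tsv(do.call(rbind, conv), file.path(outdir,
                                            "slam_conversions.tsv"))
  t0 <- min(cfg$timepoints_h); t1 <- max(cfg$timepoints_h)
  stab <- lapply(c("WT", "KO"), function(geno) {
    s0 <- sheet$sample[sheet$genotype == geno & sheet$timepoint == t0]
    s1 <- sheet$sample[sheet$genotype == geno & sheet$timepoint == t1]
    stability_ratio(conv[[s0]], conv[[s1]], config$slam$min_T)
  })
  names(stab) <- c("WT", "KO")
  delta <- delta_stability(stab$WT, stab$KO)
  write_tsv(delta, file.path(outdir, "slam_delta_stability.tsv"))
  invisible(list(conversions = conv, stability = stab, delta = delta))
}

#' Pipeline stage: master join and headline contrasts
#'
#' @inheritParams stage_simulate
#' @return invisibly, the [build_master()] result.
#' @export
stage_integrate <- function(config, outdir) {
  manifest <- .read_manifest(outdir)
  dlr <- .load_tsv(outdir, "oligo_delta_lr.tsv")
  mean_r_df <- .load_tsv(outdir, "rbns_mean_r.tsv")
  mean_r <- setNames(mean_r_df$mean_r, mean_r_df$oligo_id)
  dstab <- .load_tsv(outdir, "slam_delta_stability.tsv")
  sc_df <- .load_tsv(outdir, "structure_scores.tsv")
  scores <- setNames(sc_df$motif_pair_prob, sc_df$oligo_id)
  peaks <- read_bed(file.path(outdir, "clip_peaks.bed"))
  res <- build_master(manifest, dlr, mean_r, dstab, scores, peaks)
  write_tsv(res$master, file.path(outdir, "oligo_master.tsv"))
  write_tsv(res$contrasts, file.path(outdir, "contrasts.tsv"))
  invisible(res)
}

#' Run the full pipeline
#'
#' Chains simulate -> gene-level stats -> pool design -> MPRA -> folding
#' -> binding -> stability -> integration, writing every stage's tables
#' into `outdir` plus a manifest of artifacts and a short summary report.
#'
#' @param config a `pipeline_config` (see [default_config()]).
#' @param outdir output directory.
#' @return list with the main result tables (gene_dlr, oligo_dlr, master,
#'   contrasts, ...).
#' @export
run_all <- function(config, outdir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_config(config, file.path(outdir, "config.R"))
  stage_simulate(config, outdir)
  gene <- stage_gene_level(config, outdir)
  stage_design(config, outdir)
  mpra <- stage_mpra(config, outdir)
  fold <- stage_structure(config, outdir)
  rbns <- stage_rbns(config, outdir)
  slam <- stage_slam(config, outdir)
  integ <- stage_integrate(config, outdir)
  files <- list.files(outdir, recursive = FALSE)
  writeLines(files, file.path(outdir, "MANIFEST"))
  summ <- c("pipeline summary",
            sprintf("seed: %d", config$sim_config$seed),
            sprintf("pool oligos: %d",
                    nrow(.read_manifest(outdir))),
            "contrasts:",
            utils::capture.output(print(integ$contrasts,
                                        row.names = FALSE)))
  writeLines(summ, file.path(outdir, "summary.txt"))
  invisible(list(gene_dlr = gene$gene_dlr, kmers = gene$kmers,
                 clip_groups = gene$clip_groups,
                 oligo_dlr = mpra$oligo_dlr, profile = mpra$profile,
                 structure = fold, rbns = rbns, slam = slam,
                 master = integ$master, contrasts = integ$contrasts))
}
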