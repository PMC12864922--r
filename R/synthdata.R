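#' Simulation configuration
#'
#' Builds the validated parameter set that drives every synthetic-data
#' generator. The defaults define the package's desk-scale study
#' conditions: target UTRs carry one planted canonical TDP-43 motif per
#' slot (cycling through GTGTG, TGTGT, GTATG), a `frac_occupied` fraction
#' of planted motifs sit in accessible single-stranded context (these are
#' the in vivo "occupied" sites, covered by CLIP peaks and carrying the
#' localization, binding and stability effects), and the remainder are
#' buried in designed 12-bp hairpin stems. Binding reactions use the
#' three protein concentrations 500, 50 and 5 nM in duplicate; metabolic
#' labeling is chased for 0 and 12 h.
#'
#' @param seed integer; fully determines every emitted byte.
#' @param n_target_utrs,n_background_utrs number of motif-planted and
#'   motif-free 3' UTRs.
#' @param utr_length UTR length (nt); must host `motifs_per_target`
#'   well-separated motif constructs (>= 100 nt per motif).
#' @param motifs_per_target planted motifs per target UTR.
#' @param frac_occupied fraction of planted motifs that are occupied
#'   (single-stranded context + CLIP peak + functional effects).
#' @param read_depth MPRA read pairs per sample.
#' @param seq_error_rate per-base substitution error rate.
#' @param umi_length UMI length in nt (first bases of the reverse read).
#' @param conversion_rate_labeled,background_conversion_rate per-T T>C
#'   conversion probabilities for labeled and unlabeled molecules.
#' @param timepoints_h chase timepoints in hours.
#' @param halflife_wt_h,halflife_ko_h half-life (hours) of occupied-motif
#'   oligos in wild-type and knockout cells; `halflife_other_h` applies to
#'   all other oligos in both genotypes.
#' @param affinity_scale fold change in relative binding affinity per
#'   occupied motif.
#' @param concentrations_nM protein concentrations for the binding assay.
#' @param replicates biological replicates for count-based assays.
#' @param fractionation_delta_lr planted gene-level change in localization
#'   ratio (log2, knockout - wild-type) for target genes.
#' @param fractionation_depth,nb_dispersion mean library size and
#'   negative-binomial dispersion of the fractionation count model.
#' @param mpra_delta_lr_occupied,mpra_delta_lr_paired per-motif
#'   localization-ratio effect (log2) contributed by an intact occupied or
#'   stem-buried planted motif in a reporter oligo.
#' @param rbns_depth read pairs per binding-assay sample.
#' @param slam_depth_per_oligo metabolic-labeling read pairs per oligo per
#'   sample.
#' @param clip_read_rate background CLIP read density (reads per kb);
#'   `clip_enrichment` is the fold elevation inside peaks;
#'   `clip_read_len` the emitted read length.
#' @param read_len sequencer read length for simulated paired-end reads.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_target_utrs = 30, n_background_utrs = 60,
                       utr_length = 300, motifs_per_target = 3,
                       frac_occupied = 0.5,
                       read_depth = 120000, seq_error_rate = 0.002,
                       umi_length = 8,
                       conversion_rate_labeled = 0.05,
                       background_conversion_rate = 0.001,
                       timepoints_h = c(0, 12),
                       halflife_wt_h = 6, halflife_ko_h = 12,
                       halflife_other_h = 24,
                       affinity_scale = 2,
                       concentrations_nM = c(500, 50, 5),
                       replicates = 3,
                       fractionation_delta_lr = 4,
                       fractionation_depth = 1e6, nb_dispersion = 0.1,
                       mpra_delta_lr_occupied = 1.5,
                       mpra_delta_lr_paired = 0.2,
                       rbns_depth = 80000,
                       slam_depth_per_oligo = 100,
                       clip_read_rate = 10, clip_enrichment = 13,
                       clip_read_len = 30,
                       read_len = 150) {
  cfg <- as.list(environment())
  errs <- character(0)
  chk <- function(ok, msg) if (!ok) errs <<- c(errs, msg)
  for (p in c("frac_occupied", "seq_error_rate", "conversion_rate_labeled",
              "background_conversion_rate")) {
    chk(is.numeric(cfg[[p]]) && length(cfg[[p]]) == 1 &&
          cfg[[p]] >= 0 && cfg[[p]] <= 1,
        paste0(p, " must be a probability in [0,1]"))
  }
  for (p in c("n_target_utrs", "n_background_utrs", "utr_length",
              "motifs_per_target", "read_depth", "umi_length",
              "replicates", "rbns_depth", "slam_depth_per_oligo")) {
    chk(is.numeric(cfg[[p]]) && length(cfg[[p]]) == 1 && cfg[[p]] >= 0 &&
          cfg[[p]] == round(cfg[[p]]),
        paste0(p, " must be a non-negative integer count"))
  }
  chk(length(cfg$seed) == 1 && cfg$seed == round(cfg$seed),
      "seed must be an integer")
  chk(all(cfg$timepoints_h >= 0), "timepoints_h must be non-negative")
  chk(all(c(cfg$halflife_wt_h, cfg$halflife_ko_h, cfg$halflife_other_h) > 0),
      "half-lives must be positive")
  chk(all(cfg$concentrations_nM > 0), "concentrations must be positive")
  chk(cfg$affinity_scale > 0, "affinity_scale must be positive")
  chk(cfg$read_len > cfg$umi_length + 60,
      "read_len too short for adapters plus informative sequence")
  if (length(errs) > 0) {
    stop("invalid simulation config:\n  ", paste(errs, collapse = "\n  "))
  }
  structure(cfg, class = "sim_config")
}

# Independent RNG stream per generator so each op is deterministic on its
# own; offsets stay far below .Machine$integer.max.
.seed_for <- function(cfg, offset) {
  set.seed((cfg$seed %% 1000000L) * 1000L + offset)
}

#' @noRd
.ss_context <- function(motif) {
  # the motif alone; accessibility is enforced by scrubbing motif-
  # complementary stacks from the surrounding (otherwise random) body
  motif
}

# Pairing energy (kT, positive = stabilising here) used only by the
# accessibility scrubber below; mirrors the folding backend's pair set.
.pair_e <- function(a, b) {
  k <- paste0(a, b)
  if (k %in% c("GC", "CG")) return(3)
  if (k %in% c("AT", "TA")) return(2)
  if (k %in% c("GT", "TG")) return(1)
  0
}

# Remove body sequence near an accessible (single-stranded) motif that
# could form a stable contiguous stack with it: any antiparallel 2-5 bp
# stack against the motif with every position pairable and summed pair
# energy >= 5 kT (i.e. comparable to the helix-initiation penalty) gets
# one base replaced by a letter that cannot pair its aligned motif base.
# Positions inside planted constructs are never touched. Without this, a
# random complement run within the same fold window occasionally buries a
# motif meant to be accessible; with it, the motif's neighbourhood stays
# unstructured without planting any fixed flank composition (a fixed
# flank would itself become an enriched k-mer in the discovery analyses).
.scrub_accessible <- function(chars, m_start, m_end, protected, reach = 85) {
  mot <- chars[(m_start + 1):m_end]
  L <- length(chars)
  lo <- max(0, m_start - reach)
  hi <- min(L, m_end + reach)
  for (pass in 1:6) {
    changed <- FALSE
    for (len in 2:5) {
      if (len > length(mot)) next
      for (mo in 0:(length(mot) - len)) {
        msub <- mot[(mo + 1):(mo + len)]
        for (bo in lo:(hi - len)) {
          idx <- (bo + 1):(bo + len)
          if (any(protected[idx])) next
          es <- vapply(seq_len(len), function(k) {
            .pair_e(chars[bo + k], msub[len + 1 - k])
          }, numeric(1))
          if (all(es > 0) && sum(es) >= 5) {
            mid <- (len + 1) %/% 2
            partner <- msub[len + 1 - mid]
            # random non-pairing letter, so edits add no composition bias
            pool <- c("A", "C", "G", "T")
            pool <- pool[vapply(pool, function(x) .pair_e(x, partner) == 0,
                                logical(1))]
            chars[bo + mid] <- sample(pool, 1)
            changed <- TRUE
          }
        }
      }
    }
    if (!changed) break
  }
  chars
}

# Wobble-randomised pairing partner of a stem arm: each G pairs C or U,
# each T pairs A or G, so no fixed complement string (which would show up
# as an enriched k-mer across targets) is planted.
.wobble_partner <- function(arm) {
  ch <- rev(strsplit(arm, "")[[1]])
  partner <- vapply(ch, function(b) {
    switch(b,
           G = sample(c("C", "T"), 1, prob = c(0.7, 0.3)),
           C = "G",
           T = sample(c("A", "G"), 1, prob = c(0.7, 0.3)),
           A = "T")
  }, character(1))
  paste(partner, collapse = "")
}

#' @noRd
.stem_context <- function(motif) {
  construct <- NULL
  for (try in 1:20) {
    arm <- paste0(random_dna(1, 4, c("G", "C")), motif,
                  random_dna(1, 3, c("G", "C")))
    partner <- .wobble_partner(arm)
    construct <- paste0(arm, "AAAC", partner)
    # reject arms whose partner happens to contain a canonical motif
    if (nrow(find_motifs(partner)) == 0) break
  }
  construct
}

#' Generate a synthetic 3' UTR set with planted motifs
#'
#' Target UTRs receive `motifs_per_target` planted canonical motifs in
#' well-separated slots (so no 80-nt fold window sees two constructs).
#' Occupied motifs sit in accessible context: their random neighbourhood
#' is scrubbed of motif-complementary stacks, leaving no stable helix the
#' motif could join. The remaining motifs sit inside the 5' arm of a
#' designed 12-bp hairpin stem whose partner arm is wobble-randomised (so
#' no fixed complement k-mer is planted across targets). Background UTRs
#' are plain random sequence; chance motif occurrences anywhere are left in
#' place and recorded as unplanted. Two decoy isoform records (a disallowed
#' tag and a non-conserved polyA site) are appended so the design filters
#' have something to reject.
#'
#' @param cfg a [sim_config()].
#' @return list with `utrs` (named character vector), `metadata`
#'   (data.frame: gene_id, transcript_id, sequence, tags, polya_conserved,
#'   utr_start, utr_end, upstream_flank, downstream_flank), `truth_genes`
#'   (gene_id, is_target, planted_delta_lr) and `truth_motifs` (gene_id,
#'   motif, start, end, planted, occupied, structural_context).
#' @export
gen_utr_set <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  .seed_for(cfg, 101L)
  L <- cfg$utr_length
  m <- cfg$motifs_per_target
  if (m > 0 && cfg$n_target_utrs > 0 && L < 100 * m) {
    stop("utr_length ", L, " too short to host ", m,
         " well-separated motif constructs (need >= ", 100 * m, " nt)")
  }
  genes <- c(if (cfg$n_target_utrs > 0)
               sprintf("tgt%03d", seq_len(cfg$n_target_utrs)),
             if (cfg$n_background_utrs > 0)
               sprintf("bg%03d", seq_len(cfg$n_background_utrs)))
  is_target <- grepl("^tgt", genes)
  motifs <- tdp43_motifs()

  utrs <- character(length(genes))
  motif_rows <- list()
  for (g in seq_along(genes)) {
    seq_g <- random_dna(1, L)
    if (is_target[g] && m > 0) {
      chars <- strsplit(seq_g, "")[[1]]
      protected <- rep(FALSE, L)
      slot_w <- L %/% m
      gene_rows <- vector("list", m)
      for (k in seq_len(m)) {
        motif <- motifs[(k - 1) %% length(motifs) + 1]
        occupied <- runif(1) < cfg$frac_occupied
        construct <- if (occupied) .ss_context(motif)
                     else .stem_context(motif)
        cl <- nchar(construct)
        slot_mid <- (k - 1) * slot_w + slot_w %/% 2
        at <- slot_mid - cl %/% 2          # 0-based construct start
        chars[(at + 1):(at + cl)] <- strsplit(construct, "")[[1]]
        protected[(at + 1):(at + cl)] <- TRUE
        moff <- regexpr(motif, construct, fixed = TRUE)[1] - 1L
        gene_rows[[k]] <- data.frame(
          gene_id = genes[g], motif = motif,
          start = at + moff, end = at + moff + 5L,
          planted = TRUE, occupied = occupied,
          structural_context = if (occupied) "single_stranded" else "paired",
          stringsAsFactors = FALSE)
      }
      for (k in seq_len(m)) {
        if (gene_rows[[k]]$occupied) {
          chars <- .scrub_accessible(chars, gene_rows[[k]]$start,
                                     gene_rows[[k]]$end, protected)
        }
      }
      motif_rows <- c(motif_rows, gene_rows)
      seq_g <- paste(chars, collapse = "")
    }
    utrs[g] <- seq_g
  }
  names(utrs) <- genes

  planted <- if (length(motif_rows) > 0) do.call(rbind, motif_rows) else
    data.frame(gene_id = character(), motif = character(), start = integer(),
               end = integer(), planted = logical(), occupied = logical(),
               structural_context = character(), stringsAsFactors = FALSE)
  # record chance occurrences not coinciding with a planted interval
  chance <- lapply(genes, function(g) {
    hits <- find_motifs(utrs[[g]])
    if (nrow(hits) == 0) return(NULL)
    pl <- planted[planted$gene_id == g, , drop = FALSE]
    new <- !(paste(hits$motif, hits$start) %in% paste(pl$motif, pl$start))
    if (!any(new)) return(NULL)
    data.frame(gene_id = g, motif = hits$motif[new],
               start = hits$start[new], end = hits$end[new],
               planted = FALSE, occupied = FALSE,
               structural_context = "random", stringsAsFactors = FALSE)
  })
  truth_motifs <- rbind(planted, do.call(rbind, chance))
  truth_motifs <- truth_motifs[order(truth_motifs$gene_id,
                                     truth_motifs$start), , drop = FALSE]
  rownames(truth_motifs) <- NULL

  metadata <- data.frame(
    gene_id = genes, transcript_id = paste0(genes, ".1"),
    sequence = unname(utrs), tags = "", polya_conserved = TRUE,
    utr_start = 0L, utr_end = nchar(utrs),
    upstream_flank = random_dna(length(genes), 260),
    downstream_flank = random_dna(length(genes), 260),
    stringsAsFactors = FALSE)
  if (length(genes) > 0) {
    decoys <- metadata[rep(1, 2), , drop = FALSE]
    decoys$transcript_id <- paste0(genes[1], c(".d1", ".d2"))
    decoys$tags <- c("cds_end_NF", "")
    decoys$polya_conserved <- c(TRUE, FALSE)
    metadata <- rbind(metadata, decoys)
    rownames(metadata) <- NULL
  }
  truth_genes <- data.frame(
    gene_id = genes, is_target = is_target,
    planted_delta_lr = ifelse(is_target, cfg$fractionation_delta_lr, 0),
    stringsAsFactors = FALSE)
  list(utrs = utrs, metadata = metadata, truth_genes = truth_genes,
       truth_motifs = truth_motifs)
}

#' Simulate gene-level fractionation counts
#'
#' Soma/neurite counts for each gene under a negative-binomial model
#' (mean/dispersion parameterisation). Expected soma means are identical
#' across genotypes; the expected neurite mean in knockout equals the
#' wild-type mean times `2^planted_delta_lr`. Library sizes vary
#' log-normally across samples.
#'
#' @param cfg a [sim_config()].
#' @param truth_genes data.frame with `gene_id` and `planted_delta_lr`.
#' @return list with `counts` (genes x samples integer matrix) and
#'   `samples` (data.frame: sample, compartment, genotype, replicate).
#' @export
gen_fractionation_counts <- function(cfg, truth_genes) {
  stopifnot(inherits(cfg, "sim_config"))
  .seed_for(cfg, 202L)
  n_g <- nrow(truth_genes)
  expr <- exp(rnorm(n_g, 0, 1))
  lr0 <- rnorm(n_g, 0, 0.25)
  samples <- expand.grid(replicate = seq_len(cfg$replicates),
                         genotype = c("WT", "KO"),
                         compartment = c("soma", "neurite"),
                         stringsAsFactors = FALSE)
  samples <- samples[, c("compartment", "genotype", "replicate")]
  samples$sample <- sprintf("frac_%s_%s_r%d", samples$compartment,
                            samples$genotype, samples$replicate)
  counts <- matrix(0L, n_g, nrow(samples),
                   dimnames = list(truth_genes$gene_id, samples$sample))
  for (s in seq_len(nrow(samples))) {
    w <- expr
    if (samples$compartment[s] == "neurite") {
      lr <- lr0 + if (samples$genotype[s] == "KO")
        truth_genes$planted_delta_lr else 0
      w <- expr * 2^lr
    }
    libsize <- cfg$fractionation_depth * exp(rnorm(1, 0, 0.2))
    mu <- libsize * w / sum(w)
    counts[, s] <- if (cfg$nb_dispersion > 0) {
      rnbinom(n_g, mu = mu, size = 1 / cfg$nb_dispersion)
    } else {
      rpois(n_g, mu)
    }
  }
  list(counts = counts, samples = samples[, c("sample", "compartment",
                                              "genotype", "replicate")])
}

#' Derive per-oligo ground truth from the pool manifest
#'
#' An oligo inherits the effects of every planted motif whose interval is
#' fully contained in the oligo's footprint, provided the motif is intact
#' (mutant companions carry complemented motifs, so inherit nothing).
#' Occupied motifs contribute `mpra_delta_lr_occupied` log2 units of
#' localization effect, one `affinity_scale` fold of binding affinity, and
#' switch the oligo to the destabilised half-life class; stem-buried
#' planted motifs contribute the small `mpra_delta_lr_paired` effect and
#' half an affinity step.
#'
#' @param manifest pool manifest from [assemble_pool()].
#' @param truth_motifs motif truth from [gen_utr_set()].
#' @param cfg a [sim_config()].
#' @return data.frame with oligo_id, n_occupied, n_paired,
#'   planted_delta_lr, planted_affinity, planted_halflife_wt/ko.
#' @export
oligo_truth <- function(manifest, truth_motifs, cfg) {
  planted <- truth_motifs[truth_motifs$planted, , drop = FALSE]
  tile_len <- nchar(manifest$variable_seq[1])
  n_occ <- integer(nrow(manifest))
  n_par <- integer(nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    if (manifest$is_mutant[i]) next
    pm <- planted[planted$gene_id == manifest$gene_id[i], , drop = FALSE]
    if (nrow(pm) == 0) next
    inside <- pm$start >= manifest$start[i] &
      pm$end <= manifest$start[i] + tile_len
    n_occ[i] <- sum(inside & pm$occupied)
    n_par[i] <- sum(inside & !pm$occupied)
  }
  data.frame(
    oligo_id = manifest$oligo_id,
    n_occupied = n_occ, n_paired = n_par,
    planted_delta_lr = n_occ * cfg$mpra_delta_lr_occupied +
      n_par * cfg$mpra_delta_lr_paired,
    planted_affinity = cfg$affinity_scale^(n_occ + 0.5 * n_par),
    planted_halflife_wt = ifelse(n_occ > 0, cfg$halflife_wt_h,
                                 cfg$halflife_other_h),
    planted_halflife_ko = ifelse(n_occ > 0, cfg$halflife_ko_h,
                                 cfg$halflife_other_h),
    stringsAsFactors = FALSE)
}

# shared read constructor: amplicon read pair for oligo variable regions
.build_reads <- function(var_seqs, idx, umis, cfg) {
  if (length(idx) == 0) {
    return(list(fwd = character(0), rev = character(0)))
  }
  cover_f <- cfg$read_len - nchar(mpra_fwd_adapter())
  cover_r <- cfg$read_len - nchar(mpra_rev_adapter()) - cfg$umi_length
  fwd <- paste0(mpra_fwd_adapter(), substr(var_seqs[idx], 1, cover_f))
  rc <- revcomp(var_seqs)
  rev <- paste0(mpra_rev_adapter(), umis, substr(rc[idx], 1, cover_r))
  if (cfg$seq_error_rate > 0) {
    fwd <- inject_errors_cpp(fwd, cfg$seq_error_rate)
    rev <- inject_errors_cpp(rev, cfg$seq_error_rate)
  }
  list(fwd = fwd, rev = rev)
}

.random_umis <- function(n, umi_length) {
  if (n == 0) return(character(0))
  if (umi_length == 0) return(rep("", n))
  random_dna(n, umi_length)
}

.write_pair <- function(prefix, ids, reads, outdir) {
  f1 <- file.path(outdir, paste0(prefix, "_R1.fastq"))
  f2 <- file.path(outdir, paste0(prefix, "_R2.fastq"))
  write_fastq(ids, reads$fwd, f1)
  write_fastq(ids, reads$rev, f2)
  c(fastq1 = f1, fastq2 = f2)
}

#' Simulate MPRA amplicon read pairs
#'
#' For each soma/neurite x genotype x replicate sample, read counts are
#' multinomial in the sample's expected oligo abundances: a common
#' log-normal baseline per oligo, with neurite abundance scaled by
#' `2^(planted_delta_lr)` in knockout samples. Forward reads carry the
#' forward adapter plus the 5' end of the variable region; reverse reads
#' carry the reverse adapter, the UMI, and the reverse-complemented 3' end.
#'
#' @param manifest pool manifest from [assemble_pool()].
#' @param otruth per-oligo truth from [oligo_truth()].
#' @param cfg a [sim_config()].
#' @param outdir output directory for FASTQ files.
#' @return sample sheet data.frame (sample, fastq1, fastq2, compartment,
#'   genotype, replicate).
#' @export
gen_mpra_reads <- function(manifest, otruth, cfg, outdir) {
  stopifnot(inherits(cfg, "sim_config"))
  if (nrow(manifest) == 0) stop("empty oligo pool")
  .seed_for(cfg, 303L)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stopifnot(identical(manifest$oligo_id, otruth$oligo_id))
  n <- nrow(manifest)
  base <- exp(rnorm(n, 0, 0.5))
  samples <- expand.grid(replicate = seq_len(cfg$replicates),
                         genotype = c("WT", "KO"),
                         compartment = c("soma", "neurite"),
                         stringsAsFactors = FALSE)
  sheet <- data.frame(sample = sprintf("mpra_%s_%s_r%d", samples$compartment,
                                       samples$genotype, samples$replicate),
                      fastq1 = "", fastq2 = "",
                      compartment = samples$compartment,
                      genotype = samples$genotype,
                      replicate = samples$replicate,
                      stringsAsFactors = FALSE)
  for (s in seq_len(nrow(sheet))) {
    w <- base
    if (sheet$compartment[s] == "neurite" && sheet$genotype[s] == "KO") {
      w <- base * 2^otruth$planted_delta_lr
    }
    counts <- as.vector(rmultinom(1, cfg$read_depth, w / sum(w)))
    idx <- rep.int(seq_len(n), counts)
    umis <- .random_umis(length(idx), cfg$umi_length)
    reads <- .build_reads(manifest$variable_seq, idx, umis, cfg)
    ids <- sprintf("%s_read%07d", sheet$sample[s], seq_along(idx))
    paths <- .write_pair(sheet$sample[s], ids, reads, outdir)
    sheet$fastq1[s] <- paths[["fastq1"]]
    sheet$fastq2[s] <- paths[["fastq2"]]
  }
  sheet
}

#' Simulate RNA Bind-n-Seq read pairs
#'
#' The input library is multinomial in uniform oligo frequencies; each
#' protein-bound library is multinomial in frequencies proportional to
#' input frequency times planted affinity raised to a concentration-
#' dependent exponent (higher concentrations, wider dynamic range), so R
#' values increase monotonically with planted affinity at every
#' concentration.
#'
#' @inheritParams gen_mpra_reads
#' @return sample sheet data.frame (sample, fastq1, fastq2, role,
#'   concentration, replicate); one input plus one bound sample per
#'   concentration, per replicate (duplicates by default).
#' @export
gen_rbns_reads <- function(manifest, otruth, cfg, outdir) {
  stopifnot(inherits(cfg, "sim_config"))
  if (nrow(manifest) == 0) stop("empty oligo pool")
  if (any(otruth$planted_affinity < 0)) stop("affinities must be >= 0")
  .seed_for(cfg, 404L)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  n <- nrow(manifest)
  conc <- sort(cfg$concentrations_nM, decreasing = TRUE)
  gamma <- if (length(conc) == 1) 1 else {
    0.4 + 0.6 * (log(conc) - log(min(conc))) /
      (log(max(conc)) - log(min(conc)))
  }
  n_rep <- min(cfg$replicates, 2)   # binding assays run in duplicate
  rows <- list()
  for (r in seq_len(n_rep)) {
    specs <- c(list(list(role = "input", conc = NA_real_, prob = rep(1, n))),
               lapply(seq_along(conc), function(ci) {
                 list(role = "bound", conc = conc[ci],
                      prob = otruth$planted_affinity^gamma[ci])
               }))
    for (sp in specs) {
      name <- if (sp$role == "input") sprintf("rbns_input_r%d", r)
              else sprintf("rbns_bound_%gnM_r%d", sp$conc, r)
      counts <- as.vector(rmultinom(1, cfg$rbns_depth,
                                    sp$prob / sum(sp$prob)))
      idx <- rep.int(seq_len(n), counts)
      umis <- .random_umis(length(idx), cfg$umi_length)
      reads <- .build_reads(manifest$variable_seq, idx, umis, cfg)
      ids <- sprintf("%s_read%07d", name, seq_along(idx))
      paths <- .write_pair(name, ids, reads, outdir)
      rows[[length(rows) + 1]] <- data.frame(
        sample = name, fastq1 = paths[["fastq1"]],
        fastq2 = paths[["fastq2"]], role = sp$role,
        concentration = sp$conc, replicate = r, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Simulate metabolic-labeling (SLAM-seq) read pairs
#'
#' Molecules are fully labeled at the start of the chase; at chase time t
#' the labeled fraction of an oligo's molecules is `2^(-t / halflife)`.
#' Each T of a labeled molecule converts to C at
#' `conversion_rate_labeled`, unlabeled molecules at
#' `background_conversion_rate`; sequencing errors are then applied on
#' top. Each oligo receives exactly `slam_depth_per_oligo` read pairs per
#' sample.
#'
#' @inheritParams gen_mpra_reads
#' @return sample sheet data.frame (sample, fastq1, fastq2, genotype,
#'   timepoint).
#' @export
gen_slam_reads <- function(manifest, otruth, cfg, outdir) {
  stopifnot(inherits(cfg, "sim_config"))
  if (nrow(manifest) == 0) stop("empty oligo pool")
  .seed_for(cfg, 505L)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  n <- nrow(manifest)
  rows <- list()
  for (geno in c("WT", "KO")) {
    hl <- if (geno == "WT") otruth$planted_halflife_wt
          else otruth$planted_halflife_ko
    for (t in cfg$timepoints_h) {
      name <- sprintf("slam_%s_t%g", geno, t)
      idx <- rep.int(seq_len(n), cfg$slam_depth_per_oligo)
      labeled <- runif(length(idx)) < 2^(-t / hl[idx])
      conv <- slam_convert_cpp(manifest$variable_seq, idx, labeled,
                               cfg$conversion_rate_labeled,
                               cfg$background_conversion_rate)
      umis <- .random_umis(length(idx), cfg$umi_length)
      reads <- .build_reads(conv, seq_along(idx), umis, cfg)
      ids <- sprintf("%s_read%07d", name, seq_along(idx))
      paths <- .write_pair(name, ids, reads, outdir)
      rows[[length(rows) + 1]] <- data.frame(
        sample = name, fastq1 = paths[["fastq1"]],
        fastq2 = paths[["fastq2"]], genotype = geno, timepoint = t,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Simulate CLIP-style peak and read intervals
#'
#' One peak per occupied planted motif (motif interval +/- 20 nt, clipped
#' to the UTR); read intervals are Poisson-placed with a `clip_enrichment`
#' -fold elevated rate inside peaks. Coordinates are 0-based half-open
#' with the gene id as the chromosome name.
#'
#' @param truth_motifs motif truth from [gen_utr_set()].
#' @param utr_lengths named integer vector of UTR lengths per gene.
#' @param cfg a [sim_config()].
#' @return list with `peaks` and `reads` data.frames (chrom, start, end,
#'   name).
#' @export
gen_clip_features <- function(truth_motifs, utr_lengths, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  .seed_for(cfg, 606L)
  occ <- truth_motifs[truth_motifs$planted & truth_motifs$occupied, ,
                      drop = FALSE]
  peaks <- if (nrow(occ) == 0) {
    data.frame(chrom = character(), start = integer(), end = integer(),
               name = character(), stringsAsFactors = FALSE)
  } else {
    data.frame(chrom = occ$gene_id,
               start = pmax(0L, occ$start - 20L),
               end = pmin(unname(utr_lengths[occ$gene_id]), occ$end + 20L),
               name = sprintf("peak_%s_%d", occ$gene_id, occ$start),
               stringsAsFactors = FALSE)
  }
  reads <- list()
  for (g in names(utr_lengths)) {
    L <- utr_lengths[[g]]
    pk <- peaks[peaks$chrom == g, , drop = FALSE]
    in_peak <- rep(FALSE, L)
    for (p in seq_len(nrow(pk))) in_peak[(pk$start[p] + 1):pk$end[p]] <- TRUE
    lam_out <- cfg$clip_read_rate / 1000
    lam_in <- lam_out * cfg$clip_enrichment
    n_in <- rpois(1, sum(in_peak) * lam_in)
    n_out <- rpois(1, sum(!in_peak) * lam_out)
    pos <- c(if (n_in > 0) sample(which(in_peak), n_in, replace = TRUE),
             if (n_out > 0) sample(which(!in_peak), n_out, replace = TRUE))
    if (length(pos) == 0) next
    start <- pmin(pos - 1L, L - 1L)
    reads[[g]] <- data.frame(
      chrom = g, start = start,
      end = pmin(start + cfg$clip_read_len, L),
      name = sprintf("clipread_%s_%d", g, seq_along(start)),
      stringsAsFactors = FALSE)
  }
  reads <- if (length(reads) > 0) do.call(rbind, reads) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               name = character(), stringsAsFactors = FALSE)
  rownames(reads) <- NULL
  list(peaks = peaks, reads = reads)
}
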