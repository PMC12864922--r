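#' 5-mer enrichment between UTR sets
#'
#' Presence/absence of every k-mer per UTR feeds a two-sided Fisher exact
#' test (target-with / target-without vs background-with /
#' background-without); enrichment is the pseudocounted log2 ratio of
#' presence frequencies. FDR is Benjamini-Hochberg across all 4^k k-mers;
#' output is ranked by Fisher p-value with enrichment as tiebreak (at
#' moderate set sizes the p-value separates consistent enrichment from
#' single-k-mer sampling flukes far more reliably than the ratio alone),
#' positively enriched k-mers first.
#'
#' @param target_seqs,bg_seqs character vectors of UTR sequences (DNA).
#' @param k k-mer length.
#' @return data.frame: kmer, n_target_with, n_target_without, n_bg_with,
#'   n_bg_without, log2_enrichment, p_value, fdr.
#' @export
kmer_enrichment <- function(target_seqs, bg_seqs, k = 5) {
  if (k <= 0) stop("k must be positive")
  stopifnot(length(target_seqs) > 0, length(bg_seqs) > 0)
  pres <- function(seqs) {
    m <- Biostrings::oligonucleotideFrequency(
      Biostrings::DNAStringSet(seqs), width = k)
    colSums(m > 0)
  }
  tw <- pres(target_seqs)
  bw <- pres(bg_seqs)
  nt <- length(target_seqs); nb <- length(bg_seqs)
  p <- vapply(seq_along(tw), function(i) {
    fisher.test(matrix(c(tw[i], nt - tw[i], bw[i], nb - bw[i]), 2))$p.value
  }, numeric(1))
  enr <- log2(((tw + 0.5) / (nt + 1)) / ((bw + 0.5) / (nb + 1)))
  out <- data.frame(kmer = names(tw),
                    n_target_with = as.integer(unname(tw)),
                    n_target_without = as.integer(nt - unname(tw)),
                    n_bg_with = as.integer(unname(bw)),
                    n_bg_without = as.integer(nb - unname(bw)),
                    log2_enrichment = unname(enr),
                    p_value = p, fdr = p.adjust(p, "BH"),
                    stringsAsFactors = FALSE)
  out[order(out$log2_enrichment <= 0, out$p_value, -out$log2_enrichment,
            out$kmer), , drop = FALSE]
}

#' Peak overlap and read density per UTR group
#'
#' Each UTR spans [0, length) on its own gene-named chromosome. A UTR
#' "has a peak" if any peak overlaps it by >= 1 nt (half-open
#' coordinates); read density is overlapping reads per kb of UTR. Group
#' summaries are compared to `control_group` as fold ratios.
#'
#' @param utrs data.frame: gene_id, length, group.
#' @param peaks,reads BED-style data.frames (chrom, start, end) with gene
#'   ids as chroms.
#' @param control_group group name used as the fold-change denominator.
#' @return list with `per_utr` (gene_id, group, has_peak, n_reads,
#'   density) and `groups` (group, n, frac_with_peak, mean_density,
#'   fold_peak, fold_density).
#' @export
clip_overlap_stats <- function(utrs, peaks, reads,
                               control_group = NULL) {
  count_overlaps <- function(features) {
    vapply(seq_len(nrow(utrs)), function(i) {
      f <- features[features$chrom == utrs$gene_id[i], , drop = FALSE]
      if (nrow(f) == 0) return(0L)
      sum(f$start < utrs$length[i] & f$end > 0)
    }, integer(1))
  }
  per_utr <- data.frame(gene_id = utrs$gene_id, group = utrs$group,
                        has_peak = count_overlaps(peaks) > 0,
                        n_reads = count_overlaps(reads),
                        stringsAsFactors = FALSE)
  per_utr$density <- per_utr$n_reads / (utrs$length / 1000)
  groups <- do.call(rbind, lapply(split(per_utr, per_utr$group), function(d) {
    data.frame(group = d$group[1], n = nrow(d),
               frac_with_peak = mean(d$has_peak),
               mean_density = mean(d$density), stringsAsFactors = FALSE)
  }))
  rownames(groups) <- NULL
  if (!is.null(control_group)) {
    ctrl <- groups[groups$group == control_group, , drop = FALSE]
    if (nrow(ctrl) != 1) stop("unknown control group: ", control_group)
    groups$fold_peak <- groups$frac_with_peak / ctrl$frac_with_peak
    groups$fold_density <- groups$mean_density / ctrl$mean_density
  }
  list(per_utr = per_utr, groups = groups)
}

#' Pairwise Wilcoxon rank-sum comparisons between groups
#'
#' Exact test when the smaller group has at most 25 observations and
#' there are no ties; normal approximation with continuity correction
#' otherwise.
#'
#' @param values numeric vector.
#' @param labels group label per value.
#' @return data.frame with one row per group pair: group1, group2, n1,
#'   n2, median1, median2, p_value.
#' @export
group_compare <- function(values, labels) {
  ok <- is.finite(values) & !is.na(labels)
  values <- values[ok]; labels <- as.character(labels[ok])
  lev <- unique(labels)
  if (length(lev) < 2) stop("need at least two groups with values")
  pairs <- combn(lev, 2)
  out <- lapply(seq_len(ncol(pairs)), function(j) {
    x <- values[labels == pairs[1, j]]
    y <- values[labels == pairs[2, j]]
    ties <- anyDuplicated(c(x, y)) > 0
    exact <- min(length(x), length(y)) <= 25 && !ties
    p <- suppressWarnings(
      wilcox.test(x, y, exact = exact, correct = TRUE)$p.value)
    data.frame(group1 = pairs[1, j], group2 = pairs[2, j],
               n1 = length(x), n2 = length(y),
               median1 = median(x), median2 = median(y),
               p_value = p, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Motif/CLIP class labels for pool oligos
#'
#' Non-mutant oligos partition into: `no_motif`; `motif_no_clip` (contains
#' a motif, none of whose occurrences overlap a peak); `motif_clip` (at
#' least one motif occurrence overlaps a peak by >= 1 nt in half-open gene
#' coordinates). Mutant companions are labelled `mutant`.
#'
#' @param manifest pool manifest from [assemble_pool()].
#' @param peaks peak data.frame (chrom = gene_id, start, end).
#' @return character vector of class labels, named by oligo_id.
#' @export
motif_class_assign <- function(manifest, peaks) {
  hits <- decode_hits(manifest$motif_hits)
  cls <- vapply(seq_len(nrow(manifest)), function(i) {
    if (manifest$is_mutant[i]) return("mutant")
    h <- hits[[i]]
    if (nrow(h) == 0) return("no_motif")
    pk <- peaks[peaks$chrom == manifest$gene_id[i], , drop = FALSE]
    if (nrow(pk) == 0) return("motif_no_clip")
    gs <- manifest$start[i] + h$start
    ge <- manifest$start[i] + h$end
    ov <- vapply(seq_len(nrow(h)), function(m) {
      any(pk$start < ge[m] & pk$end > gs[m])
    }, logical(1))
    if (any(ov)) "motif_clip" else "motif_no_clip"
  }, character(1))
  setNames(cls, manifest$oligo_id)
}

#' Correlation of UTR motif count with stability change
#'
#' Motif counting uses all (overlapping) occurrences of the three
#' canonical motifs; medians are reported in bins {0, 1, 2, 3, 4+} and
#' Spearman's rho is computed on the unbinned values.
#'
#' @param motif_count named integer vector per RNA.
#' @param stability_change named numeric vector (matched ids).
#' @return list with `bins` (data.frame bin, n, median_change), `rho`,
#'   `p_value`.
#' @export
motifcount_stability_correlation <- function(motif_count, stability_change) {
  ids <- intersect(names(motif_count), names(stability_change))
  mc <- motif_count[ids]; sc <- stability_change[ids]
  ok <- is.finite(sc)
  mc <- mc[ok]; sc <- sc[ok]
  bin <- ifelse(mc >= 4, "4+", as.character(mc))
  bin <- factor(bin, levels = c("0", "1", "2", "3", "4+"))
  bins <- do.call(rbind, lapply(levels(bin), function(b) {
    sel <- bin == b
    data.frame(bin = b, n = sum(sel),
               median_change = if (any(sel)) median(sc[sel]) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  if (length(unique(mc)) < 2 || length(unique(sc)) < 2) {
    rho <- 0; p <- 1
  } else {
    ct <- suppressWarnings(cor.test(sc, mc, method = "spearman"))
    rho <- unname(ct$estimate); p <- ct$p.value
  }
  list(bins = bins, rho = rho, p_value = p)
}

#' @noRd
.contrast <- function(name, values, labels, g1, g2) {
  sel <- labels %in% c(g1, g2) & is.finite(values)
  if (length(unique(labels[sel])) < 2) {
    return(data.frame(contrast = name, group1 = g1, group2 = g2,
                      n1 = sum(labels == g1 & is.finite(values)),
                      n2 = sum(labels == g2 & is.finite(values)),
                      median1 = NA_real_, median2 = NA_real_,
                      p_value = NA_real_, stringsAsFactors = FALSE))
  }
  gc <- group_compare(values[sel], labels[sel])
  row <- gc[(gc$group1 == g1 & gc$group2 == g2) |
              (gc$group1 == g2 & gc$group2 == g1), , drop = FALSE][1, ]
  if (row$group1 != g1) {
    row <- data.frame(group1 = row$group2, group2 = row$group1,
                      n1 = row$n2, n2 = row$n1, median1 = row$median2,
                      median2 = row$median1, p_value = row$p_value)
  }
  cbind(data.frame(contrast = name, stringsAsFactors = FALSE), row)
}

#' Join all per-oligo measurements and run the headline contrasts
#'
#' Outer join of localization, binding, stability and structure results
#' over the pool manifest, followed by the contrast suite: class-wise
#' delta LR / R / delta stability (motif+CLIP vs motif-only vs no-motif),
#' mutant-vs-wild-type attenuation for each measure, the structure
#' top/bottom split of delta LR, and delta stability by delta-LR
#' direction.
#'
#' @param manifest pool manifest.
#' @param dlr oligo-level data.frame from [delta_lr_test()].
#' @param mean_r named vector of mean R per oligo (or NULL).
#' @param dstab data.frame from [delta_stability()] (or NULL).
#' @param structure_scores named vector of motif mean pairing
#'   probabilities (or NULL).
#' @param peaks peak data.frame for class assignment.
#' @param split_q quantile for the structure split.
#' @return list with `master` (one row per pool member) and `contrasts`
#'   (data.frame of group comparisons).
#' @export
build_master <- function(manifest, dlr, mean_r = NULL, dstab = NULL,
                         structure_scores = NULL, peaks = NULL,
                         split_q = 0.20) {
  master <- manifest[, c("oligo_id", "gene_id", "start", "is_mutant",
                         "companion_id", "motif_hits")]
  master$motif_count <- vapply(decode_hits(manifest$motif_hits), nrow,
                               integer(1))
  if (!is.null(dlr)) {
    m <- match(master$oligo_id, dlr$feature_id)
    if (all(is.na(m))) warning("no shared oligo ids with delta-LR table")
    master$delta_lr <- dlr$delta_lr[m]
    master$delta_lr_fdr <- dlr$fdr[m]
  } else master$delta_lr <- NA_real_
  master$mean_r <- if (!is.null(mean_r))
    unname(mean_r[master$oligo_id]) else NA_real_
  master$delta_stability <- if (!is.null(dstab))
    dstab$delta_stability[match(master$oligo_id, dstab$oligo_id)] else
      NA_real_
  master$motif_pair_prob <- if (!is.null(structure_scores))
    unname(structure_scores[master$oligo_id]) else NA_real_
  master$class <- if (!is.null(peaks))
    unname(motif_class_assign(manifest, peaks)) else NA_character_

  contrasts <- list()
  cls <- master$class
  for (measure in c("delta_lr", "mean_r", "delta_stability")) {
    v <- master[[measure]]
    if (all(is.na(v))) next
    contrasts[[length(contrasts) + 1]] <-
      .contrast(paste0(measure, ":motif_clip_vs_no_motif"), v, cls,
                "no_motif", "motif_clip")
    contrasts[[length(contrasts) + 1]] <-
      .contrast(paste0(measure, ":motif_no_clip_vs_no_motif"), v, cls,
                "no_motif", "motif_no_clip")
    # mutant companions of motif+CLIP oligos vs their wild-type partners
    wt_ids <- master$oligo_id[!master$is_mutant & cls == "motif_clip"]
    mut_ids <- master$companion_id[match(wt_ids, master$oligo_id)]
    vv <- c(v[match(wt_ids, master$oligo_id)],
            v[match(mut_ids, master$oligo_id)])
    ll <- rep(c("wild_type", "mutant"), each = length(wt_ids))
    if (sum(is.finite(vv[ll == "wild_type"])) > 0 &&
        sum(is.finite(vv[ll == "mutant"])) > 0) {
      contrasts[[length(contrasts) + 1]] <-
        .contrast(paste0(measure, ":mutant_vs_wt_motif_clip"), vv, ll,
                  "wild_type", "mutant")
    }
  }
  if (!all(is.na(master$motif_pair_prob)) && !all(is.na(master$delta_lr))) {
    sc <- setNames(master$motif_pair_prob, master$oligo_id)
    sc <- sc[!is.na(sc) & !master$is_mutant[match(names(sc),
                                                  master$oligo_id)]]
    if (length(sc) >= 5) {
      sp <- structure_quantile_split(sc, split_q)
      lab <- rep(NA_character_, nrow(master))
      lab[master$oligo_id %in% sp$bottom] <- "single_stranded_20pct"
      lab[master$oligo_id %in% sp$top] <- "paired_20pct"
      contrasts[[length(contrasts) + 1]] <-
        .contrast("delta_lr:ss_vs_paired_motif", master$delta_lr, lab,
                  "paired_20pct", "single_stranded_20pct")
    }
  }
  if (!all(is.na(master$delta_stability)) && !all(is.na(master$delta_lr))) {
    dir <- ifelse(master$delta_lr > 0, "lr_up", "lr_down")
    contrasts[[length(contrasts) + 1]] <-
      .contrast("delta_stability:by_delta_lr_direction",
                master$delta_stability, dir, "lr_down", "lr_up")
  }
  list(master = master,
       contrasts = if (length(contrasts) > 0) do.call(rbind, contrasts)
                   else NULL)
}
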