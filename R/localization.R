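#' Normalise counts to relative abundances
#'
#' Adds a pseudocount and divides by the sample total so every column sums
#' to one; the pseudocount keeps localization ratios finite for
#' zero-count features without dominating moderate counts.
#'
#' @param counts features x samples matrix.
#' @param pseudocount added to every cell before normalisation.
#' @return matrix of relative abundances (columns sum to 1).
#' @export
normalize_counts <- function(counts, pseudocount = 0.5) {
  counts <- as.matrix(counts)
  zero <- colSums(counts) + nrow(counts) * pseudocount <= 0
  if (any(zero)) {
    stop("all-zero sample(s) with no pseudocount: ",
         paste(colnames(counts)[zero], collapse = ", "))
  }
  x <- counts + pseudocount
  sweep(x, 2, colSums(x), "/")
}

#' Localization ratio per feature and replicate
#'
#' LR = log2(relative abundance in the neurite fraction / relative
#' abundance in the cell-body fraction), computed replicate-by-replicate
#' within each genotype.
#'
#' @param rel relative-abundance matrix from [normalize_counts()].
#' @param samples data.frame with columns sample, compartment ("soma" /
#'   "neurite"), genotype, replicate; `sample` must match `colnames(rel)`.
#' @return long data.frame: feature_id, genotype, replicate, lr.
#' @export
compute_lr <- function(rel, samples) {
  stopifnot(all(samples$sample %in% colnames(rel)))
  keys <- unique(samples[, c("genotype", "replicate")])
  out <- lapply(seq_len(nrow(keys)), function(k) {
    sel <- samples$genotype == keys$genotype[k] &
      samples$replicate == keys$replicate[k]
    neu <- samples$sample[sel & samples$compartment == "neurite"]
    som <- samples$sample[sel & samples$compartment == "soma"]
    if (length(neu) != 1 || length(som) != 1) {
      stop("unmatched neurite/soma pair for genotype ", keys$genotype[k],
           " replicate ", keys$replicate[k])
    }
    data.frame(feature_id = rownames(rel), genotype = keys$genotype[k],
               replicate = keys$replicate[k],
               lr = log2(rel[, neu] / rel[, som]),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, out)
}

#' Genotype difference in localization ratio with Welch test
#'
#' Per feature: mean LR per genotype, delta_lr = mean(KO) - mean(WT), a
#' two-sided Welch t-test across replicate LRs (NA with fewer than two
#' replicates in either genotype), and Benjamini-Hochberg FDR across
#' features.
#'
#' With `center = TRUE` (default) each replicate's LR vector is centred
#' on its median across features before testing. Relative abundances are
#' compositional: when a sizeable set of features genuinely gains neurite
#' abundance in one genotype, every other feature's relative abundance
#' shrinks, shifting all LRs. Median centring removes that shift under
#' the standard assumption that most features are unaffected -- the same
#' assumption size-factor normalisation makes in count-based differential
#' tools.
#'
#' @param lr long data.frame from [compute_lr()].
#' @param genotypes the two genotype labels, difference taken as
#'   `genotypes[2] - genotypes[1]`.
#' @param method only "welch" is implemented.
#' @param center median-centre each replicate's LR vector first.
#' @return data.frame: feature_id, mean_lr_wt, mean_lr_ko, delta_lr,
#'   statistic, p_value, fdr, n_wt, n_ko.
#' @export
delta_lr_test <- function(lr, genotypes = c("WT", "KO"), method = "welch",
                          center = TRUE) {
  if (!identical(method, "welch")) stop("unknown method: ", method)
  dt <- data.table::as.data.table(lr)
  if (center) {
    dt[, lr := lr - median(lr, na.rm = TRUE),
       by = c("genotype", "replicate")]
  }
  g1 <- genotypes[1]; g2 <- genotypes[2]
  res <- dt[, {
    x <- lr[genotype == g2]
    y <- lr[genotype == g1]
    n1 <- sum(is.finite(y)); n2 <- sum(is.finite(x))
    if (n1 >= 2 && n2 >= 2 && (sd(x) > 0 || sd(y) > 0)) {
      tt <- t.test(x, y)
      list(mean_lr_wt = mean(y), mean_lr_ko = mean(x),
           delta_lr = mean(x) - mean(y),
           statistic = unname(tt$statistic), p_value = tt$p.value,
           n_wt = n1, n_ko = n2)
    } else {
      # degenerate: too few replicates, or zero variance in both groups
      p <- if (n1 >= 2 && n2 >= 2 && isTRUE(all.equal(mean(x), mean(y))))
        1 else NA_real_
      list(mean_lr_wt = mean(y), mean_lr_ko = mean(x),
           delta_lr = mean(x) - mean(y),
           statistic = NA_real_, p_value = p,
           n_wt = n1, n_ko = n2)
    }
  }, by = "feature_id"]
  res <- as.data.frame(res)
  res$fdr <- p.adjust(res$p_value, method = "BH")
  res
}

#' Rolling positional profile of oligo effects
#'
#' Centred rolling mean of per-tile values (e.g. delta LR) along tile
#' start positions; window ends shrink to the available tiles.
#'
#' @param starts tile start coordinates (wild-type tiles of one gene).
#' @param values per-tile values, same length.
#' @param window number of consecutive tiles averaged (odd recommended).
#' @return data.frame: start, value, rolling_mean, ordered by start.
#' @export
rolling_profile <- function(starts, values, window = 5) {
  stopifnot(length(starts) == length(values), window >= 1)
  o <- order(starts)
  starts <- starts[o]; values <- values[o]
  n <- length(values)
  half <- (window - 1) %/% 2
  up <- window - 1 - half
  rm <- vapply(seq_len(n), function(i) {
    mean(values[max(1, i - half):min(n, i + up)], na.rm = TRUE)
  }, numeric(1))
  data.frame(start = starts, value = values, rolling_mean = rm)
}

#' Fold enrichment by the delta-delta-Ct method
#'
#' fold = 2^-ddCt with ddCt = (Ct_target - Ct_ref)_condition -
#' (Ct_target - Ct_ref)_control.
#'
#' @param ct_target_cond,ct_ref_cond,ct_target_ctrl,ct_ref_ctrl Ct values.
#' @return fold enrichment (vectorised).
#' @export
ddct_fold <- function(ct_target_cond, ct_ref_cond, ct_target_ctrl,
                      ct_ref_ctrl) {
  stopifnot(all(is.finite(c(ct_target_cond, ct_ref_cond, ct_target_ctrl,
                            ct_ref_ctrl))))
  ddct <- (ct_target_cond - ct_ref_cond) - (ct_target_ctrl - ct_ref_ctrl)
  2^(-ddct)
}

#' Per-cell projection/soma spot enrichment with group comparison
#'
#' Single-molecule FISH readout: ratio of spot counts in the projection
#' over the soma per cell; cells with zero soma spots are excluded and
#' logged. Groups are compared by a two-sided Wilcoxon rank-sum test.
#'
#' @param projection,soma integer spot counts per cell.
#' @param group group label per cell (exactly two levels for the test).
#' @return list with `cells` (data.frame group, projection, soma, ratio),
#'   `excluded` (count of zero-soma cells) and `p_value`.
#' @export
smfish_ratio <- function(projection, soma, group) {
  stopifnot(length(projection) == length(soma),
            length(group) == length(soma))
  ok <- soma > 0
  cells <- data.frame(group = group[ok], projection = projection[ok],
                      soma = soma[ok],
                      ratio = projection[ok] / soma[ok],
                      stringsAsFactors = FALSE)
  lev <- unique(cells$group)
  p <- if (length(lev) == 2) {
    group_compare(cells$ratio, cells$group)$p_value[1]
  } else {
    NA_real_
  }
  list(cells = cells, excluded = sum(!ok), p_value = p)
}
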