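#' RBNS enrichment (R values)
#'
#' R of an oligo is its relative frequency in a protein-bound sample
#' divided by its relative frequency in the input sample. Oligos with
#' fewer than `min_input` input reads are set NA: the ratio's variance
#' explodes at small denominators.
#'
#' @param counts oligos x samples count matrix (one input plus bound
#'   samples; columns named).
#' @param samples data.frame with columns sample, role ("input"/"bound"),
#'   concentration, replicate.
#' @param min_input minimum input reads for a defined R.
#' @return list with `r` (oligos x bound-samples matrix of R values),
#'   `mean_r` (unweighted mean across bound samples per oligo) and
#'   `samples` (bound-sample metadata).
#' @export
compute_r <- function(counts, samples, min_input = 10) {
  counts <- as.matrix(counts)
  stopifnot(all(samples$sample %in% colnames(counts)))
  reps <- unique(samples$replicate)
  bound <- samples[samples$role == "bound", , drop = FALSE]
  if (nrow(bound) == 0) stop("no bound samples")
  rmat <- matrix(NA_real_, nrow(counts), nrow(bound),
                 dimnames = list(rownames(counts), bound$sample))
  for (b in seq_len(nrow(bound))) {
    inp <- samples$sample[samples$role == "input" &
                            samples$replicate == bound$replicate[b]]
    if (length(inp) != 1) {
      stop("missing input sample for replicate ", bound$replicate[b])
    }
    ic <- counts[, inp]
    bc <- counts[, bound$sample[b]]
    if (sum(ic) == 0 || sum(bc) == 0) stop("zero-total sample")
    r <- (bc / sum(bc)) / (ic / sum(ic))
    r[ic < min_input] <- NA_real_
    rmat[, b] <- r
  }
  list(r = rmat, mean_r = rowMeans(rmat, na.rm = TRUE), samples = bound)
}

#' Concordance of R values across concentrations and replicates
#'
#' Pairwise Spearman correlations of log R (NA-pairwise exclusion) and
#' average-linkage hierarchical clustering on 1 - rho.
#'
#' @param rmat oligos x bound-samples R matrix from [compute_r()].
#' @return list with `rho` (correlation matrix) and `hclust`.
#' @export
concentration_concordance <- function(rmat) {
  if (ncol(rmat) < 2) stop("need at least 2 bound samples")
  lr <- log(rmat)
  lr[!is.finite(lr)] <- NA
  rho <- cor(lr, method = "spearman", use = "pairwise.complete.obs")
  list(rho = rho, hclust = hclust(as.dist(1 - rho), method = "average"))
}

#' R value by motif count with trend test
#'
#' Median R per motif-count bin plus a Spearman trend test of R against
#' motif count on the unbinned values.
#'
#' @param r named numeric vector of per-oligo (mean) R values.
#' @param motif_count named integer vector of motif counts (same ids).
#' @param min_bin_n bins with fewer oligos are flagged `low_n`.
#' @return list with `bins` (data.frame motif_count, n, median_r, low_n),
#'   `rho` and `p_value`.
#' @export
r_by_motif_count <- function(r, motif_count, min_bin_n = 5) {
  ids <- intersect(names(r), names(motif_count))
  r <- r[ids]; mc <- motif_count[ids]
  ok <- is.finite(r)
  r <- r[ok]; mc <- mc[ok]
  bins <- aggregate(r, by = list(motif_count = mc), FUN = median)
  names(bins)[2] <- "median_r"
  bins$n <- as.vector(table(mc)[as.character(bins$motif_count)])
  bins$low_n <- bins$n < min_bin_n
  if (length(unique(mc)) < 2 || length(unique(r)) < 2) {
    rho <- 0; p <- 1
  } else {
    ct <- suppressWarnings(cor.test(r, mc, method = "spearman"))
    rho <- unname(ct$estimate); p <- ct$p.value
  }
  list(bins = bins[, c("motif_count", "n", "median_r", "low_n")],
       rho = rho, p_value = p)
}
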