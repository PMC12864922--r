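#' Base-pair probability matrix of one folding window
#'
#' Boltzmann-weighted pair probabilities over all nested secondary
#' structures of the window. The default backend is a McCaskill-style
#' partition function under a simple base-pair-counting energy model with
#' helix cooperativity: pair energies (kT) GC = -3, AU = -2, GU = -1, a
#' minimum hairpin loop of 3 unpaired bases, no stacking or dangle terms,
#' plus a Turner-scale helix-initiation penalty (+8 kT per maximal helix)
#' that keeps isolated base pairs rare. The model is simple enough that an
#' exact brute-force enumeration oracle exists; a thermodynamic ViennaRNA
#' backend ([vienna_backend()]) can be dropped in.
#'
#' @param seq DNA or RNA string (A/C/G/T/U; N is rejected).
#' @param backend a function `seq -> symmetric pair-probability matrix`;
#'   defaults to [mccaskill_backend()].
#' @return n x n symmetric matrix, `P[i, j]` = probability that bases i
#'   and j are paired; row sums are at most 1.
#' @export
fold_window <- function(seq, backend = mccaskill_backend()) {
  stopifnot(length(seq) == 1)
  if (grepl("[^ACGTUacgtu]", seq)) {
    stop("invalid alphabet in folding window (only A/C/G/T/U allowed)")
  }
  backend(toupper(seq))
}

#' @rdname fold_window
#' @param e_gc,e_au,e_gu pair energies in kT (negative = stabilising).
#' @param e_init helix-initiation penalty in kT, paid once per maximal
#'   helix (run of stacked pairs).
#' @param min_loop minimum number of unpaired bases in a hairpin loop.
#' @export
mccaskill_backend <- function(e_gc = -3, e_au = -2, e_gu = -1, e_init = 8,
                              min_loop = 3) {
  function(seq) {
    mccaskill_pairprob_cpp(seq, e_gc, e_au, e_gu, e_init,
                           as.integer(min_loop))
  }
}

#' @rdname fold_window
#' @details `vienna_backend()` shells out to the `RNAfold -p` binary and
#'   parses the dot-plot PostScript for ensemble pair probabilities; it is
#'   only usable where ViennaRNA is installed.
#' @export
vienna_backend <- function() {
  function(seq) {
    n <- nchar(seq)
    td <- tempfile("vfold")
    dir.create(td)
    on.exit(unlink(td, recursive = TRUE))
    old <- setwd(td)
    on.exit(setwd(old), add = TRUE, after = FALSE)
    writeLines(c(">w", chartr("T", "U", seq)), "in.fa")
    status <- suppressWarnings(
      system2("RNAfold", c("-p", "--noPS"), stdin = "in.fa",
              stdout = "out.txt", stderr = "err.txt"))
    if (status != 0 || !file.exists("w_dp.ps")) {
      stop("RNAfold failed; is ViennaRNA installed?")
    }
    P <- matrix(0, n, n)
    lines <- grep("ubox$", readLines("w_dp.ps"), value = TRUE)
    lines <- lines[grepl("^[0-9]", lines)]
    if (length(lines) > 0) {
      f <- do.call(rbind, strsplit(lines, " "))
      i <- as.integer(f[, 1]); j <- as.integer(f[, 2])
      p <- as.numeric(f[, 3])^2   # dot plot stores sqrt(probability)
      P[cbind(i, j)] <- p
      P[cbind(j, i)] <- p
    }
    P
  }
}

#' Per-position pairing probability of a sequence via sliding windows
#'
#' Folds `window`-nt windows sliding by `slide` nt; within one window a
#' position's pairing probability is the summed probability of being
#' paired to any other base (the row sum of the pair-probability matrix).
#' Positions covered by several windows take the arithmetic mean across
#' covering windows. A trailing window is added when the slide does not
#' land exactly on the sequence end, so every position is covered.
#'
#' @param seq sequence to profile (typically a 260-nt variable region).
#' @param window,slide window length and slide in nt.
#' @param backend see [fold_window()].
#' @return numeric vector of per-position pairing probabilities between 0 and 1.
#' @export
positional_profile <- function(seq, window = 80, slide = 10,
                               backend = mccaskill_backend()) {
  if (slide <= 0) stop("slide must be positive")
  n <- nchar(seq)
  if (window > n) stop("window longer than sequence")
  starts <- seq.int(0, n - window, by = slide)
  if (starts[length(starts)] + window < n) starts <- c(starts, n - window)
  acc <- numeric(n)
  cov <- numeric(n)
  for (s0 in starts) {
    P <- fold_window(substr(seq, s0 + 1, s0 + window), backend)
    idx <- (s0 + 1):(s0 + window)
    acc[idx] <- acc[idx] + rowSums(P)
    cov[idx] <- cov[idx] + 1
  }
  acc / cov
}

#' Motif-level pairing scores from a positional profile
#'
#' @param profile per-position probabilities from [positional_profile()].
#' @param hits motif hit data.frame (motif, start, end; 0-based
#'   half-open) within the same sequence.
#' @return data.frame: motif, start, end, mean_pair_prob, p1..p5 (the five
#'   positional probabilities in motif orientation).
#' @export
motif_pair_prob <- function(profile, hits) {
  if (nrow(hits) == 0) {
    return(data.frame(motif = character(), start = integer(),
                      end = integer(), mean_pair_prob = numeric()))
  }
  stopifnot(all(hits$start >= 0), all(hits$end <= length(profile)))
  vals <- t(vapply(seq_len(nrow(hits)), function(i) {
    profile[(hits$start[i] + 1):hits$end[i]]
  }, numeric(5)))
  out <- data.frame(motif = hits$motif, start = hits$start,
                    end = hits$end, mean_pair_prob = rowMeans(vals),
                    stringsAsFactors = FALSE)
  colnames(vals) <- paste0("p", 1:5)
  cbind(out, vals)
}

#' Split oligos by motif pairing probability
#'
#' Stable rank on (score, id); returns the top and bottom `q` fractions
#' (size `ceiling(q * N)` each). Ties are resolved by id order.
#'
#' @param scores named numeric vector of per-oligo motif pairing scores.
#' @param q quantile fraction (default 0.20).
#' @return list with `top` and `bottom` character vectors of ids (top =
#'   most paired).
#' @export
structure_quantile_split <- function(scores, q = 0.20) {
  if (length(scores) < 5) stop("need at least 5 scored oligos to split")
  o <- order(scores, names(scores))
  k <- ceiling(q * length(scores))
  list(bottom = names(scores)[o[seq_len(k)]],
       top = names(scores)[o[seq.int(length(scores) - k + 1,
                                     length(scores))]])
}

#' Two-class structural classification of motif scores
#'
#' Separates "paired" (stem-buried) from "single-stranded" (accessible)
#' motifs by 1-dimensional 2-means clustering of the pairing scores --
#' threshold-free, so it works for any compliant folding backend.
#'
#' @param scores numeric vector of motif mean pairing probabilities.
#' @return character vector: "paired" or "single_stranded" per score.
#' @export
classify_structure <- function(scores) {
  stopifnot(length(scores) >= 2)
  if (diff(range(scores)) == 0) {
    return(rep("single_stranded", length(scores)))
  }
  km <- kmeans(scores, centers = range(scores))
  hi <- which.max(km$centers)
  ifelse(km$cluster == hi, "paired", "single_stranded")
}
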