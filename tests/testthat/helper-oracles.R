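# Independent oracles used across the suite. These deliberately avoid the
# package's own algorithms: folding probabilities come from exhaustive
# structure enumeration, Fisher p-values from direct hypergeometric sums,
# and Wilcoxon p-values from full enumeration of rank assignments.

# --- exhaustive folding oracle ------------------------------------------
# Same energy model as the default backend: pair energies (kT) GC -3,
# AU -2, GU -1, +8 per maximal helix, min hairpin loop 3. Enumerates every
# nested structure explicitly.
oracle_pair_weight <- function(a, b) {
  k <- paste0(a, b)
  if (k %in% c("GC", "CG")) return(exp(3))
  if (k %in% c("AT", "TA")) return(exp(2))
  if (k %in% c("GT", "TG")) return(exp(1))
  0
}

oracle_enum_structures <- function(n, min_loop = 3) {
  rec <- function(i, j) {
    if (j - i < min_loop + 1) return(list(matrix(0L, 2, 0)))
    out <- rec(i, j - 1)
    for (k in i:(j - min_loop - 1)) {
      left <- if (k - 1 >= i) rec(i, k - 1) else list(matrix(0L, 2, 0))
      inner <- rec(k + 1, j - 1)
      for (L in left) for (I in inner) {
        out <- c(out, list(cbind(L, I, c(k, j))))
      }
    }
    out
  }
  rec(1, n)
}

oracle_pairprob <- function(seq, e_init = 8) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  Z <- 0
  num <- matrix(0, n, n)
  for (S in oracle_enum_structures(n)) {
    k <- ncol(S)
    w <- 1
    ok <- TRUE
    if (k > 0) {
      for (c in seq_len(k)) {
        pw <- oracle_pair_weight(ch[S[1, c]], ch[S[2, c]])
        if (pw == 0) { ok <- FALSE; break }
        w <- w * pw
      }
      if (ok) {
        key <- paste(S[1, ], S[2, ])
        n_helix <- sum(!(paste(S[1, ] - 1, S[2, ] + 1) %in% key))
        w <- w * exp(-e_init * n_helix)
      }
    }
    if (!ok) next
    Z <- Z + w
    if (k > 0) for (c in seq_len(k)) {
      num[S[1, c], S[2, c]] <- num[S[1, c], S[2, c]] + w
    }
  }
  P <- num / Z
  P + t(P)
}

# --- exact 2x2 Fisher oracle --------------------------------------------
# Two-sided p by summing hypergeometric point masses <= the observed one.
oracle_fisher2x2 <- function(a, b, c, d) {
  m <- a + b          # row 1 total
  n <- c + d          # row 2 total
  k <- a + c          # column 1 total
  lo <- max(0, k - n)
  hi <- min(k, m)
  probs <- dhyper(lo:hi, m, n, k)
  p0 <- dhyper(a, m, n, k)
  sum(probs[probs <= p0 * (1 + 1e-7)])
}

# --- Wilcoxon rank-sum enumeration oracle -------------------------------
# Two-sided p from the exact permutation distribution of the rank sum,
# enumerating all choose(n1+n2, n1) group assignments (no ties assumed).
oracle_wilcoxon <- function(x, y) {
  all <- c(x, y)
  r <- rank(all)
  n1 <- length(x)
  obs <- sum(r[seq_len(n1)])
  combs <- combn(length(all), n1)
  sums <- apply(combs, 2, function(idx) sum(r[idx]))
  mu <- n1 * (length(all) + 1) / 2
  mean(abs(sums - mu) >= abs(obs - mu) - 1e-9)
}

# --- tiny pool helper ----------------------------------------------------
# A minimal manifest-like data.frame for read-level tests.
tiny_pool <- function(n, len = 260, seed = 99) {
  set.seed(seed)
  var <- vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = "")
  }, character(1))
  data.frame(oligo_id = sprintf("oligo%02d", seq_len(n)),
             gene_id = "g1", start = 0L, variable_seq = var,
             full_seq = paste0(default_fwd_handle(), var,
                               default_rev_handle()),
             motif_hits = "", is_mutant = FALSE,
             companion_id = NA_character_, stringsAsFactors = FALSE)
}
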