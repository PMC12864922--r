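#' Trim 5' adapters from a read-pair set
#'
#' Removes each mate's 5' adapter when it matches within `max_mismatch`
#' Hamming distance; pairs failing on either mate are rejected and counted.
#' N bases count as mismatches.
#'
#' @param fwd,rev character vectors of raw mate sequences.
#' @param fwd_adapter,rev_adapter adapter sequences expected at the 5' ends.
#' @param max_mismatch per-mate mismatch tolerance.
#' @return list with `keep` (logical), `fwd`, `rev` (trimmed retained
#'   mates) and `n_rejected`.
#' @export
trim_adapters <- function(fwd, rev,
                          fwd_adapter = mpra_fwd_adapter(),
                          rev_adapter = mpra_rev_adapter(),
                          max_mismatch = 2) {
  stopifnot(nchar(fwd_adapter) > 0, nchar(rev_adapter) > 0,
            length(fwd) == length(rev))
  df <- prefix_mismatch_cpp(fwd, fwd_adapter, max_mismatch)
  dr <- prefix_mismatch_cpp(rev, rev_adapter, max_mismatch)
  keep <- df <= max_mismatch & dr <= max_mismatch
  list(keep = keep,
       fwd = substring(fwd[keep], nchar(fwd_adapter) + 1),
       rev = substring(rev[keep], nchar(rev_adapter) + 1),
       n_rejected = sum(!keep))
}

#' Extract the UMI from trimmed reverse reads
#'
#' The UMI is the first `umi_len` bases of the adapter-trimmed reverse
#' read; the remainder is what gets matched against the reference. N bases
#' are kept as literal UMI symbols. Reads not longer than the UMI are
#' flagged for rejection.
#'
#' @param rev character vector of adapter-trimmed reverse reads.
#' @param umi_len UMI length (0 degenerates to plain read counting).
#' @return list with `umi`, `remainder`, `keep` (logical).
#' @export
extract_umi <- function(rev, umi_len = 8) {
  keep <- nchar(rev) > umi_len
  list(umi = substr(rev[keep], 1, umi_len),
       remainder = substring(rev[keep], umi_len + 1),
       keep = keep)
}

#' Build the oligo matching index
#'
#' @param manifest pool manifest from [assemble_pool()] (or any data.frame
#'   with `oligo_id` and `variable_seq`).
#' @return list used by [assign_to_oligo()].
#' @export
oligo_index <- function(manifest) {
  if (nrow(manifest) == 0) stop("empty oligo pool index")
  list(ids = manifest$oligo_id,
       var = manifest$variable_seq,
       var_rc = revcomp(manifest$variable_seq))
}

#' Assign trimmed read pairs to reference oligos
#'
#' Seeded near-exact matching against the closed pool dictionary: the
#' forward remainder must match the 5' end of an oligo variable region and
#' the reverse remainder (UMI removed) the reverse-complemented 3' end,
#' each within `max_mismatch` Hamming distance (no indels). The unique
#' best-scoring oligo wins; ties (e.g. a wild-type/mutant companion pair
#' whose distinguishing motif lies outside the sequenced ends) are
#' unassigned. `tc_aware = TRUE` additionally tolerates T>C conversions
#' (A>G on the reverse mate) for metabolic-labeling reads.
#'
#' @param fwd,rev character vectors of matched trimmed remainders.
#' @param index from [oligo_index()].
#' @param max_mismatch per-mate tolerance.
#' @param tc_aware tolerate nucleotide-conversion mismatches.
#' @return character vector of oligo ids, NA where unassigned.
#' @export
assign_to_oligo <- function(fwd, rev, index, max_mismatch = 2,
                            tc_aware = FALSE) {
  stopifnot(length(fwd) == length(rev))
  if (length(fwd) == 0) return(character(0))
  hit <- assign_reads_cpp(fwd, rev, index$var, index$var_rc,
                          as.integer(max_mismatch), 20L, tc_aware)
  out <- rep(NA_character_, length(fwd))
  out[hit > 0] <- index$ids[hit[hit > 0]]
  out
}

#' Collapse assignments to unique-UMI counts
#'
#' @param assignments data.frame with columns `oligo_id`, `umi`, `sample`.
#' @param oligo_ids full set of pool oligo ids (zero rows kept explicit).
#' @param samples full set of sample names.
#' @return integer matrix oligos x samples of distinct-UMI counts.
#' @export
count_umis <- function(assignments, oligo_ids, samples) {
  counts <- matrix(0L, length(oligo_ids), length(samples),
                   dimnames = list(oligo_ids, samples))
  a <- assignments[!is.na(assignments$oligo_id), , drop = FALSE]
  if (nrow(a) > 0) {
    dt <- data.table::as.data.table(a)
    agg <- dt[, list(n = data.table::uniqueN(umi)),
              by = c("oligo_id", "sample")]
    counts[cbind(match(agg$oligo_id, oligo_ids),
                 match(agg$sample, samples))] <- agg$n
  }
  counts
}

#' Process one FASTQ pair into per-oligo assignments
#'
#' Runs trim -> UMI extraction -> assignment and returns exact
#' bookkeeping: every input pair is either rejected (adapter/length),
#' unassigned, or assigned.
#'
#' @param fastq1,fastq2 paths to the mate files.
#' @param index from [oligo_index()].
#' @param sample sample name attached to the assignments.
#' @param umi_len UMI length.
#' @param max_mismatch per-mate tolerance for both trimming and assignment.
#' @param tc_aware passed to [assign_to_oligo()].
#' @param keep_seqs also return trimmed mate sequences and qualities of
#'   assigned pairs (needed for conversion counting).
#' @return list with `assignments` (data.frame oligo_id, umi, sample),
#'   `log` (data.frame n_total, n_rejected, n_unassigned, n_assigned) and,
#'   if `keep_seqs`, `fwd`, `rev`, `fwd_qual`, `rev_qual` for assigned
#'   pairs in assignment order.
#' @export
process_fastq_pair <- function(fastq1, fastq2, index, sample,
                               umi_len = 8, max_mismatch = 2,
                               tc_aware = FALSE, keep_seqs = FALSE) {
  r1 <- read_fastq(fastq1)
  r2 <- read_fastq(fastq2)
  if (nrow(r1) != nrow(r2)) stop("mate files differ in read count")
  n_total <- nrow(r1)
  tr <- trim_adapters(r1$seq, r2$seq, max_mismatch = max_mismatch)
  um <- extract_umi(tr$rev, umi_len)
  fwd <- tr$fwd[um$keep]
  n_rejected <- tr$n_rejected + sum(!um$keep)
  ids <- assign_to_oligo(fwd, um$remainder, index, max_mismatch, tc_aware)
  assigned <- !is.na(ids)
  res <- list(
    assignments = data.frame(oligo_id = ids[assigned],
                             umi = um$umi[assigned],
                             sample = sample, stringsAsFactors = FALSE),
    log = data.frame(sample = sample, n_total = n_total,
                     n_rejected = n_rejected,
                     n_unassigned = sum(!assigned),
                     n_assigned = sum(assigned),
                     stringsAsFactors = FALSE))
  if (keep_seqs) {
    qual1 <- r1$qual[tr$keep][um$keep]
    qual2 <- r2$qual[tr$keep][um$keep]
    res$fwd <- fwd[assigned]
    res$rev <- um$remainder[assigned]
    res$fwd_qual <- substring(qual1[assigned], nchar(mpra_fwd_adapter()) + 1)
    res$rev_qual <- substring(qual2[assigned],
                              nchar(mpra_rev_adapter()) + umi_len + 1)
    res$oligo_idx <- match(ids[assigned], index$ids)
  }
  res
}

#' Quantify a sample sheet into a deduplicated count table
#'
#' @param sheet sample sheet with columns sample, fastq1, fastq2 plus any
#'   metadata columns.
#' @param manifest pool manifest.
#' @param umi_len,max_mismatch,tc_aware see [process_fastq_pair()].
#' @return list with `counts` (oligos x samples unique-UMI matrix),
#'   `samples` (the metadata columns of `sheet`) and `log` (per-sample
#'   bookkeeping).
#' @export
quantify_samples <- function(sheet, manifest, umi_len = 8,
                             max_mismatch = 2, tc_aware = FALSE) {
  index <- oligo_index(manifest)
  res <- lapply(seq_len(nrow(sheet)), function(s) {
    process_fastq_pair(sheet$fastq1[s], sheet$fastq2[s], index,
                       sheet$sample[s], umi_len, max_mismatch, tc_aware)
  })
  assignments <- do.call(rbind, lapply(res, `[[`, "assignments"))
  logs <- do.call(rbind, lapply(res, `[[`, "log"))
  counts <- count_umis(assignments, manifest$oligo_id, sheet$sample)
  meta <- sheet[, setdiff(names(sheet), c("fastq1", "fastq2")),
                drop = FALSE]
  list(counts = counts, samples = meta, log = logs)
}
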