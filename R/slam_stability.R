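#' Count T>C conversions for assigned metabolic-labeling reads
#'
#' For every assigned read pair, reference-T positions covered by either
#' mate are tallied (n_T) along with those read as C (n_TC); mismatches at
#' non-T reference positions are kept as diagnostics. Positions with base
#' quality below Q20 are skipped when qualities are present.
#'
#' @param processed result of [process_fastq_pair()] with
#'   `keep_seqs = TRUE` and `tc_aware = TRUE`.
#' @param manifest pool manifest (provides the reference variable
#'   regions).
#' @param min_phred base-quality floor.
#' @return data.frame: oligo_id, sample, n_TC, n_T, other_mismatch.
#' @export
count_conversions <- function(processed, manifest, min_phred = 20) {
  res <- count_conversions_cpp(
    processed$fwd, processed$rev, processed$fwd_qual, processed$rev_qual,
    as.integer(processed$oligo_idx), manifest$variable_seq,
    nrow(manifest), as.integer(min_phred))
  data.frame(oligo_id = manifest$oligo_id,
             sample = processed$log$sample[1],
             n_TC = res$n_TC, n_T = res$n_T,
             other_mismatch = res$other_mismatch,
             stringsAsFactors = FALSE)
}

#' Pulse-chase stability ratio per oligo
#'
#' conversion rate = n_TC / n_T per sample; the stability ratio of an
#' oligo is rate(t = t1) / rate(t = t0) -- 1 for an infinitely stable RNA,
#' 2^(-t1/halflife) under exponential decay of the labeled pool. NA when
#' either timepoint has n_T < `min_T` or a zero t0 rate. Optionally a
#' background conversion rate (e.g. from a no-label control) is
#' subtracted from both rates first.
#'
#' @param conv_t0,conv_t1 ConversionCounts data.frames from
#'   [count_conversions()] for the two timepoints of one genotype.
#' @param min_T minimum covered reference-T positions per timepoint.
#' @param background background conversion rate to subtract (default 0).
#' @return data.frame: oligo_id, rate_t0, rate_t1, stability_ratio.
#' @export
stability_ratio <- function(conv_t0, conv_t1, min_T = 200, background = 0) {
  stopifnot(identical(conv_t0$oligo_id, conv_t1$oligo_id))
  r0 <- pmax(conv_t0$n_TC / conv_t0$n_T - background, 0)
  r1 <- pmax(conv_t1$n_TC / conv_t1$n_T - background, 0)
  ratio <- r1 / r0
  bad <- conv_t0$n_T < min_T | conv_t1$n_T < min_T |
    !is.finite(r0) | r0 == 0
  ratio[bad] <- NA_real_
  data.frame(oligo_id = conv_t0$oligo_id, rate_t0 = r0, rate_t1 = r1,
             stability_ratio = ratio, stringsAsFactors = FALSE)
}

#' Genotype difference in RNA stability
#'
#' delta = log2(stability ratio in knockout / stability ratio in
#' wild-type) per oligo; positive values mean the RNA is more stable
#' (decays less over the chase) when TDP-43 is lost.
#'
#' @param wt,ko StabilityTable data.frames from [stability_ratio()].
#' @return data.frame: oligo_id, ratio_wt, ratio_ko, delta_stability.
#' @export
delta_stability <- function(wt, ko) {
  stopifnot(identical(wt$oligo_id, ko$oligo_id))
  data.frame(oligo_id = wt$oligo_id,
             ratio_wt = wt$stability_ratio,
             ratio_ko = ko$stability_ratio,
             delta_stability = log2(ko$stability_ratio /
                                      wt$stability_ratio),
             stringsAsFactors = FALSE)
}
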