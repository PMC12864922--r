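#' Canonical TDP-43 binding motifs and their mutated forms
#'
#' TDP-43 binds GU-rich elements; the three canonical 5-mers (GUGUG, UGUGU,
#' GUAUG) are handled throughout in the DNA alphabet used for pool synthesis
#' (U encoded as T). Mutant companion oligos carry the base-wise complement
#' of every motif-covered position (GTGTG -> CACAC, TGTGT -> ACACA,
#' GTATG -> CATAC), which extends consistently to overlapping occurrences.
#'
#' @format `tdp43_motifs()` returns a character vector of the three motif
#'   strings; `tdp43_motif_mutations()` returns a named character vector
#'   mapping each motif to its mutated form.
#' @export
tdp43_motifs <- function() c("GTGTG", "TGTGT", "GTATG")

#' @rdname tdp43_motifs
#' @export
tdp43_motif_mutations <- function() {
  m <- tdp43_motifs()
  setNames(vapply(m, dna_complement, character(1)), m)
}

#' Amplicon adapter and handle constants
#'
#' The 5' adapter sequences trimmed from forward and reverse amplicon reads,
#' and the default 20-nt PCR handles flanking every pool oligo. The adapters
#' are the fixed amplicon-scheme prefixes; the handle sequences are
#' configurable constants (any motif-free 20-mers work) since the assay only
#' requires that they be constant across the pool.
#'
#' @return A character scalar.
#' @export
mpra_fwd_adapter <- function() {
  "GGCGGAAAGATCGCCGTGTAAGTTTGCTTCGATATCCGCATGCTA"
}

#' @rdname mpra_fwd_adapter
#' @export
mpra_rev_adapter <- function() "CTGATCAGCGGGTTTCACTAGTGCGACCGCAAGAG"

#' @rdname mpra_fwd_adapter
#' @export
default_fwd_handle <- function() "AGCACCTGCACCTGGAAGAC"

#' @rdname mpra_fwd_adapter
#' @export
default_rev_handle <- function() "GACCAGGACTCGGACCTGGA"
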