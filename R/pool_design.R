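#' Filter 3' UTR records for pool design
#'
#' A UTR enters the design only if its transcript has a well-defined 3' end
#' (none of the disallowed annotation tags), it is at most `max_len` nt long,
#' and its polyA site is positionally conserved. Rejections are logged with
#' the first failed rule, checked in the order tag, length, polyA.
#'
#' @param records data.frame with columns `gene_id`, `transcript_id`,
#'   `sequence`, `tags` (comma-separated flags, may be empty),
#'   `polya_conserved` (logical).
#' @param max_len maximum retained UTR length in nt (default 10000; the
#'   bound is inclusive, i.e. "longer than 10 kb" is excluded).
#' @param disallowed_tags tags marking ill-defined 3' ends.
#' @return list with `retained` (subset of `records`) and `rejected`
#'   (data.frame transcript_id, reason in {"tag", "length", "polya"}).
#' @export
filter_utrs <- function(records, max_len = 10000,
                        disallowed_tags = c("cds_end_NF", "mRNA_end_NF")) {
  stopifnot(all(c("gene_id", "transcript_id", "sequence", "tags",
                  "polya_conserved") %in% names(records)))
  tag_list <- strsplit(ifelse(is.na(records$tags), "", records$tags), ",")
  has_bad_tag <- vapply(tag_list,
                        function(t) any(trimws(t) %in% disallowed_tags),
                        logical(1))
  too_long <- nchar(records$sequence) > max_len
  not_conserved <- !records$polya_conserved
  reason <- rep(NA_character_, nrow(records))
  reason[not_conserved] <- "polya"
  reason[too_long] <- "length"
  reason[has_bad_tag] <- "tag"
  keep <- is.na(reason)
  list(retained = records[keep, , drop = FALSE],
       rejected = data.frame(
         transcript_id = records$transcript_id[!keep],
         reason = reason[!keep], stringsAsFactors = FALSE))
}

#' Merge a gene's filter-passing UTR isoforms into a meta-UTR
#'
#' Isoform UTR intervals (0-based half-open, gene coordinates) are unioned;
#' the merged sequence is read off the union in coordinate order. Disjoint
#' segments are concatenated, so downstream tiles may span junctions.
#' Overlapping isoforms must agree on their shared bases.
#'
#' @param records data.frame for one gene with columns `gene_id`,
#'   `transcript_id`, `sequence`, `utr_start`, `utr_end` (gene coordinates;
#'   `sequence` spans exactly `[utr_start, utr_end)`).
#' @return list with `gene_id`, `intervals` (data.frame start/end, sorted,
#'   non-overlapping), `sequence` (merged), `transcript_ids`.
#' @export
merge_meta_utr <- function(records) {
  if (nrow(records) == 0) stop("no filter-passing records for gene")
  stopifnot(length(unique(records$gene_id)) == 1,
            all(nchar(records$sequence) ==
                  records$utr_end - records$utr_start))
  span <- max(records$utr_end)
  chars <- rep(NA_character_, span)
  for (i in seq_len(nrow(records))) {
    pos <- (records$utr_start[i] + 1):records$utr_end[i]
    new <- strsplit(records$sequence[i], "")[[1]]
    old <- chars[pos]
    clash <- !is.na(old) & old != new
    if (any(clash)) {
      stop("overlapping isoform UTRs disagree at gene position ",
           pos[which(clash)[1]] - 1, " for gene ", records$gene_id[1])
    }
    chars[pos] <- new
  }
  ir <- IRanges::reduce(IRanges::IRanges(start = records$utr_start + 1,
                                         end = records$utr_end))
  covered <- !is.na(chars)
  list(gene_id = records$gene_id[1],
       intervals = data.frame(start = IRanges::start(ir) - 1L,
                              end = IRanges::end(ir)),
       sequence = paste(chars[covered], collapse = ""),
       transcript_ids = records$transcript_id)
}

#' Tile starts across a meta-UTR with flank extension
#'
#' Tiles of `tile_len` nt advance by `step` nt starting at `-flank` (inside
#' the upstream flank, so the UTR ends are covered by full-length tiles) and
#' continue while the tile fits inside the flank-extended sequence.
#'
#' @param meta_len meta-UTR length (nt).
#' @param tile_len,step,flank tiling geometry in nt.
#' @return integer vector of 0-based tile starts relative to the meta-UTR
#'   start (negative starts lie in the upstream flank).
#' @export
tile_meta_utr <- function(meta_len, tile_len = 260, step = 6, flank = 260) {
  stopifnot(step > 0, tile_len > 0, flank >= 0)
  ext_len <- meta_len + 2L * flank
  if (ext_len < tile_len) {
    stop("flank-extended sequence (", ext_len,
         " nt) shorter than tile length ", tile_len)
  }
  as.integer(seq.int(from = -flank, by = step,
                     length.out = (ext_len - tile_len) %/% step + 1L))
}

#' Find canonical TDP-43 motif occurrences
#'
#' Scans for all, possibly overlapping, occurrences of GTGTG, TGTGT and
#' GTATG (DNA alphabet) left to right.
#'
#' @param seq a single uppercase DNA string (U is normalised to T).
#' @return data.frame with columns `motif`, `start`, `end` (0-based
#'   half-open), ordered by start.
#' @export
find_motifs <- function(seq) {
  stopifnot(length(seq) == 1)
  seq <- chartr("Uu", "Tt", toupper(seq))
  hits <- lapply(tdp43_motifs(), function(m) {
    st <- gregexpr(paste0("(?=", m, ")"), seq, perl = TRUE)[[1]]
    if (st[1] == -1) return(NULL)
    data.frame(motif = m, start = as.integer(st) - 1L,
               end = as.integer(st) + 4L, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, hits)
  if (is.null(out)) {
    return(data.frame(motif = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  out[order(out$start, out$motif), , drop = FALSE]
}

#' Mutate motif occurrences by base complementation
#'
#' Every position covered by at least one motif hit is replaced by its base
#' complement (G<->C, A<->T), which reproduces the per-motif substitutions
#' GTGTG->CACAC, TGTGT->ACACA, GTATG->CATAC and extends them consistently
#' over overlapping occurrences. Positions outside hits are untouched.
#'
#' @param seq a single DNA string.
#' @param hits data.frame as returned by [find_motifs()] on `seq`.
#' @return the mutated sequence.
#' @export
mutate_motifs <- function(seq, hits) {
  if (is.null(hits) || nrow(hits) == 0) return(seq)
  n <- nchar(seq)
  if (any(hits$start < 0) || any(hits$end > n)) {
    stop("motif hit interval out of sequence bounds")
  }
  chars <- strsplit(seq, "")[[1]]
  covered <- unique(unlist(mapply(function(s, e) (s + 1):e,
                                  hits$start, hits$end, SIMPLIFY = FALSE)))
  chars[covered] <- dna_complement(chars[covered])
  paste(chars, collapse = "")
}

#' @noRd
encode_hits <- function(hits) {
  if (nrow(hits) == 0) return("")
  paste(sprintf("%s:%d-%d", hits$motif, hits$start, hits$end),
        collapse = ";")
}

#' Decode the `motif_hits` manifest column
#' @param x character vector of encoded hit strings ("" for none).
#' @return list of data.frames with columns motif, start, end.
#' @export
decode_hits <- function(x) {
  lapply(x, function(s) {
    if (is.na(s) || s == "") {
      return(data.frame(motif = character(), start = integer(),
                        end = integer(), stringsAsFactors = FALSE))
    }
    parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], "[:-]")
    data.frame(motif = vapply(parts, `[`, character(1), 1),
               start = as.integer(vapply(parts, `[`, character(1), 2)),
               end = as.integer(vapply(parts, `[`, character(1), 3)),
               stringsAsFactors = FALSE)
  })
}

#' Assemble the tiling oligo pool
#'
#' Tiles each meta-UTR (extended by its flanks), annotates motif
#' occurrences, emits one mutant companion per motif-containing tile, and
#' adds the 20-nt PCR handles.
#'
#' @param metas list of meta-UTR objects from [merge_meta_utr()], or for the
#'   common single-isoform case, entries with fields `gene_id` and
#'   `sequence`.
#' @param flanks data.frame with columns `gene_id`, `upstream_flank`,
#'   `downstream_flank` (each at least `flank` nt).
#' @param fwd_handle,rev_handle 20-nt PCR handles.
#' @param tile_len,step,flank tiling geometry, see [tile_meta_utr()].
#' @return list with `manifest` (data.frame: oligo_id, gene_id, start,
#'   variable_seq, full_seq, motif_hits, is_mutant, companion_id) and
#'   `sequences` (named character vector of full oligo sequences).
#' @export
assemble_pool <- function(metas, flanks,
                          fwd_handle = default_fwd_handle(),
                          rev_handle = default_rev_handle(),
                          tile_len = 260, step = 6, flank = 260) {
  stopifnot(nchar(fwd_handle) == 20, nchar(rev_handle) == 20)
  rows <- vector("list", length(metas))
  for (g in seq_along(metas)) {
    meta <- metas[[g]]
    fl <- flanks[flanks$gene_id == meta$gene_id, , drop = FALSE]
    if (nrow(fl) != 1) stop("missing flank sequences for ", meta$gene_id)
    up <- fl$upstream_flank
    down <- fl$downstream_flank
    if (nchar(up) < flank || nchar(down) < flank) {
      stop("flank sequences shorter than ", flank, " nt for ", meta$gene_id)
    }
    ext <- paste0(substr(up, nchar(up) - flank + 1, nchar(up)),
                  meta$sequence, substr(down, 1, flank))
    starts <- tile_meta_utr(nchar(meta$sequence), tile_len, step, flank)
    tiles <- lapply(seq_along(starts), function(k) {
      s0 <- starts[k]
      var <- substr(ext, s0 + flank + 1, s0 + flank + tile_len)
      hits <- find_motifs(var)
      id <- sprintf("%s_t%03d", meta$gene_id, k)
      wt <- data.frame(oligo_id = id, gene_id = meta$gene_id, start = s0,
                       variable_seq = var, motif_hits = encode_hits(hits),
                       is_mutant = FALSE,
                       companion_id = if (nrow(hits) > 0) paste0(id, "_mut")
                                      else NA_character_,
                       stringsAsFactors = FALSE)
      if (nrow(hits) == 0) return(wt)
      mut <- wt
      mut$oligo_id <- paste0(id, "_mut")
      mut$variable_seq <- mutate_motifs(var, hits)
      mut$is_mutant <- TRUE
      mut$companion_id <- id
      rbind(wt, mut)
    })
    rows[[g]] <- do.call(rbind, tiles)
  }
  manifest <- do.call(rbind, rows)
  if (anyDuplicated(manifest$oligo_id)) {
    stop("duplicate oligo ids in pool: ",
         manifest$oligo_id[duplicated(manifest$oligo_id)][1])
  }
  manifest$full_seq <- paste0(fwd_handle, manifest$variable_seq, rev_handle)
  manifest <- manifest[, c("oligo_id", "gene_id", "start", "variable_seq",
                           "full_seq", "motif_hits", "is_mutant",
                           "companion_id")]
  rownames(manifest) <- NULL
  list(manifest = manifest,
       sequences = setNames(manifest$full_seq, manifest$oligo_id))
}
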