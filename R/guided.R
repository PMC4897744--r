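#' Count reads spanning known-fusion junctions
#'
#' For guided confirmation of known fusion transcripts (BCR-ABL1,
#' ETV6-RUNX1, TCF3-PBX1, MLL fusions), reads are aligned to a reference
#' of the fusion transcripts and counted when they span the annotated
#' junction by at least `min_overlap` bases on each side. Multimapping
#' reads are ignored when `unique_only` is set (the default), since only
#' uniquely aligned reads are evidence for the fusion transcript.
#'
#' @param alignments Tibble of reads aligned to fusion-transcript
#'   references: columns `ref`, `read_id`, `start`, `end` (0-based
#'   half-open positions on the reference) and `n_alignments` (1 for
#'   uniquely mapped reads).
#' @param references Tibble with columns `ref` and `junction_pos` (0-based
#'   position of the first base 3' of the junction).
#' @param min_overlap Minimum bases spanned on each side of the junction.
#' @param unique_only Count only uniquely mapped reads (default `TRUE`).
#' @param min_reads Reads required to call the fusion confirmed
#'   (default 2).
#' @return Tibble with one row per reference: `ref`, `n_junction_reads`,
#'   `confirmed`.
#' @export
count_junction_reads <- function(alignments, references, min_overlap = 10L,
                                 unique_only = TRUE, min_reads = 2L) {
  if (anyNA(references$junction_pos)) {
    bad <- references$ref[is.na(references$junction_pos)]
    stop("reference(s) without junction annotation: ",
         paste(bad, collapse = ", "))
  }
  missing_ref <- setdiff(unique(alignments$ref), references$ref)
  if (length(missing_ref) > 0) {
    stop("reference(s) without junction annotation: ",
         paste(missing_ref, collapse = ", "))
  }
  aln <- alignments
  if (unique_only) aln <- aln[aln$n_alignments == 1L, ]
  aln <- dplyr::inner_join(aln, references, by = "ref")
  spanning <- aln[aln$start <= aln$junction_pos - min_overlap &
                    aln$end >= aln$junction_pos + min_overlap, ]
  counts <- spanning |>
    dplyr::count(.data$ref, name = "n_junction_reads")
  out <- dplyr::left_join(references["ref"], counts, by = "ref")
  out$n_junction_reads[is.na(out$n_junction_reads)] <- 0L
  out$confirmed <- out$n_junction_reads >= min_reads
  tibble::as_tibble(out)
}

#' DUX4 search windows of an annotation
#'
#' The guided DUX4 search considers any region within `flank` bp of a DUX4
#' repeat copy; this returns one window interval per copy.
#'
#' @param ann A `genome_annotation`.
#' @param flank Flank size in bp (default 2000).
#' @return Tibble with columns chrom, start, end.
#' @export
dux4_windows <- function(ann, flank = 2000L) {
  cp <- ann$special$dux4_copies
  tibble::tibble(chrom = cp$chrom,
                 start = pmax(0L, cp$start - flank),
                 end = cp$end + flank)
}

#' CRLF2 search window of an annotation
#'
#' A single interval of `span` bp total centred on the CRLF2 gene (the
#' region screened for read pairs linking to the IGH locus).
#'
#' @param ann A `genome_annotation`.
#' @param span Total window span in bp (default 65 kb).
#' @return One-row tibble with columns chrom, start, end.
#' @export
crlf2_window <- function(ann, span = 65000L) {
  g <- ann$special$crlf2
  mid <- (g$start + g$end) %/% 2L
  tibble::tibble(chrom = g$chrom,
                 start = max(0L, mid - span %/% 2L),
                 end = mid + span %/% 2L + span %% 2L)
}

#' Detect a rearrangement from window-to-locus read-pair linking
#'
#' Counts read pairs with one mate overlapping any window interval and the
#' other mate overlapping the partner locus, in either mate order; a pair
#' whose window mate overlaps several window intervals (e.g. multiple DUX4
#' repeat copies) is counted once. Two preset modes fix the calling
#' threshold:
#' \describe{
#'   \item{crlf2}{a 65-kb window around CRLF2 linked to the IGH locus;
#'     called when the count exceeds 50 (strict).}
#'   \item{dux4}{2-kb flanks around every DUX4 repeat copy linked to the
#'     IGH locus; called at `min_pairs` or more pairs (default 10 — the
#'     count is always reported so any cut-off can be applied).}
#' }
#' Mapping quality is ignored by default: the multi-copy DUX4 repeat
#' forces multimapping. A `min_mapq` filter is available for single-copy
#' windows such as CRLF2.
#'
#' @param pairs BEDPE-like pair tibble (chrom1, start1, end1, chrom2,
#'   start2, end2, name, mapq1, mapq2).
#' @param window Tibble of window intervals (chrom, start, end); must be
#'   non-empty.
#' @param partner One-row tibble: the partner locus interval.
#' @param mode One of `"crlf2"`, `"dux4"`, `"custom"`.
#' @param min_pairs Calling threshold for dux4/custom modes (pairs >=
#'   threshold call; crlf2 mode uses the strict > 50 rule).
#' @param min_mapq Optional minimum mapping quality required of both
#'   mates.
#' @return List of class `link_call`: `mode`, `window`, `partner`,
#'   `n_linking_pairs`, `called`.
#' @export
detect_region_link <- function(pairs, window, partner,
                               mode = c("custom", "crlf2", "dux4"),
                               min_pairs = 10L, min_mapq = NULL) {
  mode <- match.arg(mode)
  if (is.null(window) || nrow(window) == 0) {
    stop("empty window set: the guided search needs at least one window interval")
  }
  stopifnot(nrow(partner) == 1)
  if (nrow(pairs) > 0 && !is.null(min_mapq)) {
    pairs <- pairs[pairs$mapq1 >= min_mapq & pairs$mapq2 >= min_mapq, ]
  }
  hits_any <- function(chrom, start, end, iv) {
    out <- rep(FALSE, length(chrom))
    for (i in seq_len(nrow(iv))) {
      out <- out | (chrom == iv$chrom[i] & start < iv$end[i] & end > iv$start[i])
    }
    out
  }
  n <- if (nrow(pairs) == 0) 0L else {
    w1 <- hits_any(pairs$chrom1, pairs$start1, pairs$end1, window)
    w2 <- hits_any(pairs$chrom2, pairs$start2, pairs$end2, window)
    p1 <- hits_any(pairs$chrom1, pairs$start1, pairs$end1, partner)
    p2 <- hits_any(pairs$chrom2, pairs$start2, pairs$end2, partner)
    sum((w1 & p2) | (w2 & p1))
  }
  called <- switch(mode,
    crlf2 = n > 50L,
    dux4 = n >= min_pairs,
    custom = n >= min_pairs
  )
  structure(list(mode = mode, window = window, partner = partner,
                 n_linking_pairs = as.integer(n), called = called),
            class = "link_call")
}

#' @export
print.link_call <- function(x, ...) {
  cat(sprintf("link_call [%s]: %d linking pair(s); %s\n", x$mode,
              x$n_linking_pairs, if (x$called) "CALLED" else "not called"))
  invisible(x)
}

#' Guided CRLF2/DUX4 screen of one sample
#'
#' Convenience wrapper running [detect_region_link()] with the preset
#' windows of an annotation: the 65-kb CRLF2 window or the 2-kb DUX4
#' repeat flanks, each against the IGH locus.
#'
#' @param pairs BEDPE-like pair tibble.
#' @param ann A `genome_annotation`.
#' @param mode `"crlf2"` or `"dux4"`.
#' @param ... Passed to [detect_region_link()].
#' @return A `link_call`.
#' @export
guided_screen <- function(pairs, ann, mode = c("crlf2", "dux4"), ...) {
  mode <- match.arg(mode)
  window <- switch(mode, crlf2 = crlf2_window(ann), dux4 = dux4_windows(ann))
  detect_region_link(pairs, window, ann$special$igh, mode = mode, ...)
}
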