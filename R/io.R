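#' Write an annotation to GTF
#'
#' Exports gene, exon and CDS features. Internal 0-based half-open
#' coordinates become 1-based inclusive in the file.
#'
#' @param ann A `genome_annotation`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_annotation_gtf <- function(ann, path) {
  feat <- function(df, type) {
    g <- ann$genes[match(df$gene_id, ann$genes$gene_id), ]
    tibble::tibble(
      chrom = g$chrom, start = df$start, end = df$end, strand = g$strand,
      type = type, gene_id = df$gene_id,
      transcript_id = if ("transcript_id" %in% names(df)) df$transcript_id else NA_character_,
      exon_number = if ("exon_number" %in% names(df)) df$exon_number else NA_integer_,
      gene_name = g$symbol, gene_biotype = g$biotype, locus_class = g$locus_class,
      phase = if ("phase" %in% names(df)) df$phase else NA_integer_
    )
  }
  cds <- ann$cds |>
    dplyr::arrange(.data$transcript_id, .data$exon_number) |>
    dplyr::group_by(.data$transcript_id) |>
    dplyr::mutate(phase = (3L - cumsum(dplyr::lag(.data$end - .data$start,
                                                  default = 0L)) %% 3L) %% 3L) |>
    dplyr::ungroup()
  all <- dplyr::bind_rows(
    feat(ann$genes, "gene"), feat(ann$exons, "exon"), feat(cds, "CDS")
  )
  gr <- GenomicRanges::GRanges(
    seqnames = all$chrom,
    ranges = IRanges::IRanges(start = all$start + 1L, end = all$end),
    strand = all$strand
  )
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    source = "leukotype", type = all$type, gene_id = all$gene_id,
    transcript_id = all$transcript_id, exon_number = all$exon_number,
    gene_name = all$gene_name, gene_biotype = all$gene_biotype,
    locus_class = all$locus_class, phase = all$phase
  )
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Read an annotation from GTF
#'
#' Reconstructs a `genome_annotation` from a GTF written by
#' [write_annotation_gtf()]. Files from other sources are accepted as long
#' as they carry gene, exon and CDS features with `gene_id` attributes;
#' `gene_biotype` and `locus_class` default to protein_coding/normal when
#' absent. Special regions (IGH, TRA, DUX4 repeat copies, CRLF2) are
#' rebuilt from gene symbols; DUX4 copies are reconstructed as seven
#' repeat units anchored at the annotated DUX4 gene.
#'
#' @param path GTF file path.
#' @return A `genome_annotation`.
#' @export
read_annotation_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  df <- tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,  # back to 0-based half-open
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(gr$type),
    gene_id = gr$gene_id,
    transcript_id = if (!is.null(gr$transcript_id)) gr$transcript_id else NA_character_,
    exon_number = if (!is.null(gr$exon_number)) as.integer(gr$exon_number) else NA_integer_,
    symbol = if (!is.null(gr$gene_name)) gr$gene_name else gr$gene_id,
    biotype = if (!is.null(gr$gene_biotype)) gr$gene_biotype else "protein_coding",
    locus_class = if (!is.null(gr$locus_class)) gr$locus_class else "normal"
  )
  genes <- df[df$type == "gene",
              c("gene_id", "symbol", "chrom", "start", "end", "strand",
                "biotype", "locus_class")]
  genes <- genes[order(genes$gene_id), ]
  exons <- df[df$type == "exon",
              c("gene_id", "transcript_id", "exon_number", "start", "end")]
  exons <- exons[order(exons$gene_id, exons$exon_number), ]
  cds <- df[df$type == "CDS",
            c("gene_id", "transcript_id", "exon_number", "start", "end")]
  cds <- cds[order(cds$gene_id, cds$exon_number), ]
  transcripts <- cds |>
    dplyr::group_by(.data$gene_id, .data$transcript_id) |>
    dplyr::summarise(cds_len = sum(.data$end - .data$start), .groups = "drop") |>
    dplyr::mutate(cds_divisible_by_3 = .data$cds_len %% 3L == 0L)
  sym <- function(s) genes[genes$symbol == s, c("chrom", "start", "end")]
  dux4 <- sym("DUX4")
  dux4_copies <- if (nrow(dux4) == 1) {
    unit <- (dux4$end - dux4$start) + 2000L
    tibble::tibble(copy = 1:7, chrom = dux4$chrom,
                   start = dux4$start + (0:6) * unit,
                   end = dux4$start + (0:6) * unit + (dux4$end - dux4$start))
  } else {
    tibble::tibble(copy = integer(), chrom = character(),
                   start = integer(), end = integer())
  }
  ann <- structure(
    list(genes = genes, exons = exons, cds = cds, transcripts = transcripts,
         special = list(igh = sym("IGH"), tra = sym("TRA"),
                        dux4_copies = dux4_copies, crlf2 = sym("CRLF2"))),
    class = "genome_annotation"
  )
  validate_annotation(ann)
  ann
}

#' Read/write fusion-candidate tables
#'
#' Tab-separated candidate tables with one row per caller-reported fusion:
#' caller, gene5, gene3, chrom5, pos5, strand5, chrom3, pos3, strand3,
#' junction_reads, total_reads, readthrough_flag, low_mapq_exon_fraction,
#' normal_panel_hit, interchromosomal, also_detected_by_other_caller.
#'
#' @param x Candidate tibble.
#' @param path File path.
#' @return The tibble (read) or `path` invisibly (write).
#' @export
write_candidates_tsv <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}

#' @rdname write_candidates_tsv
#' @export
read_candidates_tsv <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    caller = "c", gene5 = "c", gene3 = "c",
    chrom5 = "c", pos5 = "i", strand5 = "c",
    chrom3 = "c", pos3 = "i", strand3 = "c",
    junction_reads = "i", total_reads = "i",
    readthrough_flag = "l", low_mapq_exon_fraction = "d",
    normal_panel_hit = "l", interchromosomal = "l",
    also_detected_by_other_caller = "l"
  ))
}

#' Read/write read-pair linking evidence (BEDPE-like TSV)
#'
#' Columns: chrom1, start1, end1, chrom2, start2, end2, name, mapq1, mapq2.
#' Coordinates 0-based half-open, as in BEDPE.
#'
#' @param x Pair tibble.
#' @param path File path.
#' @return The tibble (read) or `path` invisibly (write).
#' @export
write_pairs_bedpe <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}

#' @rdname write_pairs_bedpe
#' @export
read_pairs_bedpe <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    chrom1 = "c", start1 = "i", end1 = "i",
    chrom2 = "c", start2 = "i", end2 = "i",
    name = "c", mapq1 = "i", mapq2 = "i"
  ))
}

#' Read/write per-sample splice-junction tables
#'
#' The on-disk dialect follows STAR's `SJ.out.tab`: chrom, intron start and
#' end (1-based inclusive), strand (0 = undefined, 1 = +, 2 = -), number of
#' uniquely mapping reads, and an annotated flag. In memory the junction is
#' kept 0-based half-open as (donor_pos, acceptor_pos): the first intronic
#' base and the first exonic base after the intron.
#'
#' @param x Junction tibble with columns chrom, donor_pos, acceptor_pos,
#'   strand, read_count, annotated.
#' @param path File path.
#' @return The tibble (read) or `path` invisibly (write).
#' @export
write_junctions_star <- function(x, path) {
  out <- tibble::tibble(
    chrom = x$chrom,
    intron_start = x$donor_pos + 1L,
    intron_end = x$acceptor_pos,
    strand = dplyr::case_match(x$strand, "+" ~ 1L, "-" ~ 2L, .default = 0L),
    n_unique_reads = x$read_count,
    annotated_flag = as.integer(x$annotated)
  )
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' @rdname write_junctions_star
#' @export
read_junctions_star <- function(path) {
  raw <- readr::read_tsv(
    path, col_names = c("chrom", "intron_start", "intron_end", "strand",
                        "n_unique_reads", "annotated_flag"),
    col_types = "ciiiii"
  )
  tibble::tibble(
    chrom = raw$chrom,
    donor_pos = raw$intron_start - 1L,
    acceptor_pos = raw$intron_end,
    strand = dplyr::case_match(raw$strand, 1L ~ "+", 2L ~ "-", .default = "*"),
    read_count = raw$n_unique_reads,
    annotated = raw$annotated_flag == 1L
  )
}

#' Read/write a log2 expression matrix
#'
#' Tab-separated, gene rows by sample columns, first column `gene_id`.
#'
#' @param mat Numeric matrix, genes in rows (rownames = gene ids), samples
#'   in columns.
#' @param path File path.
#' @return The matrix (read) or `path` invisibly (write).
#' @export
write_expression_tsv <- function(mat, path) {
  df <- tibble::as_tibble(mat, rownames = "gene_id")
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = "c", .default = "d"
  ))
  mat <- as.matrix(df[, -1])
  rownames(mat) <- df$gene_id
  mat
}

#' Read/write per-sample metadata
#'
#' Columns: sample, label, fusion_tokens (semicolon-joined; empty when the
#' sample carries no subtype-defining fusion evidence).
#'
#' @param meta Tibble with columns sample, label, fusion_tokens.
#' @param path File path.
#' @return The tibble (read) or `path` invisibly (write).
#' @export
write_metadata_tsv <- function(meta, path) {
  out <- meta
  if (is.list(out$fusion_tokens)) {
    out$fusion_tokens <- vapply(out$fusion_tokens, paste, "", collapse = ";")
  }
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_metadata_tsv
#' @export
read_metadata_tsv <- function(path) {
  out <- readr::read_tsv(path, col_types = readr::cols(
    sample = "c", label = "c", fusion_tokens = "c"
  ))
  out$fusion_tokens <- lapply(out$fusion_tokens, function(s) {
    if (is.na(s) || s == "") character(0) else strsplit(s, ";", fixed = TRUE)[[1]]
  })
  out
}
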