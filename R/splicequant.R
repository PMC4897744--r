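#' Relative splice-junction usage per donor/acceptor site
#'
#' Quantifies alternative splicing as the fraction of reads supporting
#' each junction among all junction reads sharing a splice donor or
#' acceptor site. The junction universe comprises intragenic junctions
#' (both ends within one annotated gene) supported by at least `min_reads`
#' reads in at least one sample and having at least one end that coincides
#' exactly with an annotated exon boundary. Junctions outside genes are
#' dropped with a message. Fractions are computed per donor site and per
#' acceptor site independently, so a junction is quantified (and later
#' reportable) via either end. When a site has no reads in a sample, its
#' fractions are reconstructed as the mean over the samples where the site
#' was observed; reconstructed values are flagged and never generate calls
#' downstream.
#'
#' @param tables Named list of per-sample junction tibbles (chrom,
#'   donor_pos, acceptor_pos, strand, read_count, annotated), as produced
#'   by [gen_junction_counts()] or [read_junctions_star()].
#' @param ann A `genome_annotation`.
#' @param min_reads Universe inclusion threshold (default 10): reads
#'   required in at least one sample.
#' @return Tibble of class `site_usage`, complete over
#'   (site x junction x sample): columns gene_id, chrom, site_pos,
#'   site_kind (`donor`/`acceptor`), donor_pos, acceptor_pos, sample,
#'   reads, fraction, observed.
#' @export
compute_site_usage <- function(tables, ann, min_reads = 10L) {
  stopifnot(length(tables) >= 1)
  if (is.null(names(tables)) || any(names(tables) == "")) {
    names(tables) <- sprintf("sample%03d", seq_along(tables))
  }
  long <- dplyr::bind_rows(tables, .id = "sample")

  genes <- ann$genes[, c("gene_id", "chrom", "start", "end")]
  jx <- long |>
    dplyr::distinct(.data$chrom, .data$donor_pos, .data$acceptor_pos, .data$strand)
  jx <- dplyr::inner_join(jx, genes, by = "chrom", relationship = "many-to-many") |>
    dplyr::filter(.data$donor_pos >= .data$start, .data$acceptor_pos <= .data$end) |>
    dplyr::select("gene_id", "chrom", "donor_pos", "acceptor_pos", "strand")
  n_dropped <- nrow(dplyr::anti_join(
    dplyr::distinct(long, .data$chrom, .data$donor_pos, .data$acceptor_pos),
    jx, by = c("chrom", "donor_pos", "acceptor_pos")
  ))
  if (n_dropped > 0) {
    message(n_dropped, " junction(s) outside any single gene dropped")
  }

  # annotated-exon-boundary requirement: >= 1 end exactly at an exon edge
  ex <- dplyr::inner_join(ann$exons, ann$genes[, c("gene_id", "chrom")],
                          by = "gene_id")
  donor_ok <- dplyr::semi_join(jx, ex, by = c("chrom", "donor_pos" = "end"))
  acceptor_ok <- dplyr::semi_join(jx, ex, by = c("chrom", "acceptor_pos" = "start"))
  jx <- dplyr::distinct(dplyr::bind_rows(donor_ok, acceptor_ok))

  # read-support requirement: >= min_reads in >= 1 sample
  support <- long |>
    dplyr::group_by(.data$chrom, .data$donor_pos, .data$acceptor_pos) |>
    dplyr::summarise(max_reads = max(.data$read_count), .groups = "drop")
  jx <- dplyr::inner_join(jx, support,
                          by = c("chrom", "donor_pos", "acceptor_pos")) |>
    dplyr::filter(.data$max_reads >= min_reads) |>
    dplyr::select(-"max_reads")

  if (nrow(jx) == 0) {
    warning("empty junction universe: no junction meets the inclusion criteria")
    out <- tibble::tibble(
      gene_id = character(), chrom = character(), site_pos = integer(),
      site_kind = character(), donor_pos = integer(), acceptor_pos = integer(),
      sample = character(), reads = integer(), fraction = double(),
      observed = logical()
    )
    return(structure(out, class = c("site_usage", class(out))))
  }

  # a junction contributes to its donor site and to its acceptor site
  sites <- dplyr::bind_rows(
    dplyr::mutate(jx, site_pos = .data$donor_pos, site_kind = "donor"),
    dplyr::mutate(jx, site_pos = .data$acceptor_pos, site_kind = "acceptor")
  )
  grid <- tidyr::crossing(sites, sample = names(tables))
  grid <- dplyr::left_join(
    grid,
    long[, c("sample", "chrom", "donor_pos", "acceptor_pos", "read_count")],
    by = c("sample", "chrom", "donor_pos", "acceptor_pos")
  )
  grid$read_count[is.na(grid$read_count)] <- 0L

  grid <- grid |>
    dplyr::group_by(.data$gene_id, .data$chrom, .data$site_pos,
                    .data$site_kind, .data$sample) |>
    dplyr::mutate(site_reads = sum(.data$read_count)) |>
    dplyr::ungroup() |>
    dplyr::mutate(observed = .data$site_reads > 0L,
                  fraction = ifelse(.data$observed,
                                    .data$read_count / .data$site_reads,
                                    NA_real_))
  grid <- grid |>
    dplyr::group_by(.data$gene_id, .data$chrom, .data$site_pos,
                    .data$site_kind, .data$donor_pos, .data$acceptor_pos) |>
    dplyr::mutate(fraction = ifelse(.data$observed, .data$fraction,
                                    mean(.data$fraction[.data$observed]))) |>
    dplyr::ungroup()

  out <- grid |>
    dplyr::transmute(
      gene_id = .data$gene_id, chrom = .data$chrom,
      site_pos = .data$site_pos, site_kind = .data$site_kind,
      donor_pos = .data$donor_pos, acceptor_pos = .data$acceptor_pos,
      sample = .data$sample, reads = .data$read_count,
      fraction = .data$fraction, observed = .data$observed
    ) |>
    dplyr::arrange(.data$gene_id, .data$site_kind, .data$site_pos,
                   .data$donor_pos, .data$acceptor_pos, .data$sample)
  structure(out, class = c("site_usage", class(out)))
}

#' Call leukaemia-specific truncated transcripts
#'
#' Reports (sample, gene, junction) triples where a junction within a
#' target gene is absent from the reference transcripts, undetected in
#' every normal-panel sample, and — in that tumour sample — observed at a
#' site-usage fraction of at least `min_fraction` with at least
#' `min_reads` supporting reads. Such junctions typically reflect
#' intragenic genomic deletions expressing internally truncated
#' transcripts.
#'
#' @param usage A `site_usage` tibble from [compute_site_usage()]
#'   (tumour samples).
#' @param reference_junctions Tibble of reference junctions (chrom,
#'   donor_pos, acceptor_pos), e.g. from [reference_junctions()].
#' @param normal_tables Named list of junction tibbles for the normal
#'   panel; sample names must not overlap the tumour samples.
#' @param ann A `genome_annotation`.
#' @param target_genes Gene symbols to screen (default CDKN2A, PAX5, ETV6,
#'   IKZF1 — the genes most frequently hit by intragenic deletions in
#'   BCP-ALL).
#' @param min_fraction Minimum site-usage fraction in the calling sample
#'   (default 0.1).
#' @param min_reads Minimum supporting reads in the calling sample
#'   (default 10).
#' @return Tibble sorted by gene then sample: sample, gene, chrom,
#'   donor_pos, acceptor_pos, fraction (the maximum over the junction's
#'   two sites), reads.
#' @export
call_truncated_transcripts <- function(usage, reference_junctions, normal_tables,
                                       ann,
                                       target_genes = c("CDKN2A", "PAX5",
                                                        "ETV6", "IKZF1"),
                                       min_fraction = 0.1, min_reads = 10L) {
  overlap <- intersect(unique(usage$sample), names(normal_tables))
  if (length(overlap) > 0) {
    stop("sample id(s) present in both tumour and normal sets: ",
         paste(overlap, collapse = ", "))
  }
  targets <- annotation_genes(ann, target_genes)
  normal_long <- dplyr::bind_rows(normal_tables, .id = "sample")
  seen_in_normal <- normal_long |>
    dplyr::filter(.data$read_count > 0) |>
    dplyr::distinct(.data$chrom, .data$donor_pos, .data$acceptor_pos)

  cand <- usage |>
    dplyr::filter(.data$gene_id %in% targets$gene_id,
                  .data$observed,
                  .data$fraction >= min_fraction,
                  .data$reads >= min_reads) |>
    dplyr::anti_join(reference_junctions[, c("chrom", "donor_pos", "acceptor_pos")],
                     by = c("chrom", "donor_pos", "acceptor_pos")) |>
    dplyr::anti_join(seen_in_normal,
                     by = c("chrom", "donor_pos", "acceptor_pos"))

  if (nrow(cand) == 0) {
    return(tibble::tibble(sample = character(), gene = character(),
                          chrom = character(), donor_pos = integer(),
                          acceptor_pos = integer(), fraction = numeric(),
                          reads = numeric()))
  }
  cand |>
    dplyr::group_by(.data$sample, .data$gene_id, .data$chrom,
                    .data$donor_pos, .data$acceptor_pos) |>
    dplyr::summarise(fraction = max(.data$fraction),
                     reads = max(.data$reads), .groups = "drop") |>
    dplyr::mutate(gene = targets$symbol[match(.data$gene_id, targets$gene_id)]) |>
    dplyr::select("sample", "gene", "chrom", "donor_pos", "acceptor_pos",
                  "fraction", "reads") |>
    dplyr::arrange(.data$gene, .data$sample, .data$donor_pos)
}

#' Write a site-usage matrix to TSV
#'
#' Rows are site:junction combinations, columns samples, values usage
#' fractions.
#'
#' @param usage A `site_usage` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_usage_tsv <- function(usage, path) {
  wide <- usage |>
    dplyr::mutate(id = sprintf("%s:%s:%d:%s:%d-%d", .data$gene_id, .data$chrom,
                               .data$site_pos, .data$site_kind,
                               .data$donor_pos, .data$acceptor_pos)) |>
    dplyr::select("id", "sample", "fraction") |>
    tidyr::pivot_wider(names_from = "sample", values_from = "fraction")
  readr::write_tsv(wide, path)
  invisible(path)
}
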