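#' Generate a synthetic genome annotation
#'
#' Builds a compact genome annotation carrying every locus the BCP-ALL
#' pipeline needs: the immunoglobulin heavy-chain (IGH) locus, a T-cell
#' receptor locus, a subtelomeric macrosatellite repeat with seven
#' near-identical DUX4 copies, CRLF2, the recurrently altered genes ETV6,
#' RUNX1, MLL, PAX5 and IKZF1, the four splice-deletion target genes
#' (CDKN2A, PAX5, ETV6, IKZF1; each with at least five exons), two HLA
#' genes, two non-coding genes and a deliberately close-spaced gene pair
#' (< 10 kb apart) to exercise the proximity exclusion rule. Remaining
#' slots are filled with generic protein-coding genes.
#'
#' Coordinates are 0-based half-open throughout the in-memory
#' representation; [write_annotation_gtf()] converts to the 1-based
#' inclusive GTF dialect at the boundary.
#'
#' @param seed Integer seed; the same seed reproduces the annotation
#'   byte-for-byte.
#' @param n_genes Total number of genes (must be at least 20 to host the
#'   required loci).
#'
#' @return An object of class `genome_annotation`: a list with elements
#'   `genes` (tibble: gene_id, symbol, chrom, start, end, strand, biotype,
#'   locus_class), `exons` (tibble: gene_id, transcript_id, exon_number,
#'   start, end), `cds` (same shape as `exons`, restricted to coding
#'   segments, plus `cds_len_mod3` recorded per transcript in
#'   `transcripts`), `transcripts` (tibble: gene_id, transcript_id,
#'   cds_divisible_by_3) and `special` (list with `igh`, `tra`,
#'   `dux4_copies`, `crlf2` interval tibbles).
#' @export
gen_annotation <- function(seed, n_genes = 50L) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  if (n_genes < 20L) {
    stop("n_genes = ", n_genes, " is too small to host the required loci; ",
         "need at least 20 genes.")
  }
  withr::with_seed(as.integer(seed), build_annotation(as.integer(n_genes)))
}

# Named loci with their designated chromosomes (echoing the human map so the
# simulated tables read naturally).
.required_loci <- function() {
  tibble::tribble(
    ~symbol,   ~chrom,  ~biotype,          ~locus_class, ~n_exons,
    "IGH",     "chr14", "IG_gene",         "IG",         3L,
    "TRA",     "chr14", "TR_gene",         "TCR",        3L,
    "DUX4",    "chr4",  "protein_coding",  "normal",     1L,
    "CRLF2",   "chrX",  "protein_coding",  "normal",     6L,
    "ERG",     "chr21", "protein_coding",  "normal",     9L,
    "ETV6",    "chr12", "protein_coding",  "normal",     8L,
    "RUNX1",   "chr21", "protein_coding",  "normal",     8L,
    "MLL",     "chr11", "protein_coding",  "normal",     9L,
    "PAX5",    "chr9",  "protein_coding",  "normal",     9L,
    "IKZF1",   "chr7",  "protein_coding",  "normal",     8L,
    "CDKN2A",  "chr9",  "protein_coding",  "normal",     5L,
    "HLA-A",   "chr6",  "protein_coding",  "HLA",        6L,
    "HLA-B",   "chr6",  "protein_coding",  "HLA",        6L,
    "LINC01A", "chr2",  "lincRNA",         "normal",     3L,
    "LINC02B", "chr3",  "lincRNA",         "normal",     3L
  )
}

build_annotation <- function(n_genes) {
  req <- .required_loci()
  n_filler <- n_genes - nrow(req) - 2L  # two filler slots reserved for the near pair
  filler_chroms <- paste0("chr", 1:22)
  filler <- tibble::tibble(
    symbol      = sprintf("GENE%03d", seq_len(max(n_filler, 0L))),
    chrom       = sample(filler_chroms, max(n_filler, 0L), replace = TRUE),
    biotype     = "protein_coding",
    locus_class = "normal",
    n_exons     = sample(5:9, max(n_filler, 0L), replace = TRUE)
  )
  near <- tibble::tibble(
    symbol      = c("NEARA", "NEARB"),
    chrom       = "chr1",
    biotype     = "protein_coding",
    locus_class = "normal",
    n_exons     = c(5L, 5L)
  )
  genes <- dplyr::bind_rows(req, filler, near)
  genes$gene_id <- sprintf("G%04d", seq_len(nrow(genes)))

  exons <- list(); cds <- list(); placed <- list()
  for (chr in unique(genes$chrom)) {
    idx <- which(genes$chrom == chr)
    # NEARB is forced to follow NEARA with a sub-10-kb gap
    idx <- idx[order(genes$symbol[idx] == "NEARB")]
    pos <- sample(10000:50000, 1)
    for (i in idx) {
      g <- genes[i, ]
      struct <- make_gene_structure(g$symbol, g$biotype, g$n_exons, pos)
      placed[[g$gene_id]] <- tibble::tibble(
        gene_id = g$gene_id, start = struct$start, end = struct$end,
        strand = struct$strand
      )
      exons[[g$gene_id]] <- dplyr::mutate(struct$exons, gene_id = g$gene_id)
      if (!is.null(struct$cds)) {
        cds[[g$gene_id]] <- dplyr::mutate(struct$cds, gene_id = g$gene_id)
      }
      gap <- if (g$symbol == "NEARA") {
        sample(2000:8000, 1)
      } else if (g$symbol == "DUX4") {
        # leave room for the six downstream repeat copies
        6L * ((struct$end - struct$start) + 2000L) + sample(15000:60000, 1)
      } else {
        sample(15000:60000, 1)
      }
      pos <- struct$end + gap
    }
  }
  placed <- dplyr::bind_rows(placed)
  genes <- dplyr::inner_join(genes, placed, by = "gene_id")
  genes <- genes[order(genes$gene_id),
                 c("gene_id", "symbol", "chrom", "start", "end", "strand",
                   "biotype", "locus_class")]

  exons <- dplyr::bind_rows(exons)
  exons$transcript_id <- paste0(exons$gene_id, ".t1")
  exons <- exons[order(exons$gene_id, exons$exon_number),
                 c("gene_id", "transcript_id", "exon_number", "start", "end")]
  cds <- dplyr::bind_rows(cds)
  cds$transcript_id <- paste0(cds$gene_id, ".t1")
  cds <- cds[order(cds$gene_id, cds$exon_number),
             c("gene_id", "transcript_id", "exon_number", "start", "end")]

  transcripts <- cds |>
    dplyr::group_by(.data$gene_id, .data$transcript_id) |>
    dplyr::summarise(cds_len = sum(.data$end - .data$start), .groups = "drop") |>
    dplyr::mutate(cds_divisible_by_3 = .data$cds_len %% 3L == 0L)

  dux4 <- genes[genes$symbol == "DUX4", ]
  copy_len <- dux4$end - dux4$start
  unit <- copy_len + 2000L  # macrosatellite repeat unit spacing
  dux4_copies <- tibble::tibble(
    copy  = seq_len(7L),
    chrom = dux4$chrom,
    start = dux4$start + (seq_len(7L) - 1L) * unit,
    end   = dux4$start + (seq_len(7L) - 1L) * unit + copy_len
  )
  sym <- function(s) genes[genes$symbol == s, c("chrom", "start", "end")]
  ann <- structure(
    list(genes = genes, exons = exons, cds = cds, transcripts = transcripts,
         special = list(igh = sym("IGH"), tra = sym("TRA"),
                        dux4_copies = dux4_copies, crlf2 = sym("CRLF2"))),
    class = "genome_annotation"
  )
  validate_annotation(ann)
  ann
}

# One transcript per gene; exon/intron sizes are drawn, CDS trimmed to a
# multiple of three so frame arithmetic has a clean reference.
make_gene_structure <- function(symbol, biotype, n_exons, gene_start) {
  exon_len <- sample(90:300, n_exons, replace = TRUE)
  intron_len <- if (n_exons > 1) sample(500:3000, n_exons - 1, replace = TRUE) else integer(0)
  starts <- gene_start + cumsum(c(0L, exon_len[-n_exons] + intron_len))
  ends <- starts + exon_len
  exons <- tibble::tibble(exon_number = seq_len(n_exons), start = starts, end = ends)
  coding <- biotype %in% c("protein_coding")
  cds <- NULL
  if (coding) {
    utr5 <- min(30L, exon_len[1] %/% 3L)
    utr3 <- min(30L, exon_len[n_exons] %/% 3L)
    cds <- exons
    cds$start[1] <- cds$start[1] + utr5
    cds$end[n_exons] <- cds$end[n_exons] - utr3
    excess <- sum(cds$end - cds$start) %% 3L
    cds$end[n_exons] <- cds$end[n_exons] - excess
  }
  list(start = gene_start, end = ends[n_exons], strand = "+",
       exons = exons, cds = cds)
}

validate_annotation <- function(ann) {
  stopifnot(inherits(ann, "genome_annotation"))
  ex <- dplyr::inner_join(ann$exons, ann$genes, by = "gene_id",
                          suffix = c("", ".g"))
  stopifnot(all(ex$start >= ex$start.g), all(ex$end <= ex$end.g))
  stopifnot(all(ann$cds$end > ann$cds$start))
  invisible(ann)
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("genome_annotation:", nrow(x$genes), "genes on",
      length(unique(x$genes$chrom)), "chromosomes;",
      nrow(x$exons), "exons;", nrow(x$special$dux4_copies), "DUX4 copies\n")
  invisible(x)
}

#' Look up genes by id or symbol
#'
#' @param ann A `genome_annotation`.
#' @param ids Character vector of gene ids or symbols.
#' @return The matching rows of `ann$genes`; unknown ids raise an error
#'   naming the offender.
#' @export
annotation_genes <- function(ann, ids) {
  hit <- ann$genes$gene_id %in% ids | ann$genes$symbol %in% ids
  found <- unique(c(ann$genes$gene_id[hit], ann$genes$symbol[hit]))
  missing <- setdiff(ids, found)
  if (length(missing) > 0) {
    stop("unknown gene id(s): ", paste(missing, collapse = ", "))
  }
  out <- ann$genes[hit, ]
  # preserve query order
  key <- ifelse(ids %in% out$gene_id, ids,
                out$gene_id[match(ids, out$symbol)])
  out[match(key, out$gene_id), ]
}

#' Reference splice junctions of an annotation
#'
#' Enumerates the intron junctions of every annotated transcript. A
#' junction is keyed by its intron interval in 0-based half-open genomic
#' coordinates: `donor_pos` is the first intronic base, `acceptor_pos` the
#' first exonic base after the intron.
#'
#' @param ann A `genome_annotation`.
#' @return Tibble with columns gene_id, chrom, donor_pos, acceptor_pos,
#'   strand.
#' @export
reference_junctions <- function(ann) {
  ex <- dplyr::inner_join(
    ann$exons,
    ann$genes[, c("gene_id", "chrom", "strand")], by = "gene_id"
  )
  ex |>
    dplyr::arrange(.data$gene_id, .data$exon_number) |>
    dplyr::group_by(.data$gene_id, .data$transcript_id) |>
    dplyr::reframe(
      chrom = .data$chrom[-1],
      donor_pos = .data$end[-dplyr::n()],
      acceptor_pos = .data$start[-1],
      strand = .data$strand[-1]
    ) |>
    dplyr::distinct(.data$gene_id, .data$chrom, .data$donor_pos,
                    .data$acceptor_pos, .data$strand)
}

# closest edge-to-edge distance between two distinct genes; Inf when on
# different chromosomes
gene_distance <- function(ann, id1, id2) {
  g1 <- annotation_genes(ann, id1)
  g2 <- annotation_genes(ann, id2)
  if (g1$chrom != g2$chrom) return(Inf)
  if (g1$start < g2$end && g2$start < g1$end) return(0)
  max(g1$start - g2$end, g2$start - g1$end)
}
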