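# Shared fixtures: one small annotation reused across tests.
TEST_ANN <- gen_annotation(42, 30)

# A hand-built two-gene annotation for frame tests: single-exon genes on one
# chromosome, CDS lengths chosen by the caller. Returns the annotation and
# the CDS start coordinates.
toy_two_gene_ann <- function(cds_len5, cds_len3, utr5 = 30L, utr3 = 30L) {
  gs1 <- 1000L; gs2 <- 100000L
  genes <- tibble::tibble(
    gene_id = c("T5", "T3"), symbol = c("T5", "T3"), chrom = "chrT",
    start = c(gs1, gs2),
    end = c(gs1 + utr5 + cds_len5 + utr3, gs2 + utr5 + cds_len3 + utr3),
    strand = "+", biotype = "protein_coding", locus_class = "normal"
  )
  exons <- tibble::tibble(
    gene_id = c("T5", "T3"), transcript_id = c("T5.t1", "T3.t1"),
    exon_number = 1L, start = genes$start, end = genes$end
  )
  cds <- tibble::tibble(
    gene_id = c("T5", "T3"), transcript_id = c("T5.t1", "T3.t1"),
    exon_number = 1L, start = genes$start + utr5,
    end = genes$start + utr5 + c(cds_len5, cds_len3)
  )
  ann <- structure(
    list(genes = genes, exons = exons, cds = cds,
         transcripts = tibble::tibble(gene_id = c("T5", "T3"),
                                      transcript_id = c("T5.t1", "T3.t1"),
                                      cds_len = c(cds_len5, cds_len3),
                                      cds_divisible_by_3 = TRUE),
         special = list(igh = genes[0, c("chrom", "start", "end")],
                        tra = genes[0, c("chrom", "start", "end")],
                        dux4_copies = tibble::tibble(copy = integer(),
                                                     chrom = character(),
                                                     start = integer(),
                                                     end = integer()),
                        crlf2 = genes[0, c("chrom", "start", "end")])),
    class = "genome_annotation"
  )
  list(ann = ann, cds_start5 = genes$start[1] + utr5,
       cds_start3 = genes$start[2] + utr5)
}

# Randomised candidate rows spanning all gene categories and read-support
# boundaries, for cascade-vs-oracle comparisons.
random_candidates <- function(n, ann, seed) {
  withr::with_seed(seed, {
    g <- ann$genes
    igh <- g[g$symbol == "IGH", ]
    pick <- function() g[sample(nrow(g), 1), ]
    rows <- lapply(seq_len(n), function(i) {
      if (stats::runif(1) < 0.05) {
        g5 <- igh; g3 <- igh
      } else {
        g5 <- pick(); g3 <- pick()
      }
      jr <- sample(c(0:20, 45:55), 1)
      tibble::tibble(
        caller = sample(c("chimerascan", "tophatfusion"), 1),
        gene5 = g5$gene_id, gene3 = g3$gene_id,
        chrom5 = g5$chrom, pos5 = as.integer(sample(g5$start:(g5$end - 1L), 1)),
        strand5 = g5$strand,
        chrom3 = g3$chrom, pos3 = as.integer(sample(g3$start:(g3$end - 1L), 1)),
        strand3 = g3$strand,
        junction_reads = jr,
        total_reads = jr + sample(c(0:10, 40:60), 1),
        readthrough_flag = stats::runif(1) < 0.15,
        low_mapq_exon_fraction = sample(c(stats::runif(1, 0, 0.75),
                                          0.75, 0.76,
                                          stats::runif(1, 0.76, 1)), 1),
        normal_panel_hit = stats::runif(1) < 0.15,
        interchromosomal = g5$chrom != g3$chrom,
        also_detected_by_other_caller = stats::runif(1) < 0.5
      )
    })
    dplyr::bind_rows(rows)
  })
}

# Independent single-rule brute-force oracle for the filter cascade. Each
# rule is evaluated in isolation, directly from the candidate fields and
# the annotation tables, without calling the package's rule functions.
oracle_filter <- function(candidates, ann, known_fusions,
                          rescue_bypasses_exclusion = FALSE) {
  g <- ann$genes
  row_of <- function(id) g[g$gene_id == id | g$symbol == id, ]
  inside <- function(iv, chrom, pos) {
    nrow(iv) == 1 && chrom == iv$chrom && pos >= iv$start && pos < iv$end
  }
  nc_biotypes <- c("lincRNA", "ncRNA", "misc_RNA", "antisense")

  one_inc <- function(cd) {
    (cd$caller == "chimerascan" && (cd$junction_reads >= 10 || cd$total_reads > 50)) ||
      (cd$caller == "tophatfusion" && cd$junction_reads > 15) ||
      (cd$interchromosomal && cd$also_detected_by_other_caller)
  }
  one_exc <- function(cd) {
    g5 <- row_of(cd$gene5); g3 <- row_of(cd$gene3)
    e <- character(0)
    if (cd$readthrough_flag) e <- c(e, "E1")
    if (cd$low_mapq_exon_fraction > 0.75) e <- c(e, "E2")
    if (cd$normal_panel_hit) e <- c(e, "E3")
    if ((inside(ann$special$igh, cd$chrom5, cd$pos5) &&
         inside(ann$special$igh, cd$chrom3, cd$pos3)) ||
        (inside(ann$special$tra, cd$chrom5, cd$pos5) &&
         inside(ann$special$tra, cd$chrom3, cd$pos3)) ||
        (g5$locus_class == "HLA" && g3$locus_class == "HLA")) {
      e <- c(e, "E4")
    }
    if (g5$biotype %in% nc_biotypes && g3$biotype %in% nc_biotypes) e <- c(e, "E5")
    if (g5$gene_id != g3$gene_id && g5$chrom == g3$chrom) {
      gap <- if (g5$start < g3$end && g3$start < g5$end) 0 else
        max(g5$start - g3$end, g3$start - g5$end)
      if (gap < 10000) e <- c(e, "E6")
    }
    e
  }
  n <- nrow(candidates)
  inc <- logical(n); exc <- vector("list", n)
  for (i in seq_len(n)) {
    inc[i] <- one_inc(candidates[i, ])
    exc[[i]] <- one_exc(candidates[i, ])
  }
  pass <- inc & lengths(exc) == 0
  pass_keys <- paste(candidates$gene5[pass], candidates$gene3[pass], sep = "--")
  known_keys <- paste(known_fusions$gene5, known_fusions$gene3, sep = "--")
  verdict <- character(n)
  for (i in seq_len(n)) {
    cd <- candidates[i, ]
    if (pass[i]) { verdict[i] <- "included"; next }
    if (!inc[i]) {
      g5 <- row_of(cd$gene5); g3 <- row_of(cd$gene3)
      recip <- c(paste(cd$gene3, cd$gene5, sep = "--"),
                 paste(g3$symbol, g5$symbol, sep = "--"))
      r1 <- any(recip %in% c(pass_keys, known_keys))
      r2 <- any(c(g5$symbol, g3$symbol) %in%
                  c("ETV6", "RUNX1", "MLL", "PAX5", "IKZF1"))
      if ((r1 || r2) && (rescue_bypasses_exclusion || length(exc[[i]]) == 0)) {
        verdict[i] <- "rescued"; next
      }
    }
    verdict[i] <- "excluded"
  }
  verdict
}

# Translation oracle for frame classification. Builds actual nucleotide
# sequences for a toy gene pair whose codons avoid T entirely (so no stop
# codon can arise in any reading frame of the body), joins them at the
# breakpoint, translates the chimera, and checks whether the 3' partner's
# C-terminal peptide is produced. Requires Biostrings.
translation_frame_oracle <- function(retained5, offset3, cds_len3, seed) {
  withr::with_seed(seed, {
    base3 <- c("A", "C", "G")
    seq3 <- paste(sample(base3, cds_len3 - 3L, replace = TRUE), collapse = "")
    seq3 <- paste0(seq3, "TAA")
    seq5 <- paste(sample(base3, retained5, replace = TRUE), collapse = "")
    prot3 <- as.character(Biostrings::translate(Biostrings::DNAString(seq3)))
    suffix <- substr(prot3, nchar(prot3) - 6L, nchar(prot3) - 1L)  # before the stop
    chim <- paste0(seq5, substr(seq3, offset3 + 1L, cds_len3))
    chim <- substr(chim, 1L, nchar(chim) - nchar(chim) %% 3L)
    prot_chim <- as.character(Biostrings::translate(Biostrings::DNAString(chim),
                                                    if.fuzzy.codon = "solve"))
    if (grepl(suffix, prot_chim, fixed = TRUE)) "in_frame" else "out_of_frame"
  })
}
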