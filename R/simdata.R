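#' Simulate fusion-candidate tables with planted truth
#'
#' Emulates the merged output of two de-novo fusion callers on a BCP-ALL
#' transcriptome: `n_true` genuine fusion candidates that satisfy the
#' inclusion thresholds and violate no exclusion rule, plus
#' `n_per_artifact` candidates for each artifact class, each engineered to
#' trip exactly one exclusion rule while still clearing the inclusion
#' thresholds (so that the artifact filter, not the read-support filter, is
#' what removes it). Artifact classes: `read_through`, `low_mapq`,
#' `normal_shared`, `ig_tcr_internal`, `hla_pair`, `noncoding_pair`,
#' `near_genes`.
#'
#' Read support is drawn from a negative-binomial background on top of the
#' inclusion threshold (defaults mean 5, dispersion 2).
#'
#' @param seed Integer seed.
#' @param ann A `genome_annotation` from [gen_annotation()].
#' @param n_true Number of genuine candidates.
#' @param n_per_artifact Candidates per artifact class.
#' @param nb_mu,nb_size Negative-binomial mean and dispersion for the extra
#'   read support above threshold.
#' @return A list with `candidates` (tibble in the candidate-TSV dialect
#'   plus a `row_id`) and `truth` (tibble: row_id, artifact_class,
#'   expected_verdict, expected_rule).
#' @export
gen_fusion_candidates <- function(seed, ann, n_true = 10L, n_per_artifact = 3L,
                                  nb_mu = 5, nb_size = 2) {
  stopifnot(inherits(ann, "genome_annotation"))
  withr::with_seed(as.integer(seed), {
    genes <- ann$genes
    normal_pc <- genes[genes$biotype == "protein_coding" &
                         genes$locus_class == "normal" &
                         !genes$symbol %in% c("NEARA", "NEARB", "ETV6", "RUNX1",
                                              "MLL", "PAX5", "IKZF1"), ]
    support <- function(n) as.integer(10L + stats::rnbinom(n, size = nb_size, mu = nb_mu))

    mk_row <- function(g5, g3, class, pos5 = NULL, pos3 = NULL) {
      jr <- support(1L)
      tibble::tibble(
        caller = "chimerascan",
        gene5 = g5$gene_id, gene3 = g3$gene_id,
        chrom5 = g5$chrom,
        pos5 = if (is.null(pos5)) as.integer(sample(g5$start:g5$end, 1)) else as.integer(pos5),
        strand5 = g5$strand,
        chrom3 = g3$chrom,
        pos3 = if (is.null(pos3)) as.integer(sample(g3$start:g3$end, 1)) else as.integer(pos3),
        strand3 = g3$strand,
        junction_reads = jr,
        total_reads = jr + as.integer(stats::rnbinom(1, size = nb_size, mu = 4 * nb_mu)),
        readthrough_flag = class == "read_through",
        low_mapq_exon_fraction = if (class == "low_mapq") {
          stats::runif(1, 0.76, 0.95)
        } else {
          stats::runif(1, 0, 0.5)
        },
        normal_panel_hit = class == "normal_shared",
        interchromosomal = g5$chrom != g3$chrom,
        also_detected_by_other_caller = stats::runif(1) < 0.5,
        artifact_class = class
      )
    }

    pick_pair <- function(same_chrom = FALSE) {
      repeat {
        g5 <- normal_pc[sample(nrow(normal_pc), 1), ]
        pool <- normal_pc[normal_pc$gene_id != g5$gene_id &
                            ((normal_pc$chrom == g5$chrom) == same_chrom), ]
        if (nrow(pool) == 0) next
        g3 <- pool[sample(nrow(pool), 1), ]
        if (same_chrom && gene_distance(ann, g5$gene_id, g3$gene_id) < 10000) next
        return(list(g5 = g5, g3 = g3))
      }
    }

    rows <- list()
    for (i in seq_len(n_true)) {
      p <- pick_pair(same_chrom = FALSE)
      rows[[length(rows) + 1L]] <- mk_row(p$g5, p$g3, "true")
    }
    igh <- genes[genes$symbol == "IGH", ]
    hla_a <- genes[genes$symbol == "HLA-A", ]
    hla_b <- genes[genes$symbol == "HLA-B", ]
    linc1 <- genes[genes$symbol == "LINC01A", ]
    linc2 <- genes[genes$symbol == "LINC02B", ]
    near_a <- genes[genes$symbol == "NEARA", ]
    near_b <- genes[genes$symbol == "NEARB", ]
    for (i in seq_len(n_per_artifact)) {
      p <- pick_pair(same_chrom = TRUE)
      rows[[length(rows) + 1L]] <- mk_row(p$g5, p$g3, "read_through")
      p <- pick_pair(same_chrom = FALSE)
      rows[[length(rows) + 1L]] <- mk_row(p$g5, p$g3, "low_mapq")
      p <- pick_pair(same_chrom = FALSE)
      rows[[length(rows) + 1L]] <- mk_row(p$g5, p$g3, "normal_shared")
      rows[[length(rows) + 1L]] <- mk_row(igh, igh, "ig_tcr_internal")
      rows[[length(rows) + 1L]] <- mk_row(hla_a, hla_b, "hla_pair")
      rows[[length(rows) + 1L]] <- mk_row(linc1, linc2, "noncoding_pair")
      rows[[length(rows) + 1L]] <- mk_row(near_a, near_b, "near_genes")
    }
    out <- dplyr::bind_rows(rows)
    out$row_id <- seq_len(nrow(out))
    rule_of <- c(read_through = "E1", low_mapq = "E2", normal_shared = "E3",
                 ig_tcr_internal = "E4", hla_pair = "E4",
                 noncoding_pair = "E5", near_genes = "E6")
    truth <- tibble::tibble(
      row_id = out$row_id,
      artifact_class = out$artifact_class,
      expected_verdict = ifelse(out$artifact_class == "true", "included", "excluded"),
      expected_rule = unname(rule_of[out$artifact_class])
    )
    out$artifact_class <- NULL
    list(candidates = out, truth = truth)
  })
}

#' Simulate discordant read-pair linking evidence
#'
#' Plants `n_support` read pairs linking a genomic window to a partner
#' locus (emulating, e.g., an insertion of DUX4 into the IGH locus, or an
#' IGH-CRLF2 rearrangement), on top of Poisson background linking pairs at
#' `background_rate` per kb of window span. When the window is the DUX4
#' repeat, the window-side mate is placed in a randomly chosen repeat copy.
#'
#' @param seed Integer seed.
#' @param ann A `genome_annotation`.
#' @param insertion `NULL`, or a list with `window` (tibble of intervals:
#'   chrom, start, end — one row, or all repeat copies), `partner` (one
#'   interval tibble) and `n_support` (number of planted linking pairs).
#' @param background_rate Background linking pairs per kb of window span.
#' @param read_len Simulated read length (bp).
#' @return Tibble in the BEDPE-like dialect: chrom1, start1, end1, chrom2,
#'   start2, end2, name, mapq1, mapq2. Mate 1 is in the window, mate 2 in
#'   the partner locus; consumers must not rely on that order.
#' @export
gen_linking_pairs <- function(seed, ann, insertion = NULL,
                              background_rate = 0, read_len = 100L) {
  stopifnot(inherits(ann, "genome_annotation"))
  withr::with_seed(as.integer(seed), {
    empty <- tibble::tibble(
      chrom1 = character(), start1 = integer(), end1 = integer(),
      chrom2 = character(), start2 = integer(), end2 = integer(),
      name = character(), mapq1 = integer(), mapq2 = integer()
    )
    if (is.null(insertion) && background_rate == 0) return(empty)

    window <- if (!is.null(insertion)) insertion$window else NULL
    partner <- if (!is.null(insertion)) insertion$partner else NULL
    if (!is.null(window)) {
      chrom_max <- max(ann$genes$end[ann$genes$chrom %in% window$chrom],
                       window$end)
      if (any(window$start < 0) || any(window$end > chrom_max + 1e6)) {
        stop("insertion window lies outside the annotated genome")
      }
    }
    place_in <- function(iv_tbl, n) {
      idx <- sample(nrow(iv_tbl), n, replace = TRUE)
      start <- vapply(idx, function(i) {
        hi <- max(iv_tbl$end[i] - read_len, iv_tbl$start[i] + 1L)
        as.integer(sample(iv_tbl$start[i]:hi, 1))
      }, integer(1))
      tibble::tibble(chrom = iv_tbl$chrom[idx], start = start,
                     end = start + read_len)
    }
    n_sup <- if (!is.null(insertion)) insertion$n_support else 0L
    span_kb <- if (!is.null(window)) sum(window$end - window$start) / 1000 else 0
    n_bg <- if (background_rate > 0 && span_kb > 0) {
      stats::rpois(1, background_rate * span_kb)
    } else 0L
    n <- n_sup + n_bg
    if (n == 0) return(empty)
    m1 <- place_in(window, n)
    m2 <- place_in(partner, n)
    tibble::tibble(
      chrom1 = m1$chrom, start1 = m1$start, end1 = m1$end,
      chrom2 = m2$chrom, start2 = m2$start, end2 = m2$end,
      name = sprintf("pair%05d", seq_len(n)),
      mapq1 = as.integer(sample(0:60, n, replace = TRUE)),
      mapq2 = as.integer(sample(20:60, n, replace = TRUE))
    )
  })
}

#' Simulate per-sample splice-junction count tables
#'
#' Generates STAR-style junction tables for tumour samples carrying planted
#' intragenic deletions and for a panel of normal samples containing
#' reference junctions only. For each planted deletion the skipping
#' junction shares its donor site with a reference junction; at that site
#' the read depth is fixed at `depth` and the skipping-junction count is
#' Binomial(`depth`, `f`), so the site-usage fraction estimates the clone
#' fraction `f` directly. All other junction counts are
#' Poisson(`depth`)-distributed.
#'
#' @param seed Integer seed.
#' @param ann A `genome_annotation`.
#' @param deletions List of lists with `gene` (symbol), `skipped_exons`
#'   (integer vector of consecutive exon numbers, not the first or last
#'   exon) and `f` (clone fraction in \[0, 1\]). Each tumour sample carries
#'   all listed deletions.
#' @param depth Site read depth.
#' @param n_tumour Number of tumour samples.
#' @param n_normal Number of normal-panel samples (default 20, the size of
#'   the sorted normal bone-marrow panel the pipeline assumes).
#' @return A list with `tumour` and `normal` (named lists of junction
#'   tibbles: chrom, donor_pos, acceptor_pos, strand, read_count,
#'   annotated), `reference_junctions` (from [reference_junctions()]) and
#'   `truth` (tibble: sample, gene, donor_pos, acceptor_pos, f).
#' @export
gen_junction_counts <- function(seed, ann, deletions = list(), depth = 100L,
                                n_tumour = 1L, n_normal = 20L) {
  stopifnot(inherits(ann, "genome_annotation"), depth > 0)
  ref <- reference_junctions(ann)
  del_info <- lapply(deletions, function(d) {
    stopifnot(d$f >= 0, d$f <= 1)
    g <- annotation_genes(ann, d$gene)
    ex <- ann$exons[ann$exons$gene_id == g$gene_id, ]
    if (!all(d$skipped_exons %in% ex$exon_number) ||
        min(d$skipped_exons) <= 1L || max(d$skipped_exons) >= max(ex$exon_number)) {
      stop("deletion in ", d$gene, " references exons that cannot be skipped: ",
           paste(d$skipped_exons, collapse = ","))
    }
    donor <- ex$end[ex$exon_number == min(d$skipped_exons) - 1L]
    acceptor_skip <- ex$start[ex$exon_number == max(d$skipped_exons) + 1L]
    acceptor_ref <- ex$start[ex$exon_number == min(d$skipped_exons)]
    list(gene = g$symbol, chrom = g$chrom, strand = g$strand, donor = donor,
         acceptor_skip = acceptor_skip, acceptor_ref = acceptor_ref, f = d$f)
  })
  withr::with_seed(as.integer(seed), {
    base_counts <- function() {
      tab <- ref
      tab$read_count <- stats::rpois(nrow(tab), depth)
      tab$annotated <- TRUE
      tab[tab$read_count > 0,
          c("chrom", "donor_pos", "acceptor_pos", "strand", "read_count", "annotated")]
    }
    truth <- list()
    tumour <- list()
    for (s in seq_len(n_tumour)) {
      sample_id <- sprintf("tumour%03d", s)
      tab <- base_counts()
      for (d in del_info) {
        skip_n <- stats::rbinom(1, depth, d$f)
        ref_n <- depth - skip_n
        at_ref <- tab$chrom == d$chrom & tab$donor_pos == d$donor &
          tab$acceptor_pos == d$acceptor_ref
        tab$read_count[at_ref] <- ref_n
        if (skip_n > 0) {
          tab <- dplyr::bind_rows(tab, tibble::tibble(
            chrom = d$chrom, donor_pos = d$donor, acceptor_pos = d$acceptor_skip,
            strand = d$strand, read_count = skip_n, annotated = FALSE
          ))
        }
        truth[[length(truth) + 1L]] <- tibble::tibble(
          sample = sample_id, gene = d$gene, donor_pos = d$donor,
          acceptor_pos = d$acceptor_skip, f = d$f
        )
      }
      tab <- tab[tab$read_count > 0, ]
      tumour[[sample_id]] <- tab
    }
    normal <- list()
    for (s in seq_len(n_normal)) {
      normal[[sprintf("normal%03d", s)]] <- base_counts()
    }
    list(tumour = tumour, normal = normal, reference_junctions = ref,
         truth = dplyr::bind_rows(truth))
  })
}

#' Simulated subtype classes
#'
#' The six mutually exclusive molecular subtypes the classifier models:
#' four defined by a hallmark fusion (BCR-ABL1, ETV6-RUNX1, MLL
#' rearrangements, TCF3-PBX1), high hyperdiploidy (HeH) and the residual
#' B-other group.
#'
#' @return Character vector of the six class names, alphabetical.
#' @export
subtype_classes <- function() {
  sort(c("BCR-ABL1", "ETV6-RUNX1", "HeH", "MLL", "TCF3-PBX1", "B-other"))
}

fusion_defined_classes <- function() {
  c("BCR-ABL1", "ETV6-RUNX1", "MLL", "TCF3-PBX1")
}

#' Simulate a log2 expression matrix with subtype structure
#'
#' Generates a genes-by-samples matrix of log2 expression values for six
#' balanced subtype classes. Each informative gene is assigned to one
#' class and its mean is shifted by `delta` within-class standard
#' deviations in that class; uninformative genes are class-independent.
#' Noise is Gaussian with unit within-class SD on top of a gene-specific
#' baseline, so `delta` is the class separation in SD units.
#'
#' Samples in fusion-defined classes carry their hallmark fusion token
#' (`BCR-ABL1`, `ETV6-RUNX1`, `MLL-AFF1`, `TCF3-PBX1`) with probability
#' `fusion_fraction`; HeH and B-other samples never carry tokens.
#'
#' @param seed Integer seed.
#' @param n_per_class Samples per class.
#' @param n_genes Total genes.
#' @param n_informative Number of informative genes (must not exceed
#'   `n_genes`).
#' @param delta Class separation in within-class SD units (>= 0).
#' @param fusion_fraction Probability that a sample in a fusion-defined
#'   class carries its fusion token (default 0.95, the detection rate of
#'   hallmark fusions a well-powered RNA-seq screen achieves).
#' @return List with `matrix` (genes x samples), `labels` (character,
#'   per sample), `fusion_tokens` (list of character vectors per sample)
#'   and `truth` (tibble: gene_id, informative, class).
#' @export
gen_expression <- function(seed, n_per_class = 10L, n_genes = 300L,
                           n_informative = 60L, delta = 3,
                           fusion_fraction = 0.95) {
  stopifnot(n_informative <= n_genes, delta >= 0,
            fusion_fraction >= 0, fusion_fraction <= 1)
  classes <- subtype_classes()
  token_of <- c("BCR-ABL1" = "BCR-ABL1", "ETV6-RUNX1" = "ETV6-RUNX1",
                "MLL" = "MLL-AFF1", "TCF3-PBX1" = "TCF3-PBX1")
  withr::with_seed(as.integer(seed), {
    n <- n_per_class * length(classes)
    labels <- rep(classes, each = n_per_class)
    samples <- sprintf("S%03d", seq_len(n))
    gene_ids <- sprintf("EG%04d", seq_len(n_genes))
    info_class <- rep(classes, length.out = n_informative)
    baseline <- stats::runif(n_genes, 3, 10)
    mat <- matrix(stats::rnorm(n_genes * n, mean = baseline, sd = 1),
                  nrow = n_genes, ncol = n,
                  dimnames = list(gene_ids, samples))
    for (g in seq_len(n_informative)) {
      mat[g, labels == info_class[g]] <- mat[g, labels == info_class[g]] + delta
    }
    tokens <- lapply(seq_len(n), function(i) {
      cl <- labels[i]
      if (cl %in% names(token_of) && stats::runif(1) < fusion_fraction) {
        unname(token_of[cl])
      } else {
        character(0)
      }
    })
    truth <- tibble::tibble(
      gene_id = gene_ids,
      informative = seq_len(n_genes) <= n_informative,
      class = c(info_class, rep(NA_character_, n_genes - n_informative))
    )
    list(matrix = mat, labels = labels, fusion_tokens = tokens, truth = truth)
  })
}

#' Write a full simulated study to disk
#'
#' Runs every generator with sub-seeds derived from one master seed and
#' writes the complete set of pipeline inputs (GTF, candidate TSV, BEDPE
#' pair TSV, STAR-style junction TSVs, expression TSV, metadata TSV) plus a
#' JSON truth file to `outdir`.
#'
#' @param seed Master seed; each generator receives a fixed offset of it.
#' @param outdir Output directory (created if needed).
#' @param n_genes,n_true,n_per_artifact,deletions,depth,n_tumour,n_normal,n_per_class,delta
#'   Passed to the individual generators.
#' @return `outdir`, invisibly.
#' @export
simulate_study <- function(seed, outdir, n_genes = 50L, n_true = 10L,
                           n_per_artifact = 3L,
                           deletions = list(list(gene = "ETV6",
                                                 skipped_exons = 3:5, f = 0.5)),
                           depth = 100L, n_tumour = 5L, n_normal = 20L,
                           n_per_class = 10L, delta = 3) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(seed)
  ann <- gen_annotation(seed, n_genes)
  write_annotation_gtf(ann, file.path(outdir, "annotation.gtf"))

  cand <- gen_fusion_candidates(seed + 1L, ann, n_true, n_per_artifact)
  write_candidates_tsv(cand$candidates, file.path(outdir, "candidates.tsv"))

  dux4_win <- dux4_windows(ann)
  pairs <- gen_linking_pairs(
    seed + 2L, ann,
    insertion = list(window = dux4_win, partner = ann$special$igh, n_support = 60L),
    background_rate = 0.01
  )
  write_pairs_bedpe(pairs, file.path(outdir, "pairs.tsv"))

  jc <- gen_junction_counts(seed + 3L, ann, deletions, depth, n_tumour, n_normal)
  jdir <- file.path(outdir, "junctions"); ndir <- file.path(outdir, "normals")
  dir.create(jdir, showWarnings = FALSE); dir.create(ndir, showWarnings = FALSE)
  for (s in names(jc$tumour)) {
    write_junctions_star(jc$tumour[[s]], file.path(jdir, paste0(s, ".SJ.tab")))
  }
  for (s in names(jc$normal)) {
    write_junctions_star(jc$normal[[s]], file.path(ndir, paste0(s, ".SJ.tab")))
  }

  expr <- gen_expression(seed + 4L, n_per_class = n_per_class, delta = delta)
  write_expression_tsv(expr$matrix, file.path(outdir, "expression.tsv"))
  write_metadata_tsv(
    tibble::tibble(sample = colnames(expr$matrix), label = expr$labels,
                   fusion_tokens = expr$fusion_tokens),
    file.path(outdir, "metadata.tsv")
  )

  truth <- list(
    seed = seed,
    fusion_truth = cand$truth,
    junction_truth = jc$truth,
    expression_truth = expr$truth,
    labels = expr$labels
  )
  jsonlite::write_json(truth, file.path(outdir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}
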