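#' Inclusion thresholds for fusion candidates
#'
#' A candidate clears inclusion when any of three paths holds:
#' \describe{
#'   \item{I1}{reported by chimerascan with >= 10 junction reads or > 50
#'     total reads;}
#'   \item{I2}{reported by tophatfusion with > 15 junction reads;}
#'   \item{I3}{interchromosomal and also detected by the other caller.}
#' }
#' Boundary semantics are literal: ">= 10" is inclusive, "> 50", "> 15"
#' strict.
#'
#' @param candidate One-row tibble (or list) with the candidate fields.
#' @return `TRUE` when any inclusion path holds.
#' @export
apply_inclusion <- function(candidate) {
  c(
    (candidate$caller == "chimerascan" &&
       (candidate$junction_reads >= 10L || candidate$total_reads > 50L)) ||
      (candidate$caller == "tophatfusion" && candidate$junction_reads > 15L) ||
      (isTRUE(candidate$interchromosomal) &&
         isTRUE(candidate$also_detected_by_other_caller))
  )
}

inclusion_rules_fired <- function(candidate) {
  fired <- character(0)
  if (candidate$caller == "chimerascan" &&
      (candidate$junction_reads >= 10L || candidate$total_reads > 50L)) {
    fired <- c(fired, "I1")
  }
  if (candidate$caller == "tophatfusion" && candidate$junction_reads > 15L) {
    fired <- c(fired, "I2")
  }
  if (isTRUE(candidate$interchromosomal) &&
      isTRUE(candidate$also_detected_by_other_caller)) {
    fired <- c(fired, "I3")
  }
  fired
}

#' Exclusion rules for fusion candidates
#'
#' Tests the six artifact filters and returns the ids of every rule whose
#' condition holds:
#' \describe{
#'   \item{E1}{the caller annotated the event as a read-through;}
#'   \item{E2}{more than 75\% of reads on the affected exons mapped with
#'     quality below 5 (strict > 0.75);}
#'   \item{E3}{the same fusion was detected in the normal panel;}
#'   \item{E4}{both breakpoints fall within the same IG or TCR locus, or
#'     both partners are HLA genes (presumed constitutional variants);}
#'   \item{E5}{both partner genes are non-coding;}
#'   \item{E6}{the two (distinct) partner genes lie on the same chromosome
#'     with closest edges less than 10 kb apart.}
#' }
#'
#' E6 measures the closest edge-to-edge distance between distinct genes; an
#' intra-locus event (identical partners) is the province of E4, not E6.
#'
#' @param candidate One-row tibble (or list) with the candidate fields.
#' @param ann A `genome_annotation` containing both partner genes.
#' @return Character vector of fired rule ids (possibly empty).
#' @export
apply_exclusion <- function(candidate, ann) {
  g5 <- annotation_genes(ann, candidate$gene5)
  g3 <- annotation_genes(ann, candidate$gene3)
  fired <- character(0)
  if (isTRUE(candidate$readthrough_flag)) fired <- c(fired, "E1")
  if (candidate$low_mapq_exon_fraction > 0.75) fired <- c(fired, "E2")
  if (isTRUE(candidate$normal_panel_hit)) fired <- c(fired, "E3")
  in_locus <- function(iv, chrom, pos) {
    nrow(iv) == 1 && chrom == iv$chrom && pos >= iv$start && pos < iv$end
  }
  both_in <- function(iv) {
    in_locus(iv, candidate$chrom5, candidate$pos5) &&
      in_locus(iv, candidate$chrom3, candidate$pos3)
  }
  e4 <- both_in(ann$special$igh) || both_in(ann$special$tra) ||
    (g5$locus_class == "HLA" && g3$locus_class == "HLA")
  if (e4) fired <- c(fired, "E4")
  # "non-coding" means ncRNA biotypes; IG/TR segment genes are rearranging
  # coding loci and belong to E4's jurisdiction, not E5's
  coding_like <- c("protein_coding", "IG_gene", "TR_gene")
  if (!(g5$biotype %in% coding_like) && !(g3$biotype %in% coding_like)) {
    fired <- c(fired, "E5")
  }
  if (g5$gene_id != g3$gene_id &&
      gene_distance(ann, g5$gene_id, g3$gene_id) < 10000) {
    fired <- c(fired, "E6")
  }
  fired
}

#' Recurrently altered genes driving the rescue rule
#' @return Character vector of gene symbols.
#' @export
rescue_genes <- function() c("ETV6", "RUNX1", "MLL", "PAX5", "IKZF1")

#' Rescue rules for fusion candidates failing inclusion
#'
#' A candidate that fails the inclusion thresholds is rescued when it
#' \describe{
#'   \item{R1}{is the reciprocal of a fusion in the passing set or of a
#'     previously reported BCP-ALL fusion; or}
#'   \item{R2}{involves one of the recurrently altered genes ETV6, RUNX1,
#'     MLL, PAX5 or IKZF1.}
#' }
#'
#' @param candidate One-row tibble with `gene5`/`gene3` (ids or symbols).
#' @param passing_set Two-column tibble/data.frame (gene5, gene3) of
#'   fusions that passed the cascade, or character vector `"A--B"` pairs.
#' @param known_fusions Same shape: previously reported BCP-ALL fusions.
#' @param ann Optional `genome_annotation` used to translate gene ids to
#'   symbols for the R2 gene-name match.
#' @return `TRUE` when a rescue rule fires.
#' @export
apply_rescue <- function(candidate, passing_set, known_fusions, ann = NULL) {
  length(rescue_rules_fired(candidate, passing_set, known_fusions, ann)) > 0
}

rescue_rules_fired <- function(candidate, passing_set, known_fusions, ann = NULL) {
  as_keys <- function(x) {
    if (is.null(x) || (is.data.frame(x) && nrow(x) == 0) || length(x) == 0) {
      return(character(0))
    }
    if (is.data.frame(x)) paste(x$gene5, x$gene3, sep = "--") else as.character(x)
  }
  syms <- c(candidate$gene5, candidate$gene3)
  if (!is.null(ann)) {
    syms <- unique(c(syms, annotation_genes(ann, candidate$gene5)$symbol,
                     annotation_genes(ann, candidate$gene3)$symbol))
  }
  fired <- character(0)
  reciprocal <- paste(candidate$gene3, candidate$gene5, sep = "--")
  if (!is.null(ann)) {
    reciprocal <- c(reciprocal,
                    paste(annotation_genes(ann, candidate$gene3)$symbol,
                          annotation_genes(ann, candidate$gene5)$symbol,
                          sep = "--"))
  }
  if (any(reciprocal %in% c(as_keys(passing_set), as_keys(known_fusions)))) {
    fired <- c(fired, "R1")
  }
  if (any(syms %in% rescue_genes())) fired <- c(fired, "R2")
  fired
}

#' Run the full fusion-candidate filter cascade
#'
#' Evaluates inclusion thresholds, exclusion rules and rescue rules for
#' every candidate, in input order. A candidate is:
#' \describe{
#'   \item{included}{inclusion passes and no exclusion rule fires;}
#'   \item{rescued}{inclusion fails, a rescue rule fires, and (by default)
#'     no exclusion rule fires;}
#'   \item{excluded}{otherwise.}
#' }
#' The passing set available to the reciprocal rescue rule (R1) is the set
#' of candidates included on the first pass. By default rescued candidates
#' must still clear the artifact filters E1-E6; letting artifact-flagged
#' events back in through rescue would readmit read-throughs, so the
#' literal any-rescue reading is available behind
#' `rescue_bypasses_exclusion = TRUE`.
#'
#' @param candidates Candidate tibble (one row per candidate).
#' @param ann A `genome_annotation`.
#' @param known_fusions Previously reported BCP-ALL fusions (see
#'   [apply_rescue()]); defaults to the list shipped with the package.
#' @param rescue_bypasses_exclusion Let rescue override the exclusion
#'   rules (default `FALSE`).
#' @return Tibble with one row per candidate: `row_id` (input order),
#'   `gene5`, `gene3`, `verdict` and `fired_rules` (semicolon-joined rule
#'   trace).
#' @export
filter_candidates <- function(candidates, ann, known_fusions = known_fusions_bcpall(),
                              rescue_bypasses_exclusion = FALSE) {
  n <- nrow(candidates)
  if (n == 0) {
    return(tibble::tibble(row_id = integer(), gene5 = character(),
                          gene3 = character(), verdict = character(),
                          fired_rules = character()))
  }
  inc <- vector("list", n); exc <- vector("list", n)
  for (i in seq_len(n)) {
    inc[[i]] <- inclusion_rules_fired(candidates[i, ])
    exc[[i]] <- apply_exclusion(candidates[i, ], ann)
  }
  pass1 <- vapply(seq_len(n), function(i) {
    length(inc[[i]]) > 0 && length(exc[[i]]) == 0
  }, logical(1))
  passing_set <- candidates[pass1, c("gene5", "gene3")]
  verdict <- character(n); trace <- character(n)
  for (i in seq_len(n)) {
    fired <- c(inc[[i]], exc[[i]])
    if (pass1[i]) {
      verdict[i] <- "included"
    } else if (length(inc[[i]]) == 0) {
      res <- rescue_rules_fired(candidates[i, ], passing_set, known_fusions, ann)
      fired <- c(fired, res)
      if (length(res) > 0 &&
          (rescue_bypasses_exclusion || length(exc[[i]]) == 0)) {
        verdict[i] <- "rescued"
      } else {
        verdict[i] <- "excluded"
      }
    } else {
      verdict[i] <- "excluded"
    }
    trace[i] <- paste(fired, collapse = ";")
  }
  tibble::tibble(
    row_id = if ("row_id" %in% names(candidates)) candidates$row_id else seq_len(n),
    gene5 = candidates$gene5, gene3 = candidates$gene3,
    verdict = verdict, fired_rules = trace
  )
}

#' Previously reported BCP-ALL fusions
#'
#' The default known-fusion list used by the reciprocal rescue rule,
#' shipped as a plain-text table in `extdata` and user-replaceable via the
#' `known_fusions` argument of [filter_candidates()].
#'
#' @param path Path to a two-column TSV (gene5, gene3); defaults to the
#'   packaged list.
#' @return Tibble with columns gene5, gene3.
#' @export
known_fusions_bcpall <- function(path = system.file("extdata", "known_fusions_bcpall.tsv",
                                                    package = "leukotype")) {
  readr::read_tsv(path, col_types = "cc")
}

#' Classify the reading frame of a fusion transcript
#'
#' Computes the coding phase on each side of the junction from annotated
#' CDS segments. The 5' phase is the cumulative CDS length retained
#' upstream of the breakpoint, modulo 3; the 3' phase is the CDS offset at
#' which the downstream partner is joined, modulo 3. The fusion is in
#' frame when the phases agree and both breakpoints fall inside the CDS.
#' A fusion whose 5' partner contributes no coding sequence (an IG locus,
#' or a breakpoint upstream of the start codon) cannot produce a chimeric
#' protein; likewise when nothing coding of the 3' partner is retained.
#'
#' Breakpoints are 0-based junction coordinates: for the 5' gene the
#' retained genomic interval is `[gene_start, pos5)` on the + strand; for
#' the 3' gene it is `[pos3, gene_end)`. Intronic breakpoints resolve to
#' the spliced product (the intron is absent from the transcript);
#' a 3' breakpoint beyond the last exon leaves nothing to join and the
#' call is `undetermined`.
#'
#' @param candidate One-row tibble with gene5, gene3, pos5, pos3 (and
#'   chrom5/chrom3, checked against the annotation).
#' @param ann A `genome_annotation`.
#' @return List of class `frame_call`: `status` in `in_frame`,
#'   `out_of_frame`, `no_chimeric_protein`, `undetermined`; `phase5`,
#'   `phase3` (integers 0-2, or `NA` when undefined).
#' @export
classify_frame <- function(candidate, ann) {
  g5 <- annotation_genes(ann, candidate$gene5)
  g3 <- annotation_genes(ann, candidate$gene3)
  check_span <- function(g, pos, side) {
    ex <- ann$exons[ann$exons$gene_id == g$gene_id, ]
    if (pos < min(ex$start) || pos > max(ex$end)) {
      stop("breakpoint ", pos, " lies outside all transcripts of ", g$symbol)
    }
  }
  check_span(g5, candidate$pos5, "5'")
  check_span(g3, candidate$pos3, "3'")

  cds5 <- ann$cds[ann$cds$gene_id == g5$gene_id, ]
  cds3 <- ann$cds[ann$cds$gene_id == g3$gene_id, ]
  ex3 <- ann$exons[ann$exons$gene_id == g3$gene_id, ]
  # + strand model: retained 5' CDS is upstream of pos5, the 3' join offset
  # is the CDS lost upstream of pos3
  overlap_left <- function(cds, pos) {
    sum(pmax(0L, pmin(cds$end, pos) - cds$start))
  }
  total5 <- sum(cds5$end - cds5$start)
  total3 <- sum(cds3$end - cds3$start)
  retained5 <- if (nrow(cds5) > 0) overlap_left(cds5, candidate$pos5) else 0L
  offset3 <- if (nrow(cds3) > 0) overlap_left(cds3, candidate$pos3) else 0L

  if (candidate$pos3 >= max(ex3$end)) {
    return(structure(list(status = "undetermined",
                          phase5 = NA_integer_, phase3 = NA_integer_),
                     class = "frame_call"))
  }
  # no coding contribution from the 5' side (or its stop codon is retained,
  # terminating translation at the junction), or nothing coding joined from
  # the 3' side: no chimeric protein can arise
  if (nrow(cds5) == 0 || retained5 == 0 || retained5 >= total5 ||
      nrow(cds3) == 0 || offset3 >= total3) {
    return(structure(list(status = "no_chimeric_protein",
                          phase5 = NA_integer_, phase3 = NA_integer_),
                     class = "frame_call"))
  }
  phase5 <- retained5 %% 3L
  phase3 <- offset3 %% 3L
  status <- if (phase5 == phase3) "in_frame" else "out_of_frame"
  structure(list(status = status, phase5 = as.integer(phase5),
                 phase3 = as.integer(phase3)),
            class = "frame_call")
}

#' @export
print.frame_call <- function(x, ...) {
  cat("frame_call:", x$status,
      if (!is.na(x$phase5)) sprintf("(phase5=%d, phase3=%d)", x$phase5, x$phase3),
      "\n")
  invisible(x)
}

#' Fusion-gene network and recurrently fused genes
#'
#' Builds the gene-fusion network from a set of unique fusions (reciprocal
#' pairs collapsed to one unordered edge) and reports the genes incident to
#' two or more distinct edges — the recurrently fused genes.
#'
#' @param fusions Two-column tibble/data.frame (gene5, gene3) or character
#'   vector of `"A--B"` pairs.
#' @return List with `edges` (tibble gene_a, gene_b, sorted
#'   lexicographically, gene_a < gene_b) and `recurrent_genes` (sorted
#'   character vector).
#' @export
build_fusion_network <- function(fusions) {
  if (is.character(fusions)) {
    parts <- strsplit(fusions, "--", fixed = TRUE)
    fusions <- tibble::tibble(gene5 = vapply(parts, `[`, "", 1),
                              gene3 = vapply(parts, `[`, "", 2))
  }
  if (nrow(fusions) == 0) {
    return(list(edges = tibble::tibble(gene_a = character(), gene_b = character()),
                recurrent_genes = character(0)))
  }
  edges <- tibble::tibble(
    gene_a = pmin(fusions$gene5, fusions$gene3),
    gene_b = pmax(fusions$gene5, fusions$gene3)
  ) |>
    dplyr::distinct() |>
    dplyr::arrange(.data$gene_a, .data$gene_b)
  degree <- table(c(edges$gene_a, edges$gene_b))
  list(edges = edges,
       recurrent_genes = sort(names(degree)[degree >= 2]))
}
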