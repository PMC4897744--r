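base_candidate <- function(ann, ...) {
  g <- annotation_genes(ann, c("GENE001", "GENE002"))
  cd <- tibble::tibble(
    caller = "chimerascan", gene5 = g$gene_id[1], gene3 = g$gene_id[2],
    chrom5 = g$chrom[1], pos5 = g$start[1] + 10L, strand5 = "+",
    chrom3 = g$chrom[2], pos3 = g$start[2] + 10L, strand3 = "+",
    junction_reads = 20L, total_reads = 40L,
    readthrough_flag = FALSE, low_mapq_exon_fraction = 0.1,
    normal_panel_hit = FALSE,
    interchromosomal = g$chrom[1] != g$chrom[2],
    also_detected_by_other_caller = FALSE
  )
  dplyr::mutate(cd, ...)
}

test_that("inclusion thresholds honour the literal boundary semantics", {
  cd <- base_candidate(TEST_ANN)
  expect_true(apply_inclusion(dplyr::mutate(cd, junction_reads = 10L, total_reads = 10L)))
  expect_false(apply_inclusion(dplyr::mutate(cd, junction_reads = 9L, total_reads = 50L)))
  expect_true(apply_inclusion(dplyr::mutate(cd, junction_reads = 0L, total_reads = 51L)))
  tf <- dplyr::mutate(cd, caller = "tophatfusion")
  expect_false(apply_inclusion(dplyr::mutate(tf, junction_reads = 15L)))
  expect_true(apply_inclusion(dplyr::mutate(tf, junction_reads = 16L)))
  # co-detection path requires interchromosomal
  weak <- dplyr::mutate(cd, junction_reads = 1L, total_reads = 2L,
                        also_detected_by_other_caller = TRUE)
  expect_equal(apply_inclusion(weak), isTRUE(weak$interchromosomal))
})

test_that("each exclusion rule fires on its own condition and only then", {
  cd <- base_candidate(TEST_ANN)
  expect_length(apply_exclusion(cd, TEST_ANN), 0)
  expect_identical(apply_exclusion(dplyr::mutate(cd, readthrough_flag = TRUE),
                                   TEST_ANN), "E1")
  expect_identical(apply_exclusion(dplyr::mutate(cd, low_mapq_exon_fraction = 0.76),
                                   TEST_ANN), "E2")
  expect_length(apply_exclusion(dplyr::mutate(cd, low_mapq_exon_fraction = 0.75),
                                TEST_ANN), 0)
  expect_identical(apply_exclusion(dplyr::mutate(cd, normal_panel_hit = TRUE),
                                   TEST_ANN), "E3")

  hla <- annotation_genes(TEST_ANN, c("HLA-A", "HLA-B"))
  cd_hla <- dplyr::mutate(cd, gene5 = hla$gene_id[1], gene3 = hla$gene_id[2],
                          chrom5 = hla$chrom[1], pos5 = hla$start[1] + 5L,
                          chrom3 = hla$chrom[2], pos3 = hla$start[2] + 5L,
                          interchromosomal = FALSE)
  expect_identical(apply_exclusion(cd_hla, TEST_ANN), "E4")

  igh <- annotation_genes(TEST_ANN, "IGH")
  cd_igh <- dplyr::mutate(cd, gene5 = igh$gene_id, gene3 = igh$gene_id,
                          chrom5 = igh$chrom, pos5 = igh$start + 100L,
                          chrom3 = igh$chrom, pos3 = igh$start + 900L,
                          interchromosomal = FALSE)
  expect_identical(apply_exclusion(cd_igh, TEST_ANN), "E4")

  nc <- annotation_genes(TEST_ANN, c("LINC01A", "LINC02B"))
  cd_nc <- dplyr::mutate(cd, gene5 = nc$gene_id[1], gene3 = nc$gene_id[2],
                         chrom5 = nc$chrom[1], pos5 = nc$start[1] + 5L,
                         chrom3 = nc$chrom[2], pos3 = nc$start[2] + 5L)
  expect_identical(apply_exclusion(cd_nc, TEST_ANN), "E5")

  near <- annotation_genes(TEST_ANN, c("NEARA", "NEARB"))
  cd_near <- dplyr::mutate(cd, gene5 = near$gene_id[1], gene3 = near$gene_id[2],
                           chrom5 = near$chrom[1], pos5 = near$start[1] + 5L,
                           chrom3 = near$chrom[2], pos3 = near$start[2] + 5L,
                           interchromosomal = FALSE)
  expect_identical(apply_exclusion(cd_near, TEST_ANN), "E6")
  expect_lt(gene_distance(TEST_ANN, "NEARA", "NEARB"), 10000)

  expect_error(apply_exclusion(dplyr::mutate(cd, gene5 = "NOSUCH"), TEST_ANN),
               "NOSUCH")
})

test_that("rescue applies to reciprocals, known fusions and recurrently altered genes", {
  passing <- tibble::tibble(gene5 = "A", gene3 = "B")
  known <- tibble::tibble(gene5 = "TCF3", gene3 = "HLF")
  cd <- tibble::tibble(gene5 = "B", gene3 = "A")
  expect_true(apply_rescue(cd, passing, known))
  expect_true(apply_rescue(tibble::tibble(gene5 = "HLF", gene3 = "TCF3"),
                           passing, known))
  expect_false(apply_rescue(tibble::tibble(gene5 = "GAPDH", gene3 = "ACTB"),
                            passing[0, ], known[0, ]))
  expect_true(apply_rescue(tibble::tibble(gene5 = "IKZF1", gene3 = "GAPDH"),
                           passing[0, ], known[0, ]))
})

test_that("the cascade reproduces planted truth and rescues weak recurrent-gene fusions", {
  sim <- gen_fusion_candidates(19, TEST_ANN, n_true = 10, n_per_artifact = 3)
  dec <- filter_candidates(sim$candidates, TEST_ANN)
  expect_identical(dec$verdict, sim$truth$expected_verdict)
  # exclusion traces name exactly the planted rule
  art <- !is.na(sim$truth$expected_rule)
  expect_true(all(mapply(grepl, sim$truth$expected_rule[art],
                         dec$fired_rules[art], fixed = TRUE)))

  # a weak ETV6 candidate is rescued, but not if an artifact flag fires too
  etv6 <- annotation_genes(TEST_ANN, c("ETV6", "GENE003"))
  weak <- base_candidate(TEST_ANN) |>
    dplyr::mutate(gene5 = etv6$gene_id[1], gene3 = etv6$gene_id[2],
                  chrom5 = etv6$chrom[1], pos5 = etv6$start[1] + 5L,
                  chrom3 = etv6$chrom[2], pos3 = etv6$start[2] + 5L,
                  junction_reads = 2L, total_reads = 4L,
                  interchromosomal = etv6$chrom[1] != etv6$chrom[2],
                  also_detected_by_other_caller = FALSE)
  expect_identical(filter_candidates(weak, TEST_ANN)$verdict, "rescued")
  flagged <- dplyr::mutate(weak, readthrough_flag = TRUE)
  expect_identical(filter_candidates(flagged, TEST_ANN)$verdict, "excluded")
  expect_identical(
    filter_candidates(flagged, TEST_ANN, rescue_bypasses_exclusion = TRUE)$verdict,
    "rescued")

  expect_equal(nrow(filter_candidates(sim$candidates[0, ], TEST_ANN)), 0)
})

test_that("cascade verdicts match the independent single-rule oracle on random candidates", {
  known <- known_fusions_bcpall()
  cands <- random_candidates(400, TEST_ANN, seed = 23)
  dec <- filter_candidates(cands, TEST_ANN, known)
  oracle <- oracle_filter(cands, TEST_ANN, known)
  expect_identical(dec$verdict, oracle)
})

test_that("toggling a rule's driving field flips exactly that rule", {
  cands <- random_candidates(60, TEST_ANN, seed = 31)
  toggles <- list(
    E1 = function(cd) dplyr::mutate(cd, readthrough_flag = !cd$readthrough_flag),
    E2 = function(cd) dplyr::mutate(cd, low_mapq_exon_fraction =
                                      ifelse(cd$low_mapq_exon_fraction > 0.75, 0.3, 0.9)),
    E3 = function(cd) dplyr::mutate(cd, normal_panel_hit = !cd$normal_panel_hit)
  )
  for (rule in names(toggles)) {
    for (i in seq_len(nrow(cands))) {
      before <- apply_exclusion(cands[i, ], TEST_ANN)
      after <- apply_exclusion(toggles[[rule]](cands[i, ]), TEST_ANN)
      expect_identical(setdiff(union(before, after), intersect(before, after)),
                       rule)
    }
  }
})

test_that("included fusions keep their reciprocal in via rescue", {
  sim <- gen_fusion_candidates(29, TEST_ANN, n_true = 5, n_per_artifact = 1)
  incl <- sim$candidates[sim$truth$expected_verdict == "included", ][1, ]
  recip <- incl |>
    dplyr::mutate(gene5 = incl$gene3, gene3 = incl$gene5,
                  chrom5 = incl$chrom3, pos5 = incl$pos3,
                  chrom3 = incl$chrom5, pos3 = incl$pos5,
                  junction_reads = 1L, total_reads = 2L,
                  also_detected_by_other_caller = FALSE,
                  row_id = max(sim$candidates$row_id) + 1L)
  dec <- filter_candidates(dplyr::bind_rows(sim$candidates, recip), TEST_ANN)
  expect_identical(dec$verdict[nrow(dec)], "rescued")
  expect_match(dec$fired_rules[nrow(dec)], "R1")
})

test_that("frame classification follows CDS phase arithmetic", {
  # retained 300 coding bases joined at offset 0: phases 0/0, in frame
  toy <- toy_two_gene_ann(360, 300)
  fc <- classify_frame(list(gene5 = "T5", gene3 = "T3",
                            pos5 = toy$cds_start5 + 300L,
                            pos3 = toy$cds_start3), toy$ann)
  expect_identical(fc$status, "in_frame")
  expect_equal(fc$phase5, 0L); expect_equal(fc$phase3, 0L)
  # retained 100 (phase 1) vs offset 0 (phase 0): out of frame
  fc2 <- classify_frame(list(gene5 = "T5", gene3 = "T3",
                             pos5 = toy$cds_start5 + 100L,
                             pos3 = toy$cds_start3), toy$ann)
  expect_identical(fc2$status, "out_of_frame")
  expect_equal(fc2$phase5, 1L); expect_equal(fc2$phase3, 0L)
  # breakpoint upstream of the start codon: nothing coding from the 5' side
  fc3 <- classify_frame(list(gene5 = "T5", gene3 = "T3",
                             pos5 = toy$cds_start5 - 10L,
                             pos3 = toy$cds_start3), toy$ann)
  expect_identical(fc3$status, "no_chimeric_protein")
  expect_error(classify_frame(list(gene5 = "T5", gene3 = "T3",
                                   pos5 = 1L, pos3 = toy$cds_start3), toy$ann),
               "outside")
})

test_that("an IG locus driving a full coding gene yields no chimeric protein", {
  igh <- annotation_genes(TEST_ANN, "IGH")
  dux4 <- annotation_genes(TEST_ANN, "DUX4")
  fc <- classify_frame(list(gene5 = "IGH", gene3 = "DUX4",
                            pos5 = igh$start + 500L, pos3 = dux4$start), TEST_ANN)
  expect_identical(fc$status, "no_chimeric_protein")
})

test_that("frame classification agrees with the translation oracle", {
  skip_if_not_installed("Biostrings")
  set.seed(101)
  for (k in 1:120) {
    retained5 <- sample(3:200, 1)
    cds_len3 <- 3L * sample(30:80, 1)
    offset3 <- sample(0:(cds_len3 - 30L), 1)
    toy <- toy_two_gene_ann(retained5 + 60L, cds_len3)
    fc <- classify_frame(list(gene5 = "T5", gene3 = "T3",
                              pos5 = toy$cds_start5 + retained5,
                              pos3 = toy$cds_start3 + offset3), toy$ann)
    oracle <- translation_frame_oracle(retained5, offset3, cds_len3, seed = k)
    expect_identical(fc$status, oracle,
                     label = sprintf("retained5=%d offset3=%d: %s",
                                     retained5, offset3, fc$status))
  }
})

test_that("fusion-network recurrence equals brute-force degree counting", {
  net <- build_fusion_network(c("IGH--DUX4", "ERG--DUX4"))
  expect_identical(net$recurrent_genes, "DUX4")
  expect_identical(build_fusion_network(c("A--B"))$recurrent_genes, character(0))
  # reciprocal pairs collapse to one edge
  expect_equal(nrow(build_fusion_network(c("A--B", "B--A"))$edges), 1)

  genes <- sprintf("g%02d", 1:30)
  set.seed(5)
  pairs <- unique(t(apply(matrix(sample(genes, 2 * 58, replace = TRUE),
                                 ncol = 2), 1, sort)))
  pairs <- pairs[pairs[, 1] != pairs[, 2], , drop = FALSE]
  fus <- paste(pairs[, 1], pairs[, 2], sep = "--")
  net2 <- build_fusion_network(fus)
  degree <- sapply(genes, function(g) sum(pairs[, 1] == g | pairs[, 2] == g))
  expect_identical(net2$recurrent_genes, sort(names(degree)[degree >= 2]))
})
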