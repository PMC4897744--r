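test_that("annotation generation is deterministic, seed-sensitive and complete", {
  a1 <- gen_annotation(1, 50)
  a2 <- gen_annotation(1, 50)
  expect_identical(a1, a2)
  a3 <- gen_annotation(2, 50)
  expect_false(identical(a1$genes$start, a3$genes$start))
  expect_identical(names(a3), names(a1))

  expect_equal(nrow(a1$genes), 50)
  for (cls in c("IG", "TCR", "HLA", "normal")) {
    expect_true(cls %in% a1$genes$locus_class)
  }
  expect_equal(nrow(a1$special$dux4_copies), 7)
  # identical-length repeat copies, evenly spaced
  cp <- a1$special$dux4_copies
  expect_length(unique(cp$end - cp$start), 1)
  expect_length(unique(diff(cp$start)), 1)
  for (s in c("IGH", "CRLF2", "CDKN2A", "PAX5", "ETV6", "IKZF1")) {
    expect_true(s %in% a1$genes$symbol)
  }
  # splice-target genes have >= 5 exons
  tg <- annotation_genes(a1, c("CDKN2A", "PAX5", "ETV6", "IKZF1"))
  n_ex <- table(a1$exons$gene_id)[tg$gene_id]
  expect_true(all(n_ex >= 5))
  # exons within gene bounds, CDS length divisible by 3 recorded
  expect_true(all(a1$transcripts$cds_divisible_by_3))

  expect_error(gen_annotation(1, 5), "too small")
})

test_that("candidate generation partitions rows into truth classes that trip exactly their rule", {
  sim <- gen_fusion_candidates(7, TEST_ANN, n_true = 10, n_per_artifact = 3)
  expect_equal(nrow(sim$candidates), 10 + 3 * 7)
  expect_identical(sim$candidates$row_id, sim$truth$row_id)
  expect_equal(sum(sim$truth$expected_verdict == "included"), 10)
  expect_equal(sum(sim$truth$expected_verdict == "excluded"), 21)

  # every candidate clears inclusion; artifacts fire exactly their own rule
  for (i in seq_len(nrow(sim$candidates))) {
    cd <- sim$candidates[i, ]
    expect_true(apply_inclusion(cd))
    fired <- apply_exclusion(cd, TEST_ANN)
    expected <- sim$truth$expected_rule[i]
    if (is.na(expected)) {
      expect_length(fired, 0)
    } else {
      expect_identical(fired, expected)
    }
  }

  # engineered boundary properties of specific artifact classes
  near <- sim$candidates[which(sim$truth$artifact_class == "near_genes"), ]
  for (i in seq_len(nrow(near))) {
    expect_lt(gene_distance(TEST_ANN, near$gene5[i], near$gene3[i]), 10000)
  }
  lowq <- sim$candidates[which(sim$truth$artifact_class == "low_mapq"), ]
  expect_true(all(lowq$low_mapq_exon_fraction > 0.75))

  expect_identical(gen_fusion_candidates(7, TEST_ANN, 10, 3), sim)
})

test_that("linking-pair generation plants exactly the requested support", {
  win <- dux4_windows(TEST_ANN)
  igh <- TEST_ANN$special$igh
  p <- gen_linking_pairs(3, TEST_ANN,
                         insertion = list(window = win, partner = igh,
                                          n_support = 60),
                         background_rate = 0)
  expect_equal(nrow(p), 60)
  expect_identical(gen_linking_pairs(3, TEST_ANN,
                                     insertion = list(window = win, partner = igh,
                                                      n_support = 60),
                                     background_rate = 0), p)
  expect_equal(nrow(gen_linking_pairs(4, TEST_ANN)), 0)
  expect_error(
    gen_linking_pairs(5, TEST_ANN,
                      insertion = list(window = tibble::tibble(chrom = "chr4",
                                                               start = -5000L,
                                                               end = -100L),
                                       partner = igh, n_support = 1)),
    "outside"
  )
})

test_that("background linking pairs follow the Poisson closed form", {
  win <- crlf2_window(TEST_ANN)  # 65-kb span
  igh <- TEST_ANN$special$igh
  counts <- vapply(1:1000, function(s) {
    nrow(gen_linking_pairs(s, TEST_ANN,
                           insertion = list(window = win, partner = igh,
                                            n_support = 60),
                           background_rate = 0.01))
  }, numeric(1))
  lambda <- 0.01 * 65  # mean background pairs over the window span
  expect_equal(mean(counts), 60 + lambda,
               tolerance = 3 * sqrt(lambda / 1000) / (60 + lambda))
})

test_that("junction-count generation plants binomial skipping at the shared donor site", {
  del <- list(list(gene = "ETV6", skipped_exons = 3:5, f = 1))
  jc <- gen_junction_counts(11, TEST_ANN, del, depth = 100, n_tumour = 2,
                            n_normal = 3)
  # f = 1: reference junction at the skipped donor absent everywhere
  donor <- jc$truth$donor_pos[1]
  for (tab in jc$tumour) {
    at_site <- tab[tab$donor_pos == donor, ]
    expect_true(all(!at_site$annotated))  # only the skipping junction remains
  }
  # f = 0: skipping junction never appears
  jc0 <- gen_junction_counts(11, TEST_ANN,
                             list(list(gene = "ETV6", skipped_exons = 3:5, f = 0)),
                             depth = 100, n_tumour = 3, n_normal = 2)
  skip_acc <- jc0$truth$acceptor_pos[1]
  for (tab in jc0$tumour) {
    expect_equal(nrow(tab[tab$donor_pos == donor & tab$acceptor_pos == skip_acc, ]), 0)
  }
  # normals contain reference junctions only
  ref_keys <- paste(jc$reference_junctions$donor_pos,
                    jc$reference_junctions$acceptor_pos)
  for (tab in jc$normal) {
    expect_true(all(paste(tab$donor_pos, tab$acceptor_pos) %in% ref_keys))
  }
  expect_error(
    gen_junction_counts(1, TEST_ANN,
                        list(list(gene = "ETV6", skipped_exons = 98:99, f = 0.5))),
    "cannot be skipped"
  )
})

test_that("expression generator separates classes by delta and tokens follow the protocol", {
  ex <- gen_expression(1, n_per_class = 10, n_genes = 300, n_informative = 60,
                       delta = 3)
  expect_equal(dim(ex$matrix), c(300, 60))
  expect_equal(table(ex$labels)[subtype_classes()],
               table(rep(subtype_classes(), each = 10))[subtype_classes()])
  # informative genes separate their class by about delta
  info <- ex$truth[ex$truth$informative, ]
  shifts <- vapply(seq_len(nrow(info)), function(i) {
    in_cl <- ex$labels == info$class[i]
    mean(ex$matrix[info$gene_id[i], in_cl]) - mean(ex$matrix[info$gene_id[i], !in_cl])
  }, numeric(1))
  expect_equal(mean(shifts), 3, tolerance = 0.1)

  # delta = 0: no separation signal
  ex0 <- gen_expression(2, n_per_class = 100, n_genes = 50, n_informative = 20,
                        delta = 0)
  p <- vapply(seq_len(20), function(i) {
    cl <- ex0$truth$class[i]
    stats::t.test(ex0$matrix[i, ex0$labels == cl],
                  ex0$matrix[i, ex0$labels != cl])$p.value
  }, numeric(1))
  expect_gt(mean(p > 0.05), 0.9)

  # fusion_fraction = 1: every fusion-defined-class sample carries a token,
  # HeH and B-other never do
  ex1 <- gen_expression(3, n_per_class = 5, fusion_fraction = 1)
  has_tok <- lengths(ex1$fusion_tokens) > 0
  fusion_cls <- ex1$labels %in% c("BCR-ABL1", "ETV6-RUNX1", "MLL", "TCF3-PBX1")
  expect_identical(has_tok, fusion_cls)
  expect_identical(unname(vapply(ex1$fusion_tokens[has_tok],
                                 function(t) fusion_token_class(t)[1], "")),
                   ex1$labels[has_tok])
})

test_that("skipping-fraction recovery is unbiased across clone fractions", {
  for (f in c(0.1, 0.9)) {
    jc <- gen_junction_counts(17, TEST_ANN,
                              list(list(gene = "PAX5", skipped_exons = 3:4, f = f)),
                              depth = 100, n_tumour = 200, n_normal = 2)
    skip <- vapply(jc$tumour, function(tab) {
      at <- tab[tab$donor_pos == jc$truth$donor_pos[1], ]
      s <- at$read_count[!at$annotated]
      if (length(s) == 0) 0 else s / sum(at$read_count)
    }, numeric(1))
    se <- sqrt(f * (1 - f) / 100) / sqrt(200)
    expect_lt(abs(mean(skip) - f), 3 * se)
  }
})

test_that("simulate_study writes the full input set with a truth file", {
  outdir <- withr::local_tempdir()
  simulate_study(5, outdir, n_tumour = 2, n_normal = 3, n_per_class = 3)
  expect_true(file.exists(file.path(outdir, "annotation.gtf")))
  expect_true(file.exists(file.path(outdir, "candidates.tsv")))
  expect_true(file.exists(file.path(outdir, "pairs.tsv")))
  expect_true(file.exists(file.path(outdir, "expression.tsv")))
  expect_true(file.exists(file.path(outdir, "truth.json")))
  expect_length(list.files(file.path(outdir, "junctions")), 2)
  expect_length(list.files(file.path(outdir, "normals")), 3)
  truth <- jsonlite::read_json(file.path(outdir, "truth.json"))
  expect_equal(truth$seed, 5)
  # data frames serialise row-wise: one JSON object per candidate row
  expect_equal(length(truth$fusion_truth), 31)
})
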