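test_that("the fixture bundle is deterministic: written twice, files are byte-identical", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  b1 <- build_fixture_cohort(d1)
  b2 <- build_fixture_cohort(d2)
  for (nm in names(b1$paths)) {
    expect_identical(unname(tools::md5sum(b1$paths[[nm]])),
                     unname(tools::md5sum(b2$paths[[nm]])),
                     label = paste("md5 of", nm))
  }
})

test_that("every frameshift row's printed c. position lies within or adjacent to its fs codon span", {
  b <- cached_fixture()
  fs <- b$expected_hits[grepl("fs$", b$expected_hits$p_or_splice), ]
  expect_gte(nrow(fs), 6L)
  for (i in seq_len(nrow(fs))) {
    cpos <- as.integer(regmatches(fs$c_hgvs[i],
                                  gregexpr("\\d+", fs$c_hgvs[i]))[[1]])
    codon <- as.integer(sub("^p\\.[A-Z](\\d+)fs$", "\\1", fs$p_or_splice[i]))
    span <- c(3L * codon - 2L, 3L * codon)
    expect_true(max(cpos) >= span[1L] - 1L && min(cpos) <= span[2L] + 1L,
                label = paste(fs$c_hgvs[i], "within or adjacent to codon span of",
                              fs$p_or_splice[i]))
  }
})

test_that("fixture transcripts satisfy the panel contract: 106 genes, one transcript each, CDS a multiple of 3", {
  b <- cached_fixture()
  expect_identical(length(b$panel$genes), 106L)
  expect_identical(length(b$txset), 106L)
  for (m in b$txset$transcripts) {
    expect_identical(m$cds_len %% 3L, 0L)
    expect_identical(substr(m$cds_seq, 1L, 3L), "ATG")
  }
})

test_that("emitted fixture files round-trip through the package readers without loss", {
  b <- cached_fixture()
  genome2 <- load_genome(b$paths$fasta)
  expect_identical(genome2[names(b$genome)], b$genome)
  txset2 <- load_transcripts(b$paths$transcripts, b$paths$fasta)
  expect_setequal(names(txset2$transcripts), names(b$txset$transcripts))
  for (id in names(b$txset$transcripts)) {
    m1 <- b$txset$transcripts[[id]]
    m2 <- txset2$transcripts[[id]]
    expect_identical(m2$exon_starts, m1$exon_starts)
    expect_identical(m2$spliced, m1$spliced)
    expect_identical(m2$cds_seq, m1$cds_seq)
  }
  cohort <- read_cohort(b$paths$vcf)
  expect_identical(length(cohort$individuals), 46L)
  # every planted variant is present as a call for its carrier
  for (id in names(b$manifest$individuals)) {
    calls <- cohort$calls[cohort$calls$individual_id == id, ]
    for (e in b$manifest$individuals[[id]]) {
      hit <- calls[calls$contig == e$contig & calls$pos == e$pos &
                   calls$alt == e$alt, ]
      expect_identical(nrow(hit), 1L)
      expect_identical(hit$zygosity, e$zygosity)
    }
  }
})

test_that("the simulator is seed-reproducible and seed-sensitive", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  d3 <- withr::local_tempdir()
  cfg <- cohort_config(n_individuals = 12L, panel_size = 6L,
                       per_gene_null_allele_freq = 0.05, seed = 42L)
  suppressMessages(simulate_cohort(cfg, d1))
  suppressMessages(simulate_cohort(cfg, d2))
  expect_identical(unname(tools::md5sum(file.path(d1, "cohort.vcf"))),
                   unname(tools::md5sum(file.path(d2, "cohort.vcf"))))
  cfg2 <- cohort_config(n_individuals = 12L, panel_size = 6L,
                        per_gene_null_allele_freq = 0.05, seed = 43L)
  suppressMessages(simulate_cohort(cfg2, d3))
  expect_false(identical(unname(tools::md5sum(file.path(d1, "cohort.vcf"))),
                         unname(tools::md5sum(file.path(d3, "cohort.vcf")))))
})

test_that("zero rates and frequencies give an empty cohort that screens to k = 0", {
  cfg <- cohort_config(n_individuals = 8L, panel_size = 4L,
                       per_gene_null_allele_freq = 0,
                       background_rates = c(synonymous = 0, missense = 0,
                                            deep_intronic = 0,
                                            noncanonical_splice_region = 0),
                       seed = 9L)
  d <- withr::local_tempdir()
  b <- simulate_cohort(cfg, d)
  expect_identical(nrow(b$records), 0L)
  cohort <- read_cohort(file.path(d, "cohort.vcf"))
  scr <- screen_cohort(cohort, b$txset, b$panel)
  expect_identical(scr$k, 0L)
  expect_identical(b$manifest$k, 0L)
})

test_that("planted simulator variants classify as intended: nulls null, benigns benign", {
  set.seed(1)
  cfg <- cohort_config(n_individuals = 10L, panel_size = 10L,
                       per_gene_null_allele_freq = 0.2, seed = 77L)
  b <- suppressMessages(simulate_cohort(cfg))
  n_null <- 0L; n_benign <- 0L
  for (id in names(b$manifest$individuals)) {
    for (e in b$manifest$individuals[[id]]) {
      tx <- gene_transcript(b$txset, e$gene)
      v <- normalize_variant(variant(e$contig, e$pos, e$ref, e$alt),
                             b$genome[[e$contig]])
      call <- classify_variant(v, tx)
      if (isTRUE(e$is_null)) {
        n_null <- n_null + 1L
        expect_true(call$is_null)
        expect_identical(call$category, e$category)
      } else {
        n_benign <- n_benign + 1L
        expect_false(call$is_null)
      }
    }
  }
  expect_gt(n_null, 0L)
  expect_gt(n_benign, 50L)
})

test_that("empirical carrier frequency over many simulated cohorts converges to the configured expectation", {
  G <- 3L; q <- 0.03; n_ind <- 40L
  p_carrier <- 1 - (1 - (2 * q * (1 - q) + q^2))^G
  reps <- 500L
  ks <- integer(reps)
  for (r in seq_len(reps)) {
    cfg <- cohort_config(n_individuals = n_ind, panel_size = G,
                         per_gene_null_allele_freq = q,
                         background_rates = c(synonymous = 0, missense = 0,
                                              deep_intronic = 0,
                                              noncanonical_splice_region = 0),
                         seed = 10000L + r)
    b <- suppressMessages(simulate_cohort(cfg))
    ks[r] <- b$manifest$k
  }
  emp <- sum(ks) / (reps * n_ind)
  mc_se <- sqrt(p_carrier * (1 - p_carrier) / (reps * n_ind))
  expect_lt(abs(emp - p_carrier), 3 * mc_se)
})
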