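test_that("transcript construction, spliced CDS and codon lookup agree with a base-walk oracle on both strands", {
  for (seed in 1:8) {
    m <- random_test_tx(seed)
    maps <- oracle_maps(m)
    expect_identical(m$spliced, maps$spliced)
    expect_identical(m$cds_seq, substr(maps$spliced, maps$t1, maps$t2))
    expect_identical(m$utr5_len, maps$t1 - 1L)
    # codon_at agrees with direct triplet chunking
    cods <- substring(m$cds_seq, seq(1L, m$cds_len, 3L),
                      seq(3L, m$cds_len, 3L))
    for (cpos in sample(seq_len(m$cds_len), 25L)) {
      ca <- codon_at(m, cpos)
      expect_identical(ca$codon_index, (cpos + 2L) %/% 3L)
      expect_identical(ca$codon_bases, cods[ca$codon_index])
      expect_identical(ca$frame_offset, (cpos - 1L) %% 3L)
    }
  }
})

test_that("model invariants are enforced at construction", {
  seqs <- paste(rep("ACGT", 100L), collapse = "")
  expect_error(
    transcript_model("G", "T1", "c", "+", c(10L, 30L), c(40L, 60L),
                     12L, 55L, seqs),
    "overlap")
  expect_error(
    transcript_model("G", "T1", "c", "+", c(10L, 60L), c(40L, 90L),
                     45L, 80L, seqs),  # CDS start in the intron
    "CDS outside exon union")
  expect_error(
    transcript_model("G", "T1", "c", "+", 10L, 40L, 12L, 38L, ""),
    "contig sequence")
  expect_error(
    transcript_model("G", "T1", "c", "*", 10L, 40L, 12L, 38L, seqs),
    "strand")
  # CDS length not a multiple of 3 warns but constructs
  expect_warning(
    transcript_model("G", "T1", "c", "+", 10L, 40L, 12L, 21L, seqs),
    "not a multiple of 3")
})

test_that("coordinate mapping round-trips and matches exhaustive enumeration, exons and introns, both strands", {
  for (seed in c(11, 12, 13, 14)) {
    m <- random_test_tx(seed)
    span <- c(min(m$exon_starts), max(m$exon_ends))
    gs <- seq(span[1L], span[2L])
    got <- lapply(gs, function(g) genomic_to_cds(m, g))
    want <- lapply(gs, function(g) oracle_c(m, g))
    enc <- function(x) paste(x$kind, x$base, x$offset,
                             if (identical(x$kind, "intronic")) x$intron_index
                             else 0L)
    expect_identical(vapply(got, enc, character(1)),
                     vapply(want, enc, character(1)))
    # round trip
    expect_identical(vapply(got, function(cc) cds_to_genomic(m, cc),
                            integer(1)), gs)
    # strand -: increasing c.base maps to decreasing genomic position
    if (m$strand == "-") {
      g1 <- cds_to_genomic(m, cds_coord(1L))
      g2 <- cds_to_genomic(m, cds_coord(2L))
      expect_lt(g2, g1)
    }
  }
  # positions outside the transcript are rejected
  m <- random_test_tx(11)
  expect_error(genomic_to_cds(m, min(m$exon_starts) - 5L), "outside transcript")
  expect_error(codon_at(m, m$cds_len + 1L), "outside CDS")
  expect_error(cds_to_genomic(m, cds_coord(m$cds_len + 3L)), "outside CDS")
})

test_that("engineered fixture transcripts expose the printed coordinate landmarks", {
  b <- cached_fixture()
  cep <- gene_transcript(b$txset, "CEP290")
  expect_gte(cep$cds_len, 3L * 1465L)  # coding position 4393 exists
  ca <- codon_at(cep, 4393L)
  expect_identical(ca$codon_index, 1465L)
  expect_identical(ca$frame_offset, 0L)
  abca4 <- gene_transcript(b$txset, "ABCA4")
  ca2 <- codon_at(abca4, 834L)
  expect_identical(ca2$codon_index, 278L)
  expect_identical(ca2$frame_offset, 2L)
  expect_identical(codon_at(abca4, 1L)$codon_index, 1L)
  expect_identical(codon_at(abca4, 3L)$codon_index, 1L)

  # first base of the start codon is c.1
  g_start <- cds_to_genomic(cep, cds_coord(1L))
  cc <- genomic_to_cds(cep, g_start)
  expect_identical(cc$kind, "coding")
  expect_identical(cc$base, 1L)

  # donor +1 of intron 11 of the CC2D2A stand-in renders c.1017+1
  cc2 <- gene_transcript(b$txset, "CC2D2A")
  g <- cds_to_genomic(cc2, cds_coord(1017L, 1L))
  cc_int <- genomic_to_cds(cc2, g)
  expect_identical(cc_int$kind, "intronic")
  expect_identical(cc_int$base, 1017L)
  expect_identical(cc_int$offset, 1L)
  expect_identical(cc_int$intron_index, 11L)
  expect_identical(format(cc_int), "1017+1")

  # 5'UTR intron of the AHI1 stand-in renders c.-55+1
  ahi <- gene_transcript(b$txset, "AHI1")
  g <- cds_to_genomic(ahi, cds_coord(-55L, 1L, "five_prime_utr"))
  cc_utr <- genomic_to_cds(ahi, g)
  expect_identical(cc_utr$base, -55L)
  expect_identical(cc_utr$offset, 1L)
  expect_identical(cc_utr$intron_index, 2L)
  expect_identical(format(cc_utr), "-55+1")
})

test_that("transcript TSV loading validates contigs, duplicates, and applies the canonical-transcript rule", {
  dir <- withr::local_tempdir()
  contig <- paste(rep("ACGTTGCA", 60L), collapse = "")
  fa <- file.path(dir, "ref.fa")
  writeLines(c(">c1", contig), fa)
  tsv <- file.path(dir, "tx.tsv")
  hdr <- paste("gene_symbol", "transcript_id", "contig", "strand",
               "exon_starts", "exon_ends", "cds_start", "cds_end", sep = "\t")
  row <- function(gene, id, cds_end, contig_name = "c1")
    paste(gene, id, contig_name, "+", "11,101", "60,200", "21", cds_end,
          sep = "\t")
  # two transcripts of one gene: longest CDS wins
  writeLines(c(hdr, row("G1", "TX_B", "153"), row("G1", "TX_A", "44")), tsv)
  txset <- load_transcripts(tsv, fa)
  expect_identical(length(txset), 1L)
  expect_identical(gene_transcript(txset, "G1")$transcript_id, "TX_B")

  # tie on CDS length: lexicographically smallest id
  writeLines(c(hdr, row("G1", "TX_B", "153"), row("G1", "TX_A", "153")), tsv)
  expect_identical(gene_transcript(load_transcripts(tsv, fa), "G1")$transcript_id,
                   "TX_A")

  writeLines(c(hdr, row("G1", "TX_A", "153"), row("G1", "TX_A", "153")), tsv)
  expect_error(load_transcripts(tsv, fa), "duplicate transcript_id")

  writeLines(c(hdr, row("G1", "TX_A", "153", contig_name = "cMissing")), tsv)
  expect_error(load_transcripts(tsv, fa), "cMissing")
})

test_that("the minimal GTF reader reconstructs the same models as the TSV reader", {
  b <- cached_fixture()
  m <- gene_transcript(b$txset, "ROM1")
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "ref.fa")
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(b$genome["ctg_ROM1"]), fa)
  gtf <- file.path(dir, "g.gtf")
  attrs <- sprintf('gene_name "%s"; transcript_id "%s";',
                   m$gene_symbol, m$transcript_id)
  lines <- c("# comment",
    sprintf("ctg_ROM1\tsyn\texon\t%d\t%d\t.\t+\t.\t%s",
            m$exon_starts, m$exon_ends, attrs),
    sprintf("ctg_ROM1\tsyn\tCDS\t%d\t%d\t.\t+\t.\t%s",
            m$cds_start_genomic, m$cds_end_genomic, attrs),
    sprintf("ctg_ROM1\tsyn\tfive_prime_utr\t1\t10\t.\t+\t.\t%s", attrs))
  writeLines(lines, gtf)
  txset2 <- read_gtf_transcripts(gtf, fa)
  m2 <- gene_transcript(txset2, "ROM1")
  expect_identical(m2$exon_starts, m$exon_starts)
  expect_identical(m2$exon_ends, m$exon_ends)
  expect_identical(m2$cds_seq, m$cds_seq)
})

test_that("gene panel reading normalizes case, strips comments and rejects empty panels", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "panel.txt")
  writeLines(c("# my panel", "abca4", "ABCA4", "Ush2a", "", "  rom1  "), p)
  panel <- read_gene_panel(p)
  expect_setequal(panel$genes, c("ABCA4", "USH2A", "ROM1"))
  writeLines("# nothing", p)
  expect_error(read_gene_panel(p), "empty gene panel")
})
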