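# Deterministic fixture cohort: 46 diploid individuals, a 106-gene recessive
# retinal-degeneration panel, ten heterozygous null variants planted in ten
# distinct individuals, and benign background variants in every genome.
# Gene sequences are synthetic; only the coordinate and codon context needed
# for the planted variants' printed c./p. annotations is engineered.

# Cohort sample identifiers (public repository IDs) and the population
# labels cycled over the remaining genomes. The labels are cosmetic
# metadata; they affect no computation.
.FIXTURE_IDS <- c(
  "NA06985", "NA06994", "NA07357", "NA10851", "NA12004", "NA18501",
  "NA18502", "NA18504", "NA18505", "NA18508", "NA18517", "NA18526",
  "NA18537", "NA18555", "NA18558", "NA18940", "NA18942", "NA18947",
  "NA18956", "NA19017", "NA19020", "NA19025", "NA19026", "NA19129",
  "NA19648", "NA19649", "NA19669", "NA19670", "NA19700", "NA19701",
  "NA19703", "NA19704", "NA19735", "NA19834", "NA20502", "NA20509",
  "NA20510", "NA20511", "NA20845", "NA20846", "NA20847", "NA20850",
  "NA21732", "NA21733", "NA21737", "NA21767")

.FIXTURE_POPULATIONS <- c("European American", "African American", "Mexican",
                          "Italian", "Maasai", "Yoruba", "Luhya", "Chinese",
                          "Japanese", "Gujarati")

# The ten planted null variants: carrier, ethnicity label, gene, expected
# c./p. annotation, and the transcript-space plant specification.
#' @noRd
.fixture_null_rows <- function() {
  list(
    list(id = "NA10851", eth = "European American", gene = "ROM1",
         c_hgvs = "c.493_494insA", p = "p.R165fs",
         plant = list(kind = "ins", c_after = 493L, seq_t = "A")),
    list(id = "NA19700", eth = "African American", gene = "ROM1",
         c_hgvs = "c.868delC", p = "p.Q290fs",
         plant = list(kind = "del", c_from = 868L, c_to = 868L)),
    list(id = "NA18526", eth = "Chinese", gene = "PCDH15",
         c_hgvs = "c.4866_4867insGACA", p = "p.D1623fs",
         plant = list(kind = "ins", c_after = 4866L, seq_t = "GACA")),
    list(id = "NA20846", eth = "Gujarati", gene = "CEP290",
         c_hgvs = "c.7392_7393delAG", p = "p.E2465fs",
         plant = list(kind = "del", c_from = 7392L, c_to = 7393L)),
    list(id = "NA20850", eth = "Gujarati", gene = "CEP290",
         c_hgvs = "c.4393C>T", p = "p.R1465X",
         plant = list(kind = "snv", coord = 4393L, ref_t = "C", alt_t = "T")),
    list(id = "NA19020", eth = "Luhya", gene = "PCDH15",
         c_hgvs = "c.5264_5265insGTCT", p = "p.Q1755fs",
         plant = list(kind = "ins", c_after = 5264L, seq_t = "GTCT")),
    list(id = "NA20509", eth = "Italian", gene = "USH2A",
         c_hgvs = "c.917_918insCAGC", p = "p.S307fs",
         plant = list(kind = "ins", c_after = 917L, seq_t = "CAGC")),
    list(id = "NA18501", eth = "Yoruba", gene = "CC2D2A",
         c_hgvs = "c.1017+1G>A", p = "IVS11+1G>A",
         plant = list(kind = "snv", coord = cds_coord(1017L, 1L),
                      ref_t = "G", alt_t = "A")),
    list(id = "NA18504", eth = "Yoruba", gene = "ABCA4",
         c_hgvs = "c.834delT", p = "p.S278fs",
         plant = list(kind = "del", c_from = 834L, c_to = 834L)),
    list(id = "NA19129", eth = "Yoruba", gene = "AHI1",
         c_hgvs = "c.-55+1G>T", p = "IVS2+1G>T",
         plant = list(kind = "snv",
                      coord = cds_coord(-55L, 1L, "five_prime_utr"),
                      ref_t = "G", alt_t = "T")))
}

# Engineered transcript definitions. Codon overrides pin down exactly the
# reference context each planted variant needs (reference amino acids,
# wobble behaviour of partially affected codons, and flanking bases chosen
# so VCF left-alignment cannot shift the planted spellings).
#' @noRd
.fixture_gene_defs <- function() {
  list(
    ROM1 = list(utr5 = 50L, n_codons = 352L, utr3 = 60L, strand = "+",
                overrides = list("165" = "CGA", "290" = "CAA"),
                exons = c(400L, 400L, 366L), introns = c(90L, 90L)),
    PCDH15 = list(utr5 = 80L, n_codons = 1801L, utr3 = 100L, strand = "+",
                  overrides = list("1622" = "CTG", "1623" = "GAT",
                                   "1755" = "CAA"),
                  exons = c(1200L, 1200L, 1200L, 1200L, 783L),
                  introns = rep(90L, 4L)),
    CEP290 = list(utr5 = 100L, n_codons = 2480L, utr3 = 100L, strand = "+",
                  overrides = list("1465" = "CGA", "2464" = "CTA",
                                   "2465" = "GAA", "2466" = "TGG"),
                  exons = c(1600L, 1600L, 1600L, 1600L, 1240L),
                  introns = rep(90L, 4L)),
    USH2A = list(utr5 = 60L, n_codons = 1201L, utr3 = 80L, strand = "+",
                 overrides = list("306" = "TTC", "307" = "TCT"),
                 exons = c(1000L, 1000L, 1000L, 743L),
                 introns = rep(90L, 3L)),
    CC2D2A = list(utr5 = 120L, n_codons = 1101L, utr3 = 90L, strand = "+",
                  overrides = list(),
                  exons = c(rep(103L, 10L), 107L, 800L, 800L, 776L),
                  introns = rep(90L, 13L)),
    ABCA4 = list(utr5 = 60L, n_codons = 801L, utr3 = 70L, strand = "-",
                 overrides = list("278" = "TCT", "279" = "GCT"),
                 exons = c(900L, 900L, 733L), introns = c(90L, 90L)),
    AHI1 = list(utr5 = 109L, n_codons = 1001L, utr3 = 80L, strand = "+",
                overrides = list(),
                exons = c(40L, 15L, 1200L, 1000L, 937L),
                introns = rep(90L, 4L))
  )
}

#' Build the deterministic fixture cohort
#'
#' Constructs, with no randomness, a complete input bundle for the screening
#' pipeline: a 106-gene panel whose seven engineered genes carry transcripts
#' reproducing the ten planted null variants' printed c. and p./IVS
#' annotations; 46 diploid individuals with those ten variants planted
#' heterozygously in ten distinct genomes; and six benign background
#' variants (synonymous, missense, deep-intronic) per individual inside
#' panel genes. Written twice, the bundle is byte-identical.
#'
#' @param out_dir Optional output directory. When given, writes
#'   `reference.fa`, `transcripts.tsv`, `panel.txt`, `cohort.vcf`,
#'   `samples.tsv` and `truth.json` there.
#' @return Invisibly, a list with the in-memory bundle: `genome` (named
#'   character), `txset`, `panel`, `cohort`, `samples` (data frame),
#'   `manifest`, `expected_hits` (the ten expected report rows) and, when
#'   `out_dir` was given, `paths`.
#' @export
build_fixture_cohort <- function(out_dir = NULL) {
  defs <- .fixture_gene_defs()
  models <- list()
  genome <- character(0)
  for (gene in names(defs)) {
    d <- defs[[gene]]
    lay <- .layout_gene(
      gene = gene, tx_id = paste0("SYNT_", gene, ".1"),
      contig = paste0("ctg_", gene), strand = d$strand,
      utr5_len = d$utr5,
      codons = .make_codons(d$n_codons, d$overrides),
      utr3_len = d$utr3, exon_tx_lens = d$exons, intron_lens = d$introns)
    models[[length(models) + 1L]] <- lay$model
    genome[paste0("ctg_", gene)] <- lay$contig_seq
  }
  filler_syms <- sprintf("RETS%03d", seq_len(99L))
  for (i in seq_along(filler_syms)) {
    sym <- filler_syms[i]
    lay <- .layout_gene(
      gene = sym, tx_id = paste0("SYNT_", sym, ".1"),
      contig = paste0("ctg_", sym),
      strand = if (i %% 2L == 0L) "-" else "+",
      utr5_len = 24L, codons = .make_codons(62L, phase = i), utr3_len = 24L,
      exon_tx_lens = c(100L, 134L), intron_lens = 80L)
    models[[length(models) + 1L]] <- lay$model
    genome[paste0("ctg_", sym)] <- lay$contig_seq
  }
  txset <- transcript_set(models)
  panel_genes <- c(names(defs), filler_syms)
  panel <- gene_panel(panel_genes, label = "synthetic HRD panel (106 genes)")

  # ethnicity labels: fixed for the ten carriers, cycled for the rest
  rows <- .fixture_null_rows()
  eth <- stats::setNames(rep(NA_character_, length(.FIXTURE_IDS)),
                         .FIXTURE_IDS)
  for (r in rows) eth[r$id] <- r$eth
  open_idx <- which(is.na(eth))
  eth[open_idx] <- .FIXTURE_POPULATIONS[((seq_along(open_idx) - 1L) %%
                                         length(.FIXTURE_POPULATIONS)) + 1L]
  samples_df <- data.frame(individual_id = .FIXTURE_IDS,
                           ethnicity = unname(eth),
                           stringsAsFactors = FALSE)

  plants <- list()
  manifest_vars <- stats::setNames(
    replicate(length(.FIXTURE_IDS), list(), simplify = FALSE), .FIXTURE_IDS)
  add_plant <- function(id, rec, gene, category, is_null, zygosity,
                        c_hgvs = NULL, p_or_splice = NULL) {
    plants[[length(plants) + 1L]] <<- data.frame(
      individual_id = id, contig = rec$contig, pos = rec$pos,
      ref = rec$ref, alt = rec$alt, zygosity = zygosity,
      stringsAsFactors = FALSE)
    entry <- list(contig = rec$contig, pos = rec$pos, ref = rec$ref,
                  alt = rec$alt, gene = gene, category = category,
                  is_null = is_null, zygosity = zygosity)
    if (!is.null(c_hgvs)) entry$c_hgvs <- c_hgvs
    if (!is.null(p_or_splice)) entry$p_or_splice <- p_or_splice
    manifest_vars[[id]][[length(manifest_vars[[id]]) + 1L]] <<- entry
  }

  null_category <- function(p) {
    if (startsWith(p, "IVS")) "canonical_splice"
    else if (endsWith(p, "fs")) "frameshift"
    else "stop_gained"
  }
  for (r in rows) {
    model <- gene_transcript(txset, r$gene)
    rec <- .plant_to_vcf(model, r$plant)
    add_plant(r$id, rec, r$gene, null_category(r$p), TRUE, "het",
              c_hgvs = r$c_hgvs, p_or_splice = r$p)
  }

  # benign background: six variants per individual (synonymous, missense,
  # deep intronic cycled), drawn deterministically across the panel
  catalog <- lapply(stats::setNames(panel_genes, panel_genes), function(g) {
    .benign_site_catalog(gene_transcript(txset, g))
  })
  types <- c("synonymous", "missense", "deep_intronic")
  for (i in seq_along(.FIXTURE_IDS)) {
    id <- .FIXTURE_IDS[i]
    for (j in 0:5) {
      gene <- panel_genes[(((i - 1L) * 7L + j * 17L) %% length(panel_genes)) + 1L]
      type <- types[(j %% 3L) + 1L]
      site <- catalog[[gene]][[type]][[1L]]
      add_plant(id, site$rec, gene, type, FALSE, "het")
    }
  }

  plants_df <- do.call(rbind, plants)
  # each individual's records must be unique sites
  stopifnot(!anyDuplicated(paste(plants_df$individual_id, plants_df$contig,
                                 plants_df$pos, plants_df$ref,
                                 plants_df$alt)))

  manifest <- list(
    n = length(.FIXTURE_IDS),
    k = length(unique(vapply(rows, `[[`, character(1), "id"))),
    panel_size = length(panel_genes),
    individuals = manifest_vars)

  expected_hits <- do.call(rbind, lapply(rows, function(r) {
    data.frame(individual_id = r$id, ethnicity = r$eth, gene = r$gene,
               c_hgvs = r$c_hgvs, p_or_splice = r$p, stringsAsFactors = FALSE)
  }))
  expected_hits <- expected_hits[order(expected_hits$individual_id,
                                       expected_hits$gene), , drop = FALSE]
  rownames(expected_hits) <- NULL

  asm <- .assemble_genotypes(plants_df, .FIXTURE_IDS)
  bundle <- list(genome = genome, txset = txset, panel = panel,
                 records = asm$records, gt = asm$gt,
                 samples = samples_df, manifest = manifest,
                 expected_hits = expected_hits)
  if (!is.null(out_dir)) {
    bundle$paths <- .write_bundle(out_dir, genome, txset$transcripts,
                                  panel_genes, plants_df, .FIXTURE_IDS,
                                  samples_df, manifest)
  }
  invisible(bundle)
}

# Guaranteed-benign SNV sites of a synthetic transcript: a synonymous
# wobble site (CTT codon, T>C), a missense site (GCT codon, C>T) and a deep
# intronic site (+15 from the first donor). Sites keep >=4 exonic bases
# clear of every exon boundary so no rule interaction can occur.
#' @noRd
.benign_site_catalog <- function(model) {
  codons <- codon_split(model$cds_seq)
  n <- length(codons)
  clear_of_boundary <- function(cpos) {
    t <- cpos + model$utr5_len
    j <- which(model$t_start <= t & t <= model$t_end)
    (t - model$t_start[j]) >= 4L && (model$t_end[j] - t) >= 4L
  }
  pick_codon <- function(codon) {
    idx <- which(codons == codon)
    idx <- idx[idx > 2L & idx < n - 1L]
    idx <- idx[vapply(idx, function(i) clear_of_boundary(3L * i - 2L) &&
                        clear_of_boundary(3L * i), logical(1))]
    stopifnot(length(idx) >= 1L)
    idx[1L]
  }
  syn_i <- pick_codon("CTT")
  mis_i <- pick_codon("GCT")
  syn <- list(kind = "snv", coord = 3L * syn_i, ref_t = "T", alt_t = "C")
  mis <- list(kind = "snv", coord = 3L * mis_i - 1L, ref_t = "C", alt_t = "T")
  # first intron, 15 bases past the donor (intron lengths are >= 80)
  deep_coord <- genomic_to_cds(
    model, cds_to_genomic(model, .donor_plus_offset(model, 1L, 15L)))
  stopifnot(deep_coord$kind == "intronic", abs(deep_coord$offset) > 8L)
  g <- cds_to_genomic(model, deep_coord)
  ref_g <- substr(model$contig_seq, g, g)
  alt_g <- c(A = "G", C = "T", G = "A", T = "C")[[ref_g]]
  ref_t <- if (model$strand == "+") ref_g else comp_base(ref_g)
  alt_t <- if (model$strand == "+") alt_g else comp_base(alt_g)
  deep <- list(kind = "snv", coord = deep_coord, ref_t = ref_t, alt_t = alt_t)
  list(
    synonymous = list(list(rec = .plant_to_vcf(model, syn))),
    missense = list(list(rec = .plant_to_vcf(model, mis))),
    deep_intronic = list(list(rec = .plant_to_vcf(model, deep)))
  )
}

# cds_coord of the base `offset` past the donor of intron `i` (transcript
# order).
#' @noRd
.donor_plus_offset <- function(model, intron_index, offset) {
  j <- intron_index  # transcript-order exon whose end is the donor
  t_donor <- model$t_end[j]
  cc <- t_to_c(model, t_donor)
  cds_coord(cc$base, offset, cc$kind)
}
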