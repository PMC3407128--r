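# Shared builders for the synthetic-data module: deterministic sequence
# fillers, gene layout (spliced parts -> contig + transcript model), plant
# spec -> VCF record conversion, and the plain-text bundle writers.

# Non-stop filler codons cycled deterministically; CTT and GCT occurrences
# double as guaranteed synonymous (CTT>CTC) and missense (GCT>GTT) SNV sites.
.CODON_CYCLE <- c("CTT", "GCT", "GAT", "AAA", "GGC", "TTC",
                  "ACA", "GAG", "TCC", "ATC", "CAC", "GTG")

#' @noRd
.filler_codons <- function(n, phase = 0L) {
  .CODON_CYCLE[((seq_len(n) - 1L + phase) %% length(.CODON_CYCLE)) + 1L]
}

#' @noRd
.filler_seq <- function(len, phase = 0L) {
  if (len <= 0L) return("")
  pat <- strsplit("TACGCTAGCA", "")[[1]]
  paste(pat[((seq_len(len) - 1L + phase) %% length(pat)) + 1L], collapse = "")
}

# Intron with canonical GT...AG dinucleotides.
#' @noRd
.intron_seq <- function(len, phase = 0L) {
  stopifnot(len >= 10L)
  paste0("GT", .filler_seq(len - 4L, phase), "AG")
}

# Standard CDS construction: ATG + filler codons (+ overrides) + stop.
# overrides is a named list, names = codon indices.
#' @noRd
.make_codons <- function(n_codons, overrides = list(), phase = 0L) {
  stopifnot(n_codons >= 3L)
  codons <- c("ATG", .filler_codons(n_codons - 2L, phase), "TAA")
  for (idx in names(overrides)) {
    i <- as.integer(idx)
    stopifnot(i >= 2L, i <= n_codons - 1L)
    codons[i] <- overrides[[idx]]
  }
  stopifnot(!codons[-n_codons] %in% c("TAA", "TAG", "TGA"))
  codons
}

# Lay a transcript (5'UTR + codons + 3'UTR, split into exons of the given
# transcript-order lengths, introns in between) onto a fresh contig.
# Returns the transcript_model plus the contig sequence.
#' @noRd
.layout_gene <- function(gene, tx_id, contig, strand, utr5_len, codons,
                         utr3_len, exon_tx_lens, intron_lens, flank = 100L) {
  tx_seq <- paste0(.filler_seq(utr5_len, 3L), paste(codons, collapse = ""),
                   .filler_seq(utr3_len, 7L))
  total <- nchar(tx_seq)
  stopifnot(sum(exon_tx_lens) == total,
            length(intron_lens) == length(exon_tx_lens) - 1L)
  t_ends <- cumsum(exon_tx_lens)
  t_starts <- t_ends - exon_tx_lens + 1L
  pieces <- character(0)
  for (i in seq_along(exon_tx_lens)) {
    pieces <- c(pieces, substr(tx_seq, t_starts[i], t_ends[i]))
    if (i < length(exon_tx_lens))
      pieces <- c(pieces, .intron_seq(intron_lens[i], phase = i))
  }
  region <- paste(pieces, collapse = "")
  L <- nchar(region)
  contig_seq <- paste0(.filler_seq(flank, 1L),
                       if (strand == "+") region else revcomp(region),
                       .filler_seq(flank, 5L))
  # genomic coordinates of each transcript-order exon
  reg_starts <- integer(length(exon_tx_lens))  # 1-based within region, tx order
  off <- 0L
  for (i in seq_along(exon_tx_lens)) {
    reg_starts[i] <- off + 1L
    off <- off + exon_tx_lens[i] +
      if (i < length(exon_tx_lens)) intron_lens[i] else 0L
  }
  reg_ends <- reg_starts + exon_tx_lens - 1L
  if (strand == "+") {
    gstart <- flank + reg_starts
    gend <- flank + reg_ends
  } else {
    gstart <- flank + (L - reg_ends) + 1L
    gend <- flank + (L - reg_starts) + 1L
  }
  ord <- order(gstart)
  t_cds_1 <- utr5_len + 1L
  t_cds_2 <- utr5_len + 3L * length(codons)
  g_of_t <- function(t) {
    i <- which(t_starts <= t & t <= t_ends)
    stopifnot(length(i) == 1L)
    if (strand == "+") gstart[i] + (t - t_starts[i])
    else gend[i] - (t - t_starts[i])
  }
  cds_g <- sort(c(g_of_t(t_cds_1), g_of_t(t_cds_2)))
  m <- transcript_model(
    gene_symbol = gene, transcript_id = tx_id, contig = contig,
    strand = strand, exon_starts = gstart[ord], exon_ends = gend[ord],
    cds_start = cds_g[1L], cds_end = cds_g[2L], contig_seq = contig_seq)
  stopifnot(identical(m$cds_seq, paste(codons, collapse = "")),
            m$utr5_len == utr5_len, m$utr3_len == utr3_len)
  list(model = m, contig_seq = contig_seq)
}

# Convert a transcript-space plant specification into a VCF-style record.
# Kinds: snv (coord, ref_t, alt_t), ins (c_after, seq_t), del (c_from, c_to).
# coord may be a coding base number or a cds_coord (for intronic/UTR SNVs).
#' @noRd
.plant_to_vcf <- function(model, plant) {
  plus <- model$strand == "+"
  contig_seq <- model$contig_seq
  base_at <- function(g) substr(contig_seq, g, g)
  as_coord <- function(x) if (inherits(x, "cds_coord")) x else cds_coord(x)
  if (plant$kind == "snv") {
    g <- cds_to_genomic(model, as_coord(plant$coord))
    ref_g <- base_at(g)
    expect_ref <- if (plus) plant$ref_t else comp_base(plant$ref_t)
    stopifnot(identical(ref_g, expect_ref))
    alt_g <- if (plus) plant$alt_t else comp_base(plant$alt_t)
    return(list(contig = model$contig, pos = g, ref = ref_g, alt = alt_g))
  }
  if (plant$kind == "ins") {
    gL <- if (plus) cds_to_genomic(model, as_coord(plant$c_after))
          else cds_to_genomic(model, as_coord(plant$c_after + 1L))
    seq_g <- if (plus) plant$seq_t else revcomp(plant$seq_t)
    anchor <- base_at(gL)
    return(list(contig = model$contig, pos = gL, ref = anchor,
                alt = paste0(anchor, seq_g)))
  }
  if (plant$kind == "del") {
    g1 <- cds_to_genomic(model, as_coord(plant$c_from))
    g2 <- cds_to_genomic(model, as_coord(plant$c_to))
    lo <- min(g1, g2); hi <- max(g1, g2)
    anchor <- lo - 1L
    return(list(contig = model$contig, pos = anchor,
                ref = substr(contig_seq, anchor, hi),
                alt = base_at(anchor)))
  }
  stop("unknown plant kind: ", plant$kind)
}

# Write a multi-sample VCF v4.2 (GT only). records: data frame with contig,
# pos, ref, alt; gt: character matrix records x samples.
#' @noRd
.write_vcf <- function(path, genome, records, gt, sample_ids) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=hrdscreen-synthetic",
    sprintf("##contig=<ID=%s,length=%d>", names(genome), nchar(genome)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_ids), collapse = "\t"))
  if (nrow(records)) {
    ord <- order(match(records$contig, names(genome)), records$pos,
                 records$ref, records$alt)
    records <- records[ord, , drop = FALSE]
    gt <- gt[ord, , drop = FALSE]
    body <- vapply(seq_len(nrow(records)), function(i) {
      paste(c(records$contig[i], records$pos[i], ".", records$ref[i],
              records$alt[i], ".", "PASS", ".", "GT", gt[i, ]),
            collapse = "\t")
    }, character(1))
  } else body <- character(0)
  writeLines(c(header, body), path)
  invisible(path)
}

#' @noRd
.write_transcript_tsv <- function(path, models) {
  rows <- vapply(models, function(m) {
    paste(m$gene_symbol, m$transcript_id, m$contig, m$strand,
          paste(m$exon_starts, collapse = ","),
          paste(m$exon_ends, collapse = ","),
          m$cds_start_genomic, m$cds_end_genomic, sep = "\t")
  }, character(1))
  writeLines(c(paste("gene_symbol", "transcript_id", "contig", "strand",
                     "exon_starts", "exon_ends", "cds_start", "cds_end",
                     sep = "\t"), rows), path)
  invisible(path)
}

# Assemble per-individual planted variants into a site x sample genotype
# matrix. plants: data frame individual_id, contig, pos, ref, alt, zygosity.
#' @noRd
.assemble_genotypes <- function(plants, sample_ids) {
  if (!nrow(plants)) {
    return(list(records = data.frame(contig = character(0), pos = integer(0),
                                     ref = character(0), alt = character(0),
                                     stringsAsFactors = FALSE),
                gt = matrix(character(0), nrow = 0L,
                            ncol = length(sample_ids))))
  }
  key <- paste(plants$contig, plants$pos, plants$ref, plants$alt, sep = "\r")
  ukey <- unique(key)
  idx <- match(key, ukey)
  first <- match(ukey, key)
  records <- data.frame(contig = plants$contig[first],
                        pos = plants$pos[first], ref = plants$ref[first],
                        alt = plants$alt[first], stringsAsFactors = FALSE)
  gt <- matrix("0/0", nrow = length(ukey), ncol = length(sample_ids),
               dimnames = list(NULL, sample_ids))
  for (i in seq_len(nrow(plants))) {
    g <- if (plants$zygosity[i] == "hom_alt") "1/1" else "0/1"
    gt[idx[i], plants$individual_id[i]] <- g
  }
  list(records = records, gt = gt)
}

# Write a complete fixture bundle; returns the file paths.
#' @noRd
.write_bundle <- function(out_dir, genome, models, panel_genes, plants,
                          sample_ids, samples_df, manifest) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    fasta = file.path(out_dir, "reference.fa"),
    transcripts = file.path(out_dir, "transcripts.tsv"),
    panel = file.path(out_dir, "panel.txt"),
    vcf = file.path(out_dir, "cohort.vcf"),
    samples = file.path(out_dir, "samples.tsv"),
    manifest = file.path(out_dir, "truth.json"))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), paths$fasta,
                              width = 70L)
  .write_transcript_tsv(paths$transcripts, models)
  writeLines(c("# gene panel", panel_genes), paths$panel)
  asm <- .assemble_genotypes(plants, sample_ids)
  .write_vcf(paths$vcf, genome, asm$records, asm$gt, sample_ids)
  utils::write.table(samples_df, paths$samples, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  paths
}
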