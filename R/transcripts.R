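#' Stranded multi-exon transcript model
#'
#' Builds a validated transcript model: the coordinate system against which
#' all variant consequences are called. Genomic inputs are 1-based inclusive
#' (VCF/GTF convention); internally intervals are kept 0-based half-open and
#' converted only at the interface.
#'
#' @param gene_symbol Gene symbol the transcript belongs to.
#' @param transcript_id Unique transcript identifier.
#' @param contig Name of the reference contig carrying the gene.
#' @param strand `"+"` or `"-"`. For `"-"`, exon 1 (in transcription order)
#'   is the genomically last interval.
#' @param exon_starts,exon_ends Integer vectors of exon boundaries, 1-based
#'   inclusive, sorted by genomic start and pairwise non-overlapping.
#' @param cds_start,cds_end 1-based genomic positions of the first and last
#'   base of the coding sequence (genomic orientation, so `cds_start <=
#'   cds_end` on either strand).
#' @param contig_seq Reference sequence of the contig as a character string.
#'   Mandatory: transcripts without retrievable sequence are rejected.
#'
#' @return An object of class `transcript_model` with precomputed spliced
#'   sequence, CDS sequence and exon coordinate maps.
#' @export
transcript_model <- function(gene_symbol, transcript_id, contig, strand,
                             exon_starts, exon_ends, cds_start, cds_end,
                             contig_seq) {
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  exon_starts <- as.integer(exon_starts)
  exon_ends <- as.integer(exon_ends)
  cds_start <- as.integer(cds_start)
  cds_end <- as.integer(cds_end)
  if (length(exon_starts) != length(exon_ends) || length(exon_starts) < 1L)
    stop("exon_starts/exon_ends must be non-empty and of equal length")
  if (any(exon_starts > exon_ends))
    stop("transcript ", transcript_id, ": exon start beyond exon end")
  if (is.unsorted(exon_starts, strictly = TRUE))
    stop("transcript ", transcript_id, ": exons must be sorted by genomic start")
  if (length(exon_starts) > 1L &&
      any(exon_starts[-1L] <= exon_ends[-length(exon_ends)]))
    stop("transcript ", transcript_id, ": overlapping exons")
  if (!is.character(contig_seq) || length(contig_seq) != 1L || !nzchar(contig_seq))
    stop("transcript ", transcript_id, ": missing contig sequence")
  if (min(exon_starts) < 1L || max(exon_ends) > nchar(contig_seq))
    stop("transcript ", transcript_id, ": exon outside contig ", contig)
  in_exon <- function(g) any(exon_starts <= g & g <= exon_ends)
  if (cds_start > cds_end)
    stop("transcript ", transcript_id, ": cds_start beyond cds_end")
  if (!in_exon(cds_start) || !in_exon(cds_end))
    stop("transcript ", transcript_id, ": CDS outside exon union")

  # 0-based half-open internally
  start0 <- exon_starts - 1L
  end0 <- exon_ends
  n_exons <- length(start0)
  exon_len <- end0 - start0
  tx_order <- if (strand == "+") seq_len(n_exons) else rev(seq_len(n_exons))
  t_end <- cumsum(exon_len[tx_order])
  t_start <- t_end - exon_len[tx_order] + 1L

  exon_seq <- substring(contig_seq, start0 + 1L, end0)
  spliced <- paste(if (strand == "+") exon_seq else revcomp(rev(exon_seq)),
                   collapse = "")

  m <- structure(list(
    gene_symbol = gene_symbol, transcript_id = transcript_id,
    contig = contig, strand = strand,
    exon_starts = exon_starts, exon_ends = exon_ends,
    cds_start_genomic = cds_start, cds_end_genomic = cds_end,
    start0 = start0, end0 = end0, n_exons = n_exons,
    tx_order = tx_order, t_start = t_start, t_end = t_end,
    spliced = spliced, contig_seq = contig_seq
  ), class = "transcript_model")

  t_cds_1 <- tx_position(m, if (strand == "+") cds_start else cds_end)
  t_cds_2 <- tx_position(m, if (strand == "+") cds_end else cds_start)
  m$t_cds_start <- t_cds_1
  m$t_cds_end <- t_cds_2
  m$utr5_len <- t_cds_1 - 1L
  m$cds_len <- t_cds_2 - t_cds_1 + 1L
  m$utr3_len <- nchar(spliced) - t_cds_2
  m$cds_seq <- substr(spliced, t_cds_1, t_cds_2)
  if (m$cds_len < 3L)
    stop("transcript ", transcript_id, ": CDS shorter than one codon")
  if (m$cds_len %% 3L != 0L)
    warning("transcript ", transcript_id, ": CDS length ", m$cds_len,
            " is not a multiple of 3")
  m
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s (%s) %s:%d-%d [%s]\n",
              x$transcript_id, x$gene_symbol, x$contig,
              min(x$exon_starts), max(x$exon_ends), x$strand))
  cat(sprintf("  %d exon(s); CDS %d nt (%d codons); 5'UTR %d nt; 3'UTR %d nt\n",
              x$n_exons, x$cds_len, x$cds_len %/% 3L, x$utr5_len, x$utr3_len))
  invisible(x)
}

# Genomic span of the transcript (introns included), 1-based inclusive.
#' @noRd
tx_span <- function(tx) c(min(tx$exon_starts), max(tx$exon_ends))

# 1-based transcript coordinate of an exonic genomic position, NA if intronic.
#' @noRd
tx_position <- function(tx, gpos) {
  i <- which(tx$start0 < gpos & gpos <= tx$end0)
  if (length(i) != 1L) return(NA_integer_)
  j <- match(i, tx$tx_order)
  if (tx$strand == "+") {
    tx$t_start[j] + (gpos - 1L - tx$start0[i])
  } else {
    tx$t_start[j] + (tx$end0[i] - gpos)
  }
}

# Genomic position of a 1-based transcript coordinate.
#' @noRd
genomic_position <- function(tx, tpos) {
  j <- which(tx$t_start <= tpos & tpos <= tx$t_end)
  if (length(j) != 1L) stop("transcript position ", tpos, " outside transcript")
  i <- tx$tx_order[j]
  if (tx$strand == "+") {
    tx$start0[i] + (tpos - tx$t_start[j]) + 1L
  } else {
    tx$end0[i] - (tpos - tx$t_start[j])
  }
}

#' Read transcript models from a TSV table plus reference FASTA
#'
#' The table is tab-separated with a header and one row per transcript:
#' `gene_symbol`, `transcript_id`, `contig`, `strand`, `exon_starts`
#' (comma-joined, 1-based), `exon_ends` (comma-joined, 1-based inclusive),
#' `cds_start`, `cds_end`. When a gene has several transcripts only the
#' canonical one is retained: longest CDS, ties broken by lexicographically
#' smallest transcript id.
#'
#' @param table_path Path to the transcript TSV.
#' @param fasta_path Path to the reference FASTA (record id = contig name).
#' @return A `transcript_set`: validated models indexed by transcript id,
#'   at most one per gene.
#' @export
load_transcripts <- function(table_path, fasta_path) {
  genome <- load_genome(fasta_path)
  tab <- utils::read.delim(table_path, sep = "\t", stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("gene_symbol", "transcript_id", "contig", "strand",
            "exon_starts", "exon_ends", "cds_start", "cds_end")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols))
    stop("transcript table lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(tab$transcript_id))
    stop("duplicate transcript_id: ",
         paste(unique(tab$transcript_id[duplicated(tab$transcript_id)]), collapse = ", "))
  models <- lapply(seq_len(nrow(tab)), function(i) {
    row <- tab[i, ]
    if (!row$contig %in% names(genome))
      stop("contig '", row$contig, "' (transcript ", row$transcript_id,
           ") not present in FASTA")
    transcript_model(
      gene_symbol = row$gene_symbol, transcript_id = row$transcript_id,
      contig = row$contig, strand = row$strand,
      exon_starts = as.integer(strsplit(row$exon_starts, ",")[[1]]),
      exon_ends = as.integer(strsplit(row$exon_ends, ",")[[1]]),
      cds_start = as.integer(row$cds_start), cds_end = as.integer(row$cds_end),
      contig_seq = genome[[row$contig]]
    )
  })
  transcript_set(models)
}

#' Bundle transcript models into a set, one canonical transcript per gene
#'
#' @param models List of [transcript_model()] objects.
#' @return A `transcript_set` keeping, per gene, the transcript with the
#'   longest CDS (ties: smallest transcript id).
#' @export
transcript_set <- function(models) {
  if (!length(models)) stop("empty transcript set")
  ids <- vapply(models, `[[`, character(1), "transcript_id")
  if (anyDuplicated(ids))
    stop("duplicate transcript_id: ", paste(ids[duplicated(ids)], collapse = ", "))
  genes <- vapply(models, `[[`, character(1), "gene_symbol")
  cds_lens <- vapply(models, `[[`, integer(1), "cds_len")
  keep <- unlist(lapply(split(seq_along(models), genes), function(idx) {
    idx <- idx[order(-cds_lens[idx], ids[idx])]
    idx[1L]
  }), use.names = FALSE)
  keep <- sort(keep)
  models <- models[keep]
  names(models) <- ids[keep]
  structure(list(
    transcripts = models,
    by_gene = stats::setNames(ids[keep], genes[keep])
  ), class = "transcript_set")
}

#' @export
print.transcript_set <- function(x, ...) {
  cat(sprintf("<transcript_set> %d transcript(s) / %d gene(s)\n",
              length(x$transcripts), length(unique(names(x$by_gene)))))
  invisible(x)
}

#' @export
length.transcript_set <- function(x) length(x$transcripts)

#' Look up the canonical transcript of a gene
#' @param txset A `transcript_set`.
#' @param gene Gene symbol.
#' @return A `transcript_model`, or `NULL` when the gene is absent.
#' @export
gene_transcript <- function(txset, gene) {
  id <- txset$by_gene[gene]
  if (is.na(id)) return(NULL)
  txset$transcripts[[id]]
}

#' Read a reference FASTA into named character strings
#'
#' @param fasta_path Multi-record FASTA; record ids are contig names (first
#'   whitespace-separated token).
#' @return Named character vector, one string per contig.
#' @export
load_genome <- function(fasta_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  out <- as.character(seqs)
  names(out) <- sub("\\s.*$", "", names(seqs))
  out
}

#' Read a gene panel file
#'
#' Plain text, one gene symbol per line; `#` starts a comment. Symbols are
#' case-normalized to upper case and deduplicated.
#'
#' @param path Panel file path.
#' @param label Optional display label for the panel.
#' @return A `gene_panel` object.
#' @export
read_gene_panel <- function(path, label = basename(path)) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  genes <- toupper(trimws(lines))
  genes <- unique(genes[nzchar(genes)])
  gene_panel(genes, label)
}

#' Construct a gene panel from symbols
#' @param gene_symbols Character vector of gene symbols (case-insensitive).
#' @param label Display label.
#' @return A `gene_panel`.
#' @export
gene_panel <- function(gene_symbols, label = "panel") {
  genes <- unique(toupper(trimws(gene_symbols)))
  genes <- genes[nzchar(genes)]
  if (!length(genes)) stop("empty gene panel")
  structure(list(genes = genes, label = label), class = "gene_panel")
}

#' @export
print.gene_panel <- function(x, ...) {
  cat(sprintf("<gene_panel> '%s': %d gene(s)\n", x$label, length(x$genes)))
  invisible(x)
}

#' Read transcript models from a minimal GTF subset
#'
#' Only feature types `exon` and `CDS` are used and only the `gene_name` and
#' `transcript_id` attributes are consulted; everything else in the file is
#' ignored. CDS bounds are taken as the min/max over CDS features per
#' transcript.
#'
#' @param gtf_path Path to the GTF file.
#' @param fasta_path Reference FASTA path.
#' @return A `transcript_set`.
#' @export
read_gtf_transcripts <- function(gtf_path, fasta_path) {
  genome <- load_genome(fasta_path)
  lines <- readLines(gtf_path, warn = FALSE)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 9L)
  if (length(bad)) stop("malformed GTF line ", bad[1L])
  feat <- vapply(fields, `[[`, character(1), 3L)
  keep <- feat %in% c("exon", "CDS")
  fields <- fields[keep]
  feat <- feat[keep]
  attr_get <- function(a, key) {
    m <- regmatches(a, regexec(paste0(key, "\\s+\"([^\"]+)\""), a))[[1]]
    if (length(m) < 2L) NA_character_ else m[2L]
  }
  rec <- data.frame(
    contig = vapply(fields, `[[`, character(1), 1L),
    feature = feat,
    start = as.integer(vapply(fields, `[[`, character(1), 4L)),
    end = as.integer(vapply(fields, `[[`, character(1), 5L)),
    strand = vapply(fields, `[[`, character(1), 7L),
    gene = vapply(fields, function(f) attr_get(f[[9L]], "gene_name"), character(1)),
    tx = vapply(fields, function(f) attr_get(f[[9L]], "transcript_id"), character(1)),
    stringsAsFactors = FALSE
  )
  if (anyNA(rec$tx) || anyNA(rec$gene))
    stop("GTF exon/CDS feature without gene_name or transcript_id attribute")
  models <- lapply(split(rec, rec$tx), function(d) {
    ex <- d[d$feature == "exon", ]
    cds <- d[d$feature == "CDS", ]
    if (!nrow(ex) || !nrow(cds))
      stop("transcript ", d$tx[1L], ": needs both exon and CDS features")
    ex <- ex[order(ex$start), ]
    if (!ex$contig[1L] %in% names(genome))
      stop("contig '", ex$contig[1L], "' (transcript ", d$tx[1L],
           ") not present in FASTA")
    transcript_model(
      gene_symbol = d$gene[1L], transcript_id = d$tx[1L],
      contig = ex$contig[1L], strand = ex$strand[1L],
      exon_starts = ex$start, exon_ends = ex$end,
      cds_start = min(cds$start), cds_end = max(cds$end),
      contig_seq = genome[[ex$contig[1L]]]
    )
  })
  transcript_set(unname(models))
}
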