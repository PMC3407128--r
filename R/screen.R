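#' Screen a cohort for null alleles in a gene panel
#'
#' The pipeline stage: intersects every non-reference call with the panel
#' genes' canonical transcripts, normalizes and classifies each variant, and
#' keeps those whose consequence is null (nonsense, frameshift, canonical
#' splice). An individual is a carrier when it holds at least one null
#' allele in any panel gene; zygosity does not affect carrier status, but a
#' homozygous null counts two alleles in the per-individual tally and is
#' flagged with a warning.
#'
#' @param cohort A `cohort` from [read_cohort()].
#' @param txset A `transcript_set`; every panel gene must have a transcript.
#' @param panel A `gene_panel`.
#' @return An `hrd_screen` object: `hits` (one row per individual x gene x
#'   variant, ordered by individual, gene, position), `per_individual`
#'   (named null-allele counts covering all cohort members), `n`, `k`, and
#'   the panel metadata. Methods: `print`, `summary` (carrier frequency and
#'   CI), [report_table()].
#' @export
screen_cohort <- function(cohort, txset, panel) {
  stopifnot(inherits(cohort, "cohort"), inherits(txset, "transcript_set"),
            inherits(panel, "gene_panel"))
  panel_tx <- txset$by_gene[names(txset$by_gene) %in% panel$genes]
  missing_genes <- setdiff(panel$genes, names(txset$by_gene))
  if (length(missing_genes))
    stop("panel gene(s) lacking a transcript model: ",
         paste(sort(missing_genes), collapse = ", "))
  models <- txset$transcripts[unname(panel_tx)]

  tx_contig <- vapply(models, `[[`, character(1), "contig")
  tx_lo <- vapply(models, function(m) tx_span(m)[1L], integer(1))
  tx_hi <- vapply(models, function(m) tx_span(m)[2L], integer(1))

  calls <- cohort$calls
  hits <- list()
  if (nrow(calls)) {
    # normalize each distinct variant once against its contig sequence
    key <- paste(calls$contig, calls$pos, calls$ref, calls$alt, sep = ":")
    contig_seqs <- stats::setNames(
      vapply(models, `[[`, character(1), "contig_seq"), tx_contig)
    norm_cache <- new.env(parent = emptyenv())
    for (i in seq_len(nrow(calls))) {
      row <- calls[i, ]
      if (!row$zygosity %in% c("het", "hom_alt")) next
      end <- row$pos + nchar(row$ref) - 1L + (nchar(row$alt) > nchar(row$ref))
      overlapping <- which(tx_contig == row$contig &
                           tx_lo <= end & row$pos <= tx_hi)
      if (!length(overlapping)) next
      nv <- norm_cache[[key[i]]]
      if (is.null(nv)) {
        nv <- normalize_variant(variant(row$contig, row$pos, row$ref, row$alt),
                                contig_seqs[[row$contig]])
        assign(key[i], nv, envir = norm_cache)
      }
      for (j in overlapping) {
        tx <- models[[j]]
        rng <- affected_range(nv)
        span <- tx_span(tx)
        if (rng[2L] < span[1L] || rng[1L] > span[2L]) next
        call <- classify_variant(nv, tx)
        if (!call$is_null) next
        if (row$zygosity == "hom_alt")
          warning("homozygous null allele in ", tx$gene_symbol, " for ",
                  row$individual_id, " (", call$c_hgvs, ")")
        hits[[length(hits) + 1L]] <- data.frame(
          individual_id = row$individual_id,
          ethnicity = unname(cohort$ethnicity[row$individual_id]),
          gene_symbol = tx$gene_symbol,
          transcript_id = tx$transcript_id,
          contig = nv$contig, pos = nv$pos, ref = nv$ref, alt = nv$alt,
          zygosity = row$zygosity, category = call$category,
          c_hgvs = call$c_hgvs, p_or_splice = call$p_or_splice,
          stringsAsFactors = FALSE)
      }
    }
  }
  hits_df <- if (length(hits)) do.call(rbind, hits)
    else data.frame(individual_id = character(0), ethnicity = character(0),
                    gene_symbol = character(0), transcript_id = character(0),
                    contig = character(0), pos = integer(0),
                    ref = character(0), alt = character(0),
                    zygosity = character(0), category = character(0),
                    c_hgvs = character(0), p_or_splice = character(0),
                    stringsAsFactors = FALSE)
  hits_df <- hits_df[order(hits_df$individual_id, hits_df$gene_symbol,
                           hits_df$contig, hits_df$pos), , drop = FALSE]
  rownames(hits_df) <- NULL

  per_ind <- stats::setNames(integer(length(cohort$individuals)),
                             cohort$individuals)
  if (nrow(hits_df)) {
    allele_counts <- ifelse(hits_df$zygosity == "hom_alt", 2L, 1L)
    agg <- tapply(allele_counts, hits_df$individual_id, sum)
    per_ind[names(agg)] <- as.integer(agg)
  }
  structure(list(
    hits = hits_df,
    per_individual = per_ind,
    n = length(cohort$individuals),
    k = length(unique(hits_df$individual_id)),
    panel_label = panel$label,
    panel_size = length(panel$genes),
    n_skipped_genotypes = cohort$n_skipped_genotypes
  ), class = "hrd_screen")
}

#' @export
print.hrd_screen <- function(x, ...) {
  cat(sprintf("<hrd_screen> panel '%s' (%d genes), %d individuals\n",
              x$panel_label, x$panel_size, x$n))
  cat(sprintf("  null-allele hits: %d (%d carrier(s), max %s per individual)\n",
              nrow(x$hits), x$k,
              if (length(x$per_individual)) max(x$per_individual) else 0L))
  if (nrow(x$hits)) {
    utils::head(x$hits[, c("individual_id", "gene_symbol", "c_hgvs",
                           "p_or_splice")], 10L) |> print()
    if (nrow(x$hits) > 10L) cat("  ...\n")
  }
  invisible(x)
}

#' @param object An `hrd_screen`.
#' @param confidence Confidence level for the carrier CI.
#' @param method CI method (see [binom_ci()]).
#' @param ... Unused.
#' @rdname screen_cohort
#' @export
summary.hrd_screen <- function(object, confidence = 0.95, method = "wald", ...) {
  carrier_summary(object$k, object$n, confidence, method)
}

#' Tabular report of screen hits
#'
#' One data row per null-allele hit, in the fixed order (individual, gene,
#' position): columns `individual_id`, `ethnicity`, `gene`, `c_hgvs`,
#' `p_or_splice`.
#'
#' @param x An `hrd_screen`.
#' @return A data frame (zero rows when there were no hits).
#' @export
report_table <- function(x) {
  stopifnot(inherits(x, "hrd_screen"))
  out <- x$hits[, c("individual_id", "ethnicity", "gene_symbol",
                    "c_hgvs", "p_or_splice")]
  names(out)[3L] <- "gene"
  out
}

#' Write the screen report TSV and summary JSON
#'
#' @param x An `hrd_screen`.
#' @param out_dir Output directory (created if needed). Writes
#'   `report.tsv` (the [report_table()]) and `summary.json`
#'   (n, k, frequency, ci_low, ci_high, per_individual_counts, panel_size).
#' @param confidence,method Passed to [carrier_summary()].
#' @return Invisibly, the paths written.
#' @export
write_screen_outputs <- function(x, out_dir, confidence = 0.95,
                                 method = "wald") {
  stopifnot(inherits(x, "hrd_screen"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  report_path <- file.path(out_dir, "report.tsv")
  utils::write.table(report_table(x), report_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cs <- carrier_summary(x$k, x$n, confidence, method)
  summary_path <- file.path(out_dir, "summary.json")
  jsonlite::write_json(list(
    n = x$n, k = x$k, frequency = cs$frequency,
    ci_low = cs$ci_low, ci_high = cs$ci_high,
    confidence = cs$confidence, ci_method = cs$method,
    per_individual_counts = as.list(x$per_individual),
    panel_size = x$panel_size
  ), summary_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(report = report_path, summary = summary_path))
}
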