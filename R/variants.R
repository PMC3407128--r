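#' Construct a genomic sequence variant
#'
#' A variant is a substitution of `ref` by `alt` starting at 1-based genomic
#' position `pos` on `contig`, in VCF style (indels carry a single anchor
#' base). The derived `vtype` is one of `snv`, `ins`, `del`, `delins`.
#'
#' @param contig Contig name.
#' @param pos 1-based genomic position of the first `ref` base.
#' @param ref,alt Non-empty base strings (A/C/G/T).
#' @return A `variant` object.
#' @export
variant <- function(contig, pos, ref, alt) {
  pos <- as.integer(pos)
  if (is.na(pos) || pos < 1L) stop("pos must be a positive integer")
  ref <- toupper(ref); alt <- toupper(alt)
  if (!is_dna_string(ref) || !is_dna_string(alt))
    stop("ref/alt must be non-empty A/C/G/T strings (got '", ref, "'/'", alt, "')")
  structure(list(contig = contig, pos = pos, ref = ref, alt = alt,
                 vtype = variant_type(ref, alt)),
            class = "variant")
}

#' @noRd
variant_type <- function(ref, alt) {
  nr <- nchar(ref); na <- nchar(alt)
  if (nr == 1L && na == 1L) "snv"
  else if (nr == 1L && na > 1L && substr(alt, 1L, 1L) == ref) "ins"
  else if (na == 1L && nr > 1L && substr(ref, 1L, 1L) == alt) "del"
  else "delins"
}

#' @export
print.variant <- function(x, ...) {
  cat(sprintf("<variant> %s:%d %s>%s (%s)\n", x$contig, x$pos, x$ref, x$alt,
              x$vtype), sep = "")
  invisible(x)
}

#' Normalize a variant against the reference
#'
#' Trims shared prefix/suffix down to the conventional single anchor base for
#' indels and left-aligns indels against the reference (shifting left while
#' the flanking sequence permits an equivalent spelling), i.e. the VCF
#' normalization convention. SNVs pass through unchanged.
#'
#' @param v A [variant()].
#' @param contig_seq Reference sequence of `v$contig` as a character string.
#' @return The normalized `variant`.
#' @export
normalize_variant <- function(v, contig_seq) {
  stopifnot(inherits(v, "variant"))
  ref_here <- substr(contig_seq, v$pos, v$pos + nchar(v$ref) - 1L)
  if (!identical(ref_here, v$ref))
    stop("reference mismatch at ", v$contig, ":", v$pos,
         " (expected '", ref_here, "', variant says '", v$ref, "')")
  pos <- v$pos; ref <- v$ref; alt <- v$alt
  if (v$vtype == "snv") return(v)
  repeat {
    changed <- FALSE
    nr <- nchar(ref); na <- nchar(alt)
    if (nr > 0L && na > 0L &&
        substr(ref, nr, nr) == substr(alt, na, na) &&
        !(nr == 1L && na == 1L)) {
      ref <- substr(ref, 1L, nr - 1L)
      alt <- substr(alt, 1L, na - 1L)
      changed <- TRUE
    }
    if (nchar(ref) == 0L || nchar(alt) == 0L) {
      if (pos == 1L) stop("cannot left-align at contig start (",
                          v$contig, ":", v$pos, ")")
      b <- substr(contig_seq, pos - 1L, pos - 1L)
      ref <- paste0(b, ref); alt <- paste0(b, alt)
      pos <- pos - 1L
      changed <- TRUE
    }
    if (!changed) break
  }
  # trim shared prefix, keeping one anchor base for indels
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substr(ref, 2L); alt <- substr(alt, 2L)
    pos <- pos + 1L
  }
  variant(v$contig, pos, ref, alt)
}

# 1-based inclusive genomic range of reference bases affected by a variant.
# Insertions affect no reference base; their two flanking bases are returned
# (used for splice-region adjacency).
#' @noRd
affected_range <- function(v) {
  switch(v$vtype,
    snv = c(v$pos, v$pos),
    ins = c(v$pos, v$pos + 1L),
    del = c(v$pos + 1L, v$pos + nchar(v$ref) - 1L),
    delins = c(v$pos, v$pos + nchar(v$ref) - 1L))
}

#' Read a cohort of per-individual variant calls from VCF
#'
#' Reads one or more VCF v4.2 files (plain or gzipped; `GT` is the only
#' FORMAT key consumed), splits multi-allelic records into biallelic
#' variants, and derives one call set per sample column. Records with a
#' missing genotype for a sample are skipped for that sample and counted.
#'
#' @param paths Character vector of VCF paths. Sample names must be unique
#'   across files.
#' @param samples Optional data frame with columns `individual_id` and
#'   `ethnicity` attaching cosmetic metadata to samples.
#' @param pass_only If `TRUE`, keep only records with FILTER equal to
#'   `PASS` or `.` (by default the FILTER column is ignored).
#' @return A `cohort` object: `individuals` (sample ids in column order),
#'   `calls` (long data frame: individual_id, contig, pos, ref, alt,
#'   zygosity with levels het/hom_alt), `ethnicity` (named vector) and
#'   `n_skipped_genotypes`.
#' @export
read_cohort <- function(paths, samples = NULL, pass_only = FALSE) {
  all_ind <- character(0)
  eth <- character(0)
  calls <- list()
  skipped <- 0L
  for (path in paths) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- v@fix
    gt <- v@gt
    ids <- colnames(gt)[-1L]
    if (any(ids %in% all_ind))
      stop("duplicate sample name(s) across VCF files: ",
           paste(intersect(ids, all_ind), collapse = ", "))
    all_ind <- c(all_ind, ids)
    if (nrow(fix) == 0L) next
    pos <- suppressWarnings(as.integer(fix[, "POS"]))
    bad <- which(is.na(pos) | is.na(fix[, "REF"]) | is.na(fix[, "ALT"]) |
                 !nzchar(fix[, "REF"]) | !nzchar(fix[, "ALT"]))
    if (length(bad))
      stop("malformed VCF record at data line ", bad[1L], " of ", path)
    keep <- rep(TRUE, nrow(fix))
    if (pass_only)
      keep <- fix[, "FILTER"] %in% c("PASS", ".") | is.na(fix[, "FILTER"])
    fmt <- v@gt[, "FORMAT"]
    gt_index <- vapply(strsplit(fmt, ":", fixed = TRUE),
                       function(k) match("GT", k), integer(1))
    if (anyNA(gt_index))
      stop("VCF record without GT in FORMAT in ", path)
    for (r in which(keep)) {
      alts <- strsplit(fix[r, "ALT"], ",", fixed = TRUE)[[1]]
      for (s in seq_along(ids)) {
        raw <- gt[r, s + 1L]
        gt_str <- if (is.na(raw)) NA_character_
                  else strsplit(raw, ":", fixed = TRUE)[[1]][gt_index[r]]
        if (is.na(gt_str) || grepl("\\.", gt_str)) {
          skipped <- skipped + 1L
          next
        }
        alleles <- suppressWarnings(
          as.integer(strsplit(gt_str, "[/|]")[[1]]))
        if (anyNA(alleles)) {
          skipped <- skipped + 1L
          next
        }
        for (a in seq_along(alts)) {
          cnt <- sum(alleles == a)
          if (cnt == 0L) next
          calls[[length(calls) + 1L]] <- data.frame(
            individual_id = ids[s], contig = fix[r, "CHROM"], pos = pos[r],
            ref = fix[r, "REF"], alt = alts[a],
            zygosity = if (cnt >= 2L) "hom_alt" else "het",
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  calls_df <- if (length(calls)) do.call(rbind, calls)
    else data.frame(individual_id = character(0), contig = character(0),
                    pos = integer(0), ref = character(0), alt = character(0),
                    zygosity = character(0), stringsAsFactors = FALSE)
  eth <- stats::setNames(rep(NA_character_, length(all_ind)), all_ind)
  if (!is.null(samples)) {
    stopifnot(all(c("individual_id", "ethnicity") %in% names(samples)))
    m <- match(all_ind, samples$individual_id)
    eth[!is.na(m)] <- samples$ethnicity[m[!is.na(m)]]
  }
  structure(list(individuals = all_ind, calls = calls_df, ethnicity = eth,
                 n_skipped_genotypes = skipped),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d individual(s), %d variant call(s)%s\n",
              length(x$individuals), nrow(x$calls),
              if (x$n_skipped_genotypes > 0L)
                sprintf(" (%d missing genotypes skipped)", x$n_skipped_genotypes)
              else ""))
  invisible(x)
}
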