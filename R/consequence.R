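#' Classify a variant against a transcript model
#'
#' Assigns one consequence category by the first matching rule:
#' \enumerate{
#'   \item \strong{canonical_splice} — any affected reference base lies at
#'     intronic offset +1, +2, -1 or -2 of any intron (including introns
#'     flanked only by UTR exons). Indels touching such a base are splice,
#'     taking precedence over coding rules.
#'   \item Within the CDS: an indel whose length change is not a multiple of
#'     3 is a \strong{frameshift}; a multiple of 3 is an
#'     \strong{inframe_indel}; an SNV whose mutated codon translates to stop
#'     is \strong{stop_gained}; an SNV destroying the ATG of codon 1 is
#'     \strong{start_lost}; otherwise \strong{missense} or
#'     \strong{synonymous}. A length-preserving multi-nucleotide substitution
#'     is inframe unless it writes a stop codon into the replaced range.
#'   \item Exonic UTR positions are \strong{utr}; intronic positions beyond
#'     +/-2 are \strong{intronic_other}; anything else overlapping the
#'     transcript is \strong{noncoding_other}.
#' }
#' Null alleles — the screen's "clear-cut deleterious" set — are exactly
#' \{stop_gained, frameshift, canonical_splice\}. Stop gains are null
#' regardless of position (no last-exon escape rule) and start_lost is
#' deliberately \emph{not} null.
#'
#' @param v A normalized [variant()] on the same contig as `tx`.
#' @param tx A [transcript_model()].
#' @return A `consequence_call`: variant, transcript_id, gene_symbol,
#'   category, `c_hgvs`, `p_or_splice` and `is_null`.
#' @export
classify_variant <- function(v, tx) {
  stopifnot(inherits(v, "variant"), inherits(tx, "transcript_model"))
  if (v$contig != tx$contig)
    stop("variant on ", v$contig, " does not overlap transcript ",
         tx$transcript_id, " on ", tx$contig)
  span <- tx_span(tx)
  rng <- affected_range(v)
  if (rng[2L] < span[1L] || rng[1L] > span[2L])
    stop("variant ", v$contig, ":", v$pos, " does not overlap transcript ",
         tx$transcript_id)

  gpos_all <- seq.int(rng[1L], rng[2L])
  gpos_in <- gpos_all[gpos_all >= span[1L] & gpos_all <= span[2L]]
  coords <- lapply(gpos_in, function(g) genomic_to_cds(tx, g))
  kinds <- vapply(coords, `[[`, character(1), "kind")
  offsets <- vapply(coords, `[[`, integer(1), "offset")

  splice_idx <- which(kinds == "intronic" & abs(offsets) <= 2L)
  category <- NULL
  splice_coord <- NULL
  if (length(splice_idx)) {
    category <- "canonical_splice"
    splice_coord <- coords[[splice_idx[which.min(abs(offsets[splice_idx]))]]]
  } else if (v$vtype == "ins") {
    # both flanking bases exonic and coding => coding insertion
    if (length(kinds) == 2L && all(kinds == "coding")) {
      category <- classify_coding(v, tx, coords)
    } else if (all(kinds %in% c("five_prime_utr", "three_prime_utr", "coding"))) {
      category <- "utr"
    } else {
      category <- "intronic_other"
    }
  } else if (all(kinds == "coding") && identical(gpos_in, gpos_all)) {
    category <- classify_coding(v, tx, coords)
  } else if (all(kinds %in% c("five_prime_utr", "three_prime_utr"))) {
    category <- "utr"
  } else if (all(kinds == "intronic")) {
    category <- "intronic_other"
  } else {
    category <- "noncoding_other"
  }

  call <- structure(list(
    variant = v, transcript_id = tx$transcript_id,
    gene_symbol = tx$gene_symbol, category = category,
    c_hgvs = hgvs_c(v, tx),
    p_or_splice = "", is_null = category %in% NULL_CATEGORIES
  ), class = "consequence_call")
  call$p_or_splice <- render_p_or_splice(v, tx, category, splice_coord)
  call
}

# The only categories ever reported as null alleles.
#' @noRd
NULL_CATEGORIES <- c("stop_gained", "frameshift", "canonical_splice")

#' @export
print.consequence_call <- function(x, ...) {
  cat(sprintf("<consequence_call> %s / %s: %s %s%s%s\n",
              x$gene_symbol, x$transcript_id, x$category, x$c_hgvs,
              if (nzchar(x$p_or_splice)) paste0(" | ", x$p_or_splice) else "",
              if (x$is_null) " [null]" else ""))
  invisible(x)
}

# Coding-region rule block. coords are the cds_coords of the affected bases
# (for insertions: the two coding flanks).
#' @noRd
classify_coding <- function(v, tx, coords) {
  nr <- nchar(v$ref); na <- nchar(v$alt)
  if (v$vtype == "snv") {
    cpos <- coords[[1L]]$base
    cod <- codon_at(tx, cpos)
    altT <- if (tx$strand == "+") v$alt else comp_base(v$alt)
    mut <- cod$codon_bases
    substr(mut, cod$frame_offset + 1L, cod$frame_offset + 1L) <- altT
    ref_aa <- translate_codon(cod$codon_bases)
    mut_aa <- translate_codon(mut)
    if (cod$codon_index == 1L && cod$codon_bases == "ATG" && mut != "ATG")
      return("start_lost")
    if (mut_aa == "*" && ref_aa != "*") return("stop_gained")
    if (mut_aa == ref_aa) return("synonymous")
    return("missense")
  }
  if (v$vtype == "ins") {
    ilen <- na - 1L
    return(if (ilen %% 3L != 0L) "frameshift" else "inframe_indel")
  }
  if (v$vtype == "del") {
    dlen <- nr - 1L
    return(if (dlen %% 3L != 0L) "frameshift" else "inframe_indel")
  }
  # delins
  if (nr != na)
    return(if (abs(nr - na) %% 3L != 0L) "frameshift" else "inframe_indel")
  # length-preserving: inframe unless a stop appears in the replaced codons
  mut_cds <- mutant_coding_sequence(v, tx)
  ref_codons <- codon_split(tx$cds_seq)
  mut_codons <- codon_split(substr(mut_cds, 1L, tx$cds_len))
  changed <- which(mut_codons != ref_codons[seq_along(mut_codons)])
  if (length(changed) && any(translate_codon(mut_codons[changed]) == "*"))
    "stop_gained" else "inframe_indel"
}

# Spliced mutant sequence from the first CDS base to the transcript end
# (frameshifted reading continues into the 3'UTR).
#' @noRd
mutant_coding_sequence <- function(v, tx) {
  sp <- tx$spliced
  plus <- tx$strand == "+"
  if (v$vtype == "snv") {
    t <- tx_position(tx, v$pos)
    substr(sp, t, t) <- if (plus) v$alt else comp_base(v$alt)
  } else if (v$vtype == "ins") {
    seq_in <- substr(v$alt, 2L, nchar(v$alt))
    t_left <- if (plus) tx_position(tx, v$pos) else tx_position(tx, v$pos + 1L)
    seqT <- if (plus) seq_in else revcomp(seq_in)
    sp <- paste0(substr(sp, 1L, t_left), seqT,
                 substr(sp, t_left + 1L, nchar(sp)))
  } else if (v$vtype == "del") {
    g1 <- v$pos + 1L; g2 <- v$pos + nchar(v$ref) - 1L
    tt <- sort(c(tx_position(tx, g1), tx_position(tx, g2)))
    sp <- paste0(substr(sp, 1L, tt[1L] - 1L),
                 substr(sp, tt[2L] + 1L, nchar(sp)))
  } else { # delins
    g1 <- v$pos; g2 <- v$pos + nchar(v$ref) - 1L
    tt <- sort(c(tx_position(tx, g1), tx_position(tx, g2)))
    altT <- if (plus) v$alt else revcomp(v$alt)
    sp <- paste0(substr(sp, 1L, tt[1L] - 1L), altT,
                 substr(sp, tt[2L] + 1L, nchar(sp)))
  }
  substr(sp, tx$t_cds_start, nchar(sp))
}

#' HGVS-style c. name of a variant on a transcript
#'
#' Renders substitutions as `c.<N><ref>><alt>`, single-base deletions as
#' `c.<N>del<base>`, multi-base deletions as `c.<N>_<M>del<bases>` and
#' insertions as `c.<N>_<M>ins<bases>`, with intronic positions as
#' `<base>+<k>` / `<base>-<k>` and 5'UTR bases negative. Bases are reported
#' in transcript orientation. Spellings follow the left-aligned (VCF)
#' representation; no HGVS 3'-shifting is applied.
#'
#' @param v A [variant()] overlapping `tx`.
#' @param tx A [transcript_model()].
#' @return Character scalar, e.g. `"c.4393C>T"`, `"c.-55+1G>T"`.
#' @export
hgvs_c <- function(v, tx) {
  plus <- tx$strand == "+"
  fmt <- function(g) format(genomic_to_cds(tx, g))
  if (v$vtype == "snv") {
    refT <- if (plus) v$ref else comp_base(v$ref)
    altT <- if (plus) v$alt else comp_base(v$alt)
    return(paste0("c.", fmt(v$pos), refT, ">", altT))
  }
  if (v$vtype == "ins") {
    seq_in <- substr(v$alt, 2L, nchar(v$alt))
    seqT <- if (plus) seq_in else revcomp(seq_in)
    gl <- if (plus) v$pos else v$pos + 1L
    gr <- if (plus) v$pos + 1L else v$pos
    return(paste0("c.", fmt(gl), "_", fmt(gr), "ins", seqT))
  }
  if (v$vtype == "del") {
    g1 <- v$pos + 1L; g2 <- v$pos + nchar(v$ref) - 1L
    del_seq <- substr(v$ref, 2L, nchar(v$ref))
    seqT <- if (plus) del_seq else revcomp(del_seq)
    ga <- if (plus) g1 else g2
    gb <- if (plus) g2 else g1
    if (g1 == g2) return(paste0("c.", fmt(ga), "del", seqT))
    return(paste0("c.", fmt(ga), "_", fmt(gb), "del", seqT))
  }
  # delins
  g1 <- v$pos; g2 <- v$pos + nchar(v$ref) - 1L
  altT <- if (plus) v$alt else revcomp(v$alt)
  ga <- if (plus) g1 else g2
  gb <- if (plus) g2 else g1
  if (g1 == g2) return(paste0("c.", fmt(ga), "delins", altT))
  paste0("c.", fmt(ga), "_", fmt(gb), "delins", altT)
}

#' Protein or splicing annotation of a classified call
#'
#' Stop gains render as `p.<Aa><codon>X` (one-letter code, X for stop),
#' frameshifts as `p.<Aa><codon>fs` naming the first codon whose nucleotide
#' triplet differs from the reference under the shifted frame (labelled with
#' the reference amino acid), and canonical splice changes in legacy intron
#' notation `IVS<intron><+/-k><ref>><alt>`. Benign categories return short
#' descriptive text (or an empty string) never used for null reporting.
#'
#' @param call A `consequence_call` from [classify_variant()].
#' @param tx The [transcript_model()] it was classified against.
#' @return Character scalar.
#' @export
hgvs_p_or_splice <- function(call, tx) {
  stopifnot(inherits(call, "consequence_call"))
  call$p_or_splice
}

#' @noRd
render_p_or_splice <- function(v, tx, category, splice_coord) {
  plus <- tx$strand == "+"
  if (category == "canonical_splice") {
    off <- sprintf("%+d", splice_coord$offset)
    if (v$vtype == "snv") {
      refT <- if (plus) v$ref else comp_base(v$ref)
      altT <- if (plus) v$alt else comp_base(v$alt)
      return(paste0("IVS", splice_coord$intron_index, off, refT, ">", altT))
    }
    if (v$vtype == "ins") {
      seq_in <- substr(v$alt, 2L, nchar(v$alt))
      return(paste0("IVS", splice_coord$intron_index, off, "ins",
                    if (plus) seq_in else revcomp(seq_in)))
    }
    del_seq <- substr(v$ref, 2L, nchar(v$ref))
    return(paste0("IVS", splice_coord$intron_index, off, "del",
                  if (plus) del_seq else revcomp(del_seq)))
  }
  if (category == "stop_gained") {
    idx <- affected_codon_index(v, tx)
    if (v$vtype == "snv") {
      cod <- codon_at(tx, genomic_to_cds(tx, v$pos)$base)
      return(paste0("p.", translate_codon(cod$codon_bases), cod$codon_index, "X"))
    }
    # delins writing a stop: name the first stop-carrying codon
    mut_cds <- mutant_coding_sequence(v, tx)
    mut_codons <- codon_split(substr(mut_cds, 1L, tx$cds_len))
    stops <- which(translate_codon(mut_codons) == "*")
    ref_codons <- codon_split(tx$cds_seq)
    i <- stops[1L]
    return(paste0("p.", translate_codon(ref_codons[i]), i, "X"))
  }
  if (category == "frameshift") {
    ref_codons <- codon_split(tx$cds_seq)
    mut_cds <- mutant_coding_sequence(v, tx)
    mut_codons <- codon_split(mut_cds)
    n <- min(length(ref_codons), length(mut_codons))
    diff_idx <- which(ref_codons[seq_len(n)] != mut_codons[seq_len(n)])
    i <- if (length(diff_idx)) diff_idx[1L] else affected_codon_index(v, tx)
    return(paste0("p.", translate_codon(ref_codons[i]), i, "fs"))
  }
  if (category == "missense") {
    cod <- codon_at(tx, genomic_to_cds(tx, v$pos)$base)
    altT <- if (plus) v$alt else comp_base(v$alt)
    mut <- cod$codon_bases
    substr(mut, cod$frame_offset + 1L, cod$frame_offset + 1L) <- altT
    return(paste0("p.", translate_codon(cod$codon_bases), cod$codon_index,
                  translate_codon(mut)))
  }
  if (category == "synonymous") {
    cod <- codon_at(tx, genomic_to_cds(tx, v$pos)$base)
    return(paste0("p.", translate_codon(cod$codon_bases), cod$codon_index, "="))
  }
  if (category == "start_lost") return("p.M1?")
  ""
}

# Codon index of the first coding base touched by (or flanking) a variant.
#' @noRd
affected_codon_index <- function(v, tx) {
  rng <- affected_range(v)
  for (g in seq.int(rng[1L], rng[2L])) {
    cc <- tryCatch(genomic_to_cds(tx, g), error = function(e) NULL)
    if (!is.null(cc) && cc$kind == "coding")
      return((cc$base + 2L) %/% 3L)
  }
  NA_integer_
}
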