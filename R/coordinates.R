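#' CDS-relative coordinate of a genomic position
#'
#' Maps a 1-based genomic position onto a transcript's c. coordinate system:
#' coding positions count from the A of the start codon (c.1), 5'UTR exonic
#' positions are negative, 3'UTR positions are `*N`, and intronic positions
#' are expressed relative to the nearest exon boundary with HGVS sign (`+k`
#' downstream of a donor, `-k` upstream of an acceptor; ties go to the
#' donor side).
#'
#' @param tx A [transcript_model()].
#' @param gpos 1-based genomic position; must lie within the transcript span
#'   (exons or introns).
#' @return A `cds_coord` with fields `kind` (coding / five_prime_utr /
#'   three_prime_utr / intronic), `base` (c. position of the position itself,
#'   or of the nearest exonic base when intronic; negative in the 5'UTR),
#'   `offset` (signed intronic offset, 0 when exonic), `intron_index`
#'   (1-based in transcription order, 0 when exonic) and `anchor_kind` (the
#'   region the anchor base lies in, for intronic coordinates).
#' @export
genomic_to_cds <- function(tx, gpos) {
  gpos <- as.integer(gpos)
  span <- tx_span(tx)
  if (gpos < span[1L] || gpos > span[2L])
    stop("position ", tx$contig, ":", gpos, " outside transcript ",
         tx$transcript_id)
  t <- tx_position(tx, gpos)
  if (!is.na(t)) {
    cc <- t_to_c(tx, t)
    return(new_cds_coord(cc$kind, cc$base, 0L, 0L, cc$kind))
  }
  # intronic: locate the genomic gap between genomic-order exons j and j+1
  j <- findInterval(gpos, tx$exon_starts) # gpos > end of exon j, < start of j+1
  stopifnot(j >= 1L, j < tx$n_exons)
  if (tx$strand == "+") {
    intron_index <- j
    d_don <- gpos - tx$exon_ends[j]
    d_acc <- tx$exon_starts[j + 1L] - gpos
    donor_g <- tx$exon_ends[j]
    acc_g <- tx$exon_starts[j + 1L]
  } else {
    intron_index <- tx$n_exons - j
    d_don <- tx$exon_starts[j + 1L] - gpos
    d_acc <- gpos - tx$exon_ends[j]
    donor_g <- tx$exon_starts[j + 1L]
    acc_g <- tx$exon_ends[j]
  }
  if (d_don <= d_acc) {
    anchor <- t_to_c(tx, tx_position(tx, donor_g))
    new_cds_coord("intronic", anchor$base, d_don, intron_index, anchor$kind)
  } else {
    anchor <- t_to_c(tx, tx_position(tx, acc_g))
    new_cds_coord("intronic", anchor$base, -d_acc, intron_index, anchor$kind)
  }
}

#' Genomic position of a CDS-relative coordinate
#'
#' Strand-aware inverse of [genomic_to_cds()] on its image.
#'
#' @param tx A [transcript_model()].
#' @param coord A `cds_coord` (or the result of [cds_coord()]).
#' @return 1-based genomic position.
#' @export
cds_to_genomic <- function(tx, coord) {
  stopifnot(inherits(coord, "cds_coord"))
  kind <- if (coord$kind == "intronic") coord$anchor_kind else coord$kind
  t <- c_to_t(tx, kind, coord$base)
  g <- genomic_position(tx, t)
  if (coord$offset == 0L) return(g)
  sign_dir <- if (tx$strand == "+") 1L else -1L
  out <- g + coord$offset * sign_dir
  check <- genomic_to_cds(tx, out)
  if (check$kind != "intronic" || check$offset != coord$offset ||
      check$base != coord$base)
    stop("intronic offset ", coord$offset, " from c.", coord$base,
         " does not fall in an intron of ", tx$transcript_id)
  out
}

#' Construct a CDS-relative coordinate
#'
#' @param base c. base number: positive coding position, negative 5'UTR
#'   position, or (with `kind = "three_prime_utr"`) the positive `*N` number.
#' @param offset Signed intronic offset (0 for exonic positions).
#' @param kind Region of the (anchor) base. Defaults to coding for positive
#'   `base`, 5'UTR for negative.
#' @return A `cds_coord`.
#' @export
cds_coord <- function(base, offset = 0L,
                      kind = if (base < 0) "five_prime_utr" else "coding") {
  kind <- match.arg(kind, c("coding", "five_prime_utr", "three_prime_utr"))
  if (kind == "coding" && base < 1L) stop("coding base must be >= 1")
  if (kind == "five_prime_utr" && base > -1L) stop("5'UTR base must be <= -1")
  if (offset == 0L) new_cds_coord(kind, as.integer(base), 0L, 0L, kind)
  else new_cds_coord("intronic", as.integer(base), as.integer(offset), NA_integer_, kind)
}

#' @noRd
new_cds_coord <- function(kind, base, offset, intron_index, anchor_kind) {
  structure(list(kind = kind, base = as.integer(base),
                 offset = as.integer(offset),
                 intron_index = as.integer(intron_index),
                 anchor_kind = anchor_kind),
            class = "cds_coord")
}

#' Render a `cds_coord` in HGVS c. style (without the "c." prefix)
#' @param x A `cds_coord`.
#' @param ... Unused.
#' @return Character, e.g. `"4393"`, `"-55+1"`, `"1017+1"`, `"*12"`.
#' @export
format.cds_coord <- function(x, ...) {
  kind <- if (x$kind == "intronic") x$anchor_kind else x$kind
  base_str <- switch(kind,
    coding = as.character(x$base),
    five_prime_utr = as.character(x$base),
    three_prime_utr = paste0("*", x$base))
  if (x$offset == 0L) base_str
  else paste0(base_str, sprintf("%+d", x$offset))
}

#' @export
print.cds_coord <- function(x, ...) {
  cat("<cds_coord> c.", format(x), " (", x$kind,
      if (x$kind == "intronic") paste0(", intron ", x$intron_index), ")\n",
      sep = "")
  invisible(x)
}

# transcript position -> region kind + c. base
#' @noRd
t_to_c <- function(tx, t) {
  if (t < tx$t_cds_start) {
    list(kind = "five_prime_utr", base = t - tx$t_cds_start)
  } else if (t <= tx$t_cds_end) {
    list(kind = "coding", base = t - tx$utr5_len)
  } else {
    list(kind = "three_prime_utr", base = t - tx$t_cds_end)
  }
}

# region kind + c. base -> transcript position
#' @noRd
c_to_t <- function(tx, kind, base) {
  t <- switch(kind,
    coding = {
      if (base < 1L || base > tx$cds_len)
        stop("coding position ", base, " outside CDS of ", tx$transcript_id)
      base + tx$utr5_len
    },
    five_prime_utr = {
      if (base > -1L || base < -tx$utr5_len)
        stop("5'UTR position ", base, " outside 5'UTR of ", tx$transcript_id)
      base + tx$t_cds_start
    },
    three_prime_utr = {
      if (base < 1L || base > tx$utr3_len)
        stop("3'UTR position *", base, " outside 3'UTR of ", tx$transcript_id)
      base + tx$t_cds_end
    },
    stop("invalid coordinate kind: ", kind))
  t
}

#' Codon spanning a coding position
#'
#' @param tx A [transcript_model()].
#' @param coding_pos Coding position, `1 <= coding_pos <= CDS length`.
#' @return List with `codon_index` (`ceiling(coding_pos/3)`), `codon_bases`
#'   (triplet read from the spliced coding sequence, transcript orientation)
#'   and `frame_offset` (`(coding_pos-1) %% 3`).
#' @export
codon_at <- function(tx, coding_pos) {
  coding_pos <- as.integer(coding_pos)
  if (coding_pos < 1L || coding_pos > tx$cds_len)
    stop("coding position ", coding_pos, " outside CDS of ", tx$transcript_id)
  idx <- (coding_pos + 2L) %/% 3L
  list(
    codon_index = idx,
    codon_bases = substr(tx$cds_seq, 3L * idx - 2L, 3L * idx),
    frame_offset = (coding_pos - 1L) %% 3L
  )
}
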