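# Independent oracles used by the property tests. These deliberately avoid
# the package's coordinate/classification code paths: they walk sequences
# base by base and compare whole proteins.

# --- cached fixture bundle (built once per test session) ---------------------

.fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function() {
  if (is.null(.fixture_cache$bundle)) {
    dir <- file.path(tempdir(), "hrdscreen-fixture")
    b <- build_fixture_cohort(dir)
    .fixture_cache$bundle <- b
  }
  .fixture_cache$bundle
}

cached_fixture_screen <- function() {
  if (is.null(.fixture_cache$screen)) {
    b <- cached_fixture()
    txset <- load_transcripts(b$paths$transcripts, b$paths$fasta)
    panel <- read_gene_panel(b$paths$panel)
    samples <- utils::read.delim(b$paths$samples, stringsAsFactors = FALSE)
    cohort <- read_cohort(b$paths$vcf, samples = samples)
    .fixture_cache$screen <- screen_cohort(cohort, txset, panel)
  }
  .fixture_cache$screen
}

# --- base-walk coordinate oracle ---------------------------------------------

# Exonic genomic positions in transcription order, plus spliced sequence and
# CDS bounds, derived by explicit enumeration.
oracle_maps <- function(m) {
  pos_plus <- unlist(Map(seq, m$exon_starts, m$exon_ends))
  pos_tx <- if (m$strand == "+") pos_plus else rev(pos_plus)
  bases <- substring(m$contig_seq, pos_tx, pos_tx)
  if (m$strand == "-") bases <- chartr("ACGT", "TGCA", bases)
  t1 <- match(if (m$strand == "+") m$cds_start_genomic else m$cds_end_genomic,
              pos_tx)
  t2 <- match(if (m$strand == "+") m$cds_end_genomic else m$cds_start_genomic,
              pos_tx)
  list(pos_tx = pos_tx, spliced = paste(bases, collapse = ""),
       t1 = t1, t2 = t2,
       exon_lens_tx = (if (m$strand == "+") m$exon_ends - m$exon_starts + 1L
                       else rev(m$exon_ends - m$exon_starts + 1L)))
}

oracle_t_to_c <- function(maps, t) {
  if (t < maps$t1) list(kind = "five_prime_utr", base = t - maps$t1)
  else if (t <= maps$t2) list(kind = "coding", base = t - maps$t1 + 1L)
  else list(kind = "three_prime_utr", base = t - maps$t2)
}

# Full c. coordinate of any genomic position in the transcript span.
oracle_c <- function(m, g) {
  maps <- oracle_maps(m)
  t <- match(g, maps$pos_tx)
  if (!is.na(t)) {
    cc <- oracle_t_to_c(maps, t)
    return(list(kind = cc$kind, base = cc$base, offset = 0L,
                intron_index = 0L))
  }
  # intronic: boundaries in transcript order
  bnd <- cumsum(maps$exon_lens_tx)
  for (i in seq_len(length(bnd) - 1L)) {
    donor_g <- maps$pos_tx[bnd[i]]
    acc_g <- maps$pos_tx[bnd[i] + 1L]
    lo <- min(donor_g, acc_g); hi <- max(donor_g, acc_g)
    if (g > lo && g < hi) {
      d_don <- abs(g - donor_g); d_acc <- abs(acc_g - g)
      if (d_don <= d_acc) {
        cc <- oracle_t_to_c(maps, bnd[i])
        return(list(kind = "intronic", base = cc$base, offset = d_don,
                    intron_index = i, anchor_kind = cc$kind))
      } else {
        cc <- oracle_t_to_c(maps, bnd[i] + 1L)
        return(list(kind = "intronic", base = cc$base, offset = -d_acc,
                    intron_index = i, anchor_kind = cc$kind))
      }
    }
  }
  stop("oracle: position ", g, " not in transcript")
}

# --- mutate-splice-translate consequence oracle ------------------------------

oracle_translate <- function(seq) {
  n <- nchar(seq) %/% 3L
  if (n == 0L) return("")
  cods <- substring(seq, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  aas <- unname(Biostrings::GENETIC_CODE[cods])
  aas[is.na(aas)] <- "X"
  stop_at <- which(aas == "*")
  if (length(stop_at)) aas <- aas[seq_len(stop_at[1L] - 1L)]
  paste(aas, collapse = "")
}

# Category of a normalized variant, derived by rebuilding the mutant
# transcript and comparing translated proteins (no rule reuse).
oracle_classify <- function(m, v) {
  maps <- oracle_maps(m)
  plus <- m$strand == "+"
  nr <- nchar(v$ref); na <- nchar(v$alt)
  affected <- if (nr == 1L && na > 1L) c(v$pos, v$pos + 1L)
    else if (na == 1L && nr > 1L) seq(v$pos + 1L, v$pos + nr - 1L)
    else seq(v$pos, v$pos + nr - 1L)
  ccs <- lapply(affected, function(g) oracle_c(m, g))
  offs <- vapply(ccs, function(x) x$offset, integer(1))
  kinds <- vapply(ccs, function(x) x$kind, character(1))
  if (any(kinds == "intronic" & abs(offs) <= 2L)) return("canonical_splice")
  if (any(kinds == "intronic")) {
    if (all(kinds == "intronic") ||
        (nr == 1L && na > 1L)) return("intronic_other")
    return("noncoding_other")
  }
  if (!all(kinds == "coding")) {
    if (nr == 1L && na > 1L) {
      # insertion flanks: exonic, at most one side coding => UTR boundary
      if (all(kinds %in% c("five_prime_utr", "three_prime_utr", "coding")))
        return("utr")
      return("noncoding_other")
    }
    if (all(kinds %in% c("five_prime_utr", "three_prime_utr")))
      return("utr")
    return("noncoding_other")
  }
  # all affected bases coding; insertions between two coding bases
  is_indel <- nr != na
  # build mutant spliced sequence in transcript space
  t_of <- function(g) match(g, maps$pos_tx)
  sp <- maps$spliced
  if (nr == 1L && na == 1L) {
    t <- t_of(v$pos)
    altT <- if (plus) v$alt else chartr("ACGT", "TGCA", v$alt)
    substr(sp, t, t) <- altT
  } else if (nr == 1L && na > 1L) {
    ins <- substr(v$alt, 2L, na)
    insT <- if (plus) ins else paste(rev(strsplit(chartr("ACGT", "TGCA", ins),
                                                  "")[[1]]), collapse = "")
    t_left <- if (plus) t_of(v$pos) else t_of(v$pos + 1L)
    sp <- paste0(substr(sp, 1L, t_left), insT,
                 substr(sp, t_left + 1L, nchar(sp)))
  } else if (na == 1L && nr > 1L) {
    tt <- sort(vapply(seq(v$pos + 1L, v$pos + nr - 1L), t_of, integer(1)))
    sp <- paste0(substr(sp, 1L, tt[1L] - 1L),
                 substr(sp, tt[length(tt)] + 1L, nchar(sp)))
  } else {
    tt <- sort(vapply(seq(v$pos, v$pos + nr - 1L), t_of, integer(1)))
    altT <- if (plus) v$alt else paste(rev(strsplit(chartr("ACGT", "TGCA",
                                                           v$alt),
                                                    "")[[1]]), collapse = "")
    sp <- paste0(substr(sp, 1L, tt[1L] - 1L), altT,
                 substr(sp, tt[length(tt)] + 1L, nchar(sp)))
  }
  if (is_indel) {
    if (abs(nr - na) %% 3L != 0L) return("frameshift")
    return("inframe_indel")
  }
  # length-preserving change: translate the (equal-length) mutant CDS region
  ref_cds <- substr(maps$spliced, maps$t1, maps$t2)
  prot_ref <- oracle_translate(ref_cds)
  prot_mut <- oracle_translate(substr(sp, maps$t1, maps$t2))
  if (nr > 1L) { # length-preserving MNV
    if (nchar(prot_mut) < nchar(prot_ref)) return("stop_gained")
    return("inframe_indel")
  }
  # SNV: compare proteins positionally
  if (identical(prot_mut, prot_ref)) return("synonymous")
  if (nchar(prot_mut) < nchar(prot_ref)) return("stop_gained")
  d <- which(strsplit(prot_mut, "")[[1]][seq_len(nchar(prot_ref))] !=
             strsplit(prot_ref, "")[[1]])
  if (length(d) && d[1L] == 1L &&
      substr(ref_cds, 1L, 3L) == "ATG") {
    t <- t_of(v$pos)
    if (t - maps$t1 + 1L <= 3L) return("start_lost")
  }
  "missense"
}

# --- brute-force variant-normalization oracle --------------------------------

# All VCF-style (pos, ref, alt) spellings on `window` equivalent to the
# given edited haplotype, minimal and leftmost first.
oracle_leftmost_rep <- function(window, hap) {
  W <- nchar(window); H <- nchar(hap)
  delta <- H - W
  best <- NULL
  for (p in seq_len(W)) {
    for (rl in 1L:(W - p + 1L)) {
      al <- rl + delta
      if (al < 1L) next
      if (substr(window, 1L, p - 1L) != substr(hap, 1L, p - 1L)) break
      if (substr(window, p + rl, W) != substr(hap, p + al, H)) next
      ref <- substr(window, p, p + rl - 1L)
      alt <- substr(hap, p, p + al - 1L)
      # minimal representation: no shared suffix; shared prefix only as the
      # single anchor base of an indel
      nrf <- nchar(ref); nal <- nchar(alt)
      if (nrf > 0L && nal > 0L &&
          substr(ref, nrf, nrf) == substr(alt, nal, nal) &&
          !(nrf == 1L && nal == 1L)) next
      if (nrf > 1L && nal > 1L && substr(ref, 1L, 1L) == substr(alt, 1L, 1L))
        next
      cand <- list(pos = p, ref = ref, alt = alt)
      if (is.null(best) || p < best$pos ||
          (p == best$pos && nchar(ref) < nchar(best$ref)))
        best <- cand
    }
  }
  best
}

# --- random transcript generator for property tests --------------------------

# Small random transcript built directly from random exon layout (not via
# the package's synthetic-data builders).
random_test_tx <- function(seed, strand = NULL) {
  set.seed(seed)
  strand <- strand %||% sample(c("+", "-"), 1L)
  n_exons <- sample(2:5, 1L)
  exon_lens <- sample(60:200, n_exons, replace = TRUE)
  intron_lens <- sample(30:80, n_exons - 1L, replace = TRUE)
  flank <- 50L
  total_tx <- sum(exon_lens)
  utr5 <- sample(10:40, 1L)
  utr3 <- sample(10:40, 1L)
  n_cds <- total_tx - utr5 - utr3
  n_cds <- n_cds - (n_cds %% 3L)
  utr3 <- total_tx - utr5 - n_cds
  stopifnot(n_cds >= 9L)
  region_len <- sum(exon_lens) + sum(intron_lens)
  contig_len <- region_len + 2L * flank
  contig <- paste(sample(c("A", "C", "G", "T"), contig_len, replace = TRUE),
                  collapse = "")
  gstart <- integer(n_exons); gend <- integer(n_exons)
  off <- flank
  for (i in seq_len(n_exons)) {
    gstart[i] <- off + 1L
    gend[i] <- off + exon_lens[i]
    off <- gend[i] + if (i < n_exons) intron_lens[i] else 0L
  }
  # CDS bounds: transcript-order positions utr5+1 and utr5+n_cds mapped to
  # genomic by explicit walk
  pos_plus <- unlist(Map(seq, gstart, gend))
  pos_tx <- if (strand == "+") pos_plus else rev(pos_plus)
  # remove in-frame stop codons from the designed CDS by direct surgery on
  # the contig (second codon base -> C), so reference proteins are open
  for (i in seq_len(n_cds %/% 3L)) {
    tpos <- utr5 + 3L * i - 2L + 0:2
    gpos <- pos_tx[tpos]
    bases <- substring(contig, gpos, gpos)
    if (strand == "-") bases <- chartr("ACGT", "TGCA", bases)
    codon <- paste(bases, collapse = "")
    if (codon %in% c("TAA", "TAG", "TGA")) {
      g_mid <- gpos[2L]
      substr(contig, g_mid, g_mid) <- if (strand == "+") "C" else "G"
    }
  }
  g1 <- pos_tx[utr5 + 1L]
  g2 <- pos_tx[utr5 + n_cds]
  suppressWarnings(transcript_model(
    gene_symbol = paste0("G", seed), transcript_id = paste0("T", seed),
    contig = paste0("c", seed), strand = strand,
    exon_starts = gstart, exon_ends = gend,
    cds_start = min(g1, g2), cds_end = max(g1, g2), contig_seq = contig))
}

# Random normalized variant overlapping the transcript (coding-biased).
random_variant_on <- function(m, coding_only = FALSE) {
  span <- c(min(m$exon_starts), max(m$exon_ends))
  repeat {
    g <- sample(seq(span[1L] + 2L, span[2L] - 6L), 1L)
    if (coding_only) {
      cc <- tryCatch(oracle_c(m, g), error = function(e) NULL)
      if (is.null(cc) || cc$kind != "coding" || cc$offset != 0L) next
    }
    type <- sample(c("snv", "ins", "del"), 1L, prob = c(0.5, 0.25, 0.25))
    ref1 <- substr(m$contig_seq, g, g)
    v <- switch(type,
      snv = {
        alt <- sample(setdiff(c("A", "C", "G", "T"), ref1), 1L)
        variant(m$contig, g, ref1, alt)
      },
      ins = {
        ins_len <- sample(1:4, 1L)
        seq_in <- paste(sample(c("A", "C", "G", "T"), ins_len,
                               replace = TRUE), collapse = "")
        variant(m$contig, g, ref1, paste0(ref1, seq_in))
      },
      del = {
        del_len <- sample(1:4, 1L)
        variant(m$contig, g, substr(m$contig_seq, g, g + del_len), ref1)
      })
    nv <- normalize_variant(v, m$contig_seq)
    rng <- c(nv$pos, nv$pos + max(nchar(nv$ref), 2L) - 1L)
    if (rng[1L] > span[1L] + 1L && rng[2L] < span[2L] - 1L) return(nv)
  }
}
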