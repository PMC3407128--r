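#' Configuration for a simulated cohort
#'
#' Defaults emulate the study conditions of the fixture cohort: 46
#' individuals, a 106-gene recessive panel, and a per-gene null-allele
#' frequency chosen so the expected number of null alleles per genome is
#' about 0.217 in aggregate (0.217 / (2 x 106) per gene). Background rates
#' are expected benign variants per individual per category.
#'
#' @param n_individuals Cohort size.
#' @param panel_size Number of panel genes.
#' @param per_gene_null_allele_freq Single frequency or vector of length
#'   `panel_size`, each in `[0, 0.5]`.
#' @param background_rates Named numeric vector with entries `synonymous`,
#'   `missense`, `deep_intronic`, `noncanonical_splice_region` (expected
#'   count per individual; Poisson draws).
#' @param seed Integer seed fixing every downstream draw.
#' @param ethnicity_labels Optional labels cycled over individuals.
#' @return A `cohort_config`.
#' @export
cohort_config <- function(n_individuals = 46L,
                          panel_size = 106L,
                          per_gene_null_allele_freq = 0.217 / (2 * 106),
                          background_rates = c(synonymous = 4,
                                               missense = 4,
                                               deep_intronic = 6,
                                               noncanonical_splice_region = 2),
                          seed = 1L,
                          ethnicity_labels = NULL) {
  stopifnot(n_individuals >= 1L, panel_size >= 1L)
  q <- per_gene_null_allele_freq
  if (length(q) == 1L) q <- rep(q, panel_size)
  if (length(q) != panel_size || any(q < 0) || any(q > 0.5))
    stop("per_gene_null_allele_freq must be in [0, 0.5], one value or one per gene")
  need <- c("synonymous", "missense", "deep_intronic",
            "noncanonical_splice_region")
  if (!all(need %in% names(background_rates)) || any(background_rates < 0))
    stop("background_rates must be non-negative and named: ",
         paste(need, collapse = ", "))
  structure(list(n_individuals = as.integer(n_individuals),
                 panel_size = as.integer(panel_size),
                 q = q, background_rates = background_rates[need],
                 seed = as.integer(seed),
                 ethnicity_labels = ethnicity_labels),
            class = "cohort_config")
}

#' Simulate a diploid cohort with planted null and benign variants
#'
#' Generates a synthetic gene panel (random multi-exon structures, CDS a
#' multiple of 3), engineers one null-allele site per gene (type drawn
#' uniformly from nonsense, frameshift insertion, frameshift deletion,
#' canonical +/-1/2 splice change), draws per-individual genotypes at those
#' sites under Hardy-Weinberg (het `2q(1-q)`, hom `q^2` — homozygotes are
#' reported via a message), plants benign background variants guaranteed
#' non-null by construction, and records everything in a truth manifest
#' consistent with the emitted calls record-for-record. Fully reproducible
#' from `config$seed`.
#'
#' @param config A [cohort_config()].
#' @param out_dir Optional directory; when given, the bundle is written as
#'   plain-text files (FASTA, transcript TSV, panel, VCF v4.2, samples TSV,
#'   manifest JSON).
#' @return Invisibly, the in-memory bundle: `genome`, `txset`, `panel`,
#'   `records`/`gt`, `samples`, `manifest` (with per-individual planted
#'   variants and aggregate `k`, `n`), plus `paths` when written.
#' @export
simulate_cohort <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  if (exists(".Random.seed", globalenv()))
    old_seed <- get(".Random.seed", globalenv())
  else old_seed <- NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)

  syms <- sprintf("SIMG%03d", seq_len(config$panel_size))
  models <- list()
  genome <- character(0)
  null_sites <- list()
  catalogs <- list()
  for (i in seq_along(syms)) {
    g <- .simulate_gene(syms[i])
    models[[i]] <- g$model
    genome[g$model$contig] <- g$contig_seq
    null_sites[[syms[i]]] <- g$null_site
    catalogs[[syms[i]]] <- g$catalog
  }
  txset <- transcript_set(models)
  panel <- gene_panel(syms, label = sprintf("simulated panel (%d genes)",
                                            config$panel_size))

  ids <- sprintf("SIM%04d", seq_len(config$n_individuals))
  eth <- if (is.null(config$ethnicity_labels)) rep(NA_character_, length(ids))
         else config$ethnicity_labels[((seq_along(ids) - 1L) %%
                                       length(config$ethnicity_labels)) + 1L]
  samples_df <- data.frame(individual_id = ids, ethnicity = eth,
                           stringsAsFactors = FALSE)

  plants <- list()
  manifest_vars <- stats::setNames(
    replicate(length(ids), list(), simplify = FALSE), ids)
  add_plant <- function(id, rec, gene, category, is_null, zygosity) {
    plants[[length(plants) + 1L]] <<- data.frame(
      individual_id = id, contig = rec$contig, pos = rec$pos,
      ref = rec$ref, alt = rec$alt, zygosity = zygosity,
      stringsAsFactors = FALSE)
    manifest_vars[[id]][[length(manifest_vars[[id]]) + 1L]] <<- list(
      contig = rec$contig, pos = rec$pos, ref = rec$ref, alt = rec$alt,
      gene = gene, category = category, is_null = is_null,
      zygosity = zygosity)
  }

  n_hom <- 0L
  null_carriers <- character(0)
  for (s in seq_along(ids)) {
    for (gi in seq_along(syms)) {
      q <- config$q[gi]
      if (q <= 0) next
      u <- stats::runif(1)
      zyg <- if (u < q^2) "hom_alt"
             else if (u < q^2 + 2 * q * (1 - q)) "het"
             else NA_character_
      if (is.na(zyg)) next
      if (zyg == "hom_alt") n_hom <- n_hom + 1L
      null_carriers <- union(null_carriers, ids[s])
      site <- null_sites[[syms[gi]]]
      add_plant(ids[s], site$rec, syms[gi], site$category, TRUE, zyg)
    }
    # benign background
    for (type in names(config$background_rates)) {
      n_draw <- stats::rpois(1L, config$background_rates[[type]])
      if (n_draw == 0L) next
      used <- character(0)
      for (d in seq_len(n_draw)) {
        gene <- syms[sample.int(length(syms), 1L)]
        sites <- catalogs[[gene]][[type]]
        if (!length(sites)) next
        site <- sites[[sample.int(length(sites), 1L)]]
        key <- paste(site$rec$contig, site$rec$pos, site$rec$ref,
                     site$rec$alt)
        if (key %in% used) next
        used <- c(used, key)
        add_plant(ids[s], site$rec, gene, type, FALSE, "het")
      }
    }
  }
  if (n_hom > 0L)
    message("simulate_cohort: ", n_hom, " homozygous null genotype(s) drawn")

  plants_df <- if (length(plants)) do.call(rbind, plants)
    else data.frame(individual_id = character(0), contig = character(0),
                    pos = integer(0), ref = character(0),
                    alt = character(0), zygosity = character(0),
                    stringsAsFactors = FALSE)
  # an individual may hold both a null and a benign plant; sites are
  # engineered distinct within each gene, so (individual, site) is unique
  stopifnot(!anyDuplicated(paste(plants_df$individual_id, plants_df$contig,
                                 plants_df$pos, plants_df$ref,
                                 plants_df$alt)))
  manifest <- list(n = length(ids),
                   k = length(null_carriers),
                   panel_size = config$panel_size,
                   seed = config$seed,
                   individuals = manifest_vars)

  asm <- .assemble_genotypes(plants_df, ids)
  bundle <- list(genome = genome, txset = txset, panel = panel,
                 records = asm$records, gt = asm$gt, samples = samples_df,
                 manifest = manifest)
  if (!is.null(out_dir)) {
    bundle$paths <- .write_bundle(out_dir, genome, txset$transcripts, syms,
                                  plants_df, ids, samples_df, manifest)
  }
  invisible(bundle)
}

# One random gene: multi-exon structure (2-26 exons), CDS a multiple of 3,
# an engineered null site, and catalogs of guaranteed-benign sites.
#' @noRd
.simulate_gene <- function(sym) {
  n_codons <- sample(80:300, 1L)
  # reserve interior codons for engineered sites
  interior <- 4:(n_codons - 3L)
  special <- sample(interior, 9L)
  overrides <- stats::setNames(
    as.list(c("CGA", rep("CTT", 4L), rep("GCT", 4L))),
    as.character(special))
  codons <- .make_codons(n_codons, overrides)
  utr5 <- sample(20:80, 1L)
  utr3 <- sample(20:80, 1L)
  total <- utr5 + 3L * n_codons + utr3
  max_exons <- max(2L, min(26L, total %/% 80L))
  n_exons <- sample(2:max_exons, 1L)
  # exon boundaries at least 30 bp apart, none inside an engineered codon
  cuts <- sort(sample(seq(30L, total - 30L, by = 1L), n_exons - 1L))
  while (any(diff(c(0L, cuts, total)) < 30L)) {
    cuts <- sort(sample(seq(30L, total - 30L, by = 1L), n_exons - 1L))
  }
  special_t <- utr5 + as.vector(outer(3L * special - 2L, 0:2, `+`))
  bad <- function(cuts) any(vapply(cuts, function(cc)
    any(abs(cc - special_t) < 6L), logical(1)))
  tries <- 0L
  while (bad(cuts)) {
    cuts <- sort(sample(seq(30L, total - 30L, by = 1L), n_exons - 1L))
    tries <- tries + 1L
    if (tries > 200L) stop("gene construction failed for ", sym)
  }
  exon_tx_lens <- diff(c(0L, cuts, total))
  intron_lens <- sample(60:150, n_exons - 1L, replace = TRUE)
  strand <- sample(c("+", "-"), 1L)
  lay <- .layout_gene(sym, paste0("SIMT_", sym, ".1"),
                      paste0("ctg_", sym), strand, utr5, codons, utr3,
                      exon_tx_lens, intron_lens)
  model <- lay$model

  cga <- special[1L]
  ctt <- special[2:5]
  gct <- special[6:9]

  null_type <- sample(c("nonsense", "frameshift_ins", "frameshift_del",
                        "splice"), 1L)
  null_site <- switch(null_type,
    nonsense = list(category = "stop_gained",
                    rec = .plant_to_vcf(model, list(
                      kind = "snv", coord = 3L * cga - 2L,
                      ref_t = "C", alt_t = "T"))),
    frameshift_ins = {
      # insert one base inside a reserved CTT codon, between the C and T;
      # flanks C/T differ from the inserted G so left-alignment is a no-op
      c_after <- 3L * ctt[1L] - 2L
      list(category = "frameshift",
           rec = .plant_to_vcf(model, list(kind = "ins",
                                           c_after = c_after, seq_t = "G")))
    },
    frameshift_del = {
      # delete the C of a reserved GCT codon: neighbours G and T differ
      # from C on either strand
      cpos <- 3L * gct[1L] - 1L
      list(category = "frameshift",
           rec = .plant_to_vcf(model, list(kind = "del",
                                           c_from = cpos, c_to = cpos)))
    },
    splice = {
      intron <- sample(model$n_exons - 1L, 1L)
      offset <- sample(c(1L, 2L, -1L, -2L), 1L)
      coord <- .intron_edge_coord(model, intron, offset)
      g <- cds_to_genomic(model, coord)
      ref_g <- substr(model$contig_seq, g, g)
      alt_g <- c(A = "G", C = "T", G = "A", T = "C")[[ref_g]]
      list(category = "canonical_splice",
           rec = list(contig = model$contig, pos = g, ref = ref_g,
                      alt = alt_g))
    })

  catalog <- .simulated_benign_catalog(model, ctt, gct)
  list(model = model, contig_seq = lay$contig_seq, null_site = null_site,
       catalog = catalog)
}

# cds_coord at a canonical splice position of the given transcript-order
# intron: offset +k past the donor or -k before the acceptor.
#' @noRd
.intron_edge_coord <- function(model, intron_index, offset) {
  if (offset > 0L) {
    t_anchor <- model$t_end[intron_index]
  } else {
    t_anchor <- model$t_start[intron_index + 1L]
  }
  cc <- t_to_c(model, t_anchor)
  cds_coord(cc$base, offset, cc$kind)
}

#' @noRd
.simulated_benign_catalog <- function(model, ctt, gct) {
  syn <- lapply(ctt[-1L], function(i) {
    list(rec = .plant_to_vcf(model, list(kind = "snv", coord = 3L * i,
                                         ref_t = "T", alt_t = "C")))
  })
  mis <- lapply(gct[-1L], function(i) {
    list(rec = .plant_to_vcf(model, list(kind = "snv", coord = 3L * i - 1L,
                                         ref_t = "C", alt_t = "T")))
  })
  intron_site <- function(intron, offset) {
    coord <- .donor_plus_offset(model, intron, offset)
    g <- cds_to_genomic(model, coord)
    ref_g <- substr(model$contig_seq, g, g)
    alt_g <- c(A = "G", C = "T", G = "A", T = "C")[[ref_g]]
    list(rec = list(contig = model$contig, pos = g, ref = ref_g,
                    alt = alt_g))
  }
  n_introns <- model$n_exons - 1L
  deep <- lapply(seq_len(min(3L, n_introns)), function(i)
    intron_site(i, 15L + 3L * i))
  noncanon <- lapply(seq_len(min(3L, n_introns)), function(i)
    intron_site(i, 3L + (i %% 6L)))
  list(synonymous = syn, missense = mis, deep_intronic = deep,
       noncanonical_splice_region = noncanon)
}
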