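#' Define an experimental-evolution scenario
#'
#' Collects every knob of the synthetic lineage generator. The defaults emulate
#' the mutation regime observed after long-term anode growth of a
#' *Geobacter*-like clone: ~120 SNPs against the parent, transition/transversion
#' ratio 2.76, genome-wide dN/dS 0.776, and a nonsense fraction that puts the
#' loss-of-function share of functional mutations near 14%.
#'
#' @param n_genes Number of CDS features.
#' @param mean_gene_len Mean gene length in codons (including start and stop).
#' @param intergenic_frac Fraction of the genome that is intergenic.
#' @param n_snps Number of substitutions to plant.
#' @param kappa Target transition/transversion count ratio.
#' @param omega Target genome-wide dN/dS.
#' @param lof_rate Fraction of coding substitutions that are nonsense.
#' @param indel_rate Number of 1-bp frameshift deletions, as a fraction of
#'   `n_snps`.
#' @param hotspot_loci Named numeric vector: functional-mutation density
#'   multipliers (>= 1) keyed by locus ID.
#' @param deletion_spans Integer vector of lengths for large streaming
#'   deletions.
#' @param gene_len_jitter Relative SD of gene lengths (0 = all genes have
#'   exactly `mean_gene_len` codons).
#' @param seed Master seed; every stage derives its own stream from it.
#' @return An object of class `evolution_scenario`.
#' @export
evolution_scenario <- function(n_genes = 150,
                               mean_gene_len = 300,
                               intergenic_frac = 0.13,
                               n_snps = 120,
                               kappa = 2.76,
                               omega = 0.776,
                               lof_rate = 0.1,
                               indel_rate = 0,
                               hotspot_loci = NULL,
                               deletion_spans = integer(0),
                               gene_len_jitter = 0,
                               seed = 1L) {
  check_scalar_number(n_genes, "n_genes", min = 1)
  check_scalar_number(mean_gene_len, "mean_gene_len", min = 3)
  check_scalar_number(intergenic_frac, "intergenic_frac", min = 0, max = 0.99)
  check_scalar_number(n_snps, "n_snps", min = 0)
  check_scalar_number(kappa, "kappa")
  if (kappa <= 0) abort("`kappa` must be > 0.")
  check_scalar_number(omega, "omega")
  if (omega <= 0) abort("`omega` must be > 0.")
  check_scalar_number(lof_rate, "lof_rate", min = 0, max = 1)
  check_scalar_number(indel_rate, "indel_rate", min = 0, max = 1)
  check_scalar_number(gene_len_jitter, "gene_len_jitter", min = 0, max = 1)
  if (!is.null(hotspot_loci)) {
    if (is.null(names(hotspot_loci)) || any(!nzchar(names(hotspot_loci)))) {
      abort("`hotspot_loci` must be a named numeric vector keyed by locus ID.")
    }
    if (any(hotspot_loci < 1)) abort("All hotspot multipliers must be >= 1.")
  }
  if (length(deletion_spans) > 0 && any(deletion_spans < 1)) {
    abort("`deletion_spans` must be positive lengths.")
  }
  structure(
    list(n_genes = as.integer(n_genes),
         mean_gene_len = as.integer(mean_gene_len),
         intergenic_frac = intergenic_frac,
         n_snps = as.integer(n_snps),
         kappa = kappa, omega = omega,
         lof_rate = lof_rate, indel_rate = indel_rate,
         hotspot_loci = hotspot_loci,
         deletion_spans = as.integer(deletion_spans),
         gene_len_jitter = gene_len_jitter,
         seed = as.integer(seed)),
    class = "evolution_scenario"
  )
}

#' @export
print.evolution_scenario <- function(x, ...) {
  cat(sprintf(paste0(
    "<evolution_scenario> %d genes x ~%d codons, intergenic %.0f%%\n",
    "  n_snps=%d kappa=%.3g omega=%.3g lof_rate=%.3g indel_rate=%.3g\n",
    "  hotspots=%d deletions=%d seed=%d\n"),
    x$n_genes, x$mean_gene_len, 100 * x$intergenic_frac,
    x$n_snps, x$kappa, x$omega, x$lof_rate, x$indel_rate,
    length(x$hotspot_loci), length(x$deletion_spans), x$seed))
  invisible(x)
}

#' Generate a synthetic ancestral genome
#'
#' Builds an annotated bacterial-style genome for the scenario: `n_genes`
#' non-overlapping CDS on both strands, each starting with ATG, ending in a
#' stop codon, with body codons drawn uniformly over the 61 sense codons, and
#' random intergenic spacers sized to hit `intergenic_frac`. Deterministic for
#' a fixed scenario seed.
#'
#' @param scenario An [evolution_scenario()].
#' @param id Genome identifier.
#' @return An [annotated_genome()].
#' @export
generate_ancestral_genome <- function(scenario, id = "anc") {
  stopifnot(inherits(scenario, "evolution_scenario"))
  with_seed(derive_seed(scenario$seed, 1L), {
    n <- scenario$n_genes
    lens <- if (scenario$gene_len_jitter > 0) {
      pmax(4L, as.integer(round(stats::rnorm(
        n, scenario$mean_gene_len,
        scenario$gene_len_jitter * scenario$mean_gene_len))))
    } else {
      rep(scenario$mean_gene_len, n)
    }
    strands <- sample(c("+", "-"), n, replace = TRUE)
    # guarantee both strands appear when there are >= 2 genes
    if (n >= 2 && length(unique(strands)) == 1L) {
      strands[1] <- setdiff(c("+", "-"), strands[1])
    }
    genes <- vapply(lens, function(L) {
      body <- sample(SENSE_CODONS, L - 2L, replace = TRUE)
      paste0("ATG", paste(body, collapse = ""), sample(STOP_CODONS, 1L))
    }, character(1))

    coding_total <- sum(3L * lens)
    f <- scenario$intergenic_frac
    intergenic_total <- as.integer(round(coding_total * f / (1 - f)))
    n_spacers <- n + 1L
    base_len <- if (intergenic_total >= 2L * n_spacers) 2L else 0L
    extra <- intergenic_total - base_len * n_spacers
    spacer_lens <- rep(base_len, n_spacers)
    if (extra > 0) {
      add <- stats::rmultinom(1, extra, rep(1, n_spacers))[, 1]
      spacer_lens <- spacer_lens + add
    }
    spacers <- vapply(spacer_lens, function(L) {
      if (L == 0) "" else paste(sample(BASES, L, replace = TRUE), collapse = "")
    }, character(1))

    segs <- character(2L * n + 1L)
    starts <- integer(n)
    pos <- 0L
    for (i in seq_len(n)) {
      segs[2L * i - 1L] <- spacers[i]
      pos <- pos + spacer_lens[i]
      g <- if (strands[i] == "-") revcomp(genes[i]) else genes[i]
      segs[2L * i] <- g
      starts[i] <- pos + 1L
      pos <- pos + nchar(g)
    }
    segs[2L * n + 1L] <- spacers[n_spacers]
    seq <- paste(segs, collapse = "")

    feats <- tibble(
      locus_id = sprintf("g%04d", seq_len(n)),
      start = starts,
      end = starts + 3L * lens - 1L,
      strand = strands,
      product = sprintf("synthetic protein %d", seq_len(n))
    )
    annotated_genome(id, seq, feats)
  })
}
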