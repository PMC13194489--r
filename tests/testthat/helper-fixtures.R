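# Hand-built two-gene genome with known codon content, one CDS per strand.
# Layout: 5 nt spacer | gene A (+) | 4 nt spacer | gene B (-) | 6 nt spacer
# gene A CDS: ATG GGA CCT TGG TTT TAA   (M G P W F *)
# gene B CDS: ATG GGA CCT TGG TTT TAA   (same protein, minus strand)
tiny_genome <- function() {
  cds <- "ATGGGACCTTGGTTTTAA"
  spacer1 <- "ACGTA"
  spacer2 <- "TTCA"
  spacer3 <- "GGATCC"
  seq <- paste0(spacer1, cds, spacer2, geoadapt:::revcomp(cds), spacer3)
  a_start <- nchar(spacer1) + 1L
  a_end <- a_start + nchar(cds) - 1L
  b_start <- a_end + nchar(spacer2) + 1L
  b_end <- b_start + nchar(cds) - 1L
  annotated_genome(
    "tiny", seq,
    tibble::tibble(
      locus_id = c("geneA", "geneB"),
      start = c(a_start, b_start),
      end = c(a_end, b_end),
      strand = c("+", "-"),
      product = c("test protein A", "test protein B")
    )
  )
}

# Genomic coordinate of position `off` (1-based within the CDS) of a gene.
cds_pos <- function(genome, locus, off) {
  f <- genome$features[genome$features$locus_id == locus, ]
  if (f$strand == "+") f$start + off - 1L else f$end - off + 1L
}

# Independent translate-and-compare effect oracle for a single-base
# substitution inside one codon, using Biostrings for translation.
oracle_effect <- function(ref_codon, pos_in_codon, alt_base) {
  alt_codon <- ref_codon
  substr(alt_codon, pos_in_codon, pos_in_codon) <- alt_base
  tr <- function(x) as.character(Biostrings::translate(
    Biostrings::DNAStringSet(x), no.init.codon = TRUE))
  aa_ref <- tr(ref_codon); aa_alt <- tr(alt_codon)
  if (aa_alt == "*" && aa_ref != "*") "nonsense"
  else if (aa_ref == aa_alt) "synonymous"
  else if (aa_ref == "*") "stop_loss"
  else "missense"
}

# Small LT-like scenario that keeps simulation tests fast.
small_scenario <- function(...) {
  args <- utils::modifyList(
    list(n_genes = 60, mean_gene_len = 120, n_snps = 200, seed = 42),
    list(...))
  do.call(evolution_scenario, args)
}
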