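#' Transition/transversion ratio of a SNP set
#'
#' Transitions are A<->G and C<->T; everything else is a transversion. Indels
#' are ignored. When no transversions are present the ratio is infinite and a
#' warning is raised.
#'
#' @param variants Tibble with `ref` and `alt` columns (single-base rows are
#'   used; a `type` column, if present, restricts to `type == "SNP"`).
#' @return A single number (possibly `Inf`).
#' @export
ts_tv <- function(variants) {
  v <- as_tibble(variants)
  nm <- tolower(names(v)); names(v)[match(c("ref", "alt"), nm)] <- c("ref", "alt")
  if ("type" %in% names(v)) v <- v[v$type == "SNP", , drop = FALSE]
  v <- v[nchar(v$ref) == 1L & nchar(v$alt) == 1L, , drop = FALSE]
  if (nrow(v) == 0L) abort("ts_tv() needs at least one SNP.")
  ts <- sum(is_transition(v$ref, v$alt))
  tv <- nrow(v) - ts
  if (tv == 0L) {
    warn("No transversions observed; Ts/Tv is infinite.")
    return(Inf)
  }
  ts / tv
}

#' Nei-Gojobori site totals for a genome
#'
#' Sums fractional synonymous and nonsynonymous sites over codons 2..(n-1) of
#' every CDS (the annotated start codon, which is constrained to an initiator,
#' and the stop codon are excluded; see the methods vignette).
#'
#' @param genome An [annotated_genome()].
#' @return Tibble with `n_sites`, `s_sites`, `n_codons`.
#' @export
ng_site_totals <- function(genome) {
  stopifnot(is_annotated_genome(genome))
  cds <- all_cds_seqs(genome)
  syn <- 0; total_codons <- 0L
  for (s in cds) {
    L <- nchar(s)
    if (L < 9L) next
    starts <- seq(4L, L - 5L, by = 3L)
    codons <- substring(s, starts, starts + 2L)
    codons <- codons[codons %in% SENSE_CODONS]
    syn <- syn + sum(NG_SYN_SITES[codons])
    total_codons <- total_codons + length(codons)
  }
  tibble(n_sites = 3 * total_codons - syn, s_sites = syn,
         n_codons = total_codons)
}

#' Genome-wide dN/dS by Nei-Gojobori counting
#'
#' dN/dS = (Nd/N) / (Sd/S): observed nonsynonymous and synonymous substitution
#' counts scaled by the genome's nonsynonymous and synonymous site totals. No
#' multiple-hit correction is applied by default (appropriate for the
#' within-experiment divergences this package targets, ~1e-5..1e-3 per site);
#' `correction = "JC"` applies the Jukes-Cantor correction to the two
#' proportions. With zero synonymous substitutions the ratio is undefined and
#' returned as `NA` with a warning.
#'
#' @param genome An [annotated_genome()].
#' @param variants Annotated variants ([annotate_variants()] output, or any
#'   tibble with an `effect` column); only single-base coding substitutions
#'   are counted.
#' @param correction `"none"` (default) or `"JC"`.
#' @return One-row tibble: `dnds`, `nd`, `sd`, `n_sites`, `s_sites`, `pn`,
#'   `ps`.
#' @export
genome_dnds <- function(genome, variants, correction = c("none", "JC")) {
  correction <- match.arg(correction)
  v <- as_tibble(variants)
  if (!"effect" %in% names(v)) {
    v <- annotate_variants(genome, v)
  }
  if ("type" %in% names(v)) v <- v[v$type == "SNP", , drop = FALSE]
  v <- dplyr::distinct(v, .data$pos, .keep_all = TRUE)  # overlap-safe totals
  nd <- sum(v$effect %in% c("missense", "nonsense", "stop_loss", "start_loss"))
  sd_ <- sum(v$effect == "synonymous")
  sites <- ng_site_totals(genome)
  if (sd_ == 0L) {
    warn("No synonymous substitutions; dN/dS is undefined.")
    return(tibble(dnds = NA_real_, nd = nd, sd = sd_,
                  n_sites = sites$n_sites, s_sites = sites$s_sites,
                  pn = nd / sites$n_sites, ps = 0))
  }
  pn <- nd / sites$n_sites
  ps <- sd_ / sites$s_sites
  if (correction == "JC") {
    jc <- function(p) -3 / 4 * log(1 - 4 * p / 3)
    pn <- jc(pn); ps <- jc(ps)
  }
  tibble(dnds = pn / ps, nd = nd, sd = sd_,
         n_sites = sites$n_sites, s_sites = sites$s_sites, pn = pn, ps = ps)
}

#' Genome mutational background density
#'
#' Functional substitutions per kb. The default denominator is the total CDS
#' length (the convention the per-gene hotspot densities are compared
#' against); the denominator used is echoed in the output.
#'
#' @param profiles Gene mutation profiles ([aggregate_gene_profiles()]).
#' @param coding_length_kb Denominator in kb (> 0).
#' @return One-row tibble: `n_functional`, `coding_length_kb`,
#'   `density_per_kb`.
#' @export
mutational_background <- function(profiles, coding_length_kb) {
  check_scalar_number(coding_length_kb, "coding_length_kb")
  if (coding_length_kb <= 0) abort("`coding_length_kb` must be > 0.")
  nf <- sum(profiles$n_functional)
  tibble(n_functional = nf, coding_length_kb = coding_length_kb,
         density_per_kb = nf / coding_length_kb)
}

#' Detect mutational hotspot genes
#'
#' A hotspot is a gene with at least one functional mutation whose per-gene
#' functional-mutation density (functional mutations per kb of gene) is at
#' least `factor` times the genome background density. `mode = "count"`
#' instead thresholds on the expected count given gene length (for
#' sensitivity analysis).
#'
#' @param profiles Gene mutation profiles with `gene_length_bp` and
#'   `n_functional`.
#' @param background_density Genome background, functional mutations per kb
#'   (>= 0).
#' @param factor Density multiple defining a hotspot (default 3).
#' @param mode `"density"` (default) or `"count"`.
#' @return Tibble of hotspot loci sorted by density, descending:
#'   `locus_id`, `gene_length_bp`, `n_functional`, `density_per_kb`,
#'   `fold_over_background`.
#' @export
detect_hotspots <- function(profiles, background_density, factor = 3,
                            mode = c("density", "count")) {
  mode <- match.arg(mode)
  check_scalar_number(background_density, "background_density", min = 0)
  p <- as_tibble(profiles)
  if (any(p$gene_length_bp <= 0 | is.na(p$gene_length_bp))) {
    abort("All profiles need a positive gene_length_bp.")
  }
  p <- p %>%
    dplyr::mutate(
      density_per_kb = .data$n_functional / (.data$gene_length_bp / 1000),
      fold_over_background = ifelse(background_density > 0,
                                    .data$density_per_kb / background_density,
                                    Inf)
    )
  keep <- if (mode == "density") {
    p$n_functional >= 1 & p$density_per_kb >= factor * background_density
  } else {
    expected <- background_density * p$gene_length_bp / 1000
    p$n_functional >= 1 & p$n_functional >= factor * expected
  }
  p[keep, c("locus_id", "gene_length_bp", "n_functional", "density_per_kb",
            "fold_over_background")] %>%
    dplyr::arrange(dplyr::desc(.data$density_per_kb))
}

#' Loss-of-function share of functional mutations
#'
#' 100 * (nonsense + frameshift + start-loss) / functional mutations. With no
#' functional mutations the share is undefined (`NA`, with a warning).
#'
#' @param profiles Gene mutation profiles.
#' @return Percent (single number).
#' @export
lof_fraction <- function(profiles) {
  nf <- sum(profiles$n_functional)
  if (nf == 0) {
    warn("No functional mutations; LOF fraction undefined.")
    return(NA_real_)
  }
  100 * sum(profiles$n_lof) / nf
}

#' Genome size reduction
#'
#' 100 * (parent - descendant) / parent; negative values indicate growth.
#'
#' @param size_parent,size_descendant Genome sizes in bp (> 0).
#' @return Percent reduction.
#' @examples
#' genome_reduction(3814128, 3726411)  # 2.3
#' @export
genome_reduction <- function(size_parent, size_descendant) {
  check_scalar_number(size_parent, "size_parent")
  check_scalar_number(size_descendant, "size_descendant")
  if (size_parent <= 0 || size_descendant <= 0) {
    abort("Genome sizes must be positive.")
  }
  100 * (size_parent - size_descendant) / size_parent
}

#' Find large alignment gaps on the reference
#'
#' Given coords-style alignment blocks (1-based inclusive, non-overlapping,
#' sorted by reference start), reports every reference interval of length >=
#' `min_gap` not covered by a block, including terminal gaps when
#' `ref_length` is supplied. Each gap carries the query coordinates flanking
#' it.
#'
#' @param blocks Tibble with `ref_start`, `ref_end`, `qry_start`, `qry_end`
#'   and optionally `orientation`.
#' @param min_gap Minimum gap length in bp (default 1000).
#' @param ref_length Total reference length (enables terminal gaps).
#' @return Tibble: `ref_start`, `ref_end`, `length`, `qry_before`,
#'   `qry_after`.
#' @export
find_large_gaps <- function(blocks, min_gap = 1000, ref_length = NULL) {
  b <- as_tibble(blocks)
  req <- c("ref_start", "ref_end", "qry_start", "qry_end")
  if (!all(req %in% names(b))) {
    abort(sprintf("`blocks` needs columns %s.", paste(req, collapse = ", ")))
  }
  if (nrow(b) == 0L) abort("`blocks` must contain at least one block.")
  b <- b[order(b$ref_start), , drop = FALSE]
  if (any(b$ref_end < b$ref_start)) abort("Block ends must be >= starts.")
  if (nrow(b) > 1 && any(b$ref_start[-1] <= b$ref_end[-nrow(b)])) {
    abort("Alignment blocks overlap on the reference.")
  }
  gaps <- tibble(
    ref_start = b$ref_end[-nrow(b)] + 1L,
    ref_end = b$ref_start[-1] - 1L,
    qry_before = b$qry_end[-nrow(b)],
    qry_after = b$qry_start[-1]
  )
  if (b$ref_start[1] > 1L) {
    gaps <- dplyr::bind_rows(
      tibble(ref_start = 1L, ref_end = b$ref_start[1] - 1L,
             qry_before = NA_integer_, qry_after = b$qry_start[1]),
      gaps)
  }
  if (!is.null(ref_length) && b$ref_end[nrow(b)] < ref_length) {
    gaps <- dplyr::bind_rows(
      gaps,
      tibble(ref_start = b$ref_end[nrow(b)] + 1L,
             ref_end = as.integer(ref_length),
             qry_before = b$qry_end[nrow(b)], qry_after = NA_integer_))
  }
  gaps$length <- gaps$ref_end - gaps$ref_start + 1L
  gaps <- gaps[gaps$length >= min_gap, c("ref_start", "ref_end", "length",
                                         "qry_before", "qry_after")]
  gaps
}

#' Genome-wide mutation summary for a parent/descendant pair
#'
#' Assembles all comparison statistics into one row: total SNPs, Ts/Tv,
#' genome-wide dN/dS, functional SNP count, background functional density,
#' genes with functional SNPs, hotspot count, LOF count and LOF share.
#'
#' @param genome_parent Parent [annotated_genome()] (the classification
#'   frame).
#' @param genome_desc Descendant [annotated_genome()] (for the size-reduction
#'   column); may be `NULL`.
#' @param variants Variant tibble (`pos`/`ref`/`alt`, annotated or not).
#' @param comparison Label for the row.
#' @param hotspot_factor Density multiple for [detect_hotspots()].
#' @param background_denominator `"coding"` (default: total CDS length) or
#'   `"genome"`.
#' @return One-row tibble of class `comparison_summary`.
#' @export
comparison_summary <- function(genome_parent, genome_desc, variants,
                               comparison = "descendant vs parent",
                               hotspot_factor = 3,
                               background_denominator = c("coding", "genome")) {
  background_denominator <- match.arg(background_denominator)
  stopifnot(is_annotated_genome(genome_parent))
  v <- as_tibble(variants)
  if (!"effect" %in% names(v)) v <- annotate_variants(genome_parent, v)
  snps <- dplyr::distinct(v[v$type == "SNP", , drop = FALSE], .data$pos,
                          .keep_all = TRUE)
  prof <- aggregate_gene_profiles(v, genome_parent)
  denom_kb <- if (background_denominator == "coding") {
    coding_length(genome_parent, "kb")
  } else {
    genome_length(genome_parent) / 1000
  }
  bg <- mutational_background(prof, denom_kb)
  hs <- detect_hotspots(prof, bg$density_per_kb, factor = hotspot_factor)
  n_functional <- sum(prof$n_functional)
  out <- tibble(
    comparison = comparison,
    total_snps = nrow(snps),
    ts_tv = if (nrow(snps) > 0) ts_tv(snps) else NA_real_,
    dnds = if (nrow(snps) > 0) genome_dnds(genome_parent, v)$dnds else NA_real_,
    n_functional = n_functional,
    background_density = bg$density_per_kb,
    background_denominator = background_denominator,
    n_genes_with_functional = sum(prof$n_functional > 0),
    n_hotspots = nrow(hs),
    n_lof = sum(prof$n_lof),
    lof_percent = if (n_functional > 0) lof_fraction(prof) else NA_real_,
    genome_reduction_percent = if (is.null(genome_desc)) NA_real_ else
      genome_reduction(genome_length(genome_parent), genome_length(genome_desc))
  )
  class(out) <- c("comparison_summary", class(out))
  out
}
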