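#' Statistical test dispatcher
#'
#' Thin, shape-checked wrappers over the base stats routines used throughout
#' the analyses: paired and independent t-tests, Wilcoxon signed-rank,
#' chi-squared and McNemar. All p-values are two-sided.
#'
#' @param x First sample, or a 2-D contingency table/matrix for
#'   `chi_squared` / `mcnemar`.
#' @param y Second sample (required for the paired and two-sample kinds).
#' @param kind One of `"paired_t"`, `"wilcoxon_signed_rank"`,
#'   `"independent_t"`, `"chi_squared"`, `"mcnemar"`.
#' @param ... Passed to the underlying stats routine.
#' @return One-row tibble: `kind`, `statistic`, `p_value`, `method`.
#' @export
stat_tests <- function(x, y = NULL,
                       kind = c("paired_t", "wilcoxon_signed_rank",
                                "independent_t", "chi_squared", "mcnemar"),
                       ...) {
  kind <- match.arg(kind)
  needs_pair <- kind %in% c("paired_t", "wilcoxon_signed_rank")
  if (needs_pair) {
    if (is.null(y) || length(x) != length(y)) {
      abort(sprintf("'%s' needs two samples of equal length.", kind))
    }
  }
  if (kind == "independent_t" && is.null(y)) {
    abort("'independent_t' needs two samples.")
  }
  if (kind %in% c("chi_squared", "mcnemar")) {
    x <- as.matrix(x)
    if (length(dim(x)) != 2L) abort(sprintf("'%s' needs a 2-D table.", kind))
    if (kind == "mcnemar" && (nrow(x) != ncol(x))) {
      abort("'mcnemar' needs a square table.")
    }
  }
  if (needs_pair && stats::sd(x - y) == 0) {
    # degenerate pairing: no variance in the differences
    return(tibble(kind = kind, statistic = 0,
                  p_value = if (mean(x - y) == 0) 1 else NA_real_,
                  method = paste(kind, "(degenerate: constant differences)")))
  }
  res <- switch(kind,
    paired_t = stats::t.test(x, y, paired = TRUE, ...),
    wilcoxon_signed_rank = stats::wilcox.test(x, y, paired = TRUE, ...),
    independent_t = stats::t.test(x, y, ...),
    chi_squared = stats::chisq.test(x, ...),
    mcnemar = stats::mcnemar.test(x, ...)
  )
  tibble(kind = kind, statistic = unname(res$statistic),
         p_value = res$p.value, method = res$method)
}

#' Configure an end-to-end synthetic analysis run
#'
#' @param scenario An [evolution_scenario()] driving the genomic stages.
#' @param n_lineages Number of descendant lineages to simulate.
#' @param hotspot_factor Density multiple for hotspot detection.
#' @param background_denominator `"coding"` or `"genome"`.
#' @param min_gap Minimum alignment gap length (bp).
#' @param structure Parameters for [generate_structure_pair()] (list).
#' @param expression_folds Planted fold tibble for [generate_ct_table()]
#'   (`NULL` for a small default).
#' @param growth_k Named rate vector for [generate_growth_curves()].
#' @param alpha Significance level recorded in the manifest.
#' @param seed Master seed (overrides the scenario seed for derived stages).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(scenario = evolution_scenario(),
                            n_lineages = 5,
                            hotspot_factor = 3,
                            background_denominator = "coding",
                            min_gap = 1000,
                            structure = list(length = 407, n_perturbed = 20,
                                             displacement = 2, n_ss_changes = 11,
                                             n_hemes = 6, heme_shift = 0.1),
                            expression_folds = NULL,
                            growth_k = c(parent = 0.12, evolved = 0.224),
                            alpha = 0.05,
                            seed = 1L) {
  check_scalar_number(alpha, "alpha")
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must be in (0, 1).")
  check_scalar_number(n_lineages, "n_lineages", min = 1)
  if (is.null(expression_folds)) {
    expression_folds <- tibble(
      strain = rep(c("parent", "evolved"), each = 3),
      gene = rep(c("pilA", "omcZ", "omcB"), 2),
      fold = c(2, 2, 2, 6, 5, 4)
    )
  }
  structure(
    list(scenario = scenario, n_lineages = as.integer(n_lineages),
         hotspot_factor = hotspot_factor,
         background_denominator = background_denominator,
         min_gap = min_gap, structure = structure,
         expression_folds = expression_folds, growth_k = growth_k,
         alpha = alpha, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Run the full synthetic analysis pipeline
#'
#' Simulates an ancestor and `n_lineages` descendants, annotates every
#' lineage's variants, and writes the complete report bundle to `out_dir`:
#' per-lineage genome-wide mutation summaries, a hotspot table (which
#' lineages carry each hotspot), a per-gene amino-acid-change table, a
#' structure-comparison report, an expression table and a phenotype (growth
#' rate) table, plus a run manifest. Identical config + seed gives a
#' byte-identical bundle.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with all result objects and `files` (the paths
#'   written).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(...) file.path(out_dir, ...)

  ## genomic stages
  scn <- config$scenario
  scn$seed <- derive_seed(config$seed, 10L)
  ancestor <- generate_ancestral_genome(scn)
  sites <- enumerate_sites(ancestor)
  lineages <- list()
  summaries <- list()
  profiles <- list()
  for (i in seq_len(config$n_lineages)) {
    scn_i <- scn
    scn_i$seed <- derive_seed(config$seed, 100L + i)
    lin <- evolve_lineage(ancestor, scn_i, sites = sites)
    ann <- annotate_variants(ancestor, lin$variants)
    lineages[[i]] <- lin
    profiles[[i]] <- aggregate_gene_profiles(ann, ancestor) %>%
      dplyr::mutate(lineage = sprintf("LT%d", i), .before = 1)
    summaries[[i]] <- comparison_summary(
      ancestor, lin$descendant, ann,
      comparison = sprintf("LT%d vs %s", i, ancestor$id),
      hotspot_factor = config$hotspot_factor,
      background_denominator = config$background_denominator)
  }
  summary_tbl <- dplyr::bind_rows(summaries)
  prof_tbl <- dplyr::bind_rows(profiles)

  denom_kb <- if (config$background_denominator == "coding") {
    coding_length(ancestor, "kb")
  } else genome_length(ancestor) / 1000
  hotspot_tbl <- prof_tbl %>%
    dplyr::group_split(.data$lineage) %>%
    purrr::map_dfr(function(p) {
      bg <- mutational_background(p, denom_kb)
      detect_hotspots(p, bg$density_per_kb, factor = config$hotspot_factor) %>%
        dplyr::mutate(lineage = p$lineage[1])
    }) %>%
    dplyr::summarise(lineages = paste(sort(unique(.data$lineage)), collapse = ","),
                     n_lineages = dplyr::n_distinct(.data$lineage),
                     .by = "locus_id") %>%
    dplyr::left_join(
      ancestor$features[, c("locus_id", "product")], by = "locus_id")

  aa_change_tbl <- prof_tbl %>%
    dplyr::summarise(
      n_snps = sum(.data$n_total),
      n_aa_changes = sum(.data$n_functional),
      n_category_changes = sum(.data$n_category_changes),
      .by = c("lineage", "locus_id"))

  gaps <- find_large_gaps(alignment_blocks(lineages[[1]]),
                          min_gap = config$min_gap,
                          ref_length = genome_length(ancestor))

  ## structure stage
  sp <- do.call(generate_structure_pair,
                c(config$structure, list(seed = derive_seed(config$seed, 20L))))
  struct_cmp <- compare_structures(sp$a, sp$b)

  ## expression stage
  ref_strain <- "reference"
  ct <- generate_ct_table(config$expression_folds, reference_strain = ref_strain,
                          seed = derive_seed(config$seed, 30L))
  expr <- delta_delta_ct(ct, "recA", ref_strain)

  ## phenotype stage
  curves <- generate_growth_curves(config$growth_k, t_grid = seq(0, 10, by = 0.5),
                                   noise_sd = 0.02, replicates = 3,
                                   seed = derive_seed(config$seed, 40L))
  rates <- fit_growth_rates(curves)

  files <- c(
    summary = fp("comparison_summary.tsv"),
    hotspots = fp("hotspot_genes.tsv"),
    aa_changes = fp("gene_aa_changes.tsv"),
    gaps = fp("alignment_gaps.tsv"),
    structure = fp("structure_comparison.tsv"),
    expression = fp("expression.tsv"),
    phenotype = fp("growth_rates.tsv"),
    manifest = fp("manifest.yaml")
  )
  readr::write_tsv(summary_tbl, files["summary"])
  readr::write_tsv(hotspot_tbl, files["hotspots"])
  readr::write_tsv(aa_change_tbl, files["aa_changes"])
  readr::write_tsv(gaps, files["gaps"])
  readr::write_tsv(struct_cmp$report, files["structure"])
  readr::write_tsv(as_tibble(expr), files["expression"])
  readr::write_tsv(rates, files["phenotype"])

  manifest <- list(
    package = "geoadapt",
    package_version = as.character(utils::packageVersion("geoadapt")),
    seed = config$seed,
    alpha = config$alpha,
    hotspot_factor = config$hotspot_factor,
    background_denominator = config$background_denominator,
    min_gap = config$min_gap,
    n_lineages = config$n_lineages,
    scenario = unclass(config$scenario)[
      c("n_genes", "mean_gene_len", "intergenic_frac", "n_snps", "kappa",
        "omega", "lof_rate", "indel_rate")],
    outputs = as.list(stats::setNames(basename(files), names(files)))
  )
  yaml::write_yaml(manifest, files["manifest"])

  invisible(list(ancestor = ancestor, lineages = lineages,
                 summary = summary_tbl, hotspots = hotspot_tbl,
                 aa_changes = aa_change_tbl, gaps = gaps,
                 structure = struct_cmp, expression = expr, rates = rates,
                 files = files))
}
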