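test_that("ts_tv counts transitions over transversions", {
  v <- tibble::tibble(ref = c("A", "G", "C", "A"), alt = c("G", "A", "T", "C"))
  expect_equal(ts_tv(v), 3)
  expect_equal(ts_tv(tibble::tibble(ref = "A", alt = "C")), 0)
  expect_warning(r <- ts_tv(tibble::tibble(ref = c("A", "C"), alt = c("G", "T"))),
                 "infinite")
  expect_identical(r, Inf)
  expect_error(ts_tv(tibble::tibble(ref = character(0), alt = character(0))),
               "at least one")
  # indels are excluded
  v2 <- tibble::tibble(ref = c("A", "AT"), alt = c("G", "A"),
                       type = c("SNP", "deletion"))
  suppressWarnings(expect_identical(ts_tv(v2), Inf))
})

test_that("genome-wide NG site totals equal per-codon enumeration", {
  scn <- evolution_scenario(n_genes = 10, mean_gene_len = 25, seed = 13)
  g <- generate_ancestral_genome(scn)
  tot <- ng_site_totals(g)
  # oracle: enumerate internal codons gene by gene
  s_oracle <- 0; n_codons <- 0
  for (loc in g$features$locus_id) {
    cds <- geoadapt:::cds_seq(g, loc)
    for (k in 2:(nchar(cds) / 3 - 1)) {
      cd <- substr(cds, 3 * k - 2, 3 * k)
      s_oracle <- s_oracle + ng_site_counts(cd)$syn_sites
      n_codons <- n_codons + 1
    }
  }
  expect_equal(tot$s_sites, s_oracle)
  expect_equal(tot$n_sites, 3 * n_codons - s_oracle)
  # consistency with the site enumeration used by the simulator
  sites <- enumerate_sites(g)
  expect_equal(sites$s_sites, tot$s_sites)
  expect_equal(sites$n_sites, tot$n_sites)
})

test_that("dN/dS matches a hand-computed two-substitution micro-example", {
  # single gene ATG GGA TTT TGG TAA; internal codons GGA TTT TGG:
  # S = 1 + 1/3 + 0 = 4/3,  N = 2 + 8/3 + 3 = 23/3
  cds <- "ATGGGATTTTGGTAA"
  seq <- paste0("AAC", cds, "GGT")
  g <- annotated_genome("micro", seq, tibble::tibble(
    locus_id = "m1", start = 4L, end = 18L, strand = "+", product = NA))
  v <- tibble::tibble(pos = c(9L, 10L), ref = c("A", "T"), alt = c("G", "C"))
  ann <- annotate_variants(g, v)
  expect_identical(sort(ann$effect), c("missense", "synonymous"))
  res <- genome_dnds(g, ann)
  expect_equal(res$s_sites, 4 / 3)
  expect_equal(res$n_sites, 23 / 3)
  expect_equal(res$dnds, 4 / 23)
  # purely synonymous set -> 0; purely nonsynonymous -> undefined
  expect_equal(genome_dnds(g, ann[ann$effect == "synonymous", ])$dnds, 0)
  expect_warning(res2 <- genome_dnds(g, ann[ann$effect == "missense", ]),
                 "undefined")
  expect_true(is.na(res2$dnds))
})

test_that("mutational background density follows its definition", {
  prof <- tibble::tibble(locus_id = "x", gene_length_bp = 1000L,
                         n_functional = 41L, n_lof = 6L)
  expect_equal(mutational_background(prof, 3336)$density_per_kb,
               41 / 3336, tolerance = 1e-12)
  expect_equal(round(mutational_background(prof, 3336)$density_per_kb, 4), 0.0123)
  expect_equal(mutational_background(prof[0, ], 100)$density_per_kb, 0)
  d1 <- mutational_background(prof, 1000)$density_per_kb
  d2 <- mutational_background(prof, 2000)$density_per_kb
  expect_equal(d1, 2 * d2)
  expect_error(mutational_background(prof, 0), "> 0")
})

test_that("hotspot detection applies the density rule", {
  prof <- tibble::tibble(
    locus_id = c("a", "b", "c"),
    gene_length_bp = c(1000L, 1000L, 2000L),
    n_functional = c(1L, 0L, 1L),
    n_lof = 0L, n_total = c(1L, 0L, 1L), n_synonymous = 0L,
    n_category_changes = 0L
  )
  hs <- detect_hotspots(prof, background_density = 0.01, factor = 3)
  expect_setequal(hs$locus_id, c("a", "c"))       # both well above 0.03/kb
  expect_equal(hs$locus_id[1], "a")               # sorted by density
  # a gene with zero functional mutations is never a hotspot
  expect_false("b" %in% hs$locus_id)
  # raising the background excludes the weaker gene
  hs2 <- detect_hotspots(prof, background_density = 0.2, factor = 3)
  expect_setequal(hs2$locus_id, "a")
  expect_error(detect_hotspots(dplyr::mutate(prof, gene_length_bp = 0L), 0.01),
               "positive gene_length_bp")
})

test_that("hotspot calls are scale-invariant and monotone", {
  prof <- tibble::tibble(
    locus_id = letters[1:4],
    gene_length_bp = c(500L, 1500L, 900L, 3000L),
    n_functional = c(2L, 1L, 0L, 9L),
    n_lof = 0L
  )
  bg <- 0.9
  base <- detect_hotspots(prof, bg)$locus_id
  scaled <- detect_hotspots(
    dplyr::mutate(prof, gene_length_bp = gene_length_bp * 7L,
                  n_functional = n_functional * 7L), bg)$locus_id
  expect_setequal(base, scaled)
  # adding a functional SNP to a hotspot gene never removes it
  more <- dplyr::mutate(prof, n_functional = n_functional + 1L)
  expect_true(all(base %in% detect_hotspots(more, bg)$locus_id))
})

test_that("LOF share is a percentage of functional mutations", {
  prof <- tibble::tibble(locus_id = "x", gene_length_bp = 1L,
                         n_functional = 41L, n_lof = 6L)
  expect_equal(lof_fraction(prof), 100 * 6 / 41, tolerance = 1e-12)
  expect_equal(round(lof_fraction(prof), 1), 14.6)
  expect_equal(lof_fraction(dplyr::mutate(prof, n_lof = 0L)), 0)
  expect_equal(lof_fraction(dplyr::mutate(prof, n_lof = 41L)), 100)
  expect_warning(r <- lof_fraction(dplyr::mutate(prof, n_functional = 0L)),
                 "undefined")
  expect_true(is.na(r))
})

test_that("genome reduction reproduces simple arithmetic", {
  expect_equal(genome_reduction(3814128, 3726411), 2.3, tolerance = 0.005)
  # the descendant size here is itself approximate ("~"), so exact
  # arithmetic gives 0.325%: equal to the printed 0.32 at that precision
  expect_equal(genome_reduction(3726411, 3714300), 0.32, tolerance = 0.02)
  expect_equal(genome_reduction(100, 100), 0)
  expect_lt(genome_reduction(100, 110), 0)  # growth is negative
  expect_error(genome_reduction(0, 10), "positive")
})

test_that("large-gap detection handles coverage, interior and terminal gaps", {
  full <- tibble::tibble(ref_start = 1L, ref_end = 1000L,
                         qry_start = 1L, qry_end = 1000L)
  expect_equal(nrow(find_large_gaps(full, min_gap = 50, ref_length = 1000)), 0L)
  two <- tibble::tibble(ref_start = c(1L, 201L), ref_end = c(100L, 300L),
                        qry_start = c(1L, 101L), qry_end = c(100L, 200L))
  g <- find_large_gaps(two, min_gap = 50)
  expect_equal(nrow(g), 1L)
  expect_equal(c(g$ref_start, g$ref_end), c(101L, 200L))
  expect_equal(g$qry_before, 100L)
  # terminal gap needs ref_length
  g2 <- find_large_gaps(two, min_gap = 50, ref_length = 400L)
  expect_equal(nrow(g2), 2L)
  # below min_gap is ignored
  expect_equal(nrow(find_large_gaps(two, min_gap = 150)), 0L)
  overlapping <- tibble::tibble(ref_start = c(1L, 50L), ref_end = c(100L, 160L),
                                qry_start = c(1L, 50L), qry_end = c(100L, 160L))
  expect_error(find_large_gaps(overlapping), "overlap")
})

test_that("comparison summary assembles all statistics consistently", {
  scn <- small_scenario(n_snps = 150)
  g <- generate_ancestral_genome(scn)
  lin <- evolve_lineage(g, scn)
  s <- comparison_summary(g, lin$descendant, lin$variants)
  expect_equal(s$total_snps, lin$truth$counts$n_snps)
  expect_equal(s$n_lof, lin$truth$counts$n_lof)
  expect_equal(s$ts_tv, lin$truth$counts$n_ts / lin$truth$counts$n_tv)
  expect_true(s$n_hotspots <= s$n_genes_with_functional)
  expect_true(s$lof_percent >= 0 && s$lof_percent <= 100)
  # identical lineages give identical summaries
  s2 <- comparison_summary(g, lin$descendant, lin$variants)
  expect_equal(as.data.frame(s), as.data.frame(s2))
  # null scenario: zero counts, undefined ratios
  scn0 <- small_scenario(n_snps = 0)
  lin0 <- evolve_lineage(g, scn0)
  s0 <- comparison_summary(g, lin0$descendant, lin0$variants)
  expect_equal(s0$total_snps, 0L)
  expect_true(is.na(s0$ts_tv))
  expect_true(is.na(s0$dnds))
})
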