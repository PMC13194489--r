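test_that("classic codon cases classify correctly on the plus strand", {
  g <- tiny_genome()
  # gene A codon 2 is GGA (Gly); third-position A->G is synonymous
  p <- cds_pos(g, "geneA", 6)
  res <- classify_variant(g, p, "A", "G")
  expect_identical(res$effect, "synonymous")
  expect_false(res$is_functional)
  expect_identical(res$ref_codon, "GGA")
  expect_identical(res$alt_codon, "GGG")
  # gene A codon 3 is CCT (Pro); first-position C->G gives GCT (Ala):
  # missense with a category change (proline -> alanine)
  p <- cds_pos(g, "geneA", 7)
  res <- classify_variant(g, p, "C", "G")
  expect_identical(res$effect, "missense")
  expect_identical(res$ref_aa, "P")
  expect_identical(res$alt_aa, "A")
  expect_true(res$is_category_change)
  # gene A codon 4 is TGG (Trp); TGG->TGA is nonsense and LOF
  p <- cds_pos(g, "geneA", 12)
  res <- classify_variant(g, p, "G", "A")
  expect_identical(res$effect, "nonsense")
  expect_true(res$is_lof)
})

test_that("all nine substitutions of TGG give 7 missense and 2 nonsense", {
  g <- tiny_genome()
  effects <- character(0)
  for (off in 10:12) {
    p <- cds_pos(g, "geneA", off)
    ref <- substr(g$seq, p, p)
    for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
      effects <- c(effects, classify_variant(g, p, ref, alt)$effect)
    }
  }
  expect_equal(sum(effects == "missense"), 7L)
  expect_equal(sum(effects == "nonsense"), 2L)
})

test_that("minus-strand classification mirrors the plus strand (strand symmetry)", {
  g <- tiny_genome()
  for (off in c(5, 7, 11, 14)) {
    pa <- cds_pos(g, "geneA", off)
    pb <- cds_pos(g, "geneB", off)
    ref_a <- substr(g$seq, pa, pa)
    for (alt_a in setdiff(c("A", "C", "G", "T"), ref_a)) {
      ra <- classify_variant(g, pa, ref_a, alt_a)
      comp <- geoadapt:::COMPLEMENT
      rb <- classify_variant(g, pb, unname(comp[ref_a]), unname(comp[alt_a]))
      expect_identical(rb$effect, ra$effect)
      expect_identical(rb$ref_aa, ra$ref_aa)
      expect_identical(rb$alt_aa, ra$alt_aa)
    }
  }
})

test_that("start and stop codon edge cases follow bacterial initiator rules", {
  g <- tiny_genome()
  # ATG -> GTG at the annotated start: still an initiator, read as Met
  p <- cds_pos(g, "geneA", 1)
  res <- classify_variant(g, p, "A", "G")
  expect_identical(res$effect, "synonymous")
  expect_identical(res$ref_aa, "M")
  # ATG -> ATA: no longer an initiator
  p <- cds_pos(g, "geneA", 3)
  res <- classify_variant(g, p, "G", "A")
  expect_identical(res$effect, "start_loss")
  expect_true(res$is_lof)
  # stop TAA -> TAG stays a stop (synonymous); TAA -> CAA loses the stop
  p <- cds_pos(g, "geneA", 18)
  res <- classify_variant(g, p, "A", "G")
  expect_identical(res$effect, "synonymous")
  p <- cds_pos(g, "geneA", 16)
  res <- classify_variant(g, p, "T", "C")
  expect_identical(res$effect, "stop_loss")
  expect_false(res$is_lof)   # stop-loss is functional but not LOF
  expect_true(res$is_functional)
})

test_that("indels and intergenic variants classify by rule", {
  g <- tiny_genome()
  # 1-bp deletion inside gene A: frameshift, LOF
  p <- cds_pos(g, "geneA", 8)
  ref2 <- substr(g$seq, p, p + 1)
  res <- classify_variant(g, p, ref2, substr(ref2, 1, 1))
  expect_identical(res$effect, "frameshift")
  expect_true(res$is_lof)
  # 3-bp deletion: in-frame, functional but not LOF
  ref4 <- substr(g$seq, p, p + 3)
  res <- classify_variant(g, p, ref4, substr(ref4, 1, 1))
  expect_identical(res$effect, "inframe_indel")
  expect_false(res$is_lof)
  expect_true(res$is_functional)
  # intergenic SNP
  res <- classify_variant(g, 2L, substr(g$seq, 2, 2),
                          setdiff(c("A", "C", "G", "T"), substr(g$seq, 2, 2))[1])
  expect_identical(res$effect, "intergenic")
  expect_false(res$is_functional)
})

test_that("multi-base substitutions in one codon are classified jointly", {
  g <- tiny_genome()
  # codon 5 of gene A is TTT (Phe); TTT -> CTC is Leu: one missense call,
  # even though T->C at position 3 alone would be synonymous
  p <- cds_pos(g, "geneA", 13)
  res <- classify_variant(g, p, "TTT", "CTC")
  expect_equal(nrow(res), 1L)
  expect_identical(res$effect, "missense")
  expect_identical(res$alt_aa, "L")
})

test_that("input validation catches coordinate and allele errors", {
  g <- tiny_genome()
  expect_error(classify_variant(g, 10000L, "A", "G"), "outside")
  ref <- substr(g$seq, 10, 10)
  wrong <- setdiff(c("A", "C", "G", "T"), ref)[1]
  expect_error(classify_variant(g, 10L, wrong, ref), "mismatch")
  expect_error(classify_variant(g, 10L, ref, "N"), "A/C/G/T")
})

test_that("effect calls equal a translate-and-compare oracle on random genes", {
  set.seed(20240915)
  scn <- evolution_scenario(n_genes = 4, mean_gene_len = 30, seed = 77)
  g <- generate_ancestral_genome(scn)
  f <- g$features
  n_checked <- 0
  for (i in seq_len(nrow(f))) {
    cds <- geoadapt:::cds_seq(g, f$locus_id[i])
    # sample internal codon positions (skip start and stop codons)
    offs <- sample(4:(nchar(cds) - 3), 25)
    for (off in offs) {
      p <- cds_pos(g, f$locus_id[i], off)
      ref_fwd <- substr(g$seq, p, p)
      codon_idx <- (off - 1) %/% 3 + 1
      pic <- (off - 1) %% 3 + 1
      codon <- substr(cds, 3 * codon_idx - 2, 3 * codon_idx)
      for (alt_fwd in setdiff(c("A", "C", "G", "T"), ref_fwd)) {
        alt_cds <- if (f$strand[i] == "-")
          unname(geoadapt:::COMPLEMENT[alt_fwd]) else alt_fwd
        expected <- oracle_effect(codon, pic, alt_cds)
        got <- classify_variant(g, p, ref_fwd, alt_fwd)$effect
        expect_identical(got, expected)
        n_checked <- n_checked + 1
      }
    }
  }
  expect_gte(n_checked, 300)
})

test_that("gene profiles count variants per locus", {
  g <- tiny_genome()
  vars <- tibble::tibble(
    pos = c(cds_pos(g, "geneA", 7), cds_pos(g, "geneA", 8),
            cds_pos(g, "geneA", 10), cds_pos(g, "geneA", 6)),
    ref = c("C", "C", "T", "A"),
    alt = c("G", "A", "C", "G")
  )
  ann <- annotate_variants(g, vars)
  prof <- aggregate_gene_profiles(ann, g)
  expect_equal(nrow(prof), 1L)
  expect_equal(prof$n_total, 4L)
  expect_equal(prof$n_functional, 3L)
  expect_equal(prof$n_synonymous, 1L)
  expect_equal(prof$gene_length_bp, 18L)
  # zero-count profiles on request
  prof0 <- aggregate_gene_profiles(ann, g, include_zero = TRUE)
  expect_equal(nrow(prof0), 2L)
  expect_equal(prof0$n_total[prof0$locus_id == "geneB"], 0L)
  # empty input
  expect_equal(nrow(aggregate_gene_profiles(annotate_variants(g, vars[0, ]), g)), 0L)
  # unknown locus
  bad <- ann
  bad$locus_id[1] <- "nope"
  expect_error(aggregate_gene_profiles(bad, g), "absent")
})

test_that("snippy-style TSV reader feeds the annotator", {
  g <- tiny_genome()
  d <- withr::local_tempdir()
  path <- file.path(d, "snps.tab")
  writeLines(c("CHROM\tPOS\tTYPE\tREF\tALT\tEFFECT",
               sprintf("tiny\t%d\tsnp\tC\tG\tmissense_variant",
                       cds_pos(g, "geneA", 7))), path)
  v <- read_variants_snippy(path)
  expect_identical(v$type, "snp")
  res <- annotate_variants(g, v)
  expect_identical(res$effect, "missense")
})
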