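EFFECT_LEVELS <- c("synonymous", "missense", "nonsense", "start_loss",
                   "stop_loss", "frameshift", "inframe_indel", "intergenic")
LOF_EFFECTS <- c("nonsense", "frameshift", "start_loss")

#' Annotate variants against an annotated genome
#'
#' Classifies each variant into exactly one effect class by strand-aware codon
#' comparison against the reference: `synonymous`, `missense`, `nonsense`,
#' `start_loss` (start codon changed to a non-initiator), `stop_loss`,
#' `frameshift` (CDS indel with length not a multiple of 3), `inframe_indel`,
#' or `intergenic`. Multi-base substitutions confined to one codon are
#' classified jointly from the composite codon. A variant falling in several
#' overlapping CDS yields one row per locus. Functional variants are all
#' coding variants that alter the protein; loss-of-function variants are
#' nonsense, frameshift and start-loss.
#'
#' @param genome An [annotated_genome()].
#' @param variants Tibble with columns `pos` (1-based reference coordinate),
#'   `ref`, `alt` (uppercase A/C/G/T strings; indels in VCF anchor style).
#'   Column names `POS`/`REF`/`ALT` are also accepted.
#' @return Tibble: the input plus `type`, `locus_id`, `strand`, `codon_index`,
#'   `ref_codon`, `alt_codon`, `ref_aa`, `alt_aa`, `effect`, `is_functional`,
#'   `is_lof`, `is_category_change`.
#' @examples
#' scn <- evolution_scenario(n_genes = 5, mean_gene_len = 30, seed = 2)
#' g <- generate_ancestral_genome(scn)
#' annotate_variants(g, tibble::tibble(pos = 10L,
#'   ref = substr(g$seq, 10, 10),
#'   alt = setdiff(c("A", "C", "G", "T"), substr(g$seq, 10, 10))[1]))
#' @export
annotate_variants <- function(genome, variants) {
  stopifnot(is_annotated_genome(genome))
  v <- normalize_variants(variants)
  n <- nrow(v)
  if (n == 0L) return(empty_annotation())
  Lg <- genome_length(genome)
  if (any(v$pos < 1L | v$pos > Lg)) {
    abort("Variant position outside the reference sequence.")
  }
  obs_ref <- stringr::str_sub(genome$seq, v$pos, v$pos + nchar(v$ref) - 1L)
  if (any(obs_ref != v$ref)) {
    bad <- which(obs_ref != v$ref)[1]
    abort(sprintf(
      "Reference allele mismatch at position %d: expected '%s', genome has '%s'.",
      v$pos[bad], v$ref[bad], obs_ref[bad]))
  }
  v$type <- dplyr::case_when(
    nchar(v$ref) == 1L & nchar(v$alt) == 1L ~ "SNP",
    nchar(v$ref) == nchar(v$alt) ~ "MNV",
    nchar(v$ref) > nchar(v$alt) ~ "deletion",
    TRUE ~ "insertion"
  )

  f <- genome$features
  hits <- overlap_features(v, f)
  out <- dplyr::bind_rows(
    annotate_intergenic(v, hits),
    annotate_coding(genome, v, hits)
  )
  dplyr::arrange(out, .data$pos, .data$locus_id)
}

#' @rdname annotate_variants
#' @param pos,ref,alt Scalars describing a single variant.
#' @export
classify_variant <- function(genome, pos, ref, alt) {
  annotate_variants(genome, tibble(pos = as.integer(pos), ref = ref, alt = alt))
}

normalize_variants <- function(variants) {
  v <- as_tibble(variants)
  nm <- tolower(names(v))
  names(v)[match(c("pos", "ref", "alt"), nm)] <- c("pos", "ref", "alt")
  if (!all(c("pos", "ref", "alt") %in% names(v))) {
    abort("`variants` must have columns pos/ref/alt (or POS/REF/ALT).")
  }
  v$pos <- as.integer(v$pos)
  v$ref <- toupper(v$ref); v$alt <- toupper(v$alt)
  if (any(!nzchar(v$ref)) || any(!nzchar(v$alt)) ||
      any(grepl("[^ACGT]", c(v$ref, v$alt)))) {
    abort("Alleles must be non-empty uppercase A/C/G/T strings.")
  }
  v[, c("pos", "ref", "alt")]
}

# For each variant, the indices of features whose span overlaps the variant's
# reference footprint. Fast path for the usual sorted non-overlapping case.
overlap_features <- function(v, f) {
  vend <- v$pos + nchar(v$ref) - 1L
  if (nrow(f) == 0L) return(replicate(nrow(v), integer(0), simplify = FALSE))
  overlapping <- nrow(f) > 1 && any(f$start[-1] <= f$end[-nrow(f)])
  if (!overlapping) {
    k <- findInterval(v$pos, f$start)
    lapply(seq_len(nrow(v)), function(i) {
      hit <- integer(0)
      if (k[i] > 0 && v$pos[i] <= f$end[k[i]]) hit <- k[i]
      # footprint may also reach into the next feature (indel spanning)
      if (k[i] < nrow(f) && vend[i] >= f$start[k[i] + 1L]) hit <- c(hit, k[i] + 1L)
      hit
    })
  } else {
    lapply(seq_len(nrow(v)), function(i) {
      which(f$start <= vend[i] & f$end >= v$pos[i])
    })
  }
}

empty_annotation <- function() {
  tibble(pos = integer(0), ref = character(0), alt = character(0),
         type = character(0), locus_id = character(0), strand = character(0),
         codon_index = integer(0), ref_codon = character(0),
         alt_codon = character(0), ref_aa = character(0), alt_aa = character(0),
         effect = character(0), is_functional = logical(0), is_lof = logical(0),
         is_category_change = logical(0))
}

annotate_intergenic <- function(v, hits) {
  idx <- which(lengths(hits) == 0L)
  if (length(idx) == 0L) return(empty_annotation())
  tibble(
    pos = v$pos[idx], ref = v$ref[idx], alt = v$alt[idx], type = v$type[idx],
    locus_id = NA_character_, strand = NA_character_,
    codon_index = NA_integer_, ref_codon = NA_character_,
    alt_codon = NA_character_, ref_aa = NA_character_, alt_aa = NA_character_,
    effect = "intergenic", is_functional = FALSE, is_lof = FALSE,
    is_category_change = FALSE
  )
}

annotate_coding <- function(genome, v, hits) {
  rows <- tibble(vi = rep(seq_len(nrow(v)), lengths(hits)),
                 fi = unlist(hits, use.names = FALSE))
  if (nrow(rows) == 0L) return(empty_annotation())
  f <- genome$features
  cds <- all_cds_seqs(genome)

  snp <- v$type[rows$vi] %in% c("SNP", "MNV")
  out_list <- list()

  ## indels in CDS: frameshift vs in-frame by length difference
  if (any(!snp)) {
    r <- rows[!snp, ]
    ldiff <- abs(nchar(v$ref[r$vi]) - nchar(v$alt[r$vi]))
    eff <- ifelse(ldiff %% 3L == 0L, "inframe_indel", "frameshift")
    out_list$indel <- tibble(
      pos = v$pos[r$vi], ref = v$ref[r$vi], alt = v$alt[r$vi],
      type = v$type[r$vi],
      locus_id = f$locus_id[r$fi], strand = f$strand[r$fi],
      codon_index = NA_integer_, ref_codon = NA_character_,
      alt_codon = NA_character_, ref_aa = NA_character_,
      alt_aa = NA_character_, effect = eff,
      is_functional = TRUE, is_lof = eff == "frameshift",
      is_category_change = FALSE
    )
  }

  ## single-base substitutions: fully vectorized strand-aware codon lookup
  single <- snp & v$type[rows$vi] == "SNP"
  if (any(single)) {
    r <- rows[single, ]
    out_list$snp <- classify_snps_vec(genome, cds, f, r$fi, v$pos[r$vi],
                                      v$ref[r$vi], v$alt[r$vi])
  }

  ## multi-base substitutions: per-variant composite-codon path
  mnv <- snp & v$type[rows$vi] == "MNV"
  if (any(mnv)) {
    r <- rows[mnv, ]
    out_list$mnv <- purrr::map_dfr(seq_len(nrow(r)), function(j) {
      vi <- r$vi[j]; fi <- r$fi[j]
      classify_substitution(genome, cds, f[fi, ], v$pos[vi], v$ref[vi],
                            v$alt[vi], v$type[vi])
    })
  }
  dplyr::bind_rows(out_list)
}

# Vectorized classifier for 1-bp substitutions inside CDS.
classify_snps_vec <- function(genome, cds, f, fi, pos, ref, alt) {
  strand <- f$strand[fi]
  off <- ifelse(strand == "+", pos - f$start[fi] + 1L, f$end[fi] - pos + 1L)
  n_codons <- (f$end[fi] - f$start[fi] + 1L) %/% 3L
  ci <- (off - 1L) %/% 3L + 1L
  pic <- (off - 1L) %% 3L + 1L
  cds_vec <- unname(cds[f$locus_id[fi]])
  cstart <- off - pic + 1L
  ref_cd <- stringr::str_sub(cds_vec, cstart, cstart + 2L)
  alt_b <- ifelse(strand == "-", unname(COMPLEMENT[alt]), alt)
  alt_cd <- paste0(stringr::str_sub(ref_cd, 1L, pic - 1L), alt_b,
                   stringr::str_sub(ref_cd, pic + 1L, 3L))
  ref_aa <- unname(GENETIC_CODE_STD[ref_cd])
  alt_aa <- unname(GENETIC_CODE_STD[alt_cd])
  if (anyNA(ref_aa)) abort("Reference CDS contains invalid codons.")

  at_start <- ci == 1L
  start_ok <- alt_cd %in% START_CODONS
  effect <- dplyr::case_when(
    at_start & !start_ok ~ "start_loss",
    at_start & start_ok ~ "synonymous",
    ref_aa == "*" & alt_aa == "*" ~ "synonymous",
    ref_aa == "*" & alt_aa != "*" ~ "stop_loss",
    alt_aa == "*" ~ "nonsense",
    ref_aa == alt_aa ~ "synonymous",
    TRUE ~ "missense"
  )
  ref_aa[at_start] <- "M"
  alt_aa[at_start & start_ok] <- "M"
  is_mis <- effect == "missense"
  cat_change <- rep(FALSE, length(effect))
  if (any(is_mis)) {
    cat_change[is_mis] <- aa_category(ref_aa[is_mis]) != aa_category(alt_aa[is_mis])
  }
  tibble(
    pos = pos, ref = ref, alt = alt, type = "SNP",
    locus_id = f$locus_id[fi], strand = strand,
    codon_index = as.integer(ci), ref_codon = ref_cd, alt_codon = alt_cd,
    ref_aa = ref_aa, alt_aa = alt_aa, effect = effect,
    is_functional = !effect %in% c("synonymous", "intergenic"),
    is_lof = effect %in% LOF_EFFECTS,
    is_category_change = cat_change
  )
}

# Classify one (possibly multi-base) substitution against one CDS.
classify_substitution <- function(genome, cds, feat, pos, ref, alt, type) {
  s <- cds[[feat$locus_id]]
  L <- nchar(s)
  n_codons <- L %/% 3L
  width <- nchar(ref)
  gpos <- pos:(pos + width - 1L)
  inside <- gpos >= feat$start & gpos <= feat$end
  gpos <- gpos[inside]
  ref_b <- strsplit(ref, "")[[1]][inside]
  alt_b <- strsplit(alt, "")[[1]][inside]
  off <- if (feat$strand == "+") gpos - feat$start + 1L else feat$end - gpos + 1L
  if (feat$strand == "-") {
    ref_b <- unname(COMPLEMENT[ref_b]); alt_b <- unname(COMPLEMENT[alt_b])
  }
  ci <- sort(unique((off - 1L) %/% 3L + 1L))
  chars <- strsplit(s, "")[[1]]
  alt_chars <- chars
  alt_chars[off] <- alt_b
  get_codons <- function(ch, idx) {
    vapply(idx, function(k) paste(ch[(3L * k - 2L):(3L * k)], collapse = ""),
           character(1))
  }
  ref_cd <- get_codons(chars, ci)
  alt_cd <- get_codons(alt_chars, ci)
  ref_aa <- translate_codons(ref_cd)
  alt_aa <- translate_codons(alt_cd)

  effect <- composite_effect(ci, ref_aa, alt_aa, alt_cd, n_codons)
  first <- 1L
  is_mis <- effect == "missense"
  tibble(
    pos = pos, ref = ref, alt = alt, type = type,
    locus_id = feat$locus_id, strand = feat$strand,
    codon_index = ci[first],
    ref_codon = ref_cd[first], alt_codon = alt_cd[first],
    ref_aa = ref_aa[first], alt_aa = alt_aa[first],
    effect = effect,
    is_functional = !effect %in% c("synonymous", "intergenic"),
    is_lof = effect %in% LOF_EFFECTS,
    is_category_change = is_mis &&
      any(aa_category(ref_aa[ref_aa != "*" & alt_aa != "*"]) !=
            aa_category(alt_aa[ref_aa != "*" & alt_aa != "*"]))
  )
}

# One effect class for a set of affected codons of a single CDS.
composite_effect <- function(ci, ref_aa, alt_aa, alt_cd, n_codons) {
  if (any(ci == 1L)) {
    # annotated start: ATG/GTG/TTG all read as Met (bacterial initiator tRNA)
    k <- which(ci == 1L)
    if (!alt_cd[k] %in% START_CODONS) return("start_loss")
    ref_aa[k] <- "M"; alt_aa[k] <- "M"
  }
  if (any(ci == n_codons)) {
    k <- which(ci == n_codons)
    if (ref_aa[k] == "*" && alt_aa[k] != "*") return("stop_loss")
  }
  if (any(alt_aa == "*" & ref_aa != "*")) return("nonsense")
  if (identical(ref_aa, alt_aa)) return("synonymous")
  "missense"
}

#' Aggregate annotated variants into per-gene mutation profiles
#'
#' One row per locus carrying at least one variant (optionally all loci),
#' with the counts behind hotspot detection and genome-wide summaries:
#' total variants, synonymous, functional, loss-of-function, and amino-acid
#' category changes.
#'
#' @param annotated Output of [annotate_variants()].
#' @param genome The [annotated_genome()] the variants were classified against.
#' @param include_zero Include loci with no variants (zero counts)?
#' @return Tibble with `locus_id`, `gene_length_bp`, `n_total`,
#'   `n_synonymous`, `n_functional`, `n_lof`, `n_category_changes`.
#' @export
aggregate_gene_profiles <- function(annotated, genome, include_zero = FALSE) {
  stopifnot(is_annotated_genome(genome))
  a <- as_tibble(annotated)
  coding <- a[!is.na(a$locus_id), , drop = FALSE]
  unknown <- setdiff(unique(coding$locus_id), genome$features$locus_id)
  if (length(unknown) > 0) {
    abort(sprintf("Variants reference loci absent from the genome: %s",
                  paste(unknown, collapse = ", ")))
  }
  prof <- coding %>%
    dplyr::group_by(.data$locus_id) %>%
    dplyr::summarise(
      n_total = dplyr::n(),
      n_synonymous = sum(.data$effect == "synonymous"),
      n_functional = sum(.data$is_functional),
      n_lof = sum(.data$is_lof),
      n_category_changes = sum(.data$is_category_change),
      .groups = "drop"
    )
  lengths_tbl <- tibble(
    locus_id = genome$features$locus_id,
    gene_length_bp = genome$features$end - genome$features$start + 1L
  )
  if (include_zero) {
    prof <- dplyr::left_join(lengths_tbl["locus_id"], prof, by = "locus_id") %>%
      dplyr::mutate(dplyr::across(dplyr::starts_with("n_"),
                                  ~ tidyr::replace_na(.x, 0L)))
  }
  dplyr::left_join(prof, lengths_tbl, by = "locus_id") %>%
    dplyr::relocate("gene_length_bp", .after = "locus_id")
}
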