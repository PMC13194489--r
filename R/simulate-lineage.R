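#' Enumerate every possible substitution in a genome
#'
#' Classifies all single-base changes of a genome up front: for every coding
#' site in codons 2..(n-1) of each CDS (annotated start and stop codons are
#' excluded; see the methods vignette) and each of its three alternative
#' bases, the substitution is labelled synonymous, missense or nonsense, and
#' flagged as transition or transversion. Intergenic positions are listed
#' separately. The table drives exact planting of mutation spectra in
#' [evolve_lineage()] and can be precomputed once per ancestor when simulating
#' many lineages.
#'
#' @param genome An [annotated_genome()].
#' @return A list with elements `coding` (tibble: `pos`, `ref`, `alt`,
#'   `class`, `ts`, `locus_id`), `intergenic` (tibble: `pos`, `ref`),
#'   `n_sites`, `s_sites` (Nei-Gojobori site totals over the enumerated
#'   codons).
#' @export
enumerate_sites <- function(genome) {
  stopifnot(is_annotated_genome(genome))
  f <- genome$features
  cds <- all_cds_seqs(genome)
  len <- f$end - f$start + 1L

  keep <- len >= 9L  # need at least one internal codon
  fk <- f[keep, , drop = FALSE]
  lenk <- len[keep]
  n_off <- lenk - 6L
  gene_idx <- rep.int(seq_len(nrow(fk)), n_off)
  offs <- sequence(n_off) + 3L

  cds_vec <- unname(cds[fk$locus_id])[gene_idx]
  base_cds <- stringr::str_sub(cds_vec, offs, offs)
  pic <- (offs - 1L) %% 3L + 1L
  cstart <- offs - pic + 1L
  codon <- stringr::str_sub(cds_vec, cstart, cstart + 2L)

  sense <- codon %in% SENSE_CODONS
  gene_idx <- gene_idx[sense]; offs <- offs[sense]
  base_cds <- base_cds[sense]; pic <- pic[sense]; codon <- codon[sense]

  strand <- fk$strand[gene_idx]
  pos <- ifelse(strand == "+",
                fk$start[gene_idx] + offs - 1L,
                fk$end[gene_idx] - offs + 1L)

  # expand to the three alternative bases per site
  parts <- lapply(BASES, function(b) {
    sel <- base_cds != b
    list(i = which(sel), alt_cds = rep(b, sum(sel)))
  })
  idx <- unlist(lapply(parts, `[[`, "i"), use.names = FALSE)
  alt_cds <- unlist(lapply(parts, `[[`, "alt_cds"), use.names = FALSE)

  codon_e <- codon[idx]; pic_e <- pic[idx]
  alt_codon <- paste0(
    stringr::str_sub(codon_e, 1L, pic_e - 1L),
    alt_cds,
    stringr::str_sub(codon_e, pic_e + 1L, 3L)
  )
  aa_ref <- GENETIC_CODE_STD[codon_e]
  aa_alt <- GENETIC_CODE_STD[alt_codon]
  class <- ifelse(aa_alt == "*", "nonsense",
                  ifelse(aa_ref == aa_alt, "synonymous", "missense"))
  ts <- is_transition(base_cds[idx], alt_cds)
  neg <- strand[idx] == "-"
  alt_fwd <- alt_cds
  if (any(neg)) alt_fwd[neg] <- unname(COMPLEMENT[alt_cds[neg]])
  ref_fwd <- stringr::str_sub(genome$seq, pos[idx], pos[idx])

  coding <- tibble(
    pos = as.integer(pos[idx]),
    ref = ref_fwd,
    alt = alt_fwd,
    class = unname(class),
    ts = ts,
    locus_id = fk$locus_id[gene_idx[idx]]
  )

  covered <- rep(FALSE, genome_length(genome))
  for (i in seq_len(nrow(f))) covered[f$start[i]:f$end[i]] <- TRUE
  ig_pos <- which(!covered)
  intergenic <- tibble(
    pos = ig_pos,
    ref = stringr::str_sub(genome$seq, ig_pos, ig_pos)
  )

  list(
    coding = coding,
    intergenic = intergenic,
    s_sites = sum(coding$class == "synonymous") / 3,
    n_sites = sum(coding$class != "synonymous") / 3
  )
}

# Solve for the per-alternative transition weight w such that the overall
# expected transition fraction across all sampled classes equals
# kappa / (1 + kappa). theta_c(w) = w*T_c / (w*T_c + V_c).
solve_ts_weight <- function(p, T, V, kappa) {
  target <- kappa / (1 + kappa)
  # classes with zero pools must have p = 0; normalize over active classes
  act <- p > 0
  fr <- function(w) {
    th <- (w * T[act]) / (w * T[act] + V[act])
    sum(p[act] * th) / sum(p[act]) - target
  }
  if (all(!act)) return(1)
  lo <- fr(1e-9); hi <- fr(1e9)
  if (lo > 0 || hi < 0) {
    abort("Requested kappa is unreachable for this genome's mutation pools.")
  }
  stats::uniroot(fr, lower = 1e-9, upper = 1e9, tol = 1e-12)$root
}

# Weighted sampling without replacement via exponential keys.
sample_weighted <- function(n_pool, size, w) {
  if (size == 0L) return(integer(0))
  key <- stats::rexp(n_pool) / w
  order(key)[seq_len(size)]
}

#' Evolve a descendant lineage from an ancestral genome
#'
#' Plants `n_snps` substitutions so that the realized transition/transversion
#' ratio matches `kappa` and the realized genome-wide dN/dS (by Nei-Gojobori
#' counting against the same reference) matches `omega` in expectation, with a
#' `lof_rate` share of coding substitutions made nonsense. Hotspot loci
#' receive functional substitutions at `multiplier` times the background
#' density. Large deletions (and optional 1-bp frameshift deletions in CDS
#' interiors) are applied to the descendant sequence after the substitutions.
#' Every planted event is recorded in a truth table whose per-variant effect
#' classes are, by construction, exactly what [annotate_variants()] reports
#' for the same records.
#'
#' @param genome Ancestor from [generate_ancestral_genome()] (or any
#'   [annotated_genome()]).
#' @param scenario An [evolution_scenario()]; hotspot locus IDs must exist in
#'   the genome.
#' @param sites Optional precomputed [enumerate_sites()] table for `genome`.
#' @return A list of class `evolved_lineage`: `ancestor`, `descendant`
#'   ([annotated_genome()]), `variants` (tibble: `pos`, `ref`, `alt`, `type`),
#'   and `truth` (class `lineage_truth`: per-variant classes, realized counts,
#'   per-gene functional densities, deleted intervals).
#' @export
evolve_lineage <- function(genome, scenario, sites = NULL) {
  stopifnot(is_annotated_genome(genome), inherits(scenario, "evolution_scenario"))
  hot <- scenario$hotspot_loci
  if (!is.null(hot) && !all(names(hot) %in% genome$features$locus_id)) {
    abort("All hotspot loci must be loci of the genome.")
  }
  sites <- sites %||% enumerate_sites(genome)
  Lg <- genome_length(genome)

  with_seed(derive_seed(scenario$seed, 2L), {
    ## -- large deletions -----------------------------------------------------
    del <- plant_deletions(scenario$deletion_spans, Lg, genome$features, hot)

    in_del <- function(p) {
      if (nrow(del) == 0L) rep(FALSE, length(p))
      else {
        hit <- rep(FALSE, length(p))
        for (i in seq_len(nrow(del))) hit <- hit | (p >= del$start[i] & p <= del$end[i])
        hit
      }
    }

    coding <- sites$coding[!in_del(sites$coding$pos), , drop = FALSE]
    ig <- sites$intergenic[!in_del(sites$intergenic$pos), , drop = FALSE]

    ## -- class target proportions -------------------------------------------
    n_snps <- scenario$n_snps
    variants <- empty_variants()
    if (n_snps > 0) {
      R <- sites$n_sites / sites$s_sites
      p_syn <- 1 / (1 + scenario$omega * R)
      p_fun <- 1 - p_syn
      if (scenario$lof_rate > p_fun + 1e-12) {
        abort(sprintf(
          "lof_rate (%.3g) exceeds the achievable functional fraction (%.3g) for this omega.",
          scenario$lof_rate, p_fun))
      }
      p_non <- scenario$lof_rate
      p_mis <- p_fun - p_non
      n_cds_sites <- length(unique(coding$pos))
      n_ig_sites <- nrow(ig)
      if (n_cds_sites == 0L) {
        abort("Scenario requires coding substitutions but the genome has no usable coding sites.")
      }
      p_coding <- n_cds_sites / (n_cds_sites + n_ig_sites)
      p <- c(intergenic = 1 - p_coding,
             synonymous = p_coding * p_syn,
             missense = p_coding * p_mis,
             nonsense = p_coding * p_non)

      ## -- hotspot weights and transition-weight solve -----------------------
      mult <- stats::setNames(rep(1, nrow(genome$features)), genome$features$locus_id)
      if (!is.null(hot)) mult[names(hot)] <- hot
      hw <- unname(mult[coding$locus_id])
      w_fun <- ifelse(coding$class == "synonymous", 1, hw)

      tallies <- function(cl) {
        sel <- coding$class == cl
        c(T = sum(w_fun[sel][coding$ts[sel]]),
          V = sum(w_fun[sel][!coding$ts[sel]]))
      }
      t_syn <- tallies("synonymous"); t_mis <- tallies("missense")
      t_non <- tallies("nonsense")
      Tc <- c(n_ig_sites, t_syn["T"], t_mis["T"], t_non["T"])
      Vc <- c(2 * n_ig_sites, t_syn["V"], t_mis["V"], t_non["V"])
      for (k in 2:4) if (p[k] > 0 && Tc[k] + Vc[k] == 0) {
        abort(sprintf("omega/lof_rate unreachable: no candidate '%s' substitutions exist.",
                      names(p)[k]))
      }
      w <- solve_ts_weight(p, Tc, Vc, scenario$kappa)

      ## -- draw class counts and sample sites --------------------------------
      counts <- stats::rmultinom(1, n_snps, p)[, 1]
      picks <- list()
      for (cl in c("synonymous", "missense", "nonsense")) {
        nc <- counts[[cl]]
        if (nc == 0L) next
        rows <- which(coding$class == cl)
        if (nc > length(rows)) abort(sprintf("Not enough candidate '%s' sites.", cl))
        wt <- w_fun[rows] * ifelse(coding$ts[rows], w, 1)
        sel <- rows[sample_weighted(length(rows), nc, wt)]
        picks[[cl]] <- coding[sel, c("pos", "ref", "alt", "class", "ts", "locus_id")]
      }
      if (counts[["intergenic"]] > 0L) {
        nc <- counts[["intergenic"]]
        if (nc > nrow(ig)) abort("Not enough intergenic sites for the requested SNP count.")
        sel <- sample(nrow(ig), nc)
        refs <- ig$ref[sel]
        take_ts <- stats::runif(nc) < w / (w + 2)
        alts <- ifelse(take_ts, TRANSITION_PARTNER[refs],
                       vapply(refs, function(r) sample(setdiff(BASES, c(r, TRANSITION_PARTNER[[r]])), 1L),
                              character(1)))
        picks[["intergenic"]] <- tibble(
          pos = ig$pos[sel], ref = refs, alt = unname(alts),
          class = "intergenic", ts = unname(take_ts), locus_id = NA_character_)
      }
      variants <- dplyr::bind_rows(picks)

      ## -- resolve rare site collisions (one variant per site) --------------
      guard <- 0L
      while (anyDuplicated(variants$pos) && guard < 100L) {
        guard <- guard + 1L
        dup <- duplicated(variants$pos)
        keep <- variants[!dup, , drop = FALSE]
        for (i in which(dup)) {
          cl <- variants$class[i]
          if (cl == "intergenic") {
            free <- ig[!(ig$pos %in% keep$pos), , drop = FALSE]
            j <- sample(nrow(free), 1L)
            r <- free$ref[j]
            take_ts <- stats::runif(1) < w / (w + 2)
            a <- if (take_ts) TRANSITION_PARTNER[[r]] else
              sample(setdiff(BASES, c(r, TRANSITION_PARTNER[[r]])), 1L)
            keep <- dplyr::bind_rows(keep, tibble(
              pos = free$pos[j], ref = r, alt = a, class = cl,
              ts = take_ts, locus_id = NA_character_))
          } else {
            rows <- which(coding$class == cl & !(coding$pos %in% keep$pos))
            wt <- w_fun[rows] * ifelse(coding$ts[rows], w, 1)
            sel <- rows[sample_weighted(length(rows), 1L, wt)]
            keep <- dplyr::bind_rows(keep, coding[sel, c("pos", "ref", "alt", "class", "ts", "locus_id")])
          }
        }
        variants <- keep
      }
      variants$type <- "SNP"
    }

    ## -- 1-bp frameshift deletions in CDS interiors -------------------------
    n_indels <- as.integer(round(scenario$indel_rate * scenario$n_snps))
    indels <- empty_variants()
    if (n_indels > 0L) {
      cand <- unique(coding$pos)
      # avoid clashing with SNPs at the deleted base or at the VCF anchor base
      cand <- cand[!(cand %in% variants$pos) & !((cand - 1L) %in% variants$pos)]
      cand <- cand[cand > 1L]
      if (n_indels > length(cand)) abort("Not enough CDS-interior sites for the requested indels.")
      ip <- sort(sample(cand, n_indels))
      # keep indels non-adjacent so every anchor coordinate stays unique
      while (any(diff(ip) <= 1L)) {
        drop <- which(diff(ip) <= 1L)[1] + 1L
        pool <- setdiff(cand, c(ip, ip + 1L, ip - 1L))
        ip <- sort(c(ip[-drop], sample(pool, 1L)))
      }
      loc <- coding$locus_id[match(ip, coding$pos)]
      indels <- tibble(
        pos = ip - 1L,
        ref = stringr::str_sub(genome$seq, ip - 1L, ip),
        alt = stringr::str_sub(genome$seq, ip - 1L, ip - 1L),
        class = "frameshift", ts = NA, locus_id = loc, type = "deletion")
    }

    ## -- apply to the descendant sequence -----------------------------------
    chars <- strsplit(genome$seq, "", fixed = TRUE)[[1]]
    if (nrow(variants) > 0) chars[variants$pos] <- variants$alt
    drop_pos <- logical(length(chars))
    if (nrow(indels) > 0) drop_pos[indels$pos + 1L] <- TRUE
    if (nrow(del) > 0) for (i in seq_len(nrow(del))) drop_pos[del$start[i]:del$end[i]] <- TRUE
    desc_seq <- paste(chars[!drop_pos], collapse = "")

    removed <- c(
      if (nrow(del) > 0) lapply(seq_len(nrow(del)), function(i) c(del$start[i], del$end[i])),
      if (nrow(indels) > 0) lapply(indels$pos + 1L, function(p) c(p, p))
    )
    desc_feats <- shift_features(genome$features, removed)
    descendant <- annotated_genome(paste0(genome$id, "_desc"), desc_seq, desc_feats)

    all_var <- dplyr::arrange(dplyr::bind_rows(variants, indels), .data$pos)
    truth <- build_truth(all_var, del, indels, genome, mult_tbl = scenario$hotspot_loci)

    structure(
      list(ancestor = genome,
           descendant = descendant,
           variants = all_var[, c("pos", "ref", "alt", "type")],
           truth = truth),
      class = "evolved_lineage"
    )
  })
}

empty_variants <- function() {
  tibble(pos = integer(0), ref = character(0), alt = character(0),
         class = character(0), ts = logical(0), locus_id = character(0),
         type = character(0))
}

# Place non-overlapping deletion intervals avoiding hotspot CDS.
plant_deletions <- function(spans, genome_len, features, hotspots) {
  if (length(spans) == 0L) {
    return(tibble(start = integer(0), end = integer(0), length = integer(0)))
  }
  avoid <- features[features$locus_id %in% names(hotspots), , drop = FALSE]
  placed <- tibble(start = integer(0), end = integer(0), length = integer(0))
  for (s in sort(spans, decreasing = TRUE)) {
    ok <- FALSE
    for (try in 1:2000) {
      st <- sample.int(genome_len - s + 1L, 1L)
      en <- st + s - 1L
      clash <- any(placed$start <= en & placed$end >= st) ||
        (nrow(avoid) > 0 && any(avoid$start <= en & avoid$end >= st))
      if (!clash) { ok <- TRUE; break }
    }
    if (!ok) abort("Could not place deletion spans without overlapping hotspot CDS.")
    placed <- dplyr::bind_rows(placed, tibble(start = st, end = en, length = s))
  }
  dplyr::arrange(placed, .data$start)
}

# Shift feature coordinates for removed intervals; drop features overlapping one.
shift_features <- function(features, removed) {
  if (length(removed) == 0L) return(features)
  rs <- vapply(removed, `[`, integer(1), 1L)
  re <- vapply(removed, `[`, integer(1), 2L)
  o <- order(rs); rs <- rs[o]; re <- re[o]
  lens <- re - rs + 1L
  cum <- cumsum(lens)
  # for a position outside every removed interval, the shift is the total
  # length of intervals ending before it
  shift_at <- function(p) {
    k <- findInterval(p, re)
    ifelse(k > 0, cum[pmax(k, 1L)], 0L)
  }
  keep <- rep(TRUE, nrow(features))
  for (i in seq_along(rs)) {
    keep <- keep & !(features$start <= re[i] & features$end >= rs[i])
  }
  f <- features[keep, , drop = FALSE]
  f$start <- f$start - as.integer(shift_at(f$start))
  f$end <- f$end - as.integer(shift_at(f$end))
  f
}

build_truth <- function(all_var, del, indels, genome, mult_tbl) {
  snps <- all_var[all_var$type == "SNP", , drop = FALSE]
  counts <- tibble(
    n_snps = nrow(snps),
    n_indels = nrow(indels),
    n_ts = sum(snps$ts %in% TRUE),
    n_tv = sum(snps$ts %in% FALSE),
    n_synonymous = sum(snps$class == "synonymous"),
    n_missense = sum(snps$class == "missense"),
    n_nonsense = sum(snps$class == "nonsense"),
    n_intergenic = sum(snps$class == "intergenic"),
    n_functional = sum(all_var$class %in% c("missense", "nonsense", "frameshift")),
    n_lof = sum(all_var$class %in% c("nonsense", "frameshift"))
  )
  f <- genome$features
  fun <- all_var[all_var$class %in% c("missense", "nonsense", "frameshift") &
                   !is.na(all_var$locus_id), , drop = FALSE]
  gene_fun <- fun %>%
    dplyr::count(.data$locus_id, name = "n_functional") %>%
    dplyr::left_join(tibble(locus_id = f$locus_id,
                            gene_length_bp = f$end - f$start + 1L),
                     by = "locus_id") %>%
    dplyr::mutate(density_per_kb = .data$n_functional / (.data$gene_length_bp / 1000))
  gene_fun$multiplier <- if (is.null(mult_tbl)) {
    rep(1, nrow(gene_fun))
  } else {
    m <- unname(mult_tbl[gene_fun$locus_id])
    ifelse(is.na(m), 1, m)
  }
  dels <- dplyr::bind_rows(
    tibble(start = integer(0), end = integer(0), length = integer(0),
           kind = character(0)),
    if (nrow(del) > 0) dplyr::mutate(del, kind = "span"),
    if (nrow(indels) > 0) tibble(start = indels$pos + 1L, end = indels$pos + 1L,
                                 length = 1L, kind = "frameshift")
  )
  structure(
    list(variants = all_var, counts = counts, gene_functional = gene_fun,
         deletions = dplyr::arrange(dels, .data$start)),
    class = "lineage_truth"
  )
}

#' @export
print.evolved_lineage <- function(x, ...) {
  ct <- x$truth$counts
  cat(sprintf(
    "<evolved_lineage> %s -> %s: %d SNPs (%d Ts / %d Tv), %d indels, %d deletions\n",
    x$ancestor$id, x$descendant$id, ct$n_snps, ct$n_ts, ct$n_tv, ct$n_indels,
    sum(x$truth$deletions$kind == "span")))
  invisible(x)
}

#' Alignment blocks implied by a lineage's planted deletions
#'
#' Converts the planted deletion intervals of an evolved lineage into
#' coords-style alignment blocks between the reference (ancestor) and query
#' (descendant): maximal reference segments untouched by any deletion, with
#' query coordinates offset by the cumulative deleted length. Feeding these to
#' [find_large_gaps()] recovers the planted deletions exactly.
#'
#' @param lineage An `evolved_lineage` from [evolve_lineage()].
#' @return Tibble with `ref_start`, `ref_end`, `qry_start`, `qry_end`,
#'   `orientation`.
#' @export
alignment_blocks <- function(lineage) {
  stopifnot(inherits(lineage, "evolved_lineage"))
  dels <- lineage$truth$deletions
  L <- genome_length(lineage$ancestor)
  if (nrow(dels) == 0L) {
    return(tibble(ref_start = 1L, ref_end = L, qry_start = 1L, qry_end = L,
                  orientation = "+"))
  }
  starts <- c(1L, dels$end + 1L)
  ends <- c(dels$start - 1L, L)
  keep <- ends >= starts
  starts <- starts[keep]; ends <- ends[keep]
  cum_before <- vapply(starts, function(s) sum(dels$length[dels$end < s]), numeric(1))
  tibble(
    ref_start = starts, ref_end = ends,
    qry_start = as.integer(starts - cum_before),
    qry_end = as.integer(ends - cum_before),
    orientation = "+"
  )
}
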