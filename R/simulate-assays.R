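#' Generate a matched pair of toy protein structure models
#'
#' Builds a protein-like C-alpha trace (persistent random walk, 3.8 A steps)
#' with a run-structured secondary-structure string and optional heme iron
#' pseudo-atoms, then derives a second model by applying a random proper rigid
#' motion plus (i) Gaussian coordinate displacement at `n_perturbed` randomly
#' chosen residues, (ii) secondary-structure letter changes at exactly
#' `n_ss_changes` positions, and (iii) a displacement of length `heme_shift`
#' in a random direction for every heme iron. With all perturbation knobs at
#' zero the pair is related by a pure rigid motion.
#'
#' @param length Number of residues (>= 3).
#' @param n_perturbed Residues receiving Gaussian coordinate noise.
#' @param displacement SD (A) of the per-coordinate Gaussian noise.
#' @param n_ss_changes Number of secondary-structure positions changed.
#' @param n_hemes Number of heme iron pseudo-atoms.
#' @param heme_shift Displacement length (A) applied to every heme iron.
#' @param seed Integer seed.
#' @return List with elements `a` and `b` ([structure_model()]s),
#'   `perturbed_idx`, `ss_changed_idx`.
#' @export
generate_structure_pair <- function(length, n_perturbed = 0, displacement = 0,
                                    n_ss_changes = 0, n_hemes = 0,
                                    heme_shift = 0, seed = 1L) {
  if (length < 3) abort("`length` must be at least 3 residues.")
  if (n_perturbed > length) abort("`n_perturbed` cannot exceed `length`.")
  if (n_ss_changes > length) abort("`n_ss_changes` cannot exceed `length`.")
  with_seed(derive_seed(seed, 3L), {
    xyz <- matrix(0, length, 3)
    dir <- c(1, 0, 0)
    for (i in 2:length) {
      dir <- dir + 0.6 * stats::rnorm(3)
      dir <- dir / sqrt(sum(dir^2))
      xyz[i, ] <- xyz[i - 1, ] + 3.8 * dir
    }
    ss <- character(0)
    while (sum(nchar(ss)) < length) {
      ss <- c(ss, strrep(sample(c("H", "E", "C"), 1), sample(3:12, 1)))
    }
    ss <- substr(paste(ss, collapse = ""), 1, length)

    hemes <- NULL
    if (n_hemes > 0) {
      idx <- round(seq(1, length, length.out = n_hemes + 2))[2:(n_hemes + 1)]
      hemes <- xyz[idx, , drop = FALSE] + matrix(stats::rnorm(3 * n_hemes, sd = 1),
                                                 n_hemes, 3)
    }
    a <- structure_model("model_a", xyz, ss, hemes)

    rot <- random_rotation()
    trans <- stats::runif(3, -20, 20)
    xyz_b <- xyz %*% rot + matrix(trans, length, 3, byrow = TRUE)
    perturbed_idx <- integer(0)
    if (n_perturbed > 0) {
      perturbed_idx <- sort(sample(length, n_perturbed))
      xyz_b[perturbed_idx, ] <- xyz_b[perturbed_idx, ] +
        matrix(stats::rnorm(3 * n_perturbed, sd = displacement), n_perturbed, 3)
    }
    ss_b <- strsplit(ss, "")[[1]]
    ss_changed_idx <- integer(0)
    if (n_ss_changes > 0) {
      ss_changed_idx <- sort(sample(length, n_ss_changes))
      ss_b[ss_changed_idx] <- vapply(ss_b[ss_changed_idx], function(s) {
        sample(setdiff(c("H", "E", "C"), s), 1)
      }, character(1))
    }
    hemes_b <- NULL
    if (n_hemes > 0) {
      hemes_b <- hemes %*% rot + matrix(trans, n_hemes, 3, byrow = TRUE)
      if (heme_shift > 0) {
        d <- matrix(stats::rnorm(3 * n_hemes), n_hemes, 3)
        d <- d / sqrt(rowSums(d^2)) * heme_shift
        hemes_b <- hemes_b + d
      }
    }
    b <- structure_model("model_b", xyz_b, paste(ss_b, collapse = ""), hemes_b)
    list(a = a, b = b, perturbed_idx = perturbed_idx,
         ss_changed_idx = ss_changed_idx)
  })
}

# Uniform random proper rotation (QR of a Gaussian matrix, det corrected).
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  q <- qr.Q(qr_)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' Generate a synthetic qRT-PCR CT table
#'
#' Simulates threshold-cycle values consistent with the 2^-ddCt model: the
#' housekeeping gene amplifies at `housekeeping_ct` cycles in every sample,
#' target genes at `base_ct` in the reference strain, and a strain with a
#' planted fold change f amplifies log2(f) cycles earlier. Gaussian cycle
#' noise with SD `noise_sd` is added to every CT value, so
#' [delta_delta_ct()] recovers the planted folds in (geometric) expectation.
#'
#' @param folds Tibble with columns `strain`, `gene`, `fold` (planted fold
#'   change relative to the reference strain; all > 0), and optionally
#'   `condition`.
#' @param reference_strain Reference strain name (must appear in `folds` or is
#'   added with fold 1 for every gene).
#' @param housekeeping_gene Housekeeping gene name.
#' @param housekeeping_ct,base_ct Mean CT of the housekeeping gene / of target
#'   genes in the reference strain.
#' @param noise_sd SD of CT noise, in cycles.
#' @param replicates Replicates per strain x condition.
#' @param seed Integer seed.
#' @return Tibble with `strain`, `condition`, `gene`, `replicate`, `ct`.
#' @export
generate_ct_table <- function(folds, reference_strain,
                              housekeeping_gene = "recA",
                              housekeeping_ct = 18, base_ct = 24,
                              noise_sd = 0.3, replicates = 3, seed = 1L) {
  folds <- as_tibble(folds)
  if (!all(c("strain", "gene", "fold") %in% names(folds))) {
    abort("`folds` must have columns strain, gene, fold.")
  }
  if (any(folds$fold <= 0)) abort("All planted folds must be positive.")
  if (replicates < 1) abort("`replicates` must be >= 1.")
  if (!"condition" %in% names(folds)) folds$condition <- "condition1"
  genes <- unique(folds$gene)
  conds <- unique(folds$condition)
  if (!reference_strain %in% folds$strain) {
    folds <- dplyr::bind_rows(
      folds,
      tidyr::expand_grid(strain = reference_strain, gene = genes,
                         condition = conds) %>% dplyr::mutate(fold = 1))
  }
  with_seed(derive_seed(seed, 4L), {
    full <- tidyr::expand_grid(
      dplyr::distinct(folds, .data$strain, .data$condition, .data$gene,
                      .data$fold),
      replicate = seq_len(replicates)
    )
    target <- full %>%
      dplyr::mutate(ct = base_ct - log2(.data$fold) +
                      stats::rnorm(dplyr::n(), sd = noise_sd)) %>%
      dplyr::select("strain", "condition", "gene", "replicate", "ct")
    hk <- tidyr::expand_grid(
      dplyr::distinct(folds, .data$strain, .data$condition),
      replicate = seq_len(replicates)
    ) %>%
      dplyr::mutate(gene = housekeeping_gene,
                    ct = housekeeping_ct + stats::rnorm(dplyr::n(), sd = noise_sd)) %>%
      dplyr::select("strain", "condition", "gene", "replicate", "ct")
    dplyr::arrange(dplyr::bind_rows(target, hk),
                   .data$condition, .data$strain, .data$gene, .data$replicate)
  })
}

#' Generate synthetic exponential growth curves
#'
#' Values follow y0 * exp(k t), optionally capped at a plateau, with
#' multiplicative Gaussian noise: y * (1 + e), e ~ N(0, noise_sd). One curve
#' per strain and replicate.
#'
#' @param k Named numeric vector of specific growth rates per strain (per unit
#'   of `time_unit`).
#' @param t_grid Strictly increasing time points.
#' @param y0 Initial value.
#' @param noise_sd Relative noise SD.
#' @param replicates Replicates per strain.
#' @param plateau Carrying capacity cap (default none).
#' @param time_unit Time base tag, e.g. `"day"` or `"h"`.
#' @param seed Integer seed.
#' @return Tibble with `strain`, `replicate`, `time`, `value`, `time_unit`.
#' @export
generate_growth_curves <- function(k, t_grid, y0 = 0.01, noise_sd = 0,
                                   replicates = 1, plateau = Inf,
                                   time_unit = "day", seed = 1L) {
  if (length(t_grid) == 0) abort("`t_grid` must be non-empty.")
  if (is.unsorted(t_grid, strictly = TRUE)) abort("`t_grid` must be strictly increasing.")
  if (any(!is.finite(k))) abort("All growth rates must be finite.")
  if (is.null(names(k))) names(k) <- paste0("strain", seq_along(k))
  with_seed(derive_seed(seed, 5L), {
    tidyr::expand_grid(strain = names(k), replicate = seq_len(replicates),
                       time = t_grid) %>%
      dplyr::mutate(
        value = pmin(y0 * exp(unname(k[.data$strain]) * .data$time), plateau) *
          (1 + stats::rnorm(dplyr::n(), sd = noise_sd)),
        time_unit = time_unit
      )
  })
}
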