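#' Relative expression by the 2^-ddCt method
#'
#' For every replicate, dCt = CT(gene) - CT(housekeeping); ddCt subtracts the
#' mean dCt of the reference strain for the same gene and condition; the fold
#' change is 2^-ddCt. Replicates are aggregated on the log2 scale (geometric
#' mean fold), so the reference strain's mean fold is exactly 1 for every
#' gene and condition, and adding a constant to every CT value of a sample
#' leaves all folds unchanged.
#'
#' @param table CT table: tibble with `strain`, `gene`, `replicate`, `ct` and
#'   optionally `condition`.
#' @param housekeeping_gene Housekeeping gene; must be present in every
#'   (strain, condition, replicate) group.
#' @param reference_strain Strain all folds are relative to; must be present
#'   for every gene and condition.
#' @return Tibble of class `expression_result` with `strain`, `condition`,
#'   `gene`, `fold` (geometric mean), `log2_fold`, `sd_log2`, `fold_sd`
#'   (SD of per-replicate folds), `n`. Per-replicate folds are attached as
#'   attribute `"replicates"`.
#' @examples
#' ct <- generate_ct_table(tibble::tibble(strain = "LT", gene = "pilA",
#'                                        fold = 4),
#'                         reference_strain = "PCA", noise_sd = 0, seed = 1)
#' delta_delta_ct(ct, "recA", "PCA")
#' @export
delta_delta_ct <- function(table, housekeeping_gene, reference_strain) {
  tb <- as_tibble(table)
  if (!"condition" %in% names(tb)) tb$condition <- "condition1"
  req <- c("strain", "condition", "gene", "replicate", "ct")
  if (!all(req %in% names(tb))) {
    abort(sprintf("CT table needs columns %s.", paste(req, collapse = ", ")))
  }
  if (any(!is.finite(tb$ct))) abort("All CT values must be finite.")
  hk <- tb[tb$gene == housekeeping_gene, , drop = FALSE]
  samples <- dplyr::distinct(tb, .data$strain, .data$condition, .data$replicate)
  have_hk <- dplyr::distinct(hk, .data$strain, .data$condition, .data$replicate)
  if (nrow(dplyr::anti_join(samples, have_hk,
                            by = c("strain", "condition", "replicate"))) > 0) {
    abort(sprintf("Housekeeping gene '%s' missing for some sample group.",
                  housekeeping_gene))
  }
  if (!reference_strain %in% tb$strain) {
    abort(sprintf("Reference strain '%s' absent from the table.", reference_strain))
  }
  targets <- tb[tb$gene != housekeeping_gene, , drop = FALSE]
  dct <- targets %>%
    dplyr::left_join(
      hk %>% dplyr::summarise(ct_hk = mean(.data$ct),
                              .by = c("strain", "condition", "replicate")),
      by = c("strain", "condition", "replicate")) %>%
    dplyr::mutate(dct = .data$ct - .data$ct_hk)
  ref <- dct %>%
    dplyr::filter(.data$strain == reference_strain) %>%
    dplyr::summarise(ref_dct = mean(.data$dct), .by = c("condition", "gene"))
  missing_ref <- dplyr::anti_join(
    dplyr::distinct(dct, .data$condition, .data$gene), ref,
    by = c("condition", "gene"))
  if (nrow(missing_ref) > 0) {
    abort("Reference strain lacks measurements for some gene/condition.")
  }
  reps <- dct %>%
    dplyr::inner_join(ref, by = c("condition", "gene")) %>%
    dplyr::mutate(ddct = .data$dct - .data$ref_dct,
                  fold = 2^(-.data$ddct))
  out <- reps %>%
    dplyr::summarise(
      log2_fold = mean(-.data$ddct),
      sd_log2 = stats::sd(-.data$ddct),
      fold_sd = stats::sd(.data$fold),
      n = dplyr::n(),
      .by = c("strain", "condition", "gene")) %>%
    dplyr::mutate(fold = 2^.data$log2_fold) %>%
    dplyr::relocate("fold", .before = "log2_fold") %>%
    dplyr::arrange(.data$condition, .data$gene, .data$strain)
  attr(out, "replicates") <- reps[, c("strain", "condition", "gene",
                                      "replicate", "ddct", "fold")]
  attr(out, "housekeeping_gene") <- housekeeping_gene
  attr(out, "reference_strain") <- reference_strain
  class(out) <- c("expression_result", class(out))
  out
}

#' Contrast expression between strain groups
#'
#' Unpaired t-test on per-replicate log2 fold changes of one gene between two
#' strain groups. With a single replicate in either group only point
#' estimates are returned and `method` says no test was run.
#'
#' @param result An `expression_result` from [delta_delta_ct()].
#' @param gene Gene to contrast.
#' @param strain_groups List of two character vectors of strain names,
#'   optionally named.
#' @param condition Restrict to one condition (default: all).
#' @return One-row tibble: `gene`, `condition`, group names, geometric mean
#'   folds, `log2_difference`, `statistic`, `p_value`, `method`.
#' @export
expression_contrast <- function(result, gene, strain_groups, condition = NULL) {
  stopifnot(inherits(result, "expression_result"), length(strain_groups) == 2L)
  reps <- attr(result, "replicates")
  if (!is.null(condition)) reps <- reps[reps$condition %in% condition, ]
  reps <- reps[reps$gene == gene, ]
  if (nrow(reps) == 0L) abort(sprintf("No replicates for gene '%s'.", gene))
  nm <- names(strain_groups) %||% c("group_a", "group_b")
  ga <- -reps$ddct[reps$strain %in% strain_groups[[1]]]
  gb <- -reps$ddct[reps$strain %in% strain_groups[[2]]]
  if (length(ga) == 0L || length(gb) == 0L) {
    abort("Both strain groups must have measurements for the gene.")
  }
  if (length(ga) >= 2L && length(gb) >= 2L && stats::sd(c(ga, gb)) > 0) {
    tt <- stats::t.test(ga, gb)
    stat <- unname(tt$statistic); p <- tt$p.value
    method <- "independent t on log2 folds"
  } else if (length(ga) >= 2L && length(gb) >= 2L) {
    stat <- NA_real_; p <- 1; method <- "degenerate (no variance)"
  } else {
    stat <- NA_real_; p <- NA_real_
    method <- "no test (single replicate); point estimate only"
  }
  tibble(gene = gene,
         condition = paste(unique(reps$condition), collapse = ","),
         group_a = nm[1], group_b = nm[2],
         fold_a = 2^mean(ga), fold_b = 2^mean(gb),
         log2_difference = mean(ga) - mean(gb),
         statistic = stat, p_value = p, method = method)
}

#' Read / write CT tables as CSV
#'
#' @param path File path.
#' @return `read_ct_table()` returns a tibble with `strain`, `condition`,
#'   `gene`, `replicate`, `ct`.
#' @export
read_ct_table <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' @rdname read_ct_table
#' @param result An `expression_result`.
#' @export
write_expression_csv <- function(result, path) {
  readr::write_csv(as_tibble(result), path)
  invisible(result)
}
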