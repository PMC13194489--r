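#' Position-wise secondary-structure comparison
#'
#' Counts the positions at which two equal-length H/E/C strings differ,
#' tallies the class transitions (a -> b) at those positions, and reports
#' per-model mean strand length and helix content.
#'
#' @param ss_a,ss_b Secondary-structure strings over H/E/C (equal length), or
#'   [structure_model()]s.
#' @return Object of class `ss_comparison`: `n_positions`, `n_diff`,
#'   `fraction_diff`, `percent_diff`, `transitions` (tibble `from`, `to`,
#'   `n`), `mean_strand_len_a/b`, `helix_content_a/b`.
#' @examples
#' ss_diff("HHEECC", "HHEECH")$n_diff  # 1
#' @export
ss_diff <- function(ss_a, ss_b) {
  a <- ss_string(ss_a); b <- ss_string(ss_b)
  if (nchar(a) != nchar(b)) abort("Secondary-structure strings differ in length.")
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  diff <- ca != cb
  trans <- tibble(from = ca[diff], to = cb[diff]) %>%
    dplyr::count(.data$from, .data$to, name = "n")
  n <- nchar(a)
  structure(
    list(n_positions = n, n_diff = sum(diff),
         fraction_diff = sum(diff) / n,
         percent_diff = 100 * sum(diff) / n,
         diff_positions = which(diff),
         transitions = trans,
         mean_strand_len_a = mean_run_length(a, "E"),
         mean_strand_len_b = mean_run_length(b, "E"),
         helix_content_a = helix_content(a),
         helix_content_b = helix_content(b)),
    class = "ss_comparison"
  )
}

#' @export
print.ss_comparison <- function(x, ...) {
  cat(sprintf("<ss_comparison> %d/%d positions differ (%.1f%%)\n",
              x$n_diff, x$n_positions, x$percent_diff))
  invisible(x)
}

ss_string <- function(x) {
  if (inherits(x, "structure_model")) x$ss else {
    stopifnot(is.character(x), length(x) == 1L)
    toupper(x)
  }
}

run_lengths <- function(ss, class) {
  r <- rle(strsplit(ss, "")[[1]])
  r$lengths[r$values == class]
}

mean_run_length <- function(ss, class) {
  L <- run_lengths(ss, class)
  if (length(L) == 0L) NA_real_ else mean(L)
}

#' Segment-length statistics for one secondary-structure class
#'
#' Extracts maximal runs of `class` from both strings and tests whether their
#' lengths differ. When both models have the same number of segments the runs
#' are paired by rank order (both sorted descending) and a paired t-test is
#' used; with unequal counts an unpaired Welch test is used and flagged in
#' `method`.
#'
#' @param ss_a,ss_b Secondary-structure strings or [structure_model()]s.
#' @param class `"E"` (strand) or `"H"` (helix).
#' @return One-row tibble: `class`, `n_a`, `n_b`, `mean_len_a`, `mean_len_b`,
#'   `mean_diff` (b - a), `statistic`, `p_value`, `method`; run lengths are
#'   attached as attributes `lengths_a`, `lengths_b`.
#' @export
segment_stats <- function(ss_a, ss_b, class = c("E", "H")) {
  class <- match.arg(class)
  a <- ss_string(ss_a); b <- ss_string(ss_b)
  la <- run_lengths(a, class); lb <- run_lengths(b, class)
  if (length(la) == 0L && length(lb) == 0L) {
    warn(sprintf("No '%s' segments in either model.", class))
    out <- tibble(class = class, n_a = 0L, n_b = 0L,
                  mean_len_a = NA_real_, mean_len_b = NA_real_,
                  mean_diff = NA_real_, statistic = NA_real_,
                  p_value = NA_real_, method = "undefined")
    return(out)
  }
  paired <- length(la) == length(lb) && length(la) >= 2L
  if (paired) {
    sa <- sort(la, decreasing = TRUE); sb <- sort(lb, decreasing = TRUE)
    diffs <- sb - sa
    if (stats::sd(diffs) == 0) {
      # identical pairings: no variance; p = 1 when nothing changed
      stat <- NA_real_
      p <- if (mean(diffs) == 0) 1 else NA_real_
      method <- "paired t (degenerate)"
    } else {
      tt <- stats::t.test(sb, sa, paired = TRUE)
      stat <- unname(tt$statistic); p <- tt$p.value
      method <- "paired t, rank-order pairing"
    }
    mean_diff <- mean(diffs)
  } else {
    ok <- length(la) >= 2L && length(lb) >= 2L
    if (ok) {
      tt <- stats::t.test(lb, la)
      stat <- unname(tt$statistic); p <- tt$p.value
    } else {
      stat <- NA_real_; p <- NA_real_
    }
    method <- "unpaired Welch t (segment counts differ)"
    mean_diff <- mean(lb) - mean(la)
  }
  out <- tibble(class = class, n_a = length(la), n_b = length(lb),
                mean_len_a = if (length(la)) mean(la) else NA_real_,
                mean_len_b = if (length(lb)) mean(lb) else NA_real_,
                mean_diff = mean_diff, statistic = stat, p_value = p,
                method = method)
  attr(out, "lengths_a") <- la
  attr(out, "lengths_b") <- lb
  out
}

#' Helix content of a secondary-structure string
#'
#' @param ss Secondary-structure string or [structure_model()].
#' @return Percent of residues assigned H.
#' @export
helix_content <- function(ss) {
  s <- ss_string(ss)
  if (nchar(s) == 0L) abort("Empty secondary-structure string.")
  100 * stringr::str_count(s, "H") / nchar(s)
}

#' Change in secondary-structure content between two models
#'
#' Reports the content change (b - a, percentage points) for one class and a
#' paired t-test on per-window class proportions (the two strings are cut
#' into matched contiguous windows and the within-window proportions are
#' compared pairwise).
#'
#' @param ss_a,ss_b Secondary-structure strings or [structure_model()]s of
#'   equal length.
#' @param class `"H"` (default) or `"E"`.
#' @param window Window size in residues (default 50).
#' @return One-row tibble: `class`, `content_a`, `content_b`,
#'   `delta_percent`, `statistic`, `p_value`, `n_windows`.
#' @export
content_change <- function(ss_a, ss_b, class = c("H", "E"), window = 50) {
  class <- match.arg(class)
  a <- ss_string(ss_a); b <- ss_string(ss_b)
  if (nchar(a) != nchar(b)) abort("Strings must have equal length.")
  n <- nchar(a)
  content <- function(s) 100 * stringr::str_count(s, stringr::fixed(class)) / nchar(s)
  idx <- split(seq_len(n), pmin((seq_len(n) - 1L) %/% window + 1L,
                                max(1L, n %/% window)))
  prop <- function(s, ii) {
    ch <- strsplit(s, "")[[1]]
    vapply(ii, function(i) mean(ch[i] == class), numeric(1))
  }
  pa <- prop(a, idx); pb <- prop(b, idx)
  if (length(pa) >= 2L && stats::sd(pb - pa) > 0) {
    tt <- stats::t.test(pb, pa, paired = TRUE)
    stat <- unname(tt$statistic); p <- tt$p.value
  } else {
    stat <- NA_real_
    p <- if (all(pb == pa)) 1 else NA_real_
  }
  tibble(class = class, content_a = content(a), content_b = content(b),
         delta_percent = content(b) - content(a),
         statistic = stat, p_value = p, n_windows = length(pa))
}

#' Inter-heme distance statistics between two models
#'
#' Matches hemes by index, computes iron-iron Euclidean distances within each
#' model (consecutive sequence-adjacent pairs by default, or all pairs), and
#' tests the paired difference (model b minus model a).
#'
#' @param model_a,model_b [structure_model()]s with equal heme counts (>= 2).
#' @param mode `"consecutive"` (default) or `"all_pairs"`.
#' @return Object of class `heme_comparison`: tibble row with `mode`,
#'   `n_pairs`, `mean_dist_a`, `mean_dist_b`, `mean_difference`, `statistic`,
#'   `p_value`; pairwise distances attached as attributes.
#' @export
heme_distance_stats <- function(model_a, model_b,
                                mode = c("consecutive", "all_pairs")) {
  mode <- match.arg(mode)
  ha <- model_a$hemes; hb <- model_b$hemes
  if (is.null(ha) || is.null(hb)) abort("Both models need heme coordinates.")
  if (nrow(ha) != nrow(hb)) abort("Heme counts differ; hemes must be index-matched.")
  if (nrow(ha) < 2L) abort("Need at least two hemes per model.")
  dists <- function(h) {
    if (mode == "consecutive") {
      i <- seq_len(nrow(h) - 1L)
      sqrt(rowSums((h[i + 1L, , drop = FALSE] - h[i, , drop = FALSE])^2))
    } else {
      as.numeric(stats::dist(h))
    }
  }
  da <- dists(ha); db <- dists(hb)
  diffs <- db - da
  if (length(diffs) >= 2L && stats::sd(diffs) > 0) {
    tt <- stats::t.test(db, da, paired = TRUE)
    stat <- unname(tt$statistic); p <- tt$p.value
  } else {
    stat <- NA_real_
    p <- if (all(diffs == 0)) 1 else NA_real_
  }
  out <- tibble(mode = mode, n_pairs = length(da),
                mean_dist_a = mean(da), mean_dist_b = mean(db),
                mean_difference = mean(diffs), statistic = stat, p_value = p)
  attr(out, "dist_a") <- da
  attr(out, "dist_b") <- db
  class(out) <- c("heme_comparison", class(out))
  out
}

#' Full structural divergence report for a model pair
#'
#' Superposes the pair, compares secondary structure, segment lengths, helix
#' content and (when present) inter-heme distances, and returns everything as
#' one tidy statistic table.
#'
#' @param model_a,model_b [structure_model()]s of equal length.
#' @param heme_mode Pairing mode for [heme_distance_stats()].
#' @return Object of class `structure_comparison`: list with `superposition`,
#'   `ss`, `strand_stats`, `helix_change`, `heme` (may be `NULL`), and a
#'   `report` tibble (`statistic`, `value`).
#' @export
compare_structures <- function(model_a, model_b,
                               heme_mode = c("consecutive", "all_pairs")) {
  heme_mode <- match.arg(heme_mode)
  sup <- kabsch_superpose(model_a, model_b)
  ssc <- ss_diff(model_a, model_b)
  strand <- segment_stats(model_a, model_b, "E")
  helix <- content_change(model_a, model_b, "H")
  heme <- NULL
  if (!is.null(model_a$hemes) && !is.null(model_b$hemes) &&
      nrow(model_a$hemes) >= 2 && nrow(model_b$hemes) >= 2) {
    heme <- heme_distance_stats(model_a, model_b, heme_mode)
  }
  report <- tibble(
    statistic = c("n_aligned", "global_rmsd_A", "tm_score",
                  "ss_n_diff", "ss_percent_diff",
                  "strand_mean_len_a", "strand_mean_len_b", "strand_p",
                  "helix_content_a", "helix_content_b", "helix_delta", "helix_p",
                  if (!is.null(heme)) c("heme_mean_difference_A", "heme_p")),
    value = c(sup$n_aligned, sup$global_rmsd, sup$tm_score,
              ssc$n_diff, ssc$percent_diff,
              strand$mean_len_a, strand$mean_len_b, strand$p_value,
              helix$content_a, helix$content_b, helix$delta_percent,
              helix$p_value,
              if (!is.null(heme)) c(heme$mean_difference, heme$p_value))
  )
  structure(list(superposition = sup, ss = ssc, strand_stats = strand,
                 helix_change = helix, heme = heme, report = report),
            class = "structure_comparison")
}

#' @export
print.structure_comparison <- function(x, ...) {
  print(x$report, n = Inf)
  invisible(x)
}
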