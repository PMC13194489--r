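#' Construct a protein structure model
#'
#' A minimal model for structure comparison: C-alpha coordinates, a 3-class
#' secondary-structure string (H = helix, E = strand, C = coil; 8-class DSSP
#' letters should be reduced beforehand with [reduce_dssp()]), and optional
#' heme iron coordinates.
#'
#' @param id Model identifier.
#' @param xyz Numeric matrix (n x 3) of C-alpha coordinates in Angstrom.
#' @param ss Secondary-structure string over H/E/C, one letter per residue.
#' @param hemes Optional numeric matrix (m x 3) of heme iron coordinates.
#' @return Object of class `structure_model`.
#' @export
structure_model <- function(id, xyz, ss, hemes = NULL) {
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3L || !is.numeric(xyz) || any(!is.finite(xyz))) {
    abort("`xyz` must be a finite numeric n x 3 matrix.")
  }
  stopifnot(is.character(ss), length(ss) == 1L)
  ss <- toupper(ss)
  if (nchar(ss) != nrow(xyz)) {
    abort("`ss` must have one letter per residue.")
  }
  if (grepl("[^HEC]", ss)) abort("`ss` may contain only H, E, C.")
  if (!is.null(hemes)) {
    hemes <- unname(as.matrix(hemes))
    if (ncol(hemes) != 3L || any(!is.finite(hemes))) {
      abort("`hemes` must be a finite numeric m x 3 matrix.")
    }
  }
  structure(list(id = id, xyz = unname(xyz), ss = ss, hemes = hemes),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("<structure_model> %s: %d residues, %d hemes\n",
              x$id, nrow(x$xyz), if (is.null(x$hemes)) 0L else nrow(x$hemes)))
  invisible(x)
}

#' Reduce 8-class DSSP letters to H/E/C
#'
#' H, G, I -> H (helix); E, B -> E (strand); everything else -> C (coil).
#'
#' @param ss DSSP string (spaces allowed for unassigned residues).
#' @return 3-class string.
#' @export
reduce_dssp <- function(ss) {
  ch <- strsplit(toupper(ss), "")[[1]]
  out <- ifelse(ch %in% c("H", "G", "I"), "H",
                ifelse(ch %in% c("E", "B"), "E", "C"))
  paste(out, collapse = "")
}

#' Read a structure model from PDB plus a secondary-structure file
#'
#' C-alpha atoms are taken from the PDB (through bio3d), heme irons from
#' HETATM records with residue name HEM or HEC and element Fe. The
#' secondary-structure file holds one letter per residue (a single line or
#' one letter per line); 8-class DSSP alphabets are reduced to H/E/C.
#'
#' @param pdb_file PDB path.
#' @param ss_file Plain-text secondary-structure path (optional; all-coil
#'   string used when absent).
#' @param id Model identifier (defaults to the file name).
#' @param chain Optional chain to restrict to.
#' @return A [structure_model()].
#' @export
read_structure_pdb <- function(pdb_file, ss_file = NULL, id = NULL,
                               chain = NULL) {
  if (!requireNamespace("bio3d", quietly = TRUE)) {
    abort("Package 'bio3d' is required to read PDB files.")
  }
  pdb <- bio3d::read.pdb(pdb_file)
  at <- pdb$atom
  ca <- at[at$elety == "CA" & at$type == "ATOM", , drop = FALSE]
  if (!is.null(chain)) ca <- ca[ca$chain %in% chain, , drop = FALSE]
  ca <- ca[order(ca$resno), , drop = FALSE]
  xyz <- as.matrix(ca[, c("x", "y", "z")])
  fe <- at[at$type == "HETATM" & at$resid %in% c("HEM", "HEC") &
             toupper(at$elesy %||% at$elety) %in% c("FE", "FE2", "FE3"), ,
           drop = FALSE]
  hemes <- if (nrow(fe) > 0) as.matrix(fe[, c("x", "y", "z")]) else NULL
  ss <- if (!is.null(ss_file)) {
    raw <- readLines(ss_file)
    reduce_dssp(paste(trimws(raw), collapse = ""))
  } else {
    strrep("C", nrow(xyz))
  }
  structure_model(id %||% basename(pdb_file), xyz, ss, hemes)
}

#' Write a structure model to PDB plus a secondary-structure file
#'
#' @param model A [structure_model()].
#' @param pdb_file,ss_file Output paths (`ss_file` optional).
#' @return The model, invisibly.
#' @export
write_structure_pdb <- function(model, pdb_file, ss_file = NULL) {
  n <- nrow(model$xyz)
  lines <- sprintf(
    "ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    seq_len(n), seq_len(n),
    model$xyz[, 1], model$xyz[, 2], model$xyz[, 3])
  if (!is.null(model$hemes)) {
    m <- nrow(model$hemes)
    lines <- c(lines, sprintf(
      "HETATM%5d FE   HEM B%4d    %8.3f%8.3f%8.3f  1.00  0.00          FE",
      n + seq_len(m), seq_len(m),
      model$hemes[, 1], model$hemes[, 2], model$hemes[, 3]))
  }
  writeLines(c(lines, "END"), pdb_file)
  if (!is.null(ss_file)) writeLines(model$ss, ss_file)
  invisible(model)
}

#' Optimal rigid-body superposition of matched C-alpha sets
#'
#' Kabsch algorithm: the least-squares proper rotation and translation
#' mapping set B onto set A, with reflections excluded. Returns the global
#' RMSD, per-residue deviations in the superposed frame, and the TM-score
#' normalized by the length of A (the reference).
#'
#' @param a,b Matched coordinate sets: n x 3 matrices or [structure_model()]s
#'   of equal length, n >= 3.
#' @return Object of class `superposition`: `rotation` (3 x 3, det +1),
#'   `translation`, `global_rmsd`, `per_residue_dev`, `tm_score`,
#'   `n_aligned`, `b_transformed`.
#' @examples
#' s <- generate_structure_pair(50, seed = 3)
#' kabsch_superpose(s$a, s$b)$global_rmsd  # ~0: pure rigid motion
#' @export
kabsch_superpose <- function(a, b) {
  A <- if (inherits(a, "structure_model")) a$xyz else as.matrix(a)
  B <- if (inherits(b, "structure_model")) b$xyz else as.matrix(b)
  if (nrow(A) != nrow(B)) abort("Coordinate sets must be matched (equal length).")
  n <- nrow(A)
  if (n < 3L) abort("At least 3 matched points are required.")
  ca <- colMeans(A); cb <- colMeans(B)
  Ac <- sweep(A, 2, ca); Bc <- sweep(B, 2, cb)
  sv_a <- svd(Ac)$d; sv_b <- svd(Bc)$d
  if (sv_a[2] < 1e-8 * max(sv_a[1], 1) || sv_b[2] < 1e-8 * max(sv_b[1], 1)) {
    abort(paste0("Degenerate (collinear) coordinates: the optimal rotation ",
                 "is not unique."))
  }
  H <- crossprod(Bc, Ac)           # 3x3 covariance
  sv <- svd(H)
  d <- sign(det(tcrossprod(sv$v, sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)      # maps centered B onto centered A
  Bfit <- Bc %*% t(R)
  dev <- sqrt(rowSums((Ac - Bfit)^2))
  rmsd <- sqrt(mean(dev^2))
  translation <- as.numeric(ca - R %*% cb)
  structure(
    list(rotation = R, translation = translation,
         global_rmsd = rmsd, per_residue_dev = dev,
         tm_score = tm_score(dev, n), n_aligned = n,
         b_transformed = sweep(Bfit, 2, ca, `+`)),
    class = "superposition"
  )
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition> n=%d  RMSD=%.3f A  TM-score=%.3f\n",
              x$n_aligned, x$global_rmsd, x$tm_score))
  invisible(x)
}

#' TM-score from per-residue deviations
#'
#' TM-score = (1/L) * sum_i 1 / (1 + (d_i/d0)^2) with d0 = 1.24 (L-15)^(1/3)
#' - 1.8 Angstrom, floored at 0.5 A (the Zhang-Skolnick normalization).
#' `L_target` is the normalizing length; by convention the reference
#' (first) structure's length.
#'
#' @param per_residue_dev Deviations (A) of aligned residues in the superposed
#'   frame.
#' @param L_target Normalizing length.
#' @return Score in (0, 1].
#' @export
tm_score <- function(per_residue_dev, L_target) {
  if (length(per_residue_dev) == 0L) abort("Empty deviation list.")
  if (any(per_residue_dev < 0)) abort("Deviations must be non-negative.")
  check_scalar_number(L_target, "L_target", min = 1)
  d0 <- if (L_target <= 15) 0.5 else max(1.24 * (L_target - 15)^(1 / 3) - 1.8, 0.5)
  sum(1 / (1 + (per_residue_dev / d0)^2)) / L_target
}

#' Bin per-residue deviations into similarity colour classes
#'
#' The default cuts reproduce a blue/white/red per-residue colouring: blue
#' (< 0.5 A, highest similarity), white (0.5-2 A, intermediate), red (> 2 A,
#' largest difference).
#'
#' @param per_residue_dev Non-negative deviations (A).
#' @param thresholds Increasing cut points (default `c(0.5, 2)`).
#' @param labels Bin labels (default blue/white/red).
#' @return Character vector of bin labels, one per residue.
#' @export
deviation_bins <- function(per_residue_dev, thresholds = c(0.5, 2),
                           labels = c("blue", "white", "red")) {
  if (any(per_residue_dev < 0)) abort("Deviations must be non-negative.")
  if (is.unsorted(thresholds, strictly = TRUE)) {
    abort("`thresholds` must be strictly increasing.")
  }
  if (length(labels) != length(thresholds) + 1L) {
    abort("Need one more label than thresholds.")
  }
  as.character(cut(per_residue_dev, breaks = c(-Inf, thresholds, Inf),
                   labels = labels, right = FALSE))
}
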