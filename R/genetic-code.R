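# Standard bacterial genetic code (translation table 11 behaviour: the code
# itself is the standard code; the alternative GTG/TTG initiators are handled
# at annotated start codons by the classifier, not here).

GENETIC_CODE_STD <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G"
)

STOP_CODONS <- names(GENETIC_CODE_STD)[GENETIC_CODE_STD == "*"]
SENSE_CODONS <- names(GENETIC_CODE_STD)[GENETIC_CODE_STD != "*"]
START_CODONS <- c("ATG", "GTG", "TTG")

BASES <- c("A", "C", "G", "T")
COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")
# transitions: purine<->purine, pyrimidine<->pyrimidine
TRANSITION_PARTNER <- c(A = "G", G = "A", C = "T", T = "C")

revcomp <- function(x) {
  vapply(strsplit(x, ""), function(ch) {
    paste(rev(unname(COMPLEMENT[ch])), collapse = "")
  }, character(1))
}

is_transition <- function(ref, alt) {
  unname(TRANSITION_PARTNER[ref] == alt)
}

#' Chemical category of an amino acid
#'
#' Maps each of the 20 standard residues to one of six chemical categories:
#' nonpolar-aliphatic (A, V, L, I, M), aromatic (F, W, Y), polar-uncharged
#' (S, T, N, Q), positive (K, R, H), negative (D, E) and special (C, G, P).
#' Substitutions that cross categories are counted as amino-acid category
#' changes in gene mutation profiles. The scheme is the package default;
#' supply `scheme` to override it with a different named mapping.
#'
#' @param aa Character vector of one-letter residue codes.
#' @param scheme Optional named character vector mapping all 20 residues to
#'   category labels.
#' @return Character vector of category labels.
#' @examples
#' aa_category(c("D", "K", "P", "A"))
#' @export
aa_category <- function(aa, scheme = NULL) {
  map <- scheme %||% AA_CATEGORY_DEFAULT
  if (is.null(names(map)) || !all(AA_LETTERS %in% names(map))) {
    abort("`scheme` must be a named vector covering all 20 standard residues.")
  }
  bad <- setdiff(unique(aa), names(map))
  if (length(bad) > 0) {
    abort(sprintf("Unknown residue letter(s): %s", paste(bad, collapse = ", ")))
  }
  unname(map[aa])
}

AA_LETTERS <- sort(unique(GENETIC_CODE_STD[GENETIC_CODE_STD != "*"]))

AA_CATEGORY_DEFAULT <- c(
  A = "nonpolar-aliphatic", V = "nonpolar-aliphatic", L = "nonpolar-aliphatic",
  I = "nonpolar-aliphatic", M = "nonpolar-aliphatic",
  F = "aromatic", W = "aromatic", Y = "aromatic",
  S = "polar-uncharged", T = "polar-uncharged", N = "polar-uncharged",
  Q = "polar-uncharged",
  K = "positive", R = "positive", H = "positive",
  D = "negative", E = "negative",
  C = "special", G = "special", P = "special"
)

translate_codons <- function(codons) {
  aa <- GENETIC_CODE_STD[codons]
  if (anyNA(aa)) {
    abort(sprintf("Invalid codon(s): %s",
                  paste(unique(codons[is.na(aa)]), collapse = ", ")))
  }
  unname(aa)
}

#' Nei-Gojobori synonymous and nonsynonymous site counts for a codon
#'
#' For a sense codon, counts fractional synonymous and nonsynonymous sites by
#' the equal-pathway (Nei-Gojobori 1986) rule: at each codon position the
#' synonymous site fraction is the fraction of the three possible single-base
#' changes that preserve the encoded amino acid. Changes to a stop codon count
#' as nonsynonymous. The two fractions always sum to 3.
#'
#' @param codon Character vector of 3-letter sense codons.
#' @return A tibble with columns `codon`, `syn_sites`, `nonsyn_sites`.
#' @examples
#' ng_site_counts("TTT")  # 1/3 synonymous sites
#' ng_site_counts("GGA")  # fourfold-degenerate third position: 1 and 2
#' @export
ng_site_counts <- function(codon) {
  codon <- toupper(codon)
  if (any(codon %in% STOP_CODONS)) {
    abort("ng_site_counts() is defined for sense codons only; got a stop codon.")
  }
  if (!all(codon %in% SENSE_CODONS)) {
    abort("All inputs must be valid sense codons (A/C/G/T, length 3).")
  }
  tibble(
    codon = codon,
    syn_sites = unname(NG_SYN_SITES[codon]),
    nonsyn_sites = 3 - unname(NG_SYN_SITES[codon])
  )
}

# Precomputed per-codon synonymous site fractions (enumeration over all nine
# single-base neighbours of each sense codon).
.ng_syn_sites_compute <- function() {
  out <- numeric(length(SENSE_CODONS))
  names(out) <- SENSE_CODONS
  for (cd in SENSE_CODONS) {
    aa <- GENETIC_CODE_STD[[cd]]
    syn <- 0
    for (p in 1:3) {
      ref_base <- substr(cd, p, p)
      for (b in setdiff(BASES, ref_base)) {
        alt <- cd
        substr(alt, p, p) <- b
        if (GENETIC_CODE_STD[[alt]] == aa) syn <- syn + 1 / 3
      }
    }
    out[[cd]] <- syn
  }
  out
}

NG_SYN_SITES <- .ng_syn_sites_compute()
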