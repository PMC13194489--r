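#' Write variants as VCF 4.2
#'
#' Minimal single-sample-free VCF: fixed columns only, 1-based positions,
#' REF/ALT on the forward strand.
#'
#' @param variants Tibble with `pos`, `ref`, `alt` (and optionally `type`).
#' @param genome The [annotated_genome()] the coordinates refer to.
#' @param path Output path.
#' @return The variants, invisibly.
#' @export
write_variants_vcf <- function(variants, genome, path) {
  v <- normalize_variants(variants)
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", genome$id, genome_length(genome)),
    "##source=geoadapt",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.",
                  genome$id, v$pos, v$ref, v$alt)
  writeLines(c(header, body), path)
  invisible(variants)
}

#' Read variants from VCF or a Snippy-style TSV
#'
#' `read_variants_vcf()` goes through vcfR; `read_variants_snippy()` reads the
#' tab dialect with columns CHROM, POS, TYPE, REF, ALT (extra columns such as
#' EFFECT are kept). Both return the `pos`/`ref`/`alt` tibble the annotation
#' functions consume.
#'
#' @param path Input path.
#' @return Tibble with `chrom`, `pos`, `ref`, `alt` (and `type` when
#'   available).
#' @export
read_variants_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort("Package 'vcfR' is required to read VCF.")
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  tibble(
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = fix$REF,
    alt = fix$ALT
  )
}

#' @rdname read_variants_vcf
#' @export
read_variants_snippy <- function(path) {
  tb <- readr::read_tsv(path, show_col_types = FALSE)
  nm <- toupper(names(tb))
  req <- c("CHROM", "POS", "REF", "ALT")
  if (!all(req %in% nm)) {
    abort("Snippy-style TSV needs columns CHROM, POS, REF, ALT.")
  }
  out <- tibble(
    chrom = tb[[which(nm == "CHROM")]],
    pos = as.integer(tb[[which(nm == "POS")]]),
    ref = toupper(tb[[which(nm == "REF")]]),
    alt = toupper(tb[[which(nm == "ALT")]])
  )
  if ("TYPE" %in% nm) out$type <- tb[[which(nm == "TYPE")]]
  out
}

#' Write annotated variants / alignment blocks / reports as TSV
#'
#' @param x A tibble.
#' @param path Output path.
#' @return `x`, invisibly.
#' @export
write_tsv_report <- function(x, path) {
  readr::write_tsv(as_tibble(x), path)
  invisible(x)
}

#' Read coords-style alignment blocks
#'
#' TSV with columns ref_start, ref_end, qry_start, qry_end, orientation.
#'
#' @param path Input path.
#' @return Tibble of alignment blocks.
#' @export
read_alignment_blocks <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}
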