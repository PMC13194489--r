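#' Construct an annotated genome
#'
#' Bundles a nucleotide sequence with its CDS features. This is the coordinate
#' frame against which every variant is classified: features are 1-based
#' inclusive (GFF3 convention), strand-aware, and each CDS length must be a
#' multiple of three after strand resolution.
#'
#' @param id Genome identifier.
#' @param seq Single uppercase A/C/G/T string.
#' @param features Tibble with columns `locus_id`, `start`, `end`, `strand`
#'   (`"+"`/`"-"`) and optionally `product`.
#' @return An object of class `annotated_genome`.
#' @export
annotated_genome <- function(id, seq, features) {
  stopifnot(is.character(id), length(id) == 1L,
            is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  if (grepl("[^ACGT]", seq)) {
    abort("Genome sequence may contain only A/C/G/T.")
  }
  features <- as_tibble(features)
  req <- c("locus_id", "start", "end", "strand")
  if (!all(req %in% names(features))) {
    abort(sprintf("`features` must have columns: %s.", paste(req, collapse = ", ")))
  }
  if (!"product" %in% names(features)) features$product <- NA_character_
  if (anyDuplicated(features$locus_id)) abort("Locus IDs must be unique.")
  if (any(features$end < features$start)) abort("Feature ends must be >= starts.")
  n <- nchar(seq)
  if (any(features$start < 1L) || any(features$end > n)) {
    abort("Features must lie within the sequence bounds.")
  }
  if (!all(features$strand %in% c("+", "-"))) {
    abort("Feature strand must be '+' or '-'.")
  }
  len <- features$end - features$start + 1L
  if (any(len %% 3L != 0L)) {
    abort("Every CDS length must be a multiple of 3.")
  }
  features <- features[order(features$start), , drop = FALSE]
  structure(
    list(id = id, seq = seq, features = features),
    class = "annotated_genome"
  )
}

#' @export
print.annotated_genome <- function(x, ...) {
  cat(sprintf("<annotated_genome> %s: %s bp, %d CDS\n",
              x$id, format(nchar(x$seq), big.mark = ","), nrow(x$features)))
  invisible(x)
}

#' @export
#' @rdname annotated_genome
#' @param x Object to test.
is_annotated_genome <- function(x) inherits(x, "annotated_genome")

genome_length <- function(genome) nchar(genome$seq)

# Strand-resolved coding sequence of one locus (character scalar).
cds_seq <- function(genome, locus_id) {
  f <- genome$features[genome$features$locus_id == locus_id, ]
  if (nrow(f) != 1L) abort(sprintf("Unknown locus '%s'.", locus_id))
  s <- substr(genome$seq, f$start, f$end)
  if (f$strand == "-") revcomp(s) else s
}

# Strand-resolved coding sequences for all loci, in feature order.
all_cds_seqs <- function(genome) {
  f <- genome$features
  segs <- stringr::str_sub(genome$seq, f$start, f$end)
  neg <- f$strand == "-"
  if (any(neg)) segs[neg] <- revcomp(segs[neg])
  stats::setNames(segs, f$locus_id)
}

#' Total coding length of a genome
#'
#' @param genome An [annotated_genome()].
#' @param unit `"bp"` or `"kb"`.
#' @return Total CDS length.
#' @export
coding_length <- function(genome, unit = c("bp", "kb")) {
  unit <- match.arg(unit)
  bp <- sum(genome$features$end - genome$features$start + 1L)
  if (unit == "kb") bp / 1000 else bp
}

#' Write / read an annotated genome as FASTA + GFF3
#'
#' The FASTA writer goes through Biostrings; the GFF3 writer emits CDS features
#' with 1-based inclusive coordinates. `read_annotated_genome()` inverts both
#' (GFF3 reading goes through rtracklayer).
#'
#' @param genome An [annotated_genome()].
#' @param fasta,gff3 File paths.
#' @return `read_annotated_genome()` returns an [annotated_genome()];
#'   the writer returns the genome invisibly.
#' @export
write_annotated_genome <- function(genome, fasta, gff3) {
  dna <- Biostrings::DNAStringSet(stats::setNames(genome$seq, genome$id))
  Biostrings::writeXStringSet(dna, fasta)
  f <- genome$features
  lines <- c(
    "##gff-version 3",
    sprintf("##sequence-region %s 1 %d", genome$id, genome_length(genome)),
    sprintf("%s\tgeoadapt\tCDS\t%d\t%d\t.\t%s\t0\tID=%s;locus_tag=%s%s",
            genome$id, f$start, f$end, f$strand, f$locus_id, f$locus_id,
            ifelse(is.na(f$product), "", paste0(";product=", f$product)))
  )
  writeLines(lines, gff3)
  invisible(genome)
}

#' @rdname write_annotated_genome
#' @param id Genome identifier to assign on reading (defaults to the FASTA
#'   record name).
#' @export
read_annotated_genome <- function(fasta, gff3, id = NULL) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    abort("Package 'rtracklayer' is required to read GFF3.")
  }
  dna <- Biostrings::readDNAStringSet(fasta)
  seq <- as.character(dna[[1]])
  gid <- id %||% sub("\\s.*$", "", names(dna)[1])
  gr <- rtracklayer::import(gff3, format = "gff3")
  gr <- gr[gr$type == "CDS"]
  locus <- if (!is.null(gr$locus_tag)) as.character(gr$locus_tag) else as.character(gr$ID)
  feats <- tibble(
    locus_id = locus,
    start = BiocGenerics::start(gr),
    end = BiocGenerics::end(gr),
    strand = as.character(BiocGenerics::strand(gr)),
    product = if (!is.null(gr$product)) as.character(gr$product) else NA_character_
  )
  annotated_genome(gid, seq, feats)
}
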