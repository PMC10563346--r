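#' Read variants from a VCF file
#'
#' Multi-allelic records are decomposed into one row per (record, alt) pair.
#' Symbolic/CNV alleles and multi-nucleotide block substitutions (both
#' alleles longer than one base) are skipped and counted; SNVs and
#' left-anchored indels are kept as-is. Allele frequencies are pulled from
#' the named INFO keys; a key that is absent (globally or for a record)
#' yields a missing frequency.
#'
#' @param path VCF file.
#' @param af_sources Character vector of INFO keys holding allele
#'   frequencies (e.g. \code{c("AF_gnomAD", "AF_KGP")}). The stored source
#'   name is the key without any \code{AF_} prefix.
#' @return A [variants()] table; attribute \code{"skipped"} counts the
#'   records dropped as symbolic/CNV/MNV.
#' @export
read_vcf <- function(path, af_sources = character()) {
  vcf <- tryCatch(
    suppressWarnings(VariantAnnotation::readVcf(path)),
    error = function(e)
      stop("VCF parse error in '", path, "': ", conditionMessage(e)))
  vcf <- VariantAnnotation::expand(vcf)
  rr <- SummarizedExperiment::rowRanges(vcf)
  chrom <- as.character(GenomicRanges::seqnames(rr))
  pos <- GenomicRanges::start(rr)
  ref <- as.character(rr$REF)
  alt <- as.character(rr$ALT)

  plain <- grepl("^[ACGT]+$", ref) & grepl("^[ACGT]+$", alt)
  anchored <- nchar(ref) == 1L | nchar(alt) == 1L  # SNV or anchored indel
  keep <- plain & anchored & ref != alt
  skipped <- sum(!keep)
  if (skipped > 0)
    message("read_vcf: skipped ", skipped,
            " symbolic/CNV/MNV allele(s) in ", basename(path))

  af <- list()
  info <- VariantAnnotation::info(vcf)
  for (key in af_sources) {
    src <- sub("^AF_", "", key)
    if (!nzchar(src)) src <- key
    x <- if (key %in% names(info)) info[[key]] else rep(NA_real_, length(rr))
    if (is.list(x) || methods::is(x, "List"))
      x <- vapply(as.list(x), function(e)
        if (length(e) == 0) NA_real_ else as.numeric(e[[1]]), 0.0)
    af[[src]] <- as.numeric(x)[keep]
  }
  variants(chrom[keep], pos[keep], ref[keep], alt[keep], af = af)
}

fmt_num <- function(x) {
  # compact float formatting for INFO fields
  sub("0+$", "", sub("\\.$", "", formatC(x, digits = 6, format = "fg")))
}

#' Write variants (optionally with pathogenicity scores) to VCF
#'
#' Emits VCF 4.2 with one \code{AF_<source>} INFO field per allele-frequency
#' column and, when \code{scores} is given, a \code{PDIVAS} INFO key of the
#' form \code{<gene_id>|<score to 3 decimals>}. Variants without a score
#' carry \code{PDIVAS=.|.}.
#'
#' @param v A [variants()] table.
#' @param scores Named numeric vector of scores keyed by
#'   \code{chrom:pos:ref:alt}, or NULL to omit the PDIVAS field.
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
write_vcf_scores <- function(v, scores, path) {
  sources <- af_sources_of(v)
  hdr <- c("##fileformat=VCFv4.2",
           sprintf(paste0("##INFO=<ID=AF_%s,Number=1,Type=Float,",
                          "Description=\"Allele frequency (%s)\">"),
                   sources, sources))
  if (!is.null(scores))
    hdr <- c(hdr, paste0("##INFO=<ID=PDIVAS,Number=1,Type=String,",
                         "Description=\"Deep-intronic splice pathogenicity:",
                         " gene|score\">"))
  hdr <- c(hdr, sprintf("##contig=<ID=%s>", unique(v$chrom)),
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", sep = "\t"))
  info <- vapply(seq_len(nrow(v)), function(i) {
    parts <- character(0)
    for (s in sources) {
      x <- v[[paste0("AF_", s)]][i]
      if (!is.na(x)) parts <- c(parts, sprintf("AF_%s=%s", s, fmt_num(x)))
    }
    if (!is.null(scores)) {
      key <- variant_key(v[i, , drop = FALSE])
      sc <- scores[key]
      gene <- v$gene_id[i]
      parts <- c(parts, if (is.null(scores) || is.na(sc)) "PDIVAS=.|."
                 else sprintf("PDIVAS=%s|%.3f",
                              if (is.na(gene)) "." else gene, sc))
    }
    if (length(parts) == 0) "." else paste(parts, collapse = ";")
  }, "")
  body <- paste(v$chrom, v$pos, ".", v$ref, v$alt, ".", "PASS", info,
                sep = "\t")
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot write VCF: ", path))
  on.exit(close(con))
  writeLines(c(hdr, body), con)
  invisible(path)
}
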