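#' Construct a variant table
#'
#' The internal variant representation is a plain data.frame with one row per
#' (record, alt allele) pair and 1-based VCF-style coordinates: columns
#' \code{chrom}, \code{pos}, \code{ref}, \code{alt}, one \code{AF_<source>}
#' column per allele-frequency source (NA = absent from that database), and
#' optional \code{gene_id} / \code{transcript_id}.
#'
#' @param chrom Chromosome names.
#' @param pos 1-based positions of the first reference base.
#' @param ref,alt Reference and alternate allele strings over A,C,G,T.
#' @param af Named list of allele-frequency vectors, one element per source
#'   (e.g. \code{list(gnomAD = ..., KGP = ...)}); values in [0,1] or NA.
#' @param gene_id,transcript_id Optional annotations.
#' @return A \code{data.frame} of class \code{"pdivas_variants"}.
#' @export
variants <- function(chrom, pos, ref, alt, af = list(),
                     gene_id = NA_character_, transcript_id = NA_character_) {
  n <- max(length(chrom), length(pos), length(ref), length(alt))
  chrom <- rep_len(as.character(chrom), n)
  pos <- rep_len(as.integer(pos), n)
  ref <- rep_len(as.character(ref), n)
  alt <- rep_len(as.character(alt), n)
  if (n > 0) {
    if (any(pos < 1)) stop("variant positions must be >= 1")
    if (any(ref == alt)) stop("ref and alt alleles must differ")
    ok <- grepl("^[ACGT]+$", ref) & grepl("^[ACGT]+$", alt)
    if (!all(ok)) stop("alleles must be nonempty strings over {A,C,G,T}")
  }
  df <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                   gene_id = rep_len(as.character(gene_id), n),
                   transcript_id = rep_len(as.character(transcript_id), n),
                   stringsAsFactors = FALSE)
  for (src in names(af)) {
    v <- rep_len(as.numeric(af[[src]]), n)
    if (any(!is.na(v) & (v < 0 | v > 1)))
      stop("allele frequencies must lie in [0,1]")
    df[[paste0("AF_", src)]] <- v
  }
  class(df) <- c("pdivas_variants", "data.frame")
  df
}

#' @export
print.pdivas_variants <- function(x, ...) {
  cat("<pdivas_variants> ", nrow(x), " variant(s)\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 10), ...)
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}

variant_key <- function(v) paste(v$chrom, v$pos, v$ref, v$alt, sep = ":")

af_sources_of <- function(v) {
  sub("^AF_", "", grep("^AF_", names(v), value = TRUE))
}

af_matrix <- function(v, sources) {
  m <- sapply(sources, function(s) {
    col <- paste0("AF_", s)
    if (col %in% names(v)) as.numeric(v[[col]]) else rep(NA_real_, nrow(v))
  })
  matrix(m, nrow = nrow(v), dimnames = list(NULL, sources))
}

#' Rarity and commonness filters on allele frequency
#'
#' A variant passes the rare filter when its allele frequency is below
#' \code{cutoff} (default 1\%) in \emph{every} listed population source; it
#' passes the common filter when the frequency is at or above \code{cutoff}
#' (default 5\%) in every source. A missing frequency counts as 0 (a variant
#' absent from the databases is novel, hence rare), so the two filters can
#' never both pass at the default cutoffs.
#'
#' @param v A variant table (see [variants()]).
#' @param sources Character vector of AF source names.
#' @param cutoff Frequency cutoff.
#' @return Logical vector, one element per variant.
#' @export
passes_rare_filter <- function(v, sources, cutoff = 0.01) {
  if (nrow(v) == 0) return(logical(0))
  m <- af_matrix(v, sources)
  m[is.na(m)] <- 0
  apply(m < cutoff, 1, all)
}

#' @rdname passes_rare_filter
#' @export
passes_common_filter <- function(v, sources, cutoff = 0.05) {
  if (nrow(v) == 0) return(logical(0))
  m <- af_matrix(v, sources)
  m[is.na(m)] <- 0
  apply(m >= cutoff, 1, all)
}
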