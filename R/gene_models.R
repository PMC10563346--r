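#' Construct a transcript model
#'
#' A transcript is a strand-aware ordered set of exons in 1-based closed
#' genomic coordinates. Splice sites are derived, not stored: for every
#' internal exon boundary the annotated site is the intronic base flanking
#' the boundary (first intronic base of the intron for a donor, last intronic
#' base for an acceptor, in transcript orientation).
#'
#' @param gene_id,transcript_id Identifiers.
#' @param chrom Chromosome name.
#' @param strand "+" or "-".
#' @param exons Two-column matrix (start, end), 1-based closed, sorted.
#' @return A list of class \code{"transcript_model"}.
#' @export
transcript_model <- function(gene_id, transcript_id, chrom, strand, exons) {
  exons <- matrix(as.integer(exons), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  if (nrow(exons) < 1) stop("transcript needs at least one exon")
  if (any(exons[, 1] > exons[, 2])) stop("exon start > end")
  o <- order(exons[, 1])
  exons <- exons[o, , drop = FALSE]
  if (nrow(exons) > 1 &&
      any(exons[-1, 1] <= exons[-nrow(exons), 2]))
    stop("overlapping exons in transcript ", transcript_id)
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  structure(list(gene_id = gene_id, transcript_id = transcript_id,
                 chrom = chrom, strand = strand, exons = exons),
            class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat("<transcript_model> ", x$transcript_id, " (", x$gene_id, ") ",
      x$chrom, x$strand, " ", nrow(x$exons), " exon(s)\n", sep = "")
  invisible(x)
}

tx_span <- function(t) c(t$exons[1, 1], t$exons[nrow(t$exons), 2])

#' Annotated splice-site positions of a transcript
#'
#' @param t A [transcript_model()].
#' @return data.frame with columns \code{pos} (genomic, 1-based), \code{kind}
#'   ("donor"/"acceptor") and \code{strand}. Single-exon transcripts have none.
#' @export
splice_sites <- function(t) {
  n <- nrow(t$exons)
  if (n < 2)
    return(data.frame(pos = integer(0), kind = character(0),
                      strand = character(0), stringsAsFactors = FALSE))
  up <- t$exons[-n, 2] + 1L   # first intronic base after each internal exon
  dn <- t$exons[-1, 1] - 1L   # last intronic base before the next exon
  if (t$strand == "+") {
    df <- data.frame(pos = c(up, dn),
                     kind = rep(c("donor", "acceptor"), each = n - 1))
  } else {
    df <- data.frame(pos = c(up, dn),
                     kind = rep(c("acceptor", "donor"), each = n - 1))
  }
  df$strand <- t$strand
  df[order(df$pos), , drop = FALSE]
}

#' Read transcript models from GTF or BED12
#'
#' Both dialects are normalized to identical [transcript_model()] objects
#' (GTF is 1-based closed, BED 0-based half-open; conversions happen here).
#' One transcript is retained per gene — the one with the largest total
#' exonic length (ties broken by transcript id) — emulating single-transcript
#' "picked" annotation.
#'
#' For BED12 the name field encodes \code{gene_id:transcript_id}; a name
#' without a colon is used as both.
#'
#' @param path GTF (\code{.gtf}) or BED12 (\code{.bed}) file.
#' @param format "auto" (by extension), "gtf" or "bed".
#' @return Named list of \code{transcript_model}, one per gene.
#' @export
read_gene_models <- function(path, format = c("auto", "gtf", "bed")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.bed(\\.gz)?$", path, ignore.case = TRUE)) "bed"
              else "gtf"
  gr <- rtracklayer::import(path, format = format)
  txs <- if (format == "gtf") models_from_gtf(gr) else models_from_bed(gr)
  pick_one_per_gene(txs)
}

models_from_gtf <- function(gr) {
  gr <- gr[gr$type == "exon"]
  if (length(gr) == 0) stop("no exon records in GTF")
  key <- paste(gr$gene_id, gr$transcript_id, sep = "\r")
  lapply(split(seq_along(gr), key), function(i) {
    g <- gr[i]
    transcript_model(gene_id = g$gene_id[1],
                     transcript_id = g$transcript_id[1],
                     chrom = as.character(GenomicRanges::seqnames(g))[1],
                     strand = as.character(GenomicRanges::strand(g))[1],
                     exons = cbind(GenomicRanges::start(g),
                                   GenomicRanges::end(g)))
  })
}

models_from_bed <- function(gr) {
  lapply(seq_along(gr), function(i) {
    g <- gr[i]
    nm <- strsplit(g$name, ":", fixed = TRUE)[[1]]
    gene <- nm[1]
    tx <- if (length(nm) > 1) paste(nm[-1], collapse = ":") else nm[1]
    blocks <- g$blocks[[1]]  # block ranges are relative to the feature start
    off <- GenomicRanges::start(g) - 1L
    transcript_model(gene_id = gene, transcript_id = tx,
                     chrom = as.character(GenomicRanges::seqnames(g)),
                     strand = as.character(GenomicRanges::strand(g)),
                     exons = cbind(off + IRanges::start(blocks),
                                   off + IRanges::end(blocks)))
  })
}

pick_one_per_gene <- function(txs) {
  genes <- vapply(txs, function(t) t$gene_id, "")
  picked <- lapply(split(txs, genes), function(cand) {
    len <- vapply(cand, function(t)
      sum(t$exons[, 2] - t$exons[, 1] + 1L), 0L)
    ids <- vapply(cand, function(t) t$transcript_id, "")
    cand[[order(-len, ids)[1]]]
  })
  picked[order(names(picked))]
}

#' Construct and read a splicing-constraint track
#'
#' Interval scores in [0,1] over 0-based half-open coordinates (BED-like:
#' chrom, start, end, score). Intervals must not overlap within a chromosome.
#'
#' @param chrom,start,end,score Track columns.
#' @return data.frame of class \code{"constraint_track"}.
#' @export
constraint_track <- function(chrom, start, end, score) {
  df <- data.frame(chrom = as.character(chrom), start = as.integer(start),
                   end = as.integer(end), score = as.numeric(score),
                   stringsAsFactors = FALSE)
  if (any(df$start < 0 | df$end <= df$start))
    stop("constraint intervals must satisfy 0 <= start < end")
  if (any(df$score < 0 | df$score > 1))
    stop("constraint scores must lie in [0,1]")
  for (ch in unique(df$chrom)) {
    x <- df[df$chrom == ch, , drop = FALSE]
    x <- x[order(x$start), , drop = FALSE]
    if (nrow(x) > 1 && any(x$start[-1] < x$end[-nrow(x)]))
      stop("overlapping constraint intervals on ", ch)
  }
  class(df) <- c("constraint_track", "data.frame")
  df
}

#' @rdname constraint_track
#' @param path BED4-style file (chrom, start, end, score; no header).
#' @export
read_constraint_track <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start", "end", "score"),
                          stringsAsFactors = FALSE)
  constraint_track(df$chrom, df$start, df$end, df$score)
}

#' Look up the constraint score covering each variant
#'
#' Returns NA where no interval covers a position; such variants are excluded
#' from scoring downstream (a score is computed only when all five features
#' are present).
#'
#' @param v A variant table.
#' @param track A [constraint_track()].
#' @return Numeric vector of scores or NA.
#' @export
constraint_lookup <- function(v, track) {
  vapply(seq_len(nrow(v)), function(i) {
    p0 <- v$pos[i] - 1L  # 0-based
    hit <- which(track$chrom == v$chrom[i] &
                 track$start <= p0 & p0 < track$end)
    if (length(hit) > 1) stop("ambiguous constraint intervals at ",
                              v$chrom[i], ":", v$pos[i])
    if (length(hit) == 0) NA_real_ else track$score[hit]
  }, 0.0)
}

#' Read a Mendelian-disease gene list
#'
#' Plain text, one gene identifier per line; blank lines and \code{#}
#' comments ignored.
#'
#' @param path File path.
#' @return Character vector of gene ids.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x) & !startsWith(x, "#")]
}
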