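#' Distance from a position to the nearest annotated splice site
#'
#' For intronic positions, the count of intronic bases from the nearest of
#' the two flanking splice sites to the position, inclusive of the position
#' itself (the first intronic base of an intron is at distance 1). Exonic
#' positions return 0; positions outside the transcript span return NA.
#'
#' @param pos Vector of 1-based genomic positions.
#' @param t A [transcript_model()].
#' @return Integer vector of distances (0 = exonic, NA = outside the gene).
#' @export
nearest_splice_distance <- function(pos, t) {
  span <- tx_span(t)
  ex <- t$exons
  vapply(as.integer(pos), function(p) {
    if (p < span[1] || p > span[2]) return(NA_integer_)
    if (any(ex[, 1] <= p & p <= ex[, 2])) return(0L)
    i <- max(which(ex[, 2] < p))        # intron between exon i and i+1
    as.integer(min(p - ex[i, 2], ex[i + 1, 1] - p))
  }, 0L)
}

#' Classify variants relative to transcript structure
#'
#' Deep-intronic means intronic and >= 50 bases from the nearest annotated
#' splice site (inclusive boundary). For multi-base reference alleles
#' (deletions) the most splice-proximal affected base determines the call, so
#' an indel is deep-intronic only when it lies wholly in the deep intron.
#'
#' @param v A variant table.
#' @param t A [transcript_model()].
#' @param deep_cutoff Deep-intron distance cutoff in bases (default 50).
#' @return data.frame with columns \code{zone} (one of "exonic",
#'   "near_splice_intronic", "deep_intronic", "outside_gene") and
#'   \code{distance_bp} (NA unless intronic).
#' @export
classify_region <- function(v, t, deep_cutoff = 50L) {
  zones <- character(nrow(v))
  dist <- rep(NA_integer_, nrow(v))
  for (i in seq_len(nrow(v))) {
    span_pos <- v$pos[i] + seq_len(nchar(v$ref[i])) - 1L
    d <- nearest_splice_distance(span_pos, t)
    if (all(is.na(d))) {
      zones[i] <- "outside_gene"
    } else {
      dmin <- min(d, na.rm = TRUE)  # most splice-proximal affected base
      if (dmin == 0L) {
        zones[i] <- "exonic"
      } else {
        dist[i] <- dmin
        zones[i] <- if (dmin >= deep_cutoff) "deep_intronic"
                    else "near_splice_intronic"
      }
    }
  }
  data.frame(zone = zones, distance_bp = dist, stringsAsFactors = FALSE)
}

#' Classify a position relative to a splice-site motif window
#'
#' The donor motif window spans 9 bases (3 exonic + 6 intronic around the
#' donor junction); the acceptor window spans 23 bases (20 intronic + 3
#' exonic). Windows are defined in transcript orientation; \code{site_pos} is
#' the genomic position of the intronic base flanking the junction (first
#' intronic base for a donor, last for an acceptor).
#'
#' @param variant_pos Genomic position of the variant.
#' @param site_pos Genomic position of the splice site.
#' @param kind "donor" or "acceptor".
#' @param strand "+" or "-".
#' @return "donor_motif", "acceptor_motif" or "outside".
#' @export
classify_motif_region <- function(variant_pos, site_pos,
                                  kind = c("donor", "acceptor"),
                                  strand = c("+", "-")) {
  kind <- match.arg(kind)
  strand <- match.arg(strand)
  if (kind == "donor") {
    rng <- if (strand == "+") c(site_pos - 3L, site_pos + 5L)
           else c(site_pos - 5L, site_pos + 3L)
    lab <- "donor_motif"
  } else {
    rng <- if (strand == "+") c(site_pos - 19L, site_pos + 3L)
           else c(site_pos - 3L, site_pos + 19L)
    lab <- "acceptor_motif"
  }
  ifelse(variant_pos >= rng[1] & variant_pos <= rng[2], lab, "outside")
}

# Assign each variant the (single picked) transcript whose span contains it.
# Returns the variant table with gene_id / transcript_id filled in where a
# transcript covers the position; untouched (NA) rows are outside all genes.
#' Assign variants to transcripts by position
#'
#' @param v A variant table.
#' @param txs Named list of [transcript_model()] (one per gene).
#' @return The variant table with \code{gene_id}/\code{transcript_id} filled.
#' @export
assign_genes <- function(v, txs) {
  for (t in txs) {
    span <- tx_span(t)
    hit <- is.na(v$gene_id) & v$chrom == t$chrom &
      v$pos >= span[1] & v$pos <= span[2]
    v$gene_id[hit] <- t$gene_id
    v$transcript_id[hit] <- t$transcript_id
  }
  v
}
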