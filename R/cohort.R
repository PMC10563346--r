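#' Construct a cohort sample
#'
#' One sequenced individual: a sample id plus the variants it carries.
#' Variant keys must be unique within a sample.
#'
#' @param sample_id Identifier.
#' @param v A [variants()] table.
#' @return List of class \code{"cohort_sample"}.
#' @export
cohort_sample <- function(sample_id, v) {
  if (anyDuplicated(variant_key(v)))
    stop("duplicate variant keys in sample ", sample_id)
  structure(list(sample_id = sample_id, variants = v),
            class = "cohort_sample")
}

#' @export
print.cohort_sample <- function(x, ...) {
  cat("<cohort_sample> ", x$sample_id, ": ", nrow(x$variants),
      " variant(s)\n", sep = "")
  invisible(x)
}

#' Prioritize candidate pathogenic deep-intronic variants in one sample
#'
#' The clinical filtering cascade: deep-intronic variants in annotated genes
#' -> restrict to the Mendelian-disease gene list -> rare in every
#' population source (< 1\% AF, missing = 0) -> score complete feature
#' vectors with the trained model (unscorable variants are dropped and
#' counted) -> keep scores at or above the threshold, sorted descending.
#'
#' @param sample A [cohort_sample()].
#' @param genes Character vector of Mendelian-disease gene ids.
#' @param txs,genome,scorer,model,track Annotation inputs as in
#'   [annotate_variants()].
#' @param fit A [pdivas()] fit.
#' @param threshold Minimum score retained (0 ranks every scored variant).
#' @param af_sources Population sources for the rarity filter.
#' @param d,raw_gain_agg Feature-extraction options.
#' @return List: \code{candidates} (data.frame sorted by descending score)
#'   and \code{stage_counts} (named, non-increasing along the cascade).
#' @export
prioritize <- function(sample, genes, txs, genome, scorer,
                       model = default_motif_model(), track = NULL,
                       fit, threshold = 0, af_sources = NULL,
                       d = 300L, raw_gain_agg = "mean") {
  v <- assign_genes(sample$variants, txs)
  counts <- c(input = nrow(v))
  if (is.null(af_sources)) af_sources <- af_sources_of(v)

  zone <- rep("outside_gene", nrow(v))
  for (g in unique(stats::na.omit(v$gene_id))) {
    i <- which(v$gene_id %in% g)
    zone[i] <- classify_region(v[i, , drop = FALSE], txs[[g]])$zone
  }
  v <- v[zone == "deep_intronic", , drop = FALSE]
  counts["deep_intronic"] <- nrow(v)

  v <- v[v$gene_id %in% genes, , drop = FALSE]
  counts["mendelian_gene"] <- nrow(v)

  v <- v[passes_rare_filter(v, af_sources), , drop = FALSE]
  counts["rare"] <- nrow(v)

  if (nrow(v) > 0) {
    ann <- annotate_variants(v, txs, genome, scorer, model, track,
                             d = d, raw_gain_agg = raw_gain_agg)
    scored <- ann[ann$complete, , drop = FALSE]
    counts["scored"] <- nrow(scored)
    scored$score <- predict(fit, scored)
    scored <- scored[scored$score >= threshold, , drop = FALSE]
    scored <- scored[order(-scored$score, scored$key), , drop = FALSE]
  } else {
    scored <- data.frame()
    counts["scored"] <- 0L
  }
  counts["above_threshold"] <- nrow(scored)
  list(candidates = scored, stage_counts = counts)
}

#' Build simulated patients by spiking pathogenic variants into controls
#'
#' The full cross product: every (pathogenic test variant, control sample)
#' pair becomes one simulated patient.
#'
#' @param test_savs A [variants()] table of pathogenic splice-altering
#'   variants.
#' @param cohort List of [cohort_sample()].
#' @return data.frame with one row per simulated patient (\code{sav_key},
#'   \code{sample_id}).
#' @export
simulate_patients <- function(test_savs, cohort) {
  if (nrow(test_savs) == 0 || length(cohort) == 0)
    stop("simulate_patients needs nonempty variants and cohort")
  ids <- vapply(cohort, function(s) s$sample_id, "")
  expand.grid(sav_key = variant_key(test_savs), sample_id = ids,
              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
}

#' Rank of the spiked causative variant among scored candidates
#'
#' Pessimistic tie handling: the rank is the number of candidates whose
#' score is greater than or equal to the spiked variant's score (the spiked
#' variant included), so ties never overstate performance. An unscorable
#' spiked variant is undetected (NA).
#'
#' @param background_scores Scores of the sample's own scored candidates.
#' @param spiked_score Score of the spiked variant (NA = unscorable).
#' @return 1-based rank, or NA for undetected.
#' @export
rank_causative <- function(background_scores, spiked_score) {
  if (is.na(spiked_score)) return(NA_integer_)
  as.integer(1L + sum(background_scores >= spiked_score))
}

#' Undiagnosed rate at top-k rank cutoffs
#'
#' Fraction of simulated patients whose causative variant is not ranked
#' within each cutoff; undetected (NA) ranks count beyond every cutoff.
#'
#' @param ranks Integer ranks from [rank_causative()] (NA = undetected).
#' @param cutoffs Integer rank cutoffs.
#' @return Named numeric vector, non-increasing in the cutoff.
#' @export
undiagnosed_rate <- function(ranks, cutoffs) {
  setNames(vapply(cutoffs, function(c)
    mean(is.na(ranks) | ranks > c), 0.0), paste0("top", cutoffs))
}

#' Run the spike-in ranking benchmark
#'
#' Scores each control sample's candidate list once (threshold-free), scores
#' each pathogenic variant once against the reference, then ranks every
#' spiked variant within every background via [rank_causative()]. The spiked
#' variant inherits AF 0 in every population source.
#'
#' @param test_savs Pathogenic variants to spike.
#' @param cohort List of [cohort_sample()].
#' @param genes,txs,genome,scorer,model,track,fit,af_sources,d,raw_gain_agg
#'   Pipeline inputs as in [prioritize()].
#' @return data.frame: one row per simulated patient with \code{sav_key},
#'   \code{sample_id}, \code{rank} (NA = undetected).
#' @export
run_spikein <- function(test_savs, cohort, genes, txs, genome, scorer,
                        model = default_motif_model(), track = NULL, fit,
                        af_sources = NULL, d = 300L, raw_gain_agg = "mean") {
  patients <- simulate_patients(test_savs, cohort)
  if (is.null(af_sources)) af_sources <- af_sources_of(test_savs)

  # spiked variants: AF 0 everywhere (absent from population databases)
  sav <- test_savs
  for (s in af_sources) sav[[paste0("AF_", s)]] <- 0
  ann <- annotate_variants(sav, txs, genome, scorer, model, track,
                           d = d, raw_gain_agg = raw_gain_agg)
  sav_score <- setNames(rep(NA_real_, nrow(ann)), ann$key)
  ok <- ann$complete
  if (any(ok))
    sav_score[ok] <- predict(fit, ann[ok, , drop = FALSE])

  bg <- lapply(cohort, function(s)
    prioritize(s, genes, txs, genome, scorer, model, track, fit,
               threshold = 0, af_sources = af_sources, d = d,
               raw_gain_agg = raw_gain_agg)$candidates)
  names(bg) <- vapply(cohort, function(s) s$sample_id, "")

  patients$rank <- mapply(function(k, id) {
    cand <- bg[[id]]
    sc <- if (length(cand)) cand$score[cand$key != k] else numeric(0)
    rank_causative(sc, sav_score[k])
  }, patients$sav_key, patients$sample_id)
  patients
}
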