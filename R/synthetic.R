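#' Specification of the synthetic fixture world
#'
#' Describes the toy genome, cohort, and class-conditional feature
#' distributions that emulate, at desk scale, a curated deep-intronic
#' variant dataset and a control cohort: multi-exon genes with introns long
#' enough to host deep-intronic positions, a constraint track with
#' high-constraint disease genes (score >= 0.5) and low-constraint others
#' (< 0.2), pathogenic-like variants that complete pre-embedded near-miss
#' splice motifs deep in introns, and benign variants that are common or
#' neutral.
#'
#' @param seed Global seed; fans out to per-stage child seeds.
#' @param n_genes Number of genes (one per toy contig).
#' @param exons_per_gene Exons per gene.
#' @param intron_range Intron length range (min must be >= 120 so every
#'   intron admits deep-intronic positions under the 50-base rule).
#' @param exon_length Exon length.
#' @param flank Flanking bases outside the gene on each side.
#' @param disease_frac Fraction of genes on the Mendelian-disease list
#'   (these get high constraint scores).
#' @param cryptic_per_intron Near-miss cryptic splice motifs embedded per
#'   intron.
#' @param n_samples Cohort size.
#' @param benign_per_sample,path_per_sample Variants per individual.
#' @param common_frac Fraction of benign cohort variants drawn with common
#'   allele frequencies (>= 5\% in both sources); the rest are rare neutral.
#' @param n_path,n_benign Labeled feature-table rows per class.
#' @param motif_only_frac Fraction of pathogenic feature rows in the
#'   "motif-only" hard stratum (low splice-gain delta, high motif score).
#' @return List of class \code{"synthetic_spec"}.
#' @export
synthetic_spec <- function(seed = 1, n_genes = 20, exons_per_gene = 3,
                           intron_range = c(400, 700), exon_length = 150,
                           flank = 350, disease_frac = 0.5,
                           cryptic_per_intron = 1, n_samples = 50,
                           benign_per_sample = 40, path_per_sample = 2,
                           common_frac = 0.7, n_path = 50, n_benign = 500,
                           motif_only_frac = 0.1) {
  stopifnot(n_genes >= 1, exons_per_gene >= 2, n_samples >= 1,
            n_path >= 1, n_benign >= 1)
  if (intron_range[1] < 120)
    stop("introns must be >= 120 bases to host deep-intronic positions")
  structure(as.list(environment()), class = "synthetic_spec")
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf("<synthetic_spec> %d genes, %d samples, %d+%d labeled rows, seed %d\n",
              x$n_genes, x$n_samples, x$n_path, x$n_benign, x$seed))
  invisible(x)
}

rand_bases <- function(n, prob = c(.3, .2, .2, .3))
  sample(BASES, n, replace = TRUE, prob = prob)

`seq_put<-` <- function(x, at, value) { x[at + seq_along(value) - 1L] <- value; x }

# Near-miss motif templates. Each cryptic site is written as a consensus
# window with one permanent mild mismatch plus one critical mismatch; the
# recorded variant restores the critical base, creating a strong site.
plant_cryptic_donor <- function(chars, c) {
  # window c-3..c+5; permanent mismatch at -1 (G->T), critical at +1 (G->A)
  seq_put(chars, c - 3L) <- c("C", "A", "T", "A", "T", "A", "A", "G", "T")
  list(chars = chars, var_pos = c, ref = "A", alt = "G")
}

plant_cryptic_acceptor <- function(chars, c) {
  # window c-19..c+3; mediocre pyrimidine tract, critical mismatch at the
  # last intronic base (G->T)
  tract <- sample(BASES, 17, replace = TRUE, prob = c(.15, .25, .12, .48))
  seq_put(chars, c - 19L) <- c(tract, "C", "A", "T")
  list(chars = chars, var_pos = c, ref = "T", alt = "G")
}

#' Generate the synthetic reference world
#'
#' Builds a toy genome (one contig per gene), transcript models with
#' consensus splice motifs planted at every annotated junction, cryptic
#' near-miss motifs embedded deep in introns (the substrate for
#' pathogenic-like variants), a constraint track scoring disease genes high
#' and the rest low, and the disease gene list. Deterministic per seed.
#'
#' @param spec A [synthetic_spec()].
#' @param dir Optional directory; when given, writes \code{genome.fa},
#'   \code{transcripts.gtf}, \code{constraint.bed}, \code{genes.txt} and
#'   \code{cryptic_sites.tsv}.
#' @return List of class \code{"pdivas_reference"}: \code{genome}
#'   (DNAStringSet), \code{transcripts}, \code{constraint},
#'   \code{gene_list}, \code{cryptic} (data.frame), \code{spec}.
#' @export
gen_reference <- function(spec, dir = NULL) {
  set.seed(child_seed(spec$seed, 1))
  genomes <- character(spec$n_genes)
  contigs <- sprintf("ctg%02d", seq_len(spec$n_genes))
  gene_ids <- sprintf("G%02d", seq_len(spec$n_genes))
  txs <- list()
  cryptic <- list()
  for (g in seq_len(spec$n_genes)) {
    ne <- spec$exons_per_gene
    introns <- sample(seq(spec$intron_range[1], spec$intron_range[2]), ne - 1,
                      replace = TRUE)
    starts <- spec$flank + 1L +
      cumsum(c(0L, introns + spec$exon_length))[seq_len(ne)]
    ends <- starts + spec$exon_length - 1L
    total <- ends[ne] + spec$flank
    chars <- rand_bases(total)
    for (i in seq_len(ne - 1)) {
      # annotated donor (intron start) and acceptor (intron end) consensus
      seq_put(chars, ends[i] - 2L) <- c("C", "A", "G", "G", "T", "A",
                                        "A", "G", "T")
      tract <- sample(c("T", "C"), 17, replace = TRUE, prob = c(.6, .4))
      seq_put(chars, starts[i + 1] - 20L) <- c(tract, "C", "A", "G")
    }
    for (i in seq_len(ne - 1)) {
      lo <- ends[i] + 1L; hi <- starts[i + 1] - 1L
      if (hi - 60L < lo + 80L) next  # intron too short to host a cryptic site
      used <- integer(0)
      for (j in seq_len(spec$cryptic_per_intron)) {
        for (try in 1:50) {
          c_pos <- sample(seq(lo + 80L, hi - 60L), 1)
          if (all(abs(c_pos - used) > 40L)) break
        }
        used <- c(used, c_pos)
        kind <- sample(c("donor", "acceptor"), 1)
        planted <- if (kind == "donor") plant_cryptic_donor(chars, c_pos)
                   else plant_cryptic_acceptor(chars, c_pos)
        chars <- planted$chars
        cryptic[[length(cryptic) + 1]] <- data.frame(
          chrom = contigs[g], gene_id = gene_ids[g], kind = kind,
          site_pos = c_pos, pos = planted$var_pos, ref = planted$ref,
          alt = planted$alt, stringsAsFactors = FALSE)
      }
    }
    genomes[g] <- paste(chars, collapse = "")
    txs[[gene_ids[g]]] <- transcript_model(
      gene_ids[g], paste0("T", substring(gene_ids[g], 2)), contigs[g], "+",
      cbind(starts, ends))
  }
  genome <- Biostrings::DNAStringSet(setNames(genomes, contigs))
  disease <- sort(sample(gene_ids, round(spec$disease_frac * spec$n_genes)))
  lens <- vapply(genomes, nchar, 0L)
  score <- ifelse(gene_ids %in% disease, runif(spec$n_genes, 0.6, 0.95),
                  runif(spec$n_genes, 0.02, 0.15))
  track <- constraint_track(contigs, 0L, lens, score)
  cryptic <- do.call(rbind, cryptic)
  ref <- structure(list(genome = genome, transcripts = txs,
                        constraint = track, gene_list = disease,
                        cryptic = cryptic, spec = spec),
                   class = "pdivas_reference")
  if (!is.null(dir)) write_reference(ref, dir)
  ref
}

#' @export
print.pdivas_reference <- function(x, ...) {
  cat(sprintf("<pdivas_reference> %d contigs, %d transcripts, %d disease genes, %d cryptic sites\n",
              length(x$genome), length(x$transcripts),
              length(x$gene_list), nrow(x$cryptic)))
  invisible(x)
}

write_reference <- function(ref, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(ref$genome, file.path(dir, "genome.fa"))
  gtf <- unlist(lapply(ref$transcripts, function(t) {
    attrs <- sprintf('gene_id "%s"; transcript_id "%s";',
                     t$gene_id, t$transcript_id)
    c(paste(t$chrom, "synth", "transcript", t$exons[1, 1],
            t$exons[nrow(t$exons), 2], ".", t$strand, ".", attrs,
            sep = "\t"),
      paste(t$chrom, "synth", "exon", t$exons[, 1], t$exons[, 2], ".",
            t$strand, ".", attrs, sep = "\t"))
  }))
  writeLines(gtf, file.path(dir, "transcripts.gtf"))
  utils::write.table(as.data.frame(ref$constraint),
                     file.path(dir, "constraint.bed"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  writeLines(ref$gene_list, file.path(dir, "genes.txt"))
  utils::write.table(ref$cryptic, file.path(dir, "cryptic_sites.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a reference directory written by [gen_reference()]
#'
#' @param dir Directory with genome.fa, transcripts.gtf, constraint.bed,
#'   genes.txt (and optionally cryptic_sites.tsv).
#' @return A \code{"pdivas_reference"} (without a spec).
#' @export
read_reference <- function(dir) {
  cryptic_path <- file.path(dir, "cryptic_sites.tsv")
  structure(list(
    genome = Biostrings::readDNAStringSet(file.path(dir, "genome.fa")),
    transcripts = read_gene_models(file.path(dir, "transcripts.gtf")),
    constraint = read_constraint_track(file.path(dir, "constraint.bed")),
    gene_list = read_gene_list(file.path(dir, "genes.txt")),
    cryptic = if (file.exists(cryptic_path))
      utils::read.table(cryptic_path, header = TRUE, sep = "\t",
                        stringsAsFactors = FALSE) else NULL,
    spec = NULL), class = "pdivas_reference")
}

draw_af <- function(common) {
  if (common) runif(1, 0.05, 0.5) else runif(1, 0, 0.009)
}

#' Generate a synthetic control cohort
#'
#' Per individual: benign variants (a mix of common variants with allele
#' frequency >= 5\% in both population sources and rare neutral
#' substitutions) plus pathogenic-like variants that complete cryptic splice
#' motifs deep inside introns of disease-list genes, carried with allele
#' frequency 0. Truth labels are recorded.
#'
#' @param spec A [synthetic_spec()].
#' @param ref A [gen_reference()] result.
#' @param dir Optional directory for per-sample VCFs and truth.tsv.
#' @return List: \code{cohort} (list of [cohort_sample()]), \code{truth}
#'   (data.frame sample_id, key, label).
#' @export
gen_cohort <- function(spec, ref, dir = NULL) {
  set.seed(child_seed(spec$seed, 2))
  lens <- vapply(as.character(ref$genome), nchar, 0L)
  contigs <- names(ref$genome)
  cry_disease <- ref$cryptic[ref$cryptic$gene_id %in% ref$gene_list, ,
                             drop = FALSE]
  cohort <- vector("list", spec$n_samples)
  truth <- list()
  for (s in seq_len(spec$n_samples)) {
    id <- sprintf("S%03d", s)
    rows <- list()
    keys <- character(0)
    for (b in seq_len(spec$benign_per_sample)) {
      repeat {
        ci <- sample(length(contigs), 1)
        p <- sample(seq(60L, lens[ci] - 60L), 1)
        if (any(ref$cryptic$chrom == contigs[ci] &
                abs(ref$cryptic$pos - p) <= 25L)) next  # keep clear of motifs
        rb <- substr(as.character(ref$genome[[ci]]), p, p)
        ab <- sample(setdiff(BASES, rb), 1)
        k <- paste(contigs[ci], p, rb, ab, sep = ":")
        if (!k %in% keys) break
      }
      keys <- c(keys, k)
      common <- runif(1) < spec$common_frac
      rows[[length(rows) + 1]] <- data.frame(
        chrom = contigs[ci], pos = p, ref = rb, alt = ab,
        af1 = draw_af(common), af2 = draw_af(common),
        label = "benign", stringsAsFactors = FALSE)
    }
    pick <- sample(nrow(cry_disease), min(spec$path_per_sample,
                                          nrow(cry_disease)))
    for (i in pick) {
      cr <- cry_disease[i, ]
      k <- paste(cr$chrom, cr$pos, cr$ref, cr$alt, sep = ":")
      if (k %in% keys) next
      keys <- c(keys, k)
      rows[[length(rows) + 1]] <- data.frame(
        chrom = cr$chrom, pos = cr$pos, ref = cr$ref, alt = cr$alt,
        af1 = 0, af2 = 0, label = "pathogenic", stringsAsFactors = FALSE)
    }
    df <- do.call(rbind, rows)
    v <- variants(df$chrom, df$pos, df$ref, df$alt,
                  af = list(gnomAD = df$af1, KGP = df$af2))
    cohort[[s]] <- cohort_sample(id, v)
    truth[[s]] <- data.frame(sample_id = id, key = variant_key(v),
                             label = df$label, stringsAsFactors = FALSE)
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      write_vcf_scores(v, NULL, file.path(dir, paste0(id, ".vcf")))
    }
  }
  truth <- do.call(rbind, truth)
  if (!is.null(dir))
    utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  list(cohort = cohort, truth = truth)
}

#' Generate a class-conditional labeled feature table
#'
#' Emulates the qualitative class separations of a curated dataset:
#' pathogenic splice-gain deltas concentrated high with a ~10\% "motif-only"
#' hard stratum (delta <= 0.2 but high motif score), benign deltas low,
#' benign constraint mass mostly below 0.2, raw scores exceeding deltas.
#' Deterministic per seed.
#'
#' @param spec A [synthetic_spec()].
#' @return data.frame with \code{key}, \code{label}
#'   ("pathogenic"/"benign") and the five [pdivas_features()] columns.
#' @export
gen_feature_table <- function(spec) {
  set.seed(child_seed(spec$seed, 3))
  np <- spec$n_path; nb <- spec$n_benign
  n_mo <- round(spec$motif_only_frac * np)
  n_main <- np - n_mo

  del_max_p <- c(rbeta(n_main, 8, 2), runif(n_mo, 0, 0.2))
  mes_p <- c(rbeta(n_main, 3, 2), rbeta(n_mo, 10, 2))
  raw_p <- pmin(1, pmax(del_max_p, rbeta(np, 6, 2)))
  path <- data.frame(
    label = "pathogenic",
    spliceai_del_gain_mean = del_max_p * runif(np, 0.6, 1),
    spliceai_del_gain_max = del_max_p,
    spliceai_raw_gain_mean = raw_p,
    consplice = rbeta(np, 6, 2),
    maxentscan = mes_p, stringsAsFactors = FALSE)

  del_max_b <- rbeta(nb, 1.2, 10)
  benign <- data.frame(
    label = "benign",
    spliceai_del_gain_mean = del_max_b * runif(nb, 0.5, 1),
    spliceai_del_gain_max = del_max_b,
    spliceai_raw_gain_mean = pmin(1, pmax(del_max_b, rbeta(nb, 2, 6))),
    consplice = rbeta(nb, 1.2, 8),
    maxentscan = rbeta(nb, 1.5, 8), stringsAsFactors = FALSE)

  out <- rbind(path, benign)
  out <- cbind(key = sprintf("synth:%04d", seq_len(np + nb)), out,
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Run the whole synthetic pipeline end to end
#'
#' Generate the reference world and cohort, generate and split the labeled
#' feature table, tune and train the forest, evaluate held-out performance,
#' compute the sensitivity threshold table, prioritize each control sample,
#' and run the spike-in ranking benchmark on a subset of (variant, sample)
#' pairs.
#'
#' @param spec A [synthetic_spec()].
#' @param grid Tuning grid (default the reduced grid, sized for desk runs).
#' @param n_spike_savs,n_spike_samples Spike-in subset sizes.
#' @param threshold_level Sensitivity level (percent) used to pick the
#'   prioritization threshold.
#' @return List with the generated objects, the fit, the held-out
#'   evaluation, the threshold table, per-sample candidate counts, and the
#'   spike-in rank table.
#' @export
synthetic_pipeline <- function(spec = synthetic_spec(),
                               grid = pdivas_grid_small(),
                               n_spike_savs = 10, n_spike_samples = 10,
                               threshold_level = 95) {
  ref <- gen_reference(spec)
  coh <- gen_cohort(spec, ref)
  tab <- gen_feature_table(spec)

  y <- as.integer(tab$label == "pathogenic")
  sp <- split_dataset(sum(y == 1), sum(y == 0), 0.7,
                      child_seed(spec$seed, 4))
  ip <- which(y == 1); ib <- which(y == 0)
  tr <- c(ip[sp$idx$path_train], ib[sp$idx$benign_train])
  te <- setdiff(seq_along(y), tr)

  fit <- pdivas(tab[tr, ], y[tr], grid = grid, seed = child_seed(spec$seed, 5))
  test_scores <- predict(fit, tab[te, ])
  ev <- eval_curves(y[te], test_scores)
  tt <- threshold_table(test_scores[y[te] == 1])
  thr <- threshold_for_sensitivity(test_scores[y[te] == 1], threshold_level)

  scorer <- pwm_site_scorer()
  prio <- lapply(coh$cohort[seq_len(min(3, length(coh$cohort)))], function(s)
    prioritize(s, ref$gene_list, ref$transcripts, ref$genome, scorer,
               track = ref$constraint, fit = fit, threshold = thr))

  set.seed(child_seed(spec$seed, 6))
  cry <- ref$cryptic[ref$cryptic$gene_id %in% ref$gene_list, , drop = FALSE]
  pick <- cry[sample(nrow(cry), min(n_spike_savs, nrow(cry))), ]
  savs <- variants(pick$chrom, pick$pos, pick$ref, pick$alt,
                   af = list(gnomAD = 0, KGP = 0))
  sub <- coh$cohort[sample(length(coh$cohort),
                           min(n_spike_samples, length(coh$cohort)))]
  spikes <- run_spikein(savs, sub, ref$gene_list, ref$transcripts,
                        ref$genome, scorer, track = ref$constraint,
                        fit = fit)
  list(reference = ref, cohort = coh, features = tab, split = sp, fit = fit,
       eval = ev, thresholds = tt, threshold = thr, prioritization = prio,
       spikein = spikes)
}
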