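#' @title Imprinting calls from reciprocal-cross allele counts
#' @description
#' MEGs and PEGs are called from allele-resolved endosperm counts of a
#' reciprocal interspecies cross. For each gene and each pairing of one
#' sample per cross direction, the proportion of species-A reads is compared
#' between the two directions with a two-sided Fisher's exact test. Because
#' the endosperm of this system is diploid (1:1 maternal:paternal), the
#' anticipated null ratio is 1; an observed genome-wide maternal expression
#' bias shifts that null, so maternal counts are divided by the bias ratio
#' beta (default 1.32, i.e. a null maternal proportion of 1.32/2.32 = 0.57)
#' and rounded half away from zero before testing. Calls are additionally
#' gated on maternal-fraction thresholds (70%/30%), a confidence-interval
#' based imprinting factor (>= 2), a cis-effect factor (<= 15) that excludes
#' genes with a shared species-of-allele bias, and cross-replicate
#' consistency (called in >= 75% of all direction-1 x direction-2 pairings).
#' @name imprinting
NULL

#' Configuration for imprinting calls
#'
#' @param beta maternal:paternal expression bias ratio used as the null
#'   (default 1.32); use [estimate_maternal_bias()] to estimate it from data
#' @param alpha BH-adjusted significance cutoff (default 0.01)
#' @param min_reads minimum allele-specific reads per gene in EACH sample of
#'   a comparison (default 50)
#' @param min_if minimum imprinting factor (default 2)
#' @param max_cef maximum cis-effect factor (default 15)
#' @param meg_min_maternal minimum maternal fraction, both directions, for a
#'   MEG (default 0.70, boundary inclusive)
#' @param peg_max_maternal maximum maternal fraction, both directions, for a
#'   PEG (default 0.30, boundary inclusive)
#' @param consistency_min fraction of pairwise comparisons in which a gene
#'   must be called to be consolidated (default 0.75)
#' @param ci_level confidence level of the Wilson intervals behind the
#'   imprinting and cis-effect factors (default 0.95)
#' @return list of class `imprinting_config`
#' @export
imprinting_config <- function(beta = 1.32, alpha = 0.01, min_reads = 50,
                              min_if = 2, max_cef = 15,
                              meg_min_maternal = 0.70, peg_max_maternal = 0.30,
                              consistency_min = 0.75, ci_level = 0.95) {
  stopifnot(beta > 0, alpha > 0, alpha < 1, min_reads >= 0,
            min_if >= 0, max_cef >= 1,
            peg_max_maternal >= 0, peg_max_maternal < meg_min_maternal,
            meg_min_maternal <= 1,
            consistency_min > 0, consistency_min <= 1,
            ci_level > 0, ci_level < 1)
  structure(list(beta = beta, alpha = alpha, min_reads = min_reads,
                 min_if = min_if, max_cef = max_cef,
                 meg_min_maternal = meg_min_maternal,
                 peg_max_maternal = peg_max_maternal,
                 consistency_min = consistency_min, ci_level = ci_level),
            class = "imprinting_config")
}

# maternal / paternal count columns of one sample, given the table's species
.mat_pat_counts <- function(tab, sample_row) {
  sp <- species_labels(tab)
  sub <- tab[tab$sample_id == sample_row$sample_id, , drop = FALSE]
  if (sample_row$maternal_species == sp[1]) {
    list(gene_id = sub$gene_id, maternal = sub$count_A, paternal = sub$count_B)
  } else if (sample_row$maternal_species == sp[2]) {
    list(gene_id = sub$gene_id, maternal = sub$count_B, paternal = sub$count_A)
  } else {
    stop("consistency error: sample ", sample_row$sample_id,
         " has maternal species ", sample_row$maternal_species,
         " not present in the count table", call. = FALSE)
  }
}

#' Estimate the genome-wide maternal expression bias
#'
#' Per sample, over genes passing the read filter in that sample, the pooled
#' maternal:paternal read ratio is computed; per cross direction the maximum
#' over replicates is taken, and the returned bias is the arithmetic mean of
#' the two directional maxima ("average maximum observed maternal allele
#' expression bias").
#'
#' @param tab `allele_counts`
#' @param samples `cross_samples` (endosperm hybrids of both directions)
#' @param min_reads per-gene, per-sample allele-specific read cutoff
#' @return bias ratio beta > 0
#' @export
estimate_maternal_bias <- function(tab, samples, min_reads = 50) {
  samples <- as.data.frame(samples)
  dir_key <- paste(samples$maternal_species, samples$paternal_species, sep = "x")
  dirs <- unique(dir_key)
  if (length(dirs) != 2) {
    stop("configuration error: need samples from exactly 2 cross directions, ",
         "found ", length(dirs), call. = FALSE)
  }
  per_sample <- vapply(seq_len(nrow(samples)), function(i) {
    mp <- .mat_pat_counts(tab, samples[i, ])
    pass <- (mp$maternal + mp$paternal) >= min_reads
    pat <- sum(mp$paternal[pass])
    if (pat == 0) {
      stop("value error: zero paternal reads over passing genes in sample ",
           samples$sample_id[i], call. = FALSE)
    }
    sum(mp$maternal[pass]) / pat
  }, numeric(1))
  maxima <- tapply(per_sample, dir_key, max)
  mean(maxima)
}

# beta adjustment: maternal counts divided by beta, rounded half away from
# zero; paternal counts untouched
.adjust_maternal <- function(maternal, beta) round_half_away(maternal / beta)

#' Bias-adjusted exact test for one gene in one reciprocal comparison
#'
#' Builds the 2x2 table of species-A vs species-B reads in the two cross
#' directions after dividing each maternal count by `beta` (rounding half
#' away from zero; `beta = 1` leaves counts unchanged) and applies a
#' two-sided Fisher's exact test. Maternal fractions are reported from the
#' unadjusted counts.
#'
#' @param counts_dir1 c(maternal, paternal) reads in the direction where
#'   species A is the mother
#' @param counts_dir2 c(maternal, paternal) reads in the direction where
#'   species B is the mother
#' @param config `imprinting_config`
#' @return list with p_raw, maternal_fraction_dir1, maternal_fraction_dir2,
#'   and the adjusted 2x2 `table` (rows = directions, cols = species A/B)
#' @export
test_gene_pair <- function(counts_dir1, counts_dir2,
                           config = imprinting_config()) {
  stopifnot(length(counts_dir1) == 2, length(counts_dir2) == 2)
  if (any(c(counts_dir1, counts_dir2) < 0)) {
    stop("value error: negative counts", call. = FALSE)
  }
  m1 <- counts_dir1[1]; p1 <- counts_dir1[2]
  m2 <- counts_dir2[1]; p2 <- counts_dir2[2]
  tab <- rbind(dir1 = c(A = .adjust_maternal(m1, config$beta), B = p1),
               dir2 = c(A = p2, B = .adjust_maternal(m2, config$beta)))
  list(p_raw = fisher_p(tab),
       maternal_fraction_dir1 = if (m1 + p1 > 0) m1 / (m1 + p1) else NA_real_,
       maternal_fraction_dir2 = if (m2 + p2 > 0) m2 / (m2 + p2) else NA_real_,
       table = tab)
}

# Wilson ratio interval on the species-A proportion of each sample, after
# beta adjustment. x_a, x_b: species-A / species-B counts (vectorised).
.ratio_interval <- function(x_a, x_b, level) {
  n <- x_a + x_b
  ci <- wilson_interval(x_a, pmax(n, 1), level = level)
  list(lo = .prop_to_ratio(ci$lower), hi = .prop_to_ratio(ci$upper),
       point = ifelse(x_b > 0, x_a / x_b, Inf))
}

# species-A / species-B adjusted counts of both samples of one comparison
.species_adjusted <- function(m1, p1, m2, p2, beta) {
  list(a1 = .adjust_maternal(m1, beta), b1 = p1,
       a2 = p2, b2 = .adjust_maternal(m2, beta))
}

#' Imprinting factor (vectorised)
#'
#' A confidence-interval based measure of the magnitude of imprinting: per
#' sample a Wilson interval on the (beta-adjusted) species-A read proportion
#' is transformed to a species-A:species-B ratio interval; the factor is the
#' lower ratio bound of the sample with the larger point-estimate ratio
#' divided by the upper ratio bound of the other sample. Values below 1 mean
#' the two intervals overlap (no separation between cross directions).
#'
#' @param counts_dir1,counts_dir2 c(maternal, paternal) vectors or 2-column
#'   matrices (rows = genes)
#' @param config `imprinting_config`
#' @return numeric vector of factors >= 0 (Inf possible at extreme counts)
#' @export
imprinting_factor <- function(counts_dir1, counts_dir2,
                              config = imprinting_config()) {
  c1 <- rbind(counts_dir1); c2 <- rbind(counts_dir2)
  sp <- .species_adjusted(c1[, 1], c1[, 2], c2[, 1], c2[, 2], config$beta)
  r1 <- .ratio_interval(sp$a1, sp$b1, config$ci_level)
  r2 <- .ratio_interval(sp$a2, sp$b2, config$ci_level)
  one_high <- r1$point >= r2$point
  lo_high <- ifelse(one_high, r1$lo, r2$lo)
  hi_low <- ifelse(one_high, r2$hi, r1$hi)
  out <- ifelse(is.infinite(lo_high) & is.infinite(hi_low), 1,
         ifelse(is.infinite(hi_low), 0, lo_high / hi_low))
  unname(out)
}

#' Cis-effect factor (vectorised)
#'
#' Measures species-of-allele (strain) expression bias shared across both
#' cross directions, using the same beta-adjusted Wilson ratio intervals in
#' species-A:species-B orientation for BOTH samples: if both lower ratio
#' bounds exceed 1 the factor is the smaller lower bound; if both upper
#' bounds are below 1 it is the reciprocal of the larger upper bound;
#' otherwise (directions disagree) it is 1. Genes with a factor above
#' `max_cef` are excluded from MEG/PEG status.
#'
#' @inheritParams imprinting_factor
#' @return numeric vector of factors >= 1
#' @export
cis_effect_factor <- function(counts_dir1, counts_dir2,
                              config = imprinting_config()) {
  c1 <- rbind(counts_dir1); c2 <- rbind(counts_dir2)
  sp <- .species_adjusted(c1[, 1], c1[, 2], c2[, 1], c2[, 2], config$beta)
  r1 <- .ratio_interval(sp$a1, sp$b1, config$ci_level)
  r2 <- .ratio_interval(sp$a2, sp$b2, config$ci_level)
  out <- rep(1, length(r1$lo))
  both_up <- r1$lo > 1 & r2$lo > 1
  out[both_up] <- pmin(r1$lo, r2$lo)[both_up]
  both_down <- r1$hi < 1 & r2$hi < 1
  out[both_down] <- (1 / pmax(r1$hi, r2$hi))[both_down]
  unname(out)
}

#' Call one reciprocal pairwise comparison
#'
#' Tests every gene of the table for the given pair of samples (one per
#' cross direction), BH-adjusts the p-values of the testable genes, and
#' assigns status: MEG iff p_adj < alpha AND both maternal fractions >=
#' `meg_min_maternal` AND imprinting factor >= `min_if` AND cis-effect
#' factor <= `max_cef`; PEG symmetric with fractions <= `peg_max_maternal`.
#' Genes failing the per-sample read cutoff are `untestable`.
#'
#' @param tab `allele_counts`
#' @param sample_dir1,sample_dir2 single rows of the `cross_samples` sheet
#'   from opposite cross directions
#' @param config `imprinting_config`
#' @return data.frame (one row per gene) with test results and status
#' @export
call_comparison <- function(tab, sample_dir1, sample_dir2,
                            config = imprinting_config()) {
  sample_dir1 <- as.data.frame(sample_dir1)
  sample_dir2 <- as.data.frame(sample_dir2)
  if (sample_dir1$maternal_species == sample_dir2$maternal_species) {
    stop("configuration error: the two samples of a comparison must be from ",
         "opposite cross directions", call. = FALSE)
  }
  mp1 <- .mat_pat_counts(tab, sample_dir1)
  mp2 <- .mat_pat_counts(tab, sample_dir2)
  stopifnot(identical(mp1$gene_id, mp2$gene_id))
  genes <- mp1$gene_id
  m1 <- mp1$maternal; p1 <- mp1$paternal
  m2 <- mp2$maternal; p2 <- mp2$paternal
  testable <- (m1 + p1) >= config$min_reads & (m2 + p2) >= config$min_reads

  sp <- .species_adjusted(m1, p1, m2, p2, config$beta)
  p_raw <- rep(NA_real_, length(genes))
  idx <- which(testable)
  p_raw[idx] <- vapply(idx, function(i) {
    fisher_p(rbind(c(sp$a1[i], sp$b1[i]), c(sp$a2[i], sp$b2[i])))
  }, numeric(1))
  p_adj <- rep(NA_real_, length(genes))
  p_adj[idx] <- stats::p.adjust(p_raw[idx], method = "BH")

  f1 <- ifelse(m1 + p1 > 0, m1 / (m1 + p1), NA_real_)
  f2 <- ifelse(m2 + p2 > 0, m2 / (m2 + p2), NA_real_)

  impf <- cef <- rep(NA_real_, length(genes))
  if (length(idx)) {
    impf[idx] <- imprinting_factor(cbind(m1, p1)[idx, , drop = FALSE],
                                   cbind(m2, p2)[idx, , drop = FALSE], config)
    cef[idx] <- cis_effect_factor(cbind(m1, p1)[idx, , drop = FALSE],
                                  cbind(m2, p2)[idx, , drop = FALSE], config)
  }

  status <- rep("untestable", length(genes))
  status[idx] <- "none"
  sig <- testable & !is.na(p_adj) & p_adj < config$alpha &
         impf >= config$min_if & cef <= config$max_cef
  sig[is.na(sig)] <- FALSE
  status[sig & f1 >= config$meg_min_maternal & f2 >= config$meg_min_maternal] <- "MEG"
  status[sig & f1 <= config$peg_max_maternal & f2 <= config$peg_max_maternal] <- "PEG"

  data.frame(gene_id = genes,
             comparison_id = paste(sample_dir1$sample_id,
                                   sample_dir2$sample_id, sep = "_vs_"),
             testable = testable, p_raw = p_raw, p_adj = p_adj,
             maternal_fraction_dir1 = f1, maternal_fraction_dir2 = f2,
             imprinting_factor = impf, cis_effect_factor = cef,
             status = status, stringsAsFactors = FALSE)
}

#' Enumerate all reciprocal pairwise comparisons of a sample sheet
#'
#' All pairings of one endosperm sample from each cross direction (e.g. a
#' 2+2 replicate design yields 4 comparisons).
#'
#' @param samples `cross_samples`
#' @return data.frame with columns sample_dir1, sample_dir2 (sample ids)
#' @export
enumerate_comparisons <- function(samples) {
  samples <- as.data.frame(samples)
  samples <- samples[samples$tissue == "endosperm" &
                     samples$maternal_species != samples$paternal_species, ,
                     drop = FALSE]
  dir_key <- paste(samples$maternal_species, samples$paternal_species, sep = "x")
  dirs <- sort(unique(dir_key))
  if (length(dirs) != 2) {
    stop("configuration error: need hybrid endosperm samples from exactly 2 ",
         "cross directions, found ", length(dirs), call. = FALSE)
  }
  s1 <- samples$sample_id[dir_key == dirs[1]]
  s2 <- samples$sample_id[dir_key == dirs[2]]
  expand.grid(sample_dir1 = s1, sample_dir2 = s2,
              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
}

#' Run every reciprocal comparison of a dataset
#'
#' @param tab `allele_counts`
#' @param samples `cross_samples`
#' @param config `imprinting_config`
#' @return named list of per-comparison data.frames (see [call_comparison()])
#' @export
call_all_comparisons <- function(tab, samples, config = imprinting_config()) {
  pairs <- enumerate_comparisons(samples)
  samples <- as.data.frame(samples)
  out <- lapply(seq_len(nrow(pairs)), function(i) {
    call_comparison(tab,
                    samples[samples$sample_id == pairs$sample_dir1[i], ],
                    samples[samples$sample_id == pairs$sample_dir2[i], ],
                    config)
  })
  names(out) <- vapply(out, function(df) df$comparison_id[1], character(1))
  out
}

#' Consolidate per-comparison calls with the consistency rule
#'
#' The denominator is the total number of possible direction-1 x direction-2
#' pairings; an untestable gene counts as not called. A gene is a
#' consolidated MEG iff it is called MEG in at least `consistency_min` of
#' all pairings (e.g. 3 of 4), symmetrically for PEGs. A gene passing both
#' rules (impossible with disjoint fraction gates, kept as a guard) is
#' reported as `none` with a log note.
#'
#' @param comparisons list of data.frames from [call_comparison()]
#' @param config `imprinting_config`
#' @return data.frame with gene_id, n_comparisons_total, n_called_MEG,
#'   n_called_PEG, final_status
#' @export
consolidate_calls <- function(comparisons, config = imprinting_config()) {
  if (length(comparisons) == 0) {
    stop("configuration error: zero comparisons to consolidate", call. = FALSE)
  }
  all_df <- do.call(rbind, comparisons)
  genes <- sort(unique(all_df$gene_id))
  n_total <- length(comparisons)
  f <- factor(all_df$gene_id, levels = genes)
  n_meg <- as.vector(rowsum((all_df$status == "MEG") + 0, f))
  n_peg <- as.vector(rowsum((all_df$status == "PEG") + 0, f))
  meg_ok <- n_meg / n_total >= config$consistency_min
  peg_ok <- n_peg / n_total >= config$consistency_min
  final <- ifelse(meg_ok & peg_ok, "none",
           ifelse(meg_ok, "MEG", ifelse(peg_ok, "PEG", "none")))
  if (any(meg_ok & peg_ok)) {
    log_note(sum(meg_ok & peg_ok), " gene(s) passed both MEG and PEG ",
             "consistency; reported as none")
  }
  data.frame(gene_id = genes, n_comparisons_total = n_total,
             n_called_MEG = n_meg, n_called_PEG = n_peg,
             final_status = final, stringsAsFactors = FALSE)
}
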