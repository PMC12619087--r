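#' @title Whole-seed (maternal tissue) contamination correction
#' @description
#' Endosperm dissections can carry transcripts from surrounding maternal
#' (sporophytic) seed tissue, which inflates maternal-allele counts and can
#' create spurious MEG calls. Given a whole-seed expression profile and an
#' assumed contaminated fraction f of the endosperm transcript pool, the
#' expected number of contaminating reads for gene g in a sample with T
#' allele-specific reads is f * T * share_g; that many reads are subtracted
#' from the gene's maternal-allele count (contaminating tissue is maternal
#' sporophyte, so it carries only maternal alleles), clamped at zero, and
#' imprinting is re-called on the corrected table.
#' @name contamination
NULL

#' Correct maternal-allele counts for assumed whole-seed contamination
#'
#' @param tab `allele_counts`
#' @param samples `cross_samples`
#' @param profile `wholeseed_profile` (gene shares summing to 1; genes absent
#'   from the profile get share 0)
#' @param f assumed contaminated fraction of the endosperm transcript pool,
#'   in [0, 1); the study's grid is c(0.25, 0.5)
#' @return corrected `allele_counts` (paternal counts unchanged)
#' @export
correct_maternal_counts <- function(tab, samples, profile, f) {
  if (!is.numeric(f) || length(f) != 1 || f < 0 || f >= 1) {
    stop("value error: f must be a single number in [0, 1)", call. = FALSE)
  }
  if (abs(sum(profile$share) - 1) > 1e-9) {
    stop("value error: whole-seed profile is not normalised", call. = FALSE)
  }
  if (f == 0) return(tab)
  sp <- species_labels(tab)
  samples <- as.data.frame(samples)
  out <- as.data.frame(tab)
  share <- stats::setNames(profile$share, profile$gene_id)
  for (i in seq_len(nrow(samples))) {
    sid <- samples$sample_id[i]
    rows <- which(out$sample_id == sid)
    if (!length(rows)) next
    total <- sum(out$count_A[rows] + out$count_B[rows])
    g_share <- share[out$gene_id[rows]]
    g_share[is.na(g_share)] <- 0
    contam <- f * total * g_share
    mat_col <- if (samples$maternal_species[i] == sp[1]) "count_A"
               else "count_B"
    corrected <- pmax(0, round_half_away(out[[mat_col]][rows] - contam))
    out[[mat_col]][rows] <- corrected
  }
  allele_counts(out, sp[1], sp[2])
}

#' Compare corrected and uncorrected consolidated MEG calls
#'
#' For each assumed contamination fraction, reports the corrected MEG set,
#' whether it is a subset of the uncorrected MEG set, and the genes lost
#' (and, should the monotonicity of the correction ever be violated,
#' gained — logged as an anomaly).
#'
#' @param original consolidated calls of the uncorrected table
#'   (from [consolidate_calls()])
#' @param corrected named list of consolidated calls, one per f (names are
#'   the f values)
#' @return data.frame with one row per f: f, n_meg_original, n_meg_corrected,
#'   is_subset, n_lost, n_gained, plus attribute `sets` (list of per-f MEG
#'   id vectors and lost/gained genes)
#' @export
corrected_call_report <- function(original, corrected) {
  stopifnot(is.list(corrected), length(corrected) >= 1)
  orig_genes <- sort(original$gene_id)
  meg0 <- original$gene_id[original$final_status == "MEG"]
  rows <- list(); sets <- list()
  for (fname in names(corrected)) {
    cc <- corrected[[fname]]
    if (!identical(sort(cc$gene_id), orig_genes)) {
      stop("consistency error: corrected and original call tables cover ",
           "different gene universes", call. = FALSE)
    }
    meg_f <- cc$gene_id[cc$final_status == "MEG"]
    gained <- setdiff(meg_f, meg0)
    lost <- setdiff(meg0, meg_f)
    if (length(gained)) {
      log_note("anomaly: ", length(gained), " gene(s) became MEG only after ",
               "correction at f=", fname)
    }
    rows[[fname]] <- data.frame(f = as.numeric(fname),
                                n_meg_original = length(meg0),
                                n_meg_corrected = length(meg_f),
                                is_subset = length(gained) == 0,
                                n_lost = length(lost),
                                n_gained = length(gained))
    sets[[fname]] <- list(meg = meg_f, lost = lost, gained = gained)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "sets") <- sets
  out
}
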