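#' @title DMR calling, feature association and metagene profiles
#' @description
#' Differentially methylated regions between two allele-resolved methylomes
#' are called per sequence context (CG / CHG / CHH) in fixed, non-overlapping
#' 300-bp windows anchored at position 1. A window is eligible when at least
#' `min_cytosines` cytosines of the context are covered by at least
#' `min_coverage` reads in BOTH methylomes; its methylation level is the
#' weighted (pooled-count) percent over eligible cytosines, and its p-value a
#' two-sided Fisher's exact test on the pooled methylated/unmethylated
#' counts. BH adjustment runs per context over all eligible windows of one
#' comparison; a DMR additionally requires the context-specific absolute
#' difference (35 points CG/CHG, 10 points CHH). DMRs are associated with
#' genes/repeats by any overlap with the feature interval extended by
#' +/- 2 kb, and gene associations are consolidated across replicate
#' comparisons with a 75% / 25% (same / opposite direction) rule.
#' @name methylation
NULL

#' Configuration for DMR calling and feature association
#'
#' @param window_size window width in bp (default 300)
#' @param min_cytosines minimum eligible cytosines per window (default 3)
#' @param min_coverage minimum reads per cytosine in each methylome
#'   (default 5)
#' @param min_diff_cg,min_diff_chg,min_diff_chh minimum absolute methylation
#'   difference in percentage points (defaults 35 / 35 / 10)
#' @param alpha BH-adjusted p-value cutoff (default 0.01)
#' @param flank bp added on both sides of a feature for DMR association
#'   (default 2000)
#' @param assoc_min minimum fraction of comparisons with a same-direction
#'   overlap (default 0.75, boundary inclusive)
#' @param assoc_max_opposite maximum fraction with an opposite-direction
#'   overlap (default 0.25, boundary inclusive)
#' @param merge_adjacent merge runs of adjacent significant windows into one
#'   region (off by default; the pipeline counts windows)
#' @return list of class `dmr_config`
#' @export
dmr_config <- function(window_size = 300, min_cytosines = 3, min_coverage = 5,
                       min_diff_cg = 35, min_diff_chg = 35, min_diff_chh = 10,
                       alpha = 0.01, flank = 2000, assoc_min = 0.75,
                       assoc_max_opposite = 0.25, merge_adjacent = FALSE) {
  stopifnot(window_size >= 1, min_cytosines >= 1, min_coverage >= 0,
            alpha > 0, alpha < 1, flank >= 0,
            min_diff_cg > 0, min_diff_cg <= 100,
            min_diff_chg > 0, min_diff_chg <= 100,
            min_diff_chh > 0, min_diff_chh <= 100,
            assoc_min > 0, assoc_min <= 1,
            assoc_max_opposite >= 0, assoc_max_opposite <= 1)
  structure(list(window_size = window_size, min_cytosines = min_cytosines,
                 min_coverage = min_coverage,
                 min_diff = c(CG = min_diff_cg, CHG = min_diff_chg,
                              CHH = min_diff_chh),
                 alpha = alpha, flank = flank, assoc_min = assoc_min,
                 assoc_max_opposite = assoc_max_opposite,
                 merge_adjacent = merge_adjacent),
            class = "dmr_config")
}

#' Tile contigs into fixed windows
#'
#' Non-overlapping tiles starting at position 1: [1..w], [w+1..2w], ...; the
#' final partial tile is retained.
#'
#' @param contig_lengths named numeric vector of contig lengths
#' @param window_size window width in bp
#' @return data.frame with contig, start, end (1-based inclusive)
#' @export
tile_windows <- function(contig_lengths, window_size = 300) {
  stopifnot(all(contig_lengths >= 1), !is.null(names(contig_lengths)))
  out <- lapply(names(contig_lengths), function(ctg) {
    len <- contig_lengths[[ctg]]
    starts <- seq(1, len, by = window_size)
    data.frame(contig = ctg, start = starts,
               end = pmin(starts + window_size - 1, len),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Test one window of one context
#'
#' Eligible cytosines are positions covered by at least `min_coverage` reads
#' in BOTH methylomes. With fewer than `min_cytosines` eligible positions the
#' window is ineligible (returns NULL; excluded from BH downstream). Levels
#' are weighted methylation percents over eligible cytosines, and p_raw a
#' two-sided Fisher's exact test on the pooled counts.
#'
#' @param cyt1,cyt2 `cx_report`-shaped data.frames restricted to one window
#'   and one context (position-matched by contig/position/strand)
#' @param config `dmr_config`
#' @return list(n_eligible, level_1, level_2, diff, p_raw) or NULL
#' @export
window_test <- function(cyt1, cyt2, config = dmr_config()) {
  if (length(unique(c(cyt1$context, cyt2$context))) > 1) {
    stop("consistency error: window_test called with mixed contexts",
         call. = FALSE)
  }
  m <- merge(cyt1, cyt2, by = c("contig", "position", "strand"),
             suffixes = c("_1", "_2"))
  cov1 <- m$n_meth_1 + m$n_unmeth_1
  cov2 <- m$n_meth_2 + m$n_unmeth_2
  ok <- cov1 >= config$min_coverage & cov2 >= config$min_coverage
  if (sum(ok) < config$min_cytosines) return(NULL)
  m <- m[ok, , drop = FALSE]
  meth1 <- sum(m$n_meth_1); unm1 <- sum(m$n_unmeth_1)
  meth2 <- sum(m$n_meth_2); unm2 <- sum(m$n_unmeth_2)
  lev1 <- 100 * meth1 / (meth1 + unm1)
  lev2 <- 100 * meth2 / (meth2 + unm2)
  list(n_eligible = sum(ok), level_1 = lev1, level_2 = lev2,
       diff = lev1 - lev2,
       p_raw = fisher_p(rbind(c(meth1, unm1), c(meth2, unm2))))
}

#' Call DMRs between two methylomes
#'
#' Applies [window_test()] to every window x context, BH-adjusts per context
#' across all eligible windows of this comparison, and resolves `is_dmr`
#' (|diff| at or above the context threshold AND p_adj < alpha) and
#' `direction` (`hyper_1` when methylome 1 is the more methylated).
#'
#' @param methylome_1,methylome_2 `cx_report` data.frames on the same
#'   coordinate system
#' @param contig_lengths named vector of contig lengths (windows are clipped
#'   to these)
#' @param config `dmr_config`
#' @return data.frame of eligible windows: contig, start, end, context,
#'   n_eligible_cytosines, level_1, level_2, diff, p_raw, p_adj, is_dmr,
#'   direction
#' @export
call_dmrs <- function(methylome_1, methylome_2, contig_lengths,
                      config = dmr_config()) {
  empty <- data.frame(contig = character(0), start = numeric(0),
                      end = numeric(0), context = character(0),
                      n_eligible_cytosines = numeric(0),
                      level_1 = numeric(0), level_2 = numeric(0),
                      diff = numeric(0), p_raw = numeric(0),
                      p_adj = numeric(0), is_dmr = logical(0),
                      direction = character(0), stringsAsFactors = FALSE)
  if (nrow(methylome_1) == 0 || nrow(methylome_2) == 0) {
    log_note("empty methylome: no eligible windows")
    return(empty)
  }
  m <- merge(as.data.frame(methylome_1), as.data.frame(methylome_2),
             by = c("contig", "position", "strand", "context"),
             suffixes = c("_1", "_2"))
  cov1 <- m$n_meth_1 + m$n_unmeth_1
  cov2 <- m$n_meth_2 + m$n_unmeth_2
  m <- m[cov1 >= config$min_coverage & cov2 >= config$min_coverage, ,
         drop = FALSE]
  if (nrow(m) == 0) return(empty)
  w <- config$window_size
  win <- (m$position - 1) %/% w
  key <- paste(m$contig, m$context, win, sep = "\r")
  grp <- factor(key)
  agg <- rowsum(cbind(n = 1, m1 = m$n_meth_1, u1 = m$n_unmeth_1,
                      m2 = m$n_meth_2, u2 = m$n_unmeth_2), grp)
  parts <- do.call(rbind, strsplit(rownames(agg), "\r", fixed = TRUE))
  res <- data.frame(contig = parts[, 1], context = parts[, 2],
                    win = as.numeric(parts[, 3]),
                    n_eligible_cytosines = agg[, "n"],
                    m1 = agg[, "m1"], u1 = agg[, "u1"],
                    m2 = agg[, "m2"], u2 = agg[, "u2"],
                    stringsAsFactors = FALSE)
  res <- res[res$n_eligible_cytosines >= config$min_cytosines, , drop = FALSE]
  if (nrow(res) == 0) return(empty)
  res$start <- res$win * w + 1
  len <- contig_lengths[res$contig]
  res$end <- pmin(res$start + w - 1, ifelse(is.na(len), Inf, len))
  res$level_1 <- 100 * res$m1 / (res$m1 + res$u1)
  res$level_2 <- 100 * res$m2 / (res$m2 + res$u2)
  res$diff <- res$level_1 - res$level_2
  res$p_raw <- vapply(seq_len(nrow(res)), function(i) {
    fisher_p(rbind(c(res$m1[i], res$u1[i]), c(res$m2[i], res$u2[i])))
  }, numeric(1))
  res$p_adj <- NA_real_
  for (ctx in unique(res$context)) {
    sel <- res$context == ctx
    res$p_adj[sel] <- stats::p.adjust(res$p_raw[sel], method = "BH")
  }
  thr <- config$min_diff[res$context]
  res$is_dmr <- abs(res$diff) >= thr & res$p_adj < config$alpha
  res$direction <- ifelse(!res$is_dmr, "none",
                          ifelse(res$diff > 0, "hyper_1", "hyper_2"))
  res <- res[order(res$contig, res$start, res$context), , drop = FALSE]
  rownames(res) <- NULL
  out <- res[, c("contig", "start", "end", "context", "n_eligible_cytosines",
                 "level_1", "level_2", "diff", "p_raw", "p_adj", "is_dmr",
                 "direction")]
  if (config$merge_adjacent) attr(out, "merged") <- .merge_adjacent_dmrs(out)
  out
}

# optional: collapse runs of adjacent significant windows (same contig,
# context, direction) into regions; returned as an attribute, the window
# table itself is what the pipeline counts
.merge_adjacent_dmrs <- function(windows) {
  sig <- windows[windows$is_dmr, , drop = FALSE]
  if (!nrow(sig)) return(sig)
  sig <- sig[order(sig$contig, sig$context, sig$start), , drop = FALSE]
  run <- cumsum(c(TRUE, !(sig$contig[-1] == sig$contig[-nrow(sig)] &
                          sig$context[-1] == sig$context[-nrow(sig)] &
                          sig$direction[-1] == sig$direction[-nrow(sig)] &
                          sig$start[-1] == sig$end[-nrow(sig)] + 1)))
  data.frame(contig = tapply(sig$contig, run, `[`, 1),
             start = as.vector(tapply(sig$start, run, min)),
             end = as.vector(tapply(sig$end, run, max)),
             context = tapply(sig$context, run, `[`, 1),
             direction = tapply(sig$direction, run, `[`, 1),
             n_windows = as.vector(table(run)),
             stringsAsFactors = FALSE)
}

#' Normalise DMR direction labels to maternal / paternal
#'
#' @param windows window table from [call_dmrs()]
#' @param maternal_is_1 TRUE when methylome 1 of the comparison was the
#'   maternal allele
#' @return the table with direction in {maternal, paternal, none}
#' @export
normalize_dmr_direction <- function(windows, maternal_is_1 = TRUE) {
  map <- if (maternal_is_1) c(hyper_1 = "maternal", hyper_2 = "paternal",
                              none = "none")
         else c(hyper_1 = "paternal", hyper_2 = "maternal", none = "none")
  windows$direction <- unname(map[windows$direction])
  windows
}

.features_granges <- function(features, kind, flank) {
  f <- features[features$kind == kind, , drop = FALSE]
  GenomicRanges::GRanges(f$contig,
                         IRanges::IRanges(pmax(1, f$start - flank),
                                          f$end + flank),
                         feature_id = f$feature_id)
}

.dmr_granges <- function(dmrs) {
  GenomicRanges::GRanges(dmrs$contig, IRanges::IRanges(dmrs$start, dmrs$end))
}

#' Classify and average DMR counts across replicate comparisons
#'
#' Each significant window of each comparison (direction already normalised
#' to maternal/paternal, see [normalize_dmr_direction()]) is classified by
#' any-overlap (>= 1 bp) with gene and repeat intervals extended by the
#' flank into {gene, gene+repeat, repeat, neither}; counts are averaged over
#' comparisons per direction, context and class.
#'
#' @param dmr_list list of per-comparison window tables (maternal/paternal
#'   directions)
#' @param features `feature_set`
#' @param config `dmr_config`
#' @return data.frame: direction, context, overlap_class, mean_count
#' @export
summarize_dmrs <- function(dmr_list, features, config = dmr_config()) {
  stopifnot(length(dmr_list) >= 1)
  genes_gr <- .features_granges(features, "gene", config$flank)
  reps_gr <- .features_granges(features, "repeat", config$flank)
  lv <- expand.grid(direction = c("maternal", "paternal"),
                    context = c("CG", "CHG", "CHH"),
                    overlap_class = c("gene", "gene+repeat", "repeat",
                                      "neither"),
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  counts <- matrix(0, nrow(lv), length(dmr_list))
  for (k in seq_along(dmr_list)) {
    sig <- dmr_list[[k]]
    sig <- sig[isTRUE_v(sig$is_dmr), , drop = FALSE]
    if (!nrow(sig)) next
    gr <- .dmr_granges(sig)
    in_gene <- IRanges::overlapsAny(gr, genes_gr)
    in_rep <- IRanges::overlapsAny(gr, reps_gr)
    klass <- ifelse(in_gene & in_rep, "gene+repeat",
             ifelse(in_gene, "gene", ifelse(in_rep, "repeat", "neither")))
    key <- paste(sig$direction, sig$context, klass)
    tabk <- table(factor(key, levels = paste(lv$direction, lv$context,
                                             lv$overlap_class)))
    counts[, k] <- as.vector(tabk)
  }
  lv$mean_count <- rowMeans(counts)
  lv
}

#' Consolidated per-gene DMR association across comparisons
#'
#' For each gene and context, the fractions of comparisons in which at least
#' one maternal-hyper (resp. paternal-hyper) DMR overlaps the gene +/- flank
#' are computed; the gene is maternal-associated iff the first fraction is at
#' least `assoc_min` AND the second at most `assoc_max_opposite` (boundaries
#' inclusive), symmetrically for paternal; otherwise none.
#'
#' @inheritParams summarize_dmrs
#' @return data.frame: gene_id, context, frac_maternal, frac_paternal,
#'   association in {maternal, paternal, none}
#' @export
consistent_gene_association <- function(dmr_list, features,
                                        config = dmr_config()) {
  stopifnot(length(dmr_list) >= 1)
  genes <- features[features$kind == "gene", , drop = FALSE]
  genes_gr <- .features_granges(features, "gene", config$flank)
  contexts <- c("CG", "CHG", "CHH")
  n_cmp <- length(dmr_list)
  hit_m <- hit_p <- array(0, dim = c(nrow(genes), length(contexts)),
                          dimnames = list(genes$feature_id, contexts))
  for (k in seq_len(n_cmp)) {
    sig <- dmr_list[[k]]
    sig <- sig[isTRUE_v(sig$is_dmr), , drop = FALSE]
    if (!nrow(sig)) next
    gr <- .dmr_granges(sig)
    ov <- GenomicRanges::findOverlaps(genes_gr, gr)
    if (!length(ov)) next
    gi <- S4Vectors::queryHits(ov)
    di <- S4Vectors::subjectHits(ov)
    for (ctx in contexts) {
      m_sel <- sig$context[di] == ctx & sig$direction[di] == "maternal"
      p_sel <- sig$context[di] == ctx & sig$direction[di] == "paternal"
      hit_m[unique(gi[m_sel]), ctx] <- hit_m[unique(gi[m_sel]), ctx] + 1
      hit_p[unique(gi[p_sel]), ctx] <- hit_p[unique(gi[p_sel]), ctx] + 1
    }
  }
  out <- expand.grid(gene_id = genes$feature_id, context = contexts,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$frac_maternal <- as.vector(hit_m) / n_cmp
  out$frac_paternal <- as.vector(hit_p) / n_cmp
  mat <- out$frac_maternal >= config$assoc_min &
         out$frac_paternal <= config$assoc_max_opposite
  pat <- out$frac_paternal >= config$assoc_min &
         out$frac_maternal <= config$assoc_max_opposite
  out$association <- ifelse(mat & pat, "none",
                     ifelse(mat, "maternal", ifelse(pat, "paternal", "none")))
  out
}

#' Metagene methylation profile
#'
#' Features are oriented so their 5' end is on the left (minus-strand
#' features are reversed). For each bin relative to the chosen anchor — the
#' 5' transcription start (`align = "start_5prime"`: flank upstream, flank
#' into the body) or the 3' end (`align = "end_3prime"`: flank of body, flank
#' downstream) — methylated and total calls of each context are pooled over
#' all cytosines falling in that bin across all features, and the bin value
#' is the weighted methylation percent. Body-side positions beyond a
#' feature's far end are excluded; bins with zero pooled coverage are NA.
#'
#' @param methylome `cx_report`
#' @param features `feature_set` (typically one kind)
#' @param flank bp on each side of the anchor (default 2000)
#' @param bin bin width in bp; must divide flank (default 100)
#' @param align "start_5prime" or "end_3prime"
#' @param kind restrict to features of this kind (default "gene"; NULL for
#'   all)
#' @return numeric matrix (2*flank/bin rows, one column per context) of
#'   percents; rownames are bin start offsets relative to the anchor
#' @export
metagene_profile <- function(methylome, features, flank = 2000, bin = 100,
                             align = c("start_5prime", "end_3prime"),
                             kind = "gene") {
  align <- match.arg(align)
  if (flank %% bin != 0) {
    stop("configuration error: bin width must divide the flank", call. = FALSE)
  }
  if (!is.null(kind)) features <- features[features$kind == kind, , drop = FALSE]
  contexts <- c("CG", "CHG", "CHH")
  n_bins <- 2 * flank / bin
  offsets <- seq(-flank, flank - bin, by = bin)
  meth <- tot <- matrix(0, n_bins, length(contexts),
                        dimnames = list(offsets, contexts))
  mx <- as.data.frame(methylome)
  for (i in seq_len(nrow(features))) {
    ft <- features[i, ]
    sel <- mx$contig == ft$contig &
           mx$position >= ft$start - flank & mx$position <= ft$end + flank
    if (!any(sel)) next
    sub <- mx[sel, , drop = FALSE]
    plus <- ft$strand != "-"
    ft_len <- ft$end - ft$start
    # rel: signed distance from the anchor along the 5'->3' orientation of
    # the feature (left of anchor in the output = negative)
    anchor <- if (align == "start_5prime") {
      if (plus) ft$start else ft$end
    } else {
      if (plus) ft$end else ft$start
    }
    rel <- if (plus) sub$position - anchor else anchor - sub$position
    keep <- rel >= -flank & rel < flank
    if (align == "start_5prime") {
      keep <- keep & (rel < 0 | rel <= ft_len)    # body side clipped at TES
    } else {
      keep <- keep & (rel > 0 | -rel <= ft_len)   # body side clipped at TSS
    }
    if (!any(keep)) next
    sub <- sub[keep, , drop = FALSE]
    b <- (rel[keep] + flank) %/% bin + 1
    for (ctx in contexts) {
      csel <- sub$context == ctx
      if (!any(csel)) next
      mm <- rowsum(sub$n_meth[csel], b[csel])
      tt <- rowsum(sub$n_meth[csel] + sub$n_unmeth[csel], b[csel])
      ridx <- as.integer(rownames(mm))
      meth[ridx, ctx] <- meth[ridx, ctx] + as.vector(mm)
      tot[ridx, ctx] <- tot[ridx, ctx] + as.vector(tt)
    }
  }
  out <- 100 * meth / tot
  out[tot == 0] <- NA_real_
  attr(out, "pooled_meth") <- meth
  attr(out, "pooled_total") <- tot
  out
}

#' Estimate the methyl-conversion rate from an unmethylated control contig
#'
#' Conversion = 100 * sum(unmethylated calls) / sum(all calls) over every
#' cytosine of the designated control contig, which is assumed truly
#' unmethylated; 100 minus this is the false-methylation noise floor.
#'
#' @param methylome `cx_report`
#' @param control_contig name of the control contig
#' @return percent in [0, 100]
#' @export
estimate_conversion_rate <- function(methylome, control_contig) {
  sub <- methylome[methylome$contig == control_contig, , drop = FALSE]
  if (nrow(sub) == 0) {
    stop("configuration error: control contig ", sQuote(control_contig),
         " absent from the methylome", call. = FALSE)
  }
  total <- sum(sub$n_meth) + sum(sub$n_unmeth)
  if (total == 0) {
    stop("value error: control contig has zero coverage", call. = FALSE)
  }
  rate <- 100 * sum(sub$n_unmeth) / total
  if (rate == 0) log_note("degenerate control: every call methylated")
  rate
}
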