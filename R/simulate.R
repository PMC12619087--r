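#' @title Synthetic allele-resolved expression and methylation data
#' @description
#' Generators that emulate the study design — two (or more) replicates per
#' direction of a reciprocal interspecies cross, allele-resolved endosperm
#' read counts for ~10^4 genes with a genome-wide maternal bias, planted
#' MEGs/PEGs and cis-effect genes, optional whole-seed contamination, and
#' paired maternal/paternal methylomes with context-specific background
#' levels, planted DMRs, finite coverage and a small conversion-failure
#' rate — together with ground-truth tables, so every stage of the pipeline
#' is testable with known truth. All generators are pure functions of the
#' configuration (seed included).
#' @name synthetic_data
NULL

#' Simulation configuration
#'
#' Defaults mirror the study conditions: 2 replicates per cross direction of
#' diploid (1:1) endosperm, a genome-wide maternal bias of 1.32, deeply
#' sequenced libraries (5e6 allele-assignable reads over 10^4 genes, i.e.
#' median per-gene depth of a few hundred), MEGs planted at a 0.92 maternal
#' share, strong cis genes at a 20-fold species ratio, and a 0.15%
#' conversion-failure rate matching the reported mean conversion of 99.85%.
#'
#' @param seed integer seed; mandatory, no implicit entropy
#' @param n_genes number of genes (default 10000)
#' @param replicates_per_direction default 2
#' @param library_size allele-assignable reads per sample (default 5e6)
#' @param beta_true genome-wide maternal:paternal bias (default 1.32)
#' @param frac_meg,frac_peg,frac_cis planted fractions (floors of
#'   frac * n_genes genes; defaults 0.02, 0.005, 0.01)
#' @param imprint_maternal_share maternal share of planted MEGs before the
#'   global bias (default 0.92); PEGs use 1 - this
#' @param cis_ratio species-A:species-B expression ratio of planted cis genes
#'   (default 20)
#' @param expression_dispersion negative-binomial dispersion of per-gene
#'   totals (default 0.05; variance = mu + dispersion * mu^2)
#' @param contamination_f_true fraction of each library's transcript pool
#'   drawn from the whole-seed pool by
#'   [simulate_wholeseed_and_contaminate()] (default 0)
#' @param species labels of the two parents (c("Nt", "Nd"))
#' @param n_contigs,contig_length methylome genome geometry (2 x 100 kb)
#' @param meth_depth mean per-cytosine read depth (default 20)
#' @param backgrounds named list of per-annotation context levels
#'   (proportions), elements `gene`, `repeat_`, `other`, each c(CG=, CHG=,
#'   CHH=)
#' @param n_dmrs_per_class planted DMR windows per context per direction
#'   (default 4)
#' @param dmr_effects added methylation (proportion) on the hypermethylated
#'   parent of a planted DMR, per context (defaults CG/CHG 0.7, CHH 0.2 —
#'   twice the calling thresholds)
#' @param conversion_failure false-methylation rate (default 0.0015)
#' @param control_contig,control_cytosines,control_depth unmethylated control
#'   contig used for conversion-rate estimation
#' @return list of class `sim_config`
#' @export
sim_config <- function(seed,
                       n_genes = 10000,
                       replicates_per_direction = 2,
                       library_size = 5e6,
                       beta_true = 1.32,
                       frac_meg = 0.02, frac_peg = 0.005, frac_cis = 0.01,
                       imprint_maternal_share = 0.92,
                       cis_ratio = 20,
                       expression_dispersion = 0.05,
                       contamination_f_true = 0,
                       species = c("Nt", "Nd"),
                       n_contigs = 2, contig_length = 1e5,
                       meth_depth = 20,
                       backgrounds = list(
                         gene = c(CG = 0.30, CHG = 0.05, CHH = 0.03),
                         repeat_ = c(CG = 0.80, CHG = 0.60, CHH = 0.15),
                         other = c(CG = 0.10, CHG = 0.05, CHH = 0.02)),
                       n_dmrs_per_class = 4,
                       dmr_effects = c(CG = 0.70, CHG = 0.70, CHH = 0.20),
                       conversion_failure = 0.0015,
                       control_contig = "chrC",
                       control_cytosines = 10000,
                       control_depth = 50) {
  if (missing(seed)) stop("value error: seed is mandatory", call. = FALSE)
  stopifnot(n_genes >= 1, replicates_per_direction >= 1, library_size >= 1,
            beta_true > 0, imprint_maternal_share > 0.5,
            imprint_maternal_share < 1, cis_ratio > 0,
            expression_dispersion >= 0,
            contamination_f_true >= 0, contamination_f_true < 1,
            length(species) == 2, species[1] != species[2],
            n_contigs >= 1, contig_length >= 1, meth_depth >= 1,
            conversion_failure >= 0, conversion_failure < 1)
  if (any(c(frac_meg, frac_peg, frac_cis) < 0) ||
      frac_meg + frac_peg + frac_cis > 1) {
    stop("value error: planted fractions must be >= 0 and sum to <= 1",
         call. = FALSE)
  }
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate allele-resolved endosperm expression for a reciprocal cross
#'
#' Per gene a baseline abundance is drawn from a long-tailed (log-normal)
#' distribution. The expected maternal:paternal odds of a gene combine the
#' global bias `beta_true` with its planted status: MEGs use
#' `imprint_maternal_share` odds, PEGs the mirror image, cis genes a fixed
#' species-A:species-B ratio that follows the allele's species (not its
#' parent) across directions. Per sample, gene totals are drawn with
#' negative-binomial overdispersion around the library-scaled abundance and
#' the allele split is binomial in the direction-resolved maternal share.
#'
#' @param config `sim_config`
#' @return list with `counts` (`allele_counts`), `samples` (`cross_samples`)
#'   and `truth` (gene_id, status in {MEG, PEG, cis, null}, maternal_share,
#'   cis_ratio)
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_genes
  genes <- sprintf("g%05d", seq_len(n))
  n_meg <- floor(config$frac_meg * n)
  n_peg <- floor(config$frac_peg * n)
  n_cis <- floor(config$frac_cis * n)
  status <- rep("null", n)
  planted <- sample.int(n, n_meg + n_peg + n_cis)
  status[planted[seq_len(n_meg)]] <- "MEG"
  if (n_peg) status[planted[n_meg + seq_len(n_peg)]] <- "PEG"
  if (n_cis) status[planted[n_meg + n_peg + seq_len(n_cis)]] <- "cis"

  share <- config$imprint_maternal_share
  status_odds <- ifelse(status == "MEG", share / (1 - share),
                 ifelse(status == "PEG", (1 - share) / share, 1))
  truth <- data.frame(gene_id = genes, status = status,
                      maternal_share = ifelse(status == "MEG", share,
                                       ifelse(status == "PEG", 1 - share, 0.5)),
                      cis_ratio = ifelse(status == "cis", config$cis_ratio, 1),
                      stringsAsFactors = FALSE)

  abundance <- stats::rlnorm(n, meanlog = 0, sdlog = 1)
  mu_gene <- config$library_size * abundance / sum(abundance)
  reps <- config$replicates_per_direction
  sp <- config$species
  sheet <- data.frame(
    sample_id = c(sprintf("%sx%s_r%d", sp[1], sp[2], seq_len(reps)),
                  sprintf("%sx%s_r%d", sp[2], sp[1], seq_len(reps))),
    maternal_species = rep(sp, each = reps),
    paternal_species = rep(rev(sp), each = reps),
    tissue = "endosperm",
    replicate_index = rep(seq_len(reps), 2), stringsAsFactors = FALSE)
  samples <- cross_samples(sheet)

  size <- if (config$expression_dispersion > 0)
            1 / config$expression_dispersion else Inf
  rows <- lapply(seq_len(nrow(samples)), function(i) {
    maternal_is_a <- samples$maternal_species[i] == sp[1]
    # cis genes are biased toward species A wherever that allele sits
    cis_term <- ifelse(status == "cis",
                       if (maternal_is_a) config$cis_ratio
                       else 1 / config$cis_ratio, 1)
    odds <- config$beta_true * status_odds * cis_term
    p_mat <- odds / (1 + odds)
    total <- if (is.finite(size)) stats::rnbinom(n, mu = mu_gene, size = size)
             else stats::rpois(n, mu_gene)
    m <- stats::rbinom(n, total, p_mat)
    p <- total - m
    data.frame(gene_id = genes, sample_id = samples$sample_id[i],
               count_A = if (maternal_is_a) m else p,
               count_B = if (maternal_is_a) p else m,
               stringsAsFactors = FALSE)
  })
  counts <- allele_counts(do.call(rbind, rows), sp[1], sp[2],
                          samples = samples)
  list(counts = counts, samples = samples, truth = truth)
}

#' Simulate a whole-seed profile and contaminate an endosperm table
#'
#' The whole-seed per-gene share is drawn correlated with the endosperm
#' abundances (log-normal noise around the observed pooled gene totals) and
#' normalised. Contaminating reads — all maternal-allele, since the
#' contaminant is maternal sporophytic tissue — are added per sample and gene
#' as Poisson draws with expectation f * T * share, where T is the sample's
#' allele-specific total.
#'
#' @param sim result of [simulate_expression()]
#' @param config `sim_config` (uses `contamination_f_true`; seed offset +1)
#' @return list with `counts` (contaminated `allele_counts`), `profile`
#'   (`wholeseed_profile`), `samples`, `truth`, and `added` (reads added per
#'   sample)
#' @export
simulate_wholeseed_and_contaminate <- function(sim, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  tab <- as.data.frame(sim$counts)
  sp <- species_labels(sim$counts)
  genes <- sort(unique(tab$gene_id))
  pooled <- rowsum(tab$count_A + tab$count_B, tab$gene_id)[genes, 1]
  w <- (pooled + 0.5) * stats::rlnorm(length(genes), 0, 0.5)
  profile <- wholeseed_profile(data.frame(gene_id = genes, share = w / sum(w),
                                          stringsAsFactors = FALSE))
  f <- config$contamination_f_true
  added <- stats::setNames(numeric(nrow(sim$samples)), sim$samples$sample_id)
  if (f > 0) {
    share <- stats::setNames(profile$share, profile$gene_id)
    for (i in seq_len(nrow(sim$samples))) {
      sid <- sim$samples$sample_id[i]
      rows <- which(tab$sample_id == sid)
      total <- sum(tab$count_A[rows] + tab$count_B[rows])
      extra <- stats::rpois(length(rows), f * total * share[tab$gene_id[rows]])
      mat_col <- if (sim$samples$maternal_species[i] == sp[1]) "count_A"
                 else "count_B"
      tab[[mat_col]][rows] <- tab[[mat_col]][rows] + extra
      added[sid] <- sum(extra)
    }
  }
  list(counts = allele_counts(tab, sp[1], sp[2], samples = sim$samples),
       profile = profile, samples = sim$samples, truth = sim$truth,
       added = added)
}

# deterministic feature layout: one 3-kb gene every 20 kb (alternating
# strand) with a 1-kb repeat 4 kb downstream, leaving unannotated space
# (clear of the 2-kb association flanks) where DMRs can be planted cleanly
.sim_features <- function(config) {
  out <- list()
  for (ci in seq_len(config$n_contigs)) {
    ctg <- paste0("chr", ci)
    gene_starts <- seq(2001, config$contig_length - 5000, by = 20000)
    gi <- seq_along(gene_starts)
    out[[length(out) + 1]] <- data.frame(
      feature_id = sprintf("%s_gene%02d", ctg, gi), contig = ctg,
      start = gene_starts, end = gene_starts + 2999,
      strand = ifelse(gi %% 2 == 1, "+", "-"), kind = "gene",
      stringsAsFactors = FALSE)
    rep_starts <- gene_starts + 7000
    rep_starts <- rep_starts[rep_starts + 999 <= config$contig_length]
    out[[length(out) + 1]] <- data.frame(
      feature_id = sprintf("%s_rep%02d", ctg, seq_along(rep_starts)),
      contig = ctg, start = rep_starts, end = rep_starts + 999,
      strand = "+", kind = "repeat", stringsAsFactors = FALSE)
  }
  feature_set(do.call(rbind, out))
}

#' Simulate paired maternal/paternal endosperm methylomes
#'
#' Cytosine positions are placed at context-dependent densities along the
#' simulated contigs; per-cytosine methylated counts are binomial in a level
#' set by the annotation (gene body / repeat / elsewhere, per context) and
#' shifted by planted DMR effects on the designated parent. Conversion
#' failure adds false methylation at rate `conversion_failure` everywhere,
#' including on the fully unmethylated control contig. Planted DMR windows
#' are aligned to the 300-bp window grid and kept clear of features so the
#' intended effect size is not mixed with annotation backgrounds.
#'
#' @param config `sim_config` (seed offset +2)
#' @return list with `maternal`, `paternal` (`cx_report`s), `features`
#'   (`feature_set`), `contig_lengths`, and `truth` (planted DMR table:
#'   contig, start, end, context, direction, effect)
#' @export
simulate_methylomes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  features <- .sim_features(config)
  contig_lengths <- stats::setNames(rep(config$contig_length, config$n_contigs),
                                    paste0("chr", seq_len(config$n_contigs)))
  density <- c(CG = 1 / 15, CHG = 1 / 15, CHH = 1 / 8)

  # plant DMR windows on the 300-bp grid in unannotated space
  win <- 300
  picks <- list()
  for (ci in names(contig_lengths)) {
    cand_starts <- seq(1, contig_lengths[[ci]] - win + 1, by = win)
    f_ctg <- features[features$contig == ci, , drop = FALSE]
    clear <- vapply(cand_starts, function(s) {
      !any(f_ctg$start - 2000 <= s + win - 1 & f_ctg$end + 2000 >= s)
    }, logical(1))
    cand_starts <- cand_starts[clear]
    need <- 6 * config$n_dmrs_per_class / length(contig_lengths)
    picked <- sample(cand_starts, min(need, length(cand_starts)))
    picks[[ci]] <- picked
  }
  slots <- data.frame(contig = rep(names(picks), lengths(picks)),
                      start = unlist(picks, use.names = FALSE))
  classes <- expand.grid(context = c("CG", "CHG", "CHH"),
                         direction = c("maternal", "paternal"),
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  planted <- do.call(rbind, lapply(seq_len(nrow(classes)), function(k) {
    n_per <- config$n_dmrs_per_class
    if (n_per == 0) return(NULL)
    take <- seq((k - 1) * n_per + 1, length.out = n_per)
    if (max(take) > nrow(slots)) {
      stop("value error: not enough clear windows to plant the requested DMRs",
           call. = FALSE)
    }
    data.frame(contig = slots$contig[take], start = slots$start[take],
               end = slots$start[take] + win - 1,
               context = classes$context[k], direction = classes$direction[k],
               effect = unname(config$dmr_effects[classes$context[k]]),
               stringsAsFactors = FALSE)
  }))
  if (is.null(planted)) {
    planted <- data.frame(contig = character(0), start = numeric(0),
                          end = numeric(0), context = character(0),
                          direction = character(0), effect = numeric(0),
                          stringsAsFactors = FALSE)
  }

  # the two parental alleles share one coordinate system: cytosine sites and
  # their annotation-driven base levels are drawn once, then each parent gets
  # its own planted shifts, depths and methylated counts
  sites <- list()
  for (ci in names(contig_lengths)) {
    len <- contig_lengths[[ci]]
    f_ctg <- features[features$contig == ci, , drop = FALSE]
    genes <- f_ctg[f_ctg$kind == "gene", , drop = FALSE]
    reps <- f_ctg[f_ctg$kind == "repeat", , drop = FALSE]
    for (ctx in c("CG", "CHG", "CHH")) {
      n_sites <- round(len * density[[ctx]])
      pos <- sort(sample.int(len, n_sites))
      in_rep <- .in_any(pos, reps$start, reps$end)
      in_gene <- .in_any(pos, genes$start, genes$end)
      base <- ifelse(in_rep, config$backgrounds$repeat_[[ctx]],
              ifelse(in_gene, config$backgrounds$gene[[ctx]],
                     config$backgrounds$other[[ctx]]))
      sites[[length(sites) + 1]] <- data.frame(
        contig = ci, position = pos,
        strand = sample(c("+", "-"), n_sites, replace = TRUE),
        context = ctx, base = base, stringsAsFactors = FALSE)
    }
  }
  sites[[length(sites) + 1]] <- data.frame(
    contig = config$control_contig,
    position = seq(1, by = 10, length.out = config$control_cytosines),
    strand = "+",
    context = rep(c("CG", "CHG", "CHH"),
                  length.out = config$control_cytosines),
    base = 0, stringsAsFactors = FALSE)
  sites <- do.call(rbind, sites)

  make_methylome <- function(parent) {
    level <- sites$base
    hyper_here <- planted[planted$direction == parent, , drop = FALSE]
    for (i in seq_len(nrow(hyper_here))) {
      hit <- sites$contig == hyper_here$contig[i] &
             sites$context == hyper_here$context[i] &
             sites$position >= hyper_here$start[i] &
             sites$position <= hyper_here$end[i]
      level[hit] <- pmin(1, level[hit] + hyper_here$effect[i])
    }
    level <- level + (1 - level) * config$conversion_failure
    on_control <- sites$contig == config$control_contig
    mean_depth <- ifelse(on_control, config$control_depth, config$meth_depth)
    depth <- stats::rpois(nrow(sites), mean_depth)
    meth <- stats::rbinom(nrow(sites), depth, level)
    cx_report(data.frame(contig = sites$contig, position = sites$position,
                         strand = sites$strand, context = sites$context,
                         n_meth = meth, n_unmeth = depth - meth,
                         stringsAsFactors = FALSE))
  }
  maternal <- make_methylome("maternal")
  paternal <- make_methylome("paternal")
  list(maternal = maternal, paternal = paternal, features = features,
       contig_lengths = contig_lengths, truth = planted)
}

# is each position inside any of the [starts, ends] intervals
.in_any <- function(pos, starts, ends) {
  if (!length(starts)) return(rep(FALSE, length(pos)))
  hits <- GenomicRanges::findOverlaps(
    GenomicRanges::GRanges("x", IRanges::IRanges(pos, pos)),
    GenomicRanges::GRanges("x", IRanges::IRanges(starts, ends)))
  out <- rep(FALSE, length(pos))
  out[unique(S4Vectors::queryHits(hits))] <- TRUE
  out
}

#' Write a complete synthetic dataset to disk
#'
#' Writes counts TSV, sample sheet, whole-seed profile, per-parent CX
#' reports, gene GFF3, repeat BED, truth tables and the configuration used.
#' The `tiny` preset (500 genes, one 30-kb contig) completes in seconds and
#' is what the test-suite fixtures are built from; `default` is the
#' full-scale study design.
#'
#' @param out_dir output directory (created if absent)
#' @param preset "tiny" or "default"
#' @param seed integer seed
#' @return invisibly, the named list of file paths written
#' @export
make_fixture <- function(out_dir, preset = c("tiny", "default"), seed = 1L) {
  preset <- match.arg(preset)
  cfg <- fixture_config(preset, seed)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  sim <- simulate_expression(cfg)
  contam <- simulate_wholeseed_and_contaminate(sim, cfg)
  meth <- simulate_methylomes(cfg)
  p <- function(f) file.path(out_dir, f)
  write_allele_counts(sim$counts, p("counts.tsv"))
  write_sample_sheet(sim$samples, p("samples.tsv"))
  write_wholeseed_profile(contam$profile, p("wholeseed.tsv"))
  write_cx_report(meth$maternal, p("maternal.cx.tsv"))
  write_cx_report(meth$paternal, p("paternal.cx.tsv"))
  .write_atomic(p("genes.gff3"), function(tmp) {
    g <- meth$features[meth$features$kind == "gene", ]
    writeLines(c("##gff-version 3",
                 sprintf("%s\tsim\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                         g$contig, g$start, g$end, g$strand, g$feature_id)),
               tmp)
  })
  .write_atomic(p("repeats.bed"), function(tmp) {
    r <- meth$features[meth$features$kind == "repeat", ]
    writeLines(sprintf("%s\t%d\t%d\t%s", r$contig, r$start - 1, r$end,
                       r$feature_id), tmp)
  })
  .write_atomic(p("truth_genes.tsv"), function(tmp) {
    utils::write.table(sim$truth, tmp, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  })
  .write_atomic(p("truth_dmrs.tsv"), function(tmp) {
    utils::write.table(meth$truth, tmp, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  })
  .write_atomic(p("contig_lengths.tsv"), function(tmp) {
    utils::write.table(data.frame(contig = names(meth$contig_lengths),
                                  length = unname(meth$contig_lengths)),
                       tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  })
  .write_atomic(p("sim_config.yaml"), function(tmp) {
    yaml::write_yaml(unclass(cfg), tmp)
  })
  invisible(list(dir = out_dir))
}

#' Preset simulation configurations
#' @param preset "tiny" (500 genes, one 30-kb contig; seconds) or "default"
#'   (the full study-scale design)
#' @param seed integer seed
#' @return `sim_config`
#' @export
fixture_config <- function(preset = c("tiny", "default"), seed = 1L) {
  preset <- match.arg(preset)
  if (preset == "tiny") {
    sim_config(seed = seed, n_genes = 500, library_size = 2.5e5,
               n_contigs = 1, contig_length = 3e4, n_dmrs_per_class = 1,
               control_cytosines = 2000)
  } else {
    sim_config(seed = seed)
  }
}
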