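#' @title Run configuration and end-to-end orchestration
#' @description
#' A run is described by a YAML (or in-memory list) configuration whose
#' defaults are the study parameters: imprinting (beta 1.32, alpha 0.01,
#' 50 reads, IF 2, CEF 15, 70/30 fraction gates, 75% consistency), DMRs
#' (300-bp windows, 3 cytosines at 5 reads, 35/35/10-point thresholds, BH
#' 0.01, +/- 2 kb association, 75/25 consistency), contamination grid
#' {0.25, 0.5}. [run_pipeline()] executes simulate -> (decontam) ->
#' imprint -> dmr -> annotate -> metagene as one reproducible run; stages
#' communicate only through on-disk artifacts in the standard formats, so
#' any stage can also be run standalone on user data through the exported
#' stage functions.
#' @name pipeline
NULL

.default_run_config <- function() {
  list(
    seed = 1L,
    out_dir = NULL,
    inputs = list(counts = NULL, samples = NULL, wholeseed = NULL,
                  cx_maternal = NULL, cx_paternal = NULL,
                  genes_gff3 = NULL, repeats_bed = NULL,
                  contig_lengths = NULL),
    simulate = list(enabled = TRUE, preset = "tiny"),
    imprinting = list(beta = 1.32, alpha = 0.01, min_reads = 50, min_if = 2,
                      max_cef = 15, meg_min_maternal = 0.70,
                      peg_max_maternal = 0.30, consistency_min = 0.75,
                      ci_level = 0.95),
    contamination = list(enabled = TRUE, f_grid = c(0.25, 0.5)),
    dmr = list(window_size = 300, min_cytosines = 3, min_coverage = 5,
               min_diff_cg = 35, min_diff_chg = 35, min_diff_chh = 10,
               alpha = 0.01, flank = 2000, assoc_min = 0.75,
               assoc_max_opposite = 0.25),
    metagene = list(flank = 2000, bin = 100),
    control_contig = "chrC")
}

.merge_config <- function(defaults, user, path = character(0)) {
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    stop("configuration error: unknown key(s): ",
         paste(paste(c(path, ""), collapse = "."), unknown,
               sep = "", collapse = ", "), call. = FALSE)
  }
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]]))) {
      if (!is.list(user[[k]]) && !is.null(user[[k]])) {
        stop("configuration error: key ", paste(c(path, k), collapse = "."),
             " expects a mapping", call. = FALSE)
      }
      defaults[[k]] <- .merge_config(defaults[[k]], user[[k]], c(path, k))
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  defaults
}

#' Validate a run configuration
#'
#' Reads a YAML file (or takes a list), fills defaults — which are the study
#' parameter set — and checks types and ranges. Unknown keys are an error
#' listing them.
#'
#' @param config path to a YAML file, or a (possibly partial) list
#' @return fully-resolved configuration list of class `run_config`
#' @export
validate_run_config <- function(config = list()) {
  if (is.character(config)) {
    config <- yaml::read_yaml(config)
    if (is.null(config)) {
      log_note("empty configuration file: using pure defaults")
      config <- list()
    }
  }
  stopifnot(is.list(config))
  cfg <- .merge_config(.default_run_config(), config)
  # range checks ride on the component constructors
  cfg$imprinting_config <- do.call(imprinting_config, cfg$imprinting)
  cfg$dmr_config <- do.call(dmr_config, cfg$dmr)
  if (any(cfg$contamination$f_grid < 0) || any(cfg$contamination$f_grid >= 1)) {
    stop("configuration error: contamination f values must lie in [0, 1)",
         call. = FALSE)
  }
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- c("run_config", "list")
  cfg
}

.checksum <- function(paths) {
  paths <- paths[file.exists(paths)]
  if (!length(paths)) return(character(0))
  tools::md5sum(paths)
}

#' Run the full pipeline
#'
#' Stages: (1) simulate or load inputs; (2) imprinting over all
#' direction-1 x direction-2 sample pairings, consolidated with the
#' consistency rule; (3) contamination correction over the configured f
#' grid with re-called imprinting and the nesting report; (4) DMR calling
#' between the maternal and paternal methylomes (one comparison per
#' replicate pair), summarised and gene-associated across comparisons;
#' (5) metagene profiles (5' and 3' aligned) and conversion-rate estimates.
#' Every stage writes its artifact under `out_dir`, and a run log records
#' the configuration, seed and per-file checksums.
#'
#' @param config a `run_config` (see [validate_run_config()]), a path to a
#'   YAML file, or a partial list
#' @param out_dir output directory; overrides `config$out_dir`
#' @return list of class `run_summary` (counts per stage, recovery metrics
#'   when simulation truth is available, paths of artifacts)
#' @export
run_pipeline <- function(config = list(), out_dir = NULL) {
  if (!inherits(config, "run_config")) config <- validate_run_config(config)
  if (!is.null(out_dir)) config$out_dir <- out_dir
  if (is.null(config$out_dir)) {
    stop("configuration error: out_dir is required", call. = FALSE)
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(config$out_dir, f)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  summary <- list(seed = config$seed)

  # --- inputs -------------------------------------------------------------
  truth <- NULL; meth <- NULL
  if (isTRUE(config$simulate$enabled)) {
    stage("simulate", {
      cfg <- fixture_config(config$simulate$preset, seed = config$seed)
      sim <- simulate_expression(cfg)
      ws <- simulate_wholeseed_and_contaminate(sim, cfg)
      meth <- simulate_methylomes(cfg)
      counts <- sim$counts; samples <- sim$samples
      profile <- ws$profile
      truth <- list(genes = sim$truth, dmrs = meth$truth)
      write_allele_counts(counts, p("counts.tsv"))
      write_sample_sheet(samples, p("samples.tsv"))
    })
  } else {
    stage("load", {
      inp <- config$inputs
      rd <- read_allele_counts(inp$counts, inp$samples)
      counts <- rd$counts; samples <- rd$samples
      profile <- if (!is.null(inp$wholeseed))
        read_wholeseed_profile(inp$wholeseed) else NULL
      if (!is.null(inp$cx_maternal)) {
        lens <- utils::read.delim(inp$contig_lengths)
        meth <- list(
          maternal = read_cx_report(inp$cx_maternal),
          paternal = read_cx_report(inp$cx_paternal),
          features = read_features(inp$genes_gff3, inp$repeats_bed),
          contig_lengths = stats::setNames(lens$length, lens$contig),
          truth = NULL)
      }
    })
  }

  # --- imprinting ---------------------------------------------------------
  icfg <- config$imprinting_config
  stage("imprint", {
    comparisons <- call_all_comparisons(counts, samples, icfg)
    consolidated <- consolidate_calls(comparisons, icfg)
    for (nm in names(comparisons)) {
      write_imprinting_calls(comparisons[[nm]],
                             p(paste0("imprinting_", nm, ".tsv")))
    }
    write_imprinting_calls(consolidated, p("imprinting_consolidated.tsv"))
  })
  summary$n_comparisons <- length(comparisons)
  summary$n_genes_tested <- sum(consolidated$n_comparisons_total > 0)
  summary$n_meg <- sum(consolidated$final_status == "MEG")
  summary$n_peg <- sum(consolidated$final_status == "PEG")
  if (!is.null(truth)) {
    planted_meg <- truth$genes$gene_id[truth$genes$status == "MEG"]
    called_meg <- consolidated$gene_id[consolidated$final_status == "MEG"]
    null_genes <- truth$genes$gene_id[truth$genes$status == "null"]
    summary$meg_sensitivity <- if (length(planted_meg))
      mean(planted_meg %in% called_meg) else NA_real_
    summary$null_false_call_rate <- mean(
      null_genes %in% c(called_meg,
                        consolidated$gene_id[consolidated$final_status == "PEG"]))
  }

  # --- contamination ------------------------------------------------------
  if (isTRUE(config$contamination$enabled) && !is.null(profile)) {
    stage("decontam", {
      corr <- list()
      for (f in config$contamination$f_grid) {
        ctab <- correct_maternal_counts(counts, samples, profile, f)
        ccomp <- call_all_comparisons(ctab, samples, icfg)
        corr[[as.character(f)]] <- consolidate_calls(ccomp, icfg)
      }
      report <- corrected_call_report(consolidated, corr)
      write_imprinting_calls(report, p("contamination_report.tsv"))
      summary$contamination <- report[, c("f", "n_meg_corrected", "is_subset")]
    })
  }

  # --- methylation --------------------------------------------------------
  if (!is.null(meth)) {
    dcfg <- config$dmr_config
    stage("dmr", {
      wt <- call_dmrs(meth$maternal, meth$paternal, meth$contig_lengths, dcfg)
      wt <- normalize_dmr_direction(wt, maternal_is_1 = TRUE)
      dmr_list <- list(rep1 = wt)
      write_dmrs(wt, tsv_path = p("dmrs_rep1.tsv"),
                 bed_path = p("dmrs_rep1.bed"))
      summ <- summarize_dmrs(dmr_list, meth$features, dcfg)
      assoc <- consistent_gene_association(dmr_list, meth$features, dcfg)
      write_imprinting_calls(summ, p("dmr_summary.tsv"))
      write_imprinting_calls(assoc, p("dmr_gene_association.tsv"))
      summary$n_dmrs <- sum(isTRUE_v(wt$is_dmr))
      summary$n_dmrs_maternal_hyper <- sum(wt$direction == "maternal")
      summary$n_dmrs_paternal_hyper <- sum(wt$direction == "paternal")
    })
    stage("metagene", {
      prof5 <- metagene_profile(meth$maternal, meth$features,
                                flank = config$metagene$flank,
                                bin = config$metagene$bin,
                                align = "start_5prime")
      prof3 <- metagene_profile(meth$maternal, meth$features,
                                flank = config$metagene$flank,
                                bin = config$metagene$bin,
                                align = "end_3prime")
      write_metagene(prof5, p("metagene_5prime.tsv"))
      write_metagene(prof3, p("metagene_3prime.tsv"))
    })
    stage("conversion", {
      summary$conversion_rate_maternal <-
        estimate_conversion_rate(meth$maternal, config$control_contig)
      summary$conversion_rate_paternal <-
        estimate_conversion_rate(meth$paternal, config$control_contig)
    })
    if (!is.null(truth) && !is.null(truth$dmrs)) {
      wt <- dmr_list[[1]]
      sig <- wt[isTRUE_v(wt$is_dmr), , drop = FALSE]
      hit <- vapply(seq_len(nrow(truth$dmrs)), function(i) {
        any(sig$contig == truth$dmrs$contig[i] &
            sig$start == truth$dmrs$start[i] &
            sig$context == truth$dmrs$context[i] &
            sig$direction == truth$dmrs$direction[i])
      }, logical(1))
      summary$dmr_sensitivity <- mean(hit)
    }
  }

  # --- run log ------------------------------------------------------------
  files <- list.files(config$out_dir, full.names = TRUE)
  log <- list(seed = config$seed,
              config = unclass(config[setdiff(names(config),
                                              c("imprinting_config",
                                                "dmr_config"))]),
              checksums = as.list(.checksum(files)))
  yaml::write_yaml(log, p("run_log.yaml"))
  jsonlite::write_json(summary[!vapply(summary, is.null, logical(1))],
                       p("summary.json"), auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  class(summary) <- c("run_summary", "list")
  invisible(summary)
}
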