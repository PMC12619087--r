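#' @title File formats: allele counts, sample sheets, CX reports, features
#' @description
#' Readers and writers for every external file the pipeline touches. All
#' internal coordinates are 1-based inclusive (the GFF3 / Bismark-CX
#' convention); BED input and output is converted at the boundary (start
#' shifted by exactly one). Every reader/writer pair is a round trip on valid
#' data, and readers never silently drop rows.
#' @name io_formats
NULL

SAMPLE_SHEET_COLS <- c("sample_id", "maternal_species", "paternal_species",
                       "tissue", "replicate_index")

.check_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("format error in ", what, ": missing column(s) ",
         paste(sQuote(missing), collapse = ", "), call. = FALSE)
  }
  invisible(df)
}

#' Construct / validate a cross-sample sheet
#'
#' @param df data.frame with columns sample_id, maternal_species,
#'   paternal_species, tissue (endosperm or leaf), replicate_index
#' @return validated data.frame of class `cross_samples`
#' @export
cross_samples <- function(df) {
  .check_columns(df, SAMPLE_SHEET_COLS, "sample sheet")
  df <- df[, SAMPLE_SHEET_COLS]
  df$sample_id <- as.character(df$sample_id)
  df$maternal_species <- as.character(df$maternal_species)
  df$paternal_species <- as.character(df$paternal_species)
  df$tissue <- as.character(df$tissue)
  df$replicate_index <- as.integer(df$replicate_index)
  if (anyDuplicated(df$sample_id)) {
    stop("consistency error: duplicated sample_id in sample sheet", call. = FALSE)
  }
  if (!all(df$tissue %in% c("endosperm", "leaf"))) {
    stop("value error: tissue must be 'endosperm' or 'leaf'", call. = FALSE)
  }
  if (any(df$replicate_index < 1L)) {
    stop("value error: replicate_index must be >= 1", call. = FALSE)
  }
  hybrid <- df$maternal_species != df$paternal_species
  if (any(!hybrid & df$tissue == "endosperm")) {
    # self-fertilised endosperm is allowed as metadata but cannot enter the
    # reciprocal-cross test; hybrids must have distinct parents
  }
  class(df) <- c("cross_samples", "data.frame")
  df
}

#' Construct / validate an allele-resolved count table
#'
#' Rows are keyed by (gene_id, sample_id); `count_A`/`count_B` are reads
#' assigned to the two parental species, whose labels are fixed for the whole
#' table and carried as attributes `species_A` and `species_B`. Genes absent
#' in some samples are filled in with zero counts, so the gene set is
#' identical across samples; rows are ordered by (gene_id, sample_id).
#'
#' @param df data.frame with gene_id, sample_id, count_A, count_B
#' @param species_a,species_b species labels for the two count columns
#' @param samples optional `cross_samples` sheet to validate sample ids against
#' @return data.frame of class `allele_counts`
#' @export
allele_counts <- function(df, species_a, species_b, samples = NULL) {
  .check_columns(df, c("gene_id", "sample_id", "count_A", "count_B"),
                 "allele count table")
  stopifnot(is.character(species_a) || is.factor(species_a),
            length(species_a) == 1, length(species_b) == 1)
  df <- df[, c("gene_id", "sample_id", "count_A", "count_B")]
  df$gene_id <- as.character(df$gene_id)
  df$sample_id <- as.character(df$sample_id)
  for (cc in c("count_A", "count_B")) {
    v <- df[[cc]]
    if (!is.numeric(v) || any(is.na(v)) || any(v != floor(v))) {
      stop("value error: non-integer values in ", cc, call. = FALSE)
    }
    if (any(v < 0)) stop("value error: negative counts in ", cc, call. = FALSE)
    df[[cc]] <- as.numeric(v)
  }
  if (!is.null(samples)) {
    unknown <- setdiff(unique(df$sample_id), samples$sample_id)
    if (length(unknown)) {
      stop("consistency error: sample(s) in counts but not in sample sheet: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  # zero-fill the full gene x sample grid
  genes <- sort(unique(df$gene_id))
  sids <- sort(unique(df$sample_id))
  full <- expand.grid(sample_id = sids, gene_id = genes,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  full <- full[, c("gene_id", "sample_id")]
  m <- merge(full, df, by = c("gene_id", "sample_id"), all.x = TRUE)
  m$count_A[is.na(m$count_A)] <- 0
  m$count_B[is.na(m$count_B)] <- 0
  m <- m[order(m$gene_id, m$sample_id), , drop = FALSE]
  rownames(m) <- NULL
  attr(m, "species_A") <- as.character(species_a)
  attr(m, "species_B") <- as.character(species_b)
  class(m) <- c("allele_counts", "data.frame")
  m
}

#' Species labels of an allele count table
#' @param tab an `allele_counts` table
#' @return character vector of length 2 (species A, species B)
#' @export
species_labels <- function(tab) {
  c(attr(tab, "species_A"), attr(tab, "species_B"))
}

#' Read a sample sheet TSV
#' @param path TSV with the `cross_samples` columns; `#` lines are comments
#' @return `cross_samples` data.frame
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  cross_samples(df)
}

#' Write a sample sheet TSV
#' @param samples `cross_samples`
#' @param path output path
#' @export
write_sample_sheet <- function(samples, path) {
  .write_atomic(path, function(tmp) {
    utils::write.table(as.data.frame(samples), tmp, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  })
}

#' Read an allele-resolved count table with its sample sheet
#'
#' The counts TSV must have a header line `gene_id sample_id count_A count_B`
#' and may carry the species labels as `#species_A=<label>` /
#' `#species_B=<label>` comment lines (written by [write_allele_counts()]).
#' When absent, the two labels are taken as the sorted unique species in the
#' sample sheet.
#'
#' @param path counts TSV
#' @param sample_sheet sample sheet TSV path or a `cross_samples` data.frame
#' @return list with elements `counts` (`allele_counts`) and `samples`
#' @export
read_allele_counts <- function(path, sample_sheet) {
  samples <- if (is.data.frame(sample_sheet)) cross_samples(sample_sheet)
             else read_sample_sheet(sample_sheet)
  head_lines <- readLines(path, n = 10L)
  get_tag <- function(tag) {
    hit <- grep(paste0("^#", tag, "="), head_lines, value = TRUE)
    if (length(hit)) sub(paste0("^#", tag, "="), "", hit[1]) else NA_character_
  }
  sp_a <- get_tag("species_A")
  sp_b <- get_tag("species_B")
  if (is.na(sp_a) || is.na(sp_b)) {
    sp <- sort(unique(c(samples$maternal_species, samples$paternal_species)))
    if (length(sp) != 2) {
      stop("consistency error: cannot infer the two species labels from the ",
           "sample sheet; found ", length(sp), call. = FALSE)
    }
    sp_a <- sp[1]; sp_b <- sp[2]
  }
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  counts <- allele_counts(df, sp_a, sp_b, samples = samples)
  list(counts = counts, samples = samples)
}

#' Write an allele-resolved count table
#' @param tab `allele_counts`
#' @param path output TSV path
#' @export
write_allele_counts <- function(tab, path) {
  sp <- species_labels(tab)
  .write_atomic(path, function(tmp) {
    con <- file(tmp, open = "wt")
    on.exit(close(con))
    writeLines(c(paste0("#species_A=", sp[1]), paste0("#species_B=", sp[2])), con)
    utils::write.table(as.data.frame(tab), con, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  })
}

#' Read a Bismark-CX-style per-cytosine report
#'
#' Columns (no header): contig, position (1-based), strand, count_methylated,
#' count_unmethylated, context, trinucleotide. The trinucleotide column is
#' ignored. Records are returned sorted by (contig, position). Contexts other
#' than CG/CHG/CHH are rejected.
#'
#' @param path TSV path
#' @param merge_cg_strands if TRUE, the +/- records of a symmetric CG site
#'   (positions p and p+1) are pooled into one plus-strand record. Off by
#'   default: each cytosine is a separate record.
#' @return data.frame of class `cx_report` with columns contig, position,
#'   strand, context, n_meth, n_unmeth
#' @export
read_cx_report <- function(path, merge_cg_strands = FALSE) {
  df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE,
                          colClasses = c("character", "numeric", "character",
                                         "numeric", "numeric", "character",
                                         "character"))
  names(df) <- c("contig", "position", "strand", "n_meth", "n_unmeth",
                 "context", "tri")
  cx_report(df[, c("contig", "position", "strand", "context",
                   "n_meth", "n_unmeth")],
            merge_cg_strands = merge_cg_strands)
}

#' Construct / validate a per-cytosine methylation table
#' @param df data.frame with contig, position, strand, context, n_meth, n_unmeth
#' @param merge_cg_strands see [read_cx_report()]
#' @return data.frame of class `cx_report`, sorted by (contig, position)
#' @export
cx_report <- function(df, merge_cg_strands = FALSE) {
  .check_columns(df, c("contig", "position", "strand", "context",
                       "n_meth", "n_unmeth"), "CX report")
  df <- df[, c("contig", "position", "strand", "context", "n_meth", "n_unmeth")]
  df$contig <- as.character(df$contig)
  df$strand <- as.character(df$strand)
  df$context <- as.character(df$context)
  for (cc in c("position", "n_meth", "n_unmeth")) {
    v <- df[[cc]]
    if (!is.numeric(v) || any(is.na(v)) || any(v != floor(v))) {
      stop("value error: non-integer values in column ", cc, call. = FALSE)
    }
    df[[cc]] <- as.numeric(v)
  }
  if (any(df$position < 1)) stop("value error: position < 1", call. = FALSE)
  if (any(df$n_meth < 0) || any(df$n_unmeth < 0)) {
    stop("value error: negative methylation counts", call. = FALSE)
  }
  bad_ctx <- setdiff(unique(df$context), c("CG", "CHG", "CHH"))
  if (length(bad_ctx)) {
    stop("value error: unknown methylation context(s): ",
         paste(bad_ctx, collapse = ", "), call. = FALSE)
  }
  if (!all(df$strand %in% c("+", "-"))) {
    stop("value error: strand must be '+' or '-'", call. = FALSE)
  }
  if (merge_cg_strands) {
    cg <- df$context == "CG"
    minus <- cg & df$strand == "-"
    # a minus-strand CG cytosine at p pairs with the plus-strand one at p-1
    df$position[minus] <- df$position[minus] - 1
    df$strand[cg] <- "+"
    key <- paste(df$contig, df$position, df$strand, df$context, sep = "\r")
    agg <- rowsum(df[, c("n_meth", "n_unmeth")], group = key)
    parts <- do.call(rbind, strsplit(rownames(agg), "\r", fixed = TRUE))
    df <- data.frame(contig = parts[, 1], position = as.numeric(parts[, 2]),
                     strand = parts[, 3], context = parts[, 4],
                     n_meth = agg$n_meth, n_unmeth = agg$n_unmeth,
                     stringsAsFactors = FALSE)
  }
  df <- df[order(df$contig, df$position, df$strand), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("cx_report", "data.frame")
  df
}

#' Write a Bismark-CX-style per-cytosine report
#' @param cx `cx_report` data.frame
#' @param path output path
#' @export
write_cx_report <- function(cx, path) {
  out <- data.frame(cx$contig, cx$position, cx$strand, cx$n_meth,
                    cx$n_unmeth, cx$context, cx$context)
  .write_atomic(path, function(tmp) {
    utils::write.table(out, tmp, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  })
}

#' Read gene and repeat annotations into one feature set
#'
#' Genes come from GFF3 (1-based inclusive); repeats from BED (0-based
#' half-open), converted to the internal 1-based inclusive convention at the
#' boundary. Unknown strands are treated as "+" with a logged warning.
#'
#' @param gff3_path GFF3 with gene features (records of type "gene"; if none
#'   are typed "gene", all records are used)
#' @param bed_path BED3+ of repeat regions, or NULL for none
#' @return data.frame of class `feature_set` with columns feature_id, contig,
#'   start, end, strand, kind
#' @export
read_features <- function(gff3_path, bed_path = NULL) {
  gr <- rtracklayer::import(gff3_path, format = "gff3")
  if ("type" %in% names(S4Vectors::mcols(gr)) &&
      any(as.character(gr$type) == "gene")) {
    gr <- gr[as.character(gr$type) == "gene"]
  }
  ids <- if ("ID" %in% names(S4Vectors::mcols(gr))) as.character(gr$ID)
         else NA_character_
  if (all(is.na(ids))) ids <- paste0("gene_", seq_along(gr))
  genes <- data.frame(feature_id = ids,
                      contig = as.character(GenomicRanges::seqnames(gr)),
                      start = GenomicRanges::start(gr),
                      end = GenomicRanges::end(gr),
                      strand = as.character(GenomicRanges::strand(gr)),
                      kind = "gene", stringsAsFactors = FALSE)
  feats <- genes
  if (!is.null(bed_path)) {
    br <- rtracklayer::import(bed_path, format = "bed")
    rid <- if ("name" %in% names(S4Vectors::mcols(br))) as.character(br$name)
           else paste0("repeat_", seq_along(br))
    rid[is.na(rid)] <- paste0("repeat_", which(is.na(rid)))
    reps <- data.frame(feature_id = rid,
                       contig = as.character(GenomicRanges::seqnames(br)),
                       start = GenomicRanges::start(br),
                       end = GenomicRanges::end(br),
                       strand = as.character(GenomicRanges::strand(br)),
                       kind = "repeat", stringsAsFactors = FALSE)
    feats <- rbind(feats, reps)
  }
  feature_set(feats)
}

#' Construct / validate a feature set
#' @param df data.frame with feature_id, contig, start, end, strand, kind
#' @return data.frame of class `feature_set`
#' @export
feature_set <- function(df) {
  .check_columns(df, c("feature_id", "contig", "start", "end", "strand", "kind"),
                 "feature set")
  df <- df[, c("feature_id", "contig", "start", "end", "strand", "kind")]
  df$feature_id <- as.character(df$feature_id)
  df$contig <- as.character(df$contig)
  df$strand <- as.character(df$strand)
  df$kind <- as.character(df$kind)
  if (any(df$end < df$start)) {
    stop("value error: feature with end < start", call. = FALSE)
  }
  if (!all(df$kind %in% c("gene", "repeat"))) {
    stop("value error: feature kind must be 'gene' or 'repeat'", call. = FALSE)
  }
  odd <- !(df$strand %in% c("+", "-"))
  if (any(odd)) {
    log_note("treating ", sum(odd), " feature(s) with unknown strand as '+'")
    df$strand[odd] <- "+"
  }
  for (k in unique(df$kind)) {
    if (anyDuplicated(df$feature_id[df$kind == k])) {
      stop("value error: duplicated feature_id within kind ", k, call. = FALSE)
    }
  }
  rownames(df) <- NULL
  class(df) <- c("feature_set", "data.frame")
  df
}

#' Write imprinting calls as TSV
#' @param calls a per-comparison or consolidated call data.frame
#' @param path output path
#' @export
write_imprinting_calls <- function(calls, path) {
  .write_atomic(path, function(tmp) {
    utils::write.table(as.data.frame(calls), tmp, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  })
}

DMR_TSV_COLS <- c("contig", "start", "end", "context", "n_eligible_cytosines",
                  "level_1", "level_2", "diff", "p_raw", "p_adj", "is_dmr",
                  "direction")

#' Write DMR window tests as a full TSV plus a BED6 of significant windows
#'
#' The BED uses the 0-based half-open convention (internal start minus one),
#' name `context:direction` and score `-log10(p_adj)` capped at 1000.
#'
#' @param windows a window-test data.frame from [call_dmrs()]
#' @param tsv_path,bed_path output paths (either may be NULL to skip)
#' @export
write_dmrs <- function(windows, tsv_path = NULL, bed_path = NULL) {
  windows <- as.data.frame(windows)
  if (!is.null(tsv_path)) {
    .write_atomic(tsv_path, function(tmp) {
      utils::write.table(windows[, intersect(DMR_TSV_COLS, names(windows))],
                         tmp, sep = "\t", quote = FALSE, row.names = FALSE)
    })
  }
  if (!is.null(bed_path)) {
    sig <- windows[isTRUE_v(windows$is_dmr), , drop = FALSE]
    score <- if (nrow(sig)) pmin(1000, -log10(pmax(sig$p_adj, 1e-300))) else numeric(0)
    nm <- if (nrow(sig)) paste0(sig$context, ":", sig$direction) else character(0)
    bed <- data.frame(chrom = sig$contig, start = sig$start - 1, end = sig$end,
                      name = nm, score = round(score, 3),
                      strand = rep(".", nrow(sig)))
    .write_atomic(bed_path, function(tmp) {
      con <- file(tmp, open = "wt")
      on.exit(close(con))
      writeLines("#chrom\tstart\tend\tname\tscore\tstrand", con)
      if (nrow(bed)) {
        utils::write.table(bed, con, sep = "\t", quote = FALSE,
                           row.names = FALSE, col.names = FALSE)
      }
    })
  }
  invisible(NULL)
}

isTRUE_v <- function(x) if (is.null(x)) logical(0) else !is.na(x) & x

#' Read a DMR TSV written by [write_dmrs()]
#' @param path TSV path
#' @return window-test data.frame
#' @export
read_dmrs <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  .check_columns(df, DMR_TSV_COLS, "DMR table")
  df
}

#' Write a metagene profile matrix as TSV
#' @param profile matrix from [metagene_profile()] (bins x contexts)
#' @param path output path
#' @export
write_metagene <- function(profile, path) {
  out <- data.frame(bin_start = rownames(profile), as.data.frame(profile),
                    check.names = FALSE)
  .write_atomic(path, function(tmp) {
    utils::write.table(out, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  })
}

#' Read a whole-seed expression profile
#'
#' TSV with columns gene_id and share (or raw counts; normalised on load with
#' a logged note so that shares sum to one).
#'
#' @param path TSV path
#' @return data.frame with gene_id, share summing to 1
#' @export
read_wholeseed_profile <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  .check_columns(df, c("gene_id", "share"), "whole-seed profile")
  wholeseed_profile(df)
}

#' Construct / validate a whole-seed profile
#' @param df data.frame with gene_id and non-negative share
#' @return normalised profile data.frame of class `wholeseed_profile`
#' @export
wholeseed_profile <- function(df) {
  .check_columns(df, c("gene_id", "share"), "whole-seed profile")
  df <- df[, c("gene_id", "share")]
  df$gene_id <- as.character(df$gene_id)
  if (any(df$share < 0) || any(is.na(df$share))) {
    stop("value error: whole-seed shares must be non-negative", call. = FALSE)
  }
  s <- sum(df$share)
  if (s <= 0) stop("value error: whole-seed profile sums to zero", call. = FALSE)
  if (abs(s - 1) > 1e-9) {
    log_note("whole-seed profile sums to ", format(s), "; normalising to 1")
    df$share <- df$share / s
  }
  class(df) <- c("wholeseed_profile", "data.frame")
  df
}

#' Write a whole-seed profile TSV
#' @param profile `wholeseed_profile`
#' @param path output path
#' @export
write_wholeseed_profile <- function(profile, path) {
  .write_atomic(path, function(tmp) {
    utils::write.table(as.data.frame(profile), tmp, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  })
}
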