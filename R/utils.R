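#' Round half away from zero
#'
#' Rounds to the nearest integer with ties broken away from zero, the
#' convention used throughout when converting bias-adjusted or
#' contamination-corrected read counts back to integers (so that the exact
#' test still sees integer tables). `round()` in R rounds half to even, which
#' is not what we want for count adjustment.
#'
#' @param x numeric vector
#' @return integer-valued numeric vector
#' @export
round_half_away <- function(x) {
  stopifnot(is.numeric(x))
  sign(x) * floor(abs(x) + 0.5)
}

#' Wilson score confidence interval for a binomial proportion
#'
#' Closed-form Wilson interval without continuity correction. Non-degenerate
#' at observed proportions of 0 or 1 (the bound touches 0 or 1 only when the
#' count itself is 0 or n), which matters because allelic ratios are later
#' formed as p/(1-p) of these bounds.
#'
#' @param x successes (vectorised)
#' @param n trials (vectorised, n >= 1)
#' @param level confidence level, default 0.95
#' @return list with numeric vectors `lower` and `upper`
#' @export
wilson_interval <- function(x, n, level = 0.95) {
  stopifnot(all(n >= 1), all(x >= 0), all(x <= n), level > 0, level < 1)
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  list(lower = pmax(0, centre - half), upper = pmin(1, centre + half))
}

# Odds-scale transform of a proportion interval: p/(1-p) with 0 -> 0 and
# 1 -> Inf as stated limits.
.prop_to_ratio <- function(p) {
  r <- p / (1 - p)
  r[p >= 1] <- Inf
  r
}

# Atomic write: materialise in a temp file in the same directory, then rename.
.write_atomic <- function(path, writer) {
  dir <- dirname(path)
  if (!dir.exists(dir)) {
    stop("I/O error: directory does not exist: ", dir, call. = FALSE)
  }
  tmp <- tempfile(pattern = paste0(".", basename(path), "."), tmpdir = dir)
  ok <- FALSE
  on.exit(if (!ok && file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) {
    stop("I/O error: could not move temporary file onto ", path, call. = FALSE)
  }
  ok <- TRUE
  invisible(path)
}

# Lightweight run-log messaging; kept as message() so callers can suppress.
log_note <- function(...) message("[lilyprint] ", ...)

#' Two-sided Fisher exact p-value for a 2x2 table
#'
#' Thin wrapper around [stats::fisher.test()] used for both the imprinting
#' test and the DMR window test; isolated here so every exact test in the
#' pipeline goes through one code path.
#'
#' @param tab 2x2 matrix of non-negative integer counts
#' @return two-sided p-value
#' @export
fisher_p <- function(tab) {
  stopifnot(is.matrix(tab), all(dim(tab) == c(2L, 2L)))
  if (any(tab < 0)) stop("value error: negative counts in 2x2 table", call. = FALSE)
  if (sum(tab) == 0) return(1)
  stats::fisher.test(tab, alternative = "two.sided")$p.value
}
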