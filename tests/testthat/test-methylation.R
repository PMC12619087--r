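test_that("window tiling covers contigs exactly, partial tile retained", {
  w <- tile_windows(c(chrA = 900), 300)
  expect_equal(nrow(w), 3)
  w <- tile_windows(c(chrA = 650), 300)
  expect_equal(w$start, c(1, 301, 601))
  expect_equal(w$end, c(300, 600, 650))
  set.seed(2)
  lens <- setNames(sample.int(5000, 5) + 10, paste0("c", 1:5))
  tw <- tile_windows(lens, 300)
  for (ctg in names(lens)) {
    sub <- tw[tw$contig == ctg, ]
    expect_equal(sum(sub$end - sub$start + 1), unname(lens[ctg]))
    expect_true(all(sub$start[-1] == sub$end[-nrow(sub)] + 1))
  }
})

mk_cyt <- function(pos, meth, unmeth, context = "CG", contig = "chr1") {
  data.frame(contig = contig, position = pos, strand = "+",
             context = context, n_meth = meth, n_unmeth = unmeth)
}

test_that("window test pools eligible cytosines and matches the oracle", {
  # only 2 positions covered >= 5x in both: ineligible
  a <- mk_cyt(c(10, 20, 30), c(5, 5, 1), c(5, 5, 1))
  b <- mk_cyt(c(10, 20, 30), c(0, 0, 0), c(10, 10, 2))
  expect_null(window_test(a, b))
  # 3 fully opposed cytosines -> levels 100 vs 0, oracle on [[30,0],[0,30]]
  a <- mk_cyt(c(10, 20, 30), 10, 0)
  b <- mk_cyt(c(10, 20, 30), 0, 10)
  wt <- window_test(a, b)
  expect_equal(wt$n_eligible, 3)
  expect_equal(c(wt$level_1, wt$level_2, wt$diff), c(100, 0, 100))
  expect_equal(wt$p_raw, oracle_fisher_p(30, 0, 0, 30), tolerance = 1e-12)
  expect_error(window_test(a, mk_cyt(c(10, 20, 30), 0, 10, context = "CHG")),
               "contexts")
})

test_that("context difference thresholds are boundary-inclusive", {
  # pooled levels 70% vs exactly 35%: diff 35.0 meets the CG threshold;
  # 349/500 vs 35% (diff 34.8) falls just short
  pos <- c(10, 20, 30)
  a <- mk_cyt(pos, 70, 30)          # level 70 at every cytosine
  b <- mk_cyt(pos, 35, 65)          # level 35
  wt <- window_test(a, b)
  expect_equal(wt$diff, 35)
  cfg <- dmr_config()
  expect_true(abs(wt$diff) >= cfg$min_diff[["CG"]])
  wt2 <- window_test(mk_cyt(pos, 349, 151), b)   # level 69.8
  expect_lt(abs(wt2$diff), cfg$min_diff[["CG"]])
})

test_that("a methylome against itself yields zero DMRs", {
  meth <- tiny_methylomes()
  wt <- call_dmrs(meth$maternal, meth$maternal, meth$contig_lengths)
  expect_gt(nrow(wt), 0)
  expect_equal(sum(wt$is_dmr), 0)
})

test_that("swapping methylomes flips directions and nothing else", {
  meth <- tiny_methylomes()
  ab <- call_dmrs(meth$maternal, meth$paternal, meth$contig_lengths)
  ba <- call_dmrs(meth$paternal, meth$maternal, meth$contig_lengths)
  expect_equal(nrow(ab), nrow(ba))
  expect_equal(ab$p_raw, ba$p_raw, tolerance = 1e-12)
  expect_equal(ab$diff, -ba$diff, tolerance = 1e-12)
  flip <- c(hyper_1 = "hyper_2", hyper_2 = "hyper_1", none = "none")
  expect_equal(unname(flip[ab$direction]), ba$direction)
  # and a constructed window's p-value agrees with the enumeration oracle
  a <- mk_cyt(c(5, 15, 25), c(9, 8, 7), c(1, 2, 3))
  b <- mk_cyt(c(5, 15, 25), c(2, 1, 3), c(8, 9, 7))
  expect_equal(window_test(a, b)$p_raw, oracle_fisher_p(24, 6, 6, 24),
               tolerance = 1e-12)
})

test_that("DMR calls ignore record order and ineligible windows leave p_adj alone", {
  meth <- tiny_methylomes()
  base <- call_dmrs(meth$maternal, meth$paternal, meth$contig_lengths)
  set.seed(4)
  shuf <- function(df) df[sample.int(nrow(df)), ]
  perm <- call_dmrs(cx_report(shuf(as.data.frame(meth$maternal))),
                    cx_report(shuf(as.data.frame(meth$paternal))),
                    meth$contig_lengths)
  expect_equal(perm, base)
  # appending under-covered (ineligible) records changes nothing
  extra <- mk_cyt(c(101, 111, 121), 1, 1, context = "CG", contig = "chrX")
  m1 <- cx_report(rbind(as.data.frame(meth$maternal), extra))
  m2 <- cx_report(rbind(as.data.frame(meth$paternal), extra))
  aug <- call_dmrs(m1, m2, meth$contig_lengths)
  expect_equal(aug, base)
})

test_that("planted DMRs are recovered with controlled false positives", {
  dm <- default_methylomes()
  truth <- dm$meth$truth
  sig <- dm$windows[dm$windows$is_dmr, ]
  hit <- vapply(seq_len(nrow(truth)), function(i) {
    any(sig$contig == truth$contig[i] & sig$start == truth$start[i] &
        sig$context == truth$context[i] &
        sig$direction == truth$direction[i])
  }, logical(1))
  expect_gte(mean(hit), 0.9)
  null_w <- dm$windows[!(paste(dm$windows$contig, dm$windows$start,
                               dm$windows$context) %in%
                         paste(truth$contig, truth$start, truth$context)), ]
  expect_lte(mean(null_w$is_dmr), 0.01)
})

test_that("DMR-feature classification matches a brute-force overlap oracle", {
  meth <- tiny_methylomes()
  feats <- meth$features
  set.seed(8)
  dmrs <- data.frame(contig = "chr1",
                     start = sample(seq(1, 29701, by = 300), 12))
  dmrs$end <- dmrs$start + 299
  dmrs$context <- sample(c("CG", "CHG", "CHH"), 12, TRUE)
  dmrs$is_dmr <- TRUE
  dmrs$direction <- sample(c("maternal", "paternal"), 12, TRUE)
  cfg <- dmr_config()
  summ <- summarize_dmrs(list(dmrs), feats, cfg)
  g <- feats[feats$kind == "gene", ]; r <- feats[feats$kind == "repeat", ]
  in_g <- oracle_overlaps(dmrs$contig, dmrs$start, dmrs$end,
                          g$contig, g$start, g$end, flank = 2000)
  in_r <- oracle_overlaps(dmrs$contig, dmrs$start, dmrs$end,
                          r$contig, r$start, r$end, flank = 2000)
  klass <- ifelse(in_g & in_r, "gene+repeat",
           ifelse(in_g, "gene", ifelse(in_r, "repeat", "neither")))
  want <- table(paste(dmrs$direction, dmrs$context, klass))
  got <- setNames(summ$mean_count,
                  paste(summ$direction, summ$context, summ$overlap_class))
  expect_equal(got[names(want)], c(want)[names(want)], ignore_attr = TRUE)
  expect_equal(sum(summ$mean_count), nrow(dmrs))
  # a specific convention case: DMR 2100-2400 vs gene 4000-6000, flank 2000
  one <- data.frame(contig = "chrZ", start = 2100, end = 2400, context = "CG",
                    is_dmr = TRUE, direction = "maternal")
  fz <- feature_set(data.frame(feature_id = "gz", contig = "chrZ",
                               start = 4000, end = 6000, strand = "+",
                               kind = "gene"))
  sz <- summarize_dmrs(list(one), fz, cfg)
  expect_equal(sz$mean_count[sz$direction == "maternal" &
                             sz$context == "CG" &
                             sz$overlap_class == "gene"], 1)
})

test_that("consistent gene association applies 75/25 inclusively", {
  fz <- feature_set(data.frame(feature_id = "g1", contig = "c", start = 5000,
                               end = 8000, strand = "+", kind = "gene"))
  dmr <- function(dirn) {
    data.frame(contig = "c", start = 3100, end = 3400, context = "CG",
               is_dmr = TRUE, direction = dirn)
  }
  none <- dmr("maternal")[0, ]
  # maternal overlap in 4/4, no paternal
  a4 <- consistent_gene_association(replicate(4, dmr("maternal"),
                                              simplify = FALSE), fz)
  expect_equal(a4$association[a4$context == "CG"], "maternal")
  # 3/4 maternal and 1/4 paternal: exactly 0.75 and 0.25, still associated
  a31 <- consistent_gene_association(
    c(replicate(3, dmr("maternal"), simplify = FALSE), list(dmr("paternal"))),
    fz)
  expect_equal(a31$association[a31$context == "CG"], "maternal")
  # 2/4 both ways: none
  a22 <- consistent_gene_association(
    c(replicate(2, dmr("maternal"), simplify = FALSE),
      replicate(2, dmr("paternal"), simplify = FALSE)), fz)
  expect_equal(a22$association[a22$context == "CG"], "none")
})

test_that("metagene profiles honour orientation and constructed levels", {
  # gene 1001-3000; flank cytosines unmethylated, body 50% methylated
  mkm <- function(strand) {
    pos <- seq(1, 5000, by = 20)
    body <- pos >= 1001 & pos <= 3000
    cx_report(data.frame(contig = "c", position = pos, strand = "+",
                         context = "CG", n_meth = ifelse(body, 5, 0),
                         n_unmeth = ifelse(body, 5, 10)))
  }
  run <- function(strand, align = "start_5prime") {
    f <- feature_set(data.frame(feature_id = "g", contig = "c", start = 1001,
                                end = 3000, strand = strand, kind = "gene"))
    metagene_profile(mkm(strand), f, flank = 1000, bin = 100, align = align)
  }
  plus <- run("+")
  expect_equal(dim(plus), c(20, 3))
  expect_true(all(plus[1:10, "CG"] == 0))    # upstream flank
  expect_true(all(plus[11:20, "CG"] == 50))  # body
  minus <- run("-")
  # a minus-strand copy of the same layout is symmetric about the gene
  # centre, so its 5'-aligned profile is identical
  expect_equal(minus, plus)
  tail3 <- run("+", align = "end_3prime")
  expect_true(all(tail3[1:10, "CG"] == 50))  # body side of the 3' anchor
  expect_true(all(tail3[11:20, "CG"] == 0))  # downstream flank
  # fully methylated methylome -> every covered bin is 100
  full <- cx_report(data.frame(contig = "c", position = seq(1, 5000, 20),
                               strand = "+", context = "CHH", n_meth = 4,
                               n_unmeth = 0))
  f <- feature_set(data.frame(feature_id = "g", contig = "c", start = 1001,
                              end = 3000, strand = "+", kind = "gene"))
  pf <- metagene_profile(full, f, flank = 1000, bin = 100)
  expect_true(all(pf[, "CHH"] == 100, na.rm = TRUE))
  expect_true(all(is.na(pf[, "CG"])))        # uncovered contexts are NA
  # counts are conserved between the profile and the profiled region
  pooled <- attr(plus, "pooled_total")
  pos <- seq(1, 5000, by = 20)
  expect_equal(sum(pooled[, "CG"]), sum(pos < 2001) * 10)
  expect_true(all(plus >= 0 & plus <= 100, na.rm = TRUE))
  expect_error(metagene_profile(full, f, flank = 1000, bin = 333),
               "divide")
})

test_that("conversion-rate estimation recovers the planted failure rate", {
  meth <- tiny_methylomes()
  est <- estimate_conversion_rate(meth$maternal, "chrC")
  expect_lt(abs(est - 99.85), 0.05)
  expect_error(estimate_conversion_rate(meth$maternal, "nope"),
               "control contig")
  clean <- cx_report(data.frame(contig = "ctl", position = 1:100,
                                strand = "+", context = "CG",
                                n_meth = 0, n_unmeth = 10))
  expect_equal(estimate_conversion_rate(clean, "ctl"), 100)
  dirty <- cx_report(data.frame(contig = "ctl", position = 1:100,
                                strand = "+", context = "CG",
                                n_meth = 10, n_unmeth = 0))
  expect_message(r <- estimate_conversion_rate(dirty, "ctl"), "degenerate")
  expect_equal(r, 0)
})
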