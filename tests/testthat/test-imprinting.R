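test_that("maternal bias estimation follows the per-direction-maximum rule", {
  sheet <- cross_samples(data.frame(
    sample_id = c("d1r1", "d1r2", "d2r1", "d2r2"),
    maternal_species = c("Nt", "Nt", "Nd", "Nd"),
    paternal_species = c("Nd", "Nd", "Nt", "Nt"),
    tissue = "endosperm", replicate_index = c(1, 2, 1, 2)))
  # one gene per sample is enough: pooled per-sample ratios are then exactly
  # the chosen maternal/paternal quotients 1.2, 1.4 | 1.1, 1.5
  mk <- function(ratios) {
    df <- data.frame(gene_id = "g1", sample_id = sheet$sample_id,
                     maternal = ratios * 1000, paternal = 1000)
    df$count_A <- ifelse(sheet$maternal_species == "Nt", df$maternal,
                         df$paternal)
    df$count_B <- ifelse(sheet$maternal_species == "Nt", df$paternal,
                         df$maternal)
    allele_counts(df[, c("gene_id", "sample_id", "count_A", "count_B")],
                  "Nt", "Nd", samples = sheet)
  }
  expect_equal(estimate_maternal_bias(mk(c(1.2, 1.4, 1.1, 1.5)), sheet),
               (1.4 + 1.5) / 2)
  # perfect 50/50 everywhere -> beta = 1
  expect_equal(estimate_maternal_bias(mk(c(1, 1, 1, 1)), sheet), 1)
  expect_error(estimate_maternal_bias(mk(c(1, 1, 1, 1)), sheet[1:2, ]),
               "directions")
})

test_that("the bias-adjusted exact test builds the stated 2x2 table", {
  # beta = 1: homogeneous table, p = 1
  r <- test_gene_pair(c(100, 100), c(100, 100), imprinting_config(beta = 1))
  expect_equal(r$p_raw, 1)
  expect_equal(c(r$maternal_fraction_dir1, r$maternal_fraction_dir2),
               c(0.5, 0.5))

  # strong reciprocal bias: p agrees with the enumeration oracle
  r <- test_gene_pair(c(90, 10), c(90, 10), imprinting_config(beta = 1))
  expect_equal(unname(r$table), rbind(c(90, 10), c(10, 90)))
  expect_equal(r$p_raw, oracle_fisher_p(90, 10, 10, 90), tolerance = 1e-12)
  expect_lt(r$p_raw, 0.01)
  expect_equal(c(r$maternal_fraction_dir1, r$maternal_fraction_dir2),
               c(0.9, 0.9))

  # beta = 1.32 divides only the maternal counts, rounding half away from 0;
  # dir2's maternal allele is species B, so its adjusted count sits in
  # column B
  r <- test_gene_pair(c(66, 50), c(43, 57), imprinting_config(beta = 1.32))
  expect_equal(unname(r$table), rbind(c(50, 50), c(57, 33)))
  expect_equal(r$p_raw, oracle_fisher_p(50, 50, 57, 33), tolerance = 1e-12)

  expect_error(test_gene_pair(c(-1, 5), c(5, 5)), "negative")
})

test_that("beta = 1 leaves every adjusted table equal to the raw table", {
  set.seed(5)
  for (i in 1:25) {
    m1 <- rpois(1, 80); p1 <- rpois(1, 80)
    m2 <- rpois(1, 80); p2 <- rpois(1, 80)
    r <- test_gene_pair(c(m1, p1), c(m2, p2), imprinting_config(beta = 1))
    expect_equal(unname(r$table), rbind(c(m1, p1), c(p2, m2)))
  }
})

test_that("imprinting factor matches the closed-form Wilson oracle", {
  cfg <- imprinting_config(beta = 1)
  # identical counts in both directions: no parent-of-origin separation
  expect_lte(imprinting_factor(c(80, 80), c(80, 80), cfg), 1)
  # a pure species bias (same allelic ratio both directions) is not
  # imprinting: the two species-ratio intervals coincide
  expect_lte(imprinting_factor(c(90, 10), c(10, 90), cfg), 1)

  # a 90% maternal gene in both directions: the species-A ratio intervals
  # of the two directions separate; the oracle rebuilds the factor from
  # prop.test bounds
  ci1 <- oracle_wilson(90, 100); ci2 <- oracle_wilson(10, 100)
  want <- (ci1["lower"] / (1 - ci1["lower"])) /
          (ci2["upper"] / (1 - ci2["upper"]))
  got <- imprinting_factor(c(90, 10), c(90, 10), cfg)
  expect_equal(got, unname(want), tolerance = 1e-12)
  expect_gt(got, 2)

  # all-or-nothing proportions hit the stated limits without faults
  meg_extreme <- imprinting_factor(c(100, 0), c(100, 0), cfg)
  peg_extreme <- imprinting_factor(c(0, 100), c(0, 100), cfg)
  expect_true(is.finite(meg_extreme))
  expect_gt(meg_extreme, 2)
  expect_equal(meg_extreme, peg_extreme, tolerance = 1e-12)
})

test_that("cis-effect factor flags shared species bias and only that", {
  cfg <- imprinting_config(beta = 1)
  # balanced: no species bias
  expect_equal(cis_effect_factor(c(50, 50), c(50, 50), cfg), 1)
  # both samples 95% species A (sample 2's maternal is B, so (5,95))
  ci <- oracle_wilson(95, 100)
  want <- ci["lower"] / (1 - ci["lower"])
  got <- cis_effect_factor(c(95, 5), c(5, 95), cfg)
  expect_equal(got, unname(want), tolerance = 1e-12)
  # at deeper counts the shared bias exceeds the 15-fold exclusion gate
  expect_gt(cis_effect_factor(c(990, 10), c(10, 990), cfg), 15)
  # disagreeing directions (an imprinted pattern): factor stays 1
  expect_equal(cis_effect_factor(c(90, 10), c(90, 10), cfg), 1)
})

test_that("comparison calls gate on fractions, IF, CEF and significance", {
  sheet <- cross_samples(data.frame(
    sample_id = c("d1", "d2"), maternal_species = c("Nt", "Nd"),
    paternal_species = c("Nd", "Nt"), tissue = "endosperm",
    replicate_index = 1))
  mk <- function(m1, p1, m2, p2, gene = "g1") {
    data.frame(gene_id = gene, sample_id = c("d1", "d2"),
               count_A = c(m1, p2), count_B = c(p1, m2))
  }
  # boundary-inclusive MEG at exactly 70% maternal in both directions
  df <- rbind(mk(700, 300, 700, 300, "meg"),
              mk(650, 350, 720, 280, "fail_gate"),
              mk(500, 500, 500, 500, "null"),
              mk(10, 10, 10, 10, "shallow"))
  tab <- allele_counts(df, "Nt", "Nd", samples = sheet)
  calls <- call_comparison(tab, sheet[1, ], sheet[2, ],
                           imprinting_config(beta = 1))
  st <- setNames(calls$status, calls$gene_id)
  expect_equal(st[["meg"]], "MEG")
  expect_equal(st[["fail_gate"]], "none")   # 0.65 < 0.70 in one direction
  expect_equal(st[["null"]], "none")
  expect_equal(st[["shallow"]], "untestable")
  expect_error(call_comparison(tab, sheet[1, ], sheet[1, ]), "opposite")
})

test_that("BH adjustment matches the reference step-up and is rank-monotone", {
  set.seed(11)
  for (i in 1:10) {
    p <- runif(sample(5:400, 1))^2
    expect_equal(p.adjust(p, "BH"), oracle_bh(p), tolerance = 1e-12)
  }
  st <- default_study()
  one <- st$comparisons[[1]]
  one <- one[one$testable, ]
  expect_equal(one$p_adj, oracle_bh(one$p_raw), tolerance = 1e-12)
  o <- order(one$p_raw)
  expect_true(all(diff(one$p_adj[o]) >= -1e-12))
  expect_true(all(one$p_adj >= one$p_raw - 1e-12))
})

test_that("consolidation counts all pairings and applies 75% inclusively", {
  mk_cmp <- function(status, id) {
    data.frame(gene_id = "g1", comparison_id = id, testable = TRUE,
               p_raw = 1e-9, p_adj = 1e-8, maternal_fraction_dir1 = 0.9,
               maternal_fraction_dir2 = 0.9, imprinting_factor = 10,
               cis_effect_factor = 1, status = status)
  }
  as_meg <- function(k) {
    cmp <- lapply(1:4, function(i) {
      mk_cmp(if (i <= k) "MEG" else "none", paste0("c", i))
    })
    consolidate_calls(cmp)$final_status
  }
  expect_equal(as_meg(4), "MEG")
  expect_equal(as_meg(3), "MEG")   # 3 of 4 = 0.75, boundary inclusive
  expect_equal(as_meg(2), "none")
  # untestable counts against the denominator
  cmp <- c(lapply(1:3, function(i) mk_cmp("MEG", paste0("c", i))),
           list(mk_cmp("untestable", "c4")))
  expect_equal(consolidate_calls(cmp)$final_status, "MEG")
  expect_error(consolidate_calls(list()), "zero comparisons")
})

test_that("status is invariant to species labelling and sample order", {
  sim <- tiny_expression()
  cfg <- imprinting_config()
  s <- as.data.frame(sim$samples)
  d1 <- s[s$maternal_species == "Nt", ][1, ]
  d2 <- s[s$maternal_species == "Nd", ][1, ]
  base <- call_comparison(sim$counts, d1, d2, cfg)

  # swap the species labels of both columns everywhere
  df <- as.data.frame(sim$counts)
  names(df)[names(df) == "count_A"] <- "tmp"
  names(df)[names(df) == "count_B"] <- "count_A"
  names(df)[names(df) == "tmp"] <- "count_B"
  sp <- species_labels(sim$counts)
  swapped <- allele_counts(df, sp[2], sp[1], samples = sim$samples)
  sw <- call_comparison(swapped, d1, d2, cfg)
  expect_equal(sw$status, base$status)
  expect_equal(sw$p_raw, base$p_raw, tolerance = 1e-12)

  # swap the two samples' roles
  rev <- call_comparison(sim$counts, d2, d1, cfg)
  expect_equal(rev$status, base$status)
  expect_equal(rev$p_raw, base$p_raw, tolerance = 1e-12)
  expect_equal(rev$imprinting_factor, base$imprinting_factor,
               tolerance = 1e-12)
  expect_equal(rev$cis_effect_factor, base$cis_effect_factor,
               tolerance = 1e-12)
  expect_equal(rev$maternal_fraction_dir1, base$maternal_fraction_dir2)
})

test_that("planted imprinting is recovered and cis genes are excluded", {
  st <- default_study()
  truth <- st$sim$truth
  called <- st$consolidated
  meg_called <- called$gene_id[called$final_status == "MEG"]
  peg_called <- called$gene_id[called$final_status == "PEG"]
  sens_meg <- mean(truth$gene_id[truth$status == "MEG"] %in% meg_called)
  expect_gte(sens_meg, 0.9)
  sens_peg <- mean(truth$gene_id[truth$status == "PEG"] %in% peg_called)
  expect_gte(sens_peg, 0.9)
  # cis genes (20-fold species ratio) must never be called imprinted
  cis <- truth$gene_id[truth$status == "cis"]
  expect_equal(sum(cis %in% c(meg_called, peg_called)), 0)
  # false calls among null genes
  nulls <- truth$gene_id[truth$status == "null"]
  fcr <- mean(nulls %in% c(meg_called, peg_called))
  expect_lte(fcr, 0.02)
})
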