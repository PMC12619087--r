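# Study-scale simulations are expensive, so they are built once per test run
# and shared between the blocks that need them (including the acceptance
# checks). Seeds are fixed: these fixtures ARE the study conditions.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, build) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, build(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# tiny reciprocal-cross expression fixture (seconds)
tiny_expression <- function() {
  cached("tiny_expression", function() {
    simulate_expression(fixture_config("tiny", seed = 7))
  })
}

tiny_methylomes <- function() {
  cached("tiny_methylomes", function() {
    simulate_methylomes(fixture_config("tiny", seed = 7))
  })
}

# 10^4 genes, 2+2 replicates, no planted signal: pure null at beta = 1.32
null_study <- function() {
  cached("null_study", function() {
    cfg <- sim_config(seed = 101, frac_meg = 0, frac_peg = 0, frac_cis = 0)
    sim <- simulate_expression(cfg)
    cons <- consolidate_calls(call_all_comparisons(sim$counts, sim$samples))
    list(sim = sim, consolidated = cons)
  })
}

# the default study-scale fixture: planted MEGs/PEGs/cis genes
default_study <- function() {
  cached("default_study", function() {
    cfg <- sim_config(seed = 202)
    sim <- simulate_expression(cfg)
    comparisons <- call_all_comparisons(sim$counts, sim$samples)
    cons <- consolidate_calls(comparisons)
    list(cfg = cfg, sim = sim, comparisons = comparisons, consolidated = cons)
  })
}

# contamination-corrected re-calls of the default fixture at f = 0.25, 0.5
default_contamination <- function() {
  cached("default_contamination", function() {
    st <- default_study()
    ws <- simulate_wholeseed_and_contaminate(st$sim, st$cfg)
    corrected <- lapply(c("0.25" = 0.25, "0.5" = 0.5), function(f) {
      ctab <- correct_maternal_counts(st$sim$counts, st$sim$samples,
                                      ws$profile, f)
      consolidate_calls(call_all_comparisons(ctab, st$sim$samples))
    })
    list(profile = ws$profile, corrected = corrected)
  })
}

# study-scale methylome pair with planted DMRs
default_methylomes <- function() {
  cached("default_methylomes", function() {
    meth <- simulate_methylomes(sim_config(seed = 303))
    windows <- normalize_dmr_direction(
      call_dmrs(meth$maternal, meth$paternal, meth$contig_lengths))
    list(meth = meth, windows = windows)
  })
}
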