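# A small cohort keeps unit tests fast; 80 samples is enough for every
# structural property (the full 268-array recovery runs in the acceptance
# suite). With 80 samples a singleton call sits at 1.25% frequency, safely
# below the 2% reclassification threshold.
small_config <- function(seed = 42) {
  simulation_config(
    seed = seed, n_samples = 80L,
    platform_counts = c(SNP6 = 18L, C750K = 16L, CYTOHD = 46L))
}

test_that("simulation is fully deterministic under the seed", {
  cfg <- small_config()
  t1 <- simulate_tracks(cfg); t2 <- simulate_tracks(cfg)
  expect_identical(t1, t2)
  c1 <- simulate_cohort(cfg, t1); c2 <- simulate_cohort(cfg, t2)
  expect_identical(c1, c2)
  # a different seed changes the cohort
  cfg2 <- small_config(seed = 43)
  c3 <- simulate_cohort(cfg2, simulate_tracks(cfg2))
  expect_false(identical(c1$calls, c3$calls))
})

test_that("generated tracks give each intended tier exactly one evidence route", {
  cfg <- small_config()
  tr <- simulate_tracks(cfg)
  layout <- attr(tr, "layout")
  live <- layout[!layout$spike, ]
  # per-rule slot counts match per-rule track record counts
  expect_equal(nrow(tr$benign_population$records),
               sum(live$intended_rule == "B-DGV50") +
                 sum(cfg$recurrent_regions$intended_label == "benign"))
  expect_equal(nrow(tr$syndrome$records), sum(live$intended_rule == "P-SYND"))
  expect_equal(nrow(tr$affected$records),
               sum(live$intended_rule %in% c("V-1", "V-3", "LP-DBCONS",
                                             "P-CONS")))
  expect_true(all(tr$benign_population$records$support_individuals >= 3))
  # slots never overlap one another (pairwise disjoint layout)
  by_chrom <- split(layout, layout$chrom)
  for (b in by_chrom) {
    b <- b[order(b$start), ]
    if (nrow(b) > 1) expect_true(all(b$start[-1] >= b$end[-nrow(b)]))
  }
  # a recurrent region demanding a pathogenic tier is contradictory
  rr <- recurrent_region_defaults()
  rr$intended_label[1] <- "pathogenic"
  expect_error(simulation_config(recurrent_regions = rr), "contradictory")
})

test_that("cohort calibration tracks the configured study conditions", {
  cfg <- simulation_config(seed = 9)     # full 268-sample conditions
  tr <- simulate_tracks(cfg)
  co <- simulate_cohort(cfg, tr)
  inc <- !co$ground_truth$spike
  calls <- co$calls[inc, ]
  expect_gt(nrow(calls), 1000)

  # per-platform mean calls within 3 standard errors of the Poisson means
  n_by_sample <- tabulate(factor(calls$sample_id,
                                 levels = co$roster$sample_id),
                          nbins = nrow(co$roster))
  for (p in CNV_PLATFORMS) {
    sel <- co$roster$platform == p
    se <- sqrt(cfg$mean_calls[[p]] / sum(sel))
    expect_lt(abs(mean(n_by_sample[sel]) - cfg$mean_calls[[p]]), 3 * se)
  }

  # overall gain fraction within 3 binomial SE of 80.3%
  p0 <- cfg$gain_fraction
  se <- sqrt(p0 * (1 - p0) / nrow(calls))
  expect_lt(abs(mean(calls$cnv_type == "gain") - p0), 3 * se)

  # injected recurrent carrier fractions within binomial 99% intervals
  gt <- co$ground_truth
  for (k in seq_len(nrow(cfg$recurrent_regions))) {
    rg <- cfg$recurrent_regions[k, ]
    obs <- length(unique(gt$sample_id[gt$region %in% rg$name]))
    lim <- qbinom(c(0.005, 0.995), cfg$n_samples, rg$target_frequency)
    expect_gte(obs, lim[1])
    expect_lte(obs, lim[2])
  }

  # all calls autosomal, gains >= 200 kb and losses >= 150 kb when included
  expect_true(all(calls$chrom %in% AUTOSOMES))
  expect_true(all((calls$end - calls$start) >=
                    ifelse(calls$cnv_type == "gain", 2e5, 1.5e5)))
  expect_true(all(calls$probe_count >= 50))
})

test_that("ground-truth labels are recovered exactly on a small cohort", {
  cfg <- small_config()
  tr <- simulate_tracks(cfg)
  co <- simulate_cohort(cfg, tr)
  rep <- verify_recovery(co, tr)
  expect_equal(rep$n_gate_unexpected, 0)
  expect_equal(rep$n_initial_mismatch, 0)
  expect_equal(rep$n_final_mismatch, 0)
  expect_equal(rep$recovery_pct, 100)
  expect_equal(nrow(rep$mismatches), 0)
  # spike calls all died at the intended gate
  spikes <- co$ground_truth$spike
  expect_equal(rep$n_calls - rep$n_included_observed, sum(spikes))
})

test_that("QC failures remove whole samples from the analyzed cohort", {
  cfg <- simulation_config(seed = 5, n_samples = 80L,
                           platform_counts = c(SNP6 = 18L, C750K = 16L,
                                               CYTOHD = 46L),
                           qc_fail_rate = 0.15)
  tr <- simulate_tracks(cfg)
  co <- simulate_cohort(cfg, tr)
  qc <- evaluate_sample_qc(co$qc_metrics)
  expect_true(any(!qc$pass))
  rep <- verify_recovery(co, tr)
  expect_equal(rep$recovery_pct, 100)
  expect_equal(rep$cohort_size, sum(qc$pass))
  failing <- qc$sample_id[!qc$pass]
  expect_false(any(rep$classified$sample_id %in% failing))
})

test_that("written cohorts round-trip through the parsers", {
  cfg <- small_config()
  tr <- simulate_tracks(cfg)
  co <- simulate_cohort(cfg, tr)
  dir <- withr::local_tempdir()
  paths <- write_simulated_cohort(co, tr, dir)
  back <- parse_cnv_table(paths[["calls"]])
  expect_equal(nrow(back$errors), 0)
  expect_equal(back$calls[c("chrom", "start", "end", "cnv_type")],
               co$calls[c("chrom", "start", "end", "cnv_type")])
  ben <- parse_track(paths[["benign_population"]], "benign_population")
  expect_equal(ben$records, tr$benign_population$records)
})
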