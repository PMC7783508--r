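# Synthetic-cohort generator
#
# Emulates the statistical structure of a 268-array clinical cohort across
# three Affymetrix platforms: per-platform Poisson call counts, ~80:20
# gain:loss ratio, right-skewed log-normal call sizes, and four injected
# recurrent gain regions at their observed population frequencies. Every
# generated call carries a ground-truth tier reachable by exactly one
# classification rule, so a full pipeline run must recover the intended
# labels exactly; mismatches indicate pipeline bugs, not noise.

# hg19 autosome lengths (bp); coordinates only, no sequence.
HG19_AUTOSOME_LEN <- c(
  `1` = 249250621, `2` = 243199373, `3` = 198022430, `4` = 191154276,
  `5` = 180915260, `6` = 171115067, `7` = 159138663, `8` = 146364022,
  `9` = 141213431, `10` = 135534747, `11` = 135006516, `12` = 133851895,
  `13` = 115169878, `14` = 107349540, `15` = 102531392, `16` = 90354753,
  `17` = 81195210, `18` = 78077248, `19` = 59128983, `20` = 63025520,
  `21` = 48129895, `22` = 51304566)

#' Default recurrent-region specifications
#'
#' The four recurrent gain loci injected by the generator, with their
#' hg19-like coordinates (internal convention), target carrier frequencies
#' and intended pre-reclassification tiers: 14q32.33 (97.8% of arrays,
#' benign), 22q11.22 (32.1%, benign), 1p36.32 (9.7%, VUS) and 1q21.1
#' (6.7%, likely benign).
#'
#' @return data.frame with one row per region.
#' @export
recurrent_region_defaults <- function() {
  data.frame(
    name = c("14q32.33", "22q11.22", "1p36.32", "1q21.1"),
    chrom = c("14", "22", "1", "1"),
    start = c(105800000, 22900000, 2412000, 145380000),
    end = c(106300000, 23250000, 2730000, 146332000),
    cnv_type = "gain",
    target_frequency = c(0.978, 0.321, 0.097, 0.067),
    intended_label = c("benign", "benign", "vus", "likely_benign"))
}

#' Simulation configuration
#'
#' The defaults are the emulated study conditions: 268 samples split
#' 59/54/155 over SNP6/750K/HD, per-platform mean call counts of
#' 12.6/2.9/3.9, an overall 80.3% gain fraction, log-normal sizes calibrated
#' to mean ~704 kb for gains and ~1.0 Mb for losses (truncated to the
#' inclusion minima and 25 Mb), the overall tier mix
#' 92.9/1.6/2.6/0.2/2.7%, and the four recurrent regions of
#' [recurrent_region_defaults()]. Because the injected recurrent calls are
#' all gains with benign/LB/VUS tiers, the generator back-computes the
#' gain fraction and tier mix of the *non-recurrent* calls so the overall
#' cohort matches these targets.
#'
#' @param seed integer seed fixing the entire output.
#' @param n_samples number of arrays.
#' @param platform_counts named integer vector of samples per platform.
#' @param mean_calls named numeric vector, Poisson mean calls per sample.
#' @param gain_fraction overall fraction of gains.
#' @param size_mean_target target mean call size per type (bp); the
#'   log-normal `meanlog` is calibrated numerically so the distribution
#'   truncated to \[inclusion minimum, `size_max`\] has this mean.
#' @param size_sdlog log-normal shape (log-scale SD) per type.
#' @param size_max size truncation ceiling (bp).
#' @param recurrent_regions data.frame as [recurrent_region_defaults()];
#'   intended labels must be benign/likely_benign/vus (a recurrent region
#'   demanding a pathogenic tier would contradict the frequency-based
#'   reclassification semantics and is rejected).
#' @param label_mix named overall tier proportions (normalized to sum 1).
#' @param filter_spike_rate fraction (relative to the expected included call
#'   count) of extra below-threshold calls injected to exercise the
#'   inclusion filter.
#' @param qc_fail_rate per-sample probability of failing array QC.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(
    seed = 1L, n_samples = 268L,
    platform_counts = c(SNP6 = 59L, C750K = 54L, CYTOHD = 155L),
    mean_calls = c(SNP6 = 12.6, C750K = 2.9, CYTOHD = 3.9),
    gain_fraction = 0.803,
    size_mean_target = c(gain = 704000, loss = 1000000),
    size_sdlog = c(gain = 1, loss = 1),
    size_max = 25e6,
    recurrent_regions = recurrent_region_defaults(),
    label_mix = c(benign = 0.929, likely_benign = 0.016, vus = 0.026,
                  likely_pathogenic = 0.002, pathogenic = 0.027),
    filter_spike_rate = 0.1,
    qc_fail_rate = 0) {
  stopifnot(n_samples > 0, gain_fraction >= 0, gain_fraction <= 1,
            filter_spike_rate >= 0, qc_fail_rate >= 0, qc_fail_rate <= 1,
            setequal(names(platform_counts), CNV_PLATFORMS),
            setequal(names(mean_calls), CNV_PLATFORMS),
            all(names(label_mix) %in% CNV_LABELS), all(label_mix >= 0))
  if (!is.null(recurrent_regions) && nrow(recurrent_regions)) {
    bad <- setdiff(recurrent_regions$intended_label,
                   c("benign", "likely_benign", "vus"))
    if (length(bad)) {
      stop("contradictory recurrent-region config: intended label(s) ",
           paste(bad, collapse = ", "),
           " cannot coexist with frequency-based benign reclassification")
    }
    validate_intervals(recurrent_regions, "recurrent region")
  }
  label_mix <- label_mix / sum(label_mix)
  size_meanlog <- c(
    gain = calibrate_meanlog(size_mean_target[["gain"]],
                             size_sdlog[["gain"]], 200000, size_max),
    loss = calibrate_meanlog(size_mean_target[["loss"]],
                             size_sdlog[["loss"]], 150000, size_max))
  structure(list(seed = as.integer(seed), n_samples = as.integer(n_samples),
                 platform_counts = platform_counts, mean_calls = mean_calls,
                 gain_fraction = gain_fraction,
                 size_mean_target = size_mean_target,
                 size_meanlog = size_meanlog,
                 size_sdlog = size_sdlog, size_max = size_max,
                 recurrent_regions = recurrent_regions,
                 label_mix = label_mix,
                 filter_spike_rate = filter_spike_rate,
                 qc_fail_rate = qc_fail_rate),
            class = "simulation_config")
}

# One shared stream split hierarchically by stage: each stage re-seeds from
# a sub-seed drawn once from the master seed, so adding draws to one stage
# never perturbs another stage's output.
SIM_STAGES <- c("layout", "tracks", "roster", "qc", "recurrent", "calls")

stage_seed <- function(seed, stage) {
  idx <- match(stage, SIM_STAGES)
  stopifnot(!is.na(idx))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv())
  set.seed(seed)
  s <- sample.int(.Machine$integer.max, length(SIM_STAGES))[idx]
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  s
}

# Truncated log-normal via inverse-CDF; vectorized over all parameters.
rtrunc_lnorm <- function(n, meanlog, sdlog, lo, hi) {
  p_lo <- stats::plnorm(lo, meanlog, sdlog)
  p_hi <- stats::plnorm(hi, meanlog, sdlog)
  stats::qlnorm(stats::runif(n, p_lo, p_hi), meanlog, sdlog)
}

# Mean of a log-normal truncated to [lo, hi].
trunc_lnorm_mean <- function(meanlog, sdlog, lo, hi) {
  a <- (log(lo) - meanlog) / sdlog
  b <- (log(hi) - meanlog) / sdlog
  exp(meanlog + sdlog^2 / 2) *
    (stats::pnorm(b - sdlog) - stats::pnorm(a - sdlog)) /
    (stats::pnorm(b) - stats::pnorm(a))
}

# meanlog such that the [lo, hi]-truncated distribution has the target mean.
calibrate_meanlog <- function(target_mean, sdlog, lo, hi) {
  stats::uniroot(function(m) trunc_lnorm_mean(m, sdlog, lo, hi) - target_mean,
                 lower = log(lo) - 5, upper = log(hi))$root
}

min_call_size <- function(cnv_type) ifelse(cnv_type == "gain", 200000, 150000)

# Expected included calls and expected recurrent members, used to
# back-compute non-recurrent gain fraction and tier mix.
sim_expectations <- function(config) {
  e_total <- sum(config$platform_counts[CNV_PLATFORMS] *
                   config$mean_calls[CNV_PLATFORMS])
  rr <- config$recurrent_regions
  e_rec <- if (is.null(rr) || !nrow(rr)) 0
           else config$n_samples * sum(rr$target_frequency)
  e_rec_gain <- if (is.null(rr) || !nrow(rr)) 0
                else config$n_samples *
                  sum(rr$target_frequency[rr$cnv_type == "gain"])
  e_rec_label <- stats::setNames(numeric(length(CNV_LABELS)), CNV_LABELS)
  if (!is.null(rr) && nrow(rr)) {
    for (k in seq_len(nrow(rr))) {
      e_rec_label[rr$intended_label[k]] <-
        e_rec_label[rr$intended_label[k]] +
        config$n_samples * rr$target_frequency[k]
    }
  }
  gain_nr <- (config$gain_fraction * e_total - e_rec_gain) /
    max(e_total - e_rec, 1)
  gain_nr <- min(max(gain_nr, 0), 1)
  mix_full <- stats::setNames(numeric(length(CNV_LABELS)), CNV_LABELS)
  mix_full[names(config$label_mix)] <- config$label_mix
  mix_nr <- pmax(mix_full * e_total - e_rec_label, 0)
  mix_nr <- mix_nr / sum(mix_nr)
  list(e_total = e_total, e_recurrent = e_rec, gain_fraction_nr = gain_nr,
       label_mix_nr = mix_nr)
}

# Lay out slot intervals left-to-right over the autosomes, skipping spans
# reserved for the recurrent regions, with a fixed inter-slot margin so no
# two slots (or their private track records) ever overlap.
place_slots <- function(sizes, reserved, margin = 200000) {
  segs <- do.call(rbind, lapply(names(HG19_AUTOSOME_LEN), function(ch) {
    s <- 0
    e <- HG19_AUTOSOME_LEN[[ch]]
    res <- reserved[reserved$chrom == ch, , drop = FALSE]
    res <- res[order(res$start), , drop = FALSE]
    out <- list()
    for (k in seq_len(nrow(res))) {
      if (res$start[k] > s) {
        out[[length(out) + 1]] <- data.frame(chrom = ch, s = s,
                                             e = res$start[k])
      }
      s <- max(s, res$end[k])
    }
    out[[length(out) + 1]] <- data.frame(chrom = ch, s = s, e = e)
    do.call(rbind, out)
  }))
  n <- length(sizes)
  chroms <- character(n)
  starts <- numeric(n)
  si <- 1
  cur <- segs$s[1]
  for (k in seq_len(n)) {
    w <- sizes[k] + margin
    while (si <= nrow(segs) && cur + w > segs$e[si]) {
      si <- si + 1
      if (si <= nrow(segs)) cur <- segs$s[si]
    }
    if (si > nrow(segs)) {
      stop("synthetic genome capacity exceeded; reduce cohort size or ",
           "call sizes")
    }
    chroms[k] <- segs$chrom[si]
    starts[k] <- cur
    cur <- cur + w
  }
  data.frame(chrom = chroms, start = starts, end = starts + sizes)
}

#' Simulate the reference tracks (and the evidence layout behind them)
#'
#' Generates the benign-population, affected, gene, syndrome and cytoband
#' tracks such that each intended tier of the cohort is reachable by exactly
#' one classification rule: benign slots get a same-type benign record with
#' support from at least three unaffected individuals; VUS slots get one of
#' the three VUS evidence patterns; likely-pathogenic slots an OMIM gene
#' plus a reported-but-unclear affected record; pathogenic slots one of
#' size/syndrome/consistent-database evidence. Slot intervals are laid out
#' disjointly across the autosomes (recurrent loci reserved), so no call
#' sees another call's evidence. Deterministic under the config seed.
#'
#' @param config a [simulation_config()].
#' @return a named list of five [cnv_track()]s (class `cnv_track_bundle`)
#'   with the slot layout attached as attribute `layout`.
#' @export
simulate_tracks <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  exp <- sim_expectations(config)
  set.seed(stage_seed(config$seed, "layout"))

  n_slots <- ceiling(1.25 * exp$e_total) + 50
  lab <- sample(CNV_LABELS, n_slots, replace = TRUE,
                prob = exp$label_mix_nr)
  type <- ifelse(stats::runif(n_slots) < exp$gain_fraction_nr, "gain", "loss")
  rule <- character(n_slots)
  rule[lab == "benign"] <- "B-DGV50"
  rule[lab == "likely_benign"] <- "LB"
  rule[lab == "vus"] <- sample(c("V-1", "V-2", "V-3"), sum(lab == "vus"),
                               replace = TRUE)
  rule[lab == "likely_pathogenic"] <- "LP-DBCONS"
  rule[lab == "pathogenic"] <- sample(c("P-SIZE", "P-SYND", "P-CONS"),
                                      sum(lab == "pathogenic"),
                                      replace = TRUE)
  lo <- min_call_size(type)
  hi <- rep(2.9e6, n_slots)              # keep non-size rules below 3 Mb
  hi[rule == "B-DGV50"] <- config$size_max   # benign support dominates size
  lo[rule == "P-SIZE"] <- 3.1e6
  hi[rule == "P-SIZE"] <- config$size_max
  size <- round(rtrunc_lnorm(n_slots, config$size_meanlog[type],
                             config$size_sdlog[type], lo, hi))
  size <- pmax(size, lo)

  n_spike <- ceiling(config$filter_spike_rate * exp$e_total)
  spike_mode <- rep(c("size", "probes"), length.out = n_spike)
  spike_type <- ifelse(stats::runif(n_spike) < exp$gain_fraction_nr,
                       "gain", "loss")
  spike_size <- ifelse(
    spike_mode == "size",
    round(stats::runif(n_spike, 0.4, 0.95) * min_call_size(spike_type)),
    round(stats::runif(n_spike, 1, 4) * min_call_size(spike_type)))

  slots <- data.frame(
    intended_label = c(lab, rep("excluded", n_spike)),
    intended_rule = c(rule, paste0("EXCL-", toupper(spike_mode))),
    cnv_type = c(type, spike_type),
    size = c(size, spike_size),
    spike = c(rep(FALSE, n_slots), rep(TRUE, n_spike)),
    spike_mode = c(rep(NA_character_, n_slots), spike_mode))
  slots <- slots[sample.int(nrow(slots)), , drop = FALSE]
  rownames(slots) <- NULL

  rr <- config$recurrent_regions
  reserved <- if (is.null(rr) || !nrow(rr)) {
    data.frame(chrom = character(), start = numeric(), end = numeric())
  } else {
    data.frame(chrom = rr$chrom, start = pmax(0, rr$start - 2e6),
               end = rr$end + 2e6)
  }
  pos <- place_slots(slots$size, reserved)
  slots$chrom <- pos$chrom
  slots$start <- pos$start
  slots$end <- pos$end
  slots$slot_id <- sprintf("SL%05d", seq_len(nrow(slots)))

  set.seed(stage_seed(config$seed, "tracks"))
  live <- slots[!slots$spike, , drop = FALSE]

  ben <- live[live$intended_rule == "B-DGV50", , drop = FALSE]
  benign_rec <- data.frame(chrom = ben$chrom, start = ben$start,
                           end = ben$end, cnv_type = ben$cnv_type,
                           support_individuals =
                             sample(3:8, nrow(ben), replace = TRUE),
                           label = paste0("POP-", ben$slot_id))

  gene_rules <- c("V-1", "V-2", "V-3", "LP-DBCONS", "P-CONS")
  gn <- live[live$intended_rule %in% gene_rules, , drop = FALSE]
  gwidth <- pmax(20000, floor(gn$size / 3))
  gstart <- gn$start + floor((gn$size - gwidth) / 2)
  gene_rec <- data.frame(chrom = gn$chrom, start = gstart,
                         end = gstart + gwidth,
                         is_omim = gn$intended_rule != "V-1",
                         label = sprintf("GENE%04d", seq_len(nrow(gn))))

  aff_rules <- c(`V-1` = "uncertain", `V-3` = "uncertain",
                 `LP-DBCONS` = "reported_no_clear_association",
                 `P-CONS` = "consistent_pathogenic")
  af <- live[live$intended_rule %in% names(aff_rules), , drop = FALSE]
  affected_rec <- data.frame(chrom = af$chrom, start = af$start,
                             end = af$end, cnv_type = af$cnv_type,
                             curation_status =
                               unname(aff_rules[af$intended_rule]),
                             label = sprintf("AFF%04d", seq_len(nrow(af))))

  sy <- live[live$intended_rule == "P-SYND", , drop = FALSE]
  syndrome_rec <- data.frame(chrom = sy$chrom, start = sy$start,
                             end = sy$end, cnv_type = sy$cnv_type,
                             label = sprintf("SYND%03d", seq_len(nrow(sy))))

  cyto_rec <- data.frame(chrom = character(), start = numeric(),
                         end = numeric(), label = character())
  if (!is.null(rr) && nrow(rr)) {
    for (k in seq_len(nrow(rr))) {
      if (rr$intended_label[k] == "benign") {
        benign_rec <- rbind(benign_rec, data.frame(
          chrom = rr$chrom[k], start = rr$start[k], end = rr$end[k],
          cnv_type = rr$cnv_type[k],
          support_individuals = sample(3:8, 1),
          label = paste0("POP-", rr$name[k])))
      } else if (rr$intended_label[k] == "vus") {
        mid <- floor((rr$start[k] + rr$end[k]) / 2)
        gene_rec <- rbind(gene_rec, data.frame(
          chrom = rr$chrom[k], start = mid - 25000, end = mid + 25000,
          is_omim = TRUE, label = paste0("GENE-", rr$name[k])))
      }   # likely_benign regions need no evidence at all
    }
    cyto_rec <- data.frame(
      chrom = rr$chrom,
      start = pmax(0, rr$start - 1e6),
      end = pmin(HG19_AUTOSOME_LEN[rr$chrom], rr$end + 1e6),
      label = rr$name)
  }

  bundle <- list(
    benign_population = cnv_track(benign_rec, "benign_population"),
    affected = cnv_track(affected_rec, "affected"),
    gene = cnv_track(gene_rec, "gene"),
    syndrome = cnv_track(syndrome_rec, "syndrome"),
    cytoband = cnv_track(cyto_rec, "cytoband"))
  attr(bundle, "layout") <- slots
  class(bundle) <- "cnv_track_bundle"
  bundle
}

#' Simulate a cohort of CNV calls with ground truth
#'
#' Draws the roster (platform assignment), sample QC metrics, the recurrent
#' region member calls (one near-identical jittered interval per Bernoulli
#' carrier), and per-sample non-recurrent calls (Poisson counts, with
#' recurrent members replacing rather than adding to the per-sample budget),
#' plus the below-threshold spike calls that exercise the inclusion filter.
#' Every call is tied to its evidence slot, giving a per-call ground-truth
#' tier.
#'
#' @param config a [simulation_config()].
#' @param tracks the matching [simulate_tracks()] result.
#' @return list of class `cnv_simulated_cohort` with `calls`, `qc_metrics`,
#'   `roster`, `ground_truth` and `config`.
#' @export
simulate_cohort <- function(config, tracks) {
  stopifnot(inherits(config, "simulation_config"),
            inherits(tracks, "cnv_track_bundle"))
  layout <- attr(tracks, "layout")
  n <- config$n_samples

  set.seed(stage_seed(config$seed, "roster"))
  counts <- config$platform_counts
  if (sum(counts) != n) {
    counts <- round(counts / sum(counts) * n)
    counts[1] <- counts[1] + (n - sum(counts))
  }
  roster <- data.frame(sample_id = sprintf("S%04d", seq_len(n)),
                       platform = sample(rep(names(counts), counts)))

  set.seed(stage_seed(config$seed, "qc"))
  fail <- stats::runif(n) < config$qc_fail_rate
  is6 <- roster$platform == "SNP6"
  mapd <- ifelse(is6, stats::runif(n, 0.15, 0.349),
                 stats::runif(n, 0.10, 0.249))
  mapd[fail] <- ifelse(is6[fail], stats::runif(sum(fail), 0.36, 0.45),
                       stats::runif(sum(fail), 0.26, 0.35))
  qc_metrics <- data.frame(
    sample_id = roster$sample_id, platform = roster$platform, mapd = mapd,
    snpqc = ifelse(is6, NA_real_, stats::runif(n, 15.5, 25)),
    waviness_sd = ifelse(is6, NA_real_, stats::runif(n, 0.02, 0.119)))

  set.seed(stage_seed(config$seed, "recurrent"))
  rr <- config$recurrent_regions
  rec_calls <- NULL
  if (!is.null(rr) && nrow(rr)) {
    pieces <- lapply(seq_len(nrow(rr)), function(k) {
      carrier <- which(stats::runif(n) < rr$target_frequency[k])
      m <- length(carrier)
      if (!m) return(NULL)
      size0 <- rr$end[k] - rr$start[k]
      shift <- round(stats::runif(m, -1, 1) * 0.02 * size0)
      size <- round(size0 * stats::runif(m, 0.96, 1.04))
      start <- rr$start[k] + shift
      data.frame(sample_id = roster$sample_id[carrier], chrom = rr$chrom[k],
                 start = start, end = start + size,
                 cnv_type = rr$cnv_type[k],
                 probe_count = pmax(50L, as.integer(round(
                   size / 2000 * stats::runif(m, 0.8, 1.2)))),
                 intended_label = rr$intended_label[k],
                 intended_rule = unname(c(benign = "B-DGV50", vus = "V-2",
                                          likely_benign = "LB")[
                                            rr$intended_label[k]]),
                 region = rr$name[k], spike = FALSE)
    })
    rec_calls <- do.call(rbind, pieces)
  }

  set.seed(stage_seed(config$seed, "calls"))
  n_i <- stats::rpois(n, config$mean_calls[roster$platform])
  r_i <- if (is.null(rec_calls)) integer(n) else {
    tab <- table(factor(rec_calls$sample_id, levels = roster$sample_id))
    as.integer(tab)
  }
  k_i <- pmax(0L, n_i - r_i)
  live <- layout[!layout$spike, , drop = FALSE]
  if (sum(k_i) > nrow(live)) {
    stop("slot layout exhausted; increase the layout head-room")
  }
  used <- live[seq_len(sum(k_i)), , drop = FALSE]
  nr_calls <- data.frame(
    sample_id = rep(roster$sample_id, k_i),
    chrom = used$chrom, start = used$start, end = used$end,
    cnv_type = used$cnv_type,
    probe_count = pmax(50L, as.integer(round(
      used$size / 2000 * stats::runif(nrow(used), 0.8, 1.2)))),
    intended_label = used$intended_label,
    intended_rule = used$intended_rule,
    region = NA_character_, spike = FALSE)

  spikes <- layout[layout$spike, , drop = FALSE]
  sp_calls <- NULL
  if (nrow(spikes)) {
    sp_calls <- data.frame(
      sample_id = sample(roster$sample_id, nrow(spikes), replace = TRUE),
      chrom = spikes$chrom, start = spikes$start, end = spikes$end,
      cnv_type = spikes$cnv_type,
      probe_count = ifelse(
        spikes$spike_mode == "probes",
        sample(10:49, nrow(spikes), replace = TRUE),
        pmax(50L, as.integer(round(spikes$size / 2000)))),
      intended_label = "excluded",
      intended_rule = spikes$intended_rule,
      region = NA_character_, spike = TRUE)
  }

  all_calls <- rbind(nr_calls, rec_calls, sp_calls)
  ord <- order(all_calls$sample_id, match(all_calls$chrom, AUTOSOMES),
               all_calls$start)
  all_calls <- all_calls[ord, , drop = FALSE]
  all_calls$call_id <- sprintf("C%05d", seq_len(nrow(all_calls)))
  rownames(all_calls) <- NULL

  call_cols <- c("call_id", "sample_id", "chrom", "start", "end", "cnv_type",
                 "probe_count")
  calls <- all_calls[call_cols]
  calls$platform <- roster$platform[match(calls$sample_id, roster$sample_id)]

  ground_truth <- all_calls[c("call_id", "sample_id", "intended_label",
                              "intended_rule", "region", "spike")]
  ground_truth$sample_qc_pass <-
    !fail[match(ground_truth$sample_id, roster$sample_id)]

  structure(list(calls = calls, qc_metrics = qc_metrics, roster = roster,
                 ground_truth = ground_truth, config = config),
            class = "cnv_simulated_cohort")
}

#' Run the full pipeline on a simulated cohort and check label recovery
#'
#' Applies the gates, gathers evidence, classifies, clusters and
#' reclassifies, then compares against the generator's ground truth. The
#' expected post-reclassification label is derived from the *observed*
#' carrier frequency of each ground-truth group (injected region, or the
#' call itself for non-recurrent calls) under the same threshold the
#' pipeline uses, so recovery must be exact at any seed; any mismatch is a
#' pipeline defect.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param tracks the matching [simulate_tracks()] bundle.
#' @param reciprocal_threshold,frequency_threshold recurrence parameters
#'   passed to [cluster_regions()] and [reclassify_recurrent()].
#' @return list with recovery counts and rates, the mismatch table, the
#'   gate attrition, the recurrence report and the final classified calls.
#' @export
verify_recovery <- function(cohort, tracks, reciprocal_threshold = 0.5,
                            frequency_threshold = 0.02) {
  stopifnot(inherits(cohort, "cnv_simulated_cohort"))
  gt <- cohort$ground_truth
  gated <- apply_gates(cohort$calls, cohort$qc_metrics)

  exp_inc <- gt$call_id[gt$sample_qc_pass & !gt$spike]
  gate_unexpected <- c(setdiff(gated$calls$call_id, exp_inc),
                       setdiff(exp_inc, gated$calls$call_id))

  ev <- gather_evidence(gated$calls, tracks)
  cls <- classify_cnvs(gated$calls, ev)
  gti <- gt[match(cls$call_id, gt$call_id), , drop = FALSE]
  initial_mismatch <- cls$label != gti$intended_label

  qc <- evaluate_sample_qc(cohort$qc_metrics)
  cohort_size <- sum(qc$pass)
  clusters <- cluster_regions(cls, cohort_size, reciprocal_threshold)
  rec <- reclassify_recurrent(cls, clusters, frequency_threshold,
                              cytoband_track = tracks$cytoband)
  final <- rec$classified

  group <- ifelse(is.na(gti$region), gti$call_id, gti$region)
  expected_final <- gti$intended_label
  for (gname in unique(group)) {
    idx <- which(group == gname)
    freq <- length(unique(gti$sample_id[idx])) / cohort_size
    if (freq >= frequency_threshold) {
      flip <- idx[expected_final[idx] %in% c("likely_benign", "vus")]
      expected_final[flip] <- "benign"
    }
  }
  final_mismatch <- final$label != expected_final

  mism <- data.frame(call_id = cls$call_id, region = gti$region,
                     intended = gti$intended_label,
                     expected_final = expected_final,
                     observed_initial = cls$label,
                     observed_final = final$label)[
                       initial_mismatch | final_mismatch, , drop = FALSE]
  rownames(mism) <- NULL

  list(n_calls = nrow(cohort$calls),
       n_included_expected = length(exp_inc),
       n_included_observed = nrow(gated$calls),
       n_gate_unexpected = length(gate_unexpected),
       n_initial_mismatch = sum(initial_mismatch),
       n_final_mismatch = sum(final_mismatch),
       recovery_pct = 100 * mean(!final_mismatch),
       mismatches = mism,
       attrition = gated$attrition,
       recurrence_report = rec$report,
       classified = final,
       cohort_size = cohort_size)
}

#' Write a simulated cohort and its tracks to disk
#'
#' Emits the canonical TSV inputs of the pipeline (CNV table, QC table,
#' roster, four reference tracks plus cytobands, ground truth), all
#' re-readable with [parse_cnv_table()] / [parse_track()].
#'
#' @param cohort a [simulate_cohort()] result.
#' @param tracks the matching [simulate_tracks()] bundle.
#' @param dir output directory (created if needed).
#' @return named character vector of the written paths.
#' @export
write_simulated_cohort <- function(cohort, tracks, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_cnv_table(cohort$calls, p("calls.tsv"))
  write_tsv_atomic(cohort$qc_metrics, p("qc_metrics.tsv"))
  write_tsv_atomic(cohort$roster, p("roster.tsv"))
  write_tsv_atomic(cohort$ground_truth, p("ground_truth.tsv"))
  for (kind in c("benign_population", "affected", "gene", "syndrome",
                 "cytoband")) {
    write_track(tracks[[kind]], p(paste0(kind, ".tsv")))
  }
  stats::setNames(
    file.path(dir, c("calls.tsv", "qc_metrics.tsv", "roster.tsv",
                     "ground_truth.tsv", "benign_population.tsv",
                     "affected.tsv", "gene.tsv", "syndrome.tsv",
                     "cytoband.tsv")),
    c("calls", "qc_metrics", "roster", "ground_truth", "benign_population",
      "affected", "gene", "syndrome", "cytoband"))
}
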