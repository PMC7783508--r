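classified_from <- function(calls, labels) {
  calls$label <- labels
  calls$rule <- "x"
  calls$rule_trail <- "x"
  calls$original_label <- labels
  calls$reclassified <- FALSE
  calls
}

test_that("clustering links identical intervals and separates disjoint ones", {
  calls <- classified_from(
    make_calls(sample_id = c("A", "B", "C"), start = 1e6, end = 1.5e6),
    rep("vus", 3))
  cl <- cluster_regions(calls, cohort_size = 100)
  expect_equal(nrow(cl$regions), 1)
  expect_equal(cl$regions$carrier_samples, 3L)
  expect_equal(cl$regions$cohort_frequency, 0.03)

  disj <- classified_from(
    make_calls(sample_id = c("A", "B"), start = c(1e6, 9e6),
               end = c(1.5e6, 9.5e6)), rep("vus", 2))
  expect_equal(nrow(cluster_regions(disj, 100)$regions), 2)

  # same interval, opposite types -> no link
  mixed <- classified_from(
    make_calls(sample_id = c("A", "B"), start = 1e6, end = 1.5e6,
               cnv_type = c("gain", "loss")), rep("vus", 2))
  expect_equal(nrow(cluster_regions(mixed, 100)$regions), 2)

  expect_error(cluster_regions(calls, 100, reciprocal_threshold = 0),
               "reciprocal_threshold")
  expect_error(cluster_regions(calls, 100, reciprocal_threshold = 1.2),
               "reciprocal_threshold")
})

test_that("single linkage chains a~b~c into one region without a~c overlap", {
  # a and c overlap b reciprocally ~0.6 but each other only ~0.2
  calls <- classified_from(
    make_calls(sample_id = c("A", "B", "C"),
               start = c(1.0e6, 1.4e6, 1.8e6),
               end = c(2.0e6, 2.4e6, 2.8e6)), rep("vus", 3))
  cl <- cluster_regions(calls, 100)
  expect_equal(nrow(cl$regions), 1)
  expect_equal(cl$regions$n_members, 3L)
  expect_equal(cl$regions$start, 1.0e6)
  expect_equal(cl$regions$end, 2.8e6)
})

test_that("clustering matches a brute-force connected-components oracle", {
  set.seed(77)
  for (trial in 1:5) {
    n <- 50
    starts <- sample.int(2e7, n)
    calls <- classified_from(
      make_calls(sample_id = sample(LETTERS, n, TRUE), start = starts,
                 end = starts + sample(c(2e5, 5e5, 1e6), n, TRUE),
                 cnv_type = sample(c("gain", "loss"), n, TRUE)),
      sample(CNV_LABELS, n, TRUE))
    cl <- cluster_regions(calls, 1000)

    adj <- matrix(FALSE, n, n)
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i == j || calls$cnv_type[i] != calls$cnv_type[j]) next
        ol <- max(0, min(calls$end[i], calls$end[j]) -
                    max(calls$start[i], calls$start[j]))
        adj[i, j] <- ol / (calls$end[i] - calls$start[i]) >= 0.5 &&
          ol / (calls$end[j] - calls$start[j]) >= 0.5
      }
    }
    oracle <- bf_components(adj)
    # same partition (membership labels may differ)
    expect_equal(length(unique(cl$membership)), length(unique(oracle)))
    expect_true(all(tapply(oracle, cl$membership,
                           function(x) length(unique(x))) == 1))

    # permutation invariance of the induced partition
    perm <- sample.int(n)
    cl2 <- cluster_regions(calls[perm, ], 1000)
    expect_true(all(tapply(cl2$membership[order(perm)], cl$membership,
                           function(x) length(unique(x))) == 1))
    expect_equal(cl2$regions, cl$regions)
  }
})

test_that("reclassification flips only LB/VUS in regions at or above 2%", {
  calls <- classified_from(
    make_calls(sample_id = c("A", "B", "C"), start = 1e6, end = 1.5e6),
    c("vus", "vus", "vus"))
  cl <- cluster_regions(calls, 100)          # 3% >= 2%
  res <- reclassify_recurrent(calls, cl)
  expect_equal(res$classified$label, rep("benign", 3))
  expect_equal(res$classified$original_label, rep("vus", 3))
  expect_true(all(res$classified$reclassified))
  expect_equal(res$report$n_reclassified_vus, 3L)

  # below threshold: untouched
  one <- classified_from(make_calls(sample_id = "A", start = 1e6,
                                    end = 1.5e6), "vus")
  res1 <- reclassify_recurrent(one, cluster_regions(one, 100))
  expect_equal(res1$classified$label, "vus")
  expect_false(res1$classified$reclassified)
  expect_equal(nrow(res1$report), 0)

  # pathogenic members of a 5% region survive; VUS members flip
  mix <- classified_from(
    make_calls(sample_id = c("A", "B", "C", "D", "E"), start = 1e6,
               end = 1.5e6),
    c("pathogenic", "vus", "vus", "benign", "likely_benign"))
  resm <- reclassify_recurrent(mix, cluster_regions(mix, 100))
  expect_equal(resm$classified$label,
               c("pathogenic", "benign", "benign", "benign", "benign"))
  expect_equal(resm$classified$reclassified,
               c(FALSE, TRUE, TRUE, FALSE, TRUE))
})

test_that("reclassification is idempotent and conserves counts", {
  set.seed(88)
  n <- 60
  starts <- sample(seq(1e6, 5e7, by = 4e5), n)
  calls <- classified_from(
    make_calls(sample_id = sample(sprintf("S%02d", 1:20), n, TRUE),
               start = starts, end = starts + 3e5),
    sample(CNV_LABELS, n, TRUE, prob = c(.5, .15, .2, .05, .1)))
  cl <- cluster_regions(calls, 40)
  r1 <- reclassify_recurrent(calls, cl)
  cl2 <- cluster_regions(r1$classified, 40)
  r2 <- reclassify_recurrent(r1$classified, cl2)
  expect_identical(r2$classified, r1$classified)    # idempotence

  expect_equal(nrow(r1$classified), n)              # count conservation
  before <- table(factor(calls$label, CNV_LABELS))
  after <- table(factor(r1$classified$label, CNV_LABELS))
  expect_equal(sum(after), sum(before))
  # only LB->B and VUS->B transitions occur
  expect_equal(after[["pathogenic"]], before[["pathogenic"]])
  expect_equal(after[["likely_pathogenic"]], before[["likely_pathogenic"]])
  expect_gte(after[["benign"]], before[["benign"]])
  chg <- r1$classified[r1$classified$reclassified, ]
  expect_true(all(chg$original_label %in% c("likely_benign", "vus")))
  expect_true(all(chg$label == "benign"))
})

test_that("cytoband annotation joins overlapping band labels", {
  cyto <- cnv_track(data.frame(chrom = "1", start = c(0, 2e6),
                               end = c(2e6, 4e6),
                               label = c("1p36.33", "1p36.32")), "cytoband")
  regions <- data.frame(chrom = "1", start = c(0.5e6, 1.5e6, 9e6),
                        end = c(1.0e6, 2.5e6, 9.5e6))
  expect_equal(annotate_cytoband(regions, cyto),
               c("1p36.33", "1p36.33-1p36.32", ""))
  expect_equal(annotate_cytoband(regions, NULL), rep("", 3))
})
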