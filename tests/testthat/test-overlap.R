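test_that("overlap_stats matches hand-computed and degenerate cases", {
  st <- overlap_stats(data.frame(chrom = "1", start = 100000, end = 200000),
                      data.frame(chrom = "1", start = 150000, end = 250000))
  expect_equal(st$overlap_len, 50000)
  expect_equal(st$query_fraction, 0.5)
  expect_equal(st$ref_fraction, 0.5)

  same <- data.frame(chrom = "2", start = 10, end = 400)
  expect_equal(unlist(overlap_stats(same, same)),
               c(overlap_len = 390, query_fraction = 1, ref_fraction = 1))

  st2 <- overlap_stats(data.frame(chrom = "1", start = 0, end = 100),
                       data.frame(chrom = "1", start = 100, end = 200))
  expect_equal(st2$overlap_len, 0)
  expect_equal(st2$query_fraction, 0)

  # different chromosomes never overlap
  st3 <- overlap_stats(data.frame(chrom = "1", start = 0, end = 100),
                       data.frame(chrom = "2", start = 0, end = 100))
  expect_equal(st3$overlap_len, 0)
})

test_that("overlap_stats agrees with the per-base set-intersection oracle", {
  set.seed(101)
  n <- 1000
  s1 <- sample.int(9000, n); e1 <- s1 + sample.int(1000, n)
  s2 <- sample.int(9000, n); e2 <- s2 + sample.int(1000, n)
  st <- overlap_stats(data.frame(chrom = "1", start = s1, end = e1),
                      data.frame(chrom = "1", start = s2, end = e2))
  oracle <- mapply(bf_overlap_len, s1, e1, s2, e2)
  expect_equal(st$overlap_len, unname(oracle))
  expect_true(all(st$query_fraction >= 0 & st$query_fraction <= 1))
  expect_true(all(st$ref_fraction >= 0 & st$ref_fraction <= 1))
  expect_true(all(st$overlap_len <= pmin(e1 - s1, e2 - s2)))
  expect_true(all((st$overlap_len == 0) ==
                    (st$query_fraction == 0 & st$ref_fraction == 0)))

  # symmetry: swapping the sides swaps the fractions
  sw <- overlap_stats(data.frame(chrom = "1", start = s2, end = e2),
                      data.frame(chrom = "1", start = s1, end = e1))
  expect_equal(sw$overlap_len, st$overlap_len)
  expect_equal(sw$query_fraction, st$ref_fraction)
})

test_that("benign support applies the two 50% clauses and same-type rule", {
  call <- make_calls(start = 1e6, end = 2e6, cnv_type = "loss")
  # contributing record: same type, full reciprocal overlap, support 3
  tr <- make_track("benign_population", start = 1e6, end = 2e6,
                   cnv_type = "loss", support_individuals = 3)
  expect_equal(as.integer(benign_support(call, tr)), 3L)

  # query fraction exactly 0.5 does NOT contribute (strict >)
  half <- make_track("benign_population", start = 1.5e6, end = 2.5e6,
                     cnv_type = "loss", support_individuals = 5)
  expect_equal(as.integer(benign_support(call, half)), 0L)

  # ref fraction exactly 0.5 DOES contribute (nonoverlap <= 50%)
  big <- make_track("benign_population", start = 0.5e6, end = 2.5e6,
                    cnv_type = "loss", support_individuals = 4)
  # query covered fully (qf = 1), record covered half (rf = 0.5)
  expect_equal(as.integer(benign_support(call, big)), 4L)

  # opposite type never contributes even at full overlap
  opp <- make_track("benign_population", start = 1e6, end = 2e6,
                    cnv_type = "gain", support_individuals = 9)
  expect_equal(as.integer(benign_support(call, opp)), 0L)

  expect_error(benign_support(call, make_track("gene")), "benign_population")
})

test_that("benign support sums over contributors and is monotone", {
  call <- make_calls(start = 1e6, end = 2e6, cnv_type = "loss")
  two <- cnv_track(data.frame(chrom = "1", start = c(1e6, 1.1e6),
                              end = c(2e6, 1.9e6), cnv_type = "loss",
                              support_individuals = c(3, 2)),
                   "benign_population")
  expect_equal(as.integer(benign_support(call, two)), 5L)
  # raising a contributor's support count never lowers the total
  more <- two
  more$records$support_individuals[2] <- 7L
  expect_gte(as.integer(benign_support(call, more)),
             as.integer(benign_support(call, two)))
})

test_that("gene containment needs 1 bp; OMIM flag implies gene flag", {
  call <- make_calls(start = 1e6, end = 2e6)
  onebp <- make_track("gene", start = 2e6 - 1, end = 2.1e6, is_omim = FALSE,
                      label = "G1")
  gc <- gene_content(call, onebp)
  expect_true(gc$contains_genes)
  expect_false(gc$contains_omim_genes)

  gc0 <- gene_content(call, make_track("gene", start = 3e6, end = 4e6))
  expect_false(gc0$contains_genes)

  both <- cnv_track(data.frame(chrom = "1", start = c(1.1e6, 1.5e6),
                               end = c(1.2e6, 1.6e6),
                               is_omim = c(TRUE, FALSE),
                               label = c("OM", "NO")), "gene")
  gc2 <- gene_content(call, both)
  expect_true(gc2$contains_genes && gc2$contains_omim_genes)
  expect_equal(gc2$gene_labels, "OM;NO")
})

test_that("affected matches need strict >50% query coverage of the call", {
  call <- make_calls(start = 1e6, end = 2e6, cnv_type = "gain")
  full <- make_track("affected", start = 0.9e6, end = 2.1e6,
                     cnv_type = "gain", curation_status = "uncertain")
  expect_equal(nrow(affected_matches(call, full)), 1)

  part <- make_track("affected", start = 1.6e6, end = 3e6, cnv_type = "gain",
                     curation_status = "uncertain")  # qf = 0.4
  expect_equal(nrow(affected_matches(call, part)), 0)

  two <- cnv_track(data.frame(chrom = "1", start = c(1.2e6, 0.9e6),
                              end = c(2.2e6, 2e6), cnv_type = "any",
                              curation_status = c("uncertain",
                                                  "consistent_pathogenic"),
                              label = c("b", "a")), "affected")
  m <- affected_matches(call, two)
  expect_equal(nrow(m), 2)
  expect_equal(m$label, c("a", "b"))  # genomic order
})

test_that("syndrome hits are type-matched", {
  loss <- make_calls(start = 1e6, end = 2e6, cnv_type = "loss")
  del_synd <- make_track("syndrome", start = 0.9e6, end = 2.1e6,
                         cnv_type = "loss", label = "DEL-SYN")
  dup_synd <- make_track("syndrome", start = 0.9e6, end = 2.1e6,
                         cnv_type = "gain", label = "DUP-SYN")
  expect_true(syndrome_hit(loss, del_synd)$hit)
  expect_false(syndrome_hit(loss, dup_synd)$hit)
  expect_false(syndrome_hit(loss, make_track("syndrome",
                                             start = 5e6, end = 6e6))$hit)
})

test_that("gather_evidence composes the four engines and is order-invariant", {
  calls <- make_calls(start = 1e6, end = 2e6, cnv_type = "loss")
  tracks <- list(
    benign_population = make_track("benign_population", start = 1e6,
                                   end = 2e6, cnv_type = "loss",
                                   support_individuals = 4),
    affected = make_track("affected", start = 1e6, end = 2e6,
                          cnv_type = "loss",
                          curation_status = "uncertain"),
    gene = make_track("gene", start = 1.2e6, end = 1.4e6, is_omim = TRUE,
                      label = "G"),
    syndrome = make_track("syndrome", start = 1e6, end = 2e6,
                          cnv_type = "loss", label = "S"))
  ev <- gather_evidence(calls, tracks)
  expect_equal(ev$benign_support, 4L)
  expect_true(ev$contains_omim_genes)
  expect_equal(ev$n_affected, 1L)
  expect_equal(ev$affected_status[[1]], "uncertain")
  expect_true(ev$syndrome_hit)
  expect_equal(ev$length_bp, 1e6)

  # composition equals the individual engines
  expect_equal(ev$benign_support,
               as.integer(benign_support(calls, tracks$benign_population)))
  expect_equal(ev$contains_genes,
               gene_content(calls, tracks$gene)$contains_genes)

  # permuting track records changes nothing
  tracks2 <- tracks
  tracks2$benign_population$records <-
    tracks2$benign_population$records[rev(seq_len(1)), , drop = FALSE]
  expect_equal(gather_evidence(calls, tracks2), ev)

  # empty/missing tracks give vacuous evidence
  ev0 <- gather_evidence(calls, list())
  expect_equal(ev0$benign_support, 0L)
  expect_false(ev0$contains_genes)
  expect_equal(ev0$n_affected, 0L)
  expect_false(ev0$syndrome_hit)
})
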