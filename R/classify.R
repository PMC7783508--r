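#' Five-tier labels and the classification rule vocabulary
#'
#' `CNV_LABELS` is the ACMG-style tier vocabulary in reporting order (benign
#' < likely benign < VUS < likely pathogenic < pathogenic). `CNV_RULES` is
#' the stable public vocabulary of classification rules, in the precedence
#' order they are tested; the same identifiers appear in output tables and
#' logs.
#' @export
CNV_LABELS <- c("benign", "likely_benign", "vus", "likely_pathogenic",
                "pathogenic")

#' @rdname CNV_LABELS
#' @export
CNV_RULES <- c("B-DGV50", "P-SIZE", "P-SYND", "P-CONS", "LP-DBCONS",
               "V-1", "V-2", "V-3", "LB", "V-FALLBACK")

CNV_RULE_LABELS <- c(`B-DGV50` = "benign", `P-SIZE` = "pathogenic",
                     `P-SYND` = "pathogenic", `P-CONS` = "pathogenic",
                     `LP-DBCONS` = "likely_pathogenic", `V-1` = "vus",
                     `V-2` = "vus", `V-3` = "vus", `LB` = "likely_benign",
                     `V-FALLBACK` = "vus")

#' Classify evidence bundles into the five tiers
#'
#' Total function over evidence: rules are tested in a fixed precedence
#' order and the first satisfied rule assigns the label.
#'
#' 1. `B-DGV50` (benign): benign-population support from at least three
#'    unaffected individuals. Benign support dominates everything else —
#'    population-polymorphic CNVs are benign regardless of size or gene
#'    content, which is why benign calls larger than 3 Mb exist.
#' 2. `P-SIZE` (pathogenic): length strictly greater than 3 Mb.
#' 3. `P-SYND` (pathogenic): overlap with a matching-type syndrome region.
#' 4. `P-CONS` (pathogenic): OMIM gene content plus at least one affected
#'    match curated as consistently correlated with phenotypic alterations.
#' 5. `LP-DBCONS` (likely pathogenic): OMIM gene content, affected matches
#'    whose statuses are all consistent/reported (database consistency
#'    indicating phenotypic alterations) but with no consistent-pathogenic
#'    match at the call level.
#' 6. `V-1`/`V-2`/`V-3` (VUS): non-OMIM genes with an affected match;
#'    OMIM genes with no affected match; OMIM genes with an uncertain
#'    affected match (no clear correlation/consistency).
#' 7. `LB` (likely benign): no genes, or only non-OMIM genes, and no
#'    affected match.
#' 8. `V-FALLBACK` (VUS): any evidence combination not matched above.
#'
#' @param evidence a `cnv_evidence` data.frame from [gather_evidence()].
#' @return data.frame with `label`, `rule` (the rule that fired) and
#'   `rule_trail` (semicolon-joined identifiers of every rule tested, ending
#'   with the one that fired).
#' @export
classify_evidence <- function(evidence) {
  n <- nrow(evidence)
  st <- evidence$affected_status
  n_match <- evidence$n_affected
  any_cons <- vapply(st, function(s) any(s == "consistent_pathogenic"),
                     logical(1))
  any_unc <- vapply(st, function(s) any(s == "uncertain"), logical(1))
  all_db <- n_match > 0 &
    vapply(st, function(s) all(s %in% c("consistent_pathogenic",
                                        "reported_no_clear_association")),
           logical(1))
  genes <- evidence$contains_genes
  omim <- evidence$contains_omim_genes

  cond <- cbind(
    `B-DGV50`    = evidence$benign_support >= 3,
    `P-SIZE`     = evidence$length_bp > 3e6,
    `P-SYND`     = evidence$syndrome_hit,
    `P-CONS`     = omim & any_cons,
    `LP-DBCONS`  = omim & all_db & !any_cons,
    `V-1`        = genes & !omim & n_match >= 1,
    `V-2`        = omim & n_match == 0,
    `V-3`        = omim & any_unc,
    `LB`         = !omim & n_match == 0,
    `V-FALLBACK` = rep(TRUE, n))
  fired <- max.col(cond, ties.method = "first")
  rule <- CNV_RULES[fired]
  trail <- vapply(fired, function(k) paste(CNV_RULES[seq_len(k)],
                                           collapse = ";"), character(1))
  data.frame(label = unname(CNV_RULE_LABELS[rule]), rule = rule,
             rule_trail = trail)
}

#' Classify a set of CNV calls
#'
#' Binds the calls to their classification: tier label, fired rule, rule
#' trail, and the bookkeeping fields used by recurrence reclassification
#' (`original_label`, `reclassified`).
#'
#' @param calls call data.frame in internal coordinates.
#' @param evidence matching [gather_evidence()] result (same row order).
#' @return the calls with `label`, `rule`, `rule_trail`, `original_label`,
#'   `reclassified` columns appended.
#' @export
classify_cnvs <- function(calls, evidence) {
  stopifnot(nrow(calls) == nrow(evidence))
  cls <- classify_evidence(evidence)
  out <- cbind(calls, cls)
  out$original_label <- out$label
  out$reclassified <- FALSE
  out
}

#' Size bins for cohort cross-tabulation
#'
#' Partition of CNV lengths used for reporting: below 0.5 Mb, 0.5-1 Mb,
#' 1-3 Mb, 3-5 Mb and above 5 Mb. The 3 Mb boundary belongs to the 1-3 Mb
#' bin so that a CNV of exactly 3 Mb — which is not pathogenic by the strict
#' "more than 3 Mb" size rule — never appears in the 3-5 Mb row.
#'
#' @param length_bp positive lengths in bp.
#' @return factor with the five bin labels of `SIZE_BINS` as levels.
#' @export
size_bin <- function(length_bp) {
  if (any(!is.finite(length_bp)) || any(length_bp <= 0)) {
    stop("size_bin() requires positive finite lengths")
  }
  idx <- ifelse(length_bp < 5e5, 1L,
         ifelse(length_bp < 1e6, 2L,
         ifelse(length_bp <= 3e6, 3L,
         ifelse(length_bp <= 5e6, 4L, 5L))))
  factor(SIZE_BINS[idx], levels = SIZE_BINS)
}

#' @rdname size_bin
#' @export
SIZE_BINS <- c("<0.5 Mb", "0.5-1 Mb", "1-3 Mb", "3-5 Mb", ">5 Mb")
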