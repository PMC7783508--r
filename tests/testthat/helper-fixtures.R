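# Shared in-code fixtures. Coordinates are internal 0-based half-open.

make_calls <- function(chrom = "1", start = 1e6, end = 1.5e6,
                       cnv_type = "gain", sample_id = "S1",
                       probe_count = 100, platform = "CYTOHD") {
  data.frame(sample_id = sample_id, chrom = chrom, start = start, end = end,
             cnv_type = cnv_type, probe_count = probe_count,
             platform = platform)
}

make_track <- function(kind, chrom = "1", start = 1e6, end = 1.5e6, ...) {
  cnv_track(data.frame(chrom = chrom, start = start, end = end, ...), kind)
}

# Evidence row built directly, for classifier tests that bypass the tracks.
make_evidence <- function(length_bp = 5e5, benign_support = 0,
                          contains_genes = FALSE,
                          contains_omim_genes = FALSE,
                          affected_status = list(character()),
                          syndrome_hit = FALSE) {
  ev <- data.frame(length_bp = length_bp, benign_support = benign_support,
                   contains_genes = contains_genes,
                   contains_omim_genes = contains_omim_genes,
                   gene_labels = "", n_affected = lengths(affected_status),
                   affected_labels = "", syndrome_hit = syndrome_hit,
                   syndrome_labels = "")
  ev$affected_status <- affected_status
  class(ev) <- c("cnv_evidence", "data.frame")
  ev
}

# Brute-force per-base overlap length for the half-open interval pair
# [s1,e1) x [s2,e2): explicit set intersection of covered base positions.
bf_overlap_len <- function(s1, e1, s2, e2) {
  length(intersect(seq.int(s1, e1 - 1L), seq.int(s2, e2 - 1L)))
}

# Brute-force connected components over an explicit adjacency matrix
# (BFS), independent of igraph.
bf_components <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  cur <- 0L
  for (v in seq_len(n)) {
    if (comp[v] == 0L) {
      cur <- cur + 1L
      queue <- v
      comp[v] <- cur
      while (length(queue)) {
        u <- queue[1]
        queue <- queue[-1]
        nb <- which(adj[u, ] & comp == 0L)
        comp[nb] <- cur
        queue <- c(queue, nb)
      }
    }
  }
  comp
}
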