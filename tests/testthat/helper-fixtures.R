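# Small fixtures built in code: a hand-sized counts table, its sample map,
# and an evidence-record builder with clean defaults so tests only state the
# field under scrutiny.

toy_counts <- function() {
  tibble::tibble(
    protein_id = c("P1", "P2", "P3"),
    A1 = c(10, 0, 4), A2 = c(8, 0, 6),
    B1 = c(2, 5, 4), B2 = c(4, 7, 6), B3 = c(3, 6, 5)
  )
}

toy_samples <- function() {
  tibble::tibble(sample_id = c("A1", "A2", "B1", "B2", "B3"),
                 group = c("A", "A", "B", "B", "B"))
}

ev_record <- function(sample_id = "S1", protein_id = "P", peptide_seq = "PEPTIDE",
                      charge = 2L, peptide_prob = 0.95, protein_prob = 0.995,
                      protein_fdr = 0.005) {
  tibble::tibble(sample_id = sample_id, protein_id = protein_id,
                 peptide_seq = peptide_seq, charge = as.integer(charge),
                 peptide_prob = peptide_prob, protein_prob = protein_prob,
                 protein_fdr = protein_fdr)
}

small_config <- function(...) {
  args <- utils::modifyList(
    list(total_proteins = 60, n_unique_a = 5, n_unique_b = 4,
         n_up = 8, n_down = 8, seed = 42),
    list(...)
  )
  do.call(sim_config, args)
}

# Independent UPGMA agglomeration: cluster distance is the mean pairwise
# distance between original members; returns merge heights in order.
upgma_heights_oracle <- function(d) {
  d <- as.matrix(d)
  clusters <- as.list(seq_len(nrow(d)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- NULL
    bestd <- Inf
    for (i in seq_len(length(clusters) - 1)) {
      for (j in (i + 1):length(clusters)) {
        dd <- mean(d[clusters[[i]], clusters[[j]]])
        if (dd < bestd - 1e-12) {
          bestd <- dd
          best <- c(i, j)
        }
      }
    }
    heights <- c(heights, bestd)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}

# Independent step-up adjustment written from the definition.
bh_oracle <- function(p) {
  n <- length(p)
  ord <- order(p)
  q <- numeric(n)
  running <- 1
  for (i in rev(seq_len(n))) {
    running <- min(running, p[ord[i]] * n / i)
    q[ord[i]] <- running
  }
  q
}
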