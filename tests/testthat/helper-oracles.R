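# Independent oracles used across the test files.

# Exhaustive Fitch minimization: tries every 0/1 assignment of internal
# nodes and counts changes along edges; a missing leaf is free and copies
# its parent. Feasible for trees with <= 10 internal nodes.
brute_force_steps <- function(t, states) {
  tr <- ape::reorder.phylo(t, "postorder")
  n <- length(tr$tip.label)
  M <- tr$Nnode
  tipst <- states[tr$tip.label]
  best <- Inf
  for (mask in 0:(2^M - 1)) {
    st <- c(tipst, as.integer(intToBits(mask))[seq_len(M)])
    ch <- 0
    for (e in seq_len(nrow(tr$edge))) {
      p <- tr$edge[e, 1]; k <- tr$edge[e, 2]
      if (is.na(st[k])) next
      if (st[k] != st[p]) ch <- ch + 1
    }
    best <- min(best, ch)
  }
  as.integer(best)
}

# Hand tally of a, b, c band-sharing counts for a sample pair.
abc_counts <- function(x, y) {
  use <- !is.na(x) & !is.na(y)
  c(a = sum(x[use] == 1 & y[use] == 1),
    b = sum(x[use] == 1 & y[use] == 0),
    c = sum(x[use] == 0 & y[use] == 1))
}

# Small two-digest fixture with one locus of each MSAP type for sample A;
# sample B is non-methylated everywhere (type I at every amplified locus).
toy_digest_pair <- function() {
  hpa <- band_matrix(rbind(A = c(1, 0, 1, 0), B = c(1, 1, 1, 1)),
                     locus_ids = paste0("L", 1:4),
                     marker_system = "MSAP_HPAII")
  msp <- band_matrix(rbind(A = c(1, 1, 0, 0), B = c(1, 1, 1, 1)),
                     locus_ids = paste0("L", 1:4),
                     marker_system = "MSAP_MSPI")
  list(hpa = hpa, msp = msp)
}
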