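# Independent brute-force oracle: dense matrix powers over an explicitly
# assembled adjacency matrix, with no shared code with the package's sparse
# trace routine.
brute_force_traces <- function(edges, n_nodes, k_max = 5L) {
  A <- matrix(0, n_nodes, n_nodes)
  for (r in seq_len(nrow(edges))) {
    i <- edges[r, 1L] + 1L
    j <- edges[r, 2L] + 1L
    A[i, j] <- 1
    A[j, i] <- 1
  }
  out <- numeric(k_max + 1L)
  P <- diag(n_nodes)
  out[1L] <- sum(diag(P))
  for (k in seq_len(k_max)) {
    P <- P %*% A
    out[k + 1L] <- sum(diag(P))
  }
  out
}

random_sequence <- function(max_len = 30L, alphabet = 18L) {
  n <- sample.int(max_len, 1L)
  paste(sample(letters[seq_len(alphabet)], n, replace = TRUE), collapse = "")
}

# Small deterministic case table: 2 CNTs x 2 reps x a few times.
toy_records <- function() {
  data.frame(
    flux = c(10, 14, 20, 24, 30, 34, 40, 44),
    cnt_id = rep(c("CNT1", "CNT2"), each = 4),
    rep = rep(c("0", "0", "1", "1"), 2),
    cnt_type = rep(c("MWCNT", "SWCNT"), each = 4),
    func_type = rep(c("COOH", "0"), each = 4),
    solvent = rep(c("H2O", "DMSO"), each = 4),
    time = rep(c(0, 10), 4),
    stringsAsFactors = FALSE
  )
}

toy_invariants <- function() {
  invariant_table(list(
    CNT1 = trace_invariants(build_star_graph("abn")),
    CNT2 = trace_invariants(build_star_graph("npq"))
  ))
}
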