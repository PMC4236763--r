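# shared fixture helpers: small constructed networks and seeded random draws

lossy_diamond <- function() {
  net <- fixture_diamond()
  S <- net$stoich
  S["C", 3] <- 0.5           # the r3 branch wastes half the carbon
  metabolic_network(S, net$reaction_ids, net$metabolite_ids)
}

# ladder of k two-way layers: 2^k source-to-sink modes, all unit flux
ladder_network <- function(k) {
  mets <- paste0("L", 0:k)
  n_rxn <- 2L + 2L * k
  S <- matrix(0, k + 1L, n_rxn)
  rownames(S) <- mets
  S["L0", 1] <- 1
  S[paste0("L", k), 2] <- -1
  ids <- c("uptake", "drain")
  col <- 2L
  for (i in seq_len(k)) {
    for (branch in c("a", "b")) {
      col <- col + 1L
      S[paste0("L", i - 1L), col] <- -1
      S[paste0("L", i), col] <- 1
      ids <- c(ids, sprintf("step%d%s", i, branch))
    }
  }
  metabolic_network(S, ids, mets)
}

# seeded random networks with oracle-checkable dimensions (DoF <= 6)
oracle_scale_network <- function(seed) {
  nm <- 4L + (seed %% 7L)
  nr <- nm + 2L + (seed %% 4L)
  net <- random_network(nm, nr, density = 0.35, seed = seed)
  if (nullspace_basis(net$stoich)$dof > 6L) return(NULL)
  net
}

expect_same_modes <- function(a, b) {
  expect_true(same_efm_sets(a, b),
              label = sprintf("EFM sets match (%d vs %d modes)",
                              length(a), length(b)))
}
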