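test_that("RREF nullspace basis has unit pivots at the leading reactions", {
  chain <- fixture_chain()
  b <- nullspace_basis(chain)
  expect_equal(b$dof, 1L)
  expect_equal(unname(b$ns[, 1]), c(1, 1, 1))
  expect_equal(b$pivot_rows, 1L)

  for (net in list(fixture_diamond(), fixture_toy())) {
    b <- nullspace_basis(net)
    expect_lt(max(abs(net$stoich %*% b$ns)), 1e-8)
    expect_equal(unname(b$ns[b$pivot_rows, ]), diag(b$dof))
    expect_equal(rank_of(b$ns), b$dof)
    # pivots are the lexicographically smallest admissible row set
    greedy <- integer(0)
    for (i in seq_len(nrow(b$ns))) {
      if (length(greedy) == b$dof) break
      if (rank_of(b$ns[c(greedy, i), , drop = FALSE]) == length(greedy) + 1L)
        greedy <- c(greedy, i)
    }
    expect_identical(b$pivot_rows, greedy)
  }
  expect_equal(nullspace_basis(fixture_toy())$dof, 6L)
})

test_that("rank_adds agrees with batch rank on random row subsets", {
  b <- nullspace_basis(fixture_toy())
  expect_true(rank_adds(b, integer(0), 1L))
  set.seed(11)
  for (i in 1:50) {
    rows <- sample(nrow(b$ns), sample(0:4, 1))
    cand <- sample(setdiff(seq_len(nrow(b$ns)), rows), 1)
    inc <- rank_adds(b, rows, cand)
    batch <- rank_of(b$ns[c(rows, cand), , drop = FALSE]) ==
      rank_of(b$ns[rows, , drop = FALSE]) + 1L
    expect_identical(inc, batch)
  }
  # proportional rows never add rank: diamond r2 and r4 carry the same flux
  bd <- nullspace_basis(fixture_diamond())
  expect_false(rank_adds(bd, 2L, 4L))
  expect_true(rank_adds(bd, 2L, 3L))
})

test_that("elementarity test accepts single modes and rejects combinations", {
  di <- fixture_diamond()
  expect_true(is_elementary(c(1, 2, 4, 6), di))
  expect_true(is_elementary(c(1, 3, 5, 6), di))
  expect_false(is_elementary(1:6, di))            # both branches: nullity 2
  expect_true(is_elementary(1:3, fixture_chain()))

  # every oracle mode passes, and has exactly DoF-1 independent inactive rows
  for (seed in c(2, 5, 9)) {
    net <- oracle_scale_network(seed)
    if (is.null(net)) next
    b <- nullspace_basis(net$stoich)
    o <- brute_force_efms(net)
    sup <- efm_supports(o)
    for (i in seq_len(nrow(sup))) {
      expect_true(is_elementary(sup[i, ], net$stoich))
      inact <- which(!sup[i, ])
      expect_equal(rank_of(b$ns[inact, , drop = FALSE]), b$dof - 1L)
    }
  }
})

test_that("row-sorting heuristic orders by positive x negative counts", {
  ns <- rbind(c(0, 0, 0),          # p*n = 0
              c(1, -1, 2),         # p=2, n=1 -> 2
              c(1, 1, 1),          # p=3, n=0 -> 0
              c(-1, -2, 3))        # p=1, n=2 -> 2
  fake <- structure(list(ns = ns, dof = 3L, kind = "rref",
                         pivot_rows = 1:3, sign_free_columns = integer(0)),
                    class = "nullspace_basis")
  perm <- sort_rows_heuristic(fake)
  expect_identical(perm, c(1L, 3L, 2L, 4L))   # stable: ties by index

  # applying the permutation leaves the enumerated set unchanged
  toy <- fixture_toy()
  expect_same_modes(enumerate_efms(toy, sort_rows = TRUE),
                    enumerate_efms(toy))
})

test_that("sparse basis columns are independent short modes", {
  chain <- fixture_chain()
  sb <- sparse_efm_basis(chain)
  expect_equal(unname(sb$ns[, 1]), c(1, 1, 1))

  for (net in list(fixture_diamond(), fixture_toy())) {
    sb <- sparse_efm_basis(net)
    expect_identical(sb$kind, "efm")
    expect_equal(rank_of(sb$ns), sb$dof)
    for (j in seq_len(sb$dof)) {
      v <- sb$ns[, j]
      expect_true(is_elementary(v > 1e-9 * max(v), net$stoich))
    }
  }
  # the two diamond EFMs form the basis and need no negative coefficients
  sd <- sparse_efm_basis(fixture_diamond())
  expect_length(sd$sign_free_columns, 0L)
})
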