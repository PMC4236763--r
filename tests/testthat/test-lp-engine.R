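test_that("blank-objective feasibility matches hand-derived cases", {
  di <- fixture_diamond()
  b <- nullspace_basis(di)
  expect_true(lp_feasible(b, constraint_set(faf = 6)))
  expect_false(lp_feasible(b, constraint_set(iff = c(2, 3), faf = 6)))

  toy <- fixture_toy()
  bt <- nullspace_basis(toy)
  expect_true(lp_feasible(bt, constraint_set(faf = 1, iff = 2)))
  # with the uptake active and the first branch blocked, the alternative
  # branch entry cannot also be silenced
  expect_false(lp_feasible(bt, constraint_set(faf = 1, iff = c(2, 4))))
})

test_that("both LP backends agree on random constraint configurations", {
  toy <- fixture_toy()
  b <- nullspace_basis(toy)
  set.seed(4)
  for (i in 1:60) {
    iff <- sample(1:14, sample(0:4, 1))
    faf <- sample(setdiff(1:14, iff), sample(0:3, 1))
    cs <- constraint_set(iff = iff, faf = faf)
    expect_identical(lp_feasible(b, cs, backend = "simplex"),
                     lp_feasible(b, cs, backend = "quadprog"),
                     label = paste("config", i))
  }
})

test_that("feasibility equals support coverage by admissible oracle modes", {
  # independent route: a configuration {iff = 0, faf > 0} is feasible iff
  # every faf reaction is active in some mode whose support avoids the iff
  for (seed in c(3, 7, 12, 19)) {
    net <- oracle_scale_network(seed)
    if (is.null(net)) next
    b <- nullspace_basis(net$stoich)
    sup <- efm_supports(brute_force_efms(net))
    R <- ncol(sup)
    set.seed(seed)
    for (i in 1:25) {
      iff <- sample(R, sample(0:3, 1))
      faf <- sample(setdiff(seq_len(R), iff), sample(0:2, 1))
      admissible <- if (length(iff)) rowSums(sup[, iff, drop = FALSE]) == 0
        else rep(TRUE, nrow(sup))
      covered <- all(vapply(faf, function(r) {
        any(sup[admissible, r])
      }, TRUE))
      expect_identical(lp_feasible(b, constraint_set(iff = iff, faf = faf)),
                       covered)
    }
  }
})

test_that("strict positivity as >= 1 is scale-invariant on the cone", {
  toy <- fixture_toy()
  b <- nullspace_basis(toy)
  o <- brute_force_efms(toy)
  set.seed(8)
  for (i in 1:20) {
    w <- stats::runif(length(o), 0.01, 2)
    v <- colSums(o$fluxes * w)             # strictly interior cone point
    pos <- which(v > 1e-9)
    # all active reactions can be required active simultaneously
    expect_true(lp_feasible(b, constraint_set(faf = pos)))
  }
})

test_that("forced_active finds dependently-active fluxes and is monotone", {
  di <- fixture_diamond()
  b <- nullspace_basis(di)
  expect_identical(forced_active(b, constraint_set(faf = 2)),
                   c(1L, 4L, 6L))
  expect_length(forced_active(b, constraint_set()), 0L)

  toy <- fixture_toy()
  bt <- nullspace_basis(toy)
  got <- forced_active(bt, constraint_set(faf = 1, iff = 2))
  expect_true(4L %in% got)

  # both detection methods agree
  expect_identical(got,
                   forced_active(bt, constraint_set(faf = 1, iff = 2),
                                 method = "fva"))

  # adding constraints never shrinks the forced set
  set.seed(21)
  for (i in 1:10) {
    faf1 <- sample(14, 1)
    extra <- sample(setdiff(1:14, faf1), 1)
    cs1 <- constraint_set(faf = faf1)
    cs2 <- constraint_set(faf = c(faf1, extra))
    if (!lp_feasible(bt, cs2)) next
    f1 <- forced_active(bt, cs1)
    f2 <- forced_active(bt, cs2)
    expect_true(all(setdiff(f1, c(faf1, extra)) %in% f2))
  }
})

test_that("realized flux vectors satisfy their constraints", {
  di <- fixture_diamond()
  b <- nullspace_basis(di)
  v <- realize_flux(b, constraint_set(iff = 2, faf = 3))
  expect_equal(unname(v), c(1, 0, 1, 0, 1, 1))

  chain <- fixture_chain()
  vc <- realize_flux(nullspace_basis(chain), constraint_set(faf = 1))
  expect_equal(unname(vc), c(1, 1, 1))

  expect_error(realize_flux(b, constraint_set(iff = c(2, 3), faf = 6)),
               "infeasible")

  toy <- fixture_toy()
  bt <- nullspace_basis(toy)
  set.seed(5)
  for (i in 1:20) {
    iff <- sample(14, sample(0:3, 1))
    faf <- sample(setdiff(1:14, iff), sample(1:2, 1))
    cs <- constraint_set(iff = iff, faf = faf)
    if (!lp_feasible(bt, cs)) next
    v <- realize_flux(bt, cs)
    expect_lt(max(abs(toy$stoich %*% v)), 1e-8 * max(abs(v)))
    expect_true(all(v >= -1e-9))
    expect_true(all(v[iff] == 0))
    expect_true(all(v[faf] > 0))
  }
})

test_that("maximum yields match mass balance on constructed networks", {
  chain <- fixture_chain()
  expect_equal(max_yield(chain, "r3", "r1"), 1, tolerance = 1e-9)
  # the optimum routes around the lossy branch
  expect_equal(max_yield(lossy_diamond(), "r6", "r1"), 1, tolerance = 1e-9)
  # blocking the lossless branch forces the lossy yield
  lame <- lossy_diamond()
  S <- lame$stoich[, -2, drop = FALSE]
  lame2 <- metabolic_network(S, lame$reaction_ids[-2], lame$metabolite_ids)
  expect_equal(max_yield(lame2, "r6", "r1"), 0.5, tolerance = 1e-9)
})

test_that("constraint strings parse and serialize losslessly", {
  di <- fixture_diamond()
  cs <- parse_constraints(c("vr4>=1", "vr6>=0.25"), di)
  expect_equal(unname(cs$flux_bounds[, "reaction"]), c(4, 6))
  expect_equal(unname(cs$flux_bounds[, "k"]), c(1, 0.25))
  expect_error(parse_constraints("r4>1", di), "cannot parse")
  expect_error(parse_constraints("vnothere>=1", di), "unknown reaction")

  tf <- withr::local_tempfile(fileext = ".json")
  full <- constraint_set(iff = 2, faf = 3,
                         flux_bounds = cbind(reaction = 4, k = 0.5),
                         t_signs = c("1" = "inactive", "2" = "active"))
  write_constraints_json(full, tf)
  back <- read_constraints_json(tf)
  expect_equal(back$iff, full$iff)
  expect_equal(back$faf, full$faf)
  expect_equal(unname(back$flux_bounds), unname(full$flux_bounds))
  expect_equal(back$t_signs, full$t_signs)
})
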