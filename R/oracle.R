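#' Brute-force elementary flux mode enumeration
#'
#' Reference enumerator used to verify the depth-first search: every EFM has
#' a unique identification by `DoF - 1` independent inactive free fluxes, so
#' scanning all `choose(R, DoF - 1)` reaction subsets is exhaustive.  For
#' each subset whose nullspace rows have rank `DoF - 1`, the complementary
#' column submatrix of `S` has a one-dimensional kernel; the kernel ray is
#' kept if it can be signed nonnegative.  Results are deduplicated by
#' support and normalized (smallest positive entry = 1), matching the
#' depth-first enumerator so sets compare exactly.
#'
#' @param net an irreversible [metabolic_network()].
#' @param zero_tol relative zero tolerance for support extraction.
#' @param max_combinations guard on `choose(R, DoF - 1)` (default `1e7`).
#' @return an [efm_set()].
#' @export
brute_force_efms <- function(net, zero_tol = 1e-9, max_combinations = 1e7) {
  stopifnot(inherits(net, "metabolic_network"))
  if (any(net$reversible)) {
    stop("oracle requires an irreversible network; call split_reversible() first")
  }
  S <- net$stoich
  R <- ncol(S)
  basis <- nullspace_basis(S)
  dof <- basis$dof
  if (dof == 0L) return(efm_set(matrix(0, 0, R), net$reaction_ids, zero_tol))
  k <- dof - 1L
  if (choose(R, k) > max_combinations) {
    stop("choose(R, DoF-1) = ", choose(R, k), " exceeds the oracle guard; ",
         "use the depth-first enumerator instead")
  }
  ns <- basis$ns
  subsets <- if (k == 0L) list(integer(0)) else
    utils::combn(R, k, simplify = FALSE)
  seen <- new.env(parent = emptyenv())
  rows <- list()
  for (sub in subsets) {
    if (k > 0L && rank_of(ns[sub, , drop = FALSE]) != k) next
    comp <- setdiff(seq_len(R), sub)
    z <- null_basis(S[, comp, drop = FALSE])
    if (ncol(z) != 1L) next     # degenerate; rank bookkeeping disagrees
    z <- drop(z)
    mx <- max(abs(z))
    z[abs(z) < zero_tol * mx] <- 0
    if (all(z <= 0)) z <- -z
    if (any(z < 0) || !any(z > 0)) next
    v <- numeric(R)
    v[comp] <- z
    v <- v / min(v[v > 0])
    key <- paste(which(v > 0), collapse = ",")
    if (is.null(seen[[key]])) {
      seen[[key]] <- TRUE
      rows[[length(rows) + 1L]] <- v
    }
  }
  fluxes <- if (length(rows)) do.call(rbind, rows) else matrix(0, 0, R)
  efm_set(fluxes, net$reaction_ids, zero_tol)
}

#' Generate a random feasible metabolic network
#'
#' Deterministic for a given seed.  Produces an irreversible network with at
#' least one pure source and one pure sink column, integer stoichiometric
#' coefficients in `{-2, -1, 1, 2}`, distinct columns, and at least one
#' nonzero steady-state flux (checked by LP); the draw is repeated until a
#' feasible network is found, up to `max_retries`.
#'
#' @param n_mets number of internal metabolites (>= 1).
#' @param n_rxns number of reactions (> `n_mets`).
#' @param density expected fraction of nonzero entries per interior column
#'   (in `(0, 1]`).
#' @param seed integer seed; the same seed always returns the same network.
#' @param max_retries draws before giving up.
#' @return a [metabolic_network()].
#' @export
random_network <- function(n_mets, n_rxns, density = 0.3, seed = 1L,
                           max_retries = 100L) {
  stopifnot(n_rxns > n_mets, n_mets >= 1, density > 0, density <= 1)
  with_seed(as.integer(seed), {
    for (attempt in seq_len(max_retries)) {
      S <- matrix(0, n_mets, n_rxns)
      # one pure source and one pure sink, then sparse interior columns
      S[sample.int(n_mets, 1L), 1L] <- 1
      S[sample.int(n_mets, 1L), 2L] <- -1
      for (j in 3:n_rxns) {
        repeat {
          nnz <- max(1L, stats::rbinom(1L, n_mets, density))
          nnz <- min(nnz, n_mets)
          rows <- sample.int(n_mets, nnz)
          coefs <- sample(c(-2L, -1L, 1L, 2L), nnz, replace = TRUE)
          col <- numeric(n_mets)
          col[rows] <- coefs
          # reject columns proportional (positive scale) to an earlier one:
          # they are duplicate reactions, not distinct chemistry
          u <- col / sqrt(sum(col^2))
          dup <- any(vapply(seq_len(j - 1L), function(i) {
            ni <- sqrt(sum(S[, i]^2))
            ni > 0 && max(abs(S[, i] / ni - u)) < 1e-9
          }, TRUE))
          if (!dup) {
            S[, j] <- col
            break
          }
        }
      }
      net <- metabolic_network(S, sprintf("R%02d", seq_len(n_rxns)),
                               sprintf("M%02d", seq_len(n_mets)))
      basis <- nullspace_basis(S)
      if (basis$dof < 1L) next
      ok <- any(vapply(seq_len(n_rxns), function(r) {
        lp_feasible(basis, constraint_set(faf = r))
      }, TRUE))
      if (ok) return(net)
    }
    stop("no feasible random network found after ", max_retries, " draws")
  })
}
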