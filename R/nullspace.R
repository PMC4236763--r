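#' Numerical rank of a matrix
#'
#' Rank by QR with a relative tolerance of `tol_rel` times the largest
#' column norm, matching the rank-revealing convention used throughout the
#' search (float computations need an explicit threshold).
#'
#' @param A numeric matrix (may have zero rows/columns).
#' @param tol_rel relative tolerance.
#' @return integer rank.
#' @export
rank_of <- function(A, tol_rel = 1e-10) {
  A <- as.matrix(A)
  if (nrow(A) == 0L || ncol(A) == 0L) return(0L)
  mx <- max(sqrt(colSums(A^2)))
  if (mx == 0) return(0L)
  # SVD is the reliable rank revealer here: QR's pivoted rank estimate
  # mishandles exactly-zero columns.  The scale is floored at 1 so that
  # numerically-zero matrices rank as 0; every matrix ranked in this
  # package (integer stoichiometry, unit-pivot bases) has natural scale >= 1.
  d <- svd(A, nu = 0, nv = 0)$d
  sum(d > tol_rel * max(mx, 1))
}

# orthonormal basis of null(A), SVD-based
null_basis <- function(A, tol_rel = 1e-10) {
  A <- as.matrix(A)
  n <- ncol(A)
  if (n == 0L) return(matrix(0, 0, 0))
  if (nrow(A) == 0L || max(abs(A)) == 0) return(diag(n))
  sv <- svd(A, nu = 0, nv = n)
  mx <- max(sqrt(colSums(A^2)))
  r <- sum(sv$d > tol_rel * max(mx, 1))
  if (r == n) return(matrix(0, n, 0))
  sv$v[, (r + 1):n, drop = FALSE]
}

#' Reduced-row-echelon nullspace basis
#'
#' Constructs the `R x DoF` nullspace basis `NS_rref` of a stoichiometric
#' matrix in which the rows indexed by the pivot reactions form the identity
#' matrix.  Pivot reactions are chosen greedily in ascending index order
#' ("leading" reactions), so `pivot_rows` is the lexicographically smallest
#' admissible set.  Every steady-state flux vector is `v = NS %*% t` with a
#' unique coefficient vector `t`, and for this basis `t` equals the fluxes of
#' the pivot reactions, hence `t >= 0` on the irreversible cone.
#'
#' @param x a [metabolic_network()] or a stoichiometric matrix.
#' @param tol_rel relative rank tolerance.
#' @return an object of class `nullspace_basis`: list with `ns` (R x DoF),
#'   `pivot_rows`, `dof`, `kind = "rref"`, `sign_free_columns` (empty) and
#'   `S` (the stoichiometric matrix the basis was built from).
#' @export
#' @examples
#' chain <- metabolic_network(cbind(c(1, 0), c(-1, 1), c(0, -1)),
#'                            c("r1", "r2", "r3"), c("A", "B"))
#' b <- nullspace_basis(chain)
#' b$dof          # 1
#' b$ns           # the single mode (1, 1, 1)
nullspace_basis <- function(x, tol_rel = 1e-10) {
  S <- if (inherits(x, "metabolic_network")) x$stoich else as.matrix(x)
  R <- ncol(S)
  if (R == 0L) stop("empty stoichiometric matrix")
  N <- null_basis(S, tol_rel)
  dof <- ncol(N)
  if (dof == 0L) {
    return(new_nullspace_basis(matrix(0, R, 0), integer(0), 0L, "rref",
                               integer(0), S))
  }
  # RREF of t(N) (dof x R): pivot columns scanned left to right are the
  # leading independent reaction set; NS_rref = t(rref).
  W <- t(N)
  pivots <- integer(0)
  r <- 0L
  for (j in seq_len(R)) {
    if (r == dof) break
    sub <- W[(r + 1L):dof, j]
    p <- which.max(abs(sub))
    if (abs(sub[p]) <= tol_rel * max(abs(W))) next
    p <- r + p
    if (p != r + 1L) W[c(r + 1L, p), ] <- W[c(p, r + 1L), ]
    r <- r + 1L
    W[r, ] <- W[r, ] / W[r, j]
    others <- setdiff(seq_len(dof), r)
    if (length(others)) {
      W[others, ] <- W[others, , drop = FALSE] - outer(W[others, j], W[r, ])
    }
    pivots <- c(pivots, j)
  }
  if (r < dof) stop("failed to find a full pivot set (rank deficiency)")
  ns <- t(W)
  ns[abs(ns) < 1e-12] <- 0   # scrub elimination residue (scale >= unit pivots)
  # snap pivot rows exactly to the identity
  ns[pivots, ] <- 0
  ns[cbind(pivots, seq_len(dof))] <- 1
  new_nullspace_basis(ns, pivots, dof, "rref", integer(0), S)
}

new_nullspace_basis <- function(ns, pivot_rows, dof, kind,
                                sign_free_columns, S) {
  structure(list(ns = ns, pivot_rows = as.integer(pivot_rows),
                 dof = as.integer(dof), kind = kind,
                 sign_free_columns = as.integer(sign_free_columns), S = S),
            class = "nullspace_basis")
}

#' @export
print.nullspace_basis <- function(x, ...) {
  cat(sprintf("Nullspace basis (%s): %d reactions, DoF = %d", x$kind,
              nrow(x$ns), x$dof))
  if (length(x$sign_free_columns)) {
    cat(sprintf(", %d sign-free column(s)", length(x$sign_free_columns)))
  }
  cat("\n")
  invisible(x)
}

#' Does a candidate reaction row increase the rank of an IFF row set?
#'
#' The rank test used during forward-tracking: a reaction is only worth
#' constraining to zero if its nullspace row is linearly independent of the
#' rows of the reactions already constrained, i.e. if the constraint actually
#' shrinks the solution space.
#'
#' @param basis a [nullspace_basis()].
#' @param iff_rows integer vector of reaction indices already constrained.
#' @param candidate reaction index not in `iff_rows`.
#' @return `TRUE` iff rank increases by one.
#' @export
rank_adds <- function(basis, iff_rows, candidate) {
  stopifnot(!candidate %in% iff_rows)
  base <- if (length(iff_rows)) {
    rank_of(basis$ns[iff_rows, , drop = FALSE])
  } else 0L
  rank_of(basis$ns[c(iff_rows, candidate), , drop = FALSE]) == base + 1L
}

#' Elementarity (rank) test on a flux support
#'
#' A nonzero steady-state flux vector is elementary iff the stoichiometric
#' submatrix over its active reactions has nullity one and the
#' one-dimensional kernel can be signed all-positive on the active set.
#'
#' @param support integer vector of active reaction indices, or a logical
#'   vector of length R.
#' @param S stoichiometric matrix (or [metabolic_network()]).
#' @param tol_rel rank tolerance.
#' @return logical.
#' @export
is_elementary <- function(support, S, tol_rel = 1e-10) {
  if (inherits(S, "metabolic_network")) S <- S$stoich
  if (is.logical(support)) support <- which(support)
  if (!length(support)) return(FALSE)
  sub <- S[, support, drop = FALSE]
  k <- length(support) - rank_of(sub, tol_rel)
  if (k != 1L) return(FALSE)
  z <- null_basis(sub, tol_rel)
  z <- drop(z)
  big <- abs(z) > 1e-9 * max(abs(z))
  if (!all(big)) return(FALSE)        # kernel vector inactive somewhere
  all(z > 0) || all(z < 0)
}

#' Reaction ordering heuristic from nullspace row fill
#'
#' Stable sort of reaction indices by ascending `p * n`, where `p` and `n`
#' count the strictly positive and strictly negative entries of the
#' reaction's nullspace row — the number of possible combinations between
#' positive and negative elements.  Ties are broken by original index.  To
#' use the ordering, permute the network columns and rebuild the basis
#' ([nullspace_basis()]) on the permuted matrix.
#'
#' @param basis a [nullspace_basis()].
#' @param zero_tol entries with absolute value at or below this count as
#'   zero.
#' @return an integer permutation of `1:R` (new order as old indices).
#' @export
sort_rows_heuristic <- function(basis, zero_tol = 1e-9) {
  ns <- basis$ns
  p <- rowSums(ns > zero_tol)
  n <- rowSums(ns < -zero_tol)
  order(p * n, seq_len(nrow(ns)))
}

#' Sparse nullspace basis of short elementary modes
#'
#' Assembles a `kind = "efm"` basis whose `DoF` columns are mutually
#' independent EFM flux vectors of the network.  For each pivot reaction `j`
#' of the RREF basis in turn, an LP minimizing total flux subject to
#' `S v = 0`, `v >= 0`, `v_j = 1` is solved; the LP vertex is an elementary
#' mode, and it is kept if it increases the rank of the accumulating basis.
#' If fewer than `DoF` independent EFMs are found after scanning all
#' reactions, the RREF basis is returned with a warning.
#'
#' `sign_free_columns` lists the columns whose activity coefficient may need
#' to be negative to express some nonnegative steady-state flux vector
#' (detected per column by LP feasibility of `ns t >= 0` with `t_c <= -1`).
#'
#' @param net an irreversible [metabolic_network()].
#' @param zero_tol zero tolerance for support extraction.
#' @return a `nullspace_basis` of kind `"efm"` (or `"rref"` on fallback).
#' @export
sparse_efm_basis <- function(net, zero_tol = 1e-9) {
  S <- net$stoich
  R <- ncol(S)
  rref <- nullspace_basis(S)
  dof <- rref$dof
  if (dof < 1L) stop("network has DoF 0; no modes exist")
  cols <- list()
  rk <- 0L
  tried <- c(rref$pivot_rows, setdiff(seq_len(R), rref$pivot_rows))
  for (j in tried) {
    if (rk == dof) break
    sol <- lp_flux_opt_sum(S, fix = j)
    if (sol$status != "optimal") next
    v <- sol$x
    v[abs(v) < zero_tol * max(abs(v))] <- 0
    if (!any(v > 0)) next
    v <- v / min(v[v > 0])
    cand <- do.call(cbind, c(cols, list(v)))
    if (rank_of(cand) == rk + 1L) {
      cols <- c(cols, list(v))
      rk <- rk + 1L
    }
  }
  if (rk < dof) {
    warning("could not assemble ", dof,
            " independent short modes; falling back to the RREF basis")
    return(rref)
  }
  ns <- do.call(cbind, cols)
  piv <- leading_independent_rows(ns, dof)
  sign_free <- integer(0)
  for (cc in seq_len(dof)) {
    if (column_can_go_negative(ns, cc)) sign_free <- c(sign_free, cc)
  }
  new_nullspace_basis(ns, piv, dof, "efm", sign_free, S)
}

# min sum(v) s.t. S v = 0, v >= 0, v_fix = 1; LP vertex => elementary
lp_flux_opt_sum <- function(S, fix) {
  R <- ncol(S)
  row <- numeric(R)
  row[fix] <- 1
  A <- rbind(S, row)
  lp_solve(rep(1, R), A, rep("=", nrow(A)), c(numeric(nrow(S)), 1))
}

# leading (smallest-index) set of k independent rows of a matrix
leading_independent_rows <- function(M, k) {
  picked <- integer(0)
  for (i in seq_len(nrow(M))) {
    if (length(picked) == k) break
    if (rank_of(M[c(picked, i), , drop = FALSE]) == length(picked) + 1L) {
      picked <- c(picked, i)
    }
  }
  if (length(picked) < k) stop("matrix has fewer than ", k, " independent rows")
  picked
}

# can basis column cc take a negative coefficient in some v = ns t >= 0?
column_can_go_negative <- function(ns, cc) {
  dof <- ncol(ns)
  # variables: t split into t+ - t-, constraint ns t >= 0, t_cc <= -1
  A <- cbind(ns, -ns)
  row <- numeric(2 * dof)
  row[cc] <- 1
  row[dof + cc] <- -1
  A <- rbind(A, row)
  dir <- c(rep(">=", nrow(ns)), "<=")
  b <- c(numeric(nrow(ns)), -1)
  res <- lp_solve(numeric(2 * dof), A, dir, b)
  res$status == "optimal"
}
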