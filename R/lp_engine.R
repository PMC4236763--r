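#' @title LP feasibility services on a nullspace basis
#'
#' @description
#' The search never works with the stoichiometric matrix directly: every
#' flux vector is `v = NS %*% t`, so constraint configurations are posed as
#' linear programs over the low-dimensional coefficient vector `t` and
#' solved with a blank objective — only feasibility matters.  Strict
#' positivity ("flux > 0") is encoded as `>= 1`, which is equivalent on a
#' cone because any strictly positive solution can be rescaled.
#' @name lp-engine
NULL

# assemble the feasibility LP over t for a basis + constraint set (+ extra
# search iff/faf).  Free (sign-unrestricted) t columns are split u - w.
# Returns list(A, dir, b, nvar, dof, free)
build_t_lp <- function(basis, cs, iff = integer(0), faf = integer(0)) {
  ns <- basis$ns
  R <- nrow(ns)
  dof <- basis$dof
  iff_all <- sort(unique(c(cs$iff, iff)))
  faf_all <- sort(unique(c(cs$faf, faf)))
  dir <- rep(">=", R)
  b <- numeric(R)
  b[faf_all] <- 1
  dir[iff_all] <- "="
  b[iff_all] <- 0
  A <- ns
  # a reaction both inactive and active: keep the "= 0" row above and add an
  # explicit ">= 1" row so the contradiction is reported as infeasibility
  clash <- intersect(iff_all, faf_all)
  for (r in clash) {
    A <- rbind(A, ns[r, ])
    dir <- c(dir, ">=")
    b <- c(b, 1)
  }
  if (!is.null(cs$flux_bounds) && nrow(cs$flux_bounds)) {
    for (i in seq_len(nrow(cs$flux_bounds))) {
      r <- cs$flux_bounds[i, "reaction"]
      k <- cs$flux_bounds[i, "k"]
      A <- rbind(A, ns[r, ])
      dir <- c(dir, ">=")
      b <- c(b, k)
    }
  }
  if (!is.null(cs$t_signs) && length(cs$t_signs)) {
    for (j in seq_along(cs$t_signs)) {
      col <- as.integer(names(cs$t_signs)[j])
      row <- numeric(dof)
      row[col] <- 1
      A <- rbind(A, row)
      if (cs$t_signs[j] == "inactive") {
        dir <- c(dir, "=")
        b <- c(b, 0)
      } else {
        dir <- c(dir, ">=")
        b <- c(b, 1)
      }
    }
  }
  free <- basis$sign_free_columns
  if (length(free)) {
    A <- cbind(A, -A[, free, drop = FALSE])
  }
  list(A = A, dir = dir, b = b, nvar = ncol(A), dof = dof, free = free)
}

# fold the split variables back into t
fold_t <- function(x, dof, free) {
  t <- x[seq_len(dof)]
  if (length(free)) t[free] <- t[free] - x[dof + seq_along(free)]
  t
}

lp_backends <- c("simplex", "quadprog")

# solve the feasibility problem; returns list(feasible, t)
solve_t_feasibility <- function(basis, cs, iff = integer(0), faf = integer(0),
                                backend = "simplex") {
  backend <- match.arg(backend, lp_backends)
  lp <- build_t_lp(basis, cs, iff, faf)
  if (backend == "simplex") {
    # blank objective; min sum(v) is used so the returned point is a vertex
    obj <- colSums(basis$ns)
    obj <- c(obj, -obj[lp$free])[seq_len(lp$nvar)]
    res <- try(lp_solve(obj, lp$A, lp$dir, lp$b), silent = TRUE)
    if (inherits(res, "try-error")) {  # retry once, then surface the error
      res <- lp_solve(obj, lp$A, lp$dir, lp$b)
    }
    if (res$status == "unbounded") {
      # cone objective unbounded below cannot happen (sum v >= 0); but a
      # blank retry keeps feasibility information if it ever does
      res <- lp_solve(numeric(lp$nvar), lp$A, lp$dir, lp$b)
    }
    if (res$status == "optimal") {
      return(list(feasible = TRUE, t = fold_t(res$x, lp$dof, lp$free)))
    }
    return(list(feasible = FALSE, t = NULL))
  }
  # quadprog: min-norm point; solve.QP errors iff constraints inconsistent.
  # variables are t directly (free by nature); nonnegativity of non-free
  # columns enters as inequality rows.
  dof <- lp$dof
  A <- lp$A[, seq_len(dof), drop = FALSE]
  dir <- lp$dir
  b <- lp$b
  nonfree <- setdiff(seq_len(dof), lp$free)
  if (length(nonfree)) {
    bound_rows <- matrix(0, length(nonfree), dof)
    bound_rows[cbind(seq_along(nonfree), nonfree)] <- 1
    A <- rbind(A, bound_rows)
    dir <- c(dir, rep(">=", length(nonfree)))
    b <- c(b, numeric(length(nonfree)))
  }
  eq <- dir == "="
  Amat <- t(rbind(A[eq, , drop = FALSE], A[!eq, , drop = FALSE]))
  bvec <- c(b[eq], b[!eq])
  res <- try(quadprog::solve.QP(Dmat = diag(dof), dvec = numeric(dof),
                                Amat = Amat, bvec = bvec, meq = sum(eq)),
             silent = TRUE)
  if (inherits(res, "try-error")) return(list(feasible = FALSE, t = NULL))
  list(feasible = TRUE, t = res$solution)
}

#' Feasibility of a constraint configuration (blank-objective LP)
#'
#' Tests whether a nonzero flux vector exists under the constraint set:
#' `v = NS t`, `v >= 0`, `v = 0` on iff rows, `v >= 1` on faf rows,
#' `v_r >= k` for flux bounds, and t-sign column assignments.
#'
#' @param basis a [nullspace_basis()].
#' @param cs a [constraint_set()] (or `NULL` for no constraints).
#' @param backend `"simplex"` (two-phase LP) or `"quadprog"` (min-norm QP);
#'   both must agree — the backends exist so correctness is never tied to a
#'   single solver.
#' @return logical.
#' @export
#' @examples
#' chain <- metabolic_network(cbind(c(1, 0), c(-1, 1), c(0, -1)),
#'                            c("r1", "r2", "r3"), c("A", "B"))
#' b <- nullspace_basis(chain)
#' lp_feasible(b, constraint_set(faf = 1))           # TRUE: the chain mode
#' lp_feasible(b, constraint_set(iff = 2, faf = 1))  # FALSE: r2 is essential
lp_feasible <- function(basis, cs = NULL, backend = "simplex") {
  cs <- as_constraint_set(cs)
  check_cs_range(cs, nrow(basis$ns), basis$dof)
  solve_t_feasibility(basis, cs, backend = backend)$feasible
}

#' Reactions forced active by a constraint configuration
#'
#' Flux variability analysis reduced to the zero-feasibility question: a
#' candidate reaction is "dependently constrained to be active" iff setting
#' its flux to zero makes the configuration infeasible.  One LP per
#' candidate (roughly half the LP calls of classic min/max FVA); set
#' `method = "fva"` for the classic minimum-based variant.
#'
#' @param basis a [nullspace_basis()].
#' @param cs a [constraint_set()]; must be feasible.
#' @param candidates integer vector of reaction indices to test (default:
#'   all reactions not already constrained).
#' @param method `"zero"` (default) or `"fva"`.
#' @param backend LP backend.
#' @return integer vector: the candidates that are forced active.
#' @export
forced_active <- function(basis, cs = NULL, candidates = NULL,
                          method = c("zero", "fva"), backend = "simplex") {
  cs <- as_constraint_set(cs)
  method <- match.arg(method)
  R <- nrow(basis$ns)
  if (is.null(candidates)) {
    candidates <- setdiff(seq_len(R), c(cs$iff, cs$faf))
  }
  out <- integer(0)
  for (r in candidates) {
    if (r %in% cs$faf) {
      out <- c(out, r)
      next
    }
    if (method == "zero") {
      ok <- solve_t_feasibility(basis, cs, iff = r, backend = backend)$feasible
      if (!ok) out <- c(out, r)
    } else {
      # classic FVA: minimize v_r; forced active iff the minimum is > 0.
      lp <- build_t_lp(basis, cs)
      obj_v <- basis$ns[r, ]
      obj <- c(obj_v, -obj_v[lp$free])[seq_len(lp$nvar)]
      # bound v_r above so the minimization is over a nonempty face
      res <- lp_solve(obj, lp$A, lp$dir, lp$b)
      if (res$status == "optimal" && res$value > 1e-9) out <- c(out, r)
      if (res$status == "infeasible") {
        stop("forced_active requires a feasible constraint set")
      }
    }
  }
  out
}

#' Materialize a feasible flux vector
#'
#' Returns `v = NS t` for a feasible point of the constraint configuration.
#' When the constraint set pins `DoF - 1` independent iff rows the solution
#' space is a single ray and the result is normalized so its smallest
#' positive entry equals one (the canonical EFM scaling).
#'
#' @param basis a [nullspace_basis()].
#' @param cs a [constraint_set()].
#' @param backend LP backend.
#' @param zero_tol entries below `zero_tol * max(v)` are snapped to zero.
#' @return numeric flux vector of length R.
#' @export
realize_flux <- function(basis, cs = NULL, backend = "simplex",
                         zero_tol = 1e-9) {
  cs <- as_constraint_set(cs)
  sol <- solve_t_feasibility(basis, cs, backend = backend)
  if (!sol$feasible) stop("constraint set is infeasible; nothing to realize")
  v <- as.vector(basis$ns %*% sol$t)
  v[abs(v) < zero_tol * max(abs(v), 1e-300)] <- 0
  iff_rows <- cs$iff
  if (length(iff_rows) &&
      rank_of(basis$ns[iff_rows, , drop = FALSE]) == basis$dof - 1L &&
      any(v > 0)) {
    v <- v / min(v[v > 0])
  }
  v
}

#' Maximum product yield per unit substrate
#'
#' LP maximum of the product flux with the substrate flux fixed to one unit,
#' over the steady-state cone `S v = 0`, `v >= 0`.
#'
#' @param net a [metabolic_network()].
#' @param product reaction id (or index) of the product drain.
#' @param substrate reaction id (or index) of the substrate uptake.
#' @return the maximum yield (mol product per mol substrate).
#' @export
max_yield <- function(net, product, substrate) {
  p <- if (is.character(product)) reaction_index(net, product) else product
  s <- if (is.character(substrate)) reaction_index(net, substrate) else substrate
  res <- lp_flux_opt(net$stoich, p, fixed = stats::setNames(1, s),
                     cap = Inf, sense = "max")
  if (res$status == "infeasible") {
    stop("yield LP infeasible: substrate flux cannot be sustained")
  }
  if (res$status == "unbounded") {
    stop("yield LP unbounded: the network likely contains a free cycle ",
         "producing the product")
  }
  res$value
}
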