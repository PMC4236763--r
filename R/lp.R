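#' @title Dense linear-programming utilities
#'
#' @description
#' A small, self-contained two-phase primal simplex used for all LP services
#' in the package: feasibility testing of flux-cone constraint
#' configurations, flux variability analysis, blocked-reaction detection and
#' yield maximization.  Problems arising here are tiny (tens of rows and
#' columns) but are solved many thousands of times per enumeration, so the
#' implementation is fully vectorized and uses Bland's anti-cycling rule
#' throughout.
#'
#' The solver works on the standard form
#'   min c'x   s.t.  A x (<=|=|>=) b,  x >= 0
#' and reports one of three statuses: `"optimal"`, `"infeasible"`,
#' `"unbounded"`.
#' @name lp-internal
#' @keywords internal
NULL

#' Solve a small dense linear program
#'
#' Two-phase primal simplex with Bland's rule.  All variables are
#' nonnegative; free variables must be split by the caller.
#'
#' @param obj numeric objective coefficients (length n).
#' @param A constraint matrix (m x n); may have zero rows.
#' @param dir character vector of `"<="`, `">="`, `"="` per row.
#' @param b right-hand side (length m).
#' @param maximize maximize instead of minimize.
#' @param tol numeric tolerance for pivoting and feasibility decisions.
#' @param max_iter iteration cap (safeguard; Bland's rule cannot cycle).
#' @return list with `status` (`"optimal"`, `"infeasible"`, `"unbounded"`),
#'   `x` (primal solution, `NULL` unless optimal) and `value` (objective).
#' @keywords internal
lp_solve <- function(obj, A, dir, b, maximize = FALSE,
                     tol = 1e-9, max_iter = 20000L) {
  A <- as.matrix(A)
  m <- nrow(A)
  n <- ncol(A)
  stopifnot(length(obj) == n, length(dir) == m, length(b) == m)
  if (m == 0L) {
    cc <- if (maximize) -obj else obj
    # no constraints: x = 0 optimal unless some cost is negative (unbounded)
    if (any(cc < -tol)) {
      return(list(status = "unbounded", x = NULL, value = NA_real_))
    }
    return(list(status = "optimal", x = numeric(n), value = 0))
  }

  # normalize rows to b >= 0
  neg <- b < 0
  if (any(neg)) {
    A[neg, , drop = FALSE] -> Aneg
    A[neg, ] <- -Aneg
    b[neg] <- -b[neg]
    dir[neg] <- ifelse(dir[neg] == "<=", ">=",
                       ifelse(dir[neg] == ">=", "<=", "="))
  }

  n_le <- sum(dir == "<=")
  n_ge <- sum(dir == ">=")
  # columns: structural | slack(<=) | surplus(>=) | artificial(>= and =)
  n_art <- n_ge + sum(dir == "=")
  ncol_tab <- n + n_le + n_ge + n_art

  Tmat <- matrix(0, m, ncol_tab)
  Tmat[, seq_len(n)] <- A
  basis <- integer(m)
  slack_i <- n
  surp_i <- n + n_le
  art_i <- n + n_le + n_ge
  art_cols <- integer(0)
  for (i in seq_len(m)) {
    if (dir[i] == "<=") {
      slack_i <- slack_i + 1L
      Tmat[i, slack_i] <- 1
      basis[i] <- slack_i
    } else if (dir[i] == ">=") {
      surp_i <- surp_i + 1L
      Tmat[i, surp_i] <- -1
      art_i <- art_i + 1L
      Tmat[i, art_i] <- 1
      basis[i] <- art_i
      art_cols <- c(art_cols, art_i)
    } else {
      art_i <- art_i + 1L
      Tmat[i, art_i] <- 1
      basis[i] <- art_i
      art_cols <- c(art_cols, art_i)
    }
  }

  rhs <- b

  pivot <- function(pr, pc) {
    pv <- Tmat[pr, pc]
    Tmat[pr, ] <<- Tmat[pr, ] / pv
    rhs[pr] <<- rhs[pr] / pv
    col <- Tmat[, pc]
    rows <- which(abs(col) > 0 & seq_len(m) != pr)
    if (length(rows)) {
      Tmat[rows, ] <<- Tmat[rows, , drop = FALSE] -
        outer(col[rows], Tmat[pr, ])
      rhs[rows] <<- rhs[rows] - col[rows] * rhs[pr]
    }
    Tmat[, pc] <<- 0
    Tmat[pr, pc] <<- 1
    basis[pr] <<- pc
  }

  # run simplex iterations on reduced costs of `cost` over allowed columns
  run <- function(cost, allowed) {
    iter <- 0L
    repeat {
      iter <- iter + 1L
      if (iter > max_iter) stop("simplex iteration limit reached")
      cb <- cost[basis]
      red <- cost - as.vector(crossprod(Tmat, cb))  # reduced costs
      red[!allowed] <- Inf
      ent <- which(red < -tol)
      if (!length(ent)) return("optimal")
      pc <- ent[1L]                               # Bland: smallest index
      col <- Tmat[, pc]
      pos <- which(col > tol)
      if (!length(pos)) return("unbounded")
      ratio <- rhs[pos] / col[pos]
      pr <- pos[ratio <= min(ratio) + tol]
      pr <- pr[which.min(basis[pr])]              # Bland on leaving index
      pivot(pr, pc)
    }
  }

  allowed <- rep(TRUE, ncol_tab)
  if (n_art > 0L) {
    cost1 <- numeric(ncol_tab)
    cost1[art_cols] <- 1
    st <- run(cost1, allowed)
    obj1 <- sum(cost1[basis] * rhs)     # residual artificial mass
    if (st != "optimal" || obj1 > 1e-7 * max(1, max(abs(b)))) {
      return(list(status = "infeasible", x = NULL, value = NA_real_))
    }
    # drive remaining artificials out of the basis where possible
    for (i in seq_len(m)) {
      if (basis[i] %in% art_cols) {
        cand <- which(abs(Tmat[i, seq_len(n + n_le + n_ge)]) > tol)
        if (length(cand)) {
          pivot(i, cand[1L])
        }
        # else: redundant row; its artificial stays basic at zero
      }
    }
    allowed[art_cols] <- FALSE
  }

  cost2 <- numeric(ncol_tab)
  cost2[seq_len(n)] <- if (maximize) -obj else obj
  st <- run(cost2, allowed)
  if (st == "unbounded") {
    return(list(status = "unbounded", x = NULL, value = NA_real_))
  }
  x <- numeric(ncol_tab)
  x[basis] <- rhs
  xs <- x[seq_len(n)]
  val <- sum(obj * xs)
  list(status = "optimal", x = xs, value = val)
}

#' Maximize (or minimize) one flux over the bounded steady-state cone
#'
#' Solves `opt v_target` subject to `S v = 0`, `0 <= v <= cap`, with optional
#' pinned fluxes `v_i = f_i`.  The upper cap keeps the flux cone bounded so
#' that maxima are finite; only the zero/nonzero distinction is meaningful
#' for cone questions.
#'
#' @param S stoichiometric matrix (M x R).
#' @param target column index of the flux to optimize.
#' @param fixed optional named-by-index numeric vector: `fixed[i]` pins
#'   reaction `i` to that value (a list of `index = value` pairs given as a
#'   numeric vector with integer names).
#' @param cap upper bound applied to every flux (default `1e6`).
#' @param sense `"max"` or `"min"`.
#' @return list with `status` and `value` (the optimum when `"optimal"`).
#' @keywords internal
lp_flux_opt <- function(S, target, fixed = NULL, cap = 1e6, sense = "max") {
  S <- as.matrix(S)
  M <- nrow(S)
  R <- ncol(S)
  A <- S
  dir <- rep("=", M)
  b <- numeric(M)
  if (!is.null(fixed) && length(fixed)) {
    idx <- as.integer(names(fixed))
    for (k in seq_along(idx)) {
      row <- numeric(R)
      row[idx[k]] <- 1
      A <- rbind(A, row)
      dir <- c(dir, "=")
      b <- c(b, unname(fixed[k]))
    }
  }
  if (is.finite(cap)) {
    A <- rbind(A, diag(R))
    dir <- c(dir, rep("<=", R))
    b <- c(b, rep(cap, R))
  }
  obj <- numeric(R)
  obj[target] <- 1
  lp_solve(obj, A, dir, b, maximize = identical(sense, "max"))
}
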