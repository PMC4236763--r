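#' @title Depth-first enumeration of elementary flux modes
#'
#' @description
#' Every EFM of an irreversible network is identified by a unique leading
#' set of `DoF - 1` inactive free fluxes (IFF).  The search walks these
#' identification sets depth-first: forward-tracking extends the IFF list
#' with downstream reactions that pass a rank test (the zero constraint
#' actually shrinks the solution space) and an LP feasibility test;
#' backtracking converts the terminal IFF into a fixed-to-active flux (FAF)
#' and clears downstream FAF.  A recording matrix marks reactions forced
#' active by each IFF so they are skipped as candidates, and progress
#' check-points prune branches that cannot reach `DoF - 1` IFF.
#' @name dfs-search
NULL

#' Enumerate elementary flux modes depth-first
#'
#' @param net an irreversible [metabolic_network()] (see
#'   [split_reversible()]).
#' @param cs optional [constraint_set()]; only EFMs satisfying it are
#'   generated.  An infeasible constraint set yields an empty set, not an
#'   error.
#' @param basis optional precomputed [nullspace_basis()]; defaults to the
#'   RREF basis of the network.
#' @param sort_rows apply the positive-times-negative row-count ordering
#'   heuristic ([sort_rows_heuristic()]) before searching; results are
#'   mapped back to the original reaction order.
#' @param batch_size number of EFM records buffered before flushing to
#'   `sink`; bounds the memory retained during a run.
#' @param sink `NULL` (accumulate and return all EFMs) or a function
#'   `function(batch, state)` receiving a flux matrix (rows = EFMs, columns
#'   = reactions) and a resumable search-state snapshot at every flush.
#' @param backend LP backend (`"simplex"` or `"quadprog"`).
#' @param zero_tol relative zero tolerance for support extraction.
#' @param use_m_record enable the forced-active recording matrix speed-up.
#' @param check_duplicates assert that no support is emitted twice (cheap at
#'   desk scale; the leading-IFF uniqueness theorem makes duplicates a bug).
#' @param resume_state a snapshot (list `iff`, `faf`, `cursor`, `phase`) from
#'   a previous run's sink callback; the recording matrix is recomputed.
#' @param max_efms stop after this many EFMs (safety valve).
#' @return an [efm_set()] (empty when `sink` consumed the batches), with
#'   attributes `"counters"` (`lp_calls`, `rank_tests`, `n_efms`,
#'   `peak_buffer`, `duplicates_suppressed`) and `"iff_sets"` (the
#'   identifying DoF-1 inactive-free-flux index set of each emitted mode,
#'   in emission order).
#' @export
#' @examples
#' chain <- metabolic_network(cbind(c(1, 0), c(-1, 1), c(0, -1)),
#'                            c("r1", "r2", "r3"), c("A", "B"))
#' enumerate_efms(chain)               # the single mode (1, 1, 1)
enumerate_efms <- function(net, cs = NULL, basis = NULL, sort_rows = FALSE,
                           batch_size = 10000L, sink = NULL,
                           backend = "simplex", zero_tol = 1e-9,
                           use_m_record = TRUE, check_duplicates = TRUE,
                           resume_state = NULL, max_efms = Inf) {
  stopifnot(inherits(net, "metabolic_network"))
  if (any(net$reversible)) {
    stop("enumeration requires an irreversible network; call split_reversible() first")
  }
  if (sort_rows) {
    if (!is.null(basis) || !is.null(resume_state)) {
      stop("sort_rows cannot be combined with a precomputed basis or resume")
    }
    b0 <- nullspace_basis(net$stoich)
    perm <- sort_rows_heuristic(b0)
    pnet <- metabolic_network(net$stoich[, perm, drop = FALSE],
                              net$reaction_ids[perm], net$metabolite_ids,
                              net$reversible[perm])
    pcs <- remap_cs(cs, perm)
    res <- enumerate_efms(pnet, pcs, sort_rows = FALSE,
                          batch_size = batch_size, sink = sink,
                          backend = backend, zero_tol = zero_tol,
                          use_m_record = use_m_record,
                          check_duplicates = check_duplicates,
                          max_efms = max_efms)
    inv <- order(perm)
    out <- efm_set(res$fluxes[, inv, drop = FALSE], net$reaction_ids,
                   zero_tol)
    attr(out, "counters") <- attr(res, "counters")
    attr(out, "iff_sets") <- lapply(attr(res, "iff_sets"),
                                    function(ix) sort(perm[ix]))
    return(out)
  }

  S <- net$stoich
  R <- ncol(S)
  if (is.null(basis)) basis <- nullspace_basis(S)
  dof <- basis$dof
  cs <- as_constraint_set(cs)
  check_cs_range(cs, R, dof)
  ns <- basis$ns

  counters <- new.env(parent = emptyenv())
  counters$lp_calls <- 0L
  counters$rank_tests <- 0L
  counters$peak_buffer <- 0L
  counters$duplicates_suppressed <- 0L

  buffer <- list()
  collected <- list()
  seen <- new.env(parent = emptyenv())
  iff_sets <- list()
  n_efms <- 0L

  finish <- function() {
    flush_buffer()
    fluxes <- if (length(collected)) do.call(rbind, collected) else
      matrix(0, 0, R)
    out <- efm_set(fluxes, net$reaction_ids, zero_tol)
    attr(out, "counters") <- list(
      lp_calls = counters$lp_calls,
      rank_tests = counters$rank_tests,
      n_efms = n_efms,
      peak_buffer = counters$peak_buffer,
      duplicates_suppressed = counters$duplicates_suppressed)
    attr(out, "iff_sets") <- iff_sets
    out
  }

  iff <- integer(0)
  faf <- integer(0)
  m_rec <- matrix(FALSE, R, max(dof - 1L, 0L))
  cursor <- 0L
  phase <- "backward"
  empty_handoff <- FALSE

  state_snapshot <- function() {
    list(iff = iff, faf = faf, cursor = cursor, phase = phase)
  }

  flush_buffer <- function() {
    if (!length(buffer)) return(invisible())
    batch <- do.call(rbind, buffer)
    colnames(batch) <- net$reaction_ids
    if (is.null(sink)) collected[[length(collected) + 1L]] <<- batch
    else sink(batch, state_snapshot())
    buffer <<- list()
  }

  cfg_feasible <- function(extra_iff, extra_faf) {
    counters$lp_calls <- counters$lp_calls + 1L
    solve_t_feasibility(basis, cs, iff = extra_iff, faf = extra_faf,
                        backend = backend)
  }

  rank_tick <- function() counters$rank_tests <- counters$rank_tests + 1L

  emit <- function(v, iff_set, origin = "normal") {
    v[abs(v) < zero_tol * max(abs(v), 1e-300)] <- 0
    if (!any(v > 0)) stop("internal: attempted to emit a zero flux vector")
    v <- v / min(v[v > 0])
    key <- paste(which(v > 0), collapse = ",")
    prev <- seen[[key]]
    if (!is.null(prev)) {
      # the nullity-one early exit can re-find a mode already identified in
      # another subtree (the leading-IFF uniqueness theorem only covers
      # full-depth identifications); suppress those re-finds silently
      if (origin == "early" || prev == "early") {
        counters$duplicates_suppressed <- counters$duplicates_suppressed + 1L
        return(invisible())
      }
      if (check_duplicates) {
        stop("duplicate EFM emission (support ", key,
             "); this violates the leading-IFF uniqueness property")
      }
      return(invisible())
    }
    seen[[key]] <- origin
    buffer[[length(buffer) + 1L]] <<- v
    iff_sets[[length(iff_sets) + 1L]] <<- sort(as.integer(iff_set))
    n_efms <<- n_efms + 1L
    counters$peak_buffer <- max(counters$peak_buffer, length(buffer))
    if (length(buffer) >= batch_size) flush_buffer()
    invisible()
  }

  realize_config <- function(sol_t) {
    v <- as.vector(ns %*% sol_t)
    v
  }

  # leading DoF-1 independent inactive rows identifying an EFM
  complete_leading_iff <- function(v) {
    inactive <- which(v <= zero_tol * max(abs(v)))
    picked <- integer(0)
    for (i in inactive) {
      if (length(picked) == dof - 1L) break
      rank_tick()
      if (rank_of(ns[c(picked, i), , drop = FALSE]) == length(picked) + 1L) {
        picked <- c(picked, i)
      }
    }
    picked
  }

  # does the ray v satisfy the user constraints up to cone rescaling?
  ray_satisfies_cs <- function(v) {
    mx <- max(abs(v))
    if (length(cs$iff) && any(v[cs$iff] > zero_tol * mx)) return(FALSE)
    if (length(cs$faf) && any(v[cs$faf] <= zero_tol * mx)) return(FALSE)
    if (!is.null(cs$flux_bounds) && nrow(cs$flux_bounds)) {
      r <- cs$flux_bounds[, "reaction"]
      k <- cs$flux_bounds[, "k"]
      if (any(k > 0 & v[r] <= zero_tol * mx)) return(FALSE)
    }
    if (!is.null(cs$t_signs) && length(cs$t_signs)) {
      tt <- qr.solve(ns, v)
      j <- as.integer(names(cs$t_signs))
      inact <- cs$t_signs == "inactive"
      if (any(abs(tt[j[inact]]) > 1e-7 * max(abs(tt), 1e-300))) return(FALSE)
      if (any(tt[j[!inact]] <= 1e-7 * max(abs(tt), 1e-300))) return(FALSE)
    }
    TRUE
  }

  marked_vec <- function() {
    if (ncol(m_rec)) rowSums(m_rec) > 0 else rep(FALSE, R)
  }

  mark_column <- function() {
    if (!use_m_record || !ncol(m_rec)) return(invisible())
    marked <- marked_vec()
    unresolved <- setdiff(which(!marked), c(iff, faf, cs$iff, cs$faf))
    if (!length(unresolved)) return(invisible())
    forced <- unresolved[vapply(unresolved, function(f) {
      !cfg_feasible(c(iff, f), faf)$feasible
    }, TRUE)]
    m_rec[forced, length(iff)] <<- TRUE
    invisible()
  }

  initialize_search <- function() {
    iff <<- if (dof > 1L) {
      leading_independent_rows(ns, dof - 1L)
    } else integer(0)
    # preset: the leading DoF-1 independent reactions
    # (for the RREF basis these are exactly its pivot rows)
    cursor <<- if (length(iff)) max(iff) else 0L
    start <- cursor
    phase <<- "backward"
    for (r in seq_len(R)) {
      if (r <= start || r %in% iff) next
      sol <- cfg_feasible(iff, r)
      if (sol$feasible) {
        emit(realize_config(sol$t), iff)
        break
      }
    }
  }

  backward_step <- function() {
    repeat {
      if (!length(iff)) {
        if (empty_handoff) phase <<- "done"
        else {
          empty_handoff <<- TRUE
          phase <<- "forward"
        }
        return(invisible())
      }
      j <- iff[length(iff)]
      iff <<- iff[-length(iff)]
      if (ncol(m_rec)) m_rec[, length(iff) + 1L] <<- FALSE
      faf <<- c(faf[faf < j], j)
      cursor <<- j
      if (cfg_feasible(iff, faf)$feasible) {
        phase <<- "forward"
        return(invisible())
      }
    }
  }

  forward_step <- function() {
    pos <- cursor
    all_idx <- seq_len(R)
    repeat {
      marked <- marked_vec()
      cand <- all_idx[all_idx > pos & !marked]
      cand <- setdiff(cand, c(iff, faf))
      # check-point 1: enough candidates left to reach DoF-1 IFF
      if (length(iff) + length(cand) < dof - 1L) {
        phase <<- "backward"
        return(invisible())
      }
      # check-point 2: enough independent rows among IFF and candidates
      rank_tick()
      if (rank_of(ns[c(iff, cand), , drop = FALSE]) < dof - 1L) {
        phase <<- "backward"
        return(invisible())
      }
      # check-point 3: the forced-active submatrix must admit no internal
      # mode (nullity 0); nullity exactly 1 means the branch's only
      # possible EFM is that kernel ray — emit it and turn back
      active_set <- sort(unique(c(which(marked), faf, cs$faf)))
      if (length(active_set)) {
        rank_tick()
        nullity <- length(active_set) -
          rank_of(S[, active_set, drop = FALSE])
        if (nullity >= 1L) {
          phase <<- "backward"
          if (nullity == 1L) try_early_exit(active_set)
          return(invisible())
        }
      }
      if (!length(cand)) {
        phase <<- "backward"
        return(invisible())
      }
      r <- cand[1L]
      pos <- r
      rank_tick()
      if (!rank_adds(basis, iff, r)) next
      sol <- cfg_feasible(c(iff, r), faf)
      if (!sol$feasible) next
      iff <<- c(iff, r)
      empty_handoff <<- FALSE
      mark_column()
      if (length(iff) == dof - 1L) {
        # flip the phase before emitting so a batch flush snapshots the
        # post-emission state (resume must not re-find this mode)
        phase <<- "backward"
        emit(realize_config(sol$t), iff)
        return(invisible())
      }
    }
  }

  # nullity-one early exit: the unique kernel ray of the forced-active
  # columns is the only EFM this branch can contain
  try_early_exit <- function(active_set) {
    z <- drop(null_basis(S[, active_set, drop = FALSE]))
    if (is.matrix(z)) return(invisible())   # numerically ambiguous; skip
    mx <- max(abs(z))
    if (any(abs(z) <= 1e-9 * mx)) return(invisible())  # ray misses a column
    if (all(z < 0)) z <- -z
    if (any(z < 0)) return(invisible())
    v <- numeric(R)
    v[active_set] <- z
    if (!ray_satisfies_cs(v)) return(invisible())
    emit(v, complete_leading_iff(v), origin = "early")
    invisible()
  }

  if (dof == 0L) return(finish())

  # start-up: infeasible user constraints yield an empty stream
  if (!cfg_feasible(integer(0), integer(0))$feasible) return(finish())

  if (is.null(resume_state)) {
    initialize_search()
    if (dof == 1L) phase <- "done"
  } else {
    iff <- as.integer(resume_state$iff)
    faf <- as.integer(resume_state$faf)
    cursor <- as.integer(resume_state$cursor)
    phase <- as.character(resume_state$phase)
    if (dof == 1L) phase <- "done"
    # recompute the recording matrix.  Column k may only assume the FAF
    # entries below iff[k]: those can never be cleared while iff[k] lives,
    # whereas later FAF additions are dropped again during backtracking and
    # marks conditioned on them would over-prune after resuming
    if (use_m_record && ncol(m_rec)) {
      for (k in seq_along(iff)) {
        faf_k <- faf[faf < iff[k]]
        marked <- marked_vec()
        unresolved <- setdiff(which(!marked),
                              c(iff[seq_len(k)], faf_k, cs$iff, cs$faf))
        forced <- unresolved[vapply(unresolved, function(f) {
          !cfg_feasible(c(iff[seq_len(k)], f), faf_k)$feasible
        }, TRUE)]
        m_rec[forced, k] <- TRUE
      }
    }
  }

  while (phase != "done" && n_efms < max_efms) {
    if (phase == "backward") backward_step() else forward_step()
  }
  finish()
}

# remap reaction indices of a constraint set through a column permutation
remap_cs <- function(cs, perm) {
  cs <- as_constraint_set(cs)
  inv <- order(perm)        # old index -> new position
  fb <- cs$flux_bounds
  if (!is.null(fb)) fb[, "reaction"] <- inv[fb[, "reaction"]]
  constraint_set(iff = inv[cs$iff], faf = inv[cs$faf], flux_bounds = fb,
                 t_signs = cs$t_signs)
}
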