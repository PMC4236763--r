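#' Lossless network compression
#'
#' Iterates to a fixed point over four lossless reductions:
#' \enumerate{
#'   \item removal of blocked reactions (zero maximum flux under
#'     `S v = 0`, `v >= 0`, detected by per-reaction LP maximization with
#'     all fluxes capped at `cap` so maxima are finite);
#'   \item lumping of enzyme subsets — reactions whose fluxes are in a fixed
#'     strictly-positive ratio in every steady state, detected from
#'     proportional rows of a nullspace basis (optional via `lump_subsets`);
#'   \item merging of duplicate columns (equal up to a positive scale,
#'     optional via `merge_duplicates`, off by default — see below);
#'   \item dropping metabolite rows that become all-zero (isolated
#'     conservation relations).
#' }
#'
#' Blocked-reaction removal, enzyme-subset lumping and zero-row dropping
#' preserve EFM counts one-to-one under [expand_efms()].  Duplicate-column
#' merging does not: modes that differ only in the choice among duplicated
#' reactions collapse to a single compressed mode (expansion then routes
#' flux through the representative, first-listed member).  It is therefore
#' disabled by default and intended for workflows that deliberately count
#' duplicate-equivalent modes once.
#'
#' @param net an irreversible [metabolic_network()].
#' @param cs optional [constraint_set()]: its `iff` reactions are removed as
#'   blocked before compression (other constraint kinds do not change which
#'   reductions are lossless and are ignored here).
#' @param lump_subsets lump enzyme subsets (default `TRUE`).
#' @param merge_duplicates merge duplicate columns (default `FALSE`; not
#'   EFM-count-preserving, see Details).
#' @param cap LP flux cap used for blocked-reaction detection.
#' @param zero_tol tolerance: a reaction is blocked when its capped LP
#'   maximum is below `zero_tol * cap` scale floor `zero_tol`.
#' @return list with `network` (the compressed [metabolic_network()]) and
#'   `map` (a `compression_map`: `groups`, each with `id`, `kind`,
#'   `members` = (original id, ratio) pairs and possibly
#'   `duplicates_absorbed`; and `dropped`, the removed reaction ids).
#' @export
compress_network <- function(net, cs = NULL, lump_subsets = TRUE,
                             merge_duplicates = FALSE, cap = 1e6,
                             zero_tol = 1e-9) {
  stopifnot(inherits(net, "metabolic_network"))
  if (any(net$reversible)) {
    stop("compression requires an irreversible network")
  }
  S <- net$stoich
  met_ids <- net$metabolite_ids
  # per current column: expansion members (orig id -> ratio) and absorbed
  # duplicate alternatives (recorded, expanded to zero)
  cols <- lapply(net$reaction_ids, function(id) {
    list(members = stats::setNames(1, id), absorbed = list())
  })
  dropped <- character(0)

  if (!is.null(cs) && length(as_constraint_set(cs)$iff)) {
    kill <- as_constraint_set(cs)$iff
    dropped <- c(dropped, unlist(lapply(cols[kill],
                                        function(c) names(c$members))))
    S <- S[, -kill, drop = FALSE]
    cols <- cols[-kill]
  }

  repeat {
    changed <- FALSE
    ## (a) blocked reactions
    if (ncol(S) && nrow(S)) {
      blocked <- vapply(seq_len(ncol(S)), function(r) {
        res <- lp_flux_opt(S, r, cap = cap, sense = "max")
        res$status != "optimal" || res$value < zero_tol
      }, TRUE)
      if (any(blocked)) {
        dropped <- c(dropped, unlist(lapply(cols[blocked], function(c) {
          c(names(c$members),
            unlist(lapply(c$absorbed, function(a) names(a))))
        })))
        S <- S[, !blocked, drop = FALSE]
        cols <- cols[!blocked]
        changed <- TRUE
      }
    }
    if (!ncol(S)) break
    ## (b) enzyme subsets from proportional nullspace rows
    if (lump_subsets && ncol(S) > 1L && nrow(S)) {
      N <- null_basis(S)
      if (ncol(N)) {
        grp <- proportional_row_groups(N)
        if (any(lengths(grp) > 1L)) {
          res <- lump_groups(S, cols, N, grp)
          S <- res$S
          cols <- res$cols
          changed <- TRUE
        }
      }
    }
    ## (c) duplicate columns (equal up to positive scale)
    if (merge_duplicates && ncol(S) > 1L) {
      res <- merge_duplicate_columns(S, cols)
      if (res$changed) {
        S <- res$S
        cols <- res$cols
        changed <- TRUE
      }
    }
    ## (d) all-zero metabolite rows
    if (nrow(S)) {
      zero_row <- rowSums(abs(S)) == 0
      if (any(zero_row)) {
        S <- S[!zero_row, , drop = FALSE]
        met_ids <- met_ids[!zero_row]
        changed <- TRUE
      }
    }
    if (!changed) break
  }

  ids <- vapply(cols, function(c) names(c$members)[1L], "")
  network <- new_compressed_network(S, ids, met_ids)
  groups <- lapply(cols, function(c) {
    g <- list(id = names(c$members)[1L],
              kind = if (length(c$absorbed)) "duplicate" else
                if (length(c$members) > 1L) "subset" else "single",
              members = lapply(seq_along(c$members), function(i) {
                list(id = names(c$members)[i], ratio = unname(c$members[i]))
              }))
    if (length(c$absorbed)) {
      g$duplicates_absorbed <- lapply(c$absorbed, function(a) {
        lapply(seq_along(a), function(i) {
          list(id = names(a)[i], ratio = unname(a[i]))
        })
      })
    }
    g
  })
  map <- structure(list(groups = groups, dropped = unique(dropped)),
                   class = "compression_map")
  list(network = network, map = map)
}

# compressed networks may legitimately contain all-zero columns (fully
# lumped exchange-to-exchange routes) and zero metabolites
new_compressed_network <- function(S, ids, met_ids) {
  if (!ncol(S)) {
    return(structure(list(stoich = matrix(0, length(met_ids), 0,
                                          dimnames = list(met_ids, NULL)),
                          reaction_ids = character(0),
                          metabolite_ids = met_ids,
                          reversible = logical(0)),
                     class = "metabolic_network"))
  }
  dimnames(S) <- list(met_ids, ids)
  structure(list(stoich = S, reaction_ids = ids, metabolite_ids = met_ids,
                 reversible = rep(FALSE, ncol(S))),
            class = "metabolic_network")
}

#' @export
print.compression_map <- function(x, ...) {
  sizes <- vapply(x$groups, function(g) length(g$members), 1L)
  cat(sprintf(
    "Compression map: %d group(s) (%d lumped), %d dropped reaction(s)\n",
    length(x$groups), sum(sizes > 1L), length(x$dropped)))
  invisible(x)
}

# group row indices of N that are proportional with positive ratio
proportional_row_groups <- function(N, tol = 1e-8) {
  n <- nrow(N)
  norms <- sqrt(rowSums(N^2))
  unit <- N / pmax(norms, 1e-300)
  assigned <- rep(NA_integer_, n)
  g <- 0L
  for (i in seq_len(n)) {
    if (!is.na(assigned[i]) || norms[i] == 0) next
    g <- g + 1L
    assigned[i] <- g
    if (i < n) {
      for (k in (i + 1L):n) {
        if (!is.na(assigned[k]) || norms[k] == 0) next
        if (max(abs(unit[k, ] - unit[i, ])) < tol) assigned[k] <- g
      }
    }
  }
  split(seq_len(n)[!is.na(assigned)], assigned[!is.na(assigned)])
}

lump_groups <- function(S, cols, N, grp) {
  keep <- logical(ncol(S))
  newS <- S
  for (g in grp) {
    ref <- g[1L]
    keep[ref] <- TRUE
    if (length(g) == 1L) next
    ratios <- vapply(g, function(i) {
      sum(N[i, ] * N[ref, ]) / sum(N[ref, ]^2)
    }, 0)
    # v_i = ratios[i] * w for the common subset flux w (= flux of ref)
    col <- as.vector(S[, g, drop = FALSE] %*% ratios)
    col[abs(col) < 1e-9] <- 0      # cancellation residue (integer-scale S)
    newS[, ref] <- col
    merged <- stats::setNames(numeric(0), character(0))
    for (k in seq_along(g)) {
      m <- cols[[g[k]]]$members * ratios[k]
      merged <- c(merged, m)
    }
    absorbed <- unlist(lapply(g, function(i) cols[[i]]$absorbed),
                       recursive = FALSE)
    cols[[ref]] <- list(members = merged, absorbed = absorbed)
  }
  list(S = newS[, keep, drop = FALSE], cols = cols[keep])
}

merge_duplicate_columns <- function(S, cols, tol = 1e-9) {
  n <- ncol(S)
  norms <- sqrt(colSums(S^2))
  drop <- logical(n)
  changed <- FALSE
  for (i in seq_len(n - 1L)) {
    if (drop[i]) next
    for (k in (i + 1L):n) {
      if (drop[k]) next
      if (norms[i] == 0 || norms[k] == 0) {
        same <- norms[i] == 0 && norms[k] == 0
      } else {
        same <- max(abs(S[, i] / norms[i] - S[, k] / norms[k])) < tol
      }
      if (same) {
        scale <- if (norms[i] > 0) norms[k] / norms[i] else 1
        # unit flux through column k equals `scale` flux through column i
        cols[[i]]$absorbed <- c(cols[[i]]$absorbed,
                                list(cols[[k]]$members * scale),
                                cols[[k]]$absorbed)
        drop[k] <- TRUE
        changed <- TRUE
      }
    }
  }
  list(S = S[, !drop, drop = FALSE], cols = cols[!drop], changed = changed)
}

#' Expand EFMs of a compressed network to the original reaction space
#'
#' Inverse of [compress_network()]: each compressed EFM maps to exactly one
#' original-space EFM.  Flux through a lumped enzyme subset distributes over
#' its members by the recorded ratios; flux through a merged duplicate group
#' is routed through the representative (first-listed) member; dropped
#' reactions get zero flux.
#'
#' @param efms an [efm_set()] computed on the compressed network.
#' @param map the `compression_map` from [compress_network()].
#' @param original_ids reaction ids of the original network, in order.
#' @return an [efm_set()] over `original_ids`.
#' @export
expand_efms <- function(efms, map, original_ids) {
  stopifnot(inherits(efms, "efm_set"), inherits(map, "compression_map"))
  if (ncol(efms$fluxes) != length(map$groups)) {
    stop("EFM set has ", ncol(efms$fluxes), " reactions but the map has ",
         length(map$groups), " groups")
  }
  E <- matrix(0, length(original_ids), length(map$groups),
              dimnames = list(original_ids, NULL))
  for (j in seq_along(map$groups)) {
    for (m in map$groups[[j]]$members) {
      i <- match(m$id, original_ids)
      if (is.na(i)) stop("map references unknown reaction id: ", m$id)
      E[i, j] <- m$ratio
    }
  }
  fluxes <- efms$fluxes %*% t(E)
  fluxes <- normalize_efm_rows(fluxes, efms$zero_tol)
  efm_set(fluxes, original_ids, efms$zero_tol)
}

#' Serialize a compression map to JSON
#'
#' @param map a `compression_map`.
#' @param path output path.
#' @export
write_compression_map <- function(map, path) {
  jsonlite::write_json(unclass(map), path, auto_unbox = TRUE, digits = NA)
}

#' Flux-variability model reduction at maximum objective yield
#'
#' Fixes the substrate uptake to one unit, maximizes the objective reaction,
#' pins the objective at its maximum, then runs flux variability analysis
#' (per-reaction LP minimum and maximum, fluxes capped at `cap`).  Exactly
#' the reactions whose |min| or |max| exceeds the zero tolerance are
#' retained; metabolite rows that become all-zero are dropped.  The retained
#' set is a column subset of the input and the operation is idempotent.
#'
#' @param net a [metabolic_network()].
#' @param objective reaction id (or index) to maximize.
#' @param fixed_uptake reaction id (or index) fixed to 1 unit.
#' @param cap internal LP flux cap.
#' @param zero_tol flux-carrying threshold.
#' @return the reduced [metabolic_network()].
#' @export
fva_reduce <- function(net, objective, fixed_uptake, cap = 1e6,
                       zero_tol = 1e-9) {
  obj <- if (is.character(objective)) reaction_index(net, objective) else objective
  upt <- if (is.character(fixed_uptake)) reaction_index(net, fixed_uptake) else fixed_uptake
  S <- net$stoich
  fixed <- stats::setNames(1, upt)
  top <- lp_flux_opt(S, obj, fixed = fixed, cap = cap, sense = "max")
  if (top$status != "optimal") {
    stop("objective LP ", top$status, ": cannot fix the maximum yield")
  }
  if (top$value <= zero_tol) {
    stop("objective maximum is zero with unit uptake; nothing to retain")
  }
  fixed2 <- stats::setNames(c(1, top$value), c(upt, obj))
  keep <- vapply(seq_len(ncol(S)), function(r) {
    hi <- lp_flux_opt(S, r, fixed = fixed2, cap = cap, sense = "max")
    if (hi$status == "optimal" && abs(hi$value) > zero_tol) return(TRUE)
    lo <- lp_flux_opt(S, r, fixed = fixed2, cap = cap, sense = "min")
    lo$status == "optimal" && abs(lo$value) > zero_tol
  }, TRUE)
  Sk <- S[, keep, drop = FALSE]
  nz_row <- rowSums(abs(Sk)) > 0
  metabolic_network(Sk[nz_row, , drop = FALSE],
                    net$reaction_ids[keep],
                    net$metabolite_ids[nz_row],
                    net$reversible[keep])
}

#' Replace a composite reaction by individual component drains
#'
#' Removes the reaction and adds one unit-stoichiometry drain column per
#' internal metabolite it consumed (and a unit source column per metabolite
#' it produced).  Used to decompose a lumped biomass equation into
#' individual biomass component drains.
#'
#' @param net a [metabolic_network()].
#' @param reaction reaction id to replace.
#' @param drain_prefix,source_prefix prefixes for the new column ids.
#' @return the modified [metabolic_network()].
#' @export
replace_with_drains <- function(net, reaction, drain_prefix = "drain_",
                                source_prefix = "source_") {
  j <- reaction_index(net, reaction)
  col <- net$stoich[, j]
  consumed <- which(col < 0)
  produced <- which(col > 0)
  if (!length(consumed)) {
    stop("reaction '", reaction, "' consumes no internal metabolite")
  }
  S <- net$stoich[, -j, drop = FALSE]
  ids <- net$reaction_ids[-j]
  rev <- net$reversible[-j]
  add <- function(S, i, coef) {
    col <- numeric(nrow(S))
    col[i] <- coef
    cbind(S, col)
  }
  for (i in consumed) {
    S <- add(S, i, -1)
    ids <- c(ids, paste0(drain_prefix, net$metabolite_ids[i]))
    rev <- c(rev, FALSE)
  }
  for (i in produced) {
    S <- add(S, i, 1)
    ids <- c(ids, paste0(source_prefix, net$metabolite_ids[i]))
    rev <- c(rev, FALSE)
  }
  metabolic_network(S, ids, net$metabolite_ids, rev)
}
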