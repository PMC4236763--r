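#' Build a flux-cone constraint set
#'
#' Bundles the constraint kinds understood by the LP feasibility engine:
#' reactions forced inactive (`iff`, flux = 0), reactions forced active
#' (`faf`, flux >= 1, which on a cone is equivalent to "> 0" by rescaling),
#' explicit flux lower bounds (`flux_bounds`, rows `v_r >= k`), and
#' activity assignments for nullspace basis columns (`t_signs`, used by the
#' divide-and-conquer partitioning: `"inactive"` pins `t_j = 0`,
#' `"active"` requires `t_j >= 1`; unassigned columns stay free).
#'
#' @param iff integer vector of reaction indices with flux forced to zero.
#' @param faf integer vector of reaction indices with flux forced positive.
#' @param flux_bounds `NULL`, or a two-column matrix/data.frame
#'   (`reaction` index, lower bound `k >= 0`).
#' @param t_signs `NULL`, or a named character vector, names = basis column
#'   indices, values in `c("inactive", "active")`.
#' @return an object of class `constraint_set`.
#' @export
constraint_set <- function(iff = integer(0), faf = integer(0),
                           flux_bounds = NULL, t_signs = NULL) {
  iff <- sort(unique(as.integer(iff)))
  faf <- sort(unique(as.integer(faf)))
  if (length(intersect(iff, faf))) {
    stop("a reaction cannot be both inactive (iff) and active (faf): ",
         paste(intersect(iff, faf), collapse = ", "))
  }
  if (!is.null(flux_bounds)) {
    flux_bounds <- as.matrix(flux_bounds)
    if (ncol(flux_bounds) != 2L) {
      stop("flux_bounds must have two columns: reaction index and bound k")
    }
    colnames(flux_bounds) <- c("reaction", "k")
    if (any(flux_bounds[, "k"] < 0)) stop("flux bounds k must be >= 0")
  }
  if (!is.null(t_signs)) {
    if (is.null(names(t_signs)) || !all(t_signs %in% c("inactive", "active"))) {
      stop("t_signs must be named by column index with values inactive/active")
    }
  }
  structure(list(iff = iff, faf = faf, flux_bounds = flux_bounds,
                 t_signs = t_signs),
            class = "constraint_set")
}

#' @export
print.constraint_set <- function(x, ...) {
  nb <- if (is.null(x$flux_bounds)) 0L else nrow(x$flux_bounds)
  nt <- length(x$t_signs)
  cat(sprintf("Constraint set: %d iff, %d faf, %d flux bound(s), %d t-sign(s)\n",
              length(x$iff), length(x$faf), nb, nt))
  invisible(x)
}

empty_cs <- function() constraint_set()

as_constraint_set <- function(cs) {
  if (is.null(cs)) return(empty_cs())
  stopifnot(inherits(cs, "constraint_set"))
  cs
}

# validate cs indices against a network / basis dimension
check_cs_range <- function(cs, R, dof = NULL) {
  idx <- c(cs$iff, cs$faf,
           if (!is.null(cs$flux_bounds)) cs$flux_bounds[, "reaction"])
  if (length(idx) && (any(idx < 1) || any(idx > R))) {
    stop("constraint reaction index out of range 1..", R)
  }
  if (!is.null(cs$t_signs) && !is.null(dof)) {
    j <- as.integer(names(cs$t_signs))
    if (any(is.na(j)) || any(j < 1) || any(j > dof)) {
      stop("t_signs column index out of range 1..", dof)
    }
  }
  invisible(TRUE)
}

#' Parse textual flux constraints
#'
#' Grammar: `vREACTION>=NUMBER`, e.g. `"vR04>=1"` or `"vvaline_drain>=0.85"`.
#' The reaction id is looked up in the network; the bound must be
#' nonnegative.
#'
#' @param strings character vector of constraint strings.
#' @param net a [metabolic_network()] used to resolve reaction ids.
#' @return a [constraint_set()] carrying the parsed flux bounds.
#' @export
parse_constraints <- function(strings, net) {
  if (!length(strings)) return(empty_cs())
  m <- regmatches(strings, regexec("^v(.+?)>=([0-9.eE+-]+)$", strings))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) {
    stop("cannot parse constraint string(s): ",
         paste(strings[bad], collapse = ", "),
         " (expected vREACTION>=NUMBER)")
  }
  ids <- vapply(m, `[[`, "", 2L)
  ks <- as.numeric(vapply(m, `[[`, "", 3L))
  if (any(!is.finite(ks)) || any(ks < 0)) {
    stop("constraint bounds must be finite and >= 0")
  }
  idx <- reaction_index(net, ids)
  constraint_set(flux_bounds = cbind(reaction = idx, k = ks))
}

#' Serialize / deserialize a constraint set as JSON
#'
#' @param cs a [constraint_set()].
#' @param path file path.
#' @export
write_constraints_json <- function(cs, path) {
  obj <- list(iff = cs$iff, faf = cs$faf)
  if (!is.null(cs$flux_bounds)) {
    obj$flux_bounds <- apply(cs$flux_bounds, 1, function(r) {
      list(reaction = unname(r[1]), k = unname(r[2]))
    })
  }
  if (!is.null(cs$t_signs)) {
    obj$t_signs <- as.list(cs$t_signs)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
}

#' @rdname write_constraints_json
#' @export
read_constraints_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  fb <- NULL
  if (length(obj$flux_bounds)) {
    fb <- do.call(rbind, lapply(obj$flux_bounds, function(e) {
      c(reaction = as.integer(e$reaction), k = as.numeric(e$k))
    }))
  }
  ts <- NULL
  if (length(obj$t_signs)) {
    ts <- vapply(obj$t_signs, as.character, "")
  }
  constraint_set(iff = unlist(obj$iff), faf = unlist(obj$faf),
                 flux_bounds = fb, t_signs = ts)
}
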