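#' Construct a metabolic network
#'
#' A `metabolic_network` couples a stoichiometric matrix `S` (rows = internal
#' metabolites, columns = reactions) with reaction and metabolite identifiers
#' and per-reaction reversibility flags.  External (boundary) metabolites are
#' never represented as rows; exchange with the environment appears as
#' columns with net production or consumption.
#'
#' @param stoich numeric matrix, M metabolites x R reactions.
#' @param reaction_ids character vector of R unique reaction ids.
#' @param metabolite_ids character vector of M unique metabolite ids.
#' @param reversible logical vector of length R.
#' @param drop_zero_columns drop all-zero columns with a warning instead of
#'   failing validation.
#' @return an object of class `metabolic_network` with elements `stoich`,
#'   `reaction_ids`, `metabolite_ids`, `reversible`.
#' @export
#' @examples
#' net <- metabolic_network(
#'   stoich = cbind(c(1, 0), c(-1, 1), c(0, -1)),
#'   reaction_ids = c("uptake", "conv", "drain"),
#'   metabolite_ids = c("A", "B"),
#'   reversible = c(FALSE, FALSE, FALSE)
#' )
#' print(net)
metabolic_network <- function(stoich, reaction_ids, metabolite_ids,
                              reversible = rep(FALSE, ncol(stoich)),
                              drop_zero_columns = FALSE) {
  stoich <- as.matrix(stoich)
  storage.mode(stoich) <- "double"
  if (!all(is.finite(stoich))) {
    stop("stoichiometric coefficients must all be finite numbers")
  }
  if (length(reaction_ids) != ncol(stoich)) {
    stop("reaction_ids length must equal the number of columns of stoich")
  }
  if (length(metabolite_ids) != nrow(stoich)) {
    stop("metabolite_ids length must equal the number of rows of stoich")
  }
  if (anyDuplicated(reaction_ids)) {
    stop("duplicate reaction id: ",
         paste(unique(reaction_ids[duplicated(reaction_ids)]), collapse = ", "))
  }
  if (anyDuplicated(metabolite_ids)) {
    stop("duplicate metabolite id: ",
         paste(unique(metabolite_ids[duplicated(metabolite_ids)]), collapse = ", "))
  }
  if (length(reversible) != ncol(stoich) || !is.logical(reversible)) {
    stop("reversible must be a logical vector of length R")
  }
  if (ncol(stoich) > 0 && nrow(stoich) > 0) {
    zero_col <- colSums(abs(stoich)) == 0
    if (any(zero_col)) {
      if (drop_zero_columns) {
        warning("dropping all-zero reaction column(s): ",
                paste(reaction_ids[zero_col], collapse = ", "))
        stoich <- stoich[, !zero_col, drop = FALSE]
        reaction_ids <- reaction_ids[!zero_col]
        reversible <- reversible[!zero_col]
      } else {
        stop("all-zero stoichiometry for reaction(s): ",
             paste(reaction_ids[zero_col], collapse = ", "))
      }
    }
  }
  dimnames(stoich) <- list(metabolite_ids, reaction_ids)
  structure(
    list(stoich = stoich,
         reaction_ids = as.character(reaction_ids),
         metabolite_ids = as.character(metabolite_ids),
         reversible = as.logical(reversible)),
    class = "metabolic_network"
  )
}

#' @export
print.metabolic_network <- function(x, ...) {
  cat(sprintf(
    "Metabolic network: %d internal metabolites x %d reactions (%d reversible)\n",
    length(x$metabolite_ids), length(x$reaction_ids), sum(x$reversible)))
  invisible(x)
}

#' @export
summary.metabolic_network <- function(object, ...) {
  S <- object$stoich
  dof <- ncol(S) - rank_of(S)
  cat(sprintf(
    "Metabolic network: M = %d, R = %d, rank(S) = %d, DoF = %d, reversible = %d\n",
    nrow(S), ncol(S), ncol(S) - dof, dof, sum(object$reversible)))
  invisible(list(M = nrow(S), R = ncol(S), dof = dof))
}

n_reactions <- function(net) length(net$reaction_ids)
n_metabolites <- function(net) length(net$metabolite_ids)

reaction_index <- function(net, id) {
  i <- match(id, net$reaction_ids)
  if (any(is.na(i))) {
    stop("unknown reaction id: ", paste(id[is.na(i)], collapse = ", "))
  }
  i
}

#' Read a metabolic model from file
#'
#' Supported dialects:
#' \describe{
#'   \item{json}{`{"metabolites":[{"id":..,"external":bool}],
#'     "reactions":[{"id":.., "stoich":{met: coef, ..}, "reversible":bool}]}`.
#'     Metabolites flagged `external` are excluded from the stoichiometric
#'     rows.}
#'   \item{tsv}{one reaction per line, `id<TAB>equation<TAB>R|I`, equation
#'     grammar `a M1 + b M2 -> c M3` with implicit coefficient 1; metabolite
#'     ids prefixed `x_` are external.}
#'   \item{sbml}{SBML Level 3 (read-only); species with
#'     `boundaryCondition="true"` are treated as external.}
#' }
#'
#' @param path file path.
#' @param format one of `"json"`, `"tsv"`, `"sbml"`; default guessed from the
#'   file extension.
#' @return a validated [metabolic_network()]; metabolite and reaction order
#'   follows file order.
#' @export
read_network <- function(path, format = c("guess", "json", "tsv", "sbml")) {
  format <- match.arg(format)
  if (format == "guess") {
    format <- switch(tolower(tools::file_ext(path)),
                     json = "json", tsv = "tsv", txt = "tsv",
                     xml = "sbml", sbml = "sbml",
                     stop("cannot guess model format from extension of ", path))
  }
  if (!file.exists(path)) stop("model file not found: ", path)
  switch(format,
         json = read_network_json(path),
         tsv = read_network_tsv(path),
         sbml = read_network_sbml(path))
}

read_network_json <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(doc$metabolites) || is.null(doc$reactions)) {
    stop("JSON model must contain 'metabolites' and 'reactions' arrays")
  }
  met_ids <- vapply(doc$metabolites, function(m) as.character(m$id), "")
  ext <- vapply(doc$metabolites, function(m) isTRUE(m$external), TRUE)
  internal <- met_ids[!ext]
  R <- length(doc$reactions)
  rxn_ids <- vapply(doc$reactions, function(r) as.character(r$id), "")
  rev <- vapply(doc$reactions, function(r) isTRUE(r$reversible), TRUE)
  S <- matrix(0, length(internal), R)
  for (j in seq_len(R)) {
    st <- doc$reactions[[j]]$stoich
    for (met in names(st)) {
      coef <- st[[met]]
      if (!is.numeric(coef) || length(coef) != 1L || !is.finite(coef)) {
        stop("non-finite stoichiometric coefficient for metabolite '", met,
             "' in reaction '", rxn_ids[j], "'")
      }
      k <- match(met, internal)
      if (!is.na(k)) S[k, j] <- S[k, j] + coef
      else if (!met %in% met_ids) {
        stop("reaction '", rxn_ids[j], "' references unknown metabolite '",
             met, "'")
      }
    }
  }
  metabolic_network(S, rxn_ids, internal, rev, drop_zero_columns = TRUE)
}

parse_equation_side <- function(side, line_no) {
  side <- trimws(side)
  if (side == "") return(list(mets = character(0), coefs = numeric(0)))
  terms <- strsplit(side, "\\+")[[1]]
  mets <- character(0)
  coefs <- numeric(0)
  for (term in terms) {
    term <- trimws(term)
    if (term == "") {
      stop("malformed equation (empty term) at line ", line_no)
    }
    parts <- strsplit(term, "[[:space:]]+")[[1]]
    if (length(parts) == 1L) {
      coef <- 1
      met <- parts[1L]
    } else if (length(parts) == 2L) {
      coef <- suppressWarnings(as.numeric(parts[1L]))
      if (is.na(coef)) {
        stop("malformed coefficient '", parts[1L], "' at line ", line_no)
      }
      met <- parts[2L]
    } else {
      stop("malformed equation term '", term, "' at line ", line_no)
    }
    if (!is.finite(coef)) {
      stop("non-finite stoichiometric coefficient at line ", line_no)
    }
    mets <- c(mets, met)
    coefs <- c(coefs, coef)
  }
  list(mets = mets, coefs = coefs)
}

read_network_tsv <- function(path) {
  lines <- readLines(path)
  lines <- lines[trimws(lines) != "" & !startsWith(trimws(lines), "#")]
  rxn_ids <- character(0)
  rev <- logical(0)
  terms <- list()
  for (k in seq_along(lines)) {
    fields <- strsplit(lines[k], "\t", fixed = TRUE)[[1]]
    if (length(fields) != 3L) {
      stop("expected 3 tab-separated fields at line ", k, " of ", path)
    }
    if (!fields[3] %in% c("R", "I")) {
      stop("reversibility flag must be R or I at line ", k)
    }
    sides <- strsplit(fields[2], "->", fixed = TRUE)[[1]]
    if (length(sides) > 2L) stop("multiple '->' at line ", k)
    if (length(sides) == 1L) {
      sides <- c(sides, "")
      if (!grepl("->", fields[2], fixed = TRUE)) {
        stop("equation lacks '->' at line ", k)
      }
    }
    lhs <- parse_equation_side(sides[1], k)
    rhs <- parse_equation_side(if (length(sides) >= 2) sides[2] else "", k)
    rxn_ids <- c(rxn_ids, fields[1])
    rev <- c(rev, fields[3] == "R")
    terms[[k]] <- list(mets = c(lhs$mets, rhs$mets),
                       coefs = c(-lhs$coefs, rhs$coefs))
  }
  all_mets <- unique(unlist(lapply(terms, `[[`, "mets")))
  internal <- all_mets[!startsWith(all_mets, "x_")]
  S <- matrix(0, length(internal), length(rxn_ids))
  for (j in seq_along(terms)) {
    t <- terms[[j]]
    for (i in seq_along(t$mets)) {
      k <- match(t$mets[i], internal)
      if (!is.na(k)) S[k, j] <- S[k, j] + t$coefs[i]
    }
  }
  metabolic_network(S, rxn_ids, internal, rev, drop_zero_columns = TRUE)
}

read_network_sbml <- function(path) {
  if (!requireNamespace("xml2", quietly = TRUE)) {
    stop("SBML import requires the xml2 package")
  }
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "s")
  species <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
  met_ids <- xml2::xml_attr(species, "id")
  boundary <- xml2::xml_attr(species, "boundaryCondition") %in% c("true", "1")
  internal <- met_ids[!boundary]
  rxns <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)
  rxn_ids <- xml2::xml_attr(rxns, "id")
  rev <- xml2::xml_attr(rxns, "reversible") %in% c("true", "1")
  S <- matrix(0, length(internal), length(rxns))
  for (j in seq_along(rxns)) {
    for (side in c("listOfReactants", "listOfProducts")) {
      sr <- xml2::xml_find_all(
        rxns[[j]], sprintf("./s:%s/s:speciesReference", side), ns)
      sgn <- if (side == "listOfReactants") -1 else 1
      for (ref in sr) {
        met <- xml2::xml_attr(ref, "species")
        coef <- xml2::xml_attr(ref, "stoichiometry")
        coef <- if (is.na(coef)) 1 else as.numeric(coef)
        if (!is.finite(coef)) {
          stop("non-finite stoichiometry in reaction ", rxn_ids[j])
        }
        k <- match(met, internal)
        if (!is.na(k)) S[k, j] <- S[k, j] + sgn * coef
      }
    }
  }
  metabolic_network(S, rxn_ids, internal, rev, drop_zero_columns = TRUE)
}

#' Write a metabolic model to the canonical JSON dialect
#'
#' @param net a [metabolic_network()].
#' @param path output file path.
#' @export
write_network_json <- function(net, path) {
  mets <- lapply(net$metabolite_ids, function(id) {
    list(id = id, external = FALSE)
  })
  rxns <- lapply(seq_along(net$reaction_ids), function(j) {
    col <- net$stoich[, j]
    nz <- which(col != 0)
    st <- as.list(col[nz])
    names(st) <- net$metabolite_ids[nz]
    list(id = net$reaction_ids[j], stoich = st,
         reversible = net$reversible[j])
  })
  jsonlite::write_json(list(metabolites = mets, reactions = rxns), path,
                       auto_unbox = TRUE, digits = NA)
}

#' Split reversible reactions into irreversible pairs
#'
#' Each reversible reaction is decomposed into an opposing pair of
#' irreversible reactions: the forward column keeps the original id, the
#' backward column is its negation and receives the suffix `"_rev"`.
#'
#' @param net a [metabolic_network()].
#' @return a `metabolic_network` with all reactions irreversible and an
#'   attribute `"split_map"`: a named list mapping each originally reversible
#'   reaction id to its `c(forward, backward)` id pair.
#' @export
split_reversible <- function(net) {
  rev_idx <- which(net$reversible)
  if (!length(rev_idx)) {
    out <- net
    attr(out, "split_map") <- list()
    return(out)
  }
  back_ids <- paste0(net$reaction_ids[rev_idx], "_rev")
  clash <- back_ids %in% net$reaction_ids
  if (any(clash)) {
    stop("backward id collision for: ", paste(back_ids[clash], collapse = ", "))
  }
  S <- cbind(net$stoich, -net$stoich[, rev_idx, drop = FALSE])
  ids <- c(net$reaction_ids, back_ids)
  out <- metabolic_network(S, ids, net$metabolite_ids,
                           rep(FALSE, ncol(S)))
  split_map <- stats::setNames(
    lapply(seq_along(rev_idx),
           function(k) c(net$reaction_ids[rev_idx[k]], back_ids[k])),
    net$reaction_ids[rev_idx])
  attr(out, "split_map") <- split_map
  out
}

#' Permute the reaction order of a network
#'
#' Deterministic column permutation drawn from `seed`; the convention
#' `seed = 0` yields the identity permutation.  The EFM set of the network is
#' invariant under permutation up to relabeling.
#'
#' @param net a [metabolic_network()].
#' @param seed integer seed (0 = identity).
#' @return the permuted network, with attribute `"perm"` holding the column
#'   permutation applied (new order as indices into the old).
#' @export
permute_reactions <- function(net, seed = 0L) {
  R <- n_reactions(net)
  if (seed == 0L) {
    perm <- seq_len(R)
  } else {
    perm <- with_seed(seed, sample.int(R))
  }
  out <- metabolic_network(net$stoich[, perm, drop = FALSE],
                           net$reaction_ids[perm],
                           net$metabolite_ids,
                           net$reversible[perm])
  attr(out, "perm") <- perm
  out
}

# evaluate expr under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
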