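#' Built-in fixture networks
#'
#' Three small irreversible networks used throughout tests, examples and the
#' vignette:
#' \describe{
#'   \item{`fixture_chain()`}{a 3-reaction linear chain
#'     (uptake, conversion, drain) with a single EFM `(1, 1, 1)`.}
#'   \item{`fixture_diamond()`}{a 6-reaction diamond (uptake `r1`, two
#'     branches `r2`/`r3` re-merging via `r4`/`r5`, drain `r6`) with two
#'     EFMs, one per branch.}
#'   \item{`fixture_toy()`}{a SYNTHETIC 14-reaction, 8-metabolite worked
#'     example constructed for this package.  It is a reconstruction built
#'     to match a published toy network's stated summary properties — 8
#'     internal metabolites, 14 irreversible reactions, nullity (DoF) 6,
#'     exactly 9 EFMs, and the forced-activity relation "with R01 fixed
#'     active and R02 inactive, R04 must be active" — but its wiring is this
#'     package's own construction, not a transcription of any published
#'     figure.  The network is a branched conversion route from a single
#'     substrate uptake (R01) to a single product drain (R11) with
#'     alternative internal branches.}
#' }
#'
#' @return a [metabolic_network()].
#' @export
fixture_chain <- function() {
  metabolic_network(cbind(c(1, 0), c(-1, 1), c(0, -1)),
                    c("r1", "r2", "r3"), c("A", "B"))
}

#' @rdname fixture_chain
#' @export
fixture_diamond <- function() {
  S <- matrix(0, 4, 6, dimnames = list(c("A", "B", "C", "D"), NULL))
  S["A", 1] <- 1
  S["A", 2] <- -1; S["B", 2] <- 1
  S["A", 3] <- -1; S["C", 3] <- 1
  S["B", 4] <- -1; S["D", 4] <- 1
  S["C", 5] <- -1; S["D", 5] <- 1
  S["D", 6] <- -1
  metabolic_network(S, paste0("r", 1:6), rownames(S))
}

#' @rdname fixture_chain
#' @export
fixture_toy <- function() {
  mets <- LETTERS[1:8]
  edges <- list(
    R01 = c(NA, "A"),    # uptake -> A
    R02 = c("A", "B"),
    R03 = c("A", "C"),
    R04 = c("C", "D"),
    R05 = c("B", "D"),
    R06 = c("D", "E"),
    R07 = c("E", "F"),
    R08 = c("E", "G"),
    R09 = c("F", "H"),
    R10 = c("G", "H"),
    R11 = c("H", NA),    # H -> drain
    R12 = c("B", "F"),
    R13 = c("D", "G"),
    R14 = c("E", "H")
  )
  S <- matrix(0, 8, length(edges), dimnames = list(mets, names(edges)))
  for (j in seq_along(edges)) {
    e <- edges[[j]]
    if (!is.na(e[1])) S[e[1], j] <- S[e[1], j] - 1
    if (!is.na(e[2])) S[e[2], j] <- S[e[2], j] + 1
  }
  metabolic_network(S, names(edges), mets)
}

#' Write the fixture networks to a directory as canonical JSON models
#'
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_fixture_models <- function(dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(chain = file.path(dir, "chain.json"),
             diamond = file.path(dir, "diamond.json"),
             toy_synthetic = file.path(dir, "toy_synthetic.json"))
  write_network_json(fixture_chain(), paths["chain"])
  write_network_json(fixture_diamond(), paths["diamond"])
  write_network_json(fixture_toy(), paths["toy_synthetic"])
  invisible(paths)
}
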