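#' Elementary flux mode set
#'
#' Container for a set of EFMs over a fixed reaction list.  Flux vectors are
#' stored row-wise, each normalized so its smallest positive entry equals
#' one; the binary support matrix is derived on demand.
#'
#' @param fluxes numeric matrix, one EFM per row, R columns.
#' @param reaction_ids character vector of R reaction ids.
#' @param zero_tol entries below `zero_tol * max(row)` count as zero.
#' @return object of class `efm_set`.
#' @export
efm_set <- function(fluxes, reaction_ids, zero_tol = 1e-9) {
  fluxes <- as.matrix(fluxes)
  if (nrow(fluxes) > 0) {
    stopifnot(ncol(fluxes) == length(reaction_ids))
    colnames(fluxes) <- reaction_ids
  } else {
    fluxes <- matrix(0, 0, length(reaction_ids),
                     dimnames = list(NULL, reaction_ids))
  }
  structure(list(fluxes = fluxes, reaction_ids = reaction_ids,
                 zero_tol = zero_tol),
            class = "efm_set")
}

#' @export
print.efm_set <- function(x, ...) {
  cat(sprintf("EFM set: %d mode(s) over %d reactions\n",
              nrow(x$fluxes), length(x$reaction_ids)))
  invisible(x)
}

#' @export
summary.efm_set <- function(object, ...) {
  sup <- efm_supports(object)
  len <- rowSums(sup)
  cat(sprintf("EFM set: %d mode(s) over %d reactions\n",
              nrow(sup), ncol(sup)))
  if (nrow(sup)) {
    cat(sprintf("  support size: min %d, median %g, max %d\n",
                min(len), stats::median(len), max(len)))
    cat(sprintf("  reactions used in at least one mode: %d\n",
                sum(colSums(sup) > 0)))
  }
  invisible(list(n = nrow(sup), support_sizes = len))
}

#' @export
length.efm_set <- function(x) nrow(x$fluxes)

#' @export
as.matrix.efm_set <- function(x, ...) x$fluxes

#' Binary support matrix of an EFM set
#'
#' @param efms an [efm_set()].
#' @return logical matrix, rows = EFMs, columns = reactions.
#' @export
efm_supports <- function(efms) {
  fl <- efms$fluxes
  if (!nrow(fl)) {
    return(matrix(FALSE, 0, length(efms$reaction_ids),
                  dimnames = list(NULL, efms$reaction_ids)))
  }
  mx <- apply(abs(fl), 1, max)
  fl > efms$zero_tol * pmax(mx, 1e-300)
}

#' Canonical support keys of an EFM set
#'
#' One string per mode listing its active reaction indices, used for exact
#' set comparison across enumerations.
#'
#' @param efms an [efm_set()].
#' @return character vector of keys like `"1,4,6"`.
#' @export
support_keys <- function(efms) {
  sup <- efm_supports(efms)
  apply(sup, 1, function(r) paste(which(r), collapse = ","))
}

#' Compare two EFM sets by support
#'
#' @param a,b [efm_set()] objects over the same reaction list.
#' @return `TRUE` iff the two sets contain exactly the same supports.
#' @export
same_efm_sets <- function(a, b) {
  setequal(support_keys(a), support_keys(b))
}

# normalize each row: smallest positive entry = 1, tiny entries zeroed
normalize_efm_rows <- function(fluxes, zero_tol = 1e-9) {
  if (!nrow(fluxes)) return(fluxes)
  t(apply(fluxes, 1, function(v) {
    v[abs(v) < zero_tol * max(abs(v), 1e-300)] <- 0
    if (any(v > 0)) v <- v / min(v[v > 0])
    v
  }))
}

#' Write / read an EFM set (MatrixMarket supports + TSV fluxes)
#'
#' `write_efm_set` writes `<prefix>.mtx` (sparse binary support matrix,
#' rows = EFMs, columns = reactions) and `<prefix>.tsv` (normalized flux
#' values with a reaction-id header).  `read_efm_set` reads the TSV back.
#'
#' @param efms an [efm_set()].
#' @param prefix output path prefix.
#' @export
write_efm_set <- function(efms, prefix) {
  sup <- Matrix::Matrix(efm_supports(efms) * 1, sparse = TRUE)
  Matrix::writeMM(sup, paste0(prefix, ".mtx"))
  df <- as.data.frame(efms$fluxes)
  utils::write.table(df, paste0(prefix, ".tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(prefix)
}

#' @rdname write_efm_set
#' @param path path to a `.tsv` written by `write_efm_set`.
#' @export
read_efm_set <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE)
  efm_set(as.matrix(df), colnames(df))
}
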