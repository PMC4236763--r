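#' Partition an enumeration into exclusive sub-jobs
#'
#' The flux space is divided into exclusive subspaces by controlling the
#' participation of chosen nullspace basis columns: each chosen column is
#' fixed either inactive (`t_j = 0`) or active (`t_j >= 1`; equivalent to
#' "> 0" on the cone), giving `2^k` sub-jobs that partition the EFM set.
#' With an RREF basis a column's assignment fixes whether its pivot reaction
#' is inactive or active, so the jobs partition EFMs by pivot-reaction
#' activity pattern.
#'
#' @param basis a [nullspace_basis()].
#' @param columns column indices to constrain.  Default: for an `"efm"`
#'   basis, its sign-free columns (the ones useful for splitting); for an
#'   `"rref"` basis an explicit choice is required.
#' @return list of `efm_job` descriptors: `job_id`, `t_signs`,
#'   `basis_kind`, `extra_constraints` (`NULL` placeholder for flux bounds).
#' @export
partition_jobs <- function(basis, columns = NULL) {
  stopifnot(inherits(basis, "nullspace_basis"))
  if (is.null(columns)) {
    if (basis$kind == "efm") columns <- basis$sign_free_columns
    else stop("choose the basis columns to split on (rref basis)")
  }
  columns <- as.integer(columns)
  if (anyDuplicated(columns)) stop("split columns must be distinct")
  if (length(columns) &&
      (min(columns) < 1L || max(columns) > basis$dof)) {
    stop("split columns out of range 1..", basis$dof)
  }
  if (length(columns) > 20L) {
    stop("refusing to split on ", length(columns),
         " columns (2^k job explosion); choose at most 20")
  }
  k <- length(columns)
  n_jobs <- 2L^k
  lapply(seq_len(n_jobs) - 1L, function(code) {
    bits <- if (k) as.integer(intToBits(code))[seq_len(k)] else integer(0)
    signs <- ifelse(bits == 1L, "active", "inactive")
    names(signs) <- as.character(columns)
    structure(list(job_id = sprintf("job%04d", code + 1L),
                   t_signs = if (k) signs else NULL,
                   basis_kind = basis$kind,
                   extra_constraints = NULL),
              class = "efm_job")
  })
}

#' @export
print.efm_job <- function(x, ...) {
  cat(sprintf("EFM sub-job %s (%s basis): %s\n", x$job_id, x$basis_kind,
              if (is.null(x$t_signs)) "no column constrained" else
                paste(names(x$t_signs), x$t_signs, sep = "=",
                      collapse = ", ")))
  invisible(x)
}

#' Run one enumeration sub-job
#'
#' Merges the job's t-sign assignments (and any extra constraints) into the
#' constraint set and runs [enumerate_efms()].  The result is tagged with
#' the job id.
#'
#' @param net an irreversible [metabolic_network()].
#' @param job an `efm_job` from [partition_jobs()].
#' @param basis the [nullspace_basis()] the job was created from.
#' @param cs optional extra [constraint_set()].
#' @param ... passed to [enumerate_efms()].
#' @return an [efm_set()] with attribute `"job_id"`.
#' @export
run_job <- function(net, job, basis, cs = NULL, ...) {
  stopifnot(inherits(job, "efm_job"))
  cs <- as_constraint_set(cs)
  ts <- c(cs$t_signs, job$t_signs)
  if (anyDuplicated(names(ts))) {
    stop("job and user constraints assign the same basis column")
  }
  ecs <- job$extra_constraints
  if (!is.null(ecs)) {
    cs2 <- constraint_set(iff = c(cs$iff, ecs$iff),
                          faf = c(cs$faf, ecs$faf),
                          flux_bounds = rbind(cs$flux_bounds,
                                              ecs$flux_bounds),
                          t_signs = ts)
  } else {
    cs2 <- constraint_set(iff = cs$iff, faf = cs$faf,
                          flux_bounds = cs$flux_bounds, t_signs = ts)
  }
  out <- enumerate_efms(net, cs2, basis = basis, ...)
  attr(out, "job_id") <- job$job_id
  out
}

#' Merge sub-job results, verifying exclusivity
#'
#' Concatenates partial EFM sets from one split, verifies that no support
#' appears in more than one part (the sub-jobs must not overlap), and
#' reports per-job counts.
#'
#' @param parts list of [efm_set()] objects from [run_job()].
#' @return an [efm_set()] with attribute `"job_counts"`.
#' @export
merge_jobs <- function(parts) {
  stopifnot(length(parts) >= 1L)
  keys <- unlist(lapply(parts, support_keys))
  if (anyDuplicated(keys)) {
    stop("duplicate support across sub-jobs (",
         keys[duplicated(keys)][1L],
         "); the split is not exclusive")
  }
  fluxes <- do.call(rbind, lapply(parts, function(p) p$fluxes))
  out <- efm_set(fluxes, parts[[1L]]$reaction_ids, parts[[1L]]$zero_tol)
  counts <- vapply(parts, length, 1L)
  names(counts) <- vapply(seq_along(parts), function(i) {
    id <- attr(parts[[i]], "job_id")
    if (is.null(id)) sprintf("part%d", i) else id
  }, "")
  attr(out, "job_counts") <- counts
  out
}

#' Write / read job descriptors as a jobs directory
#'
#' One JSON descriptor per job plus a `manifest.json` holding the split
#' definition, so any scheduler (or a shell loop) can dispatch the jobs.
#'
#' @param jobs list of `efm_job` descriptors.
#' @param dir directory (created if needed).
#' @export
write_jobs <- function(jobs, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- vapply(jobs, function(j) {
    path <- file.path(dir, paste0(j$job_id, ".json"))
    obj <- unclass(j)
    # a length-one named vector would lose its name under auto_unbox
    if (!is.null(obj$t_signs)) obj$t_signs <- as.list(obj$t_signs)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
    path
  }, "")
  manifest <- list(n_jobs = length(jobs),
                   job_files = basename(files),
                   basis_kind = jobs[[1L]]$basis_kind,
                   columns = names(jobs[[1L]]$t_signs))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(files)
}

#' @rdname write_jobs
#' @param path path to one job JSON file.
#' @export
read_job <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  ts <- NULL
  if (length(obj$t_signs)) ts <- vapply(obj$t_signs, as.character, "")
  structure(list(job_id = obj$job_id, t_signs = ts,
                 basis_kind = obj$basis_kind,
                 extra_constraints = NULL),
            class = "efm_job")
}
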