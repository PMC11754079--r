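#' Read voltage-clamp sweeps from a container
#'
#' Two on-disk forms are supported. The native container is an HDF5 file with
#' one group per sweep under `/sweeps/<id>/`, a `samples` dataset, and the
#' acquisition parameters plus all metadata stored as group attributes. A plain
#' CSV is accepted for single sweeps: `#key=value` header lines (which must
#' declare `sampling_rate`) followed by a one-column table of current samples.
#'
#' @param path File path.
#' @param format `"hdf5"` or `"csv"`.
#' @return A list of [sweep_recording] objects.
#' @seealso [write_sweeps()]
#' @export
read_sweeps <- function(path, format = c("hdf5", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (format == "csv") list(read_sweep_csv(path)) else read_sweeps_h5(path)
}

meta_fields <- c("cell_id", "animal_id", "genotype", "zeitgeber_time",
                 "circuit", "drug", "polarity", "units")

read_sweeps_h5 <- function(path) {
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  contents <- rhdf5::h5ls(path)
  if (!any(contents$name == "sweeps" & contents$group == "/")) {
    stop("not a sweep container: missing /sweeps group")
  }
  ids <- sort(contents$name[contents$group == "/sweeps"])
  lapply(ids, function(id) {
    grp <- paste0("/sweeps/", id)
    samples <- as.numeric(rhdf5::h5read(path, paste0(grp, "/samples")))
    at <- rhdf5::h5readAttributes(path, grp)
    if (is.null(at$sampling_rate)) stop(sprintf("sampling rate undeclared for sweep '%s'", id))
    meta <- at[intersect(names(at), meta_fields)]
    meta <- lapply(meta, function(v) if (is.array(v)) as.vector(v) else v)
    sweep_recording(samples,
                    sampling_rate = as.numeric(at$sampling_rate),
                    holding_potential = as.numeric(at$holding_potential %||% NA_real_),
                    meta = meta)
  })
}

read_sweep_csv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  kv <- list()
  for (h in hdr) {
    m <- regmatches(h, regexec("^#\\s*([A-Za-z_]+)\\s*=\\s*(.*)$", h))[[1]]
    if (length(m) == 3) kv[[m[2]]] <- m[3]
  }
  if (is.null(kv$sampling_rate)) stop("sampling rate undeclared")
  body <- lines[!grepl("^#", lines)]
  tab <- utils::read.csv(text = paste(body, collapse = "\n"))
  samples <- as.numeric(tab[[1]])
  meta <- kv[intersect(names(kv), meta_fields)]
  if (!is.null(meta$zeitgeber_time)) meta$zeitgeber_time <- as.numeric(meta$zeitgeber_time)
  sweep_recording(samples, sampling_rate = as.numeric(kv$sampling_rate),
                  holding_potential = as.numeric(kv$holding_potential %||% NA_real_),
                  meta = meta)
}

#' Write voltage-clamp sweeps to a container
#'
#' Inverse of [read_sweeps()]: `read_sweeps(write_sweeps(recs, path))`
#' reproduces samples and metadata exactly (HDF5 stores doubles losslessly).
#' Sweeps with different sampling rates may share one container. An empty list
#' produces a valid empty container.
#'
#' @param recs List of [sweep_recording] objects.
#' @param path Output path.
#' @param format `"hdf5"` or `"csv"` (CSV accepts a single sweep only).
#' @return `path`, invisibly.
#' @export
write_sweeps <- function(recs, path, format = c("hdf5", "csv")) {
  format <- match.arg(format)
  stopifnot(all(vapply(recs, inherits, logical(1), "sweep_recording")))
  if (format == "csv") {
    if (length(recs) != 1) stop("CSV format accepts exactly one sweep")
    return(write_sweep_csv(recs[[1]], path))
  }
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5createGroup(path, "sweeps")
  ids <- vapply(seq_along(recs), function(i) {
    recs[[i]]$meta$cell_id %||% sprintf("sweep%04d", i)
  }, character(1))
  if (anyDuplicated(ids)) ids <- sprintf("%s_%04d", ids, seq_along(ids))
  for (i in seq_along(recs)) {
    rec <- recs[[i]]
    grp <- paste0("sweeps/", ids[i])
    rhdf5::h5createGroup(path, grp)
    rhdf5::h5write(rec$samples, path, paste0(grp, "/samples"))
    fid <- rhdf5::H5Fopen(path)
    gid <- rhdf5::H5Gopen(fid, grp)
    rhdf5::h5writeAttribute(rec$sampling_rate, gid, "sampling_rate")
    rhdf5::h5writeAttribute(rec$holding_potential, gid, "holding_potential")
    for (nm in intersect(names(rec$meta), meta_fields)) {
      if (!is.null(rec$meta[[nm]]) && !is.na(rec$meta[[nm]])[1]) {
        rhdf5::h5writeAttribute(rec$meta[[nm]], gid, nm)
      }
    }
    rhdf5::H5Gclose(gid)
    rhdf5::H5Fclose(fid)
  }
  invisible(path)
}

write_sweep_csv <- function(rec, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#sampling_rate=%.10g", rec$sampling_rate), con)
  if (!is.na(rec$holding_potential)) {
    writeLines(sprintf("#holding_potential=%.10g", rec$holding_potential), con)
  }
  for (nm in intersect(names(rec$meta), meta_fields)) {
    v <- rec$meta[[nm]]
    if (!is.null(v) && !is.na(v)[1]) writeLines(sprintf("#%s=%s", nm, as.character(v)), con)
  }
  writeLines("current", con)
  writeLines(format(rec$samples, digits = 17, scientific = TRUE, trim = TRUE), con)
  invisible(path)
}
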