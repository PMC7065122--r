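# Dataset containers.
#
# Two interchangeable on-disk formats, both lossless for complex
# double data:
#   * "rds"  — a single serialized R object;
#   * "dir"  — a directory with a JSON header (schedule, shapes) and
#     one raw binary file per group (little-endian interleaved
#     re/im doubles), mirroring the group layout of an HDF5/NPZ
#     container: kspace, navigators, reacq, reacq_navigators, truth.

write_cplx <- function(x, path) {
  dms <- dim(x)
  con <- file(path, "wb")
  on.exit(close(con))
  v <- as.complex(x)
  writeBin(as.double(rbind(Re(v), Im(v))), con, size = 8, endian = "little")
  invisible(dms)
}

read_cplx <- function(path, dims) {
  n <- prod(dims)
  con <- file(path, "rb")
  on.exit(close(con))
  raw <- readBin(con, "double", n = 2L * n, size = 8, endian = "little")
  z <- complex(real = raw[c(TRUE, FALSE)], imaginary = raw[c(FALSE, TRUE)])
  array(z, dim = dims)
}

#' Write a k-space dataset to disk
#'
#' @param dataset a `kspace_dataset`.
#' @param path output path (file for `"rds"`, directory for `"dir"`).
#' @param format `"rds"` (single file) or `"dir"` (JSON header plus
#'   raw complex binaries, one per group).
#' @return `path`, invisibly.  Round trips are bit-exact.
#' @export
write_dataset <- function(dataset, path, format = c("rds", "dir")) {
  format <- match.arg(format)
  if (format == "rds") {
    saveRDS(dataset, path)
    return(invisible(path))
  }
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  groups <- list(kspace = dataset$data,
                 navigators = dataset$navigators,
                 reacq = dataset$reacq_data,
                 reacq_navigators = dataset$reacq_navigators)
  shapes <- list()
  for (g in names(groups)) {
    if (is.null(groups[[g]])) next
    write_cplx(groups[[g]], file.path(path, paste0(g, ".cplx")))
    shapes[[g]] <- dim(groups[[g]])
  }
  sch <- dataset$schedule
  header <- list(
    shapes = shapes,
    schedule = list(matrix_size = unname(sch$matrix_size),
                    partial_fourier = sch$partial_fourier,
                    acquired_ky = sch$acquired_ky,
                    center_line = sch$center_line,
                    n_slices = sch$n_slices, tr_s = sch$tr_s,
                    echo_spacing_ms = sch$echo_spacing_ms,
                    n_imaging_echoes = sch$n_imaging_echoes,
                    navigator_echo_index = sch$navigator_echo_index,
                    n_reacq_trs = sch$n_reacq_trs,
                    n_prep_trs = sch$n_prep_trs),
    reacq_trs = dataset$reacq_trs,
    truth = if (is.null(dataset$truth)) NULL else list(
      events = dataset$truth$motion$events,
      drift = dataset$truth$motion$drift,
      corrupted_trs = dataset$truth$corrupted_trs),
    noise_sd = dataset$noise_sd,
    rng_seed = dataset$rng_seed
  )
  writeLines(jsonlite::toJSON(header, auto_unbox = TRUE, digits = NA),
             file.path(path, "header.json"))
  invisible(path)
}

#' Read a k-space dataset from disk
#'
#' @param path path written by [write_dataset()].
#' @param format `"rds"` or `"dir"` (guessed from the path when
#'   missing: directories are `"dir"`).
#' @return the `kspace_dataset`; errors name any missing group.
#' @export
read_dataset <- function(path, format = NULL) {
  if (is.null(format)) format <- if (dir.exists(path)) "dir" else "rds"
  if (format == "rds") {
    ds <- readRDS(path)
    if (!inherits(ds, "kspace_dataset")) stop("not a kspace_dataset rds")
    return(ds)
  }
  hfile <- file.path(path, "header.json")
  if (!file.exists(hfile)) stop("malformed container: missing group header.json")
  h <- jsonlite::fromJSON(readLines(hfile), simplifyVector = TRUE)
  need <- c("navigators")
  for (g in need) {
    if (is.null(h$shapes[[g]]) ||
          !file.exists(file.path(path, paste0(g, ".cplx")))) {
      stop("malformed container: missing group /", g)
    }
  }
  sch <- h$schedule
  schedule <- mese_schedule(
    matrix_size = sch$matrix_size,
    partial_fourier = sch$partial_fourier,
    n_slices = sch$n_slices, tr_s = sch$tr_s,
    echo_spacing_ms = sch$echo_spacing_ms,
    n_imaging_echoes = sch$n_imaging_echoes,
    n_reacq_trs = sch$n_reacq_trs, n_prep_trs = sch$n_prep_trs)
  get <- function(g) {
    f <- file.path(path, paste0(g, ".cplx"))
    if (is.null(h$shapes[[g]]) || !file.exists(f)) return(NULL)
    read_cplx(f, h$shapes[[g]])
  }
  truth <- NULL
  if (!is.null(h$truth)) {
    ev <- h$truth$events
    if (NROW(ev) == 0L) ev <- NULL
    truth <- list(
      motion = motion_spec(ev, drift = h$truth$drift),
      corrupted_trs = as.logical(h$truth$corrupted_trs))
  }
  structure(list(
    data = get("kspace"),
    navigators = get("navigators"),
    schedule = schedule,
    reacq_data = get("reacq"),
    reacq_navigators = get("reacq_navigators"),
    reacq_trs = h$reacq_trs,
    truth = truth,
    noise_sd = h$noise_sd,
    rng_seed = h$rng_seed
  ), class = "kspace_dataset")
}
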