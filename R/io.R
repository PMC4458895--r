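# Readers and writers for the package's plain-text and TIFF interchange
# formats, plus config snapshots with seeds for reproducibility.
#
# CSV dialect: comma-separated, '.' decimal, UTF-8, header mandatory.
# Lengths are stored in nm; angstroms appear only in presentation output.

check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort_input(sprintf("%s is missing column(s): %s", what,
                        paste(missing, collapse = ", ")))
  }
}

#' Read / write a force-extension trace CSV
#'
#' Columns `time_s`, `extension_nm`, `force_pN` (header mandatory).
#' Reading validates the schema and that extension is non-decreasing.
#'
#' @param path File path.
#' @return `read_trace_csv()`: a tibble of class `fx_trace`.
#' @export
read_trace_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  check_columns(df, c("time_s", "extension_nm", "force_pN"), "trace CSV")
  if (any(diff(df$extension_nm) < -1e-9)) {
    abort_input("`extension_nm` must be non-decreasing")
  }
  class(df) <- c("fx_trace", class(df))
  df
}

#' @rdname read_trace_csv
#' @param trace Data frame with `time_s`, `extension_nm`, `force_pN`.
#' @export
write_trace_csv <- function(trace, path) {
  check_columns(trace, c("time_s", "extension_nm", "force_pN"), "trace")
  readr::write_csv(trace[, c("time_s", "extension_nm", "force_pN")], path)
  invisible(path)
}

#' Read / write a denaturation curve CSV
#'
#' Columns `denaturant_M`, `signal`.
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_curve_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  check_columns(df, c("denaturant_M", "signal"), "curve CSV")
  if (any(df$denaturant_M < 0)) abort_input("`denaturant_M` must be >= 0")
  df
}

#' @rdname read_curve_csv
#' @param curve Data frame with `denaturant_M`, `signal`.
#' @export
write_curve_csv <- function(curve, path) {
  check_columns(curve, c("denaturant_M", "signal"), "curve")
  readr::write_csv(curve[, c("denaturant_M", "signal")], path)
  invisible(path)
}

#' Read / write a chevron rate table CSV
#'
#' Columns `denaturant_M`, `kobs_s`.
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_chevron_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  check_columns(df, c("denaturant_M", "kobs_s"), "chevron CSV")
  df
}

#' @rdname read_chevron_csv
#' @param data Data frame with `denaturant_M`, `kobs_s`.
#' @export
write_chevron_csv <- function(data, path) {
  check_columns(data, c("denaturant_M", "kobs_s"), "chevron table")
  readr::write_csv(data[, c("denaturant_M", "kobs_s")], path)
  invisible(path)
}

#' Read / write a multi-frame 16-bit TIFF movie
#'
#' Movies are stored as 16-bit grayscale TIFF stacks in camera counts
#' (clipped to 0..65535). Reading returns an array y-by-x-by-frame.
#'
#' @param path File path.
#' @return `read_movie()`: numeric array of counts.
#' @export
read_movie <- function(path) {
  frames <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(frames)) frames <- list(frames)
  stack <- array(0, dim = c(nrow(frames[[1]]), ncol(frames[[1]]), length(frames)))
  for (i in seq_along(frames)) stack[, , i] <- frames[[i]]
  stack
}

#' @rdname read_movie
#' @param stack Array y-by-x-by-frame of counts, or a `tirf_movie`.
#' @export
write_movie <- function(stack, path) {
  if (inherits(stack, "tirf_movie")) stack <- stack$stack
  frames <- lapply(seq_len(dim(stack)[3]), function(i) {
    m <- round(pmin(pmax(stack[, , i], 0), 65535))
    m / 65535
  })
  tiff::writeTIFF(frames, path, bits.per.sample = 16)
  invisible(path)
}

#' Write a bead chain as a minimal PDB or XYZ file
#'
#' CA-style HETATM bead records (coordinates in angstroms in the PDB, nm in
#' the XYZ) for visualization in standard structure viewers.
#'
#' @param chain A `bead_chain`.
#' @param path File path.
#' @export
write_chain_pdb <- function(chain, path) {
  b <- chain$beads
  lines <- sprintf(
    "HETATM%5d  CA  BEA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    seq_len(nrow(b)) %% 100000, b$domain %% 10000,
    b$x * 10, b$y * 10, b$z * 10
  )
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' @rdname write_chain_pdb
#' @export
write_chain_xyz <- function(chain, path) {
  b <- chain$beads
  writeLines(c(
    as.character(nrow(b)),
    "bead chain (nm)",
    sprintf("C %10.4f %10.4f %10.4f", b$x, b$y, b$z)
  ), path)
  invisible(path)
}

#' Write a scattering profile as a 3-column .dat file
#'
#' Columns: s (nm^-1), I, sigma (placeholder zeros for model profiles).
#'
#' @param profile A `scattering_profile`.
#' @param path File path.
#' @export
write_profile_dat <- function(profile, path) {
  writeLines(sprintf("%12.6e %14.6e %14.6e", profile$s, profile$I,
                     rep(0, length(profile$s))), path)
  invisible(path)
}

#' Write a P(r) curve as CSV
#'
#' @param pr A `pair_distribution`.
#' @param path File path.
#' @export
write_pr_csv <- function(pr, path) {
  readr::write_csv(tibble(r_nm = pr$r, p = pr$p), path)
  invisible(path)
}

#' Snapshot a run configuration (with seed) as JSON
#'
#' Every simulated or analyzed dataset can be regenerated from its config
#' snapshot; the snapshot records the package version alongside all
#' parameters, including the seed.
#'
#' @param config Any of the package's config objects (or a plain list).
#' @param path File path.
#' @export
write_config_json <- function(config, path) {
  payload <- list(
    tool = "rodfold",
    version = as.character(utils::packageVersion("rodfold")),
    class = class(config)[1],
    config = unclass(config)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_config_json
#' @export
read_config_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
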