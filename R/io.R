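# Plain-text serialization for the package's containers. Images travel as
# CSV matrices with a JSON metadata sidecar carrying the physical
# calibration; fate tables as one-row-per-track-timepoint CSV; phantom
# ground truth as JSON.

.sidecar_path <- function(path) paste0(path, ".meta.json")

#' Write / read a voxel stack as CSV + JSON sidecar
#'
#' The stack is flattened to a `nx x (ny * nz)` numeric table; the sidecar
#' records dimensions, voxel size and channel so the array can be rebuilt.
#'
#' @param stack A [voxel_stack()].
#' @param path Output CSV path; the sidecar is written to
#'   `<path>.meta.json`.
#' @return `path`, invisibly (writer); a `voxel_stack` (reader).
#' @export
write_stack_text <- function(stack, path) {
  stopifnot(inherits(stack, "voxel_stack"))
  d <- dim(stack$data)
  m <- matrix(stack$data, nrow = d[1])
  utils::write.table(m, path, sep = ",", row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(
    list(dims = d, voxel_size_um = stack$voxel_size_um,
         channel = stack$channel),
    .sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_stack_text
#' @export
read_stack_text <- function(path) {
  meta <- jsonlite::read_json(.sidecar_path(path), simplifyVector = TRUE)
  m <- as.matrix(utils::read.table(path, sep = ","))
  a <- array(as.numeric(m), dim = meta$dims)
  voxel_stack(a, voxel_size_um = meta$voxel_size_um, channel = meta$channel)
}

#' Write / read a line-scan image as CSV + JSON sidecar
#'
#' @param img A [linescan_image()].
#' @param path Output CSV path.
#' @return `path`, invisibly (writer); a `linescan_image` (reader).
#' @export
write_linescan_text <- function(img, path) {
  stopifnot(inherits(img, "linescan_image"))
  utils::write.table(img$img, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  jsonlite::write_json(
    list(line_period_ms = img$line_period_ms,
         pixel_pitch_um = img$pixel_pitch_um),
    .sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_linescan_text
#' @export
read_linescan_text <- function(path) {
  meta <- jsonlite::read_json(.sidecar_path(path), simplifyVector = TRUE)
  m <- as.matrix(utils::read.table(path, sep = ","))
  dimnames(m) <- NULL
  linescan_image(m, line_period_ms = meta$line_period_ms,
                 pixel_pitch_um = meta$pixel_pitch_um)
}

#' Write / read a fate table as CSV
#'
#' One row per track-timepoint; columns as documented in
#' [generate_fate_table()].
#'
#' @param tracks Fate table data frame.
#' @param path CSV path.
#' @return `path`, invisibly (writer); the data frame (reader).
#' @export
write_fate_table <- function(tracks, path) {
  utils::write.csv(tracks, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fate_table
#' @export
read_fate_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write phantom ground truth as JSON
#'
#' @param truth A `phantom_truth` from [generate_vessel_stack()].
#' @param path JSON path.
#' @return `path`, invisibly.
#' @export
write_phantom_truth <- function(truth, path) {
  stopifnot(inherits(truth, "phantom_truth"))
  cyl <- lapply(truth$specs, function(s) {
    list(p0 = s$p0, p1 = s$p1, radius = s$radius)
  })
  jsonlite::write_json(
    list(n_vessels = truth$n_vessels, total_length = truth$total_length,
         total_volume = truth$total_volume, cylinders = cyl),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
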