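#' Write a field's channels as 16-bit TIFFs
#'
#' Files are named `{plate}_{well}_{field}_{channel}.tif` with channels
#' `ch1` (nuclear) and `ch2` (lipid). Intensities are rounded to integer
#' AU counts and clipped to the 16-bit range.
#'
#' @param field A list with `nuclear` and `lipid` matrices (from
#'   [generate_field()]).
#' @param dir Output directory (created if needed).
#' @param plate,well Plate and well ids used in the file names.
#' @param field_index Field number within the well.
#' @return Invisibly, the two file paths.
#' @export
write_field_tiffs <- function(field, dir, plate, well, field_index = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, sprintf("%s_%s_%d_ch%d.tif", plate, well,
                                  field_index, 1:2))
  for (i in 1:2) {
    m <- if (i == 1) field$nuclear else field$lipid
    m <- pmin(pmax(round(m), 0), 65535)
    tiff::writeTIFF(m / 65535, paths[i], bits.per.sample = 16,
                    compression = "none")
  }
  invisible(paths)
}

#' Read a field written by [write_field_tiffs()]
#'
#' @param dir Directory holding the TIFFs.
#' @param plate,well,field_index File-name components.
#' @return List with `nuclear` and `lipid` matrices (AU counts).
#' @export
read_field_tiffs <- function(dir, plate, well, field_index = 1L) {
  paths <- file.path(dir, sprintf("%s_%s_%d_ch%d.tif", plate, well,
                                  field_index, 1:2))
  rd <- function(p) {
    if (!file.exists(p)) stop("missing TIFF: ", p, call. = FALSE)
    round(tiff::readTIFF(p) * 65535)
  }
  list(nuclear = rd(paths[1]), lipid = rd(paths[2]))
}

#' Write / read a plate's well summaries as CSV
#'
#' Column layout is stable: `plate`, `well`, `role`, `n_fields`,
#' `n_cells`, `mean_iss`, `mean_spots`, `mean_spot_area`,
#' `low_cell_flag`. Values round-trip exactly (full double precision).
#'
#' @param wells Well-summary data frame.
#' @param path CSV path.
#' @param plate Plate id recorded in the `plate` column.
#' @return `write_well_csv`: invisibly, `path`; `read_well_csv`: the data
#'   frame.
#' @export
write_well_csv <- function(wells, path, plate = "P01") {
  out <- cbind(plate = plate, wells)
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  # full precision so round-tripped calls are bit-identical
  num <- vapply(out, is.numeric, TRUE) & names(out) != "n_cells" &
    names(out) != "n_fields"
  for (j in which(num)) out[[j]] <- sprintf("%.17g", out[[j]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_well_csv
#' @export
read_well_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  d$low_cell_flag <- as.logical(d$low_cell_flag)
  d
}

#' Write / read a plate layout spec as YAML
#'
#' @param spec A [plate_spec()].
#' @param path YAML path.
#' @return `write_plate_spec`: invisibly, `path`; `read_plate_spec`: a
#'   `plate_spec` object.
#' @export
write_plate_spec <- function(spec, path) {
  stopifnot(inherits(spec, "plate_spec"))
  eff <- spec$layout[spec$layout$role == "compound" &
                       (spec$layout$inhibition != 0 |
                          spec$layout$cell_loss != 0), ]
  obj <- list(n_rows = spec$n_rows, n_cols = spec$n_cols,
              stim_col = spec$stim_col, neutral_col = spec$neutral_col,
              empty_wells = spec$layout$well[spec$layout$role == "empty"],
              inhibition = as.list(stats::setNames(eff$inhibition,
                                                   eff$well)),
              cell_loss = as.list(stats::setNames(
                eff$cell_loss[eff$cell_loss != 0],
                eff$well[eff$cell_loss != 0])))
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_plate_spec
#' @export
read_plate_spec <- function(path) {
  o <- yaml::read_yaml(path)
  plate_spec(n_rows = o$n_rows, n_cols = o$n_cols, stim_col = o$stim_col,
             neutral_col = o$neutral_col,
             inhibition = unlist(o$inhibition),
             cell_loss = unlist(o$cell_loss),
             empty_wells = unlist(o$empty_wells) %||% character())
}
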