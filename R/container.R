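#' Write a volume container
#'
#' Single-file container for a tomogram, optional phantom truth and derived
#' volumes, with the producing configuration echoed as a JSON attribute and a
#' config hash stamped on every derived dataset. (Layout mirrors an
#' HDF5-style grouping: `field`, `truth/*`, `derived/*`, attributes.)
#'
#' @param path output file path.
#' @param tomo a `jones_tomogram`.
#' @param truth optional `phantom_truth`.
#' @param derived optional named list of derived volumes (e.g. `dopu`,
#'   `intensity`, `mu`, `decorrelation`, `frpe`).
#' @param config optional run configuration to echo.
#' @return `path`, invisibly.
#' @export
write_volume <- function(path, tomo, truth = NULL, derived = NULL,
                         config = NULL) {
  .assert(inherits(tomo, "jones_tomogram"), "tomo must be a jones_tomogram")
  cfg_json <- jsonlite::toJSON(config %||% tomo$config, auto_unbox = TRUE,
                               digits = NA, null = "null", force = TRUE)
  obj <- list(
    field = tomo$field,
    truth = truth,
    derived = derived,
    attributes = list(
      axial_pitch_um = tomo$axial_pitch_um,
      aline_pitch_mm = tomo$aline_pitch_mm,
      bscan_pitch_mm = tomo$bscan_pitch_mm,
      noise_variance_per_channel = tomo$noise_variance_per_channel,
      subject_id = tomo$subject_id,
      software_version = as.character(utils::packageVersion("melanoct")),
      config_json = as.character(cfg_json),
      config_hash = config_hash(config %||% tomo$config)
    )
  )
  saveRDS(obj, path)
  invisible(path)
}

#' Read a volume container
#'
#' Validates dimensional consistency between the field and any stored truth
#' or derived datasets; inconsistent containers are rejected with a message
#' naming the offending dataset.
#'
#' @param path container path written by [write_volume()].
#' @return List with `tomo`, `truth`, `derived`, `attributes`.
#' @export
read_volume <- function(path) {
  obj <- readRDS(path)
  .assert(is.list(obj) && !is.null(obj$field), "not a volume container")
  at <- obj$attributes
  d <- dim(obj$field)[1:3]
  check_dims <- function(x, nm) {
    if (is.array(x) && length(dim(x)) == 3L && !identical(dim(x), d))
      stop(sprintf("container dataset '%s' is dimensionally inconsistent", nm),
           call. = FALSE)
  }
  for (nm in names(obj$derived %||% list())) check_dims(obj$derived[[nm]], nm)
  if (!is.null(obj$truth)) {
    check_dims(obj$truth$melanin_mask, "truth/melanin_mask")
    check_dims(obj$truth$flow_mask, "truth/flow_mask")
  }
  tomo <- structure(list(
    field = obj$field,
    axial_pitch_um = at$axial_pitch_um,
    aline_pitch_mm = at$aline_pitch_mm,
    bscan_pitch_mm = at$bscan_pitch_mm,
    noise_variance_per_channel = at$noise_variance_per_channel,
    subject_id = at$subject_id,
    config = jsonlite::fromJSON(at$config_json)
  ), class = "jones_tomogram")
  list(tomo = tomo, truth = obj$truth, derived = obj$derived, attributes = at)
}

#' Export a volume as a 32-bit float TIFF B-scan stack
#'
#' One TIFF page per B-scan (rows = depth, columns = A-lines). Values must
#' lie in [0, 1] (DOPU, decorrelation, normalized intensity); NA is written
#' as `na_value`.
#'
#' @param volume `[depth, aline, bscan]` array with values in [0, 1].
#' @param path output `.tiff` path.
#' @param na_value replacement for NA voxels (default 0).
#' @return `path`, invisibly.
#' @export
export_tiff_stack <- function(volume, path, na_value = 0) {
  v <- volume
  v[is.na(v)] <- na_value
  .assert(min(v) >= 0 && max(v) <= 1, "values must lie in [0, 1] for export")
  pages <- lapply(seq_len(dim(v)[3L]), function(b) v[, , b])
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none")
  invisible(path)
}

#' Read a float TIFF B-scan stack back into a volume
#'
#' @param path TIFF file written by [export_tiff_stack()].
#' @return `[depth, aline, bscan]` array.
#' @export
read_tiff_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  array(unlist(pages), c(dim(pages[[1L]]), length(pages)))
}
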