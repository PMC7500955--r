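#' Write a synthetic centriole image as a multichannel TIFF
#'
#' Channels are stored as 16-bit pages in order (tubulin, protein); the
#' acquisition metadata (channel names, view, pixel size, expansion
#' calibration) is written to a JSON sidecar `<path>.json` so that
#' [read_centriole_tiff()] can reconstruct the object.
#'
#' @param image A `centriole_image`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_centriole_tiff <- function(image, path) {
  stopifnot(inherits(image, "centriole_image"))
  scale <- 65535
  pages <- lapply(image$channels, function(m) {
    pmax(pmin(round(m), scale), 0) / scale
  })
  tiff::writeTIFF(unname(pages), path, bits.per.sample = 16)
  jsonlite::write_json(list(
    channels = names(image$channels), view = image$view,
    pixel_nm = image$calib$pixel_nm,
    gel_size_mm = image$calib$gel_size_mm,
    coverslip_mm = image$calib$coverslip_mm,
    z_step_nm = image$calib$z_step_nm,
    scale = scale), paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a multichannel TIFF written by [write_centriole_tiff()]
#'
#' @param path TIFF file path.
#' @return A `centriole_image`.
#' @export
read_centriole_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- jsonlite::fromJSON(paste0(path, ".json"))
  channels <- lapply(pages, function(p) round(p * meta$scale))
  names(channels) <- meta$channels
  calib <- expansion_calibration(meta$gel_size_mm, meta$coverslip_mm,
                                 meta$pixel_nm, meta$z_step_nm)
  new_centriole_image(channels, view = meta$view, calib = calib)
}

#' Write a ground-truth manifest (JSON lines + CSV mirror)
#'
#' @param manifest Data frame of per-image truths.
#' @param path Base path; `.jsonl` and `.csv` extensions are appended.
#' @return Named character vector of the two written paths, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  jl <- paste0(path, ".jsonl"); cs <- paste0(path, ".csv")
  con <- file(jl, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(manifest))) {
    writeLines(as.character(jsonlite::toJSON(as.list(manifest[i, ]),
                                             auto_unbox = TRUE,
                                             digits = NA, na = "null")), con)
  }
  utils::write.csv(manifest, cs, row.names = FALSE)
  invisible(c(jsonl = jl, csv = cs))
}

#' Read a JSON-lines manifest written by [write_manifest()]
#'
#' @param path Path to the `.jsonl` file (or the base path used at write time).
#' @return Data frame with one row per image.
#' @export
read_manifest <- function(path) {
  if (!grepl("\\.jsonl$", path)) path <- paste0(path, ".jsonl")
  rows <- lapply(readLines(path), function(l) {
    x <- jsonlite::fromJSON(l)
    x[vapply(x, is.null, logical(1))] <- NA
    as.data.frame(x, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
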