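#' Write a case image as a 16-bit multi-page TIFF
#'
#' Pages follow the fixed panel order (hoechst, oatp, iba1, gfap, lectin,
#' pdgfrb; see [oq_channels()]). Float intensities are clipped to
#' [0, 65535] and quantized to 16 bits on write only.
#'
#' @param case A `case_image`.
#' @param path Output .tif path.
#' @return `path`, invisibly.
#' @export
write_case_tiff <- function(case, path) {
  pages <- lapply(oq_channels(), function(ch)
    pmin(pmax(case$channels[[ch]], 0), 65535) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  invisible(path)
}

#' Read a case image from TIFF(s)
#'
#' Accepts either one multi-page TIFF in panel order or a directory of
#' six single-channel files named `<prefix>_<channel>.tif`.
#'
#' @param path Multi-page .tif path, or a directory.
#' @param case_id,group,isoform Metadata to attach.
#' @param pixel_size Pixel size in micrometers.
#' @param prefix Filename prefix for the single-channel layout.
#' @return A `case_image` with intensities rescaled back to 0..65535.
#' @export
read_case_tiff <- function(path, case_id = "case", group = "gbm",
                           isoform = "OATP", pixel_size = 0.325,
                           prefix = case_id) {
  chs <- oq_channels()
  if (dir.exists(path)) {
    channels <- lapply(chs, function(ch) {
      f <- file.path(path, paste0(prefix, "_", ch, ".tif"))
      if (!file.exists(f))
        stop("read_case_tiff: case '", case_id, "' missing channel '", ch, "'")
      tiff::readTIFF(f) * 65535
    })
  } else {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (length(pages) != length(chs))
      stop("read_case_tiff: expected ", length(chs), " pages, found ",
           length(pages))
    channels <- lapply(pages, function(p) p * 65535)
  }
  names(channels) <- chs
  structure(list(channels = channels, case_id = case_id, group = group,
                 isoform = isoform, pixel_size = pixel_size,
                 shape = dim(channels[[1]])),
            class = "case_image")
}

#' Write ground truth to plain-text files
#'
#' Object table as CSV, region label map as a single-channel TIFF
#' (integer codes scaled by 1/65535), and the seed as JSON.
#'
#' @param truth A `ground_truth`.
#' @param dir Output directory.
#' @param stem File stem (e.g. the case id).
#' @return Invisibly, the paths written.
#' @export
write_ground_truth <- function(truth, dir, stem) {
  obj_path <- file.path(dir, paste0(stem, "_objects.csv"))
  utils::write.csv(truth$objects, obj_path, row.names = FALSE)
  reg_path <- file.path(dir, paste0(stem, "_regions.tif"))
  tiff::writeTIFF(truth$regions / 65535, reg_path, bits.per.sample = 16)
  meta_path <- file.path(dir, paste0(stem, "_meta.json"))
  jsonlite::write_json(list(seed = truth$seed,
                            region_codes = as.list(truth$region_codes)),
                       meta_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(obj_path, reg_path, meta_path))
}

#' Write a label map as a single-channel 16-bit TIFF
#'
#' @param labels Integer matrix.
#' @param path Output path.
#' @export
write_label_tiff <- function(labels, path) {
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16)
  invisible(path)
}
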