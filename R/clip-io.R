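#' Read a clip from disk
#'
#' Two lossless on-disk layouts are supported:
#' \describe{
#'   \item{PNG frame directory}{a directory of single-frame PNGs read in
#'     lexicographic order, with an optional `metadata.json` sidecar holding
#'     `rate`, `label`, `patient_id`, `condition` and `id`.}
#'   \item{multi-frame TIFF}{a single `.tif`/`.tiff` stack with an optional
#'     `<stem>.json` sidecar.}
#' }
#' Both store 8-bit grayscale; RGB sources are reduced to one channel by
#' averaging. Integer-valued clips round-trip bitwise through either format.
#'
#' @param path directory of PNG frames, or a TIFF file.
#' @param rate sampling-rate override in Hz; required when no sidecar is
#'   present.
#' @return a [vog_clip].
#' @export
load_clip <- function(path, rate = NULL) {
  meta <- list()
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
    if (length(files) == 0L) stop("no PNG frames found in ", path)
    frames <- lapply(files, function(f) as_gray255(png::readPNG(f)))
    side <- file.path(path, "metadata.json")
    if (file.exists(side)) meta <- jsonlite::read_json(side)
  } else if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("the 'tiff' package is required to read TIFF stacks")
    imgs <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(imgs)) imgs <- list(imgs)
    frames <- lapply(imgs, as_gray255)
    side <- sub("\\.tiff?$", ".json", path, ignore.case = TRUE)
    if (file.exists(side)) meta <- jsonlite::read_json(side)
  } else {
    stop("unreadable clip path (expected a PNG frame directory or .tif): ",
         path)
  }
  dims <- unique(lapply(frames, dim))
  if (length(dims) != 1L) stop("frames have inconsistent sizes")
  if (is.null(rate)) rate <- meta$rate
  if (is.null(rate)) stop("no sampling rate in sidecar; supply 'rate'")
  vog_clip(frames, rate = rate,
           label = meta$label %||% NA_character_,
           patient_id = meta$patient_id %||% NA_character_,
           condition = meta$condition %||% NA_character_,
           id = meta$id, source = path)
}

#' Write a clip to disk
#'
#' @param clip a [vog_clip]; intensities are rounded to 8-bit on write.
#' @param path output directory (`format = "png_dir"`) or `.tif` file path.
#' @param format `"png_dir"` or `"tiff"`; both are lossless for 8-bit data.
#' @return `path`, invisibly.
#' @export
save_clip <- function(clip, path, format = c("png_dir", "tiff")) {
  format <- match.arg(format)
  meta <- list(rate = clip$rate)
  if (!is.na(clip$label)) meta$label <- clip$label
  if (!is.na(clip$patient_id)) meta$patient_id <- clip$patient_id
  if (!is.na(clip$condition)) meta$condition <- clip$condition
  if (!is.null(clip$id)) meta$id <- clip$id
  T <- n_frames(clip)
  if (format == "png_dir") {
    dir.create(path, recursive = TRUE, showWarnings = FALSE)
    for (t in seq_len(T)) {
      png::writePNG(round(clip$frames[, , t]) / 255,
                    file.path(path, sprintf("frame_%05d.png", t)))
    }
    jsonlite::write_json(meta, file.path(path, "metadata.json"),
                         auto_unbox = TRUE, digits = NA)
  } else {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("the 'tiff' package is required to write TIFF stacks")
    imgs <- lapply(seq_len(T), function(t) round(clip$frames[, , t]) / 255)
    tiff::writeTIFF(imgs, path, bits.per.sample = 8, compression = "none")
    jsonlite::write_json(meta, sub("\\.tiff?$", ".json", path,
                                   ignore.case = TRUE),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# any readPNG/readTIFF result -> H x W matrix in [0, 255]
as_gray255 <- function(img) {
  if (length(dim(img)) == 3L) {
    nc <- dim(img)[3]
    img <- if (nc >= 3L) (img[, , 1] + img[, , 2] + img[, , 3]) / 3 else img[, , 1]
  }
  # 8-bit sources decode as k/255; round off the float error so integer
  # frames round-trip exactly
  round(img * 255, 6)
}
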