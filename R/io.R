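# Sequence readers and writers. Internal raster convention: `data[i, j]`
# (2D) with i along x and j along y, pixel centre of `data[i, j]` at
# `((i - 1/2) h, (j - 1/2) h)`; PNG/TIFF rows map to y. 16-bit TIFF values
# are read as stored integers (no rescale); 8-bit PNG values are scaled to
# 0..255.

as_gray <- function(img) {
  if (length(dim(img)) == 3L) img <- apply(img, c(1, 2), mean)
  t(img)                      # file row-major -> internal [x, y]
}

read_raster <- function(path) {
  lp <- tolower(path)
  if (grepl("\\.png$", lp)) {
    as_gray(png::readPNG(path)) * 255
  } else if (grepl("\\.(tif|tiff)$", lp)) {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    slices <- lapply(pages, as_gray)
    if (length(slices) == 1L) slices[[1]] else
      array(unlist(slices), c(dim(slices[[1]]), length(slices)))
  } else stop("unsupported raster format: ", path)
}

write_raster <- function(data, path, bits = 8L) {
  lp <- tolower(path)
  if (length(dim(data)) == 2L) {
    img <- t(data)            # internal [x, y] -> file row-major
    if (grepl("\\.png$", lp)) {
      png::writePNG(pmin(pmax(img / 255, 0), 1), path)
    } else if (grepl("\\.(tif|tiff)$", lp)) {
      mx <- if (bits == 16L) 65535 else 255
      tiff::writeTIFF(pmin(pmax(img / mx, 0), 1), path,
                      bits.per.sample = bits)
    } else stop("unsupported raster format: ", path)
  } else {
    if (!grepl("\\.(tif|tiff)$", lp)) stop("3D rasters are written as TIFF")
    mx <- if (bits == 16L) 65535 else 255
    pages <- lapply(seq_len(dim(data)[3]), function(z)
      pmin(pmax(t(data[, , z]) / mx, 0), 1))
    tiff::writeTIFF(pages, path, bits.per.sample = bits)
  }
  invisible(path)
}

#' Read an image sequence
#'
#' Accepts a directory of numbered single-channel PNG/TIFF files (frames in
#' lexicographic order), a single multi-page TIFF (2D frames), or a
#' directory of multi-page TIFF stacks (3D frames, one stack per frame).
#' Stored integer values are preserved (16-bit TIFFs are not rescaled);
#' PNGs are scaled to 0..255. Mixed frame shapes raise an error.
#'
#' @param path file or directory.
#' @return list of [image_frame()].
#' @export
read_sequence <- function(path) {
  frames <- if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(png|tif|tiff)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (!length(files)) stop("no raster files in ", path)
    lapply(files, read_raster)
  } else {
    if (!file.exists(path)) stop("unreadable path: ", path)
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    lapply(pages, as_gray)
  }
  shp <- dim(frames[[1]])
  if (!all(vapply(frames, function(f) identical(dim(f), shp), logical(1))))
    stop("frames have inconsistent shapes")
  lapply(frames, image_frame)
}

#' Write tracking outputs
#'
#' Per-frame binary mask PNGs (`mask_0001.png`, ...), contours as CSV
#' (columns `frame`, `component`, then 0-based pixel-centre coordinates
#' `x`, `y`[, `z`]), a diagnostics CSV, and the effective configuration as
#' YAML.
#'
#' @param masks list of binary masks.
#' @param contours list (per frame) of lists of polyline matrices in
#'   physical coordinates, or point matrices in 3D; may be NULL.
#' @param diagnostics data.frame.
#' @param out_dir output directory (created if needed).
#' @param config optional [run_config()] echoed to `config.yaml`.
#' @param spacing,lower raster geometry used to convert physical contour
#'   coordinates to pixel-centre coordinates.
#' @return `out_dir`, invisibly.
#' @export
write_outputs <- function(masks, contours = NULL, diagnostics = NULL,
                          out_dir, config = NULL, spacing = 1,
                          lower = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("unwritable directory: ", out_dir)
  for (k in seq_along(masks)) {
    m <- masks[[k]]
    if (length(dim(m)) == 2L)
      write_raster(255 * (m != 0), file.path(out_dir,
                                             sprintf("mask_%04d.png", k)))
    else
      write_raster(255 * (m != 0), file.path(out_dir,
                                             sprintf("mask_%04d.tif", k)))
  }
  if (!is.null(contours)) {
    rows <- list()
    for (k in seq_along(contours)) {
      comp <- contours[[k]]
      if (is.null(comp)) next
      if (is.matrix(comp)) comp <- list(comp)
      for (ci in seq_along(comp)) {
        pl <- comp[[ci]]
        if (is.null(pl) || !nrow(pl)) next
        d <- ncol(pl)
        if (is.null(lower)) lower <- rep(0, d)
        pix <- sweep(pl, 2, lower[seq_len(d)], `-`) / spacing - 0.5
        df <- data.frame(frame = k, component = ci, x = pix[, 1],
                         y = pix[, 2])
        if (d == 3L) df$z <- pix[, 3]
        rows[[length(rows) + 1]] <- df
      }
    }
    if (length(rows))
      utils::write.csv(do.call(rbind, rows),
                       file.path(out_dir, "contours.csv"),
                       row.names = FALSE)
  }
  if (!is.null(diagnostics))
    utils::write.csv(diagnostics, file.path(out_dir, "diagnostics.csv"),
                     row.names = FALSE)
  if (!is.null(config)) write_config(config, file.path(out_dir,
                                                       "config.yaml"))
  invisible(out_dir)
}
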