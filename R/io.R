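# File I/O: images (PNG/TIFF natively, JPEG via EBImage when available),
# feature matrices as delimited text, masks and label maps.

#' Read an image file
#'
#' PNG and TIFF are read natively; JPEG requires the EBImage package.
#' Values are returned on the \[0, 255\] scale as a grayscale matrix or an
#' H x W x 3 color array (an alpha channel, if present, is dropped).
#'
#' @param path path to a .png, .tif/.tiff or .jpg/.jpeg file.
#' @return grayscale matrix or color array in \[0, 255\].
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    jpg = ,
    jpeg = {
      if (!requireNamespace("EBImage", quietly = TRUE)) {
        stop("reading JPEG requires the EBImage package")
      }
      im <- EBImage::readImage(path)
      a <- EBImage::imageData(im)
      # EBImage stores x (columns) first; transpose back to row = y
      if (length(dim(a)) == 2L) t(a) else aperm(a, c(2L, 1L, 3L))
    },
    stop("unsupported image format: ", ext)
  )
  v <- raw * 255
  if (is.matrix(v)) return(v)
  if (length(dim(v)) == 3L && dim(v)[3] >= 3L) return(v[, , 1:3, drop = FALSE])
  if (length(dim(v)) == 3L && dim(v)[3] == 1L) return(v[, , 1])
  stop("unexpected image shape: ", paste(dim(v), collapse = "x"))
}

#' Write an image file
#'
#' Grayscale matrices are written as 8-bit single-channel images; label maps
#' (see `bits = 16`) as 16-bit grayscale PNG. Values outside \[0, 255\]
#' (or \[0, 65535\] for 16-bit) are clipped.
#'
#' @param img grayscale matrix or H x W x 3 array on the \[0, 255\] scale
#'   (\[0, 65535\] when `bits = 16`).
#' @param path output path ending in .png or .tif/.tiff.
#' @param bits 8 or 16 (16 only for PNG label maps).
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path, bits = 8L) {
  top <- if (bits == 16L) 65535 else 255
  v <- pmin(pmax(img / top, 0), 1)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(v, target = path, dpi = NULL),
    tif = ,
    tiff = tiff::writeTIFF(v, where = path, bits.per.sample = if (bits == 16L) 16L else 8L),
    stop("unsupported output format: ", ext)
  )
  invisible(path)
}

#' Write a superpixel label map as a 16-bit image
#'
#' Label maps are stored as 16-bit grayscale TIFF (the png package writes
#' 8 bits per sample only, which would truncate label ids above 255).
#'
#' @param labels integer label matrix (labels 0..n-1).
#' @param path output .tif/.tiff path.
#' @return `path`, invisibly.
#' @export
write_label_map <- function(labels, path) {
  if (max(labels) > 65535) stop("more than 65536 labels cannot be stored in 16 bits")
  if (!tolower(tools::file_ext(path)) %in% c("tif", "tiff")) {
    stop("label maps are written as 16-bit TIFF; use a .tif path")
  }
  write_image(labels, path, bits = 16L)
}

#' Read a 16-bit label map written by [write_label_map()]
#'
#' @param path .tif/.tiff path.
#' @return integer label matrix.
#' @export
read_label_map <- function(path) {
  v <- tiff::readTIFF(path)
  matrix(as.integer(round(v * 65535)), nrow(v), ncol(v))
}

#' Read / write feature matrices as delimited text
#'
#' Rows are images, columns are features; the first column holds image
#' identifiers. The format round-trips through `read_feature_matrix()`.
#'
#' @param f numeric feature matrix (rownames used as image ids when present).
#' @param path output path (.csv or .tsv; the delimiter follows the extension).
#' @return `path` invisibly for the writer; a matrix with rownames for the reader.
#' @export
write_feature_matrix <- function(f, path) {
  sep <- if (tolower(tools::file_ext(path)) == "tsv") "\t" else ","
  ids <- rownames(f)
  if (is.null(ids)) ids <- sprintf("img_%04d", seq_len(nrow(f)))
  df <- data.frame(image_id = ids, f, check.names = FALSE)
  colnames(df) <- c("image_id", sprintf("f%04d", seq_len(ncol(f)) - 1L))
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  sep <- if (tolower(tools::file_ext(path)) == "tsv") "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write a feature-selection mask as JSON
#'
#' Stores the kept feature indices (1-based), the total dimension and the
#' selected count.
#'
#' @param mask logical keep/drop vector.
#' @param path output .json path.
#' @return `path`, invisibly.
#' @export
write_mask_json <- function(mask, path) {
  jsonlite::write_json(
    list(dim = length(mask), n_selected = sum(mask), kept = which(mask)),
    path, auto_unbox = TRUE
  )
  invisible(path)
}

#' @rdname write_mask_json
#' @export
read_mask_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  mask <- rep(FALSE, obj$dim)
  mask[obj$kept] <- TRUE
  mask
}
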