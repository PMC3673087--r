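## Image I/O. Images are integer arrays H x W x 3 with 8-bit levels in
## [0, 255]. PNG goes through the png package; BMP (the uncompressed field
## storage format) through a minimal 24-bit BI_RGB codec written here, since
## no installed R package handles BMP.

#' Read / write 8-bit RGB images
#'
#' Supported formats, chosen by file extension: PNG and uncompressed
#' 24-bit BMP.
#'
#' @param path file path ending in `.png` or `.bmp`.
#' @return `readImageRGB`: integer array H x W x 3 with values in 0..255.
#' @export
readImageRGB <- function(path) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    a <- png::readPNG(path)
    if (length(dim(a)) == 2) a <- array(rep(a, 3), c(dim(a), 3))
    if (dim(a)[3] > 3) a <- a[, , 1:3, drop = FALSE]
    img <- roundHalfUp(a * 255)
  } else if (grepl("\\.bmp$", path, ignore.case = TRUE)) {
    img <- readBMP(path)
  } else stop("unsupported image format: ", path, call. = FALSE)
  storage.mode(img) <- "integer"
  img
}

#' @param image integer array H x W x 3, values 0..255.
#' @rdname readImageRGB
#' @export
writeImageRGB <- function(image, path) {
  assertRGBImage(image)
  if (min(image) < 0 || max(image) > 255)
    stop("image values must lie in [0, 255]", call. = FALSE)
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::writePNG(image / 255, path)
  } else if (grepl("\\.bmp$", path, ignore.case = TRUE)) {
    writeBMP(image, path)
  } else stop("unsupported image format: ", path, call. = FALSE)
  invisible(path)
}

#' Read / write binary masks as single-channel PNG
#'
#' Masks are logical matrices; on disk white (255) is TRUE (vegetation/ROI)
#' and black (0) is FALSE.
#'
#' @param mask logical matrix.
#' @param path file path (`.png`).
#' @export
writeMaskPNG <- function(mask, path) {
  assertMask(mask)
  png::writePNG(mask * 1.0, path)
  invisible(path)
}

#' @rdname writeMaskPNG
#' @export
readMaskPNG <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3) a <- a[, , 1]
  a >= 0.5
}

## --- minimal BMP codec (24-bit, BI_RGB, bottom-up) ------------------------

writeBMP <- function(image, path) {
  d <- dim(image)
  H <- d[1]; W <- d[2]
  rowBytes <- W * 3
  pad <- (4 - rowBytes %% 4) %% 4
  imgBytes <- (rowBytes + pad) * H
  con <- file(path, "wb")
  on.exit(close(con))
  u16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  u32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  writeBin(charToRaw("BM"), con)
  u32(54 + imgBytes); u16(0); u16(0); u32(54)      # file header
  u32(40); u32(W); u32(H); u16(1); u16(24)         # BITMAPINFOHEADER
  u32(0); u32(imgBytes); u32(2835); u32(2835); u32(0); u32(0)
  padRaw <- as.raw(rep(0, pad))
  for (r in H:1) {                                 # bottom-up rows, BGR order
    px <- rbind(image[r, , 3], image[r, , 2], image[r, , 1])
    writeBin(as.raw(px), con)
    if (pad) writeBin(padRaw, con)
  }
  invisible(path)
}

readBMP <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 54 || rawToChar(raw[1:2]) != "BM")
    stop("not a BMP file: ", path, call. = FALSE)
  u16 <- function(o) sum(as.integer(raw[o + 1:2]) * c(1, 256))
  u32 <- function(o) sum(as.integer(raw[o + 1:4]) * 256^(0:3))
  offset <- u32(10)
  W <- u32(18); Hraw <- u32(22)
  topDown <- Hraw > 2^31
  H <- if (topDown) 2^32 - Hraw else Hraw
  bpp <- u16(28); compression <- u32(30)
  if (bpp != 24 || compression != 0)
    stop("only uncompressed 24-bit BMP is supported", call. = FALSE)
  rowBytes <- W * 3
  stride <- rowBytes + (4 - rowBytes %% 4) %% 4
  img <- array(0L, c(H, W, 3))
  for (i in seq_len(H)) {
    r <- if (topDown) i else H - i + 1
    row <- as.integer(raw[offset + (i - 1) * stride + seq_len(rowBytes)])
    m <- matrix(row, nrow = 3)                     # BGR
    img[r, , 1] <- m[3, ]; img[r, , 2] <- m[2, ]; img[r, , 3] <- m[1, ]
  }
  img
}
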