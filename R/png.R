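# Minimal pure-R PNG codec. No PNG package is available in this R stack, so
# frames and heat-map overlays are written as valid 8-bit grayscale/RGB PNG
# files using stored (uncompressed) deflate blocks; the reader handles the
# same subset (stored-block zlib streams, filter type 0), which is exactly
# what this package emits, so simulator frames round-trip losslessly.

pngCrcTable <- local({
  tab <- integer(256)
  for (n in 0:255) {
    c <- n
    for (k in 1:8) {
      c <- if (bitwAnd(c, 1L) == 1L) {
        bitwXor(-306674912L, bitwShiftR(c, 1))   # 0xEDB88320
      } else bitwShiftR(c, 1)
    }
    tab[n + 1] <- c
  }
  tab
})

pngCrc32 <- function(bytes) {
  crc <- -1L                                      # 0xFFFFFFFF
  v <- as.integer(bytes)
  for (b in v) {
    crc <- bitwXor(bitwShiftR(crc, 8),
                   pngCrcTable[bitwAnd(bitwXor(crc, b), 255L) + 1L])
  }
  bitwXor(crc, -1L)
}

pngAdler32 <- function(bytes) {
  d <- as.numeric(bytes)
  n <- length(d)
  a <- (1 + sum(d)) %% 65521
  b <- (n + sum(d * (n - seq_len(n) + 1))) %% 65521
  c(b, a)                                          # high word, low word
}

packUInt32 <- function(x) {
  x <- as.numeric(x) %% 4294967296
  as.raw(c(x %/% 16777216, (x %/% 65536) %% 256, (x %/% 256) %% 256,
           x %% 256))
}

readUInt32 <- function(raw4) {
  sum(as.numeric(raw4) * c(16777216, 65536, 256, 1))
}

pngChunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  crc <- pngCrc32(body)
  c(packUInt32(length(data)), body,
    packUInt32(if (crc < 0) crc + 4294967296 else crc))
}

# zlib stream with stored deflate blocks (BTYPE = 00)
zlibStored <- function(bytes) {
  n <- length(bytes)
  blocks <- raw(0)
  off <- 0L
  repeat {
    len <- min(65535L, n - off)
    final <- if (off + len >= n) as.raw(1L) else as.raw(0L)
    blocks <- c(blocks, final,
                as.raw(c(len %% 256, len %/% 256,
                         255 - len %% 256, 255 - len %/% 256)),
                bytes[seq_len(len) + off])
    off <- off + len
    if (off >= n) break
  }
  ad <- pngAdler32(bytes)
  c(as.raw(c(0x78, 0x01)), blocks,
    as.raw(c(ad[1] %/% 256, ad[1] %% 256, ad[2] %/% 256, ad[2] %% 256)))
}

pngEncode <- function(pixels, path) {
  gray <- length(dim(pixels)) == 2
  h <- dim(pixels)[1]; w <- dim(pixels)[2]
  if (gray) {
    scan <- t(pixels)                               # row-major bytes
    rows <- rbind(0L, scan)                         # filter byte 0 per row
  } else {
    rows <- matrix(0L, nrow = 1 + 3 * w, ncol = h)
    rows[1 + seq(1, 3 * w, by = 3), ] <- t(pixels[, , 1])
    rows[1 + seq(2, 3 * w, by = 3), ] <- t(pixels[, , 2])
    rows[1 + seq(3, 3 * w, by = 3), ] <- t(pixels[, , 3])
  }
  raw <- as.raw(pmax(0L, pmin(255L, as.integer(rows))))
  ihdr <- c(packUInt32(w), packUInt32(h),
            as.raw(c(8, if (gray) 0 else 2, 0, 0, 0)))
  out <- c(as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a)),
           pngChunk("IHDR", ihdr),
           pngChunk("IDAT", zlibStored(raw)),
           pngChunk("IEND", raw(0)))
  writeBin(out, path)
  invisible(path)
}

#' Write an image as an 8-bit PNG
#'
#' `writeGrayPNG` takes an integer matrix (rows = image y, values 0-255);
#' `writeRGBPNG` takes an `h x w x 3` array. `writeFramePNG` exports a
#' simulator [Frame-class].
#'
#' @param pixels matrix or 3d array of 0-255 values
#' @param path output file
#' @return the path, invisibly
#' @export
writeGrayPNG <- function(pixels, path) {
  stopifnot(is.matrix(pixels))
  pngEncode(pixels, path)
}

#' @rdname writeGrayPNG
#' @export
writeRGBPNG <- function(pixels, path) {
  stopifnot(length(dim(pixels)) == 3, dim(pixels)[3] == 3)
  pngEncode(pixels, path)
}

#' @rdname writeGrayPNG
#' @param frame a [Frame-class]
#' @export
writeFramePNG <- function(frame, path) writeGrayPNG(frame@pixels, path)

inflateStored <- function(z) {
  stopifnot(length(z) > 6)
  # 2-byte zlib header, then stored blocks only
  pos <- 3L
  out <- list()
  repeat {
    hdr <- as.integer(z[pos])
    if (bitwAnd(hdr, 6L) != 0L)
      stop("only stored-block deflate streams are supported")
    len <- as.integer(z[pos + 1]) + 256L * as.integer(z[pos + 2])
    out[[length(out) + 1]] <- z[pos + 5L + seq_len(len) - 1L]
    pos <- pos + 5L + len
    if (bitwAnd(hdr, 1L) == 1L) break
  }
  do.call(c, out)
}

#' Read an 8-bit PNG written by this package
#'
#' Decodes grayscale (returned as an integer matrix) or RGB (returned as an
#' `h x w x 3` array) PNG files with stored-block deflate streams and filter
#' type 0 -- the subset emitted by [writeGrayPNG()]. `frameFromPNG` wraps a
#' grayscale file as a [Frame-class] so offline snapshots can be pushed
#' through the vision pipeline.
#'
#' @param path PNG file path
#' @return integer matrix or array
#' @export
readPNGImage <- function(path) {
  bytes <- readBin(path, "raw", file.size(path))
  sig <- as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a))
  if (length(bytes) < 8 || !identical(bytes[1:8], sig))
    stop("not a PNG file: ", path)
  pos <- 9L
  w <- h <- colorType <- NULL
  idat <- list()
  while (pos <= length(bytes)) {
    len <- readUInt32(bytes[pos:(pos + 3)])
    type <- rawToChar(bytes[(pos + 4):(pos + 7)])
    data <- if (len > 0) bytes[(pos + 8):(pos + 7 + len)] else raw(0)
    if (type == "IHDR") {
      w <- readUInt32(data[1:4]); h <- readUInt32(data[5:8])
      if (as.integer(data[9]) != 8)
        stop("only 8-bit PNG supported")
      colorType <- as.integer(data[10])
    } else if (type == "IDAT") {
      idat[[length(idat) + 1]] <- data
    } else if (type == "IEND") break
    pos <- pos + 12L + len
  }
  raw <- inflateStored(do.call(c, idat))
  ch <- if (colorType == 0) 1L else if (colorType == 2) 3L else
    stop("unsupported PNG color type: ", colorType)
  stride <- 1L + ch * w
  m <- matrix(as.integer(raw), nrow = stride)
  if (any(m[1, ] != 0L)) stop("unsupported PNG filter type")
  body <- m[-1, , drop = FALSE]
  if (ch == 1L) {
    t(body)
  } else {
    arr <- array(0L, dim = c(h, w, 3))
    for (k in 1:3) arr[, , k] <- t(body[seq(k, 3 * w, by = 3), , drop = FALSE])
    arr
  }
}

#' @rdname readPNGImage
#' @param camera camera label to attach
#' @param omega omega (deg) to record on the frame
#' @export
frameFromPNG <- function(path, camera = "file", omega = NA_real_) {
  px <- readPNGImage(path)
  if (length(dim(px)) == 3) {
    px <- round((px[, , 1] + px[, , 2] + px[, , 3]) / 3)
    storage.mode(px) <- "integer"
  }
  new("Frame", camera = camera, pixels = px, omegaAtCapture = omega)
}
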