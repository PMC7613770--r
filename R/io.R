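# File formats: PFM float maps (the disparity interchange format), 16-bit
# grayscale PNG (x256 fixed-point disparity encoding), and 8-bit PNG via the
# png package.  The png package reads 16-bit PNG but writes only 8-bit, so
# the 16-bit writer below emits the container directly (stored-block deflate,
# CRC32/Adler32); png::readPNG serves as the independent reader in tests.

#' Write a 2-D float map as PFM
#'
#' Grayscale PFM: `Pf` header, dimensions, negative scale for little-endian,
#' rows stored bottom-up.
#' @param x H x W numeric matrix
#' @param path output file
#' @export
write_pfm <- function(x, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c("Pf", sprintf("%d %d", ncol(x), nrow(x)), "-1.0"), con, sep = "\n")
  flipped <- x[rev(seq_len(nrow(x))), , drop = FALSE]   # bottom-up
  writeBin(as.numeric(t(flipped)), con, size = 4, endian = "little")
  invisible(path)
}

#' Read a grayscale PFM file
#' @param path PFM file
#' @return H x W numeric matrix
#' @export
read_pfm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readLines(con, n = 3L)
  if (hdr[1] != "Pf") stop("only grayscale ('Pf') PFM is supported")
  dims <- as.integer(strsplit(trimws(hdr[2]), "\\s+")[[1]])
  scale <- as.numeric(hdr[3])
  endian <- if (scale < 0) "little" else "big"
  vals <- readBin(con, "numeric", n = dims[1] * dims[2], size = 4, endian = endian)
  m <- matrix(vals, nrow = dims[2], ncol = dims[1], byrow = TRUE)
  m[rev(seq_len(nrow(m))), , drop = FALSE]
}

# CRC32 (PNG chunk checksum), table-driven.
crc32_table <- local({
  tab <- NULL
  function() {
    if (!is.null(tab)) return(tab)
    t <- integer(256)
    for (n in 0:255) {
      c <- n
      for (k in 1:8)
        c <- if (bitwAnd(c, 1L) != 0L) bitwXor(-306674912L, bitwShiftR(c, 1)) else bitwShiftR(c, 1)
      t[n + 1] <- c
    }
    tab <<- t
    tab
  }
})

crc32 <- function(bytes) {
  tab <- crc32_table()
  c <- -1L
  b <- as.integer(bytes)
  for (i in seq_along(b)) {
    idx <- bitwAnd(bitwXor(c, b[i]), 255L)
    c <- bitwXor(tab[idx + 1], bitwShiftR(bitwAnd(c, -256L), 8))
  }
  bitwXor(c, -1L)
}

adler32 <- function(bytes) {
  MOD <- 65521
  b <- as.integer(bytes)
  # process in chunks to stay in double precision safely
  a <- 1; s <- 0
  step <- 3000L
  for (start in seq(1L, length(b), by = step)) {
    chunk <- b[start:min(start + step - 1L, length(b))]
    ca <- cumsum(chunk)
    s <- (s + length(chunk) * a + sum(ca)) %% MOD
    a <- (a + ca[length(ca)]) %% MOD
  }
  a + s * 65536
}

u32be <- function(x) {
  x <- as.numeric(x) %% 2^32
  as.raw(c(x %/% 2^24, (x %/% 2^16) %% 256, (x %/% 256) %% 256, x %% 256))
}

png_chunk <- function(type, data) {
  payload <- c(charToRaw(type), data)
  crc <- crc32(payload) %% 2^32
  c(u32be(length(data)), payload, u32be(crc))
}

# deflate "stored" blocks (no compression) wrapped in a zlib stream
zlib_stored <- function(data) {
  out <- list(as.raw(c(0x78, 0x01)))
  n <- length(data)
  pos <- 1L
  repeat {
    len <- min(65535L, n - pos + 1L)
    final <- if (pos + len - 1L >= n) 0x01 else 0x00
    hdr <- as.raw(c(final, len %% 256, len %/% 256,
                    255 - len %% 256, 255 - len %/% 256))
    out[[length(out) + 1L]] <- c(hdr, data[pos:(pos + len - 1L)])
    pos <- pos + len
    if (pos > n) break
  }
  out[[length(out) + 1L]] <- u32be(adler32(data))
  do.call(c, out)
}

#' Write a matrix as 16-bit grayscale PNG
#'
#' Values in `[0, 1]` are quantized to 16 bits.  Use `scale` to store e.g.
#' disparity in x256 fixed point: `write_png16(d * 256 / 65535, path)` or
#' simply pass `disparity` with `scale = 256`.
#' @param x H x W matrix; with `scale`, raw values are mapped as
#'   `round(x * scale)` 16-bit counts
#' @param path output file
#' @param scale optional fixed-point factor (e.g. 256 for disparity)
#' @export
write_png16 <- function(x, path, scale = NULL) {
  v <- if (is.null(scale)) round(x * 65535) else round(x * scale)
  if (any(v < 0 | v > 65535)) stop("values exceed the 16-bit range after scaling")
  H <- nrow(v); W <- ncol(v)
  # scanlines: filter byte 0 + big-endian 16-bit samples
  vt <- t(v)
  hi <- as.raw(vt %/% 256); lo <- as.raw(vt %% 256)
  px <- as.vector(rbind(hi, lo))
  dim(px) <- NULL
  rows_raw <- matrix(px, nrow = 2L * W)
  scan <- as.raw(unlist(lapply(seq_len(H), function(r) c(as.raw(0), rows_raw[, r]))))
  ihdr <- c(u32be(W), u32be(H), as.raw(c(16, 0, 0, 0, 0)))  # 16-bit grayscale
  out <- c(as.raw(c(137, 80, 78, 71, 13, 10, 26, 10)),
           png_chunk("IHDR", ihdr),
           png_chunk("IDAT", zlib_stored(scan)),
           png_chunk("IEND", raw(0)))
  writeBin(out, path)
  invisible(path)
}

#' Write an image or mask as 8-bit PNG
#' @param x H x W (x3) array in `[0, 1]` or a logical mask (stored as 0/255)
#' @param path output file
#' @export
write_png8 <- function(x, path) {
  if (is.logical(x)) x <- x * 1
  png::writePNG(pmin(pmax(x, 0), 1), path)
  invisible(path)
}

#' Save a stereo sample to a directory
#'
#' Writes left/right 8-bit PNGs, disparity as PFM and 16-bit x256 PNG, the
#' validity and instrument masks as 0/255 PNGs, and a JSON sidecar with the
#' generation metadata.
#' @param sample a [stereo_sample()]
#' @param dir output directory (created if needed)
#' @param meta named list stored in the JSON sidecar (seed, shift, rig, ...)
#' @export
save_stereo_sample <- function(sample, dir, meta = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_png8(sample$left, file.path(dir, "left.png"))
  write_png8(sample$right, file.path(dir, "right.png"))
  if (!is.null(sample$disparity)) {
    write_pfm(sample$disparity, file.path(dir, "disparity.pfm"))
    write_png16(sample$disparity, file.path(dir, "disparity16.png"), scale = 256)
  }
  if (!is.null(sample$valid)) write_png8(sample$valid, file.path(dir, "valid.png"))
  if (!is.null(sample$mask)) write_png8(sample$mask, file.path(dir, "mask.png"))
  meta$image_size <- dim(sample$left)[1:2]
  jsonlite::write_json(meta, file.path(dir, "sample.json"), auto_unbox = TRUE)
  invisible(dir)
}
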