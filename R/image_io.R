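# Image containers and I/O.
#
# An RGB image is a numeric array H x W x 3 with values in [0, 1]; a mask is a
# logical H x W matrix. Images are stored on disk as binary NetPBM files
# (PPM/P6 for RGB, PGM/P5 for masks): a self-describing, dependency-free
# raster format readable by every common image tool.

#' Write an RGB image as binary PPM (P6)
#'
#' @param img numeric array `H x W x 3`, values in `[0, 1]`.
#' @param path output file path.
#' @export
write_ppm <- function(img, path) {
  stopifnot(length(dim(img)) == 3L, dim(img)[3] == 3L)
  h <- dim(img)[1]; w <- dim(img)[2]
  px <- pmin(pmax(round(img * 255), 0), 255)
  # interleave channels, row-major pixel order
  flat <- aperm(px, c(3L, 2L, 1L))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(sprintf("P6\n%d %d\n255\n", w, h), con, eos = NULL)
  writeBin(as.integer(flat), con, size = 1L)
  invisible(path)
}

#' Write a mask or grayscale image as binary PGM (P5)
#'
#' @param m logical or numeric matrix; logical masks are written as 0/255.
#' @param path output file path.
#' @export
write_pgm <- function(m, path) {
  stopifnot(is.matrix(m))
  h <- nrow(m); w <- ncol(m)
  px <- if (is.logical(m)) ifelse(m, 255L, 0L) else pmin(pmax(round(m * 255), 0), 255)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(sprintf("P5\n%d %d\n255\n", w, h), con, eos = NULL)
  writeBin(as.integer(t(px)), con, size = 1L)
  invisible(path)
}

read_pnm_header <- function(con) {
  magic <- readChar(con, 2L)
  vals <- integer(0)
  while (length(vals) < 3L) {
    ch <- readChar(con, 1L)
    if (ch == "#") {
      repeat {
        ch <- readChar(con, 1L)
        if (ch == "\n") break
      }
    } else if (grepl("[0-9]", ch)) {
      num <- ch
      repeat {
        ch <- readChar(con, 1L)
        if (!grepl("[0-9]", ch)) break
        num <- paste0(num, ch)
      }
      vals <- c(vals, as.integer(num))
    }
  }
  list(magic = magic, w = vals[1], h = vals[2], maxval = vals[3])
}

#' Read a binary PPM (P6) image
#' @param path file path.
#' @return numeric array `H x W x 3` in `[0, 1]`.
#' @export
read_ppm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hd <- read_pnm_header(con)
  if (hd$magic != "P6") stop("not a P6 PPM file: ", path)
  raw <- readBin(con, "integer", n = 3L * hd$w * hd$h, size = 1L, signed = FALSE)
  aperm(array(raw / hd$maxval, dim = c(3L, hd$w, hd$h)), c(3L, 2L, 1L))
}

#' Read a binary PGM (P5) image
#' @param path file path.
#' @param as_mask logical; return a logical matrix (`value > 0.5`)?
#' @return numeric (or logical) `H x W` matrix.
#' @export
read_pgm <- function(path, as_mask = FALSE) {
  con <- file(path, "rb")
  on.exit(close(con))
  hd <- read_pnm_header(con)
  if (hd$magic != "P5") stop("not a P5 PGM file: ", path)
  raw <- readBin(con, "integer", n = hd$w * hd$h, size = 1L, signed = FALSE)
  m <- t(matrix(raw / hd$maxval, hd$w, hd$h))
  if (as_mask) m > 0.5 else m
}

#' Bilinear resize of an RGB image
#'
#' @param img numeric array `H x W x 3`.
#' @param out_h,out_w target size in pixels.
#' @return resized array `out_h x out_w x 3`.
#' @export
resize_bilinear <- function(img, out_h, out_w) {
  h <- dim(img)[1]; w <- dim(img)[2]
  if (h == out_h && w == out_w) return(img)
  # map output pixel centres onto input pixel centres
  ys <- (seq_len(out_h) - 0.5) * h / out_h + 0.5
  xs <- (seq_len(out_w) - 0.5) * w / out_w + 0.5
  y0 <- pmin(pmax(floor(ys), 1), h); y1 <- pmin(y0 + 1, h)
  x0 <- pmin(pmax(floor(xs), 1), w); x1 <- pmin(x0 + 1, w)
  wy <- pmin(pmax(ys - y0, 0), 1)
  wx <- pmin(pmax(xs - x0, 0), 1)
  out <- array(0, dim = c(out_h, out_w, dim(img)[3]))
  for (ch in seq_len(dim(img)[3])) {
    m <- img[, , ch]
    top <- m[y0, x0, drop = FALSE] * (1 - wx)[col(matrix(0, out_h, out_w))] +
      m[y0, x1, drop = FALSE] * wx[col(matrix(0, out_h, out_w))]
    bot <- m[y1, x0, drop = FALSE] * (1 - wx)[col(matrix(0, out_h, out_w))] +
      m[y1, x1, drop = FALSE] * wx[col(matrix(0, out_h, out_w))]
    out[, , ch] <- top * (1 - wy) + bot * wy
  }
  out
}
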