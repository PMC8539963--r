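#' Load an image as a float field
#'
#' Reads an 8- or 16-bit PNG, PPM (binary P6) or PGM (binary P5) file and
#' normalises intensities to \[0, 1\] (`value / maxval`). Greyscale files
#' yield a single-channel field; a PNG alpha channel, if present, is
#' dropped.
#'
#' @param path File path; format chosen by extension
#'   (`.png`, `.ppm`, `.pgm`).
#' @return An image field `H x W x C`.
#' @export
load_image <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = {
      x <- try(png::readPNG(path), silent = TRUE)
      if (inherits(x, "try-error")) {
        stop("cannot read PNG file: ", path, call. = FALSE)
      }
      if (length(dim(x)) == 3L && dim(x)[3] %in% c(2L, 4L)) {
        x <- x[, , -dim(x)[3], drop = FALSE]   # drop alpha
      }
      x
    },
    ppm = .read_pnm(path),
    pgm = .read_pnm(path),
    stop("unsupported image format '.", ext, "' (PNG, PPM or PGM expected): ",
         path, call. = FALSE)
  )
  as_image_field(img)
}

#' Save an image to PNG or PPM/PGM
#'
#' Clips to \[0, 1\], quantises to 8 bits with round-half-up
#' (`floor(255 v + 0.5)`), and writes the format implied by the file
#' extension. The explicit quantisation convention keeps golden-image
#' comparisons stable across platforms.
#'
#' @param image Image field (any finite values; clipped here).
#' @param path Output path ending in `.png`, `.ppm` or `.pgm`.
#' @return The path, invisibly.
#' @export
save_image <- function(image, path) {
  u <- as_image_field(image, check = FALSE)
  if (!all(is.finite(u))) stop("image contains non-finite values", call. = FALSE)
  u[u < 0] <- 0
  u[u > 1] <- 1
  q <- floor(255 * u + 0.5)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    x <- q / 255
    if (dim(x)[3] == 1L) x <- x[, , 1L]
    png::writePNG(x, target = path)
  } else if (ext %in% c("ppm", "pgm")) {
    .write_pnm(q, path)
  } else {
    stop("unsupported output format '.", ext, "' (PNG, PPM or PGM expected)",
         call. = FALSE)
  }
  invisible(path)
}

# --- minimal binary PNM (P5/P6) support ------------------------------------
# No installed package reads PPM; the format is a trivial header plus raw
# samples, so it is implemented directly here.

.read_pnm <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  pos <- 1L
  n <- length(raw)
  skip_ws <- function(pos) {
    while (pos <= n) {
      b <- as.integer(raw[pos])
      if (b == 35L) {                       # '#' comment to end of line
        while (pos <= n && as.integer(raw[pos]) != 10L) pos <- pos + 1L
      } else if (b %in% c(9L, 10L, 13L, 32L)) {
        pos <- pos + 1L
      } else break
    }
    pos
  }
  read_token <- function(pos) {
    pos <- skip_ws(pos)
    start <- pos
    while (pos <= n && !as.integer(raw[pos]) %in% c(9L, 10L, 13L, 32L)) {
      pos <- pos + 1L
    }
    list(token = rawToChar(raw[start:(pos - 1L)]), pos = pos)
  }
  tk <- read_token(pos)
  magic <- tk$token
  if (!magic %in% c("P5", "P6")) {
    stop("unsupported PNM file (binary P5/P6 expected, got '", magic, "'): ",
         path, call. = FALSE)
  }
  tk <- read_token(tk$pos); width <- as.integer(tk$token)
  tk <- read_token(tk$pos); height <- as.integer(tk$token)
  tk <- read_token(tk$pos); maxval <- as.integer(tk$token)
  if (anyNA(c(width, height, maxval)) || width < 1L || height < 1L ||
      maxval < 1L || maxval > 65535L) {
    stop("malformed PNM header in ", path, call. = FALSE)
  }
  pos <- tk$pos + 1L                        # single whitespace after maxval
  channels <- if (magic == "P6") 3L else 1L
  nsamp <- width * height * channels
  if (maxval < 256L) {
    needed <- nsamp
    if (n - pos + 1L < needed) stop("truncated PNM data in ", path, call. = FALSE)
    vals <- as.integer(raw[pos:(pos + needed - 1L)])
  } else {
    needed <- 2L * nsamp
    if (n - pos + 1L < needed) stop("truncated PNM data in ", path, call. = FALSE)
    b <- as.integer(raw[pos:(pos + needed - 1L)])
    vals <- 256L * b[seq(1L, needed, 2L)] + b[seq(2L, needed, 2L)]  # big-endian
  }
  # PNM is row-major, samples interleaved by channel
  arr <- aperm(array(vals, c(channels, width, height)), c(3L, 2L, 1L))
  arr / maxval
}

.write_pnm <- function(q, path) {
  d <- dim(q)
  channels <- d[3]
  magic <- if (channels == 3L) "P6" else "P5"
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(sprintf("%s\n%d %d\n255\n", magic, d[2], d[1]), con, eos = NULL)
  writeBin(as.raw(aperm(q, c(3L, 2L, 1L))), con)
  invisible(path)
}
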