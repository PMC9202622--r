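#' Read a PGM image
#'
#' Reads a portable gray map (plain `P2` or binary `P5`) into a numeric
#' matrix with values in `[0, maxval]`. PGM is the format the reference
#' angiogram ground-truth masks are distributed in.
#'
#' @param path Path to a `.pgm` file.
#' @return Numeric matrix (rows x columns) of pixel intensities.
#' @export
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 2L, useBytes = TRUE)
  if (!magic %in% c("P2", "P5")) stop_config("not a PGM file (magic %s)", magic)
  toks <- character(0)
  # header: width height maxval, with '#' comments allowed
  read_tok <- function() {
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (length(ch) == 0 || ch == "") stop_config("truncated PGM header")
      if (grepl("[ \t\r\n]", ch)) next
      if (ch == "#") {
        repeat {
          ch <- readChar(con, 1L, useBytes = TRUE)
          if (ch == "\n" || ch == "") break
        }
        next
      }
      tok <- ch
      repeat {
        ch <- readChar(con, 1L, useBytes = TRUE)
        if (ch == "" || grepl("[ \t\r\n#]", ch)) break
        tok <- paste0(tok, ch)
      }
      return(tok)
    }
  }
  w <- as.integer(read_tok()); h <- as.integer(read_tok())
  maxval <- as.integer(read_tok())
  n <- w * h
  if (magic == "P5") {
    raw <- readBin(con, "integer", n = n, size = if (maxval > 255) 2L else 1L,
                   signed = FALSE, endian = "big")
    vals <- raw
  } else {
    rest <- readChar(con, file.size(path), useBytes = TRUE)
    vals <- as.integer(strsplit(trimws(rest), "[ \t\r\n]+")[[1]])[seq_len(n)]
  }
  matrix(vals, nrow = h, ncol = w, byrow = TRUE)
}

#' Write a PGM image
#'
#' Writes a numeric matrix as binary (`P5`) or plain (`P2`) PGM with
#' `maxval` 255; values are clipped and rounded.
#'
#' @param img Numeric matrix.
#' @param path Output path.
#' @param ascii Write plain-text `P2` instead of binary `P5`.
#' @return Invisibly, `path`.
#' @export
write_pgm <- function(img, path, ascii = FALSE) {
  check_image(img)
  v <- as.integer(round(clamp(img, 0, 255)))
  m <- matrix(v, nrow(img), ncol(img))
  if (ascii) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("P2", paste(ncol(m), nrow(m)), "255"), con)
    write(t(m), file = con, ncolumns = ncol(m))
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeChar(sprintf("P5\n%d %d\n255\n", ncol(m), nrow(m)), con, eos = NULL)
    writeBin(as.integer(t(m)), con, size = 1L)
  }
  invisible(path)
}

#' Read a grayscale image (PGM or PNG)
#'
#' PNG images are converted to grayscale in `[0, 255]` (luma average over
#' channels when RGB).
#'
#' @param path Path ending in `.pgm` or `.png`.
#' @return Numeric matrix of intensities in `[0, 255]`.
#' @export
read_angio_image <- function(path) {
  if (grepl("\\.pgm$", path, ignore.case = TRUE)) return(read_pgm(path))
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    a <- png::readPNG(path)
    if (length(dim(a)) == 3) a <- apply(a[, , 1:min(3, dim(a)[3]), drop = FALSE], c(1, 2), mean)
    return(a * 255)
  }
  stop_config("unsupported image format: %s", path)
}

#' Write a grayscale image (PGM or PNG)
#'
#' @param img Numeric matrix in `[0, 255]`.
#' @param path Path ending in `.pgm` or `.png`.
#' @return Invisibly, `path`.
#' @export
write_angio_image <- function(img, path) {
  if (grepl("\\.pgm$", path, ignore.case = TRUE)) return(write_pgm(img, path))
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::writePNG(clamp(img / 255, 0, 1), path)
    return(invisible(path))
  }
  stop_config("unsupported image format: %s", path)
}
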