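#' Read and write PGM images
#'
#' Minimal portable-graymap support (types P2 ASCII and P5 binary, maxval
#' <= 255) used for frame-sequence directories. No image package in the
#' dependency stack handles this trivial format, so it is implemented here.
#'
#' @param path file path.
#' @param img numeric matrix with values in \[0, 255\].
#' @param ascii write ASCII (P2) instead of binary (P5).
#' @return `read_pgm` returns a numeric matrix (rows = image rows).
#' @export
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 2L, useBytes = TRUE)
  if (!magic %in% c("P2", "P5")) stop("not a PGM file: ", path)
  vals <- integer(3)
  got <- 0L
  # header tokens: width, height, maxval; '#' starts a comment line
  tok <- ""
  while (got < 3L) {
    ch <- readChar(con, 1L, useBytes = TRUE)
    if (length(ch) == 0L || !nzchar(ch)) stop("truncated PGM header: ", path)
    if (ch == "#") {
      repeat {
        ch <- readChar(con, 1L, useBytes = TRUE)
        if (!nzchar(ch) || ch == "\n") break
      }
      ch <- " "
    }
    if (grepl("[0-9]", ch)) {
      tok <- paste0(tok, ch)
    } else if (nzchar(tok)) {
      got <- got + 1L
      vals[got] <- as.integer(tok)
      tok <- ""
    }
  }
  w <- vals[1]; h <- vals[2]; maxval <- vals[3]
  if (maxval > 255L) stop("only 8-bit PGM supported: ", path)
  n <- as.integer(w) * as.integer(h)
  px <- if (magic == "P5") {
    as.integer(readBin(con, "raw", n))
  } else {
    as.integer(scan(con, integer(), n = n, quiet = TRUE))
  }
  if (length(px) < n) stop("truncated PGM pixel data: ", path)
  matrix(px, nrow = h, ncol = w, byrow = TRUE)
}

#' @rdname read_pgm
#' @export
write_pgm <- function(img, path, ascii = FALSE) {
  img <- round(as.matrix(img))
  if (any(img < 0 | img > 255)) stop("pixel values must be in [0, 255]")
  h <- nrow(img); w <- ncol(img)
  if (ascii) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("P2", paste(w, h), "255"), con)
    write(t(img), con, ncolumns = w)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeChar(paste0("P5\n", w, " ", h, "\n255\n"), con, eos = NULL)
    writeBin(as.raw(t(img)), con)
  }
  invisible(path)
}
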