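## Minimal NumPy .npy (format version 1.0) support for float32/float64 arrays.
## Only what the MRNet-style exam layout needs: C-ordered numeric arrays of
## arbitrary rank, little-endian.

#' Write a numeric array to a NumPy .npy file
#'
#' Writes a base-R numeric array (or vector/matrix) as a little-endian,
#' C-ordered NumPy array in format version 1.0.
#'
#' @param x numeric vector, matrix or array.
#' @param path output file path.
#' @param dtype element type on disk, `"float32"` (default) or `"float64"`.
#' @return `path`, invisibly.
#' @export
writeNpy <- function(x, path, dtype = c("float32", "float64")) {
  dtype <- match.arg(dtype)
  if (!is.numeric(x)) stop("writeNpy: 'x' must be numeric")
  dims <- dim(x)
  if (is.null(dims)) dims <- length(x)
  descr <- if (dtype == "float32") "<f4" else "<f8"
  shape <- if (length(dims) == 1L) sprintf("(%d,)", dims) else
    sprintf("(%s)", paste(dims, collapse = ", "))
  header <- sprintf("{'descr': '%s', 'fortran_order': False, 'shape': %s, }",
                    descr, shape)
  ## magic(6) + version(2) + headerlen(2) + header must be a multiple of 64
  unpadded <- 10L + nchar(header, type = "bytes") + 1L
  pad <- (64L - unpadded %% 64L) %% 64L
  header <- paste0(header, strrep(" ", pad), "\n")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x93, charToRaw("NUMPY"), 0x01, 0x00)), con)
  writeBin(as.integer(nchar(header, type = "bytes")), con, size = 2,
           endian = "little")
  writeChar(header, con, eos = NULL)
  ## C order: last index varies fastest -> reverse-permute the column-major array
  v <- if (length(dims) > 1L) as.vector(aperm(x, rev(seq_along(dims)))) else
    as.vector(x)
  writeBin(v, con, size = if (dtype == "float32") 4L else 8L,
           endian = "little")
  invisible(path)
}

#' Read a NumPy .npy file into an R array
#'
#' Supports format versions 1.x with little-endian float32/float64 (and
#' integer) C- or Fortran-ordered data, which covers the MRNet-style layout
#' written by [writeNpy()].
#'
#' @param path file path.
#' @return numeric array with the stored shape (a vector for rank-1 data).
#' @export
readNpy <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 6L)
  if (length(magic) < 6L ||
      !identical(magic, as.raw(c(0x93, charToRaw("NUMPY")))))
    stop("readNpy: not an NPY file: ", path)
  ver <- readBin(con, "raw", n = 2L)
  if (as.integer(ver[1]) != 1L)
    stop("readNpy: unsupported NPY format version ", as.integer(ver[1]))
  hlen <- readBin(con, "integer", n = 1L, size = 2L, endian = "little",
                  signed = FALSE)
  header <- readChar(con, hlen, useBytes = TRUE)
  descr <- sub(".*'descr':\\s*'([^']+)'.*", "\\1", header)
  fortran <- grepl("'fortran_order':\\s*True", header)
  shapeStr <- sub(".*'shape':\\s*\\(([^)]*)\\).*", "\\1", header)
  dims <- as.integer(strsplit(gsub("\\s", "", shapeStr), ",")[[1]])
  dims <- dims[!is.na(dims)]
  n <- if (length(dims)) prod(dims) else 1L
  elt <- switch(descr,
    "<f4" = list(what = "numeric", size = 4L),
    "<f8" = list(what = "numeric", size = 8L),
    "<i4" = list(what = "integer", size = 4L),
    "<i8" = list(what = "integer", size = 8L),
    stop("readNpy: unsupported dtype ", descr))
  v <- readBin(con, elt$what, n = n, size = elt$size, endian = "little")
  if (length(v) != n) stop("readNpy: truncated data in ", path)
  if (length(dims) <= 1L) return(as.numeric(v))
  if (fortran) array(v, dim = dims) else
    aperm(array(v, dim = rev(dims)), rev(seq_along(dims)))
}
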