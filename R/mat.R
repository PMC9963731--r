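# Minimal MATLAB v5 (Level 5 MAT-file) import: numeric arrays only,
# uncompressed and zlib-compressed data elements. Read-only by design; used
# to import public cubes distributed as .mat.

.miSpec <- function(type) {
  switch(as.character(type),
    "1" = list(what = "integer", size = 1L, signed = TRUE),    # miINT8
    "2" = list(what = "integer", size = 1L, signed = FALSE),   # miUINT8
    "3" = list(what = "integer", size = 2L, signed = TRUE),    # miINT16
    "4" = list(what = "integer", size = 2L, signed = FALSE),   # miUINT16
    "5" = list(what = "integer", size = 4L, signed = TRUE),    # miINT32
    "6" = list(what = "integer", size = 4L, signed = TRUE),    # miUINT32*
    "7" = list(what = "double",  size = 4L, signed = TRUE),    # miSINGLE
    "9" = list(what = "double",  size = 8L, signed = TRUE),    # miDOUBLE
    NULL)
}

.matCursor <- function(raw, endian) {
  env <- new.env(parent = emptyenv())
  env$raw <- raw; env$pos <- 1L; env$endian <- endian
  env
}

.matTake <- function(cur, n) {
  if (cur$pos + n - 1L > length(cur$raw)) stop("truncated MAT element")
  out <- cur$raw[cur$pos:(cur$pos + n - 1L)]
  cur$pos <- cur$pos + n
  out
}

.matInt <- function(bytes, endian, size = 4L, signed = TRUE) {
  readBin(bytes, "integer", n = length(bytes) %/% size, size = size,
          signed = signed, endian = endian)
}

# Returns list(type, data raw vector); handles the packed small-element form.
.matReadElement <- function(cur) {
  head4 <- .matTake(cur, 4L)
  upper <- if (cur$endian == "little") head4[3:4] else head4[1:2]
  if (any(upper != as.raw(0))) {           # small element: size in upper 16
    type <- .matInt(if (cur$endian == "little") c(head4[1:2], raw(2))
                    else c(raw(2), head4[3:4]), cur$endian)
    nb <- .matInt(if (cur$endian == "little") c(upper, raw(2))
                  else c(raw(2), upper), cur$endian)
    data <- .matTake(cur, 4L)[seq_len(nb)]
  } else {
    type <- .matInt(head4, cur$endian)
    nb <- .matInt(.matTake(cur, 4L), cur$endian)
    data <- .matTake(cur, nb)
    pad <- (8L - nb %% 8L) %% 8L
    if (pad > 0 && cur$pos + pad - 1L <= length(cur$raw)) .matTake(cur, pad)
  }
  list(type = type, data = data)
}

.matParseMatrix <- function(payload, endian) {
  cur <- .matCursor(payload, endian)
  flagsEl <- .matReadElement(cur)                  # array flags (miUINT32 x2)
  classId <- as.integer(flagsEl$data[if (endian == "little") 1L else 4L])
  if (!classId %in% 6:15)                          # numeric mx classes only
    stop("unsupported MAT array class ", classId)
  dimsEl <- .matReadElement(cur)
  dims <- .matInt(dimsEl$data, endian)
  nameEl <- .matReadElement(cur)
  name <- rawToChar(nameEl$data[nameEl$data != as.raw(0)])
  dataEl <- .matReadElement(cur)
  spec <- .miSpec(dataEl$type)
  if (is.null(spec)) stop("unsupported MAT data type ", dataEl$type)
  v <- readBin(dataEl$data, spec$what, n = length(dataEl$data) %/% spec$size,
               size = spec$size, signed = spec$signed, endian = endian)
  if (dataEl$type == 6L) {                         # miUINT32 read as signed
    v <- as.numeric(v); v[v < 0] <- v[v < 0] + 2^32
  }
  v <- as.numeric(v)
  if (prod(dims) != length(v))
    stop("MAT dims/payload mismatch for variable '", name, "'")
  list(name = name, value = array(v, dim = dims))  # column-major matches R
}

#' Import numeric arrays from a MATLAB v5 file
#'
#' Minimal read-only importer for Level 5 MAT-files: numeric (real) arrays
#' of any dimensionality, stored plainly or as zlib-compressed elements.
#' Cell arrays, structs, sparse, complex and character data are not
#' supported.
#'
#' @param path path to the .mat file.
#' @return Named list of numeric arrays.
#' @seealso [readCube()] with \code{format = "mat"}.
#' @export
readMat5 <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  header <- readBin(con, "raw", 128L)
  if (length(header) < 128L) stop("not a MAT v5 file (short header): ", path)
  ind <- rawToChar(header[127:128])
  endian <- if (ind == "IM") "little" else if (ind == "MI") "big"
            else stop("not a MAT v5 file (bad endian indicator): ", path)
  out <- list()
  repeat {
    tag <- readBin(con, "raw", 8L)
    if (length(tag) < 8L) break
    type <- .matInt(if (endian == "little") tag[1:4] else tag[1:4], endian)
    nb <- .matInt(tag[5:8], endian)
    payload <- readBin(con, "raw", nb)
    pad <- (8L - nb %% 8L) %% 8L
    if (pad > 0) readBin(con, "raw", pad)
    el <- NULL
    if (type == 15L) {                              # miCOMPRESSED
      full <- memDecompress(payload, type = "gzip")
      cur <- .matCursor(full, endian)
      inner <- .matReadElement(cur)
      if (inner$type == 14L)
        el <- tryCatch(.matParseMatrix(inner$data, endian),
                       error = function(e) NULL)
    } else if (type == 14L) {                       # miMATRIX
      el <- tryCatch(.matParseMatrix(payload, endian),
                     error = function(e) NULL)
    }
    if (!is.null(el)) out[[el$name]] <- el$value
  }
  out
}
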