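#' Read and write point clouds
#'
#' Supported formats: whitespace-separated ASCII XYZ (a single header row is
#' auto-detected and skipped), PLY (ascii and binary_little_endian, vertex
#' x/y/z properties) and LAS 1.2 point format 0. XYZ (17 significant
#' digits) and binary PLY (float64 properties) round-trip coordinates at
#' full double precision; LAS quantizes to its coordinate scale (0.0001 m
#' here).
#'
#' @param path file path
#' @param format `"xyz"`, `"ply"` or `"las"`; guessed from the extension
#'   when missing
#' @return `read_cloud`: a `point_cloud`
#' @export
read_cloud <- function(path, format = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  format <- format %||% guess_format(path)
  switch(format,
         xyz = read_xyz(path),
         ply = read_ply(path),
         las = read_las(path),
         stop("unknown point-cloud format: ", format))
}

#' @rdname read_cloud
#' @param cloud a `point_cloud`
#' @param binary for PLY: write `binary_little_endian` (default) or ascii
#' @export
write_cloud <- function(cloud, path, format = NULL, binary = TRUE) {
  stopifnot(inherits(cloud, "point_cloud"))
  format <- format %||% guess_format(path)
  switch(format,
         xyz = write_xyz(cloud, path),
         ply = write_ply(cloud, path, binary = binary),
         las = write_las(cloud, path),
         stop("unknown point-cloud format: ", format))
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("xyz", "txt", "asc")) return("xyz")
  if (ext %in% c("ply", "las")) return(ext)
  stop("cannot guess point-cloud format from extension '", ext, "'")
}

read_xyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty XYZ file: ", path)
  first <- strsplit(trimws(lines[1]), "\\s+|,")[[1]]
  skip <- suppressWarnings(any(is.na(as.numeric(first))))
  if (skip) lines <- lines[-1]
  if (length(lines) == 0) stop("XYZ file has a header but no data: ", path)
  parts <- strsplit(trimws(lines), "\\s+|,")
  nc <- lengths(parts)
  if (any(nc < 3))
    stop("malformed XYZ record at line ", which(nc < 3)[1] + skip,
         " of ", path)
  m <- suppressWarnings(
    matrix(as.numeric(unlist(lapply(parts, `[`, 1:3))), ncol = 3,
           byrow = TRUE))
  if (any(is.na(m)))
    stop("non-numeric coordinate near line ",
         which(rowSums(is.na(m)) > 0)[1] + skip, " of ", path)
  point_cloud(m)
}

write_xyz <- function(cloud, path) {
  m <- cloud$xyz
  lines <- sprintf("%.17g %.17g %.17g", m[, 1], m[, 2], m[, 3])
  writeLines(lines, path)
}

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character(0)
  repeat {
    ln <- readLines(con, n = 1)
    if (length(ln) == 0) stop("unexpected end of PLY header in ", path)
    header <- c(header, ln)
    if (trimws(ln) == "end_header") break
    if (length(header) > 200) stop("malformed PLY header in ", path)
  }
  if (header[1] != "ply") stop("not a PLY file: ", path)
  fmt_line <- grep("^format ", header, value = TRUE)
  if (length(fmt_line) != 1) stop("missing PLY format line in ", path)
  fmt <- strsplit(trimws(fmt_line), "\\s+")[[1]][2]
  ve_line <- grep("^element vertex ", header, value = TRUE)
  if (length(ve_line) != 1) stop("missing vertex element in ", path)
  nv <- as.integer(strsplit(trimws(ve_line), "\\s+")[[1]][3])
  # properties of the vertex element (assume it is the first element)
  el_idx <- grep("^element ", header)
  v_at <- which(header == ve_line[1])[1]
  next_el <- el_idx[el_idx > v_at]
  p_end <- if (length(next_el)) next_el[1] - 1 else length(header) - 1
  props <- header[(v_at + 1):p_end]
  props <- props[grepl("^property ", props)]
  pp <- do.call(rbind, strsplit(trimws(props), "\\s+"))
  types <- pp[, 2]; names_p <- pp[, 3]
  sizes <- c(char = 1, uchar = 1, int8 = 1, uint8 = 1, short = 2,
             ushort = 2, int16 = 2, uint16 = 2, int = 4, uint = 4,
             int32 = 4, uint32 = 4, float = 4, float32 = 4, double = 8,
             float64 = 8)
  if (!all(types %in% names(sizes)))
    stop("unsupported PLY property type in ", path)
  if (!all(c("x", "y", "z") %in% names_p))
    stop("PLY vertex element lacks x/y/z properties in ", path)
  if (fmt == "ascii") {
    txt <- readLines(con)
    txt <- txt[nzchar(trimws(txt))][seq_len(nv)]
    m <- matrix(as.numeric(unlist(strsplit(trimws(txt), "\\s+"))),
                ncol = length(names_p), byrow = TRUE)
    xyz <- m[, match(c("x", "y", "z"), names_p), drop = FALSE]
  } else if (fmt == "binary_little_endian") {
    rec <- sum(sizes[types])
    raw <- readBin(con, "raw", n = nv * rec)
    if (length(raw) < nv * rec) stop("truncated PLY payload in ", path)
    offs <- cumsum(c(0, sizes[types]))[seq_along(types)]
    read_col <- function(k) {
      type <- types[k]; sz <- sizes[type]
      idx <- rep(offs[k] + seq_len(sz), nv) +
        rep((seq_len(nv) - 1) * rec, each = sz)
      b <- raw[idx]
      if (type %in% c("float", "float32"))
        readBin(b, "double", n = nv, size = 4, endian = "little")
      else if (type %in% c("double", "float64"))
        readBin(b, "double", n = nv, size = 8, endian = "little")
      else
        readBin(b, "integer", n = nv, size = sz, endian = "little",
                signed = !(type %in% c("uchar", "uint8", "ushort",
                                       "uint16")))
    }
    xyz <- cbind(read_col(which(names_p == "x")),
                 read_col(which(names_p == "y")),
                 read_col(which(names_p == "z")))
  } else stop("unsupported PLY format '", fmt, "' in ", path)
  point_cloud(xyz)
}

write_ply <- function(cloud, path, binary = TRUE) {
  m <- cloud$xyz
  n <- nrow(m)
  hdr <- c("ply",
           if (binary) "format binary_little_endian 1.0"
           else "format ascii 1.0",
           sprintf("element vertex %d", n),
           "property double x", "property double y", "property double z",
           "end_header")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con)
  if (binary) {
    writeBin(as.vector(t(m)), con, size = 8, endian = "little")
  } else {
    writeLines(sprintf("%.17g %.17g %.17g", m[, 1], m[, 2], m[, 3]), con)
  }
}

las_scale <- 1e-4

write_las <- function(cloud, path) {
  m <- cloud$xyz
  n <- nrow(m)
  off <- if (n > 0) apply(m, 2, min) else c(0, 0, 0)
  con <- file(path, "wb")
  on.exit(close(con))
  wb <- function(x, size, type = "integer")
    writeBin(if (type == "integer") as.integer(x) else as.numeric(x), con,
             size = size, endian = "little")
  writeChar("LASF", con, nchars = 4, eos = NULL)
  wb(0, 2); wb(0, 2)                      # source id, global encoding
  wb(rep(0, 16), 1)                       # GUID
  wb(1, 1); wb(2, 1)                      # version 1.2
  writeChar(formatC("nadirchm", width = -32), con, nchars = 32, eos = NULL)
  writeChar(formatC("nadirchm", width = -32), con, nchars = 32, eos = NULL)
  wb(1, 2); wb(2026, 2)                   # day, year
  wb(227, 2)                              # header size
  wb(227, 4)                              # offset to point data
  wb(0, 4)                                # number of VLRs
  wb(0, 1)                                # point data format 0
  wb(20, 2)                               # point record length
  wb(n, 4)                                # number of point records
  wb(c(n, 0, 0, 0, 0), 4)                 # points by return
  wb(rep(las_scale, 3), 8, "double")      # xyz scale
  wb(off, 8, "double")                    # xyz offset
  mm <- if (n > 0) c(max(m[, 1]), min(m[, 1]), max(m[, 2]), min(m[, 2]),
                     max(m[, 3]), min(m[, 3])) else rep(0, 6)
  wb(mm, 8, "double")
  if (n > 0) {
    xi <- as.integer(round((m[, 1] - off[1]) / las_scale))
    yi <- as.integer(round((m[, 2] - off[2]) / las_scale))
    zi <- as.integer(round((m[, 3] - off[3]) / las_scale))
    rec <- raw(20 * n)
    ints <- rbind(xi, yi, zi)
    coord_raw <- writeBin(as.vector(ints), raw(), size = 4,
                          endian = "little")
    pos <- rep((seq_len(n) - 1) * 20, each = 12) + seq_len(12)
    rec[pos] <- coord_raw
    writeBin(rec, con)
  }
}

read_las <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  sig <- readChar(con, 4, useBytes = TRUE)
  if (!identical(sig, "LASF")) stop("not a LAS file: ", path)
  seek(con, 96)
  offset_data <- readBin(con, "integer", size = 4, endian = "little")
  seek(con, 104)
  fmt <- readBin(con, "integer", size = 1, endian = "little")
  rec_len <- readBin(con, "integer", size = 2, endian = "little")
  np <- readBin(con, "integer", size = 4, endian = "little")
  seek(con, 131)
  scl <- readBin(con, "double", n = 3, size = 8, endian = "little")
  off <- readBin(con, "double", n = 3, size = 8, endian = "little")
  seek(con, offset_data)
  raw <- readBin(con, "raw", n = np * rec_len)
  if (length(raw) < np * rec_len) stop("truncated LAS payload in ", path)
  idx <- rep((seq_len(np) - 1) * rec_len, each = 12) + seq_len(12)
  ints <- readBin(raw[idx], "integer", n = 3 * np, size = 4,
                  endian = "little")
  ints <- matrix(ints, ncol = 3, byrow = TRUE)
  point_cloud(sweep(sweep(ints, 2, scl, `*`), 2, off, `+`))
}
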