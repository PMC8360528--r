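#' Read a triangle mesh from OFF, OBJ, PLY, or vertex/face tables
#'
#' ASCII readers for the common small-mesh interchange formats plus plain
#' whitespace/comma-delimited vertex and face tables. All faces must be
#' triangles; the result is validated and consistently oriented by
#' [triangle_mesh()].
#'
#' @param path file path (for \code{format = "tables"}, the vertex table;
#'   pass the face table via \code{faces_path}).
#' @param format one of \code{"off"}, \code{"obj"}, \code{"ply"},
#'   \code{"tables"}; default guesses from the file extension.
#' @param faces_path face-table path when \code{format = "tables"}.
#' @param ... passed to [triangle_mesh()].
#' @return a \code{triangle_mesh}.
#' @export
read_mesh <- function(path, format = NULL, faces_path = NULL, ...) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(format)) {
    format <- tolower(tools::file_ext(path))
    if (!format %in% c("off", "obj", "ply")) format <- "tables"
  }
  format <- match.arg(tolower(format), c("off", "obj", "ply", "tables"))
  out <- switch(format,
    off = read_off(path),
    obj = read_obj(path),
    ply = read_ply(path),
    tables = {
      if (is.null(faces_path)) stop("format 'tables' needs faces_path")
      v <- as.matrix(utils::read.table(path, header = FALSE, sep = ""))
      f <- as.matrix(utils::read.table(faces_path, header = FALSE, sep = ""))
      list(vertices = v, faces = f)
    })
  if (ncol(out$faces) != 3L) stop("non-triangular face in ", path)
  triangle_mesh(out$vertices, out$faces, ...)
}

read_off <- function(path) {
  ln <- trimws(readLines(path, warn = FALSE))
  ln <- ln[nzchar(ln) & !startsWith(ln, "#")]
  if (toupper(ln[1]) != "OFF") stop("unsupported format: missing OFF header")
  hdr <- scan(text = ln[2], what = integer(), quiet = TRUE)
  nv <- hdr[1]; nf <- hdr[2]
  body <- scan(text = ln[-(1:2)], what = double(), quiet = TRUE)
  v <- matrix(body[seq_len(3 * nv)], ncol = 3, byrow = TRUE)
  rest <- body[-seq_len(3 * nv)]
  faces <- matrix(NA_integer_, nf, 3)
  pos <- 1L
  for (i in seq_len(nf)) {
    k <- rest[pos]
    if (k != 3) stop("non-triangular face (", k, " vertices) in OFF file")
    faces[i, ] <- rest[pos + 1:3] + 1L   # OFF is 0-based
    pos <- pos + k + 1L
  }
  list(vertices = v, faces = faces)
}

read_obj <- function(path) {
  ln <- readLines(path, warn = FALSE)
  vl <- ln[startsWith(ln, "v ")]
  fl <- ln[startsWith(ln, "f ")]
  v <- do.call(rbind, lapply(strsplit(trimws(sub("^v", "", vl)), "[[:space:]]+"),
                             function(x) as.numeric(x[1:3])))
  f <- lapply(strsplit(trimws(sub("^f", "", fl)), "[[:space:]]+"), function(x) {
    idx <- as.integer(vapply(strsplit(x, "/"), `[[`, "", 1L))
    if (length(idx) != 3L) stop("non-triangular face in OBJ file")
    idx
  })
  list(vertices = v, faces = do.call(rbind, f))
}

read_ply <- function(path) {
  ln <- readLines(path, warn = FALSE)
  if (trimws(ln[1]) != "ply") stop("unsupported format: missing ply header")
  if (!any(grepl("format ascii", ln))) stop("unsupported format: only ASCII PLY is handled")
  endh <- which(trimws(ln) == "end_header")[1]
  nv <- as.integer(sub(".*element vertex +", "", grep("element vertex", ln, value = TRUE)[1]))
  nf <- as.integer(sub(".*element face +", "", grep("element face", ln, value = TRUE)[1]))
  vl <- ln[endh + seq_len(nv)]
  fl <- ln[endh + nv + seq_len(nf)]
  v <- do.call(rbind, lapply(strsplit(trimws(vl), "[[:space:]]+"),
                             function(x) as.numeric(x[1:3])))
  f <- lapply(strsplit(trimws(fl), "[[:space:]]+"), function(x) {
    x <- as.integer(x)
    if (x[1] != 3L) stop("non-triangular face in PLY file")
    x[2:4] + 1L
  })
  list(vertices = v, faces = do.call(rbind, f))
}

#' Write a triangle mesh to an ASCII OFF or OBJ file
#'
#' @param mesh a \code{triangle_mesh}.
#' @param path destination path.
#' @param format \code{"off"} or \code{"obj"}; default from the extension.
#' @param digits coordinate precision.
#' @export
write_mesh <- function(mesh, path, format = NULL, digits = 15) {
  if (is.null(format)) format <- tolower(tools::file_ext(path))
  format <- match.arg(format, c("off", "obj"))
  v <- mesh$vertices
  if (ncol(v) == 2L) v <- cbind(v, 0)
  vs <- apply(v, 1, function(r) paste(formatC(r, digits = digits, format = "g"), collapse = " "))
  if (format == "off") {
    fs <- apply(mesh$faces - 1L, 1, function(r) paste(c(3L, r), collapse = " "))
    writeLines(c("OFF", paste(nrow(v), nrow(mesh$faces), 0), vs, fs), path)
  } else {
    fs <- apply(mesh$faces, 1, function(r) paste(c("f", r), collapse = " "))
    writeLines(c(paste("v", vs), fs), path)
  }
  invisible(path)
}

#' Read per-vertex retinotopic data
#'
#' Reads a delimited table with (a subset of) the columns
#' \code{vertex, ecc, ang, sigma, gain, expt, r2, label, hemi}:
#' eccentricity in degrees, polar angle in radians, pRF size/gain/exponent,
#' percent variance explained, visual-area label (V1v/V1d/V2v/V2d/V3v/V3d)
#' and hemisphere.
#'
#' @param path TSV/CSV path (delimiter sniffed from the header line).
#' @param n_vertices optional expected vertex count to validate against.
#' @return a data.frame ordered by vertex index.
#' @export
read_vertex_data <- function(path, n_vertices = NULL) {
  hdr <- readLines(path, n = 1L)
  sep <- if (grepl(",", hdr)) "," else "\t"
  d <- utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE)
  if (!"vertex" %in% names(d)) stop("vertex column missing")
  d <- d[order(d$vertex), , drop = FALSE]
  if (!is.null(n_vertices) && nrow(d) != n_vertices)
    stop(sprintf("vertex table has %d rows, mesh has %d vertices", nrow(d), n_vertices))
  d
}
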