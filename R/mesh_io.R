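#' Import an MSMS .vert/.face mesh
#'
#' Reads the text output of the MSMS molecular-surface program (standard
#' layout: 3 header lines, the third carrying the record count, then one
#' record per line). Face indices are 1-based in MSMS files and map
#' directly onto this package's 1-based [TriMesh-class] convention.
#'
#' @param vert path to the `.vert` file (x, y, z in the first 3 columns).
#' @param face path to the `.face` file (3 vertex indices per record).
#' @return A [TriMesh-class].
#' @export
importMSMS <- function(vert, face) {
  vlines <- readLines(vert)
  flines <- readLines(face)
  if (length(vlines) < 4L || length(flines) < 4L)
    stop("MSMS parse error: fewer than 3 header lines + records")
  vcount <- suppressWarnings(as.integer(strsplit(trimws(vlines[3L]), "\\s+")[[1L]][1L]))
  fcount <- suppressWarnings(as.integer(strsplit(trimws(flines[3L]), "\\s+")[[1L]][1L]))
  vrec <- vlines[-(1:3)]
  frec <- flines[-(1:3)]
  vrec <- vrec[nzchar(trimws(vrec))]
  frec <- frec[nzchar(trimws(frec))]
  if (is.na(vcount) || vcount != length(vrec))
    stop("MSMS parse error: .vert header count ", vcount,
         " != ", length(vrec), " records")
  if (is.na(fcount) || fcount != length(frec))
    stop("MSMS parse error: .face header count ", fcount,
         " != ", length(frec), " records")
  vm <- do.call(rbind, lapply(strsplit(trimws(vrec), "\\s+"), function(f)
    as.numeric(f[1:3])))
  fm <- do.call(rbind, lapply(strsplit(trimws(frec), "\\s+"), function(f)
    as.integer(f[1:3])))
  if (anyNA(vm) || anyNA(fm)) stop("MSMS parse error: non-numeric record")
  new_trimesh(vm, fm)
}

#' Read and write meshes in OFF format
#'
#' Plain ASCII Object File Format: an `OFF` magic line, a counts line
#' (`nv nf ne`), vertex rows, then face rows `3 i j k` with 0-based
#' indices (converted to the package's 1-based convention on read).
#'
#' @param mesh a [TriMesh-class] (for `writeOFF`).
#' @param path file path.
#' @return `writeOFF` returns `path` invisibly; `readOFF` a
#'   [TriMesh-class].
#' @export
writeOFF <- function(mesh, path) {
  stopifnot(is(mesh, "TriMesh"))
  v <- mesh@vertices
  f <- mesh@faces
  writeLines(c("OFF",
               sprintf("%d %d 0", nrow(v), nrow(f)),
               sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]),
               sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L)),
             path)
  invisible(path)
}

#' @rdname writeOFF
#' @export
readOFF <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (toupper(trimws(lines[1L])) != "OFF") stop("not an OFF file")
  counts <- as.integer(strsplit(trimws(lines[2L]), "\\s+")[[1L]])
  nv <- counts[1L]; nf <- counts[2L]
  if (length(lines) < 2L + nv + nf) stop("OFF parse error: truncated file")
  vm <- do.call(rbind, lapply(strsplit(trimws(lines[3:(2 + nv)]), "\\s+"),
                              function(x) as.numeric(x[1:3])))
  fm <- do.call(rbind, lapply(strsplit(trimws(lines[(3 + nv):(2 + nv + nf)]), "\\s+"),
                              function(x) as.integer(x[2:4]) + 1L))
  if (anyNA(vm) || anyNA(fm)) stop("OFF parse error: non-numeric record")
  new_trimesh(vm, fm)
}

#' Read and write meshes in ASCII PLY format
#'
#' Minimal Stanford Triangle Format support (ascii 1.0, xyz vertex
#' properties, triangular faces). PLY indices are 0-based on disk.
#'
#' @param mesh a [TriMesh-class] (for `writePLY`).
#' @param path file path.
#' @return `writePLY` returns `path` invisibly; `readPLY` a
#'   [TriMesh-class].
#' @export
writePLY <- function(mesh, path) {
  stopifnot(is(mesh, "TriMesh"))
  v <- mesh@vertices
  f <- mesh@faces
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(v)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(f)),
               "property list uchar int vertex_indices", "end_header",
               sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]),
               sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L)),
             path)
  invisible(path)
}

#' @rdname writePLY
#' @export
readPLY <- function(path) {
  lines <- readLines(path)
  if (trimws(lines[1L]) != "ply") stop("not a PLY file")
  endh <- which(trimws(lines) == "end_header")[1L]
  if (is.na(endh)) stop("PLY parse error: no end_header")
  hdr <- lines[1:endh]
  nv <- as.integer(sub("element vertex\\s+", "",
                       grep("^element vertex", hdr, value = TRUE)[1L]))
  nf <- as.integer(sub("element face\\s+", "",
                       grep("^element face", hdr, value = TRUE)[1L]))
  if (is.na(nv) || is.na(nf)) stop("PLY parse error: missing element counts")
  body <- lines[-seq_len(endh)]
  vm <- do.call(rbind, lapply(strsplit(trimws(body[1:nv]), "\\s+"),
                              function(x) as.numeric(x[1:3])))
  fm <- do.call(rbind, lapply(strsplit(trimws(body[(nv + 1):(nv + nf)]), "\\s+"),
                              function(x) as.integer(x[2:4]) + 1L))
  if (anyNA(vm) || anyNA(fm)) stop("PLY parse error: non-numeric record")
  new_trimesh(vm, fm)
}

#' Export a residue distance matrix as TSV
#'
#' Writes the symmetric matrix with residue identifiers
#' (`<seq_pos><icode>`) as the header row and first column; flagged
#' (cross-component geodesic) entries are written as `NA`.
#'
#' @param dmat a [ResidueDistanceMatrix-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeDistanceMatrix <- function(dmat, path) {
  stopifnot(is(dmat, "ResidueDistanceMatrix"))
  ids <- paste0(dmat@residues$seq_pos, dmat@residues$icode)
  m <- dmat@values
  dimnames(m) <- list(ids, ids)
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  writeLines(paste0("# metric\t", dmat@metric), con)
  write.table(m, con, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}
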