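#' Build a LAD profile from a residue distance matrix
#'
#' The local average distance of residue i is the mean of its averaged
#' distances to the neighbouring residues within a window of `window`
#' positions centred on i (up to `(window - 1) / 2` on each side), sliding
#' from N- to C-terminus over the surface-residue ordering. Windows are
#' truncated at the termini: the mean runs over the neighbours that exist.
#' Buried residues are absent from the matrix and are skipped, not gapped,
#' so profiles stay dense and alignable.
#'
#' @param dmat a [ResidueDistanceMatrix-class].
#' @param window odd window size >= 3; the package default of 9 is used
#'   everywhere else.
#' @return A [LADProfile-class] with one LAD value (Angstrom) per surface
#'   residue.
#' @examples
#' vals <- matrix(c(0, 2, 4, 2, 0, 2, 4, 2, 0), 3, 3)
#' dm <- new("ResidueDistanceMatrix", structureId = "toy", metric = "ED",
#'           residues = data.frame(residue = 1:3, seq_pos = 1:3,
#'                                 icode = "", resname = "GLY"),
#'           values = vals)
#' ladValues(buildLADProfile(dm, window = 9))  # 3, 2, 3
#' @export
buildLADProfile <- function(dmat, window = 9L) {
  stopifnot(is(dmat, "ResidueDistanceMatrix"))
  window <- as.integer(window)
  if (length(window) != 1L || is.na(window) || window < 3L ||
      window %% 2L == 0L)
    stop("window must be a single odd integer >= 3")
  n <- nResidues(dmat)
  if (n < 2L)
    stop("profile of length ", n, ": no neighbours to average over")
  half <- (window - 1L) %/% 2L
  m <- dmat@values
  lad <- vapply(seq_len(n), function(i) {
    j <- setdiff(max(1L, i - half):min(n, i + half), i)
    mean(m[i, j])
  }, numeric(1))
  if (anyNA(lad))
    stop("window spans disconnected surface components; ",
         "geodesic LAD undefined for this mesh")
  rt <- dmat@residues
  entries <- data.frame(residue = rt$residue, seq_pos = rt$seq_pos,
                        resname = rt$resname, lad = lad,
                        stringsAsFactors = FALSE)
  new("LADProfile", structureId = dmat@structureId, metric = dmat@metric,
      window = window, entries = entries)
}

#' End-to-end LAD profile of a backbone structure
#'
#' Convenience pipeline: build the probe-inflated backbone surface,
#' simplify it, associate vertices to atoms, compute the averaged residue
#' distance matrix and reduce it to a LAD profile.
#'
#' @param structure a [BackboneStructure-class].
#' @param metric `"ED"` or `"GD"`.
#' @param window odd sliding-window size (default 9).
#' @param probe_radius,grid_resolution meshing parameters, see
#'   [buildSurface()].
#' @param face_fraction simplification target, see [simplifyMesh()].
#' @return A [LADProfile-class].
#' @export
ladProfile <- function(structure, metric = c("ED", "GD"), window = 9L,
                       probe_radius = 1.5, grid_resolution = 0.7,
                       face_fraction = 0.15) {
  metric <- match.arg(metric)
  mesh <- buildSurface(structure, probe_radius = probe_radius,
                       grid_resolution = grid_resolution)
  mesh <- simplifyMesh(mesh, face_fraction = face_fraction)
  assoc <- associateVertices(mesh, structure)
  dmat <- residueDistanceMatrix(structure, assoc, mesh = mesh,
                                metric = metric)
  buildLADProfile(dmat, window = window)
}

#' Sweep LAD window sizes
#'
#' Rebuilds the profile for a range of odd window sizes (the 3-21 sweep
#' used when re-tuning the descriptor on new data).
#'
#' @param dmat a [ResidueDistanceMatrix-class].
#' @param windows odd window sizes (default `seq(3, 21, by = 2)`).
#' @return Named list of [LADProfile-class] objects, one per window.
#' @export
ladWindowSweep <- function(dmat, windows = seq(3L, 21L, by = 2L)) {
  out <- lapply(windows, function(w) buildLADProfile(dmat, window = w))
  names(out) <- paste0("w", windows)
  out
}
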