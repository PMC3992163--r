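BACKBONE_TAGS <- c("N", "CA", "C", "O")

#' Backbone-only protein chain
#'
#' One protein chain reduced to its backbone atoms (N, CA, C, O), the unit of
#' comparison for LAD profiles. The `atoms` slot is a flat table with one row
#' per atom; `residue` is a contiguous 1-based internal residue index in chain
#' order (author numbering and insertion codes are kept alongside as labels).
#'
#' @slot id character label, conventionally `"<pdb>:<chain>"`.
#' @slot atoms data.frame with columns `residue` (integer), `seq_pos`
#'   (integer, author numbering), `icode` (character), `resname` (character),
#'   `tag` (one of N/CA/C/O), `x`, `y`, `z` (Angstrom).
#'
#' @seealso [readBackbone()], [makeToyChain()]
#' @export
setClass("BackboneStructure",
  representation(id = "character", atoms = "data.frame"))

setValidity("BackboneStructure", function(object) {
  a <- object@atoms
  need <- c("residue", "seq_pos", "icode", "resname", "tag", "x", "y", "z")
  if (!all(need %in% names(a)))
    return(paste("atoms must have columns", paste(need, collapse = ", ")))
  if (nrow(a) == 0L) return("empty structure: no backbone atoms")
  if (!all(a$tag %in% BACKBONE_TAGS))
    return("atom tags must be drawn from N, CA, C, O")
  if (!all(is.finite(c(a$x, a$y, a$z))))
    return("all coordinates must be finite")
  if (is.unsorted(a$residue))
    return("atoms must be ordered by residue index")
  r <- unique(a$residue)
  if (!identical(as.integer(r), seq_along(r)))
    return("residue indices must be contiguous 1..n in order")
  per <- table(a$residue)
  if (any(per > 4L))
    return("a residue may carry at most 4 backbone atoms")
  if (anyDuplicated(paste(a$residue, a$tag)))
    return("duplicated atom tag within a residue")
  TRUE
})

#' Triangulated surface mesh
#'
#' A plain triangle soup with shared vertices: `vertices` holds x/y/z rows in
#' Angstrom, `faces` holds 1-based vertex-index triples. Faces imported from
#' MSMS (1-based on disk) and OFF (0-based on disk) are converted to this
#' convention on read.
#'
#' @slot vertices numeric matrix, one row per vertex.
#' @slot faces integer matrix, one row per triangle.
#' @seealso [buildSurface()], [simplifyMesh()], [importMSMS()],
#'   [makeAnalyticMesh()]
#' @export
setClass("TriMesh",
  representation(vertices = "matrix", faces = "matrix"))

setValidity("TriMesh", function(object) {
  v <- object@vertices; f <- object@faces
  if (ncol(v) != 3L) return("vertices must have 3 columns")
  if (!is.numeric(v) || !all(is.finite(v))) return("vertex coordinates must be finite numeric")
  if (nrow(f) > 0L) {
    if (ncol(f) != 3L) return("faces must have 3 columns")
    if (!is.numeric(f)) return("faces must be numeric indices")
    if (min(f) < 1L || max(f) > nrow(v))
      return("face indices out of [1, nVertices] range")
    deg <- f[, 1L] == f[, 2L] | f[, 1L] == f[, 3L] | f[, 2L] == f[, 3L]
    if (any(deg)) return("degenerate faces (repeated vertex index)")
  }
  TRUE
})

#' Vertex-to-atom ownership map
#'
#' Each mesh vertex belongs to the closest backbone atom of the structure it
#' was meshed from; the map is total over vertices (a partition). Built by
#' [associateVertices()]; the basis of geodesic averaging and of the
#' surface-residue call.
#'
#' @slot structureId character, id of the associated structure.
#' @slot vertexOwner data.frame with one row per vertex: `vertex`, `residue`
#'   (internal index), `tag` (backbone atom tag).
#' @slot residues residue table of the structure (see [residueTable()]).
#' @export
setClass("VertexAssociation",
  representation(structureId = "character", vertexOwner = "data.frame",
                 residues = "data.frame"))

setValidity("VertexAssociation", function(object) {
  vo <- object@vertexOwner
  if (!all(c("vertex", "residue", "tag") %in% names(vo)))
    return("vertexOwner needs columns vertex, residue, tag")
  if (nrow(vo) == 0L) return("association must cover at least one vertex")
  if (!identical(as.integer(vo$vertex), seq_len(nrow(vo))))
    return("vertexOwner must be total over vertices 1..V in order")
  if (!all(vo$tag %in% BACKBONE_TAGS)) return("bad atom tag in association")
  if (!all(vo$residue %in% object@residues$residue))
    return("association refers to unknown residue")
  TRUE
})

#' Averaged pairwise residue distance matrix
#'
#' Symmetric matrix of averaged distances (Angstrom) between surface
#' residues, either Euclidean (`ED`, between atom centers) or geodesic
#' (`GD`, averaged over mesh-vertex pairs along the surface). For GD on a
#' mesh with several connected components, entries between residues on
#' different components are flagged as `NA`, never silently infinite.
#'
#' @slot structureId character.
#' @slot metric `"ED"` or `"GD"`.
#' @slot residues data.frame of the surface residues the rows/columns refer
#'   to, in sequence order.
#' @slot values symmetric numeric matrix, zero diagonal.
#' @seealso [residueDistanceMatrix()]
#' @export
setClass("ResidueDistanceMatrix",
  representation(structureId = "character", metric = "character",
                 residues = "data.frame", values = "matrix"))

setValidity("ResidueDistanceMatrix", function(object) {
  if (!object@metric %in% c("ED", "GD")) return("metric must be ED or GD")
  m <- object@values
  n <- nrow(object@residues)
  if (!identical(dim(m), c(n, n))) return("values dimension != residue count")
  if (n == 0L) return("no surface residues")
  if (any(diag(m) != 0)) return("diagonal must be zero")
  fin <- !is.na(m)
  if (any(m[fin] < 0) || any(!is.finite(m[fin]))) return("distances must be finite and >= 0")
  if (any(is.na(m) != is.na(t(m))) || any(abs(m[fin] - t(m)[fin]) > 1e-9))
    return("matrix must be symmetric")
  if (object@metric == "ED" && any(!fin)) return("ED matrix cannot have flagged entries")
  TRUE
})

#' LAD profile of a chain
#'
#' The descriptor itself: per surface residue, the mean distance (ED or GD)
#' to its sequence neighbours inside a sliding window, ordered from N- to
#' C-terminus. This 1-D profile is what gets aligned between two structures.
#'
#' @slot structureId character.
#' @slot metric `"ED"` or `"GD"`.
#' @slot window odd integer window size (default 9 throughout the package).
#' @slot entries data.frame with columns `residue`, `seq_pos`, `resname`,
#'   `lad` (Angstrom), in surface-residue sequence order.
#' @seealso [buildLADProfile()], [writeProfile()], [alignProfiles()]
#' @export
setClass("LADProfile",
  representation(structureId = "character", metric = "character",
                 window = "integer", entries = "data.frame"))

setValidity("LADProfile", function(object) {
  if (!object@metric %in% c("ED", "GD")) return("metric must be ED or GD")
  w <- object@window
  if (length(w) != 1L || is.na(w) || w < 3L || w %% 2L == 0L)
    return("window must be a single odd integer >= 3")
  e <- object@entries
  if (!all(c("residue", "seq_pos", "resname", "lad") %in% names(e)))
    return("entries need columns residue, seq_pos, resname, lad")
  if (nrow(e) > 0L) {
    if (is.unsorted(e$residue, strictly = TRUE))
      return("entries must follow increasing residue order")
    if (any(!is.finite(e$lad)) || any(e$lad <= 0))
      return("LAD values must be finite and > 0")
  }
  TRUE
})

#' Local alignment of two LAD profiles
#'
#' Result of the Smith-Waterman style local alignment of two profiles:
#' the aligned position pairs, the count of equivalent residues `Ne`, the
#' RMSD of LAD values over aligned pairs (not a coordinate RMSD), and the
#' LAD_div diversity score in [0, 1] (lower = more similar).
#'
#' @slot queryId,subjectId character structure ids.
#' @slot metric `"ED"` or `"GD"`.
#' @slot pairs integer matrix (columns `query`, `subject`), strictly
#'   increasing in both columns.
#' @slot ne integer, number of aligned residues.
#' @slot ladRmsd numeric, RMSD of LAD values over aligned pairs (Angstrom).
#' @slot nq,ns integer profile lengths of query and subject.
#' @slot ladDiv numeric LAD_div score.
#' @slot score numeric, raw DP alignment score.
#' @slot params list with elements `D` and `alpha` used for `ladDiv`.
#' @seealso [alignProfiles()], [ladDiv()]
#' @export
setClass("ProfileAlignment",
  representation(queryId = "character", subjectId = "character",
                 metric = "character", pairs = "matrix", ne = "integer",
                 ladRmsd = "numeric", nq = "integer", ns = "integer",
                 ladDiv = "numeric", score = "numeric", params = "list"))

setValidity("ProfileAlignment", function(object) {
  p <- object@pairs
  if (nrow(p) != object@ne) return("ne must equal the number of aligned pairs")
  if (object@ne > min(object@nq, object@ns)) return("ne exceeds min profile length")
  if (nrow(p) > 1L) {
    if (any(diff(p[, 1L]) <= 0) || any(diff(p[, 2L]) <= 0))
      return("aligned pairs must be strictly increasing in both indices")
  }
  if (object@ne > 0L && (object@ladRmsd < 0 || !is.finite(object@ladRmsd)))
    return("ladRmsd must be finite and >= 0")
  if (object@ladDiv < -1e-12 || object@ladDiv > 1 + 1e-12)
    return("ladDiv must lie in [0, 1]")
  TRUE
})

#' Ranked retrieval of a database against one query
#'
#' Database structures sorted by ascending LAD_div (most similar first),
#' with same-group relevance labels; ties in score are broken
#' lexicographically by subject id so rankings are reproducible.
#'
#' @slot queryId character.
#' @slot ranking data.frame with columns `subject_id`, `lad_div`,
#'   `relevant` (logical), in rank order.
#' @seealso [rankDatabase()], [interpolatedPR()], [averagePrecision()]
#' @export
setClass("RetrievalRun",
  representation(queryId = "character", ranking = "data.frame"))

setValidity("RetrievalRun", function(object) {
  r <- object@ranking
  if (!all(c("subject_id", "lad_div", "relevant") %in% names(r)))
    return("ranking needs columns subject_id, lad_div, relevant")
  if (anyDuplicated(r$subject_id)) return("duplicated subject in ranking")
  if (nrow(r) > 1L) {
    d <- diff(r$lad_div)
    if (any(d < -1e-12)) return("ranking must be sorted ascending by lad_div")
    tie <- abs(d) <= 1e-12
    if (any(tie & diff(rank(r$subject_id)) < 0))
      return("ties must be broken lexicographically by subject_id")
  }
  TRUE
})

#' Hinge-bend morph group
#'
#' A group of conformers of one chain spanning a rigid hinge-bending motion:
#' frame 1 and the last frame are the two extreme states, intermediate
#' frames interpolate the bend angle monotonically (plus small coordinate
#' jitter so conformers are homologous-but-not-identical).
#'
#' @slot groupId character.
#' @slot conformers list of [BackboneStructure-class], all sharing residue
#'   count and sequence.
#' @slot hinges integer residue indices of the hinge points (1 to 3).
#' @slot angles numeric bend angles (degrees), one per conformer,
#'   monotonically non-decreasing from 0.
#' @seealso [makeMorphGroup()]
#' @export
setClass("MorphGroup",
  representation(groupId = "character", conformers = "list",
                 hinges = "integer", angles = "numeric"))

setValidity("MorphGroup", function(object) {
  cs <- object@conformers
  if (length(cs) < 2L) return("a morph group needs at least 2 conformers")
  if (!all(vapply(cs, is, logical(1), "BackboneStructure")))
    return("conformers must be BackboneStructure objects")
  n0 <- nrow(cs[[1L]]@atoms)
  if (!all(vapply(cs, function(s) nrow(s@atoms) == n0, logical(1))))
    return("all conformers must share atom count")
  rs0 <- cs[[1L]]@atoms$resname
  if (!all(vapply(cs, function(s) identical(s@atoms$resname, rs0), logical(1))))
    return("all conformers must share residue sequence")
  if (length(object@angles) != length(cs))
    return("one bend angle per conformer required")
  if (is.unsorted(object@angles)) return("bend angles must be monotone")
  TRUE
})
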