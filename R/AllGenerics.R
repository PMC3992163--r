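#' @include AllClasses.R
NULL

#' Identifier of the structure a ladflex object describes
#'
#' @param x a [BackboneStructure-class], [VertexAssociation-class],
#'   [ResidueDistanceMatrix-class] or [LADProfile-class] object.
#' @return A character scalar such as `"5rsa:A"`.
#' @export
setGeneric("structureId", function(x) standardGeneric("structureId"))

#' Number of residues in an object
#'
#' @param x an object carrying residues.
#' @return Integer scalar.
#' @export
setGeneric("nResidues", function(x) standardGeneric("nResidues"))

#' Residue-level summary table
#'
#' One row per residue: internal index `residue`, author sequence number
#' `seq_pos`, insertion code `icode` and 3-letter `resname`.
#'
#' @param x an object carrying residues.
#' @return A data.frame, one row per residue, in chain order.
#' @export
setGeneric("residueTable", function(x) standardGeneric("residueTable"))

#' Number of mesh vertices
#' @param x a [TriMesh-class].
#' @return Integer scalar.
#' @export
setGeneric("nVertices", function(x) standardGeneric("nVertices"))

#' Number of mesh faces
#' @param x a [TriMesh-class].
#' @return Integer scalar.
#' @export
setGeneric("nFaces", function(x) standardGeneric("nFaces"))

#' Vertex coordinates of a mesh
#' @param x a [TriMesh-class].
#' @return Numeric matrix, one row per vertex, columns x/y/z in Angstrom.
#' @export
setGeneric("meshVertices", function(x) standardGeneric("meshVertices"))

#' Face index matrix of a mesh
#' @param x a [TriMesh-class].
#' @return Integer matrix, one row per triangle, 1-based vertex indices.
#' @export
setGeneric("meshFaces", function(x) standardGeneric("meshFaces"))

#' Surface residues of a vertex association
#'
#' A residue counts as a surface residue when at least one mesh vertex is
#' owned by one of its backbone atoms.
#'
#' @param x a [VertexAssociation-class].
#' @return A data.frame (subset of [residueTable()]) in sequence order.
#' @export
setGeneric("surfaceResidues", function(x) standardGeneric("surfaceResidues"))

#' Vertices associated with each backbone atom
#'
#' @param x a [VertexAssociation-class].
#' @return A named list of integer vertex-index vectors; names are
#'   `"<residue>|<tag>"` keys.
#' @export
setGeneric("atomVertices", function(x) standardGeneric("atomVertices"))

#' LAD values of a profile
#' @param x a [LADProfile-class].
#' @return Numeric vector of per-residue LAD values (Angstrom).
#' @export
setGeneric("ladValues", function(x) standardGeneric("ladValues"))

#' Distance metric an object was computed with
#' @param x a [ResidueDistanceMatrix-class] or [LADProfile-class].
#' @return `"ED"` or `"GD"`.
#' @export
setGeneric("ladMetric", function(x) standardGeneric("ladMetric"))

#' Sliding-window size of a LAD profile
#' @param x a [LADProfile-class].
#' @return Odd integer scalar.
#' @export
setGeneric("windowSize", function(x) standardGeneric("windowSize"))

#' Aligned index pairs of a profile alignment
#' @param x a [ProfileAlignment-class].
#' @return Integer matrix with columns `query` and `subject` (profile
#'   positions, 1-based), strictly increasing in both.
#' @export
setGeneric("alignedPairs", function(x) standardGeneric("alignedPairs"))
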