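#' @include AllClasses.R AllGenerics.R
NULL

#' @describeIn BackboneStructure-class structure id
#' @param x object
#' @export
setMethod("structureId", "BackboneStructure", function(x) x@id)

#' @describeIn BackboneStructure-class residue count
#' @export
setMethod("nResidues", "BackboneStructure",
          function(x) length(unique(x@atoms$residue)))

#' @describeIn BackboneStructure-class residue table
#' @export
setMethod("residueTable", "BackboneStructure", function(x) {
  a <- x@atoms
  keep <- !duplicated(a$residue)
  out <- a[keep, c("residue", "seq_pos", "icode", "resname")]
  rownames(out) <- NULL
  out
})

#' Backbone atom coordinate table
#'
#' @param x a [BackboneStructure-class].
#' @return The atom table: one row per backbone atom with residue index,
#'   author numbering, tag and x/y/z coordinates.
#' @export
atomTable <- function(x) {
  stopifnot(is(x, "BackboneStructure"))
  x@atoms
}

setMethod("show", "BackboneStructure", function(object) {
  cat(sprintf("BackboneStructure %s: %d residues, %d backbone atoms\n",
              object@id, nResidues(object), nrow(object@atoms)))
})

#' @describeIn TriMesh-class vertex count
#' @param x object
#' @export
setMethod("nVertices", "TriMesh", function(x) nrow(x@vertices))

#' @describeIn TriMesh-class face count
#' @export
setMethod("nFaces", "TriMesh", function(x) nrow(x@faces))

#' @describeIn TriMesh-class vertex coordinate matrix
#' @export
setMethod("meshVertices", "TriMesh", function(x) x@vertices)

#' @describeIn TriMesh-class face index matrix (1-based)
#' @export
setMethod("meshFaces", "TriMesh", function(x) x@faces)

setMethod("show", "TriMesh", function(object) {
  cat(sprintf("TriMesh: %d vertices, %d faces, %d component(s)\n",
              nVertices(object), nFaces(object),
              length(meshComponents(object))))
})

#' @describeIn VertexAssociation-class id of the structure
#' @param x object
#' @export
setMethod("structureId", "VertexAssociation", function(x) x@structureId)

#' @describeIn VertexAssociation-class surface residues (>= 1 owned vertex)
#' @export
setMethod("surfaceResidues", "VertexAssociation", function(x) {
  hit <- sort(unique(x@vertexOwner$residue))
  out <- x@residues[x@residues$residue %in% hit, , drop = FALSE]
  rownames(out) <- NULL
  out
})

#' @describeIn VertexAssociation-class vertex lists per atom
#' @export
setMethod("atomVertices", "VertexAssociation", function(x) {
  vo <- x@vertexOwner
  split(vo$vertex, paste(vo$residue, vo$tag, sep = "|"))
})

setMethod("show", "VertexAssociation", function(object) {
  cat(sprintf("VertexAssociation for %s: %d vertices over %d surface residues\n",
              object@structureId, nrow(object@vertexOwner),
              nrow(surfaceResidues(object))))
})

#' @describeIn ResidueDistanceMatrix-class id of the structure
#' @param x object
#' @export
setMethod("structureId", "ResidueDistanceMatrix", function(x) x@structureId)

#' @describeIn ResidueDistanceMatrix-class metric ("ED" or "GD")
#' @export
setMethod("ladMetric", "ResidueDistanceMatrix", function(x) x@metric)

#' @describeIn ResidueDistanceMatrix-class surface-residue count
#' @export
setMethod("nResidues", "ResidueDistanceMatrix", function(x) nrow(x@residues))

#' @describeIn ResidueDistanceMatrix-class residue table of the rows/columns
#' @export
setMethod("residueTable", "ResidueDistanceMatrix", function(x) x@residues)

#' Distance values of a residue distance matrix
#'
#' @param x a [ResidueDistanceMatrix-class].
#' @return The symmetric numeric matrix (Angstrom); `NA` marks residue pairs
#'   on different mesh components (GD only).
#' @export
distanceValues <- function(x) {
  stopifnot(is(x, "ResidueDistanceMatrix"))
  x@values
}

setMethod("show", "ResidueDistanceMatrix", function(object) {
  cat(sprintf("ResidueDistanceMatrix (%s) for %s: %d x %d, %d flagged pair(s)\n",
              object@metric, object@structureId, nResidues(object),
              nResidues(object), sum(is.na(object@values)) %/% 2L))
})

#' @describeIn LADProfile-class id of the structure
#' @param x object
#' @export
setMethod("structureId", "LADProfile", function(x) x@structureId)

#' @describeIn LADProfile-class metric ("ED" or "GD")
#' @export
setMethod("ladMetric", "LADProfile", function(x) x@metric)

#' @describeIn LADProfile-class window size
#' @export
setMethod("windowSize", "LADProfile", function(x) x@window)

#' @describeIn LADProfile-class LAD values in profile order
#' @export
setMethod("ladValues", "LADProfile", function(x) x@entries$lad)

#' @describeIn LADProfile-class profile length (surface residues)
#' @export
setMethod("nResidues", "LADProfile", function(x) nrow(x@entries))

#' @describeIn LADProfile-class profile entry table
#' @export
setMethod("residueTable", "LADProfile", function(x) x@entries)

setMethod("show", "LADProfile", function(object) {
  v <- ladValues(object)
  cat(sprintf("LADProfile %s (LAD_%s, window %d): %d residues, LAD %.2f-%.2f A\n",
              object@structureId, object@metric, object@window, length(v),
              if (length(v)) min(v) else NA_real_,
              if (length(v)) max(v) else NA_real_))
})

#' @describeIn ProfileAlignment-class aligned position pairs
#' @param x object
#' @export
setMethod("alignedPairs", "ProfileAlignment", function(x) x@pairs)

setMethod("show", "ProfileAlignment", function(object) {
  cat(sprintf(
    "ProfileAlignment %s vs %s (LAD_%s): Ne = %d (NQ %d, NS %d), LAD-RMSD = %.4g A, LAD_div = %.4g\n",
    object@queryId, object@subjectId, object@metric, object@ne,
    object@nq, object@ns, object@ladRmsd, object@ladDiv))
})

setMethod("show", "RetrievalRun", function(object) {
  r <- object@ranking
  cat(sprintf("RetrievalRun for %s: %d subjects, %d relevant, top hit %s (LAD_div %.4g)\n",
              object@queryId, nrow(r), sum(r$relevant),
              r$subject_id[1L], r$lad_div[1L]))
})

#' Ranking table of a retrieval run
#'
#' @param x a [RetrievalRun-class].
#' @return data.frame `subject_id`, `lad_div`, `relevant` in rank order.
#' @export
rankingTable <- function(x) {
  stopifnot(is(x, "RetrievalRun"))
  x@ranking
}

#' Conformers of a morph group
#'
#' @param x a [MorphGroup-class].
#' @return List of [BackboneStructure-class] objects in frame order.
#' @export
morphConformers <- function(x) {
  stopifnot(is(x, "MorphGroup"))
  x@conformers
}

setMethod("show", "MorphGroup", function(object) {
  cat(sprintf("MorphGroup %s: %d conformers of %d residues, hinge(s) at %s, bend 0-%g deg\n",
              object@groupId, length(object@conformers),
              nResidues(object@conformers[[1L]]),
              paste(object@hinges, collapse = ","),
              max(object@angles)))
})
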