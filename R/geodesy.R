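# Weighted graph over mesh vertices. Base edges are the mesh edges with
# Euclidean lengths. With augment = TRUE, for every interior edge the two
# adjacent triangles are unfolded into a common plane and the opposite
# vertices are joined by an extra edge whenever the unfolded straight
# segment crosses the shared edge; this "one-level unfolding" sharply
# reduces the metrication error of graph shortest paths while remaining an
# upper bound on the exact surface geodesic (unfolded paths are genuine
# on-surface paths).
mesh_graph <- function(mesh, augment = TRUE) {
  v <- mesh@vertices
  f <- mesh@faces
  ea <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(1L, 3L)])
  swap <- ea[, 1L] > ea[, 2L]
  ea[swap, ] <- ea[swap, c(2L, 1L)]
  opp <- c(f[, 3L], f[, 1L], f[, 2L])
  key <- paste(ea[, 1L], ea[, 2L])
  keep <- !duplicated(key)
  edges <- ea[keep, , drop = FALSE]
  wts <- sqrt(rowSums((v[edges[, 1L], , drop = FALSE] -
                       v[edges[, 2L], , drop = FALSE])^2))

  if (augment && nrow(f) > 1L) {
    # pair up the two triangles flanking each interior edge
    ord <- order(key)
    k <- key[ord]
    first <- which(duplicated(k))          # position of the 2nd occurrence
    if (length(first)) {
      i2 <- ord[first]
      i1 <- ord[first - 1L]
      u <- ea[i1, 1L]; w <- ea[i1, 2L]
      o1 <- opp[i1]; o2 <- opp[i2]
      ok <- o1 != o2
      u <- u[ok]; w <- w[ok]; o1 <- o1[ok]; o2 <- o2[ok]
      if (length(u)) {
        L <- sqrt(rowSums((v[w, , drop = FALSE] - v[u, , drop = FALSE])^2))
        d_uo1 <- sqrt(rowSums((v[o1, , drop = FALSE] - v[u, , drop = FALSE])^2))
        d_wo1 <- sqrt(rowSums((v[o1, , drop = FALSE] - v[w, , drop = FALSE])^2))
        d_uo2 <- sqrt(rowSums((v[o2, , drop = FALSE] - v[u, , drop = FALSE])^2))
        d_wo2 <- sqrt(rowSums((v[o2, , drop = FALSE] - v[w, , drop = FALSE])^2))
        xa <- (d_uo1^2 - d_wo1^2 + L^2) / (2 * L)
        ya <- sqrt(pmax(d_uo1^2 - xa^2, 0))
        xb <- (d_uo2^2 - d_wo2^2 + L^2) / (2 * L)
        yb <- sqrt(pmax(d_uo2^2 - xb^2, 0))
        denom <- ya + yb
        xs <- ifelse(denom > 0, xa + ya * (xb - xa) / denom, NA_real_)
        cross <- !is.na(xs) & xs >= 0 & xs <= L
        if (any(cross)) {
          extra <- cbind(o1[cross], o2[cross])
          extra_w <- sqrt((xb - xa)[cross]^2 + denom[cross]^2)
          eswap <- extra[, 1L] > extra[, 2L]
          extra[eswap, ] <- extra[eswap, c(2L, 1L)]
          edges <- rbind(edges, extra)
          wts <- c(wts, extra_w)
          dup <- duplicated(paste(edges[, 1L], edges[, 2L]))
          # keep the shorter weight when an unfolded edge duplicates a mesh edge
          ord2 <- order(paste(edges[, 1L], edges[, 2L]), wts)
          edges <- edges[ord2, , drop = FALSE]
          wts <- wts[ord2]
          dup <- duplicated(paste(edges[, 1L], edges[, 2L]))
          edges <- edges[!dup, , drop = FALSE]
          wts <- wts[!dup]
        }
      }
    }
  }
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, nrow(v) - igraph::vcount(g)))
  igraph::E(g)$weight <- wts
  g
}

#' Geodesic distances between mesh vertices
#'
#' Shortest on-surface distances computed by Dijkstra's algorithm on the
#' mesh edge graph, augmented with two-triangle unfolding edges for
#' accuracy (see Details). Distances are symmetric, zero on the diagonal,
#' and never smaller than the straight-line distance. Vertex pairs on
#' different mesh components are flagged `NA`, never silently infinite.
#'
#' @details The graph path is itself a path on (or across pairs of) the
#' triangulated surface, so every reported distance is an upper bound on
#' the exact polyhedral geodesic; the unfolding edges bring the
#' overestimate on smooth, simplified molecular meshes to well under the
#' discretization noise of the meshing step itself. Set `augment = FALSE`
#' for plain edge-graph Dijkstra.
#'
#' @param mesh a [TriMesh-class].
#' @param sources,targets integer vertex indices (default: all vertices).
#' @param augment add unfolding shortcut edges (default `TRUE`).
#' @return Numeric matrix of distances, `length(sources)` x
#'   `length(targets)`, `NA` for disconnected pairs.
#' @examples
#' ico <- makeAnalyticMesh("icosphere", subdivisions = 2)
#' g <- vertexGeodesics(ico, sources = 1L)
#' max(g, na.rm = TRUE)  # close to pi for a unit sphere
#' @export
vertexGeodesics <- function(mesh, sources = NULL, targets = NULL,
                            augment = TRUE) {
  stopifnot(is(mesh, "TriMesh"))
  nv <- nVertices(mesh)
  if (is.null(sources)) sources <- seq_len(nv)
  if (is.null(targets)) targets <- seq_len(nv)
  if (any(sources < 1L | sources > nv) || any(targets < 1L | targets > nv))
    stop("vertex index out of range")
  g <- mesh_graph(mesh, augment = augment)
  d <- igraph::distances(g, v = sources, to = targets, mode = "all",
                         algorithm = "dijkstra")
  d[is.infinite(d)] <- NA_real_
  dimnames(d) <- NULL
  d
}

#' Average geodesic distance between two backbone atoms
#'
#' The atom-level geodesic distance is the arithmetic mean of the vertex
#' geodesics over all M x N pairs of the two atoms' associated vertices;
#' both M and N must be at least 1 (atoms without vertices carry no
#' surface information).
#'
#' @param assoc a [VertexAssociation-class].
#' @param vgd full vertex geodesic matrix from [vertexGeodesics()] (all
#'   vertices as both sources and targets).
#' @param atom_i,atom_j atoms given as `c(residue, tag)`, e.g.
#'   `c("12", "CA")` (residue is the internal index).
#' @return Mean geodesic distance in Angstrom (`NA` if any vertex pair is
#'   disconnected).
#' @export
atomGD <- function(assoc, vgd, atom_i, atom_j) {
  stopifnot(is(assoc, "VertexAssociation"))
  av <- atomVertices(assoc)
  ki <- paste(atom_i[1L], atom_i[2L], sep = "|")
  kj <- paste(atom_j[1L], atom_j[2L], sep = "|")
  if (is.null(av[[ki]]))
    stop("atom ", ki, " has no associated vertices")
  if (is.null(av[[kj]]))
    stop("atom ", kj, " has no associated vertices")
  mean(vgd[av[[ki]], av[[kj]]])
}

#' Averaged pairwise residue distance matrix
#'
#' Computes the symmetric matrix of averaged distances between all surface
#' residues of a structure. For `metric = "GD"`, the distance between two
#' atoms is the mean vertex-pair geodesic over their associated vertices
#' and the residue-level distance is the mean over pairs of associated
#' backbone atoms. For `metric = "ED"`, the atom-level distance is the
#' Euclidean distance between atom centers, averaged over the same
#' vertex-associated atom set, so ED and GD matrices cover identical atoms
#' and stay comparable. The diagonal is zero by definition. Geodesic
#' entries between residues on different mesh components are `NA`.
#'
#' @param structure a [BackboneStructure-class].
#' @param assoc the [VertexAssociation-class] for this structure (its atom
#'   set defines which atoms enter the averages). For ED the association
#'   may come from another conformer of the same chain, which holds the
#'   surface-residue set fixed across conformers.
#' @param mesh the associated [TriMesh-class]; required for GD, unused for
#'   ED.
#' @param metric `"ED"` or `"GD"`.
#' @param augment passed to [vertexGeodesics()] (GD only).
#' @return A [ResidueDistanceMatrix-class].
#' @examples
#' s <- makeToyChain(10, "helix")
#' m <- simplifyMesh(buildSurface(s, grid_resolution = 0.8))
#' a <- associateVertices(m, s)
#' d <- residueDistanceMatrix(s, a, metric = "ED")
#' @export
residueDistanceMatrix <- function(structure, assoc, mesh = NULL,
                                  metric = c("ED", "GD"), augment = TRUE) {
  metric <- match.arg(metric)
  stopifnot(is(structure, "BackboneStructure"),
            is(assoc, "VertexAssociation"))
  vo <- assoc@vertexOwner
  atom_key <- paste(vo$residue, vo$tag, sep = "|")
  atoms <- unique(data.frame(residue = vo$residue, tag = vo$tag,
                             stringsAsFactors = FALSE))
  atoms <- atoms[order(atoms$residue, match(atoms$tag, BACKBONE_TAGS)), ,
                 drop = FALSE]
  akeys <- paste(atoms$residue, atoms$tag, sep = "|")
  sres <- sort(unique(atoms$residue))

  if (metric == "ED") {
    sa <- structure@atoms
    skey <- paste(sa$residue, sa$tag, sep = "|")
    idx <- match(akeys, skey)
    if (anyNA(idx))
      stop("association refers to atoms absent from the structure")
    coords <- cbind(sa$x, sa$y, sa$z)[idx, , drop = FALSE]
    amat <- as.matrix(dist(coords))
  } else {
    if (is.null(mesh))
      stop("metric 'GD' requires the mesh the association was built on")
    vgd <- vertexGeodesics(mesh, augment = augment)
    grp <- match(atom_key, akeys)
    cnt <- tabulate(grp, nbins = length(akeys))
    sums <- rowsum(vgd, grp, reorder = TRUE)
    sums <- t(rowsum(t(sums), grp, reorder = TRUE))
    amat <- sums / outer(cnt, cnt)
  }
  dimnames(amat) <- NULL

  rgrp <- match(atoms$residue, sres)
  rcnt <- tabulate(rgrp, nbins = length(sres))
  rsums <- rowsum(amat, rgrp, reorder = TRUE)
  rsums <- t(rowsum(t(rsums), rgrp, reorder = TRUE))
  rmat <- rsums / outer(rcnt, rcnt)
  diag(rmat) <- 0
  dimnames(rmat) <- NULL

  rt <- assoc@residues
  rt <- rt[match(sres, rt$residue), , drop = FALSE]
  rownames(rt) <- NULL
  new("ResidueDistanceMatrix", structureId = structure@id, metric = metric,
      residues = rt, values = rmat)
}
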