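single_atom <- function(tag = "N") {
  structure_from_atoms(data.frame(residue = 1, tag = tag, x = 0, y = 0, z = 0))
}

test_that("a single atom meshes to a sphere of radius vdw + probe", {
  s <- single_atom("N")
  m <- buildSurface(s, probe_radius = 1.5, grid_resolution = 0.5)
  r <- 1.55 + 1.5
  expect_lt(abs(meshArea(m) / (4 * pi * r^2) - 1), 0.05)
  # every vertex sits on the sphere, within grid tolerance
  rad <- sqrt(rowSums(meshVertices(m)^2))
  expect_lt(max(abs(rad - r)), 0.5)
  # atom center is enclosed: distance from center to surface ~ r
  d <- ladflex:::cpp_point_mesh_dist(matrix(0, 1, 3), meshVertices(m),
                                     meshFaces(m))
  expect_lt(abs(d - r), 0.5)
})

test_that("two far-apart atoms produce exactly two mesh components", {
  s <- structure_from_atoms(data.frame(residue = c(1, 2), tag = "CA",
                                       x = c(0, 30), y = 0, z = 0))
  m <- buildSurface(s, grid_resolution = 0.6)
  expect_equal(length(meshComponents(m)), 2L)
})

test_that("a toy helix meshes to one component with every residue on the surface", {
  s <- makeToyChain(10, "helix")
  m <- buildSurface(s, grid_resolution = 0.7)
  expect_equal(length(meshComponents(m)), 1L)
  assoc <- associateVertices(simplifyMesh(m), s)
  expect_equal(surfaceResidues(assoc)$residue, 1:10)
})

test_that("simplification respects the face budget and stays close in shape", {
  ico <- makeAnalyticMesh("icosphere", subdivisions = 3)  # 1280 faces
  expect_equal(nFaces(ico), 1280L)
  slim <- simplifyMesh(ico, 0.15)
  expect_lte(nFaces(slim), ceiling(0.15 * 1280))
  expect_lt(meshDistance(ico, slim), 0.05)   # < 5% of unit radius
  # face_fraction = 1 is a no-op
  expect_equal(nFaces(simplifyMesh(ico, 1)), 1280L)
  # default keeps 15% of faces
  expect_equal(formals(simplifyMesh)$face_fraction, 0.15)
  # collapsing below a valid mesh is refused
  expect_error(simplifyMesh(ico, 1e-5), "face_fraction too small")
})

test_that("simplification never increases the face count", {
  for (kind in c("icosphere", "torus")) {
    m <- makeAnalyticMesh(kind, subdivisions = 2)
    for (ff in c(0.9, 0.5, 0.2)) {
      expect_lte(nFaces(simplifyMesh(m, ff)), ceiling(ff * nFaces(m)))
    }
  }
})

test_that("vertex association is a partition with deterministic tie-breaking", {
  s <- makeToyChain(6, "helix")
  m <- simplifyMesh(buildSurface(s, grid_resolution = 0.8))
  assoc <- associateVertices(m, s)
  # partition: every vertex owned exactly once
  expect_equal(sum(lengths(atomVertices(assoc))), nVertices(m))
  # single-atom structure owns everything
  s1 <- single_atom()
  m1 <- buildSurface(s1, grid_resolution = 0.6)
  a1 <- associateVertices(m1, s1)
  expect_equal(unique(a1@vertexOwner$residue), 1L)
  expect_equal(surfaceResidues(a1)$residue, 1L)
  # a vertex equidistant from two atoms goes to the earlier residue
  s2 <- structure_from_atoms(data.frame(residue = c(1, 2), tag = "CA",
                                        x = c(-1, 1), y = 0, z = 0))
  mesh <- ladflex:::new_trimesh(rbind(c(0, 0, 0), c(0, 1, 0), c(0, 0, 1)),
                                matrix(c(1L, 2L, 3L), 1, 3))
  a2 <- associateVertices(mesh, s2)
  expect_equal(a2@vertexOwner$residue[1L], 1L)
})

test_that("a residue caged by its neighbours is called buried", {
  cage <- data.frame(
    residue = c(1, 1, 1, 1, 2, 3, 3),
    tag = c("N", "CA", "C", "O", "CA", "N", "CA"),
    x = c(2.2, -2.2, 0, 0, 0, 0, 0),
    y = c(0, 0, 2.2, -2.2, 0, 0, 0),
    z = c(0, 0, 0, 0, 0, 2.2, -2.2))
  s <- structure_from_atoms(cage)
  m <- buildSurface(s, grid_resolution = 0.5)
  assoc <- associateVertices(m, s)
  sr <- surfaceResidues(assoc)$residue
  expect_false(2L %in% sr)          # the central residue has no vertex
  expect_setequal(sr, c(1L, 3L))
})

test_that("the surface-residue set is invariant under rigid motion", {
  s <- makeToyChain(12, "helix")
  moved <- rigidly_moved(s)
  sr1 <- surfaceResidues(associateVertices(simplifyMesh(buildSurface(s)), s))
  sr2 <- surfaceResidues(associateVertices(simplifyMesh(buildSurface(moved)),
                                           moved))
  expect_equal(sr1$residue, sr2$residue)
})

test_that("MSMS .vert/.face files import with their 1-based face indexing", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  vert <- c("# MSMS solvent excluded surface", "#", "    4    1  1.00  1.50",
            sprintf("%9.3f %9.3f %9.3f %9.3f %9.3f %9.3f", v[, 1], v[, 2],
                    v[, 3], 0, 0, 1))
  face <- c("# MSMS solvent excluded surface", "#", "    4    1  1.00  1.50",
            "    1    2    3 1 1", "    1    2    4 1 1",
            "    1    3    4 1 1", "    2    3    4 1 1")
  vf <- tempfile(fileext = ".vert"); ff <- tempfile(fileext = ".face")
  writeLines(vert, vf); writeLines(face, ff)
  m <- importMSMS(vf, ff)
  expect_equal(nVertices(m), 4L)
  expect_equal(nFaces(m), 4L)
  # "1 2 3" on disk addresses the first three vertices
  expect_equal(meshFaces(m)[1L, ], c(1L, 2L, 3L))
  # header/record count mismatch is a parse error
  writeLines(face[-4L], ff)
  expect_error(importMSMS(vf, ff), "count")
})

test_that("OFF and PLY exports round-trip through their readers", {
  m <- makeAnalyticMesh("icosphere", subdivisions = 1)
  off <- tempfile(fileext = ".off")
  writeOFF(m, off)
  m2 <- readOFF(off)
  expect_equal(nVertices(m2), nVertices(m))
  expect_equal(meshFaces(m2), meshFaces(m))
  expect_equal(meshVertices(m2), meshVertices(m), tolerance = 1e-8)
  ply <- tempfile(fileext = ".ply")
  writePLY(m, ply)
  m3 <- readPLY(ply)
  expect_equal(meshFaces(m3), meshFaces(m))
})
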