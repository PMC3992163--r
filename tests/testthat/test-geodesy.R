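fake_assoc <- function(owner_res, owner_tag) {
  n <- length(owner_res)
  new("VertexAssociation", structureId = "fix:A",
      vertexOwner = data.frame(vertex = seq_len(n),
                               residue = as.integer(owner_res),
                               tag = owner_tag, stringsAsFactors = FALSE),
      residues = data.frame(residue = sort(unique(as.integer(owner_res))),
                            seq_pos = sort(unique(as.integer(owner_res))),
                            icode = "", resname = "GLY",
                            stringsAsFactors = FALSE))
}

test_that("vertex geodesics are zero on the diagonal, symmetric, and >= chords", {
  ico <- makeAnalyticMesh("icosphere", subdivisions = 2)
  v <- meshVertices(ico)
  idx <- c(1L, 5L, 40L, 100L)
  g <- vertexGeodesics(ico, idx, idx)
  expect_equal(diag(g), rep(0, 4))
  expect_equal(g, t(g), tolerance = 1e-12)
  chord <- as.matrix(dist(v[idx, ]))
  expect_true(all(g - chord >= -1e-9))
})

test_that("on a flat grid the geodesic equals the Euclidean distance", {
  pl <- makeAnalyticMesh("plane", n = 6, spacing = 1)
  # adjacent vertices: exactly the edge length
  expect_equal(vertexGeodesics(pl, 1L, 2L)[1, 1], 1)
  # along a straight row of edges: exact Euclidean distance
  expect_equal(vertexGeodesics(pl, 1L, 7L)[1, 1], 6)
  # along the grid diagonal (a straight edge path too)
  d <- vertexGeodesics(pl, 1L, 49L)[1, 1]
  expect_equal(d, 6 * sqrt(2), tolerance = 1e-9)
})

test_that("antipodal geodesics on the unit icosphere approach pi", {
  ico <- makeAnalyticMesh("icosphere", subdivisions = 4)
  v <- meshVertices(ico)
  anti <- which.min(colSums((t(v) + v[1L, ])^2))
  g <- vertexGeodesics(ico, 1L, anti)[1, 1]
  expect_lt(abs(g / pi - 1), 0.03)
})

test_that("the triangle inequality holds for mesh geodesics", {
  ico <- makeAnalyticMesh("icosphere", subdivisions = 2)
  idx <- seq(1L, nVertices(ico), by = 11L)
  g <- vertexGeodesics(ico, idx, idx)
  n <- length(idx)
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      expect_true(all(g[i, j] <= g[i, ] + g[, j] + 1e-9))
    }
  }
})

test_that("disconnected vertex pairs are flagged NA, not infinite", {
  s <- structure_from_atoms(data.frame(residue = c(1, 2), tag = "CA",
                                       x = c(0, 30), y = 0, z = 0))
  m <- buildSurface(s, grid_resolution = 0.6)
  comps <- meshComponents(m)
  g <- vertexGeodesics(m, comps[[1L]][1L], comps[[2L]][1L])
  expect_true(is.na(g[1, 1]))
  # and the GD residue matrix flags the cross-component pair
  assoc <- associateVertices(m, s)
  dm <- residueDistanceMatrix(s, assoc, mesh = m, metric = "GD")
  expect_true(is.na(distanceValues(dm)[1, 2]))
  expect_equal(diag(distanceValues(dm)), c(0, 0))
})

test_that("atom-level GD is the mean over all associated vertex pairs", {
  # vertices 1,2 belong to atom (1, N); vertex 3 to atom (2, CA)
  assoc <- fake_assoc(c(1, 1, 2), c("N", "N", "CA"))
  vgd <- matrix(0, 3, 3)
  vgd[1, 3] <- vgd[3, 1] <- 3
  vgd[2, 3] <- vgd[3, 2] <- 5
  # M = 2, N = 1: hand evaluation of the double sum -> (3 + 5) / 2
  expect_equal(atomGD(assoc, vgd, c(1, "N"), c(2, "CA")), 4)
  # symmetry of the mean
  expect_equal(atomGD(assoc, vgd, c(2, "CA"), c(1, "N")), 4)
  # M = N = 1 reduces to the single vertex geodesic
  assoc1 <- fake_assoc(c(1, 2), c("N", "CA"))
  vgd1 <- matrix(c(0, 7, 7, 0), 2, 2)
  expect_equal(atomGD(assoc1, vgd1, c(1, "N"), c(2, "CA")), 7)
  expect_error(atomGD(assoc1, vgd1, c(1, "O"), c(2, "CA")),
               "no associated vertices")
})

test_that("residue-level ED averages over the vertex-associated atom set", {
  # two single-atom residues 7.25 A apart
  s <- structure_from_atoms(data.frame(residue = c(1, 2), tag = "CA",
                                       x = c(0, 7.25), y = 0, z = 0))
  assoc <- fake_assoc(c(1, 2), c("CA", "CA"))
  dm <- residueDistanceMatrix(s, assoc, metric = "ED")
  expect_equal(distanceValues(dm)[1, 2], 7.25)
  # residues {a1, a2} vs {b1} with atom EDs {2, 4} -> mean 3
  s2 <- structure_from_atoms(data.frame(residue = c(1, 1, 2),
                                        tag = c("N", "CA", "CA"),
                                        x = c(0, 6, 2), y = 0, z = 0))
  assoc2 <- fake_assoc(c(1, 1, 2), c("N", "CA", "CA"))
  dm2 <- residueDistanceMatrix(s2, assoc2, metric = "ED")
  expect_equal(distanceValues(dm2)[1, 2], 3)
})

test_that("geodesic residue distances dominate Euclidean ones on a sphere", {
  # single-CA residues at the 12 icosahedral vertices of a sphere: every
  # pair is separated by >= 63 degrees of arc, where geodesics clearly
  # exceed chords
  ico <- makeAnalyticMesh("icosphere", subdivisions = 3, radius = 4)
  v <- meshVertices(ico)
  picks <- 1:12
  s <- structure_from_atoms(data.frame(residue = seq_along(picks), tag = "CA",
                                       x = v[picks, 1], y = v[picks, 2],
                                       z = v[picks, 3]))
  assoc <- associateVertices(ico, s)
  gd <- distanceValues(residueDistanceMatrix(s, assoc, mesh = ico,
                                             metric = "GD"))
  ed <- distanceValues(residueDistanceMatrix(s, assoc, metric = "ED"))
  off <- upper.tri(gd)
  expect_true(all(gd[off] >= ed[off] - 1e-9))
  expect_true(any(gd[off] > ed[off] + 0.1))  # strictly longer somewhere
})

test_that("the ED residue matrix is exactly invariant under rigid motion", {
  s <- makeToyChain(8, "zigzag")
  m <- simplifyMesh(buildSurface(s, grid_resolution = 0.8))
  assoc <- associateVertices(m, s)
  d1 <- distanceValues(residueDistanceMatrix(s, assoc, metric = "ED"))
  d2 <- distanceValues(residueDistanceMatrix(rigidly_moved(s), assoc,
                                             metric = "ED"))
  expect_equal(d1, d2, tolerance = 1e-9)
})
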