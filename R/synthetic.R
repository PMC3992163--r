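#' Deterministic toy backbone chain
#'
#' Generates an idealized backbone with exact 3.8 Angstrom consecutive
#' CA-CA spacing and N/C/O atoms placed in a local frame around each CA.
#' Geometries: `helix` (alpha-helical rise 1.5 A, 100 degrees per residue,
#' radius solved so the CA-CA spacing is exactly 3.8 A), `extended`
#' (near-straight chain) and `zigzag` (strongly kinked chain). The
#' generator is a pure function of its arguments; `seed` is accepted for
#' interface symmetry with the stochastic generators but the geometry is
#' noise-free.
#'
#' @param n_residues number of residues (>= 5).
#' @param geometry `"helix"`, `"extended"` or `"zigzag"`.
#' @param seed unused for this noise-free generator (kept for a uniform
#'   generator interface).
#' @return A [BackboneStructure-class] with id `"toy-<geometry>-<n>:A"`.
#' @examples
#' s <- makeToyChain(10, "helix")
#' ca <- atomTable(s)
#' ca <- ca[ca$tag == "CA", c("x", "y", "z")]
#' dist(ca[1:2, ])  # 3.8
#' @export
makeToyChain <- function(n_residues, geometry = c("helix", "extended", "zigzag"),
                         seed = 1L) {
  geometry <- match.arg(geometry)
  n <- as.integer(n_residues)
  if (is.na(n) || n < 5L) stop("n_residues must be >= 5")
  ca <- switch(geometry,
    helix = {
      rise <- 1.5
      step <- 100 * pi / 180
      rad <- sqrt(3.8^2 - rise^2) / (2 * sin(step / 2))
      t <- (seq_len(n) - 1L) * step
      cbind(rad * cos(t), rad * sin(t), (seq_len(n) - 1L) * rise)
    },
    extended = {
      b <- 1.0
      a <- sqrt(3.8^2 - b^2)
      cbind((seq_len(n) - 1L) * a, (seq_len(n) %% 2L) * b, 0)
    },
    zigzag = {
      b <- 2.4
      a <- sqrt(3.8^2 - b^2)
      cbind((seq_len(n) - 1L) * a, (seq_len(n) %% 2L) * b, 0)
    })

  # local frame per residue: u along the chain, p and q perpendicular
  up <- ca[c(2:n, n), ] - ca[c(1L, 1:(n - 1L)), ]
  u <- up / sqrt(rowSums(up^2))
  ref <- matrix(rep(c(0, 0, 1), each = n), n, 3L)
  para <- abs(u[, 3L]) > 0.9
  ref[para, ] <- matrix(rep(c(1, 0, 0), each = sum(para)), ncol = 3L)
  p <- ref - u * rowSums(ref * u)
  p <- p / sqrt(rowSums(p^2))
  q <- cbind(u[, 2L] * p[, 3L] - u[, 3L] * p[, 2L],
             u[, 3L] * p[, 1L] - u[, 1L] * p[, 3L],
             u[, 1L] * p[, 2L] - u[, 2L] * p[, 1L])

  coords <- rbind(ca - 1.2 * u + 0.7 * p,   # N
                  ca,                       # CA
                  ca + 1.2 * u + 0.7 * p,   # C
                  ca + 1.2 * u + 0.7 * p + 1.23 * q)  # O (off the carbonyl C)
  tags <- rep(c("N", "CA", "C", "O"), each = n)
  atoms <- data.frame(residue = rep(seq_len(n), 4L),
                      seq_pos = rep(seq_len(n), 4L),
                      icode = "", resname = "GLY", tag = tags,
                      x = coords[, 1L], y = coords[, 2L], z = coords[, 3L],
                      stringsAsFactors = FALSE)
  new_backbone(sprintf("toy-%s-%d:A", geometry, n), atoms)
}

#' Apply a rigid hinge bend to a backbone chain
#'
#' Rotates every residue strictly after the hinge residue rigidly about an
#' axis through the hinge CA; residues up to and including the hinge are
#' untouched. Both sides therefore stay internally rigid: all intra-side
#' pairwise atom distances are preserved exactly, only cross-side
#' distances change.
#'
#' @param s a [BackboneStructure-class].
#' @param hinge residue index of the hinge (1 < hinge < n).
#' @param angle bend angle in degrees.
#' @param axis rotation axis (3-vector, need not be normalized).
#' @return A bent [BackboneStructure-class] with the same id.
#' @export
applyHingeBend <- function(s, hinge, angle, axis = c(0, 0, 1)) {
  stopifnot(is(s, "BackboneStructure"))
  n <- nResidues(s)
  hinge <- as.integer(hinge)
  if (is.na(hinge) || hinge <= 1L || hinge >= n)
    stop("hinge must lie strictly inside the chain (1 < hinge < ", n, ")")
  if (sqrt(sum(axis^2)) < 1e-12) stop("axis must be non-zero")
  a <- s@atoms
  pivot <- unlist(a[a$residue == hinge & a$tag == "CA", c("x", "y", "z")])
  if (length(pivot) != 3L)
    pivot <- colMeans(a[a$residue == hinge, c("x", "y", "z")])
  R <- rotation_matrix(axis, angle * pi / 180)
  move <- a$residue > hinge
  xyz <- t(as.matrix(a[move, c("x", "y", "z")]))
  xyz <- R %*% (xyz - pivot) + pivot
  a$x[move] <- xyz[1L, ]
  a$y[move] <- xyz[2L, ]
  a$z[move] <- xyz[3L, ]
  new_backbone(s@id, a)
}

default_hinge_axis <- function(s, hinge) {
  a <- s@atoms
  n <- nResidues(s)
  ca <- function(i) unlist(a[a$residue == i & a$tag == "CA", c("x", "y", "z")])
  u <- ca(min(hinge + 1L, n)) - ca(max(hinge - 1L, 1L))
  u <- u / sqrt(sum(u^2))
  ref <- if (abs(u[3L]) > 0.9) c(1, 0, 0) else c(0, 0, 1)
  ax <- ref - sum(ref * u) * u
  ax / sqrt(sum(ax^2))
}

#' Generate a hinge-bend morph group
#'
#' Conformers of one chain spanning a rigid hinge-bending motion: bend
#' angles are linearly spaced in `[0, max_angle]` over `n_frames` frames
#' (frame 1 is the unbent state, the last frame the fully bent state), and
#' a small Gaussian coordinate jitter (default sigma 0.05 Angstrom) makes
#' conformers homologous-but-not-identical, emulating interpolated morph
#' structures. 1 to 3 hinge points are supported; with several hinges the
#' same frame angle is applied at each in turn.
#'
#' @param base a [BackboneStructure-class], the unbent chain.
#' @param hinges integer vector of 1-3 hinge residue indices.
#' @param max_angle maximal bend angle in degrees.
#' @param n_frames number of conformers (>= 2).
#' @param seed RNG seed for the jitter; the group is a pure function of
#'   (arguments, seed).
#' @param jitter_sd per-coordinate Gaussian jitter in Angstrom.
#' @param axes optional list of rotation axes, one per hinge; defaults to
#'   a deterministic perpendicular of the local chain direction.
#' @param group_id id of the group; defaults to the base structure's id.
#' @return A [MorphGroup-class]; conformer ids are `"<group_id>_f<k>"`.
#' @examples
#' g <- makeMorphGroup(makeToyChain(30, "helix"), hinges = 15,
#'                     max_angle = 60, n_frames = 5, seed = 7)
#' g
#' @export
makeMorphGroup <- function(base, hinges, max_angle, n_frames = 10L,
                           seed = 1L, jitter_sd = 0.05, axes = NULL,
                           group_id = NULL) {
  stopifnot(is(base, "BackboneStructure"))
  n_frames <- as.integer(n_frames)
  if (is.na(n_frames) || n_frames < 2L) stop("n_frames must be >= 2")
  hinges <- as.integer(hinges)
  if (length(hinges) < 1L || length(hinges) > 3L)
    stop("1 to 3 hinge points are supported")
  if (is.null(group_id)) group_id <- base@id
  if (is.null(axes)) axes <- lapply(hinges, default_hinge_axis, s = base)
  angles <- seq(0, max_angle, length.out = n_frames)
  conformers <- with_seed(seed, lapply(seq_len(n_frames), function(k) {
    s <- base
    for (hi in seq_along(hinges))
      s <- applyHingeBend(s, hinges[hi], angles[k], axes[[hi]])
    a <- s@atoms
    m <- nrow(a)
    a$x <- a$x + rnorm(m, sd = jitter_sd)
    a$y <- a$y + rnorm(m, sd = jitter_sd)
    a$z <- a$z + rnorm(m, sd = jitter_sd)
    new_backbone(sprintf("%s_f%02d", group_id, k), a)
  }))
  new("MorphGroup", groupId = group_id, conformers = conformers,
      hinges = hinges, angles = angles)
}

#' Synthetic labeled alignment-statistic pairs
#'
#' Emulates a training set of positive (homologous / domain-swapping,
#' expected low LAD_div) and negative (non-homologous, expected high
#' LAD_div) pairs by drawing alignment statistics directly: positives get
#' low LAD-RMSD (`|N(0.3, 0.1)|`) and high aligned coverage
#' (`Beta(8, 2)`); negatives high LAD-RMSD (`|N(2.0, 0.5)|`) and low
#' coverage (`Beta(2, 5)`). Profile lengths are uniform in `len_range`;
#' positives, being conformers/homologs of one protein, share a length
#' (`nq == ns`, so coverage keeps its Beta distribution), while negative
#' pairs draw unrelated lengths independently. `ne` is the coverage times
#' the mean length, clamped to the shorter profile.
#'
#' @param n_pos,n_neg pair counts (>= 1).
#' @param seed RNG seed; output is a pure function of (arguments, seed).
#' @param pos_rmsd,neg_rmsd c(mean, sd) of the folded-normal RMSD draws.
#' @param pos_cov,neg_cov c(shape1, shape2) of the Beta coverage draws.
#' @param len_range integer range of profile lengths.
#' @return data.frame with columns `label` ("pos"/"neg"), `ne`,
#'   `lad_rmsd`, `nq`, `ns`.
#' @export
makeLabeledPairs <- function(n_pos, n_neg, seed = 1L,
                             pos_rmsd = c(0.3, 0.1), neg_rmsd = c(2.0, 0.5),
                             pos_cov = c(8, 2), neg_cov = c(2, 5),
                             len_range = c(50L, 300L)) {
  stopifnot(n_pos >= 1L, n_neg >= 1L)
  with_seed(seed, {
    draw <- function(nn, rmsd_par, cov_par, paired) {
      nq <- sample(len_range[1L]:len_range[2L], nn, replace = TRUE)
      ns <- if (paired) nq
            else sample(len_range[1L]:len_range[2L], nn, replace = TRUE)
      cov <- rbeta(nn, cov_par[1L], cov_par[2L])
      ne <- pmin(round(cov * (nq + ns) / 2), pmin(nq, ns))
      data.frame(ne = as.integer(ne),
                 lad_rmsd = abs(rnorm(nn, rmsd_par[1L], rmsd_par[2L])),
                 nq = nq, ns = ns)
    }
    pos <- draw(n_pos, pos_rmsd, pos_cov, paired = TRUE)
    neg <- draw(n_neg, neg_rmsd, neg_cov, paired = FALSE)
    cbind(label = rep(c("pos", "neg"), c(n_pos, n_neg)), rbind(pos, neg))
  })
}

#' Analytic test meshes with known geodesics
#'
#' Fixtures for validating geodesic computations: `icosphere` (great-circle
#' geodesics; `20 * 4^subdivisions` faces), `plane` (a triangulated square
#' grid where on-surface equals straight-line distance) and `torus`
#' (geodesics strictly longer than chords for most vertex pairs).
#'
#' @param kind `"icosphere"`, `"plane"` or `"torus"`.
#' @param subdivisions icosphere subdivision level (default 3).
#' @param radius icosphere radius (default 1).
#' @param n plane grid cells per side (default 10).
#' @param spacing plane grid spacing (default 1).
#' @param R,r torus major/minor radius (defaults 2 and 0.7).
#' @param nu,nv torus grid resolution (defaults 48 and 24).
#' @return A [TriMesh-class].
#' @examples
#' nFaces(makeAnalyticMesh("icosphere", subdivisions = 2))  # 320
#' @export
makeAnalyticMesh <- function(kind = c("icosphere", "plane", "torus"),
                             subdivisions = 3L, radius = 1,
                             n = 10L, spacing = 1,
                             R = 2, r = 0.7, nu = 48L, nv = 24L) {
  kind <- match.arg(kind)
  if (kind == "icosphere") return(icosphere_mesh(subdivisions, radius))
  if (kind == "plane") return(plane_mesh(n, spacing))
  torus_mesh(R, r, nu, nv)
}

icosphere_mesh <- function(subdivisions, radius) {
  phi <- (1 + sqrt(5)) / 2
  v <- matrix(c(-1, phi, 0,   1, phi, 0,  -1, -phi, 0,   1, -phi, 0,
                 0, -1, phi,  0, 1, phi,   0, -1, -phi,  0, 1, -phi,
                 phi, 0, -1,  phi, 0, 1,  -phi, 0, -1,  -phi, 0, 1),
              ncol = 3L, byrow = TRUE)
  v <- v / sqrt(rowSums(v^2))
  f <- matrix(c(1, 12, 6,  1, 6, 2,   1, 2, 8,   1, 8, 11,  1, 11, 12,
                2, 6, 10,  6, 12, 5,  12, 11, 3, 11, 8, 7,  8, 2, 9,
                4, 10, 5,  4, 5, 3,   4, 3, 7,   4, 7, 9,   4, 9, 10,
                5, 10, 6,  3, 5, 12,  7, 3, 11,  9, 7, 8,   10, 9, 2),
              ncol = 3L, byrow = TRUE)
  for (lvl in seq_len(subdivisions)) {
    edge_mid <- new.env(hash = TRUE)
    vlist <- v
    midpoint <- function(a, b) {
      key <- if (a < b) paste(a, b) else paste(b, a)
      id <- edge_mid[[key]]
      if (!is.null(id)) return(id)
      m <- (vlist[a, ] + vlist[b, ]) / 2
      m <- m / sqrt(sum(m^2))
      vlist <<- rbind(vlist, m)
      id <- nrow(vlist)
      edge_mid[[key]] <- id
      id
    }
    nf <- nrow(f)
    fnew <- matrix(0L, nf * 4L, 3L)
    for (i in seq_len(nf)) {
      a <- f[i, 1L]; b <- f[i, 2L]; cc <- f[i, 3L]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      fnew[(4L * i - 3L):(4L * i), ] <- rbind(c(a, ab, ca), c(b, bc, ab),
                                              c(cc, ca, bc), c(ab, bc, ca))
    }
    v <- vlist
    f <- fnew
  }
  new_trimesh(v * radius, f)
}

plane_mesh <- function(n, spacing) {
  n <- as.integer(n)
  g <- expand.grid(x = 0:n, y = 0:n)
  v <- cbind(g$x * spacing, g$y * spacing, 0)
  idx <- function(i, j) i + 1L + (n + 1L) * j  # i, j 0-based
  fl <- vector("list", n * n)
  k <- 1L
  for (j in 0:(n - 1L)) {
    for (i in 0:(n - 1L)) {
      fl[[k]] <- rbind(c(idx(i, j), idx(i + 1L, j), idx(i + 1L, j + 1L)),
                       c(idx(i, j), idx(i + 1L, j + 1L), idx(i, j + 1L)))
      k <- k + 1L
    }
  }
  new_trimesh(v, do.call(rbind, fl))
}

torus_mesh <- function(R, r, nu, nv) {
  nu <- as.integer(nu); nv <- as.integer(nv)
  iu <- rep(0:(nu - 1L), times = nv)
  iv <- rep(0:(nv - 1L), each = nu)
  u <- 2 * pi * iu / nu
  vv <- 2 * pi * iv / nv
  vtx <- cbind((R + r * cos(vv)) * cos(u), (R + r * cos(vv)) * sin(u),
               r * sin(vv))
  idx <- function(i, j) (i %% nu) + 1L + nu * (j %% nv)
  fl <- vector("list", nu * nv)
  k <- 1L
  for (j in 0:(nv - 1L)) {
    for (i in 0:(nu - 1L)) {
      fl[[k]] <- rbind(c(idx(i, j), idx(i + 1L, j), idx(i + 1L, j + 1L)),
                       c(idx(i, j), idx(i + 1L, j + 1L), idx(i, j + 1L)))
      k <- k + 1L
    }
  }
  new_trimesh(vtx, do.call(rbind, fl))
}

#' Default synthetic retrieval benchmark
#'
#' Five hinge-bend morph groups of 10 conformers each, with distinct base
#' geometries and chain lengths (30, 50, 60, 80, 100 residues), hinges at
#' mid-chain and bends up to 60 degrees -- a reduced-scale stand-in for a
#' morph database. Frame 1 of each group is the group representative.
#'
#' @param seed RNG seed driving the per-frame jitter.
#' @param n_groups number of groups (lengths and geometries are recycled
#'   beyond 5).
#' @param n_frames conformers per group.
#' @param max_angle maximal bend angle in degrees.
#' @return List with `groups` (list of [MorphGroup-class]), `structures`
#'   (flat named list of all conformers) and `manifest` (data.frame
#'   `structure_id`, `group_id`, `is_representative`).
#' @export
makeDefaultBenchmark <- function(seed = 42L, n_groups = 5L, n_frames = 10L,
                                 max_angle = 60) {
  lens <- rep(c(30L, 50L, 60L, 80L, 100L), length.out = n_groups)
  geos <- rep(c("helix", "extended", "zigzag", "helix", "extended"),
              length.out = n_groups)
  groups <- lapply(seq_len(n_groups), function(g) {
    base <- makeToyChain(lens[g], geos[g])
    makeMorphGroup(base, hinges = lens[g] %/% 2L, max_angle = max_angle,
                   n_frames = n_frames, seed = seed + g,
                   group_id = sprintf("g%d", g))
  })
  structures <- unlist(lapply(groups, morphConformers), recursive = FALSE)
  names(structures) <- vapply(structures, structureId, character(1))
  manifest <- do.call(rbind, lapply(groups, function(g) {
    ids <- vapply(g@conformers, structureId, character(1))
    data.frame(structure_id = ids, group_id = g@groupId,
               is_representative = seq_along(ids) == 1L,
               stringsAsFactors = FALSE)
  }))
  list(groups = groups, structures = structures, manifest = manifest)
}
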