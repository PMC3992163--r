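# Run code with a fixed RNG seed, restoring the caller's RNG state after.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else suppressWarnings(rm(".Random.seed", envir = env))
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# order atoms by (residue, canonical backbone tag order N < CA < C < O)
order_atoms <- function(atoms) {
  atoms[order(atoms$residue, match(atoms$tag, BACKBONE_TAGS)), , drop = FALSE]
}

new_backbone <- function(id, atoms) {
  atoms <- order_atoms(atoms)
  rownames(atoms) <- NULL
  atoms$residue <- as.integer(atoms$residue)
  atoms$seq_pos <- as.integer(atoms$seq_pos)
  new("BackboneStructure", id = id, atoms = atoms)
}

new_trimesh <- function(vertices, faces) {
  storage.mode(faces) <- "integer"
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  dimnames(faces) <- NULL
  new("TriMesh", vertices = vertices, faces = faces)
}

# 3x3 rotation matrix about unit axis by angle (radians), Rodrigues form
rotation_matrix <- function(axis, theta) {
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}
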