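# One fixed-width PDB ATOM/HETATM record (wwPDB v3.3 columns).
pdb_record <- function(serial, name, resname, chain, resno, x, y, z,
                       occ = 1, alt = " ", icode = " ", record = "ATOM") {
  sprintf("%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial,
          ifelse(nchar(name) < 4L, paste0(" ", name), name),
          alt, resname, chain, resno, icode, x, y, z, occ, 0,
          substr(trimws(name), 1L, 1L))
}

# Minimal two-residue backbone chain as PDB text.
two_residue_pdb <- function() {
  k <- 0L
  lines <- character(0)
  for (res in 1:2) {
    for (tag in c("N", "CA", "C", "O")) {
      k <- k + 1L
      lines <- c(lines, pdb_record(k, tag, "ALA", "A", res,
                                   res * 4 + k * 0.1, 0, 0))
    }
  }
  c(lines, "END")
}

# BackboneStructure with arbitrary atoms, one per row of `df`
# (columns residue, tag, x, y, z).
structure_from_atoms <- function(df, id = "fix:A") {
  atoms <- data.frame(residue = as.integer(df$residue),
                      seq_pos = as.integer(df$residue),
                      icode = "", resname = "GLY", tag = df$tag,
                      x = df$x, y = df$y, z = df$z,
                      stringsAsFactors = FALSE)
  ladflex:::new_backbone(id, atoms)
}

# ResidueDistanceMatrix wrapper around a plain symmetric matrix.
dmat_from_matrix <- function(m, metric = "ED", id = "fix:A") {
  n <- nrow(m)
  new("ResidueDistanceMatrix", structureId = id, metric = metric,
      residues = data.frame(residue = seq_len(n), seq_pos = seq_len(n),
                            icode = "", resname = "GLY",
                            stringsAsFactors = FALSE),
      values = m)
}

# LADProfile with given values.
profile_from_values <- function(v, metric = "ED", window = 9L, id = "fix:A") {
  new("LADProfile", structureId = id, metric = metric,
      window = as.integer(window),
      entries = data.frame(residue = seq_along(v), seq_pos = seq_along(v),
                           resname = "GLY", lad = v,
                           stringsAsFactors = FALSE))
}

# RetrievalRun from a relevance vector (rank order), distinct scores.
run_from_relevance <- function(rel, query = "q") {
  n <- length(rel)
  new("RetrievalRun", queryId = query,
      ranking = data.frame(subject_id = sprintf("s%03d", seq_len(n)),
                           lad_div = seq_len(n) / (n + 1),
                           relevant = as.logical(rel),
                           stringsAsFactors = FALSE))
}

# Rigid transform of a structure: fixed rotation + translation.
rigidly_moved <- function(s, axis = c(1, 2, 3), angle = 0.7,
                          shift = c(5, -3, 2)) {
  R <- ladflex:::rotation_matrix(axis, angle)
  a <- s@atoms
  xyz <- R %*% t(as.matrix(a[, c("x", "y", "z")])) + shift
  a$x <- xyz[1L, ]; a$y <- xyz[2L, ]; a$z <- xyz[3L, ]
  ladflex:::new_backbone(s@id, a)
}
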