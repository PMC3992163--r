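#' Read a backbone-only chain from a PDB file
#'
#' Parses standard `ATOM` records of one chain and keeps only the backbone
#' atoms N, CA, C and O. `HETATM` records, hydrogens and side chains are
#' ignored. Alternate locations are resolved by keeping, per atom, the
#' record with the highest occupancy (ties go to the alphabetically first
#' altloc). Only the first model of a multi-model file is used. Residues
#' are ordered by (sequence number, insertion code); a residue is retained
#' when at least one backbone atom is present.
#'
#' @param pdb path to a PDB file, or a character vector of PDB-format lines.
#' @param chain single chain identifier, e.g. `"A"`.
#' @return A [BackboneStructure-class] with id `"<file stem>:<chain>"`.
#' @examples
#' pdb <- makeToyChain(10, "helix")
#' tf <- tempfile(fileext = ".pdb")
#' writeBackbonePDB(pdb, tf)
#' s <- readBackbone(tf, chain = "A")
#' nResidues(s)
#' @export
readBackbone <- function(pdb, chain) {
  stopifnot(is.character(chain), length(chain) == 1L)
  if (length(pdb) == 1L && !grepl("\n", pdb) && file.exists(pdb)) {
    path <- pdb
    stem <- sub("\\.(pdb|ent)$", "", basename(pdb), ignore.case = TRUE)
  } else {
    path <- tempfile(fileext = ".pdb")
    on.exit(unlink(path), add = TRUE)
    writeLines(unlist(strsplit(pdb, "\n", fixed = TRUE)), path)
    stem <- "structure"
  }
  p <- bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE)
  a <- p$atom
  a <- a[a$type == "ATOM", , drop = FALSE]
  if (!chain %in% a$chain)
    stop("chain not found: '", chain, "' has no ATOM records")
  a <- a[a$chain == chain & a$elety %in% BACKBONE_TAGS, , drop = FALSE]
  if (nrow(a) == 0L)
    stop("empty structure: chain '", chain, "' has no backbone atoms")
  a$insert[is.na(a$insert)] <- ""
  a$alt[is.na(a$alt)] <- ""
  a$o[is.na(a$o)] <- 1

  # altloc: per (resno, insert, atom) keep highest occupancy, tie -> first
  # altloc letter; then drop any residual duplicates (e.g. repeated models)
  key <- paste(a$resno, a$insert, a$elety, sep = "\r")
  a <- a[order(key, -a$o, a$alt), , drop = FALSE]
  a <- a[!duplicated(paste(a$resno, a$insert, a$elety, sep = "\r")), , drop = FALSE]

  rkey <- paste(a$resno, a$insert, sep = "\r")
  ruid <- unique(rkey[order(a$resno, a$insert)])
  atoms <- data.frame(
    residue = match(rkey, ruid),
    seq_pos = a$resno,
    icode = a$insert,
    resname = a$resid,
    tag = a$elety,
    x = a$x, y = a$y, z = a$z,
    stringsAsFactors = FALSE)
  new_backbone(paste0(stem, ":", chain), atoms)
}

#' Write a backbone structure as a PDB file
#'
#' Emits minimal fixed-width `ATOM` records (wwPDB v3.3 layout) for the
#' backbone atoms, chain `A`, plus a terminating `END`.
#'
#' @param x a [BackboneStructure-class].
#' @param path output file path.
#' @param chain chain identifier to write (default `"A"`).
#' @return `path`, invisibly.
#' @export
writeBackbonePDB <- function(x, path, chain = "A") {
  stopifnot(is(x, "BackboneStructure"))
  a <- x@atoms
  elem <- substr(a$tag, 1L, 1L)
  lines <- sprintf(
    "ATOM  %5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(a)),
    ifelse(nchar(a$tag) < 4L, paste0(" ", a$tag), a$tag), " ",
    a$resname, chain, a$seq_pos, ifelse(a$icode == "", " ", a$icode),
    a$x, a$y, a$z, 1, 0, elem)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Write / read a LAD profile as TSV
#'
#' The on-disk format is a diff-friendly TSV: `#`-prefixed header lines
#' carry metadata (`structure_id`, `metric`, `window`), followed by a column
#' header and one row per surface residue with columns `residue` (internal
#' chain index), `seq_pos`, `resname`, `lad_angstrom`. Values are written
#' with 7 significant digits, so round-trips preserve at least 6.
#'
#' @param profile a [LADProfile-class].
#' @param path destination (for `writeProfile`) or source (for
#'   `readProfile`) file path.
#' @return `writeProfile` returns `path` invisibly; `readProfile` returns a
#'   [LADProfile-class].
#' @examples
#' d <- matrix(c(0, 2, 4, 2, 0, 2, 4, 2, 0), 3, 3)
#' dm <- new("ResidueDistanceMatrix", structureId = "toy", metric = "ED",
#'           residues = data.frame(residue = 1:3, seq_pos = 1:3,
#'                                 icode = "", resname = "GLY"),
#'           values = d)
#' p <- buildLADProfile(dm, window = 9)
#' tf <- tempfile(fileext = ".tsv")
#' writeProfile(p, tf)
#' identicalish <- readProfile(tf)
#' @export
writeProfile <- function(profile, path) {
  stopifnot(is(profile, "LADProfile"))
  e <- profile@entries
  hdr <- c("# ladflex LAD profile",
           paste0("# structure_id\t", profile@structureId),
           paste0("# metric\t", profile@metric),
           paste0("# window\t", profile@window),
           "residue\tseq_pos\tresname\tlad_angstrom")
  rows <- sprintf("%d\t%d\t%s\t%.7g", e$residue, e$seq_pos, e$resname, e$lad)
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @rdname writeProfile
#' @export
readProfile <- function(path) {
  lines <- readLines(path)
  meta <- list(structure_id = NA_character_, metric = NA_character_,
               window = NA_integer_)
  i <- 1L
  while (i <= length(lines) && startsWith(lines[i], "#")) {
    fields <- strsplit(sub("^#\\s*", "", lines[i]), "\t", fixed = TRUE)[[1L]]
    if (length(fields) == 2L && fields[1L] %in% names(meta))
      meta[[fields[1L]]] <- fields[2L]
    i <- i + 1L
  }
  if (i > length(lines) || !startsWith(lines[i], "residue\t"))
    stop("profile parse error at line ", i, ": expected column header")
  if (is.na(meta$metric) || is.na(meta$window))
    stop("profile parse error: missing metric/window metadata header")
  hdr_line <- i
  body <- lines[-seq_len(i)]
  body <- body[nzchar(body)]
  n <- length(body)
  entries <- data.frame(residue = integer(n), seq_pos = integer(n),
                        resname = character(n), lad = numeric(n),
                        stringsAsFactors = FALSE)
  for (k in seq_len(n)) {
    f <- strsplit(body[k], "\t", fixed = TRUE)[[1L]]
    lineno <- hdr_line + k
    if (length(f) != 4L)
      stop("profile parse error at line ", lineno, ": expected 4 fields")
    ri <- suppressWarnings(as.integer(f[1L]))
    sp <- suppressWarnings(as.integer(f[2L]))
    lv <- suppressWarnings(as.numeric(f[4L]))
    if (is.na(ri) || is.na(sp) || is.na(lv))
      stop("profile parse error at line ", lineno, ": non-numeric value")
    entries$residue[k] <- ri
    entries$seq_pos[k] <- sp
    entries$resname[k] <- f[3L]
    entries$lad[k] <- lv
  }
  w <- suppressWarnings(as.integer(meta$window))
  if (is.na(w)) stop("profile parse error: non-numeric window in header")
  new("LADProfile", structureId = meta$structure_id, metric = meta$metric,
      window = w, entries = entries)
}
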