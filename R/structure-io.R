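# Coordinate I/O and junction topology annotation.
#
# Structures are held as a flat atom table in author (file) numbering: all
# internal APIs address residues as (chain, resno) pairs exactly as they
# appear in the PDB/mmCIF record, matching the convention of deposited
# structures.

ION_RESIDUES <- c("K", "NA", "MG", "CL", "SR", "BA", "CO", "NCO", "3CO",
                  "CAC", "AS", "ARS")
ION_ELEMENTS <- c("K", "NA", "MG", "SR", "BA", "CO", "AS")

#' Construct an HJ structure object
#'
#' @param atoms Data frame with columns `chain`, `resno`, `resid`, `elety`
#'   (atom name), `elesy` (element), `x`, `y`, `z`.  An `is_ion` logical
#'   column is added (or kept) flagging ion/ion-like atoms.
#' @param cell Optional [lattice_params()] unit cell.
#' @return An object of class `hj_structure`.  Topology fields (`strands`,
#'   `branch_point`, `stacks`) are unset until [annotate_junction()] is
#'   called.
#' @export
hj_structure <- function(atoms, cell = NULL) {
  need <- c("chain", "resno", "resid", "elety", "elesy", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atoms is missing columns: ", paste(miss, collapse = ", "))
  if (nrow(atoms) == 0) stop("structure has no atoms")
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite atom coordinates")
  if (any(!nzchar(atoms$elesy))) stop("empty element symbols in atom table")
  if (is.null(atoms$is_ion)) atoms$is_ion <- flag_ions(atoms)
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, strands = NULL, stacks = NULL, cell = cell),
            class = "hj_structure")
}

# Residue-name whitelist with element fallback.  Cacodylate (CAC/ARS) is
# treated as one ion-like site located at its arsenic atom.
flag_ions <- function(atoms) {
  resid <- toupper(trimws(atoms$resid))
  elesy <- toupper(trimws(atoms$elesy))
  ion <- resid %in% setdiff(ION_RESIDUES, c("CAC", "ARS")) |
    (!resid %in% c("DA", "DC", "DG", "DT", "A", "C", "G", "T", "U", "HOH") &
       elesy %in% ION_ELEMENTS)
  ion | (resid %in% c("CAC", "ARS") & elesy == "AS")
}

#' @export
print.hj_structure <- function(x, ...) {
  cat("<hj_structure> ", nrow(x$atoms), " atoms, ",
      length(unique(paste(x$atoms$chain, x$atoms$resno))), " residues, ",
      sum(x$atoms$is_ion), " ion(s)\n", sep = "")
  if (!is.null(x$strands)) {
    cat("  annotated: 4 strands, branch residues ",
        paste(x$strands$branch, collapse = "/"), "; stacks ",
        paste(vapply(x$stacks, paste, character(1), collapse = "+"),
              collapse = " and "), "\n", sep = "")
  }
  if (!is.null(x$cell))
    cat(sprintf("  cell: a=%.2f b=%.2f c=%.2f alpha=%.1f beta=%.1f gamma=%.1f %s\n",
                x$cell$a, x$cell$b, x$cell$c, x$cell$alpha, x$cell$beta,
                x$cell$gamma, x$cell$spacegroup))
  invisible(x)
}

#' Unit-cell constants
#'
#' @param a,b,c Cell edge lengths in Angstrom (positive).
#' @param alpha,beta,gamma Cell angles in degrees, each in (0, 180).
#' @param spacegroup Space-group label (e.g. `"P 32 2 1"`); may be `""`.
#' @return A list of class `lattice_params`.
#' @export
lattice_params <- function(a, b, c, alpha = 90, beta = 90, gamma = 90,
                           spacegroup = "") {
  if (any(c(a, b, c) <= 0)) stop("cell lengths must be positive")
  if (any(c(alpha, beta, gamma) <= 0 | c(alpha, beta, gamma) >= 180))
    stop("cell angles must lie in (0, 180) degrees")
  structure(list(a = a, b = b, c = c, alpha = alpha, beta = beta,
                 gamma = gamma, spacegroup = spacegroup),
            class = "lattice_params")
}

parse_cryst1 <- function(line) {
  num <- function(i, j) suppressWarnings(as.numeric(substr(line, i, j)))
  vals <- c(num(7, 15), num(16, 24), num(25, 33),
            num(34, 40), num(41, 47), num(48, 54))
  if (any(is.na(vals))) stop("malformed CRYST1 record: ", trimws(line))
  lattice_params(vals[1], vals[2], vals[3], vals[4], vals[5], vals[6],
                 spacegroup = trimws(substr(line, 56, 66)))
}

format_cryst1 <- function(cell) {
  sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f %-11s",
          cell$a, cell$b, cell$c, cell$alpha, cell$beta, cell$gamma,
          cell$spacegroup)
}

#' Read a structure from PDB or mmCIF
#'
#' PDB files are parsed with bio3d; a minimal built-in reader handles the
#' `_atom_site` loop and `_cell` block of mmCIF files.  Ions are auto-flagged
#' by residue-name whitelist (K, NA, MG, cacodylate/arsenic, ...) with an
#' element-symbol fallback.  A `CRYST1`/`_cell` block, when present, is mapped
#' to [lattice_params()]; its absence is not an error.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"pdb"` or `"cif"`.
#' @return An unannotated `hj_structure`.
#' @export
read_hj_structure <- function(path, format = c("auto", "pdb", "cif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "cif" else "pdb"
  }
  if (file.size(path) == 0) stop("cannot parse ", path, ": file is empty")
  if (format == "pdb") read_structure_pdb(path) else read_structure_cif(path)
}

read_structure_pdb <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!any(grepl("^(ATOM|HETATM)", lines)))
    stop("cannot parse ", path, ": no ATOM/HETATM records")
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  atoms <- data.frame(chain = as.character(at$chain),
                      resno = as.integer(at$resno),
                      resid = as.character(at$resid),
                      elety = as.character(at$elety),
                      elesy = as.character(at$elesy),
                      x = at$x, y = at$y, z = at$z,
                      stringsAsFactors = FALSE)
  atoms$elesy[is.na(atoms$elesy) | !nzchar(atoms$elesy)] <-
    substr(gsub("[^A-Za-z]", "", atoms$elety[is.na(atoms$elesy) |
                                               !nzchar(atoms$elesy)]), 1, 1)
  cell <- NULL
  cl <- grep("^CRYST1", lines, value = TRUE)
  if (length(cl)) cell <- parse_cryst1(cl[1])
  hj_structure(atoms, cell = cell)
}

# Minimal mmCIF reader: _atom_site loop (whitespace-delimited with quoting)
# plus _cell / _symmetry items.  Sufficient for deposited DNA structures; not
# a general CIF parser.
read_structure_cif <- function(path) {
  lines <- readLines(path, warn = FALSE)
  toks <- function(s) scan(text = s, what = "", quiet = TRUE, quote = "\"'")
  # locate the atom_site loop
  i <- grep("^\\s*loop_", lines)
  hdr <- NULL; start <- NA
  for (k in i) {
    j <- k + 1
    fields <- character(0)
    while (j <= length(lines) && grepl("^\\s*_atom_site\\.", lines[j])) {
      fields <- c(fields, trimws(lines[j])); j <- j + 1
    }
    if (length(fields)) { hdr <- sub("^_atom_site\\.", "", fields); start <- j; break }
  }
  if (is.null(hdr)) stop("cannot parse ", path, ": no _atom_site loop found")
  rows <- list()
  j <- start
  while (j <= length(lines)) {
    ln <- trimws(lines[j])
    if (ln == "" || grepl("^(#|loop_|_|data_)", ln)) break
    v <- toks(ln)
    if (length(v) != length(hdr))
      stop("malformed _atom_site row at line ", j, " of ", path,
           ": expected ", length(hdr), " fields, got ", length(v))
    rows[[length(rows) + 1]] <- v
    j <- j + 1
  }
  if (!length(rows)) stop("cannot parse ", path, ": empty _atom_site loop")
  m <- do.call(rbind, rows)
  colnames(m) <- hdr
  pick <- function(...) {
    for (nm in c(...)) if (nm %in% hdr) return(m[, nm])
    stop("mmCIF _atom_site loop lacks required item (tried: ",
         paste(c(...), collapse = ", "), ") in ", path)
  }
  atoms <- data.frame(
    chain = as.character(pick("auth_asym_id", "label_asym_id")),
    resno = as.integer(pick("auth_seq_id", "label_seq_id")),
    resid = as.character(pick("auth_comp_id", "label_comp_id")),
    elety = as.character(pick("auth_atom_id", "label_atom_id")),
    elesy = as.character(pick("type_symbol")),
    x = as.numeric(pick("Cartn_x")), y = as.numeric(pick("Cartn_y")),
    z = as.numeric(pick("Cartn_z")), stringsAsFactors = FALSE)
  cif_item <- function(tag) {
    ln <- grep(paste0("^\\s*", tag, "\\s"), lines, value = TRUE)
    if (!length(ln)) return(NA)
    toks(ln[1])[2]
  }
  cell <- NULL
  ca <- suppressWarnings(as.numeric(cif_item("_cell\\.length_a")))
  if (!is.na(ca)) {
    cell <- lattice_params(
      ca,
      as.numeric(cif_item("_cell\\.length_b")),
      as.numeric(cif_item("_cell\\.length_c")),
      as.numeric(cif_item("_cell\\.angle_alpha")),
      as.numeric(cif_item("_cell\\.angle_beta")),
      as.numeric(cif_item("_cell\\.angle_gamma")),
      spacegroup = {
        sg <- cif_item("_symmetry\\.space_group_name_H-M")
        if (is.na(sg)) "" else sg
      })
  }
  hj_structure(atoms, cell = cell)
}

# Convert to a bio3d pdb object for writing.
as_bio3d_pdb <- function(s, xyz = NULL) {
  at <- s$atoms
  if (is.null(xyz)) xyz <- as.matrix(at[, c("x", "y", "z")])
  n <- nrow(at)
  atom <- data.frame(
    type = ifelse(at$is_ion | !at$resid %in% c("DA", "DC", "DG", "DT"),
                  "HETATM", "ATOM"),
    eleno = seq_len(n), elety = at$elety, alt = as.character(NA),
    resid = at$resid, chain = at$chain, resno = at$resno,
    insert = as.character(NA),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    o = 1, b = 0, segid = as.character(NA), elesy = at$elesy,
    charge = as.character(NA), stringsAsFactors = FALSE)
  pdb <- list(atom = atom,
              xyz = matrix(t(xyz), nrow = 1))
  class(pdb) <- "pdb"
  pdb
}

#' Write a structure (or trajectory frames) as PDB
#'
#' Single structures become one-model files; a matrix/list of frame
#' coordinates produces a multi-model (`MODEL`/`ENDMDL`) file.  A `CRYST1`
#' record is emitted when the structure carries a unit cell.
#'
#' @param s An `hj_structure`.
#' @param path Output path.
#' @param frames Optional list of n_atoms x 3 coordinate matrices to write as
#'   models (defaults to the structure's own coordinates).
#' @return Invisibly, the path written.
#' @export
write_hj_structure <- function(s, path, frames = NULL) {
  stopifnot(inherits(s, "hj_structure"))
  pdb <- as_bio3d_pdb(s)
  if (is.null(frames)) {
    xyz <- pdb$xyz
  } else {
    xyz <- do.call(rbind, lapply(frames, function(f) as.numeric(t(f))))
  }
  bio3d::write.pdb(pdb, file = path, xyz = xyz)
  if (!is.null(s$cell)) {
    body <- readLines(path, warn = FALSE)
    writeLines(c(format_cryst1(s$cell), body), path)
  }
  invisible(path)
}

#' Annotate four-strand junction topology
#'
#' Declares the four strands, their crossover residues and the two coaxial
#' stacks on a structure, and validates the four-arm topology.  Strand i runs
#' 5'->3' through arm i into arm i+1; `branch` is the last residue of the
#' strand's first arm (the residue at the crossover).  Arm i is then the
#' duplex of strand i residues `first..branch` and strand i-1 residues
#' `branch+1..last`, which must have equal lengths.
#'
#' @param s An `hj_structure`.
#' @param strands Data frame with four rows (strand 1..4 in order) and columns
#'   `chain`, `first`, `last`, `branch` (author residue numbers).
#' @param stacks List of two integer pairs of arm indices declared coaxially
#'   stacked, e.g. `list(c(1, 3), c(2, 4))`.  All four arms must be covered
#'   exactly once; non-opposite pairings are accepted with a warning.
#' @return The annotated `hj_structure`.  Annotation is idempotent: re-running
#'   with the same declaration returns an identical object.
#' @export
annotate_junction <- function(s, strands,
                              stacks = list(c(1L, 3L), c(2L, 4L))) {
  stopifnot(inherits(s, "hj_structure"))
  if (is.list(strands) && !is.data.frame(strands))
    strands <- do.call(rbind, lapply(strands, as.data.frame))
  need <- c("chain", "first", "last", "branch")
  if (!all(need %in% names(strands)))
    stop("strand declaration needs columns: ", paste(need, collapse = ", "))
  if (nrow(strands) != 4)
    stop("a Holliday junction has exactly 4 strands (got ", nrow(strands), ")")
  strands <- data.frame(chain = as.character(strands$chain),
                        first = as.integer(strands$first),
                        last = as.integer(strands$last),
                        branch = as.integer(strands$branch),
                        stringsAsFactors = FALSE)
  for (i in 1:4) {
    st <- strands[i, ]
    if (!(st$first <= st$branch && st$branch < st$last))
      stop("strand ", i, ": branch residue must lie inside the strand run")
    have <- unique(s$atoms$resno[s$atoms$chain == st$chain])
    want <- st$first:st$last
    if (!all(want %in% have))
      stop("strand ", i, " (chain ", st$chain, "): residues ",
           paste(setdiff(want, have), collapse = ","), " absent from structure")
  }
  # arm i: strand i (first..branch) paired with strand i-1 (branch+1..last)
  arm_len <- integer(4)
  for (i in 1:4) {
    p <- ((i - 2) %% 4) + 1
    len_ref <- strands$branch[i] - strands$first[i] + 1L
    len_par <- strands$last[p] - strands$branch[p]
    if (len_ref != len_par)
      stop("arm ", i, ": reference strand contributes ", len_ref,
           " residues but partner strand contributes ", len_par,
           " - unequal pairing lengths")
    arm_len[i] <- len_ref
  }
  if (!is.list(stacks) || length(stacks) != 2 ||
      !setequal(unlist(stacks), 1:4) || length(unlist(stacks)) != 4)
    stop("stacks must be two pairs of arm indices covering all four arms")
  stacks <- lapply(stacks, as.integer)
  opp <- function(p) abs(diff(p)) == 2
  if (!(opp(stacks[[1]]) && opp(stacks[[2]])))
    warning("declared stacks are not opposite-arm pairs; a stacked-X ",
            "junction coaxially stacks opposing arms")
  s$strands <- strands
  s$stacks <- stacks
  s$arm_length <- arm_len
  s
}

# Base-pair atom lookup: pair j of arm i (j = 1 at the branch point,
# increasing toward the distal end) pairs strand i residue branch_i - j + 1
# with strand i-1 residue branch_{i-1} + j.
arm_pair_residues <- function(s, arm, j) {
  st <- s$strands
  p <- ((arm - 2) %% 4) + 1
  list(ref = list(chain = st$chain[arm], resno = st$branch[arm] - j + 1),
       partner = list(chain = st$chain[p], resno = st$branch[p] + j))
}

atom_xyz <- function(s, chain, resno, elety, xyz = NULL) {
  sel <- which(s$atoms$chain == chain & s$atoms$resno == resno &
                 s$atoms$elety == elety)
  if (!length(sel)) return(NULL)
  if (is.null(xyz)) as.numeric(s$atoms[sel[1], c("x", "y", "z")])
  else as.numeric(xyz[sel[1], ])
}

residue_base <- function(s, chain, resno) {
  r <- s$atoms$resid[s$atoms$chain == chain & s$atoms$resno == resno][1]
  sub("^D", "", toupper(r))
}

#' Strand sequences of an annotated structure
#'
#' @param s Annotated `hj_structure`.
#' @return Named character vector of the four strand sequences, 5'->3'.
#' @export
strand_sequences <- function(s) {
  stopifnot(inherits(s, "hj_structure"), !is.null(s$strands))
  out <- vapply(1:4, function(i) {
    st <- s$strands[i, ]
    paste0(vapply(st$first:st$last, function(r)
      residue_base(s, st$chain, r), character(1)), collapse = "")
  }, character(1))
  names(out) <- paste0("strand", 1:4)
  out
}

#' Read and write junction topology specs as JSON
#'
#' The junction spec records the strand declaration and stack pairing used by
#' [annotate_junction()], so an annotation can travel alongside coordinate
#' files.
#'
#' @param spec List with elements `strands` (data frame) and `stacks`.
#' @param path JSON file path.
#' @return `read_junction_spec` returns the spec list; `write_junction_spec`
#'   invisibly returns the path.
#' @export
write_junction_spec <- function(spec, path) {
  jsonlite::write_json(list(strands = spec$strands,
                            stacks = lapply(spec$stacks, as.integer)),
                       path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_junction_spec
#' @export
read_junction_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  stacks <- x$stacks
  if (is.matrix(stacks)) {
    stacks <- lapply(seq_len(nrow(stacks)), function(i) as.integer(stacks[i, ]))
  } else {
    stacks <- lapply(stacks, as.integer)
  }
  list(strands = as.data.frame(x$strands), stacks = stacks)
}

#' Read a trajectory
#'
#' Frames are stored as a multi-model PDB (the `MODEL`/`ENDMDL` dialect, the
#' lowest-common-denominator trajectory format used throughout this package).
#' Every model must contain exactly the topology's atoms in the same order.
#'
#' @param topology An `hj_structure` or the path of a single-model PDB file.
#' @param frames_path Path of the multi-model PDB holding the coordinates; a
#'   single-model file yields a one-frame trajectory.
#' @param spec Optional junction spec (list or JSON path) applied to the
#'   topology with [annotate_junction()].
#' @return An object of class `hj_trajectory`: list with `topology` and
#'   `frames` (list of n_atoms x 3 matrices).
#' @export
read_hj_trajectory <- function(topology, frames_path, spec = NULL) {
  if (is.character(topology)) topology <- read_hj_structure(topology)
  stopifnot(inherits(topology, "hj_structure"))
  if (is.character(spec)) spec <- read_junction_spec(spec)
  if (!is.null(spec))
    topology <- annotate_junction(topology, spec$strands, spec$stacks)
  n_top <- nrow(topology$atoms)
  lines <- readLines(frames_path, warn = FALSE)
  is_atom <- grepl("^(ATOM|HETATM)", lines)
  model_starts <- grep("^MODEL", lines)
  if (length(model_starts)) {
    model_ends <- grep("^ENDMDL", lines)
    if (length(model_ends) != length(model_starts))
      stop("unbalanced MODEL/ENDMDL records in ", frames_path)
    counts <- mapply(function(a, b) sum(is_atom[a:b]), model_starts, model_ends)
    bad <- which(counts != n_top)
    if (length(bad))
      stop("frame ", bad[1], " of ", frames_path, " has ", counts[bad[1]],
           " atoms but the topology has ", n_top)
  } else if (sum(is_atom) != n_top) {
    stop("frame 1 of ", frames_path, " has ", sum(is_atom),
         " atoms but the topology has ", n_top)
  }
  multi <- bio3d::read.pdb(frames_path, multi = TRUE, verbose = FALSE)
  xyz <- multi$xyz
  if (ncol(xyz) != 3 * n_top)
    stop("frames are not congruent with the topology atom list")
  frames <- lapply(seq_len(nrow(xyz)), function(i)
    matrix(xyz[i, ], ncol = 3, byrow = TRUE))
  hj_trajectory(topology, frames)
}

#' Assemble a trajectory object
#'
#' @param topology Annotated or unannotated `hj_structure`.
#' @param frames List of n_atoms x 3 coordinate matrices.
#' @return An `hj_trajectory`.
#' @export
hj_trajectory <- function(topology, frames) {
  stopifnot(inherits(topology, "hj_structure"))
  n <- nrow(topology$atoms)
  for (i in seq_along(frames)) {
    f <- frames[[i]]
    if (!is.matrix(f) || nrow(f) != n || ncol(f) != 3)
      stop("frame ", i, " is not an ", n, " x 3 coordinate matrix")
  }
  structure(list(topology = topology, frames = frames),
            class = "hj_trajectory")
}

#' @export
print.hj_trajectory <- function(x, ...) {
  cat("<hj_trajectory> ", length(x$frames), " frame(s), ",
      nrow(x$topology$atoms), " atoms\n", sep = "")
  invisible(x)
}

#' Write trajectory frames as a multi-model PDB
#'
#' @param traj An `hj_trajectory`.
#' @param path Output path.
#' @return Invisibly, the path written.
#' @export
write_hj_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "hj_trajectory"))
  write_hj_structure(traj$topology, path, frames = traj$frames)
  invisible(path)
}

#' Rigid-body and mirror transformations
#'
#' `transform_structure` applies `x -> R x + t` to all atom coordinates;
#' `mirror_structure` reflects through a coordinate plane (an improper
#' operation, used to flip junction handedness exactly).
#'
#' @param s An `hj_structure` or `hj_trajectory`.
#' @param R 3 x 3 rotation (or general linear) matrix.
#' @param t Length-3 translation vector.
#' @param axis For `mirror_structure`: which coordinate is negated.
#' @return The transformed object.
#' @export
transform_structure <- function(s, R = diag(3), t = c(0, 0, 0)) {
  tf <- function(m) sweep(as.matrix(m) %*% t(R), 2, -t)
  if (inherits(s, "hj_trajectory")) {
    s$topology <- transform_structure(s$topology, R, t)
    s$frames <- lapply(s$frames, tf)
    return(s)
  }
  stopifnot(inherits(s, "hj_structure"))
  xyz <- tf(s$atoms[, c("x", "y", "z")])
  s$atoms$x <- xyz[, 1]; s$atoms$y <- xyz[, 2]; s$atoms$z <- xyz[, 3]
  s
}

#' @rdname transform_structure
#' @export
mirror_structure <- function(s, axis = c("z", "x", "y")) {
  axis <- match.arg(axis)
  R <- diag(3)
  i <- match(axis, c("x", "y", "z"))
  R[i, i] <- -1
  transform_structure(s, R)
}
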