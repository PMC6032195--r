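#' @importFrom stats rnorm runif sd lm coef pnorm dnorm pt qt integrate
#'   uniroot rchisq setNames aggregate cov var
#' @importFrom utils write.csv head
NULL

.atom_cols <- c("type", "name", "resname", "chain", "resid",
                "x", "y", "z", "element", "b")

#' Construct a structure object
#'
#' A `groove_structure` holds one conformation as an ordered atom table:
#' record type (ATOM/HETATM), atom name, residue name, chain ID, author
#' residue number, Cartesian coordinates in Angstrom, element symbol and a
#' B-factor channel. The `(chain, resid, name)` triple must be unique and
#' iteration order is the row order of `atom`.
#'
#' @param atom data.frame with columns `type`, `name`, `resname`, `chain`,
#'   `resid`, `x`, `y`, `z`, `element`, `b`.
#' @param label free-text label.
#' @return An object of class `groove_structure`.
#' @export
groove_structure <- function(atom, label = "") {
  stopifnot(is.data.frame(atom))
  missing_cols <- setdiff(.atom_cols, names(atom))
  if (length(missing_cols))
    stop("atom table lacks columns: ", paste(missing_cols, collapse = ", "))
  atom <- atom[, .atom_cols]
  atom$resid <- as.integer(atom$resid)
  if (!all(is.finite(c(atom$x, atom$y, atom$z))))
    stop("non-finite atom coordinates")
  if (any(!nzchar(atom$name)))
    stop("empty atom names are not allowed")
  key <- paste(atom$chain, atom$resid, atom$name)
  if (anyDuplicated(key))
    stop("duplicated (chain, resid, name): ", key[duplicated(key)][1])
  rownames(atom) <- NULL
  structure(list(atom = atom, label = as.character(label)[1]),
            class = "groove_structure")
}

#' @export
print.groove_structure <- function(x, ...) {
  a <- x$atom
  cat(sprintf("groove_structure '%s': %d atoms, chains: %s\n",
              x$label, nrow(a),
              paste(unique(a$chain), collapse = " ")))
  invisible(x)
}

#' Number of atoms in a structure or trajectory topology
#' @param x a `groove_structure` or `groove_trajectory`.
#' @return integer atom count.
#' @export
n_atoms <- function(x) {
  if (inherits(x, "groove_trajectory")) x <- x$topology
  nrow(x$atom)
}

#' Atom coordinates as an N x 3 matrix
#' @param x a `groove_structure`.
#' @return numeric matrix with one row per atom (Angstrom).
#' @export
atom_xyz <- function(x) {
  cbind(x = x$atom$x, y = x$atom$y, z = x$atom$z)
}

## Replace coordinates of a structure from an N x 3 matrix (internal).
set_xyz <- function(s, xyz) {
  stopifnot(nrow(xyz) == nrow(s$atom))
  s$atom$x <- xyz[, 1]; s$atom$y <- xyz[, 2]; s$atom$z <- xyz[, 3]
  s
}

#' Construct a trajectory object
#'
#' A `groove_trajectory` is an ordered set of frames sharing one topology.
#' Coordinates are stored as a frames x (3 * n_atoms) matrix in
#' (x1, y1, z1, x2, ...) order, the layout used throughout bio3d.
#'
#' @param topology a `groove_structure` defining atom identity and order.
#' @param xyz numeric matrix, one row per frame, `3 * n_atoms` columns.
#' @param dt time between frames in ns (must be > 0).
#' @return An object of class `groove_trajectory`.
#' @export
groove_trajectory <- function(topology, xyz, dt = 0.004) {
  stopifnot(inherits(topology, "groove_structure"))
  xyz <- unclass(as.matrix(xyz))
  if (ncol(xyz) != 3L * nrow(topology$atom))
    stop("frame width (", ncol(xyz), ") does not match topology (",
         3L * nrow(topology$atom), " coordinates)")
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("dt must be a single positive number (ns)")
  structure(list(topology = topology, xyz = xyz, dt = dt),
            class = "groove_trajectory")
}

#' @export
print.groove_trajectory <- function(x, ...) {
  cat(sprintf("groove_trajectory: %d frames x %d atoms, dt = %g ns (%.3g ns total)\n",
              nrow(x$xyz), n_atoms(x), x$dt, (nrow(x$xyz) - 1) * x$dt))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param t a `groove_trajectory`.
#' @return integer frame count.
#' @export
n_frames <- function(t) nrow(t$xyz)

#' Frame times in ns
#' @param t a `groove_trajectory`.
#' @return numeric vector `(0:(n-1)) * dt`.
#' @export
frame_times <- function(t) (seq_len(n_frames(t)) - 1) * t$dt

#' Extract one frame of a trajectory as a structure
#' @param t a `groove_trajectory`.
#' @param i frame index (1-based).
#' @return a `groove_structure` with that frame's coordinates.
#' @export
frame_structure <- function(t, i) {
  if (i < 1L || i > n_frames(t)) stop("frame index out of range")
  set_xyz(t$topology, matrix(t$xyz[i, ], ncol = 3, byrow = TRUE))
}

## --- PDB reading -----------------------------------------------------------

## Pre-validation: the spec'd error behaviours (line-level coordinate check,
## insertion-code rejection) that bio3d handles silently or with warnings.
.validate_pdb_lines <- function(lines, path) {
  rec <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(rec))
    stop("no ATOM/HETATM records in '", path, "'")
  idx <- which(rec)
  fld <- function(a, b) suppressWarnings(as.numeric(substr(lines[idx], a, b)))
  bad <- is.na(fld(31, 38)) | is.na(fld(39, 46)) | is.na(fld(47, 54))
  if (any(bad))
    stop("malformed coordinate field at line ", idx[which(bad)[1]],
         " of '", path, "'")
  ins <- substr(lines[idx], 27, 27)
  if (any(ins != " " & ins != ""))
    stop("insertion codes are not supported (line ",
         idx[which(ins != " " & ins != "")[1]], " of '", path, "')")
  invisible(idx)
}

## bio3d atom table -> groove_structure atom table, resolving altlocs:
## keep the highest-occupancy conformer, ties broken toward altloc 'A'.
.bio3d_atoms <- function(atom) {
  alt <- ifelse(is.na(atom$alt), "", atom$alt)
  occ <- ifelse(is.na(atom$o), 1, atom$o)
  key <- paste(atom$chain, atom$resno, atom$elety)
  if (anyDuplicated(key)) {
    ord <- order(match(key, unique(key)), -occ, alt)
    keep <- ord[!duplicated(key[ord])]
    atom <- atom[sort(keep), ]
  }
  ele <- if ("elesy" %in% names(atom)) trimws(atom$elesy) else ""
  ele[is.na(ele) | !nzchar(ele)] <-
    substr(trimws(atom$elety[is.na(ele) | !nzchar(ele)]), 1, 1)
  data.frame(type = atom$type, name = atom$elety, resname = atom$resid,
             chain = ifelse(is.na(atom$chain), " ", atom$chain),
             resid = atom$resno,
             x = atom$x, y = atom$y, z = atom$z,
             element = ele,
             b = ifelse(is.na(atom$b), 0, atom$b),
             stringsAsFactors = FALSE)
}

#' Read a single-conformation PDB file
#'
#' Parses ATOM and HETATM records (via bio3d) into a [groove_structure].
#' Alternate locations are resolved to the highest-occupancy conformer
#' (ties toward altloc A); insertion codes are rejected with an error.
#'
#' @param path path to a PDB file.
#' @return a `groove_structure`.
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  .validate_pdb_lines(lines, path)
  pdb <- bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE)
  groove_structure(.bio3d_atoms(pdb$atom), label = basename(path))
}

#' Read a multi-model PDB file as a trajectory
#'
#' MODEL/ENDMDL blocks become ordered frames on the topology of the first
#' model. Every model must contain the same number of atoms; a mismatch is
#' reported with the offending model number. `dt` is not stored in PDB and
#' must be supplied by the caller (default 0.004 ns/frame, i.e. 1250 frames
#' for a 5-ns run).
#'
#' @param path path to a (multi-model) PDB file.
#' @param dt time between frames, ns.
#' @return a `groove_trajectory`.
#' @export
read_trajectory <- function(path, dt = 0.004) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  .validate_pdb_lines(lines, path)
  model_at <- grepl("^MODEL ", lines)
  if (any(model_at)) {
    model_id <- cumsum(model_at)
    rec <- grepl("^(ATOM  |HETATM)", lines)
    counts <- tabulate(model_id[rec], nbins = sum(model_at))
    if (length(unique(counts)) > 1L) {
      k <- which(counts != counts[1])[1]
      stop("model ", k, " has ", counts[k], " atoms; expected ", counts[1])
    }
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE)
  if (any(!is.na(pdb$atom$alt) & nzchar(pdb$atom$alt)))
    stop("alternate locations are not supported in multi-model trajectories")
  topo <- groove_structure(.bio3d_atoms(pdb$atom), label = basename(path))
  groove_trajectory(topo, unclass(pdb$xyz), dt = dt)
}

## --- PDB writing -----------------------------------------------------------

.write_models <- function(atom, xyz, path) {
  bio3d::write.pdb(file = path, xyz = xyz,
                   type = atom$type, resno = atom$resid, resid = atom$resname,
                   chain = atom$chain, elety = atom$name, elesy = atom$element,
                   b = atom$b, o = rep(1, nrow(atom)))
}

#' Write a structure to a PDB file
#'
#' Emits fixed-column ATOM/HETATM records (via bio3d), including the
#' B-factor channel used by [encode_bfactor()]. Coordinates are written to
#' 3 decimals, the PDB precision.
#'
#' @param s a `groove_structure`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(s, path) {
  stopifnot(inherits(s, "groove_structure"))
  .write_models(s$atom, as.vector(t(atom_xyz(s))), path)
  invisible(path)
}

#' Write a trajectory as a multi-model PDB file
#' @param t a `groove_trajectory`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(t, path) {
  stopifnot(inherits(t, "groove_trajectory"))
  .write_models(t$topology$atom, t$xyz, path)
  invisible(path)
}

## --- Selections ------------------------------------------------------------

#' General atom selection
#'
#' Returns the (ordered, stable) indices of atoms matching all the given
#' filters. `heavy = TRUE` drops hydrogens.
#'
#' @param s a `groove_structure` (or the topology of a `groove_trajectory`).
#' @param chain,resname,name,element optional vectors of allowed values.
#' @param resid optional inclusive `c(lo, hi)` residue-number range.
#' @param heavy drop hydrogen atoms.
#' @return integer vector of atom indices (rows of `s$atom`).
#' @export
atom_select <- function(s, chain = NULL, resname = NULL, name = NULL,
                        element = NULL, resid = NULL, heavy = FALSE) {
  if (inherits(s, "groove_trajectory")) s <- s$topology
  a <- s$atom
  keep <- rep(TRUE, nrow(a))
  if (!is.null(chain))   keep <- keep & a$chain %in% chain
  if (!is.null(resname)) keep <- keep & a$resname %in% resname
  if (!is.null(name))    keep <- keep & a$name %in% name
  if (!is.null(element)) keep <- keep & a$element %in% element
  if (!is.null(resid))   keep <- keep & a$resid >= resid[1] & a$resid <= resid[2]
  if (heavy)             keep <- keep & toupper(a$element) != "H"
  which(keep)
}

#' Select C-alpha atoms of a chain and residue range
#'
#' The workhorse selection for every groove metric: `CA` atoms of one chain
#' inside an inclusive author-numbered residue range, ordered by residue
#' number. An empty result triggers an explicit warning rather than failing
#' silently.
#'
#' @param s a `groove_structure`.
#' @param chain chain ID.
#' @param resid_range inclusive `c(lo, hi)` residue-number range.
#' @return data.frame of the selected atoms (ordered by `resid`) with the
#'   original atom indices in attribute `"indices"`.
#' @export
select_calpha <- function(s, chain, resid_range) {
  if (inherits(s, "groove_trajectory")) s <- s$topology
  idx <- atom_select(s, chain = chain, name = "CA", resid = resid_range)
  idx <- idx[order(s$atom$resid[idx])]
  if (!length(idx))
    warning("empty C-alpha selection: chain '", chain, "', residues ",
            resid_range[1], "-", resid_range[2])
  out <- s$atom[idx, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "indices") <- idx
  out
}

## Coerce a selection (index vector or select_calpha() result) to indices.
sel_indices <- function(selection) {
  idx <- attr(selection, "indices")
  if (!is.null(idx)) return(idx)
  if (is.numeric(selection)) return(as.integer(selection))
  stop("selection must be an index vector or a selection data.frame")
}

## Extract an n_frames x (3*k) coordinate block for selected atoms.
traj_sel_xyz <- function(t, selection) {
  idx <- sel_indices(selection)
  cols <- as.vector(rbind(3 * idx - 2, 3 * idx - 1, 3 * idx))
  t$xyz[, cols, drop = FALSE]
}
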