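## Voxel occupancy maps of ligand/peptide positions over a trajectory and
## extraction of threshold occupancy volumes (e.g. the 50% envelope).

#' Voxel occupancy grid over a trajectory
#'
#' Bins the centers of the selected atoms into a regular voxel lattice.
#' Each voxel's value is the fraction of frames in which at least one
#' selected atom center falls inside it. The grid spans the selection's
#' bounding box over all frames plus `padding` (or an explicit
#' `origin`/`dims` pair). When `align_on` is given, every frame is first
#' superposed onto the first frame using that (receptor-framework)
#' selection, so occupancy is measured in the receptor frame.
#'
#' Occupancy counts atom centers, not van-der-Waals spheres.
#'
#' @param t a `groove_trajectory` with >= 1 frame.
#' @param selection atom indices or a [select_calpha()] result; non-empty.
#' @param spacing voxel edge length, Angstrom (default 1.0).
#' @param padding margin added around the bounding box, Angstrom.
#' @param align_on optional framework selection for per-frame superposition
#'   onto frame 1.
#' @param origin,dims optional explicit grid origin (3-vector, Angstrom) and
#'   voxel counts (3 integers); both must be given together. Atoms outside
#'   an explicit grid are ignored.
#' @return list with `origin`, `spacing`, `dims`, `values` (3-d array of
#'   occupied-frame fractions in [0, 1]) and `n_frames`, class
#'   `occupancy_grid`.
#' @export
occupancy_grid <- function(t, selection, spacing = 1.0, padding = 2.0,
                           align_on = NULL, origin = NULL, dims = NULL) {
  stopifnot(inherits(t, "groove_trajectory"))
  if (spacing <= 0) stop("spacing must be > 0")
  idx <- sel_indices(selection)
  if (!length(idx)) stop("empty selection")
  nf <- n_frames(t)
  if (nf < 1L) stop("trajectory has no frames")

  block <- traj_sel_xyz(t, idx)
  coords <- lapply(seq_len(nf), function(i) .row_xyz(block[i, ]))
  if (!is.null(align_on)) {
    fw <- traj_sel_xyz(t, align_on)
    ref <- .row_xyz(fw[1L, ])
    for (i in seq_len(nf)) {
      sp <- superpose(.row_xyz(fw[i, ]), ref)
      coords[[i]] <- apply_transform(coords[[i]], sp)
    }
  }
  all_xyz <- do.call(rbind, coords)
  if (is.null(origin) != is.null(dims))
    stop("origin and dims must be supplied together")
  clip <- !is.null(origin)
  if (is.null(origin)) {
    origin <- apply(all_xyz, 2, min) - padding
    dims <- pmax(1L, ceiling((apply(all_xyz, 2, max) + padding - origin) /
                             spacing))
  }
  dims <- as.integer(dims)
  if (any(dims < 1L)) stop("grid dims must be positive")

  counts <- array(0L, dim = dims)
  for (i in seq_len(nf)) {
    v <- floor(sweep(coords[[i]], 2, origin) / spacing) + 1L
    if (clip) {
      ok <- v[, 1] >= 1L & v[, 1] <= dims[1] &
            v[, 2] >= 1L & v[, 2] <= dims[2] &
            v[, 3] >= 1L & v[, 3] <= dims[3]
      v <- v[ok, , drop = FALSE]
    }
    if (!nrow(v)) next
    lin <- unique((v[, 3] - 1L) * dims[1] * dims[2] +
                  (v[, 2] - 1L) * dims[1] + v[, 1])
    counts[lin] <- counts[lin] + 1L
  }
  structure(list(origin = as.numeric(origin), spacing = spacing,
                 dims = dims, values = counts / nf, n_frames = nf),
            class = "occupancy_grid")
}

#' @export
print.occupancy_grid <- function(x, ...) {
  cat(sprintf("occupancy_grid: %d x %d x %d voxels @ %.2f A (%d frames, max %.2f)\n",
              x$dims[1], x$dims[2], x$dims[3], x$spacing, x$n_frames,
              max(x$values)))
  invisible(x)
}

#' Threshold occupancy volume of a grid
#'
#' Voxels whose occupied-frame fraction is greater than or equal to
#' `threshold` (inclusive boundary), plus the enclosed volume
#' `count * spacing^3`. `threshold = 0.5` gives the 50% occupancy volume.
#'
#' @param g an [occupancy_grid()].
#' @param threshold occupancy fraction in (0, 1].
#' @return list with `voxels` (k x 3 integer voxel indices), `n_voxels`,
#'   `volume` (Angstrom^3) and `threshold`, class `occupancy_isovolume`.
#' @export
occupancy_isovolume <- function(g, threshold = 0.5) {
  stopifnot(inherits(g, "occupancy_grid"))
  if (threshold <= 0 || threshold > 1)
    stop("threshold must be in (0, 1]")
  vox <- which(g$values >= threshold, arr.ind = TRUE)
  colnames(vox) <- c("i", "j", "k")
  structure(list(voxels = vox, n_voxels = nrow(vox),
                 volume = nrow(vox) * g$spacing^3, threshold = threshold),
            class = "occupancy_isovolume")
}

#' @export
print.occupancy_isovolume <- function(x, ...) {
  cat(sprintf("occupancy_isovolume: %d voxels >= %.2f, volume %.1f A^3\n",
              x$n_voxels, x$threshold, x$volume))
  invisible(x)
}

#' Write an occupancy grid in OpenDX scalar-field format
#'
#' Emits the plain-text DX format readable by common molecular viewers
#' (PyMOL, VMD, Chimera). Data follow the DX convention with the z index
#' varying fastest.
#'
#' @param g an [occupancy_grid()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_opendx <- function(g, path) {
  stopifnot(inherits(g, "occupancy_grid"))
  n <- prod(g$dims)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(
    sprintf("object 1 class gridpositions counts %d %d %d",
            g$dims[1], g$dims[2], g$dims[3]),
    sprintf("origin %.6f %.6f %.6f", g$origin[1], g$origin[2], g$origin[3]),
    sprintf("delta %.6f 0.000000 0.000000", g$spacing),
    sprintf("delta 0.000000 %.6f 0.000000", g$spacing),
    sprintf("delta 0.000000 0.000000 %.6f", g$spacing),
    sprintf("object 2 class gridconnections counts %d %d %d",
            g$dims[1], g$dims[2], g$dims[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows", n)
  ), con)
  vals <- as.vector(aperm(g$values, c(3, 2, 1)))  # z fastest
  pad <- (-n) %% 3
  if (pad) vals <- c(vals, rep(NA_real_, pad))
  m <- matrix(vals, ncol = 3, byrow = TRUE)
  lines <- apply(m, 1, function(r)
    paste(sprintf("%.6e", r[!is.na(r)]), collapse = " "))
  writeLines(lines, con)
  writeLines(c("attribute \"dep\" string \"positions\"",
               "object \"occupancy\" class field",
               "component \"positions\" value 1",
               "component \"connections\" value 2",
               "component \"data\" value 3"), con)
  invisible(path)
}

#' Read an OpenDX scalar field back into an occupancy grid
#'
#' Counterpart of [write_opendx()] for round-trip checks and for consuming
#' grids produced elsewhere. Only regular axis-aligned grids are supported.
#'
#' @param path a DX file written by [write_opendx()] or compatible.
#' @return an `occupancy_grid` (with `n_frames = NA`).
#' @export
read_opendx <- function(path) {
  lines <- readLines(path, warn = FALSE)
  cnt <- regmatches(lines[1], gregexpr("[0-9]+", lines[1]))[[1]]
  dims <- as.integer(cnt[(length(cnt) - 2):length(cnt)])
  origin <- as.numeric(strsplit(trimws(sub("origin", "", lines[2])),
                                "\\s+")[[1]])
  spacing <- as.numeric(strsplit(trimws(sub("delta", "", lines[3])),
                                 "\\s+")[[1]])[1]
  start <- grep("data follows", lines)[1] + 1L
  end <- grep("^attribute", lines)[1] - 1L
  vals <- as.numeric(unlist(strsplit(trimws(lines[start:end]), "\\s+")))
  arr <- aperm(array(vals, dim = rev(dims)), c(3, 2, 1))
  structure(list(origin = origin, spacing = spacing, dims = dims,
                 values = arr, n_frames = NA_integer_),
            class = "occupancy_grid")
}
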