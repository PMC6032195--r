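## Synthetic groove structures and trajectories with known ground truth:
## two ideal antiparallel helices at a controlled inter-helical separation,
## an extended peptide strand along the groove axis, and an optional
## three-center ligand pseudo-molecule near the mid-groove (a P4-pocket
## analog). Every downstream metric in the package can be validated
## against these generators without any external data.

#' Specification for a synthetic groove simulation
#'
#' Collects the generator's ground-truth parameters. The per-frame
#' inter-helical separation follows `d(t) = d0 + slope * t + eps_t` with
#' `eps_t ~ N(0, sigma_d)` (independent across frames), realized by rigid
#' displacement of the beta helix along the separation axis.
#' `residue_jitter` adds independent isotropic Gaussian noise per protein
#' atom (scalar, or one value per residue over chains A, B, C in order);
#' the ligand has its own `ligand_jitter`. The ligand is present in each
#' frame with probability `ligand_presence` (absent frames park it far
#' outside the groove).
#'
#' @param n_res_alpha,n_res_beta residues per helix (defaults 33 and 38,
#'   the spans of the HLA-DR preset ranges 46-78 and 54-91).
#' @param d0 baseline inter-helical separation, Angstrom.
#' @param slope linear drift of the separation, Angstrom/ns.
#' @param sigma_d per-frame separation noise SD, Angstrom.
#' @param residue_jitter per-residue isotropic positional SD, Angstrom
#'   (scalar or vector over all protein residues).
#' @param n_frames number of frames (>= 1).
#' @param dt time step between frames, ns.
#' @param peptide_len peptide residues (chain C); 13 gives the HA 306-318
#'   sequence PRYVKQNTLKLAT.
#' @param ligand include the ligand pseudo-molecule (resname `"NVP"`).
#' @param ligand_presence per-frame presence probability in `[0, 1]`.
#' @param ligand_jitter isotropic positional SD of the ligand atoms,
#'   Angstrom.
#' @param seed RNG seed driving all randomness of the generator.
#' @return an object of class `groove_sim_spec`.
#' @export
groove_sim_spec <- function(n_res_alpha = 33L, n_res_beta = 38L,
                            d0 = 13.0, slope = 0, sigma_d = 0,
                            residue_jitter = 0, n_frames = 1250L,
                            dt = 0.004, peptide_len = 13L,
                            ligand = FALSE, ligand_presence = 1,
                            ligand_jitter = 0, seed = 1L) {
  spec <- list(n_res_alpha = as.integer(n_res_alpha),
               n_res_beta = as.integer(n_res_beta),
               d0 = d0, slope = slope, sigma_d = sigma_d,
               residue_jitter = residue_jitter,
               n_frames = as.integer(n_frames), dt = dt,
               peptide_len = as.integer(peptide_len),
               ligand = isTRUE(ligand),
               ligand_presence = ligand_presence,
               ligand_jitter = ligand_jitter,
               seed = as.integer(seed))
  stopifnot(spec$n_res_alpha >= 2L, spec$n_res_beta >= 2L,
            spec$n_frames >= 1L, spec$dt > 0, spec$sigma_d >= 0,
            all(spec$residue_jitter >= 0), spec$ligand_jitter >= 0,
            spec$ligand_presence >= 0, spec$ligand_presence <= 1,
            spec$peptide_len >= 0, spec$d0 > 0)
  n_prot <- spec$n_res_alpha + spec$n_res_beta + spec$peptide_len
  if (!length(spec$residue_jitter) %in% c(1L, n_prot))
    stop("residue_jitter must be scalar or one value per protein residue (",
         n_prot, ")")
  class(spec) <- "groove_sim_spec"
  spec
}

## Ideal C-alpha helix trace: rise 1.5 A/residue, radius 2.3 A,
## 100 degrees/residue, axis along +x starting at the origin.
.helix_trace <- function(n, rise = 1.5, radius = 2.3, turn = 100 * pi / 180) {
  i <- seq_len(n) - 1
  cbind(rise * i, radius * cos(turn * i), radius * sin(turn * i))
}

.ha_seq <- c("PRO", "ARG", "TYR", "VAL", "LYS", "GLN", "ASN",
             "THR", "LEU", "LYS", "LEU", "ALA", "THR")

## Assemble coordinates for a given beta-helix offset D (separation axis -y).
.groove_coords <- function(spec, D) {
  na <- spec$n_res_alpha; nb <- spec$n_res_beta
  A <- .helix_trace(na)
  A[, 1] <- A[, 1] - mean(A[, 1])
  B <- .helix_trace(nb)
  B[, 1] <- -(B[, 1] - mean(B[, 1]))   # antiparallel
  B[, 2] <- B[, 2] - D
  out <- list(A = A, B = B)
  if (spec$peptide_len > 0L) {
    i <- seq_len(spec$peptide_len) - 1
    P <- cbind(3.4 * i, 0, 0)
    P[, 1] <- P[, 1] - mean(P[, 1])
    P[, 2] <- -D / 2
    out$P <- P
  }
  if (spec$ligand)
    out$L <- cbind(c(-3, 0, 3), -D / 2, -2.5)
  out
}

#' Build a synthetic groove structure
#'
#' Two ideal antiparallel C-alpha helices (chain A numbered 46 upward,
#' chain B numbered 54 upward so the HLA-DR preset ranges apply), an
#' extended peptide strand (chain C, HA numbering 306 upward, rise 3.4
#' Angstrom/residue) along the groove axis between them, and an optional
#' three-atom ligand pseudo-molecule (chain L, resname `"NVP"`) near the
#' mid-groove. The beta-helix offset is calibrated so that
#' [inter_helical_distance()] of the built structure equals `d0` (the
#' helical wobble of the traces would otherwise bias the metric).
#'
#' @param spec a [groove_sim_spec()].
#' @return a `groove_structure` with the matching [groove_definition()] in
#'   attribute `"groove"` and the calibrated beta offset in attribute
#'   `"beta_offset"`.
#' @export
build_groove <- function(spec) {
  stopifnot(inherits(spec, "groove_sim_spec"))
  ## calibrate the offset so the directional metric hits d0 exactly
  D <- spec$d0
  for (it in 1:50) {
    co <- .groove_coords(spec, D)
    m <- .ihd_xyz(co$A, co$B)
    if (abs(spec$d0 - m) < 1e-9) break
    D <- D + (spec$d0 - m)
  }
  co <- .groove_coords(spec, D)

  mk <- function(xyz, chain, resid0, resname, name = "CA", type = "ATOM",
                 element = "C") {
    n <- nrow(xyz)
    data.frame(type = type,
               name = if (length(name) == 1L) rep(name, n) else name,
               resname = if (length(resname) == 1L) rep(resname, n) else resname,
               chain = chain,
               resid = if (length(resid0) == 1L) resid0 + seq_len(n) - 1L
                       else resid0,
               x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
               element = element, b = 0,
               stringsAsFactors = FALSE)
  }
  pep_names <- if (spec$peptide_len == 13L) .ha_seq
               else rep("ALA", spec$peptide_len)
  atom <- rbind(mk(co$A, "A", 46L, "ALA"),
                mk(co$B, "B", 54L, "ALA"))
  if (spec$peptide_len > 0L)
    atom <- rbind(atom, mk(co$P, "C", 306L, pep_names))
  if (spec$ligand)
    atom <- rbind(atom, mk(co$L, "L", rep(1L, 3), "NVP",
                           name = c("C1", "C2", "C3"), type = "HETATM"))
  s <- groove_structure(atom, label = "synthetic groove")
  g <- groove_definition(
    alpha_chain = "A", beta_chain = "B",
    alpha_helix = c(46L, 46L + spec$n_res_alpha - 1L),
    beta_helix = c(54L, 54L + spec$n_res_beta - 1L),
    peptide_chain = if (spec$peptide_len > 0L) "C" else NULL)
  attr(s, "groove") <- g
  attr(s, "beta_offset") <- D
  s
}

#' Groove definition attached to a synthetic structure
#' @param s a [build_groove()] result (or a trajectory built from one).
#' @return the attached [groove_definition()].
#' @export
groove_of <- function(s) {
  g <- attr(s, "groove")
  if (is.null(g) && inherits(s, "groove_trajectory"))
    g <- attr(s$topology, "groove")
  if (is.null(g)) stop("no groove definition attached")
  g
}

#' Simulate a synthetic groove trajectory
#'
#' Frame `t` realizes the separation `d0 + slope * t + eps_t`
#' (`eps_t ~ N(0, sigma_d)`) by rigidly displacing the beta helix along
#' the separation axis of the calibrated base structure, then adds
#' independent isotropic per-atom jitter (`residue_jitter` for protein,
#' `ligand_jitter` for the ligand). When the ligand is enabled it is
#' present in each frame with probability `ligand_presence`; absent frames
#' park it 40 Angstrom above the groove. All randomness derives from
#' `spec$seed` (draw order: separation noise, ligand presence, jitter), so
#' output is byte-identical across runs.
#'
#' @param spec a [groove_sim_spec()].
#' @return a `groove_trajectory` whose topology carries the groove
#'   definition attribute (see [groove_of()]).
#' @export
simulate_trajectory <- function(spec) {
  stopifnot(inherits(spec, "groove_sim_spec"))
  base <- build_groove(spec)
  a <- base$atom
  natoms <- nrow(a)
  nf <- spec$n_frames
  times <- (seq_len(nf) - 1) * spec$dt

  set.seed(spec$seed)
  sep <- spec$d0 + spec$slope * times + rnorm(nf, 0, spec$sigma_d)
  present <- if (spec$ligand) runif(nf) < spec$ligand_presence else logical(0)

  ## per-atom jitter SDs (protein residues in chain order A, B, C)
  n_prot <- spec$n_res_alpha + spec$n_res_beta + spec$peptide_len
  rj <- if (length(spec$residue_jitter) == 1L)
          rep(spec$residue_jitter, n_prot) else spec$residue_jitter
  sd_atom <- numeric(natoms)
  prot_rows <- which(a$chain %in% c("A", "B", "C"))
  sd_atom[prot_rows] <- rj   # one CA per residue, same order as built
  sd_atom[a$chain == "L"] <- spec$ligand_jitter
  sd_coord <- rep(sd_atom, each = 3L)

  xyz <- matrix(rep(as.vector(t(atom_xyz(base))), each = nf), nrow = nf)
  if (any(sd_coord > 0))
    xyz <- xyz + matrix(rnorm(nf * 3L * natoms), nrow = nf) *
      rep(sd_coord, each = nf)

  ## Realize each frame's separation by a rigid -y shift of the beta
  ## helix. The metric responds to the shift almost, but not exactly,
  ## linearly (nearest-neighbour pairings drift with the helical wobble),
  ## so the shift is obtained by inverting the metric/shift map with a
  ## monotone spline; the realized metric then equals the drawn separation
  ## to well below coordinate precision.
  ia <- which(a$chain == "A"); ib <- which(a$chain == "B")
  A_xyz <- atom_xyz(base)[ia, , drop = FALSE]
  B_xyz <- atom_xyz(base)[ib, , drop = FALSE]
  metric_at <- function(delta) {
    B2 <- B_xyz; B2[, 2] <- B2[, 2] - delta
    .ihd_xyz(A_xyz, B2)
  }
  target <- sep - spec$d0
  if (diff(range(target)) < 1e-9) {
    delta <- target   # constant separation: the calibrated base is exact
  } else {
    grid <- seq(min(target) - 0.1, max(target) + 0.1, length.out = 41)
    mg <- vapply(grid, metric_at, numeric(1))
    inv <- stats::splinefun(mg - spec$d0, grid, method = "hyman")
    delta <- inv(target)
  }
  ycols_b <- 3L * ib - 1L
  xyz[, ycols_b] <- xyz[, ycols_b] - delta

  if (spec$ligand && any(!present)) {
    zcols_l <- 3L * which(a$chain == "L")
    xyz[!present, zcols_l] <- xyz[!present, zcols_l] + 40
  }
  traj <- groove_trajectory(base, xyz, dt = spec$dt)
  attr(traj$topology, "groove") <- attr(base, "groove")
  attr(traj, "ligand_present") <- present
  traj
}

#' Baseline separation needed for a target trajectory mean
#'
#' With a linear drift, the analytic mean separation over a run is
#' `d0 + slope * mean(times)`; this inverts that relation so a generator
#' can be parameterized from a published trajectory mean and slope.
#'
#' @param target_mean desired trajectory-mean separation, Angstrom.
#' @param slope drift, Angstrom/ns.
#' @param n_frames,dt trajectory size and time step.
#' @return the `d0` to pass to [groove_sim_spec()].
#' @export
d0_for_mean <- function(target_mean, slope, n_frames = 1250L, dt = 0.004) {
  target_mean - slope * (n_frames - 1) * dt / 2
}

#' Closed-form expected ligand occupancy
#'
#' The oracle for [occupancy_grid()] on generator output: for each ligand
#' atom, the expected occupancy of its home voxel in a given grid equals
#' the presence probability times the probability that the jittered atom
#' center falls inside that voxel (a product of normal interval
#' probabilities per axis). Ligand atoms are built 3 Angstrom apart, so
#' with voxel edges of ~1 Angstrom and modest jitter the contribution of
#' neighboring atoms to a home voxel is negligible and the per-atom
#' expectation is the voxel expectation.
#'
#' @param spec a [groove_sim_spec()] with `ligand = TRUE`.
#' @param grid an [occupancy_grid()] computed over the ligand selection.
#' @return data.frame with one row per ligand atom: `name`, voxel indices
#'   `i`, `j`, `k`, and `expected` occupancy.
#' @export
ligand_occupancy_truth <- function(spec, grid) {
  stopifnot(inherits(spec, "groove_sim_spec"),
            inherits(grid, "occupancy_grid"))
  if (!spec$ligand) stop("ligand is not enabled in this spec")
  base <- build_groove(spec)
  il <- atom_select(base, chain = "L")
  pos <- atom_xyz(base)[il, , drop = FALSE]
  sdv <- spec$ligand_jitter
  rows <- lapply(seq_along(il), function(m) {
    p <- pos[m, ]
    v <- floor((p - grid$origin) / grid$spacing) + 1L
    lo <- grid$origin + (v - 1L) * grid$spacing
    hi <- lo + grid$spacing
    p_in <- if (sdv > 0)
      prod(pnorm((hi - p) / sdv) - pnorm((lo - p) / sdv))
    else prod(p >= lo & p < hi)
    data.frame(name = base$atom$name[il[m]], i = v[1], j = v[2], k = v[3],
               expected = spec$ligand_presence * p_in)
  })
  do.call(rbind, rows)
}
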