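## Peptide registration-frame enumeration: slide the peptide along the
## groove axis, score each pose by clashes and per-chain contacts, rank the
## poses, and map a chosen register onto the P1-P9 pocket positions.

#' Principal axis of the binding groove
#'
#' The largest-variance principal direction of the combined alpha+beta
#' helix C-alpha coordinates, with the sign chosen to point toward
#' increasing alpha-helix residue number.
#'
#' @param s a `groove_structure`.
#' @param g a [groove_definition()].
#' @return list with unit vector `axis` and `centroid` (Angstrom).
#' @export
groove_axis <- function(s, g) {
  stopifnot(inherits(s, "groove_structure"),
            inherits(g, "groove_definition"))
  sa <- select_calpha(s, g$alpha_chain, g$alpha_helix)
  sb <- select_calpha(s, g$beta_chain, g$beta_helix)
  ia <- sel_indices(sa); ib <- sel_indices(sb)
  if (!length(ia) || !length(ib)) stop("empty helix selection")
  xyz <- atom_xyz(s)[c(ia, ib), , drop = FALSE]
  ev <- eigen(cov(xyz), symmetric = TRUE)
  if (ev$values[1] < 1.05 * ev$values[2])
    stop("degenerate (near-isotropic) helix point cloud: no unique axis")
  axis <- ev$vectors[, 1]
  a_xyz <- atom_xyz(s)[ia, , drop = FALSE]
  direction <- a_xyz[which.max(sa$resid), ] - a_xyz[which.min(sa$resid), ]
  if (sum(axis * direction) < 0) axis <- -axis
  list(axis = axis / sqrt(sum(axis^2)), centroid = colMeans(xyz))
}

## Count pairs between two coordinate sets closer than cutoff (heavy-atom
## centers); plain all-pairs distance evaluation.
.pair_count <- function(A, B, cutoff) {
  d2 <- outer(rowSums(A^2), rep(1, nrow(B))) +
        outer(rep(1, nrow(A)), rowSums(B^2)) - 2 * tcrossprod(A, B)
  sum(d2 < cutoff^2)
}

#' Enumerate peptide registration frames along the groove axis
#'
#' Translates the peptide chain by `offset * step` along the groove axis
#' for every integer offset in `[-max_shift, max_shift]` and scores each
#' pose: `clash_count` is the number of peptide/HLA heavy-atom pairs closer
#' than `clash_cutoff`; `contacts_alpha`/`contacts_beta` count
#' peptide/chain heavy-atom pairs within `contact_cutoff`. With the default
#' step of 3.4 Angstrom (the extended-peptide rise per residue) one offset
#' corresponds to roughly one register shift.
#'
#' @param s a `groove_structure` containing the peptide chain.
#' @param g a [groove_definition()] with a `peptide_chain`.
#' @param max_shift maximum register shift in residues (default 3).
#' @param step translation per offset, Angstrom (default 3.4).
#' @param clash_cutoff,contact_cutoff heavy-atom distance cutoffs, Angstrom
#'   (defaults 2.5 and 4.5).
#' @return data.frame with one row per offset (`2 * max_shift + 1` rows):
#'   `offset`, `label`, translation components `dx`, `dy`, `dz`,
#'   `clash_count`, `contacts_alpha`, `contacts_beta`; class
#'   `register_frames`.
#' @export
enumerate_registers <- function(s, g, max_shift = 3L, step = 3.4,
                                clash_cutoff = 2.5, contact_cutoff = 4.5) {
  stopifnot(inherits(s, "groove_structure"),
            inherits(g, "groove_definition"))
  if (step <= 0) stop("step must be > 0")
  if (is.null(g$peptide_chain))
    stop("groove definition has no peptide_chain")
  ip <- atom_select(s, chain = g$peptide_chain, heavy = TRUE)
  if (!length(ip)) stop("peptide chain '", g$peptide_chain, "' not found")
  ia <- atom_select(s, chain = g$alpha_chain, heavy = TRUE)
  ib <- atom_select(s, chain = g$beta_chain, heavy = TRUE)
  ax <- groove_axis(s, g)$axis
  xyz <- atom_xyz(s)
  P0 <- xyz[ip, , drop = FALSE]
  A <- xyz[ia, , drop = FALSE]; B <- xyz[ib, , drop = FALSE]
  HLA <- rbind(A, B)
  offsets <- seq.int(-max_shift, max_shift)
  rows <- lapply(offsets, function(k) {
    tr <- k * step * ax
    P <- sweep(P0, 2, tr, "+")
    data.frame(offset = k,
               label = sprintf("offset%+d", k),
               dx = tr[1], dy = tr[2], dz = tr[3],
               clash_count = .pair_count(P, HLA, clash_cutoff),
               contacts_alpha = .pair_count(P, A, contact_cutoff),
               contacts_beta = .pair_count(P, B, contact_cutoff))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("register_frames", "data.frame")
  out
}

#' Rank registration frames
#'
#' A geometric ranking of register poses: fewest clashes first, then most
#' total contacts, then the larger of min(contacts_alpha, contacts_beta)
#' first -- rewarding poses in good contact with both sides of the groove.
#' Remaining ties go to the smaller |offset| (then the smaller offset, so
#' the order is total). The ranking is independent of input row order.
#'
#' @param frames a [enumerate_registers()] result (>= 1 row).
#' @return the same data.frame reordered, with a `rank` column prepended.
#' @export
rank_registers <- function(frames) {
  stopifnot(is.data.frame(frames), nrow(frames) >= 1L)
  total <- frames$contacts_alpha + frames$contacts_beta
  both <- pmin(frames$contacts_alpha, frames$contacts_beta)
  ord <- order(frames$clash_count, -total, -both,
               abs(frames$offset), frames$offset)
  out <- frames[ord, , drop = FALSE]
  out <- cbind(rank = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  class(out) <- c("register_frames", "data.frame")
  out
}

.aa3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
          Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
          L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
          S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

#' Assign peptide residues to the P1-P9 binding pockets
#'
#' Maps a chosen 9-residue core register onto the class II pocket positions
#' P1..P9: pocket Pi holds peptide position `p1_index + i - 1`. For the HA
#' peptide PRYVKQNTLKLAT with P1 at position 3, P1-P5 are
#' Tyr-Val-Lys-Gln-Asn.
#'
#' @param peptide peptide sequence: a one-letter string (e.g.
#'   `"PRYVKQNTLKLAT"`) or a character vector of 3-letter residue codes.
#' @param p1_index 1-based peptide position anchoring pocket P1; the core
#'   `p1_index .. p1_index + 8` must fit inside the peptide.
#' @return data.frame with `pocket` (P1..P9), `position` (1-based peptide
#'   position) and `resname` (3-letter code), class `pocket_assignment`.
#' @export
assign_pockets <- function(peptide, p1_index) {
  if (is.character(peptide) && length(peptide) == 1L)
    peptide <- strsplit(peptide, "")[[1]]
  peptide <- toupper(peptide)
  if (all(nchar(peptide) == 1L)) {
    unknown <- setdiff(peptide, names(.aa3))
    if (length(unknown))
      stop("unknown residue code(s): ", paste(unknown, collapse = ","))
    peptide <- unname(.aa3[peptide])
  }
  n <- length(peptide)
  p1_index <- as.integer(p1_index)
  if (p1_index < 1L || p1_index + 8L > n)
    stop("9-mer core does not fit: p1_index ", p1_index,
         " + 8 exceeds peptide length ", n)
  pos <- p1_index:(p1_index + 8L)
  out <- data.frame(pocket = paste0("P", 1:9), position = pos,
                    resname = peptide[pos])
  class(out) <- c("pocket_assignment", "data.frame")
  out
}
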