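## Per-residue C-alpha displacement of the bound peptide between a
## drug-bound (trimer) and drug-free (dimer) representative structure,
## measured after superposing the two receptors on their framework atoms.

#' Drug-induced peptide displacement between two structures
#'
#' Superposes `trimer` onto `dimer` using the HLA framework C-alphas of the
#' groove definition (never the peptide itself), then reports the Euclidean
#' distance between corresponding peptide C-alphas. The framework fit makes
#' the statistic insensitive to global rigid motion and sensitive only to
#' where the peptide sits relative to the receptor.
#'
#' @param trimer a `groove_structure` (typically drug + HLA + peptide).
#' @param dimer a `groove_structure` (typically HLA + peptide).
#' @param g a [groove_definition()] with a `peptide_chain`.
#' @param clamp_range length-2 display clamp in Angstrom for
#'   [encode_bfactor()] (default `c(0, 10)`); raw values are always kept.
#' @return data.frame with `resid`, `resname`, `displacement` (Angstrom),
#'   class `displacement_table`, with the clamp range as an attribute.
#' @export
peptide_displacement <- function(trimer, dimer, g, clamp_range = c(0, 10)) {
  stopifnot(inherits(trimer, "groove_structure"),
            inherits(dimer, "groove_structure"),
            inherits(g, "groove_definition"))
  if (is.null(g$peptide_chain))
    stop("groove definition has no peptide_chain")

  fw_key <- function(s, idx) paste(s$atom$chain[idx], s$atom$resid[idx])
  it <- framework_indices(trimer, g); id <- framework_indices(dimer, g)
  common <- intersect(fw_key(trimer, it), fw_key(dimer, id))
  if (length(common) < 3L) stop("framework selections share < 3 atoms")
  it <- it[match(common, fw_key(trimer, it))]
  id <- id[match(common, fw_key(dimer, id))]

  pep_t <- select_calpha(trimer, g$peptide_chain, c(-Inf, Inf))
  pep_d <- select_calpha(dimer, g$peptide_chain, c(-Inf, Inf))
  if (!setequal(pep_t$resid, pep_d$resid)) {
    only_t <- setdiff(pep_t$resid, pep_d$resid)
    only_d <- setdiff(pep_d$resid, pep_t$resid)
    stop("peptide residue sets differ",
         if (length(only_t)) paste0("; only in trimer: ",
                                    paste(only_t, collapse = ",")) else "",
         if (length(only_d)) paste0("; only in dimer: ",
                                    paste(only_d, collapse = ",")) else "")
  }
  sp <- superpose(atom_xyz(trimer)[it, , drop = FALSE],
                  atom_xyz(dimer)[id, , drop = FALSE])
  xyz_t <- apply_transform(atom_xyz(trimer), sp)
  m <- match(pep_d$resid, pep_t$resid)
  pt <- xyz_t[sel_indices(pep_t)[m], , drop = FALSE]
  pd <- atom_xyz(dimer)[sel_indices(pep_d), , drop = FALSE]
  out <- data.frame(resid = pep_d$resid, resname = pep_d$resname,
                    displacement = sqrt(rowSums((pt - pd)^2)))
  attr(out, "clamp_range") <- clamp_range
  class(out) <- c("displacement_table", "data.frame")
  out
}

#' Encode peptide displacements into the B-factor column
#'
#' Writes each peptide residue's displacement, clamped to `clamp_range`
#' (default 0-10 Angstrom), into the B-factor of its C-alpha atom, so the
#' structure can be colored by displacement in any molecular viewer. All
#' other B-factors are left untouched.
#'
#' @param s a `groove_structure` containing the peptide chain.
#' @param table a [peptide_displacement()] result.
#' @param peptide_chain chain ID holding the peptide (default `"C"`).
#' @return the structure with updated B-factors.
#' @export
encode_bfactor <- function(s, table, peptide_chain = "C") {
  stopifnot(inherits(s, "groove_structure"),
            inherits(table, "displacement_table"))
  cr <- attr(table, "clamp_range")
  if (is.null(cr)) cr <- c(0, 10)
  idx <- atom_select(s, chain = peptide_chain, name = "CA")
  m <- match(s$atom$resid[idx], table$resid)
  if (anyNA(m))
    stop("structure peptide residues absent from displacement table: ",
         paste(s$atom$resid[idx][is.na(m)], collapse = ","))
  s$atom$b[idx] <- pmin(cr[2], pmax(cr[1], table$displacement[m]))
  s
}
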