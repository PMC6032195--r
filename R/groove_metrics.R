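## The inter-helical distance metric of the MHC class II binding groove,
## its per-frame time series, and mean/SD/slope summaries.

#' Define the peptide-binding groove of an MHC class II molecule
#'
#' Records which chains and residue ranges form the groove: the alpha-1 and
#' beta-1 helices flanking the beta-sheet floor, the framework selection
#' used for superposition, and (optionally) the bound peptide chain and the
#' ligand residue name. Residue ranges use author (PDB) numbering, 1-based
#' and inclusive, as in the HLA structural literature.
#'
#' @param alpha_chain,beta_chain chain IDs of the alpha and beta chains.
#' @param alpha_helix,beta_helix inclusive `c(lo, hi)` residue ranges of the
#'   groove helices.
#' @param framework framework selection for superposition: `"calpha"` (all
#'   alpha+beta-chain C-alphas, the default) or `"helices"` (helix C-alphas
#'   only).
#' @param peptide_chain chain ID of the bound peptide, or `NULL`.
#' @param ligand_resname residue name addressing the small-molecule ligand
#'   (default `"NVP"`, nevirapine).
#' @return an object of class `groove_definition`.
#' @export
groove_definition <- function(alpha_chain, beta_chain,
                              alpha_helix, beta_helix,
                              framework = c("calpha", "helices"),
                              peptide_chain = NULL,
                              ligand_resname = "NVP") {
  framework <- match.arg(framework)
  stopifnot(length(alpha_helix) == 2L, length(beta_helix) == 2L)
  if (alpha_helix[1] > alpha_helix[2] || beta_helix[1] > beta_helix[2])
    stop("helix residue ranges must be non-empty (lo <= hi)")
  if (!is.null(peptide_chain) && identical(alpha_chain, peptide_chain))
    stop("alpha_chain and peptide_chain must differ")
  structure(list(alpha_chain = alpha_chain, beta_chain = beta_chain,
                 alpha_helix = as.integer(alpha_helix),
                 beta_helix = as.integer(beta_helix),
                 framework = framework,
                 peptide_chain = peptide_chain,
                 ligand_resname = ligand_resname),
            class = "groove_definition")
}

#' Named groove-definition presets
#'
#' `"drb1-default"` is the package's HLA-DR architecture preset: alpha-1
#' helix residues 46-78 of the alpha chain, beta-1 helix residues 54-91 of
#' the beta chain, C-alpha atoms only. Helix spans differ slightly between
#' depositions, so the preset is configuration, not a constant: override
#' any field via `...`.
#'
#' @param name preset name (currently only `"drb1-default"`).
#' @param ... overrides passed to [groove_definition()].
#' @return a `groove_definition`.
#' @export
groove_preset <- function(name = "drb1-default", ...) {
  defaults <- switch(name,
    "drb1-default" = list(alpha_chain = "A", beta_chain = "B",
                          alpha_helix = c(46L, 78L), beta_helix = c(54L, 91L),
                          peptide_chain = "C"),
    stop("unknown groove preset: '", name, "'"))
  args <- utils::modifyList(defaults, list(...))
  do.call(groove_definition, args)
}

#' @export
print.groove_definition <- function(x, ...) {
  cat(sprintf("groove_definition: alpha %s %d-%d | beta %s %d-%d | framework %s%s\n",
              x$alpha_chain, x$alpha_helix[1], x$alpha_helix[2],
              x$beta_chain, x$beta_helix[1], x$beta_helix[2], x$framework,
              if (is.null(x$peptide_chain)) ""
              else paste0(" | peptide ", x$peptide_chain)))
  invisible(x)
}

## Framework atom indices per the groove definition.
framework_indices <- function(s, g) {
  if (inherits(s, "groove_trajectory")) s <- s$topology
  if (g$framework == "helices") {
    c(atom_select(s, chain = g$alpha_chain, name = "CA", resid = g$alpha_helix),
      atom_select(s, chain = g$beta_chain, name = "CA", resid = g$beta_helix))
  } else {
    c(atom_select(s, chain = g$alpha_chain, name = "CA"),
      atom_select(s, chain = g$beta_chain, name = "CA"))
  }
}

## Core directional metric on raw coordinate matrices: mean over rows of A
## of the minimum Euclidean distance to any row of B.
.ihd_xyz <- function(A, B) {
  d2 <- outer(rowSums(A^2), rep(1, nrow(B))) +
        outer(rep(1, nrow(A)), rowSums(B^2)) - 2 * tcrossprod(A, B)
  mean(sqrt(pmax(0, apply(d2, 1, min))))
}

#' Inter-helical distance of the binding groove
#'
#' For each C-alpha in the alpha-chain helix, the minimum Euclidean
#' distance to any C-alpha in the beta-chain helix; the metric is the
#' arithmetic mean of these minima. It is directional (alpha -> beta) by
#' default; `symmetrize = TRUE` averages both directions.
#'
#' @param frame a `groove_structure` (one conformation).
#' @param g a [groove_definition()].
#' @param symmetrize average the alpha->beta and beta->alpha values.
#' @return distance in Angstrom.
#' @export
inter_helical_distance <- function(frame, g, symmetrize = FALSE) {
  stopifnot(inherits(frame, "groove_structure"),
            inherits(g, "groove_definition"))
  ia <- sel_indices(select_calpha(frame, g$alpha_chain, g$alpha_helix))
  ib <- sel_indices(select_calpha(frame, g$beta_chain, g$beta_helix))
  if (!length(ia) || !length(ib))
    stop("empty helix selection; check the groove definition")
  xyz <- atom_xyz(frame)
  d <- .ihd_xyz(xyz[ia, , drop = FALSE], xyz[ib, , drop = FALSE])
  if (symmetrize)
    d <- (d + .ihd_xyz(xyz[ib, , drop = FALSE], xyz[ia, , drop = FALSE])) / 2
  d
}

#' Inter-helical distance time series
#'
#' Evaluates [inter_helical_distance()] on every frame of a trajectory,
#' paired with the time axis from `dt`.
#'
#' @param t a `groove_trajectory`.
#' @param g a [groove_definition()].
#' @param symmetrize see [inter_helical_distance()].
#' @return a [metric_series] in Angstrom, labelled
#'   "inter_helical_distance".
#' @export
groove_distance_series <- function(t, g, symmetrize = FALSE) {
  stopifnot(inherits(t, "groove_trajectory"))
  ia <- sel_indices(select_calpha(t$topology, g$alpha_chain, g$alpha_helix))
  ib <- sel_indices(select_calpha(t$topology, g$beta_chain, g$beta_helix))
  if (!length(ia) || !length(ib))
    stop("empty helix selection; check the groove definition")
  A <- traj_sel_xyz(t, ia); B <- traj_sel_xyz(t, ib)
  vals <- vapply(seq_len(nrow(A)), function(i) {
    a <- .row_xyz(A[i, ]); b <- .row_xyz(B[i, ])
    d <- .ihd_xyz(a, b)
    if (symmetrize) (d + .ihd_xyz(b, a)) / 2 else d
  }, numeric(1))
  metric_series(frame_times(t), vals, label = "inter_helical_distance")
}

#' Construct a per-frame metric series
#'
#' A scalar observable against a strictly increasing time axis (ns). Used
#' for RMSD curves, the inter-helical distance, and any externally supplied
#' per-frame scalar (e.g. total energies) that only needs summarization.
#'
#' @param times numeric, ns, strictly increasing.
#' @param values numeric, same length as `times`.
#' @param label free text.
#' @return an object of class `metric_series`.
#' @export
metric_series <- function(times, values, label = "") {
  if (length(times) != length(values))
    stop("times and values must have equal length")
  if (length(times) > 1L && any(diff(times) <= 0))
    stop("times must be strictly increasing")
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 label = as.character(label)[1]),
            class = "metric_series")
}

#' @export
print.metric_series <- function(x, ...) {
  cat(sprintf("metric_series '%s': %d points over %.3g ns, mean %.4g\n",
              x$label, length(x$values),
              diff(range(x$times)), mean(x$values)))
  invisible(x)
}

#' @export
as.data.frame.metric_series <- function(x, ...) {
  data.frame(time_ns = x$times, value = x$values)
}

#' Summarize a metric series (mean, SD, OLS slope)
#'
#' The per-trajectory summary reported for each observable: arithmetic
#' mean, sample standard deviation (n-1 denominator), and the ordinary
#' least-squares slope of value on time (per ns), with no detrending or
#' smoothing beforehand.
#'
#' @param s a [metric_series] with >= 2 points.
#' @return list with `mean`, `sd`, `slope`, `n_frames`, class
#'   `series_summary`.
#' @export
summarize_series <- function(s) {
  stopifnot(inherits(s, "metric_series"))
  if (length(s$values) < 2L)
    stop("series summary (slope) needs at least 2 points")
  fit <- lm(s$values ~ s$times)
  structure(list(mean = mean(s$values), sd = sd(s$values),
                 slope = unname(coef(fit)[2]),
                 n_frames = length(s$values), label = s$label),
            class = "series_summary")
}

#' @export
print.series_summary <- function(x, ...) {
  cat(sprintf("%s: mean %.4g +/- %.4g, slope %.4g per ns (n = %d)\n",
              if (nzchar(x$label)) x$label else "series",
              x$mean, x$sd, x$slope, x$n_frames))
  invisible(x)
}
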