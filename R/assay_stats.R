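## Competitive-assay analysis: percent-of-control normalization, the
## two-tailed Dunnett many-to-one comparison (replicate, summary-statistics
## and fixed-reference modes), and a seeded assay simulator.

#' Normalize raw assay counts to percent of control
#'
#' Scales every replicate by `100 / mean(control replicates)`, so the
#' control group averages exactly 100 and treatment values read as
#' "% binding relative to control".
#'
#' @param x long data.frame with columns `group` and `value` (raw counts).
#' @param control label of the control group (default `"DMSO"`).
#' @return the same data.frame with scaled `value`, class `assay_table`,
#'   with the control label in attribute `"control"`.
#' @export
percent_of_control <- function(x, control = "DMSO") {
  stopifnot(is.data.frame(x), all(c("group", "value") %in% names(x)))
  if (!control %in% x$group) stop("control group '", control, "' not found")
  cm <- mean(x$value[x$group == control])
  if (!is.finite(cm) || cm <= 0)
    stop("control mean must be positive (got ", format(cm), ")")
  x$value <- x$value * 100 / cm
  attr(x, "control") <- control
  class(x) <- c("assay_table", "data.frame")
  x
}

## --- Dunnett distribution --------------------------------------------------

## Density of S = sqrt(chi^2_df / df) (the pooled-SD scale factor).
.s_density <- function(s, df) {
  exp((1 - df / 2) * log(2) + (df / 2) * log(df) - lgamma(df / 2) +
      (df - 1) * log(s) - df * s^2 / 2)
}

#' Family-wise tail probability of the two-sided Dunnett max-|t| statistic
#'
#' Computes `P(max_i |T_i| >= q)` for `k` many-to-one comparisons sharing
#' one pooled standard deviation, where the comparison statistics have the
#' product correlation structure `corr(T_i, T_j) = b_i * b_j` (for equal
#' group sizes with a measured control, `b_i = sqrt(n_i / (n_i + n_0))`,
#' giving the classical correlation 1/2; with a fixed reference the
#' numerators are independent and `b_i = 0`). Evaluated by nested Gauss
#' quadrature of the standard conditioning integral over the common normal
#' variate and the pooled-SD scale factor, with full relative precision in
#' the far tail; [dunnett_maxt_mc()] is the seeded Monte Carlo
#' cross-check.
#'
#' @param q non-negative critical value / observed max-|t|.
#' @param df pooled degrees of freedom.
#' @param b numeric vector of length k of product-correlation loadings in
#'   `[0, 1)`.
#' @return the family-wise tail probability (adjusted p when `q = |t_i|`).
#' @export
dunnett_maxt_p <- function(q, df, b) {
  stopifnot(length(q) == 1L, q >= 0, df > 0, length(b) >= 1L,
            all(b >= 0 & b < 1))
  if (q == 0) return(1)
  k <- length(b)
  cc <- sqrt(1 - b^2)
  ## P(any |T_i| > q | S = s) as a stable complement
  cond_tail <- function(s) {
    if (all(b == 0))
      return(-expm1(k * log1p(-pmin(1 - 1e-16, 2 * pnorm(-q * s)))))
    f <- function(z) {
      vapply(z, function(zz) {
        e <- pnorm(-(q * s + b * zz) / cc) + pnorm((-q * s + b * zz) / cc)
        -expm1(sum(log1p(-pmin(e, 1 - 1e-16))))
      }, numeric(1)) * dnorm(z)
    }
    integrate(f, -Inf, Inf, rel.tol = 1e-10, abs.tol = 0)$value
  }
  out <- integrate(function(s) vapply(s, cond_tail, numeric(1)) *
                     .s_density(s, df),
                   0, Inf, rel.tol = 1e-9, abs.tol = 0)
  min(1, max(0, out$value))
}

#' Monte Carlo estimate of the Dunnett family-wise tail probability
#'
#' Seeded simulation of the max-|t| distribution used to cross-check
#' [dunnett_maxt_p()]: draws the common variate, the k independent
#' components and the pooled-SD scale factor, and reports the fraction of
#' draws with `max |T_i| >= q`.
#'
#' @param q critical value.
#' @param df pooled degrees of freedom.
#' @param b product-correlation loadings (length k).
#' @param n_draws number of Monte Carlo draws.
#' @param seed RNG seed.
#' @return estimated tail probability.
#' @export
dunnett_maxt_mc <- function(q, df, b, n_draws = 1e6, seed = 1L) {
  set.seed(seed)
  k <- length(b)
  z0 <- rnorm(n_draws)
  s <- sqrt(rchisq(n_draws, df) / df)
  mx <- rep(-Inf, n_draws)
  for (i in seq_len(k)) {
    ti <- (b[i] * z0 + sqrt(1 - b[i]^2) * rnorm(n_draws)) / s
    mx <- pmax(mx, abs(ti))
  }
  mean(mx >= q)
}

#' Two-sided Dunnett critical value
#'
#' Inverts [dunnett_maxt_p()] to the critical value with family-wise tail
#' probability `alpha`.
#'
#' @param alpha family-wise error rate.
#' @param df pooled degrees of freedom.
#' @param b product-correlation loadings (length k).
#' @return the critical value q with `P(max|T| >= q) = alpha`.
#' @export
dunnett_critical <- function(alpha, df, b) {
  uniroot(function(q) dunnett_maxt_p(q, df, b) - alpha,
          lower = 1e-3, upper = 100, tol = 1e-7)$root
}

## --- The test --------------------------------------------------------------

#' Two-tailed Dunnett many-to-one comparison test
#'
#' Compares each treatment group with a control, controlling the
#' family-wise error rate. Three input modes:
#'
#' * replicate mode: a long data.frame with columns `group` and `value`
#'   plus a `control` label; the pooled variance uses all groups and
#'   `t_i = (m_i - m_0) / (s_p * sqrt(1/n_i + 1/n_0))`.
#' * summary mode: a data.frame with columns `group`, `mean`, `sd`, `n`
#'   plus a `control` label among the groups.
#' * fixed-reference mode (`fixed_reference` given, e.g. 100): the control
#'   is the stated constant with no sampling variance, the pooled variance
#'   comes from the treatment groups alone, and
#'   `t_i = (m_i - ref) / (s_p / sqrt(n_i))`. This is the documented route
#'   for published percent-of-control tables whose control SD is not
#'   printed; the comparisons then share only the pooled SD (loadings
#'   `b_i = 0`).
#'
#' Adjusted two-sided p-values come from [dunnett_maxt_p()] with
#' `b_i = sqrt(n_i / (n_i + n_0))` (the `n`-weighted generalization of the
#' equal-`n` correlation 1/2) or `b_i = 0` in fixed-reference mode.
#'
#' @param x a data.frame in replicate or summary layout (see above).
#' @param control label of the control group (ignored in fixed-reference
#'   mode).
#' @param fixed_reference optional constant control value (e.g. 100).
#' @return data.frame with one row per treatment group: `group`,
#'   `estimate` (mean difference from control), `t`, `p_unadj`, `p_adj`;
#'   pooled `df`, `k` and the loadings in attributes; class
#'   `dunnett_result`.
#' @export
dunnett_test <- function(x, control = "DMSO", fixed_reference = NULL) {
  stopifnot(is.data.frame(x))
  summary_mode <- all(c("group", "mean", "sd", "n") %in% names(x))
  if (!summary_mode && !all(c("group", "value") %in% names(x)))
    stop("x must have columns (group, value) or (group, mean, sd, n)")

  if (summary_mode) {
    g <- data.frame(group = as.character(x$group), mean = x$mean,
                    sd = x$sd, n = as.integer(x$n))
  } else {
    sp <- split(x$value, as.character(x$group))
    sp <- sp[unique(as.character(x$group))]
    g <- data.frame(group = names(sp),
                    mean = vapply(sp, mean, numeric(1)),
                    sd = vapply(sp, sd, numeric(1)),
                    n = vapply(sp, length, integer(1)))
  }
  if (any(g$n < 2))
    stop("every group needs n >= 2 replicates for a pooled variance")
  if (any(g$sd < 0) || any(!is.finite(g$sd))) stop("invalid group SDs")

  if (is.null(fixed_reference)) {
    if (!control %in% g$group)
      stop("control group '", control, "' not found")
    ctrl <- g[g$group == control, ]
    trt <- g[g$group != control, , drop = FALSE]
    if (!nrow(trt)) stop("no treatment groups to compare (k = 0)")
    all_g <- g
    df <- sum(all_g$n - 1L)
    s2 <- sum((all_g$n - 1L) * all_g$sd^2) / df
    se <- sqrt(s2 * (1 / trt$n + 1 / ctrl$n))
    tt <- (trt$mean - ctrl$mean) / se
    b <- sqrt(trt$n / (trt$n + ctrl$n))
    est <- trt$mean - ctrl$mean
  } else {
    trt <- g
    if (!nrow(trt)) stop("no treatment groups to compare (k = 0)")
    df <- sum(trt$n - 1L)
    s2 <- sum((trt$n - 1L) * trt$sd^2) / df
    tt <- (trt$mean - fixed_reference) / sqrt(s2 / trt$n)
    b <- rep(0, nrow(trt))
    est <- trt$mean - fixed_reference
  }
  p_adj <- vapply(abs(tt), dunnett_maxt_p, numeric(1), df = df, b = b)
  out <- data.frame(group = trt$group, estimate = est, t = tt,
                    p_unadj = 2 * pt(-abs(tt), df), p_adj = p_adj)
  rownames(out) <- NULL
  attr(out, "df") <- df
  attr(out, "k") <- nrow(trt)
  attr(out, "b") <- b
  attr(out, "fixed_reference") <- fixed_reference
  class(out) <- c("dunnett_result", "data.frame")
  out
}

#' @export
print.dunnett_result <- function(x, ...) {
  cat(sprintf("Two-tailed Dunnett test: k = %d comparisons, pooled df = %d%s\n",
              attr(x, "k"), attr(x, "df"),
              if (!is.null(attr(x, "fixed_reference")))
                sprintf(" (fixed reference = %g)", attr(x, "fixed_reference"))
              else ""))
  print.data.frame(x, digits = 4)
  invisible(x)
}

#' Simulate a competitive-assay table
#'
#' Gaussian replicate counts around `control_mean * effect` for each dose
#' group plus a control group at effect 1, fully determined by `seed`.
#' Used as the ground-truth fixture for calibration and power checks.
#'
#' @param effects named numeric vector of multiplicative effect sizes per
#'   dose group (e.g. `c("1000" = 2.639, "200" = 1.0)`).
#' @param noise_sd replicate SD on the response scale.
#' @param replicates replicates per group (>= 2).
#' @param control_mean control group mean (default 100).
#' @param control label for the control group (default `"DMSO"`).
#' @param seed RNG seed.
#' @return long data.frame (`group`, `value`) with the control group
#'   first, class `assay_table`.
#' @export
simulate_assay <- function(effects, noise_sd, replicates = 4L,
                           control_mean = 100, control = "DMSO",
                           seed = 1L) {
  if (replicates < 2L) stop("replicates must be >= 2")
  if (is.null(names(effects)))
    names(effects) <- as.character(seq_along(effects))
  set.seed(seed)
  groups <- c(control, names(effects))
  means <- c(control_mean, control_mean * effects)
  vals <- lapply(means, function(m) rnorm(replicates, m, noise_sd))
  out <- data.frame(group = rep(groups, each = replicates),
                    value = unlist(vals, use.names = FALSE))
  attr(out, "control") <- control
  class(out) <- c("assay_table", "data.frame")
  out
}
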