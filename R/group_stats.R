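#' Collect per-subject phiIRFs into a cohort
#'
#' @param fits List of `"phirf"` objects on identical grids (n >= 2).
#' @return An object of class `"phirf_group"`: array `h` of dimension
#'   `[subject, response time, stimulus phase]` plus the shared grids.
#' @export
phirf_group <- function(fits) {
  stopifnot(length(fits) >= 1L)
  ref <- fits[[1]]
  for (f in fits) {
    stopifnot(inherits(f, "phirf"))
    if (length(f$tr) != length(ref$tr) || length(f$phases) != length(ref$phases))
      stop("phirf_group(): subjects are on different grids")
  }
  h <- array(0, dim = c(length(fits), length(ref$tr), length(ref$phases)))
  for (i in seq_along(fits)) h[i, , ] <- fits[[i]]$h
  structure(list(h = h, tr = ref$tr, phases = ref$phases, dt = ref$dt,
                 horizon = ref$horizon, n = length(fits),
                 T_bar = mean(vapply(fits, function(f) f$T_bar, numeric(1))),
                 channel = ref$channel, input = ref$input,
                 units_out = ref$units_out, units_in = ref$units_in,
                 fits = fits),
            class = "phirf_group")
}

#' @export
print.phirf_group <- function(x, ...) {
  cat(sprintf("<phiIRF cohort> n = %d subjects, %s -> %s, %d x %d grid\n",
              x$n, x$input, x$channel, length(x$tr), length(x$phases)))
  invisible(x)
}

#' Group-mean phiIRF of a cohort
#'
#' @param g A `"phirf_group"`.
#' @return A `"phirf"` whose matrix is the subject mean.
#' @export
group_mean_phirf <- function(g) {
  stopifnot(inherits(g, "phirf_group"))
  out <- g$fits[[1]]
  out$h <- apply(g$h, c(2, 3), mean)
  out$method <- "group mean"
  out
}

#' Normal-theory confidence intervals for the cohort mean
#'
#' Per-cell sample mean and confidence interval of the mean at level
#' `1 - alpha` under the normal model (t quantile, as in a normal-fit
#' analysis of the subject sample).
#'
#' @param g A `"phirf_group"` with at least 2 subjects.
#' @param alpha Significance level (default 0.05).
#' @return An object of class `"phirf_stats"` with `mean` and `ci_halfwidth`
#'   matrices `[response time, stimulus phase]`.
#' @export
group_ci <- function(g, alpha = 0.05) {
  stopifnot(inherits(g, "phirf_group"))
  if (g$n < 2L) stop("group_ci(): need at least 2 subjects")
  mu <- apply(g$h, c(2, 3), mean)
  sd <- apply(g$h, c(2, 3), stats::sd)
  hw <- stats::qt(1 - alpha / 2, df = g$n - 1L) * sd / sqrt(g$n)
  structure(list(mean = mu, ci_halfwidth = hw, alpha = alpha, n = g$n,
                 tr = g$tr, phases = g$phases, t = NULL, p_adj = NULL,
                 significant = NULL, n_perm = NULL, horizon = g$horizon),
            class = "phirf_stats")
}

#' Sign-flip permutation tests with tmax FWER control
#'
#' Tests the null hypothesis of zero mean response at every normalized
#' response time within each stimulus phase, using subject-level sign-flip
#' permutations of the one-sample t statistic.  Within each stimulus phase,
#' all response times up to `horizon` cycles after stimulus onset form one
#' family; the null distribution of the maximum absolute t over the family
#' (tmax) yields adjusted p-values with strong family-wise error control.
#' Stimulus phases are not corrected jointly.  The observed labeling is
#' counted as one permutation, so the smallest attainable adjusted p is
#' `1/n_perm`.  Zero-variance cells are excluded from the family and
#' assigned p = 1.
#'
#' @param g A `"phirf_group"`.
#' @param n_perm Number of permutations (default 1000).
#' @param alpha Significance level (default 0.05).
#' @param horizon Family horizon in cycles after onset (default the cohort
#'   horizon, 3).
#' @param seed Integer seed for the sign flips.
#' @return A `"phirf_stats"` with `mean`, `ci_halfwidth`, `t`, `p_adj` and
#'   `significant` matrices; cells outside the per-phase family are `NA`.
#' @export
permutation_tmax <- function(g, n_perm = 1000, alpha = 0.05,
                             horizon = NULL, seed = NULL) {
  stopifnot(inherits(g, "phirf_group"))
  if (g$n < 2L) stop("permutation_tmax(): need at least 2 subjects")
  if (g$n < 5L) warning("permutation_tmax(): fewer than 5 subjects; permutation null is coarse")
  if (is.null(horizon)) horizon <- g$horizon
  if (!is.null(seed)) set.seed(seed)
  n <- g$n
  base <- group_ci(g, alpha = alpha)
  tmat <- matrix(NA_real_, length(g$tr), length(g$phases))
  pmat <- matrix(NA_real_, length(g$tr), length(g$phases))

  signs <- matrix(sample(c(-1, 1), n * n_perm, replace = TRUE), n, n_perm)
  signs[, 1L] <- 1                                   # observed labeling

  for (mph in seq_along(g$phases)) {
    lag <- g$tr - g$phases[mph]
    fam <- which(lag >= -1e-9 & lag <= horizon + 1e-9)
    X <- g$h[, fam, mph, drop = TRUE]                # n x cells
    if (is.null(dim(X))) X <- matrix(X, nrow = n)
    s2 <- colSums(X^2)
    mu_obs <- colMeans(X)
    var_obs <- pmax(0, (s2 - n * mu_obs^2) / (n - 1))
    nz <- var_obs > 0                                # zero-variance cells excluded
    t_obs <- rep(NA_real_, length(fam))
    t_obs[nz] <- mu_obs[nz] / sqrt(var_obs[nz] / n)
    tmat[fam, mph] <- t_obs

    if (!any(nz)) { pmat[fam, mph] <- 1; next }
    Xn <- X[, nz, drop = FALSE]
    s2n <- s2[nz]
    M <- crossprod(signs, Xn) / n                    # n_perm x cells
    V <- sweep(-n * M^2, 2, s2n, `+`) / (n - 1)
    V[V < .Machine$double.eps] <- .Machine$double.eps
    Tp <- abs(M) / sqrt(V / n)
    tmax <- apply(Tp, 1, max)
    p <- vapply(abs(t_obs[nz]), function(tv) mean(tmax >= tv - 1e-12), numeric(1))
    pcell <- rep(1, length(fam))
    pcell[nz] <- p
    pmat[fam, mph] <- pcell
  }
  base$t <- tmat
  base$p_adj <- pmat
  base$significant <- !is.na(pmat) & pmat < alpha
  base$n_perm <- n_perm
  base$horizon <- horizon
  base$tr <- g$tr
  base$phases <- g$phases
  base
}

#' @export
print.phirf_stats <- function(x, ...) {
  cat(sprintf("<phiIRF group statistics> n = %d subjects, alpha = %g\n", x$n, x$alpha))
  if (!is.null(x$p_adj)) {
    nsig <- sum(x$significant, na.rm = TRUE)
    ntest <- sum(!is.na(x$p_adj))
    cat(sprintf("  tmax permutation tests: %d permutations, %d/%d cells significant\n",
                x$n_perm, nsig, ntest))
  }
  invisible(x)
}

#' Significance-mask heatmap of cohort statistics
#'
#' @param x A `"phirf_stats"` from [permutation_tmax()].
#' @param ... Passed to [graphics::image()].
#' @export
plot.phirf_stats <- function(x, ...) {
  z <- x$mean
  if (!is.null(x$significant)) z[!x$significant] <- NA
  pal <- grDevices::hcl.colors(65, "Blue-Red 3")
  zmax <- max(abs(x$mean), na.rm = TRUE)
  graphics::image(x$phases, x$tr, t(z), zlim = c(-zmax, zmax), col = pal,
                  xlab = "stimulus phase (cycles)",
                  ylab = "normalized response time (cycles)",
                  main = "significant group-mean response", ...)
  graphics::abline(0, 1, lwd = 2)
  invisible(x)
}
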