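#' Observable time series
#'
#' Per-frame values of an observable (scalar or per-subunit columns) with
#' strictly increasing times.
#'
#' @param times frame times in ps (strictly increasing).
#' @param values numeric vector or matrix (one row per frame).
#' @param label observable name.
#' @param units unit string (e.g. `"deg"`, `"A"`, `"nm^2"`).
#' @return an object of class `obs_series`.
#' @export
obs_series <- function(times, values, label = "", units = "") {
  values <- if (is.matrix(values)) values else matrix(values, ncol = 1)
  if (length(times) != nrow(values)) {
    stop("times and values disagree on the frame count")
  }
  if (length(times) > 1 && any(diff(times) <= 0)) {
    stop("times must be strictly increasing")
  }
  if (is.null(colnames(values))) {
    colnames(values) <- if (ncol(values) == 1) "value" else
      paste0("v", seq_len(ncol(values)))
  }
  structure(list(times = as.numeric(times), values = values,
                 label = label, units = units),
            class = "obs_series")
}

#' @export
print.obs_series <- function(x, ...) {
  cat(sprintf("obs_series '%s' [%s]: %d frames x %d column(s)\n",
              x$label, x$units, length(x$times), ncol(x$values)))
  invisible(x)
}

#' C-alpha selection specification
#'
#' Builds a reusable atom-matching rule (chain/residue-range/atom-name)
#' used by [superpose()] and [rmsd_series()] so that mobile and reference
#' structures are matched by (chain, resno, elety) identity rather than
#' by position.
#'
#' @param topo a [receptor_topology()].
#' @param domain `"tm"`, `"ec"` or `"all"`.
#' @param chains chains to include (default: all five).
#' @param elety atom names (default `"CA"`).
#' @return an object of class `selection_spec`.
#' @export
selection_spec <- function(topo, domain = c("tm", "ec", "all"),
                           chains = topo$chains, elety = "CA") {
  domain <- match.arg(domain)
  ranges <- switch(domain,
                   tm = list(topo$tm_range),
                   ec = list(topo$ec_range),
                   all = list(topo$ec_range, topo$tm_range))
  structure(list(chains = chains, ranges = ranges, elety = elety,
                 domain = domain),
            class = "selection_spec")
}

# Resolve a selection_spec (or a plain integer index vector) on a
# snapshot/trajectory atom table, returning keyed indices.
.resolve_selection <- function(atoms, sel) {
  if (is.numeric(sel)) return(as.integer(sel))
  stopifnot(inherits(sel, "selection_spec"))
  keep <- atoms$chain %in% sel$chains & atoms$elety %in% sel$elety
  in_range <- rep(FALSE, nrow(atoms))
  for (r in sel$ranges) in_range <- in_range | (atoms$resno >= r[1] &
                                                  atoms$resno <= r[2])
  which(keep & in_range)
}

# Match selection atoms between two atom tables by (chain, resno, elety);
# returns list(mobile =, ref =) of equal-length index vectors.
.match_selection <- function(mobile_atoms, ref_atoms, sel) {
  im <- .resolve_selection(mobile_atoms, sel)
  ir <- .resolve_selection(ref_atoms, sel)
  km <- paste(mobile_atoms$chain[im], mobile_atoms$resno[im],
              mobile_atoms$elety[im])
  kr <- paste(ref_atoms$chain[ir], ref_atoms$resno[ir], ref_atoms$elety[ir])
  common <- intersect(km, kr)
  if (length(common) < 3) stop("fewer than 3 matched atoms in the selection")
  list(mobile = im[match(common, km)], ref = ir[match(common, kr)])
}

# Kabsch: optimal proper rotation R and translation t mapping P onto Q
# (both n x 3), minimizing ||P R + t - Q||.
.kabsch <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  H <- crossprod(Pc, Qc)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  t_vec <- cq - as.numeric(cp %*% R)
  fitted <- sweep(Pc %*% R, 2, cq, `+`)
  list(R = R, t = t_vec, rmsd = sqrt(mean(rowSums((fitted - Q)^2))))
}

#' Least-squares superposition of two snapshots
#'
#' Optimal rigid-body (proper rotation + translation) fit of the mobile
#' snapshot onto the reference over a matched atom selection, via the
#' Kabsch/SVD construction with the determinant corrected to +1 so
#' reflections are never returned.
#'
#' @param mobile,ref [snapshot()] objects.
#' @param sel a [selection_spec()] (matched by chain/resno/atom name) or
#'   an integer index vector valid in both structures.
#' @return a list of class `superposition`: rotation `R` (applied on the
#'   right: `x %*% R + t`), translation `t`, and the fit `rmsd` (A).
#' @export
superpose <- function(mobile, ref, sel) {
  m <- .match_selection(mobile$atoms, ref$atoms, sel)
  res <- .kabsch(mobile$xyz[m$mobile, , drop = FALSE],
                 ref$xyz[m$ref, , drop = FALSE])
  structure(c(res, list(n_fit = length(m$mobile))), class = "superposition")
}

#' Apply a superposition transform to a whole snapshot
#' @param snap a [snapshot()].
#' @param fit a [superpose()] result.
#' @export
apply_transform <- function(snap, fit) {
  snap$xyz <- sweep(snap$xyz %*% fit$R, 2, fit$t, `+`)
  snap
}

# RMSD between matched coordinate sets, no fitting.
.raw_rmsd <- function(P, Q) sqrt(mean(rowSums((P - Q)^2)))

#' C-alpha RMSD time series
#'
#' Per frame, superposes the trajectory frame onto the reference over the
#' fit selection and reports the RMSD over the measure selection. The
#' default convention is domain-wise: fit and measure on the same domain
#' (`measure_sel = fit_sel`), so e.g. a TM RMSD is insensitive to EC
#' motion; pass a different `measure_sel` for a cross-fit RMSD. Set
#' `fit = FALSE` to skip superposition.
#'
#' @param traj a [trajectory()].
#' @param ref reference [snapshot()].
#' @param fit_sel a [selection_spec()] or index vector for the fit.
#' @param measure_sel selection for the reported RMSD (default: fit_sel).
#' @param fit superpose before measuring? (default TRUE)
#' @return an [obs_series()] of RMSD (A), labeled by the fit domain.
#' @export
rmsd_series <- function(traj, ref, fit_sel, measure_sel = fit_sel,
                        fit = TRUE) {
  mf <- .match_selection(traj$atoms, ref$atoms, fit_sel)
  mm <- .match_selection(traj$atoms, ref$atoms, measure_sel)
  Qf <- ref$xyz[mf$ref, , drop = FALSE]
  Qm <- ref$xyz[mm$ref, , drop = FALSE]
  nf <- n_frames(traj)
  vals <- vapply(seq_len(nf), function(i) {
    Pf <- traj$xyz[mf$mobile, , i]
    Pm <- traj$xyz[mm$mobile, , i]
    if (fit) {
      k <- .kabsch(Pf, Qf)
      Pm <- sweep(Pm %*% k$R, 2, k$t, `+`)
    }
    .raw_rmsd(Pm, Qm)
  }, numeric(1))
  obs_series(traj$times, vals, label = "Calpha RMSD", units = "A")
}

#' Block (running) average of an observable series
#'
#' Means over consecutive non-overlapping windows of `window` frames, the
#' smoothing used for every reported time series; a trailing partial
#' window is dropped. With 10 ps frames the default window of 500 frames
#' is a 5 ns average.
#'
#' @param series an [obs_series()].
#' @param window window length in frames (>= 1).
#' @return an [obs_series()] of window means, timed at window-mean times.
#' @export
block_average <- function(series, window = 500) {
  n <- length(series$times)
  if (window < 1) stop("window must be >= 1")
  if (window > n) stop("window (", window, ") exceeds series length (", n, ")")
  nb <- n %/% window
  idx <- seq_len(nb * window)
  g <- rep(seq_len(nb), each = window)
  vals <- apply(series$values[idx, , drop = FALSE], 2,
                function(col) tapply(col, g, mean))
  if (nb == 1) vals <- matrix(vals, nrow = 1,
                              dimnames = list(NULL, colnames(series$values)))
  obs_series(tapply(series$times[idx], g, mean), vals,
             label = series$label, units = series$units)
}

#' Autocorrelation time by exponential fit
#'
#' Normalized autocorrelation function of a scalar series (acf(0) = 1),
#' computed to lag = half the series length, followed by an unweighted
#' least-squares fit of A * exp(-t / tau). The initial tau guess is the
#' first lag where the acf drops below 1/e.
#'
#' @param series an [obs_series()] with one column (or a numeric vector,
#'   in which case `dt` gives the frame spacing in ps).
#' @param dt frame spacing in ps when `series` is a bare vector.
#' @return a list of class `acf_fit`: `tau_ps`, `amplitude`, `resid`
#'   (root-mean-square fit residual), `lags_ps`, `acf`.
#' @export
acf_exp_fit <- function(series, dt = NULL) {
  if (inherits(series, "obs_series")) {
    x <- series$values[, 1]
    dt <- stats::median(diff(series$times))
  } else {
    x <- as.numeric(series)
    if (is.null(dt)) dt <- 1
  }
  n <- length(x)
  if (n < 50) stop("need at least 50 frames for an autocorrelation fit")
  if (stats::var(x) < .Machine$double.eps) {
    stop("series has zero variance: autocorrelation undefined")
  }
  lag_max <- floor(n / 2)
  ac <- stats::acf(x, lag.max = lag_max, plot = FALSE, demean = TRUE)$acf[, 1, 1]
  lags <- (seq_along(ac) - 1) * dt
  below <- which(ac < exp(-1))
  tau0 <- if (length(below)) max(lags[below[1]], dt) else lags[length(lags)] / 2
  df <- data.frame(t = lags, y = ac)
  fit <- minpack.lm::nlsLM(y ~ A * exp(-t / tau), data = df,
                           start = list(A = 1, tau = tau0),
                           lower = c(A = -Inf, tau = 1e-6),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  structure(list(tau_ps = unname(cf["tau"]), amplitude = unname(cf["A"]),
                 resid = sqrt(mean(stats::residuals(fit)^2)),
                 lags_ps = lags, acf = ac),
            class = "acf_fit")
}

#' @export
print.acf_fit <- function(x, ...) {
  cat(sprintf("acf fit: tau = %.1f ps, A = %.3f, rms resid %.3g\n",
              x$tau_ps, x$amplitude, x$resid))
  invisible(x)
}

#' Pearson correlation between two observable series
#'
#' @param x,y [obs_series()] (first column used) or numeric vectors of
#'   equal length (>= 3).
#' @return the Pearson correlation coefficient.
#' @export
pearson <- function(x, y) {
  gx <- if (inherits(x, "obs_series")) x$values[, 1] else as.numeric(x)
  gy <- if (inherits(y, "obs_series")) y$values[, 1] else as.numeric(y)
  if (length(gx) != length(gy)) stop("series lengths differ")
  if (length(gx) < 3) stop("need at least 3 points")
  if (stats::var(gx) == 0 || stats::var(gy) == 0) {
    stop("zero variance: correlation undefined")
  }
  stats::cor(gx, gy)
}
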