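#' Quantified EMSA band table
#'
#' Container for quantified electrophoretic mobility shift assay lanes: one
#' row per lane, one `band_k` column per band species (`k = 0` is the free
#' probe, `k >= 1` are the shifted species with `k` proteins bound).
#' Intensities are arbitrary densitometry units. A zero-protein lane must be
#' present (gels are normalised against it and it anchors the titration).
#'
#' @param conc numeric vector of protein concentrations per lane, uM.
#' @param intensities numeric matrix, lanes x band species (`>= 0`, finite).
#' @param replicate replicate identifier per lane (recycled).
#' @return a data.frame of class `band_table` with columns `lane`,
#'   `replicate`, `conc`, `band_0..band_n`.
#' @export
band_table <- function(conc, intensities, replicate = 1L) {
  intensities <- as.matrix(intensities)
  cf_assert(is.numeric(conc) && length(conc) >= 1L, "need at least one lane")
  cf_assert(nrow(intensities) == length(conc),
            "one row of intensities per lane")
  cf_assert(all(is.finite(conc)) && all(conc >= 0),
            "concentrations must be finite and >= 0")
  cf_assert(all(is.finite(intensities)) && all(intensities >= 0),
            "intensities must be finite and >= 0")
  cf_assert(any(conc == 0),
            "a zero-protein lane is required (gel normalisation anchor)")
  n_bands <- ncol(intensities)
  out <- data.frame(lane = seq_along(conc),
                    replicate = rep_len(replicate, length(conc)),
                    conc = conc)
  colnames(intensities) <- paste0("band_", seq_len(n_bands) - 1L)
  out <- cbind(out, as.data.frame(intensities))
  class(out) <- c("band_table", "data.frame")
  out
}

.band_cols <- function(tab) grep("^band_", names(tab), value = TRUE)

#' Saturation curve container
#'
#' @param concentration numeric, uM, non-negative.
#' @param Y fractional saturation in `[0, 1]`.
#' @param sem standard error of the mean of `Y` (NA when unreplicated).
#' @param n_replicates replicates contributing to each point.
#' @return data.frame of class `saturation_curve`, sorted by concentration.
#' @export
saturation_curve <- function(concentration, Y, sem = NA_real_,
                             n_replicates = 1L) {
  cf_assert(all(concentration >= 0), "concentrations must be >= 0")
  cf_assert(all(Y >= 0 & Y <= 1), "Y must lie in [0, 1]")
  cf_assert(!anyDuplicated(concentration),
            "concentrations must be distinct after aggregation")
  d <- data.frame(concentration = concentration, Y = Y,
                  sem = rep_len(sem, length(Y)),
                  n_replicates = rep_len(n_replicates, length(Y)))
  d <- d[order(d$concentration), , drop = FALSE]
  rownames(d) <- NULL
  class(d) <- c("saturation_curve", "data.frame")
  d
}

#' Fractional saturation from a band table
#'
#' Per lane, with `saturation = "any_bound"` (the default) the fractional
#' saturation is the summed intensity of all shifted species (`k >= 1`, i.e.
#' every probe molecule with at least one protein bound) divided by the total
#' lane intensity. With `saturation = "per_site"` each band species is
#' weighted by its occupancy count, `Y = sum(k * I_k) / (n * sum(I_k))`: the
#' mean per-site occupancy, which is what [fractional_saturation()] predicts
#' for the generating model. The two coincide for single-site (two-band)
#' gels; for multi-band gels `"any_bound"` saturates as soon as the tightest
#' site fills and so hides the affinity ladder that `"per_site"` resolves.
#' Values are clamped to `[0, 1]` against round-off. Replicate lanes at the
#' same concentration are averaged and the standard error of the mean
#' reported.
#'
#' @param table a [band_table()].
#' @param saturation `"any_bound"` (bound fraction of probe molecules) or
#'   `"per_site"` (mean per-site occupancy).
#' @return a [saturation_curve()].
#' @export
band_table_to_saturation <- function(table,
                                     saturation = c("any_bound", "per_site")) {
  saturation <- match.arg(saturation)
  tab <- as.data.frame(table)
  bands <- .band_cols(tab)
  cf_assert(length(bands) >= 2L, "band table needs at least band_0 and band_1")
  intens <- as.matrix(tab[bands])
  totals <- rowSums(intens)
  if (any(totals <= 0)) {
    cf_stop("lane with zero total intensity", "coopfit_empty_lane")
  }
  n_sites <- length(bands) - 1L
  bound <- if (saturation == "any_bound") {
    rowSums(intens[, -1L, drop = FALSE])
  } else {
    as.vector(intens %*% (0:n_sites)) / n_sites
  }
  y <- pmin(pmax(bound / totals, 0), 1)
  agg_mean <- tapply(y, tab$conc, mean)
  agg_n <- tapply(y, tab$conc, length)
  agg_sem <- tapply(y, tab$conc, function(v) {
    if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else NA_real_
  })
  conc <- as.numeric(names(agg_mean))
  saturation_curve(conc, as.numeric(agg_mean), as.numeric(agg_sem),
                   as.integer(agg_n))
}

#' Hill transform of a saturation curve
#'
#' Maps each usable point to `(log10 conc, log10 theta)` with
#' `theta = Y / (1 - Y)`. Points at zero concentration or with degenerate
#' saturation (`Y <= eps` or `Y >= 1 - eps`) carry no information on the Hill
#' line and are excluded, not errors; the number excluded is reported in the
#' `n_excluded` attribute so the filtering is auditable.
#'
#' @param curve a [saturation_curve()].
#' @param eps exclusion threshold for degenerate `Y` (default 1e-6).
#' @return data.frame of class `hill_points` with columns `log_conc`,
#'   `log_theta` and attribute `n_excluded`.
#' @export
hill_transform <- function(curve, eps = 1e-6) {
  d <- as.data.frame(curve)
  keep <- d$concentration > 0 & d$Y > eps & d$Y < 1 - eps
  n_excluded <- sum(!keep)
  d <- d[keep, , drop = FALSE]
  if (nrow(d) < 2L) {
    cf_stop("fewer than 2 usable points after excluding degenerate Y",
            "coopfit_insufficient_data")
  }
  out <- data.frame(log_conc = log10(d$concentration),
                    log_theta = log10(d$Y / (1 - d$Y)))
  rownames(out) <- NULL
  attr(out, "n_excluded") <- n_excluded
  class(out) <- c("hill_points", "data.frame")
  out
}

#' Hill-plot fit: Hill coefficient and dissociation constant
#'
#' Ordinary least-squares line through the Hill points lying in the local
#' window `|log10 theta| <= window` around half saturation (the region where
#' the Hill slope is defined); if fewer than 2 points fall in the window, the
#' 4 points nearest `log theta = 0` are used instead. The Hill coefficient
#' `n_H` is the slope; the dissociation constant is extracted from the
#' x-intercept as `Kd = 10^(x-intercept)` (base-10 logs throughout). On
#' points drawn from an exact Hill law `theta = (conc/Kd)^n` the generating
#' `n` and `Kd` are recovered exactly.
#'
#' @param points a `hill_points` data.frame from [hill_transform()].
#' @param window half-width of the `log theta` selection window (default 1.0,
#'   i.e. roughly `Y` in 0.09..0.91).
#' @param tol classification tolerance passed to [classify_cooperativity()].
#' @return object of class `hill_result`: list with `n_h`, `x_intercept`,
#'   `kd` (uM, `= 10^x_intercept`), `n_points_used`, `r_squared`,
#'   `classification`.
#' @export
hill_fit <- function(points, window = 1.0, tol = 0.10) {
  d <- as.data.frame(points)
  cf_assert(all(c("log_conc", "log_theta") %in% names(d)),
            "points need columns log_conc and log_theta")
  sel <- abs(d$log_theta) <= window
  if (sum(sel) < 2L) {
    ord <- order(abs(d$log_theta))
    sel <- seq_len(nrow(d)) %in% ord[seq_len(min(4L, nrow(d)))]
  }
  d <- d[sel, , drop = FALSE]
  if (nrow(d) < 2L || length(unique(d$log_conc)) < 2L) {
    cf_stop("all selected Hill points share one concentration",
            "coopfit_singular_fit")
  }
  fit <- stats::lm(log_theta ~ log_conc, data = d)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  if (!is.finite(slope) || slope <= 0) {
    cf_stop("non-positive Hill slope: pathological fit", "coopfit_pathological_fit")
  }
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((d$log_theta - mean(d$log_theta))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  x_int <- -intercept / slope
  res <- structure(list(n_h = slope, x_intercept = x_int, kd = 10^x_int,
                        n_points_used = nrow(d), r_squared = r2,
                        classification = NA_character_),
                   class = "hill_result")
  res$classification <- classify_cooperativity(res, tol = tol)
  res
}

#' @export
print.hill_result <- function(x, ...) {
  cat(sprintf("Hill fit: n_H = %.4f, Kd = %.4g uM (%s; %d points, R2 = %.4f)\n",
              x$n_h, x$kd, x$classification, x$n_points_used, x$r_squared))
  invisible(x)
}

#' Classify binding cooperativity from the Hill coefficient
#'
#' `n_H < 1 - tol` is negative cooperativity, `n_H > 1 + tol` positive,
#' anything in between non-cooperative.
#'
#' @param result a `hill_result` or a numeric Hill coefficient.
#' @param tol classification dead band around 1 (default 0.10).
#' @return one of `"negative"`, `"non-cooperative"`, `"positive"`.
#' @export
classify_cooperativity <- function(result, tol = 0.10) {
  n_h <- if (inherits(result, "hill_result")) result$n_h else result
  cf_assert(is_scalar_number(n_h), "need a single finite Hill coefficient")
  if (n_h < 1 - tol) "negative"
  else if (n_h > 1 + tol) "positive"
  else "non-cooperative"
}

#' Full EMSA analysis pipeline
#'
#' Chains [band_table_to_saturation()], [hill_transform()] and [hill_fit()]:
#' band intensities to fractional saturation to Hill plot to Hill
#' coefficient, dissociation constant and cooperativity class.
#'
#' @param table a [band_table()].
#' @param window,tol passed to [hill_fit()].
#' @param eps passed to [hill_transform()].
#' @param saturation passed to [band_table_to_saturation()].
#' @return list with `curve` (saturation_curve), `points` (hill_points) and
#'   `result` (hill_result).
#' @export
analyze_emsa <- function(table, window = 1.0, tol = 0.10, eps = 1e-6,
                         saturation = c("any_bound", "per_site")) {
  curve <- band_table_to_saturation(table, saturation = saturation)
  points <- hill_transform(curve, eps = eps)
  result <- hill_fit(points, window = window, tol = tol)
  list(curve = curve, points = points, result = result)
}

#' Plot a saturation curve or Hill plot
#'
#' Base-graphics diagnostic plots: fractional saturation against
#' concentration (linear or semi-log x) with SEM bars when present.
#'
#' @param x a `saturation_curve`.
#' @param log_x plot concentration on a log axis (zero-concentration point
#'   dropped).
#' @param ... passed to [plot()].
#' @export
plot.saturation_curve <- function(x, log_x = FALSE, ...) {
  d <- as.data.frame(x)
  if (log_x) d <- d[d$concentration > 0, , drop = FALSE]
  graphics::plot(d$concentration, d$Y, xlab = "[protein] (uM)",
       ylab = "fractional saturation Y", ylim = c(0, 1),
       log = if (log_x) "x" else "", pch = 19, ...)
  has_sem <- is.finite(d$sem)
  if (any(has_sem)) {
    graphics::arrows(d$concentration[has_sem], d$Y[has_sem] - d$sem[has_sem],
                     d$concentration[has_sem], d$Y[has_sem] + d$sem[has_sem],
                     angle = 90, code = 3, length = 0.03)
  }
  invisible(x)
}

#' @rdname plot.saturation_curve
#' @export
plot.hill_points <- function(x, ...) {
  d <- as.data.frame(x)
  graphics::plot(d$log_conc, d$log_theta, xlab = "log10 [protein] (uM)",
       ylab = "log10 theta", pch = 19, ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}
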