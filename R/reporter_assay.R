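#' Kinetic beta-galactosidase plate read
#'
#' One well's kinetic OD420 series (colour development from ONPG cleavage)
#' plus the OD600 cell-density reading at the first time point, with optional
#' condition labels (promoter construct, antitoxin plasmid, IPTG induction).
#' The assay takes OD420 and OD600 readings every 90 s for 1 h; times here
#' are minutes.
#'
#' @param times numeric, minutes, strictly increasing, `>= 3` points.
#' @param od420 absorbance series, same length as `times`.
#' @param od600_first OD600 at the first time point, `> 0`.
#' @param well_id well identifier.
#' @param condition named list of condition labels (free-form).
#' @return object of class `kinetic_plate_read`.
#' @export
kinetic_plate_read <- function(times, od420, od600_first, well_id = "well",
                               condition = list()) {
  cf_assert(is.numeric(times) && length(times) >= 3L,
            "need at least 3 time points", "coopfit_insufficient_data")
  cf_assert(all(diff(times) > 0), "times must be strictly increasing")
  cf_assert(length(od420) == length(times), "od420 must match times")
  cf_assert(all(is.finite(times)) && all(is.finite(od420)),
            "series must be finite")
  if (!is_scalar_number(od600_first) || od600_first <= 0) {
    cf_stop("od600_first must be a single value > 0", "coopfit_input_error")
  }
  structure(list(well_id = well_id, times = times, od420 = od420,
                 od600_first = od600_first, condition = condition),
            class = "kinetic_plate_read")
}

#' Miller units from a kinetic read
#'
#' Converts a kinetic OD420 series into beta-galactosidase activity: the
#' OD420-versus-time slope (OD420/min, ordinary least squares over the full
#' series, or over `window = c(t_min, t_max)` minutes if given) is multiplied
#' by 5000 and divided by the OD600 reading from the first time point:
#' `mU = slope * 5000 / OD600_first`. A negative slope is returned as
#' computed and flagged (`negative_slope = TRUE`, with a warning) rather than
#' silently truncated.
#'
#' @param read a [kinetic_plate_read()].
#' @param window optional `c(t_min, t_max)` in minutes restricting the slope
#'   fit (e.g. to exclude late saturation); default uses the full series.
#' @return object of class `miller_result`: list with `mu` (Miller units),
#'   `slope` (OD420/min), `od600_first`, `well_id`, `condition`,
#'   `negative_slope`.
#' @export
miller_units <- function(read, window = NULL) {
  cf_assert(inherits(read, "kinetic_plate_read"),
            "read must be a kinetic_plate_read")
  t <- read$times
  y <- read$od420
  if (!is.null(window)) {
    cf_assert(length(window) == 2L && window[1] < window[2],
              "window must be c(t_min, t_max)")
    keep <- t >= window[1] & t <= window[2]
    t <- t[keep]; y <- y[keep]
    if (length(t) < 3L) {
      cf_stop("fewer than 3 points in the slope window",
              "coopfit_insufficient_data")
    }
  }
  slope <- unname(stats::coef(stats::lm(y ~ t))[2])
  mu <- slope * 5000 / read$od600_first
  neg <- slope < 0
  if (neg) warning("negative OD420 slope; Miller units returned as computed")
  structure(list(mu = mu, slope = slope, od600_first = read$od600_first,
                 well_id = read$well_id, condition = read$condition,
                 negative_slope = neg),
            class = "miller_result")
}

#' @export
print.miller_result <- function(x, ...) {
  cat(sprintf("%s: %.4g mU (slope %.4g OD420/min, OD600 %.3g)%s\n",
              x$well_id, x$mu, x$slope, x$od600_first,
              if (x$negative_slope) " [negative slope]" else ""))
  invisible(x)
}

#' Summarise replicate Miller results per condition label
#'
#' @param results list of `miller_result` objects.
#' @param labels character vector of condition labels, one per result.
#' @return data.frame with columns `label`, `mu` (mean), `sd`, `n`.
#' @export
aggregate_miller <- function(results, labels) {
  cf_assert(length(results) == length(labels),
            "one label per result is required")
  mus <- vapply(results, function(r) r$mu, numeric(1))
  out <- do.call(rbind, lapply(split(mus, labels), function(v) {
    data.frame(mu = mean(v), sd = if (length(v) > 1L) stats::sd(v) else 0,
               n = length(v))
  }))
  out <- data.frame(label = rownames(out), out, row.names = NULL)
  out[match(unique(labels), out$label), , drop = FALSE]
}

#' Normalise promoter activities to a control condition
#'
#' Divides each condition's mean Miller units by the control's, so the
#' control normalises to exactly 1. Uncertainty on the ratio is propagated by
#' the first-order delta method for a ratio of independent estimates:
#' `sd(r) = |r| * sqrt((sd_s / mu_s)^2 + (sd_c / mu_c)^2)` (the control row
#' itself is identically 1 with sd 0).
#'
#' @param activity data.frame with columns `label`, `mu` and optionally `sd`
#'   (as from [aggregate_miller()]).
#' @param control_label the label of the normalising control.
#' @return the data.frame with `normalized_mu` and `normalized_sd` appended.
#' @export
normalize_activity <- function(activity, control_label) {
  d <- as.data.frame(activity)
  cf_assert(all(c("label", "mu") %in% names(d)),
            "activity needs columns label and mu")
  if (is.null(d$sd)) d$sd <- 0
  i <- match(control_label, d$label)
  if (is.na(i)) cf_stop("control label not found", "coopfit_input_error")
  mu_c <- d$mu[i]
  if (mu_c == 0) cf_stop("control has zero Miller units",
                         "coopfit_degenerate_control")
  sd_c <- d$sd[i]
  r <- d$mu / mu_c
  # delta method for a ratio of independent estimates; at mu = 0 only the
  # numerator term survives
  sd_r <- ifelse(d$mu != 0,
                 abs(r) * sqrt((d$sd / d$mu)^2 + (sd_c / mu_c)^2),
                 d$sd / abs(mu_c))
  d$normalized_mu <- r
  d$normalized_sd <- sd_r
  d$normalized_mu[i] <- 1
  d$normalized_sd[i] <- 0
  d
}

#' Fold repression on induction
#'
#' Ratio of induced to uninduced promoter activity; values below 1 indicate
#' negative autoregulation (the induced repressor shuts its own promoter
#' down).
#'
#' @param induced,uninduced `miller_result` objects or numeric Miller units.
#' @return scalar fold repression.
#' @export
repression_ratio <- function(induced, uninduced) {
  mu_i <- if (inherits(induced, "miller_result")) induced$mu else induced
  mu_u <- if (inherits(uninduced, "miller_result")) uninduced$mu else uninduced
  cf_assert(is_scalar_number(mu_i) && is_scalar_number(mu_u),
            "need single Miller-unit values")
  if (mu_u <= 0) cf_stop("uninduced activity must be > 0",
                         "coopfit_input_error")
  mu_i / mu_u
}
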