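#' Equilibrium promoter-binding model
#'
#' Builds an equilibrium statistical-thermodynamic model of a repressor
#' binding `n` operator sites (1 <= n <= 8) on one promoter fragment. Each
#' site `i` has a dissociation constant `kd_i` (micromolar); occupancy of a
#' configuration `S` of sites carries the Boltzmann weight
#' `prod_{i in S} (c / kd_i) * prod_{i<j in S} omega_ij`, where `c` is the
#' free repressor concentration and `omega_ij` are optional pairwise coupling
#' factors. `omega = 1` (the default everywhere) means the sites bind
#' independently; `omega > 1` models positive cooperativity between a site
#' pair, `omega < 1` an anti-cooperative pair.
#'
#' The free-protein approximation is used throughout: the probe is assumed to
#' be present in trace amounts relative to the titrated protein, so the input
#' concentration is taken as the free concentration with no ligand-depletion
#' correction (the standard EMSA excess-protein assumption).
#'
#' @param kds numeric vector of per-site dissociation constants in uM, all
#'   positive. Names are used as site identifiers; unnamed sites are labelled
#'   `S1..Sn`. Order is the 5'-to-3' order of the sites on the promoter.
#' @param coupling optional coupling specification: either an `n x n`
#'   symmetric numeric matrix of pairwise factors (diagonal ignored), or a
#'   data.frame/list of records with fields `i`, `j` (site ids or indices)
#'   and `omega`. Unspecified pairs default to 1.
#' @return an object of class `promoter_model` with elements `site_ids`,
#'   `kds` (named numeric) and `omega` (full symmetric matrix).
#' @examples
#' m <- promoter_model(c(IR1 = 0.0205, IR2 = 0.862, IR3 = 11.0, IR4 = 0.121))
#' fractional_saturation(m, 0.5)
#' @export
promoter_model <- function(kds, coupling = NULL) {
  cf_assert(is.numeric(kds), "kds must be numeric")
  n <- length(kds)
  cf_assert(n <= 8L, "at most 8 sites are supported")
  if (n > 0L && (any(!is.finite(kds)) || any(kds <= 0))) {
    cf_stop("all dissociation constants must be finite and > 0",
            "coopfit_invalid_model")
  }
  ids <- names(kds)
  if (is.null(ids)) ids <- if (n > 0L) paste0("S", seq_len(n)) else character()
  cf_assert(!anyNA(ids) && !any(ids == "") && !anyDuplicated(ids),
            "site ids must be unique and non-empty")
  names(kds) <- ids

  omega <- matrix(1, n, n, dimnames = list(ids, ids))
  if (!is.null(coupling) && n > 0L) {
    if (is.matrix(coupling)) {
      cf_assert(all(dim(coupling) == c(n, n)),
                "coupling matrix must be n x n")
      cf_assert(isTRUE(all.equal(coupling, t(coupling))),
                "coupling matrix must be symmetric")
      omega[] <- coupling
      diag(omega) <- 1
    } else {
      recs <- if (is.data.frame(coupling)) {
        lapply(seq_len(nrow(coupling)), function(r) as.list(coupling[r, ]))
      } else coupling
      for (rec in recs) {
        i <- .site_index(rec$i, ids)
        j <- .site_index(rec$j, ids)
        cf_assert(i != j, "coupling requires two distinct sites")
        w <- rec$omega
        cf_assert(is_scalar_number(w) && w > 0, "omega must be a positive number")
        omega[i, j] <- w
        omega[j, i] <- w
      }
    }
    if (any(omega <= 0) || any(!is.finite(omega))) {
      cf_stop("coupling factors must be finite and > 0", "coopfit_invalid_model")
    }
  }
  structure(list(site_ids = ids, kds = kds, omega = omega),
            class = "promoter_model")
}

.site_index <- function(x, ids) {
  if (is.character(x)) {
    k <- match(x, ids)
    cf_assert(!is.na(k), paste0("unknown site id: ", x))
    return(k)
  }
  k <- as.integer(x)
  cf_assert(!is.na(k) && k >= 1L && k <= length(ids), "site index out of range")
  k
}

#' @export
print.promoter_model <- function(x, ...) {
  n <- length(x$kds)
  cat("Promoter binding model:", n, "site(s)\n")
  if (n > 0L) {
    print(x$kds)
    if (any(x$omega[upper.tri(x$omega)] != 1)) {
      cat("with pairwise coupling factors != 1\n")
    }
  }
  invisible(x)
}

#' The four-operator promoter model with the measured per-repeat affinities
#'
#' Convenience constructor for the Rv2827c autoregulation promoter
#' (P_rv2827c), which carries four 23-bp inverted-repeat operators in tandem
#' (IR1, IR2 upstream; IR3, IR4 over the core promoter). The per-repeat
#' dissociation constants measured by single-site EMSA titrations with polyC
#' mutant probes are IR1 = 0.0205 uM, IR4 = 0.121 uM, IR2 = 0.862 uM and
#' IR3 = 11.0 uM; the wide affinity spread produces an ordered series of
#' binding events and an apparent Hill coefficient below 1 (negative
#' apparent cooperativity) even though the sites are modelled as independent.
#'
#' @return a `promoter_model` with sites IR1..IR4 in promoter order and
#'   `omega = 1` everywhere.
#' @export
rv2827c_promoter_model <- function() {
  promoter_model(c(IR1 = 0.0205, IR2 = 0.862, IR3 = 11.0, IR4 = 0.121))
}

.check_model <- function(model) {
  cf_assert(inherits(model, "promoter_model"),
            "model must be a promoter_model")
  if (length(model$kds) > 0L && any(model$kds <= 0)) {
    cf_stop("model has non-positive kd", "coopfit_invalid_model")
  }
  invisible(model)
}

.check_conc <- function(conc) {
  cf_assert(is.numeric(conc) && length(conc) == 1L && is.finite(conc),
            "conc must be a single finite number")
  if (conc < 0) cf_stop("concentration must be >= 0", "coopfit_domain_error")
  invisible(conc)
}

# 2^n x n matrix of occupancy flags, site 1 varying fastest; row order is
# fixed so outputs are deterministic.
.configs <- function(n) {
  if (n == 0L) return(matrix(integer(), 1L, 0L))
  as.matrix(expand.grid(rep(list(0:1), n), KEEP.OUT.ATTRS = FALSE))
}

#' Equilibrium distribution over binding configurations
#'
#' Enumerates all `2^n` occupancy configurations of the model's sites at a
#' given free protein concentration and returns their equilibrium
#' probabilities. The weight of configuration `S` is
#' `prod_{i in S}(conc/kd_i) * prod_{i<j in S} omega_ij`, normalised over the
#' exhaustive enumeration, so probabilities sum to 1.
#'
#' @param model a [promoter_model()].
#' @param conc free protein concentration, uM, `>= 0`.
#' @return object of class `configuration_distribution`: list with `configs`
#'   (2^n x n 0/1 matrix, columns named by site), `prob` (probabilities
#'   summing to 1), `concentration`.
#' @export
configuration_distribution <- function(model, conc) {
  .check_model(model)
  .check_conc(conc)
  n <- length(model$kds)
  configs <- .configs(n)
  m <- nrow(configs)
  ratio <- if (n > 0L) conc / model$kds else numeric()
  w <- numeric(m)
  has_coupling <- n > 1L && any(model$omega[upper.tri(model$omega)] != 1)
  for (r in seq_len(m)) {
    s <- which(configs[r, ] == 1L)
    wr <- prod(ratio[s])
    if (has_coupling && length(s) > 1L) {
      om <- model$omega[s, s, drop = FALSE]
      wr <- wr * prod(om[upper.tri(om)])
    }
    w[r] <- wr
  }
  prob <- w / sum(w)
  colnames(configs) <- model$site_ids
  structure(list(configs = configs, prob = prob, concentration = conc),
            class = "configuration_distribution")
}

#' Distribution of the number of sites bound (band species)
#'
#' Marginalises [configuration_distribution()] over the count of occupied
#' sites. On a native EMSA gel each count `k = 0..n` migrates as one band
#' species, so this is the predicted distribution of band intensities at a
#' given concentration. With all coupling factors equal to 1 it is the
#' Poisson-binomial distribution of independent per-site occupancies
#' `p_i = conc / (conc + kd_i)`.
#'
#' @inheritParams configuration_distribution
#' @return object of class `band_distribution`: list with `probs` (named
#'   `"0".."n"`, summing to 1) and `concentration`.
#' @export
band_distribution <- function(model, conc) {
  cd <- configuration_distribution(model, conc)
  n <- ncol(cd$configs)
  k <- if (n > 0L) rowSums(cd$configs) else 0L
  probs <- vapply(0:n, function(i) sum(cd$prob[k == i]), numeric(1))
  names(probs) <- as.character(0:n)
  structure(list(probs = probs, concentration = conc),
            class = "band_distribution")
}

#' Fractional saturation of the promoter
#'
#' Mean fraction of sites occupied, `Y = E[k] / n`, computed from the band
#' distribution. `Y(0) = 0`, `Y` is strictly increasing in concentration and
#' tends to 1 as concentration grows. A zero-site model returns 0.
#'
#' @inheritParams configuration_distribution
#' @return scalar `Y` in `[0, 1]`.
#' @export
fractional_saturation <- function(model, conc) {
  bd <- band_distribution(model, conc)
  n <- length(bd$probs) - 1L
  if (n == 0L) return(0)
  sum(seq(0L, n) * bd$probs) / n
}

#' Apparent Hill coefficient of a binding model
#'
#' The Hill coefficient is the slope of the Hill plot,
#' `log10(Y / (1 - Y))` versus `log10(conc)`, evaluated at half saturation
#' (`Y = 0.5`, i.e. `log theta = 0`). The half-saturation concentration is
#' located by bisection on log-concentration (tolerance 1e-10 in `Y`;
#' bracketing is guaranteed because `Y` is continuous and strictly monotone),
#' and the slope is taken by a central finite difference with a relative step
#' of 1e-4 in log-space.
#'
#' Independent identical sites give exactly 1; strong positive coupling
#' drives the value towards `n`; independent sites with widely differing
#' affinities give a value below 1 — apparent negative cooperativity arising
#' purely from affinity heterogeneity.
#'
#' @param model a [promoter_model()] with at least one site.
#' @return the dimensionless apparent Hill coefficient.
#' @export
apparent_hill_coefficient <- function(model) {
  .check_model(model)
  n <- length(model$kds)
  cf_assert(n >= 1L, "model must have at least one site",
            class = "coopfit_invalid_model")
  f <- function(lc) fractional_saturation(model, 10^lc)
  lo <- log10(min(model$kds)) - 4
  hi <- log10(max(model$kds)) + 4
  # expand bracket defensively (coupling can shift the midpoint)
  while (f(lo) > 0.5) lo <- lo - 2
  while (f(hi) < 0.5) hi <- hi + 2
  for (iter in seq_len(400L)) {
    mid <- (lo + hi) / 2
    y <- f(mid)
    if (abs(y - 0.5) < 1e-10) break
    if (y < 0.5) lo <- mid else hi <- mid
  }
  x <- (lo + hi) / 2
  dx <- 1e-4 * max(1, abs(x))
  ltheta <- function(lc) {
    y <- f(lc)
    log10(y / (1 - y))
  }
  (ltheta(x + dx) - ltheta(x - dx)) / (2 * dx)
}

# ---- Kd fitting ------------------------------------------------------------

.fit_result <- function(kds, residual, n_evaluations) {
  structure(list(kds = sort(unname(kds)), residual = residual,
                 n_evaluations = n_evaluations),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Kd fit:", paste(signif(x$kds, 6), collapse = ", "), "uM; SSR =",
      format(x$residual, digits = 4), "\n")
  invisible(x)
}

#' Fit a single-site binding isotherm
#'
#' Least-squares fit of the hyperbolic isotherm `Y = conc / (conc + Kd)` to a
#' saturation curve, with `Kd` parameterised on a log10 scale. Optimisation is
#' deterministic: a log-spaced grid of starting values (5 per decade spanning
#' the observed concentration range, widened by two decades each side) is
#' refined by `nlminb`; ties are broken by lowest residual then lowest `Kd`.
#'
#' @param curve a [saturation_curve()] or data.frame with columns
#'   `concentration` (uM) and `Y`.
#' @return a `fit_result` with the recovered `kds` (length 1), the residual
#'   sum of squares and the number of objective evaluations.
#' @export
fit_single_site <- function(curve) {
  d <- as.data.frame(curve)
  cf_assert(all(c("concentration", "Y") %in% names(d)),
            "curve needs columns concentration and Y")
  cf_assert(all(d$concentration >= 0), "concentrations must be >= 0")
  interior <- d$Y > 0 & d$Y < 1
  if (sum(interior) < 3L) {
    cf_stop("need at least 3 points with 0 < Y < 1 to identify Kd",
            "coopfit_nonidentifiable")
  }
  conc <- d$concentration
  y <- d$Y
  ssq <- function(lk) {
    kd <- 10^lk
    sum((y - conc / (conc + kd))^2)
  }
  cpos <- conc[conc > 0]
  lo <- log10(min(cpos)) - 2
  hi <- log10(max(cpos)) + 2
  starts <- seq(lo, hi, by = 0.2)
  n_eval <- 0L
  best <- NULL
  for (s in starts) {
    fit <- stats::nlminb(s, ssq, lower = lo - 4, upper = hi + 4,
                         control = list(abs.tol = 0, rel.tol = 1e-14,
                                        x.tol = 1e-14))
    n_eval <- n_eval + fit$evaluations[["function"]]
    cand <- list(lk = fit$par, obj = fit$objective)
    if (is.null(best) || cand$obj < best$obj - 1e-15 ||
        (abs(cand$obj - best$obj) <= 1e-15 && cand$lk < best$lk)) {
      best <- cand
    }
  }
  .fit_result(10^best$lk, best$obj, n_eval)
}

#' Fit per-site dissociation constants from a multi-band titration
#'
#' Global least-squares fit of the independent-site band-count model
#' (coupling fixed at 1) to the observed band fractions of an EMSA band
#' table: for every lane the `n_sites + 1` observed band fractions are
#' compared with [band_distribution()] predictions, and the per-site `Kd`s
#' (log10-parameterised) are refined by Levenberg-Marquardt least squares
#' from a deterministic set of spread-pattern starts. The recovered `Kd`s are
#' reported sorted ascending (the likelihood is invariant to permutation of
#' independent sites).
#'
#' @param table a [band_table()] whose lanes have `n_sites + 1` band columns.
#' @param n_sites number of operator sites to fit.
#' @return a `fit_result` with `n_sites` recovered `kds` (uM, ascending).
#' @export
fit_multisite <- function(table, n_sites) {
  tab <- as.data.frame(table)
  band_cols <- grep("^band_", names(tab), value = TRUE)
  cf_assert(length(band_cols) == n_sites + 1L,
            paste0("band table must have n_sites + 1 = ", n_sites + 1L,
                   " band columns"))
  conc <- tab$conc
  if (length(unique(conc)) < 2L * n_sites) {
    cf_stop("need at least 2 * n_sites distinct concentrations",
            "coopfit_nonidentifiable")
  }
  intens <- as.matrix(tab[band_cols])
  totals <- rowSums(intens)
  cf_assert(all(totals > 0), "every lane needs positive total intensity",
            class = "coopfit_empty_lane")
  frac <- intens / totals

  resid_fn <- function(lk) {
    m <- promoter_model(10^lk)
    pred <- t(vapply(conc, function(cc) band_distribution(m, cc)$probs,
                     numeric(n_sites + 1L)))
    as.vector(frac - pred)
  }

  cpos <- conc[conc > 0]
  lo <- log10(min(cpos)) - 1
  hi <- log10(max(cpos)) + 1
  ctr <- (lo + hi) / 2
  spread <- function(width) {
    if (n_sites == 1L) return(ctr)
    seq(ctr - width / 2, ctr + width / 2, length.out = n_sites)
  }
  starts <- list(spread(hi - lo), spread((hi - lo) / 2),
                 spread((hi - lo) / 4), rep(ctr, n_sites))
  n_eval <- 0L
  best <- NULL
  for (st in starts) {
    fit <- minpack.lm::nls.lm(
      par = st, fn = resid_fn,
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                           ptol = 1e-15))
    n_eval <- n_eval + fit$niter
    obj <- sum(fit$fvec^2)
    kds <- sort(10^fit$par)
    better <- is.null(best) || obj < best$obj - 1e-15 ||
      (abs(obj - best$obj) <= 1e-15 &&
         isTRUE(all(kds <= best$kds)) && any(kds < best$kds))
    if (better) best <- list(kds = kds, obj = obj)
  }
  .fit_result(best$kds, best$obj, n_eval)
}
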