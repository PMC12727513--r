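#' Enzyme kinetics and stability analysis
#'
#' Michaelis-Menten and two-pKa nonlinear fits with deterministic
#' initialization, rate-acceleration and fold-change arithmetic with
#' explicit unit tags, kinetic-resolution selectivity relations, and the
#' OLS stability regression on computational design metrics.
#'
#' All rates are stored internally in s^-1 and concentrations in mol/L;
#' every interface that accepts a rate takes an explicit unit tag.
#'
#' @name evaluate-kinetics
NULL

.rate_to_per_s <- function(x, unit) {
  if (missing(unit) || is.null(unit) || is.na(unit)) {
    stop("rate unit must be declared ('per_s' or 'per_min')")
  }
  switch(unit,
         per_s = x,
         per_min = x / 60,
         stop("unknown rate unit: ", unit))
}

#' Kinetics record
#'
#' @param kcat turnover rate constant
#' @param km Michaelis constant (mol/L)
#' @param kcat_unit,kuncat_unit `"per_s"` or `"per_min"`
#' @param kuncat uncatalysed background rate constant; the default is the
#'   literature retro-aldol background rate 3.9e-7 min^-1
#' @return list with all rates in s^-1 plus `efficiency` (kcat/km, 1/(M s))
#' @export
kinetics_record <- function(kcat, km, kcat_unit = "per_s",
                            kuncat = 3.9e-7, kuncat_unit = "per_min") {
  kcat_s <- .rate_to_per_s(kcat, kcat_unit)
  kuncat_s <- .rate_to_per_s(kuncat, kuncat_unit)
  stopifnot(kcat_s > 0, km > 0, kuncat_s > 0)
  list(kcat = kcat_s, km = km, kuncat = kuncat_s,
       efficiency = kcat_s / km)
}

#' Fit the Michaelis-Menten model
#'
#' Nonlinear least squares of `v = kcat * S / (km + S)` with deterministic
#' initialization `kcat0 = max(v)`, `km0 = median(S)`.
#'
#' @param s_conc substrate concentrations (mol/L), >= 3 distinct values
#' @param v rates (s^-1 per enzyme)
#' @return list with `kcat`, `km`, `covariance` (2x2), `fitted`
#' @export
fit_michaelis_menten <- function(s_conc, v) {
  stopifnot(length(s_conc) == length(v))
  if (length(unique(s_conc)) < 3) stop("need >= 3 distinct concentrations")
  if (any(s_conc <= 0) || any(v < 0)) stop("concentrations and rates must be positive")
  df <- data.frame(S = s_conc, v = v)
  start <- list(kcat = max(v), km = stats::median(s_conc))
  # strict tolerance first (exact-recovery cases), relaxed retry for noisy data
  fit <- tryCatch(
    stats::nls(v ~ kcat * S / (km + S), data = df, start = start,
               control = stats::nls.control(maxiter = 500, warnOnly = FALSE,
                                            scaleOffset = 1, tol = 1e-10,
                                            minFactor = 1e-10)),
    error = function(e) tryCatch(
      stats::nls(v ~ kcat * S / (km + S), data = df, start = start,
                 control = stats::nls.control(maxiter = 500,
                                              scaleOffset = 1)),
      error = function(e2) {
        stop("Michaelis-Menten fit did not converge: ", conditionMessage(e2),
             " (n = ", nrow(df), ", v range ", min(v), "-", max(v), ")")
      }))
  cf <- stats::coef(fit)
  list(kcat = unname(cf["kcat"]), km = unname(cf["km"]),
       covariance = tryCatch(stats::vcov(fit), error = function(e) matrix(NA, 2, 2)),
       fitted = stats::fitted(fit))
}

#' Rate acceleration over the uncatalysed reaction
#'
#' @param kcat catalysed rate constant
#' @param kuncat uncatalysed rate constant
#' @param kcat_unit,kuncat_unit unit tags (`"per_s"` / `"per_min"`), required
#' @return kcat / kuncat (unitless fold)
#' @export
rate_acceleration <- function(kcat, kuncat, kcat_unit, kuncat_unit) {
  a <- .rate_to_per_s(kcat, kcat_unit)
  b <- .rate_to_per_s(kuncat, kuncat_unit)
  stopifnot(a > 0, b > 0)
  a / b
}

#' Fold change between two rate constants
#' @param kcat_a,kcat_b rate constants (same units)
#' @param unit_a,unit_b unit tags; must agree
#' @export
fold_change <- function(kcat_a, kcat_b, unit_a = "per_s", unit_b = unit_a) {
  if (!identical(unit_a, unit_b)) {
    stop("unit mismatch: ", unit_a, " vs ", unit_b)
  }
  stopifnot(kcat_a > 0, kcat_b > 0)
  kcat_a / kcat_b
}

## E as a function of ee_substrate / ee_product at conversion c
## (log1p forms avoid cancellation when the log argument is near 1)
.E_from_ees <- function(c, ees) {
  log((1 - c) * (1 - ees)) / log1p((1 - c) * ees - c)
}
.E_from_eep <- function(c, eep) {
  log1p(-(c + c * eep)) / log1p(-c * (1 - eep))
}

#' Kinetic-resolution selectivity relations
#'
#' Standard irreversible kinetic resolution of a racemate with selectivity
#' factor E (ratio of the specificity constants for the two enantiomers).
#' At the low-conversion limit `ee_product = (E - 1)/(E + 1)`; at finite
#' conversion c the enantiomeric excesses solve
#' `E = ln[(1-c)(1-ee_s)] / ln[(1-c)(1+ee_s)]
#'    = ln[1-c(1+ee_p)] / ln[1-c(1-ee_p)]`
#' (bracketed root finding, tolerance 1e-10). `E = Inf` is handled by mass
#' balance (only the fast enantiomer is consumed).
#'
#' @param e_value selectivity factor E (>= 1; Inf allowed)
#' @param conversion fraction converted, in [0, 1); 0 gives the
#'   low-conversion limit
#' @return list (`SelectivityRecord`): `e_value`, `conversion`,
#'   `ee_product`, `ee_substrate`
#' @export
selectivity_relations <- function(e_value, conversion = 0) {
  if (e_value < 1) stop("E-value must be >= 1")
  stopifnot(conversion >= 0, conversion < 1)
  c <- conversion
  if (is.infinite(e_value)) {
    eep <- 1
    ees <- if (c == 0) 0 else min(1, c / (1 - c))
    return(list(e_value = e_value, conversion = c, ee_product = eep,
                ee_substrate = ees))
  }
  if (e_value == 1) {
    return(list(e_value = 1, conversion = c, ee_product = 0, ee_substrate = 0))
  }
  eep_lim <- (e_value - 1) / (e_value + 1)
  if (c == 0) {
    return(list(e_value = e_value, conversion = 0, ee_product = eep_lim,
                ee_substrate = 0))
  }
  eps <- 1e-12
  # product ee: solve in v = 1 - c(1 + ee_p) on a log scale; v spans
  # (max(1-2c, 0), 1-c), the relation diverges as v -> max(1-2c, 0)+ and
  # equals 1 at v = 1-c, so the bracket always closes
  v_min <- max(if (c < 0.5) (1 - 2 * c) * (1 + 1e-14) else 0, 1e-300)
  f_pv <- function(t) t / log1p((1 - 2 * c) - exp(t)) - e_value
  t_lo <- log(v_min); t_hi <- log((1 - c) * (1 - 1e-14))
  v <- if (f_pv(t_lo) <= 0) v_min else {
    exp(stats::uniroot(f_pv, lower = t_lo, upper = t_hi, tol = 1e-14)$root)
  }
  eep <- min(1, (1 - c - v) / c)
  # substrate ee: solve in u = 1 - ee_s on a log scale for precision near
  # ee_s -> 1; mass balance caps ee_s at c/(1-c) (u_min below)
  u_min <- if (c < 0.5) (1 - 2 * c) / (1 - c) * (1 + 1e-14) else 1e-300
  u_min <- max(u_min, 1e-300)
  f_s <- function(t) {
    u <- exp(t)
    (log1p(-c) + t) / log1p((1 - 2 * c) - (1 - c) * u) - e_value
  }
  t_lo <- log(u_min)
  ees <- if (f_s(t_lo) <= 0) {
    1 - u_min  # ee underflows toward the mass-balance cap in doubles
  } else {
    1 - exp(stats::uniroot(f_s, lower = t_lo, upper = 0, tol = 1e-14)$root)
  }
  list(e_value = e_value, conversion = c, ee_product = eep,
       ee_substrate = ees)
}

#' Selectivity factor E from measured conversion and ee
#'
#' Inverse of [selectivity_relations()].
#'
#' @param conversion fraction in (0, 1)
#' @param ee enantiomeric excess in (0, 1)
#' @param type whether `ee` is of the remaining substrate or the product
#' @return E-value
#' @export
e_value_from_ee <- function(conversion, ee, type = c("substrate", "product")) {
  type <- match.arg(type)
  stopifnot(conversion > 0, conversion < 1, ee >= 0, ee <= 1)
  if (ee == 0) return(1)
  if (ee >= 1) return(Inf)  # underflowed toward the mass-balance cap
  if (type == "substrate") .E_from_ees(conversion, ee)
  else .E_from_eep(conversion, ee)
}

#' Fit a two-pKa bell-shaped pH-rate profile
#'
#' Least squares of `rate(pH) = rate_max / (1 + 10^(pKa1 - pH) + 10^(pH - pKa2))`,
#' initialized deterministically from the curve maximum and the half-maximum
#' crossings. Single-limb data (no descending limb) triggers a warning and
#' `pka2 = Inf` from a one-pKa fit.
#'
#' @param ph pH values (>= 5 points)
#' @param rate rates (any consistent unit)
#' @return list (`TwoPkaFit`): `pka1`, `pka2`, `rate_max`
#' @export
fit_two_pka <- function(ph, rate) {
  stopifnot(length(ph) == length(rate))
  if (length(ph) < 5) stop("need >= 5 pH points")
  ord <- order(ph)
  ph <- ph[ord]; rate <- rate[ord]
  imax <- which.max(rate)
  half <- max(rate) / 2
  cross_lo <- if (imax > 1) {
    i <- max(which(rate[seq_len(imax)] <= half), 0)
    if (i >= 1) stats::approx(rate[c(i, i + 1)], ph[c(i, i + 1)], xout = half)$y
    else ph[1]
  } else ph[1]
  descending <- imax < length(ph) && min(rate[imax:length(ph)]) < 0.8 * max(rate)
  df <- data.frame(ph = ph, rate = rate)
  if (!descending) {
    warning("no descending limb in pH profile; pKa2 unbounded")
    fit <- stats::nls(rate ~ rmax / (1 + 10^(pka1 - ph)), data = df,
                      start = list(rmax = max(rate), pka1 = cross_lo),
                      control = stats::nls.control(scaleOffset = 1))
    cf <- stats::coef(fit)
    return(list(pka1 = unname(cf["pka1"]), pka2 = Inf,
                rate_max = unname(cf["rmax"])))
  }
  i2 <- imax - 1 + max(which(rate[imax:length(ph)] > half))
  cross_hi <- if (i2 < length(ph)) {
    stats::approx(rate[c(i2, i2 + 1)], ph[c(i2, i2 + 1)], xout = half)$y
  } else ph[length(ph)]
  start <- list(rmax = max(rate), pka1 = cross_lo, pka2 = cross_hi)
  fml <- rate ~ rmax / (1 + 10^(pka1 - ph) + 10^(ph - pka2))
  fit <- tryCatch(
    stats::nls(fml, data = df, start = start,
               control = stats::nls.control(maxiter = 500, scaleOffset = 1,
                                            tol = 1e-10, minFactor = 1e-10)),
    error = function(e) stats::nls(fml, data = df, start = start,
                                   control = stats::nls.control(
                                     maxiter = 500, scaleOffset = 1)))
  cf <- stats::coef(fit)
  out <- list(pka1 = unname(cf["pka1"]), pka2 = unname(cf["pka2"]),
              rate_max = unname(cf["rmax"]))
  if (out$pka1 >= out$pka2) warning("fitted pKa1 >= pKa2; limbs overlap")
  out
}

#' OLS stability regression on computational design metrics
#'
#' Ordinary least squares predicting chemical denaturation midpoints from
#' the four standard design metrics: relax energy total, mean prediction
#' confidence (pLDDT), SAP total and core contact density.
#'
#' @param table data.frame with columns `energy_total`, `plddt_avg`,
#'   `sap_total`, `core_contacts` and `midpoint` (M GdnHCl)
#' @param predictors predictor column names
#' @return list (`StabilityModel`): `coefficients`, `intercept`, `fit_r`
#'   (Pearson correlation of fitted vs observed), `lm` (the underlying fit)
#' @export
fit_stability_model <- function(table,
                                predictors = c("energy_total", "plddt_avg",
                                               "sap_total", "core_contacts")) {
  need <- c(predictors, "midpoint")
  miss <- setdiff(need, names(table))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (anyNA(table[, need])) stop("missing values in stability table")
  if (nrow(table) < length(predictors) + 2) {
    stop("need at least p + 2 rows for p predictors")
  }
  fml <- stats::as.formula(paste("midpoint ~", paste(predictors, collapse = " + ")))
  fit <- stats::lm(fml, data = table)
  al <- stats::alias(fit)$Complete
  if (!is.null(al)) {
    stop("rank-deficient design matrix; collinear column(s): ",
         paste(rownames(al), collapse = ", "))
  }
  cf <- stats::coef(fit)
  list(coefficients = cf[predictors], intercept = unname(cf["(Intercept)"]),
       fit_r = stats::cor(stats::fitted(fit), table$midpoint), lm = fit)
}

#' Predict denaturation midpoints from a stability model
#' @param model from [fit_stability_model()]
#' @param newdata data.frame with the predictor columns
#' @export
predict_stability <- function(model, newdata) {
  as.numeric(stats::predict(model$lm, newdata = newdata))
}

#' Pearson and Spearman correlation of a metric with activity
#' @param x,y numeric vectors
#' @return list with `pearson` and `spearman`
#' @export
cor_report <- function(x, y) {
  list(pearson = stats::cor(x, y, method = "pearson"),
       spearman = stats::cor(x, y, method = "spearman"))
}
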