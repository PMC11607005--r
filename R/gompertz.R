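#' Gompertz cumulative-hazard kernel
#'
#' Computes \eqn{(e^{b t} - 1)/b} with a series expansion below
#' `|b| < 1e-8` so the likelihood stays smooth through `b = 0`.
#'
#' @param t time since the age origin (years, nonnegative).
#' @param b Gompertz slope (per year).
#' @return numeric vector, same length as `t`.
#' @keywords internal
#' @noRd
gompertz_He <- function(t, b) {
  if (abs(b) < 1e-8) {
    t * (1 + b * t / 2 + b^2 * t^2 / 6)
  } else {
    expm1(b * t) / b
  }
}

# d/db of gompertz_He, needed for the analytic score in b.
gompertz_dHe <- function(t, b) {
  if (abs(b) < 1e-8) {
    t^2 / 2 + b * t^3 / 3 + b^2 * t^4 / 8
  } else {
    (exp(b * t) * (b * t - 1) + 1) / b^2
  }
}

#' Gompertz proportional-hazard survival function
#'
#' Survival from the age origin to age `x` under the hazard
#' \eqn{h(x) = a_0 e^{b_0 (x - \mathrm{origin})} e^{\beta Z}}:
#' \deqn{S(x) = \exp\{-(a_0 e^{\beta Z}/b_0)(e^{b_0 (x-\mathrm{origin})} - 1)\}.}
#' At `b0 = 0` the exponential limit
#' \eqn{\exp\{-a_0 e^{\beta Z}(x - \mathrm{origin})\}} is used; the function
#' is continuous in `b0` at 0.
#'
#' @param x age (years), `x >= origin`. Vectorized.
#' @param a0 baseline hazard level at the origin (per year, > 0).
#' @param b0 log-rate of hazard increase (per year).
#' @param bz linear predictor \eqn{\beta Z} (log hazard ratio), default 0.
#' @param origin age origin (years), default 65.
#' @return survival probabilities in (0, 1].
#' @examples
#' gompertz_survival(75, a0 = 0.02, b0 = 0)  # exp(-0.2)
#' @export
gompertz_survival <- function(x, a0, b0, bz = 0, origin = 65) {
  stopifnot(is.numeric(x), length(a0) == 1, length(b0) == 1)
  if (!is.finite(a0) || a0 <= 0) stop("`a0` must be a positive finite number")
  if (any(x < origin)) stop("`x` must be >= the age origin (", origin, ")")
  exp(-a0 * exp(bz) * gompertz_He(x - origin, b0))
}

# log survival on the time-since-origin scale; bz may be a vector.
gompertz_logS <- function(t, a0, b0, bz = 0) {
  -a0 * exp(bz) * gompertz_He(t, b0)
}

# log hazard on the time-since-origin scale.
gompertz_logh <- function(t, a0, b0, bz = 0) {
  log(a0) + b0 * t + bz
}

#' Draw death ages from a Gompertz proportional-hazard model
#'
#' Inverse-CDF sampling of the time to death measured from `origin`; the
#' returned value is `origin + T`. With `b0 = 0` the draws are
#' Exponential with rate `a0 * exp(bz)` beyond the origin.
#'
#' @param n number of draws.
#' @param a0,b0 Gompertz baseline level and slope (`a0 > 0`, `b0 >= 0`).
#' @param bz linear predictor \eqn{\beta Z}; scalar or length-`n` vector.
#' @param origin age origin (years), default 65.
#' @return numeric vector of `n` continuous death ages.
#' @export
simulate_death_age <- function(n, a0, b0, bz = 0, origin = 65) {
  if (!is.finite(a0) || a0 <= 0) stop("`a0` must be a positive finite number")
  if (b0 < 0) stop("`b0` must be nonnegative for sampling (defective distribution otherwise)")
  u <- stats::runif(n)
  e <- -log(u) / (a0 * exp(bz))       # He(T) = e
  t <- if (abs(b0) < 1e-12) e else log1p(b0 * e) / b0
  origin + t
}

#' Per-record death observations for the truncated likelihood
#'
#' Converts truncated person records to the observation table the
#' likelihood consumes. Integer recorded death ages are treated as
#' mid-year events (`x = death_age + 0.5`); each record's observable age
#' window is derived from its birth year and the calendar window as
#' `L = max(origin, death_year_min - birth_year - 0.5)` and
#' `U = death_year_max - birth_year + 0.5`, the half-year adjustments
#' matching the continuity correction.
#'
#' @param records tibble of person records (see [generate_cohort()]).
#' @param window a [truncation_window()].
#' @param covariates character vector of record columns to use as
#'   covariates (numeric or logical), default `"foreign_born"`.
#' @param origin age origin the hazard is measured from, default the
#'   window's minimum death age. The observability windows always use the
#'   window's age floor, so shifting `origin` only reparameterizes the
#'   model.
#' @return tibble with columns `x`, `L`, `U`, `weight`, and one column per
#'   covariate.
#' @export
death_observations <- function(records, window, covariates = "foreign_born",
                               origin = window$min_death_age) {
  stopifnot(all(c("death_age", "birth_year") %in% names(records)))
  missing_cov <- setdiff(covariates, names(records))
  if (length(missing_cov) > 0) {
    stop("covariate column(s) not in records: ", paste(missing_cov, collapse = ", "))
  }
  obs <- tibble::tibble(
    x = records$death_age + 0.5,
    L = pmax(window$min_death_age,
             window$death_year_min - records$birth_year - 0.5),
    U = window$death_year_max - records$birth_year + 0.5,
    weight = if ("weight" %in% names(records)) records$weight else rep(1, nrow(records))
  )
  for (cv in covariates) obs[[cv]] <- as.numeric(records[[cv]])
  bad <- which(obs$x < obs$L | obs$x > obs$U)
  if (length(bad) > 0) {
    stop("record(s) outside their observable window (mis-filtered?): rows ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  attr(obs, "origin") <- origin
  obs
}

#' Weighted log-likelihood of doubly truncated Gompertz death ages
#'
#' For each observation the density of age at death is conditioned on the
#' death falling inside the record's observable window `[L, U]`:
#' \deqn{\ell = \sum_i w_i [\log h(x_i) + \log S(x_i) - \log\{S(L_i) - S(U_i)\}].}
#' The denominator is evaluated in log space
#' (`log S(L) + log1p(-exp(log S(U) - log S(L)))`) for stability when the
#' window captures little probability mass.
#'
#' @param params list or numeric with elements/names `a0`, `b0`, and
#'   optionally `beta` (coefficient vector matching the covariate columns
#'   of `obs`).
#' @param obs observation table from [death_observations()], or any tibble
#'   with columns `x`, `L`, `U`, `weight`, plus covariate columns.
#' @param origin age origin; defaults to the origin recorded on `obs`.
#' @return the scalar log-likelihood.
#' @export
truncated_loglik <- function(params, obs, origin = attr(obs, "origin") %||% 65) {
  a0 <- params$a0
  b0 <- params$b0
  beta <- params$beta %||% numeric(0)
  if (!is.finite(a0) || a0 <= 0) stop("`a0` must be a positive finite number")
  covs <- setdiff(names(obs), c("x", "L", "U", "weight"))
  if (length(beta) != length(covs)) {
    stop("length(beta) (", length(beta), ") != number of covariate columns (",
         length(covs), ")")
  }
  bz <- if (length(covs) > 0) {
    as.matrix(obs[covs]) %*% beta
  } else {
    rep(0, nrow(obs))
  }
  bz <- as.numeric(bz)
  t  <- obs$x - origin
  tl <- obs$L - origin
  tu <- obs$U - origin
  logS_L <- gompertz_logS(tl, a0, b0, bz)
  logS_U <- ifelse(is.infinite(tu), -Inf, gompertz_logS(tu, a0, b0, bz))
  dlt <- logS_U - logS_L                     # <= 0
  if (any(dlt > -.Machine$double.eps)) {
    bad <- which(dlt > -.Machine$double.eps)[1]
    stop("observable window carries no probability mass (S(L) == S(U) to machine ",
         "precision) for record ", bad)
  }
  log_denom <- logS_L + log1p(-exp(dlt))
  ll <- gompertz_logh(t, a0, b0, bz) + gompertz_logS(t, a0, b0, bz) - log_denom
  sum(obs$weight * ll)
}

# Negative log-likelihood and analytic gradient in the working
# parameterization theta = (log a0, b0, beta). Written for optim().
trunc_nll_gr <- function(obs, origin) {
  covs <- setdiff(names(obs), c("x", "L", "U", "weight"))
  Z <- if (length(covs) > 0) as.matrix(obs[covs]) else NULL
  w <- obs$weight
  t  <- obs$x - origin
  tl <- obs$L - origin
  tu <- obs$U - origin
  u_inf <- is.infinite(tu)
  tu_f <- ifelse(u_inf, 0, tu)   # placeholder; masked below

  nll <- function(theta) {
    a0 <- exp(theta[1]); b0 <- theta[2]
    beta <- theta[-(1:2)]
    bz <- if (is.null(Z)) rep(0, length(t)) else as.numeric(Z %*% beta)
    A <- a0 * exp(bz)
    logS_L <- -A * gompertz_He(tl, b0)
    logS_U <- ifelse(u_inf, -Inf, -A * gompertz_He(tu_f, b0))
    dlt <- pmin(logS_U - logS_L, -1e-300)
    log_denom <- logS_L + log1p(-exp(dlt))
    ll <- log(a0) + bz + b0 * t - A * gompertz_He(t, b0) - log_denom
    -sum(w * ll)
  }

  grad <- function(theta) {
    a0 <- exp(theta[1]); b0 <- theta[2]
    beta <- theta[-(1:2)]
    bz <- if (is.null(Z)) rep(0, length(t)) else as.numeric(Z %*% beta)
    A <- a0 * exp(bz)
    H_x <- A * gompertz_He(t, b0)
    H_L <- A * gompertz_He(tl, b0)
    H_U <- ifelse(u_inf, Inf, A * gompertz_He(tu_f, b0))
    S_L <- exp(-H_L); S_U <- ifelse(u_inf, 0, exp(-H_U))
    D <- S_L - S_U
    dH_x <- A * gompertz_dHe(t, b0)
    dH_L <- A * gompertz_dHe(tl, b0)
    dH_U <- ifelse(u_inf, 0, A * gompertz_dHe(tu_f, b0))
    # scale part (common to log a0 and each beta_j, times z_ij)
    g_scale <- 1 - H_x + (S_L * H_L - ifelse(u_inf, 0, S_U * H_U)) / D
    g_b <- t - dH_x + (S_L * dH_L - S_U * dH_U) / D
    g1 <- sum(w * g_scale)
    g2 <- sum(w * g_b)
    gb <- if (is.null(Z)) numeric(0) else as.numeric(crossprod(Z, w * g_scale))
    -c(g1, g2, gb)
  }

  list(nll = nll, grad = grad, covs = covs)
}
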