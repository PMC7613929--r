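#' Equilibrium binding-isotherm models
#'
#' Two response models for titration data:
#'
#' * Single-site equilibrium response (surface plasmon resonance):
#'   `R_eq(C) = C * Rmax / (C + Kd) + B`, with analyte concentration
#'   `C`, maximum response at saturation `Rmax` and background
#'   resonance `B`.
#' * Two-step model (fluorescence polarisation of a labelled peptide
#'   titrated with protein): `F(PT) = F0 + F_Lo * PT / (Kd_Lo + PT) +
#'   F_Hi * PT / (Kd_Hi + PT)`, the sum of two saturation transitions
#'   with baseline anisotropy `F0`; the second transition reports
#'   ligand-linked polymerisation at higher protein concentration.
#'
#' Concentrations are in micromolar throughout; responses are in the
#' units of the measurement (response units, anisotropy).
#'
#' @param C,PT titrant concentration(s), uM (>= 0).
#' @param Kd,Kd_Lo,Kd_Hi dissociation constants, uM (> 0).
#' @param Rmax,F_Lo,F_Hi saturation amplitudes.
#' @param B,F0 baseline response.
#' @return Model response, same length as the concentration vector.
#' @name binding_models
NULL

#' @rdname binding_models
#' @export
spr_response <- function(C, Kd, Rmax, B = 0) {
  stopifnot(all(C >= 0), Kd > 0)
  C * Rmax / (C + Kd) + B
}

#' @rdname binding_models
#' @export
fp_anisotropy <- function(PT, F0, F_Lo, Kd_Lo, F_Hi, Kd_Hi) {
  stopifnot(all(PT >= 0), Kd_Lo > 0, Kd_Hi > 0)
  F0 + F_Lo * PT / (Kd_Lo + PT) + F_Hi * PT / (Kd_Hi + PT)
}

#' Binding isotherm container
#'
#' @param x titrant concentrations, uM (non-negative; stored sorted).
#' @param y responses, same length.
#' @param replicate optional replicate identifiers.
#' @return An `isotherm` data frame.
#' @export
isotherm <- function(x, y, replicate = NULL) {
  stopifnot(length(x) == length(y), all(x >= 0), all(is.finite(y)))
  d <- data.frame(x = as.numeric(x), y = as.numeric(y))
  if (!is.null(replicate)) d$replicate <- replicate
  d <- d[order(d$x), ]
  rownames(d) <- NULL
  class(d) <- c("isotherm", "data.frame")
  d
}

#' Read a two-column isotherm table
#' @param path delimited file with columns x, y (and optional
#'   replicate); header required.
#' @param sep field separator (default: whitespace/tab).
#' @return An [isotherm()].
#' @export
read_isotherm <- function(path, sep = "") {
  d <- utils::read.table(path, header = TRUE, sep = sep)
  isotherm(d[[1]], d[[2]],
           replicate = if (ncol(d) > 2) d[[3]] else NULL)
}

#' Fit the single-site equilibrium response model
#'
#' Ordinary (unweighted) nonlinear least squares via
#' Levenberg-Marquardt, with positivity bounds on Kd and Rmax.  Initial
#' values: Kd at the concentration nearest the half-range response,
#' Rmax at the response range, B at the minimum response.  Five
#' jittered restarts of the initial values are run (deterministic, from
#' `seed`) and the best residual wins.
#'
#' @param data an [isotherm()] (>= 4 distinct concentrations).
#' @param seed seed for the deterministic restart jitter.
#' @return An `spr_fit`: `Kd`, `Rmax`, `B`, `se` (named standard
#'   errors), `rss`, `fitted`, `data`.
#' @export
fit_spr <- function(data, seed = 1) {
  data <- as_isotherm(data)
  if (length(unique(data$x)) < 4)
    stop("fit_spr: need >= 4 distinct concentrations")
  if (stats::sd(data$y) == 0)
    stop("fit_spr: degenerate fit, constant response")
  rng <- range(data$y)
  half <- mean(rng)
  kd0 <- max(data$x[which.min(abs(data$y - half))], min(data$x[data$x > 0]))
  start <- c(Kd = kd0, Rmax = diff(rng), B = rng[1])
  fit <- nls_restarts(
    y ~ x * Rmax / (x + Kd) + B, data = data, start = start,
    lower = c(Kd = 1e-9, Rmax = 1e-9, B = -Inf), seed = seed)
  cf <- stats::coef(fit)
  structure(list(Kd = unname(cf["Kd"]), Rmax = unname(cf["Rmax"]),
                 B = unname(cf["B"]), se = fit_se(fit),
                 rss = sum(stats::residuals(fit)^2),
                 fitted = stats::fitted(fit), data = data),
            class = "spr_fit")
}

#' @export
print.spr_fit <- function(x, ...) {
  cat(sprintf(
    "spr_fit: Kd = %.4g uM (se %.2g), Rmax = %.4g, B = %.4g, rss = %.4g\n",
    x$Kd, x$se["Kd"], x$Rmax, x$B, x$rss))
  invisible(x)
}

#' Fit the two-step binding model
#'
#' Ordinary nonlinear least squares on the two-transition model with
#' positivity bounds on both dissociation constants, jittered restarts,
#' and labels assigned so that `Kd_Lo <= Kd_Hi`.  A warning is issued
#' when the two constants are within a factor of 10 of each other (the
#' transitions are then barely identifiable) and the fit is flagged when
#' the high constant exceeds the titrated range (data covering only the
#' first transition cannot bound it).
#'
#' @param data an [isotherm()] (>= 6 distinct concentrations spanning
#'   both transitions).
#' @param seed seed for the deterministic restart jitter.
#' @return A `two_step_fit`: `F0`, `F_Lo`, `Kd_Lo`, `F_Hi`, `Kd_Hi`,
#'   `se`, `rss`, `identifiable` (FALSE when the Kd ratio < 10),
#'   `hi_unbounded` (TRUE when `Kd_Hi` exceeds the data range),
#'   `fitted`, `data`.
#' @export
fit_fp <- function(data, seed = 1) {
  data <- as_isotherm(data)
  if (length(unique(data$x)) < 6)
    stop("fit_fp: need >= 6 distinct concentrations")
  if (stats::sd(data$y) == 0)
    stop("fit_fp: degenerate fit, constant response")
  xp <- data$x[data$x > 0]
  amp <- diff(range(data$y))
  start <- c(F0 = min(data$y), F_Lo = amp / 2,
             Kd_Lo = stats::quantile(xp, 0.2, names = FALSE),
             F_Hi = amp / 2,
             Kd_Hi = stats::quantile(xp, 0.8, names = FALSE))
  fit <- nls_restarts(
    y ~ F0 + F_Lo * x / (Kd_Lo + x) + F_Hi * x / (Kd_Hi + x),
    data = data, start = start,
    lower = c(F0 = -Inf, F_Lo = 0, Kd_Lo = 1e-9, F_Hi = 0,
              Kd_Hi = 1e-9),
    seed = seed)
  cf <- stats::coef(fit)
  se <- fit_se(fit)
  if (cf["Kd_Lo"] > cf["Kd_Hi"]) {     # enforce labelling convention
    cf[c("Kd_Lo", "Kd_Hi")] <- cf[c("Kd_Hi", "Kd_Lo")]
    cf[c("F_Lo", "F_Hi")] <- cf[c("F_Hi", "F_Lo")]
    se[c("Kd_Lo", "Kd_Hi")] <- se[c("Kd_Hi", "Kd_Lo")]
    se[c("F_Lo", "F_Hi")] <- se[c("F_Hi", "F_Lo")]
  }
  ratio <- cf["Kd_Hi"] / cf["Kd_Lo"]
  identifiable <- is.finite(ratio) && ratio >= 10
  if (!identifiable)
    warning("fit_fp: Kd_Hi/Kd_Lo = ", format(ratio, digits = 3),
            " < 10; the two transitions are barely identifiable",
            call. = FALSE)
  hi_unbounded <- cf["Kd_Hi"] > 10 * max(data$x)
  if (hi_unbounded)
    warning("fit_fp: Kd_Hi exceeds the titrated range; the second ",
            "transition is not bounded by the data", call. = FALSE)
  structure(list(F0 = unname(cf["F0"]), F_Lo = unname(cf["F_Lo"]),
                 Kd_Lo = unname(cf["Kd_Lo"]), F_Hi = unname(cf["F_Hi"]),
                 Kd_Hi = unname(cf["Kd_Hi"]), se = se,
                 rss = sum(stats::residuals(fit)^2),
                 identifiable = identifiable,
                 hi_unbounded = unname(hi_unbounded),
                 fitted = stats::fitted(fit), data = data),
            class = "two_step_fit")
}

#' @export
print.two_step_fit <- function(x, ...) {
  cat(sprintf(
    "two_step_fit: Kd_Lo = %.4g uM, Kd_Hi = %.4g uM (F0 %.4g, F_Lo %.4g, F_Hi %.4g), rss = %.4g%s\n",
    x$Kd_Lo, x$Kd_Hi, x$F0, x$F_Lo, x$F_Hi, x$rss,
    if (!x$identifiable) " [poorly identifiable]" else ""))
  invisible(x)
}

as_isotherm <- function(data) {
  if (inherits(data, "isotherm")) return(data)
  if (is.data.frame(data) && all(c("x", "y") %in% names(data)))
    return(isotherm(data$x, data$y))
  stop("expected an isotherm (see ?isotherm)")
}

# Levenberg-Marquardt with jittered multistart; best residual wins
nls_restarts <- function(formula, data, start, lower, seed,
                         n_restarts = 5) {
  jitters <- local({
    old <- get0(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    lapply(seq_len(n_restarts - 1), function(i)
      stats::rlnorm(length(start), 0, 0.5))
  })
  starts <- c(list(start),
              lapply(jitters, function(j) pmax(start * j, lower + 1e-12)))
  best <- NULL
  errs <- character()
  for (s0 in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(formula, data = data, start = as.list(s0),
                        lower = lower,
                        control = minpack.lm::nls.lm.control(
                          maxiter = 200)),
      error = function(e) conditionMessage(e))
    if (is.character(fit)) { errs <- c(errs, fit); next }
    if (is.null(best) ||
        sum(stats::residuals(fit)^2) < sum(stats::residuals(best)^2))
      best <- fit
  }
  if (is.null(best))
    stop("nonlinear fit failed to converge from any start ",
         "(initials: ", paste(names(start), signif(start, 3), sep = "=",
                              collapse = ", "), "); last error: ",
         utils::tail(errs, 1))
  best
}

fit_se <- function(fit) {
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) NULL)
  if (is.null(se)) {
    cf <- stats::coef(fit)
    se <- stats::setNames(rep(NA_real_, length(cf)), names(cf))
  }
  se
}

#' Predicted response curve of a fit
#' @param fit an `spr_fit` or `two_step_fit`.
#' @param x concentrations at which to evaluate (default: 200 points
#'   log-spaced over the fitted range).
#' @return Data frame with `x` and `y`.
#' @export
predict_isotherm <- function(fit, x = NULL) {
  if (is.null(x)) {
    xr <- range(fit$data$x[fit$data$x > 0])
    x <- exp(seq(log(xr[1]), log(xr[2]), length.out = 200))
  }
  y <- if (inherits(fit, "spr_fit")) {
    spr_response(x, fit$Kd, fit$Rmax, fit$B)
  } else if (inherits(fit, "two_step_fit")) {
    fp_anisotropy(x, fit$F0, fit$F_Lo, fit$Kd_Lo, fit$F_Hi, fit$Kd_Hi)
  } else stop("predict_isotherm: unknown fit type")
  data.frame(x = x, y = y)
}
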