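#' Whole-field ratiometric response in a time window
#'
#' Mean-field PKA response to an agonist addition: the numerator and
#' denominator channels are each averaged over the whole field and over the
#' frames falling in `window` minutes after the addition, and the ratio of
#' the two averages is returned (channels are averaged first, then divided).
#'
#' @param numerator,denominator 3-D channel arrays `[row, col, frame]`.
#' @param frame_interval min.
#' @param window `c(from, to)` in minutes after `t_addition` (default
#'   `c(20, 30)`).
#' @param t_addition Addition time, min (default 0; frame 1 is t = 0).
#' @return Scalar response, ratio units.
#' @export
field_response <- function(numerator, denominator, frame_interval,
                           window = c(20, 30), t_addition = 0) {
  if (!identical(dim(numerator), dim(denominator)))
    stop("channel stacks differ in shape")
  nt <- dim(numerator)[3]
  times <- (seq_len(nt) - 1) * frame_interval
  sel <- which(times >= t_addition + window[1] &
               times <= t_addition + window[2])
  if (length(sel) == 0L)
    stop("the response window lies outside the stack")
  mean(numerator[, , sel, drop = FALSE]) /
    mean(denominator[, , sel, drop = FALSE])
}

#' Fit a four-parameter Hill dose-response curve
#'
#' Nonlinear least squares of
#' `R(C) = r_min + (r_max - r_min) C^h / (EC50^h + C^h)`
#' via Levenberg-Marquardt ([minpack.lm::nlsLM()]), initialized from the
#' data: `r_min` from the minimum response, `r_max` from the maximum, EC50
#' from the concentration nearest the half-maximal response, and `h = 1`.
#'
#' @param concentrations Concentrations (>= 4 distinct values spanning the
#'   transition).
#' @param responses Responses, same length.
#' @param hill_fixed Optionally fix the Hill slope at this value.
#' @return List of class `hill_fit`: `r_min`, `r_max`, `ec50`, `hill`,
#'   `rss`, `converged`, `fit` (the `nls` object).
#' @export
fit_hill <- function(concentrations, responses, hill_fixed = NULL) {
  if (length(unique(concentrations)) < 4L)
    stop("at least 4 distinct concentrations are required")
  if (stats::sd(responses) == 0)
    stop("all responses are equal: nothing to fit")
  df <- data.frame(C = concentrations, R = responses)
  r_min0 <- min(responses); r_max0 <- max(responses)
  half <- (r_min0 + r_max0) / 2
  pos <- df$C > 0
  ec50_0 <- df$C[pos][which.min(abs(df$R[pos] - half))]
  fit <- tryCatch({
    if (is.null(hill_fixed)) {
      minpack.lm::nlsLM(
        R ~ r_min + (r_max - r_min) * C^h / (ec50^h + C^h), data = df,
        start = list(r_min = r_min0, r_max = r_max0, ec50 = ec50_0, h = 1),
        lower = c(-Inf, -Inf, 1e-12, 1e-3),
        control = minpack.lm::nls.lm.control(maxiter = 200))
    } else {
      h <- hill_fixed
      minpack.lm::nlsLM(
        R ~ r_min + (r_max - r_min) * C^h / (ec50^h + C^h), data = df,
        start = list(r_min = r_min0, r_max = r_max0, ec50 = ec50_0),
        lower = c(-Inf, -Inf, 1e-12),
        control = minpack.lm::nls.lm.control(maxiter = 200))
    }
  }, error = function(e) NULL)
  if (is.null(fit))
    return(structure(list(r_min = NA_real_, r_max = NA_real_,
                          ec50 = NA_real_, hill = NA_real_, rss = NA_real_,
                          converged = FALSE, fit = NULL),
                     class = "hill_fit"))
  cf <- stats::coef(fit)
  structure(list(
    r_min = unname(cf["r_min"]), r_max = unname(cf["r_max"]),
    ec50 = unname(cf["ec50"]),
    hill = if (is.null(hill_fixed)) unname(cf["h"]) else hill_fixed,
    rss = sum(stats::residuals(fit)^2),
    converged = fit$convInfo$isConv, fit = fit), class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf(
    "hill_fit: r_min %.4g, r_max %.4g, EC50 %.4g, h %.3g (%s, RSS %.3g)\n",
    x$r_min, x$r_max, x$ec50, x$hill,
    if (isTRUE(x$converged)) "converged" else "NOT converged", x$rss))
  invisible(x)
}

#' EC50 fold change between two density conditions
#'
#' `EC50(low density) / EC50(high density)`; values above 1 mean the
#' high-density condition is the more sensitive one.
#'
#' @param fit_low,fit_high `hill_fit` objects for the low- and high-density
#'   titrations.
#' @return Scalar fold ratio.
#' @export
ec50_fold <- function(fit_low, fit_high) {
  stopifnot(inherits(fit_low, "hill_fit"), inherits(fit_high, "hill_fit"))
  if (!isTRUE(fit_low$converged) || !isTRUE(fit_high$converged))
    stop("both Hill fits must have converged")
  fit_low$ec50 / fit_high$ec50
}

#' Fit every density of a titration table
#'
#' @param titration data.frame from [generate_dose_response()] (columns
#'   `density`, `concentration_uM`, `response`).
#' @param hill_fixed Optionally fix the Hill slope.
#' @return Named list of `hill_fit` objects, one per density (names are the
#'   densities).
#' @export
fit_titration <- function(titration, hill_fixed = NULL) {
  fits <- lapply(split(titration, titration$density), function(g)
    fit_hill(g$concentration_uM, g$response, hill_fixed))
  fits
}
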