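#' Turnover rate from product formation
#'
#' Converts an end-point product measurement into a turnover number:
#' `rate = product / (enzyme * time)`, in units of min^-1 when product and
#' enzyme concentration share a unit (conventionally umol L^-1) and time is
#' in minutes.
#'
#' @param product_conc Product concentration formed (umol L^-1, >= 0).
#' @param enzyme_conc Enzyme concentration (umol L^-1, > 0).
#' @param time_min Reaction time (min, > 0).
#' @return Turnover rate in min^-1.
#' @examples
#' activity_from_product(31, 2, 5)  # 3.1 min^-1
#' @export
activity_from_product <- function(product_conc, enzyme_conc, time_min) {
  if (any(product_conc < 0)) stop("product_conc must be >= 0")
  if (any(enzyme_conc <= 0)) stop("enzyme_conc must be > 0")
  if (any(time_min <= 0)) stop("time_min must be > 0")
  product_conc / (enzyme_conc * time_min)
}

#' Michaelis-Menten and substrate-surplus-inhibition rate laws
#'
#' `mm_rate()` is the original Michaelis-Menten turnover
#' `v = kcat * S / (Km + S)`. `si_rate()` adds uncompetitive substrate
#' surplus inhibition, `v = kcat * S / (Km + S * (1 + S / Ki))`, which is
#' non-monotone with its maximum at `S = sqrt(Km * Ki)` and reduces to
#' Michaelis-Menten as `Ki -> Inf`.
#'
#' @param S Substrate concentration (mmol L^-1).
#' @param kcat Turnover number (min^-1).
#' @param km Michaelis constant (mmol L^-1).
#' @param ki Substrate-inhibition constant (mmol L^-1).
#' @return Turnover rate(s) in min^-1.
#' @examples
#' mm_rate(0.30, kcat = 47.6, km = 0.30)  # half of kcat
#' @export
mm_rate <- function(S, kcat, km) {
  stopifnot(kcat > 0, km > 0)
  kcat * S / (km + S)
}

#' @rdname mm_rate
#' @export
si_rate <- function(S, kcat, km, ki) {
  stopifnot(kcat > 0, km > 0, ki > 0)
  kcat * S / (km + S * (1 + S / ki))
}

#' Fit a kinetic model to saturation data by nonlinear least squares
#'
#' Fits the Michaelis-Menten model (`"MM"`) or its substrate-surplus-
#' inhibition extension (`"MM_SI"`) to (substrate, rate) data with
#' unweighted least squares via the Levenberg-Marquardt algorithm
#' ([minpack.lm::nlsLM()]). Standard errors come from the Jacobian at the
#' optimum. Starting values are scale-free: `kcat0` is the maximum observed
#' rate, `km0` the substrate concentration nearest half of it, `ki0` the
#' largest substrate concentration. An optimiser failure or stall is
#' reported as `converged = FALSE` with `NA` parameters rather than an
#' error, since on strongly inhibited data over a wide substrate range a
#' plain Michaelis-Menten fit legitimately fails to converge.
#'
#' @param data `data.frame` with columns `substrate_mM` and `rate_per_min`
#'   (a replicate column is allowed and ignored: the fit is pointwise).
#' @param model `"MM"` (needs >= 4 distinct substrate levels) or `"MM_SI"`
#'   (>= 5).
#' @param start Optional named list overriding the default starting values.
#' @param max_iter Maximum optimiser iterations.
#' @return An object of class `kinetic_fit`: list with `model`, `kcat`,
#'   `km`, `ki` (MM_SI only, else `NA`), `se` (named vector), `rss`,
#'   `converged`, `n_points`, `apparent` (set by [apparent_fit()]), and the
#'   underlying `fit` object when available.
#' @examples
#' d <- data.frame(substrate_mM = c(0.05, 0.1, 0.3, 1, 3),
#'                 rate_per_min = mm_rate(c(0.05, 0.1, 0.3, 1, 3), 47.6, 0.3))
#' fit_model(d, "MM")
#' @export
fit_model <- function(data, model = c("MM", "MM_SI"), start = NULL,
                      max_iter = 500L) {
  model <- match.arg(model)
  stopifnot(all(c("substrate_mM", "rate_per_min") %in% names(data)))
  S <- data$substrate_mM; v <- data$rate_per_min
  if (any(S <= 0)) stop("substrate concentrations must be > 0")
  if (any(v < 0)) stop("rates must be >= 0")
  n_distinct <- length(unique(S))
  need <- if (model == "MM") 4L else 5L
  if (n_distinct < need)
    stop(model, " fit needs >= ", need, " distinct substrate levels (got ",
         n_distinct, ")")

  kcat0 <- max(v)
  # half-saturation read off the rising limb: the smallest substrate level
  # whose mean rate reaches half the maximum (robust when inhibition bends
  # the curve back down at high substrate)
  mean_v <- tapply(v, S, mean)
  s_lev <- as.numeric(names(mean_v))
  above <- which(mean_v >= kcat0 / 2)
  km0 <- if (length(above) > 0) s_lev[min(above)] else stats::median(s_lev)
  init <- list(kcat = kcat0, km = max(km0, min(S) / 2))
  formula <- rate_per_min ~ kcat * substrate_mM / (km + substrate_mM)
  lower <- c(kcat = 1e-12, km = 1e-12)
  if (model == "MM_SI") {
    init$ki <- max(S)
    formula <- rate_per_min ~
      kcat * substrate_mM / (km + substrate_mM * (1 + substrate_mM / ki))
    lower <- c(lower, ki = 1e-12)
  }
  if (!is.null(start)) init[names(start)] <- start

  df <- data.frame(substrate_mM = S, rate_per_min = v)
  fit <- tryCatch(
    minpack.lm::nlsLM(formula, data = df, start = init, lower = lower,
                      control = minpack.lm::nls.lm.control(
                        maxiter = max_iter, ftol = 1e-10, ptol = 1e-10)),
    error = function(e) e)

  if (inherits(fit, "error")) {
    out <- list(model = model, kcat = NA_real_, km = NA_real_, ki = NA_real_,
                se = NULL, rss = NA_real_, converged = FALSE,
                n_points = nrow(df), apparent = FALSE, fit = NULL,
                message = conditionMessage(fit))
    return(structure(out, class = "kinetic_fit"))
  }

  est <- coef(fit)
  sm <- tryCatch(summary(fit), error = function(e) NULL)
  se <- if (!is.null(sm)) sm$coefficients[, "Std. Error"] else
    stats::setNames(rep(NA_real_, length(est)), names(est))
  conv <- isTRUE(fit$convInfo$isConv) && fit$convInfo$finIter < max_iter
  structure(list(model = model,
                 kcat = unname(est["kcat"]), km = unname(est["km"]),
                 ki = if (model == "MM_SI") unname(est["ki"]) else NA_real_,
                 se = se, rss = sum(stats::resid(fit)^2),
                 converged = conv, n_points = nrow(df),
                 apparent = FALSE, fit = fit, message = NULL),
            class = "kinetic_fit")
}

#' Apparent Michaelis-Menten parameters from a truncated substrate range
#'
#' When substrate surplus inhibition bends the saturation curve downward at
#' high substrate, apparent parameters can be estimated by fitting plain
#' Michaelis-Menten only to the low-substrate points where inhibition is not
#' yet apparent. Because the model omits the inhibitory term, the apparent
#' `Km` can only serve as a lower bound on the true `Km`; the fit is
#' flagged `apparent = TRUE` to carry that caveat.
#'
#' @param data As in [fit_model()].
#' @param s_max Upper substrate cut-off (mmol L^-1); points with
#'   `substrate_mM > s_max` are dropped. `Inf` reproduces [fit_model()].
#' @param ... Passed to [fit_model()].
#' @return A `kinetic_fit` with `apparent = TRUE`.
#' @export
apparent_fit <- function(data, s_max = Inf, ...) {
  sub <- data[data$substrate_mM <= s_max, , drop = FALSE]
  if (length(unique(sub$substrate_mM)) < 4)
    stop("truncation at s_max = ", s_max,
         " leaves fewer than 4 distinct substrate levels")
  fit <- fit_model(sub, model = "MM", ...)
  fit$apparent <- TRUE
  fit
}

#' Product-ratio of a substrate competition experiment
#'
#' Fold excess of one reduction product over another when two substrates
#' compete in the same reaction, e.g. dGDP over dGTP formed from a GDP/GTP
#' mixture.
#'
#' @param products Named numeric vector of product concentrations (>= 2
#'   species).
#' @param numerator,reference Species names; default first and second
#'   element.
#' @return Fold ratio `products[numerator] / products[reference]`.
#' @examples
#' competition_ratio(c(dGDP = 5.5, dGTP = 1.0))  # 5.5
#' @export
competition_ratio <- function(products, numerator = names(products)[1],
                              reference = names(products)[2]) {
  if (length(products) < 2 || is.null(names(products)))
    stop("products must be a named vector with >= 2 species")
  if (!numerator %in% names(products) || !reference %in% names(products))
    stop("numerator/reference must name entries of `products`")
  if (products[[reference]] <= 0)
    stop("reference species concentration must be > 0")
  products[[numerator]] / products[[reference]]
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat("Kinetic fit:", x$model, if (x$apparent) "(apparent, truncated range)",
      "\n")
  if (!x$converged && is.na(x$kcat)) {
    cat("  did not converge:", x$message, "\n")
    return(invisible(x))
  }
  fmt <- function(p, unit) {
    se <- if (!is.null(x$se) && p %in% names(x$se)) x$se[[p]] else NA
    sprintf("  %-4s %8.4g +/- %.2g %s\n", p, x[[p]], se, unit)
  }
  cat(fmt("kcat", "min^-1"))
  cat(fmt("km", "mmol L^-1"))
  if (x$model == "MM_SI") cat(fmt("ki", "mmol L^-1"))
  cat(sprintf("  RSS %.4g over %d points; converged: %s\n",
              x$rss, x$n_points, x$converged))
  invisible(x)
}
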