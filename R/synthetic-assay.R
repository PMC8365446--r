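#' Specification for a simulated saturation-kinetics assay
#'
#' Forward model for an RNR activity assay: turnover rates on a substrate
#' grid, generated from Michaelis-Menten kinetics (or its substrate-surplus-
#' inhibition extension when `true_ki` is given) with multiplicative
#' Gaussian noise, `v_obs = v * (1 + e)`, `e ~ N(0, cv^2)`, truncated at
#' `v_obs >= 0`.
#'
#' The defaults reproduce a wild-type-like design: `kcat` 47.6 min^-1 and
#' `Km` 0.30 mmol L^-1, a 10-level substrate grid spanning 0.05-3
#' mmol L^-1, 3 replicates per level, and 5% coefficient of variation —
#' i.e. triplicate measurements bracketing `Km` by more than an order of
#' magnitude on either side.
#'
#' @param true_kcat Generating turnover number (min^-1, > 0).
#' @param true_km Generating Michaelis constant (mmol L^-1, > 0).
#' @param true_ki Generating substrate-inhibition constant (mmol L^-1), or
#'   `NULL` for plain Michaelis-Menten.
#' @param enzyme_conc Enzyme concentration (umol L^-1, > 0); recorded with
#'   the dataset, the rates are already per-enzyme turnovers.
#' @param substrate_grid Substrate concentrations (mmol L^-1, all > 0).
#' @param replicates Replicates per substrate level (>= 1).
#' @param noise_cv Coefficient of variation of the multiplicative noise
#'   (>= 0).
#' @param seed Integer seed.
#' @return An object of class `assay_spec`.
#' @export
assay_spec <- function(true_kcat = 47.6, true_km = 0.30, true_ki = NULL,
                       enzyme_conc = 2,
                       substrate_grid = c(0.05, 0.1, 0.2, 0.3, 0.5, 0.75,
                                          1, 1.5, 2, 3),
                       replicates = 3L, noise_cv = 0.05, seed = 1L) {
  stopifnot(true_kcat > 0, true_km > 0, enzyme_conc > 0,
            all(substrate_grid > 0), replicates >= 1, noise_cv >= 0)
  if (!is.null(true_ki)) stopifnot(true_ki > 0)
  structure(list(true_kcat = true_kcat, true_km = true_km, true_ki = true_ki,
                 enzyme_conc = enzyme_conc,
                 substrate_grid = sort(substrate_grid),
                 replicates = as.integer(replicates),
                 noise_cv = noise_cv, seed = as.integer(seed)),
            class = "assay_spec")
}

#' Simulate a saturation-kinetics dataset
#'
#' @param spec An [assay_spec()].
#' @return A `data.frame` with columns `substrate_mM`, `rate_per_min`,
#'   `replicate`, carrying the spec as attribute `assay_spec`. With
#'   `noise_cv = 0` the rates follow the generating model exactly.
#' @examples
#' d <- simulate_assay(assay_spec(noise_cv = 0))
#' head(d)
#' @export
simulate_assay <- function(spec) {
  stopifnot(inherits(spec, "assay_spec"))
  S <- rep(spec$substrate_grid, each = spec$replicates)
  v <- if (is.null(spec$true_ki))
    mm_rate(S, spec$true_kcat, spec$true_km)
  else
    si_rate(S, spec$true_kcat, spec$true_km, spec$true_ki)
  if (spec$noise_cv > 0) {
    with_seed(spec$seed, {
      v <- v * (1 + stats::rnorm(length(v), 0, spec$noise_cv))
    })
    v <- pmax(v, 0)
  }
  structure(data.frame(substrate_mM = S, rate_per_min = v,
                       replicate = rep(seq_len(spec$replicates),
                                       times = length(spec$substrate_grid))),
            assay_spec = spec)
}
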