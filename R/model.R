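#' Loop-extrusion processivity parameters
#'
#' Parameters of the generator's contact model. Cohesin processivity is
#' summarized by the mean linear genomic length `lambda` (bp) extruded
#' before release; enhancer-promoter contact intensity at linear distance
#' `d` is modelled as
#'
#'   `intensity(d) = contact_amplitude * exp(-d / lambda) +
#'    background_scale * (max(d, background_bin) / background_bin) ^
#'    (-background_exponent)`
#'
#' The second term is a distance power-law background (the generic Hi-C
#' contact decay); setting `background_scale = 0` disables it, in which case
#' the mutant/WT intensity ratio has the closed form
#' `exp(-d * (1/lambda_mut - 1/lambda_wt))`.
#'
#' @param lambda_wt Mean extruded length in the wild type (bp).
#' @param lambda_mut Mean extruded length in the mutant (bp).
#' @param contact_amplitude Amplitude of the extrusion-driven contact term.
#' @param background_scale Coefficient of the power-law background term
#'   (0 disables it).
#' @param background_exponent Exponent of the power-law background.
#' @param background_bin Distance floor / unit of the background term (bp);
#'   also the scale at which the power law is anchored.
#' @param eta Expression coupling: expression responds to contact as
#'   `mu_mut = mu_wt * ratio(d)^eta`.
#' @return A list of class `processivity_params`.
#' @export
processivity_params <- function(lambda_wt = 400000, lambda_mut = 150000,
                                contact_amplitude = 1,
                                background_scale = 0.1,
                                background_exponent = 1,
                                background_bin = 10000,
                                eta = 1) {
  stopifnot(lambda_wt > 0, lambda_mut > 0, contact_amplitude >= 0,
            background_scale >= 0, background_bin > 0)
  structure(list(lambda_wt = lambda_wt, lambda_mut = lambda_mut,
                 contact_amplitude = contact_amplitude,
                 background_scale = background_scale,
                 background_exponent = background_exponent,
                 background_bin = background_bin, eta = eta),
            class = "processivity_params")
}

#' Expected enhancer-promoter contact intensity
#'
#' Evaluates the generator's contact model (see [processivity_params()]) at
#' linear genomic distance `d` for one condition.
#'
#' @param d Distance(s) in bp; must be >= 0.
#' @param params A [processivity_params()].
#' @param condition `"wt"` or `"mut"`; selects which lambda is used.
#' @return Numeric vector of expected intensities, strictly decreasing in
#'   `d` (for `d >= background_bin` when the background term is active).
#' @export
enhancer_contact <- function(d, params = processivity_params(),
                             condition = c("wt", "mut")) {
  condition <- match.arg(condition)
  stopifnot(inherits(params, "processivity_params"))
  if (any(d < 0)) stop("distances must be non-negative")
  lambda <- if (condition == "wt") params$lambda_wt else params$lambda_mut
  bg <- params$background_scale *
    (pmax(d, params$background_bin) / params$background_bin) ^
    (-params$background_exponent)
  params$contact_amplitude * exp(-d / lambda) + bg
}

#' Mutant/WT contact ratio
#'
#' Convenience wrapper: `enhancer_contact(d, , "mut") /
#' enhancer_contact(d, , "wt")`. With the background term disabled this is
#' exactly `exp(-d * (1/lambda_mut - 1/lambda_wt))`.
#'
#' @inheritParams enhancer_contact
#' @return Numeric vector of ratios.
#' @export
contact_ratio <- function(d, params = processivity_params()) {
  enhancer_contact(d, params, "mut") / enhancer_contact(d, params, "wt")
}
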