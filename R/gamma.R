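# Gamma modelling of IBD segment-length distributions. Recombination acts
# approximately as a Poisson process along the genome, so segment lengths of
# a given relationship are approximately gamma distributed, with faster
# decay for more distant relationships.

#' Fit a gamma distribution to segment lengths
#'
#' Maximum-likelihood fit of the gamma family (via
#' [fitdistrplus::fitdist()]) to a set of IBD segment lengths. The shape k
#' is taken from the ML fit; the scale is then set to
#' mean(lengths) / k rather than the ML scale, pinning the fitted mean to
#' the sample mean. Pairs sharing fewer than two segments (or segments of a
#' single distinct length) cannot be modelled and yield an abstention.
#'
#' @param lengths Numeric vector of segment lengths (Mbp).
#' @return List `(shape, scale)` of class `gamma_params`, or `NULL`
#'   (abstain) when the distribution cannot be fitted.
#' @export
fit_gamma <- function(lengths) {
  lengths <- lengths[is.finite(lengths) & lengths > 0]
  if (length(lengths) < 2 || length(unique(lengths)) < 2) return(NULL)
  m <- mean(lengths); v <- stats::var(lengths)
  start <- list(shape = max(m^2 / v, 1e-2), rate = max(m / v, 1e-6))
  fit <- tryCatch(
    fitdistrplus::fitdist(lengths, "gamma", method = "mle", start = start),
    error = function(e) NULL)
  shape <- if (!is.null(fit) && is.finite(fit$estimate[["shape"]]))
    fit$estimate[["shape"]]
  else start$shape  # method-of-moments fallback for pathological samples
  structure(list(shape = shape, scale = m / shape), class = "gamma_params")
}

#' Gamma segment-length profile
#'
#' Evaluates the gamma density at every integer length x = 1..`x_max` Mbp,
#' giving the discretised expected segment-length profile used for
#' profile-distance comparisons.
#'
#' @param params A `gamma_params` list (`shape`, `scale`).
#' @param x_max Upper end of the length grid in Mbp (default 150, the
#'   longest segment length the profiles need to cover).
#' @return Numeric vector of densities of length `x_max`.
#' @export
gamma_profile <- function(params, x_max = 150) {
  stopifnot(params$shape > 0, params$scale > 0)
  stats::dgamma(seq_len(x_max), shape = params$shape, scale = params$scale)
}

#' Mean absolute distance between two gamma profiles
#'
#' @param profile_p,profile_r Equal-length density profiles (see
#'   [gamma_profile()]).
#' @return Mean absolute difference over the grid.
#' @export
gamma_distance <- function(profile_p, profile_r) {
  if (length(profile_p) != length(profile_r))
    stop_input("profiles have different lengths (%d vs %d)",
               length(profile_p), length(profile_r))
  mean(abs(profile_p - profile_r))
}
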