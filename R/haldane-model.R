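#' Haldane substrate-inhibition parameters
#'
#' The parameter triple of the Haldane rate law
#' \deqn{r(S) = r^* S / (K_s + S + S^2/K_i)}
#' where `rate_star` (\eqn{\mu^*} for the growth branch, \eqn{q^*} for the
#' degradation branch) is the fitted maximum-rate parameter, `ks` the
#' half-saturation constant and `ki` the substrate-inhibition constant.
#' `rate_star` is a fitting parameter, not the rate the culture can actually
#' reach: the observable maximum is [true_max_rate()], attained at
#' [critical_substrate()].
#'
#' Setting `ki = Inf` selects the Monod limit \eqn{r^* S/(K_s + S)}, the
#' uninhibited saturation law.
#'
#' @param rate_star Fitted maximum-rate parameter, 1/h; > 0.
#' @param ks Half-saturation constant, mg/L; > 0.
#' @param ki Inhibition constant, mg/L; > 0, or `Inf` for Monod kinetics.
#' @param branch `"growth"` (specific growth rate, unprimed parameters) or
#'   `"degradation"` (specific degradation rate, primed parameters).
#' @return An object of class `haldane_params`.
#' @examples
#' p <- haldane_params(0.574, 20.29, 268.1)
#' critical_substrate(p)   # substrate level of peak growth
#' true_max_rate(p)        # the peak rate itself
#' @export
haldane_params <- function(rate_star, ks, ki = Inf,
                           branch = c("growth", "degradation")) {
  branch <- match.arg(branch)
  stop_if_not_number(rate_star, "rate_star", positive = TRUE)
  stop_if_not_number(ks, "ks", positive = TRUE)
  stop_if_not_number(ki, "ki", positive = TRUE, finite = FALSE)
  structure(
    list(rate_star = rate_star, ks = ks, ki = ki, branch = branch),
    class = "haldane_params"
  )
}

#' @export
print.haldane_params <- function(x, ...) {
  lab <- if (x$branch == "growth") c("mu*", "Ks", "Ki") else c("q*", "Ks'", "Ki'")
  cat(sprintf("Haldane %s parameters: %s = %.4g 1/h, %s = %.4g mg/L, %s = %.4g mg/L\n",
              x$branch, lab[1], x$rate_star, lab[2], x$ks, lab[3], x$ki))
  invisible(x)
}

#' Haldane specific rate at a substrate concentration
#'
#' Evaluates \eqn{r(S) = r^* S/(K_s + S + S^2/K_i)}. The law rises from 0 at
#' `S = 0`, peaks at `S = sqrt(Ks*Ki)`, and declines at higher substrate as
#' self-inhibition takes over. With `ki = Inf` the quadratic term vanishes
#' and the Monod form is evaluated.
#'
#' @param s Substrate concentration(s), mg/L; non-negative.
#' @param p A [haldane_params()] object.
#' @return Specific rate(s), 1/h.
#' @export
haldane_rate <- function(s, p) {
  stopifnot(inherits(p, "haldane_params"))
  if (!is.numeric(s) || any(is.na(s)))
    stop("'s' must be numeric with no missing values", call. = FALSE)
  if (any(s < 0))
    stop("substrate concentrations must be non-negative", call. = FALSE)
  inhib <- if (is.finite(p$ki)) s^2 / p$ki else 0
  p$rate_star * s / (p$ks + s + inhib)
}

#' Critical substrate concentration Sm
#'
#' The concentration at which the Haldane rate peaks, obtained from
#' `dr/dS = 0`: \eqn{S_m = \sqrt{K_s K_i}}. `Inf` in the Monod limit,
#' where the rate saturates instead of peaking.
#'
#' @inheritParams haldane_rate
#' @return Sm, mg/L.
#' @export
critical_substrate <- function(p) {
  stopifnot(inherits(p, "haldane_params"))
  sqrt(p$ks * p$ki)
}

#' True maximum specific rate
#'
#' The rate actually attained at the peak of the Haldane curve,
#' \eqn{r_{max} = r^*/(1 + 2\sqrt{K_s/K_i})}, algebraically equal to
#' `haldane_rate(critical_substrate(p), p)`. Always strictly below
#' `rate_star` for finite `ki`; equal to it in the Monod limit.
#'
#' @inheritParams haldane_rate
#' @return The true maximum rate, 1/h.
#' @export
true_max_rate <- function(p) {
  stopifnot(inherits(p, "haldane_params"))
  if (!is.finite(p$ki)) return(p$rate_star)
  p$rate_star / (1 + 2 * sqrt(p$ks / p$ki))
}

#' Overestimation of the fitted rate parameter
#'
#' By how much the fitting parameter `rate_star` exceeds the observable
#' maximum rate, as a percentage of the latter:
#' `100 * (rate_star - true_max) / true_max`. Quantifies how misleading it
#' is to quote \eqn{\mu^*} as "the maximum growth rate" for an inhibitory
#' substrate; 0 in the Monod limit.
#'
#' @inheritParams haldane_rate
#' @return Percent overestimation.
#' @export
overestimation_percent <- function(p) {
  tm <- true_max_rate(p)
  100 * (p$rate_star - tm) / tm
}

#' Derived kinetic quantities of a Haldane parameter set
#'
#' Bundles [critical_substrate()] and [true_max_rate()].
#'
#' @inheritParams haldane_rate
#' @return An object of class `derived_kinetics` with fields `s_m` (mg/L)
#'   and `true_max_rate` (1/h).
#' @export
derived_kinetics <- function(p) {
  stopifnot(inherits(p, "haldane_params"))
  structure(
    list(s_m = critical_substrate(p), true_max_rate = true_max_rate(p),
         branch = p$branch),
    class = "derived_kinetics"
  )
}

#' @export
print.derived_kinetics <- function(x, ...) {
  cat(sprintf("Derived %s kinetics: Sm = %.4g mg/L, true max rate = %.4g 1/h\n",
              x$branch, x$s_m, x$true_max_rate))
  invisible(x)
}
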