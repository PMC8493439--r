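# Symmetrized percent change (SPC) of cortical thickness between two scans:
# annualized change divided by the two-timepoint average thickness, x100.
# Units are % per year. SPC is the recommended two-timepoint longitudinal
# thickness statistic because it is antisymmetric in the timepoints and
# invariant to a common scale factor.

#' Symmetrized percent change
#'
#' Computes, per vertex (or per region), \deqn{SPC = 100 (T_2 - T_1) /
#' (\Delta t \cdot 0.5 (T_1 + T_2))} in percent per year, where \eqn{T_1}
#' and \eqn{T_2} are thickness (mm) at the two timepoints and
#' \eqn{\Delta t} the inter-scan interval in years.
#'
#' @param t1,t2 Numeric vectors of positive thickness values (mm), same
#'   length.
#' @param interval Inter-scan interval in years (scalar, > 0).
#' @return Numeric vector of SPC values (% per year). Every value lies
#'   strictly inside (-200/interval, 200/interval).
#' @examples
#' symmetrized_percent_change(3.0, 2.7, 4.1)  # about -2.567 %/y
#' @export
symmetrized_percent_change <- function(t1, t2, interval) {
  if (length(t1) != length(t2))
    stop("t1 and t2 must have the same length")
  if (length(interval) != 1 || !is.finite(interval) || interval <= 0)
    stop("interval must be a single positive number of years")
  if (any(!is.finite(t1)) || any(!is.finite(t2)) || any(t1 <= 0) || any(t2 <= 0))
    stop("thickness values must be positive and finite")
  100 * (t2 - t1) / (interval * 0.5 * (t1 + t2))
}

# Inverse map used by the cohort simulator: thickness at time 2 that yields
# a prescribed SPC given thickness at time 1. Requires |spc|*dt < 200.
.thickness2_from_spc <- function(t1, spc, interval) {
  r <- spc * interval / 200
  if (any(abs(r) >= 1))
    stop("requested SPC magnitude exceeds the attainable bound 200/interval")
  t1 * (1 + r) / (1 - r)
}
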