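#' Rubisco-limited assimilation
#'
#' The carboxylation-limited branch of the FvCB model,
#' \deqn{A_c = V_{cmax} (C_i - \Gamma^*) / (C_i + K_c (1 + O / K_o)) - R_d,}
#' with intercellular CO2 standing in for chloroplastic CO2 (infinite
#' mesophyll conductance).
#'
#' @param ci intercellular CO2, umol mol-1 (vectorised)
#' @param p an \code{FvCBParameters}
#' @return net assimilation, umol m-2 s-1
#' @examples
#' p <- FvCBParameters(vcmax = 100, rd = 1.5)
#' assimilationRubisco(400, p)
#' @export
assimilationRubisco <- function(ci, p) {
  stopifnot(is(p, "FvCBParameters"), all(ci >= 0))
  p@vcmax * (ci - p@gammaStar) / (ci + p@kc * (1 + p@o2 / p@ko)) - p@rd
}

#' RuBP-regeneration-limited assimilation
#'
#' The electron-transport-limited branch,
#' \deqn{A_j = J (C_i - \Gamma^*) / (4 C_i + 8 \Gamma^*) - R_d,}
#' which approaches J/4 - Rd at saturating CO2. Returns \code{Inf} when
#' \code{j} is \code{NA} (absent segment: never the binding limitation).
#'
#' @inheritParams assimilationRubisco
#' @return net assimilation, umol m-2 s-1
#' @export
assimilationRubp <- function(ci, p) {
  stopifnot(is(p, "FvCBParameters"), all(ci >= 0))
  if (is.na(p@j)) return(rep(Inf, length(ci)))
  p@j * (ci - p@gammaStar) / (4 * ci + 8 * p@gammaStar) - p@rd
}

#' TPU-limited assimilation
#'
#' The triose-phosphate-use-limited plateau, \eqn{A_p = 3 TPU - R_d},
#' independent of Ci in its baseline form. Returns \code{Inf} when
#' \code{tpu} is \code{NA}.
#'
#' @param p an \code{FvCBParameters}
#' @return net assimilation, umol m-2 s-1 (scalar)
#' @export
assimilationTpu <- function(p) {
  stopifnot(is(p, "FvCBParameters"))
  if (is.na(p@tpu)) return(Inf)
  3 * p@tpu - p@rd
}

# Shared evaluation of the min-rule model with per-point labels.
# The carboxylation minimum is taken over the GROSS rates
#   Wc = Vcmax Ci / (Ci + Kc (1 + O/Ko)),  Wj = J Ci / (4 Ci + 8 GammaStar),
# and net assimilation is A = (1 - GammaStar/Ci) min(Wc, Wj) - Rd, capped
# by the TPU plateau Ap = 3 TPU - Rd. For Ci >= GammaStar this equals the
# pointwise minimum of the three net branches; below the compensation
# point the gross-rate minimum keeps the Rubisco branch operative (the
# net-branch inequality flips there) so the limitation sequence stays
# ordered rubisco -> rubp -> tpu along ascending Ci. At Ci = 0 the branch
# is chosen by the smaller initial slope, the limit of the same rule.
evalFvCB <- function(ci, p) {
  kmEff <- p@kc * (1 + p@o2 / p@ko)
  slopeC <- p@vcmax / kmEff
  slopeJ <- if (is.na(p@j)) Inf else p@j / (8 * p@gammaStar)
  wc <- p@vcmax * ci / (ci + kmEff)
  wj <- if (is.na(p@j)) rep(Inf, length(ci)) else p@j * ci / (4 * ci + 8 * p@gammaStar)
  useC <- ifelse(ci == 0, slopeC <= slopeJ, wc <= wj)
  aCarb <- ifelse(useC, assimilationRubisco(ci, p), assimilationRubp(ci, p))
  ap <- assimilationTpu(p)
  a <- pmin(aCarb, ap)
  lab <- ifelse(aCarb <= ap, ifelse(useC, "rubisco", "rubp"), "tpu")
  list(a = a, label = lab)
}

#' Forward FvCB model: minimum-rule assimilation
#'
#' Net assimilation along an ascending Ci series under the limitation
#' minimum rule. The minimum is taken over the gross carboxylation rates
#' of the Rubisco and RuBP-regeneration branches and the result capped by
#' the TPU plateau; for Ci at or above the compensation point this equals
#' the pointwise minimum of the three net branches
#' \code{\link{assimilationRubisco}}, \code{\link{assimilationRubp}},
#' \code{\link{assimilationTpu}}, while below it the Rubisco branch
#' remains operative so limitation states stay contiguous and ordered.
#'
#' @param ci ascending Ci series, umol mol-1
#' @param p an \code{FvCBParameters}
#' @return net assimilation series, umol m-2 s-1
#' @seealso \code{\link{limitationStates}} for the per-point binding branch
#' @export
forwardAci <- function(ci, p) {
  stopifnot(all(diff(ci) > 0))
  evalFvCB(ci, p)$a
}

#' Per-point limitation assignment of the forward model
#'
#' @inheritParams forwardAci
#' @return character vector in \code{{"rubisco","rubp","tpu"}}; ties go to
#'   the earlier branch in that order
#' @export
limitationStates <- function(ci, p) {
  evalFvCB(ci, p)$label
}

#' Default activation energies for Arrhenius temperature scaling
#'
#' Activation energies (J mol-1) of the standard tobacco-derived
#' temperature responses of the FvCB parameters and Rubisco kinetic
#' constants.
#'
#' @return named numeric vector with entries vcmax, j, tpu, rd,
#'   gammaStar, kc, ko
#' @export
arrheniusEnergies <- function() {
  c(vcmax = 65330, j = 43540, tpu = 53100, rd = 46390,
    gammaStar = 37830, kc = 79430, ko = 36380)
}

#' Arrhenius scale factor
#'
#' \eqn{\exp[(H_a / R)(1/298.15 - 1/(T + 273.15))]} relative to 25 C.
#'
#' @param ha activation energy, J mol-1
#' @param tempC temperature, degrees C
#' @return dimensionless multiplier (1 at 25 C)
#' @export
arrheniusFactor <- function(ha, tempC) {
  R <- 8.314
  exp(ha / R * (1 / 298.15 - 1 / (tempC + 273.15)))
}

#' Temperature-adjust an FvCB parameter set
#'
#' Scales capacities and kinetic constants from 25 C to a target leaf
#' temperature with pure Arrhenius responses. At 25 C the operation is
#' the identity.
#'
#' @param p25 \code{FvCBParameters} at 25 C
#' @param leafTemp target leaf temperature, degrees C, in [0, 50]
#' @param energies named activation energies, J mol-1
#'   (default \code{\link{arrheniusEnergies}()})
#' @return \code{FvCBParameters} at \code{leafTemp}
#' @examples
#' p35 <- temperatureAdjust(FvCBParameters(), 35)
#' vcmax(p35) / vcmax(FvCBParameters())  # > 2
#' @export
temperatureAdjust <- function(p25, leafTemp, energies = arrheniusEnergies()) {
  stopifnot(is(p25, "FvCBParameters"), leafTemp >= 0, leafTemp <= 50)
  f <- function(nm) arrheniusFactor(energies[[nm]], leafTemp)
  FvCBParameters(
    vcmax = p25@vcmax * f("vcmax"),
    j = if (is.na(p25@j)) NA_real_ else p25@j * f("j"),
    tpu = if (is.na(p25@tpu)) NA_real_ else p25@tpu * f("tpu"),
    rd = p25@rd * f("rd"),
    gammaStar = p25@gammaStar * f("gammaStar"),
    kc = p25@kc * f("kc"),
    ko = p25@ko * f("ko"),
    o2 = p25@o2, temp = leafTemp)
}
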