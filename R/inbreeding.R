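#' Effective inbreeding relative to a source population
#'
#' Effective inbreeding expresses the proportional loss of heterozygosity of
#' a focal population relative to a reference (source) population:
#' `Fe = 1 - H_focal / H_reference`. It can be negative when the focal
#' population is more heterozygous than the reference (e.g., after an influx
#' of outbred immigrants); the value is returned as-is, with a `negative`
#' attribute flagging that case, so downstream code can decide how to treat
#' it.
#'
#' @param h_focal focal-population heterozygosity (typically multi-locus
#'   mean expected heterozygosity), in `[0, 1]`.
#' @param h_reference reference-population heterozygosity; must be positive.
#'   The default, 0.592, is the multi-locus expected heterozygosity of the
#'   Slovak Carpathian source population estimated from 60 individuals on
#'   the same 19-marker panel.
#' @return Effective inbreeding (unitless), possibly negative, with
#'   attribute `negative`.
#' @export
effective_inbreeding <- function(h_focal, h_reference = 0.592) {
  stopifnot(is.numeric(h_focal), is.numeric(h_reference))
  if (any(h_reference <= 0))
    stop("h_reference must be positive")
  fe <- 1 - h_focal / h_reference
  attr(fe, "negative") <- fe < 0
  fe
}

#' Expected inbreeding depression from lethal equivalents
#'
#' Under the classic lethal-equivalents model, fitness declines
#' exponentially with the inbreeding coefficient: `W(F) = W0 * exp(-B * F)`
#' where `2B` is the diploid number of lethal equivalents. The expected
#' inbreeding depression is the complementary proportion
#' `delta = 1 - exp(-(2B / 2) * F)`. The default of 12 diploid lethal
#' equivalents is the estimate for wild vertebrate populations commonly
#' applied in carnivore viability assessments.
#'
#' @param fe effective inbreeding, must be non-negative (clamp or reject
#'   negative values before calling).
#' @param lethal_equivalents diploid lethal equivalents `2B` (default 12).
#' @return Expected inbreeding depression in `[0, 1)`.
#' @examples
#' inbreeding_depression(0.32)           # 0.85 to 2 d.p.
#' relative_fitness(inbreeding_depression(0.32))
#' @export
inbreeding_depression <- function(fe, lethal_equivalents = 12) {
  stopifnot(is.numeric(fe), is.numeric(lethal_equivalents))
  if (any(fe < 0)) stop("fe must be non-negative")
  if (any(lethal_equivalents <= 0)) stop("lethal_equivalents must be positive")
  1 - exp(-(lethal_equivalents / 2) * fe)
}

#' Remaining relative fitness
#'
#' Fitness relative to the (non-inbred) reference population, `1 - delta`.
#'
#' @param delta expected inbreeding depression in `[0, 1]`.
#' @export
relative_fitness <- function(delta) {
  stopifnot(is.numeric(delta))
  if (any(delta < 0 | delta > 1)) stop("delta must lie in [0, 1]")
  1 - delta
}
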