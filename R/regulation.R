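# Thermodynamic promoter-occupancy model of transcriptional regulation.

#' Thermodynamic promoter occupancy
#'
#' Fraction of promoter microstates with polymerase bound, for a promoter with
#' `n_sites` identical transcription-factor binding sites at which an
#' activator and a repressor compete. Bound activator recruits polymerase with
#' cooperativity `c_act` (> 1 activates); bound repressor blocks recruitment
#' completely (its cooperativity is 0). The transcription rate of a target
#' gene is its maximal rate times this occupancy.
#'
#' The occupancy is \eqn{f = Z_{on} / (Z_{off} + Z_{on})} with
#' \eqn{Z_{off} = (1 + K A + K R)^n} and
#' \eqn{Z_{on} = K_{pol} P (1 + c\,K A)^n},
#' the partition sums over promoter states without and with polymerase.
#'
#' @param activator activator concentration (conc, >= 0).
#' @param repressor repressor concentration (conc, >= 0).
#' @param K_tf binding affinity of both factors at the sites (1/conc).
#' @param c_act activator cooperativity (dimensionless; 1 is neutral).
#' @param K_pol polymerase binding affinity (1/conc).
#' @param pol polymerase concentration (conc).
#' @param n_sites number of TF binding sites, 1 or 2 (Gli target genes carry
#'   two sites; the X site on the gli promoter is single).
#' @return Occupancy fraction in \[0, 1\]; vectorized over concentrations.
#' @examples
#' regulation_activity(0, 0, K_tf = 1, c_act = 10, K_pol = 1, pol = 1,
#'                     n_sites = 2)  # empty promoter: K_pol*pol/(1+K_pol*pol)
#' @export
regulation_activity <- function(activator, repressor, K_tf, c_act, K_pol,
                                pol, n_sites = 2) {
  if (any(c(activator, repressor, K_tf, c_act, K_pol, pol) < 0) ||
      anyNA(c(activator, repressor, K_tf, c_act, K_pol, pol)))
    stop("regulation_activity: all inputs must be nonnegative and finite")
  if (!n_sites %in% c(1L, 2L)) stop("n_sites must be 1 or 2")
  z_off <- (1 + K_tf * activator + K_tf * repressor)^n_sites
  z_on <- K_pol * pol * (1 + c_act * K_tf * activator)^n_sites
  z_on / (z_off + z_on)
}
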