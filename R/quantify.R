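# Cq -> relative quantity transformation.
#
# Relative quantities follow the standard delta-Cq rule Q = E^(Cqmin - Cq):
# each gene is anchored at its highest-expressing (lowest-Cq) sample, so
# 0 < Q <= 1 and the per-gene maximum is exactly 1. geNorm's log-ratios are
# invariant to this per-gene anchor.

#' Efficiency-corrected relative quantities
#'
#' Converts a Cq matrix to relative quantities `q_gs = E_g^(Cqmin_g - Cq_gs)`,
#' where `Cqmin_g` is the per-gene minimum over non-missing samples and `E_g`
#' the gene's amplification efficiency (fold change per cycle; 2 at 100%
#' efficiency). Missing Cq stays missing.
#'
#' @param cq numeric genes x samples Cq matrix with dimnames.
#' @param efficiencies named per-gene efficiency vector; genes not named
#'   default to E = 2. A single unnamed number is recycled to all genes.
#' @return matrix of relative quantities, same shape as `cq`, per-gene
#'   maximum 1.
#' @examples
#' cq <- matrix(c(20, 21, 25, 25), 2, byrow = TRUE,
#'              dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' relative_quantities(cq)  # g1: 1, 0.5; g2: 1, 1
#' @export
relative_quantities <- function(cq, efficiencies = NULL) {
  validate_cq_matrix(cq)
  eff <- rep(2.0, nrow(cq))
  names(eff) <- rownames(cq)
  if (!is.null(efficiencies)) {
    if (is.null(names(efficiencies)) && length(efficiencies) == 1) {
      eff[] <- efficiencies
    } else {
      unknown <- setdiff(names(efficiencies), rownames(cq))
      if (length(unknown))
        stop_refstab("efficiency for unknown gene(s): %s",
                     paste(unknown, collapse = ", "), module = "quantify")
      eff[names(efficiencies)] <- efficiencies
    }
  }
  validate_efficiencies(eff)
  all_missing <- rownames(cq)[rowSums(!is.na(cq)) == 0]
  if (length(all_missing))
    stop_refstab("gene(s) with no observed Cq: %s",
                 paste(all_missing, collapse = ", "), module = "quantify")
  cqmin <- apply(cq, 1, min, na.rm = TRUE)
  q <- eff^(cqmin - cq)          # recycles eff and cqmin down columns
  dimnames(q) <- dimnames(cq)
  q
}

#' Amplification efficiency from a standard-curve slope
#'
#' A serial-dilution standard curve regresses Cq on log10(input); its slope
#' determines the per-cycle amplification factor `E = 10^(-1/slope)` and the
#' percent efficiency `(E - 1) * 100`. A perfect doubling per cycle gives
#' slope -3.3219 and 100%. Values outside the assay-validated band
#' 93.9%-106.7% raise a warning.
#'
#' @param slope standard-curve slope in Cq per log10(input); must be negative.
#' @return list with `E` and `percent`.
#' @examples
#' efficiency_from_slope(-3.3219)  # E = 2.000, 100%
#' @export
efficiency_from_slope <- function(slope) {
  if (!is.numeric(slope) || length(slope) != 1 || is.na(slope))
    stop_refstab("slope must be a single number", module = "quantify")
  if (slope >= 0)
    stop_refstab("standard-curve slope must be negative (got %g)", slope,
                 module = "quantify")
  e <- 10^(-1 / slope)
  percent <- (e - 1) * 100
  if (percent < 93.9 || percent > 106.7)
    warn_refstab("efficiency %.1f%% outside the validated band 93.9%%-106.7%%",
                 percent, module = "quantify")
  list(E = e, percent = percent)
}
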