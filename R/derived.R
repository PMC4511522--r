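#' Derived phenotype quantities
#'
#' Closed-form quantities computed from raw instrument readings before any
#' statistics.  All functions are vectorized over their arguments and validate
#' their physical domains.
#'
#' @name derived-phenotypes
NULL

#' Maximum quantum yield of PSII photochemistry from an OJIP transient
#'
#' phi_Po = TR0/ABS = (Fm - F0)/Fm, the maximum quantum yield of primary
#' photosystem II photochemistry estimated from the minimal (F0) and maximal
#' (Fm) chlorophyll fluorescence of the fast OJIP transient.
#'
#' @param f0 minimal fluorescence, arbitrary units, > 0.
#' @param fm maximal fluorescence, same units, > `f0`.
#' @return phi_Po in (0, 1).  Scale-invariant: `phi_po(c*f0, c*fm)` equals
#'   `phi_po(f0, fm)` for any `c > 0`.
#' @examples
#' phi_po(500, 2500)  # 0.8
#' @export
phi_po <- function(f0, fm) {
  .assert(all(is.finite(f0)) && all(is.finite(fm)), "f0 and fm must be finite")
  .assert(all(f0 > 0), "f0 must be positive")
  .assert(all(fm > f0), "fm must exceed f0 (no variable fluorescence otherwise)")
  (fm - f0) / fm
}

#' Relative electrolyte leakage
#'
#' Conductivity measured at a timepoint divided by the total conductivity
#' after complete cell lysis (freezing or autoclaving); a proxy for the
#' fraction of dead cells.  Unitless, so any consistent conductivity unit
#' cancels.
#'
#' @param value_t conductivity at the timepoint, `0 <= value_t <= total`.
#' @param total total conductivity after lysis, > 0.
#' @return ratio in `[0, 1]`.
#' @examples
#' relative_leakage(30, 120)  # 0.25
#' @export
relative_leakage <- function(value_t, total) {
  .assert(all(is.finite(value_t)) && all(is.finite(total)), "inputs must be finite")
  .assert(all(total > 0), "total leakage must be positive")
  .assert(all(value_t >= 0), "conductivity cannot be negative")
  .assert(all(value_t <= total), "timepoint conductivity cannot exceed total leakage")
  value_t / total
}

#' Stomatal conductance response to a closure stimulus
#'
#' Fractional change `(gst16 - gst0)/gst0` of whole-rosette stomatal
#' conductance 16 minutes after a closure stimulus (ozone pulse, darkness,
#' or elevated CO2).  Negative values mean stomatal closure.
#'
#' @param gst0 pre-treatment conductance, > 0.
#' @param gst16 conductance 16 min post-stimulus, same units.
#' @return unitless fractional change.
#' @examples
#' conductance_response(1.0, 0.7)  # -0.3, i.e. 30% closure
#' @export
conductance_response <- function(gst0, gst16) {
  .assert(all(is.finite(gst0)) && all(is.finite(gst16)), "inputs must be finite")
  .assert(all(gst0 > 0), "pre-treatment conductance must be positive")
  .assert(all(gst16 >= 0), "conductance cannot be negative")
  (gst16 - gst0) / gst0
}

#' Salt-to-control germination ratio
#'
#' Germination percentage on salt medium (120 mM NaCl in the motivating
#' screen) divided by the percentage on control medium for the same line.
#'
#' @param pct_salt germination percentage on salt medium, in `[0, 100]`.
#' @param pct_control germination percentage on control medium, in `[0, 100]`.
#' @return unitless ratio; `NA` (with a warning) where `pct_control` is 0,
#'   since the ratio is undefined for lines that never germinate on control
#'   medium.
#' @examples
#' germination_ratio(40, 80)  # 0.5
#' @export
germination_ratio <- function(pct_salt, pct_control) {
  .assert(all(is.finite(pct_salt)) && all(is.finite(pct_control)), "inputs must be finite")
  .assert(all(pct_salt >= 0 & pct_salt <= 100), "pct_salt must be a percentage in [0, 100]")
  .assert(all(pct_control >= 0 & pct_control <= 100), "pct_control must be a percentage in [0, 100]")
  out <- rep(NA_real_, length(pct_salt))
  ok <- pct_control > 0
  if (any(!ok)) {
    warning("germination ratio undefined where control germination is 0%; returning NA")
  }
  out[ok] <- pct_salt[ok] / rep(pct_control, length.out = length(pct_salt))[ok]
  out
}

#' Relative expression by the 2^-ddCt method
#'
#' Fold change of a target transcript in a treatment relative to a control
#' condition, each normalized to reference-gene Ct values:
#' `2^-((ct_target_trt - ct_ref_trt) - (ct_target_ctl - ct_ref_ctl))`.
#' With several reference genes, pass the arithmetic mean of their Cts
#' (equivalent to geometric-mean normalization on the quantity scale).
#'
#' @param ct_target_trt,ct_ref_trt target and reference Ct in the treatment.
#' @param ct_target_ctl,ct_ref_ctl target and reference Ct in the control.
#' @return unitless fold change; 1 means no change.  Swapping treatment and
#'   control inverts the fold change exactly.
#' @examples
#' fold_change_ddct(20, 15, 22, 15)  # ddCt = -2, fold = 4
#' @export
fold_change_ddct <- function(ct_target_trt, ct_ref_trt, ct_target_ctl, ct_ref_ctl) {
  cts <- c(ct_target_trt, ct_ref_trt, ct_target_ctl, ct_ref_ctl)
  .assert(all(is.finite(cts)), "all Ct values must be finite")
  ddct <- (ct_target_trt - ct_ref_trt) - (ct_target_ctl - ct_ref_ctl)
  2^(-ddct)
}

#' Total ROS burst relative to the wild-type reference
#'
#' Sums a line's luminescence (RLU) curve over the recording window and
#' expresses the total as a percentage of the reference total (typically the
#' mean Col-0 total over the same window).
#'
#' @param line_rlu numeric vector of RLU readings over the recording window.
#' @param reference_total reference (wild-type) total RLU, > 0.
#' @return percentage; 100 means equal to the reference.
#' @examples
#' relative_rlu_total(c(10, 20, 30), 60)  # 100
#' @export
relative_rlu_total <- function(line_rlu, reference_total) {
  .assert(all(is.finite(line_rlu)), "RLU readings must be finite")
  .assert(is.finite(reference_total) && reference_total > 0,
          "reference total RLU must be positive")
  100 * sum(line_rlu) / reference_total
}

#' Percent fresh-weight loss
#'
#' Water loss of a detached rosette expressed as the percentage decrease of
#' fresh weight from the initial weight: `100 * (w0 - wt)/w0`.
#'
#' @param w0 initial fresh weight, > 0.
#' @param wt fresh weight at the timepoint, `0 <= wt <= w0` typically.
#' @return percentage loss.
#' @examples
#' water_loss_pct(2.0, 1.5)  # 25
#' @export
water_loss_pct <- function(w0, wt) {
  .assert(all(is.finite(w0)) && all(is.finite(wt)), "weights must be finite")
  .assert(all(w0 > 0), "initial fresh weight must be positive")
  100 * (w0 - wt) / w0
}
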