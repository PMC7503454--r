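#' Minimum number of runs for a target effect size
#'
#' Evaluates the scan-count power formula for a blocked contrast-agent
#' design,
#' \deqn{N_{run} = \frac{8}{TRnum} \left(\frac{\mathrm{erfc}^{-1}(p)}
#'   {tSNR \cdot eff \cdot f}\right)^2,}
#' where `p` is the target voxelwise p-value, `tSNR` the temporal
#' signal-to-noise ratio, `eff` the effect size as a fraction of the mean
#' signal, `f` the contrast-agent sensitivity multiplier (5 for MION), and
#' `TRnum` the number of volumes contributing per run.
#'
#' @param p Target voxelwise p-value.
#' @param tsnr Temporal signal-to-noise ratio.
#' @param eff Effect size as a fraction (0.001 = 0.1%).
#' @param mion_factor Sensitivity multiplier (default 5).
#' @param tr_per_run Volumes per run. The full 16-block design acquires
#'   192; after discarding the first three volumes 189 remain -- pass
#'   whichever convention is wanted, the formula is evaluated exactly as
#'   given.
#' @return Fractional run count.
#' @examples
#' required_runs(p = 1e-3, tsnr = 25, eff = 0.001, tr_per_run = 192)
#' @export
required_runs <- function(p = 1e-3, tsnr = 25, eff = 0.001, mion_factor = 5,
                          tr_per_run = 192) {
  stopifnot(is.numeric(p), p > 0, p < 1, tsnr > 0, eff > 0,
            mion_factor > 0, tr_per_run > 0)
  (8 / tr_per_run) * (pracma::erfcinv(p) / (tsnr * eff * mion_factor))^2
}
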