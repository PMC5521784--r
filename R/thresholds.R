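#' Analysis thresholds
#'
#' Bundles every tunable cutoff of the pipeline in one validated object.
#' Defaults are the study settings: abundance classes split at 1% and 0.1%
#' of total sequences, a two-fold differential threshold, ten time points
#' split after the seventh (`t_cut = 7`) with at least 4 early and 2 late
#' differential statuses required for a call, and a consensus filter run
#' with 1000 resamples of 120 non-pathway families at a 95% coherence
#' threshold.
#'
#' @param high_cut fraction above which a mean abundance is HIGH (default 0.01).
#' @param low_cut fraction below which a mean abundance is RARE (default 0.001).
#' @param fold_threshold minimum abundance ratio counted as differential (default 2).
#' @param t_cut index of the last early-stage time point (default 7).
#' @param early_min minimum differential statuses in the early stage (default 4).
#' @param late_min minimum differential statuses in the late stage (default 2).
#' @param p_threshold consensus coherence threshold in (0.5, 1] (default 0.95).
#' @param n_sim number of resampling runs for the consensus filter (default 1000).
#' @param n_nbrp_sample NBRP taxa drawn per resampling run (default 120).
#' @return A list of class `"and_thresholds"`.
#' @examples
#' th <- and_thresholds(n_sim = 100)
#' th$fold_threshold
#' @export
and_thresholds <- function(high_cut = 0.01, low_cut = 0.001,
                           fold_threshold = 2, t_cut = 7L,
                           early_min = 4L, late_min = 2L,
                           p_threshold = 0.95, n_sim = 1000L,
                           n_nbrp_sample = 120L) {
  stopifnot(is.numeric(high_cut), is.numeric(low_cut),
            is.numeric(fold_threshold), fold_threshold > 0)
  if (!(low_cut > 0 && low_cut < high_cut && high_cut < 1))
    stop("thresholds must satisfy 0 < low_cut < high_cut < 1")
  if (!(p_threshold > 0.5 && p_threshold <= 1))
    stop("p_threshold must lie in (0.5, 1]")
  t_cut <- as.integer(t_cut)
  early_min <- as.integer(early_min)
  late_min <- as.integer(late_min)
  n_sim <- as.integer(n_sim)
  n_nbrp_sample <- as.integer(n_nbrp_sample)
  stopifnot(t_cut >= 1, early_min >= 0, late_min >= 0,
            n_sim >= 1, n_nbrp_sample >= 1)
  structure(
    list(high_cut = high_cut, low_cut = low_cut,
         fold_threshold = fold_threshold, t_cut = t_cut,
         early_min = early_min, late_min = late_min,
         p_threshold = p_threshold, n_sim = n_sim,
         n_nbrp_sample = n_nbrp_sample),
    class = "and_thresholds")
}
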