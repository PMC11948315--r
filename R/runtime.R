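#' Extra epochs charged by the switching controller
#'
#' A completed switching run spends patience epochs beyond each segment's best
#' checkpoint: `p0` in the first segment and `p1` in each of the remaining
#' `afcsLoop - 1` cycles, so the extra budget is
#' \deqn{p_0 + \sum_{i=2}^{\mathrm{loop}} p_1 = p_0 + (\mathrm{loop}-1)\,p_1.}
#' Probe epochs are not part of this cost model and are reported separately by
#' [runAFCS()].
#'
#' @param p0 initial-segment patience (epochs), `>= 1`.
#' @param p1 cycle patience (epochs), `>= 1`.
#' @param afcsLoop number of cycles, `>= 2`.
#' @return integer number of extra epochs. Vectorised over its arguments.
#' @examples
#' extraEpochs(6, 5, 5)  # 26
#' extraEpochs(3, 2, 5)  # 11
#' extraEpochs(2, 1, 5)  # 6
#' @export
extraEpochs <- function(p0, p1, afcsLoop) {
  if (any(p0 < 1) || any(p1 < 1)) stop("p0 and p1 must be >= 1", call. = FALSE)
  if (any(afcsLoop < 2)) stop("afcsLoop must be >= 2", call. = FALSE)
  p0 + (afcsLoop - 1) * p1
}

#' Total runtime of a switching run
#'
#' Base runtime of the underlying model plus the per-epoch runtime times the
#' extra epochs of [extraEpochs()].
#'
#' @param rtCNN total runtime of the underlying model alone (any time unit,
#'   `>= 0`).
#' @param rtEpoch runtime of one training epoch (same unit, `>= 0`).
#' @inheritParams extraEpochs
#' @return estimated total runtime, same unit as `rtCNN`.
#' @examples
#' totalRuntime(100, 1, 2, 1, 5)  # 106
#' @export
totalRuntime <- function(rtCNN, rtEpoch, p0, p1, afcsLoop) {
  if (any(rtCNN < 0) || any(rtEpoch < 0)) stop("runtimes must be >= 0", call. = FALSE)
  rtCNN + rtEpoch * extraEpochs(p0, p1, afcsLoop)
}

#' @rdname totalRuntime
#' @return `runtimeEstimate`: a one-row data frame with columns `rtCNN`,
#'   `rtEpoch`, `extraEpochs` and `total`.
#' @export
runtimeEstimate <- function(rtCNN, rtEpoch, p0, p1, afcsLoop) {
  ex <- extraEpochs(p0, p1, afcsLoop)
  data.frame(rtCNN = rtCNN, rtEpoch = rtEpoch, extraEpochs = ex,
             total = rtCNN + rtEpoch * ex)
}
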