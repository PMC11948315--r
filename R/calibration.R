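#' Count consecutive validation-loss increases in a trace
#'
#' The calibration statistic behind the patience values: the number of
#' epoch-over-epoch strict increases in a per-epoch validation-loss trace,
#' i.e. the number of indices \eqn{i \ge 2} with
#' \eqn{\mathrm{loss}_i > \mathrm{loss}_{i-1}}. A length-1 trace has count 0.
#' The count is invariant under adding a constant to, or positively scaling,
#' the whole trace.
#'
#' @param losses numeric vector of per-epoch validation losses (all finite,
#'   length `>= 1`).
#' @return non-negative integer.
#' @examples
#' countLossIncreases(c(1.0678, 0.6680, 0.5724, 0.5992, 0.5696, 0.5554))  # 1
#' @export
countLossIncreases <- function(losses) {
  if (length(losses) < 1L) stop("trace must have length >= 1", call. = FALSE)
  if (!all(is.finite(losses))) stop("trace contains non-finite losses", call. = FALSE)
  sum(diff(losses) > 0)
}

#' Summarise a table of loss-increase counts
#'
#' Averages per-(experiment) row and then over rows, with two-decimal rounding
#' applied at the row level *before* the overall mean (and again to the overall
#' mean). This mean-of-rounded-row-means convention is deliberate: it is the
#' arithmetic that reproduces the published calibration summaries (e.g. an
#' overall 0.56 where the grand mean over cells would give 0.50). Missing cells
#' (`NA`) are permitted and excluded row-wise.
#'
#' @param counts data frame with a numeric `count` column (one row per cell).
#' @param by character vector of column names defining a summary row
#'   (default `"experiment"`; use `c("experiment", "prev_af")` for tables keyed
#'   by the activation a segment resumed from).
#' @param countCol name of the count column.
#' @return list with `perRow` (a data frame of the `by` keys plus `mean`,
#'   2-dp rounded) and `overall` (2-dp rounded mean of the row means).
#' @examples
#' tab <- data.frame(experiment = rep(c("Exp1", "Exp2", "Exp3"), each = 6),
#'                   count = c(0,3,6,2,3,2, 0,3,4,3,2,1, 1,3,6,1,2,1))
#' summarizeCounts(tab)$overall  # 2.39
#' @export
summarizeCounts <- function(counts, by = "experiment", countCol = "count") {
  stopifnot(is.data.frame(counts), countCol %in% names(counts), all(by %in% names(counts)))
  if (nrow(counts) == 0L) stop("empty counts table", call. = FALSE)
  if (any(counts[[countCol]] < 0, na.rm = TRUE)) stop("counts must be >= 0", call. = FALSE)
  key <- interaction(counts[by], drop = TRUE, lex.order = TRUE)
  empty <- tapply(counts[[countCol]], key, function(v) all(is.na(v)))
  if (any(empty)) {
    warning("dropping rows with no counts: ", paste(names(empty)[empty], collapse = ", "))
    keep <- !(key %in% names(empty)[empty])
    counts <- counts[keep, , drop = FALSE]
    key <- droplevels(key[keep])
  }
  m <- tapply(counts[[countCol]], key, mean, na.rm = TRUE)
  perRow <- unique(counts[by])
  perRow <- perRow[order(interaction(perRow, drop = TRUE, lex.order = TRUE)), , drop = FALSE]
  perRow$mean <- round2(as.numeric(m[levels(key)]))
  rownames(perRow) <- NULL
  list(perRow = perRow, overall = round2(mean(perRow$mean)))
}

# round-half-up to 2 decimals (IEC 60559 banker's rounding would turn 2.675
# into 2.67; the published summaries use half-up)
round2 <- function(x) floor(x * 100 + 0.5) / 100

#' Derive a patience value from an average increase count
#'
#' Round the overall average number of consecutive loss increases to the
#' nearest integer (half up) and allow that many increases, stopping on the
#' next one — i.e. patience = round(mean) + 1. An average of 2.39 gives
#' patience 3; 1.38 gives 2; 0 gives 1 (stop on the first increase).
#'
#' @param overallMean non-negative average increase count.
#' @return integer patience in epochs; non-decreasing in its argument.
#' @examples
#' derivePatience(2.39)  # 3
#' derivePatience(1.38)  # 2
#' @export
derivePatience <- function(overallMean) {
  if (any(overallMean < 0)) stop("mean increase count must be >= 0", call. = FALSE)
  as.integer(floor(overallMean + 0.5)) + 1L
}

#' One-call patience calibration from raw loss traces
#'
#' Counts strict epoch-over-epoch increases per trace, summarises them with
#' [summarizeCounts()] and derives the patience with [derivePatience()].
#'
#' @param traces data frame with columns `experiment`, `af`, `epoch`,
#'   `val_loss` (plus any extra key columns named in `by`); one row per epoch.
#' @param by summary-row key passed on to [summarizeCounts()].
#' @return list with `counts` (one row per trace), `perRow`, `overall` and
#'   `patience`.
#' @export
calibratePatience <- function(traces, by = "experiment") {
  stopifnot(all(c("af", "epoch", "val_loss") %in% names(traces)), all(by %in% names(traces)))
  keyCols <- unique(c(by, "af"))
  key <- interaction(traces[keyCols], drop = TRUE, lex.order = TRUE)
  ord <- order(key, traces$epoch)
  traces <- traces[ord, ]
  key <- key[ord]
  counts <- unique(traces[keyCols])
  counts <- counts[order(interaction(counts, drop = TRUE, lex.order = TRUE)), , drop = FALSE]
  counts$count <- as.integer(tapply(traces$val_loss, key, countLossIncreases)[levels(key)])
  rownames(counts) <- NULL
  s <- summarizeCounts(counts, by = by)
  list(counts = counts, perRow = s$perRow, overall = s$overall,
       patience = derivePatience(s$overall))
}

#' Bundled calibration reference data
#'
#' Reference data from the calibration experiments on Cifar-10 with the VGG16
#' and DenseNet121 backbones, shipped as plain-text CSV:
#' `referenceLossTraces()` returns the per-epoch test-loss traces of the
#' fixed-activation runs (three repeats per model, seven candidate
#' activations); `referenceIncreaseCounts()` returns the published
#' consecutive-increase counts for the initial (`phase = "initial"`, used to
#' set `p0`) and the post-switch (`phase = "next"`, used to set `p1`) training
#' phases; `referenceSwitchSchedules()` returns the published switch
#' schedules of the expansion runs on the plant-seedling
#' (`dataset = "seedling"`) and blindness-detection (`dataset = "aptos"`)
#' image sets (five steps per backbone, step 1 always at epoch 1).
#'
#' @param phase which counts table to load.
#' @param dataset which expansion experiment's schedules to load.
#' @return a data frame.
#' @examples
#' cc <- referenceIncreaseCounts("initial")
#' summarizeCounts(cc[cc$model == "DenseNet121", ])$overall  # 2.39
#' @export
referenceLossTraces <- function() {
  utils::read.csv(system.file("extdata", "calibration_losses_initial.csv",
                              package = "afcs"), stringsAsFactors = FALSE)
}

#' @rdname referenceLossTraces
#' @export
referenceIncreaseCounts <- function(phase = c("initial", "next")) {
  phase <- match.arg(phase)
  f <- sprintf("calibration_counts_%s.csv", phase)
  utils::read.csv(system.file("extdata", f, package = "afcs"),
                  stringsAsFactors = FALSE)
}

#' @rdname referenceLossTraces
#' @export
referenceSwitchSchedules <- function(dataset = c("seedling", "aptos")) {
  dataset <- match.arg(dataset)
  f <- sprintf("switch_schedules_%s.csv", dataset)
  utils::read.csv(system.file("extdata", f, package = "afcs"),
                  stringsAsFactors = FALSE)
}
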