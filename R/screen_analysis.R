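# Screen deconvolution: per-channel normalization, duplicate summarization
# with the CV reproducibility filter, and fold-change classification of
# dropout / retained miRNAs.

#' Classification thresholds for screen hits
#'
#' The screen calls a miRNA a *dropout* when its drug:vehicle signal ratio
#' falls below `dropout_max` (default 0.2) and *retained* when it exceeds
#' `retained_min` (default 5), among miRNAs whose replicate coefficient of
#' variation (CV = 100 x SD/mean) is below `cv_max` (default 60) in both
#' conditions. Both fold comparisons are strict inequalities.
#'
#' @param dropout_max Upper ratio bound for dropouts (exclusive).
#' @param retained_min Lower ratio bound for retained miRNAs (exclusive).
#' @param cv_max CV ceiling, in percent, applied per condition.
#' @param signal_floor Minimum condition mean required to enter
#'   classification; rows at or below the floor are filtered. Default 0,
#'   which filters only zero-mean rows (avoiding infinite ratios).
#' @return An object of class `screen_thresholds`.
#' @examples
#' screen_thresholds()
#' @export
screen_thresholds <- function(dropout_max = 0.2, retained_min = 5,
                              cv_max = 60, signal_floor = 0) {
  if (!(dropout_max > 0 && dropout_max < retained_min)) {
    stop("need 0 < dropout_max < retained_min")
  }
  if (cv_max <= 0) stop("`cv_max` must be positive")
  structure(
    list(dropout_max = dropout_max, retained_min = retained_min,
         cv_max = cv_max, signal_floor = signal_floor),
    class = "screen_thresholds"
  )
}

# shared validation of a long-form signal matrix
check_signal_matrix <- function(matrix) {
  required <- c("mirna_id", "array_id", "condition", "signal")
  missing <- setdiff(required, names(matrix))
  if (length(missing)) {
    stop("signal matrix lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (nrow(matrix) == 0) stop("signal matrix is empty")
  if (!all(matrix$condition %in% c("control", "treated"))) {
    stop("`condition` must be 'control' or 'treated'")
  }
  if (!is.numeric(matrix$signal) || any(is.na(matrix$signal))) {
    stop("`signal` must be numeric and non-missing")
  }
  if (any(matrix$signal < 0)) stop("signals must be non-negative")
  invisible(matrix)
}

#' Normalize two-channel array signals
#'
#' `median_scale` equalizes the per-channel medians: every channel (an
#' array/condition combination) is rescaled by
#' (global median of channel medians) / (that channel's median), so that
#' after normalization all channels share the same median intensity. Any
#' per-channel linear rescaling — e.g. labeling or scanner gain differences
#' between the two dyes — is removed, and downstream fold-change classes are
#' invariant to it. `none` returns the input unchanged.
#'
#' @param matrix Long-form signal matrix (`mirna_id`, `array_id`,
#'   `condition`, `signal`).
#' @param method `"median_scale"` or `"none"`.
#' @return A signal matrix of the same shape with rescaled signals.
#' @examples
#' sig <- data.frame(mirna_id = c("a", "b", "a", "b"), array_id = 1,
#'                   condition = rep(c("control", "treated"), each = 2),
#'                   signal = c(1, 3, 2, 6))
#' normalize_signals(sig)
#' @export
normalize_signals <- function(matrix, method = c("median_scale", "none")) {
  method <- match.arg(method)
  check_signal_matrix(matrix)
  if (method == "none") return(matrix)
  channel <- interaction(matrix$array_id, matrix$condition, drop = TRUE)
  med <- tapply(matrix$signal, channel, stats::median)
  if (any(med <= 0)) {
    bad <- names(med)[med <= 0][1]
    stop("channel ", bad, " has a non-positive median signal; ",
         "cannot median-scale")
  }
  global <- stats::median(med)
  out <- matrix
  out$signal <- matrix$signal * as.numeric(global / med[as.character(channel)])
  rownames(out) <- NULL
  out
}

#' Summarize replicate arrays per miRNA and condition
#'
#' Computes, for every miRNA in every condition, the mean and sample
#' standard deviation (denominator n - 1) of the signal over replicate
#' arrays, and the coefficient of variation CV = 100 x SD / mean. A zero
#' mean leaves the CV undefined (`NA`), which downstream classification
#' treats as a reproducibility-filter failure. With a single array per
#' condition the SD and CV are `NA`.
#'
#' @param matrix Long-form signal matrix.
#' @return A data frame with one row per miRNA x condition: `mirna_id`,
#'   `condition`, `n_arrays`, `mean`, `sd`, `cv`.
#' @examples
#' sig <- data.frame(mirna_id = "miR-574-3p", array_id = 1:2,
#'                   condition = "control", signal = c(132.445, 141.355))
#' summarize_replicates(sig)  # mean 136.9, sd 6.3, cv 4.60
#' @export
summarize_replicates <- function(matrix) {
  check_signal_matrix(matrix)
  key <- interaction(matrix$mirna_id, matrix$condition, drop = TRUE,
                     sep = "\r")
  agg <- function(f) tapply(matrix$signal, key, f)
  n <- agg(length)
  m <- agg(mean)
  s <- agg(function(x) if (length(x) >= 2) stats::sd(x) else NA_real_)
  parts <- strsplit(names(m), "\r", fixed = TRUE)
  out <- data.frame(
    mirna_id = vapply(parts, `[[`, "", 1L),
    condition = vapply(parts, `[[`, "", 2L),
    n_arrays = as.integer(n),
    mean = as.numeric(m),
    sd = as.numeric(s),
    stringsAsFactors = FALSE
  )
  out$cv <- ifelse(out$mean > 0, 100 * out$sd / out$mean, NA_real_)
  out <- out[order(out$mirna_id, out$condition), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify miRNAs as dropout, retained, neutral or filtered
#'
#' Applies the reproducibility filter and the fold-change rule to replicate
#' summaries. A miRNA passes the CV filter (`cv_pass`) when its CV is below
#' `cv_max` in *both* conditions and both condition means exceed
#' `signal_floor`. Among passing miRNAs, the drug:vehicle ratio of condition
#' means classifies each as `dropout` (ratio < `dropout_max`), `retained`
#' (ratio > `retained_min`) or `neutral`; failing miRNAs are `filtered`.
#'
#' @param summaries Replicate summaries from [summarize_replicates()], or a
#'   data frame already in wide per-miRNA form with columns `control_mean`,
#'   `control_sd`, `treated_mean`, `treated_sd` (CVs recomputed if absent).
#' @param thresholds A [screen_thresholds()].
#' @return A data frame of hit records: `mirna_id`, `control_mean`,
#'   `control_sd`, `control_cv`, `treated_mean`, `treated_sd`, `treated_cv`,
#'   `ratio`, `cv_pass`, `hit_class`.
#' @examples
#' s <- data.frame(mirna_id = "miR-574-3p",
#'                 control_mean = 136.9, control_sd = 6.3,
#'                 treated_mean = 22.0, treated_sd = 4.3)
#' classify_hits(s)$hit_class  # "dropout"
#' @export
classify_hits <- function(summaries, thresholds = screen_thresholds()) {
  if (is.null(summaries) || nrow(summaries) == 0) {
    stop("`summaries` must be nonempty")
  }
  wide <- if (all(c("condition", "mean") %in% names(summaries))) {
    widen_summaries(summaries)
  } else {
    w <- summaries
    need <- c("mirna_id", "control_mean", "control_sd",
              "treated_mean", "treated_sd")
    if (!all(need %in% names(w))) {
      stop("wide summaries need columns: ", paste(need, collapse = ", "))
    }
    if (is.null(w$control_cv)) {
      w$control_cv <- ifelse(w$control_mean > 0,
                             100 * w$control_sd / w$control_mean, NA_real_)
    }
    if (is.null(w$treated_cv)) {
      w$treated_cv <- ifelse(w$treated_mean > 0,
                             100 * w$treated_sd / w$treated_mean, NA_real_)
    }
    w
  }

  th <- thresholds
  cv_ok <- !is.na(wide$control_cv) & !is.na(wide$treated_cv) &
    wide$control_cv < th$cv_max & wide$treated_cv < th$cv_max
  floor_ok <- !is.na(wide$control_mean) & !is.na(wide$treated_mean) &
    wide$control_mean > th$signal_floor & wide$treated_mean > th$signal_floor
  cv_pass <- cv_ok & floor_ok
  ratio <- ifelse(wide$control_mean > 0,
                  wide$treated_mean / wide$control_mean, NA_real_)
  hit_class <- ifelse(!cv_pass, "filtered",
               ifelse(ratio < th$dropout_max, "dropout",
               ifelse(ratio > th$retained_min, "retained", "neutral")))
  out <- data.frame(
    mirna_id = wide$mirna_id,
    control_mean = wide$control_mean, control_sd = wide$control_sd,
    control_cv = wide$control_cv,
    treated_mean = wide$treated_mean, treated_sd = wide$treated_sd,
    treated_cv = wide$treated_cv,
    ratio = ratio, cv_pass = cv_pass, hit_class = hit_class,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

widen_summaries <- function(summaries) {
  ctrl <- summaries[summaries$condition == "control", , drop = FALSE]
  trt <- summaries[summaries$condition == "treated", , drop = FALSE]
  ids <- union(ctrl$mirna_id, trt$mirna_id)
  ic <- match(ids, ctrl$mirna_id)
  it <- match(ids, trt$mirna_id)
  data.frame(
    mirna_id = ids,
    control_mean = ctrl$mean[ic], control_sd = ctrl$sd[ic],
    control_cv = ctrl$cv[ic],
    treated_mean = trt$mean[it], treated_sd = trt$sd[it],
    treated_cv = trt$cv[it],
    stringsAsFactors = FALSE
  )
}

# round half away from zero, the convention used for printed ratios
round_half_away <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Dropout and retained hit tables
#'
#' Splits classified hit records into the two published-style tables:
#' dropouts ordered by ascending drug:vehicle ratio and retained miRNAs by
#' descending ratio. The `ratio_2dp` column renders the ratio to two
#' decimals, rounding half away from zero.
#'
#' @param records Hit records from [classify_hits()].
#' @return A list with elements `dropout` and `retained`, each a data frame.
#' @examples
#' s <- data.frame(mirna_id = c("a", "b"),
#'                 control_mean = c(100, 10), control_sd = 1,
#'                 treated_mean = c(10, 100), treated_sd = 1)
#' hit_tables(classify_hits(s))
#' @export
hit_tables <- function(records) {
  empty <- records[0, , drop = FALSE]
  dropout <- records[records$hit_class == "dropout", , drop = FALSE]
  retained <- records[records$hit_class == "retained", , drop = FALSE]
  if (nrow(dropout)) dropout <- dropout[order(dropout$ratio), , drop = FALSE]
  if (nrow(retained)) {
    retained <- retained[order(-retained$ratio), , drop = FALSE]
  }
  fmt <- function(df) {
    df$ratio_2dp <- if (nrow(df)) round_half_away(df$ratio, 2) else numeric(0)
    rownames(df) <- NULL
    df
  }
  list(dropout = fmt(if (nrow(dropout)) dropout else empty),
       retained = fmt(if (nrow(retained)) retained else empty))
}

#' Paired intensities for a reproducibility scatter plot
#'
#' Extracts, for two samples (array/condition channels), the per-miRNA
#' signal pairs restricted to miRNAs passing the CV reproducibility filter —
#' the plotting rule used for duplicate-consistency scatter plots.
#'
#' @param matrix Long-form signal matrix.
#' @param pair Character vector of two sample identifiers of the form
#'   `"<condition>_<array_id>"`, e.g. `c("control_1", "control_2")`.
#' @param cv_max CV ceiling defining the plotted subset (default 60).
#' @return Data frame with columns `mirna_id`, `x`, `y` (intensities in the
#'   first and second sample).
#' @examples
#' scr <- simulate_screen(screen_config(n_mirnas = 30, rng_seed = 1))
#' sc <- reproducibility_scatter(scr$signals, c("control_1", "control_2"))
#' cor(sc$x, sc$y)
#' @export
reproducibility_scatter <- function(matrix, pair, cv_max = 60) {
  check_signal_matrix(matrix)
  if (length(pair) != 2) stop("`pair` must name exactly two samples")
  sample_id <- paste(matrix$condition, matrix$array_id, sep = "_")
  if (!all(pair %in% sample_id)) {
    stop("unknown sample id(s): ",
         paste(setdiff(pair, sample_id), collapse = ", "))
  }
  summ <- summarize_replicates(matrix)
  cv_by_mirna <- tapply(
    summ$cv, summ$mirna_id,
    function(v) all(!is.na(v)) && all(v < cv_max)
  )
  keep <- names(cv_by_mirna)[cv_by_mirna]
  a <- matrix[sample_id == pair[1] & matrix$mirna_id %in% keep, ]
  b <- matrix[sample_id == pair[2] & matrix$mirna_id %in% keep, ]
  i <- match(a$mirna_id, b$mirna_id)
  out <- data.frame(mirna_id = a$mirna_id, x = a$signal, y = b$signal[i],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
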