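# Downstream validation statistics: 2^-ddCt relative quantification,
# dual-luciferase normalization, viability fold changes, IHC positivity,
# and an exact Wilcoxon signed-rank test.

se_of <- function(x) {
  n <- sum(!is.na(x))
  if (n < 2) return(NA_real_)
  stats::sd(x, na.rm = TRUE) / sqrt(n)
}

#' Relative expression by the 2^-ddCt method
#'
#' For each measurement, dCt = Ct(target) - Ct(reference); ddCt subtracts
#' the mean dCt of the calibrator group; the relative quantity is
#' RQ = 2^-ddCt (amplification efficiency taken as exactly 2). The group
#' point estimate is the geometric mean of replicate RQs, i.e.
#' 2^-mean(ddCt), so the calibrator group has RQ exactly 1 by construction;
#' the standard error is the sample SE of the replicate RQ values. Results
#' are invariant to adding a constant to every Ct.
#'
#' @param measurements Data frame with columns `group`, `ct_target`,
#'   `ct_reference` (one row per replicate; other columns are ignored).
#' @param calibrator_group Group label used as the RQ = 1 baseline.
#' @return Data frame with one row per group: `group`, `n`, `rq_mean`,
#'   `rq_se`.
#' @examples
#' m <- data.frame(group = rep(c("ctrl", "kd"), each = 3),
#'                 ct_target = c(24, 24, 24, 23, 23, 23),
#'                 ct_reference = 18)
#' relative_expression(m, "ctrl")  # kd has RQ 2
#' @export
relative_expression <- function(measurements, calibrator_group) {
  need <- c("group", "ct_target", "ct_reference")
  if (!all(need %in% names(measurements))) {
    stop("`measurements` needs columns: ", paste(need, collapse = ", "))
  }
  if (!calibrator_group %in% measurements$group) {
    stop("calibrator group '", calibrator_group, "' not present")
  }
  if (any(!is.finite(measurements$ct_target)) ||
      any(!is.finite(measurements$ct_reference))) {
    stop("Ct values must be finite")
  }
  dct <- measurements$ct_target - measurements$ct_reference
  baseline <- mean(dct[measurements$group == calibrator_group])
  ddct <- dct - baseline
  rq <- 2^(-ddct)
  groups <- unique(measurements$group)
  out <- do.call(rbind, lapply(groups, function(g) {
    sel <- measurements$group == g
    data.frame(group = g,
               n = sum(sel),
               rq_mean = 2^(-mean(ddct[sel])),
               rq_se = se_of(rq[sel]),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Dual-luciferase relative reporter activity
#'
#' Normalizes each well's Renilla signal (the reporter carrying the test
#' 3'-UTR) by its firefly signal (the internal transfection control), then
#' expresses every well relative to the mean normalized value of the
#' reference miRNA arm for the same construct. Wild-type versus mutant
#' constructs can then be compared on a common RQ = 1 baseline.
#'
#' @param wells Data frame with columns `construct`, `mirna_arm`, `renilla`,
#'   `firefly` (and optionally `well_id`, used in error messages).
#' @param reference_arm Label of the control miRNA arm.
#' @param reference_construct Optional: normalize *all* wells against this
#'   single (reference arm, construct) cell instead of same-construct
#'   matching — e.g. against the empty-vector mock.
#' @return Data frame with one row per construct x miRNA arm: `construct`,
#'   `mirna_arm`, `n`, `relative_mean`, `relative_se`.
#' @examples
#' w <- expand.grid(construct = c("wt", "mut"),
#'                  mirna_arm = c("ctrl", "pre-miR"), rep = 1:3)
#' w$firefly <- 1000
#' w$renilla <- ifelse(w$construct == "wt" & w$mirna_arm == "pre-miR",
#'                     250, 500)
#' dual_luciferase(w, reference_arm = "ctrl")
#' @export
dual_luciferase <- function(wells, reference_arm, reference_construct = NULL) {
  need <- c("construct", "mirna_arm", "renilla", "firefly")
  if (!all(need %in% names(wells))) {
    stop("`wells` needs columns: ", paste(need, collapse = ", "))
  }
  if (any(wells$firefly <= 0)) {
    bad <- which(wells$firefly <= 0)[1]
    id <- if (!is.null(wells$well_id)) wells$well_id[bad] else bad
    stop("non-positive firefly signal in well ", id)
  }
  if (!reference_arm %in% wells$mirna_arm) {
    stop("reference arm '", reference_arm, "' not present")
  }
  wells$normalized <- wells$renilla / wells$firefly

  ref_mean_for <- function(construct) {
    ref_c <- if (is.null(reference_construct)) construct else reference_construct
    sel <- wells$mirna_arm == reference_arm & wells$construct == ref_c
    if (!any(sel)) {
      stop("no reference wells for construct '", ref_c, "'")
    }
    mean(wells$normalized[sel])
  }

  cells <- unique(wells[, c("construct", "mirna_arm")])
  out <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    sel <- wells$construct == cells$construct[i] &
      wells$mirna_arm == cells$mirna_arm[i]
    rel <- wells$normalized[sel] / ref_mean_for(cells$construct[i])
    data.frame(construct = cells$construct[i],
               mirna_arm = cells$mirna_arm[i],
               n = sum(sel),
               relative_mean = mean(rel),
               relative_se = se_of(rel),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Viability fold change from absorbance readings
#'
#' Summarizes a colorimetric viability assay (MTS / WST-8 absorbance) as
#' fold changes: the mean absorbance of each group x timepoint divided by a
#' baseline mean. With `baseline = "control_group"` the baseline is the
#' control group at the *same* timepoint; with `"first_timepoint"` it is
#' the group's own earliest timepoint. The SE is propagated from the
#' numerator replicates: SE(fold) = SE(absorbance) / baseline mean.
#'
#' @param readings Data frame with columns `group`, `timepoint`,
#'   `absorbance`.
#' @param baseline `"control_group"` or `"first_timepoint"`.
#' @param control_group Label of the control group (required for
#'   `baseline = "control_group"`).
#' @return Data frame with one row per group x timepoint: `group`,
#'   `timepoint`, `n`, `fold_mean`, `fold_se`.
#' @examples
#' r <- expand.grid(group = c("ctrl", "anti-miR"), timepoint = c(24, 96),
#'                  rep = 1:3)
#' r$absorbance <- ifelse(r$group == "anti-miR" & r$timepoint == 96, 1.2, 0.6)
#' viability_fold(r, control_group = "ctrl")
#' @export
viability_fold <- function(readings,
                           baseline = c("control_group", "first_timepoint"),
                           control_group = NULL) {
  baseline <- match.arg(baseline)
  need <- c("group", "timepoint", "absorbance")
  if (!all(need %in% names(readings))) {
    stop("`readings` needs columns: ", paste(need, collapse = ", "))
  }
  if (any(readings$absorbance < 0)) stop("absorbance must be >= 0")
  if (baseline == "control_group") {
    if (is.null(control_group)) {
      stop("`control_group` must be given for baseline = 'control_group'")
    }
    if (!control_group %in% readings$group) {
      stop("control group '", control_group, "' not present")
    }
  }
  cells <- unique(readings[, c("group", "timepoint")])
  cells <- cells[order(cells$group, cells$timepoint), , drop = FALSE]
  out <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    g <- cells$group[i]; tp <- cells$timepoint[i]
    sel <- readings$group == g & readings$timepoint == tp
    if (!any(sel)) {
      warning("no readings for group ", g, " at timepoint ", tp,
              "; omitted")
      return(NULL)
    }
    base_sel <- if (baseline == "control_group") {
      readings$group == control_group & readings$timepoint == tp
    } else {
      readings$group == g &
        readings$timepoint == min(readings$timepoint[readings$group == g])
    }
    base_mean <- mean(readings$absorbance[base_sel])
    if (!is.finite(base_mean) || base_mean <= 0) {
      stop("baseline mean for group ", g, " at timepoint ", tp,
           " is zero or undefined")
    }
    x <- readings$absorbance[sel]
    data.frame(group = g, timepoint = tp, n = length(x),
               fold_mean = mean(x) / base_mean,
               fold_se = se_of(x) / base_mean,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Positivity proportion of binary case calls
#'
#' @param statuses Logical vector (or 0/1) of per-case positivity calls.
#' @return List with `positive`, `total`, and `percent` (rendered to the
#'   nearest integer percent, half away from zero).
#' @examples
#' positivity_proportion(c(rep(TRUE, 7), rep(FALSE, 3)))  # 70%
#' @export
positivity_proportion <- function(statuses) {
  if (length(statuses) == 0) stop("`statuses` must be nonempty")
  s <- as.logical(statuses)
  if (any(is.na(s))) stop("`statuses` must be binary without missing values")
  pos <- sum(s)
  tot <- length(s)
  list(positive = pos, total = tot,
       percent = round_half_away(100 * pos / tot, 0))
}

# exact null distribution of W+ = sum of ranks of positive differences:
# dynamic programming over 2 x (mid)ranks, so half-integer midranks become
# integer steps. Returns P(W+ = w/2) over w = 0..sum(2r).
signed_rank_null <- function(ranks2) {
  total <- sum(ranks2)
  f <- numeric(total + 1)
  f[1] <- 1
  for (r in ranks2) {
    g <- f
    g[(r + 1):(total + 1)] <- g[(r + 1):(total + 1)] + f[1:(total + 1 - r)]
    f <- g
  }
  f / 2^length(ranks2)
}

#' Wilcoxon signed-rank test with exact enumeration
#'
#' Paired two-sided signed-rank test. Zero differences are dropped
#' (Wilcoxon's original policy) and tied absolute differences receive
#' midranks. In `"exact"` mode the null distribution of the positive-rank
#' sum W is computed over all 2^n sign assignments (supported for n <= 20);
#' in `"approximate"` mode a normal approximation with tie correction and
#' continuity correction is used. The default two-sided exact p-value is
#' `P(|W - E[W]| >= |w_obs - E[W]|)` under the enumerated null
#' (`two_sided = "symmetric"`); `two_sided = "double_tail"` doubles the
#' smaller one-sided tail instead (capped at 1), matching the convention of
#' [stats::wilcox.test()].
#'
#' @param case,control Paired numeric vectors, or a data frame in `case`
#'   with columns `case_value` and `control_value`.
#' @param mode `"exact"` or `"approximate"`.
#' @param two_sided Two-sided p-value convention for exact mode.
#' @return List with `statistic` (W, positive-rank sum), `p_value`,
#'   `n_used` (pairs after zero-difference removal), `n_zero`, `mode`.
#' @examples
#' wilcoxon_signed_rank(c(3, 5, 4, 6, 8), c(1, 2, 3, 4, 5))
#' @export
wilcoxon_signed_rank <- function(case, control = NULL,
                                 mode = c("exact", "approximate"),
                                 two_sided = c("symmetric", "double_tail")) {
  mode <- match.arg(mode)
  two_sided <- match.arg(two_sided)
  if (is.data.frame(case)) {
    if (!all(c("case_value", "control_value") %in% names(case))) {
      stop("paired data frame needs columns case_value, control_value")
    }
    control <- case$control_value
    case <- case$case_value
  }
  if (length(case) != length(control)) {
    stop("`case` and `control` must have the same length")
  }
  d <- case - control
  if (any(!is.finite(d))) stop("paired values must be finite")
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stop("all differences are zero; test undefined")
  r <- rank(abs(d))  # midranks for ties
  w <- sum(r[d > 0])
  mu <- sum(r) / 2

  if (mode == "exact") {
    if (n > 20) {
      stop("exact mode supports up to 20 nonzero pairs; use approximate")
    }
    ranks2 <- as.integer(round(2 * r))
    null <- signed_rank_null(ranks2)
    w_grid <- (seq_along(null) - 1) / 2  # support of W
    if (two_sided == "symmetric") {
      p <- sum(null[abs(w_grid - mu) >= abs(w - mu) - 1e-9])
    } else {
      lower <- sum(null[w_grid <= w + 1e-9])
      upper <- sum(null[w_grid >= w - 1e-9])
      p <- min(1, 2 * min(lower, upper))
    }
  } else {
    sigma <- sqrt(sum(r^2) / 4)
    # continuity correction toward the mean
    z <- (w - mu - sign(w - mu) * 0.5) / sigma
    p <- 2 * stats::pnorm(-abs(z))
    p <- min(1, p)
  }
  list(statistic = w, p_value = p, n_used = n, n_zero = n_zero, mode = mode)
}
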