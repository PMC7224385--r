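## Nonparametric trend classification: Mann-Kendall test for monotonicity
## plus the Theil-Sen slope for direction and effect size. Exact null
## distribution of S (via the inversion-number generating function) for
## tie-free series of length <= 8; tie-corrected normal approximation with
## continuity correction otherwise.

## exact null counts of the number of inversions of a permutation of n
## items: coefficients of prod_{k=1}^{n} (1 + x + ... + x^(k-1))
inversionCounts <- function(n) {
  counts <- 1
  for (k in seq_len(n)) {
    newc <- numeric(length(counts) + k - 1)
    for (shift in 0:(k - 1))
      newc[shift + seq_along(counts)] <- newc[shift + seq_along(counts)] +
        counts
    counts <- newc
  }
  counts  # counts[i+1] = number of permutations with i inversions
}

#' Mann-Kendall trend test
#'
#' \eqn{S = \sum_{i<j} \mathrm{sign}(x_j - x_i)}. The p-value (two-sided) is
#' exact for tie-free series of length up to 8 and uses the tie-corrected
#' normal approximation with continuity correction otherwise. A series with
#' zero variance (all ties) returns p = 1.
#'
#' @param x numeric series (no missing values), length >= 4.
#' @return list with elements `S` and `p_value`.
#' @examples
#' mannKendall(1:8)  # S = 28, p ~ 5e-5
#' @export
mannKendall <- function(x) {
  n <- length(x)
  if (n < 4) stop("Mann-Kendall test needs at least 4 observations")
  if (anyNA(x)) stop("missing values must be dropped upstream")
  d <- sign(outer(x, x, "-"))
  S <- sum(d[lower.tri(d)])  # d[j, i] = sign(x_j - x_i) for j > i
  ties <- table(x)
  hasTies <- any(ties > 1)
  if (!hasTies && n <= 8) {
    counts <- inversionCounts(n)
    sVals <- n * (n - 1) / 2 - 2 * seq(0, length(counts) - 1)
    p <- if (S == 0) 1
         else min(1, 2 * sum(counts[abs(sVals) >= abs(S) &
                                      sign(sVals) == sign(S)]) / sum(counts))
  } else {
    t <- as.numeric(ties)
    varS <- (n * (n - 1) * (2 * n + 5) -
               sum(t * (t - 1) * (2 * t + 5))) / 18
    p <- if (varS <= 0 || S == 0) 1
         else 2 * stats::pnorm(-abs((S - sign(S)) / sqrt(varS)))
  }
  list(S = S, p_value = p)
}

#' Theil-Sen slope
#'
#' Median of all pairwise slopes \eqn{(x_j - x_i)/(t_j - t_i)}, i < j.
#'
#' @param x numeric series.
#' @param times observation times, no duplicates; default equally spaced.
#' @return The slope (units of x per unit time).
#' @export
theilSen <- function(x, times = seq_along(x)) {
  stopifnot(length(x) == length(times), length(x) >= 2)
  if (anyDuplicated(times)) stop("duplicate observation times")
  ij <- utils::combn(length(x), 2)
  stats::median((x[ij[2, ]] - x[ij[1, ]]) / (times[ij[2, ]] - times[ij[1, ]]))
}

#' Classify one band's time series
#'
#' `increasing` when the Mann-Kendall p-value is below `alpha` AND the
#' Theil-Sen slope exceeds `+minRelSlope`; `decreasing` symmetrically;
#' otherwise `stable`. The series is expected renormalised to its first
#' point, so `minRelSlope` is a fractional change per hour.
#'
#' @param x renormalised intensity series (dimensionless), no missing
#'   values, length >= 4.
#' @param times observation times (h).
#' @param alpha significance level; default 0.05.
#' @param minRelSlope minimal relevant slope (fraction/h); default 0.03.
#' @return data.frame: `sen_slope`, `mk_S`, `p_value`, `label`.
#' @export
classifyTrend <- function(x, times = seq_along(x), alpha = 0.05,
                          minRelSlope = 0.03) {
  mk <- mannKendall(x)
  slope <- theilSen(x, times)
  label <- if (mk$p_value < alpha && slope > minRelSlope) "increasing"
           else if (mk$p_value < alpha && slope < -minRelSlope) "decreasing"
           else "stable"
  data.frame(sen_slope = slope, mk_S = mk$S, p_value = mk$p_value,
             label = label, stringsAsFactors = FALSE)
}

#' Trend report for one condition
#'
#' One classification per catalogue band plus the agreement fraction against
#' the catalogue's expected trend column.
#'
#' @slot condition `"no_stress"` or `"inh_stress"`.
#' @slot results data.frame, one row per catalogue band.
#' @slot agreementFraction share of labels equal to the catalogue column.
#' @export
setClass("TrendTable",
  representation(condition = "character", results = "data.frame",
                 agreementFraction = "numeric"))

setValidity("TrendTable", function(object) {
  msg <- character()
  if (!object@condition %in% c("no_stress", "inh_stress"))
    msg <- c(msg, "condition must be 'no_stress' or 'inh_stress'")
  if (object@agreementFraction < 0 || object@agreementFraction > 1)
    msg <- c(msg, "agreementFraction must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

setMethod("show", "TrendTable", function(object) {
  cat(sprintf("TrendTable (%s): %d bands, agreement %.2f\n",
              object@condition, nrow(object@results),
              object@agreementFraction))
  print(object@results[, c("reference_cm1", "label", "sen_slope",
                           "p_value", "expected")], digits = 3)
})

#' @rdname TrendTable-class
#' @param object a `TrendTable`.
#' @export
trendResults <- function(object) {
  stopifnot(is(object, "TrendTable"))
  object@results
}

#' @rdname TrendTable-class
#' @export
agreementFraction <- function(object) {
  stopifnot(is(object, "TrendTable"))
  object@agreementFraction
}

#' Build the per-condition trend report
#'
#' Classifies each catalogue band's quantified series and scores agreement
#' with the catalogue's expected trend column. Bands with fewer than 4
#' usable time points are labelled `stable` with a missing-data flag. When
#' `collapseAtH` is given, only observations at or before that time enter
#' the classification (the labels describe the pre-collapse window).
#'
#' @param quant output of [quantifyRun()].
#' @param condition `"no_stress"` or `"inh_stress"`.
#' @param catalogue reference catalogue; default [referencePeaks()].
#' @param alpha significance level.
#' @param minRelSlope minimal relevant slope (fraction/h).
#' @param collapseAtH optional cutoff time (h).
#' @return A [TrendTable-class].
#' @export
buildTrendTable <- function(quant, condition = c("no_stress", "inh_stress"),
                            catalogue = referencePeaks(), alpha = 0.05,
                            minRelSlope = 0.03, collapseAtH = NA_real_) {
  condition <- match.arg(condition)
  if (!is.na(collapseAtH))
    quant <- quant[quant$timestamp_h <= collapseAtH, , drop = FALSE]
  expCol <- if (condition == "no_stress") catalogue$trend_no_stress
            else catalogue$trend_inh
  val <- if ("normalized" %in% names(quant) &&
             any(!is.na(quant$normalized))) "normalized" else "peak_to_valley"
  nUsable <- vapply(catalogue$position_cm1, function(p)
    sum(quant$reference_cm1 == p & !is.na(quant[[val]])), integer(1))
  if (max(nUsable) < 4)
    stop("insufficient time points for trend classification (need >= 4)")
  rows <- lapply(seq_len(nrow(catalogue)), function(i) {
    p <- catalogue$position_cm1[i]
    sub <- quant[quant$reference_cm1 == p & !is.na(quant[[val]]), ]
    if (nrow(sub) < 4) {
      res <- data.frame(sen_slope = NA_real_, mk_S = NA_real_,
                        p_value = NA_real_, label = "stable",
                        stringsAsFactors = FALSE)
      miss <- TRUE
    } else {
      res <- classifyTrend(sub[[val]], sub$timestamp_h, alpha, minRelSlope)
      miss <- FALSE
    }
    cbind(data.frame(reference_cm1 = p, assignment = catalogue$assignment[i],
                     stringsAsFactors = FALSE),
          res,
          data.frame(expected = expCol[i], missing_data = miss,
                     stringsAsFactors = FALSE))
  })
  results <- do.call(rbind, rows)
  results$agree <- results$label == results$expected
  new("TrendTable", condition = condition, results = results,
      agreementFraction = mean(results$agree))
}

#' Majority vote across replicate runs
#'
#' Per-band consensus label over several replicate trend tables (the
#' three-replicate design); ties fall back to `stable`.
#'
#' @param tables list of [TrendTable-class] objects for the same condition.
#' @return data.frame: `reference_cm1`, `label`.
#' @export
majorityVoteTrends <- function(tables) {
  stopifnot(length(tables) >= 1)
  labs <- sapply(tables, function(tt) trendResults(tt)$label)
  refs <- trendResults(tables[[1]])$reference_cm1
  vote <- apply(matrix(labs, nrow = length(refs)), 1, function(v) {
    tb <- sort(table(v), decreasing = TRUE)
    if (length(tb) > 1 && tb[1] == tb[2]) "stable" else names(tb)[1]
  })
  data.frame(reference_cm1 = refs, label = vote, stringsAsFactors = FALSE)
}
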