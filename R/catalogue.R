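#' Reference catalogue of tracked fingerprint bands
#'
#' The 13 Raman bands tracked throughout an experiment, with their most likely
#' assignments and the expected intensity trend over up to 8 h under the two
#' culture conditions (plain growth medium, and medium with isoniazid at the
#' minimum inhibitory concentration). Assignments are carried as metadata
#' only; no computation is attached to them.
#'
#' @return A data.frame with columns `position_cm1` (band centre, cm^-1),
#'   `assignment` (free text), `trend_no_stress` and `trend_inh` (each one of
#'   `"increasing"`, `"stable"`, `"decreasing"`).
#' @examples
#' referencePeaks()
#' @export
referencePeaks <- function() {
  out <- data.frame(
    position_cm1 = c(635, 783, 1007, 1040, 1080, 1130, 1150,
                     1303, 1443, 1523, 1606, 1658, 1750),
    assignment = c(
      "tyrosine (C-C, C-S)",
      "nucleic acids",
      "phenylalanine (C-C)",
      "carbohydrates",
      "lipids/carbohydrates/proteins (C-C, C-O-H, C-N, C-O)",
      "carbohydrates/proteins/lipids (C-N, C-C, C-O)",
      "carotenoids (C-C)",
      "lipids (CH2)",
      "lipids/proteins (CH2, CH3)",
      "carotenoids (C=C)",
      "tyrosine/phenylalanine (C=C)",
      "lipids/proteins/amide I (C=C, C=O)",
      "lipids (C=O)"),
    trend_no_stress = c("increasing", "increasing", "stable", "increasing",
                        "decreasing", "increasing", "decreasing", "stable",
                        "stable", "decreasing", "increasing", "decreasing",
                        "decreasing"),
    trend_inh = c("increasing", "stable", "stable", "increasing",
                  "increasing", "increasing", "decreasing", "increasing",
                  "increasing", "decreasing", "increasing", "increasing",
                  "increasing"),
    stringsAsFactors = FALSE)
  stopifnot(!anyDuplicated(out$position_cm1))
  out
}

#' Bands treated as carotenoid pigment signatures
#'
#' The 1150 and 1523 cm^-1 bands decay rapidly once cells are resuspended in
#' fresh medium; the synthetic scenarios model them with exponential decay
#' rather than a linear ramp.
#' @return Numeric vector of band centres (cm^-1).
#' @export
carotenoidPeaks <- function() c(1150, 1523)
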