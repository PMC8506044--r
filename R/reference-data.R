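#' Reference confusion matrices for a pooled-variant noise classifier
#'
#' Reported confusion matrices of an XGBoost signal/noise variant classifier
#' evaluated on pooled tumor-only RNA-seq callsets from FFPE tumor samples
#' with matched WES gold standards: a training pool of 458,957 called
#' variants and a testing pool of 375,148. Positive class is signal
#' (variant matched in WES by coordinate). Used for internal-consistency
#' checks (the four cells of each matrix must sum to the pooled variant
#' count) and documentation examples.
#'
#' @return Data frame with columns `dataset` (`"training"`, `"testing"`),
#'   `TN`, `FN`, `FP`, `TP`, `pool_total`.
#' @export
reference_confusion <- function() {
  data.frame(
    dataset = c("training", "testing"),
    TN = c(457276L, 373731L),
    FN = c(1050L, 1218L),
    FP = c(60L, 101L),
    TP = c(571L, 98L),
    pool_total = c(458957L, 375148L),
    stringsAsFactors = FALSE
  )
}
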