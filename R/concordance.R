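# Concordance of RNA-seq TMB against WES TMB across a cohort: correlations
# with two-sided p-values and ROC AUC of RNA-seq TMB as a continuous score
# for the WES-defined high/low classes.

#' Correlation with p-value
#'
#' Product-moment (Pearson) or rank (Spearman, mid-ranks for ties)
#' correlation with a two-sided p-value. A constant input vector leaves the
#' coefficient undefined: NA is returned with a warning.
#'
#' @param x,y Numeric vectors of equal length >= 3 with finite values.
#' @param method `"pearson"` or `"spearman"`.
#' @return List with elements `estimate` and `p_value`.
#' @export
correlation <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (length(x) < 3) stop("need at least 3 paired observations")
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("correlation requires finite values")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant vector: correlation undefined")
    return(list(estimate = NA_real_, p_value = NA_real_))
  }
  ct <- suppressWarnings(
    cor.test(x, y, method = method, alternative = "two.sided", exact = FALSE))
  list(estimate = unname(ct$estimate), p_value = ct$p.value)
}

#' ROC AUC (rank / Mann-Whitney formulation)
#'
#' The probability that a randomly chosen positive outranks a randomly
#' chosen negative, with ties counted one half. Computed from mid-ranks, so
#' it is exactly the normalized Mann-Whitney U statistic.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param binary_labels Positive-class indicator: logical, 0/1 numeric, or a
#'   factor/character with levels interpretable as 0/1.
#' @return AUC in `[0, 1]`, or NA (with a warning) if a class is absent.
#' @export
roc_auc <- function(scores, binary_labels) {
  y <- as.logical_labels(binary_labels)
  if (length(scores) != length(y)) stop("scores and labels lengths differ")
  n_pos <- sum(y); n_neg <- sum(!y)
  if (n_pos == 0 || n_neg == 0) {
    warning("one class absent: AUC not applicable")
    return(NA_real_)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[y]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

as.logical_labels <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1))) stop("numeric labels must be 0/1")
    return(labels == 1)
  }
  labels <- as.character(labels)
  if (all(labels %in% c("high", "low"))) return(labels == "high")
  if (all(labels %in% c("signal", "noise"))) return(labels == "signal")
  if (all(labels %in% c("0", "1"))) return(labels == "1")
  stop("cannot interpret labels as a binary indicator")
}

#' Build a cohort concordance report
#'
#' Pairs per-sample RNA-seq and WES TMB values by sample id, computes Pearson
#' and Spearman correlations, and for each threshold derives high/low gold
#' labels from the WES TMB (the gold standard side, always) and scores them
#' with the raw RNA-seq TMB values via ROC AUC. Thresholds whose positive or
#' negative class is empty get an NA AUC.
#'
#' @param rnaseq_tmbs,wes_tmbs Data frames with columns `sample_id` and
#'   `tmb` (as produced by [tmb_table()]), or lists of `rnatmb_tmb` objects.
#' @param thresholds Numeric TMB thresholds; default `c(6, 10, 20)`.
#' @param mode Pipeline mode annotation carried into the report.
#' @return An `rnatmb_concordance` object.
#' @export
build_concordance_report <- function(rnaseq_tmbs, wes_tmbs,
                                     thresholds = c(6, 10, 20),
                                     mode = NA_character_) {
  as_tbl <- function(x) if (is.data.frame(x)) x else tmb_table(x)
  rna <- as_tbl(rnaseq_tmbs); wes <- as_tbl(wes_tmbs)
  unmatched <- c(setdiff(rna$sample_id, wes$sample_id),
                 setdiff(wes$sample_id, rna$sample_id))
  if (length(unmatched)) {
    stop("sample ids do not match between RNA-seq and WES TMB tables: ",
         paste(unique(unmatched), collapse = ", "))
  }
  wes <- wes[match(rna$sample_id, wes$sample_id), , drop = FALSE]
  pairs <- data.frame(sample_id = rna$sample_id, rnaseq_tmb = rna$tmb,
                      wes_tmb = wes$tmb, mode = mode,
                      stringsAsFactors = FALSE)
  pe <- correlation(pairs$rnaseq_tmb, pairs$wes_tmb, "pearson")
  sp <- correlation(pairs$rnaseq_tmb, pairs$wes_tmb, "spearman")
  aucs <- positives <- setNames(numeric(length(thresholds)),
                                as.character(thresholds))
  for (i in seq_along(thresholds)) {
    gold <- classify_tmb(pairs$wes_tmb, thresholds[i])
    positives[i] <- sum(gold == "high")
    aucs[i] <- if (positives[i] == 0 || positives[i] == length(gold)) {
      NA_real_
    } else {
      roc_auc(pairs$rnaseq_tmb, gold)
    }
  }
  structure(list(pairs = pairs,
                 pearson_r = pe$estimate, pearson_p = pe$p_value,
                 spearman_rho = sp$estimate, spearman_p = sp$p_value,
                 auc_by_threshold = aucs,
                 positives_by_threshold = positives),
            class = "rnatmb_concordance")
}

#' @export
print.rnatmb_concordance <- function(x, ...) {
  cat(sprintf("<rnatmb_concordance> n=%d pairs\n", nrow(x$pairs)))
  cat(sprintf("  Pearson r   = %.3f (p = %.3g)\n", x$pearson_r, x$pearson_p))
  cat(sprintf("  Spearman rho= %.3f (p = %.3g)\n", x$spearman_rho,
              x$spearman_p))
  for (thr in names(x$auc_by_threshold)) {
    cat(sprintf("  AUC (TMB >= %s) = %s  [%d positives]\n", thr,
                ifelse(is.na(x$auc_by_threshold[[thr]]), "NA",
                       sprintf("%.3f", x$auc_by_threshold[[thr]])),
                x$positives_by_threshold[[thr]]))
  }
  invisible(x)
}

#' Serialize / deserialize a concordance report
#'
#' JSON round trip that preserves pairs, correlations and per-threshold AUCs.
#'
#' @param report An `rnatmb_concordance` object.
#' @param path Output (input) file path.
#' @return `path` invisibly; `read_concordance_report()` returns the report.
#' @export
write_concordance_report <- function(report, path) {
  x <- unclass(report)
  # named vectors serialize as JSON objects, keyed by threshold
  x$auc_by_threshold <- as.list(x$auc_by_threshold)
  x$positives_by_threshold <- as.list(x$positives_by_threshold)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_concordance_report
#' @export
read_concordance_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$pairs <- as.data.frame(x$pairs, stringsAsFactors = FALSE)
  num_or_na <- function(v) {
    vapply(v, function(e) if (is.null(e)) NA_real_ else as.numeric(e),
           numeric(1))
  }
  x$auc_by_threshold <- num_or_na(as.list(x$auc_by_threshold))
  x$positives_by_threshold <- num_or_na(as.list(x$positives_by_threshold))
  for (f in c("pearson_r", "pearson_p", "spearman_rho", "spearman_p")) {
    x[[f]] <- if (is.null(x[[f]])) NA_real_ else as.numeric(x[[f]])
  }
  structure(x, class = "rnatmb_concordance")
}
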