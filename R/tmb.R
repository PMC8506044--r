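# TMB computation and threshold dichotomization.

tmb_modes <- c("isec", "rule", "ml", "wes_matched", "wes_tumor_only")

#' Compute tumor mutation burden
#'
#' TMB is the number of variants falling inside the analyzed regions divided
#' by the region size in megabases. The callset is expected to be filtered
#' already according to the requested mode; variants outside the regions are
#' excluded from the count before division. Both substitutions and indels
#' count, irrespective of functional consequence. There is no default
#' denominator: an explicit region set is required, and an empty one is an
#' error rather than a silent infinity.
#'
#' @param callset An `rnatmb_callset`.
#' @param regions An `rnatmb_regions` object with positive total size.
#' @param mode One of `"isec"`, `"rule"`, `"ml"`, `"wes_matched"`,
#'   `"wes_tumor_only"`.
#' @return An `rnatmb_tmb` object: list with `sample_id`, `variant_count`,
#'   `region_megabases`, `tmb`, `mode`.
#' @export
compute_tmb <- function(callset, regions, mode) {
  mode <- match.arg(mode, tmb_modes)
  if (!inherits(regions, "rnatmb_regions") || regions$total_megabases <= 0) {
    stop("compute_tmb requires a region set with total_megabases > 0")
  }
  v <- callset$variants
  count <- if (nrow(v) == 0) 0L else {
    hits <- GenomicRanges::countOverlaps(variants_granges(v),
                                         regions$granges)
    sum(hits > 0)
  }
  structure(list(sample_id = callset$sample_id,
                 variant_count = as.integer(count),
                 region_megabases = regions$total_megabases,
                 tmb = count / regions$total_megabases,
                 mode = mode),
            class = "rnatmb_tmb")
}

#' @export
print.rnatmb_tmb <- function(x, ...) {
  cat(sprintf("<rnatmb_tmb> %s [%s]: %d variants / %.4f Mb = %.3f Mut/Mb\n",
              x$sample_id, x$mode, x$variant_count, x$region_megabases,
              x$tmb))
  invisible(x)
}

#' Dichotomize TMB at a clinical threshold
#'
#' @param tmb Nonnegative TMB value(s) in mutations per megabase.
#' @param threshold Positive threshold; the clinically used values are 6, 10
#'   and 20 Mut/Mb.
#' @return `"high"` if `tmb >= threshold` (inclusive), else `"low"`.
#' @export
classify_tmb <- function(tmb, threshold) {
  if (any(is.na(tmb)) || any(tmb < 0)) stop("tmb must be nonnegative")
  if (length(threshold) != 1 || threshold <= 0) {
    stop("threshold must be a single positive value")
  }
  ifelse(tmb >= threshold, "high", "low")
}

#' Collect TMB estimates into a table
#'
#' @param estimates List of `rnatmb_tmb` objects.
#' @return Data frame with columns `sample_id`, `variant_count`,
#'   `region_megabases`, `tmb`, `mode`.
#' @export
tmb_table <- function(estimates) {
  do.call(rbind, lapply(estimates, function(e) {
    data.frame(sample_id = e$sample_id, variant_count = e$variant_count,
               region_megabases = e$region_megabases, tmb = e$tmb,
               mode = e$mode, stringsAsFactors = FALSE)
  }))
}
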