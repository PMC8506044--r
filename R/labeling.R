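# Signal/noise labeling of RNA-seq variants against a WES gold standard.

#' Label RNA-seq variants by WES cross-reference
#'
#' Each RNA-seq variant is labeled `"signal"` if a variant at the same
#' genomic coordinate (default) or with the same full key is present in the
#' WES reference callset, and `"noise"` otherwise. For pooled (merged)
#' callsets, matching is always performed against the WES callset of the
#' variant's own origin sample: cross-sample matching would corrupt labels.
#'
#' @param rnaseq An `rnatmb_callset` (single-sample or pooled).
#' @param wes Either a single `rnatmb_callset` (applied to every sample) or a
#'   named list of per-sample WES callsets, keyed by sample id. WES callsets
#'   should already be filtered by the applicable rule recipe.
#' @param match_mode `"coordinate_only"` (default, the labeling rule) or
#'   `"full_key"`.
#' @return An `rnatmb_labeled` object: list with elements `callset`,
#'   `labels` (character vector in `{"signal","noise"}`), `match_mode`.
#' @export
label_by_wes <- function(rnaseq, wes,
                         match_mode = c("coordinate_only", "full_key")) {
  match_mode <- match.arg(match_mode)
  v <- rnaseq$variants
  if (inherits(wes, "rnatmb_callset")) {
    wes <- setNames(list(wes), NA_character_)
    per_sample <- FALSE
  } else {
    per_sample <- TRUE
    missing_ids <- setdiff(unique(v$sample_id), names(wes))
    if (length(missing_ids)) {
      stop("no WES reference callset for sample(s): ",
           paste(missing_ids, collapse = ", "))
    }
  }
  total_wes <- sum(vapply(wes, n_variants, numeric(1)))
  if (total_wes == 0 && nrow(v) > 0) {
    warning("empty WES reference: all RNA-seq variants labeled noise")
  }
  labels <- rep("noise", nrow(v))
  keys <- variant_key(v, match_mode)
  if (per_sample) {
    for (sid in unique(v$sample_id)) {
      rows <- v$sample_id == sid
      ref_keys <- variant_key(wes[[sid]]$variants, match_mode)
      labels[rows][keys[rows] %in% ref_keys] <- "signal"
    }
  } else {
    ref_keys <- variant_key(wes[[1]]$variants, match_mode)
    labels[keys %in% ref_keys] <- "signal"
  }
  structure(list(callset = rnaseq, labels = labels, match_mode = match_mode),
            class = "rnatmb_labeled")
}

#' @export
print.rnatmb_labeled <- function(x, ...) {
  cat(sprintf("<rnatmb_labeled> %d variants: %d signal, %d noise (%s)\n",
              length(x$labels), sum(x$labels == "signal"),
              sum(x$labels == "noise"), x$match_mode))
  invisible(x)
}
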