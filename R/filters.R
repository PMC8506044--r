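# Deterministic rule-based filtering recipes for the three callset flavors.
#
# Matched-normal WES callsets need only FILTER==PASS: the caller has already
# removed germline variants using the normal sample. Tumor-only callsets
# (WES or RNAseq) additionally need population-frequency and dbSNP filters to
# discard germline variants, since no matched normal is available.

#' Filtering configuration for tumor-only callsets
#'
#' @param exac_threshold Population allele-frequency rarity cutoff; variants
#'   with annotated frequency at or above this value are considered germline
#'   and removed (strict `<` comparison for retention). Default `0.000033`.
#' @param allowed_rnaseq_filter_sets List of caller filter-label sets that an
#'   RNA-seq tumor-only variant may carry and still be retained. The default
#'   whitelist is the empty set (PASS), `{germline_risk}`, and
#'   `{germline_risk, panel_of_normals}`: in tumor-only mode the caller flags
#'   most true somatic variants as `germline_risk`, so those labels carry
#'   candidate somatic variants rather than rejects. Pass a list without
#'   `character(0)` for the stricter reading that drops PASS records.
#' @param require_no_dbsnp Remove variants with a dbSNP identifier (either
#'   VCF ID column or annotation field). Default `TRUE`.
#' @return An object of class `rnatmb_filter_config`.
#' @export
filter_config <- function(exac_threshold = 0.000033,
                          allowed_rnaseq_filter_sets = list(
                            character(0),
                            "germline_risk",
                            c("germline_risk", "panel_of_normals")),
                          require_no_dbsnp = TRUE) {
  if (!is.numeric(exac_threshold) || exac_threshold <= 0 ||
      exac_threshold >= 1) {
    stop("exac_threshold must lie strictly between 0 and 1")
  }
  sets <- lapply(allowed_rnaseq_filter_sets,
                 function(s) sort(unique(as.character(s))))
  structure(list(exac_threshold = exac_threshold,
                 allowed_rnaseq_filter_sets = sets,
                 require_no_dbsnp = isTRUE(require_no_dbsnp)),
            class = "rnatmb_filter_config")
}

check_source <- function(callset, expected, fun) {
  if (!inherits(callset, "rnatmb_callset")) {
    stop(fun, " expects an rnatmb_callset")
  }
  if (callset$source != expected) {
    stop(fun, " requires source '", expected, "', got '", callset$source, "'")
  }
}

# absent frequency passes the rarity filter: a variant never observed in the
# population panel is treated as rare, not as frequency 0-vs-threshold unknown
exac_rare <- function(freq, threshold) is.na(freq) | freq < threshold

#' Filter a matched-normal WES callset
#'
#' Retains exactly the variants with an empty filter-label set (PASS).
#'
#' @param callset An `rnatmb_callset` with source `"wes_matched"`.
#' @return The filtered callset (subset of the input).
#' @export
filter_wes_matched <- function(callset) {
  check_source(callset, "wes_matched", "filter_wes_matched")
  keep <- callset$variants$filter == ""
  callset$variants <- callset$variants[keep, , drop = FALSE]
  rownames(callset$variants) <- NULL
  record_provenance(callset, "filter_wes_matched(FILTER==PASS)")
}

#' Filter a tumor-only WES callset
#'
#' Retains variants that are PASS, have ExAC ALL frequency below the rarity
#' threshold (or no ExAC annotation), and carry no dbSNP identifier.
#'
#' @param callset An `rnatmb_callset` with source `"wes_tumor_only"`.
#' @param config An [filter_config()] object.
#' @return The filtered callset.
#' @export
filter_wes_tumor_only <- function(callset, config = filter_config()) {
  check_source(callset, "wes_tumor_only", "filter_wes_tumor_only")
  v <- callset$variants
  keep <- v$filter == "" & exac_rare(v$ExAC_ALL, config$exac_threshold)
  if (config$require_no_dbsnp) keep <- keep & !dbsnp_member(v)
  callset$variants <- v[keep, , drop = FALSE]
  rownames(callset$variants) <- NULL
  record_provenance(callset, sprintf(
    "filter_wes_tumor_only(PASS & ExAC_ALL<%g & no_dbsnp=%s)",
    config$exac_threshold, config$require_no_dbsnp))
}

#' Filter an RNA-seq tumor-only callset by rules
#'
#' Retains variants whose caller filter-label set is on the configured
#' whitelist, whose non-TCGA ExAC frequency is below the rarity threshold
#' (or absent), and which carry no dbSNP identifier.
#'
#' @param callset An `rnatmb_callset` with source `"rnaseq_tumor_only"`.
#' @param config An [filter_config()] object.
#' @return The filtered callset.
#' @export
filter_rnaseq_tumor_only <- function(callset, config = filter_config()) {
  check_source(callset, "rnaseq_tumor_only", "filter_rnaseq_tumor_only")
  v <- callset$variants
  allowed <- vapply(config$allowed_rnaseq_filter_sets, paste,
                    character(1), collapse = ";")
  keep <- v$filter %in% allowed &
    exac_rare(v$ExAC_nontcga_ALL, config$exac_threshold)
  if (config$require_no_dbsnp) keep <- keep & !dbsnp_member(v)
  callset$variants <- v[keep, , drop = FALSE]
  rownames(callset$variants) <- NULL
  record_provenance(callset, sprintf(
    "filter_rnaseq_tumor_only(labels in {%s} & ExAC_nontcga<%g & no_dbsnp=%s)",
    paste(sprintf("[%s]", allowed), collapse = " "),
    config$exac_threshold, config$require_no_dbsnp))
}
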