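# Per-variant feature representation for the noise classifier.
#
# 31 features by default: 23 taken directly from the caller VCF, one from the
# non-TCGA ExAC annotation, and 7 engineered from REF/ALT/AD. The caller
# feature list is configurable because different caller versions emit
# different INFO/FORMAT fields; features absent from a record stay NA (the
# boosted-tree learner handles missingness natively, so no imputation is
# applied anywhere).

engineered_feature_names <- function() {
  c("INS", "DEL", "CT_transition", "CA_transversion", "total_depth",
    "ref_length", "alt_length")
}

default_caller_features <- function() {
  c("TLOD", "ECNT", "POPAF", "GERMQ", "SEQQ", "STRANDQ", "CONTQ", "ROQ",
    "MPOS", "MBQ_ref", "MBQ_alt", "MMQ_ref", "MMQ_alt", "MFRL_ref",
    "MFRL_alt", "SA_MAP_AF_1", "SA_MAP_AF_2", "AD_ref", "AD_alt", "DP",
    "AF", "F1R2_alt", "F2R1_alt")
}

#' Feature registry
#'
#' Ordered list of per-variant features with their origins. The default
#' registry has 31 entries: 23 caller VCF fields (multi-valued caller fields
#' appear as ref/alt or artifact/no-artifact pairs, e.g. `SA_MAP_AF_1`, the
#' maximum-likelihood allele fraction given a reverse-strand artifact, and
#' `SA_MAP_AF_2`, the same given no artifact), the `ExAC_nontcga_ALL`
#' annotation frequency, and 7 engineered features
#' (`INS`, `DEL`, `CT_transition`, `CA_transversion`, `total_depth`,
#' `ref_length`, `alt_length`).
#'
#' @param caller_features Character vector of caller-VCF feature names.
#' @param annotation_features Character vector of annotation feature names.
#' @param engineered Logical; include the 7 engineered features.
#' @return An `rnatmb_registry`: data.frame with columns `name`, `origin`.
#' @export
feature_registry <- function(caller_features = default_caller_features(),
                             annotation_features = "ExAC_nontcga_ALL",
                             engineered = TRUE) {
  names <- c(caller_features, annotation_features,
             if (engineered) engineered_feature_names())
  if (anyDuplicated(names)) {
    stop("duplicate feature names in registry: ",
         paste(names[duplicated(names)], collapse = ", "))
  }
  origins <- c(rep("caller_vcf", length(caller_features)),
               rep("annotation", length(annotation_features)),
               if (engineered) rep("engineered",
                                   length(engineered_feature_names())))
  structure(data.frame(name = names, origin = origins,
                       stringsAsFactors = FALSE),
            class = c("rnatmb_registry", "data.frame"))
}

registry_hash <- function(registry) paste(registry$name, collapse = "|")

#' Engineer allele-derived variant flags
#'
#' Computes the engineered indel/substitution flags and allele lengths from a
#' REF/ALT pair: `INS` (ALT longer than REF), `DEL` (ALT shorter), the
#' strand-collapsed `CT_transition` (C>T or G>A) and `CA_transversion`
#' (C>A or G>T) flags, and the literal REF/ALT string lengths. The
#' substitution flags are defined only for 1-bp pairs; longer alleles get 0
#' for both.
#'
#' @param ref,alt Allele strings (vectorized).
#' @return Data frame with columns `INS`, `DEL`, `CT_transition`,
#'   `CA_transversion`, `ref_length`, `alt_length`.
#' @export
engineer_variant_flags <- function(ref, alt) {
  ref <- as.character(ref); alt <- as.character(alt)
  if (length(ref) != length(alt)) stop("ref and alt lengths differ")
  if (any(!nzchar(ref)) || any(!nzchar(alt)) || anyNA(ref) || anyNA(alt)) {
    stop("empty allele string")
  }
  rl <- nchar(ref); al <- nchar(alt)
  snv <- rl == 1 & al == 1
  data.frame(
    INS = as.numeric(al > rl),
    DEL = as.numeric(al < rl),
    CT_transition = as.numeric(snv & ((ref == "C" & alt == "T") |
                                        (ref == "G" & alt == "A"))),
    CA_transversion = as.numeric(snv & ((ref == "C" & alt == "A") |
                                          (ref == "G" & alt == "T"))),
    ref_length = rl, alt_length = al
  )
}

#' Total depth from allelic depths
#'
#' @param ad_ref,ad_alt Nonnegative reference/alternate allele depths
#'   (vectorized); NA in either yields NA.
#' @return `ad_ref + ad_alt`.
#' @export
total_depth <- function(ad_ref, ad_alt) {
  if (any(ad_ref < 0, na.rm = TRUE) || any(ad_alt < 0, na.rm = TRUE)) {
    stop("allelic depths must be nonnegative")
  }
  ad_ref + ad_alt
}

#' Build the per-variant feature matrix
#'
#' One row per variant, keyed by origin sample id plus the variant key, with
#' columns in registry order. Caller/annotation features absent from a record
#' are NA (missing-marker), never zero. Registered caller features that the
#' ingested VCF dialect does not carry at all become all-NA columns.
#'
#' @param callset An `rnatmb_callset`.
#' @param registry A [feature_registry()].
#' @return Numeric matrix with class `rnatmb_features`; the registry is
#'   attached as attribute `"registry"`.
#' @export
build_feature_matrix <- function(callset, registry = feature_registry()) {
  v <- callset$variants
  n <- nrow(v)
  eng <- if (n) cbind(engineer_variant_flags(v$ref, v$alt),
                      total_depth = total_depth(v$AD_ref, v$AD_alt))
  cols <- lapply(seq_len(nrow(registry)), function(i) {
    nm <- registry$name[i]
    if (registry$origin[i] == "engineered") {
      if (n) eng[[nm]] else numeric(0)
    } else if (nm %in% names(v)) {
      as.numeric(v[[nm]])
    } else {
      rep(NA_real_, n)
    }
  })
  m <- do.call(cbind, c(cols, list(deparse.level = 0)))
  if (is.null(m)) m <- matrix(numeric(0), nrow = 0, ncol = nrow(registry))
  colnames(m) <- registry$name
  keys <- if (n) paste0(v$sample_id, "|", variant_key(v)) else character(0)
  if (anyDuplicated(keys)) {
    stop("duplicate feature row keys: ",
         paste(head(keys[duplicated(keys)], 3), collapse = ", "))
  }
  rownames(m) <- keys
  structure(m, registry = registry, class = c("rnatmb_features", class(m)))
}
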