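# Callset container and Mutect2-dialect VCF I/O.
#
# A callset holds one sample's (or a pooled set of samples') biallelic variant
# records as a data.frame, one row per variant, with caller fields flattened
# into fixed columns. Absent fields are NA, never 0: downstream feature
# engineering relies on that distinction.

callset_sources <- c("rnaseq_tumor_only", "wes_matched", "wes_tumor_only")

# Columns of the variant table. Multi-valued caller fields (MBQ, MMQ, MFRL,
# SA_MAP_AF, AD, F1R2, F2R1) are flattened into ref/alt (or _1/_2) pairs.
variant_columns <- function() {
  c("sample_id", "chrom", "pos", "id", "ref", "alt", "filter",
    "TLOD", "ECNT", "POPAF", "GERMQ", "SEQQ", "STRANDQ", "CONTQ", "ROQ",
    "MPOS", "MBQ_ref", "MBQ_alt", "MMQ_ref", "MMQ_alt", "MFRL_ref",
    "MFRL_alt", "SA_MAP_AF_1", "SA_MAP_AF_2",
    "AD_ref", "AD_alt", "DP", "AF",
    "F1R2_ref", "F1R2_alt", "F2R1_ref", "F2R1_alt",
    "ExAC_nontcga_ALL", "ExAC_ALL", "avsnp150")
}

empty_variant_table <- function() {
  cols <- variant_columns()
  df <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols),
                      stringsAsFactors = FALSE)
  num <- setdiff(cols, c("sample_id", "chrom", "id", "ref", "alt", "filter",
                         "avsnp150"))
  for (cl in num) df[[cl]] <- numeric(0)
  df$pos <- integer(0)
  df
}

#' Construct a callset
#'
#' Low-level constructor; most users obtain callsets from [read_callset()] or
#' [simulate_cohort()]. Variants are sorted by (chrom, pos, ref, alt) and
#' uniqueness of (sample_id, chrom, pos, ref, alt) is enforced.
#'
#' @param variants Data frame with at least columns `sample_id`, `chrom`,
#'   `pos`, `ref`, `alt`, `filter`; missing caller columns are added as NA.
#' @param source One of `"rnaseq_tumor_only"`, `"wes_matched"`,
#'   `"wes_tumor_only"`.
#' @param sample_id Sample identifier for the callset as a whole (pooled
#'   callsets keep per-row origin ids in `variants$sample_id`).
#' @param provenance Character vector of applied-operation descriptors.
#' @return An object of class `rnatmb_callset`.
#' @export
new_callset <- function(variants, source, sample_id = "sample",
                        provenance = character(0)) {
  source <- match.arg(source, callset_sources)
  full <- empty_variant_table()
  for (cl in setdiff(names(full), names(variants))) {
    variants[[cl]] <- full[[cl]][rep(NA_integer_, nrow(variants))]
  }
  variants <- variants[, names(full), drop = FALSE]
  if (nrow(variants)) {
    stopifnot(all(variants$pos >= 1), all(nchar(variants$ref) >= 1),
              all(nchar(variants$alt) >= 1))
    o <- order(chrom_rank(variants$chrom), variants$pos, variants$ref,
               variants$alt, variants$sample_id)
    variants <- variants[o, , drop = FALSE]
    key <- paste(variants$sample_id, variants$chrom, variants$pos,
                 variants$ref, variants$alt)
    if (anyDuplicated(key)) {
      stop("duplicate variant records within a sample: ",
           paste(utils::head(key[duplicated(key)], 3), collapse = ", "))
    }
    rownames(variants) <- NULL
  }
  structure(list(sample_id = sample_id, source = source, variants = variants,
                 provenance = provenance),
            class = "rnatmb_callset")
}

#' @export
print.rnatmb_callset <- function(x, ...) {
  cat(sprintf("<rnatmb_callset> %s [%s]: %d variants\n",
              x$sample_id, x$source, nrow(x$variants)))
  if (length(x$provenance)) {
    cat("provenance:\n")
    for (p in x$provenance) cat("  - ", p, "\n", sep = "")
  }
  invisible(x)
}

#' Number of variants in a callset
#' @param callset An `rnatmb_callset`.
#' @return Integer count of variant records.
#' @export
n_variants <- function(callset) nrow(callset$variants)

variant_key <- function(variants, match_mode = "full_key") {
  if (match_mode == "full_key") {
    paste(variants$chrom, variants$pos, variants$ref, variants$alt)
  } else {
    paste(variants$chrom, variants$pos)
  }
}

# dbSNP membership uses either channel: an rs-identifier in the VCF ID column
# (dbSNP resource supplied to the caller) or the avsnp150 annotation field.
dbsnp_member <- function(variants) {
  id_rs <- !is.na(variants$id) & grepl("^rs[0-9]+$", variants$id)
  ann <- !is.na(variants$avsnp150) & variants$avsnp150 != "." &
    variants$avsnp150 != ""
  id_rs | ann
}

record_provenance <- function(callset, step) {
  callset$provenance <- c(callset$provenance, step)
  callset
}

# ---------------------------------------------------------------------------
# Reading

info_num1 <- function(inf, key, n) {
  if (!key %in% names(inf)) return(rep(NA_real_, n))
  v <- inf[[key]]
  if (is.list(v) || methods::is(v, "List")) {
    v <- vapply(as.list(v), function(e) {
      if (length(e) == 0) NA_real_ else as.numeric(e[[1]])
    }, numeric(1))
  }
  suppressWarnings(as.numeric(v))
}

info_pair <- function(inf, key, n) {
  if (!key %in% names(inf)) {
    return(list(rep(NA_real_, n), rep(NA_real_, n)))
  }
  v <- as.list(inf[[key]])
  get_el <- function(i) vapply(v, function(e) {
    if (length(e) < i) NA_real_ else suppressWarnings(as.numeric(e[[i]]))
  }, numeric(1))
  list(get_el(1), get_el(2))
}

info_chr1 <- function(inf, key, n) {
  if (!key %in% names(inf)) return(rep(NA_character_, n))
  v <- inf[[key]]
  if (is.list(v) || methods::is(v, "List")) {
    v <- vapply(as.list(v), function(e) {
      if (length(e) == 0) NA_character_ else as.character(e[[1]])
    }, character(1))
  }
  v <- as.character(v)
  v[v %in% c(".", "")] <- NA_character_
  v
}

geno_pair <- function(gen, key, n) {
  if (!key %in% names(gen)) {
    return(list(rep(NA_real_, n), rep(NA_real_, n)))
  }
  v <- gen[[key]]
  if (length(dim(v)) == 3) {
    return(list(as.numeric(v[, 1, 1]), as.numeric(v[, 1, 2])))
  }
  vv <- v[, 1]
  if (!is.list(vv)) vv <- as.list(vv)
  get_el <- function(i) vapply(vv, function(e) {
    if (length(e) < i || is.null(e)) NA_real_
    else suppressWarnings(as.numeric(e[[i]]))
  }, numeric(1))
  list(get_el(1), get_el(2))
}

geno_num1 <- function(gen, key, n) {
  if (!key %in% names(gen)) return(rep(NA_real_, n))
  v <- gen[[key]]
  if (is.list(v[, 1])) {
    return(vapply(v[, 1], function(e) {
      if (length(e) == 0 || is.null(e)) NA_real_
      else suppressWarnings(as.numeric(e[[1]]))
    }, numeric(1)))
  }
  suppressWarnings(as.numeric(v[, 1]))
}

#' Read a Mutect2-dialect VCF callset
#'
#' Parses a single-sample VCF 4.x file into a callset. Multiallelic sites are
#' excluded and counted: both records whose ALT column lists several alleles
#' and groups of separate biallelic lines sharing (chrom, pos, ref) are
#' treated as one multiallelic site and dropped entirely, so only cleanly
#' biallelic sites flow downstream. Missing INFO/FORMAT/annotation fields map
#' to NA, never to 0. Chromosome names are normalized to the `chr*`
#' convention.
#'
#' @param path Path to a VCF file (optionally bgzipped).
#' @param source Source tag, one of `"rnaseq_tumor_only"`, `"wes_matched"`,
#'   `"wes_tumor_only"`.
#' @param sample_id Sample identifier; defaults to the VCF sample column name.
#' @return An `rnatmb_callset` whose `ingest_stats` element records total,
#'   retained, and multiallelic-excluded record/site counts.
#' @export
read_callset <- function(path, source, sample_id = NULL) {
  source <- match.arg(source, callset_sources)
  if (!file.exists(path)) stop("VCF file not found: ", path)
  vcf <- VariantAnnotation::readVcf(path, genome = "GRCh38")
  samples <- colnames(vcf)
  if (length(samples) == 0) {
    stop("VCF has no sample columns (genotype data required): ", path)
  }
  if (length(samples) > 1) {
    stop("expected exactly one tumor sample column, found ", length(samples),
         " in ", path)
  }
  if (is.null(sample_id)) sample_id <- samples[[1]]

  n_total <- nrow(vcf)
  rr <- SummarizedExperiment::rowRanges(vcf)
  if (n_total == 0) {
    cs <- new_callset(empty_variant_table(), source, sample_id,
                      provenance = paste0("read_callset(", basename(path), ")"))
    cs$ingest_stats <- list(n_records = 0L, n_retained = 0L,
                            n_multiallelic_records = 0L,
                            n_multiallelic_sites = 0L)
    return(cs)
  }

  chrom <- normalize_chrom(as.character(GenomicRanges::seqnames(rr)))
  pos <- GenomicRanges::start(rr)
  ref <- toupper(as.character(rr$REF))
  alt_list <- rr$ALT
  n_alt <- S4Vectors::elementNROWS(alt_list)

  # multiallelic exclusion: explicit multi-ALT records, plus biallelic lines
  # that share a (chrom, pos, ref) site
  site <- paste(chrom, pos, ref)
  shared_site <- site %in% site[duplicated(site)]
  multi <- n_alt != 1 | shared_site
  n_multi_rec <- sum(multi)
  n_multi_sites <- length(unique(site[multi]))

  alt <- rep(NA_character_, n_total)
  alt[n_alt == 1] <- toupper(vapply(as.list(alt_list[n_alt == 1]),
                                    function(a) as.character(a[[1]]),
                                    character(1)))

  filt <- as.character(rr$FILTER)
  filt[is.na(filt) | filt %in% c(".", "PASS")] <- ""
  filt <- canonical_filter(filt)

  nm <- names(rr)
  default_nm <- paste0(chrom, ":", pos, "_", ref, "/", alt)
  id <- ifelse(is.na(nm) | nm == "." | nm == default_nm, NA_character_, nm)

  inf <- VariantAnnotation::info(vcf)
  gen <- VariantAnnotation::geno(vcf)
  n <- n_total
  mbq <- info_pair(inf, "MBQ", n)
  mmq <- info_pair(inf, "MMQ", n)
  mfrl <- info_pair(inf, "MFRL", n)
  sa <- info_pair(inf, "SA_MAP_AF", n)
  ad <- geno_pair(gen, "AD", n)
  f1r2 <- geno_pair(gen, "F1R2", n)
  f2r1 <- geno_pair(gen, "F2R1", n)

  variants <- data.frame(
    sample_id = sample_id, chrom = chrom, pos = as.integer(pos), id = id,
    ref = ref, alt = alt, filter = filt,
    TLOD = info_num1(inf, "TLOD", n), ECNT = info_num1(inf, "ECNT", n),
    POPAF = info_num1(inf, "POPAF", n), GERMQ = info_num1(inf, "GERMQ", n),
    SEQQ = info_num1(inf, "SEQQ", n), STRANDQ = info_num1(inf, "STRANDQ", n),
    CONTQ = info_num1(inf, "CONTQ", n), ROQ = info_num1(inf, "ROQ", n),
    MPOS = info_num1(inf, "MPOS", n),
    MBQ_ref = mbq[[1]], MBQ_alt = mbq[[2]],
    MMQ_ref = mmq[[1]], MMQ_alt = mmq[[2]],
    MFRL_ref = mfrl[[1]], MFRL_alt = mfrl[[2]],
    SA_MAP_AF_1 = sa[[1]], SA_MAP_AF_2 = sa[[2]],
    AD_ref = ad[[1]], AD_alt = ad[[2]],
    DP = geno_num1(gen, "DP", n), AF = geno_num1(gen, "AF", n),
    F1R2_ref = f1r2[[1]], F1R2_alt = f1r2[[2]],
    F2R1_ref = f2r1[[1]], F2R1_alt = f2r1[[2]],
    ExAC_nontcga_ALL = info_num1(inf, "ExAC_nontcga_ALL", n),
    ExAC_ALL = info_num1(inf, "ExAC_ALL", n),
    avsnp150 = info_chr1(inf, "avsnp150", n),
    stringsAsFactors = FALSE
  )
  variants <- variants[!multi, , drop = FALSE]
  bad <- !grepl("^[ACGTN]+$", variants$ref) | !grepl("^[ACGTN]+$", variants$alt)
  variants <- variants[!bad, , drop = FALSE]

  cs <- new_callset(variants, source, sample_id,
                    provenance = paste0("read_callset(", basename(path), ")"))
  cs$ingest_stats <- list(n_records = n_total,
                          n_retained = nrow(cs$variants),
                          n_multiallelic_records = n_multi_rec,
                          n_multiallelic_sites = n_multi_sites)
  cs
}

# canonical filter string: semicolon-split labels, sorted, rejoined;
# "" represents PASS
canonical_filter <- function(filter) {
  vapply(strsplit(filter, ";", fixed = TRUE), function(labs) {
    labs <- sort(unique(labs[labs != "" & labs != "PASS" & labs != "."]))
    paste(labs, collapse = ";")
  }, character(1))
}

filter_label_sets <- function(filter) {
  lapply(strsplit(filter, ";", fixed = TRUE),
         function(labs) sort(labs[labs != ""]))
}

# ---------------------------------------------------------------------------
# Writing

# shortest decimal representation that re-reads to the identical double
fmt_num <- function(x, digits = 6) {
  out <- sprintf("%.*g", digits, x)
  bad <- suppressWarnings(as.numeric(out)) != x
  bad[is.na(bad)] <- FALSE
  out[bad] <- sprintf("%.17g", x[bad])
  out[is.na(x)] <- NA_character_
  out
}

vcf_header_lines <- function(variants, sample_id) {
  filters <- sort(unique(unlist(strsplit(variants$filter, ";", fixed = TRUE))))
  filters <- filters[filters != ""]
  c("##fileformat=VCFv4.2",
    "##source=rnatmb",
    "##FILTER=<ID=PASS,Description=\"All filters passed\">",
    sprintf("##FILTER=<ID=%s,Description=\"%s\">", filters, filters),
    "##INFO=<ID=TLOD,Number=1,Type=Float,Description=\"Log odds of variant presence in tumor relative to expected noise\">",
    "##INFO=<ID=ECNT,Number=1,Type=Integer,Description=\"Number of events in this haplotype\">",
    "##INFO=<ID=POPAF,Number=1,Type=Float,Description=\"Negative log10 population allele frequency\">",
    "##INFO=<ID=GERMQ,Number=1,Type=Integer,Description=\"Phred-scaled quality that alt alleles are not germline\">",
    "##INFO=<ID=SEQQ,Number=1,Type=Integer,Description=\"Phred-scaled quality that alt alleles are not sequencing errors\">",
    "##INFO=<ID=STRANDQ,Number=1,Type=Integer,Description=\"Phred-scaled quality of strand bias artifact\">",
    "##INFO=<ID=CONTQ,Number=1,Type=Integer,Description=\"Phred-scaled quality that alt alleles are not contamination\">",
    "##INFO=<ID=ROQ,Number=1,Type=Integer,Description=\"Phred-scaled quality that alt alleles are not orientation artifacts\">",
    "##INFO=<ID=MPOS,Number=1,Type=Integer,Description=\"Median distance from end of read\">",
    "##INFO=<ID=MBQ,Number=2,Type=Integer,Description=\"Median base quality (ref, alt)\">",
    "##INFO=<ID=MMQ,Number=2,Type=Integer,Description=\"Median mapping quality (ref, alt)\">",
    "##INFO=<ID=MFRL,Number=2,Type=Integer,Description=\"Median fragment length (ref, alt)\">",
    "##INFO=<ID=SA_MAP_AF,Number=2,Type=Float,Description=\"MAP estimate of allele fraction given reverse-strand artifact, no artifact\">",
    "##INFO=<ID=ExAC_nontcga_ALL,Number=1,Type=Float,Description=\"ExAC non-TCGA population allele frequency\">",
    "##INFO=<ID=ExAC_ALL,Number=1,Type=Float,Description=\"ExAC population allele frequency\">",
    "##INFO=<ID=avsnp150,Number=1,Type=String,Description=\"dbSNP 150 identifier from annotation\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths (ref, alt)\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AF,Number=A,Type=Float,Description=\"Allele fraction\">",
    "##FORMAT=<ID=F1R2,Number=R,Type=Integer,Description=\"F1R2 read counts (ref, alt)\">",
    "##FORMAT=<ID=F2R1,Number=R,Type=Integer,Description=\"F2R1 read counts (ref, alt)\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
           sample_id))
}

#' Write a callset as a Mutect2-dialect VCF
#'
#' Emits an uncompressed VCF 4.2 file that [read_callset()] re-ingests
#' losslessly for all fields the pipeline consumes. Numeric fields are
#' written with the shortest decimal representation that parses back to the
#' identical value, so write/read round trips are exact and output is
#' byte-deterministic.
#'
#' @param callset An `rnatmb_callset`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_callset <- function(callset, path) {
  v <- callset$variants
  n <- nrow(v)
  hdr <- vcf_header_lines(v, callset$sample_id)
  if (n == 0) {
    writeLines(hdr, path)
    return(invisible(path))
  }
  int1 <- function(x) ifelse(is.na(x), NA_character_,
                             sprintf("%d", as.integer(round(x))))
  info_field <- function(key, val) ifelse(is.na(val), NA_character_,
                                          paste0(key, "=", val))
  pair_field <- function(key, a, b) {
    ifelse(is.na(a) | is.na(b), NA_character_,
           paste0(key, "=", a, ",", b))
  }
  parts <- cbind(
    info_field("TLOD", fmt_num(v$TLOD)),
    info_field("ECNT", int1(v$ECNT)),
    info_field("POPAF", fmt_num(v$POPAF)),
    info_field("GERMQ", int1(v$GERMQ)),
    info_field("SEQQ", int1(v$SEQQ)),
    info_field("STRANDQ", int1(v$STRANDQ)),
    info_field("CONTQ", int1(v$CONTQ)),
    info_field("ROQ", int1(v$ROQ)),
    info_field("MPOS", int1(v$MPOS)),
    pair_field("MBQ", int1(v$MBQ_ref), int1(v$MBQ_alt)),
    pair_field("MMQ", int1(v$MMQ_ref), int1(v$MMQ_alt)),
    pair_field("MFRL", int1(v$MFRL_ref), int1(v$MFRL_alt)),
    pair_field("SA_MAP_AF", fmt_num(v$SA_MAP_AF_1), fmt_num(v$SA_MAP_AF_2)),
    info_field("ExAC_nontcga_ALL", fmt_num(v$ExAC_nontcga_ALL)),
    info_field("ExAC_ALL", fmt_num(v$ExAC_ALL)),
    info_field("avsnp150", v$avsnp150)
  )
  info <- apply(parts, 1, function(p) {
    p <- p[!is.na(p)]
    if (!length(p)) "." else paste(p, collapse = ";")
  })
  dot <- function(x) ifelse(is.na(x), ".", x)
  ad <- ifelse(is.na(v$AD_ref) | is.na(v$AD_alt), ".",
               paste0(int1(v$AD_ref), ",", int1(v$AD_alt)))
  f1r2 <- ifelse(is.na(v$F1R2_ref) | is.na(v$F1R2_alt), ".",
                 paste0(int1(v$F1R2_ref), ",", int1(v$F1R2_alt)))
  f2r1 <- ifelse(is.na(v$F2R1_ref) | is.na(v$F2R1_alt), ".",
                 paste0(int1(v$F2R1_ref), ",", int1(v$F2R1_alt)))
  gt <- paste("0/1", ad, dot(int1(v$DP)), dot(fmt_num(v$AF)), f1r2, f2r1,
              sep = ":")
  recs <- paste(v$chrom, v$pos, dot(v$id), v$ref, v$alt, ".",
                ifelse(v$filter == "", "PASS", v$filter), info,
                "GT:AD:DP:AF:F1R2:F2R1", gt, sep = "\t")
  writeLines(c(hdr, recs), path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Merge / intersect

#' Pool callsets across samples
#'
#' Concatenates callsets of the same source into one pooled callset,
#' retaining per-variant origin `sample_id` so pooled variants can later be
#' reaggregated per sample. The pooled size equals the sum of input sizes.
#'
#' @param callsets List of `rnatmb_callset` objects sharing one source tag.
#' @return A pooled `rnatmb_callset` with `sample_id = "pooled"`.
#' @export
merge_callsets <- function(callsets) {
  stopifnot(length(callsets) >= 1)
  sources <- unique(vapply(callsets, function(cs) cs$source, character(1)))
  if (length(sources) != 1) {
    stop("cannot merge callsets with mixed source tags: ",
         paste(sources, collapse = ", "))
  }
  variants <- do.call(rbind, lapply(callsets, function(cs) cs$variants))
  ids <- vapply(callsets, function(cs) cs$sample_id, character(1))
  out <- new_callset(variants, sources,
                     sample_id = if (length(callsets) == 1) ids else "pooled",
                     provenance = sprintf("merge_callsets(n=%d)",
                                          length(callsets)))
  out$member_samples <- ids
  out
}

#' Intersect two callsets
#'
#' Returns the subset of `a` whose variants are matched in `b`, either by the
#' full variant key (chrom, pos, ref, alt) or by genomic coordinate only
#' (chrom, pos). Full-key matching is the stricter rule used for the
#' upper-bound "isec" analysis; coordinate-only matching is the rule used for
#' signal/noise labeling.
#'
#' @param a,b `rnatmb_callset` objects.
#' @param match_mode `"full_key"` or `"coordinate_only"`.
#' @return An `rnatmb_callset` containing the matching subset of `a`.
#' @export
intersect_callsets <- function(a, b, match_mode = c("full_key",
                                                    "coordinate_only")) {
  match_mode <- match.arg(match_mode)
  keep <- variant_key(a$variants, match_mode) %in%
    variant_key(b$variants, match_mode)
  out <- a
  out$variants <- a$variants[keep, , drop = FALSE]
  rownames(out$variants) <- NULL
  record_provenance(out, sprintf("intersect_callsets(%s, mode=%s)",
                                 b$sample_id, match_mode))
}

# ---------------------------------------------------------------------------
# Regions

#' Construct a region set
#'
#' @param chrom,start,end Vectors describing 0-based half-open intervals
#'   (BED convention). Overlapping intervals are merged.
#' @return An `rnatmb_regions` object with elements `granges`
#'   (1-based, merged) and `total_megabases`.
#' @export
region_set <- function(chrom, start, end) {
  if (length(chrom) == 0) {
    gr <- GenomicRanges::GRanges()
    return(structure(list(granges = gr, total_megabases = 0),
                     class = "rnatmb_regions"))
  }
  if (any(start >= end)) {
    stop("region start must be < end (0-based half-open); offending interval ",
         which(start >= end)[1])
  }
  gr <- GenomicRanges::GRanges(normalize_chrom(chrom),
                               IRanges::IRanges(start = start + 1, end = end))
  gr <- GenomicRanges::reduce(gr)
  structure(list(granges = gr,
                 total_megabases = sum(as.numeric(
                   GenomicRanges::width(gr))) / 1e6),
            class = "rnatmb_regions")
}

#' @export
print.rnatmb_regions <- function(x, ...) {
  cat(sprintf("<rnatmb_regions> %d intervals, %.4f Mb\n",
              length(x$granges), x$total_megabases))
  invisible(x)
}

#' Read a BED file of analyzed regions
#'
#' Reads a 3+ column BED file (0-based half-open), merges overlapping
#' intervals, and computes the total size in megabases used as the TMB
#' denominator.
#'
#' @param path Path to a BED file.
#' @return An `rnatmb_regions` object.
#' @export
read_regions <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (length(lines) == 0) return(region_set(character(0), numeric(0),
                                            numeric(0)))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- vapply(fields, length, integer(1))
  if (any(nf < 3)) {
    stop("BED line ", which(nf < 3)[1], " has fewer than 3 columns")
  }
  chrom <- vapply(fields, `[[`, character(1), 1)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 2)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 3)))
  if (anyNA(start) || anyNA(end)) {
    stop("BED line ", which(is.na(start) | is.na(end))[1],
         " has non-numeric coordinates")
  }
  if (any(start >= end)) {
    stop("BED line ", which(start >= end)[1],
         " has start >= end (0-based half-open expected)")
  }
  region_set(chrom, start, end)
}

#' Write a region set as a BED file
#' @param regions An `rnatmb_regions` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_regions <- function(regions, path) {
  gr <- regions$granges
  lines <- sprintf("%s\t%d\t%d",
                   as.character(GenomicRanges::seqnames(gr)),
                   GenomicRanges::start(gr) - 1L, GenomicRanges::end(gr))
  writeLines(lines, path)
  invisible(path)
}

variants_granges <- function(variants) {
  GenomicRanges::GRanges(variants$chrom,
                         IRanges::IRanges(start = variants$pos,
                                          width = nchar(variants$ref)))
}
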