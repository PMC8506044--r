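# Shared fixtures and independent oracles for the test suite.

# Minimal literal VCF text, independent of the package's own writer, for
# ingestion tests.
minimal_vcf_header <- function(sample = "S1") {
  c("##fileformat=VCFv4.2",
    "##FILTER=<ID=PASS,Description=\"ok\">",
    "##FILTER=<ID=germline_risk,Description=\"g\">",
    "##FILTER=<ID=panel_of_normals,Description=\"p\">",
    "##FILTER=<ID=base_qual,Description=\"b\">",
    "##INFO=<ID=TLOD,Number=1,Type=Float,Description=\"t\">",
    "##INFO=<ID=SA_MAP_AF,Number=2,Type=Float,Description=\"sa\">",
    "##INFO=<ID=ExAC_nontcga_ALL,Number=1,Type=Float,Description=\"e\">",
    "##INFO=<ID=ExAC_ALL,Number=1,Type=Float,Description=\"ea\">",
    "##INFO=<ID=avsnp150,Number=1,Type=String,Description=\"rs\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"gt\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"ad\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", sample))
}

write_minimal_vcf <- function(records, sample = "S1",
                              path = tempfile(fileext = ".vcf")) {
  writeLines(c(minimal_vcf_header(sample), records), path)
  path
}

# quick hand-built callset from a compact variant data.frame
toy_callset <- function(df, source = "rnaseq_tumor_only",
                        sample_id = "S1") {
  if (is.null(df$sample_id)) df$sample_id <- rep(sample_id, nrow(df))
  if (is.null(df$filter)) df$filter <- rep("", nrow(df))
  new_callset(df, source, sample_id)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# exhaustive-pairs AUC oracle: mean over all positive-negative pairs with
# ties counted one half
brute_force_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  total <- 0
  for (p in pos) for (n in neg) {
    total <- total + if (p > n) 1 else if (p == n) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# closed-form product-moment correlation
pearson_closed_form <- function(x, y) {
  n <- length(x)
  (n * sum(x * y) - sum(x) * sum(y)) /
    sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
}

# brute-force double-loop labeling oracle over all variant pairs
brute_force_labels <- function(rna_variants, wes_variants, match_mode) {
  labels <- rep("noise", nrow(rna_variants))
  for (i in seq_len(nrow(rna_variants))) {
    for (j in seq_len(nrow(wes_variants))) {
      same_sample <- rna_variants$sample_id[i] == wes_variants$sample_id[j]
      coord <- rna_variants$chrom[i] == wes_variants$chrom[j] &&
        rna_variants$pos[i] == wes_variants$pos[j]
      full <- coord && rna_variants$ref[i] == wes_variants$ref[j] &&
        rna_variants$alt[i] == wes_variants$alt[j]
      hit <- if (match_mode == "full_key") full else coord
      if (same_sample && hit) labels[i] <- "signal"
    }
  }
  labels
}

# random toy variant tables for property tests
random_variant_table <- function(n, sample_id = "S1", n_pos = 50) {
  pos <- sample.int(n_pos * 10, n)
  data.frame(sample_id = sample_id,
             chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
             pos = pos,
             ref = sample(c("A", "C", "G", "T"), n, replace = TRUE),
             alt = sample(c("A", "C", "G", "T"), n, replace = TRUE),
             filter = "", stringsAsFactors = FALSE)
}

dedupe_variants <- function(df) {
  key <- paste(df$sample_id, df$chrom, df$pos, df$ref, df$alt)
  df <- df[!duplicated(key) & df$ref != df$alt, , drop = FALSE]
  df
}

# small simulated cohort reused by several test files
small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_cohort(cohort_sim_config(n_samples = 8, seed = 424))
    }
    cache
  }
})

# two-feature linearly separable fixture for classifier checks
separable_fixture <- function(n = 2000, seed = 7, separation = 3) {
  set.seed(seed)
  y <- rep(c(TRUE, FALSE), length.out = n)
  x1 <- rnorm(n) + separation * y
  x2 <- rnorm(n)
  reg <- feature_registry(caller_features = c("TLOD", "AF"),
                          annotation_features = character(0),
                          engineered = FALSE)
  m <- cbind(TLOD = x1, AF = x2)
  rownames(m) <- sprintf("S1|chr1 %d A T", seq_len(n))
  structure(m, registry = reg, class = c("rnatmb_features", class(m)))
}
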