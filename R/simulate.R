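# Synthetic paired RNA-seq / WES cohort simulator with known truth.
#
# The generator emulates the post-calling world this pipeline lives in: each
# sample has a true somatic burden drawn from a log-normal TMB distribution;
# germline variants carry population frequencies and dbSNP identifiers; the
# RNA-seq callset additionally contains FFPE-type C>T(G>A)-enriched
# artifacts and RNA-specific noise, and real variants are detected with a
# probability that saturates in sequencing depth and per-site expression.
# Depth affects only detection and read-depth fields, never the truth: all
# truth-level draws happen before any depth-dependent draw, so cohorts
# simulated at different depths from the same seed share their truth tables
# variant for variant.

#' Cohort simulation configuration
#'
#' @param n_samples Number of paired samples (default 40).
#' @param regions An `rnatmb_regions` region set (default: 25 intervals of
#'   40 kb spread over chr1-chr22/chrX/chrY, 1 Mb total).
#' @param seed Integer seed; the whole simulation is reproducible from it.
#' @param tmb_meanlog,tmb_sdlog Log-normal true-TMB distribution in Mut/Mb
#'   (default median 5, sdlog 1, giving roughly a quarter of samples at or
#'   above 10 Mut/Mb).
#' @param germline_per_mb Germline variant rate per megabase (default 50).
#' @param germline_dbsnp_prob Probability a germline variant carries a dbSNP
#'   rs-identifier (default 0.95).
#' @param germline_exac_log10_range Range of log10 population allele
#'   frequency for germline variants (default `c(-3, -0.3)`).
#' @param ffpe_per_mb FFPE artifact rate per megabase in the RNA-seq callset
#'   (default 25).
#' @param ffpe_ct_fraction Fraction of FFPE artifacts that are C>T (G>A)
#'   substitutions (default 0.8).
#' @param noise_per_mb RNA-specific noise rate per megabase (default 25).
#' @param mean_reads Mean gene-mapped reads per sample (default 23e6,
#'   the mid-depth regime; 11e6 and 68e6 emulate the low/high regimes).
#' @param depth_half_sat Depth scale of the detection curve: detection
#'   probability is `1 - exp(-(mean_reads / depth_half_sat) * expression)`
#'   with per-variant expression ~ Exp(1) (default 3e7).
#' @param site_depth_per_mgmr Expected read depth at an average-expression
#'   site per million gene-mapped reads (default 1.5).
#' @param wes_detection_prob Probability a real variant is called in WES
#'   (default 0.98).
#' @param wes_mode `"matched"` (germline emitted with a non-PASS label, as a
#'   matched-normal caller would flag them) or `"tumor_only"` (germline
#'   emitted PASS with rsID/ExAC annotations, so only the rule filter can
#'   catch them).
#' @param tlod_true_meanlog,tlod_true_sdlog,tlod_artifact_meanlog,tlod_artifact_sdlog
#'   Class-conditional log-normal TLOD distributions for real variants vs
#'   artifacts/noise; the defaults overlap so the classifier's advantage over
#'   rules is learnable but not trivial.
#' @param somatic_indel_fraction,germline_indel_fraction Fraction of real
#'   variants emitted as 1-bp insertions or deletions (default 0.1, split
#'   evenly).
#' @return A `rnatmb_sim_config` list.
#' @export
cohort_sim_config <- function(n_samples = 40,
                              regions = default_sim_regions(),
                              seed = 1,
                              tmb_meanlog = log(5), tmb_sdlog = 1,
                              germline_per_mb = 50,
                              germline_dbsnp_prob = 0.95,
                              germline_exac_log10_range = c(-3, -0.3),
                              ffpe_per_mb = 25, ffpe_ct_fraction = 0.8,
                              noise_per_mb = 25,
                              mean_reads = 23e6, depth_half_sat = 3e7,
                              site_depth_per_mgmr = 1.5,
                              wes_detection_prob = 0.98,
                              wes_mode = c("matched", "tumor_only"),
                              tlod_true_meanlog = log(30),
                              tlod_true_sdlog = 0.8,
                              tlod_artifact_meanlog = log(8),
                              tlod_artifact_sdlog = 0.8,
                              somatic_indel_fraction = 0.1,
                              germline_indel_fraction = 0.1) {
  wes_mode <- match.arg(wes_mode)
  cfg <- as.list(environment())
  rates <- c(germline_per_mb = germline_per_mb, ffpe_per_mb = ffpe_per_mb,
             noise_per_mb = noise_per_mb)
  if (any(rates < 0)) stop("rates must be nonnegative")
  if (mean_reads <= 0) stop("mean_reads must be positive")
  if (ffpe_ct_fraction < 0 || ffpe_ct_fraction > 1) {
    stop("ffpe_ct_fraction must be in [0, 1]")
  }
  structure(cfg, class = "rnatmb_sim_config")
}

#' @rdname cohort_sim_config
#' @export
default_sim_regions <- function() {
  chroms <- chrom_levels()
  idx <- seq_len(25)
  region_set(chrom = chroms[((idx - 1) %% length(chroms)) + 1],
             start = 1e6 + idx * 5e4, end = 1e6 + idx * 5e4 + 4e4)
}

bases <- c("A", "C", "G", "T")

# map 1-based offsets into the concatenated region space to (chrom, pos)
offsets_to_loci <- function(offsets, regions) {
  gr <- regions$granges
  w <- as.numeric(GenomicRanges::width(gr))
  cum <- cumsum(w)
  iv <- findInterval(offsets - 1, c(0, cum), rightmost.closed = FALSE)
  local <- offsets - c(0, cum)[iv]
  list(chrom = as.character(GenomicRanges::seqnames(gr))[iv],
       pos = GenomicRanges::start(gr)[iv] + local - 1)
}

draw_alleles <- function(class, ffpe_ct_fraction, somatic_indel_fraction,
                         germline_indel_fraction) {
  m <- length(class)
  ref <- sample(bases, m, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  # FFPE deamination: C>T on either strand (reported as C>T or G>A)
  is_ffpe <- class == "ffpe_artifact"
  ct <- is_ffpe & runif(m) < ffpe_ct_fraction
  strand <- runif(m) < 0.5
  ref[ct] <- ifelse(strand[ct], "C", "G")
  alt[ct] <- ifelse(strand[ct], "T", "A")
  # 1-bp indels for a fraction of real variants
  indel_frac <- ifelse(class == "somatic", somatic_indel_fraction,
                       ifelse(class == "germline", germline_indel_fraction, 0))
  u <- runif(m)
  ins <- u < indel_frac / 2
  del <- u >= indel_frac / 2 & u < indel_frac
  extra <- sample(bases, m, replace = TRUE)
  alt[ins] <- paste0(ref[ins], extra[ins])
  full <- paste0(ref, extra)
  alt[del] <- ref[del]
  ref[del] <- full[del]
  list(ref = ref, alt = alt)
}

draw_filter_labels <- function(class) {
  m <- length(class)
  out <- character(m)
  pick <- function(rows, labels, probs) {
    if (any(rows)) out[rows] <<- sample(labels, sum(rows), replace = TRUE,
                                        prob = probs)
  }
  pick(class == "somatic", c("germline_risk", ""), c(0.7, 0.3))
  pick(class == "germline",
       c("germline_risk", "germline_risk;panel_of_normals", ""),
       c(0.75, 0.15, 0.1))
  pick(class == "ffpe_artifact",
       c("germline_risk", "", "base_qual", "strand_bias"),
       c(0.35, 0.25, 0.25, 0.15))
  pick(class == "rna_noise",
       c("germline_risk", "", "base_qual", "weak_evidence"),
       c(0.3, 0.3, 0.3, 0.1))
  out
}

#' Simulate a paired RNA-seq / WES cohort
#'
#' Generates per-sample tumor-only RNA-seq and WES callsets plus the truth
#' table. All randomness derives from `config$seed`; a given config
#' reproduces byte-identical VCFs when written. See [cohort_sim_config()]
#' for the generative model.
#'
#' @param config A [cohort_sim_config()].
#' @param dir Optional directory; when given, per-sample VCFs
#'   (`rna_<id>.vcf`, `wes_<id>.vcf`), the region BED (`regions.bed`) and
#'   truth tables (`truth_variants.tsv`, `truth_samples.tsv`) are written
#'   there.
#' @return An `rnatmb_cohort`: list with `rnaseq` and `wes` (named lists of
#'   callsets), `regions`, `truth` (list with `variants` and `samples` data
#'   frames), `config`, and `paths` when `dir` was given.
#' @export
simulate_cohort <- function(config, dir = NULL) {
  stopifnot(inherits(config, "rnatmb_sim_config"))
  regions <- config$regions
  mb <- regions$total_megabases
  if (mb <= 0) stop("simulation requires a region set with positive size")
  total_bases <- round(mb * 1e6)
  n <- config$n_samples
  sids <- if (n > 0) sprintf("S%02d", seq_len(n)) else character(0)

  set.seed(config$seed)

  # ---- phase 1: depth-independent truth and annotation draws -------------
  tmb_draw <- rlnorm(n, config$tmb_meanlog, config$tmb_sdlog)
  n_som <- rpois(n, tmb_draw * mb)
  n_germ <- rpois(n, config$germline_per_mb * mb)
  n_ffpe <- rpois(n, config$ffpe_per_mb * mb)
  n_noise <- rpois(n, config$noise_per_mb * mb)

  cand <- do.call(rbind, lapply(seq_len(n), function(i) {
    counts <- c(somatic = n_som[i], germline = n_germ[i],
                ffpe_artifact = n_ffpe[i], rna_noise = n_noise[i])
    m <- sum(counts)
    loci <- offsets_to_loci(sample.int(total_bases, m), regions)
    data.frame(sample_id = rep(sids[i], m), chrom = loci$chrom,
               pos = loci$pos, class = rep(names(counts), counts),
               stringsAsFactors = FALSE)
  }))
  if (is.null(cand)) {
    cand <- data.frame(sample_id = character(0), chrom = character(0),
                       pos = integer(0), class = character(0))
  }
  m <- nrow(cand)
  cls <- cand$class
  real <- cls %in% c("somatic", "germline")

  al <- draw_alleles(cls, config$ffpe_ct_fraction,
                     config$somatic_indel_fraction,
                     config$germline_indel_fraction)
  cand$ref <- al$ref; cand$alt <- al$alt

  expr <- pmax(rexp(m), 0.05)
  af_true <- numeric(m)
  af_true[cls == "somatic"] <- rbeta(sum(cls == "somatic"), 2, 5)
  af_true[cls == "germline"] <- rbeta(sum(cls == "germline"), 20, 20)
  art <- !real
  af_true[art] <- rbeta(sum(art), 1.5, 12)
  af_true <- pmin(pmax(af_true, 0.02), 0.98)

  tlod <- numeric(m)
  tlod[real] <- rlnorm(sum(real), config$tlod_true_meanlog,
                       config$tlod_true_sdlog)
  tlod[art] <- rlnorm(sum(art), config$tlod_artifact_meanlog,
                      config$tlod_artifact_sdlog)
  tlod <- round(tlod, 3)

  mbq_ref <- pmin(pmax(round(rnorm(m, 34, 2)), 2), 40)
  mbq_alt <- pmin(pmax(round(rnorm(m, ifelse(real, 33, 24),
                                   ifelse(real, 3, 5))), 2), 40)
  mpos <- pmax(round(rnorm(m, ifelse(real, 25, 12), 6)), 1)
  ecnt <- 1 + rpois(m, 0.3)
  sa2 <- round(pmin(pmax(af_true + rnorm(m, 0, 0.03), 0), 1), 4)
  sa1 <- round(ifelse(real, sa2 * runif(m, 0.85, 1),
                      sa2 * runif(m, 0.05, 0.3)), 4)
  strand_p <- ifelse(real, 0.5,
                     ifelse(runif(m) < 0.5, 0.1, 0.9))

  exac <- rep(NA_real_, m)
  g <- cls == "germline"
  exac[g] <- signif(10^runif(sum(g), config$germline_exac_log10_range[1],
                             config$germline_exac_log10_range[2]), 3)
  popaf <- ifelse(g, round(-log10(exac), 2), 6)
  rsid <- rep(NA_character_, m)
  tagged <- g & runif(m) < config$germline_dbsnp_prob
  if (any(tagged)) {
    rsid[tagged] <- paste0("rs", sample.int(99999999, sum(tagged)))
  }
  filt_rna <- draw_filter_labels(cls)

  # WES-side draws (depth-independent)
  dp_wes <- rpois(m, 100) + 20L
  tlod_wes <- round(rlnorm(m, log(50), 0.5), 3)
  u_wes <- runif(m)
  in_wes <- real & u_wes < config$wes_detection_prob
  ad_alt_wes <- pmin(dp_wes, pmax(1, rbinom(m, dp_wes, af_true)))
  u_rna <- runif(m)

  # ---- phase 2: depth-dependent detection and read depths ----------------
  p_det <- 1 - exp(-(config$mean_reads / config$depth_half_sat) * expr)
  in_rna <- u_rna < p_det
  lambda <- (config$mean_reads / 1e6) * config$site_depth_per_mgmr * expr
  dp_rna <- rpois(m, lambda) + 1L
  ad_alt <- pmin(dp_rna, pmax(1, rbinom(m, dp_rna, af_true)))
  ad_ref <- dp_rna - ad_alt
  f1r2_alt <- rbinom(m, ad_alt, strand_p)
  f1r2_ref <- rbinom(m, ad_ref, 0.5)

  cand$in_wes <- in_wes
  cand$in_rnaseq <- in_rna

  matched <- config$wes_mode == "matched"
  rna_list <- wes_list <- stats::setNames(vector("list", n), sids)
  for (i in seq_len(n)) {
    rows <- which(cand$sample_id == sids[i] & in_rna)
    v <- data.frame(
      sample_id = rep(sids[i], length(rows)),
      chrom = cand$chrom[rows], pos = cand$pos[rows],
      id = rsid[rows], ref = cand$ref[rows], alt = cand$alt[rows],
      filter = filt_rna[rows],
      TLOD = tlod[rows], ECNT = as.numeric(ecnt[rows]),
      POPAF = popaf[rows], MPOS = as.numeric(mpos[rows]),
      MBQ_ref = as.numeric(mbq_ref[rows]), MBQ_alt = as.numeric(mbq_alt[rows]),
      SA_MAP_AF_1 = sa1[rows], SA_MAP_AF_2 = sa2[rows],
      AD_ref = as.numeric(ad_ref[rows]), AD_alt = as.numeric(ad_alt[rows]),
      DP = as.numeric(dp_rna[rows]),
      AF = round(ad_alt[rows] / dp_rna[rows], 4),
      F1R2_ref = as.numeric(f1r2_ref[rows]),
      F1R2_alt = as.numeric(f1r2_alt[rows]),
      F2R1_ref = as.numeric(ad_ref[rows] - f1r2_ref[rows]),
      F2R1_alt = as.numeric(ad_alt[rows] - f1r2_alt[rows]),
      ExAC_nontcga_ALL = exac[rows], ExAC_ALL = exac[rows],
      avsnp150 = rsid[rows], stringsAsFactors = FALSE)
    rna_list[[i]] <- new_callset(v, "rnaseq_tumor_only", sids[i],
                                 provenance = "simulate_cohort(rnaseq)")

    rows <- which(cand$sample_id == sids[i] & in_wes)
    germ_row <- cls[rows] == "germline"
    vw <- data.frame(
      sample_id = rep(sids[i], length(rows)),
      chrom = cand$chrom[rows], pos = cand$pos[rows],
      id = rsid[rows], ref = cand$ref[rows], alt = cand$alt[rows],
      filter = if (matched) ifelse(germ_row, "germline", "") else "",
      TLOD = tlod_wes[rows], POPAF = popaf[rows],
      AD_ref = as.numeric(dp_wes[rows] - ad_alt_wes[rows]),
      AD_alt = as.numeric(ad_alt_wes[rows]), DP = as.numeric(dp_wes[rows]),
      AF = round(ad_alt_wes[rows] / dp_wes[rows], 4),
      ExAC_nontcga_ALL = exac[rows], ExAC_ALL = exac[rows],
      avsnp150 = rsid[rows], stringsAsFactors = FALSE)
    wes_list[[i]] <- new_callset(
      vw, if (matched) "wes_matched" else "wes_tumor_only", sids[i],
      provenance = sprintf("simulate_cohort(wes_%s)", config$wes_mode))
  }

  truth_samples <- data.frame(sample_id = sids, tmb_drawn = tmb_draw,
                              somatic_count = n_som,
                              true_tmb = n_som / mb, stringsAsFactors = FALSE)
  cohort <- structure(list(rnaseq = rna_list, wes = wes_list,
                           regions = regions,
                           truth = list(variants = cand,
                                        samples = truth_samples),
                           config = config),
                      class = "rnatmb_cohort")
  if (!is.null(dir)) cohort$paths <- write_cohort(cohort, dir)
  cohort
}

#' @export
print.rnatmb_cohort <- function(x, ...) {
  cat(sprintf(paste0("<rnatmb_cohort> %d samples, %.2f Mb regions, ",
                     "%.0fM mean reads (%s WES)\n"),
              length(x$rnaseq), x$regions$total_megabases,
              x$config$mean_reads / 1e6, x$config$wes_mode))
  invisible(x)
}

#' Write a simulated cohort to disk
#' @param cohort An `rnatmb_cohort`.
#' @param dir Output directory (created if needed).
#' @return Named list of written paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rna <- vapply(names(cohort$rnaseq), function(sid) {
    write_callset(cohort$rnaseq[[sid]], file.path(dir,
                                                  paste0("rna_", sid, ".vcf")))
  }, character(1))
  wes <- vapply(names(cohort$wes), function(sid) {
    write_callset(cohort$wes[[sid]], file.path(dir,
                                               paste0("wes_", sid, ".vcf")))
  }, character(1))
  bed <- file.path(dir, "regions.bed")
  write_regions(cohort$regions, bed)
  tv <- file.path(dir, "truth_variants.tsv")
  write.table(cohort$truth$variants, tv, sep = "\t", quote = FALSE,
              row.names = FALSE)
  ts <- file.path(dir, "truth_samples.tsv")
  write.table(cohort$truth$samples, ts, sep = "\t", quote = FALSE,
              row.names = FALSE)
  list(rnaseq = rna, wes = wes, regions = bed, truth_variants = tv,
       truth_samples = ts)
}

#' Simulate the same cohort at several sequencing depths
#'
#' Re-runs [simulate_cohort()] once per depth level with identical seed and
#' configuration, so truth tables (and WES callsets) are shared across
#' levels and only RNA-seq detection thinning and read-depth fields differ.
#' Detection uniforms are shared too, so a variant detected at a lower depth
#' is always detected at any higher depth.
#'
#' @param config A [cohort_sim_config()].
#' @param depth_levels Numeric vector (length >= 2) of mean gene-mapped read
#'   counts, all positive.
#' @return Named list of `rnatmb_cohort` objects, one per level.
#' @export
depth_sweep <- function(config, depth_levels) {
  if (length(depth_levels) < 2) stop("need at least 2 depth levels")
  if (any(depth_levels <= 0)) stop("depth levels must be positive")
  out <- lapply(depth_levels, function(d) {
    cfg <- config
    cfg$mean_reads <- d
    simulate_cohort(cfg)
  })
  names(out) <- format(depth_levels, scientific = FALSE, trim = TRUE)
  out
}
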