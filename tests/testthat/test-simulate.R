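# Synthetic paired-cohort simulator: truth invariants, determinism,
# degenerate configurations, depth behavior.

test_that("truth table reproduces configured somatic burdens exactly", {
  co <- small_cohort()
  tv <- co$truth$variants
  ts <- co$truth$samples
  mb <- co$regions$total_megabases
  som <- table(factor(tv$sample_id[tv$class == "somatic"],
                      levels = ts$sample_id))
  expect_equal(as.numeric(som), ts$somatic_count)
  expect_equal(ts$true_tmb, ts$somatic_count / mb)
})

test_that("simulation is byte-identical under a fixed seed", {
  cfg <- cohort_sim_config(n_samples = 3, seed = 99)
  d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
  write_cohort(simulate_cohort(cfg), d1)
  write_cohort(simulate_cohort(cfg), d2)
  files <- list.files(d1)
  expect_gt(length(files), 0)
  for (f in files) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})

test_that("zero samples yield empty but valid outputs", {
  co <- simulate_cohort(cohort_sim_config(n_samples = 0, seed = 1))
  expect_length(co$rnaseq, 0)
  expect_equal(nrow(co$truth$variants), 0)
  d <- file.path(tempdir(), "empty-cohort")
  paths <- write_cohort(co, d)
  expect_true(file.exists(paths$regions))
})

test_that("emitted VCFs re-ingest to the same variant sets", {
  co <- small_cohort()
  d <- file.path(tempdir(), "reingest")
  paths <- write_cohort(co, d)
  for (sid in names(co$rnaseq)[1:3]) {
    back <- read_callset(paths$rnaseq[[sid]], "rnaseq_tumor_only",
                         sample_id = sid)
    expect_equal(back$variants, co$rnaseq[[sid]]$variants,
                 ignore_attr = TRUE)
  }
})

test_that("noise-free fully-detected cohorts give perfect isec concordance", {
  cfg <- cohort_sim_config(n_samples = 10, seed = 5,
                           ffpe_per_mb = 0, noise_per_mb = 0,
                           germline_per_mb = 0,
                           depth_half_sat = 1,  # detection prob ~ 1
                           wes_detection_prob = 1)
  co <- simulate_cohort(cfg)
  wes_f <- lapply(co$wes, filter_wes_matched)
  ids <- names(co$rnaseq)
  rna_t <- sapply(ids, function(s) {
    isec <- intersect_callsets(co$rnaseq[[s]], wes_f[[s]], "full_key")
    compute_tmb(isec, co$regions, "isec")$tmb
  })
  wes_t <- sapply(ids, function(s) {
    compute_tmb(wes_f[[s]], co$regions, "wes_matched")$tmb
  })
  expect_equal(unname(rna_t), unname(wes_t))
  expect_equal(correlation(rna_t, wes_t)$estimate, 1)
  # and the RNA callset is exactly the somatic truth
  expect_equal(unname(rna_t),
               co$truth$samples$true_tmb[match(ids,
                                               co$truth$samples$sample_id)])
})

test_that("FFPE artifacts are C>T enriched at the configured fraction", {
  co <- simulate_cohort(cohort_sim_config(n_samples = 20, seed = 8))
  tv <- co$truth$variants
  art <- tv[tv$class == "ffpe_artifact", ]
  ct <- (art$ref == "C" & art$alt == "T") | (art$ref == "G" & art$alt == "A")
  n <- nrow(art)
  phat <- mean(ct)
  # within 4 binomial standard errors of the configured 0.8
  expect_lt(abs(phat - 0.8), 4 * sqrt(0.8 * 0.2 / n) + 0.01)
})

test_that("depth sweep shares truth and detection is nested in depth", {
  cfg <- cohort_sim_config(n_samples = 5, seed = 12)
  sw <- depth_sweep(cfg, c(11e6, 23e6, 68e6))
  tv <- lapply(sw, function(co) co$truth$variants)
  fixed_cols <- setdiff(names(tv[[1]]), "in_rnaseq")
  expect_identical(tv[[2]][fixed_cols], tv[[1]][fixed_cols])
  expect_identical(tv[[3]][fixed_cols], tv[[1]][fixed_cols])
  # WES side identical across levels
  expect_identical(sw[[1]]$wes[[1]]$variants, sw[[3]]$wes[[1]]$variants)
  # a variant detected at lower depth is detected at every higher depth
  expect_true(all(!tv[[1]]$in_rnaseq | tv[[2]]$in_rnaseq))
  expect_true(all(!tv[[2]]$in_rnaseq | tv[[3]]$in_rnaseq))
  # per-sample detected counts non-decreasing in depth
  counts <- sapply(tv, function(v) sum(v$in_rnaseq))
  expect_true(all(diff(counts) >= 0))
  expect_error(depth_sweep(cfg, 1e7), "2 depth levels")
  expect_error(depth_sweep(cfg, c(-1, 1e7)), "positive")
})

test_that("germline records carry population frequencies and rs ids", {
  co <- small_cohort()
  for (sid in names(co$rnaseq)[1:3]) {
    v <- co$rnaseq[[sid]]$variants
    tv <- co$truth$variants
    tv <- tv[tv$sample_id == sid, ]
    key <- function(df) paste(df$chrom, df$pos, df$ref, df$alt)
    germ <- v[key(v) %in% key(tv[tv$class == "germline", ]), ]
    som <- v[key(v) %in% key(tv[tv$class == "somatic", ]), ]
    expect_true(all(germ$ExAC_nontcga_ALL >= 0.000033))
    expect_true(all(is.na(som$ExAC_nontcga_ALL)))
    expect_true(all(is.na(som$avsnp150)))
  }
})
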