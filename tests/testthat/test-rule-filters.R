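# Deterministic rule-based filtering recipes.

test_that("matched-WES filtering keeps exactly PASS records", {
  cs <- toy_callset(data.frame(chrom = "chr1", pos = c(100L, 200L, 300L),
                               ref = "C", alt = "T",
                               filter = c("", "germline_risk", "")),
                    "wes_matched")
  f <- filter_wes_matched(cs)
  expect_equal(n_variants(f), 2)
  expect_true(all(f$variants$filter == ""))
  # all-PASS identity and empty-callset cases
  allpass <- toy_callset(data.frame(chrom = "chr1", pos = c(1L, 2L),
                                    ref = "C", alt = "T"), "wes_matched")
  expect_equal(filter_wes_matched(allpass)$variants, allpass$variants)
  empty <- toy_callset(data.frame(chrom = character(0), pos = integer(0),
                                  ref = character(0), alt = character(0)),
                       "wes_matched")
  expect_equal(n_variants(filter_wes_matched(empty)), 0)
  # wrong source tag is a contract error
  expect_error(filter_wes_matched(
    toy_callset(data.frame(chrom = "chr1", pos = 1L, ref = "C", alt = "T"),
                "rnaseq_tumor_only")), "source")
})

test_that("tumor-only WES filter applies ExAC rarity strictly and dbSNP", {
  v <- data.frame(chrom = "chr1", pos = 1:4 * 100L, ref = "C", alt = "T",
                  filter = "",
                  ExAC_ALL = c(0.001, NA, 0.000033, NA),
                  id = c(NA, NA, NA, "rs12345"))
  f <- filter_wes_tumor_only(toy_callset(v, "wes_tumor_only"))
  # 0.001 removed; absent frequency treated as rare; exactly-at-threshold
  # removed (strict <); rsID removed
  expect_equal(f$variants$pos, 200)
})

test_that("RNA-seq rule filter honors the filter-label whitelist", {
  v <- data.frame(chrom = "chr1", pos = 1:5 * 100L, ref = "C", alt = "T",
                  filter = c("germline_risk",
                             "germline_risk;panel_of_normals",
                             "", "base_qual", "germline_risk"),
                  id = c(NA, NA, NA, NA, "rs12345"))
  f <- filter_rnaseq_tumor_only(toy_callset(v))
  # whitelisted label sets with no rsID/ExAC retained; base_qual and
  # dbSNP-tagged records removed
  expect_equal(f$variants$pos, c(100, 200, 300))
  # the literal whitelist reading (no PASS) is selectable
  literal <- filter_config(allowed_rnaseq_filter_sets = list(
    "germline_risk", c("germline_risk", "panel_of_normals")))
  expect_equal(filter_rnaseq_tumor_only(toy_callset(v), literal)$variants$pos,
               c(100, 200))
})

test_that("RNA-seq rule filter uses the non-TCGA ExAC channel", {
  v <- data.frame(chrom = "chr1", pos = c(100L, 200L), ref = "C", alt = "T",
                  filter = "germline_risk",
                  ExAC_nontcga_ALL = c(0.5, NA),
                  ExAC_ALL = c(NA, 0.5))
  f <- filter_rnaseq_tumor_only(toy_callset(v))
  # high non-TCGA frequency removes; the plain ExAC_ALL channel does not
  expect_equal(f$variants$pos, 200)
})

test_that("all three filters are idempotent and monotone", {
  co <- small_cohort()
  rna <- co$rnaseq[[1]]
  wes <- co$wes[[1]]
  wes_to <- wes; wes_to$source <- "wes_tumor_only"
  cases <- list(
    list(filter_rnaseq_tumor_only, rna),
    list(filter_wes_matched, wes),
    list(filter_wes_tumor_only, wes_to))
  for (case in cases) {
    f <- case[[1]]; cs <- case[[2]]
    once <- f(cs)
    expect_lte(n_variants(once), n_variants(cs))
    key_in <- paste(once$variants$chrom, once$variants$pos,
                    once$variants$ref, once$variants$alt)
    key_all <- paste(cs$variants$chrom, cs$variants$pos,
                     cs$variants$ref, cs$variants$alt)
    expect_true(all(key_in %in% key_all))
    twice <- f(once)
    expect_equal(twice$variants, once$variants)
  }
})

test_that("filters commute with restriction to a chromosome subset", {
  co <- small_cohort()
  cs <- co$rnaseq[[2]]
  chroms <- unique(cs$variants$chrom)[1:5]
  restrict <- function(x) {
    x$variants <- x$variants[x$variants$chrom %in% chroms, , drop = FALSE]
    rownames(x$variants) <- NULL
    x
  }
  a <- restrict(filter_rnaseq_tumor_only(cs))
  b <- filter_rnaseq_tumor_only(restrict(cs))
  expect_equal(a$variants, b$variants)
})

test_that("planted germline is fully removed and planted somatic untouched", {
  co <- small_cohort()
  truth <- co$truth$variants
  for (sid in names(co$rnaseq)) {
    f <- filter_rnaseq_tumor_only(co$rnaseq[[sid]])
    tv <- truth[truth$sample_id == sid & truth$in_rnaseq, , drop = FALSE]
    key <- function(df) paste(df$chrom, df$pos, df$ref, df$alt)
    kept <- key(f$variants)
    germ <- key(tv[tv$class == "germline", , drop = FALSE])
    som <- key(tv[tv$class == "somatic", , drop = FALSE])
    expect_length(intersect(kept, germ), 0)
    expect_true(all(som %in% kept))
  }
})

test_that("filter configuration validates its threshold", {
  expect_error(filter_config(exac_threshold = 0), "between 0 and 1")
  expect_error(filter_config(exac_threshold = 1), "between 0 and 1")
})
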