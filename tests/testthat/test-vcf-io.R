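# VCF ingestion, writing, merging, intersection, and BED regions.

test_that("biallelic records are parsed and multiallelic sites excluded", {
  path <- write_minimal_vcf(c(
    "chr1\t100\t.\tC\tT\t.\tPASS\tTLOD=6.3\tGT:AD\t0/1:10,5",
    "chr1\t200\t.\tA\tG,C\t.\tPASS\t.\tGT:AD\t0/1:7,2,1"))
  cs <- read_callset(path, "rnaseq_tumor_only")
  expect_equal(n_variants(cs), 1)
  expect_equal(cs$variants$pos, 100)
  expect_equal(cs$ingest_stats$n_multiallelic_sites, 1)
  # exclusion + retention partition the file
  expect_equal(cs$ingest_stats$n_retained +
                 cs$ingest_stats$n_multiallelic_records,
               cs$ingest_stats$n_records)
})

test_that("split biallelic lines at one site count as one multiallelic site", {
  path <- write_minimal_vcf(c(
    "chr1\t100\t.\tC\tT\t.\tPASS\t.\tGT:AD\t0/1:10,5",
    "chr1\t100\t.\tC\tA\t.\tPASS\t.\tGT:AD\t0/1:10,3",
    "chr2\t50\t.\tG\tA\t.\tPASS\t.\tGT:AD\t0/1:8,4"))
  cs <- read_callset(path, "rnaseq_tumor_only")
  expect_equal(n_variants(cs), 1)
  expect_equal(cs$variants$chrom, "chr2")
  expect_equal(cs$ingest_stats$n_multiallelic_records, 2)
  expect_equal(cs$ingest_stats$n_multiallelic_sites, 1)
})

test_that("header-only VCF yields an empty callset", {
  path <- write_minimal_vcf(character(0))
  cs <- read_callset(path, "rnaseq_tumor_only")
  expect_equal(n_variants(cs), 0)
})

test_that("FILTER semantics: semicolon split, '.' and PASS mean empty set", {
  path <- write_minimal_vcf(c(
    "chr1\t100\t.\tC\tT\t.\tgermline_risk;panel_of_normals\t.\tGT:AD\t0/1:1,1",
    "chr1\t200\t.\tC\tT\t.\t.\t.\tGT:AD\t0/1:1,1",
    "chr1\t300\t.\tC\tT\t.\tPASS\t.\tGT:AD\t0/1:1,1"))
  cs <- read_callset(path, "rnaseq_tumor_only")
  expect_equal(cs$variants$filter,
               c("germline_risk;panel_of_normals", "", ""))
})

test_that("missing INFO fields map to NA, never zero; chroms normalized", {
  path <- write_minimal_vcf(
    "1\t100\trs99\tC\tT\t.\tPASS\tExAC_ALL=0.2\tGT:AD\t0/1:10,5")
  cs <- read_callset(path, "rnaseq_tumor_only")
  expect_true(is.na(cs$variants$TLOD))
  expect_true(is.na(cs$variants$ExAC_nontcga_ALL))
  expect_equal(cs$variants$ExAC_ALL, 0.2)
  expect_equal(cs$variants$chrom, "chr1")
  expect_equal(cs$variants$id, "rs99")
  expect_equal(cs$variants$AD_ref, 10)
  expect_equal(cs$variants$AD_alt, 5)
})

test_that("write/read round trip preserves all downstream fields exactly", {
  co <- small_cohort()
  for (cs in list(co$rnaseq[[1]], co$wes[[2]])) {
    path <- tempfile(fileext = ".vcf")
    write_callset(cs, path)
    back <- read_callset(path, cs$source, sample_id = cs$sample_id)
    expect_equal(back$variants, cs$variants, ignore_attr = TRUE)
  }
})

test_that("merge pools variants additively and preserves origin sample ids", {
  a <- toy_callset(random_variant_table(3, "A") |> dedupe_variants(),
                   sample_id = "A")
  b <- toy_callset(random_variant_table(4, "B") |> dedupe_variants(),
                   sample_id = "B")
  pooled <- merge_callsets(list(a, b))
  expect_equal(n_variants(pooled), n_variants(a) + n_variants(b))
  expect_setequal(unique(pooled$variants$sample_id), c("A", "B"))
  # identity merge
  expect_equal(merge_callsets(list(a))$variants, a$variants)
  # the same variant key in two samples stays two pooled records
  x <- data.frame(chrom = "chr1", pos = 10L, ref = "C", alt = "T")
  two <- merge_callsets(list(toy_callset(x, sample_id = "A"),
                             toy_callset(x, sample_id = "B")))
  expect_equal(n_variants(two), 2)
})

test_that("merging mixed source tags is a contract error", {
  a <- toy_callset(data.frame(chrom = "chr1", pos = 1L, ref = "C",
                              alt = "T"), "rnaseq_tumor_only")
  b <- toy_callset(data.frame(chrom = "chr1", pos = 2L, ref = "C",
                              alt = "T"), "wes_matched")
  expect_error(merge_callsets(list(a, b)), "mixed source")
})

test_that("intersection honors full-key vs coordinate-only matching", {
  a <- toy_callset(data.frame(chrom = "chr1", pos = 100L, ref = "C",
                              alt = "T"))
  b <- toy_callset(data.frame(chrom = "chr1", pos = 100L, ref = "C",
                              alt = "A"))
  expect_equal(n_variants(intersect_callsets(a, b, "full_key")), 0)
  expect_equal(n_variants(intersect_callsets(a, b, "coordinate_only")), 1)
  # identity and empty-b cases
  expect_equal(intersect_callsets(a, a, "full_key")$variants, a$variants)
  empty <- toy_callset(empty <- data.frame(chrom = character(0),
                                           pos = integer(0),
                                           ref = character(0),
                                           alt = character(0)))
  expect_equal(n_variants(intersect_callsets(a, empty, "full_key")), 0)
})

test_that("intersection is idempotent and full-key is at most coordinate", {
  set.seed(99)
  for (rep in 1:5) {
    a <- toy_callset(dedupe_variants(random_variant_table(40)))
    b <- toy_callset(dedupe_variants(random_variant_table(40)))
    for (mode in c("full_key", "coordinate_only")) {
      once <- intersect_callsets(a, b, mode)
      twice <- intersect_callsets(once, b, mode)
      expect_equal(twice$variants, once$variants)
    }
    expect_lte(n_variants(intersect_callsets(a, b, "full_key")),
               n_variants(intersect_callsets(a, b, "coordinate_only")))
  }
})

test_that("BED regions merge overlaps and compute megabases", {
  path <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t3000000"), path)
  expect_equal(read_regions(path)$total_megabases, 3)
  writeLines(c("chr1\t0\t100", "chr1\t50\t200"), path)
  rs <- read_regions(path)
  expect_equal(rs$total_megabases * 1e6, 200)
  expect_equal(length(rs$granges), 1)
  # empty BED: zero megabases, and TMB refuses it downstream
  writeLines(character(0), path)
  empty <- read_regions(path)
  expect_equal(empty$total_megabases, 0)
  cs <- toy_callset(data.frame(chrom = "chr1", pos = 1L, ref = "C",
                               alt = "T"))
  expect_error(compute_tmb(cs, empty, "rule"), "total_megabases > 0")
})

test_that("malformed BED intervals are format errors naming the line", {
  path <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t100", "chr1\t500\t400"), path)
  expect_error(read_regions(path), "line 2")
})
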