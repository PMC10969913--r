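test_that("VCF ingestion keeps alt-carrying PASS records as full-tuple keys", {
  vcf <- write_test_vcf(withr::local_tempfile(fileext = ".vcf"),
                        "chr18", 56202768, "C", "A")
  calls <- read_patient_calls(vcf)
  expect_equal(calls$chrom, "chr18")
  expect_equal(calls$pos, 56202768L)
  expect_equal(calls$ref, "C")
  expect_equal(calls$alt, "A")
  expect_equal(calls$state, "present")

  # homozygous-reference genotype carries no alternate allele
  vcf0 <- write_test_vcf(withr::local_tempfile(fileext = ".vcf"),
                         "chr1", 100, "G", "T", gt = "0/0")
  expect_equal(nrow(read_patient_calls(vcf0)), 0L)

  # multiallelic ALT stays comma-joined as one key
  vcfm <- write_test_vcf(withr::local_tempfile(fileext = ".vcf"),
                         "chr3", 32933360, "C", "T,CTT", gt = "1/2")
  callsm <- read_patient_calls(vcfm)
  expect_equal(callsm$alt, "T,CTT")
  expect_equal(variant_id(callsm), "chr3:32933360:C:T,CTT")
})

test_that("FILTER policy defaults to PASS/. and is relaxable", {
  vcf <- write_test_vcf(withr::local_tempfile(fileext = ".vcf"),
                        "chr1", c(10, 20, 30), c("A", "C", "G"),
                        c("T", "G", "A"),
                        filter = c("PASS", "clustered_events", "."))
  strict <- read_patient_calls(vcf)
  expect_equal(strict$pos, c(10L, 30L))
  relaxed <- read_patient_calls(vcf, keep_filtered = TRUE)
  expect_equal(nrow(relaxed), 3L)
})

test_that("no-call genotypes are returned as missing, not absent", {
  vcf <- write_test_vcf(withr::local_tempfile(fileext = ".vcf"),
                        "chr2", c(5, 6), c("A", "T"), c("G", "C"),
                        gt = c("./.", "0/1"))
  calls <- read_patient_calls(vcf)
  expect_equal(calls$state[calls$pos == 5], "missing")
  expect_equal(calls$state[calls$pos == 6], "present")
})

test_that("malformed VCF input fails with a line-numbered parse error", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_test_vcf(path, "chr1", c(1, 2), c("A", "C"), c("T", "G"))
  lines <- readLines(path)
  lines[length(lines)] <- "chr1\t2\t.\tC\tG"  # truncated record
  writeLines(lines, path)
  expect_error(read_patient_calls(path), "malformed VCF line 6")

  # sites-only VCF has no genotype column to assess presence from
  path2 <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               "chr1\t1\t.\tA\tT\t.\tPASS\t."), path2)
  expect_error(read_patient_calls(path2), "genotype")
})

test_that("variant keys validate alleles, positions and chromosome labels", {
  expect_error(variant_key("chr1", 0, "A", "T"), ">= 1")
  expect_error(variant_key("chr1", 5, "", "T"), "REF")
  expect_error(variant_key("chr1", 5, "A", "U"), "ALT")
  expect_error(variant_key("chr1", 5, "A", "A"), "must differ")
  expect_error(variant_key("chr99", 5, "A", "T"), "unknown chromosome")
  expect_warning(k <- variant_key("18", 56202768, "C", "A"), "normalized")
  expect_equal(k$chrom, "chr18")
  expect_equal(parse_variant_id(variant_id(k)), k)
})

test_that("variant type partitions records into SNV and InDel", {
  expect_equal(classify_variant_type("G", "A"), "SNV")
  expect_equal(classify_variant_type("AGCGCTG", "A"), "InDel")
  expect_equal(classify_variant_type("C", "T,CTT"), "InDel")
  expect_equal(classify_variant_type("A", "T,G"), "SNV")
  expect_error(classify_variant_type("", "A"), "empty allele")

  # partition property over the bundled reference tables
  tabs <- load_printed_tables()
  both <- rbind(tabs$female[, c("ref", "alt")], tabs$male[, c("ref", "alt")])
  types <- classify_variant_type(both$ref, both$alt)
  expect_equal(sum(types == "SNV") + sum(types == "InDel"), nrow(both))
})

test_that("presence matrix is the sorted union with union-size invariant", {
  sets <- list(
    P1 = key_tbl(c("chr2", "chr1"), c(50, 10), c("A", "C"), c("G", "T")),
    P2 = key_tbl(c("chr1", "chrX", "chr2"), c(10, 99, 50),
                 c("C", "G", "A"), c("T", "A", "G")),
    P3 = key_tbl("chr10", 7, "T", "A")
  )
  pm <- build_presence_matrix(
    sets, patients_tbl(c("P1", "P2", "P3"), c("F", "F", "M"))
  )
  # brute-force union of key strings
  expect_equal(nrow(pm$variants),
               length(unique(unlist(lapply(sets, variant_id)))))
  # karyotype order: chr1 < chr2 < chr10 < chrX
  expect_equal(pm$variants$chrom, c("chr1", "chr2", "chr10", "chrX"))
  expect_equal(unname(pm$cells[, "P1"]), c("P", "P", "A", "A"))
  expect_equal(unname(pm$cells[, "P3"]), c("A", "A", "P", "A"))
  # every row has at least one present cell
  expect_true(all(rowSums(pm$cells == "P") >= 1))

  expect_error(
    build_presence_matrix(sets[c(1, 1)], patients_tbl("P1", "F")),
    "duplicate"
  )
})

test_that("presence matrix round-trips through its TSV format", {
  sets <- list(
    A = key_tbl("chr1", c(1, 2), c("A", "C"), c("T", "G")),
    B = key_tbl("chr1", c(2, 3), c("C", "G"), c("G", "AT"),
                state = c("present", "present"))
  )
  sets$B <- rbind(sets$B, key_tbl("chr1", 1, "A", "T", state = "missing"))
  pm <- build_presence_matrix(sets, patients_tbl(c("A", "B"), c("F", "M")))
  expect_equal(unname(pm$cells["chr1:1:A:T", ]), c("P", "M"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_presence_matrix(pm, path)
  back <- read_presence_matrix(path)
  expect_identical(back$cells, pm$cells)
  expect_equal(back$variants, pm$variants)
  expect_equal(back$patients, pm$patients)
})
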