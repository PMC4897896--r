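test_that("a toy VCF imports with correct counts, types and verbatim genotypes", {
  body <- c(
    "chr1\t100\tv1\tA\tT\t.\t.\t.\tGT:GQ:DP\t0|1:40:12\t./.:.:.",
    "chr1\t200\t.\tG\tGTT\t.\t.\t.\tGT:GQ:DP\t1/0:9:3\t0/0:50:20",
    "chr2\t300\tv3\tT\t<DEL>\t.\t.\t.\tGT:GQ:DP\t0/1:22:8\t1/1:33:9")
  ts <- toy_store(body)
  st <- ts$store
  proj <- get_project(st, "p")
  expect_identical(length(proj$variant_ids), 3L)
  expect_identical(proj$individuals, c("S1", "S2"))
  v <- st$data$variants
  expect_setequal(v$variant_type, c("SNP", "INDEL", "SV-like"))
  expect_identical(v$stop[v$variant_id == "v1"], 100L)
  run <- genonav:::get_run(st, "p", "r")
  expect_identical(unname(run$gt["v1", ]), c("0|1", "./."))
  expect_identical(unname(run$gt[grep("^chr1:200", rownames(run$gt)), ]), c("1/0", "0/0"))
  expect_identical(unname(run$gq["v1", ]), c(40L, NA))
  expect_identical(unname(run$dp["v3", ]), c(8L, 9L))
  # generated ID follows seq:start:ref:alts
  expect_true("chr1:200:G:GTT" %in% rownames(run$gt))
  # project registries reflect exactly the distinct sets present
  expect_identical(proj$sequences, c("chr1", "chr2"))
  expect_setequal(proj$variant_types, c("SNP", "INDEL", "SV-like"))
})

test_that("malformed VCF lines are rejected with their line number", {
  path <- write_toy_vcf(c(
    "chr1\t100\tv1\tA\tT\t.\t.\t.\tGT\t0/1\t0/0",
    "chr1\t200\tv2\tG\tC\t.\t.\t.\tGT\t0/1"))
  st <- open_store(tempfile(), "db")
  expect_error(import_vcf(st, path, "p", "r"), "line 10")
})

test_that("duplicate (project, run) imports are refused unless overwrite is requested", {
  body <- "chr1\t100\tv1\tA\tT\t.\t.\t.\tGT\t0/1\t0/0"
  ts <- toy_store(body)
  path2 <- write_toy_vcf(body)
  expect_error(import_vcf(ts$store, path2, "p", "r"), "overwrite")
  expect_silent(import_vcf(ts$store, path2, "p", "r", overwrite = TRUE))
})

test_that("incremental loading attaches new samples to existing individuals", {
  ts <- toy_store(c("chr1\t100\tv1\tA\tT\t.\t.\t.\tGT\t0/1\t0/0"),
                  samples = c("I1", "I2"))
  st <- ts$store
  before <- get_project(st, "p")
  path2 <- write_toy_vcf(c("chr1\t150\tv2\tG\tC\t.\t.\t.\tGT\t0/0\t1/1\t0/1"),
                         samples = c("I2", "I3", "I4"))
  rep <- import_vcf(st, path2, "p", "r2")
  after <- get_project(st, "p")
  # one shared individual: individuals +2, samples +3
  expect_identical(length(after$individuals) - length(before$individuals), 2L)
  expect_identical(rep$samples_registered, 3L)
  expect_identical(nrow(after$samples[after$samples$individual == "I2", ]), 2L)
})

test_that("annotation style is detected from the header and parsed from INFO", {
  expect_identical(detect_annotation_style(
    '##INFO=<ID=ANN,Number=.,Type=String,Description="x">'), "ANN")
  expect_identical(detect_annotation_style(
    '##INFO=<ID=EFF,Number=.,Type=String,Description="x">'), "EFF")
  expect_identical(detect_annotation_style("##fileformat=VCFv4.2"), "none")
  expect_warning(
    style <- detect_annotation_style(c(
      '##INFO=<ID=EFF,Number=.,Type=String,Description="x">',
      '##INFO=<ID=ANN,Number=.,Type=String,Description="x">')),
    "ANN")
  expect_identical(style, "ANN")

  ann <- parse_annotations("T|missense_variant|MODERATE|GeneX|more|fields", "ANN")
  expect_identical(ann$effects, "missense_variant")
  expect_identical(ann$genes, "GeneX")
  ann2 <- parse_annotations(
    "T|missense_variant|MODERATE|GeneX,C|stop_gained&splice_region_variant|HIGH|GeneY", "ANN")
  expect_setequal(ann2$effects, c("missense_variant", "stop_gained", "splice_region_variant"))
  expect_setequal(ann2$genes, c("GeneX", "GeneY"))
  eff <- parse_annotations(
    "NON_SYNONYMOUS_CODING(MODERATE|MISSENSE|gCa/gTa|A159V|459|GeneZ|protein_coding|CODING|TR1|1)", "EFF")
  expect_identical(eff$effects, "NON_SYNONYMOUS_CODING")
  expect_identical(eff$genes, "GeneZ")
  expect_identical(parse_annotations(".", "ANN"), list(effects = character(), genes = character()))
  expect_warning(bad <- parse_annotations("unparseable-entry", "EFF"), "skipping")
  expect_length(bad$effects, 0L)
})

test_that("a HapMap file decodes two-letter diploid codes and registers samples", {
  path <- tempfile(fileext = ".hmp.txt")
  writeLines(c(
    paste(c("rs#", "alleles", "chrom", "pos", "strand", "assembly#", "center",
            "protLSID", "assayLSID", "panelLSID", "QCcode", "H1", "H2", "H3"),
          collapse = "\t"),
    "rs1\tA/T\tchr1\t100\t+\tNA\tNA\tNA\tNA\tNA\tNA\tAT\tNN\tTT",
    "rs2\t+/-\tchr1\t250\t+\tNA\tNA\tNA\tNA\tNA\tNA\t--\t+-\t++"), path)
  st <- open_store(tempfile(), "db")
  rep <- import_hapmap(st, path, "p", "r")
  expect_identical(rep$variants_imported, 2L)
  expect_identical(rep$samples_registered, 3L)
  run <- genonav:::get_run(st, "p", "r")
  expect_identical(unname(run$gt["rs1", ]), c("0/1", "./.", "1/1"))
  # +/- indel codes are literal alleles; "--" is hom for the "-" allele here
  expect_identical(unname(run$gt["rs2", ]), c("1/1", "0/1", "0/0"))
  expect_null(run$gq)
  expect_false(any(grepl("|", run$gt, fixed = TRUE)))
  v <- st$data$variants
  expect_identical(v$variant_type[v$variant_id == "rs2"], "INDEL")
  expect_identical(v$stop[v$variant_id == "rs1"], 100L)
})

test_that("inconsistent HapMap column counts are rejected with a line number", {
  path <- tempfile(fileext = ".hmp.txt")
  writeLines(c(
    paste(c("rs#", "alleles", "chrom", "pos", "strand", "assembly#", "center",
            "protLSID", "assayLSID", "panelLSID", "QCcode", "H1"), collapse = "\t"),
    "rs1\tA/T\tchr1\t100\t+\tNA\tNA\tNA\tNA\tNA\tNA\tAT",
    "rs2\tA/T\tchr1\t200\t+\tNA\tNA\tNA\tNA\tNA\tNA"), path)
  st <- open_store(tempfile(), "db")
  expect_error(import_hapmap(st, path, "p", "r"), "line 3")
})

test_that("tag landmarks fall every chunk_size variants and survive incremental import", {
  body <- sprintf("chr1\t%d\tv%02d\tA\tT\t.\t.\t.\tGT\t0/1\t0/0", 1:10 * 10, 1:10)
  ts <- toy_store(body, chunk_size = 3L)
  st <- ts$store
  ti <- get_tag_index(st, "p")
  expect_identical(ti$tags, c("v03", "v06", "v09"))
  ti2 <- build_tag_index(st, "p", 1000L)
  expect_length(ti2$tags, 0L)
  expect_length(scan_chunks(st, "p", tag_index = ti2), 1L)
  # incremental import rebuilds the index over old + new variants
  path2 <- write_toy_vcf(sprintf("chr1\t%d\tw%02d\tG\tC\t.\t.\t.\tGT\t0/0\t0/1",
                                 11:15 * 10, 1:5))
  import_vcf(st, path2, "p", "r2", chunk_size = 3L)
  ids_all <- get_project(st, "p")$variant_ids
  got <- unlist(lapply(scan_chunks(st, "p", tag_index = get_tag_index(st, "p")),
                       genonav:::chunk_ids, ids_in_scan_order = ids_all))
  expect_identical(sort(got), sort(ids_all))
  expect_length(ids_all, 15L)
})

test_that("haploid and tetraploid VCFs import losslessly", {
  hap <- toy_store(c("chr1\t100\tv1\tA\tT\t.\t.\t.\tGT\t0\t1",
                     "chr1\t200\tv2\tG\tC\t.\t.\t.\tGT\t.\t0"))
  run <- genonav:::get_run(hap$store, "p", "r")
  expect_identical(unname(run$gt["v1", ]), c("0", "1"))
  expect_identical(run$ploidy, 1L)

  tet <- toy_store(c("chr1\t100\tv1\tA\tT\t.\t.\t.\tGT\t0/1/1/0\t1|1|0|1",
                     "chr1\t200\tv2\tG\tC\t.\t.\t.\tGT\t./././.\t0/0/0/0"))
  run4 <- genonav:::get_run(tet$store, "p", "r")
  expect_identical(run4$ploidy, 4L)
  expect_identical(unname(run4$gt["v1", ]), c("0/1/1/0", "1|1|0|1"))
  expect_identical(unname(run4$canon["v1", ]), c("0/0/1/1", "0/1/1/1"))
})

test_that("import order of distinct runs does not change the resulting store", {
  b1 <- c("chr1\t100\tv1\tA\tT\t.\t.\t.\tGT\t0/1\t0/0")
  b2 <- c("chr1\t200\tv2\tG\tC\t.\t.\t.\tGT\t1/1\t0/1")
  p1 <- write_toy_vcf(b1); p2 <- write_toy_vcf(b2)
  stA <- open_store(tempfile(), "db")
  import_vcf(stA, p1, "p", "r1"); import_vcf(stA, p2, "p", "r2")
  stB <- open_store(tempfile(), "db")
  import_vcf(stB, p2, "p", "r2"); import_vcf(stB, p1, "p", "r1")
  pa <- get_project(stA, "p"); pb <- get_project(stB, "p")
  expect_identical(pa$variant_ids, pb$variant_ids)
  expect_identical(sort(pa$runs), sort(pb$runs))
  expect_identical(data.table::setkey(data.table::copy(pa$samples), sample),
                   data.table::setkey(data.table::copy(pb$samples), sample))
  expect_identical(genonav:::get_run(stA, "p", "r1")$gt,
                   genonav:::get_run(stB, "p", "r1")$gt)
})

test_that("phase groups come from PS when present, else contiguous phased stretches", {
  body <- c(
    "chr1\t100\tv1\tA\tT\t.\t.\t.\tGT:PS\t0|1:77\t0/1:.",
    "chr1\t200\tv2\tG\tC\t.\t.\t.\tGT\t1|0\t0|1",
    "chr1\t300\tv3\tT\tA\t.\t.\t.\tGT\t0|1\t0/1",
    "chr1\t400\tv4\tC\tG\t.\t.\t.\tGT\t0/1\t1|1")
  ts <- toy_store(body)
  run <- genonav:::get_run(ts$store, "p", "r")
  expect_identical(run$phase["v1", "S1@r"], "77")
  # S1 phased at v2+v3 (one stretch anchored at pos 200), unphased at v4
  expect_identical(run$phase["v2", "S1@r"], "200")
  expect_identical(run$phase["v3", "S1@r"], "200")
  expect_true(is.na(run$phase["v4", "S1@r"]))
  # S2: isolated stretches get their own anchors
  expect_identical(run$phase["v2", "S2@r"], "200")
  expect_identical(run$phase["v4", "S2@r"], "400")
  expect_true(is.na(run$phase["v1", "S2@r"]))
})
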