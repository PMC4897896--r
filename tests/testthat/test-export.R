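test_that("consolidation picks the majority genotype; ties are seed-deterministic", {
  maj <- consolidate_individual(calls_from_strings(c("0/0", "0/0", "0/1")))
  expect_identical(sort(maj$alleles), c(0L, 0L))
  one <- consolidate_individual(calls_from_strings("0/1"))
  expect_identical(sort(one$alleles), c(0L, 1L))
  # unordered comparison: 0/1 and 1/0 are the same genotype, so no tie here
  expect_identical(sort(consolidate_individual(
    calls_from_strings(c("0/1", "1/0", "0/0")))$alleles), c(0L, 1L))
  allmiss <- consolidate_individual(calls_from_strings(c("./.", "./.")))
  expect_true(is_missing_call(allmiss))
  # tie: the seeded pick is reproducible and seed-dependent in aggregate
  tie <- calls_from_strings(c("0/0", "0/1"))
  for (seed in c(1L, 7L, 123L)) {
    expect_identical(consolidate_individual(tie, seed)$alleles,
                     consolidate_individual(tie, seed)$alleles)
  }
  picks <- vapply(1:40, function(s)
    paste(sort(consolidate_individual(tie, s)$alleles), collapse = "/"),
    character(1))
  expect_setequal(unique(picks), c("0/0", "0/1"))
})

test_that("unfiltered VCF export reproduces genotypes, GQ, DP and separators record-for-record", {
  fs <- fixture_spec(n_variants = 50, n_individuals = 6, missing_rate = 0.1,
                     phased_fraction = 0.4, fraction_indels = 0.1, seed = 17)
  ts <- fixture_store(fs)
  out <- file.path(tempfile("exp"), "out.vcf")
  dir.create(dirname(out))
  export_variants(ts$store, "p", filter_spec(),
                  export_spec("VCF", out, random_seed = 1))
  src <- oracle_parse_vcf(ts$vcf)
  got <- oracle_parse_vcf(out)
  expect_identical(length(got$recs), length(src$recs))
  src_by_id <- setNames(src$recs, vapply(src$recs, `[[`, character(1), "id"))
  for (r in got$recs) {
    s <- src_by_id[[r$id]]
    expect_identical(r$gt, s$gt)
    expect_identical(r$gq, s$gq)
    expect_identical(r$dp, s$dp)
    expect_identical(r$pos, s$pos)
    expect_identical(r$alleles, s$alleles)
  }
})

test_that("import -> export -> re-import round-trips the store including phasing and GQ/DP", {
  fs <- fixture_spec(n_variants = 40, n_individuals = 5, missing_rate = 0.12,
                     phased_fraction = 0.5, seed = 23)
  ts <- fixture_store(fs)
  out <- file.path(tempfile("exp"), "rt.vcf")
  dir.create(dirname(out))
  export_variants(ts$store, "p", filter_spec(), export_spec("VCF", out))
  st2 <- open_store(tempfile(), "db2")
  import_vcf(st2, out, "p", "r")
  r1 <- genonav:::get_run(ts$store, "p", "r")
  r2 <- genonav:::get_run(st2, "p", "r")
  ids <- sort(rownames(r1$gt))
  expect_identical(sort(rownames(r2$gt)), ids)
  expect_identical(r2$gt[ids, ], r1$gt[ids, ])
  expect_identical(r2$gq[ids, ], r1$gq[ids, ])
  expect_identical(r2$dp[ids, ], r1$dp[ids, ])
  expect_identical(is.na(r2$phase[ids, ]), is.na(r1$phase[ids, ]))
  expect_identical(r2$phase[ids, ], r1$phase[ids, ])
  v1 <- ts$store$data$variants; v2 <- st2$data$variants
  expect_identical(v2[order(v2$variant_id), ], v1[order(v1$variant_id), ])
})

test_that("phase sets survive the filtering-out of intermediate variants", {
  body <- c(
    "chr1\t100\tv1\tA\tT\t.\t.\t.\tGT\t0|1",
    "chr1\t200\tv2\tG\tC\t.\t.\t.\tGT\t1|0",
    "chr1\t300\tv3\tT\tA\t.\t.\t.\tGT\t0|1",
    "chr1\t400\tv4\tC\tG\t.\t.\t.\tGT\t0/1")
  ts <- toy_store(body, samples = "S1")
  out <- file.path(tempfile("exp"), "ph.vcf")
  dir.create(dirname(out))
  # drop the middle variant of the phased triple by position
  keep <- filter_spec(position_range = list(sequence = "chr1", start = 250, end = 500))
  export_variants(ts$store, "p", keep, export_spec("VCF", out))
  lines <- readLines(out)
  recs <- lines[!startsWith(lines, "#")]
  expect_length(recs, 2L)
  f3 <- strsplit(recs[1], "\t")[[1]]; f4 <- strsplit(recs[2], "\t")[[1]]
  fmt <- strsplit(f3[9], ":")[[1]]
  ps_idx <- match("PS", fmt)
  expect_false(is.na(ps_idx))
  g3 <- strsplit(f3[10], ":")[[1]]; g4 <- strsplit(f4[10], ":")[[1]]
  expect_true(grepl("|", g3[1], fixed = TRUE))       # v3 still phased
  expect_identical(g3[ps_idx], "100")                # same set as v1's stretch
  expect_false(grepl("|", g4[1], fixed = TRUE))      # v4 unphased -> "/"
  expect_identical(g4[ps_idx], ".")

  # and the flanking pair of the full stretch shares the set when v2 is absent
  out2 <- file.path(dirname(out), "ph2.vcf")
  export_variants(ts$store, "p",
                  filter_spec(position_range = list(sequence = "chr1", start = 1, end = 120)),
                  export_spec("VCF", out2))
  rec <- readLines(out2); rec <- rec[!startsWith(rec, "#")]
  expect_identical(strsplit(strsplit(rec[1], "\t")[[1]][10], ":")[[1]][2], "100")

  # two distinct phase groups export two distinct set IDs
  body2 <- c("chr1\t100\tw1\tA\tT\t.\t.\t.\tGT\t0|1",
             "chr1\t200\tw2\tG\tC\t.\t.\t.\tGT\t0/1",
             "chr1\t300\tw3\tT\tA\t.\t.\t.\tGT\t1|0")
  ts2 <- toy_store(body2, samples = "S1")
  out3 <- file.path(dirname(out), "ph3.vcf")
  export_variants(ts2$store, "p", filter_spec(), export_spec("VCF", out3))
  rec3 <- readLines(out3); rec3 <- rec3[!startsWith(rec3, "#")]
  ps <- vapply(rec3, function(l) strsplit(strsplit(l, "\t")[[1]][10], ":")[[1]][2], character(1))
  expect_identical(unname(ps), c("100", ".", "300"))
})

test_that("Eigenstrat export encodes reference-allele counts with 9 for missing", {
  body <- c(
    "chr1\t100\tv1\tA\tT\t.\t.\t.\tGT\t0/0\t0/1\t1/1",
    "chr1\t200\tv2\tG\tC\t.\t.\t.\tGT\t./.\t0/0\t0/1",
    "chr1\t300\tv3\tT\tA,G\t.\t.\t.\tGT\t0/1\t1/2\t0/0")
  ts <- toy_store(body, samples = c("I1", "I2", "I3"))
  base <- file.path(tempfile("exp"), "es")
  dir.create(dirname(base))
  expect_warning(
    paths <- export_variants(ts$store, "p", filter_spec(),
                             export_spec("EIGENSTRAT", base)),
    "non-bi-allelic")
  geno <- readLines(paste0(base, ".geno"))
  expect_identical(geno, c("210", "921"))     # v3 (tri-allelic) dropped
  expect_true(all(strsplit(paste(geno, collapse = ""), "")[[1]] %in% c("0", "1", "2", "9")))
  snp <- read.table(paste0(base, ".snp"), sep = "\t")
  expect_identical(nrow(snp), 2L)
  ind <- read.table(paste0(base, ".ind"), sep = "\t")
  expect_identical(as.character(ind$V1), c("I1", "I2", "I3"))
})

test_that("BED intervals are 0-based half-open and consistent with VCF positions", {
  body <- c("chr1\t100\tv1\tA\tT\t.\t.\t.\tGT\t0/1",
            "chr1\t200\tv2\tGAT\tG\t.\t.\t.\tGT\t0/1",
            "chr2\t300\tv3\tT\tA\t.\t.\t.\tGT\t1/1")
  ts <- toy_store(body, samples = "S1")
  out <- file.path(tempfile("exp"), "sel.bed")
  dir.create(dirname(out))
  export_variants(ts$store, "p", filter_spec(), export_spec("BED", out))
  bed <- read.table(out, sep = "\t")
  expect_identical(nrow(bed), 3L)
  expect_identical(bed$V2, c(99L, 199L, 299L))
  expect_identical(bed$V3, c(100L, 202L, 300L))  # deletion spans its REF length
})

test_that("all seven formats export the same variant selection at toy scale", {
  fs <- fixture_spec(n_variants = 30, n_individuals = 4, fraction_indels = 0,
                     fraction_multiallelic = 0, missing_rate = 0.1, seed = 41)
  ts <- fixture_store(fs)
  spec <- filter_spec(maf_range = c(0, 0.4))
  n <- count_variants(ts$store, "p", spec)
  dir <- tempfile("exp7"); dir.create(dir)
  counts <- c()
  for (f in c("VCF", "EIGENSTRAT", "GFF3", "BED", "HAPMAP", "DARWIN", "PLINK")) {
    paths <- export_variants(ts$store, "p", spec,
                             export_spec(f, file.path(dir, tolower(f))))
    main <- paths[1]
    k <- switch(f,
      VCF = sum(!startsWith(readLines(main), "#")),
      EIGENSTRAT = length(readLines(file.path(dir, "eigenstrat.geno"))),
      GFF3 = sum(!startsWith(readLines(main), "#")),
      BED = length(readLines(main)),
      HAPMAP = length(readLines(main)) - 1L,
      DARWIN = length(readLines(main)) - 3L,   # units as rows
      PLINK = length(readLines(file.path(dir, "plink.map"))))
    counts[f] <- if (f == "DARWIN") n else k
    if (f == "DARWIN") {
      expect_identical(k, 4L)                  # one row per individual
      hdr2 <- strsplit(readLines(main)[2], "\t")[[1]]
      expect_identical(as.integer(hdr2), c(4L, n))
    }
  }
  expect_true(all(counts == n))
})

test_that("exports with one seed are byte-identical; different seeds differ only at ties", {
  # a two-run project where each individual has two samples, engineered ties
  b <- c("chr1\t100\tv1\tA\tT\t.\t.\t.\tGT\t0/0\t0/1",
         "chr1\t200\tv2\tG\tC\t.\t.\t.\tGT\t0/1\t1/1")
  b2 <- c("chr1\t100\tv1\tA\tT\t.\t.\t.\tGT\t0/1\t0/1",
          "chr1\t200\tv2\tG\tC\t.\t.\t.\tGT\t0/1\t1/1")
  p1 <- write_toy_vcf(b, samples = c("I1", "I2"))
  p2 <- write_toy_vcf(b2, samples = c("I1", "I2"))
  st <- open_store(tempfile(), "db")
  import_vcf(st, p1, "p", "r1"); import_vcf(st, p2, "p", "r2")
  dir <- tempfile("seed"); dir.create(dir)
  f1 <- file.path(dir, "a.vcf"); f2 <- file.path(dir, "b.vcf"); f3 <- file.path(dir, "c.vcf")
  export_variants(st, "p", filter_spec(), export_spec("VCF", f1, random_seed = 5))
  export_variants(st, "p", filter_spec(), export_spec("VCF", f2, random_seed = 5))
  expect_identical(readLines(f1), readLines(f2))
  seen <- vapply(1:20, function(s) {
    export_variants(st, "p", filter_spec(), export_spec("VCF", f3, random_seed = s))
    paste(readLines(f3), collapse = "\n")
  }, character(1))
  expect_gt(length(unique(seen)), 1L)          # ties really are seed-sensitive
  # non-tied records are identical across seeds
  rec_sets <- lapply(unique(seen), function(x) {
    l <- strsplit(x, "\n")[[1]]
    l[!startsWith(l, "#")]
  })
  v2_rows <- unique(vapply(rec_sets, `[`, character(1), 2L))
  expect_length(v2_rows, 1L)                   # v2 has no tie: invariant
})

test_that("gzip-compressed exports decompress to the plain output", {
  body <- "chr1\t100\tv1\tA\tT\t.\t.\t.\tGT\t0/1"
  ts <- toy_store(body, samples = "S1")
  dir <- tempfile("gz"); dir.create(dir)
  plain <- file.path(dir, "x.bed"); gz <- file.path(dir, "y.bed")
  export_variants(ts$store, "p", filter_spec(), export_spec("BED", plain))
  paths <- export_variants(ts$store, "p", filter_spec(),
                           export_spec("BED", gz, compress = TRUE))
  expect_true(endsWith(paths[1], ".gz"))
  expect_identical(readLines(gzfile(paths[1])), readLines(plain))
})

test_that("density bins conserve the per-sequence selection counts", {
  fs <- fixture_spec(n_variants = 80, n_individuals = 6, fraction_indels = 0.2, seed = 8)
  ts <- fixture_store(fs)
  spec <- filter_spec(maf_range = c(0, 0.35))
  d <- variant_density(ts$store, "p", spec, bin_width = 50000L)
  for (sq in unique(d$sequence)) {
    want <- count_variants(ts$store, "p",
      filter_spec(maf_range = c(0, 0.35), sequences = sq), use_cache = FALSE)
    expect_identical(sum(d$count[d$sequence == sq]), want)
  }
  # empty selection: bins exist, all zero
  d0 <- variant_density(ts$store, "p",
    filter_spec(position_range = list(sequence = "chr1", start = 1, end = 2)))
  expect_gt(nrow(d0), 0L)
  expect_identical(sum(d0$count), 0L)
  # concentration: everything in one bin
  body <- c("chr1\t100\tv1\tA\tT\t.\t.\t.\tGT\t0/1",
            "chr1\t105\tv2\tG\tC\t.\t.\t.\tGT\t0/1")
  ts2 <- toy_store(body, samples = "S1")
  d2 <- variant_density(ts2$store, "p", filter_spec(), bin_width = 1000L)
  expect_identical(max(d2$count), 2L)
  expect_identical(sum(d2$count), 2L)
})

test_that("recompute_phasing reports separators and phase sets from stored groups", {
  calls <- list(genotype_call(c(0L, 1L), phased = TRUE, phase_group = "100"),
                genotype_call(c(1L, 0L), phased = TRUE, phase_group = "100"),
                genotype_call(c(0L, 1L)))
  ph <- recompute_phasing(calls)
  expect_identical(ph$separator, c("|", "|", "/"))
  expect_identical(ph$phase_set, c("100", "100", NA))
})
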