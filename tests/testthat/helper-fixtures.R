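# shared helpers: inline toy VCF construction and quick store setup

write_toy_vcf <- function(body_lines, samples = c("S1", "S2"),
                          extra_header = character(), dir = tempdir()) {
  path <- tempfile("toy", tmpdir = dir, fileext = ".vcf")
  header <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1>", "##contig=<ID=chr2>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    '##FORMAT=<ID=PS,Number=1,Type=Integer,Description="Phase set">',
    extra_header,
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  writeLines(c(header, body_lines), path)
  path
}

toy_store <- function(..., project = "p", run = "r", chunk_size = 1000L) {
  path <- write_toy_vcf(...)
  st <- open_store(tempfile("store"), "test")
  import_vcf(st, path, project, run, chunk_size = chunk_size)
  list(store = st, vcf = path)
}

fixture_store <- function(fspec, project = "p", run = "r", chunk_size = 1000L,
                          basename = "fx") {
  fx <- generate_fixture(fspec, tempfile("fxdir"), basename)
  st <- open_store(tempfile("store"), "test")
  import_vcf(st, fx$vcf, project, run, chunk_size = chunk_size)
  c(fx, list(store = st))
}

# calls helper: "0/1" style strings (with optional gq=, dp=) to gnv_call list
calls_from_strings <- function(gts, gq = NULL, dp = NULL) {
  lapply(seq_along(gts), function(i) {
    a <- strsplit(gts[i], "[/|]")[[1]]
    a[a == "."] <- NA
    genotype_call(suppressWarnings(as.integer(a)),
                  phased = grepl("|", gts[i], fixed = TRUE),
                  gq = if (!is.null(gq)) gq[i], dp = if (!is.null(dp)) dp[i])
  })
}
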