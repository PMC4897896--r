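# brute-force flat-scan oracle over a source VCF: parses the text directly
# (no store, no package filter code) and applies the full filter semantics
# naively, record by record.

`%||%` <- function(a, b) if (is.null(a)) b else a

oracle_parse_vcf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  chrom <- lines[startsWith(lines, "#CHROM")][1]
  samples <- strsplit(chrom, "\t", fixed = TRUE)[[1]][-(1:9)]
  body <- lines[!startsWith(lines, "#")]
  recs <- lapply(body, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    alleles <- c(f[4], if (!f[5] %in% c(".", "")) strsplit(f[5], ",", fixed = TRUE)[[1]])
    id <- if (!f[3] %in% c(".", "")) f[3] else
      paste(f[1], f[2], alleles[1], paste(alleles[-1], collapse = "-"), sep = ":")
    type <- if (any(grepl("^<.*>$", alleles))) "SV-like"
            else if (all(nchar(alleles) == 1L)) "SNP"
            else if (length(unique(nchar(alleles))) > 1L) "INDEL"
            else "other"
    fmt <- strsplit(f[9], ":", fixed = TRUE)[[1]]
    cells <- strsplit(f[-(1:9)], ":", fixed = TRUE)
    pick <- function(tag) {
      k <- match(tag, fmt)
      if (is.na(k)) return(rep(NA_integer_, length(samples)))
      suppressWarnings(as.integer(vapply(cells, function(x)
        if (length(x) >= k) x[k] else NA_character_, character(1))))
    }
    list(id = id, seq = f[1], pos = as.integer(f[2]),
         stop = if (type == "SV-like") as.integer(f[2]) else
           as.integer(f[2]) + nchar(f[4]) - 1L,
         alleles = alleles, type = type, info = f[8],
         gt = vapply(cells, `[`, character(1), 1L),
         gq = pick("GQ"), dp = pick("DP"))
  })
  list(samples = samples, recs = recs)
}

oracle_ann <- function(info) {
  m <- regmatches(info, regexec("(^|;)ANN=([^;]*)", info))[[1]]
  if (length(m) < 3L) return(list(effects = character(), genes = character()))
  effs <- character(); gens <- character()
  for (e in strsplit(m[3], ",", fixed = TRUE)[[1]]) {
    ff <- strsplit(e, "|", fixed = TRUE)[[1]]
    if (length(ff) >= 2L) effs <- c(effs, ff[2])
    if (length(ff) >= 4L) gens <- c(gens, ff[4])
  }
  list(effects = effs, genes = gens)
}

oracle_pattern <- function(alleles_list, pattern) {
  name <- if (is.character(pattern)) pattern else pattern$name
  thr <- if (is.character(pattern)) 0.8 else (pattern$threshold %||% 0.8)
  if (name == "any") return(TRUE)
  called <- alleles_list[vapply(alleles_list, function(a) any(!is.na(a)), logical(1))]
  n <- length(called)
  if (n == 0L) return(FALSE)
  called <- lapply(called, function(a) a[!is.na(a)])
  key <- vapply(called, function(a) paste(sort(a), collapse = "/"), character(1))
  hom <- vapply(called, function(a) length(unique(a)) == 1L, logical(1))
  homal <- vapply(called, function(a) if (length(unique(a)) == 1L) a[1] else NA_integer_,
                  integer(1))
  switch(name,
    all_same = length(unique(key)) == 1L,
    all_different = anyDuplicated(key) == 0L,
    not_all_same = length(unique(key)) > 1L,
    mostly_same = max(table(key)) / n >= thr,
    all_hom_ref = all(hom & homal == 0L),
    some_hom_ref = any(hom & homal == 0L),
    all_hom_var = all(hom & homal != 0L),
    some_hom_var = any(hom & homal != 0L),
    all_het = all(!hom),
    at_least_one_het = any(!hom),
    without_abnormal_het = {
      ok <- TRUE
      for (k in which(!hom)) {
        others <- homal[-k]; others <- others[!is.na(others)]
        if (all(unique(called[[k]]) %in% others)) { ok <- FALSE; break }
      }
      ok
    },
    stop("oracle: unknown pattern ", name))
}

oracle_matching_ids <- function(parsed, spec) {
  sel <- if (length(spec$individuals)) match(spec$individuals, parsed$samples)
         else seq_along(parsed$samples)
  eps <- 1e-12
  keep <- vapply(parsed$recs, function(r) {
    if (length(spec$variant_types) && !(r$type %in% spec$variant_types)) return(FALSE)
    if (length(spec$sequences) && !(r$seq %in% spec$sequences)) return(FALSE)
    pr <- spec$position_range
    if (!is.null(pr) && !(r$seq == pr$sequence && r$pos <= pr$end && r$stop >= pr$start))
      return(FALSE)
    if (!is.null(spec$allele_count) && length(r$alleles) != spec$allele_count)
      return(FALSE)
    if (length(spec$effects) || length(spec$genes)) {
      ann <- oracle_ann(r$info)
      if (length(spec$effects) && !any(ann$effects %in% spec$effects)) return(FALSE)
      if (length(spec$genes) && !any(ann$genes %in% spec$genes)) return(FALSE)
    }
    g <- r$gt[sel]; gq <- r$gq[sel]; dp <- r$dp[sel]
    al <- lapply(seq_along(g), function(j) {
      if (is.na(g[j]) || g[j] %in% c(".", "")) return(NA_integer_)
      t <- strsplit(g[j], "[/|]")[[1]]
      t[t == "."] <- NA
      suppressWarnings(as.integer(t))
    })
    for (j in seq_along(al)) {
      if ((!is.null(spec$min_gq) && !is.na(gq[j]) && gq[j] < spec$min_gq) ||
          (!is.null(spec$min_dp) && !is.na(dp[j]) && dp[j] < spec$min_dp))
        al[[j]] <- NA_integer_
    }
    called <- vapply(al, function(a) any(!is.na(a)), logical(1))
    if (mean(!called) > spec$max_missing_ratio + eps) return(FALSE)
    if (spec$maf_range[1] > 0 || spec$maf_range[2] < 0.5) {
      if (length(r$alleles) == 2L) {
        slots <- unlist(al); slots <- slots[!is.na(slots)]
        if (length(slots)) {
          c0 <- sum(slots == 0L)
          maf <- min(c0, length(slots) - c0) / length(slots)
          if (maf < spec$maf_range[1] - eps || maf > spec$maf_range[2] + eps)
            return(FALSE)
        }
      }
    }
    if (!is.null(spec$pattern) && spec$pattern$name != "any" &&
        !oracle_pattern(al, spec$pattern)) return(FALSE)
    TRUE
  }, logical(1))
  sort(vapply(parsed$recs[keep], `[[`, character(1), "id"), method = "radix")
}

# randomized filter specifications over a fixture's metadata
random_filter_spec <- function(individuals, sequences, annotated = FALSE,
                               sequence_length = 1e6) {
  maybe <- function(p) runif(1) < p
  pat <- NULL
  if (maybe(0.4)) {
    nm <- sample(c("any", "all_same", "not_all_same", "mostly_same",
                   "all_hom_ref", "some_hom_ref", "some_hom_var",
                   "at_least_one_het", "all_het", "all_different",
                   "all_hom_var", "without_abnormal_het"), 1L)
    pat <- genotype_pattern(nm, if (nm == "mostly_same") runif(1, 0.55, 1))
  }
  region <- NULL
  if (maybe(0.3)) {
    a <- sort(sample.int(sequence_length, 2L))
    region <- list(sequence = sample(sequences, 1L), start = a[1], end = a[2])
  }
  maf <- c(0, 0.5)
  if (maybe(0.4)) {
    maf <- round(sort(runif(2, 0, 0.5)), 3)
  }
  filter_spec(
    variant_types = if (maybe(0.25)) sample(c("SNP", "INDEL"), sample(1:2, 1L)) else character(),
    individuals = if (maybe(0.4) && length(individuals) > 1L)
      sample(individuals, sample.int(length(individuals), 1L)) else character(),
    sequences = if (maybe(0.25)) sample(sequences, sample.int(length(sequences), 1L)) else character(),
    pattern = pat,
    min_gq = if (maybe(0.35)) sample.int(60, 1L) else NULL,
    min_dp = if (maybe(0.35)) sample.int(25, 1L) else NULL,
    max_missing_ratio = if (maybe(0.4)) runif(1) else 1,
    maf_range = maf,
    allele_count = if (maybe(0.15)) sample(2:3, 1L) else NULL,
    position_range = region,
    effects = if (annotated && maybe(0.3)) sample(genonav:::ANN_EFFECTS, 2L) else character(),
    genes = if (annotated && maybe(0.3)) sprintf("GENE%03d", sample.int(20, 3L)) else character())
}
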