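#' Describe a synthetic genotyping fixture
#'
#' The generator emulates a desk-scale resequencing panel: a set of
#' variants spread over a few reference sequences, genotyped on a panel of
#' individuals, with a site-frequency spectrum drawn from a Beta
#' distribution, per-call missingness, normally distributed GQ/DP values,
#' phased stretches and optional SnpEff-style annotations.  The same
#' specification drives a VCF rendering, a HapMap rendering and a
#' machine-readable truth table, so every importer and filter can be tested
#' without external downloads.
#'
#' @param n_variants,n_individuals,n_sequences panel dimensions.
#' @param ploidy calls per genotype (1 = haploid, 2 = diploid, ...).
#' @param fraction_indels fraction of variants rendered as indels.
#' @param fraction_multiallelic fraction of variants given two ALT alleles.
#' @param missing_rate per-call probability of a missing genotype.
#' @param phased_fraction per-call probability of being phased (ploidy
#'   >= 2); contiguous phased calls of a sample form one phase group.
#' @param gq_distribution,dp_distribution `c(mean, sd)` of the per-call GQ
#'   and DP values (normal, rounded, clamped to \[0, 99\] / \[0, 500\]).
#' @param maf_spectrum `c(alpha, beta)` of the Beta distribution the
#'   alternate-allele frequency is drawn from.
#' @param annotation_style `"none"`, `"ANN"` or `"EFF"`.
#' @param sequence_length length of each reference sequence in bp.
#' @param seed RNG seed; identical seeds give byte-identical files.
#' @return an object of class `gnv_fixture_spec`.
#' @export
fixture_spec <- function(n_variants = 100L, n_individuals = 10L,
                         n_sequences = 2L, ploidy = 2L,
                         fraction_indels = 0.1, fraction_multiallelic = 0.05,
                         missing_rate = 0.05, phased_fraction = 0.3,
                         gq_distribution = c(40, 15), dp_distribution = c(20, 8),
                         maf_spectrum = c(1, 3), annotation_style = "none",
                         sequence_length = 1e6, seed = 1L) {
  stopifnot(n_variants >= 0, n_individuals >= 0, n_sequences >= 1, ploidy >= 1)
  for (fr in c(fraction_indels, fraction_multiallelic, missing_rate, phased_fraction))
    if (fr < 0 || fr > 1) stop("fractions and rates must lie in [0, 1]")
  annotation_style <- match.arg(annotation_style, c("none", "ANN", "EFF"))
  structure(list(n_variants = as.integer(n_variants),
                 n_individuals = as.integer(n_individuals),
                 n_sequences = as.integer(n_sequences), ploidy = as.integer(ploidy),
                 fraction_indels = fraction_indels,
                 fraction_multiallelic = fraction_multiallelic,
                 missing_rate = missing_rate, phased_fraction = phased_fraction,
                 gq_distribution = gq_distribution, dp_distribution = dp_distribution,
                 maf_spectrum = maf_spectrum, annotation_style = annotation_style,
                 sequence_length = sequence_length, seed = as.integer(seed)),
            class = "gnv_fixture_spec")
}

ANN_EFFECTS <- c("missense_variant", "synonymous_variant", "stop_gained",
                 "intron_variant", "upstream_gene_variant", "frameshift_variant")

# the underlying random panel; all randomness happens here, under the seed
fixture_matrix <- function(fspec) {
  with_seed(fspec$seed, {
    nv <- fspec$n_variants; ni <- fspec$n_individuals; pl <- fspec$ploidy
    per_seq <- diff(round(seq(0, nv, length.out = fspec$n_sequences + 1L)))
    seqs <- rep(paste0("chr", seq_len(fspec$n_sequences)), per_seq)
    pos <- unlist(lapply(per_seq, function(k)
      sort(sample.int(fspec$sequence_length, k))), use.names = FALSE)
    is_multi <- runif(nv) < fspec$fraction_multiallelic
    is_indel <- !is_multi & runif(nv) < fspec$fraction_indels
    bases <- c("A", "C", "G", "T")
    alleles <- lapply(seq_len(nv), function(i) {
      if (is_indel[i]) {
        if (runif(1) < 0.5) c("A", paste0("A", sample(bases, 1L))) else
          c(paste0("A", sample(bases, 1L)), "A")
      } else sample(bases, if (is_multi[i]) 3L else 2L)
    })
    # alternate-allele frequency spectrum
    p_alt <- rbeta(nv, fspec$maf_spectrum[1], fspec$maf_spectrum[2])
    geno <- array(NA_integer_, c(nv, ni, pl))
    for (i in seq_len(nv)) {
      na <- length(alleles[[i]])
      pr <- if (na == 2L) c(1 - p_alt[i], p_alt[i]) else
        c(1 - p_alt[i], p_alt[i] * 0.7, p_alt[i] * 0.3)
      geno[i, , ] <- sample.int(na, ni * pl, replace = TRUE, prob = pr) - 1L
    }
    missing <- matrix(runif(nv * ni) < fspec$missing_rate, nv, ni)
    for (k in seq_len(pl)) geno[, , k][missing] <- NA_integer_
    gq <- matrix(pmin(99L, pmax(0L, as.integer(round(
      rnorm(nv * ni, fspec$gq_distribution[1], fspec$gq_distribution[2]))))), nv, ni)
    dp <- matrix(pmin(500L, pmax(0L, as.integer(round(
      rnorm(nv * ni, fspec$dp_distribution[1], fspec$dp_distribution[2]))))), nv, ni)
    gq[missing] <- NA_integer_; dp[missing] <- NA_integer_
    phased <- if (pl >= 2L)
      matrix(runif(nv * ni) < fspec$phased_fraction, nv, ni) & !missing
    else matrix(FALSE, nv, ni)
    # phase groups: per sample, contiguous phased stretches on a sequence,
    # identified by the position of the stretch's first variant
    ps <- matrix(NA_integer_, nv, ni)
    if (any(phased)) {
      for (j in seq_len(ni)) {
        grp <- NA_integer_; prev <- FALSE; prev_seq <- ""
        for (i in seq_len(nv)) {
          if (phased[i, j]) {
            if (!prev || seqs[i] != prev_seq) grp <- pos[i]
            ps[i, j] <- grp
            prev <- TRUE
          } else prev <- FALSE
          prev_seq <- seqs[i]
        }
      }
    }
    explicit_id <- seq_len(nv) %% 2L == 1L
    ids <- ifelse(explicit_id, sprintf("var%05d", seq_len(nv)),
                  mapply(make_variant_id, seqs, pos, alleles))
    ann <- NULL
    if (fspec$annotation_style != "none")
      ann <- data.frame(effect = sample(ANN_EFFECTS, nv, replace = TRUE),
                        gene = sprintf("GENE%03d", sample.int(20L, nv, replace = TRUE)),
                        stringsAsFactors = FALSE)
    list(seqs = seqs, pos = pos, ids = ids, explicit_id = explicit_id,
         alleles = alleles, geno = geno, missing = missing, gq = gq, dp = dp,
         phased = phased, ps = ps, ann = ann)
  })
}

# ground truth computed directly from the raw allele array (independently
# of the importer and the filter layer)
fixture_truth <- function(fspec, fx) {
  nv <- fspec$n_variants; ni <- fspec$n_individuals
  ref_ind <- seq_len(min(3L, ni))
  truth <- data.frame(
    variant_id = fx$ids, sequence = fx$seqs, start = fx$pos,
    variant_type = vapply(fx$alleles, variant_type_of, character(1)),
    n_alleles = lengths(fx$alleles),
    true_maf = NA_real_, n_missing = rowSums(fx$missing),
    stringsAsFactors = FALSE)
  for (i in seq_len(nv)) {
    if (length(fx$alleles[[i]]) != 2L) next
    slots <- as.vector(fx$geno[i, , ])
    slots <- slots[!is.na(slots)]
    if (!length(slots)) next
    c0 <- sum(slots == 0L)
    truth$true_maf[i] <- min(c0, length(slots) - c0) / length(slots)
  }
  for (p in PATTERN_NAMES) truth[[paste0("pat_", p)]] <- NA
  for (i in seq_len(nv)) {
    gl <- lapply(ref_ind, function(j) {
      s <- fx$geno[i, j, ]
      s[!is.na(s)]
    })
    gl <- gl[lengths(gl) > 0L]
    n <- length(gl)
    key <- vapply(gl, function(s) paste(sort(s), collapse = "/"), character(1))
    hom <- vapply(gl, function(s) length(unique(s)) == 1L, logical(1))
    homal <- vapply(gl, function(s) if (length(unique(s)) == 1L) s[1] else NA_integer_, integer(1))
    truth[i, "pat_any"] <- TRUE
    if (n == 0L) {
      truth[i, paste0("pat_", setdiff(PATTERN_NAMES, "any"))] <- FALSE
      next
    }
    truth[i, "pat_all_same"] <- length(unique(key)) == 1L
    truth[i, "pat_all_different"] <- anyDuplicated(key) == 0L
    truth[i, "pat_not_all_same"] <- length(unique(key)) > 1L
    truth[i, "pat_mostly_same"] <- max(table(key)) / n >= 0.8
    truth[i, "pat_all_hom_ref"] <- all(hom & homal == 0L)
    truth[i, "pat_some_hom_ref"] <- any(hom & homal == 0L)
    truth[i, "pat_all_hom_var"] <- all(hom & homal != 0L)
    truth[i, "pat_some_hom_var"] <- any(hom & homal != 0L)
    truth[i, "pat_all_het"] <- all(!hom)
    truth[i, "pat_at_least_one_het"] <- any(!hom)
    ok <- TRUE
    for (k in which(!hom)) {
      others <- homal[-k]; others <- others[!is.na(others)]
      if (all(unique(gl[[k]]) %in% others)) { ok <- FALSE; break }
    }
    truth[i, "pat_without_abnormal_het"] <- ok
  }
  truth
}

fixture_gt_string <- function(slots, phased) {
  if (all(is.na(slots)))
    return(paste(rep(".", length(slots)), collapse = "/"))
  paste(slots, collapse = if (phased) "|" else "/")
}

#' Generate a synthetic VCF fixture with its truth table
#'
#' Writes a well-formed VCF plus a tab-separated truth table holding the
#' per-variant ground truth (true MAF over all individuals, missing-call
#' counts, and the twelve genotype-pattern memberships for the reference
#' individual set — the first three individuals), computed directly from
#' the simulated allele arrays so it can serve as an oracle that is
#' independent of the import and filter code paths.  Identical seeds give
#' byte-identical output.
#'
#' @param fspec a [fixture_spec()].
#' @param dir output directory (created if needed).
#' @param basename file basename (default `"fixture"`).
#' @return list with `vcf` and `truth` file paths and the in-memory
#'   `truth_table` data.frame.
#' @export
generate_fixture <- function(fspec, dir, basename = "fixture") {
  stopifnot(inherits(fspec, "gnv_fixture_spec"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fx <- fixture_matrix(fspec)
  truth <- fixture_truth(fspec, fx)
  nv <- fspec$n_variants; ni <- fspec$n_individuals
  style <- fspec$annotation_style
  header <- c(
    "##fileformat=VCFv4.2",
    paste0("##contig=<ID=chr", seq_len(fspec$n_sequences),
           ",length=", format(fspec$sequence_length, scientific = FALSE), ">"),
    if (style == "ANN") '##INFO=<ID=ANN,Number=.,Type=String,Description="Functional annotations: Allele|Annotation|Impact|Gene_Name">',
    if (style == "EFF") '##INFO=<ID=EFF,Number=.,Type=String,Description="Predicted effects: Effect(Impact|Class|Codon|AA|Len|Gene)">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    if (any(fx$phased)) '##FORMAT=<ID=PS,Number=1,Type=Integer,Description="Phase set">')
  has_ps <- any(fx$phased)
  fmt <- if (has_ps) "GT:GQ:DP:PS" else "GT:GQ:DP"
  samples <- sprintf("IND%04d", seq_len(ni))
  lines <- character(nv)
  for (i in seq_len(nv)) {
    cells <- vapply(seq_len(ni), function(j) {
      g <- fixture_gt_string(fx$geno[i, j, ], fx$phased[i, j])
      cell <- paste(g,
                    if (is.na(fx$gq[i, j])) "." else fx$gq[i, j],
                    if (is.na(fx$dp[i, j])) "." else fx$dp[i, j], sep = ":")
      if (has_ps)
        cell <- paste(cell, if (is.na(fx$ps[i, j])) "." else fx$ps[i, j], sep = ":")
      cell
    }, character(1))
    info <- "."
    if (style == "ANN")
      info <- paste0("ANN=", fx$alleles[[i]][2], "|", fx$ann$effect[i],
                     "|MODERATE|", fx$ann$gene[i])
    if (style == "EFF")
      info <- paste0("EFF=", fx$ann$effect[i], "(MODERATE|NONE|aaa/aAa|p.X1Y|100|",
                     fx$ann$gene[i], ")")
    lines[i] <- paste(c(fx$seqs[i], fx$pos[i],
                        if (fx$explicit_id[i]) fx$ids[i] else ".",
                        fx$alleles[[i]][1],
                        paste(fx$alleles[[i]][-1], collapse = ","),
                        ".", ".", info, fmt, cells), collapse = "\t")
  }
  chrom <- paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t")
  vcf_path <- file.path(dir, paste0(basename, ".vcf"))
  write_lines_to(c(header, chrom, lines), vcf_path)
  truth_path <- file.path(dir, paste0(basename, ".truth.tsv"))
  write.table(truth, truth_path, sep = "\t", quote = FALSE, row.names = FALSE)
  list(vcf = vcf_path, truth = truth_path, truth_table = truth)
}

#' Generate the HapMap rendering of a fixture
#'
#' Renders the same underlying simulated panel (same seed, same genotype
#' matrix) in the tab-delimited HapMap dialect: 11 metadata columns and
#' two-letter diploid codes, `NN` for missing.  Requires a diploid,
#' bi-allelic, SNP-only specification.
#'
#' @inheritParams generate_fixture
#' @return path of the written HapMap file.
#' @export
generate_hapmap_fixture <- function(fspec, dir, basename = "fixture") {
  stopifnot(inherits(fspec, "gnv_fixture_spec"))
  if (fspec$ploidy != 2L || fspec$fraction_indels > 0 || fspec$fraction_multiallelic > 0)
    stop("the HapMap rendering needs a diploid, bi-allelic, SNP-only fixture spec")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fx <- fixture_matrix(fspec)
  ni <- fspec$n_individuals
  samples <- sprintf("IND%04d", seq_len(ni))
  hdr <- paste(c("rs#", "alleles", "chrom", "pos", "strand", "assembly#",
                 "center", "protLSID", "assayLSID", "panelLSID", "QCcode",
                 samples), collapse = "\t")
  lines <- vapply(seq_len(fspec$n_variants), function(i) {
    al <- fx$alleles[[i]]
    cells <- vapply(seq_len(ni), function(j) {
      s <- fx$geno[i, j, ]
      if (all(is.na(s))) "NN" else paste0(al[s[1] + 1L], al[s[2] + 1L])
    }, character(1))
    paste(c(fx$ids[i], paste(al, collapse = "/"), fx$seqs[i], fx$pos[i], "+",
            rep("NA", 6), cells), collapse = "\t")
  }, character(1))
  path <- file.path(dir, paste0(basename, ".hapmap.txt"))
  write_lines_to(c(hdr, lines), path)
  path
}
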