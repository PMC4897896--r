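PATTERN_NAMES <- c("any", "all_same", "all_different", "not_all_same",
                   "mostly_same", "all_hom_ref", "some_hom_ref",
                   "all_hom_var", "some_hom_var", "all_het",
                   "at_least_one_het", "without_abnormal_het")

#' Describe a genotype pattern
#'
#' Twelve predefined patterns describe the zygosity structure of the
#' genotypes of the selected individuals at one variant.  Genotypes are
#' compared as unordered allele multisets (`0/1` equals `1/0`, phase is
#' ignored); missing calls are excluded from evaluation, and a variant with
#' zero non-missing calls matches no pattern except `any`.
#'
#' * `any` — always true.
#' * `all_same` — all calls identical.
#' * `all_different` — calls pairwise distinct.
#' * `not_all_same` — at least two distinct calls.
#' * `mostly_same` — the modal call's frequency is at least `threshold`
#'   (default 0.8).
#' * `all_hom_ref` / `some_hom_ref` — every / at least one call homozygous
#'   reference.
#' * `all_hom_var` / `some_hom_var` — every / at least one call homozygous
#'   for a non-reference allele.
#' * `all_het` / `at_least_one_het` — every / at least one call
#'   heterozygous.
#' * `without_abnormal_het` — no heterozygous call whose alleles each also
#'   appear in a homozygous call of another selected individual (a flag for
#'   putative collapsed paralogs).
#'
#' @param name one of the twelve pattern names.
#' @param threshold modal-call frequency for `mostly_same`, in (0.5, 1].
#' @return an object of class `gnv_pattern`.
#' @export
genotype_pattern <- function(name, threshold = NULL) {
  name <- match.arg(name, PATTERN_NAMES)
  if (!is.null(threshold)) {
    if (name != "mostly_same") stop("threshold applies to mostly_same only")
    if (threshold <= 0.5 || threshold > 1) stop("threshold must lie in (0.5, 1]")
  }
  structure(list(name = name, threshold = threshold), class = "gnv_pattern")
}

#' Build a filter specification
#'
#' Bundles every search criterion of the filtering interface.  Defaults are
#' chosen so that an all-default specification passes every variant: all
#' variant types and sequences, all individuals, no pattern, no GQ/DP
#' threshold, authorized missing-data ratio 100%, MAF range 0–50% and no
#' positional, allele-count or annotation constraint.
#'
#' @param variant_types character set (empty = all).
#' @param individuals ordered subset of project individuals (empty = all).
#' @param sequences character set of reference sequence names (empty = all).
#' @param pattern a [genotype_pattern()], its name, or `NULL`.
#' @param min_gq,min_dp per-sample genotype-quality / read-depth thresholds
#'   below which a call is treated as missing, or `NULL`.
#' @param max_missing_ratio maximum fraction of selected individuals with a
#'   missing (consolidated, masked) call, in \[0, 1\]; default 1.
#' @param maf_range inclusive minor-allele-frequency range as fractions,
#'   default `c(0, 0.5)`; applicable to bi-allelic variants only.
#' @param allele_count required number of known alleles, or `NULL`.
#' @param position_range `list(sequence =, start =, end =)` in 1-based bp
#'   (inclusive), or `NULL`; variants whose \[start, stop\] interval overlaps
#'   the range match.
#' @param effects,genes character sets of SnpEff effect terms / gene names
#'   (empty = no constraint); a variant matches when its annotations
#'   intersect the set.
#' @return an object of class `gnv_filter`.
#' @export
filter_spec <- function(variant_types = character(), individuals = character(),
                        sequences = character(), pattern = NULL,
                        min_gq = NULL, min_dp = NULL,
                        max_missing_ratio = 1, maf_range = c(0, 0.5),
                        allele_count = NULL, position_range = NULL,
                        effects = character(), genes = character()) {
  if (is.character(pattern)) pattern <- genotype_pattern(pattern)
  if (!is.null(pattern) && !inherits(pattern, "gnv_pattern"))
    stop("pattern must be a genotype_pattern() or a pattern name")
  if (max_missing_ratio < 0 || max_missing_ratio > 1)
    stop("max_missing_ratio must lie in [0, 1]")
  if (length(maf_range) != 2L || maf_range[1] < 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2])
    stop("maf_range must satisfy 0 <= lo <= hi <= 0.5")
  if (!is.null(position_range)) {
    if (!all(c("sequence", "start", "end") %in% names(position_range)))
      stop("position_range needs sequence, start and end")
    if (position_range$start > position_range$end)
      stop("position_range start must not exceed end")
  }
  if (!is.null(allele_count) && allele_count < 1) stop("allele_count must be >= 1")
  structure(list(
    variant_types = as.character(variant_types),
    individuals = as.character(individuals),
    sequences = as.character(sequences),
    pattern = pattern, min_gq = min_gq, min_dp = min_dp,
    max_missing_ratio = max_missing_ratio, maf_range = as.numeric(maf_range),
    allele_count = allele_count, position_range = position_range,
    effects = as.character(effects), genes = as.character(genes)),
    class = "gnv_filter")
}

#' @export
#' @method print gnv_filter
print.gnv_filter <- function(x, ...) {
  active <- character()
  if (length(x$variant_types)) active <- c(active, paste0("types=", paste(x$variant_types, collapse = ",")))
  if (length(x$individuals)) active <- c(active, paste0(length(x$individuals), " individuals"))
  if (length(x$sequences)) active <- c(active, paste0("seqs=", paste(x$sequences, collapse = ",")))
  if (!is.null(x$pattern)) active <- c(active, paste0("pattern=", x$pattern$name))
  if (!is.null(x$min_gq)) active <- c(active, paste0("minGQ=", x$min_gq))
  if (!is.null(x$min_dp)) active <- c(active, paste0("minDP=", x$min_dp))
  if (x$max_missing_ratio < 1) active <- c(active, paste0("maxMissing=", x$max_missing_ratio))
  if (!identical(x$maf_range, c(0, 0.5))) active <- c(active, paste0("maf=[", x$maf_range[1], ",", x$maf_range[2], "]"))
  if (!is.null(x$allele_count)) active <- c(active, paste0("alleles=", x$allele_count))
  if (!is.null(x$position_range)) active <- c(active, paste0("region=", x$position_range$sequence, ":", x$position_range$start, "-", x$position_range$end))
  if (length(x$effects)) active <- c(active, paste0("effects=", paste(x$effects, collapse = ",")))
  if (length(x$genes)) active <- c(active, paste0("genes=", paste(x$genes, collapse = ",")))
  cat("<filter", if (length(active)) paste0(" ", paste(active, collapse = " ")) else " (pass-all defaults)", ">\n", sep = "")
  invisible(x)
}

#' Canonical cache key of a filter specification
#'
#' Serializes a filter into a canonical string that is independent of the
#' order of its set-valued criteria, for use as a count-cache key.
#'
#' @param spec a [filter_spec()].
#' @return a single string.
#' @export
canonical_filter_key <- function(spec) {
  fmt_set <- function(x) paste(scan_sort(unique(x)), collapse = ",")
  paste(
    paste0("types=", fmt_set(spec$variant_types)),
    paste0("ind=", fmt_set(spec$individuals)),
    paste0("seqs=", fmt_set(spec$sequences)),
    paste0("pat=", if (is.null(spec$pattern)) "" else
      paste0(spec$pattern$name, ":", spec$pattern$threshold %||% "")),
    paste0("gq=", spec$min_gq %||% ""), paste0("dp=", spec$min_dp %||% ""),
    paste0("miss=", format(spec$max_missing_ratio, digits = 15)),
    paste0("maf=", paste(format(spec$maf_range, digits = 15), collapse = ":")),
    paste0("nal=", spec$allele_count %||% ""),
    paste0("pos=", if (is.null(spec$position_range)) "" else
      paste(spec$position_range$sequence, spec$position_range$start,
            spec$position_range$end, sep = ":")),
    paste0("eff=", fmt_set(spec$effects)),
    paste0("gene=", fmt_set(spec$genes)),
    sep = ";")
}

# does the spec constrain genotype-level data at all?
has_genotype_criteria <- function(spec) {
  (!is.null(spec$pattern) && spec$pattern$name != "any") ||
    !is.null(spec$min_gq) || !is.null(spec$min_dp) ||
    spec$max_missing_ratio < 1 ||
    spec$maf_range[1] > 0 || spec$maf_range[2] < 0.5
}

#' Missing-data ratio over selected individuals
#'
#' Fraction of individuals whose (consolidated, masked) call is missing.
#'
#' @param calls list of [genotype_call()] objects, one per selected
#'   individual (at least one).
#' @return fraction in \[0, 1\].
#' @export
missing_ratio <- function(calls) {
  if (!length(calls)) stop("missing_ratio needs at least one selected individual")
  mean(vapply(calls, is_missing_call, logical(1)))
}

#' Minor allele frequency over selected individuals
#'
#' Each allele is counted over all non-missing allele slots of the calls (a
#' diploid heterozygote contributes one to each allele); the MAF is the
#' smaller count divided by the total.  It is only defined for bi-allelic
#' variants with at least one called slot; otherwise `NA` is returned.
#'
#' @param calls list of [genotype_call()] objects, one per selected
#'   individual.
#' @param n_alleles the variant's number of known alleles.
#' @return fraction in \[0, 0.5\], or `NA` when undefined.
#' @export
minor_allele_frequency <- function(calls, n_alleles = 2L) {
  if (n_alleles != 2L) return(NA_real_)
  slots <- unlist(lapply(calls, `[[`, "alleles"))
  slots <- slots[!is.na(slots)]
  if (!length(slots)) return(NA_real_)
  c0 <- sum(slots == 0L)
  min(c0, length(slots) - c0) / length(slots)
}

# pattern evaluation on a vector of canonical genotypes (NA = missing)
pattern_match_canon <- function(canon, pattern) {
  if (is.character(pattern)) pattern <- list(name = pattern, threshold = NULL)
  name <- pattern$name
  if (!name %in% PATTERN_NAMES) stop("unknown genotype pattern: ", name)
  if (name == "any") return(TRUE)
  nm <- canon[!is.na(canon)]
  n <- length(nm)
  if (n == 0L) return(FALSE)
  st <- canon_stats(nm)
  het <- !st$is_hom
  switch(name,
    all_same = length(unique(nm)) == 1L,
    all_different = anyDuplicated(nm) == 0L,
    not_all_same = length(unique(nm)) > 1L,
    mostly_same = max(table(nm)) / n >= (pattern$threshold %||% 0.8),
    all_hom_ref = all(st$is_hom & st$hom_allele == 0L),
    some_hom_ref = any(st$is_hom & st$hom_allele == 0L),
    all_hom_var = all(st$is_hom & st$hom_allele != 0L),
    some_hom_var = any(st$is_hom & st$hom_allele != 0L),
    all_het = all(het),
    at_least_one_het = any(het),
    without_abnormal_het = {
      ok <- TRUE
      for (i in which(het)) {
        others_hom <- st$hom_allele[-i]
        others_hom <- others_hom[!is.na(others_hom)]
        al <- unique(as.integer(strsplit(nm[i], "/", fixed = TRUE)[[1]]))
        if (length(al) && all(al %in% others_hom)) { ok <- FALSE; break }
      }
      ok
    })
}

#' Evaluate a genotype pattern over selected individuals
#'
#' @param calls list of [genotype_call()] objects, one per selected
#'   individual (missing calls are excluded from evaluation).
#' @param pattern a [genotype_pattern()] or pattern name.
#' @return logical.
#' @export
matches_pattern <- function(calls, pattern) {
  pattern_match_canon(vapply(calls, call_canon, character(1)), pattern)
}

#' Evaluate the variant-feature criteria of a filter
#'
#' Conjunction of: variant type, sequence membership, positional overlap of
#' the variant's \[start, stop\] with the filter's range (1-based, inclusive
#' on both ends), number of known alleles, and non-empty intersection of
#' the variant's effect / gene annotations with the filter's sets.
#'
#' @param variant a list or one-row record with `variant_type`, `sequence`,
#'   `start`, `stop`, `known_alleles`.
#' @param run_annotations `list(effects =, genes =)` for the variant, or
#'   `NULL` when the run carries no functional annotations.
#' @param spec a [filter_spec()].
#' @return logical.
#' @export
matches_variant_features <- function(variant, run_annotations, spec) {
  if (length(spec$variant_types) && !(variant$variant_type %in% spec$variant_types))
    return(FALSE)
  if (length(spec$sequences) && !(variant$sequence %in% spec$sequences))
    return(FALSE)
  pr <- spec$position_range
  if (!is.null(pr) &&
      !(variant$sequence == pr$sequence && variant$start <= pr$end &&
        variant$stop >= pr$start))
    return(FALSE)
  ka <- variant$known_alleles
  if (is.list(ka)) ka <- ka[[1]]
  if (!is.null(spec$allele_count) && length(ka) != spec$allele_count)
    return(FALSE)
  if (length(spec$effects) || length(spec$genes)) {
    if (is.null(run_annotations))
      stop("effect/gene filtering requested but the run carries no functional annotations")
    if (length(spec$effects) &&
        !length(intersect(run_annotations$effects, spec$effects))) return(FALSE)
    if (length(spec$genes) &&
        !length(intersect(run_annotations$genes, spec$genes))) return(FALSE)
  }
  TRUE
}
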