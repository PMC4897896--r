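#' Construct a genotype call
#'
#' A genotype call holds the allele indices of one sample at one variant,
#' indexed into the variant's known alleles (0 = reference).  Missing allele
#' slots are `NA`; a call whose slots are all `NA` is a missing call.  Phased
#' calls may carry a phase-group identifier: two calls of the same individual
#' with equal `phase_group` lie on the same estimated haplotypes.
#'
#' @param alleles integer vector of allele indices (`NA` = missing slot);
#'   its length is the call's ploidy.
#' @param phased logical; whether the call is phased.
#' @param phase_group optional opaque group identifier (implies `phased`).
#' @param gq,dp optional non-negative integers (genotype quality, read depth).
#' @param masked logical; set by [mask_call()] when a call was turned missing
#'   by a GQ/DP threshold (as opposed to being missing in the input).
#' @return an object of class `gnv_call`.
#' @export
genotype_call <- function(alleles, phased = FALSE, phase_group = NULL,
                          gq = NULL, dp = NULL, masked = FALSE) {
  alleles <- as.integer(alleles)
  if (!length(alleles)) stop("a genotype call needs at least one allele slot (its ploidy)")
  if (!is.null(phase_group) && !phased) stop("phase_group implies phased = TRUE")
  if (!is.null(gq) && (is.na(gq) || gq < 0)) stop("gq must be a non-negative integer")
  if (!is.null(dp) && (is.na(dp) || dp < 0)) stop("dp must be a non-negative integer")
  structure(list(alleles = alleles, ploidy = length(alleles), phased = isTRUE(phased),
                 phase_group = phase_group, gq = gq, dp = dp, masked = isTRUE(masked)),
            class = "gnv_call")
}

#' Missing-call predicate
#'
#' A call is missing when none of its allele slots is called.
#' @param call a [genotype_call()].
#' @return logical.
#' @export
is_missing_call <- function(call) all(is.na(call$alleles))

#' @export
#' @method print gnv_call
print.gnv_call <- function(x, ...) {
  al <- ifelse(is.na(x$alleles), ".", x$alleles)
  sep <- if (x$phased) "|" else "/"
  cat("<genotype ", paste(al, collapse = sep),
      if (!is.null(x$gq)) paste0(" GQ=", x$gq),
      if (!is.null(x$dp)) paste0(" DP=", x$dp),
      if (!is.null(x$phase_group)) paste0(" PS=", x$phase_group),
      if (x$masked) " [masked]", ">\n", sep = "")
  invisible(x)
}

# parse a GT-style string ("0/1", "0|1", ".", "./1", "0/1/1") into an
# integer allele vector with NA for missing slots; NULL for empty input
parse_gt_string <- function(s) {
  if (is.na(s) || s == "" || s == ".") return(NA_integer_)
  toks <- strsplit(s, "[/|]")[[1]]
  toks[toks == "."] <- NA_character_
  suppressWarnings(as.integer(toks))
}

# canonical unordered genotype: sorted non-missing allele indices joined by
# "/"; NA for a fully missing call.  Patterns and MAF work on this form.
gt_canon <- function(g) {
  u <- unique(g)
  canon_u <- vapply(u, function(s) {
    if (is.na(s) || s == "" || s == ".") return(NA_character_)
    ai <- parse_gt_string(s)
    ai <- ai[!is.na(ai)]
    if (!length(ai)) return(NA_character_)
    paste(sort(ai), collapse = "/")
  }, character(1), USE.NAMES = FALSE)
  canon_u[match(g, u)]
}

call_canon <- function(call) {
  ai <- call$alleles[!is.na(call$alleles)]
  if (!length(ai)) NA_character_ else paste(sort(ai), collapse = "/")
}

# per-call statistics derived from canonical genotypes, computed once per
# distinct value: count of reference-allele slots, called slots, homozygosity
# (all called slots equal) and, if homozygous, the shared allele index
canon_stats <- function(canon) {
  u <- unique(canon)
  m <- vapply(u, function(s) {
    if (is.na(s)) return(c(NA_integer_, 0L, NA_integer_, NA_integer_))
    ai <- as.integer(strsplit(s, "/", fixed = TRUE)[[1]])
    hom <- length(unique(ai)) == 1L
    c(sum(ai == 0L), length(ai), as.integer(hom), if (hom) ai[1L] else NA_integer_)
  }, integer(4), USE.NAMES = FALSE)
  m <- m[, match(canon, u), drop = FALSE]
  list(cnt_ref = m[1L, ], nslots = m[2L, ], is_hom = m[3L, ] == 1L, hom_allele = m[4L, ])
}

#' Apply GQ/DP masking to a genotype call
#'
#' Calls whose genotype quality or read depth fall below the requested
#' per-sample thresholds are treated as missing data.  A call passes a
#' threshold when the corresponding field is absent (a call cannot fail on
#' unavailable evidence) or at least the threshold.  Threshold-masked calls
#' carry `masked = TRUE`, distinguishing them from originally missing calls
#' so that detail views can highlight them.
#'
#' @param call a [genotype_call()].
#' @param min_gq,min_dp minimum genotype quality / read depth, or `NULL` for
#'   no threshold.
#' @return the call, unchanged or replaced by a masked missing call.
#' @export
mask_call <- function(call, min_gq = NULL, min_dp = NULL) {
  fails <- (!is.null(min_gq) && !is.null(call$gq) && call$gq < min_gq) ||
           (!is.null(min_dp) && !is.null(call$dp) && call$dp < min_dp)
  if (!fails || is_missing_call(call)) return(call)
  genotype_call(rep(NA_integer_, call$ploidy), masked = TRUE)
}

#' Consolidate one individual's calls into a single genotype
#'
#' An individual genotyped in several runs has one sample (and hence one
#' call) per run.  Filtering and export are individual-based: the calls are
#' reduced to the most frequent genotype (compared as unordered allele
#' multisets); when several genotypes are tied for most frequent, one is
#' picked uniformly at random under the supplied seed, so repeated runs with
#' the same seed reproduce the same choice.  Missing calls are ignored
#' unless every call is missing, in which case the result is missing.
#'
#' @param calls list of [genotype_call()] objects (at least one).
#' @param seed integer seed for the tie-break.
#' @return the consolidated [genotype_call()].
#' @export
consolidate_individual <- function(calls, seed = 0L) {
  if (!length(calls)) stop("consolidate_individual needs at least one call")
  canon <- vapply(calls, call_canon, character(1))
  keep <- which(!is.na(canon))
  if (!length(keep)) return(calls[[1L]])
  tab <- table(canon[keep])
  best <- names(tab)[tab == max(tab)]
  chosen <- if (length(best) == 1L) best else seeded_pick(scan_sort(best), seed)
  calls[[keep[match(chosen, canon[keep])]]]
}

# vector version used by the engine: canonical genotype strings in, the
# winning canonical genotype (or NA) out
consolidate_canon <- function(canon, seed = 0L) {
  keep <- canon[!is.na(canon)]
  if (!length(keep)) return(NA_character_)
  tab <- table(keep)
  best <- names(tab)[tab == max(tab)]
  if (length(best) == 1L) best else seeded_pick(scan_sort(best), seed)
}
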