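EXPORT_FORMATS <- c("VCF", "EIGENSTRAT", "GFF3", "BED", "HAPMAP", "DARWIN", "PLINK")

#' Describe an export
#'
#' @param format one of `"VCF"`, `"EIGENSTRAT"`, `"GFF3"`, `"BED"`,
#'   `"HAPMAP"`, `"DARWIN"`, `"PLINK"` (case-insensitive).
#' @param destination output path; multi-file formats (PLINK, Eigenstrat)
#'   use it as a prefix and add their extensions.
#' @param random_seed seed for consolidation tie-breaks; identical seeds
#'   give byte-identical exports.
#' @param compress gzip the output file(s).
#' @return an object of class `gnv_export_spec`.
#' @export
export_spec <- function(format, destination, random_seed = 1L, compress = FALSE) {
  format <- toupper(format)
  if (!format %in% EXPORT_FORMATS)
    stop("unknown export format: ", format, " (supported: ",
         paste(EXPORT_FORMATS, collapse = ", "), ")")
  structure(list(format = format, destination = destination,
                 random_seed = as.integer(random_seed),
                 compress = isTRUE(compress)),
            class = "gnv_export_spec")
}

# consolidated full-call matrix for export: for each (variant, individual)
# pick the winning sample call (majority of masked canonical genotypes,
# seeded tie-break) and return its verbatim genotype plus metadata
consolidated_calls <- function(store, project_id, ids, individuals, spec, seed) {
  proj <- get_project(store, project_id)
  nv <- length(ids); ni <- length(individuals)
  mk <- function(init) matrix(init, nv, ni, dimnames = list(ids, individuals))
  out <- list(gt = mk(NA_character_), canon = mk(NA_character_),
              gq = mk(NA_integer_), dp = mk(NA_integer_), phase = mk(NA_character_))
  reg <- proj$samples[proj$samples$individual %in% individuals, ]
  # candidate calls per individual: aligned matrices per field
  cand <- setNames(vector("list", ni), individuals)
  for (r in proj$runs) {
    run <- get_run(store, project_id, r)
    rows <- ids[ids %in% rownames(run$gt)]
    if (!length(rows)) next
    keep_smp <- reg$run == r & reg$sample %in% colnames(run$gt)
    smp <- reg[which(keep_smp), ]
    if (!nrow(smp)) next
    for (j in seq_len(nrow(smp))) {
      s <- smp$sample[j]; ind <- smp$individual[j]
      canon <- rep(NA_character_, nv); names(canon) <- ids
      canon[rows] <- run$canon[rows, s]
      omiss <- is.na(canon)
      gq <- rep(NA_integer_, nv)
      if (!is.null(run$gq)) gq[match(rows, ids)] <- run$gq[rows, s]
      dp <- rep(NA_integer_, nv)
      if (!is.null(run$dp)) dp[match(rows, ids)] <- run$dp[rows, s]
      if (!is.null(spec$min_gq)) canon[!is.na(gq) & gq < spec$min_gq] <- NA_character_
      if (!is.null(spec$min_dp)) canon[!is.na(dp) & dp < spec$min_dp] <- NA_character_
      gt <- rep(NA_character_, nv)
      gt[match(rows, ids)] <- run$gt[rows, s]
      ph <- rep(NA_character_, nv)
      if (!is.null(run$phase)) ph[match(rows, ids)] <- run$phase[rows, s]
      cand[[ind]] <- c(cand[[ind]], list(list(canon = canon, omiss = omiss,
                                              gt = gt, gq = gq, dp = dp, phase = ph)))
    }
  }
  for (ind in individuals) {
    cc <- cand[[ind]]
    if (is.null(cc)) next
    if (length(cc) == 1L) {
      pick <- rep(1L, nv)
    } else {
      cmat <- vapply(cc, `[[`, character(nv), "canon")
      pick <- integer(nv)
      for (i in seq_len(nv)) {
        vals <- cmat[i, ]
        ok <- which(!is.na(vals))
        if (!length(ok)) { pick[i] <- 1L; next }
        win <- if (length(unique(vals[ok])) == 1L) vals[ok[1L]] else
          consolidate_canon(vals[ok], seed = (seed + id_hash(ids[i])) %% .Machine$integer.max)
        pick[i] <- ok[match(win, vals[ok])]
      }
    }
    for (i in seq_len(nv)) {
      ch <- cc[[pick[i]]]
      masked <- is.na(ch$canon[i]) && !ch$omiss[i]  # threshold-masked, not input-missing
      out$canon[i, ind] <- ch$canon[i]
      out$gt[i, ind] <- if (masked) NA_character_ else ch$gt[i]
      out$gq[i, ind] <- ch$gq[i]
      out$dp[i, ind] <- ch$dp[i]
      out$phase[i, ind] <- if (masked) NA_character_ else ch$phase[i]
    }
  }
  out
}

# allele-index list matrix from verbatim GT strings (NA -> NULL)
gt_allele_lists <- function(gtmat) {
  u <- unique(as.vector(gtmat))
  parsed <- lapply(u, function(s) if (is.na(s)) NA_integer_ else parse_gt_string(s))
  idx <- match(gtmat, u)
  list(u = u, parsed = parsed, idx = matrix(idx, nrow(gtmat)))
}

#' Recompute phasing annotations for an exported selection
#'
#' Phasing (haplotype estimation) is kept in the store as per-call phase
#' groups and recalculated at export time: two exported records of an
#' individual carry the phased separator and a common phase-set identifier
#' if and only if their stored calls share a phase group — regardless of
#' how many intermediate variants the filter removed.  Unphased calls use
#' the unphased separator and no phase set.
#'
#' @param calls list of [genotype_call()] objects of one individual,
#'   ordered by exported position.
#' @return data.frame with one row per call: `separator` (`"|"` or `"/"`)
#'   and `phase_set` (the group identifier, `NA` when unphased).
#' @export
recompute_phasing <- function(calls) {
  data.frame(
    separator = vapply(calls, function(c) if (c$phased) "|" else "/", character(1)),
    phase_set = vapply(calls, function(c) as.character(c$phase_group %||% NA_character_), character(1)),
    stringsAsFactors = FALSE)
}

#' Export the filtered selection to a standard format
#'
#' Recomputes the selection for `spec`, consolidates genotypes to one per
#' variant per individual (majority rule with seeded tie-break, after GQ/DP
#' masking) and writes the selection in the requested format:
#'
#' * `VCF` (v4.2): verbatim genotypes with GQ/DP and phasing; phase sets
#'   are written as the `PS` FORMAT tag carrying the stored phase group,
#'   preserved across filtered-out intermediate positions; the stored
#'   header of the project's first VCF run is merged with generated
#'   FORMAT lines.
#' * `EIGENSTRAT`: `.geno` (reference-allele count per diploid call:
#'   2/1/0, 9 = missing or non-diploid) + `.snp` + `.ind`; bi-allelic
#'   variants only (others dropped with a warning).
#' * `GFF3`: 1-based inclusive features typed with Sequence Ontology terms.
#' * `BED`: 0-based half-open intervals, positions only.
#' * `HAPMAP`: 11 standard columns + two-letter diploid codes, `NN`
#'   missing; diploid single-character-allele variants only (others
#'   dropped with a warning).
#' * `DARWIN`: DARwin 5 allelic `.var` table, individuals as rows, allele
#'   codes = allele index + 1, missing = 999.
#' * `PLINK`: `.ped` + `.map`, two allele columns per variant, 0 =
#'   missing; diploid variants only (others dropped with a warning).
#'
#' @param store a store handle.
#' @param project_id project ID.
#' @param spec a [filter_spec()] describing the selection.
#' @param xspec an [export_spec()].
#' @return character vector of the file path(s) written, invisibly.
#' @export
export_variants <- function(store, project_id, spec, xspec) {
  stopifnot(inherits(xspec, "gnv_export_spec"))
  proj <- get_project(store, project_id)
  ids <- execute_two_step(store, project_id, spec)
  vdt <- store$data$variants
  sub <- vdt[match(ids, vdt$variant_id), ]
  ord <- order(sub$sequence, sub$start, sub$variant_id, method = "radix")
  sub <- sub[ord, ]; ids <- ids[ord]
  individuals <- selected_individuals(proj, spec)
  cons <- consolidated_calls(store, project_id, ids, individuals, spec,
                             xspec$random_seed)
  dest_dir <- dirname(xspec$destination)
  if (nzchar(dest_dir) && !dir.exists(dest_dir))
    if (!dir.create(dest_dir, recursive = TRUE, showWarnings = FALSE))
      stop("unwritable export destination: ", xspec$destination)
  writer <- switch(xspec$format,
    VCF = write_vcf_export, EIGENSTRAT = write_eigenstrat_export,
    GFF3 = write_gff3_export, BED = write_bed_export,
    HAPMAP = write_hapmap_export, DARWIN = write_darwin_export,
    PLINK = write_plink_export)
  paths <- writer(store, project_id, sub, cons, individuals, xspec)
  if (xspec$compress) paths <- vapply(paths, gzip_file, character(1))
  invisible(paths)
}

gzip_file <- function(path) {
  out <- paste0(path, ".gz")
  con_in <- file(path, "rb"); con_out <- gzfile(out, "wb")
  repeat {
    chunk <- readBin(con_in, raw(), 1024 * 1024)
    if (!length(chunk)) break
    writeBin(chunk, con_out)
  }
  close(con_in); close(con_out)
  unlink(path)
  out
}

write_lines_to <- function(lines, path) {
  con <- file(path, "wb")
  writeLines(lines, con)
  close(con)
  path
}

# ---- VCF ----
write_vcf_export <- function(store, project_id, sub, cons, individuals, xspec) {
  proj <- get_project(store, project_id)
  header <- NULL
  for (r in proj$runs) {
    header <- get_vcf_header(store, project_id, r)
    if (!is.null(header)) break
  }
  if (is.null(header)) header <- "##fileformat=VCFv4.2"
  gen <- c(
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    '##FORMAT=<ID=PS,Number=1,Type=Integer,Description="Phase set">')
  ftag <- function(l) sub("^##FORMAT=<ID=([A-Za-z0-9]+).*$", "\\1", l)
  have <- ftag(header[startsWith(header, "##FORMAT=")])
  header <- c(header, gen[!ftag(gen) %in% have])
  info_src <- NULL
  for (r in proj$runs) {
    run <- get_run(store, project_id, r)
    if (!is.null(run$info)) { info_src <- run$info; break }
  }
  nv <- nrow(sub)
  has_gq <- any(!is.na(cons$gq)); has_dp <- any(!is.na(cons$dp))
  has_ps <- any(!is.na(cons$phase))
  fmt <- paste(c("GT", if (has_gq) "GQ", if (has_dp) "DP", if (has_ps) "PS"),
               collapse = ":")
  def_ploidy <- max(vapply(proj$runs, function(r) get_run(store, project_id, r)$ploidy %||% 2L,
                           integer(1)), 1L)
  lines <- character(nv)
  for (i in seq_len(nv)) {
    gt <- cons$gt[i, ]
    gt[is.na(gt)] <- paste(rep(".", def_ploidy), collapse = "/")
    cells <- gt
    if (has_gq) cells <- paste(cells, ifelse(is.na(cons$gq[i, ]), ".", cons$gq[i, ]), sep = ":")
    if (has_dp) cells <- paste(cells, ifelse(is.na(cons$dp[i, ]), ".", cons$dp[i, ]), sep = ":")
    if (has_ps) cells <- paste(cells, ifelse(is.na(cons$phase[i, ]), ".", cons$phase[i, ]), sep = ":")
    alt <- sub$known_alleles[[i]][-1]
    lines[i] <- paste(c(sub$sequence[i], sub$start[i], sub$variant_id[i],
                        sub$known_alleles[[i]][1],
                        if (length(alt)) paste(alt, collapse = ",") else ".",
                        ".", ".",
                        (info_src[[sub$variant_id[i]]] %||% "."),
                        fmt, cells), collapse = "\t")
  }
  chrom <- paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", individuals), collapse = "\t")
  write_lines_to(c(header, chrom, lines), xspec$destination)
}

# ---- Eigenstrat ----
write_eigenstrat_export <- function(store, project_id, sub, cons, individuals, xspec) {
  keep <- lengths(sub$known_alleles) == 2L
  if (any(!keep))
    warning(sum(!keep), " non-bi-allelic variant(s) dropped from Eigenstrat export")
  sub <- sub[keep, ]; canon <- cons$canon[keep, , drop = FALSE]
  code <- function(cn) {
    if (is.na(cn)) return("9")
    ai <- as.integer(strsplit(cn, "/", fixed = TRUE)[[1]])
    if (length(ai) != 2L) return("9")
    as.character(sum(ai == 0L))
  }
  u <- unique(as.vector(canon))
  map <- vapply(u, code, character(1))
  geno <- matrix(map[match(canon, u)], nrow(canon))
  base <- xspec$destination
  p1 <- write_lines_to(apply(geno, 1L, paste, collapse = ""), paste0(base, ".geno"))
  snp <- vapply(seq_len(nrow(sub)), function(i)
    paste(sub$variant_id[i], sub$sequence[i], "0.0", sub$start[i],
          sub$known_alleles[[i]][1], sub$known_alleles[[i]][2], sep = "\t"),
    character(1))
  p2 <- write_lines_to(snp, paste0(base, ".snp"))
  p3 <- write_lines_to(paste(individuals, "U", "Pop1", sep = "\t"),
                       paste0(base, ".ind"))
  c(p1, p2, p3)
}

# ---- GFF3 ----
so_term <- function(alleles, vtype) {
  if (vtype == "SNP") return("SNV")
  if (vtype == "SV-like" || vtype == "other") return("sequence_alteration")
  ref <- nchar(alleles[1]); altn <- nchar(alleles[-1])
  if (length(altn) && all(altn > ref)) return("insertion")
  if (length(altn) && all(altn < ref)) return("deletion")
  "sequence_alteration"
}

write_gff3_export <- function(store, project_id, sub, cons, individuals, xspec) {
  lines <- vapply(seq_len(nrow(sub)), function(i)
    paste(sub$sequence[i], "genonav",
          so_term(sub$known_alleles[[i]], sub$variant_type[i]),
          sub$start[i], sub$stop[i], ".", "+", ".",
          paste0("ID=", sub$variant_id[i], ";alleles=",
                 paste(sub$known_alleles[[i]], collapse = ",")),
          sep = "\t"), character(1))
  write_lines_to(c("##gff-version 3", lines), xspec$destination)
}

# ---- BED ----
write_bed_export <- function(store, project_id, sub, cons, individuals, xspec) {
  lines <- paste(sub$sequence, sub$start - 1L, sub$stop, sub$variant_id, sep = "\t")
  write_lines_to(lines, xspec$destination)
}

# ---- HapMap ----
write_hapmap_export <- function(store, project_id, sub, cons, individuals, xspec) {
  ok <- vapply(seq_len(nrow(sub)), function(i) {
    al <- sub$known_alleles[[i]]
    if (!all(nchar(al) == 1L)) return(FALSE)
    cn <- cons$canon[i, ]
    all(is.na(cn) | vapply(strsplit(cn, "/", fixed = TRUE), length, integer(1)) == 2L)
  }, logical(1))
  if (any(!ok))
    warning(sum(!ok), " variant(s) dropped from HapMap export (non-diploid calls or multi-character alleles)")
  sub <- sub[ok, ]; canon <- cons$canon[ok, , drop = FALSE]
  lines <- character(nrow(sub))
  for (i in seq_len(nrow(sub))) {
    al <- sub$known_alleles[[i]]
    cells <- vapply(canon[i, ], function(cn) {
      if (is.na(cn)) return("NN")
      ai <- as.integer(strsplit(cn, "/", fixed = TRUE)[[1]]) + 1L
      paste0(al[ai[1]], al[ai[2]])
    }, character(1))
    lines[i] <- paste(c(sub$variant_id[i], paste(al, collapse = "/"),
                        sub$sequence[i], sub$start[i], "+",
                        rep("NA", 6), cells), collapse = "\t")
  }
  hdr <- paste(c("rs#", "alleles", "chrom", "pos", "strand", "assembly#",
                 "center", "protLSID", "assayLSID", "panelLSID", "QCcode",
                 individuals), collapse = "\t")
  write_lines_to(c(hdr, lines), xspec$destination)
}

# ---- DARwin ----
write_darwin_export <- function(store, project_id, sub, cons, individuals, xspec) {
  canon <- cons$canon
  pl <- max(1L, suppressWarnings(max(vapply(as.vector(canon), function(cn)
    if (is.na(cn)) 0L else length(strsplit(cn, "/", fixed = TRUE)[[1]]),
    integer(1)))))
  hdr1 <- paste0("@DARwin 5.0 - ALLELIC - ", pl)
  hdr2 <- paste(length(individuals), nrow(sub), sep = "\t")
  hdr3 <- paste(c("Unit", unlist(lapply(sub$variant_id, function(v)
    paste0(v, "_", seq_len(pl))))), collapse = "\t")
  lines <- character(length(individuals))
  for (j in seq_along(individuals)) {
    cells <- unlist(lapply(seq_len(nrow(sub)), function(i) {
      cn <- canon[i, j]
      if (is.na(cn)) return(rep("999", pl))
      ai <- as.integer(strsplit(cn, "/", fixed = TRUE)[[1]]) + 1L
      c(as.character(ai), rep("999", pl - length(ai)))
    }))
    lines[j] <- paste(c(as.character(j), cells), collapse = "\t")
  }
  write_lines_to(c(hdr1, hdr2, hdr3, lines), xspec$destination)
}

# ---- PLINK ----
write_plink_export <- function(store, project_id, sub, cons, individuals, xspec) {
  canon <- cons$canon
  ok <- vapply(seq_len(nrow(sub)), function(i) {
    cn <- canon[i, ]
    all(is.na(cn) | vapply(strsplit(cn, "/", fixed = TRUE), length, integer(1)) == 2L)
  }, logical(1))
  if (any(!ok))
    warning(sum(!ok), " non-diploid variant(s) dropped from PLINK export")
  sub <- sub[ok, ]; canon <- canon[ok, , drop = FALSE]
  base <- xspec$destination
  map <- paste(sub$sequence, sub$variant_id, 0L, sub$start, sep = "\t")
  p1 <- write_lines_to(map, paste0(base, ".map"))
  lines <- character(length(individuals))
  for (j in seq_along(individuals)) {
    cells <- unlist(lapply(seq_len(nrow(sub)), function(i) {
      cn <- canon[i, j]
      if (is.na(cn)) return(c("0", "0"))
      ai <- as.integer(strsplit(cn, "/", fixed = TRUE)[[1]]) + 1L
      sub$known_alleles[[i]][ai]
    }))
    lines[j] <- paste(c(individuals[j], individuals[j], "0", "0", "0", "-9",
                        cells), collapse = "\t")
  }
  p2 <- write_lines_to(lines, paste0(base, ".ped"))
  c(p2, p1)
}

#' Variant-density histogram of a selection
#'
#' Histograms the start positions of the matching variants on each
#' sequence, split by variant type.  Bins cover positions 1 to the maximum
#' stop position the project holds on the sequence, so an empty selection
#' yields all-zero bins.
#'
#' @param store a store handle.
#' @param project_id project ID.
#' @param spec a [filter_spec()] describing the selection.
#' @param bin_width bin width in bp; default splits each sequence into 150
#'   bins.
#' @return data.table with columns `sequence`, `bin_start`, `bin_end`,
#'   `variant_type`, `count` (zero bins included).
#' @export
variant_density <- function(store, project_id, spec = filter_spec(),
                            bin_width = NULL) {
  proj <- get_project(store, project_id)
  ids <- execute_two_step(store, project_id, spec)
  vdt <- store$data$variants
  all_proj <- vdt[match(proj$variant_ids, vdt$variant_id), ]
  sel <- vdt[match(ids, vdt$variant_id), ]
  seqs <- if (length(spec$sequences)) intersect(proj$sequences, spec$sequences) else proj$sequences
  types <- proj$variant_types
  out <- list()
  for (sq in seqs) {
    maxstop <- max(all_proj$stop[all_proj$sequence == sq], 1L)
    bw <- as.integer(bin_width %||% max(1L, ceiling(maxstop / 150)))
    starts <- seq.int(1L, maxstop, by = bw)
    ends <- pmin(starts + bw - 1L, maxstop)
    for (ty in types) {
      pos <- sel$start[sel$sequence == sq & sel$variant_type == ty]
      cnt <- if (length(pos)) {
        bin <- findInterval(pos, starts)
        tabulate(bin, nbins = length(starts))
      } else integer(length(starts))
      out[[length(out) + 1L]] <- data.table::data.table(
        sequence = sq, bin_start = starts, bin_end = ends,
        variant_type = ty, count = cnt)
    }
  }
  if (!length(out)) return(data.table::data.table(
    sequence = character(), bin_start = integer(), bin_end = integer(),
    variant_type = character(), count = integer()))
  data.table::rbindlist(out)
}
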