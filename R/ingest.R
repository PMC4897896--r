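#' Detect the SnpEff annotation style of a VCF header
#'
#' SnpEff wrote functional annotations into the `EFF` INFO field up to
#' version 4.0 and into the `ANN` field from 4.1 onwards.  The style is
#' detected from the INFO definitions in the header; when both are defined,
#' the newer `ANN` style is preferred and a warning is emitted.
#'
#' @param header_text character vector of VCF header lines.
#' @return one of `"EFF"`, `"ANN"`, `"none"`.
#' @export
detect_annotation_style <- function(header_text) {
  has_ann <- any(grepl("^##INFO=<ID=ANN[,>]", header_text))
  has_eff <- any(grepl("^##INFO=<ID=EFF[,>]", header_text))
  if (has_ann && has_eff) {
    warning("both EFF and ANN INFO definitions present; using ANN")
    return("ANN")
  }
  if (has_ann) return("ANN")
  if (has_eff) return("EFF")
  "none"
}

#' Extract effect terms and gene names from a SnpEff INFO payload
#'
#' `ANN` entries are pipe-separated with the effect (annotation) in the
#' second field and the gene name in the fourth; `&`-joined effect terms are
#' split.  `EFF` entries have the form `EFFECT(args)` with the gene name in
#' the sixth pipe-separated sub-field.  Entries that cannot be parsed are
#' skipped with a warning; parsing never aborts an import.
#'
#' @param info_payload the value of the ANN/EFF INFO field (a full
#'   `ANN=...`/`EFF=...` key=value string is also accepted), or a whole
#'   semicolon-separated INFO column.
#' @param style `"ANN"` or `"EFF"`.
#' @return list with character-vector elements `effects` and `genes`.
#' @export
parse_annotations <- function(info_payload, style) {
  if (!style %in% c("ANN", "EFF")) stop("annotation style must be ANN or EFF")
  effects <- character(); genes <- character()
  if (is.na(info_payload) || !nzchar(info_payload) || info_payload == ".")
    return(list(effects = effects, genes = genes))
  payload <- info_payload
  if (grepl("(^|;)(ANN|EFF)=", payload)) {
    m <- regmatches(payload, regexec(paste0("(^|;)", style, "=([^;]*)"), payload))[[1]]
    if (length(m) < 3L) return(list(effects = effects, genes = genes))
    payload <- m[3]
  }
  for (entry in strsplit(payload, ",", fixed = TRUE)[[1]]) {
    if (!nzchar(entry)) next
    if (style == "ANN") {
      f <- strsplit(entry, "|", fixed = TRUE)[[1]]
      if (length(f) < 4L || !nzchar(f[2])) {
        warning("skipping unparseable ANN entry: ", entry)
        next
      }
      effects <- c(effects, strsplit(f[2], "&", fixed = TRUE)[[1]])
      if (nzchar(f[4])) genes <- c(genes, f[4])
    } else {
      m <- regmatches(entry, regexec("^([^()]+)\\(([^)]*)\\)$", entry))[[1]]
      if (length(m) < 3L) {
        warning("skipping unparseable EFF entry: ", entry)
        next
      }
      effects <- c(effects, m[2])
      sub <- strsplit(m[3], "|", fixed = TRUE)[[1]]
      if (length(sub) >= 6L && nzchar(sub[6])) genes <- c(genes, sub[6])
    }
  }
  list(effects = unique(effects), genes = unique(genes))
}

# variant-type classifier shared by the VCF and HapMap importers
variant_type_of <- function(alleles) {
  if (any(grepl("^<.*>$", alleles))) return("SV-like")
  if (any(alleles %in% c("+", "-"))) return("INDEL")
  n <- nchar(alleles)
  if (all(n == 1L)) return("SNP")
  if (length(unique(n)) > 1L) return("INDEL")
  "other"
}

# deterministic variant ID when the input provides none
make_variant_id <- function(sequence, start, alleles) {
  paste(sequence, start, alleles[1],
        paste(alleles[-1], collapse = "-"), sep = ":")
}

# tab-field count validation with line numbers (works on plain or gzip text)
validate_tsv_lines <- function(path, what) {
  con <- gzfile(path, "r")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  nf <- lengths(regmatches(lines, gregexpr("\t", lines, fixed = TRUE))) + 1L
  list(lines = lines, nfields = nf)
}

#' Import a VCF file into the store
#'
#' Creates one run record per variant for the given (project, run), stores
#' genotypes verbatim (allele order and phasing separators preserved) along
#' with per-call GQ and DP when present, registers samples — a sample column
#' name is the individual ID, so a further run naming the same individuals
#' attaches new samples to them (incremental loading) — keeps the VCF header
#' verbatim, detects the SnpEff annotation style, parses effect/gene
#' annotations, updates the project's sequence and variant-type lists and
#' rebuilds the landmark tag index.
#'
#' Phased calls (`|` separator) are recorded with a phase group: the `PS`
#' FORMAT value when present, otherwise one group per sample per contiguous
#' phased stretch, identified by the position of the stretch's first
#' variant.
#'
#' @param store a store handle.
#' @param path VCF file (plain or gzipped).
#' @param project_id,run_id project and run to import into.
#' @param chunk_size tag-index chunk size (default: existing index's size,
#'   else 1000).
#' @param overwrite replace an existing (project, run) instead of refusing.
#' @return an import report (class `gnv_import_report`) with
#'   `variants_imported`, `samples_registered`, `annotation_style`,
#'   `warnings`.
#' @export
import_vcf <- function(store, path, project_id, run_id,
                       chunk_size = NULL, overwrite = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  key <- run_key(project_id, run_id)
  if (!is.null(store$data$runs[[key]]) && !overwrite)
    stop("run ", run_id, " already exists in project ", project_id,
         "; pass overwrite = TRUE to replace it")
  vl <- validate_tsv_lines(path)
  chrom_idx <- which(startsWith(vl$lines, "#CHROM"))[1]
  if (is.na(chrom_idx)) stop("malformed VCF: no #CHROM header line")
  expected <- vl$nfields[chrom_idx]
  body_idx <- which(!startsWith(vl$lines, "#"))
  body_idx <- body_idx[body_idx > chrom_idx]
  bad <- body_idx[vl$nfields[body_idx] != expected]
  if (length(bad))
    stop("malformed VCF line ", bad[1], ": expected ", expected,
         " tab-separated fields, found ", vl$nfields[bad[1]])

  warnings <- character()
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf@fix
  if (!nrow(fix)) stop("VCF contains no variant records")
  meta <- vcf@meta

  alleles <- lapply(seq_len(nrow(fix)), function(i) {
    alt <- fix[i, "ALT"]
    unname(c(fix[i, "REF"],
             if (!is.na(alt) && alt != ".") strsplit(alt, ",", fixed = TRUE)[[1]]))
  })
  start <- as.integer(fix[, "POS"])
  seqs <- fix[, "CHROM"]
  ids <- fix[, "ID"]
  gen <- is.na(ids) | ids == "."
  if (any(gen))
    ids[gen] <- as.character(mapply(make_variant_id, seqs[gen], start[gen], alleles[gen]))
  if (anyDuplicated(ids)) stop("duplicate variant IDs in input: ", ids[duplicated(ids)][1])
  vtype <- vapply(alleles, variant_type_of, character(1))
  stop_pos <- start + ifelse(vtype == "SV-like", 0L, nchar(fix[, "REF"]) - 1L)

  new_variants <- data.table::data.table(
    variant_id = ids, variant_type = vtype, sequence = seqs,
    start = start, stop = stop_pos, known_alleles = alleles)

  # genotype matrices, verbatim GT plus extracted per-call metadata
  body <- vcf@gt
  fmt <- body[, 1]
  samples_in <- colnames(body)[-1]
  if (!length(samples_in)) stop("VCF has no sample columns")
  gt <- body[, -1, drop = FALSE]
  gt[is.na(gt)] <- "."
  gt <- sub(":.*$", "", gt)
  dim(gt) <- c(nrow(fix), length(samples_in))
  canon <- gt_canon(gt)
  dim(canon) <- dim(gt)

  extract_num <- function(tag) {
    if (!any(grepl(tag, fmt))) return(NULL)
    m <- suppressWarnings(vcfR::extract.gt(vcf, element = tag, as.numeric = TRUE))
    m <- matrix(as.integer(round(m)), nrow = nrow(fix))
    m
  }
  gq <- extract_num("GQ")
  dp <- extract_num("DP")
  ps <- if (any(grepl("PS", fmt))) {
    m <- suppressWarnings(vcfR::extract.gt(vcf, element = "PS"))
    matrix(as.character(m), nrow = nrow(fix))
  } else NULL

  phased <- matrix(grepl("|", gt, fixed = TRUE), nrow = nrow(fix))
  phase <- NULL
  if (any(phased)) {
    phase <- matrix(NA_character_, nrow(fix), length(samples_in))
    if (!is.null(ps)) phase[phased & !is.na(ps)] <- ps[phased & !is.na(ps)]
    # contiguous phased stretches (file order, per sequence) for phased
    # calls lacking an explicit PS value
    need <- phased & (if (is.null(ps)) TRUE else is.na(ps))
    if (any(need)) {
      for (s in seq_along(samples_in)) {
        col_need <- need[, s]
        if (!any(col_need)) next
        grp_start <- NA_integer_
        prev_in <- FALSE; prev_seq <- ""
        for (i in seq_len(nrow(fix))) {
          if (col_need[i]) {
            if (!prev_in || seqs[i] != prev_seq) grp_start <- start[i]
            phase[i, s] <- as.character(grp_start)
            prev_in <- TRUE
          } else prev_in <- FALSE
          prev_seq <- seqs[i]
        }
      }
    }
  }

  dimnames(gt) <- dimnames(canon) <- list(ids, samples_in)
  for (m in c("gq", "dp", "phase"))
    if (!is.null(get(m))) {
      mm <- get(m); dimnames(mm) <- list(ids, samples_in); assign(m, mm)
    }

  # annotations
  style <- withCallingHandlers(
    detect_annotation_style(meta),
    warning = function(w) {
      warnings <<- c(warnings, conditionMessage(w)); invokeRestart("muffleWarning")
    })
  info_raw <- setNames(ifelse(is.na(fix[, "INFO"]), ".", fix[, "INFO"]), ids)
  ann <- NULL
  if (style != "none") {
    parsed <- lapply(info_raw, function(x) {
      withCallingHandlers(parse_annotations(x, style), warning = function(w) {
        warnings <<- c(warnings, conditionMessage(w)); invokeRestart("muffleWarning")
      })
    })
    ann <- data.table::data.table(
      variant_id = ids,
      effects = lapply(parsed, `[[`, "effects"),
      genes = lapply(parsed, `[[`, "genes"))
  }

  ingest_run(store, project_id, run_id, new_variants,
             list(project_id = project_id, run_id = run_id,
                  samples = paste(samples_in, run_id, sep = "@"),
                  gt = gt, canon = canon, gq = gq, dp = dp, phase = phase,
                  info = info_raw, ann = ann, annotation_style = style,
                  ploidy = {
                    u <- setdiff(unique(as.vector(gt)), ".")
                    if (!length(u)) 1L
                    else max(lengths(regmatches(u, gregexpr("[/|]", u))) + 1L)
                  },
                  source = "vcf"),
             individuals = samples_in, header = meta,
             chunk_size = chunk_size, warnings = warnings)
}

#' Import a HapMap genotype file into the store
#'
#' Expects the standard tab-delimited HapMap layout: eleven leading metadata
#' columns (`rs#`, `alleles`, `chrom`, `pos`, `strand`, `assembly#`,
#' `center`, `protLSID`, `assayLSID`, `panelLSID`, `QCcode`) followed by one
#' column per sample holding two-letter diploid genotype codes.  `NN` and
#' `--` decode to missing; `+`/`-` indel codes are kept as literal alleles.
#' HapMap carries no per-call GQ/DP and no phasing.
#'
#' @inheritParams import_vcf
#' @return an import report (class `gnv_import_report`).
#' @export
import_hapmap <- function(store, path, project_id, run_id,
                          chunk_size = NULL, overwrite = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  key <- run_key(project_id, run_id)
  if (!is.null(store$data$runs[[key]]) && !overwrite)
    stop("run ", run_id, " already exists in project ", project_id,
         "; pass overwrite = TRUE to replace it")
  vl <- validate_tsv_lines(path)
  lines <- vl$lines[nzchar(vl$lines)]
  nf <- vl$nfields[nzchar(vl$lines)]
  if (length(lines) < 2L) stop("HapMap file has no data rows")
  if (any(nf != nf[1]))
    stop("malformed HapMap line ", which(nf != nf[1])[1],
         ": expected ", nf[1], " tab-separated fields, found ",
         nf[which(nf != nf[1])[1]])
  if (nf[1] < 12L) stop("HapMap file needs 11 metadata columns plus at least one sample")

  cells <- strsplit(lines, "\t", fixed = TRUE)
  headerr <- cells[[1]]
  samples_in <- headerr[-(1:11)]
  rows <- cells[-1]
  nvar <- length(rows)
  warnings <- character()

  ids <- character(nvar); seqs <- character(nvar); start <- integer(nvar)
  alleles <- vector("list", nvar)
  gt <- matrix(NA_character_, nvar, length(samples_in))
  for (i in seq_len(nvar)) {
    r <- rows[[i]]
    al <- strsplit(r[2], "/", fixed = TRUE)[[1]]
    seqs[i] <- r[3]; start[i] <- as.integer(r[4])
    cellv <- r[-(1:11)]
    for (j in seq_along(cellv)) {
      cc <- cellv[j]
      if (cc %in% c("NN", "--", "N", "-") && !all(c(substr(cc, 1, 1), substr(cc, 2, 2)) %in% al)) {
        gt[i, j] <- "./."
        next
      }
      a <- c(substr(cc, 1, 1), substr(cc, 2, 2))
      idx <- match(a, al)
      if (anyNA(idx)) {
        extra <- setdiff(a[is.na(idx)], c("N", ""))
        if (length(extra)) {
          al <- c(al, extra)
          idx <- match(a, al)
        }
      }
      if (anyNA(idx)) {
        warnings <- c(warnings, paste0("undecodable genotype '", cc,
                                       "' at row ", i, ", sample ", samples_in[j]))
        gt[i, j] <- "./."
      } else gt[i, j] <- paste(idx - 1L, collapse = "/")
    }
    alleles[[i]] <- al
    ids[i] <- if (nzchar(r[1]) && r[1] != ".") r[1] else make_variant_id(seqs[i], start[i], al)
  }
  if (anyDuplicated(ids)) stop("duplicate variant IDs in input: ", ids[duplicated(ids)][1])
  vtype <- vapply(alleles, variant_type_of, character(1))
  new_variants <- data.table::data.table(
    variant_id = ids, variant_type = vtype, sequence = seqs,
    start = start, stop = start, known_alleles = alleles)
  canon <- gt_canon(gt); dim(canon) <- dim(gt)
  dimnames(gt) <- dimnames(canon) <- list(ids, samples_in)

  ingest_run(store, project_id, run_id, new_variants,
             list(project_id = project_id, run_id = run_id,
                  samples = paste(samples_in, run_id, sep = "@"),
                  gt = gt, canon = canon, gq = NULL, dp = NULL, phase = NULL,
                  info = setNames(rep(".", nvar), ids), ann = NULL,
                  annotation_style = "none", ploidy = 2L, source = "hapmap"),
             individuals = samples_in, header = NULL,
             chunk_size = chunk_size, warnings = warnings)
}

# shared tail of the importers: register run/samples/project, merge
# variants, store header, rebuild the tag index, invalidate caches, persist
ingest_run <- function(store, project_id, run_id, new_variants, run,
                       individuals, header, chunk_size, warnings) {
  key <- run_key(project_id, run_id)
  existing <- store$data$variants$variant_id
  add <- !(new_variants$variant_id %in% existing)
  if (any(add))
    store$data$variants <- data.table::rbindlist(
      list(store$data$variants, new_variants[add, ]))

  proj <- store$data$projects[[project_id]] %||% list(
    project_id = project_id, runs = character(), individuals = character(),
    samples = data.table::data.table(sample = character(), individual = character(),
                                     run = character()),
    sequences = character(), variant_types = character(),
    variant_ids = character(), version = 0L)
  prev_samples <- nrow(proj$samples)
  proj$runs <- union(proj$runs, run_id)
  proj$individuals <- c(proj$individuals, setdiff(individuals, proj$individuals))
  reg <- data.table::data.table(sample = run$samples, individual = individuals,
                                run = run_id)
  proj$samples <- unique(data.table::rbindlist(list(
    proj$samples[proj$samples$run != run_id, ], reg)))
  proj$sequences <- scan_sort(union(proj$sequences, unique(new_variants$sequence)))
  proj$variant_types <- scan_sort(union(proj$variant_types, unique(new_variants$variant_type)))
  proj$variant_ids <- scan_sort(union(proj$variant_ids, new_variants$variant_id))

  # genotype matrices are keyed by sample IDs
  colnames(run$gt) <- colnames(run$canon) <- run$samples
  for (m in c("gq", "dp", "phase"))
    if (!is.null(run[[m]])) colnames(run[[m]]) <- run$samples

  store$data$runs[[key]] <- run
  store$data$projects[[project_id]] <- proj
  if (!is.null(header)) store$data$headers[[key]] <- header
  cs <- chunk_size %||% (store$data$tags[[project_id]]$chunk_size %||% 1000L)
  bump_project_version(store, project_id)
  build_tag_index(store, project_id, cs)

  structure(list(variants_imported = nrow(new_variants),
                 samples_registered = nrow(store$data$projects[[project_id]]$samples) - prev_samples,
                 annotation_style = run$annotation_style,
                 warnings = warnings),
            class = "gnv_import_report")
}

#' @export
#' @method print gnv_import_report
print.gnv_import_report <- function(x, ...) {
  cat("<import: ", x$variants_imported, " variants, ",
      x$samples_registered, " new samples, annotations: ",
      x$annotation_style, ">\n", sep = "")
  if (length(x$warnings)) cat(" warnings:", length(x$warnings), "\n")
  invisible(x)
}

#' Build the landmark tag index of a project
#'
#' Landmarks are taken every `chunk_size` variants in store scan order
#' (byte-order on variant IDs) and partition the project's variant
#' collection into evenly sized chunks used to split genotype-level queries
#' into parallel sub-queries.  The index is persisted in the store.
#'
#' @param store a store handle.
#' @param project_id project ID.
#' @param chunk_size variants per chunk (default 1000).
#' @return the tag index, class `gnv_tag_index`: `list(tags, chunk_size)`.
#' @export
build_tag_index <- function(store, project_id, chunk_size = 1000L) {
  proj <- get_project(store, project_id)
  n <- length(proj$variant_ids)
  if (!n) stop("project ", project_id, " has no variants")
  chunk_size <- as.integer(chunk_size)
  if (chunk_size < 1L) stop("chunk_size must be >= 1")
  pos <- if (chunk_size <= n) seq.int(chunk_size, n, by = chunk_size) else integer()
  ti <- structure(list(tags = proj$variant_ids[pos], chunk_size = chunk_size),
                  class = "gnv_tag_index")
  store$data$tags[[project_id]] <- ti
  store_save(store)
  ti
}
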