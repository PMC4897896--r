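#' Create a query handle
#'
#' A query handle tracks the chunked execution of a count/find query:
#' total and completed chunk numbers (progress is per chunk and
#' non-decreasing), an abort flag, and the result once finished.
#'
#' @return an object of class `gnv_query_handle`.
#' @export
new_query_handle <- function() {
  h <- new.env(parent = emptyenv())
  h$query_id <- paste0("q", format(as.numeric(Sys.time()) * 1000, scientific = FALSE),
                       "-", sample.int(.Machine$integer.max, 1L))
  h$total_chunks <- 0L
  h$completed_chunks <- 0L
  h$aborted <- FALSE
  h$finished <- FALSE
  h$result <- NULL
  class(h) <- "gnv_query_handle"
  h
}

#' Abort a running query
#'
#' Unscheduled chunks of the query stop promptly; no cache entry is written
#' for an aborted query.  Aborting a finished query is a no-op.
#'
#' @param handle a [new_query_handle()].
#' @export
query_abort <- function(handle) {
  if (!handle$finished) handle$aborted <- TRUE
  invisible(handle)
}

#' Progress of a query
#' @param handle a [new_query_handle()].
#' @return completed fraction in \[0, 1\], monotone over the handle's life.
#' @export
query_progress <- function(handle) {
  if (handle$total_chunks == 0L) return(if (handle$finished) 1 else 0)
  handle$completed_chunks / handle$total_chunks
}

#' @export
#' @method print gnv_query_handle
print.gnv_query_handle <- function(x, ...) {
  cat("<query ", x$query_id, ": ", round(100 * query_progress(x)), "%",
      if (x$aborted) " (aborted)", ">\n", sep = "")
  invisible(x)
}

# selected individuals of a spec, validated against the project
selected_individuals <- function(proj, spec) {
  if (!length(spec$individuals)) return(proj$individuals)
  unknown <- setdiff(spec$individuals, proj$individuals)
  if (length(unknown)) stop("unknown individual(s): ", paste(unknown, collapse = ", "))
  spec$individuals
}

# consolidated, masked canonical-genotype matrix (variants x individuals).
# Masking (GQ/DP thresholds) is applied per sample call first; an
# individual's calls across runs are then consolidated by majority with a
# per-variant deterministic tie-break seed, so the result is independent of
# chunking and evaluation order.
consolidated_canon_matrix <- function(store, project_id, ids, individuals,
                                      min_gq = NULL, min_dp = NULL, base_seed = 0L) {
  proj <- get_project(store, project_id)
  out <- matrix(NA_character_, length(ids), length(individuals),
                dimnames = list(ids, individuals))
  if (!length(ids)) return(out)
  reg <- proj$samples[proj$samples$individual %in% individuals, ]
  cand <- setNames(vector("list", length(individuals)), individuals)
  for (r in proj$runs) {
    run <- get_run(store, project_id, r)
    rows <- ids[ids %in% rownames(run$canon)]
    if (!length(rows)) next
    keep_smp <- reg$run == r & reg$sample %in% colnames(run$canon)
    smp <- reg[which(keep_smp), ]
    if (!nrow(smp)) next
    sub <- run$canon[rows, smp$sample, drop = FALSE]
    if (!is.null(min_gq) && !is.null(run$gq)) {
      g <- run$gq[rows, smp$sample, drop = FALSE]
      sub[!is.na(g) & g < min_gq] <- NA_character_
    }
    if (!is.null(min_dp) && !is.null(run$dp)) {
      d <- run$dp[rows, smp$sample, drop = FALSE]
      sub[!is.na(d) & d < min_dp] <- NA_character_
    }
    full <- matrix(NA_character_, length(ids), nrow(smp),
                   dimnames = list(ids, smp$sample))
    full[rows, ] <- sub
    for (j in seq_len(nrow(smp))) {
      ind <- smp$individual[j]
      cand[[ind]] <- cbind(cand[[ind]], full[, j])
    }
  }
  for (ind in individuals) {
    cc <- cand[[ind]]
    if (is.null(cc)) next
    if (ncol(cc) == 1L) { out[, ind] <- cc[, 1L]; next }
    nn <- rowSums(!is.na(cc))
    for (i in which(nn > 0L)) {
      vals <- cc[i, ][!is.na(cc[i, ])]
      out[i, ind] <- if (length(unique(vals)) == 1L) vals[1L] else
        consolidate_canon(vals, seed = (base_seed + id_hash(ids[i])) %% .Machine$integer.max)
    }
  }
  out
}

# row-wise genotype-level criteria over a consolidated canon matrix
eval_genotype_rows <- function(canon_mat, biallelic, spec) {
  n <- nrow(canon_mat)
  pass <- rep(TRUE, n)
  if (spec$max_missing_ratio < 1) {
    miss <- rowMeans(is.na(canon_mat))
    pass <- pass & (miss <= spec$max_missing_ratio + 1e-12)
  }
  if (spec$maf_range[1] > 0 || spec$maf_range[2] < 0.5) {
    st <- canon_stats(as.vector(canon_mat))
    c0 <- matrix(st$cnt_ref, n); ns <- matrix(st$nslots, n)
    tot <- rowSums(ns)
    cr <- rowSums(c0, na.rm = TRUE)
    maf <- ifelse(tot > 0, pmin(cr, tot - cr) / tot, NA_real_)
    defined <- biallelic & tot > 0
    pass <- pass & (!defined |
                      (maf >= spec$maf_range[1] - 1e-12 &
                       maf <= spec$maf_range[2] + 1e-12))
  }
  if (!is.null(spec$pattern) && spec$pattern$name != "any") {
    for (i in which(pass))
      pass[i] <- pattern_match_canon(canon_mat[i, ], spec$pattern)
  }
  pass
}

# full variant-feature match, vectorized over a set of IDs
eval_features <- function(store, project_id, ids, spec) {
  vdt <- store$data$variants
  sub <- vdt[match(ids, vdt$variant_id), ]
  keep <- rep(TRUE, length(ids))
  if (length(spec$variant_types)) keep <- keep & sub$variant_type %in% spec$variant_types
  if (length(spec$sequences)) keep <- keep & sub$sequence %in% spec$sequences
  pr <- spec$position_range
  if (!is.null(pr))
    keep <- keep & sub$sequence == pr$sequence & sub$start <= pr$end & sub$stop >= pr$start
  if (!is.null(spec$allele_count))
    keep <- keep & lengths(sub$known_alleles) == spec$allele_count
  if (length(spec$effects) || length(spec$genes)) {
    ann <- project_annotations(store, project_id, ids)
    if (is.null(ann))
      stop("effect/gene filtering requested but no run of project ",
           project_id, " carries functional annotations")
    if (length(spec$effects))
      keep <- keep & vapply(ids, function(v)
        length(intersect(ann$effects[[v]], spec$effects)) > 0L, logical(1))
    if (length(spec$genes))
      keep <- keep & vapply(ids, function(v)
        length(intersect(ann$genes[[v]], spec$genes)) > 0L, logical(1))
  }
  ids[keep]
}

#' Execute the two-step query strategy
#'
#' Step one applies the indexed variant-feature criteria (variant type,
#' sequence, start position) to produce a variant-ID subset; it is skipped
#' when no such criterion is set.  Step two evaluates the remaining
#' criteria — positional stop-overlap, allele count, annotations and all
#' genotype-level criteria — over evenly sized chunks: ID-membership chunks
#' of the step-one subset when it ran, landmark tag-index ranges otherwise.
#' Chunks are independent and side-effect-free, so any executor (the
#' default sequential one included) returns results identical to a
#' single-threaded full scan.
#'
#' @param store a store handle.
#' @param project_id project ID.
#' @param spec a [filter_spec()].
#' @param chunk_size overrides the stored tag index's chunk size.
#' @param workers number of parallel chunk workers (forked; 1 = sequential).
#' @param handle optional [new_query_handle()] for progress/abort.
#' @param on_chunk optional callback `function(handle, chunk_index)` invoked
#'   after each completed chunk.
#' @return character vector of matching variant IDs in scan order, or
#'   `NULL` when the query was aborted.
#' @export
execute_two_step <- function(store, project_id, spec, chunk_size = NULL,
                             workers = 1L, handle = NULL, on_chunk = NULL) {
  proj <- get_project(store, project_id)
  ids_all <- proj$variant_ids
  sel_ind <- selected_individuals(proj, spec)
  feature_pre <- length(spec$variant_types) > 0L || length(spec$sequences) > 0L ||
    !is.null(spec$position_range)

  if (feature_pre) {
    vdt <- store$data$variants
    sub <- vdt[match(ids_all, vdt$variant_id), ]
    keep <- rep(TRUE, length(ids_all))
    if (length(spec$variant_types)) keep <- keep & sub$variant_type %in% spec$variant_types
    if (length(spec$sequences)) keep <- keep & sub$sequence %in% spec$sequences
    pr <- spec$position_range
    # the preliminary indexed query uses (type, sequence, start); the
    # stop-overlap refinement is applied in step two
    if (!is.null(pr)) keep <- keep & sub$sequence == pr$sequence & sub$start <= pr$end
    cs <- chunk_size %||% (get_tag_index(store, project_id)$chunk_size %||% 1000L)
    chunks <- scan_chunks(store, project_id, variant_id_subset = ids_all[keep],
                          chunk_size = cs)
  } else {
    ti <- if (!is.null(chunk_size)) {
      pos <- if (chunk_size <= length(ids_all))
        seq.int(chunk_size, length(ids_all), by = chunk_size) else integer()
      structure(list(tags = ids_all[pos], chunk_size = as.integer(chunk_size)),
                class = "gnv_tag_index")
    } else get_tag_index(store, project_id) %||% build_tag_index(store, project_id)
    chunks <- scan_chunks(store, project_id, tag_index = ti)
  }

  if (!is.null(handle)) {
    handle$total_chunks <- length(chunks)
    handle$completed_chunks <- 0L
  }
  genotype_level <- has_genotype_criteria(spec)

  eval_chunk <- function(ch) {
    ids <- chunk_ids(ch, ids_all)
    ids <- eval_features(store, project_id, ids, spec)
    if (length(ids) && genotype_level) {
      vdt <- store$data$variants
      bial <- lengths(vdt$known_alleles[match(ids, vdt$variant_id)]) == 2L
      cm <- consolidated_canon_matrix(store, project_id, ids, sel_ind,
                                      spec$min_gq, spec$min_dp)
      ids <- ids[eval_genotype_rows(cm, bial, spec)]
    }
    ids
  }

  results <- vector("list", length(chunks))
  i <- 1L
  while (i <= length(chunks)) {
    if (!is.null(handle) && handle$aborted) return(invisible(NULL))
    batch <- i:min(i + workers - 1L, length(chunks))
    got <- if (workers > 1L && length(batch) > 1L &&
               .Platform$OS.type == "unix") {
      parallel::mclapply(chunks[batch], eval_chunk, mc.cores = workers)
    } else lapply(chunks[batch], eval_chunk)
    err <- vapply(got, inherits, logical(1), what = "try-error")
    for (k in seq_along(batch)) {
      if (inherits(got[[k]], "condition")) stop(got[[k]])
      results[[batch[k]]] <- got[[k]]
      if (!is.null(handle)) handle$completed_chunks <- handle$completed_chunks + 1L
      if (!is.null(on_chunk)) on_chunk(handle, batch[k])
      if (!is.null(handle) && handle$aborted && batch[k] < length(chunks))
        return(invisible(NULL))
    }
    i <- batch[length(batch)] + 1L
  }
  out <- scan_sort(unlist(results) %||% character())
  if (!is.null(handle)) { handle$finished <- TRUE; handle$result <- out }
  out
}

#' Count variants matching a filter
#'
#' Runs the two-step query and returns the number of matching variants.
#' The result is cached under the canonical key of (project, store version,
#' filter); a repeated identical call returns the cached value without
#' executing any chunk.  Any import into the project invalidates its cache
#' entries.  No entry is written for an aborted query.
#'
#' @inheritParams execute_two_step
#' @param use_cache consult/populate the count cache (default `TRUE`).
#' @return integer count, or `NA` if the query was aborted.
#' @export
count_variants <- function(store, project_id, spec = filter_spec(),
                           chunk_size = NULL, workers = 1L, use_cache = TRUE,
                           handle = NULL, on_chunk = NULL) {
  proj <- get_project(store, project_id)
  key <- paste(project_id, proj$version %||% 0L, canonical_filter_key(spec),
               sep = "\x1f")
  if (use_cache && !is.null(store$data$cache[[key]])) {
    store$cache_stats$hits <- store$cache_stats$hits + 1L
    if (!is.null(handle)) { handle$finished <- TRUE; handle$result <- store$data$cache[[key]] }
    return(store$data$cache[[key]])
  }
  ids <- execute_two_step(store, project_id, spec, chunk_size = chunk_size,
                          workers = workers, handle = handle, on_chunk = on_chunk)
  if (is.null(ids) && !is.null(handle) && handle$aborted) return(NA_integer_)
  n <- length(ids)
  if (use_cache) {
    store$cache_stats$misses <- store$cache_stats$misses + 1L
    store$data$cache[[key]] <- n
  }
  n
}

#' Browse matching variants as a sorted, paginated table
#'
#' Pagination is stable: concatenating all pages yields the sorted full
#' result exactly once.  Rows carry the main attributes of the result
#' table: ID, sequence, start/stop positions, alleles, and effect / gene
#' annotations when the project carries any.
#'
#' @inheritParams execute_two_step
#' @param page 1-based page number (a page beyond the result is empty).
#' @param page_size rows per page.
#' @param sort_key one of `"position"` (sequence, then start), `"sequence"`,
#'   `"start"`, `"stop"`, `"variant_id"`; ties broken by variant ID.
#' @param sort_direction `"asc"` or `"desc"`.
#' @return a `gnv_result_page`: list with `rows` (data.table),
#'   `page_number`, `page_size`, `total_rows`, `sort_key`, `sort_direction`.
#' @export
find_variants <- function(store, project_id, spec = filter_spec(),
                          page = 1L, page_size = 50L, sort_key = "position",
                          sort_direction = c("asc", "desc"),
                          chunk_size = NULL, workers = 1L,
                          handle = NULL, on_chunk = NULL) {
  sort_direction <- match.arg(sort_direction)
  sort_key <- match.arg(sort_key, c("position", "sequence", "start", "stop", "variant_id"))
  ids <- execute_two_step(store, project_id, spec, chunk_size = chunk_size,
                          workers = workers, handle = handle, on_chunk = on_chunk)
  if (is.null(ids)) stop("query aborted")
  vdt <- store$data$variants
  sub <- vdt[match(ids, vdt$variant_id), ]
  rows <- data.table::data.table(
    variant_id = sub$variant_id, sequence = sub$sequence,
    start = sub$start, stop = sub$stop,
    alleles = vapply(sub$known_alleles, paste, character(1), collapse = ","))
  ann <- tryCatch(project_annotations(store, project_id, ids), error = function(e) NULL)
  if (!is.null(ann)) {
    rows$effect <- vapply(ids, function(v) paste(ann$effects[[v]], collapse = ","), character(1))
    rows$gene <- vapply(ids, function(v) paste(ann$genes[[v]], collapse = ","), character(1))
  }
  dec <- sort_direction == "desc"
  ord <- switch(sort_key,
    position = order(rows$sequence, rows$start, rows$variant_id, method = "radix",
                     decreasing = c(dec, dec, FALSE)),
    order(rows[[sort_key]], rows$variant_id, method = "radix",
          decreasing = c(dec, FALSE)))
  rows <- rows[ord, ]
  n <- nrow(rows)
  from <- (page - 1L) * page_size + 1L
  to <- min(page * page_size, n)
  pg <- if (from > n) rows[0, ] else rows[from:to, ]
  structure(list(rows = pg, page_number = as.integer(page),
                 page_size = as.integer(page_size), total_rows = n,
                 sort_key = sort_key, sort_direction = sort_direction),
            class = "gnv_result_page")
}

#' @export
#' @method print gnv_result_page
print.gnv_result_page <- function(x, ...) {
  cat("<result page ", x$page_number, " (", nrow(x$rows), " of ",
      x$total_rows, " rows, sorted by ", x$sort_key, " ",
      x$sort_direction, ")>\n", sep = "")
  print(x$rows)
  invisible(x)
}

#' Detailed per-run view of one variant
#'
#' For each run of the project containing the variant, reports the
#' variant-level annotations and each individual's genotype with its
#' genotype-level attributes.  Calls that were non-missing in the input but
#' fail the filter's GQ/DP thresholds are reported missing with
#' `masked = TRUE` (the red-background highlight of a detail view).
#'
#' @param store a store handle.
#' @param project_id project ID.
#' @param variant_id variant ID.
#' @param spec a [filter_spec()] supplying the selected individuals and the
#'   GQ/DP thresholds.
#' @param include_unselected also report individuals outside the filter's
#'   selection.
#' @return a `gnv_variant_detail`: list with `variant_id`, `variant`
#'   (one-row data.table) and `runs` (one entry per run: `run_id`,
#'   `annotations`, `genotypes` data.table).
#' @export
variant_detail <- function(store, project_id, variant_id, spec = filter_spec(),
                           include_unselected = FALSE) {
  proj <- get_project(store, project_id)
  if (!variant_id %in% proj$variant_ids)
    stop("unknown variant in project ", project_id, ": ", variant_id)
  vdt <- store$data$variants
  vrow <- vdt[match(variant_id, vdt$variant_id), ]
  inds <- if (include_unselected) proj$individuals else selected_individuals(proj, spec)
  runs_out <- list()
  for (r in proj$runs) {
    run <- get_run(store, project_id, r)
    if (!variant_id %in% rownames(run$gt)) next
    smp <- proj$samples[proj$samples$run == r & proj$samples$individual %in% inds, ]
    gt <- run$gt[variant_id, smp$sample]
    canon <- run$canon[variant_id, smp$sample]
    gq <- if (!is.null(run$gq)) run$gq[variant_id, smp$sample] else rep(NA_integer_, nrow(smp))
    dp <- if (!is.null(run$dp)) run$dp[variant_id, smp$sample] else rep(NA_integer_, nrow(smp))
    pg <- if (!is.null(run$phase)) run$phase[variant_id, smp$sample] else rep(NA_character_, nrow(smp))
    fails <- (!is.null(spec$min_gq) & !is.na(gq) & gq < (spec$min_gq %||% 0L)) |
             (!is.null(spec$min_dp) & !is.na(dp) & dp < (spec$min_dp %||% 0L))
    orig_missing <- is.na(canon)
    geno <- data.table::data.table(
      individual = smp$individual, sample = smp$sample, genotype = gt,
      gq = as.integer(gq), dp = as.integer(dp),
      phased = grepl("|", gt, fixed = TRUE), phase_group = pg,
      missing = orig_missing | fails, masked = !orig_missing & fails)
    runs_out[[r]] <- list(
      run_id = r,
      annotations = list(
        info = run$info[[variant_id]] %||% NA_character_,
        effects = if (!is.null(run$ann)) run$ann$effects[[match(variant_id, run$ann$variant_id)]] else character(),
        genes = if (!is.null(run$ann)) run$ann$genes[[match(variant_id, run$ann$variant_id)]] else character()),
      genotypes = geno)
  }
  structure(list(variant_id = variant_id, variant = vrow, runs = runs_out),
            class = "gnv_variant_detail")
}

#' @export
#' @method print gnv_variant_detail
print.gnv_variant_detail <- function(x, ...) {
  cat("<variant ", x$variant_id, " (", x$variant$sequence, ":",
      x$variant$start, "-", x$variant$stop, ", ",
      paste(x$variant$known_alleles[[1]], collapse = "/"), ") in ",
      length(x$runs), " run(s)>\n", sep = "")
  invisible(x)
}
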