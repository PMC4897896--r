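#' Open (or create) a variant store database
#'
#' A store location is a directory holding one embedded single-file database
#' per database name.  The store is marker-oriented: a variant collection
#' (variant-level features), per-project/per-run genotype collections, the
#' verbatim VCF headers of imported runs, a landmark tag index partitioning
#' each project's variants into evenly sized chunks, and a count cache.
#'
#' The whole database is loaded into memory on open; mutating operations
#' (imports, tag-index builds, cache writes) persist it back to disk, so a
#' handle opened later on the same location sees the same contents.
#'
#' @param location directory path (created if absent).
#' @param database database name within the location.
#' @return a store handle of class `gnv_store`.
#' @export
open_store <- function(location, database) {
  if (!dir.exists(location)) {
    ok <- dir.create(location, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("store location not writable: ", location)
  }
  path <- file.path(location, paste0(database, ".gnvdb"))
  data <- if (file.exists(path)) {
    d <- tryCatch(readRDS(path), error = function(e) stop("corrupt store file: ", path))
    if (!is.list(d) || is.null(d$.format) || d$.format != "gnv1") stop("corrupt store file: ", path)
    d
  } else {
    list(.format = "gnv1",
         variants = data.table::data.table(
           variant_id = character(), variant_type = character(),
           sequence = character(), start = integer(), stop = integer(),
           known_alleles = list()),
         runs = list(), projects = list(), headers = list(),
         tags = list(), cache = list())
  }
  h <- new.env(parent = emptyenv())
  h$location <- location
  h$database <- database
  h$path <- path
  h$data <- data
  h$cache_stats <- list(hits = 0L, misses = 0L)
  class(h) <- "gnv_store"
  h
}

#' @export
#' @method print gnv_store
print.gnv_store <- function(x, ...) {
  cat("<genonav store ", x$database, ": ",
      nrow(x$data$variants), " variants, ",
      length(x$data$projects), " project(s)>\n", sep = "")
  invisible(x)
}

store_save <- function(store) {
  saveRDS(store$data, store$path)
  invisible(store)
}

#' List projects in a database
#' @param store a store handle.
#' @return character vector of project IDs.
#' @export
list_projects <- function(store) scan_sort(names(store$data$projects))

#' Retrieve a project record
#'
#' The project record tracks the elements needed to drive an interface or a
#' query quickly: its runs, the ordered individual list, the sample registry
#' mapping each sample to (individual, run), and the distinct sequence-name
#' and variant-type lists present in the project's data.
#'
#' @param store a store handle.
#' @param project_id project ID.
#' @return a list with elements `project_id`, `runs`, `individuals`,
#'   `samples` (data.table: sample, individual, run), `sequences`,
#'   `variant_types`, `variant_ids` (scan order) and `version`.
#' @export
get_project <- function(store, project_id) {
  p <- store$data$projects[[project_id]]
  if (is.null(p)) stop("unknown project: ", project_id)
  p
}

run_key <- function(project_id, run_id) paste(project_id, run_id, sep = "\x1f")

get_run <- function(store, project_id, run_id) {
  r <- store$data$runs[[run_key(project_id, run_id)]]
  if (is.null(r)) stop("unknown run ", run_id, " in project ", project_id)
  r
}

#' Verbatim VCF header of an imported run
#' @param store a store handle.
#' @param project_id,run_id run coordinates.
#' @return character vector of header lines, or `NULL` if the run was not
#'   imported from VCF.
#' @export
get_vcf_header <- function(store, project_id, run_id) {
  store$data$headers[[run_key(project_id, run_id)]]
}

#' Stored landmark tag index of a project
#' @param store a store handle.
#' @param project_id project ID.
#' @return a `gnv_tag_index` or `NULL` if none was built.
#' @export
get_tag_index <- function(store, project_id) store$data$tags[[project_id]]

#' Count-cache hit/miss counters of this handle
#' @param store a store handle.
#' @return list with integer elements `hits` and `misses`.
#' @export
cache_stats <- function(store) store$cache_stats

#' Split a project's variants into evenly sized query chunks
#'
#' A query over genotype-level data is split into partial sub-queries, each
#' restricted to one chunk of the variant collection.  When a preliminary
#' variant-feature filter produced a variant-ID subset, chunks are disjoint
#' ID-membership predicates covering exactly that subset.  Otherwise the
#' landmark tag index is used: chunks are ordered range predicates (greater
#' than the previous landmark, less than or equal to the current one, in
#' store scan order) that cover the whole collection.
#'
#' @param store a store handle.
#' @param project_id project ID.
#' @param tag_index a `gnv_tag_index` (required unless a subset is given).
#' @param variant_id_subset optional character vector of variant IDs.
#' @param chunk_size chunk size for subset mode; defaults to the tag index's
#'   chunk size, or 1000.
#' @return list of chunk descriptors, each of class `gnv_chunk`:
#'   `list(kind = "in", ids = ...)` or `list(kind = "range", gt = , lte = )`
#'   (`NULL` bounds are open).
#' @export
scan_chunks <- function(store, project_id, tag_index = NULL,
                        variant_id_subset = NULL, chunk_size = NULL) {
  if (!is.null(variant_id_subset)) {
    cs <- chunk_size %||% (if (!is.null(tag_index)) tag_index$chunk_size else 1000L)
    ids <- scan_sort(unique(variant_id_subset))
    if (!length(ids)) return(list())
    grp <- ceiling(seq_along(ids) / cs)
    return(unname(lapply(split(ids, grp), function(g)
      structure(list(kind = "in", ids = unname(g)), class = "gnv_chunk"))))
  }
  if (is.null(tag_index)) stop("scan_chunks needs a tag index or a variant-ID subset")
  proj <- get_project(store, project_id)
  if (!all(tag_index$tags %in% proj$variant_ids))
    stop("stale tag index: landmarks reference absent variants; rebuild required")
  bounds <- c(NA_character_, tag_index$tags, NA_character_)
  out <- list()
  for (i in seq_len(length(bounds) - 1L)) {
    lo <- bounds[i]; hi <- bounds[i + 1L]
    out[[length(out) + 1L]] <- structure(
      list(kind = "range",
           gt = if (is.na(lo)) NULL else lo,
           lte = if (is.na(hi)) NULL else hi),
      class = "gnv_chunk")
  }
  # drop an empty tail chunk (last landmark == last variant)
  n <- length(proj$variant_ids)
  if (length(tag_index$tags) && tag_index$tags[length(tag_index$tags)] == proj$variant_ids[n])
    out <- out[-length(out)]
  out
}

# resolve a chunk descriptor to the variant IDs it covers, given the
# project's scan-ordered ID vector
chunk_ids <- function(chunk, ids_in_scan_order) {
  if (chunk$kind == "in") return(chunk$ids)
  lo <- if (is.null(chunk$gt)) 0L else match(chunk$gt, ids_in_scan_order)
  hi <- if (is.null(chunk$lte)) length(ids_in_scan_order) else match(chunk$lte, ids_in_scan_order)
  if (is.na(lo) || is.na(hi)) stop("stale tag index: landmark not found; rebuild required")
  if (hi <= lo) return(character())
  ids_in_scan_order[(lo + 1L):hi]
}

# union of effect/gene annotations for a set of variants across a
# project's runs; NULL when no run of the project carries annotations
project_annotations <- function(store, project_id, ids) {
  proj <- get_project(store, project_id)
  anns <- list()
  annotated <- FALSE
  for (r in proj$runs) {
    run <- get_run(store, project_id, r)
    if (!is.null(run$annotation_style) && run$annotation_style != "none") annotated <- TRUE
    if (!is.null(run$ann) && nrow(run$ann)) anns[[length(anns) + 1L]] <- run$ann
  }
  if (!annotated) return(NULL)
  eff <- setNames(vector("list", length(ids)), ids)
  gen <- setNames(vector("list", length(ids)), ids)
  for (a in anns) {
    sub <- a[a$variant_id %in% ids, ]
    for (i in seq_len(nrow(sub))) {
      vid <- sub$variant_id[i]
      eff[[vid]] <- union(eff[[vid]], sub$effects[[i]])
      gen[[vid]] <- union(gen[[vid]], sub$genes[[i]])
    }
  }
  list(effects = eff, genes = gen)
}

bump_project_version <- function(store, project_id) {
  store$data$projects[[project_id]]$version <-
    (store$data$projects[[project_id]]$version %||% 0L) + 1L
  # orphaned cache entries for this project are purged eagerly
  keys <- names(store$data$cache) %||% character()
  mine <- startsWith(keys, paste0(project_id, "\x1f"))
  store$data$cache[keys[mine]] <- NULL
  invisible(store)
}
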