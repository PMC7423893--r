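#' Construct a gene-set collection
#'
#' Shared container for pathway databases and query-set batches: named gene
#' sets with optional descriptions and an optional parent/child hierarchy
#' (Reactome-style).
#'
#' @param sets named list of character vectors (names are set ids).
#' @param descriptions optional character vector parallel to `sets`.
#' @param hierarchy optional data.frame with columns `parent`, `child`
#'   referencing set ids; must be acyclic.
#' @return An object of class `geneset_collection`.
#' @export
geneset_collection <- function(sets, descriptions = NULL, hierarchy = NULL) {
  if (length(sets) > 0L &&
      (is.null(names(sets)) || any(names(sets) == "") ||
         any(is.na(names(sets)))))
    stop("every gene set needs a non-empty id")
  if (anyDuplicated(names(sets)))
    stop("duplicate gene-set ids: ",
         paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "))
  sets <- lapply(sets, function(s) unique(as.character(s)))
  if (is.null(descriptions)) descriptions <- names(sets)
  descriptions <- stats::setNames(as.character(descriptions), names(sets))
  if (!is.null(hierarchy)) {
    hierarchy <- data.frame(parent = as.character(hierarchy[[1L]]),
                            child = as.character(hierarchy[[2L]]),
                            stringsAsFactors = FALSE)
    ids <- names(sets)
    bad <- setdiff(c(hierarchy$parent, hierarchy$child), ids)
    if (length(bad) > 0L)
      stop("hierarchy references unknown set ids: ",
           paste(utils::head(bad, 5L), collapse = ", "))
    g <- igraph::graph_from_data_frame(hierarchy, directed = TRUE)
    if (!igraph::is_dag(g)) stop("hierarchy contains a cycle")
  }
  obj <- list(sets = sets, descriptions = descriptions, hierarchy = hierarchy)
  class(obj) <- "geneset_collection"
  obj
}

#' @export
print.geneset_collection <- function(x, ...) {
  sz <- lengths(x$sets)
  cat(sprintf("geneset collection: %d sets, mean size %.1f%s\n",
              length(x$sets), if (length(sz)) mean(sz) else 0,
              if (is.null(x$hierarchy)) "" else ", with hierarchy"))
  invisible(x)
}

#' Load gene sets from a GMT or long-format TSV file
#'
#' GMT is the de-facto standard for pathway collections:
#' `id<TAB>description<TAB>gene1<TAB>gene2...`.  A two-column
#' `set_id<TAB>gene` long table is accepted as an alternate dialect
#' (`format = "long"`, or auto-detected when every line has exactly two
#' fields).
#'
#' @param path input file.
#' @param format `"auto"` (default), `"gmt"` or `"long"`.
#' @return A [geneset_collection()] (no hierarchy).
#' @export
load_gene_sets <- function(path, format = c("auto", "gmt", "long")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read gene-set file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  if (length(lines) == 0L) stop("gene-set file is empty: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (format == "auto")
    format <- if (all(lengths(fields) == 2L)) "long" else "gmt"
  if (format == "long") {
    ids <- vapply(fields, `[`, "", 1L)
    genes <- vapply(fields, `[`, "", 2L)
    sets <- split(genes, factor(ids, levels = unique(ids)))
    return(geneset_collection(lapply(sets, unique)))
  }
  short <- lengths(fields) < 3L
  if (any(short))
    stop("GMT line(s) with fewer than 3 fields: line ",
         paste(utils::head(which(short), 5L), collapse = ", "))
  ids <- vapply(fields, `[`, "", 1L)
  if (anyDuplicated(ids))
    stop("duplicate gene-set ids in GMT: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  desc <- vapply(fields, `[`, "", 2L)
  sets <- lapply(fields, function(f) f[-(1:2)])
  ndup <- sum(vapply(sets, anyDuplicated, 0L) > 0L)
  if (ndup > 0L)
    warning(ndup, " set(s) contained duplicate genes; deduplicated")
  geneset_collection(stats::setNames(lapply(sets, unique), ids),
                     descriptions = desc)
}

#' Load a parent/child pathway-hierarchy table
#'
#' Two-column TSV `parent_id<TAB>child_id`, the shape of Reactome's
#' pathway-relation file.
#'
#' @param path input TSV.
#' @return data.frame with columns `parent`, `child`.
#' @export
load_hierarchy <- function(path) {
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(tab) < 2L) stop("hierarchy file must have two columns")
  data.frame(parent = tab[[1L]], child = tab[[2L]], stringsAsFactors = FALSE)
}

#' Attach a hierarchy to a collection
#'
#' @param collection a `geneset_collection`.
#' @param hierarchy data.frame (parent, child) as from [load_hierarchy()].
#' @return the collection with the hierarchy attached.
#' @export
set_hierarchy <- function(collection, hierarchy) {
  geneset_collection(collection$sets, collection$descriptions, hierarchy)
}

#' Collapse a deep pathway hierarchy into broader pathways
#'
#' Deeply hierarchical collections such as Reactome contain many tiny,
#' highly specific leaf pathways.  This merges (set union) every leaf below
#' a size threshold into its parent and removes it, iterating and raising
#' the threshold one gene at a time, until the mean set size reaches
#' `target_mean_size` (chosen so the collection resembles KEGG, roughly 80
#' genes per pathway) or no further merge is possible.  Sets below the
#' threshold with no parent cannot be merged and are kept, flagged.
#'
#' @param collection a `geneset_collection` with a hierarchy.
#' @param size_threshold starting size threshold: leaves smaller than this
#'   are merged upward.
#' @param target_mean_size stop once mean set size reaches this.
#' @return A flat `geneset_collection` (hierarchy removed) with attribute
#'   `"unmergeable"`: ids of below-threshold sets that had no parent.
#' @export
collapse_hierarchy <- function(collection, size_threshold, target_mean_size) {
  stopifnot(inherits(collection, "geneset_collection"))
  h <- collection$hierarchy
  if (is.null(h)) {
    out <- geneset_collection(collection$sets, collection$descriptions)
    attr(out, "unmergeable") <-
      names(collection$sets)[lengths(collection$sets) < size_threshold]
    return(out)
  }
  sets <- collection$sets
  # first-listed parent wins for multi-parent children
  parent_of <- h$parent[!duplicated(h$child)]
  names(parent_of) <- h$child[!duplicated(h$child)]
  thr <- size_threshold
  repeat {
    if (length(sets) > 0L && mean(lengths(sets)) >= target_mean_size) break
    ids <- names(sets)
    parent_of <- parent_of[names(parent_of) %in% ids &
                           parent_of %in% ids]
    leaves <- setdiff(ids, unique(parent_of))          # not a parent of anyone
    cand <- leaves[lengths(sets[leaves]) < thr & leaves %in% names(parent_of)]
    if (length(cand) == 0L) {
      if (length(parent_of) == 0L) break               # nothing mergeable ever
      thr <- thr + 1L
      next
    }
    for (id in cand) {
      p <- parent_of[[id]]
      sets[[p]] <- unique(c(sets[[p]], sets[[id]]))
    }
    sets <- sets[setdiff(names(sets), cand)]
  }
  out <- geneset_collection(sets, collection$descriptions[names(sets)])
  flagged <- names(sets)[lengths(sets) < size_threshold &
                         !(names(sets) %in% names(parent_of))]
  attr(out, "unmergeable") <- flagged
  out
}

#' Write a collection in GMT format
#'
#' @param collection a `geneset_collection`.
#' @param path output path.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "geneset_collection"))
  lines <- vapply(names(collection$sets), function(id) {
    paste(c(id, collection$descriptions[[id]], collection$sets[[id]]),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Map a query gene set onto the network universe
#'
#' Query lists routinely contain genes (e.g. proteome identifiers) that are
#' not nodes of the association network; those can carry no links and are
#' set aside before testing.
#'
#' @param query character vector of gene ids (or a single set from a
#'   collection).
#' @param network a `crosstalk_network`.
#' @return Object of class `mapped_query`: list with `original`, `mapped`
#'   (members present in the network) and `dropped`.
#' @export
map_query <- function(query, network) {
  query <- unique(as.character(query))
  inside <- query %in% network$genes
  if (!any(inside)) stop("query has no network support")
  if (any(!inside))
    message(sum(!inside), " query gene(s) absent from the network, dropped")
  out <- list(original = query, mapped = query[inside],
              dropped = query[!inside])
  class(out) <- "mapped_query"
  out
}
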