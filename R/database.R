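# Sketch database serialization. The file stores the sketch elements and
# metadata only; the ternary search tree and bloom prefilter are rebuilt
# deterministically on load (tree layout is an implementation detail; the
# elements are the canonical content). Format: a single JSON document,
# gzip-compressed when the path ends in .gz.
#
# Header layout (field order as written):
#   format      "ktsketch-db"
#   version     integer, currently 1
#   kmax        integer
#   k_range     integer array, ascending
#   m           integer (requested sketch size)
#   hash_seed   integer (the shared hash-order seed)
#   canonical   boolean
#   bloom_fp    double
#   tree_seed   integer
#   datasets    array of {id, n_elements, cardinalities{k: count}}
# Payload:
#   elements    object: dataset id -> array of kmax-mer strings, in sketch
#               order (ascending by hash value, lexicographic tie-break)

.DB_FORMAT <- "ktsketch-db"
.DB_VERSION <- 1L

#' Save a sketch index as a database file
#'
#' One database serves all `k <= kmax`: the payload size is independent
#' of how many k values are later queried, because only the kmax-mer
#' sketch elements are stored and smaller k are reached by prefix
#' truncation.
#'
#' @param index a [build_index()] result.
#' @param path output path; `.gz` triggers compression.
#' @return `path`, invisibly.
#' @export
save_database <- function(index, path) {
  stopifnot(inherits(index, "ktst_index"))
  datasets <- lapply(index$sketches, function(s)
    list(id = s$dataset_id, n_elements = length(s$elements),
         cardinalities = as.list(s$cardinalities)))
  elements <- setNames(lapply(index$sketches, `[[`, "elements"),
                       index$dataset_ids)
  doc <- list(format = .DB_FORMAT, version = .DB_VERSION,
              kmax = index$kmax, k_range = index$k_range,
              m = index$sketches[[1]]$m, hash_seed = index$seed,
              canonical = index$canonical, bloom_fp = index$bloom_fp,
              tree_seed = index$tree_seed, datasets = datasets,
              elements = elements)
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeLines(json, con)
  invisible(path)
}

#' Load a sketch database
#'
#' Rebuilds the in-memory index (tree and prefilter) from the stored
#' elements; loading then querying gives cell-for-cell the same results
#' as querying the index that was saved.
#'
#' @param path a file written by [save_database()].
#' @return a [build_index()]-equivalent `ktst_index`.
#' @export
load_database <- function(path) {
  if (!file.exists(path)) stop("cannot read '", path, "': no such file")
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  doc <- jsonlite::fromJSON(paste(readLines(con, warn = FALSE),
                                  collapse = "\n"),
                            simplifyVector = TRUE,
                            simplifyDataFrame = FALSE)
  if (!identical(doc$format, .DB_FORMAT))
    stop("'", path, "' is not a ", .DB_FORMAT, " file")
  if (!identical(as.integer(doc$version), .DB_VERSION))
    stop("database version ", doc$version,
         " is not supported by this build (expected ", .DB_VERSION, ")")
  order <- hash_order(doc$hash_seed)
  sketches <- lapply(doc$datasets, function(d) {
    el <- as.character(doc$elements[[d$id]])
    cards <- unlist(d$cardinalities)
    if (is.null(cards)) cards <- setNames(numeric(0), character(0))
    structure(list(dataset_id = d$id, kmax = as.integer(doc$kmax),
                   m = as.integer(doc$m), elements = el,
                   hashes = hash_kmer(el, order),
                   cardinalities = cards,
                   seed = as.integer(doc$hash_seed),
                   canonical = isTRUE(doc$canonical),
                   n_windows = NA_real_, n_skipped = NA_real_),
              class = "argmin_sketch")
  })
  build_index(sketches, k_range = as.integer(doc$k_range),
              bloom_fp = as.numeric(doc$bloom_fp),
              tree_seed = as.integer(doc$tree_seed))
}
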