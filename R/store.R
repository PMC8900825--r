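#' Validated campaign document store
#'
#' A small embedded document store backing a screening campaign: schema-less
#' JSON documents grouped into collections, with a per-collection validator
#' that checks required keys and their types on every insert. Documents are
#' persisted as JSON lines (one document per line, tagged with its
#' collection), one file per account, so a campaign's full metadata trail is
#' a single plain-text file.
#'
#' The implemented collections are `Plates`, `Wells` and `Libraries`
#' (campaign documents live in an internal `Campaigns` collection managed
#' through [create_campaign()]). An insert is permitted only if every
#' required key exists with the correct type; extra keys are always allowed.
#'
#' @param path Path of the store file; created empty if absent.
#' @return An object of class `campaign_store`.
#' @seealso [insert_document()], [create_campaign()], [advance_stage()]
#' @export
#' @examples
#' store <- campaign_store(tempfile(fileext = ".jsonl"))
#' insert_document(store, "Plates",
#'                 list(barcode = "XT1001", kind = "crystal",
#'                      campaign = "demo"))
campaign_store <- function(path) {
  if (!file.exists(path)) {
    file.create(path)
  }
  structure(list(path = path), class = "campaign_store")
}

#' @export
print.campaign_store <- function(x, ...) {
  docs <- .store_read(x)
  colls <- vapply(docs, function(d) d$collection, character(1))
  cat("Campaign document store at", x$path, "\n")
  if (length(colls)) print(table(colls)) else cat("(empty)\n")
  invisible(x)
}

# required keys and semantic types per collection; every required key has a
# declared type so the validator is total
.collection_schemas <- list(
  Plates    = list(barcode = "character", kind = "character",
                   campaign = "character"),
  Wells     = list(plate_barcode = "character", well = "character",
                   campaign = "character"),
  Libraries = list(name = "character", plate_format = "numeric"),
  Campaigns = list(name = "character", account = "character",
                   created = "character", stage_status = "list")
)

#' Collection schemas
#'
#' Returns the required keys and their semantic types for each document
#' collection. These are the keys the insert validator enforces; documents
#' may always carry additional keys.
#'
#' @return Named list: collection -> named character vector of key types.
#' @export
collection_schemas <- function() .collection_schemas[c("Plates", "Wells",
                                                       "Libraries")]

.check_type <- function(value, type) {
  switch(type,
         character = is.character(value) && length(value) == 1L,
         numeric   = is.numeric(value) && length(value) == 1L,
         logical   = is.logical(value) && length(value) == 1L,
         list      = is.list(value),
         FALSE)
}

#' Validate a document against its collection schema
#'
#' Total over all inputs: either returns invisibly or signals an error
#' naming the first offending key — never a silent partial accept.
#'
#' @param collection Collection name.
#' @param doc Named list document.
#' @return `TRUE` invisibly if valid.
#' @export
validate_document <- function(collection, doc) {
  schema <- .collection_schemas[[collection]]
  if (is.null(schema)) {
    stop("unknown collection '", collection, "'", call. = FALSE)
  }
  if (!is.list(doc) || (length(doc) && is.null(names(doc)))) {
    stop("document must be a named list", call. = FALSE)
  }
  for (key in names(schema)) {
    if (!key %in% names(doc) || is.null(doc[[key]])) {
      stop("document is missing required key '", key, "' for collection ",
           collection, call. = FALSE)
    }
    if (!.check_type(doc[[key]], schema[[key]])) {
      stop("key '", key, "' has the wrong type for collection ", collection,
           " (expected ", schema[[key]], ")", call. = FALSE)
    }
  }
  invisible(TRUE)
}

.store_read <- function(store) {
  lines <- readLines(store$path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  lapply(lines, function(l) jsonlite::fromJSON(l, simplifyVector = TRUE,
                                               simplifyDataFrame = FALSE))
}

.store_append <- function(store, record) {
  line <- jsonlite::toJSON(record, auto_unbox = TRUE, null = "null")
  cat(line, "\n", sep = "", file = store$path, append = TRUE)
}

.store_rewrite <- function(store, records) {
  lines <- vapply(records, function(r) {
    as.character(jsonlite::toJSON(r, auto_unbox = TRUE, null = "null"))
  }, character(1))
  writeLines(lines, store$path)
}

.next_id <- function(store, collection) {
  docs <- .store_read(store)
  n <- sum(vapply(docs, function(d) d$collection == collection, logical(1)))
  sprintf("%s-%06d", collection, n + 1L)
}

#' Insert a document into a collection
#'
#' The document is persisted only if it passes the collection's validator
#' ([validate_document()]); otherwise an error names the offending key and
#' nothing is written.
#'
#' @param store A [campaign_store()].
#' @param collection One of `"Plates"`, `"Wells"`, `"Libraries"`.
#' @param doc Named list with at least the schema's required keys.
#' @return The stored document id (string).
#' @export
insert_document <- function(store, collection, doc) {
  stopifnot(inherits(store, "campaign_store"))
  if (!collection %in% names(collection_schemas())) {
    stop("unknown collection '", collection, "' (expected one of ",
         paste(names(collection_schemas()), collapse = ", "), ")",
         call. = FALSE)
  }
  validate_document(collection, doc)
  id <- .next_id(store, collection)
  .store_append(store, list(collection = collection, id = id, doc = doc))
  id
}

#' Fetch and list stored documents
#'
#' @param store A [campaign_store()].
#' @param id A stored document id.
#' @param collection Collection name.
#' @return `fetch_document()`: the stored document (named list).
#'   `list_documents()`: list of documents in insert order.
#' @export
fetch_document <- function(store, id) {
  docs <- .store_read(store)
  for (d in docs) {
    if (identical(d$id, id)) return(d$doc)
  }
  stop("no document with id '", id, "'", call. = FALSE)
}

#' @rdname fetch_document
#' @export
list_documents <- function(store, collection) {
  docs <- .store_read(store)
  keep <- vapply(docs, function(d) identical(d$collection, collection),
                 logical(1))
  lapply(docs[keep], function(d) d$doc)
}
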