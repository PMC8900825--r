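#' Campaign lifecycle and stage state machine
#'
#' A screening campaign progresses through five consecutive stages:
#' `Plates` (register crystallization plates), `Cryo` (optional
#' cryoprotectant dispensing), `Soaking`, `Redissolve` (optional DMSO-free
#' soaking variant) and `Fishing` (crystal harvesting). Each stage is
#' `pending`, `in_progress`, `done` or `skipped`; only the optional stages
#' `Cryo` and `Redissolve` may be skipped, and a stage can start only after
#' every earlier mandatory stage is done. The campaign name is the unique
#' identifier within a store.
#'
#' @param store A [campaign_store()].
#' @param name Campaign name (unique, non-empty).
#' @param account Group account the campaign belongs to.
#' @return `create_campaign()` and `advance_stage()` return the campaign
#'   document: a list with `name`, `account`, `created` and `stage_status`
#'   (named list stage -> status).
#' @name campaign-lifecycle
NULL

.stages <- c("Plates", "Cryo", "Soaking", "Redissolve", "Fishing")
.optional_stages <- c("Cryo", "Redissolve")
.statuses <- c("pending", "in_progress", "done", "skipped")

#' Campaign stage names
#'
#' @return Character vector of the five stages in pipeline order.
#' @export
campaign_stages <- function() .stages

.find_campaign <- function(store, name) {
  docs <- .store_read(store)
  for (i in seq_along(docs)) {
    if (identical(docs[[i]]$collection, "Campaigns") &&
        identical(docs[[i]]$doc$name, name)) {
      return(list(index = i, record = docs[[i]], all = docs))
    }
  }
  NULL
}

#' @rdname campaign-lifecycle
#' @export
create_campaign <- function(store, name, account = "e00000") {
  stopifnot(inherits(store, "campaign_store"))
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop("campaign name must be a non-empty string", call. = FALSE)
  }
  if (!is.null(.find_campaign(store, name))) {
    stop("campaign name '", name, "' already exists; ",
         "the name is the unique identifier", call. = FALSE)
  }
  status <- stats::setNames(as.list(rep("pending", length(.stages))), .stages)
  doc <- list(name = name, account = account,
              created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
              stage_status = status)
  validate_document("Campaigns", doc)
  id <- .next_id(store, "Campaigns")
  .store_append(store, list(collection = "Campaigns", id = id, doc = doc))
  doc
}

#' @rdname campaign-lifecycle
#' @export
get_campaign <- function(store, name) {
  found <- .find_campaign(store, name)
  if (is.null(found)) {
    stop("unknown campaign '", name, "'", call. = FALSE)
  }
  found$record$doc
}

#' @rdname campaign-lifecycle
#' @param account Optional account filter.
#' @export
list_campaigns <- function(store, account = NULL) {
  docs <- list_documents_internal(store, "Campaigns")
  if (!is.null(account)) {
    docs <- Filter(function(d) identical(d$account, account), docs)
  }
  vapply(docs, function(d) d$name, character(1))
}

# Campaigns is internal: not exposed through insert_document()
list_documents_internal <- function(store, collection) {
  docs <- .store_read(store)
  keep <- vapply(docs, function(d) identical(d$collection, collection),
                 logical(1))
  lapply(docs[keep], function(d) d$doc)
}

#' Register a crystallization plate to a campaign
#'
#' Inserts a plate document into the `Plates` collection and moves the
#' campaign's `Plates` stage to `in_progress` if it was pending. Barcodes
#' must be unique within a campaign.
#'
#' @param store A [campaign_store()].
#' @param campaign Campaign name.
#' @param barcode Plate barcode (typed or scanned).
#' @param kind `"crystal"` or `"library"`.
#' @return The stored plate document id.
#' @export
register_plate <- function(store, campaign, barcode,
                           kind = c("crystal", "library")) {
  kind <- match.arg(kind)
  found <- .find_campaign(store, campaign)
  if (is.null(found)) {
    stop("unknown campaign '", campaign, "'", call. = FALSE)
  }
  if (!is.character(barcode) || length(barcode) != 1L || !nzchar(barcode)) {
    stop("plate barcode must be a non-empty string", call. = FALSE)
  }
  plates <- list_documents(store, "Plates")
  for (p in plates) {
    if (identical(p$campaign, campaign) && identical(p$barcode, barcode)) {
      stop("plate barcode '", barcode, "' already registered to campaign '",
           campaign, "'", call. = FALSE)
    }
  }
  id <- insert_document(store, "Plates",
                        list(barcode = barcode, kind = kind,
                             campaign = campaign))
  if (identical(found$record$doc$stage_status$Plates, "pending")) {
    advance_stage(store, campaign, "Plates", "in_progress")
  }
  id
}

#' @rdname campaign-lifecycle
#' @param stage One of the five stage names.
#' @param to Target status: `"in_progress"`, `"done"`, or `"skipped"` (the
#'   optional stages only).
#' @export
advance_stage <- function(store, campaign, stage, to) {
  found <- .find_campaign(store, campaign)
  if (is.null(found)) {
    stop("unknown campaign '", campaign, "'", call. = FALSE)
  }
  if (!stage %in% .stages) {
    stop("unknown stage '", stage, "' (stages: ",
         paste(.stages, collapse = " -> "), ")", call. = FALSE)
  }
  if (!to %in% .statuses) {
    stop("unknown status '", to, "'", call. = FALSE)
  }
  doc <- found$record$doc
  from <- doc$stage_status[[stage]]
  if (to == "pending") {
    stop("stages cannot be reset to pending", call. = FALSE)
  }
  if (from %in% c("done", "skipped")) {
    stop("stage ", stage, " is already ", from, call. = FALSE)
  }
  if (to == "skipped" && !stage %in% .optional_stages) {
    stop("stage ", stage, " is mandatory and cannot be skipped",
         call. = FALSE)
  }
  if (to %in% c("in_progress", "done")) {
    earlier <- .stages[seq_len(match(stage, .stages) - 1L)]
    earlier_mand <- setdiff(earlier, .optional_stages)
    not_done <- earlier_mand[vapply(earlier_mand, function(s) {
      !identical(doc$stage_status[[s]], "done")
    }, logical(1))]
    if (length(not_done)) {
      stop("cannot set ", stage, " to ", to, " while earlier stage ",
           not_done[1], " is ", doc$stage_status[[not_done[1]]],
           call. = FALSE)
    }
  }
  doc$stage_status[[stage]] <- to
  records <- found$all
  records[[found$index]]$doc <- doc
  .store_rewrite(store, records)
  doc
}
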