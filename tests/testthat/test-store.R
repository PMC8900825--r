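new_store <- function() campaign_store(tempfile(fileext = ".jsonl"))

test_that("insert validates required keys and types, naming the key", {
  store <- new_store()
  id <- insert_document(store, "Plates",
                        list(barcode = "XT1", kind = "crystal",
                             campaign = "c1"))
  expect_match(id, "^Plates-")
  expect_error(
    insert_document(store, "Plates", list(kind = "crystal", campaign = "c1")),
    "'barcode'")
  expect_error(
    insert_document(store, "Libraries",
                    list(name = "lib", plate_format = "384")),
    "'plate_format' has the wrong type")
  expect_error(insert_document(store, "Pucks", list(a = 1)),
               "unknown collection")
})

test_that("store round-trips documents and allows extra keys", {
  store <- new_store()
  doc <- list(plate_barcode = "XT1", well = "B7c", campaign = "c1",
              x_mm = 0.25, note = "skin on drop")
  id <- insert_document(store, "Wells", doc)
  expect_equal(fetch_document(store, id), doc)
  expect_equal(list_documents(store, "Wells"), list(doc))
  expect_error(fetch_document(store, "Wells-999999"), "no document")
})

test_that("validator is total: every random document is accepted or rejected with a named key", {
  store <- new_store()
  set.seed(404)
  schemas <- collection_schemas()
  pool <- list("text", 3.14, TRUE, list(a = 1), NULL)
  for (coll in names(schemas)) {
    req <- names(schemas[[coll]])
    for (i in 1:100) {
      doc <- list(barcode = "B", kind = "crystal", campaign = "c",
                  plate_barcode = "P", well = "A1a", name = "n",
                  plate_format = 384)[req]
      names(doc) <- req
      # randomly drop keys, corrupt types, add extras
      for (key in req) {
        u <- runif(1)
        if (u < 0.3) doc[[key]] <- NULL
        else if (u < 0.6) doc[[key]] <- pool[[sample.int(5, 1)]]
      }
      if (runif(1) < 0.3) doc$extra <- sample(pool[1:4], 1)[[1]]
      outcome <- tryCatch(
        list(ok = TRUE, id = insert_document(store, coll, doc)),
        error = function(e) list(ok = FALSE, msg = conditionMessage(e)))
      if (outcome$ok) {
        expect_true(nzchar(outcome$id))
      } else {
        named <- vapply(req, function(k) grepl(paste0("'", k, "'"),
                                               outcome$msg), logical(1))
        expect_true(any(named), info = outcome$msg)
      }
    }
  }
})

test_that("campaigns are created with five pending stages and unique names", {
  store <- new_store()
  doc <- create_campaign(store, "camp-1", account = "e12345")
  expect_equal(names(doc$stage_status), campaign_stages())
  expect_true(all(unlist(doc$stage_status) == "pending"))
  expect_error(create_campaign(store, "camp-1"), "unique identifier")
  expect_error(create_campaign(store, ""), "non-empty")
  create_campaign(store, "camp-2", account = "e12345")
  create_campaign(store, "other", account = "e99999")
  expect_setequal(list_campaigns(store, "e12345"), c("camp-1", "camp-2"))
})

test_that("plate registration starts the Plates stage and rejects duplicates", {
  store <- new_store()
  create_campaign(store, "c1")
  register_plate(store, "c1", "XT100")
  expect_equal(get_campaign(store, "c1")$stage_status$Plates, "in_progress")
  expect_error(register_plate(store, "c1", "XT100"), "already registered")
  expect_error(register_plate(store, "nope", "XT101"), "unknown campaign")
  # same barcode in another campaign is fine
  create_campaign(store, "c2")
  id2 <- register_plate(store, "c2", "XT100")
  expect_match(id2, "^Plates-")
})

test_that("stage order is enforced; optional stages may be skipped", {
  store <- new_store()
  create_campaign(store, "c1")
  register_plate(store, "c1", "XT1")
  expect_error(advance_stage(store, "c1", "Soaking", "done"),
               "earlier stage Plates")
  advance_stage(store, "c1", "Plates", "done")
  doc <- advance_stage(store, "c1", "Cryo", "skipped")
  expect_equal(doc$stage_status$Cryo, "skipped")
  advance_stage(store, "c1", "Soaking", "in_progress")
  advance_stage(store, "c1", "Soaking", "done")
  doc <- advance_stage(store, "c1", "Redissolve", "done")
  expect_equal(doc$stage_status$Redissolve, "done")
  advance_stage(store, "c1", "Fishing", "done")
  expect_error(advance_stage(store, "c1", "Soaking", "in_progress"),
               "already done")
  expect_error(advance_stage(store, "c1", "Plates", "pending"),
               "cannot be reset")
})

test_that("mandatory stages cannot be skipped, in any state", {
  store <- new_store()
  create_campaign(store, "c1")
  for (stage in setdiff(campaign_stages(), c("Cryo", "Redissolve"))) {
    expect_error(advance_stage(store, "c1", stage, "skipped"),
                 "mandatory")
  }
})

test_that("no call sequence makes a later mandatory stage done before an earlier one", {
  set.seed(11)
  mandatory <- setdiff(campaign_stages(), c("Cryo", "Redissolve"))
  for (rep in 1:20) {
    store <- new_store()
    create_campaign(store, "c")
    for (step in 1:15) {
      stage <- sample(campaign_stages(), 1)
      to <- sample(c("in_progress", "done", "skipped"), 1)
      try(advance_stage(store, "c", stage, to), silent = TRUE)
      status <- unlist(get_campaign(store, "c")$stage_status[mandatory])
      done <- which(status == "done")
      pending <- which(status == "pending")
      if (length(done) && length(pending)) {
        expect_true(max(pending) > max(done))
      }
    }
  }
})
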