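test_that("pixel clicks convert linearly to mm offsets and clamp", {
  expect_equal(pixel_to_offset(100, 100, c(100, 100), 0.01),
               data.frame(x_mm = 0, y_mm = 0, clamped = FALSE))
  got <- pixel_to_offset(150, 80, c(100, 100), 0.01)
  expect_equal(got$x_mm, 0.5)
  expect_equal(got$y_mm, -0.2)
  expect_false(got$clamped)
  half <- plate_geometry()$crystal$drop_half_extent_mm
  far <- pixel_to_offset(1e5, -1e5, c(100, 100), 0.01)
  expect_equal(far$x_mm, half)
  expect_equal(far$y_mm, -half)
  expect_true(far$clamped)
  expect_error(pixel_to_offset(1, 1, c(0, 0), 0))
})

test_that("transfer lists carry source wells, offsets and input order", {
  lib <- toy_library(c("Oc1ccccc1", "CCN", "c1ccncc1"))
  soaks <- plan_soaks(
    data.frame(plate_barcode = "XT-01", well = c("B2a", "A1c"),
               x_mm = c(0.3, 0), y_mm = c(-0.2, 0)),
    c("FT01", "FT03"), 25)
  tl <- build_transfer_list(soaks, lib)
  expect_s3_class(tl, "transfer_list")
  expect_equal(nrow(tl), 2)
  expect_equal(tl$source_well, c("A1", "A3"))
  expect_equal(tl$dest_well, c("B2", "A1"))  # drop encoded in the offsets
  centre_a <- plate_geometry()$crystal$drop_centre_offset_mm$a
  expect_equal(tl$dest_x_offset[1], centre_a[1] + 0.3)
  expect_equal(tl$dest_y_offset[1], centre_a[2] - 0.2)
})

test_that("transfer volumes must be positive droplet-quantum multiples", {
  lib <- toy_library(c("Oc1ccccc1"))
  tgt <- data.frame(plate_barcode = "XT-01", well = "A1a")
  expect_error(plan_soaks(tgt, "FT01", 26), "not a multiple of the 2.5")
  expect_error(plan_soaks(tgt, "FT01", 0), "positive")
  expect_error(plan_soaks(tgt, "FT01", -25), "positive")
  expect_silent(plan_soaks(tgt, "FT01", 27.5))
})

test_that("unknown fragments and duplicate destination drops are rejected", {
  lib <- toy_library(c("Oc1ccccc1", "CCN"))
  soaks <- data.frame(plate_barcode = "XT-01", well = c("A1a", "A1a"),
                      fragment_id = c("FT01", "FT02"), transfer_nl = 25)
  expect_error(build_transfer_list(soaks, lib), "duplicate destination")
  soaks2 <- data.frame(plate_barcode = "XT-01", well = "A1a",
                       fragment_id = "FT99", transfer_nl = 25)
  expect_error(build_transfer_list(soaks2, lib), "FT99")
})

test_that("random soak plans conserve volume and length", {
  lib <- toy_library(toy_smiles)
  q <- droplet_quantum()
  set.seed(99)
  for (rep in 1:20) {
    n <- sample(5:50, 1)
    soaks <- toy_soaks(lib, n, transfer_nl = q * sample(1:40, n,
                                                        replace = TRUE))
    tl <- build_transfer_list(soaks, lib)
    expect_equal(nrow(tl), n)
    # conservation: total drawn per source well = quantum x droplet count
    per_source <- tapply(tl$transfer_nl, tl$source_well, sum)
    droplets <- tapply(tl$transfer_nl / q, tl$source_well, sum)
    expect_equal(as.numeric(per_source), as.numeric(droplets) * q)
    expect_equal(sum(tl$transfer_nl), sum(soaks$transfer_nl))
  }
})

test_that("transfer list CSV round-trips exactly", {
  lib <- toy_library(toy_smiles)
  soaks <- toy_soaks(lib, 12)
  soaks$x_mm <- round(runif(12, -1, 1), 3)
  soaks$y_mm <- round(runif(12, -1, 1), 3)
  tl <- build_transfer_list(soaks, lib)
  f <- tempfile(fileext = ".csv")
  write_transfer_list(tl, f)
  expect_identical(read_transfer_list(f), tl)
  hdr <- readLines(f, n = 1)
  expect_match(hdr, "^Source Plate Barcode,Source Well,Destination")
})

test_that("DMSO percentage follows the dilution formula", {
  expect_equal(dmso_percent(475, 25), 5)
  expect_equal(dmso_percent(100, 100), 50)
  expect_equal(dmso_percent(900, 100), 10)
  expect_error(dmso_percent(0, 25), "positive")
  expect_error(dmso_percent(500, -1), "positive")
  # strictly increasing in transfer volume, bounded in (0, 100)
  v <- dmso_percent(500, seq(2.5, 5000, by = 2.5))
  expect_true(all(diff(v) > 0))
  expect_true(all(v > 0 & v < 100))
})

test_that("soak timer floors to minutes and freezes at soak_stop", {
  lib <- toy_library(c("Oc1ccccc1"))
  rec <- start_soak(toy_soaks(lib, 1),
                    as.POSIXct("2024-01-01 10:00:00", tz = "UTC"))
  now <- as.POSIXct("2024-01-01 10:45:59", tz = "UTC")
  expect_equal(soak_elapsed(rec, now), 45L)
  rec$soak_stop <- as.POSIXct("2024-01-01 11:30:00", tz = "UTC")
  expect_equal(soak_elapsed(rec, as.POSIXct("2024-01-01 12:00:00",
                                            tz = "UTC")), 90L)
  expect_error(soak_elapsed(rec, as.POSIXct("2023-12-31 00:00:00",
                                            tz = "UTC")), NA)  # frozen
  rec$soak_stop <- as.POSIXct(NA)
  expect_error(soak_elapsed(rec, as.POSIXct("2024-01-01 09:00:00",
                                            tz = "UTC")), "precedes")
  rec$soak_start <- as.POSIXct(NA)
  expect_error(soak_elapsed(rec), "soak_start is not set")
})

test_that("dispense reports update statuses, stop timers, list discrepancies", {
  lib <- toy_library(toy_smiles[1:3])
  rec <- start_soak(toy_soaks(lib, 3),
                    as.POSIXct("2024-01-01 10:00:00", tz = "UTC"))
  report <- data.frame(
    dest_barcode = c("XT-01", "XT-01", "XT-01", "XT-02"),
    dest_well = c("A1a", "A1b", "A1c", "A1a"),
    status = c("OK", "failed: no source volume", "OK", "OK"),
    message = c("", "no source volume", "", ""))
  out <- ingest_dispense_report(rec, report,
                                time = as.POSIXct("2024-01-01 10:30:00",
                                                  tz = "UTC"))
  expect_equal(out$records$status, c("dispensed", "failed", "dispensed"))
  expect_equal(out$records$error_msg[2], "no source volume")
  expect_true(all(!is.na(out$records$soak_stop)))
  expect_equal(soak_elapsed(out$records)[1], 30L)
  expect_equal(nrow(out$discrepancies), 1)
  expect_match(out$discrepancies$reason, "no planned soak")
  expect_error(ingest_dispense_report(rec, data.frame(a = 1)), "malformed")
})

test_that("redissolve plans fill drops row-major with a pending sheet", {
  lib <- toy_library(toy_smiles[1:3])
  out <- plan_redissolve(c("FT01", "FT02", "FT03"), "RED-01", lib)
  expect_equal(out$sheet$well, c("A1a", "A1b", "A1c"))
  expect_equal(nrow(out$transfers), 3)
  expect_equal(out$transfers$dest_plate, rep("RED-01", 3))
  expect_true(all(out$sheet$dispensed == "pending"))
  expect_true(all(out$sheet$redissolved == "pending"))
  empty <- plan_redissolve(character(0), "RED-01", lib)
  expect_equal(nrow(empty$transfers), 0)
  expect_equal(nrow(empty$sheet), 0)
  big <- rep(lib$fragments$fragment_id, length.out = 289)
  expect_error(plan_redissolve(big, "RED-01", lib), "289")
})
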