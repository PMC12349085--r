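test_that("delimited spectrum parsing honours the format and its errors", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# comment", "energy_keV,counts", "2.0,10", "2.1,12"), p)
  s <- read_spectrum(p)
  expect_s3_class(s, "xrf_spectrum")
  expect_equal(s$energy, c(2.0, 2.1))
  expect_equal(s$counts, c(10, 12))

  writeLines(c("3.0,5", "2.0,7"), p)
  expect_error(read_spectrum(p), "non-monotone energy")

  writeLines(c("2.0,5", "2.5,-1"), p)
  expect_error(read_spectrum(p), "negative counts")

  writeLines("2.0,5", p)
  expect_error(read_spectrum(p), "fewer than 2")
})

test_that("write_spectrum then read_spectrum is the identity", {
  s <- random_spectrum(100L, seed = 11L)
  p <- withr::local_tempfile(fileext = ".csv")
  write_spectrum(s, p)
  s2 <- read_spectrum(p)
  expect_identical(s2$energy, s$energy)
  expect_identical(s2$counts, s$counts)
})

test_that("EMSA XY files are read; unsupported data modes are rejected", {
  p <- withr::local_tempfile(fileext = ".msa")
  writeLines(c("#FORMAT      : EMSA/MAS Spectral Data File",
               "#VERSION     : 1.0",
               "#DATATYPE    : XY",
               "#NPOINTS     : 3",
               "#SPECTRUM    :",
               "1.50, 4", "1.60, 6", "1.70, 5",
               "#ENDOFDATA   :"), p)
  s <- read_spectrum(p)
  expect_equal(s$energy, c(1.5, 1.6, 1.7))
  expect_equal(s$counts, c(4, 6, 5))

  writeLines(c("#FORMAT : EMSA/MAS Spectral Data File",
               "#DATATYPE : Y",
               "#SPECTRUM :", "1", "2", "#ENDOFDATA :"), p)
  expect_error(read_spectrum(p), "XY")
})

test_that("manifest validation enforces columns, types and uniqueness", {
  man <- data.frame(zone_id = paste0("z", 1:6), file = "f.csv",
                    specimen_id = "sp1", site = "LAK", clade = "sponge",
                    zone_type = rep(c("fossil", "sediment"), each = 3),
                    session = "DiffAbs-2018", mineralogy = "phosphatic",
                    stringsAsFactors = FALSE)
  ok <- validate_manifest(man)
  expect_equal(nrow(ok), 6L)
  expect_equal(sum(ok$zone_type == "fossil"), 3L)
  expect_equal(sum(ok$zone_type == "sediment"), 3L)

  expect_error(validate_manifest(man[, -3]), "missing column.*specimen_id")
  bad <- man
  bad$zone_type[1] <- "matrix"
  expect_error(validate_manifest(bad), "unknown zone_type")
  dup <- rbind(man, man[1, ])
  expect_error(validate_manifest(dup), "duplicate")

  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(paste(colnames(man), collapse = ","), p)
  expect_error(read_manifest(p), "empty")
})

test_that("energy calibration recovers exact and least-squares solutions", {
  cal <- calibrate_energy(cbind(c(369.2, 640.5, 1495.8),
                                c(3.692, 6.405, 14.958)))
  expect_equal(cal$gain, 0.01, tolerance = 1e-10)
  expect_equal(cal$offset, 0, tolerance = 1e-8)

  ident <- calibrate_energy(cbind(c(3.692, 6.405), c(3.692, 6.405)))
  expect_equal(ident$gain, 1, tolerance = 1e-12)
  expect_equal(ident$offset, 0, tolerance = 1e-12)

  # non-collinear pairs: residuals must equal the normal-equations solution
  ch <- c(100, 500, 900)
  en <- c(1.1, 5.3, 9.0)
  cal2 <- calibrate_energy(cbind(ch, en))
  X <- cbind(1, ch)
  beta <- solve(t(X) %*% X, t(X) %*% en)
  expect_equal(max(abs(cal2$residuals)), max(abs(en - X %*% beta)),
               tolerance = 1e-10)
  expect_gt(max(abs(cal2$residuals)), 0)

  expect_error(calibrate_energy(cbind(369.2, 3.692)), "at least 2")
  expect_error(calibrate_energy(cbind(c(1, 1), c(2, 3))), "coincident")

  sp <- xrf_spectrum(c(100, 200, 300), c(1, 2, 3), "chan")
  sp2 <- apply_calibration(cal, sp)
  expect_equal(sp2$energy, cal$offset + cal$gain * c(100, 200, 300))
})

test_that("continuous reconstruction interpolates linearly and only in range", {
  s <- xrf_spectrum(c(2.0, 2.1, 2.3), c(10, 20, 16))
  f <- reconstruct_continuous(s)
  expect_equal(f(2.1), 20)          # exact at exported points
  expect_equal(f(2.05), 15)         # linear midpoint
  expect_error(f(1.0), "outside")
  # brute-force per-interval check
  set.seed(3)
  q <- runif(50, 2.0, 2.3)
  brute <- vapply(q, function(e) {
    i <- findInterval(e, s$energy, rightmost.closed = TRUE)
    w <- (e - s$energy[i]) / (s$energy[i + 1] - s$energy[i])
    (1 - w) * s$counts[i] + w * s$counts[i + 1]
  }, 0)
  expect_equal(f(q), brute, tolerance = 1e-12)
})

test_that("energy subsetting yields the exact window and is idempotent", {
  set.seed(5)
  e <- seq(0.2, 20.6, by = 0.01)
  s <- xrf_spectrum(e, rpois(length(e), 30))
  sub <- subset_energy(s)
  expect_equal(sub$energy[1], 1.7)
  expect_equal(sub$energy[length(sub$energy)], 18.3)
  # independent range-count oracle (+ up to 2 synthesised endpoints)
  n_inside <- sum(e >= 1.7 & e <= 18.3)
  expect_true(length(sub$energy) %in% (n_inside + 0:2))
  sub2 <- subset_energy(sub)
  expect_equal(sub2$energy, sub$energy)
  expect_equal(sub2$counts, sub$counts)

  narrow <- xrf_spectrum(c(2, 3, 4), c(1, 2, 3))
  expect_error(subset_energy(narrow), "does not cover")
})

test_that("log-standardisation matches direct arithmetic and z-scores exactly", {
  s <- xrf_spectrum(c(1, 2, 3), c(9, 99, 999))
  z <- log_standardize(s)
  expect_equal(z$counts, c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)

  # property: mean 0, population sd 1 over random spectra
  for (seed in 1:5) {
    r <- random_spectrum(80L, seed = seed)
    z <- log_standardize(r)
    expect_lt(abs(mean(z$counts)), 1e-12)
    expect_equal(sqrt(mean(z$counts^2)), 1, tolerance = 1e-12)
  }

  flat <- xrf_spectrum(c(1, 2, 3), c(5, 5, 5))
  expect_error(log_standardize(flat), "degenerate")
})

test_that("landmark grid and extraction follow the 0.02 keV protocol", {
  g <- landmark_grid()
  expect_length(g, 831L)
  expect_equal((18.3 - 1.7) / 0.02 + 1, 831)
  expect_equal(g[1], 1.7)
  expect_equal(g[831], 18.3)
  expect_equal(unique(round(diff(g), 10)), 0.02)

  # a spectrum linear in energy is reproduced exactly at the grid
  e <- seq(1.0, 19.0, by = 0.13)
  s <- xrf_spectrum(e, 2 + 3 * e)
  lv <- extract_landmarks(s)
  expect_length(lv, 831L)
  expect_equal(as.numeric(lv), 2 + 3 * g, tolerance = 1e-12)

  expect_error(extract_landmarks(xrf_spectrum(c(2, 3), c(1, 2))),
               "does not cover")
})

test_that("the formatting chain is deterministic bit-for-bit", {
  p <- withr::local_tempfile(fileext = ".csv")
  write_spectrum(random_spectrum(400L, seed = 9L), p)
  v1 <- format_spectrum(read_spectrum(p))
  v2 <- format_spectrum(read_spectrum(p))
  expect_identical(v1, v2)
  expect_length(v1, 831L)
})

test_that("landmark matrices round-trip through delimited export", {
  sc <- small_scenario()
  man <- design_manifest(sc)$manifest[1:4, ]
  vals <- t(vapply(1:4, function(i) smooth_row(i), numeric(831)))
  lm <- landmark_matrix(vals, man)
  base <- file.path(withr::local_tempdir(), "lm")
  write_landmark_matrix(lm, base)
  lm2 <- read_landmark_matrix(base)
  expect_equal(lm2$values, lm$values, ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_equal(lm2$meta$zone_id, lm$meta$zone_id)
})
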