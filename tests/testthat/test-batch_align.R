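test_that("homologous pairing follows the control design", {
  # full study design: 2 control specimens x 6 zones measured in 3 sessions
  man <- design_manifest(default_scenario())$manifest
  lm <- landmark_matrix(matrix(0, nrow(man), 831), man)
  pairs <- pair_homologous(lm, "PUMA-2021", "DiffAbs-2018")
  expect_equal(nrow(pairs), 12L)  # 36 control spectra / 3 sessions
  expect_equal(man$zone_id[pairs$row_session], pairs$zone_id)
  expect_equal(man$session[pairs$row_session], rep("PUMA-2021", 12L))
  expect_equal(man$session[pairs$row_reference], rep("DiffAbs-2018", 12L))

  # session paired with itself: identical rows
  self <- pair_homologous(lm, "DiffAbs-2018", "DiffAbs-2018")
  expect_equal(self$row_session, self$row_reference)

  # a control zone missing from one session reduces the pair count by one
  drop <- which(man$session == "PUMA-2021" &
                  man$zone_id == pairs$zone_id[1])[1]
  lm2 <- landmark_matrix(matrix(0, nrow(man) - 1L, 831), man[-drop, ])
  expect_message(
    pairs2 <- pair_homologous(lm2, "PUMA-2021", "DiffAbs-2018"),
    "without partner")
  expect_equal(nrow(pairs2), 11L)

  one <- landmark_matrix(matrix(0, 6, 831),
                         man[man$session == "DiffAbs-2018", ][1:6, ])
  expect_error(pair_homologous(one, "PUMA-2021", "DiffAbs-2018"), "absent")
})

test_that("mean delta is the landmark-wise arithmetic mean of pair differences", {
  man <- design_manifest(small_scenario())$manifest
  ctrl <- man[ave(man$zone_id, man$zone_id, FUN = length) == "3", ]
  ctrl <- ctrl[ctrl$session %in% c("DiffAbs-2018", "PUMA-2021"), ]
  ctrl <- ctrl[order(ctrl$zone_id, ctrl$session), ][1:4, ]  # 2 zones, 2 sess
  base <- rbind(smooth_row(1), smooth_row(2))
  # zone 1 offset +1 in PUMA-2021, zone 2 offset +3: mean delta must be +2
  meta <- ctrl
  vals <- matrix(0, 4, 831)
  for (i in 1:4) {
    z <- match(meta$zone_id[i], unique(meta$zone_id))
    vals[i, ] <- base[z, ] +
      if (meta$session[i] == "PUMA-2021") c(1, 3)[z] else 0
  }
  lm <- landmark_matrix(vals, meta)
  d <- compute_mean_delta(lm, session = "PUMA-2021",
                          reference_session = "DiffAbs-2018")
  expect_equal(unname(d$delta), rep(2, 831), tolerance = 1e-12)
  expect_equal(d$n_pairs, 2L)

  # identical homologous spectra give a zero delta; one pair gives itself
  lm0 <- lm
  lm0$values[meta$session == "PUMA-2021", ] <-
    lm0$values[meta$session == "DiffAbs-2018", ]
  d0 <- compute_mean_delta(lm0, session = "PUMA-2021",
                           reference_session = "DiffAbs-2018")
  expect_equal(max(abs(d0$delta)), 0)

  pairs <- pair_homologous(lm, "PUMA-2021", "DiffAbs-2018")[1, ]
  d1 <- compute_mean_delta(lm, pairs = pairs)
  expect_equal(unname(d1$delta),
               unname(lm$values[pairs$row_session, ] -
                        lm$values[pairs$row_reference, ]))
})

test_that("realignment cancels constant session offsets exactly", {
  offsets <- list("DiffAbs-2018" = rep(0, 831),
                  "PUMA-2021" = rep(2.5, 831),
                  "PUMA-2024" = rep(-1.25, 831))
  lm <- constructed_sessions(offsets, noise_sd = 0)
  al <- align_sessions(lm, "DiffAbs-2018")
  ref_rows <- which(al$matrix$meta$session == "DiffAbs-2018")
  for (s in c("PUMA-2021", "PUMA-2024")) {
    pr <- pair_homologous(al$matrix, s, "DiffAbs-2018")
    resid <- al$matrix$values[pr$row_session, ] -
      al$matrix$values[pr$row_reference, ]
    expect_equal(max(abs(resid)), 0)  # exact cancellation
  }
})

test_that("mean homologous residual is zero for arbitrary offset curves", {
  set.seed(21)
  offsets <- list("DiffAbs-2018" = rep(0, 831),
                  "PUMA-2021" = smooth_row(101),
                  "PUMA-2024" = smooth_row(102))
  lm <- constructed_sessions(offsets, noise_sd = 0.2, seed = 13L)
  al <- align_sessions(lm, "DiffAbs-2018")
  for (s in c("PUMA-2021", "PUMA-2024")) {
    pr <- pair_homologous(al$matrix, s, "DiffAbs-2018")
    resid <- al$matrix$values[pr$row_session, , drop = FALSE] -
      al$matrix$values[pr$row_reference, , drop = FALSE]
    expect_lt(max(abs(colMeans(resid))), 1e-12)
  }
})

test_that("realignment is the identity on the reference session and preserves within-session geometry", {
  offsets <- list("DiffAbs-2018" = rep(0, 831),
                  "PUMA-2021" = smooth_row(103))
  lm <- constructed_sessions(offsets, noise_sd = 0.1, seed = 17L)
  before <- lm$values
  d0 <- compute_mean_delta(lm, session = "DiffAbs-2018",
                           reference_session = "DiffAbs-2018")
  expect_equal(max(abs(d0$delta)), 0)
  al <- align_sessions(lm, "DiffAbs-2018")
  after <- al$matrix$values
  ref <- which(lm$meta$session == "DiffAbs-2018")
  expect_identical(after[ref, ], before[ref, ])
  s_rows <- which(lm$meta$session == "PUMA-2021")
  i <- s_rows[1]; j <- s_rows[2]
  expect_equal(after[i, ] - after[j, ], before[i, ] - before[j, ],
               tolerance = 1e-12)

  ghost <- structure(list(session = "nope", reference_session = "DiffAbs-2018",
                          delta = rep(0, 831), n_pairs = 1L),
                     class = "xrf_batch_delta")
  expect_warning(apply_realignment(lm, ghost), "absent")
})

test_that("pseudo-replicate averaging reproduces the design counts and means", {
  man <- design_manifest(default_scenario())$manifest
  expect_equal(nrow(man), 252L)
  expect_equal(sum(table(man$zone_id) > 1L) * 3L, 36L)  # control spectra
  lm <- landmark_matrix(matrix(0, 252, 831), man)
  lm$aligned_sessions <- unique(man$session)
  av <- average_pseudoreplicates(lm)
  expect_equal(nrow(av$values), 228L)
  expect_true(all(table(av$meta$zone_id) == 1L))

  # merged rows are landmark-wise means; single-session rows pass through
  z <- names(which(table(man$zone_id) == 3L))[1]
  rows <- which(man$zone_id == z)
  lm$values[rows, ] <- matrix(c(0, 2, 4), 3, 831)  # mean 2
  av2 <- average_pseudoreplicates(lm)
  expect_equal(unname(av2$values[av2$meta$zone_id == z, ]), rep(2, 831))
  expect_equal(av2$meta$session[av2$meta$zone_id == z], "merged")
  single <- names(which(table(man$zone_id) == 1L))[1]
  expect_equal(av2$values[av2$meta$zone_id == single, ],
               lm$values[man$zone_id == single, ])

  # averaging an averaged matrix is the identity
  av3 <- average_pseudoreplicates(av2)
  expect_equal(av3$values, av2$values)
})

test_that("after alignment the session effect on PC1 is negligible", {
  # three sessions differing only by additive offset curves
  offsets <- list("DiffAbs-2018" = rep(0, 831),
                  "PUMA-2021" = 2 * smooth_row(201),
                  "PUMA-2024" = 2 * smooth_row(202))
  # every zone in every session: the offset is the only session effect
  lm <- constructed_sessions(offsets, n_zones = 20L, n_extra = 0L,
                             noise_sd = 0.05, seed = 31L)
  al <- align_sessions(lm, "DiffAbs-2018")
  pc1 <- fit_pca(al$matrix)$scores[, 1]
  ses <- al$matrix$meta$session
  for (s in c("PUMA-2021", "PUMA-2024")) {
    a <- pc1[ses == s]
    b <- pc1[ses == "DiffAbs-2018"]
    pooled <- sqrt(((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
                     (length(a) + length(b) - 2))
    expect_lt(abs(mean(a) - mean(b)) / pooled, 0.1)
  }
})
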