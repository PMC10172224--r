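test_that("the generator honors counts, determinism and overcrowding", {
  f <- generateField(fieldSpec(n_cells = 3L, image_size = c(192L, 192L),
                               seed = 7))
  expect_equal(max(f$truth$nucleusLabels), 3L)         # 3 nuclei listed

  f2 <- generateField(fieldSpec(n_cells = 3L, image_size = c(192L, 192L),
                                seed = 7))
  expect_identical(pixels(f$dapi), pixels(f2$dapi))    # same seed, same field
  expect_identical(pixels(f$marker), pixels(f2$marker))
  expect_identical(f$truth$objects, f2$truth$objects)

  f3 <- generateField(fieldSpec(n_cells = 3L, image_size = c(192L, 192L),
                                seed = 8))
  expect_false(identical(pixels(f3$marker), pixels(f$marker)))

  # an impossible request errors after bounded retries
  expect_error(generateField(fieldSpec(n_cells = 40L,
                                       image_size = c(224L, 224L), seed = 1)),
               "overcrowding")
  sp <- fieldSpec(seed = 1, nucleolar_depth = 500,
                  cluster_lambda = c(perinuclear = 0, nucleolar = 50))
  expect_error(generateField(sp), "overcrowding")
})

test_that("zero-noise planted foci are recovered one for one", {
  f <- generateField(zeroNoiseSpec(17))
  res <- suppressWarnings(analyzeField(f$dapi, f$marker, synthParams()))
  det <- detectedObjects(res)
  expect_equal(nrow(det), nrow(f$truth$objects))
  for (comp in c("nucleus", "cytoplasm"))
    expect_equal(sum(det$compartment == comp),
                 sum(f$truth$objects$compartment == comp))
})

test_that("mean detected focus count tracks the planted count", {
  planted <- 0; detected <- 0
  for (s in 1:10) {
    f <- generateField(recoverySpec(300 + s))
    res <- suppressWarnings(analyzeField(f$dapi, f$marker, synthParams()))
    planted <- planted + nrow(f$truth$objects)
    detected <- detected + nrow(detectedObjects(res))
  }
  expect_lt(abs(detected - planted) / planted, 0.1)
})

test_that("condition sets are deterministic with a complete manifest", {
  tiny <- fieldSpec(n_cells = 1L, image_size = c(96L, 96L))
  profs <- list(control = list(),
                bright = list(focus_peak_mean = c(nucleus = 128,
                                                  cytoplasm = 128)))
  ds <- generateConditionSet(profs, n_fields = 5L, seed = 3L, base = tiny)
  expect_equal(nrow(ds$manifest), 10L)                 # 2 profiles x 5 fields
  expect_equal(names(ds$fields), c("control", "bright"))

  ds2 <- generateConditionSet(profs, n_fields = 5L, seed = 3L, base = tiny)
  expect_identical(pixels(ds$fields$bright[[3]]$marker),
                   pixels(ds2$fields$bright[[3]]$marker))

  # control with no deltas keeps the base parameters
  expect_equal(ds$fields$control[[1]]$spec$focus_peak_mean,
               tiny$focus_peak_mean)

  expect_error(generateConditionSet(list(bright = list()), 2L, base = tiny),
               "control")
})

test_that("written fields read back through the TIFF dialect exactly", {
  dir <- tempfile(); f <- generateField(fieldSpec(n_cells = 1L,
                                                  image_size = c(96L, 96L),
                                                  seed = 23))
  paths <- writeField(f, dir)
  expect_true(all(file.exists(paths)))
  dapi <- maxIntensityProjection(loadStack(paths[["dapi"]]))
  # the MIP of the written stack reconstructs the 2-D image exactly
  expect_equal(pixels(dapi), pixels(f$dapi))
  nuc <- readMaskTIFF(paths[["nuclei"]])
  expect_identical(nuc, f$truth$nucleusLabels)
  tr <- read.csv(paths[["truth"]])
  expect_equal(nrow(tr), nrow(f$truth$objects))
})
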