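# hand-built FociSet: areas/intensities as given, classes as given
mkFoci <- function(areas, means, classes = rep("focus", length(areas)),
                   compartment = "nucleus", dim = c(64L, 64L)) {
  n <- length(areas)
  if (n == 0L) return(HybridFoci:::emptyFociSet(dim))
  pix <- lapply(seq_len(n), function(i) seq_len(areas[i]) + (i - 1L) * 100L)
  FociSet(data.frame(id = seq_len(n), cell_id = 1L, compartment = compartment,
                     area = as.integer(areas), mean_intensity = means,
                     total_intensity = means * areas, centroid_y = 0,
                     centroid_x = 0, object_class = classes,
                     stringsAsFactors = FALSE),
          pix, dim)
}

test_that("foci density is the count over the area, in px and um^2", {
  fs <- mkFoci(rep(2, 10), rep(50, 10))
  expect_equal(fociDensity(fs, 1000)[["per_px"]], 0.01)
  d <- fociDensity(fs, 1000, pixelSize = 0.1)
  expect_equal(d[["per_um2"]], 1.0)       # 1 px = 0.01 um^2
  expect_equal(fociDensity(mkFoci(integer(0), numeric(0)), 500)[["per_px"]], 0)
  expect_error(fociDensity(fs, 0), "positive")
  # clusters are not foci
  fs2 <- mkFoci(c(2, 50), c(10, 10), c("focus", "nucleolar_cluster"))
  expect_equal(fociDensity(fs2, 100)[["per_px"]], 0.01)
})

test_that("foci intensity averages per-focus means; empty is undefined", {
  expect_equal(fociIntensity(mkFoci(c(3, 5), c(100, 300))), 200)
  expect_equal(fociIntensity(mkFoci(4, 77)), 77)
  expect_true(is.na(fociIntensity(mkFoci(integer(0), numeric(0)))))

  # 20 random synthetic foci against an explicit per-pixel loop
  set.seed(81)
  img <- matrix(rpois(96 * 96, 30), 96, 96)
  pix <- lapply(1:20, function(i) sample.int(96 * 96, sample(1:9, 1)))
  areas <- lengths(pix)
  tot <- vapply(pix, function(p) sum(img[p]), numeric(1))
  fs <- FociSet(data.frame(id = 1:20, cell_id = 1L, compartment = "nucleus",
                           area = areas, mean_intensity = tot / areas,
                           total_intensity = tot, centroid_y = 0,
                           centroid_x = 0, object_class = "focus",
                           stringsAsFactors = FALSE), pix, c(96L, 96L))
  oracle <- mean(vapply(pix, function(p) {
    s <- 0; for (q in p) s <- s + img[q]
    s / length(p)
  }, numeric(1)))
  expect_equal(fociIntensity(fs), oracle)
})

test_that("FGI is the percentage of 1-pixel foci, undefined when empty", {
  expect_equal(computeFGI(mkFoci(rep(1, 7), rep(9, 7))), 100)
  expect_equal(computeFGI(mkFoci(1:4, rep(9, 4))), 25)
  expect_true(is.na(computeFGI(mkFoci(integer(0), numeric(0)))))
  # clusters excluded by definition
  fs <- mkFoci(c(1, 2, 60), rep(9, 3), c("focus", "focus", "perinuclear_cluster"))
  expect_equal(computeFGI(fs), 50)
})

test_that("FGI is invariant to intensity rescaling and recomputes exactly", {
  fs1 <- mkFoci(c(1, 1, 2, 5), c(10, 20, 30, 40))
  fs2 <- mkFoci(c(1, 1, 2, 5), 10 * c(10, 20, 30, 40))
  expect_equal(computeFGI(fs1), computeFGI(fs2))
  # removing a 1-px focus keeps FGI in [0, 100] and recomputes exactly
  fs3 <- mkFoci(c(1, 2, 5), c(20, 30, 40))
  expect_equal(computeFGI(fs3), 100 * 1 / 3)
  expect_lte(computeFGI(fs3), 100)
})

test_that("foci density pools additively over disjoint regions", {
  a <- mkFoci(rep(1, 6), rep(5, 6)); b <- mkFoci(rep(1, 9), rep(5, 9))
  da <- fociDensity(a, 300)[["per_px"]]; db <- fociDensity(b, 700)[["per_px"]]
  pooled <- (6 + 9) / (300 + 700)
  expect_equal(pooled, (300 * da + 700 * db) / 1000)   # weighted mean
})

test_that("cluster features count and average per class", {
  fs <- mkFoci(c(50, 60, 70, 2), c(100, 200, 40, 9),
               c("perinuclear_cluster", "perinuclear_cluster",
                 "nucleolar_cluster", "focus"))
  cl <- clusterFeatures(fs, 400)
  expect_equal(cl$perinuclear_count, 2L)
  expect_equal(cl$perinuclear_density_px, 0.005)
  expect_equal(cl$perinuclear_mean_intensity, 150)
  expect_equal(cl$nucleolar_count, 1L)
  expect_equal(cl$nucleolar_mean_intensity, 40)
  none <- clusterFeatures(mkFoci(2, 9), 400)
  expect_equal(none$nucleolar_count, 0L)
  expect_true(is.na(none$nucleolar_mean_intensity))    # undefined, not 0
})

test_that("cell feature rows follow the schema conventions", {
  fs <- mkFoci(c(1, 3, 55), c(10, 30, 90),
               c("focus", "focus", "perinuclear_cluster"))
  fr <- cellFeatures(fs, nucleusArea = 500, cytoArea = 800, cellId = 7L)
  expect_equal(nrow(fr), 2L)
  nucrow <- fr[fr$compartment == "nucleus", ]
  expect_equal(nucrow$foci_count, 2L)
  expect_equal(nucrow$fgi, 50)
  expect_equal(nucrow$perinuclear_count, 1L)
  cytrow <- fr[fr$compartment == "cytoplasm", ]
  expect_equal(cytrow$foci_count, 0L)
  expect_true(is.na(cytrow$foci_mean_intensity))       # no zero imputation
  expect_true(is.na(cytrow$perinuclear_count))         # nucleus-only field
})
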