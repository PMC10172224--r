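disc <- function(ny, nx, cy, cx, r) {
  outer(seq_len(ny), seq_len(nx), function(y, x) (y - cy)^2 + (x - cx)^2 <= r^2)
}

test_that("segmentNuclei recovers planted ellipses in both modes", {
  f <- generateField(fieldSpec(n_cells = 3L, image_size = c(192L, 192L),
                               seed = 5))
  tr_lab <- f$truth$nucleusLabels
  for (mode in c("contrast_enhanced", "median_map")) {
    mask <- segmentNuclei(f$dapi, segParams(nuclear_mode = mode))
    comp <- HybridFoci:::label8_cpp(mask)
    expect_equal(max(comp), 3L)
    for (k in 1:3) {
      tr <- tr_lab == k
      ids <- setdiff(unique(comp[tr]), 0L)
      got <- comp %in% ids & comp > 0L
      expect_gt(sum(got & tr) / sum(got | tr), 0.8)   # per-nucleus Jaccard
    }
  }
})

test_that("segmentNuclei rejects blank images and fills holes", {
  expect_error(segmentNuclei(matrix(3, 64, 64)), "no nuclei")

  m <- matrix(5, 96, 96)
  m[disc(96, 96, 48, 48, 20)] <- 100
  m[disc(96, 96, 48, 48, 4)] <- 5          # hole artifact
  mask <- segmentNuclei(m, segParams(min_nucleus_area = 50L))
  expect_equal(max(HybridFoci:::label8_cpp(mask)), 1L)
  filled <- EBImage::imageData(EBImage::fillHull(EBImage::Image(mask * 1))) > 0.5
  expect_identical(mask, filled)           # simply connected
})

test_that("watershed separation partitions cells around their seeds", {
  # two disjoint blobs, one seed each: labels identical to the blobs
  cellm <- disc(64, 64, 20, 20, 10) | disc(64, 64, 45, 45, 8)
  seeds <- disc(64, 64, 20, 20, 3) | disc(64, 64, 45, 45, 3)
  map <- separateCells(cellm, seeds)
  expect_identical(cellLabels(map) > 0L, cellm)
  expect_equal(length(cellIds(map)), 2L)

  # dumbbell blob with two seeds: two labels jointly covering the blob,
  # each containing its own seed
  dumb <- disc(64, 64, 32, 22, 10) | disc(64, 64, 32, 42, 10)
  s1 <- disc(64, 64, 32, 22, 3); s2 <- disc(64, 64, 32, 42, 3)
  map <- separateCells(dumb, s1 | s2)
  lab <- cellLabels(map)
  expect_equal(length(cellIds(map)), 2L)
  expect_identical(lab > 0L, dumb)                       # partition, no loss
  expect_equal(length(unique(lab[s1])), 1L)              # seed containment
  expect_equal(length(unique(lab[s2])), 1L)
  expect_false(unique(lab[s1]) == unique(lab[s2]))

  # blob without a seed is discarded with a warning
  lonely <- disc(64, 64, 16, 48, 6)
  expect_warning(map <- separateCells(cellm | lonely, seeds), "discarded")
  expect_true(all(cellLabels(map)[lonely] == 0L))

  # border-touching cells are dropped
  edge <- disc(64, 64, 2, 32, 6)
  expect_warning(map <- separateCells(cellm | edge, seeds | disc(64, 64, 2, 32, 2)),
                 "border")
  expect_equal(length(cellIds(map)), 2L)
})

test_that("segmentFoci finds well-separated spots and is empty on constant", {
  region <- matrix(TRUE, 96, 96)
  expect_error(segmentFoci(matrix(1, 9, 9), matrix(FALSE, 9, 9)), "empty region")
  expect_equal(length(segmentFoci(matrix(7, 96, 96), region)), 0L)

  img <- matrix(0, 96, 96)
  centers <- cbind(c(20, 20, 48, 76, 76), c(20, 76, 48, 20, 76))
  for (i in 1:5)
    for (dy in -4:4) for (dx in -4:4)
      img[centers[i, 1] + dy, centers[i, 2] + dx] <-
        img[centers[i, 1] + dy, centers[i, 2] + dx] +
        round(80 * exp(-(dy^2 + dx^2) / (2 * 1.2^2)))
  fs <- segmentFoci(img, region)
  expect_equal(length(fs), 5L)
  df <- fociTable(fs)
  for (i in 1:5) {
    d <- sqrt((df$centroid_y - (centers[i, 1] - 1))^2 +
              (df$centroid_x - (centers[i, 2] - 1))^2)
    expect_lt(min(d), 1)
  }
  # intensities measured on the original image
  expect_equal(df$total_intensity,
               vapply(fociPixels(fs), function(p) sum(img[p]), numeric(1)))
})

test_that("merged blobs split into foci that partition the blob", {
  img <- matrix(0, 48, 48)
  for (ctr in list(c(24, 20), c(24, 25)))
    for (dy in -4:4) for (dx in -4:4)
      img[ctr[1] + dy, ctr[2] + dx] <- img[ctr[1] + dy, ctr[2] + dx] +
        round(90 * exp(-(dy^2 + dx^2) / (2 * 1.3^2)))
  region <- matrix(TRUE, 48, 48)
  fs <- segmentFoci(img, region)
  expect_equal(length(fs), 2L)
  pix <- fociPixels(fs)
  expect_equal(length(intersect(pix[[1]], pix[[2]])), 0L)  # no overlap
  # union equals the candidate blob computed by the independent oracle
  map <- medianOracle(img, 3)
  q3 <- quantile(map[region], 0.75, names = FALSE)
  expect_setequal(c(pix[[1]], pix[[2]]), which(map > q3))  # no loss
})

test_that("Q3 rule bounds the candidate set at a quarter of the region", {
  set.seed(61)
  for (rep in 1:5) {
    img <- matrix(rpois(48 * 48, 40), 48, 48)
    region <- matrix(TRUE, 48, 48)
    fs <- segmentFoci(img, region)
    map <- medianOracle(img, 3)
    q3 <- quantile(map, 0.75, names = FALSE)
    n_cand <- sum(map > q3)
    expect_lte(n_cand, 0.25 * length(img))
    expect_lte(sum(fociTable(fs)$area), n_cand)
  }
})

test_that("nuclear objects classify by dimension and boundary contiguity", {
  nucleus <- disc(64, 64, 32, 32, 20)
  mk <- function(pixlist) {
    n <- length(pixlist)
    FociSet(data.frame(id = seq_len(n), cell_id = 1L, compartment = "nucleus",
                       area = lengths(pixlist),
                       mean_intensity = 50, total_intensity = 50 * lengths(pixlist),
                       centroid_y = 0, centroid_x = 0, object_class = "focus",
                       stringsAsFactors = FALSE),
            pixlist, c(64L, 64L))
  }
  p <- segParams(cluster_area_threshold = 20L)
  idx <- function(m) which(m)

  one_px <- mk(list(idx(disc(64, 64, 32, 32, 0.5))))
  out <- classifyNuclearObjects(one_px, nucleus, p)
  expect_equal(fociTable(out)$object_class, "focus")

  touching <- mk(list(idx(disc(64, 64, 32, 48, 4))))   # reaches the rim
  out <- classifyNuclearObjects(touching, nucleus, p)
  expect_equal(fociTable(out)$object_class, "perinuclear_cluster")

  interior <- mk(list(idx(disc(64, 64, 32, 32, 4))))   # >= 2 px from rim
  out <- classifyNuclearObjects(interior, nucleus, p)
  expect_equal(fociTable(out)$object_class, "nucleolar_cluster")

  expect_equal(length(classifyNuclearObjects(
    HybridFoci:::emptyFociSet(c(64L, 64L)), nucleus, p)), 0L)
})

test_that("compartments partition cells and contain their foci", {
  f <- generateField(fieldSpec(seed = 71))
  res <- suppressWarnings(analyzeField(f$dapi, f$marker, synthParams()))
  lab <- cellLabels(res$map)
  for (cell in cellIds(res$map)) {
    nuc <- nucleusOf(res$map, cell)
    cyt <- cytoplasmOf(res$map, cell)
    expect_equal(sum(nuc & cyt), 0L)                    # disjoint
    expect_identical(nuc | cyt, lab == cell)            # cover the cell
    df <- fociTable(res$foci[[as.character(cell)]])
    pix <- fociPixels(res$foci[[as.character(cell)]])
    for (k in seq_along(pix)) {
      inside <- if (df$compartment[k] == "nucleus") nuc else cyt
      expect_true(all(inside[pix[[k]]]))                # containment
    }
  }
})
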