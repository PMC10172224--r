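# Independent brute-force oracles and shared fixtures. Oracles are written
# in plain R, independently of the package's compiled implementations.

# sliding-window median by explicit sort of each neighborhood (edge
# replication)
medianOracle <- function(img, w) {
  r <- (w - 1) / 2
  ny <- nrow(img); nx <- ncol(img)
  out <- matrix(0, ny, nx)
  for (i in seq_len(ny)) for (j in seq_len(nx)) {
    ii <- pmin(pmax(i + (-r:r), 1), ny)
    jj <- pmin(pmax(j + (-r:r), 1), nx)
    out[i, j] <- median(img[ii, jj])
  }
  out
}

# double-loop neighbor count for the 3x3 local density index
ldiOracle <- function(mask) {
  ny <- nrow(mask); nx <- ncol(mask)
  out <- matrix(NA_integer_, ny, nx)
  for (i in seq_len(ny)) for (j in seq_len(nx)) {
    if (!mask[i, j]) next
    c <- 0L
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      ii <- i + di; jj <- j + dj
      if (ii >= 1 && ii <= ny && jj >= 1 && jj <= nx && mask[ii, jj])
        c <- c + 1L
    }
    out[i, j] <- c
  }
  out
}

# spec of the well-separated-spot recovery fields (no clusters, generous
# separation, default photon-limited noise)
recoverySpec <- function(seed) {
  fieldSpec(n_cells = 3L, image_size = c(192L, 192L),
            cluster_lambda = c(perinuclear = 0, nucleolar = 0),
            min_sep = 12, seed = seed)
}

# zero-noise variant used for exact granulation-index checks
zeroNoiseSpec <- function(seed) {
  sp <- recoverySpec(seed)
  sp$poisson_noise <- FALSE
  sp$read_sd <- 0
  sp$marker_diffuse <- 0
  sp
}

# analysis parameters matched to the synthetic geometry: the dimension
# criterion (40 px) sits in the gap between the largest generated focus
# (~25 px) and the smallest generated cluster footprint (~50 px)
synthParams <- function(...) segParams(cluster_area_threshold = 40L, ...)

# small multi-page grayscale TIFF fixture written by the test
writeStackFixture <- function(pages, path = tempfile(fileext = ".tif")) {
  tiff::writeTIFF(lapply(pages, function(p) p / 65535), path,
                  bits.per.sample = 16L)
  path
}

detectedObjects <- function(result) {
  do.call(rbind, lapply(result$foci, fociTable))
}
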