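# independent brute-force oracles and small fixture builders

# all 26 unit offsets at Chebyshev distance 1
offsets26 <- local({
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  as.matrix(g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ])
})

# brute-force GLCM summary: enumerate every ordered voxel pair of the region
# at each of the 26 offsets and tabulate the quantized co-occurrences
oracle_glcm <- function(bins, inside) {
  dm <- dim(bins)
  cc <- list()
  coords <- which(inside, arr.ind = TRUE)
  for (r in seq_len(nrow(coords))) {
    p <- coords[r, ]
    for (o in seq_len(nrow(offsets26))) {
      q <- p + offsets26[o, ]
      if (any(q < 1) || any(q > dm)) next
      if (!inside[q[1], q[2], q[3]]) next
      key <- paste(bins[p[1], p[2], p[3]], bins[q[1], q[2], q[3]])
      cc[[key]] <- (cc[[key]] %||% 0) + 1
    }
  }
  n <- sum(unlist(cc))
  if (n == 0) return(list(contrast = NA, entropy = NA, idm = NA, n = 0))
  contrast <- 0; entropy <- 0; idm <- 0
  for (key in names(cc)) {
    ij <- as.numeric(strsplit(key, " ")[[1]])
    p <- cc[[key]] / n
    d2 <- (ij[1] - ij[2])^2
    contrast <- contrast + d2 * p
    entropy <- entropy - p * log2(p)
    idm <- idm + p / (1 + d2)
  }
  list(contrast = contrast, entropy = entropy, idm = idm, n = n)
}

# brute-force NGTDM: per voxel, average tone of its in-region neighbours
oracle_ngtdm <- function(bins, inside) {
  dm <- dim(bins)
  coords <- which(inside, arr.ind = TRUE)
  s <- list(); ncount <- list(); nvalid <- 0
  for (r in seq_len(nrow(coords))) {
    p <- coords[r, ]
    nb <- c()
    for (o in seq_len(nrow(offsets26))) {
      q <- p + offsets26[o, ]
      if (any(q < 1) || any(q > dm)) next
      if (!inside[q[1], q[2], q[3]]) next
      nb <- c(nb, bins[q[1], q[2], q[3]])
    }
    if (length(nb) == 0) next
    nvalid <- nvalid + 1
    tone <- as.character(bins[p[1], p[2], p[3]])
    s[[tone]] <- (s[[tone]] %||% 0) + abs(bins[p[1], p[2], p[3]] - mean(nb))
    ncount[[tone]] <- (ncount[[tone]] %||% 0) + 1
  }
  tones <- sort(as.numeric(names(ncount)))
  list(tone = tones,
       n = unname(vapply(as.character(tones), function(t) ncount[[t]], 0)),
       s = unname(vapply(as.character(tones), function(t) s[[t]], 0)),
       n_valid = nvalid)
}

# NGTDM features from oracle matrix components (same formulas as the
# implementation but fed by the brute-force enumeration)
oracle_ngtdm_features <- function(o, eps = 1e-6) {
  i <- o$tone; N <- o$n_valid
  p <- o$n / N; si <- o$s
  ng <- length(i)
  psi <- sum(p * si)
  coars <- 1 / max(psi, eps)
  if (ng <= 1) return(unname(c(coars, 0, 0, 0)))
  contrast <- 0; den <- 0; comp <- 0
  for (a in seq_len(ng)) for (b in seq_len(ng)) {
    contrast <- contrast + p[a] * p[b] * (i[a] - i[b])^2
    den <- den + abs(i[a] * p[a] - i[b] * p[b])
    comp <- comp + abs(i[a] - i[b]) *
      (p[a] * si[a] + p[b] * si[b]) / (p[a] + p[b])
  }
  unname(c(coars,
           contrast / (ng * (ng - 1)) * sum(si) / N,
           if (den > 0) psi / den else 0,
           comp / N))
}

# a small SUV volume with one cuboid region embedded in cool background
make_block_volume <- function(dm = c(10, 10, 10), lo = c(4, 4, 4),
                              hi = c(7, 7, 7), value = 5, bg = 1,
                              spacing = c(4, 4, 4)) {
  a <- array(bg, dm)
  a[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- value
  pet_volume(a, spacing = spacing, units = "suv")
}

# region object covering exactly the voxels of a logical mask
region_from_mask <- function(mask, spacing = c(4, 4, 4), id = 1L,
                             patient_id = "tst") {
  segmented_region(id, which(mask), dim(mask), spacing, patient_id)
}

# labelled dataset with class-separated Gaussian features for classifier
# tests: each class shifts `sep` standard deviations along its own feature
make_feature_dataset <- function(n_per_class, classes, sep = 5,
                                 n_patients = 12, seed = 7) {
  withr::with_seed(seed, {
    rows <- lapply(seq_along(classes), function(ci) {
      n <- n_per_class
      x <- matrix(rnorm(n * 31), n, 31)
      x[, ci] <- x[, ci] + sep
      colnames(x) <- FEATURE_NAMES
      data.frame(patient_id = sprintf("P%02d", sample.int(n_patients, n,
                                                          replace = TRUE)),
                 region_id = seq_len(n), label = classes[ci], x,
                 check.names = FALSE)
    })
    d <- do.call(rbind, rows)
    d$region_id <- seq_len(nrow(d))   # unique within patient
    d
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
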