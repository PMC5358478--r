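# Independent brute-force oracles: plain double loops, no shared code
# with the implementation they check.

rand_img <- function(nr, nc, seed) {
  set.seed(seed)
  gray_image(matrix(sample(0:255, nr * nc, replace = TRUE), nr, nc))
}

rand_mask <- function(nr, nc, seed, p = 0.5, clear_border = FALSE) {
  set.seed(seed)
  m <- matrix(stats::runif(nr * nc) < p, nr, nc)
  if (clear_border) {
    m[1, ] <- m[nr, ] <- FALSE
    m[, 1] <- m[, nc] <- FALSE
  }
  binary_mask(m)
}

ora_first_order <- function(vals) {
  n <- length(vals)
  m <- 0
  for (v in vals) m <- m + v / n
  v2 <- v3 <- v4 <- 0
  for (v in vals) {
    v2 <- v2 + (v - m)^2 / n
    v3 <- v3 + (v - m)^3 / n
    v4 <- v4 + (v - m)^4 / n
  }
  sdev <- sqrt(v2)
  counts <- rep(0, 256)
  for (v in vals) counts[v + 1] <- counts[v + 1] + 1
  p <- counts / n
  ent <- 0
  for (q in p) if (q > 0) ent <- ent - q * log2(q)
  c(mean = m, sd = sdev,
    entropy = ent,
    skewness = if (sdev > 0) v3 / sdev^3 else 0,
    kurtosis = if (sdev > 0) v4 / sdev^4 else 0,
    energy = sum(p^2))
}

ora_glcm <- function(img, region, offset, L, symmetric) {
  px <- unclass(img)
  nr <- nrow(px); nc <- ncol(px)
  bin <- ceiling(256 / L)
  counts <- matrix(0, L, L)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    r2 <- r + offset[1]; c2 <- c + offset[2]
    if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
    if (!is.null(region) && !(region[r, c] && region[r2, c2])) next
    a <- min(px[r, c] %/% bin, L - 1) + 1
    b <- min(px[r2, c2] %/% bin, L - 1) + 1
    counts[a, b] <- counts[a, b] + 1
    if (symmetric) counts[b, a] <- counts[b, a] + 1
  }
  counts / sum(counts)
}

ora_glcm_features <- function(g) {
  L <- nrow(g)
  con <- idm <- asm <- dm <- sxy <- 0
  px_ <- rep(0, L); py_ <- rep(0, L)
  for (i in seq_len(L)) for (j in seq_len(L)) {
    x <- i - 1; y <- j - 1; p <- g[i, j]
    con <- con + (x - y)^2 * p
    idm <- idm + p / (1 + (x - y)^2)
    asm <- asm + p^2
    dm <- dm + p * abs(x - y)
    sxy <- sxy + x * y * p
    px_[i] <- px_[i] + p
    py_[j] <- py_[j] + p
  }
  mx <- sum((0:(L - 1)) * px_); my <- sum((0:(L - 1)) * py_)
  sx <- sqrt(sum((0:(L - 1) - mx)^2 * px_))
  sy <- sqrt(sum((0:(L - 1) - my)^2 * py_))
  corr <- if (sx * sy > 0) (sxy - mx * my) / (sx * sy) else 0
  c(contrast = con, homogeneity = idm, asm = asm,
    correlation = corr, directional_moment = dm)
}

# neighborhood-scan morphology; pixels outside the raster are background
ora_morph <- function(mask, radius, op = c("erode", "dilate")) {
  op <- match.arg(op)
  m <- unclass(mask)
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(FALSE, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    hit_all <- TRUE; hit_any <- FALSE
    for (dr in -radius:radius) for (dc in -radius:radius) {
      r2 <- r + dr; c2 <- c + dc
      v <- r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc && m[r2, c2]
      hit_all <- hit_all && v
      hit_any <- hit_any || v
    }
    out[r, c] <- if (op == "erode") hit_all else hit_any
  }
  binary_mask(out)
}

# mean over each s x s block, replicated back to full size
ora_block_mean <- function(img, s) {
  px <- unclass(img) * 1.0
  nr <- nrow(px); nc <- ncol(px)
  out <- matrix(0, nr, nc)
  for (br in seq_len(nr %/% s)) for (bc in seq_len(nc %/% s)) {
    rows <- ((br - 1) * s + 1):(br * s)
    cols <- ((bc - 1) * s + 1):(bc * s)
    tot <- 0
    for (r in rows) for (c in cols) tot <- tot + px[r, c]
    out[rows, cols] <- tot / s^2
  }
  out
}

# explicit projection of a 3x3 block on each basis patch via loops
ora_bwt3 <- function(block, basis) {
  patches <- c(list(dc = basis$dc), basis$wavelets)
  vapply(patches, function(p) {
    acc <- 0
    for (i in 1:3) for (j in 1:3) acc <- acc + p[i, j] * block[i, j]
    acc
  }, numeric(1))
}
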