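# Low-level image operations shared by the census and coloc modules.
# These mirror the ImageJ primitives the original macros relied on:
# 256-bin histograms over the image's min-max range, rank (median) filters
# with a circular kernel, and 2D topological thinning.

#' 256-bin histogram of an image
#'
#' Bins intensities into 256 equal-width bins spanning the image's min-max
#' range (ImageJ convention for non-8-bit images). A constant image puts all
#' mass in bin 0.
#'
#' @param x Numeric vector, matrix or array of intensities.
#' @return Integer vector of length 256 of bin counts, with attributes
#'   `min` and `max` recording the range used.
#' @export
hist_256 <- function(x) {
  x <- as.numeric(x)
  if (length(x) == 0L) stop("empty image")
  if (anyNA(x)) stop("image contains NA")
  lo <- min(x); hi <- max(x)
  if (hi > lo) {
    idx <- floor((x - lo) / (hi - lo) * 256)
    idx[idx > 255] <- 255
  } else {
    idx <- rep(0L, length(x))
  }
  counts <- tabulate(idx + 1L, nbins = 256L)
  attr(counts, "min") <- lo
  attr(counts, "max") <- hi
  counts
}

#' Automatic histogram thresholding (Triangle, Yen, Moments)
#'
#' Computes a threshold bin from a 256-bin histogram using the published
#' Triangle, Yen, or Moments algorithms in their ImageJ-compatible
#' formulations. The returned level is a 0-based bin index; pixels in bins
#' strictly above it are foreground.
#'
#' @param counts Integer vector of 256 bin counts (see [hist_256()]).
#' @param method One of `"triangle"`, `"yen"`, `"moments"`.
#' @return Integer bin index in 0..255, with attribute `degenerate = TRUE`
#'   when the histogram has a single occupied bin (threshold is that bin).
#' @export
auto_threshold <- function(counts, method = c("triangle", "yen", "moments")) {
  method <- match.arg(method)
  counts <- as.numeric(counts)
  if (length(counts) != 256L) stop("expected a 256-bin histogram")
  if (sum(counts) <= 0) stop("histogram is empty")
  occupied <- which(counts > 0)
  if (length(occupied) == 1L) {
    lev <- as.integer(occupied - 1L)
    attr(lev, "degenerate") <- TRUE
    return(lev)
  }
  lev <- switch(method,
    triangle = .threshold_triangle(counts),
    yen      = .threshold_yen(counts),
    moments  = .threshold_moments(counts)
  )
  lev <- as.integer(max(0L, min(255L, lev)))
  attr(lev, "degenerate") <- FALSE
  lev
}

# Triangle method (Zack et al. 1977), ImageJ formulation: a line is drawn
# from the histogram peak to the far end of the occupied range; the
# threshold is the bin maximizing the perpendicular distance to that line.
.threshold_triangle <- function(data) {
  # 0-based indices throughout, matching the reference formulation
  nz <- which(data > 0) - 1L
  mn <- nz[1L];   if (mn > 0L) mn <- mn - 1L
  mx2 <- nz[length(nz)]; if (mx2 < 255L) mx2 <- mx2 + 1L
  peak <- which.max(data) - 1L
  inverted <- (peak - mn) < (mx2 - peak)
  if (inverted) {
    data <- rev(data)
    mn <- 255L - mx2
    peak <- 255L - peak
  }
  if (mn == peak) {
    split <- mn
  } else {
    nx <- data[peak + 1L]
    ny <- mn - peak
    d <- sqrt(nx * nx + ny * ny)
    nx <- nx / d; ny <- ny / d
    d <- nx * mn + ny * data[mn + 1L]
    split <- mn
    split_dist <- 0
    for (i in seq(mn + 1L, peak)) {
      new_dist <- nx * i + ny * data[i + 1L] - d
      if (new_dist > split_dist) {
        split <- i
        split_dist <- new_dist
      }
    }
    split <- split - 1L
  }
  if (inverted) 255L - split else split
}

# Yen (1995) maximum correlation criterion, ImageJ formulation.
.threshold_yen <- function(data) {
  total <- sum(data)
  p <- data / total
  P1 <- cumsum(p)
  P1_sq <- cumsum(p^2)
  P2_sq <- rev(cumsum(rev(p^2))) - p^2  # sum_{j > i} p_j^2
  crit <- numeric(256)
  for (it in 1:256) {
    a <- P1_sq[it] * P2_sq[it]
    b <- P1[it] * (1 - P1[it])
    crit[it] <- -1 * (if (a > 0) log(a) else 0) + 2 * (if (b > 0) log(b) else 0)
  }
  which.max(crit) - 1L
}

# Moments preservation (Tsai 1985): pick the p0-tile threshold that keeps
# the first three gray-level moments of the binarized image.
.threshold_moments <- function(data) {
  total <- sum(data)
  p <- data / total
  i <- 0:255
  m1 <- sum(i * p); m2 <- sum(i^2 * p); m3 <- sum(i^3 * p)
  cd <- m2 - m1 * m1
  if (cd == 0) return(as.integer(round(m1)))
  c0 <- (-m2 * m2 + m1 * m3) / cd
  c1 <- (-m3 + m2 * m1) / cd
  disc <- c1 * c1 - 4 * c0
  if (disc < 0) disc <- 0
  z0 <- 0.5 * (-c1 - sqrt(disc))
  z1 <- 0.5 * (-c1 + sqrt(disc))
  if (z1 == z0) return(as.integer(round(m1)))
  p0 <- (z1 - m1) / (z1 - z0)
  s <- 0
  for (ih in 1:256) {
    s <- s + p[ih]
    if (s > p0) return(ih - 1L)
  }
  255L
}

#' Apply a histogram threshold to an image
#'
#' @param img Numeric matrix of intensities.
#' @param level 0-based bin index from [auto_threshold()].
#' @param lo,hi Range over which the histogram was built; defaults to the
#'   image's own range.
#' @return Logical matrix: pixels whose bin is strictly above `level`.
#' @export
apply_threshold <- function(img, level, lo = min(img), hi = max(img)) {
  if (hi > lo) {
    idx <- floor((img - lo) / (hi - lo) * 256)
    idx[idx > 255] <- 255
  } else {
    idx <- array(0, dim(img))
  }
  out <- idx > as.numeric(level)
  dim(out) <- dim(img)
  out
}

# Circular kernel offsets: dx^2 + dy^2 <= r^2 + 1 (ImageJ rank-filter mask;
# radius 1 -> 3x3, radius 2 -> 21 pixels).
.kernel_offsets <- function(radius) {
  r <- ceiling(radius)
  g <- expand.grid(dy = -r:r, dx = -r:r)
  g[g$dx^2 + g$dy^2 <= radius^2 + 1, , drop = FALSE]
}

.pad_replicate <- function(img, r) {
  nr <- nrow(img); nc <- ncol(img)
  ri <- c(rep(1L, r), seq_len(nr), rep(nr, r))
  ci <- c(rep(1L, r), seq_len(nc), rep(nc, r))
  img[ri, ci, drop = FALSE]
}

#' Median filter with a circular kernel
#'
#' Rank filter over the ImageJ circular mask (radius 1 covers the full 3x3
#' neighborhood; radius 2 covers 21 pixels). Edges use replicate padding.
#' Logical input is filtered as a majority vote and returned logical.
#'
#' @param img Numeric or logical matrix.
#' @param radius Kernel radius in pixels.
#' @return Filtered matrix of the same type and dimensions.
#' @export
median_filter <- function(img, radius = 1) {
  was_logical <- is.logical(img)
  x <- img
  storage.mode(x) <- "double"
  r <- ceiling(radius)
  off <- .kernel_offsets(radius)
  pad <- .pad_replicate(x, r)
  nr <- nrow(x); nc <- ncol(x)
  k <- nrow(off)
  stack <- matrix(0, nr * nc, k)
  for (j in seq_len(k)) {
    stack[, j] <- as.vector(pad[(1:nr) + r + off$dy[j], (1:nc) + r + off$dx[j]])
  }
  if (was_logical) {
    out <- rowSums(stack) > k / 2
  } else {
    out <- apply(stack, 1, stats::median)
  }
  matrix(out, nr, nc)
}

# 8-neighborhood views of a padded binary matrix, ordered p2..p9
# (N, NE, E, SE, S, SW, W, NW) as in the thinning literature.
.neighbor_views <- function(pad, nr, nc) {
  sh <- function(dy, dx) pad[(1:nr) + 1 + dy, (1:nc) + 1 + dx, drop = FALSE]
  list(
    p2 = sh(-1, 0), p3 = sh(-1, 1), p4 = sh(0, 1), p5 = sh(1, 1),
    p6 = sh(1, 0), p7 = sh(1, -1), p8 = sh(0, -1), p9 = sh(-1, -1)
  )
}

#' Topological skeletonization of a binary mask
#'
#' Zhang-Suen iterative thinning: peels boundary pixels that do not break
#' 8-connectivity until the mask is one pixel wide, equivalent to the
#' binary skeletonization step of the original ImageJ macro.
#'
#' @param mask Logical matrix.
#' @return Logical matrix of the same size containing the skeleton.
#' @export
skeletonize_2d <- function(mask) {
  stopifnot(is.matrix(mask))
  m <- mask != 0
  nr <- nrow(m); nc <- ncol(m)
  if (!any(m)) return(m)
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      pad <- matrix(FALSE, nr + 2, nc + 2)
      pad[2:(nr + 1), 2:(nc + 1)] <- m
      nb <- .neighbor_views(pad, nr, nc)
      B <- nb$p2 + nb$p3 + nb$p4 + nb$p5 + nb$p6 + nb$p7 + nb$p8 + nb$p9
      seqn <- list(nb$p2, nb$p3, nb$p4, nb$p5, nb$p6, nb$p7, nb$p8, nb$p9, nb$p2)
      A <- matrix(0L, nr, nc)
      for (j in 1:8) A <- A + (!seqn[[j]] & seqn[[j + 1]])
      if (step == 1) {
        c3 <- !(nb$p2 & nb$p4 & nb$p6)
        c4 <- !(nb$p4 & nb$p6 & nb$p8)
      } else {
        c3 <- !(nb$p2 & nb$p4 & nb$p8)
        c4 <- !(nb$p2 & nb$p6 & nb$p8)
      }
      del <- m & B >= 2 & B <= 6 & A == 1 & c3 & c4
      if (any(del)) {
        m[del] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m
}

# Evaluate code under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. seed = NULL runs the code as-is.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}
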