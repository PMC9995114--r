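# Independent oracles and small fixture builders shared across tests.

# rasterized disk mask (pixel-centre inclusion), 1-based centre coords
raster_disk <- function(h, w, cy, cx, r) {
  outer((seq_len(h) - cy)^2, (seq_len(w) - cx)^2, `+`) <= r^2
}

# rasterized axis-aligned ellipse mask
raster_ellipse <- function(h, w, cy, cx, ry, rx) {
  outer(((seq_len(h) - cy) / ry)^2, ((seq_len(w) - cx) / rx)^2, `+`) <= 1
}

# exhaustive minimum cross-entropy threshold over integer grey levels
# (Li & Lee criterion on the histogram; independent of the fixed-point
# iteration inside the package). The criterion is piecewise constant
# between distinct data values, so the minimizing *set* is returned.
li_exhaustive_set <- function(values, levels = 0:255) {
  v <- round(as.numeric(values))
  crit <- vapply(levels[-length(levels)], function(t) {
    lo <- v[v <= t]; hi <- v[v > t]
    if (!length(lo) || !length(hi)) return(Inf)
    m0 <- mean(lo); m1 <- mean(hi)
    term <- function(x, m) if (m <= 0) 0 else -sum(x) * log(m)
    term(lo, m0) + term(hi, m1)
  }, numeric(1))
  lv <- levels[-length(levels)]
  lv[crit <= min(crit) + 1e-9 * abs(min(crit))]
}

# flood-fill connected components by graph traversal (26-connectivity),
# independent of the package's labelling; returns sorted component sizes
flood_sizes_26 <- function(mask) {
  stopifnot(requireNamespace("igraph", quietly = TRUE))
  d <- dim(mask)
  lin <- array(seq_len(prod(d)), d)
  offs <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  offs <- offs[rowSums(abs(offs)) > 0, ]
  offs <- offs[offs$dz > 0 | (offs$dz == 0 & offs$dy > 0) |
                 (offs$dz == 0 & offs$dy == 0 & offs$dx > 0), ]
  edges <- list()
  for (i in seq_len(nrow(offs))) {
    dz <- offs$dz[i]; dy <- offs$dy[i]; dx <- offs$dx[i]
    z1 <- max(1, 1 - dz):min(d[1], d[1] - dz)
    y1 <- max(1, 1 - dy):min(d[2], d[2] - dy)
    x1 <- max(1, 1 - dx):min(d[3], d[3] - dx)
    a <- lin[z1, y1, x1]
    b <- lin[z1 + dz, y1 + dy, x1 + dx]
    keep <- mask[a] & mask[b]
    if (any(keep)) edges[[length(edges) + 1L]] <- cbind(a[keep], b[keep])
  }
  fg <- which(mask)
  if (!length(fg)) return(integer())
  em <- if (length(edges)) do.call(rbind, edges) else
    matrix(integer(), 0, 2)
  ids <- match(em, fg)
  g <- igraph::make_graph(t(matrix(ids, ncol = 2)), n = length(fg),
                          directed = FALSE)
  sort(as.integer(table(igraph::components(g)$membership)))
}

# naive O(n^2) distance of each voxel to the nearest mask voxel, in nm
brute_distance_nm <- function(mask, pixel_nm, step_nm) {
  d <- dim(mask)
  src <- which(mask, arr.ind = TRUE)
  out <- array(Inf, d)
  for (i in seq_len(prod(d))) {
    p <- arrayInd(i, d)
    dz <- (src[, 1] - p[1]) * step_nm
    dy <- (src[, 2] - p[2]) * pixel_nm
    dx <- (src[, 3] - p[3]) * pixel_nm
    out[i] <- sqrt(min(dz^2 + dy^2 + dx^2))
  }
  out
}

# brute-force 2D DFT power within / outside the horizontal wedge
wedge_energy_split <- function(image, half_angle_deg) {
  h <- nrow(image); w <- ncol(image)
  F <- fft(image - mean(image))
  fy <- c(seq(0, floor((h - 1) / 2)), seq(-floor(h / 2), -1)) / h
  fx <- c(seq(0, floor((w - 1) / 2)), seq(-floor(w / 2), -1)) / w
  ang <- atan2(abs(outer(fy, rep(1, w))), abs(outer(rep(1, h), fx)))
  inside <- ang <= half_angle_deg * pi / 180
  list(inside = sum(abs(F[inside])^2), total = sum(abs(F)^2))
}
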