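# Independent brute-force oracles and fixture builders used across the
# suite.  Every oracle here deliberately avoids the package's optimized
# code paths (cell lists, distance transforms, closed-form shortcuts).

# quadratic all-pairs neighbour search
brute_pairs <- function(coords, cutoff) {
  n <- nrow(coords)
  out <- NULL
  for (i in seq_len(n - 1)) {
    d <- sqrt(rowSums(sweep(coords[(i + 1):n, , drop = FALSE], 2,
                            coords[i, ])^2))
    js <- which(d <= cutoff)
    if (length(js))
      out <- rbind(out, data.frame(i = i, j = js + i, dist = d[js]))
  }
  if (is.null(out))
    out <- data.frame(i = integer(0), j = integer(0), dist = numeric(0))
  out[order(out$i, out$j), ]
}

# pair-distance histogram by direct enumeration
brute_pair_hist <- function(coords, r_max, bin) {
  d <- as.numeric(dist(coords))
  d <- d[d <= r_max]
  nb <- length(seq(0, r_max + bin, by = bin)) - 1
  tabulate(pmin(nb, floor(d / bin) + 1), nbins = nb)
}

# radius of gyration via the double-sum identity Rg^2 = (1/2n^2) sum |ci-cj|^2
brute_rg <- function(centers) {
  n <- nrow(centers)
  s <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    s <- s + sum((centers[i, ] - centers[j, ])^2)
  sqrt(s / (2 * n^2))
}

# random unit vector / random pose helpers
rand_unit <- function() {
  v <- rnorm(3)
  v / sqrt(sum(v^2))
}

rand_pose <- function(center = rnorm(3) * 10, id = 1L) {
  nv <- rand_unit()
  ref <- if (abs(nv[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  dy <- ref - sum(ref * nv) * nv
  dy <- dy / sqrt(sum(dy^2))
  nucleosome_pose(center, nv, dy, id = id)
}

# Monte-Carlo closest-point oracle between two cylinder surfaces:
# uniform-by-area samples on caps and side, minimum cross distance, with the
# facet of the closest sample on each cylinder
mc_cylinder_oracle <- function(c1, n1, c2, n2, r = 5.5, h = 6,
                               n_samples = 1500, face_frac = 0.9) {
  sample_surface <- function(c0, a) {
    ref <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    e1 <- ref - sum(ref * a) * a
    e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(a[2] * e1[3] - a[3] * e1[2], a[3] * e1[1] - a[1] * e1[3],
            a[1] * e1[2] - a[2] * e1[1])
    area_cap <- pi * r^2
    area_side <- 2 * pi * r * h
    p_side <- area_side / (area_side + 2 * area_cap)
    n_side <- round(n_samples * p_side)
    n_cap <- n_samples - n_side
    phi <- runif(n_side, 0, 2 * pi)
    z <- runif(n_side, -h / 2, h / 2)
    side <- t(sapply(seq_len(n_side), function(k)
      c0 + r * cos(phi[k]) * e1 + r * sin(phi[k]) * e2 + z[k] * a))
    rho <- r * sqrt(runif(n_cap))
    phc <- runif(n_cap, 0, 2 * pi)
    zc <- sample(c(-h / 2, h / 2), n_cap, replace = TRUE)
    cap <- t(sapply(seq_len(n_cap), function(k)
      c0 + rho[k] * cos(phc[k]) * e1 + rho[k] * sin(phc[k]) * e2 + zc[k] * a))
    pts <- rbind(side, cap)
    facet <- c(rep("side", n_side),
               ifelse(rho <= face_frac * r, "face", "side"))
    list(pts = pts, facet = facet)
  }
  s1 <- sample_surface(c1, n1)
  s2 <- sample_surface(c2, n2)
  d2 <- outer(rowSums(s1$pts^2), rowSums(s2$pts^2), "+") -
    2 * s1$pts %*% t(s2$pts)
  k <- arrayInd(which.min(d2), dim(d2))
  list(dist = sqrt(max(0, min(d2))),
       facets = c(s1$facet[k[1]], s2$facet[k[2]]))
}

# brute-force local thickness on a small grid: for every void voxel the
# largest ball (centered at any void voxel, radius = distance to nearest
# non-void voxel) containing it
brute_local_thickness <- function(void) {
  d <- dim(void)
  idx <- which(void)
  coords <- arrayInd(idx, d)
  nonvoid <- arrayInd(which(!void), d)
  # distance to nearest non-void voxel (or grid boundary is void-limited:
  # matches the transform convention of feature = !void inside the grid)
  dt <- vapply(seq_len(nrow(coords)), function(k) {
    sqrt(min(rowSums(sweep(nonvoid, 2, coords[k, ])^2)))
  }, 0)
  lt <- numeric(nrow(coords))
  for (c0 in seq_len(nrow(coords))) {
    rad <- dt[c0]
    if (rad <= 0) next
    dd <- sqrt(rowSums(sweep(coords, 2, coords[c0, ])^2))
    cover <- dd <= rad
    lt[cover] <- pmax(lt[cover], 2 * rad)
  }
  out <- array(0, d)
  out[idx] <- lt
  out
}

# hand-buildable coarse-grained frame from an explicit bead table
make_frame <- function(...) {
  cg_frame(data.frame(...))
}
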