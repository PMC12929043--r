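# Condensate-scale pairwise statistics: RDF, nearest neighbours,
# orientation distributions, contact classification and censuses.

test_that("pair histogram equals brute-force enumeration on a toy model", {
  b <- random_bath(200, 6e5, seed = 41)
  g <- radial_distribution(b, r_max = 15, bin = 0.5, n_reference_draws = 5,
                           seed = 1)
  brute <- brute_pair_hist(b$centers, 15, 0.5)
  expect_equal(g$pairs_data, brute[seq_along(g$pairs_data)])
  expect_true(all(brute[-seq_along(g$pairs_data)] == 0) ||
                length(brute) == length(g$pairs_data))
})

test_that("cell-list neighbour search equals the quadratic scan", {
  set.seed(42)
  coords <- matrix(runif(1500, 0, 60), 500, 3)
  for (cutoff in c(3, 8, 20)) {
    a <- nucleopack:::cpp_neighbor_pairs(coords, cutoff)
    a <- a[order(a$i, a$j), ]
    b <- brute_pairs(coords, cutoff)
    expect_equal(nrow(a), nrow(b))
    expect_equal(a$i, b$i)
    expect_equal(a$j, b$j)
    expect_equal(a$dist, b$dist, tolerance = 1e-12)
  }
})

test_that("a random bath has g close to 1 beyond the exclusion scale", {
  b <- random_bath(2000, 6e5, seed = 43)
  g <- radial_distribution(b, r_max = 25, bin = 1, n_reference_draws = 40,
                           seed = 2)
  sel <- g$r_nm > 7
  expect_lt(max(abs(g$g_r[sel] - 1), na.rm = TRUE), 0.15)
})

test_that("radial_distribution validates its inputs", {
  b <- random_bath(150, 6e5, seed = 44)
  expect_error(radial_distribution(b, r_max = 1e4), "extent")
  small <- random_bath(50, 6e5, seed = 44)
  expect_error(radial_distribution(small, r_max = 10), "100")
})

test_that("nearest neighbours match enumeration and break ties by id", {
  m <- condensate_model(rbind(c(0, 0, 0), c(6, 0, 0), c(20, 0, 0)),
                        rbind(c(0, 0, 1), c(0, 0, 1), c(0, 0, 1)))
  pr <- nearest_neighbor_pairs(m, k = 1)
  expect_equal(pr$i, c(1, 2))
  expect_equal(pr$j, c(2, 3))
  # equidistant tie: pose 2 is 5 nm from both 1 and 3; lower id wins
  mt <- condensate_model(rbind(c(0, 0, 0), c(5, 0, 0), c(10, 0, 0)),
                         rbind(c(0, 0, 1), c(0, 0, 1), c(0, 0, 1)))
  pt <- nearest_neighbor_pairs(mt, k = 1)
  expect_true(all(c("1 2", "2 3") %in% paste(pt$i, pt$j)) ||
                all(paste(pt$i, pt$j) %in% c("1 2", "2 3")))
  expect_equal(pt$j[pt$i == 2][1], 3)  # pose 2 itself pairs with lower id 1
  # brute-force nearest neighbour on random poses
  set.seed(45)
  centers <- matrix(runif(1500, 0, 80), 500, 3)
  mm <- condensate_model(centers,
                         t(replicate(500, rand_unit())))
  pr2 <- nearest_neighbor_pairs(mm, k = 1)
  for (i in 1:500) {
    d <- sqrt(rowSums(sweep(centers, 2, centers[i, ])^2))
    d[i] <- Inf
    j <- which.min(d)
    key <- paste(min(i, j), max(i, j))
    expect_true(key %in% paste(pr2$i, pr2$j))
  }
  expect_error(nearest_neighbor_pairs(mm, k = 500), "smaller")
})

test_that("orientation distribution has the sinusoidal reference", {
  # all-parallel stack: all mass in the first bin
  n <- 12
  stack <- condensate_model(cbind(0, 0, seq(0, by = 6, length.out = n)),
                            matrix(rep(c(0, 0, 1), n), n, 3, byrow = TRUE))
  pr <- nearest_neighbor_pairs(stack, k = 1)
  od <- orientation_distribution(pr, stack, bin = 5)
  expect_equal(od$count[1], sum(od$count))
  # reference integrates to the sample count
  expect_equal(sum(od$reference), sum(od$count), tolerance = 1e-9)
  # independent uniform orientations: mean plane angle 57.30 degrees
  b <- random_bath(10000, 2e5, seed = 46)
  prs <- data.frame(i = seq(1, 9999, by = 2), j = seq(2, 10000, by = 2))
  odr <- orientation_distribution(prs, b)
  expect_equal(attr(odr, "mean_angle_deg"), 57.2958, tolerance = 1 / 57.2958)
})

test_that("contact classification matches constructed geometries", {
  a <- nucleosome_pose(c(0, 0, 0), c(0, 0, 1))
  # coaxial discs, caps 1 nm apart
  b <- nucleosome_pose(c(0, 0, 7), c(0, 0, 1), id = 2L)
  cb <- classify_contact(a, b)
  expect_equal(cb$class, "face-to-face")
  expect_equal(cb$separation_nm, 1, tolerance = 1e-6)
  # perpendicular discs, rim of one 1 nm from the cap of the other
  c2 <- nucleosome_pose(c(0, 0, 3 + 1 + 5.5), c(0, 1, 0), id = 3L)
  expect_equal(classify_contact(a, c2)$class, "face-to-side")
  # side by side, parallel axes
  c3 <- nucleosome_pose(c(12, 0, 0), c(0, 0, 1), id = 4L)
  expect_equal(classify_contact(a, c3)$class, "side-to-side")
  # gate: surfaces farther than the gate are not contacts
  far <- nucleosome_pose(c(0, 0, 9.1), c(0, 0, 1), id = 5L)
  expect_true(is.na(classify_contact(far, a)$class))
  # symmetry up to label order
  set.seed(47)
  for (k in 1:50) {
    p <- rand_pose(id = 1L)
    q <- rand_pose(center = p$center + runif(1, 11, 14) * rand_unit(),
                   id = 2L)
    expect_identical(classify_contact(p, q)$class, classify_contact(q, p)$class)
  }
})

test_that("classification agrees with a surface-sampling oracle", {
  # surface sampling at 2500 points/cylinder resolves distances to about
  # 0.3 nm (sample spacing ~0.26 nm, worst near touching flat faces)
  set.seed(48)
  n_pairs <- 60
  dist_ok <- 0; class_ok <- 0; gated <- 0
  for (k in seq_len(n_pairs)) {
    c1 <- c(0, 0, 0); a1 <- rand_unit()
    c2 <- runif(1, 11.5, 13.8) * rand_unit(); a2 <- rand_unit()
    cs <- cylinder_separation(c1, a1, c2, a2)
    mc <- mc_cylinder_oracle(c1, a1, c2, a2, n_samples = 2500)
    if (cs$separation >= 0) {
      # disjoint: the sampled minimum can only overestimate the distance
      if (mc$dist >= cs$separation - 1e-6 &&
          mc$dist - cs$separation < 0.4)
        dist_ok <- dist_ok + 1
    } else {
      # intersecting surfaces: the sampled surface distance must be small
      if (mc$dist < 0.4) dist_ok <- dist_ok + 1
    }
    if (cs$separation >= 0 && cs$separation <= 2) {
      gated <- gated + 1
      if (identical(sort(cs$facets), sort(mc$facets)))
        class_ok <- class_ok + 1
    }
  }
  expect_gte(dist_ok / n_pairs, 0.95)
  if (gated > 0) expect_gte(class_ok / gated, 0.85)
})

test_that("contact census matches construction and brute-force totals", {
  # isolated single-segment two-start 12-mer: ten stacked N:N+2 pairs
  f <- build_ideal_fiber("two_start", 12,
                         list(rise_nm = 6, alpha_deg = 50,
                              segment_length = 12))
  ao <- stats::setNames(rep(1L, 12), 1:12)
  m1 <- condensate_model(f$centers, f$normals, f$dyads, array_of = ao,
                         seq_index = 1:12)
  cc1 <- contact_census(m1)
  expect_equal(cc1$per_array$face_to_face, 10)
  expect_equal(cc1$per_array$inter, 0)
  # two interdigitated coaxial arrays: every stacked pair crosses arrays,
  # zero intra (within-array pairs are either distant or covalently
  # adjacent and excluded)
  centers <- rbind(cbind(0, 0, seq(0, by = 12, length.out = 4)),
                   cbind(0, 0, seq(6, by = 12, length.out = 4)))
  normals <- matrix(rep(c(0, 0, 1), 8), 8, 3, byrow = TRUE)
  ao2 <- stats::setNames(rep(1:2, each = 4), 1:8)
  m2 <- condensate_model(centers, normals, array_of = ao2,
                         seq_index = rep(1:4, 2))
  cc2 <- contact_census(m2)
  expect_equal(sum(cc2$records$scope == "inter-array"), 7)
  expect_true(all(cc2$records$geometry_class[cc2$records$scope ==
                                               "inter-array"] == "face-to-face"))
  expect_equal(sum(cc2$records$scope == "intra-array"), 0)
  # census totals equal brute-force all-pairs classification
  m3 <- gen_condensate("bp30_like", n_fibers = 8, target_density = 6e5,
                       seed = 49)
  rec <- nucleopack:::contact_records(m3)
  n <- nrow(m3$centers)
  brute_n <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (sqrt(sum((m3$centers[i, ] - m3$centers[j, ])^2)) > 18.6) next
    sep <- cylinder_separation(m3$centers[i, ], m3$normals[i, ],
                               m3$centers[j, ], m3$normals[j, ])$separation
    if (sep > 2) next
    if (m3$array_of[as.character(i)] == m3$array_of[as.character(j)] &&
        abs(m3$seq_index[i] - m3$seq_index[j]) < 2) next
    brute_n <- brute_n + 1
  }
  expect_equal(nrow(rec), brute_n)
  # contact conservation: class breakdown partitions the gated pairs
  expect_equal(sum(table(rec$geometry_class)), nrow(rec))
})

test_that("random_bath is deterministic, isotropic and density-exact", {
  b1 <- random_bath(600, 6e5, seed = 50)
  b2 <- random_bath(600, 6e5, seed = 50)
  expect_identical(b1$centers, b2$centers)
  expect_identical(b1$normals, b2$normals)
  expect_equal(mask_volume_nm3(b1$mask), 100^3, tolerance = 1e-9)
  # normals' z-components uniform on [-1, 1]
  bz <- random_bath(10000, 2e5, seed = 51)
  ks <- suppressWarnings(stats::ks.test(bz$normals[, 3], "punif", -1, 1))
  expect_gt(ks$p.value, 0.01)
  expect_error(random_bath(1000, 3e6, seed = 1), "volume fraction")
})
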