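# Per-fiber geometry: plane angles, signed dihedrals, step tables, radius
# of gyration, and the idealized fiber builders.

test_that("plane_angle handles identity, orthogonality and the folded convention", {
  a <- nucleosome_pose(c(0, 0, 0), c(0, 0, 1))
  expect_equal(plane_angle(a, a), 0)
  b <- nucleosome_pose(c(10, 0, 0), c(1, 0, 0))
  expect_equal(plane_angle(a, b), 90)
  # normals separated by 120 degrees fold to 60
  c120 <- nucleosome_pose(c(0, 10, 0), c(sin(120 * pi / 180), 0,
                                         cos(120 * pi / 180)))
  expect_equal(plane_angle(a, c120), 60, tolerance = 1e-9)
  expect_error(plane_angle(a, structure(list(center = c(0, 0, 0),
                                             normal = c(0, 0, 2),
                                             dyad = c(1, 0, 0), id = 1L),
                                        class = "nucleosome_pose")),
               "unit")
})

test_that("plane_angle is flip-invariant on random pose pairs", {
  set.seed(11)
  for (k in 1:1000) {
    a <- rand_pose()
    b <- rand_pose()
    ang <- plane_angle(a, b)
    bf <- nucleosome_pose(b$center, -b$normal, id = 2L)
    af <- nucleosome_pose(a$center, -a$normal, id = 3L)
    expect_equal(plane_angle(a, bf), ang, tolerance = 1e-9)
    expect_equal(plane_angle(af, b), ang, tolerance = 1e-9)
    expect_true(ang >= 0 && ang <= 90)
  }
})

test_that("signed_dihedral recovers constructed rotations over the full circle", {
  a <- nucleosome_pose(c(0, 0, 0), c(0, 0, 1), c(1, 0, 0))
  u <- c(1, 0, 0)
  for (theta in seq(1, 359, by = 1)) {
    R <- nucleopack:::rotation_about(u, theta)
    b <- nucleosome_pose(a$center + 10 * u, as.numeric(R %*% a$normal),
                         as.numeric(R %*% a$dyad), id = 2L)
    expect_equal(signed_dihedral(a, b, u), theta, tolerance = 1e-8)
  }
  # parallel normals, both perpendicular to the axis
  b0 <- nucleosome_pose(c(10, 0, 0), c(0, 0, 1), c(1, 0, 0), id = 2L)
  expect_equal(signed_dihedral(a, b0, u), 0)
})

test_that("reversing the step direction maps alpha to its 360-complement", {
  set.seed(21)
  for (k in 1:100) {
    a <- rand_pose(id = 1L)
    b <- rand_pose(center = a$center + 8 * rand_unit(), id = 2L)
    u <- (b$center - a$center) / sqrt(sum((b$center - a$center)^2))
    if (abs(sum(a$normal * u)) > 0.99 || abs(sum(b$normal * u)) > 0.99) next
    al <- signed_dihedral(a, b, u)
    rev <- signed_dihedral(a, b, -u)
    expect_equal((al + rev) %% 360, 0, tolerance = 1e-8)
  }
})

test_that("signed_dihedral rejects a normal parallel to the step axis", {
  a <- nucleosome_pose(c(0, 0, 0), c(0, 0, 1))
  b <- nucleosome_pose(c(0, 0, 8), c(1, 0, 0), id = 2L)
  expect_error(signed_dihedral(a, b, c(0, 0, 1)), "degenerate")
})

test_that("fiber_step_table recovers construction parameters", {
  # two-start with stacking rise 6: all within-stack D equal 6 exactly
  f <- build_ideal_fiber("two_start", 4, list(rise_nm = 6, alpha_deg = 80))
  st <- fiber_step_table(f)
  expect_equal(st$D_nm[1:2], c(6, 6), tolerance = 1e-9)
  expect_equal(attr(st, "summary")$mean_alpha_deg, 80, tolerance = 1e-6)
  # zigzag with per-step alpha 80 recovers mean alpha 80 exactly
  z <- build_ideal_fiber("zigzag", 8, list(alpha_deg = 80, para_deg = 45))
  sz <- fiber_step_table(z)
  expect_equal(sz$alpha_deg, rep(80, 7), tolerance = 1e-6)
  # collinear fiber of coplanar parallel discs: para = alpha = 0
  n <- 6
  coll <- fiber(cbind(0, 0, seq(0, by = 8, length.out = n)),
                matrix(rep(c(1, 0, 0), n), n, 3, byrow = TRUE))
  sc <- fiber_step_table(coll)
  expect_equal(sc$alpha_deg, rep(0, n - 1))
  expect_equal(sc$para_deg[1:(n - 2)], rep(0, n - 2))
  expect_error(fiber_step_table(fiber(cbind(c(0, 1), 0, 0),
                                      rbind(c(0, 0, 1), c(0, 0, 1)))),
               "length")
})

test_that("radius_of_gyration matches closed forms and the double-sum identity", {
  expect_equal(radius_of_gyration(matrix(c(0, 0, 0), 1, 3)), 0)
  expect_equal(radius_of_gyration(rbind(c(0, 0, 0), c(10, 0, 0))), 5)
  s <- 2.3
  coll <- cbind(seq(0, by = s, length.out = 12), 0, 0)
  expect_equal(radius_of_gyration(coll), s * sqrt(143 / 12), tolerance = 1e-12)
  set.seed(31)
  for (k in 1:20) {
    centers <- matrix(rnorm(36) * 10, 12, 3)
    expect_equal(radius_of_gyration(centers), brute_rg(centers),
                 tolerance = 1e-10)
  }
})

test_that("builder and step table are inverse on the noiseless zigzag", {
  for (al in c(80, 200, 230)) {
    z <- build_ideal_fiber("zigzag", 10,
                           list(alpha_deg = al, para_deg = 45, d_adj_nm = 10))
    s <- attr(fiber_step_table(z), "summary")
    expect_equal(s$mean_alpha_deg, al, tolerance = 1e-6)
    expect_equal(s$mean_d_adj_nm, 10, tolerance = 1e-6)
    expect_equal(s$mean_para_deg, 45, tolerance = 1e-6)
  }
  # at alpha = 50 adjacent discs are nearly parallel at the default spacing
  # and some steps have no clash-free exact-para solution: alpha and d_adj
  # stay exact, para takes the closest achievable value
  z50 <- build_ideal_fiber("zigzag", 10,
                           list(alpha_deg = 50, para_deg = 45,
                                d_adj_nm = 10))
  s50 <- attr(fiber_step_table(z50), "summary")
  expect_equal(s50$mean_alpha_deg, 50, tolerance = 1e-6)
  expect_equal(s50$mean_d_adj_nm, 10, tolerance = 1e-6)
  expect_equal(s50$mean_para_deg, 45, tolerance = 3 / 45)
})

test_that("two-start builder hits the configured mean dihedral", {
  for (al in c(50, 80)) {
    f <- build_ideal_fiber("two_start", 12, list(rise_nm = 6, alpha_deg = al))
    s <- attr(fiber_step_table(f), "summary")
    expect_equal(s$mean_alpha_deg, al, tolerance = 1e-6)
  }
})

test_that("the two zigzag salt-phasing constructions differ in alpha by 180 degrees", {
  z230 <- build_ideal_fiber("zigzag", 12, list(alpha_deg = 230, para_deg = 45))
  z50 <- build_ideal_fiber("zigzag", 12, list(alpha_deg = 50, para_deg = 45))
  a1 <- attr(fiber_step_table(z230), "summary")$mean_alpha_deg
  a2 <- attr(fiber_step_table(z50), "summary")$mean_alpha_deg
  expect_equal(nucleopack:::circular_diff_deg(a1, a2), 180, tolerance = 1e-6)
})

test_that("builders reject sterically impossible parameters", {
  expect_error(build_ideal_fiber("zigzag", 6,
                                 list(alpha_deg = 230, para_deg = 45,
                                      d_adj_nm = 3)),
               "steric overlap")
})
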