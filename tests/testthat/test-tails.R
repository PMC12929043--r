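# Residue-level tail contact counting and profiling on coarse-grained
# frames.

simple_frame <- function(xyz, chain, res, nuc, arr = NULL,
                         role = "tail-H4") {
  if (is.null(arr)) arr <- rep(1L, length(chain))
  make_frame(chain_id = chain, residue_index = res,
             residue_name = "LYS", role = role, nucleosome_id = nuc,
             array_id = arr, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
}

test_that("count_contacts applies the cutoff, bonded exclusion and scopes", {
  f <- simple_frame(rbind(c(0, 0, 0), c(6.9, 0, 0)), c("A", "B"), c(1, 1),
                    c(1, 2))
  ct <- count_contacts(f, cutoff = 7)
  expect_equal(nrow(ct), 1)
  expect_equal(ct$scope, "intra-array")  # different nucleosome, same array
  # same chain, residues i and i+2 within cutoff: bonded exclusion
  f2 <- simple_frame(rbind(c(0, 0, 0), c(3.8, 0, 0), c(1, 1, 0)),
                     rep("A", 3), 1:3, rep(1, 3))
  expect_equal(nrow(count_contacts(f2, cutoff = 7)), 0)
  # i and i+3 on the same chain do count (intra-nucleosome)
  f3 <- simple_frame(rbind(c(0, 0, 0), c(3.8, 0, 0), c(7.6, 0, 0),
                           c(1, 1, 0)), rep("A", 4), 1:4, rep(1, 4))
  ct3 <- count_contacts(f3, cutoff = 7)
  expect_equal(nrow(ct3), 1)
  expect_equal(ct3$scope, "intra-nucleosome")
  # beads beyond cutoff: none
  f4 <- simple_frame(rbind(c(0, 0, 0), c(7.1, 0, 0)), c("A", "B"), c(1, 1),
                     c(1, 2))
  expect_equal(nrow(count_contacts(f4, cutoff = 7)), 0)
})

test_that("cell-list contact counting equals the quadratic scan on a large frame", {
  set.seed(71)
  n <- 5000
  xyz <- matrix(runif(3 * n, 0, 120), n, 3)
  f <- simple_frame(xyz, chain = paste0("c", rep(1:100, each = 50)),
                    res = rep(1:50, 100),
                    nuc = rep(1:20, each = 250),
                    arr = rep(1:4, each = 1250))
  ct <- count_contacts(f, cutoff = 7)
  truth <- nucleopack:::.brute_scope_totals(f, 7)
  expect_equal(as.integer(table(factor(ct$scope,
                                       levels = truth$scope))),
               truth$count)
})

test_that("contact_profile averages across frames with population SDs", {
  # identical repeated frames: SD 0 everywhere
  fr <- gen_cg_frames(n_frames = 2, seed = 72)
  same <- list(fr[[1]], fr[[1]], fr[[1]])
  cp <- contact_profile(same)
  expect_true(all(cp$profile$sd == 0))
  # two hand-built frames (same topology) with 3 and 5 contacts for the
  # focal residue: mean 4, population SD 1
  mk <- function(n_in) {
    x <- c(3 + seq_len(n_in) * 0.1, rep(100, 5 - n_in))  # rest far away
    xyz <- rbind(c(0, 0, 0), cbind(x, 0, 0))
    make_frame(chain_id = c("A", paste0("B", 1:5)),
               residue_index = rep(1, 6), residue_name = "LYS",
               role = c("tail-H4", rep("DNA", 5)),
               nucleosome_id = c(1, rep(2, 5)), array_id = 1L,
               x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  }
  cp2 <- contact_profile(list(mk(3), mk(5)), cutoff = 7)
  row <- cp2$profile[cp2$profile$role == "tail-H4" &
                       cp2$profile$scope == "intra-array" &
                       cp2$profile$residue_index == 1, ]
  expect_equal(row$mean, 4)
  expect_equal(row$sd, 1)  # population convention, divide by n
  focal <- cp2$totals[cp2$totals$nucleosome_id == "1" &
                        cp2$totals$role == "tail-H4" &
                        cp2$totals$scope == "intra-array", ]
  expect_equal(focal$mean_total, 4)
  # inconsistent topology across frames is rejected
  other <- simple_frame(rbind(c(0, 0, 0), c(1, 0, 0)), c("A", "B"),
                        c(1, 1), c(1, 2))
  expect_error(contact_profile(list(mk(3), other)), "topology")
})

test_that("generated dinucleosome frames put H4 tails across the interface", {
  fr <- gen_cg_frames(n_frames = 3, seed = 73)
  cp <- contact_profile(fr)
  h4 <- cp$profile[cp$profile$role == "tail-H4" &
                     cp$profile$scope == "intra-array", ]
  h2b <- cp$profile[cp$profile$role == "tail-H2B" &
                      cp$profile$scope == "intra-array", ]
  # H4 bridges the interface; H2B walks are unbiased and contribute at
  # most stray contacts
  expect_gt(sum(h4$mean), 0)
  expect_gt(sum(h4$mean), 10 * sum(h2b$mean))
})

test_that("scope counts partition the total and profiles are stable", {
  fr <- gen_cg_frames(n_frames = 2, seed = 74)
  f <- fr[[1]]
  ct <- count_contacts(f)
  counts <- nucleopack:::.frame_bead_counts(f, 7)
  expect_equal(sum(counts), 2 * nrow(ct))  # each contact counted per bead
  expect_equal(sum(rowSums(counts[, 1:3])),
               sum(counts[, "intra-nucleosome"]) +
                 sum(counts[, "intra-array"]) + sum(counts[, "inter-array"]))
  # permutation invariance of the profile to bead row order
  set.seed(75)
  perm <- sample(nrow(f))
  fp <- cg_frame(as.data.frame(f)[perm, ])
  cp1 <- contact_profile(list(f))
  cp2 <- contact_profile(list(fp))
  expect_equal(cp1$profile, cp2$profile)
  # doubling the cutoff never decreases any per-residue count
  cp_small <- contact_profile(list(f), cutoff = 5)
  cp_big <- contact_profile(list(f), cutoff = 10)
  merged <- merge(cp_small$profile, cp_big$profile,
                  by = c("role", "residue_index", "scope"))
  expect_true(all(merged$mean.y >= merged$mean.x - 1e-12))
})

test_that("cg_frame validation catches malformed bead tables", {
  expect_error(make_frame(chain_id = "A", residue_index = 1,
                          residue_name = "LYS", role = "tail-H9",
                          nucleosome_id = 1, x = 0, y = 0, z = 0),
               "roles")
  expect_error(make_frame(chain_id = "A", residue_index = 1,
                          residue_name = "LYS", role = "tail-H4",
                          nucleosome_id = NA, x = 0, y = 0, z = 0),
               "nucleosome_id")
  expect_error(make_frame(chain_id = c("A", "A"), residue_index = c(1, 1),
                          residue_name = "LYS", role = "tail-H4",
                          nucleosome_id = 1, x = c(0, 1), y = 0, z = 0),
               "unique")
})
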