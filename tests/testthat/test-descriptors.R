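test_that("reference points handle degenerate and symmetric inputs", {
  p <- matrix(c(1.5, -2, 0.25), nrow = 1)
  rp <- compute_reference_points(p)
  expect_equal(rp$ctd, p[1, ])
  expect_equal(rp$cst, p[1, ])
  expect_equal(rp$fct, p[1, ])
  expect_equal(rp$ftf, p[1, ])

  two <- rbind(c(0, 0, 0), c(2, 0, 0))
  rp <- compute_reference_points(two)
  expect_equal(rp$ctd, c(1, 0, 0))
  # both atoms are equidistant from the midpoint: ties go to the lowest index
  expect_equal(unname(rp$idx["cst"]), 1L)
  expect_equal(unname(rp$idx["fct"]), 1L)
  expect_equal(unname(rp$idx["ftf"]), 2L)

  expect_error(compute_reference_points(matrix(nrow = 0, ncol = 3)),
               "at least one atom")
})

test_that("regular tetrahedron geometry matches the closed form", {
  tet <- rbind(c(0, 0, 0), c(1, 0, 0),
               c(0.5, sqrt(3) / 2, 0),
               c(0.5, sqrt(3) / 6, sqrt(6) / 3))
  rp <- compute_reference_points(tet)
  # all vertices lie sqrt(3/8) from the centroid; the tie rule picks vertex 1
  expect_equal(sqrt(sum((rp$fct - rp$ctd)^2)), sqrt(3 / 8), tolerance = 1e-12)
  expect_equal(unname(rp$idx["fct"]), 1L)
  v <- usr_descriptor(tet)
  expect_equal(v[1:3], c(sqrt(3 / 8), 0, 0), tolerance = 1e-12)
})

test_that("moment triple matches hand-computed values", {
  expect_equal(unname(moment_triple(3.7)), c(3.7, 0, 0))
  expect_equal(unname(moment_triple(c(0, 2))), c(1, 1, 0))
  # third central moment of {0,0,3}: ((-1)^3 + (-1)^3 + 2^3)/3 = 2
  expect_equal(unname(moment_triple(c(0, 0, 3))),
               c(1, sqrt(2), 2^(1 / 3)), tolerance = 1e-12)
  expect_error(moment_triple(numeric()), "empty")
})

test_that("USR and USRCAT vectors have the documented shape and prefix", {
  set.seed(42)
  X <- random_cloud(15)
  s <- random_subsets(15)
  v12 <- usr_descriptor(X)
  v60 <- usrcat_descriptor(X, s)
  expect_length(v12, 12)
  expect_length(v60, 60)
  expect_identical(v60[1:12], v12)
})

test_that("single considered atom gives an all-zero USR vector", {
  expect_equal(usr_descriptor(matrix(c(5, -1, 2), nrow = 1)), rep(0, 12))
  h2 <- conformer_record("h2", 0, rbind(c(0, 0, 0), c(0.74, 0, 0)),
                         elements = c("H", "H"))
  expect_error(usr_descriptor(h2, "exclude"), "no atoms")
  expect_equal(usr_descriptor(h2, "include")[2], 0)  # sigma of 2 equal dists
})

test_that("empty subsets produce exact zero blocks; full subsets repeat block 1", {
  set.seed(7)
  X <- random_cloud(10)
  none <- pharmacophore_subsets(n_atoms = 10)
  v <- usrcat_descriptor(X, none)
  expect_identical(v[13:60], rep(0, 48))
  all_idx <- 1:10
  full <- pharmacophore_subsets(all_idx, all_idx, all_idx, all_idx,
                                n_atoms = 10)
  vf <- usrcat_descriptor(X, full)
  for (b in 1:4) expect_identical(vf[b * 12 + 1:12], vf[1:12])
})

test_that("subset blocks equal moments of subset distances to all-atom points", {
  set.seed(7)
  X <- random_cloud(10)
  aro <- c(2, 5, 9)
  s <- pharmacophore_subsets(aromatic = aro, n_atoms = 10)
  v <- usrcat_descriptor(X, s)
  refs <- compute_reference_points(X)
  manual <- unlist(lapply(list(refs$ctd, refs$cst, refs$fct, refs$ftf),
                          function(p) {
    moment_triple(sqrt(rowSums(sweep(X[aro, ], 2, p)^2)))
  }), use.names = FALSE)
  expect_equal(v[25:36], manual, tolerance = 1e-14)
  bad <- pharmacophore_subsets(donor = 11)
  expect_error(usrcat_descriptor(X, bad), "out of range")
})

test_that("production descriptors match the brute-force oracle to 1e-10", {
  set.seed(1001)
  for (k in 1:60) {
    n <- sample(3:40, 1)
    X <- random_cloud(n)
    s <- random_subsets(n)
    expect_lt(max(abs(usrcat_descriptor(X, s) - oracle_usrcat(X, s))), 1e-10)
  }
})

test_that("descriptors are invariant under rigid motion and reflection", {
  set.seed(2002)
  for (k in 1:60) {
    n <- sample(3:40, 1)
    X <- random_cloud(n)
    s <- random_subsets(n)
    v <- usrcat_descriptor(X, s)
    R <- random_rotation()
    t <- rnorm(3, sd = 20)
    moved <- sweep(X %*% t(R), 2, t, `+`)
    expect_lt(max(abs(usrcat_descriptor(moved, s) - v)), 1e-8)
    mirrored <- X %*% diag(c(-1, 1, 1))
    expect_lt(max(abs(usrcat_descriptor(mirrored, s) - v)), 1e-8)
  }
})

test_that("atom-order permutation relabels but does not change descriptors", {
  set.seed(303)
  for (k in 1:20) {
    n <- sample(4:30, 1)
    X <- random_cloud(n)  # generic coordinates: reference ties have measure 0
    s <- random_subsets(n)
    perm <- sample.int(n)
    Xp <- X[perm, , drop = FALSE]
    inv <- order(perm)  # atom i moves to position inv[i]
    sp <- pharmacophore_subsets(inv[s$hydrophobic], inv[s$aromatic],
                                inv[s$acceptor], inv[s$donor], n_atoms = n)
    # summation order changes, so allow rounding at machine precision
    expect_lt(max(abs(usrcat_descriptor(Xp, sp) - usrcat_descriptor(X, s))),
              1e-12)
  }
})
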