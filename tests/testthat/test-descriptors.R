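two_atom <- conformer_record("m", 0, matrix(c(0, 0, 0, 2, 0, 0), 2, 3, byrow = TRUE),
                             charges = c(0.2, -0.1), logp_contribs = c(0.3, 0))

test_that("moment triple matches hand-computed central moments", {
  expect_equal(moment_triple(c(1, 1)), c(1, 0, 0))
  expect_equal(moment_triple(c(0, 2)), c(1, 1, 0))
  expect_equal(moment_triple(c(0, 0, 3)), c(1, sqrt(2), 2^(1 / 3)))
  expect_equal(moment_triple(5), c(5, 0, 0))  # single distance degenerates
  expect_error(moment_triple(numeric(0)), "non-empty")
  expect_error(moment_triple(c(-1, 2)), "non-negative")
})

test_that("USR reference points follow the ctd/cst/fct/ftf definitions", {
  # two points: hand enumeration
  refs <- usr_reference_points(matrix(c(0, 0, 0, 2, 0, 0), 2, 3, byrow = TRUE))
  expect_equal(refs["ctd", ], c(1, 0, 0))
  expect_equal(refs["cst", ], c(0, 0, 0))  # tie broken by lowest index
  expect_equal(refs["fct", ], c(0, 0, 0))
  expect_equal(refs["ftf", ], c(2, 0, 0))
  # three points: brute-force distance table
  pts <- matrix(c(0, 0, 0, 4, 0, 0, 0, 3, 0), 3, 3, byrow = TRUE)
  refs <- usr_reference_points(pts)
  expect_equal(refs["ctd", ], c(4 / 3, 1, 0))
  expect_equal(refs["cst", ], pts[1, ])
  expect_equal(refs["fct", ], pts[2, ])
  expect_equal(refs["ftf", ], pts[3, ])
  # degenerate single-atom cloud
  refs <- usr_reference_points(matrix(c(1, 2, 3), 1, 3))
  expect_true(all(apply(refs, 1, function(r) all(r == c(1, 2, 3)))))
})

test_that("ElectroShape reference points are selections plus a cross-product pair", {
  cl <- random_point_cloud(10, seed = 42)
  pts <- augment_points(cl, "es4d")
  refs <- electroshape_reference_points(pts)
  # c2 and c3 are members of the cloud; c1 generally is not
  in_cloud <- function(p) any(apply(pts, 1, function(r) all(abs(r - p) < 1e-12)))
  expect_true(in_cloud(refs["c2", ]))
  expect_true(in_cloud(refs["c3", ]))
  expect_false(in_cloud(refs["c1", ]))
  expect_equal(unname(refs["c4", 4]), max(pts[, 4]))
  expect_equal(unname(refs["c5", 4]), min(pts[, 4]))
  expect_equal(unname(refs["c4", 1:3]), unname(refs["c5", 1:3]))
  # single atom: every reference point collapses onto it
  single <- conformer_record("s", 0, matrix(1:3, 1, 3), charges = 0.1,
                             logp_contribs = 0.2)
  refs1 <- suppressMessages(
    electroshape_reference_points(augment_points(single, "es5d"))
  )
  expect_true(all(apply(refs1, 1, function(r) max(abs(r - refs1["c1", ])) < 1e-12)))
})

test_that("augmentation scales charge and logP onto spatial magnitudes", {
  pts <- augment_points(two_atom, descriptor_scheme("es4d", charge_scale = 25))
  expect_equal(pts[, 4], c(5, -2.5))  # 25 * 0.2, 25 * -0.1
  expect_identical(augment_points(two_atom, "usr"), unname(two_atom$coords))
  bare <- conformer_record("b", 0, matrix(rnorm(9), 3, 3))
  expect_error(augment_points(bare, "es4d"), "charges")
  # zero augmentation reduces distances to the 3D case for shared refs
  flat <- conformer_record("f", 0, two_atom$coords, charges = c(0, 0),
                           logp_contribs = c(0, 0))
  p5 <- augment_points(flat, "es5d")
  expect_equal(p5[, 4:5], matrix(0, 2, 2))
})

test_that("hydrogen exclusion respects element symbols", {
  cr <- conformer_record("h", 0, matrix(c(0, 0, 0, 1, 0, 0, 9, 9, 9), 3, 3, byrow = TRUE),
                         charges = c(0, 0.1, 0.4), elements = c("C", "C", "H"))
  pts <- augment_points(cr, descriptor_scheme("usr", include_hydrogens = FALSE))
  expect_equal(nrow(pts), 2L)
  expect_equal(nrow(augment_points(cr, "usr")), 3L)
})

test_that("two-atom USR descriptor matches the hand computation", {
  expect_equal(pkg_descriptor(two_atom, "usr"),
               c(1, 0, 0, 1, 1, 0, 1, 1, 0, 1, 1, 0))
  single <- conformer_record("s", 0, matrix(0, 1, 3))
  expect_equal(pkg_descriptor(single, "usr"), rep(0, 12))
})

test_that("descriptors match the naive loop-based oracle on random clouds", {
  for (seed in 1:25) {
    cl <- random_point_cloud(3 + seed %% 28, seed = seed)
    for (method in c("usr", "es4d", "es5d")) {
      expect_equal(pkg_descriptor(cl, method), naive_descriptor(cl, method),
                   tolerance = 1e-12)
    }
  }
})

test_that("descriptors are invariant under rigid motion, spatial dims only", {
  for (seed in 1:10) {
    cl <- random_point_cloud(4 + seed, seed = seed)
    moved <- rigid_transform(cl, seed = seed + 100)
    for (method in c("usr", "es4d", "es5d")) {
      expect_lt(max(abs(pkg_descriptor(cl, method) - pkg_descriptor(moved, method))),
                1e-9)
    }
  }
})

test_that("USR cannot distinguish enantiomers", {
  for (seed in 1:10) {
    cl <- random_point_cloud(5 + seed, seed = seed)
    expect_lt(max(abs(pkg_descriptor(cl, "usr") -
                        pkg_descriptor(mirror_conformer(cl), "usr"))), 1e-12)
  }
})

test_that("descriptors are permutation invariant and scale covariant", {
  cl <- random_point_cloud(15, seed = 9)
  perm <- sample(15)
  shuffled <- conformer_record(cl$mol_id, cl$conf_id, cl$coords[perm, ],
                               charges = cl$charges[perm],
                               logp_contribs = cl$logp_contribs[perm])
  for (method in c("usr", "es5d")) {
    expect_equal(pkg_descriptor(cl, method), pkg_descriptor(shuffled, method),
                 tolerance = 1e-12)
  }
  scaled <- conformer_record(cl$mol_id, cl$conf_id, 2.5 * cl$coords)
  base <- conformer_record(cl$mol_id, cl$conf_id, cl$coords)
  expect_equal(pkg_descriptor(scaled, "usr"), 2.5 * pkg_descriptor(base, "usr"),
               tolerance = 1e-12)
})

test_that("batch descriptor computation skips failing conformers with a warning", {
  good <- random_point_cloud(6, seed = 1, mol_id = "a")
  bare <- conformer_record("b", 0, matrix(rnorm(9), 3, 3))  # no charges
  out <- compute_descriptors(list(good, bare, good), "usr")
  expect_equal(nrow(out), 3L)
  expect_warning(out <- compute_descriptors(list(good, bare), "es5d"), "Skipped")
  expect_equal(nrow(out), 1L)
  expect_equal(attr(out, "n_skipped"), 1L)
  expect_error(suppressWarnings(compute_descriptors(list(bare), "es5d")), "All conformers")
  empty <- compute_descriptors(list(), "usr")
  expect_equal(nrow(empty), 0L)
})
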