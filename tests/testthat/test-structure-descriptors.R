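test_that("hydrogen-bond fixtures return their constructed counts", {
  expect_equal(count_imhb(build_hbond_fixture("one_imhb"))$count, 1)
  expect_equal(count_imhb(build_hbond_fixture("zero_imhb"))$count, 0)
  expect_equal(count_imhb(build_hbond_fixture("two_imhb"))$count, 2)
  expect_equal(count_imhb(build_hbond_fixture("apolar"))$count, 0)
  expect_error(build_hbond_fixture("nope"))
})

test_that("hydrogen-bond detection respects the distance and angle windows", {
  # geometry helper: donor O at origin, H on +x, acceptor at distance d from
  # H with D-H...A angle ang in the xy-plane
  make <- function(d, ang) {
    h <- c(0.96, 0, 0)
    u <- c(-1, 0, 0)
    th <- ang * pi / 180
    a <- h + d * (cos(th) * u + sin(th) * c(0, -1, 0))
    conformer_structure(c("O", "H", "O", "C"),
                        rbind(c(0, 0, 0), h, a, a + c(0, 1.22, 0)),
                        rbind(c(1L, 2L), c(3L, 4L)))
  }
  expect_equal(count_imhb(make(2.0, 165))$count, 1)   # inside both windows
  expect_equal(count_imhb(make(3.0, 165))$count, 0)   # beyond 2.6 A
  expect_equal(count_imhb(make(1.2, 165))$count, 0)   # below 1.5 A
  expect_equal(count_imhb(make(2.0, 90))$count, 0)    # below 110 degrees
  expect_equal(count_imhb(make(2.0, 111))$count, 1)   # just inside the angle
  res <- count_imhb(make(2.0, 165))
  expect_equal(res$triples$distance, 2.0, tolerance = 1e-9)
  expect_equal(res$triples$angle, 165, tolerance = 1e-6)
})

test_that("IMHB count is invariant under rigid-body motion and caps per H", {
  st <- build_hbond_fixture("two_imhb")
  for (s in 1:4) {
    st2 <- conformer_structure(st$elements,
                               random_rigid_transform(st$coords, s),
                               st$bonds)
    expect_equal(count_imhb(st2)$count, 2)
  }
  # one H flanked by two in-window acceptors counts once (nearest wins)
  h <- c(0.96, 0, 0)
  u <- c(-1, 0, 0)
  place <- function(d, ang, sgn) {
    h + d * (cos(ang * pi / 180) * u + sgn * sin(ang * pi / 180) * c(0, 1, 0))
  }
  st3 <- conformer_structure(c("O", "H", "O", "O"),
                             rbind(c(0, 0, 0), h,
                                   place(2.0, 160, 1), place(2.3, 160, -1)),
                             matrix(c(1L, 2L), 1))
  res <- count_imhb(st3)
  expect_equal(res$count, 1)
  expect_equal(res$triples$acceptor, 3)   # the closer acceptor
})

test_that("polar surface area reproduces the analytic sphere", {
  p0 <- psa_parameters(probe_radius = 0, n_sphere_points = 960)
  iso <- conformer_structure("O", matrix(0, 1, 3))
  expect_equal(psa_3d(iso, p0), 4 * pi * 1.52^2, tolerance = 0.02)
  # apolar molecule has zero polar surface
  expect_equal(psa_3d(build_hbond_fixture("apolar")), 0)
  # polar hydrogens (H on N/O) contribute, H on C does not
  xy <- rbind(c(0, 0, 0), c(0.96, 0, 0))
  oh <- conformer_structure(c("O", "H"), xy, matrix(c(1L, 2L), 1))
  oh_nobond <- conformer_structure(c("O", "H"), xy)  # H not marked polar
  expect_gt(psa_3d(oh), psa_3d(oh_nobond))
  ch <- conformer_structure(c("C", "H"), rbind(c(0, 0, 0), c(1.09, 0, 0)),
                            matrix(c(1L, 2L), 1))
  expect_equal(psa_3d(ch), 0)
  expect_error(psa_3d(conformer_structure("Xx", matrix(0, 1, 3))),
               "Xx")
})

test_that("coincident duplicate atoms do not double count surface", {
  p0 <- psa_parameters(probe_radius = 0, n_sphere_points = 960)
  one <- conformer_structure("O", matrix(0, 1, 3))
  two <- conformer_structure(c("O", "O"), matrix(0, 2, 3))
  expect_equal(psa_3d(two, p0), psa_3d(one, p0), tolerance = 1e-12)
  # nearly coincident atoms approximate the single-sphere area from above
  near <- conformer_structure(c("O", "O"),
                              rbind(c(0, 0, 0), c(0.01, 0, 0)))
  a1 <- psa_3d(one, p0)
  a2 <- psa_3d(near, p0)
  expect_lt(abs(a2 - a1) / a1, 0.05)
})

test_that("surface area shrinks as an occluder approaches, and converges", {
  p0 <- psa_parameters(probe_radius = 0)
  area_at <- function(x) {
    st <- conformer_structure(c("O", "C"), rbind(c(0, 0, 0), c(x, 0, 0)))
    psa_3d(st, p0)
  }
  areas <- vapply(c(5, 3.1, 2.5, 2.0, 1.5), area_at, numeric(1))
  expect_true(all(diff(areas) <= 1e-9))
  expect_equal(areas[1], 4 * pi * 1.52^2, tolerance = 1e-6)  # no contact at 5 A
  # lattice convergence on a multi-atom fixture
  set.seed(41)
  n <- 50
  el <- sample(c("C", "N", "O", "H"), n, TRUE, prob = c(0.4, 0.2, 0.2, 0.2))
  co <- matrix(rnorm(3 * n, sd = 3), n, 3)
  st <- conformer_structure(el, co)
  a960 <- psa_3d(st, psa_parameters(n_sphere_points = 960))
  a3840 <- psa_3d(st, psa_parameters(n_sphere_points = 3840))
  expect_lt(abs(a960 - a3840) / a3840, 0.01)
})

test_that("IMHB profiles are percentages over the 0/1/2/3+ bins", {
  kinds <- c("one_imhb", "one_imhb", "zero_imhb", "two_imhb")
  structs <- lapply(kinds, build_hbond_fixture)
  prof <- imhb_profile(structs)
  expect_equal(sum(prof$percent), 100, tolerance = 1e-9)
  expect_equal(prof$percent[prof$imhb == "1"], 50)
  expect_equal(prof$percent[prof$imhb == "0"], 25)
  expect_equal(prof$percent[prof$imhb == "2"], 25)
  # degenerate cases
  same <- imhb_profile(list(build_hbond_fixture("apolar")))
  expect_equal(same$percent[same$imhb == "0"], 100)
  expect_error(imhb_profile(list()), "no structures")
})

test_that("descriptor tables join IMHB, PSA and energy bins", {
  structs <- lapply(c("one_imhb", "zero_imhb"), build_hbond_fixture)
  df <- descriptor_table(structs, energies = c(3, 12))
  expect_equal(df$imhb, c(1, 0))
  expect_true(all(df$psa_3d > 0))
  expect_identical(as.character(df$energy_bin), c("low", "mid"))
})
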