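test_that("element stiffness matches a higher-quadrature oracle", {
  k2 <- hex8_stiffness(12000, 0.3, 0.035)
  k3 <- hex8_stiffness(12000, 0.3, 0.035, n_gauss = 3)
  expect_lt(max(abs(k2 - k3)) / max(abs(k2)), 1e-12)
  expect_lt(max(abs(k2 - t(k2))), 1e-9)
  ## rigid translations produce no force
  for (dir in 1:3) {
    u <- rep(0, 24); u[seq(dir, 24, by = 3)] <- 1
    expect_lt(max(abs(k2 %*% u)), 1e-8 * max(abs(k2)))
  }
})

test_that("a solid block under uniaxial compression follows the closed form", {
  sys <- assemble(solid_block(2, 2, 2), trab())
  sol <- solve_compression(sys, 0.001)
  expect_equal(sol$apparent_stress, 12000 * 0.001, tolerance = 1e-8)
  ## principal strains (nu e, nu e, -e) with free lateral faces
  expect_equal(unname(sol$principal[1, ]), c(3e-4, 3e-4, -1e-3),
               tolerance = 1e-7)
  ## work balance
  expect_lt(abs(sol$external_work - sol$stored_energy) /
              sol$stored_energy, 1e-6)
})

test_that("element stiffness scales linearly with solid fraction", {
  s1 <- solve_compression(assemble(single_voxel(), trab()), 0.001)
  sh <- solve_compression(assemble(manual_model(array(0.5, c(1, 1, 1))),
                                   trab()), 0.001)
  expect_equal(sh$apparent_stress / s1$apparent_stress, 0.5,
               tolerance = 1e-12)
})

test_that("a voxel column's apparent modulus equals the tissue modulus", {
  sys <- assemble(solid_block(1, 1, 8), trab())
  sol <- solve_compression(sys, 0.001)
  expect_lt(abs(sol$apparent_stress / 0.001 - 12000) / 12000, 0.01)
})

test_that("zero applied strain yields a zero field", {
  sol <- solve_compression(assemble(rod_small(), trab()), 0)
  expect_equal(max(abs(sol$u)), 0)
  expect_equal(sol$apparent_stress, 0)
})

test_that("apparent stress scales linearly with tissue modulus", {
  rod <- rod_small()
  s1 <- solve_compression(assemble(rod, trab()), 0.001)
  m2 <- material_preset("trabecular", E = 24000)
  s2 <- solve_compression(assemble(rod, m2), 0.001)
  expect_equal(s2$apparent_stress / s1$apparent_stress, 2, tolerance = 1e-9)
})

test_that("strain recovery is exact for a linear displacement field and null
           for a small rigid rotation", {
  sys <- assemble(solid_block(2, 2, 2), trab())
  xyz <- sys$xyz
  dof_xyz <- xyz[rep(seq_len(nrow(xyz)), each = 3), ]
  comp <- rep(1:3, nrow(xyz))
  ## uniform strain exx = 1e-3: u_x = 1e-3 * x
  u <- numeric(sys$ndof)
  u[comp == 1] <- 1e-3 * dof_xyz[comp == 1, 1]
  Ue <- matrix(u[sys$dofmat], sys$n_e, 24)
  eps <- Ue %*% t(sys$Bc)
  expect_equal(unname(eps[1, ]), c(1e-3, 0, 0, 0, 0, 0), tolerance = 1e-12)
  ## small rotation about z: u = omega x r, strains vanish to linear order
  om <- 1e-6
  u2 <- numeric(sys$ndof)
  u2[comp == 1] <- -om * dof_xyz[comp == 1, 2]
  u2[comp == 2] <- om * dof_xyz[comp == 2, 1]
  eps2 <- matrix(u2[sys$dofmat], sys$n_e, 24) %*% t(sys$Bc)
  expect_lt(max(abs(eps2)), 1e-15)
})

test_that("principal strain extraction matches an eigenvalue oracle", {
  set.seed(7)
  eps <- matrix(rnorm(200 * 6, sd = 0.01), 200, 6)
  got <- trabsim:::principal_from_tensor(eps)
  for (i in seq_len(nrow(eps))) {
    e <- eps[i, ]
    Tm <- matrix(c(e[1], e[4] / 2, e[6] / 2,
                   e[4] / 2, e[2], e[5] / 2,
                   e[6] / 2, e[5] / 2, e[3]), 3, 3)
    expect_equal(unname(got[i, ]), sort(eigen(Tm, symmetric = TRUE)$values,
                                        decreasing = TRUE), tolerance = 1e-9)
  }
})

test_that("solution is invariant to strut table ordering", {
  rod <- rod_small()
  rod2 <- rod
  set.seed(1)
  rod2$struts <- rod2$struts[sample(nrow(rod2$struts)), ]
  rod2 <- trabsim:::revoxelize(rod2)
  a1 <- solve_compression(assemble(rod, trab()), 0.001)$apparent_stress
  a2 <- solve_compression(assemble(rod2, trab()), 0.001)$apparent_stress
  expect_equal(a1, a2, tolerance = 1e-10)
})

test_that("floating components are dropped and empty systems error", {
  frac <- array(0, c(3, 3, 3))
  frac[2, 2, ] <- 1          # spanning column
  frac[1, 1, 2] <- 1         # floating voxel
  sys <- assemble(manual_model(frac), trab())
  expect_identical(sys$n_dropped, 1L)
  expect_identical(sys$n_e, 3L)
  expect_error(assemble(manual_model(array(0, c(2, 2, 2))), trab()),
               "no effective elements")
  ## a slab not reaching the top face has no load path
  frac2 <- array(0, c(2, 2, 3)); frac2[, , 1] <- 1
  expect_error(assemble(manual_model(frac2), trab()), "no solid component")
})

test_that("conjugate-gradient and direct solutions agree", {
  rod <- rod_small()
  sd <- solve_compression(assemble(rod, trab(), solver = "direct"), 0.001)
  sc <- solve_compression(assemble(rod, trab(), solver = "cg"), 0.001)
  expect_equal(sc$apparent_stress, sd$apparent_stress, tolerance = 1e-6)
})
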