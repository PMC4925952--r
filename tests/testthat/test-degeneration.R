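test_that("random strut selection is uniform-without-replacement and seeded", {
  rod <- rod_test()
  act <- rod$struts[!rod$struts$removed, ]
  eligible <- act$id[!act$boundary]
  expect_identical(select_random_struts(rod, 0, 1), integer(0))
  all1 <- select_random_struts(rod, length(eligible), 5)
  expect_setequal(all1, eligible)
  expect_identical(select_random_struts(rod, 10, 3),
                   select_random_struts(rod, 10, 3))
  expect_error(select_random_struts(rod, length(eligible) + 1, 1), "eligible")
  ## boundary struts are never drawn
  expect_false(any(select_random_struts(rod, 30, 2) %in% act$id[act$boundary]))
})

test_that("low-strain ranking puts an unloaded cross-brace first", {
  ## two vertical columns joined by one horizontal brace at mid-height
  a <- 500; t <- 100
  struts <- data.frame(
    id = 1:3,
    axis = c("z", "z", "x"),
    orientation = c("vertical", "vertical", "horizontal"),
    x0 = c(100, 800, 150), x1 = c(200, 900, 850),
    y0 = c(100, 100, 100), y1 = c(200, 200, 200),
    z0 = c(0, 0, 450), z1 = c(1000, 1000, 550),
    thickness = t, shrink = c("xy", "xy", "yz"),
    boundary = c(TRUE, TRUE, FALSE), removed = FALSE,
    stringsAsFactors = FALSE)
  frame <- trabsim:::new_voxel_model(struts, grid = c(20L, 4L, 20L), voxel = 50,
                                     lattice = list(type = "manual",
                                                    thickness = t, spacing = a,
                                                    cells = c(1L, 1L, 1L),
                                                    requested_voxel = 50))
  rk <- trabsim:::strut_strain_ranking(frame, trab())
  expect_identical(rk$ids[1], 3L)
  expect_identical(identify_low_strain_struts(frame, trab(), 1 / 3), 3L)
  ## percentile -> 1 returns every strut
  expect_setequal(identify_low_strain_struts(frame, trab(), 1), 1:3)
})

test_that("percentile semantics are strict on a single-strut model", {
  col <- manual_model(array(1, c(2, 2, 6)), 70)
  expect_identical(identify_low_strain_struts(col, trab(), 0.5), integer(0))
  expect_identical(identify_low_strain_struts(col, trab(), 1), 1L)
})

test_that("thinning reduces BV/TV by the junction-corrected closed form", {
  rod <- rod_small()
  bv0 <- compute_morphometrics(rod, components = FALSE)$bvtv
  thin <- thin_struts(rod, rod$struts$id, 126)
  bv1 <- compute_morphometrics(thin, components = FALSE)$bvtv
  a <- rod$lattice$spacing
  expect_lt(abs(bv1 / bv0 -
                  continuous_bvtv("rod", 126 / a) /
                  continuous_bvtv("rod", 140 / a)), 1e-9)
  ## identity cases
  expect_identical(thin_struts(rod, integer(0), 126)$frac, rod$frac)
  expect_identical(thin_struts(rod, rod$struts$id[1], 140)$frac, rod$frac)
  expect_error(thin_struts(rod, rod$struts$id[1], 150), "exceeds")
  expect_error(thin_struts(rod, rod$struts$id[1], 0), "positive")
})

test_that("thinning never touches voxels outside the listed struts", {
  rod <- rod_small()
  ids <- rod$struts$id[rod$struts$axis == "x"][1:2]
  thin <- thin_struts(rod, ids, 100)
  rows <- match(ids, rod$struts$id)
  touched <- array(FALSE, dim = rod$grid)
  for (r in rows) {
    ox <- trabsim:::axis_cover(rod$struts$x0[r], rod$struts$x1[r],
                               rod$grid[1], rod$voxel)
    oy <- trabsim:::axis_cover(rod$struts$y0[r], rod$struts$y1[r],
                               rod$grid[2], rod$voxel)
    oz <- trabsim:::axis_cover(rod$struts$z0[r], rod$struts$z1[r],
                               rod$grid[3], rod$voxel)
    touched[ox$idx, oy$idx, oz$idx] <- TRUE
  }
  expect_identical(thin$frac[!touched], rod$frac[!touched])
  expect_true(any(thin$frac[touched] != rod$frac[touched]))
})

test_that("strut removal bookkeeping matches the voxel-count oracle", {
  rod <- rod_small()
  expect_identical(remove_struts(rod, integer(0))$frac, rod$frac)
  id <- rod$struts$id[!rod$struts$boundary][1]
  rm1 <- remove_struts(rod, id)
  dv <- sum(rod$frac) - sum(rm1$frac)
  v_before <- trabsim:::continuous_solid_volume(rod$struts)
  v_after <- trabsim:::continuous_solid_volume(rm1$struts)
  expect_equal(dv * rod$voxel^3, v_before - v_after, tolerance = 1e-6)
  expect_error(remove_struts(rod, 99999L), "unknown")
  expect_error(remove_struts(rm1, id), "already removed")
})

test_that("removing all vertical struts severs the load path", {
  rod <- rod_small()
  vert <- rod$struts$id[rod$struts$orientation == "vertical"]
  cut <- remove_struts(rod, vert)
  expect_false(check_load_path(cut)$connected)
  expect_true(check_load_path(rod)$connected)
  empty <- remove_struts(rod, rod$struts$id)
  expect_false(check_load_path(empty)$connected)
})

test_that("removing one cell level of vertical struts disconnects the model", {
  rod <- rod_test()
  s <- rod$struts
  lvl <- s$id[s$orientation == "vertical" & s$z0 > 0.9 * rod$lattice$spacing &
                s$z1 < 2.1 * rod$lattice$spacing]
  expect_identical(length(lvl), 9L)
  expect_false(check_load_path(remove_struts(rod, lvl))$connected)
})

test_that("two-step aging hits the rod and plate reduction targets", {
  rod <- rod_test()
  bv0 <- compute_morphometrics(rod, components = FALSE)$bvtv
  spB <- degeneration_spec("random", "two_step", 0.15, seed = 1)
  rodB <- apply_aging(rod, spB)
  red <- 1 - compute_morphometrics(rodB, components = FALSE)$bvtv / bv0
  expect_lt(abs(red - 0.15), 0.005)
  expect_equal(attr(rodB, "achieved_reduction"), red, tolerance = 1e-6)
  spC <- degeneration_spec("low_strain", "two_step", 0.15, seed = 1)
  rodC <- apply_aging(rod, spC, trab())
  expect_lt(abs(attr(rodC, "achieved_reduction") - 0.15), 0.005)
  plate <- build_normal_model("plate", c(2, 2, 3), 140)
  bp0 <- compute_morphometrics(plate, components = FALSE)$bvtv
  plB <- apply_aging(plate, degeneration_spec("random", "two_step", 0.25,
                                              seed = 1))
  expect_lt(abs(1 - compute_morphometrics(plB, components = FALSE)$bvtv / bp0 -
                  0.25), 0.005)
  ## zero target is the identity
  sp0 <- degeneration_spec("random", "two_step", 0, seed = 1)
  expect_identical(apply_aging(rod, sp0)$frac, rod$frac)
})

test_that("single-mechanism patterns land on the 8% target", {
  rod <- rod_test()
  bv0 <- compute_morphometrics(rod, components = FALSE)$bvtv
  for (pat in c("thinning_only", "vertical_loss", "horizontal_loss")) {
    sp <- degeneration_spec("random", pat, 0.08, seed = 1, tolerance = 0.02)
    aged <- apply_aging(rod, sp)
    red <- 1 - compute_morphometrics(aged, components = FALSE)$bvtv / bv0
    expect_lt(abs(red - 0.08), 0.02)
    ## degeneration is BV/TV-non-increasing
    expect_lt(compute_morphometrics(aged, components = FALSE)$bvtv, bv0)
    ## removal patterns only remove the requested orientation
    if (pat != "thinning_only") {
      want <- if (pat == "vertical_loss") "vertical" else "horizontal"
      rem <- aged$struts[aged$struts$removed, ]
      expect_true(all(rem$orientation == want))
      expect_false(any(rem$boundary))
    }
  }
  ## equal strut volumes: both loss patterns remove equally many struts
  nv <- sum(apply_aging(rod, degeneration_spec("random", "vertical_loss",
                                               0.08, seed = 1,
                                               tolerance = 0.02))$struts$removed)
  nh <- sum(apply_aging(rod, degeneration_spec("random", "horizontal_loss",
                                               0.08, seed = 1,
                                               tolerance = 0.02))$struts$removed)
  expect_identical(nv, nh)
})

test_that("aging is bit-identical under a fixed seed", {
  rod <- rod_test()
  sp <- degeneration_spec("random", "two_step", 0.15, seed = 11)
  a1 <- apply_aging(rod, sp)
  a2 <- apply_aging(rod, sp)
  expect_identical(a1$frac, a2$frac)
  expect_identical(a1$struts, a2$struts)
  sp2 <- degeneration_spec("random", "two_step", 0.15, seed = 12)
  expect_false(identical(apply_aging(rod, sp2)$frac, a1$frac))
})

test_that("unreachable targets raise with the achieved reduction", {
  rod <- rod_small()
  ## (2,2,2) has no interior vertical struts at all
  expect_error(apply_aging(rod, degeneration_spec("random", "vertical_loss",
                                                  0.08, seed = 1)))
  expect_error(degeneration_spec("random", "two_step", 1.2), "target")
})
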