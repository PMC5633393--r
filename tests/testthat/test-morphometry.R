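plate_phantom <- function(vox = 10, shape = c(40, 40, 100)) {
  make_phantom(phantom_spec("parallel_plates", plate_thickness_um = 100,
                            plate_spacing_um = 400, voxel_um = vox,
                            shape_voxels = shape))
}

test_that("ROI slab selection follows the half-open slice arithmetic", {
  arr <- array(FALSE, c(10, 10, 150))
  arr[1, 1, ] <- TRUE # marker column so slabs are distinguishable
  v <- voxel_volume(arr, voxel_um = 10)

  slab <- select_roi(v, roi_spec(0, offset_mm = 0.36, width_mm = 1))
  expect_identical(dim(slab), c(10L, 10L, 100L)) # slices [36, 136)
  expect_identical(trabqtl:::vv_array(slab), arr[, , 37:136])

  slab2 <- select_roi(v, roi_spec(0, offset_mm = 0.25, width_mm = 0.5))
  expect_identical(dim(slab2)[3], 50L) # slices [25, 75)
  expect_identical(trabqtl:::vv_array(slab2), arr[, , 26:75])

  ident <- select_roi(v, roi_spec(0, offset_mm = 0, width_mm = 1.5))
  expect_identical(trabqtl:::vv_array(ident), arr)

  expect_error(select_roi(v, roi_spec(0, offset_mm = 1, width_mm = 1)),
               "exceeds the volume")
  expect_error(select_roi(v, roi_spec(0, offset_mm = 0.333, width_mm = 1)),
               "whole number")
})

test_that("BV/TV is exact voxel counting and axis-permutation invariant", {
  arr <- array(FALSE, c(10, 10, 10))
  arr[seq_len(200)] <- TRUE
  v <- voxel_volume(arr, 10)
  expect_identical(bv_tv(v), 0.2)
  expect_identical(bv_tv(voxel_volume(array(TRUE, c(8, 8, 8)), 10)), 1)
  expect_identical(bv_tv(voxel_volume(aperm(arr, c(3, 1, 2)), 10)), 0.2)
})

test_that("local thickness recovers plates, balls and rods", {
  pl <- plate_phantom()
  expect_equal(tb_th(pl), 0.1, tolerance = 0.01)  # 1 voxel
  expect_equal(tb_sp(pl), 0.4, tolerance = 0.01)

  ball <- make_phantom(phantom_spec("solid_ball", ball_radius_um = 200,
                                    voxel_um = 10,
                                    shape_voxels = c(60, 60, 60)))
  expect_equal(tb_th(ball), 0.4, tolerance = 0.01)

  rod <- make_phantom(phantom_spec("square_lattice_rods", rod_radius_um = 80,
                                   rod_pitch_um = 500, voxel_um = 10,
                                   shape_voxels = c(100, 100, 40)))
  expect_equal(tb_th(rod), 0.16, tolerance = 0.015)

  expect_error(tb_th(voxel_volume(array(FALSE, c(8, 8, 8)), 10)), "empty")
  expect_error(tb_sp(voxel_volume(array(TRUE, c(8, 8, 8)), 10)), "empty")
})

test_that("separation is the thickness of the complement, exactly", {
  withr::with_seed(7, {
    arr <- array(runif(12 * 10 * 8) < 0.4, c(12, 10, 8))
  })
  arr[1, 1, 1] <- TRUE # both phases non-empty
  arr[2, 1, 1] <- FALSE
  v <- voxel_volume(arr, 10)
  expect_identical(tb_sp(v), tb_th(complement_volume(v)))
})

test_that("empty phases are flagged as box-censored", {
  v <- voxel_volume(array(FALSE, c(8, 8, 8)), 10)
  expect_warning(val <- tb_sp(v), "box")
  expect_equal(val, 8 * 10 / 1000)
})

test_that("trabecular number follows the direct model and its scaling law", {
  pl <- plate_phantom()
  expect_equal(tb_n(pl), 2, tolerance = 0.05) # 1 / (0.1 + 0.4) mm
  pl2 <- make_phantom(phantom_spec("parallel_plates", 200, 800, voxel_um = 10,
                                   shape_voxels = c(40, 40, 100)))
  expect_equal(tb_n(pl2), tb_n(pl) / 2, tolerance = 0.03)
  expect_equal(tb_n(pl, model = "plate"), bv_tv(pl) / tb_th(pl))
})

test_that("trabecular number matches line-intercept counts on plates", {
  # scan lines normal to the plates cross one plate per period: the
  # intercept density equals 1/(t+s), the direct-model Tb.N for plates
  pl <- plate_phantom()
  arr <- trabqtl:::vv_array(pl)
  runs <- apply(arr, c(1, 2), function(col) sum(diff(c(FALSE, col)) == 1))
  intercepts_per_mm <- mean(runs) / (dim(arr)[3] * 10 / 1000)
  expect_equal(tb_n(pl), intercepts_per_mm, tolerance = 0.05)
})

test_that("Euler characteristic matches canonical topologies", {
  ball <- make_phantom(phantom_spec("solid_ball", ball_radius_um = 100,
                                    voxel_um = 10,
                                    shape_voxels = c(30, 30, 30)))
  expect_identical(euler_characteristic(ball), 1L)

  two <- array(FALSE, c(20, 8, 8))
  two[2:4, 2:4, 2:4] <- TRUE
  two[10:14, 2:5, 2:5] <- TRUE
  expect_identical(euler_characteristic(voxel_volume(two, 10)), 2L)
  expect_identical(oracle_euler(two), 2L)

  tor <- torus_volume(150, 50, 10)
  expect_identical(euler_characteristic(tor), 0L)
})

test_that("configuration-count Euler equals the brute-force complex count", {
  withr::with_seed(11, {
    for (i in 1:60) {
      d <- sample(2:6, 3, replace = TRUE)
      mask <- array(runif(prod(d)) < runif(1, 0.2, 0.8), d)
      pad <- array(FALSE, pmax(d, 8)) # satisfy the min-dimension invariant
      pad[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- mask
      expect_identical(euler_characteristic(voxel_volume(pad, 10)),
                       as.integer(oracle_euler(pad)))
    }
  })
})

test_that("connectivity density counts independent loops per volume", {
  # 100^3 voxels at 10 um = 1 mm^3 total volume
  ballbox <- array(FALSE, c(100, 100, 100))
  ballbox[40:60, 40:60, 40:60] <- TRUE
  expect_equal(conn_d(voxel_volume(ballbox, 10)), 0)

  torbox <- trabqtl:::vv_array(torus_volume(250, 80, 10,
                                            shape_voxels = c(100, 100, 100)))
  expect_equal(conn_d(voxel_volume(torbox, 10)), 1)

  # a two-loop frame: two square circuits sharing one strut
  frame <- array(FALSE, c(100, 100, 100))
  thick <- 1:8
  for (x0 in c(10, 45, 80)) frame[x0 + thick, 10 + thick, 30:70] <- TRUE
  frame[10:90, 10 + thick, 30 + thick] <- TRUE
  frame[10:90, 10 + thick, 62 + thick] <- TRUE
  fv <- voxel_volume(frame, 10)
  bt <- betti_numbers(fv)
  expect_identical(bt$beta0, 1L)
  expect_identical(bt$beta1, 2L)
  expect_equal(conn_d(fv), 2)

  # enclosed cavity: hollow cube has beta2 = 1, chi = 2
  shell <- array(FALSE, c(20, 20, 20))
  shell[5:15, 5:15, 5:15] <- TRUE
  shell[7:13, 7:13, 7:13] <- FALSE
  sv <- voxel_volume(shell, 10)
  expect_identical(betti_numbers(sv)$beta2, 1L)
  expect_identical(euler_characteristic(sv), 2L)
})

test_that("SMI separates plates, rods and balls", {
  pl <- plate_phantom()
  expect_lt(abs(smi(pl)), 0.5)
  rod <- make_phantom(phantom_spec("square_lattice_rods", rod_radius_um = 50,
                                   rod_pitch_um = 500, voxel_um = 10,
                                   shape_voxels = c(100, 100, 60)))
  expect_lt(abs(smi(rod) - 3), 0.5)
  ball <- make_phantom(phantom_spec("solid_ball", ball_radius_um = 200,
                                    voxel_um = 10,
                                    shape_voxels = c(60, 60, 60)))
  expect_lt(abs(smi(ball) - 4), 0.5)
  # mixed plate/rod volume sits between the two pure limits
  mx <- make_phantom(phantom_spec("mixed", 100, 400, 50, 500, voxel_um = 10,
                                  shape_voxels = c(100, 100, 100)))
  expect_gt(smi(mx), 0.5)
  expect_lt(smi(mx), 2.8)
  expect_error(smi(voxel_volume(array(FALSE, c(8, 8, 8)), 10)), "empty")
})

test_that("SMI error shrinks as the voxel size decreases at fixed geometry", {
  errs <- vapply(c(20, 10), function(vox) {
    ball <- make_phantom(phantom_spec("solid_ball", ball_radius_um = 200,
                                      voxel_um = vox,
                                      shape_voxels = rep(600 / vox, 3)))
    abs(smi(ball) - 4)
  }, numeric(1))
  expect_lt(errs[2], errs[1] + 0.05)
  expect_lt(errs[2], 0.5)
})

test_that("measure_all assembles the six parameters", {
  pl <- plate_phantom()
  res <- measure_all(pl)
  expect_identical(nrow(res), 1L)
  expect_identical(res$BVTV, 0.2)
  expect_equal(res$TbN, 2, tolerance = 0.05)
  expect_equal(res$ConnD, 0)
  expect_equal(res$TbSp, 0.4, tolerance = 0.01)
  expect_lt(abs(res$SMI), 0.5)
  expect_equal(res$TbTh, 0.1, tolerance = 0.01)
  expect_equal(res$TV_mm3, prod(c(40, 40, 100)) * 1e-6)
  expect_identical(res$euler, 2L)

  empty <- voxel_volume(array(FALSE, c(10, 10, 10)), 10)
  expect_error(measure_all(empty), "empty")
})

test_that("morphometry is rotation-tolerant", {
  pl <- plate_phantom(shape = c(60, 60, 100))
  # quarter-turn = axis permutation: BV/TV identical by counting
  rot90 <- voxel_volume(aperm(trabqtl:::vv_array(pl), c(3, 2, 1)), 10)
  expect_identical(bv_tv(rot90), bv_tv(pl))
  expect_equal(tb_th(rot90), tb_th(pl), tolerance = 1e-12)
  # oblique tilt: thickness estimate within 5% of the axis-aligned value
  tilted <- make_phantom(phantom_spec("parallel_plates", 100, 400,
                                      voxel_um = 10,
                                      shape_voxels = c(60, 60, 100),
                                      tilt_deg = 25))
  expect_equal(bv_tv(tilted), 0.2, tolerance = 0.1) # partial oblique periods
  expect_equal(tb_th(tilted), tb_th(pl), tolerance = 0.05)
})
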