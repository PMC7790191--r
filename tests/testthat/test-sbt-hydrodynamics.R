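disc16 <- stokes_discretization(16)

test_that("rod placement builds the tilted lattice", {
  g1 <- place_rods(rod_array_config(1, 1), disc16)
  expect_equal(g1$n_rods, 1L)
  expect_equal(unname(g1$bases[1, ]), c(0, 0, 0.05))
  expect_equal(asin(g1$axis[3]) * 180 / pi, 53, tolerance = 1e-10)

  # theta = 0: beating direction along the flow (y); perpendicular gaps 0.08
  g9 <- place_rods(rod_array_config(3, 3, d_perp = 0.08, theta = 0), disc16)
  expect_equal(g9$n_rods, 9L)
  expect_equal(g9$ehat, c(0, 1, 0))
  xs <- sort(unique(round(g9$bases[, 1], 10)))
  expect_equal(diff(xs), c(0.08, 0.08))

  # theta = pi/2: axes must have no y-component; compare to hand-rotation
  g4 <- place_rods(rod_array_config(2, 2, d_perp = 0.2, theta = pi / 2), disc16)
  expect_equal(g4$axis[2], 0, tolerance = 1e-12)
  alpha <- 53 * pi / 180
  expect_equal(g4$axis, c(cos(alpha), 0, sin(alpha)), tolerance = 1e-12)
  # rotating the theta = 0 lattice by 90 degrees about z gives the same bases
  g0 <- place_rods(rod_array_config(2, 2, d_perp = 0.2, theta = 0), disc16)
  rot <- cbind(g0$bases[, 2], -g0$bases[, 1], g0$bases[, 3])
  expect_equal(sort(round(rot[, 1], 10)), sort(round(g4$bases[, 1], 10)))

  expect_error(rod_array_config(2, 2, d_perp = 0.05), "perpendicular spacing")
  expect_error(rod_array_config(2, 2, d_perp = 0.2, d_par = 1.0),
               "along-beat spacing")
})

test_that("ambient shear is a linear no-slip profile", {
  expect_equal(ambient_shear(c(0, 0, 0)), c(0, 0, 0))
  expect_equal(ambient_shear(c(0.3, -1, 1)), c(0, 1, 0))
  expect_equal(ambient_shear(c(0, 0, 0.55), shear_rate = 2), c(0, 1.1, 0))
  expect_error(ambient_shear(c(0, 0, -0.1)), "z >= 0")
})

test_that("force densities vanish without forcing and match RFT in free space", {
  geom <- place_rods(rod_array_config(1, 1), stokes_discretization(16, shear_rate = 0))
  sol <- solve_force_density(geom)
  expect_lt(max(abs(sol$force_density)), 1e-12)

  # vertical rod, free space, uniform perpendicular stream: total drag within
  # 20% of the resistive-force-theory closed form C_perp U L
  cfg <- rod_array_config(1, 1, tilt_alpha = 90)
  geom <- place_rods(cfg, stokes_discretization(24))
  M <- nrow(geom$nodes)
  sol <- solve_force_density(geom, wall = FALSE, uinf = cbind(rep(1, M), 0, 0))
  Fx <- sum(sol$force_density[, 1]) * geom$h
  c_perp <- 4 * pi / (log(2 / 0.02) + 0.5)
  expect_lt(abs(Fx - c_perp) / c_perp, 0.20)
  # drag is along the stream only
  expect_lt(max(abs(colSums(sol$force_density)[2])), 1e-10)
})

test_that("single-rod torque is discretization-converged", {
  t16 <- isolated_rod_torque(pi / 2, stokes_discretization(16))
  t32 <- isolated_rod_torque(pi / 2, stokes_discretization(32))
  expect_lt(abs(t32 - t16) / t16, 0.02)
})

test_that("rod torques obey the symmetries of the shear problem", {
  # no torque when beating is along the flow
  expect_lt(abs(isolated_rod_torque(0, disc16)), 1e-10)
  # reflection theta -> -theta flips the sign exactly
  tp <- isolated_rod_torque(pi / 4, disc16)
  tm <- isolated_rod_torque(-pi / 4, disc16)
  expect_equal(tp, -tm, tolerance = 1e-10)
  expect_gt(tp, 0)
  # non-dimensional torque is invariant under the shear rate (linearity)
  for (g in c(2, 5)) {
    tg <- isolated_rod_torque(pi / 2, stokes_discretization(16, shear_rate = g))
    expect_equal(tg, isolated_rod_torque(pi / 2, disc16), tolerance = 1e-10)
  }
  # isolated torque is maximal at theta = pi/2
  th <- c(pi / 8, pi / 4, 3 * pi / 8, pi / 2)
  tv <- vapply(th, isolated_rod_torque, numeric(1), disc = disc16)
  expect_true(all(diff(tv) > 0))
})

test_that("the image system enforces no-slip on the wall", {
  sol <- solve_force_density(place_rods(rod_array_config(1, 1),
                                        stokes_discretization(16)))
  pts <- as.matrix(expand.grid(x = seq(-1, 1, 0.5), y = seq(-1, 1, 0.5), z = 0))
  u_wall <- cilialign:::induced_velocity(sol, pts)
  expect_lt(max(abs(u_wall)), 1e-6)
})

test_that("spacing along the beat direction barely affects the torque", {
  dd <- stokes_discretization(16)
  cfg_a <- rod_array_config(3, 3, d_perp = 0.24)
  cfg_b <- rod_array_config(3, 3, d_perp = 0.24, d_par = 1.5 * cfg_a$d_par_min)
  ta <- rod_torque_z(solve_force_density(place_rods(cfg_a, dd)))$mean_torque
  tb <- rod_torque_z(solve_force_density(place_rods(cfg_b, dd)))$mean_torque
  expect_lt(abs(tb - ta) / ta, 0.05)
})

test_that("screening tables are normalised, bounded and angle-resolved", {
  cfg <- rod_array_config(3, 3)
  tab <- screening_sweep(d_perp_list = c(0.16, 0.40),
                         theta_grid = c(0, pi / 4, pi / 2),
                         config = cfg, disc = stokes_discretization(12))
  # theta = 0 row ~ 0; all entries within [0, 1] up to solver noise
  expect_lt(max(abs(tab$normalized_torque[1, ])), 1e-8)
  expect_true(all(tab$normalized_torque <= 1 + 1e-6))
  expect_true(all(tab$normalized_torque >= -1e-8))
  # denser array (smaller d_perp -> larger rho) is screened more
  expect_true(all(tab$normalized_torque[3, order(tab$rho_grid)] ==
                    sort(tab$normalized_torque[3, ], decreasing = TRUE)))
  # rho bookkeeping: a_top / (d_par * d_perp)
  expect_equal(tab$rho_grid, tab$a_top / (cfg$d_par * c(0.16, 0.40)),
               tolerance = 1e-12)
  # single rod normalises to 1 at pi/2
  tab1 <- screening_sweep(d_perp_list = 0.4, theta_grid = pi / 2,
                          config = rod_array_config(1, 1),
                          disc = stokes_discretization(12))
  expect_equal(as.numeric(tab1$normalized_torque), 1, tolerance = 1e-10)

  # CSV and JSON round trip
  for (ext in c("csv", "json")) {
    path <- file.path(tempdir(), paste0("tab.", ext))
    write_screening_table(tab, path)
    back <- read_screening_table(path, isolated_reference = tab$isolated_reference)
    expect_equal(back$normalized_torque, unname(tab$normalized_torque),
                 tolerance = 1e-8, ignore_attr = TRUE)
    unlink(path)
  }
})
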