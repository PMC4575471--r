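# Pennes bioheat solver, thermal-dose metrics and CEM43.

test_that("zero deposition stays at zero and unstable steps are rejected", {
  ph <- make_limb_phantom(15, 0, 0, seed = 1, n_bones = 0)
  g <- grid_around(c(0, 0, 0), 8, 1)
  f <- solve_bioheat(ph, array(0, g$dims), 5, grid = g)
  expect_equal(max(abs(f$final)), 0)
  expect_equal(max(abs(f$runmax)), 0)
  expect_error(solve_bioheat(ph, array(0, g$dims), 5, dt_s = 10, grid = g),
               "unstable")
})

test_that("uniform interior heating matches the adiabatic closed form", {
  ph <- make_limb_phantom(15, 0, 0, seed = 1, n_bones = 0)
  g <- grid_around(c(0, 0, 0), 10, 1)
  f <- solve_bioheat(ph, array(1, g$dims), 5, grid = g)   # 1 W/cm^3
  ctr <- f$final[(g$dims[1] + 1) / 2, (g$dims[2] + 1) / 2, (g$dims[3] + 1) / 2]
  ts <- ph$tissue
  expect_equal(ctr, 1e6 * 5 / (ts$density * ts$specific_heat),
               tolerance = 1e-3)
})

test_that("a compact source matches the Green-kernel convolution within 3%", {
  ph <- make_limb_phantom(15, 0, 0, seed = 1, n_bones = 0)
  ts <- ph$tissue
  h <- 0.5
  g <- grid_around(c(0, 0, 0), 12, h)
  pts <- dbacsim:::grid_points(g)
  r2 <- rowSums(pts^2); r <- sqrt(r2)
  sig <- 1
  q <- exp(-r2 / (2 * sig^2))
  q <- q / (sum(q) * (h / 10)^3)                 # 1 W total
  f <- solve_bioheat(ph, array(q, g$dims), 10, grid = g)
  rc <- ts$density * ts$specific_heat
  kap <- ts$conductivity / rc
  green <- Vectorize(function(r_mm) {
    fint <- function(tau) {
      s2 <- (sig / 1000)^2 + 2 * kap * tau
      1 / (rc * (2 * pi * s2)^1.5) * exp(-(r_mm / 1000)^2 / (2 * s2))
    }
    stats::integrate(fint, 0, 10, rel.tol = 1e-9)$value
  })
  sel <- which(r >= 2 * h & r <= 5)
  ana <- green(r[sel])
  rel <- abs(as.vector(f$final)[sel] / ana - 1)
  expect_lt(stats::median(rel), 0.03)
  expect_lt(abs(mean(as.vector(f$final)[sel]) / mean(ana) - 1), 0.03)
})

test_that("enthalpy is conserved within 1% for a compact source", {
  ph <- make_limb_phantom(15, 0, 0, seed = 1, n_bones = 0)
  ts <- ph$tissue
  h <- 1
  g <- grid_around(c(0, 0, 0), 15, h)
  pts <- dbacsim:::grid_points(g)
  q <- exp(-rowSums(pts^2) / (2 * 2^2))
  q <- q / (sum(q) * (h / 10)^3)                 # 1 W
  t_end <- 10
  f <- solve_bioheat(ph, array(q, g$dims), t_end, grid = g)
  enthalpy <- ts$density * ts$specific_heat *
    sum(f$final) * (h / 1000)^3                  # J
  expect_lt(abs(enthalpy / (1 * t_end) - 1), 0.01)
})

test_that("the maximum principle and source linearity hold", {
  ph <- make_limb_phantom(15, 0, 0, seed = 1, n_bones = 0)
  g <- grid_around(c(0, 0, 0), 10, 1)
  pts <- dbacsim:::grid_points(g)
  q <- array(exp(-rowSums(pts^2) / 18), g$dims)
  f1 <- solve_bioheat(ph, q, 8, grid = g)
  expect_true(all(f1$final >= 0))
  f2 <- solve_bioheat(ph, q, 8, grid = g, power_scale = 2)
  expect_equal(f2$final, 2 * f1$final, tolerance = 1e-10)
  s1 <- mtv_stats(f1, c(0, 0, 0)); s2 <- mtv_stats(f2, c(0, 0, 0))
  expect_equal(s2, 2 * s1, tolerance = 1e-10)
})

test_that("grid refinement changes the end-of-dose temperature by < 5%", {
  ph <- make_limb_phantom(15, 0, 0, seed = 1, n_bones = 0)
  gauss_dep <- function(h) {
    g <- grid_around(c(0, 0, 0), 12, h)
    pts <- dbacsim:::grid_points(g)
    q <- exp(-rowSums(pts^2) / (2 * 2.5^2))
    q <- q / (sum(q) * (h / 10)^3)
    list(g = g, q = array(q, g$dims))
  }
  a <- gauss_dep(2); b <- gauss_dep(1)
  Ta <- mtv_stats(solve_bioheat(ph, a$q, 20, grid = a$g), c(0, 0, 0))[["mean"]]
  Tb <- mtv_stats(solve_bioheat(ph, b$q, 20, grid = b$g), c(0, 0, 0))[["mean"]]
  expect_lt(abs(Ta / Tb - 1), 0.05)
})

test_that("mtv_stats handles uniform fields and rejects clipped spheres", {
  ph <- make_limb_phantom(15, 0, 0, seed = 1, n_bones = 0)
  g <- grid_around(c(0, 0, 0), 10, 1)
  f <- solve_bioheat(ph, array(0, g$dims), 1, grid = g)
  f$final <- array(33, g$dims)
  expect_equal(unname(mtv_stats(f, c(0, 0, 0))), c(33, 33, 33))
  expect_error(mtv_stats(f, c(9, 9, 9)), "clipped")
})

test_that("lateral containment check distinguishes focused from defocused plans", {
  ph <- make_limb_phantom(15, 0, 0, seed = 1, n_bones = 0)
  g <- grid_around(c(0, 0, 0), 20, 1)
  pts <- dbacsim:::grid_points(g)
  lat2 <- pts[, 1]^2 + pts[, 2]^2
  focused <- array(exp(-lat2 / (2 * 2^2) - pts[, 3]^2 / (2 * 6^2)), g$dims)
  f1 <- solve_bioheat(ph, focused, 10, grid = g)
  m1 <- mttd_check(f1, c(0, 0, 0))
  expect_true(m1$pass)
  spread <- array(exp(-((pts[, 1] - 15)^2 + pts[, 2]^2) / (2 * 2^2)) +
                  exp(-((pts[, 1] + 15)^2 + pts[, 2]^2) / (2 * 2^2)) +
                  0.2 * exp(-lat2 / (2 * 2^2)), g$dims)
  f2 <- solve_bioheat(ph, spread, 10, grid = g)
  m2 <- mttd_check(f2, c(0, 0, 0))
  expect_false(m2$pass)
  f0 <- solve_bioheat(ph, array(0, g$dims), 1, grid = g)
  expect_true(mttd_check(f0, c(0, 0, 0))$pass)   # vacuous
})

test_that("CEM43 follows the Sapareto-Dewey closed forms", {
  expect_equal(cem43(rep(6, 1200), 0.5, 37), 10)        # 43 C for 10 min
  expect_equal(cem43(rep(8, 1200), 0.5, 37), 40)        # 45 C -> R = 0.5
  expect_lte(cem43(rep(0, 1200), 0.5, 37), 10 * 0.25^6) # 37 C negligible
})
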