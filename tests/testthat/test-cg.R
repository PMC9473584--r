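# Coarse-grained potentials, integrator and slab analysis.

# independent R reference for the total potential energy: direct
# minimum-image double loop assembled from pair_energy_force()
reference_energy <- function(sys) {
  ff <- sys$ff
  x <- sys$coords
  n <- nrow(x)
  mi <- function(d, L) d - L * round(d / L)
  U <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    dv <- mi(x[i, ] - x[j, ], sys$box)
    r <- sqrt(sum(dv^2))
    if (sys$chain_id[i] == sys$chain_id[j] && abs(i - j) == 1) {
      U <- U + pair_energy_force("bond", r, ff)$energy
      next
    }
    ti <- sys$type[i]; tj <- sys$type[j]
    if (ti == tj && r < ff$r_c)
      U <- U + pair_energy_force("soft_repulsion", r, ff,
                                 eps = ff$eps_type[ti + 1])$energy
    U0 <- if ((ti == 1 && tj == 2) || (ti == 2 && tj == 1)) ff$U0_YR
          else if ((ti == 3 && tj == 2) || (ti == 2 && tj == 3)) ff$U0_AR
          else 0
    if (U0 != 0 && r < ff$r0)
      U <- U + pair_energy_force("sticker_attraction", r, ff, U0 = U0)$energy
  }
  U
}

test_that("force-field defaults carry the reference ratios", {
  ff <- cg_forcefield()
  expect_equal(abs(ff$U0_AR / ff$U0_YR), 3.75)
  expect_equal(ff$k_bond, 20 / 4.5^2)
})

test_that("pair potentials match their printed forms at anchor points", {
  ff <- cg_forcefield()
  b <- pair_energy_force("bond", ff$r_b, ff)
  expect_equal(b$energy, 0)
  expect_equal(b$force, 0)
  a <- pair_energy_force("sticker_attraction", c(0, ff$r0, 3), ff)
  expect_equal(a$energy, c(2 * ff$U0_YR, 0, 0))
  # softened LJ at contact: 4*lambda*((1-lambda)^-4 - (1-lambda)^-2) ~ 232.8
  s <- pair_energy_force("soft_repulsion", 0, ff, eps = 1)
  A <- (1 - ff$lambda_lj)^2
  d_rc <- A + (ff$r_c / ff$sigma)^6
  raw_rc <- 4 * ff$lambda_lj * (d_rc^-2 - d_rc^-1)
  expect_equal(s$energy + raw_rc, 232.8, tolerance = 1e-1)
  # cutoff continuity after the shift
  expect_equal(pair_energy_force("soft_repulsion", ff$r_c - 1e-9, ff)$energy,
               0, tolerance = 1e-6)
})

test_that("analytic forces agree with finite differences of the energy", {
  ff <- cg_forcefield()
  set.seed(42)
  r <- runif(100, 0.05, 6)
  r <- r[abs(r - ff$r0) > 1e-3 & abs(r - ff$r_c) > 1e-3]
  h <- 1e-6
  for (kind in c("bond", "sticker_attraction", "soft_repulsion")) {
    num <- -(pair_energy_force(kind, r + h, ff)$energy -
             pair_energy_force(kind, r - h, ff)$energy) / (2 * h)
    expect_equal(pair_energy_force(kind, r, ff)$force, num,
                 tolerance = 1e-6)
  }
})

test_that("compiled energy and forces match the R reference", {
  sys <- build_slab_system(list(n_chains = 3, chain_length = 8, n_atp = 5,
                                box = c(20, 20, 40)), seed = 5)
  expect_equal(cg_energy(sys), reference_energy(sys), tolerance = 1e-10)
  # compiled forces are the negative gradient of the compiled energy
  i <- 7; h <- 1e-5
  f <- phasefus:::cg_forces(sys$coords, sys$type, sys$chain_id, sys$box,
                            unclass(sys$ff))
  for (d in 1:3) {
    cp <- sys$coords; cm <- sys$coords
    cp[i, d] <- cp[i, d] + h; cm[i, d] <- cm[i, d] - h
    num <- -(cg_energy(sys, coords = cp) - cg_energy(sys, coords = cm)) / (2 * h)
    expect_equal(f[i, d], num, tolerance = 1e-6)
  }
})

test_that("periodic translation leaves the energy unchanged", {
  sys <- small_slab(n_atp = 10, seed = 3)
  e0 <- cg_energy(sys)
  shift <- matrix(rep(sys$box * c(2, -1, 3), each = nrow(sys$coords)), ncol = 3)
  expect_equal(cg_energy(sys, coords = sys$coords + shift), e0,
               tolerance = 1e-9)
})

test_that("slab construction is deterministic with exact sticker counts", {
  s1 <- small_slab(seed = 9)
  s2 <- small_slab(seed = 9)
  expect_identical(s1$coords, s2$coords)
  expect_identical(s1$type, s2$type)
  for (ch in unique(s1$chain_id[s1$type != 3L])) {
    ty <- s1$type[s1$chain_id == ch]
    expect_equal(sum(ty == 1L), round(0.06 * 34))
    expect_equal(sum(ty == 2L), round(0.06 * 34))
  }
  s3 <- small_slab(n_atp = 12, seed = 9)
  expect_equal(sum(s3$type == 3L), 12)
  expect_error(build_slab_system(list(n_chains = 500, chain_length = 100,
                                      box = c(10, 10, 20))),
               "density")
})

test_that("Langevin runs are seed-reproducible and seed-sensitive", {
  sys <- small_slab(n_atp = 5, seed = 2)
  t1 <- run_langevin(sys, n_steps = 300, seed = 7, sample_every = 50)
  t2 <- run_langevin(sys, n_steps = 300, seed = 7, sample_every = 50)
  t3 <- run_langevin(sys, n_steps = 300, seed = 8, sample_every = 50)
  expect_identical(t1$frames, t2$frames)
  expect_false(identical(t1$frames, t3$frames))
  expect_true(all(diff(t1$times) > 0))
})

test_that("a bonded dimer at the bond length is a zero-temperature fixed point", {
  sys <- build_slab_system(list(n_chains = 1, chain_length = 2,
                                box = c(30, 30, 90)), seed = 1)
  sys$coords <- matrix(c(10, 10, 10, 10, 40, 44.5), 2, 3)
  tr <- run_langevin(sys, n_steps = 100, temperature = 0, seed = 1)
  expect_equal(tr$frames[[length(tr$frames)]], sys$coords)
})

test_that("density profile finds the slab and rejects uniform systems", {
  # construction-only trajectory: rectangular slab profile
  sys <- small_slab(seed = 4)
  traj <- structure(list(times = c(0, 1), frames = list(sys$coords, sys$coords),
                         type = sys$type, chain_id = sys$chain_id,
                         box = sys$box, ff = sys$ff, settings = list()),
                    class = "cg_trajectory")
  pr <- density_profile(traj, discard_frac = 0)
  expect_gt(pr$dense_density, pr$dilute_density)
  # the detected condensate overlaps the construction slab (chains
  # overhang its nominal edges by about a radius of gyration, and the
  # half-maximum region of the resulting peak need not be symmetric)
  slab <- 45 + c(-1, 1) * 0.15 * 90
  expect_lt(pr$bounds[1], slab[2])
  expect_gt(pr$bounds[2], slab[1])
  expect_lt(diff(pr$bounds), 0.7 * 90)
  expect_gt(diff(pr$bounds), 4)
  # uniform gas: no condensate
  set.seed(1)
  n <- length(sys$type)
  unif <- matrix(runif(3 * n), n, 3) %*% diag(sys$box)
  traj_u <- traj; traj_u$frames <- list(unif, unif)
  expect_error(density_profile(traj_u, discard_frac = 0), "uniform")
})

test_that("short dynamics keep the protein slab condensed", {
  sys <- small_slab(seed = 6)
  tr <- run_langevin(sys, n_steps = 6000, dt = 0.02, temperature = 2,
                     seed = 16, sample_every = 100)
  pr <- density_profile(tr)
  expect_gt(pr$dense_density, 3 * pr$dilute_density)
})

test_that("exchange counting responds to constructed crossings only", {
  box <- c(30, 30, 90)
  mk_frame <- function(z) matrix(c(5, 5, 5, 5, z, z + 1), 2, 3)
  base <- list(type = c(0L, 0L), chain_id = c(1L, 1L), box = box,
               ff = cg_forcefield(), settings = list())
  static <- structure(c(list(times = 1:30,
                             frames = replicate(30, mk_frame(70),
                                                simplify = FALSE)), base),
                      class = "cg_trajectory")
  ex0 <- exchange_statistics(static, bounds = c(35, 55))
  expect_equal(ex0$total_events, 0)
  # one committed outside -> inside crossing
  zs <- c(rep(70, 10), rep(45, 20))
  once <- structure(c(list(times = seq_along(zs),
                           frames = lapply(zs, mk_frame)), base),
                    class = "cg_trajectory")
  ex1 <- exchange_statistics(once, bounds = c(35, 55), dwell = 5)
  expect_equal(ex1$total_events, 1)
  expect_equal(ex1$n_exchanged_chains, 1)
  # a short flicker is debounced away
  zs2 <- c(rep(70, 10), rep(45, 2), rep(70, 18))
  flick <- structure(c(list(times = seq_along(zs2),
                            frames = lapply(zs2, mk_frame)), base),
                     class = "cg_trajectory")
  expect_equal(exchange_statistics(flick, bounds = c(35, 55),
                                   dwell = 5)$total_events, 0)
})

test_that("trajectories export to XYZ with a JSON sidecar", {
  sys <- build_slab_system(list(n_chains = 2, chain_length = 5,
                                box = c(20, 20, 40)), seed = 1)
  tr <- run_langevin(sys, n_steps = 100, seed = 1, sample_every = 50)
  path <- tempfile(fileext = ".xyz")
  write_xyz(tr, path)
  lines <- readLines(path)
  expect_equal(lines[1], "10")
  expect_equal(sum(lines == "10"), length(tr$frames))
  side <- jsonlite::read_json(sub("\\.xyz$", ".json", path))
  expect_equal(unlist(side$box), c(20, 20, 40))
})
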