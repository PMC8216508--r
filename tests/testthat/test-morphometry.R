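circle_poly <- function(r_nm, n = 256, c0 = c(0, 0)) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(c0[1] + r_nm * cos(th), c0[2] + r_nm * sin(th))
}

test_that("complexity equals perimeter over area with closed-form checks", {
  expect_equal(bouton_complexity(circle_poly(1000)), 2, tolerance = 5e-4)
  sq <- rbind(c(0, 0), c(2000, 0), c(2000, 2000), c(0, 2000))
  expect_equal(bouton_complexity(sq), 2)
  expect_equal(presyn_area(sq), 4)
  expect_error(bouton_complexity(rbind(c(0, 0), c(1, 1), c(2, 2))),
               "degenerate")
})

test_that("no polygon beats the circle on complexity (isoperimetry)", {
  set.seed(41)
  for (i in 1:100) {
    nv <- sample(6:40, 1)
    th <- sort(runif(nv, 0, 2 * pi))
    r <- runif(nv, 400, 1600)
    poly <- cbind(r * cos(th), r * sin(th))
    a <- boutonquant:::polygon_area(poly)
    circ <- circle_poly(sqrt(a / pi), 720)
    expect_gt(bouton_complexity(poly), bouton_complexity(circ))
  }
})

test_that("reconstructed volume is area times thickness summed", {
  sq1um2 <- rbind(c(0, 0), c(1000, 0), c(1000, 1000), c(0, 1000))
  sec <- function(z) list(z_index = z, presyn = list(sq1um2), az = list(),
                          mito = list(),
                          vesicles = tibble::tibble(x = numeric(),
                                                    y = numeric(),
                                                    r = numeric()))
  expect_equal(reconstructed_volume(reconstruction(list(sec(1)), 70)), 0.07)
  rec10 <- reconstruction(lapply(1:10, sec), 70)
  expect_equal(reconstructed_volume(rec10), 0.7)
  sim <- simulate_reconstruction(em_sim_config(seed = 42))
  expect_equal(reconstructed_volume(sim$rec), sim$truth$volume_um3,
               tolerance = 1e-9)
})

test_that("AZ stats follow count-per-volume and length-times-thickness", {
  sq <- rbind(c(0, 0), c(10000, 0), c(10000, 10000), c(0, 10000))  # 100 um2
  az_seg <- list(az_id = 1L, points = rbind(c(0, 0), c(200, 0)))
  secs <- lapply(1:3, function(z)
    list(z_index = z, presyn = list(sq), az = list(az_seg), mito = list(),
         vesicles = tibble::tibble(x = numeric(), y = numeric(),
                                   r = numeric())))
  rec <- reconstruction(secs, 70)
  st <- az_stats(rec)
  expect_equal(st$az_count, 1)
  expect_equal(st$az_areas$area_um2, 200 * 70 * 3 / 1e6)  # 0.042 um^2
  expect_equal(st$az_density, 1 / reconstructed_volume(rec))

  sim <- simulate_reconstruction(em_sim_config(seed = 43))
  st2 <- az_stats(sim$rec)
  expect_equal(st2$az_count, sim$truth$az_count)
  expect_equal(sort(st2$az_areas$area_um2), sort(sim$truth$az_area_um2),
               tolerance = 1e-9)
})

test_that("an AZ across non-contiguous sections warns but counts once", {
  sq <- rbind(c(0, 0), c(1000, 0), c(1000, 1000), c(0, 1000))
  az_seg <- list(az_id = 7L, points = rbind(c(0, 0), c(100, 0)))
  mk <- function(z, with_az) list(
    z_index = z, presyn = list(sq),
    az = if (with_az) list(az_seg) else list(), mito = list(),
    vesicles = tibble::tibble(x = numeric(), y = numeric(), r = numeric()))
  rec <- reconstruction(list(mk(1, TRUE), mk(2, FALSE), mk(3, TRUE)), 70)
  expect_warning(st <- az_stats(rec), "non-contiguous")
  expect_equal(st$az_count, 1)
})

test_that("dispersion and MNND follow their definitions on tiny cases", {
  # two vesicles 100 nm apart in 0.5 um^3
  side <- sqrt(0.5 / 0.07) * 1000  # one 70-nm section
  sq <- rbind(c(0, 0), c(side, 0), c(side, side), c(0, side))
  rec <- reconstruction(list(list(
    z_index = 1, presyn = list(sq), az = list(), mito = list(),
    vesicles = tibble::tibble(x = c(1000, 1100), y = c(1000, 1000),
                              r = 20))), 70)
  sv <- sv_stats(rec)
  expect_equal(sv$pairwise_dispersion, 100 / 0.5, tolerance = 1e-9)
  expect_equal(sv$mnnd, 100)
  expect_equal(sv$sv_density, 2 / 0.5, tolerance = 1e-9)

  # three collinear vesicles at 0, 100, 200 nm: every nearest neighbour 100
  rec3 <- reconstruction(list(list(
    z_index = 1, presyn = list(sq), az = list(), mito = list(),
    vesicles = tibble::tibble(x = c(1000, 1100, 1200), y = 1000, r = 20))),
    70)
  expect_equal(sv_stats(rec3)$mnnd, 100)

  # single vesicle: dispersion missing with a reason
  rec1 <- reconstruction(list(list(
    z_index = 1, presyn = list(sq), az = list(), mito = list(),
    vesicles = tibble::tibble(x = 1000, y = 1000, r = 20))), 70)
  sv1 <- sv_stats(rec1)
  expect_true(is.na(sv1$pairwise_dispersion))
  expect_match(sv1$dispersion_note, "fewer than 2")
})

test_that("vectorised distances equal the O(n^2) brute force", {
  sim <- simulate_reconstruction(em_sim_config(vesicle_count = 150,
                                               seed = 44))
  sv <- sv_stats(sim$rec)
  orc <- oracle_sv_stats(sim$rec)
  vol <- reconstructed_volume(sim$rec)
  expect_equal(sv$pairwise_dispersion, orc$mean_pair / vol,
               tolerance = 1e-12)
  expect_equal(sv$mnnd, orc$mnnd, tolerance = 1e-12)
})

test_that("dispersion estimator variants scale as documented", {
  sim <- simulate_reconstruction(em_sim_config(vesicle_count = 60, seed = 45))
  n <- sv_stats(sim$rec)$sv_count
  pm <- sv_stats(sim$rec, "pair_mean")$pairwise_dispersion
  sm <- sv_stats(sim$rec, "sum")$pairwise_dispersion
  pv <- sv_stats(sim$rec, "per_vesicle")$pairwise_dispersion
  expect_equal(sm, pm * choose(n, 2), tolerance = 1e-9)
  expect_equal(pv, pm * (n - 1), tolerance = 1e-9)
})

test_that("docked / tethered classification follows the gap and shell rules", {
  # vesicle radius 20: centre 20 nm from the AZ membrane -> gap 0 -> docked;
  # centre 55 nm -> tethered; centre 80 nm -> neither
  rec <- square_az_rec(c(20, 55, 80))
  out <- classify_docked_tethered(rec)
  expect_equal(out$vesicles$label, c("docked", "tethered", "neither"))
  expect_equal(out$densities$n_docked, 1)
  expect_equal(out$densities$n_tethered, 1)
  expect_equal(out$densities$rrp_density_az,
               out$densities$docked_density_az +
                 out$densities$tethered_density_az)
  # without any AZ all labels are neither and per-AZ densities missing
  rec_no <- square_az_rec(c(20, 55))
  rec_no$sections[[1]]$az <- list()
  out_no <- classify_docked_tethered(rec_no)
  expect_true(all(out_no$vesicles$label == "neither"))
  expect_true(is.na(out_no$densities$docked_density_az))
})

test_that("classification recovers the generator's docked/tethered counts", {
  for (s in 46:48) {
    sim <- simulate_reconstruction(em_sim_config(seed = s))
    out <- classify_docked_tethered(sim$rec)
    expect_equal(out$densities$n_docked, sim$truth$n_docked)
    expect_equal(out$densities$n_tethered, sim$truth$n_tethered)
  }
})

test_that("mitochondrial fraction is exact on constructed and generated data", {
  sq <- rbind(c(0, 0), c(1000, 0), c(1000, 1000), c(0, 1000))
  half <- rbind(c(0, 0), c(1000, 0), c(1000, 500), c(0, 500))
  rec <- reconstruction(list(list(z_index = 1, presyn = list(sq),
                                  az = list(), mito = list(half),
                                  vesicles = tibble::tibble(
                                    x = numeric(), y = numeric(),
                                    r = numeric()))), 70)
  expect_equal(mito_fraction(rec), 50)
  rec$sections[[1]]$mito <- list()
  expect_equal(mito_fraction(rec), 0)
  sim <- simulate_reconstruction(em_sim_config(mito_volume_fraction = 15,
                                               seed = 49))
  expect_lt(abs(mito_fraction(sim$rec) - 15), 1)
})

test_that("morphometry units transform correctly under coordinate scaling", {
  sim <- simulate_reconstruction(em_sim_config(vesicle_count = 80, seed = 50))
  rec <- sim$rec
  s <- 2
  rec2 <- rec
  rec2$section_thickness <- rec$section_thickness * s
  rec2$sections <- lapply(rec$sections, function(sec) {
    sec$presyn <- lapply(sec$presyn, function(p) p * s)
    sec$az <- lapply(sec$az, function(a) { a$points <- a$points * s; a })
    sec$mito <- lapply(sec$mito, function(p) p * s)
    sec$vesicles <- dplyr::mutate(sec$vesicles, x = x * s, y = y * s,
                                  r = r * s)
    sec
  })
  m1 <- sv_stats(rec); m2 <- sv_stats(rec2)
  expect_equal(m2$mnnd, s * m1$mnnd, tolerance = 1e-9)
  expect_equal(m2$pairwise_dispersion, m1$pairwise_dispersion / s^2,
               tolerance = 1e-9)
  expect_equal(m2$sv_density, m1$sv_density / s^3, tolerance = 1e-9)
  expect_equal(az_stats(rec2)$az_density, az_stats(rec)$az_density / s^3,
               tolerance = 1e-9)
  expect_equal(mito_fraction(rec2), mito_fraction(rec), tolerance = 1e-9)
})

test_that("uniform processes disperse more than clustered ones", {
  wins <- 0
  for (s in 1:10) {
    mk <- function(cl) sv_stats(simulate_reconstruction(em_sim_config(
      vesicle_count = 120, n_sections = 6, n_azs = 0, docked_per_az = 0,
      tethered_per_az = 0, mito_volume_fraction = 0, clustering = cl,
      seed = 500 + s))$rec)$pairwise_dispersion
    du <- mk(list(type = "uniform"))
    dc <- mk(list(type = "thomas", n_parents = 3, offspring_sd = 50,
                  parent_region_scale = 0.45))
    wins <- wins + (du > dc)
  }
  expect_equal(wins, 10)
})

test_that("zero vesicles give density zero and empty morphometry fields", {
  sim <- simulate_reconstruction(em_sim_config(vesicle_count = 0,
                                               docked_per_az = 0,
                                               tethered_per_az = 0,
                                               seed = 51))
  sv <- sv_stats(sim$rec)
  expect_equal(sv$sv_count, 0)
  expect_equal(sv$sv_density, 0)
  m <- morphometry(sim$rec)
  expect_equal(m$sv_count, 0)
})

test_that("uniform counts in a known volume give exact density", {
  # 100 vesicles placed by the generator in a known prism volume
  cfg <- em_sim_config(bouton_area_um2 = 2, n_sections = 7, n_azs = 0,
                       docked_per_az = 0, tethered_per_az = 0,
                       vesicle_count = 100, boundary_roughness = 0,
                       mito_volume_fraction = 0, seed = 52)
  sim <- simulate_reconstruction(cfg)
  vol <- reconstructed_volume(sim$rec)
  expect_equal(sv_stats(sim$rec)$sv_density, 100 / vol, tolerance = 1e-12)
  expect_equal(vol, 2 * 0.07 * 7, tolerance = 1e-9)
})
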