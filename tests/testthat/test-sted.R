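test_that("the Lorentzian kernel has unit sum and the stated half width", {
  k <- boutonquant:::lorentzian_kernel(40, 20)
  expect_equal(sum(k), 1, tolerance = 1e-12)
  c0 <- (nrow(k) + 1) / 2
  expect_equal(k[c0, c0 + 1] / k[c0, c0], 0.5, tolerance = 1e-12)  # r = FWHM/2
})

test_that("an empty field is exactly zero and a fixed separation is rendered", {
  cfg <- sted_sim_config(field_size = c(64, 64), n_triads = 0,
                         n_distractors = 0, background = 0,
                         read_noise_sd = 0, poisson = FALSE, seed = 1)
  sim <- simulate_sted_field(cfg)
  expect_true(all(vapply(sim$field$channels, function(ch) all(ch == 0),
                         logical(1))))

  cfg2 <- sted_sim_config(field_size = c(128, 128), n_triads = 1,
                          separation_distribution = list(family = "point",
                                                         value = 100),
                          n_distractors = 0, background = 0,
                          read_noise_sd = 0, poisson = FALSE, seed = 2)
  sim2 <- simulate_sted_field(cfg2)
  expect_equal(sim2$truth$separation_nm, 100)
  am_cav <- which(sim2$field$channels$cav ==
                    max(sim2$field$channels$cav), arr.ind = TRUE)
  am_munc <- which(sim2$field$channels$munc ==
                     max(sim2$field$channels$munc), arr.ind = TRUE)
  d_px <- sqrt(sum((am_cav[1, ] - am_munc[1, ])^2))
  expect_lt(abs(d_px * 20 - 100), 1.5 * 20)  # argmax within pixel rounding
})

test_that("point-mass zero separation measures as zero distance", {
  cfg <- sted_sim_config(field_size = c(128, 128), n_triads = 2,
                         separation_distribution = list(family = "point",
                                                        value = 0),
                         n_distractors = 0, background = 0,
                         read_noise_sd = 0, poisson = FALSE, seed = 3)
  sim <- simulate_sted_field(cfg)
  res <- measure_coupling(sim$field, prominence = 50)
  expect_equal(nrow(res), 2)
  expect_true(all(res$distance_nm == 0))
})

test_that("separation draws follow the configured distribution", {
  set.seed(31)
  d <- draw_separations(list(family = "truncnorm", mean = 64.6, sd = 30), 800)
  expect_true(all(d >= 0))
  # KS against the truncated-normal CDF
  pt <- function(q) {
    (pnorm(q, 64.6, 30) - pnorm(0, 64.6, 30)) / pnorm(0, 64.6, 30,
                                                      lower.tail = FALSE)
  }
  ks <- suppressWarnings(stats::ks.test(d, pt))
  expect_gt(ks$p.value, 0.01)
})

test_that("Richardson-Lucy sharpens a blurred point source in place", {
  img <- matrix(0, 64, 64)
  img <- boutonquant:::add_spot(img, 30, 41, 100, 40, 20)
  dec <- richardson_lucy_deconvolve(img, 40, 30, 20)
  am <- which(dec == max(dec), arr.ind = TRUE)
  expect_equal(unname(am[1, ]), c(30, 41))
  expect_true(all(dec >= 0))
  expect_lt(abs(sum(dec) - sum(img)) / sum(img), 0.01)
})

test_that("Richardson-Lucy leaves a uniform field unchanged", {
  u <- matrix(4, 40, 40)
  expect_equal(richardson_lucy_deconvolve(u, 40, 1, 20), u, tolerance = 1e-6)
  expect_error(richardson_lucy_deconvolve(matrix(-1, 4, 4), 40, 1, 20),
               "nonnegative")
  expect_error(richardson_lucy_deconvolve(matrix(1, 4, 4), 40, 0, 20),
               "n_iter")
})

test_that("two blurred spots deconvolve to their true separation", {
  img <- matrix(0, 96, 96)
  img <- boutonquant:::add_spot(img, 48, 40, 100, 40, 20)
  img <- boutonquant:::add_spot(img, 48, 45, 100, 40, 20)  # 5 px = 100 nm
  dec <- richardson_lucy_deconvolve(img, 40, 30, 20)
  mx <- find_maxima(dec, prominence = max(dec) / 10)
  mx <- mx[1:2, ]
  sep <- sqrt(diff(mx$row)^2 + diff(mx$col)^2) * 20
  expect_lt(abs(sep - 100), 20 + 1e-9)
})

test_that("prominence gating reproduces the definition on simple fields", {
  img <- matrix(0, 40, 40)
  img <- boutonquant:::add_spot(img, 20, 20, 100, 40, 20)
  mx <- find_maxima(img, 20)
  expect_equal(nrow(mx), 1)
  expect_equal(c(mx$row, mx$col), c(20, 20))

  img2 <- matrix(0, 40, 80)
  img2[20, 20] <- 100
  img2[20, 60] <- 15
  expect_equal(nrow(find_maxima(img2, 20)), 1)
  expect_equal(nrow(find_maxima(img2, 10)), 2)

  # plateau maxima are reported at their centroid
  img3 <- matrix(0, 20, 20)
  img3[10:11, 10:12] <- 7
  mx3 <- find_maxima(img3, 5)
  expect_equal(c(mx3$row, mx3$col), c(10.5, 11))
})

test_that("prominences match an exhaustive flood-fill oracle", {
  set.seed(33)
  for (rep in 1:6) {
    img <- matrix(sample(seq_len(400)), 20, 20)  # unique values
    mine <- find_maxima(img, 0)
    orc <- oracle_prominences(img)
    mine <- mine[order(mine$row, mine$col), ]
    orc <- orc[order(orc[, 1], orc[, 2]), , drop = FALSE]
    expect_equal(nrow(mine), nrow(orc))
    expect_equal(mine$row, orc[, 1])
    expect_equal(mine$col, orc[, 2])
    expect_equal(mine$prominence, orc[, 4])
  }
})

test_that("triad gating requires a shared Homer spot and one-to-one use", {
  cav <- tibble::tibble(row = 10, col = 10)
  munc <- tibble::tibble(row = 10, col = 14)  # 80 nm at 20 nm/px
  homer <- tibble::tibble(row = 10, col = 12)
  tri <- detect_triads(cav, munc, homer, 250, 200, 20)
  expect_equal(nrow(tri), 1)
  expect_equal(tri$pair_dist_nm, 80)
  expect_equal(nrow(detect_triads(cav, munc, homer[0, ], 250, 200, 20)), 0)

  # greedy ascending-distance matching uses each maximum once
  cav2 <- tibble::tibble(row = c(10, 10), col = c(10, 20))
  munc2 <- tibble::tibble(row = c(10, 10), col = c(12, 19))
  homer2 <- tibble::tibble(row = c(10, 10), col = c(11, 20))
  tri2 <- detect_triads(cav2, munc2, homer2, 250, 200, 20)
  expect_equal(nrow(tri2), 2)
  expect_equal(sort(tri2$pair_dist_nm), c(20, 40))
})

test_that("gating recovers ground-truth pairings among distractors", {
  set.seed(34)
  n_ok <- 0; n_tot <- 0
  for (f in 1:8) {
    cfg <- sted_sim_config(field_size = c(400, 400), n_triads = 25,
                           n_distractors = 8, seed = 340 + f)
    sim <- simulate_sted_field(cfg)
    tru <- sim$truth
    cav <- tibble::tibble(row = tru$cav_row, col = tru$cav_col)
    munc <- tibble::tibble(row = tru$munc_row, col = tru$munc_col)
    homer <- tibble::tibble(row = tru$homer_row, col = tru$homer_col)
    # add distractor coordinates to every channel
    nd <- 8
    dis <- function() tibble::tibble(row = runif(nd, 1, 400),
                                     col = runif(nd, 1, 400))
    tri <- detect_triads(dplyr::bind_rows(cav, dis()),
                         dplyr::bind_rows(munc, dis()),
                         dplyr::bind_rows(homer, dis()), 250, 200, 20)
    for (i in seq_len(nrow(tri))) {
      j <- which.min((tru$cav_row - tri$cav_row[i])^2 +
                       (tru$cav_col - tri$cav_col[i])^2)
      hit <- sqrt((tru$cav_row[j] - tri$cav_row[i])^2 +
                    (tru$cav_col[j] - tri$cav_col[i])^2) < 1e-9 &&
        sqrt((tru$munc_row[j] - tri$munc_row[i])^2 +
               (tru$munc_col[j] - tri$munc_col[i])^2) < 1e-9
      n_ok <- n_ok + hit
    }
    n_tot <- n_tot + nrow(tri)
  }
  expect_gte(n_tot, 190)
  expect_gte(n_ok / n_tot, 0.95)
})

test_that("distance measurement is exact on the grid and symmetric", {
  ch <- matrix(0, 64, 64)
  cav <- boutonquant:::add_spot(ch, 30, 20, 100, 40, 20)
  munc <- boutonquant:::add_spot(ch, 30, 25, 100, 40, 20)
  fld <- sted_field(list(cav = cav, munc = munc, homer = ch), 20)
  tri <- tibble::tibble(cav_row = 30, cav_col = 20, munc_row = 30,
                        munc_col = 25)
  expect_equal(measure_distance(fld, tri), 100)
  # swapped endpoints
  tri_sw <- tibble::tibble(cav_row = 30, cav_col = 25, munc_row = 30,
                           munc_col = 20)
  fld_sw <- sted_field(list(cav = munc, munc = cav, homer = ch), 20)
  expect_equal(measure_distance(fld_sw, tri_sw), 100)
  # coincident centres
  fld0 <- sted_field(list(cav = cav, munc = cav, homer = ch), 20)
  tri0 <- tibble::tibble(cav_row = 30, cav_col = 20, munc_row = 30,
                         munc_col = 20)
  expect_equal(measure_distance(fld0, tri0), 0)
  # translation and 90-degree rotation leave the distance unchanged
  cav_t <- boutonquant:::add_spot(ch, 40, 31, 100, 40, 20)
  munc_t <- boutonquant:::add_spot(ch, 40, 36, 100, 40, 20)
  fld_t <- sted_field(list(cav = cav_t, munc = munc_t, homer = ch), 20)
  tri_t <- tibble::tibble(cav_row = 40, cav_col = 31, munc_row = 40,
                          munc_col = 36)
  expect_equal(measure_distance(fld_t, tri_t), 100)
  cav_r <- boutonquant:::add_spot(ch, 20, 30, 100, 40, 20)
  munc_r <- boutonquant:::add_spot(ch, 25, 30, 100, 40, 20)
  fld_r <- sted_field(list(cav = cav_r, munc = munc_r, homer = ch), 20)
  tri_r <- tibble::tibble(cav_row = 20, cav_col = 30, munc_row = 25,
                          munc_col = 30)
  expect_equal(measure_distance(fld_r, tri_r), 100)
})

test_that("quantisation error stays below pixel_size/sqrt(2) off the grid", {
  px <- 20
  offs <- seq(0, 0.75, by = 0.25)
  for (dx in offs) for (dy in offs) {
    ch <- matrix(0, 64, 64)
    a <- c(30 + dx, 20 + dy)
    b <- c(30 + dx, 26 + dy)  # true separation 120 nm, variable phase
    cav <- boutonquant:::add_spot(ch, a[1], a[2], 100, 40, px)
    munc <- boutonquant:::add_spot(ch, b[1], b[2], 100, 40, px)
    fld <- sted_field(list(cav = cav, munc = munc, homer = ch), px)
    mc <- find_maxima(cav, 20); mm <- find_maxima(munc, 20)
    tri <- tibble::tibble(cav_row = mc$row[1], cav_col = mc$col[1],
                          munc_row = mm$row[1], munc_col = mm$col[1])
    d <- measure_distance(fld, tri)
    expect_lte(abs(d - 120), px / sqrt(2) + 1e-9)
  }
})

test_that("distance aggregation bins, summarises and compares groups", {
  m <- tibble::tibble(
    distance_nm = c(10, 30, 50, 10, 30, 50),
    condition = rep(c("ctrl", "fsk"), each = 3),
    animal_id = c("a1", "a1", "a2", "b1", "b1", "b2"))
  agg <- aggregate_distances(m)
  expect_equal(agg$summary$mean, c(30, 30))
  h <- dplyr::filter(agg$histogram, group == "ctrl")
  expect_equal(h$count[1:3], c(1, 1, 1))
  expect_equal(sum(h$count), 3)
  expect_true(all(diff(h$cum_freq) >= 0))
  expect_equal(max(h$cum_freq), 1)
  ks <- dplyr::filter(agg$comparisons, test == "ks_2samp")
  expect_equal(ks$statistic, 0)
  expect_error(aggregate_distances(m[c(1, 4:6), ]), "fewer than 2")
})
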