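test_that("time axis follows the 1000/2000-year spacing rule", {
  ax <- paleo_time_axis(7500, 47000)
  expect_identical(ax, c(seq(8000, 22000, 1000), seq(24000, 46000, 2000)))
  expect_length(ax, 27)
  expect_identical(paleo_time_axis(10000, 20000), seq(10000, 20000, 1000))
  expect_error(paleo_time_axis(20000, 10000), "smaller")
})

test_that("cube generation is deterministic and respects the config", {
  cfg <- tiny_config()
  c1 <- generate_climate_cube(cfg)
  c2 <- generate_climate_cube(cfg)
  expect_identical(c1, c2)
  expect_identical(c1$times, seq(10000, 20000, 1000))
  # all land cells finite, all sea cells NA
  for (v in names(c1$vars)) {
    expect_true(all(is.finite(c1$vars[[v]][c1$land])))
    expect_true(all(is.na(c1$vars[[v]][!c1$land])))
  }
  expect_error(generate_climate_cube(scenario_config(extent = c(0, 2, 40, 60))),
               "degenerate")
})

test_that("zero temporal trend makes every slice identical", {
  cfg <- tiny_config()
  cfg$variables <- lapply(cfg$variables, function(p) { p$trend <- 0; p })
  cube <- generate_climate_cube(cfg)
  for (v in names(cube$vars))
    for (it in seq_along(cube$times)[-1])
      expect_identical(cube$vars[[v]][, , it], cube$vars[[v]][, , 1])
})

test_that("glacial cooling amplitude is recovered from the arrays", {
  cfg <- scenario_config()
  cube <- generate_climate_cube(cfg)
  g <- function(t) exp(-((t - cfg$glacial$peak) / cfg$glacial$width)^2)
  i20 <- match(20000, cube$times)
  i10 <- match(10000, cube$times)
  land <- cube$land[, , 1]  # coastline is time-constant
  d_obs <- mean(cube$vars$BIO6[, , i20][land]) -
    mean(cube$vars$BIO6[, , i10][land])
  d_exp <- cfg$variables$BIO6$trend * (g(20000) - g(10000))
  expect_equal(d_obs, d_exp, tolerance = 1e-10)
})

test_that("ice extent peaks at the glacial maximum and shrinks toward present", {
  cube <- generate_climate_cube(scenario_config())
  ice_area <- apply(cube$ice, 3, sum)
  i_lgm <- match(21000, cube$times)
  expect_equal(ice_area[i_lgm], max(ice_area))
  # monotone shrinking from the peak toward the youngest slice
  expect_true(all(diff(ice_area[1:i_lgm]) >= 0))
})

test_that("niche functions respect constancy, change points and product form", {
  nf <- define_niche(list(BIO5 = list(opt = 18, width = 8)))
  e <- data.frame(BIO5 = seq(-10, 40, length.out = 30))
  expect_identical(nf(e, 40000), nf(e, 10000))

  shifted <- define_niche(list(BIO6 = list(opt = -20, width = 8)),
                          change_time = 16000,
                          post_curves = list(BIO6 = list(opt = -5, width = 8)))
  grid <- data.frame(BIO6 = seq(-30, 10, by = 0.1))
  opt_pre <- grid$BIO6[which.max(shifted(grid, 20000))]
  opt_post <- grid$BIO6[which.max(shifted(grid, 10000))]
  expect_equal(opt_pre - opt_post, -15, tolerance = 0.2)

  prod_niche <- define_niche(list(BIO5 = list(opt = 18, width = 8),
                                  BIO6 = list(opt = -5, width = 8)))
  set.seed(4)
  ee <- data.frame(BIO5 = runif(50, 0, 35), BIO6 = runif(50, -25, 10))
  s <- prod_niche(ee, 10000)
  m1 <- exp(-((ee$BIO5 - 18) / 8)^2)
  m2 <- exp(-((ee$BIO6 + 5) / 8)^2)
  expect_true(all(s <= pmin(m1, m2) + 1e-12))
  expect_true(all(s >= 0 & s <= 1))

  expect_error(define_niche(list(BIO5 = function(x) x * 2),
                            ranges = list(BIO5 = c(0, 1))),
               "outside")
})

test_that("occurrence sampling is seeded, on eligible cells, and dominated by suitability", {
  cfg <- tiny_config()
  cube <- tiny_cube()
  o1 <- sample_occurrences(cube, cfg$niche, cfg$sampling, seed = 5)
  o2 <- sample_occurrences(cube, cfg$niche, cfg$sampling, seed = 5)
  expect_identical(o1, o2)
  # no presence on sea or ice
  env <- extract_env(cube, o1)
  expect_false(any(env$flagged))
  # empty request keeps the schema
  o0 <- sample_occurrences(cube, cfg$niche,
                           list(n_per_slice = 0, age_error = 100), seed = 1)
  expect_identical(names(o0), c("species", "longitude", "latitude",
                                "age_calBP", "age_error"))
  expect_identical(nrow(o0), 0L)
  # presences sit in better habitat than the average land cell
  cfg2 <- tiny_config()
  cfg2$sampling$n_per_slice <- 50  # 550 presences
  occ <- sample_occurrences(cube, cfg2$niche, cfg2$sampling, seed = 6)
  nf <- define_niche(cfg2$niche$curves)
  pres_env <- extract_env(cube, occ)
  s_pres <- nf(pres_env, pres_env$time)
  all_cells <- do.call(rbind, lapply(cube$times, function(t)
    paleoniche:::slice_env_table(cube, t)))
  s_avail <- nf(all_cells, all_cells$time)
  expect_gt(mean(s_pres), mean(s_avail))
})

test_that("a single-cell niche concentrates all presences in that cell", {
  cfg <- tiny_config()
  cfg$variables <- lapply(cfg$variables, function(p) { p$trend <- 0; p })
  cube <- generate_climate_cube(cfg)
  cells <- paleoniche:::slice_env_table(cube, cube$times[1])
  target <- cells[7, ]
  nf <- define_niche(list(
    BIO5 = function(x) as.numeric(abs(x - target$BIO5) < 1e-9)))
  occ <- sample_occurrences(cube, nf, list(n_per_slice = 20), seed = 9)
  expect_true(all(occ$longitude == target$lon))
  expect_true(all(occ$latitude == target$lat))
})

test_that("uniform suitability sampling is multinomially uniform over cells", {
  cfg <- scenario_config(extent = c(0, 25, 40, 45), res = 2.5,
                         window = c(10000, 12000), sea_frac = 0,
                         ice = list(lat_max = 90, advance = 0))
  cube <- generate_climate_cube(cfg)
  n_cells <- cube$grid$n_lon * cube$grid$n_lat
  flat <- define_niche(list(BIO5 = function(x) rep(1, length(x))))
  occ <- sample_occurrences(cube, flat,
                            list(n_per_slice = c(10000, 0, 0),
                                 bias_strength = 0), seed = 13)
  counts <- table(factor(paste(occ$longitude, occ$latitude),
                         levels = unique(paste(rep(paleoniche:::cell_centers_lon(cube$grid),
                                                   times = cube$grid$n_lat),
                                               rep(paleoniche:::cell_centers_lat(cube$grid),
                                                   each = cube$grid$n_lon)))))
  expect_identical(sum(counts), 10000L)
  p <- chisq.test(as.vector(counts), p = rep(1 / n_cells, n_cells))$p.value
  expect_gt(p, 0.001)
})

test_that("age jitter round-trips to the generating slice", {
  occ <- tiny_occ()
  truth <- attr(occ, "slice")
  assigned <- nearest_slice(occ$age_calBP, tiny_cube()$times)
  expect_identical(assigned, truth)
})
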