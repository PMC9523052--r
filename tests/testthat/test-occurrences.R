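make_occ <- function(age, lon = 5, lat = 45, sp = "a", err = NA) {
  data.frame(species = sp, longitude = lon, latitude = lat,
             age_calBP = age, age_error = err)
}

test_that("the time window is a closed interval with logged exclusions", {
  x <- rbind(make_occ(7500), make_occ(47000), make_occ(7499),
             make_occ(47001), make_occ(50000), make_occ(20000),
             make_occ(10000), make_occ(30000), make_occ(7600),
             make_occ(46999))
  out <- read_occurrences(x)
  expect_identical(nrow(out), 7L)  # 3 of 10 outside the window
  expect_true(all(out$age_calBP >= 7500 & out$age_calBP <= 47000))
  expect_true(7500 %in% out$age_calBP && 47000 %in% out$age_calBP)
  expect_identical(attr(out, "exclusions")$outside_window, 3L)
  expect_error(read_occurrences(x[, -1]), "'species' missing")
  expect_warning(read_occurrences(rbind(x, make_occ(10000, lat = 95))),
                 "invalid")
})

test_that("collapse keeps one record per cell per slice, preferring small age errors", {
  cube <- tiny_cube()
  x <- rbind(make_occ(11050, err = 50), make_occ(11100, err = 10),
             make_occ(10900, err = 90))
  out <- collapse_occurrences(x, cube$grid, cube$times)
  expect_identical(nrow(out), 1L)
  expect_identical(out$age_error, 10)  # smallest error wins
  expect_identical(out$slice, 11000)
})

test_that("collapse equals a brute-force group-by and is idempotent and order-invariant", {
  cube <- tiny_cube()
  g <- cube$grid
  set.seed(31)
  n <- 200
  x <- data.frame(
    species = sample(c("a", "b"), n, replace = TRUE),
    longitude = runif(n, g$xmin, g$xmin + g$n_lon * g$res - 1e-9),
    latitude = runif(n, g$ymin, g$ymin + g$n_lat * g$res - 1e-9),
    age_calBP = runif(n, 10000, 20000),
    age_error = sample(c(10, 50, 100, NA), n, replace = TRUE))
  out <- collapse_occurrences(x, g, cube$times)

  # brute-force oracle: explicit grouping, min error then first in file
  ix <- floor((x$longitude - g$xmin) / g$res) + 1
  iy <- floor((x$latitude - g$ymin) / g$res) + 1
  sl <- sapply(x$age_calBP, function(a) {
    d <- abs(a - cube$times)
    cube$times[max(which(d == min(d)))]
  })
  key <- paste(x$species, sl, (iy - 1) * g$n_lon + ix)
  picked <- sapply(split(seq_len(n), key), function(rows) {
    err <- ifelse(is.na(x$age_error[rows]), Inf, x$age_error[rows])
    o <- rows[order(err, x$age_calBP[rows], x$longitude[rows],
                    x$latitude[rows])]
    o[1]  # smallest error, then content order
  })
  expect_identical(nrow(out), length(picked))
  expect_setequal(
    paste(out$species, out$longitude, out$latitude, out$age_calBP),
    paste(x$species, x$longitude, x$latitude, x$age_calBP)[picked])

  # idempotent
  again <- collapse_occurrences(out, g, cube$times)
  expect_equal(again, out)

  # order-invariant
  perm <- collapse_occurrences(x[sample(n), ], g, cube$times)
  rownames(perm) <- NULL
  expect_equal(perm, out)

  # never drops the last record of a (species, slice) pair
  expect_setequal(unique(paste(out$species, out$slice)),
                  unique(paste(x$species, sl)))
  expect_lte(nrow(out), n)
})

test_that("model tables have ratio-determined sizes and identical presences across reps", {
  cube <- tiny_cube()
  occ <- collapse_occurrences(tiny_occ(), cube$grid, cube$times)
  pres <- occ[1:10, ]
  bg <- sample_background_repetitions(pres, cube, n_rep = 2, ratio = 50,
                                      seed = 7)
  tabs <- build_model_table(pres, bg, cube)
  expect_length(tabs, 2)
  expect_identical(nrow(tabs[[1]]), 10L + 500L)
  p1 <- tabs[[1]][tabs[[1]]$response == 1, setdiff(names(tabs[[1]]), "rep")]
  p2 <- tabs[[2]][tabs[[2]]$response == 1, setdiff(names(tabs[[2]]), "rep")]
  expect_equal(p1, p2)
  b1 <- tabs[[1]][tabs[[1]]$response == 0, ]
  b2 <- tabs[[2]][tabs[[2]]$response == 0, ]
  expect_false(isTRUE(all.equal(b1$lon, b2$lon)))
  expect_false(anyNA(tabs[[1]][paleoniche:::CLIMATE_VARS]))
})

test_that("presences on ice cells are dropped with a logged count", {
  cfg <- tiny_config(ice = list(lat_max = 55, advance = 10))
  cube <- generate_climate_cube(cfg)
  # a presence placed on an icy northern cell at the glacial peak slice
  it <- which.max(apply(cube$ice, 3, sum))
  icy <- which(cube$ice[, , it], arr.ind = TRUE)[1, ]
  pres <- data.frame(
    species = "a",
    longitude = paleoniche:::cell_centers_lon(cube$grid)[icy[1]],
    latitude = paleoniche:::cell_centers_lat(cube$grid)[icy[2]],
    age_calBP = cube$times[it], age_error = 10,
    slice = cube$times[it])
  ok <- collapse_occurrences(tiny_occ(), cube$grid, cube$times)
  ok <- ok[ok$latitude < 50, ][1:5, ]  # clear of the enlarged ice sheet
  suppressMessages(
    tabs <- build_model_table(rbind(ok, pres),
                              sample_background_repetitions(ok, cube, 1, 10,
                                                            seed = 2),
                              cube))
  expect_identical(attr(tabs, "exclusions")$presence_flagged, 1L)
  expect_identical(sum(tabs[[1]]$response), 5L)
})

test_that("background environment means track the per-slice land means", {
  cube <- tiny_cube()
  occ <- collapse_occurrences(tiny_occ(), cube$grid, cube$times)
  pres <- occ[occ$slice == 15000, ][1, ]
  bg <- sample_background_repetitions(pres, cube, n_rep = 1, ratio = 2000,
                                      seed = 5)
  tabs <- build_model_table(pres, bg, cube)
  bg_rows <- tabs[[1]][tabs[[1]]$response == 0, ]
  cells <- paleoniche:::slice_env_table(cube, 15000)
  expect_equal(mean(bg_rows$BIO5), mean(cells$BIO5),
               tolerance = 4 * sd(cells$BIO5) / sqrt(2000))
})
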