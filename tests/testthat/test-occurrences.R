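test_that("one-per-cell thinning keeps one random point per occupied cell", {
  g <- sdm_grid(matrix(0, 10, 10))
  occ <- data.frame(x = c(0.2, 0.5, 0.9, 3.5, 5.1, -2),
                    y = c(0.3, 0.6, 0.1, 3.5, 5.1, 4))
  th <- thin_one_per_cell(occ, g, seed = 1)
  expect_equal(nrow(th), 3L)          # 3 in one cell -> 1; two singles
  expect_equal(attr(th, "n_excluded"), 1L)  # x = -2 outside
  # all-distinct cells: unchanged
  occ2 <- data.frame(x = c(0.5, 1.5, 2.5), y = rep(0.5, 3))
  expect_equal(nrow(thin_one_per_cell(occ2, g, seed = 5)), 3L)
  # determinism and idempotence
  set.seed(99)
  big <- data.frame(x = runif(300, 0, 10), y = runif(300, 0, 10))
  a <- thin_one_per_cell(big, g, seed = 7)
  b <- thin_one_per_cell(big, g, seed = 7)
  expect_identical(a$x, b$x)
  again <- thin_one_per_cell(a, g, seed = 8)
  expect_equal(nrow(again), nrow(a))
  # at most one point per cell
  idx <- cell_index(g, a$x, a$y)
  expect_false(any(duplicated(idx)))
  # points on nodata cells are excluded
  gv <- g; gv$values[1, 1] <- NA  # row 1 = north => cell with y in [9,10)
  thn <- thin_one_per_cell(data.frame(x = 0.5, y = 9.5), gv, seed = 1)
  expect_equal(nrow(thn), 0L)
  expect_equal(attr(thn, "n_excluded"), 1L)
})

test_that("minimum-distance thinning satisfies the all-pairs constraint and greedy maximality", {
  expect_equal(nrow(thin_min_distance(
    data.frame(x = c(0, 3), y = c(0, 0)), 5, seed = 1)), 1L)
  spread <- data.frame(x = c(0, 10, 20), y = c(0, 0, 0))
  expect_equal(nrow(thin_min_distance(spread, 5, seed = 1)), 3L)
  set.seed(31)
  cloud <- data.frame(x = runif(500, 0, 60), y = runif(500, 0, 40))
  th <- thin_min_distance(cloud, 5, seed = 3)
  dm <- as.matrix(dist(th[, c("x", "y")]))
  expect_true(all(dm[upper.tri(dm)] >= 5))
  # maximality: every excluded point is within d_min of some kept point
  key <- paste(cloud$x, cloud$y)
  excluded <- cloud[!key %in% paste(th$x, th$y), ]
  for (i in seq_len(nrow(excluded))) {
    expect_lt(min(sqrt((th$x - excluded$x[i])^2 + (th$y - excluded$y[i])^2)),
              5)
  }
  expect_identical(thin_min_distance(cloud, 5, seed = 3)$x, th$x)
})

test_that("background sampling respects the domain, regions, and seed", {
  v <- matrix(runif(200), 10, 20)
  v[, 1:3] <- NA
  dom <- sdm_grid(v)
  bg <- sample_background(dom, 500, seed = 2)
  expect_equal(nrow(bg), 500L)
  expect_true(all(!is.na(grid_extract(dom, bg$x, bg$y))))
  expect_identical(sample_background(dom, 500, seed = 2), bg)
  expect_false(identical(sample_background(dom, 500, seed = 3)$x, bg$x))
  # region restriction
  reg <- sdm_categorical(matrix(rep(1:2, each = 100), 10, 20), codes = 1:2)
  bgr <- sample_background(dom, 200, seed = 4, regions = reg, restrict = 2)
  expect_true(all(bgr$region == 2))
  # no-duplicate-cell policy errors when n exceeds distinct cells
  expect_error(sample_background(dom, 200, seed = 1, replace_cells = FALSE),
               "exceeds")
  ok <- sample_background(dom, 170, seed = 1, replace_cells = FALSE)
  expect_false(any(duplicated(cell_index(dom, ok$x, ok$y))))
})

test_that("design weights equalize class totals for any size combination", {
  g1 <- sdm_grid(matrix(runif(100), 10))
  st <- sdm_stack(list(a = g1, b = sdm_grid(matrix(runif(100), 10))))
  set.seed(13)
  for (rep in 1:10) {
    np <- sample(3:120, 1); nb <- sample(3:400, 1)
    pres <- data.frame(x = runif(np, 0, 10), y = runif(np, 0, 10))
    bg <- data.frame(x = runif(nb, 0, 10), y = runif(nb, 0, 10))
    d <- build_design(pres, bg, st)
    expect_equal(sum(d$w[d$y == 1]), sum(d$w[d$y == 0]))
    expect_equal(unique(d$w[d$y == 1]), 1)
  }
  # equal sizes -> all weights 1 (points kept south of the nodata row below)
  pres <- data.frame(x = runif(20, 0, 10), y = runif(20, 0, 9))
  bg <- data.frame(x = runif(20, 0, 10), y = runif(20, 0, 9))
  expect_equal(build_design(pres, bg, st)$w, rep(1, 40))
  # a presence on a nodata cell is dropped and counted
  gna <- sdm_grid(rbind(NA, matrix(runif(90), 9)))  # north row nodata
  stna <- sdm_stack(list(a = gna))
  pres2 <- rbind(pres, data.frame(x = 5.5, y = 9.5))
  d2 <- build_design(pres2, bg, stna)
  expect_equal(unname(d2$n_dropped["presence"]), 1L)
  expect_equal(sum(d2$y == 1), 20L)
})

test_that("balanced subsampling downsamples every region to the minimum count", {
  mk <- function(n) data.frame(x = runif(n), y = runif(n))
  set.seed(8)
  occ <- list(`1` = mk(478), `2` = mk(1372), `3` = mk(853))
  out <- subsample_balanced(occ, seed = 6)
  expect_equal(unname(vapply(out, nrow, integer(1))), c(478L, 478L, 478L))
  expect_identical(out[["1"]], occ[["1"]])  # min region unchanged
  expect_identical(subsample_balanced(occ, seed = 6)[["2"]]$x,
                   out[["2"]]$x)
  # subsample rows come from the original sets
  expect_true(all(out[["3"]]$x %in% occ[["3"]]$x))
  eq <- list(a = mk(50), b = mk(50))
  expect_identical(subsample_balanced(eq, seed = 1), eq)
  expect_error(subsample_balanced(list(a = mk(5)), seed = 1), "2 regions")
})

test_that("occurrence CSV round-trips with role column", {
  occ <- data.frame(x = c(1.5, 2.25), y = c(3, 4.5), region = c(1L, 2L))
  path <- withr::local_tempfile(fileext = ".csv")
  write_occurrences(occ, path, role = "presence")
  back <- read_occurrences(path)
  expect_equal(back$x, occ$x)
  expect_equal(back$region, occ$region)
  expect_equal(unique(back$role), "presence")
})
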