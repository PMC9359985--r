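test_that("cell assignment uses half-open intervals from the lower-left origin", {
  g <- sdm_grid(matrix(0, 4, 5), cell_size = 2, origin = c(10, 100))
  # x exactly on a cell boundary belongs to the cell to its east
  idx <- cell_index(g, x = c(10, 12, 11.999, 20 - 1e-9), y = rep(100.5, 4))
  expect_equal(idx$col, c(1L, 2L, 1L, 5L))
  # y = y0 is the southernmost row (last matrix row); row 1 is north
  idx2 <- cell_index(g, x = rep(10.5, 3), y = c(100, 102, 108 - 1e-9))
  expect_equal(idx2$row, c(4L, 3L, 1L))
  # outside points get NA
  out <- cell_index(g, x = c(9.99, 20), y = c(101, 101))
  expect_true(all(is.na(out$row)))
  # centers round-trip through cell_index
  ctr <- cell_center(g, row = c(1, 4), col = c(1, 5))
  back <- cell_index(g, ctr$x, ctr$y)
  expect_equal(back$row, c(1L, 4L))
  expect_equal(back$col, c(1L, 5L))
})

test_that("stack members must align and extraction matches manual lookup", {
  a <- sdm_grid(matrix(1:12, 3, 4))
  b <- sdm_grid(matrix(13:24, 3, 4))
  s <- sdm_stack(list(u = a, v = b))
  expect_error(sdm_stack(list(u = a, v = sdm_grid(matrix(0, 2, 4)))),
               "aligned")
  expect_error(sdm_stack(list(a, b)), "names")
  # point in row 2 (from north), col 3 of a 3-row grid
  got <- stack_extract(s, x = 2.5, y = 1.5)
  expect_equal(got$u, a$values[2, 3])
  expect_equal(got$v, b$values[2, 3])
})

test_that("ASCII grid files round-trip value-exactly with nodata honored", {
  v <- matrix(rnorm(20), 4, 5)
  v[2, 3] <- NA
  g <- sdm_grid(v, cell_size = 0.5, origin = c(-3.25, 7.5))
  path <- withr::local_tempfile(fileext = ".asc")
  write_ascii_grid(g, path)
  g2 <- read_ascii_grid(path)
  expect_identical(g2$values, g$values)
  expect_equal(g2$cell_size, g$cell_size)
  expect_equal(g2$origin, g$origin)
  expect_error(write_ascii_grid(sdm_grid(matrix(-9999, 2, 2)), path),
               "collides")
})

test_that("aggregate_proportion matches block arithmetic and partitions to 1", {
  # saturated, empty, and checkerboard blocks
  cb <- matrix(ifelse((row(matrix(0, 10, 20)) + col(matrix(0, 10, 20))) %% 2,
                      1, 2), 10, 20)
  fine <- sdm_categorical(rbind(
    cbind(matrix(1, 10, 10), matrix(2, 10, 10)), cb),
    cell_size = 0.03, codes = c(1, 2))
  out <- aggregate_proportion(fine, 1, 10)
  expect_equal(dim(out$values), c(2L, 2L))
  expect_equal(out$values[1, ], c(1, 0))
  expect_equal(out$values[2, ], c(0.5, 0.5))
  expect_equal(out$cell_size, 0.3)
  # proportions over a disjoint class partition sum to 1 cellwise
  set.seed(7)
  m <- matrix(sample(1:3, 900, replace = TRUE), 30, 30)
  m[sample(900, 40)] <- NA
  cg <- sdm_categorical(m, codes = 1:3)
  total <- Reduce(`+`, lapply(1:3, function(k)
    aggregate_proportion(cg, k, 6)$values))
  expect_equal(total, matrix(1, 5, 5))
  # trailing partial blocks are dropped and the origin shifts north
  cg2 <- sdm_categorical(matrix(1, 25, 17), codes = 1)
  out2 <- aggregate_proportion(cg2, 1, 10)
  expect_equal(dim(out2$values), c(2L, 1L))
  expect_equal(out2$origin[2], 5)  # 25 - 20 fine rows dropped at the south
  # blocks with no valid cell are nodata
  m3 <- matrix(NA_real_, 10, 10); m3[1:5, 1:5] <- 1
  out3 <- aggregate_proportion(sdm_categorical(m3, codes = 1), 1, 5)
  expect_equal(out3$values, matrix(c(1, NA, NA, NA), 2, 2))
  expect_error(aggregate_proportion(cg, integer(0), 5), "non-empty")
})

test_that("distance transform equals the brute-force nearest-target scan", {
  set.seed(11)
  for (rep in 1:5) {
    m <- matrix((runif(30 * 30) < 0.04) + 0, 30, 30)
    if (!any(m == 1)) m[15, 15] <- 1
    g <- sdm_grid(m, cell_size = 2)
    d <- distance_to_class(g)
    tg <- which(m == 1, arr.ind = TRUE)
    bf <- matrix(0, 30, 30)
    for (i in 1:30) for (j in 1:30)
      bf[i, j] <- 2 * sqrt(min((tg[, 1] - i)^2 + (tg[, 2] - j)^2))
    expect_equal(d$values, bf)
  }
  expect_error(distance_to_class(sdm_grid(matrix(0, 3, 3))), "no target")
  # nodata cells are not targets and stay nodata
  m <- matrix(0, 5, 5); m[3, 3] <- 1; m[1, 1] <- NA
  d <- distance_to_class(sdm_grid(m))
  expect_true(is.na(d$values[1, 1]))
  expect_equal(d$values[3, 3], 0)
  expect_equal(d$values[3, 4], 1)
})

test_that("correlation matrix is symmetric, unit-diagonal, affine-invariant", {
  set.seed(3)
  a <- sdm_grid(matrix(rnorm(100), 10))
  s <- sdm_stack(list(a = a, b = sdm_grid(2 - 3 * a$values),
                      c = sdm_grid(matrix(rnorm(100), 10))))
  r <- correlation_matrix(s)
  expect_equal(r, t(r))
  expect_equal(diag(r), c(a = 1, b = 1, c = 1))
  expect_equal(r["a", "b"], -1)
  # affine rescaling changes correlations only up to sign
  s2 <- sdm_stack(list(a = sdm_grid(10 - 2 * a$values), b = s$b, c = s$c))
  r2 <- correlation_matrix(s2)
  expect_equal(abs(r2["a", "c"]), abs(r["a", "c"]))
  # direct 4-cell check against the Pearson formula
  s4 <- sdm_stack(list(x = sdm_grid(matrix(c(1, 2, 3, 4), 2)),
                       y = sdm_grid(matrix(c(1, 2, 4, 3), 2))))
  expect_equal(correlation_matrix(s4)["x", "y"], 0.8)
  # zero-variance variable flagged NA, not silently 0
  sz <- sdm_stack(list(x = s$a, z = sdm_grid(matrix(5, 10, 10))))
  expect_warning(rz <- correlation_matrix(sz), "zero-variance")
  expect_true(is.na(rz["x", "z"]))
})

test_that("admissible variable sets match brute-force subset filtering", {
  vars <- c("A", "B", "C")
  corr <- diag(3); dimnames(corr) <- list(vars, vars)
  corr["A", "B"] <- corr["B", "A"] <- 0.9
  got <- admissible_variable_sets(vars, corr, 0.7)
  expect_equal(got, list("A", c("A", "C"), "B", c("B", "C"), "C"))
  # no correlated pairs: 2^n - 1 subsets; all correlated: singletons only
  corr0 <- diag(4); dimnames(corr0) <- list(letters[1:4], letters[1:4])
  expect_length(admissible_variable_sets(letters[1:4], corr0, 0.7), 15L)
  corr1 <- matrix(0.95, 3, 3, dimnames = list(vars, vars)); diag(corr1) <- 1
  expect_equal(admissible_variable_sets(vars, corr1, 0.7),
               list("A", "B", "C"))
  # brute-force oracle on a random 8-variable correlation structure
  set.seed(5)
  n <- 8L
  vn <- paste0("v", seq_len(n))
  rm8 <- matrix(runif(n * n), n, n, dimnames = list(vn, vn))
  rm8 <- (rm8 + t(rm8)) / 2; diag(rm8) <- 1
  got8 <- admissible_variable_sets(vn, rm8, 0.75)
  ok_set <- function(s) {
    if (length(s) < 2) return(TRUE)
    prs <- utils::combn(s, 2)
    all(abs(rm8[t(prs)]) < 0.75)
  }
  all_sets <- unlist(lapply(seq_len(n), function(k)
    utils::combn(vn, k, simplify = FALSE)), recursive = FALSE)
  expect_equal(length(got8), sum(vapply(all_sets, ok_set, logical(1))))
  expect_true(all(vapply(got8, ok_set, logical(1))))
})

test_that("map correlation equals flat-vector Pearson over joint support", {
  set.seed(9)
  va <- matrix(runif(400), 20); vb <- matrix(runif(400), 20)
  va[1:5, 1] <- NA; vb[3:8, 2] <- NA
  a <- sdm_grid(va); b <- sdm_grid(vb)
  ok <- !is.na(va) & !is.na(vb)
  expect_equal(map_correlation(a, b), cor(va[ok], vb[ok]))
  expect_equal(map_correlation(a, a), 1)
  expect_equal(map_correlation(a, sdm_grid(1 - va)), -1)
  expect_warning(r0 <- map_correlation(a, sdm_grid(matrix(1, 20, 20))),
                 "zero variance")
  expect_true(is.na(r0))
})
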