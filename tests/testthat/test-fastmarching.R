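test_that("uniform-speed arrival equals Euclidean distance (32^3)", {
  n <- 32L
  src <- c(8L, 8L, 8L)
  T <- msfm_arrival(voxel_grid(array(1, c(n, n, n)), 1), src)
  ijk <- as.matrix(expand.grid(1:n, 1:n, 1:n))
  d <- sqrt(rowSums(sweep(ijk, 2, src)^2))
  sel <- d >= 1
  relerr <- abs(as.numeric(T$values)[sel] - d[sel]) / d[sel]
  expect_lt(max(relerr), 0.02)
  expect_equal(T$values[src[1], src[2], src[3]], 0)
})

test_that("arrival time scales inversely with uniform speed", {
  g1 <- msfm_arrival(voxel_grid(array(1, c(12, 12, 12)), 1), c(6L, 6L, 6L))
  g2 <- msfm_arrival(voxel_grid(array(2, c(12, 12, 12)), 1), c(6L, 6L, 6L))
  expect_equal(2 * g2$values, g1$values, tolerance = 1e-12)
})

test_that("arrival agrees with a 26-neighbour Dijkstra oracle on 12^3", {
  set.seed(5)
  n <- 12L
  # smooth positive speed field
  f <- array(1, c(n, n, n))
  for (k in 1:n) f[, , k] <- 1 + 0.5 * sin(k / 2)
  src <- c(3L, 4L, 3L)
  T <- msfm_arrival(voxel_grid(f, 1), src)$values
  D <- dijkstra26(f, c(1, 1, 1), src)
  sel <- D > 5 # away from the source where both are near-exact
  # graph distance overestimates the continuous geodesic by at most the
  # 26-neighbour chordal gap: (sqrt(3)+1)/sqrt(6) - 1 = 11.5% along the
  # (1,1,2) direction, plus quadrature slack on a varying speed field;
  # the solver must never exceed the graph distance
  gap <- (T[sel] - D[sel]) / D[sel]
  expect_lt(max(gap), 0.01)
  expect_gt(min(gap), -0.15)
})

test_that("masked domains and bad inputs are rejected or unreached", {
  f <- array(1, c(8, 8, 8))
  f[, , 4] <- 0 # wall splits the domain
  T <- msfm_arrival(voxel_grid(f, 1), c(2L, 2L, 2L))$values
  expect_true(all(!is.finite(T[, , 5:8])))
  expect_true(all(is.finite(T[, , 1:3])))
  expect_error(msfm_arrival(voxel_grid(f, 1), c(2L, 2L, 4L)), "domain")
  expect_error(msfm_arrival(voxel_grid(f, 1), c(99L, 2L, 2L)), "outside")
  expect_error(msfm_arrival(voxel_grid(array(-1, c(4, 4, 4)), 1),
                            c(2L, 2L, 2L)), "positive")
})

test_that("backtracking descends T and recovers straight geodesics", {
  n <- 24L
  src <- c(4L, 4L, 4L)
  Tg <- msfm_arrival(voxel_grid(array(1, c(n, n, n)), 1), src)
  cl <- backtrack_path(Tg, c(20L, 18L, 16L))
  ends <- cl$points[c(1, nrow(cl$points)), ]
  expect_equal(ends[1, ], c(3, 3, 3)) # physical coords of source voxel
  expect_equal(ends[2, ], c(19, 17, 15))
  d_true <- sqrt(sum((c(19, 17, 15) - c(3, 3, 3))^2))
  expect_lt(abs(path_length(cl) - d_true) / d_true, 0.02)
  # arrival time decreases monotonically along the path (end -> source)
  tvals <- apply(cl$points, 1, function(p)
    tortuflow:::interp3(Tg$values, Tg, p))
  expect_true(all(diff(tvals) > -1e-9))
  # end = source degenerates to a single point
  cl0 <- backtrack_path(Tg, src)
  expect_equal(nrow(cl0$points), 1L)
  expect_equal(path_length(cl0), 0)
  expect_error(backtrack_path(Tg, c(1L, 1L, 99L)), "finite|outside")
})
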