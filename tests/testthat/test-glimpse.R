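test_that("glimpse_config validates its fields", {
  expect_error(glimpse_config(k = 0), "k must be")
  expect_error(glimpse_config(base_rows = 0), "base_rows")
  expect_error(glimpse_config(scale_factor = 1), "scale_factor")
  expect_error(glimpse_config(pad_value = NA), "pad_value")
  cfg <- glimpse_config(k = 4, base_rows = 2, base_cols = 7)
  expect_s3_class(cfg, "glimpse_config")
  expect_identical(cfg$scale_factor, 2L)
})

test_that("normalize_location maps cell centres as documented", {
  # centre cell of odd-extent grids is exactly the origin
  for (e in c(3L, 5L, 9L))
    expect_equal(normalize_location(c((e + 1) / 2, (e + 1) / 2), c(e, e)),
                 c(0, 0))
  # first cell sits a half-cell inside the corner
  for (shape in list(c(4L, 4L), c(5L, 9L), c(22L, 1000L)))
    expect_equal(normalize_location(c(1, 1), shape),
                 -1 + 1 / shape)
  expect_error(normalize_location(c(0, 1), c(5, 5)), "invalid coordinates")
  expect_error(normalize_location(c(6, 1), c(5, 5)), "invalid coordinates")
})

test_that("normalize/denormalize round-trips every cell of a 5x9 grid", {
  for (i in 1:5) for (j in 1:9) {
    coords <- normalize_location(c(i, j), c(5, 9))
    expect_identical(denormalize_location(coords, c(5, 9)), c(i, j))
  }
})

test_that("extract_glimpse handles constant and impulse fields", {
  cfg <- glimpse_config(k = 3, base_rows = 2, base_cols = 2)
  const <- matrix(7.5, 32, 32)
  g <- extract_glimpse(const, c(0, 0), cfg)
  expect_equal(dim(g), c(3L, 2L, 2L))
  expect_true(all(g == 7.5))

  img <- matrix(0, 9, 9); img[5, 5] <- 3.25
  g1 <- extract_glimpse(img, c(0, 0), glimpse_config(k = 1, base_rows = 1,
                                                     base_cols = 1))
  expect_equal(as.numeric(g1), 3.25)
})

test_that("extract_glimpse matches the hand-computed 8x8 ramp case", {
  x <- outer(0:7, 0:7, function(r, cc) r * 8 + cc)
  g <- extract_glimpse(x, c(0, 0), glimpse_config(k = 2, base_rows = 2,
                                                  base_cols = 2))
  # scale 1: central 2x2 of the ramp
  expect_equal(matrix(g[1, , ], 2, 2), matrix(c(27, 35, 28, 36), 2, 2))
  # scale 2: the four 2x2 block means of the central 4x4 window
  win <- x[3:6, 3:6]
  expected <- matrix(c(mean(win[1:2, 1:2]), mean(win[3:4, 1:2]),
                       mean(win[1:2, 3:4]), mean(win[3:4, 3:4])), 2, 2)
  expect_equal(matrix(g[2, , ], 2, 2), expected)
})

test_that("extract_glimpse agrees exactly with the brute-force oracle", {
  set.seed(11)
  for (rep in 1:40) {
    nr <- sample(6:40, 1); nc <- sample(6:40, 1)
    sig <- matrix(rnorm(nr * nc), nr, nc)
    k <- sample(1:3, 1)
    br <- sample(1:3, 1); bc <- sample(1:4, 1)
    loc <- runif(2, -1, 1)
    g <- extract_glimpse(sig, loc, glimpse_config(k, br, bc))
    o <- oracle_glimpse(sig, loc, k, br, bc)
    expect_equal(unclass(g), o, ignore_attr = TRUE, tolerance = 1e-12)
  }
})

test_that("multichannel extraction clamps the channel axis and matches the oracle", {
  cfg <- glimpse_config(k = 3, base_rows = 2, base_cols = 7)
  const <- matrix(2, 22, 1000)
  g <- extract_glimpse_multichannel(const, c(0.3, -0.2), cfg)
  expect_true(all(g == 2))

  imp <- matrix(0, 22, 1000); imp[10, 500] <- 5
  loc <- normalize_location(c(10, 500), c(22, 1000))
  g1 <- extract_glimpse_multichannel(imp, loc, glimpse_config(1, 2, 7))
  expect_equal(sum(g1 != 0), 1L)

  ramp <- matrix(seq_len(4 * 32), 4, 32)
  for (rep in 1:10) {
    loc <- runif(2, -1, 1)
    g <- extract_glimpse_multichannel(ramp, loc, cfg)
    o <- oracle_glimpse(ramp, loc, 3, 2, 7, clamp_rows = TRUE)
    expect_equal(unclass(g), o, ignore_attr = TRUE, tolerance = 1e-12)
  }
  expect_error(extract_glimpse_multichannel(matrix(0, 1, 10), c(0, 0), cfg),
               "base_rows exceeds")
})

test_that("glimpses are translation equivariant for interior shifts", {
  set.seed(21)
  cfg <- glimpse_config(k = 2, base_rows = 3, base_cols = 3)
  for (rep in 1:20) {
    x <- matrix(rnorm(40 * 40), 40, 40)
    p <- c(sample(15:25, 1), sample(15:25, 1))
    delta <- c(sample(-5:5, 1), sample(-5:5, 1))
    shifted <- matrix(0, 40, 40)
    src_r <- 1:40 - delta[1]; src_c <- 1:40 - delta[2]
    okr <- src_r >= 1 & src_r <= 40; okc <- src_c >= 1 & src_c <= 40
    shifted[okr, okc] <- x[src_r[okr], src_c[okc]]
    g0 <- extract_glimpse(x, normalize_location(p, c(40, 40)), cfg)
    g1 <- extract_glimpse(shifted, normalize_location(p + delta, c(40, 40)), cfg)
    expect_equal(unclass(g0), unclass(g1), ignore_attr = TRUE,
                 tolerance = 1e-12)
  }
})

test_that("pooling conserves the window mean when fully in-bounds", {
  set.seed(31)
  cfg <- glimpse_config(k = 3, base_rows = 2, base_cols = 2)
  x <- matrix(rnorm(64 * 64), 64, 64)
  loc <- normalize_location(c(32, 32), c(64, 64))
  g <- extract_glimpse(x, loc, cfg)
  idx <- denormalize_location(loc, c(64, 64))
  for (s in 1:3) {
    w <- 2L * 2L^(s - 1L)
    r0 <- idx[1] - w %/% 2L; c0 <- idx[2] - w %/% 2L
    win <- x[r0:(r0 + w - 1L), c0:(c0 + w - 1L)]
    expect_equal(mean(g[s, , ]), mean(win), tolerance = 1e-12)
  }
})

test_that("glimpse output shape is always (k, base_rows, base_cols)", {
  set.seed(41)
  for (rep in 1:15) {
    k <- sample(1:4, 1); br <- sample(1:3, 1); bc <- sample(1:8, 1)
    sig <- matrix(rnorm(22 * 100), 22, 100)
    g <- extract_glimpse_multichannel(sig, runif(2, -1.5, 1.5) |> clip_location(),
                                      glimpse_config(k, br, bc))
    expect_equal(dim(g), c(k, br, bc))
    expect_true(all(is.finite(g)))
  }
  expect_error(extract_glimpse(matrix(1, 4, 4), c(NA, 0), glimpse_config()),
               "finite")
})

test_that("write_glimpse_csv dumps one block per scale", {
  g <- extract_glimpse(matrix(rnorm(100), 10, 10), c(0, 0),
                       glimpse_config(2, 2, 3))
  path <- withr::local_tempfile(fileext = ".csv")
  write_glimpse_csv(g, path)
  df <- read.csv(path)
  expect_equal(nrow(df), 4L)           # 2 scales x 2 rows
  expect_equal(df$scale, c(1, 1, 2, 2))
})
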