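test_that("default geometry yields the 32/16/8/4/2/1 pyramid, 63 cells", {
  sp <- memSpec()
  expect_identical(levelCellCounts(sp), c(32L, 16L, 8L, 4L, 2L, 1L))
  expect_identical(levelSizes(sp), c(64L, 128L, 256L, 512L, 1024L, 2048L))
  expect_identical(sum(levelCellCounts(sp)), 2L * (2048L %/% 64L) - 1L)
  expect_error(memSpec(2048, 64, 5), "dyadic")
})

test_that("buildMEM computes apEnAuto on every dyadic window", {
  sp <- memSpec(256L, 32L, 4L)
  set.seed(31)
  s <- emSeries(rnorm(256), fs = 1000)
  params <- apEnParams()
  map <- buildMEM(s, sp, params)
  expect_identical(lengths(map@cells), c(8L, 4L, 2L, 1L))
  # slice-and-call oracle for every cell
  for (l in 1:4) {
    w <- 32L * 2L^(l - 1L)
    for (seg in seq_len(256L %/% w)) {
      slice <- s@v[((seg - 1L) * w + 1L):(seg * w)]
      expect_equal(memCell(map, l, seg),
                   as.numeric(apEnAuto(slice, params)),
                   info = sprintf("l=%d s=%d", l, seg))
    }
  }
  # windows at level l+1 are exact unions of two adjacent level-l windows
  tab <- memTable(map)
  for (l in 1:3) {
    lo <- tab[tab$level == l, ]
    hi <- tab[tab$level == l + 1, ]
    expect_identical(hi$start_sample, lo$start_sample[c(TRUE, FALSE)])
    expect_identical(hi$end_sample, lo$end_sample[c(FALSE, TRUE)])
  }
  # deterministic: same series, bit-identical map
  expect_identical(map@cells, buildMEM(s, sp, params)@cells)
  expect_error(buildMEM(emSeries(rnorm(100), 1000), sp), "does not match")
})

test_that("global tolerance policy shares the full-series SD", {
  sp <- memSpec(256L, 32L, 4L)
  set.seed(8)
  s <- emSeries(rnorm(256), fs = 1000)
  map <- buildMEM(s, sp, apEnParams(rPolicy = "global"))
  gsd <- sd(s@v)
  expect_equal(memCell(map, 1, 3),
               approxEntropy(s@v[65:96], 2, 0.2 * gsd))
})

test_that("constant series gives an all-zero, all-degenerate map", {
  sp <- memSpec(256L, 32L, 4L)
  map <- buildMEM(emSeries(rep(1, 256), fs = 1000), sp)
  expect_true(all(unlist(map@cells) == 0))
  expect_true(all(unlist(isDegenerate(map))))
})

test_that("averageMEMs matches a naive accumulation oracle", {
  sp <- memSpec(256L, 32L, 4L)
  set.seed(17)
  maps <- lapply(1:50, function(i) randomMap(sp, stimulus = i))
  av <- averageMEMs(maps)
  for (l in 1:4) {
    vals <- sapply(maps, function(m) m@cells[[l]])
    vals <- matrix(vals, ncol = length(maps))
    for (seg in seq_len(nrow(vals))) {
      expect_equal(memCell(av$mean, l, seg), mean(vals[seg, ]))
      expect_equal(memCell(av$sd, l, seg), sd(vals[seg, ]))
    }
  }
  # two identical maps: mean equals either, SD zero
  av2 <- averageMEMs(list(maps[[1]], maps[[1]]))
  expect_equal(av2$mean@cells, maps[[1]]@cells)
  expect_true(all(unlist(av2$sd@cells) == 0))
  # hand-set cell values average arithmetically
  m1 <- maps[[1]]; m2 <- maps[[2]]
  m1@cells[[1]][1] <- 0.2; m2@cells[[1]][1] <- 0.4
  expect_equal(memCell(averageMEMs(list(m1, m2))$mean, 1, 1), 0.3)
  expect_error(averageMEMs(list()), "non-empty")
  expect_error(averageMEMs(list(m1, randomMap(memSpec(128, 32, 3)))),
               "share")
})

test_that("entropy values fall into the fixed 8-band palette", {
  expect_identical(memBand(0.35), "green")
  expect_identical(memBand(0.4), "brown")      # left-closed bands
  expect_identical(memBand(1.2), "red")
  expect_identical(memBand(c(0.55, 0.65, 0.75, 0.85, 0.95, 1.0)),
                   c("blue", "light violet", "light burgundy",
                     "light gray", "dark gray", "red"))
})

test_that("maps survive JSON serialization and render to grid files", {
  sp <- memSpec(256L, 32L, 4L)
  set.seed(2)
  map <- buildMEM(emSeries(rnorm(256), fs = 1000), sp)
  f <- withr::local_tempfile(fileext = ".json")
  writeMEM(map, f)
  back <- readMEM(f)
  expect_equal(back@cells, map@cells)
  expect_identical(back@degenerate, map@degenerate)
  expect_identical(levelSizes(back), levelSizes(map))

  stem <- file.path(withr::local_tempdir(), "map")
  files <- renderMEM(map, stem)
  expect_true(all(file.exists(files)))
  tab <- read.csv(files[["csv"]])
  expect_identical(nrow(tab), sum(levelCellCounts(sp)))
  expect_equal(tab$apen, unlist(map@cells), tolerance = 1e-12,
               ignore_attr = TRUE)
  html <- readLines(files[["html"]])
  expect_true(any(grepl("<table", html)))
  expect_error(suppressWarnings(
    renderMEM(map, file.path(tempdir(), "no/such/dir/x"))), "cannot")
})
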