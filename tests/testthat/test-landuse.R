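make_grid <- function(m, cellsize = 10) {
  structure(list(data = m, cellsize = cellsize, xllcorner = 0,
                 yllcorner = 0), class = "ascii_grid")
}

test_that("category counting matches a cell-by-cell tally", {
  # uniform grid: all PADDY (code 3), all assigned to one node
  g <- make_grid(matrix(3L, 10, 10))
  a <- make_grid(matrix(1L, 10, 10))
  tab <- count_categories(g, a, id_map = c("1" = "A"))
  expect_equal(tab$PADDY, 100L)
  expect_equal(sum(as.matrix(tab[setdiff(landuse_categories(), "PADDY")])), 0L)

  # all-nodata category raster: the assigned node still appears, zeroed
  tab0 <- count_categories(make_grid(matrix(NA_integer_, 10, 10)), a,
                           id_map = c("1" = "A"))
  expect_equal(sum(as.matrix(tab0[landuse_categories()])), 0L)

  # random 50x50 raster over 5 nodes vs a nested-loop oracle
  set.seed(8)
  lab <- matrix(sample(c(1:9, NA), 2500, replace = TRUE), 50, 50)
  node <- matrix(sample(c(1:5, NA), 2500, replace = TRUE), 50, 50)
  tab <- count_categories(make_grid(lab), make_grid(node))
  for (i in 1:5) {
    for (c in 1:9) {
      brute <- 0L
      for (r in 1:50) for (cc in 1:50) {
        if (!is.na(node[r, cc]) && node[r, cc] == i &&
            !is.na(lab[r, cc]) && lab[r, cc] == c) brute <- brute + 1L
      }
      expect_equal(tab[tab$id == i, landuse_categories()[c]], brute)
    }
  }
  # exhaustive and exclusive: base categories sum to assigned non-nodata cells
  for (i in 1:5) {
    expect_equal(sum(as.matrix(tab[tab$id == i, landuse_categories()])),
                 sum(!is.na(node) & node == i & !is.na(lab)))
  }

  expect_error(count_categories(make_grid(lab[1:10, ]), make_grid(node)),
               "shape")
  lab2 <- lab; lab2[1, 1] <- 42L
  expect_error(count_categories(make_grid(lab2), make_grid(node)),
               "unknown category")
})

test_that("forest composites are the stated sums", {
  base <- data.frame(id = "A", WATER = 0, BUILTUP = 0, PADDY = 0, CROP = 0,
                     GRASS = 0, BARE = 0, DBF = 3, EBF = 4, ENF = 5)
  tab <- derive_composites(base)
  expect_equal(tab$EBF_ENF, 9)
  expect_equal(tab$DBF_EBF, 7)
  expect_equal(tab$FOREST, 12)

  zero <- base; zero[c("DBF", "EBF", "ENF")] <- 0
  expect_equal(unlist(derive_composites(zero)[c("EBF_ENF", "DBF_EBF", "FOREST")],
                      use.names = FALSE), c(0, 0, 0))

  set.seed(9)
  rand <- data.frame(id = letters[1:10],
                     matrix(rpois(90, 40), 10,
                            dimnames = list(NULL, landuse_categories())))
  tab <- derive_composites(rand)
  for (r in 1:10) {  # independent summation
    expect_equal(tab$EBF_ENF[r], rand$EBF[r] + rand$ENF[r])
    expect_equal(tab$DBF_EBF[r], rand$DBF[r] + rand$EBF[r])
    expect_equal(tab$FOREST[r], rand$DBF[r] + rand$EBF[r] + rand$ENF[r])
  }

  expect_error(derive_composites(base[, setdiff(names(base), "ENF")]),
               "missing forest")
})

test_that("Esri ASCII grids round-trip through write and read", {
  set.seed(10)
  m <- matrix(sample(c(1:9, NA), 48, replace = TRUE), 6, 8)
  path <- withr::local_tempfile(fileext = ".asc")
  write_ascii_grid(make_grid(m, cellsize = 25), path)
  g <- read_ascii_grid(path)
  expect_equal(g$data, m)
  expect_equal(g$cellsize, 25)
})

test_that("count CSVs are read with canonical codes and composites", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,water,builtup,paddy,crop,grass,bare,dbf,ebf,enf",
               "W01,5,2,10,1,0,0,30,20,12"), path)
  tab <- read_landuse_counts(path)
  expect_equal(tab$WATER, 5)
  expect_equal(tab$FOREST, 62)
  writeLines(c("id,water,builtup", "W01,5,2"), path)
  expect_error(read_landuse_counts(path), "lacks column")
})

test_that("cumulative counting sums over nested catchments", {
  net <- toy_network()
  tab <- derive_composites(data.frame(
    id = c("A", "B", "C"), WATER = c(1, 2, 3), BUILTUP = 0, PADDY = c(5, 0, 1),
    CROP = 0, GRASS = 0, BARE = 0, DBF = c(2, 2, 2), EBF = 0, ENF = 0
  ))
  cum <- accumulate_counts(tab, net)
  expect_equal(cum$WATER[cum$id == "C"], 6)
  expect_equal(cum$PADDY[cum$id == "C"], 6)
  expect_equal(cum$WATER[cum$id == "A"], 1)  # headwaters unchanged
  expect_equal(cum$FOREST[cum$id == "C"], 6)
})

test_that("predictor matrices select, order and optionally normalize", {
  net <- random_network(12, seed = 13)
  tab <- generate_landuse(net, synthetic_config(n_nodes = 12, seed = 13))
  ids <- rev(net$nodes$id)[1:5]
  X <- predictor_matrix(tab, c("WATER", "FOREST"), ids = ids)
  expect_identical(rownames(X), ids)
  expect_equal(X[, "FOREST"],
               stats::setNames(tab$FOREST[match(ids, tab$id)], ids))
  P <- predictor_matrix(tab, landuse_categories(), proportions = TRUE)
  expect_equal(unname(rowSums(P)), rep(1, nrow(P)))
  expect_error(predictor_matrix(tab, "LAVA"), "unknown predictor")
})
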