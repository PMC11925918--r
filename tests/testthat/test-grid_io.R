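# Raster I/O, alignment, clipping and admin-table rasterization.

test_that("ASCII grid read/write round-trips values, mask and georeference", {
  path <- withr::local_tempfile(fileext = ".asc")
  g <- random_grid(9, 7, seed = 3, cell_size = 250, origin = c(1000, 5000))
  write_raster(g, path, "ascii_grid")
  g2 <- read_raster(path)
  expect_identical(is.na(g2$values), is.na(g$values))
  expect_lt(max(abs(g2$values - g$values), na.rm = TRUE),
            1e-6 * diff(range(g$values, na.rm = TRUE)))
  expect_equal(g2$origin, g$origin)
  expect_equal(g2$cell_size, g$cell_size)
  expect_identical(g2$crs_tag, g$crs_tag)   # via .prj sidecar
})

test_that("a hand-written 3x3 ASCII grid with one nodata cell parses correctly", {
  path <- withr::local_tempfile(fileext = ".asc")
  writeLines(c("ncols 3", "nrows 3", "xllcorner 0", "yllcorner 0",
               "cellsize 1000", "NODATA_value -9999",
               "1 2 3", "4 -9999 6", "7 8 9"), path)
  g <- read_raster(path)
  expect_equal(sum(nodata_mask(g)), 1L)
  expect_true(is.na(g$values[2, 2]))
  expect_equal(g$values[1, ], c(1, 2, 3))
  expect_equal(g$origin, c(0, 3000))
})

test_that("GeoTIFF round-trips within float32 precision, degenerate grids included", {
  path <- withr::local_tempfile(fileext = ".tif")
  g <- random_grid(64, 64, seed = 11, holes = 20, crs = "EPSG:32651")
  write_raster(g, path)
  g2 <- read_raster(path)
  expect_identical(is.na(g2$values), is.na(g$values))
  expect_lt(max(abs(g2$values - g$values), na.rm = TRUE),
            1e-6 * diff(range(g$values, na.rm = TRUE)))
  expect_equal(g2$origin, g$origin)
  expect_identical(g2$crs_tag, "EPSG:32651")

  const <- hr_grid(matrix(5, 4, 4))
  write_raster(const, path)
  expect_true(all(read_raster(path)$values == 5))

  all_na <- hr_grid(matrix(NA_real_, 3, 3))
  write_raster(all_na, path)
  expect_true(all(nodata_mask(read_raster(path))))
})

test_that("the written GeoTIFF is readable by an independent TIFF implementation", {
  skip_if(Sys.which("python") == "", "python not on PATH")
  path <- withr::local_tempfile(fileext = ".tif")
  g <- random_grid(10, 8, seed = 5, holes = 0)
  write_raster(g, path)
  out <- suppressWarnings(system2("python", c("-c", shQuote(paste0(
    "import tifffile, numpy as np; a = tifffile.imread('", path, "'); ",
    "print(a.shape[0], a.shape[1], '%.6f' % float(a.mean()))"))),
    stdout = TRUE, stderr = TRUE))
  skip_if(!is.null(attr(out, "status")), "tifffile unavailable")
  parts <- strsplit(out[length(out)], " ")[[1]]
  expect_equal(as.integer(parts[1:2]), dim(g))
  expect_equal(as.numeric(parts[3]), mean(g$values), tolerance = 1e-5)
})

test_that("read_raster fails loudly on missing or malformed files", {
  expect_error(read_raster("no/such/file.tif"), "does not exist")
  bad <- withr::local_tempfile(fileext = ".tif")
  writeLines("this is not a tiff at all and has no header", bad)
  expect_error(read_raster(bad, "geotiff"), "TIFF")
})

test_that("align_stack resamples 500 m to 1000 m by nearest cell centre", {
  set.seed(7)
  fine <- hr_grid(matrix(rnorm(20 * 20), 20, 20), cell_size = 500,
                  origin = c(0, 10000), crs_tag = "t")
  specs <- list(indicator_spec("a", "hazard", "positive"))
  st <- align_stack(list(fine), specs, target_cell_size = 1000)
  out <- st$grids[[1]]
  expect_equal(dim(out$values), c(10L, 10L))
  # brute-force nearest-centre oracle
  for (i in c(1, 4, 10)) for (j in c(1, 5, 10)) {
    xc <- 0 + (j - 0.5) * 1000
    yc <- 10000 - (i - 0.5) * 1000
    d <- outer(10000 - (seq_len(20) - 0.5) * 500 - yc,
               (seq_len(20) - 0.5) * 500 - xc,
               function(dy, dx) dy^2 + dx^2)
    nearest <- which(d == min(d), arr.ind = TRUE)[1, ]
    expect_equal(out$values[i, j], fine$values[nearest[1], nearest[2]])
  }
  # never invents values
  expect_true(all(out$values %in% fine$values))
})

test_that("align_stack uses the intersection extent and is idempotent", {
  a <- hr_grid(matrix(1, 10, 10), origin = c(0, 10000), crs_tag = "t")
  b <- hr_grid(matrix(2, 10, 10), origin = c(5000, 10000), crs_tag = "t")
  specs <- specs_list <- list(indicator_spec("a", "hazard", "positive"),
                              indicator_spec("b", "exposure", "positive"))
  st <- align_stack(list(a, b), specs, 1000)
  expect_equal(dim(st$grids[[1]]$values), c(10L, 5L))  # half-width overlap
  expect_equal(st$grids[[1]]$origin, c(5000, 10000))

  again <- align_stack(st$grids, specs, 1000)
  expect_equal(again$grids[[1]]$values, st$grids[[1]]$values)
  expect_equal(again$grids[[2]]$origin, st$grids[[2]]$origin)

  far <- hr_grid(matrix(3, 10, 10), origin = c(1e6, 1e6), crs_tag = "t")
  expect_error(align_stack(list(a, far), specs, 1000), "intersection")
})

test_that("align_stack propagates the union nodata mask and rejects mixed crs", {
  a <- random_grid(8, 8, seed = 1, holes = 4, crs = "t")
  b <- random_grid(8, 8, seed = 2, holes = 4, crs = "t")
  specs <- list(indicator_spec("a", "hazard", "positive"),
                indicator_spec("b", "exposure", "positive"))
  st <- align_stack(list(a, b), specs, 1000)
  union <- is.na(a$values) | is.na(b$values)
  expect_identical(is.na(st$grids[[1]]$values), union)
  expect_identical(is.na(st$grids[[2]]$values), union)

  c2 <- random_grid(8, 8, seed = 3, crs = "other")
  expect_error(align_stack(list(a, c2), specs, 1000), "crs")
})

test_that("clip_to_boundary masks exactly the outside cells", {
  g <- hr_grid(matrix(1:100, 10, 10), crs_tag = "t")
  all_true <- hr_grid(matrix(1, 10, 10), crs_tag = "t")
  expect_equal(clip_to_boundary(g, all_true)$values, g$values)
  all_false <- hr_grid(matrix(0, 10, 10), crs_tag = "t")
  expect_true(all(is.na(clip_to_boundary(g, all_false)$values)))
  checker <- matrix((row(matrix(0, 10, 10)) + col(matrix(0, 10, 10))) %% 2,
                    10, 10)
  clipped <- clip_to_boundary(g, hr_grid(checker, crs_tag = "t"))
  expect_equal(sum(!is.na(clipped$values)), sum(checker == 1))
  shifted <- hr_grid(matrix(1, 10, 10), origin = c(3000, 10000), crs_tag = "t")
  expect_error(clip_to_boundary(g, shifted), "not aligned")
})

test_that("rasterize_admin_table fills zones uniformly and validates ids", {
  z <- matrix(0L, 6, 6)
  z[1:3, ] <- 1L
  z[4:6, ] <- 2L
  z[1, 1] <- 0L                     # id 0 is masked
  zones <- hr_grid(z * 1.0, crs_tag = "t")
  template <- hr_grid(matrix(0, 6, 6), crs_tag = "t")
  tab <- data.frame(unit_id = c(1, 2, 9), value = c(10, 20, 99))
  out <- rasterize_admin_table(tab, zones, template)
  expect_true(is.na(out$values[1, 1]))
  expect_equal(mean(out$values[z == 1], na.rm = TRUE), 10)
  expect_equal(mean(out$values[z == 2], na.rm = TRUE), 20)

  expect_error(rasterize_admin_table(data.frame(unit_id = 1, value = 10),
                                     zones, template), "missing.*2")
  single <- hr_grid(matrix(1, 4, 4), crs_tag = "t")
  out2 <- rasterize_admin_table(data.frame(unit_id = 1, value = 7), single,
                                hr_grid(matrix(0, 4, 4), crs_tag = "t"))
  expect_true(all(out2$values == 7))
})

test_that("a grid written by the generator re-reads with its recorded mean", {
  sc <- synthetic_scenario(shape = c(48, 48), seed = 9)
  reg <- make_study_region(sc)
  st <- gen_indicator_stack(sc, reg, 2010)
  recorded_mean <- mean(st$grids[["lst"]]$values, na.rm = TRUE)
  path <- withr::local_tempfile(fileext = ".tif")
  write_raster(st$grids[["lst"]], path)
  expect_equal(mean(read_raster(path)$values, na.rm = TRUE), recorded_mean,
               tolerance = 1e-6)
})
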