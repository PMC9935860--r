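test_that("standard domain reproduces the creekshed geometry at printed resolution", {
  d <- build_paper_domain(cell_scale = 1, mussel_cover = 0.10)
  za <- zone_areas(d)
  a <- function(z) za$area_m2[za$zone == z]
  expect_equal(attr(za, "total_area"), 50 * 207)
  expect_equal(attr(za, "marsh_area"), 10350 - 1000)
  expect_equal(a("CHANNEL"), 1000)               # seaward 20 m x 50 m
  expect_equal(a("CREEKHEAD") + a("MUSSEL_MOUND"), 2500)
  # proportions as reported: creekhead 27 %, mounds 2.7 % of marsh area
  expect_equal(round(100 * 2500 / attr(za, "marsh_area")), 27)
  expect_equal(round(100 * a("MUSSEL_MOUND") / attr(za, "marsh_area"), 1), 2.7)
  # 250 m^2 of mounds in 0.25 m^2 cells -> 1000 single-cell mounds
  expect_equal(d$mound_count, 1000L)
  expect_equal(sum(d$mound_frac > 0), 1000)
  expect_true(all(d$mound_frac %in% c(0, 1)))
})

test_that("zone areas partition the grid at every supported coarsening", {
  for (cs in c(1, 2, 4, 5)) {
    d <- build_paper_domain(cell_scale = cs, mussel_cover = 0.10)
    za <- zone_areas(d)
    expect_equal(sum(za$area_m2), 50 * 207, tolerance = 1e-9,
                 info = paste("cell_scale", cs))
    expect_equal(sum(d$dy), 207, tolerance = 1e-9)
    # physical mound count is resolution-invariant
    expect_lte(abs(d$mound_count - 1000), 1)
    # total mound area preserved through per-cell fractions
    expect_equal(sum(d$mound_frac * d$cell_area), 250, tolerance = 1e-6)
  }
})

test_that("unsupported cell widths are rejected with the offending extent", {
  expect_error(build_paper_domain(cell_scale = 3), "50 m")
  expect_error(build_paper_domain(cell_scale = 1.5))
})

test_that("bathymetry ramps are monotone along creek and channel", {
  d <- build_paper_domain(cell_scale = 1, mussel_cover = 0)
  ch <- match("CHANNEL", d$zone_levels)
  cr <- match("CREEK", d$zone_levels)
  # channel deepens seaward along every column
  col_z <- d$zb[d$zone[, 1] == ch, 1]
  expect_true(all(diff(col_z) > 0))
  expect_equal(min(d$zb), -6, tolerance = 0.2)
  # creek bed rises from the junction (-1 m) to its head (0.79 m)
  creek_cells <- which(d$zone == cr, arr.ind = TRUE)
  icol <- creek_cells[1, 2]
  prof <- d$zb[d$zone[, icol] == cr, icol]
  expect_true(all(diff(prof) > 0))
  expect_equal(prof[length(prof)], 0.79, tolerance = 0.02)
  expect_equal(prof[1], -1, tolerance = 0.02)
  # fixed platform elevations
  expect_true(all(d$zb[d$zone == match("LEVEE", d$zone_levels)] == 0.94))
  expect_true(all(d$zb[d$zone == match("PLATFORM", d$zone_levels)] == 0.79))
})

test_that("mound placement is deterministic, regular and capacity-checked", {
  d <- build_paper_domain(cell_scale = 1, mussel_cover = 0)
  head_mask <- d$zone == match("CREEKHEAD", d$zone_levels)
  p1 <- place_mounds(head_mask, 0.10, cell_area = d$cell_area)
  p2 <- place_mounds(head_mask, 0.10, cell_area = d$cell_area)
  expect_identical(p1$mask, p2$mask)
  expect_equal(p1$count, 1000L)
  p20 <- place_mounds(head_mask, 0.20, cell_area = d$cell_area)
  expect_equal(p20$count, 2000L)
  p0 <- place_mounds(head_mask, 0, cell_area = d$cell_area)
  expect_equal(sum(p0$mask), 0)
  # rounding can demand one cell more than the band holds
  expect_error(place_mounds(matrix(TRUE, 2, 2), cover = 1,
                            mound_area = 0.26, cell_area = 0.25),
               "creekhead cells")
  # mounds only inside the creekhead band
  d10 <- build_paper_domain(cell_scale = 1, mussel_cover = 0.10)
  mound <- d10$zone == match("MUSSEL_MOUND", d10$zone_levels)
  band <- head_mask | mound
  expect_true(all(band[mound]))
})

test_that("vegetation assignment follows the zonation and the density identity", {
  veg <- vegetation_classes()
  expect_equal(veg$n, veg$m_stems * veg$d_s)
  d <- build_paper_domain(cell_scale = 2, mussel_cover = 0.10)
  lv <- d$zone_levels
  cls <- function(z) unique(d$veg$class[d$veg_class[d$zone == match(z, lv)]])
  expect_equal(cls("LEVEE"), "tall")
  expect_equal(cls("LEVEE_ADJACENT"), "intermediate")
  expect_true(all(cls("PLATFORM") == "short"))
  expect_true(all(cls("MUSSEL_MOUND") == "short"))
  # below-MSL cells are bare even in the vegetated configuration
  expect_true(all(d$veg_class[d$zb <= 0] == 1L))
  d0 <- build_paper_domain(cell_scale = 2, mussel_cover = 0.10,
                           vegetated = FALSE)
  expect_true(all(d0$veg_class == 1L))
})

test_that("domain serialization writes a self-describing cell table", {
  d <- build_paper_domain(cell_scale = 5, mussel_cover = 0.10)
  path <- tempfile(fileext = ".tsv")
  write_domain(d, path)
  hdr <- readLines(path, n = 7)
  expect_true(any(grepl("seaward boundary", hdr)))
  df <- read.delim(path, comment.char = "#")
  expect_equal(nrow(df), d$n_rows * d$n_cols)
  expect_equal(sort(unique(df$zone)),
               sort(d$zone_levels[sort(unique(as.vector(d$zone)))]))
})
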