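test_that("isotropic map is uniform and sigma_perp follows the AR rule", {
  g <- cable_geometry()
  cm1 <- build_conductivity(g, AR = 1)
  expect_true(all(cm1$sigx == 0.154))
  cm2 <- build_conductivity(g, AR = 2)
  expect_equal(attr(cm2, "sigma_perp"), 0.0385)
  expect_error(build_conductivity(g, AR = 0.8), "AR")
})

test_that("the cable map has exactly one coupling jump at the border", {
  g <- cable_geometry(length = 64, h = 0.125)   # 512 nodes, border at 32 mm
  cm <- build_conductivity(g, AR = 4)
  sx <- as.vector(cm$sigx)
  jumps <- which(diff(sx) != 0)
  expect_length(jumps, 1)
  # link i (1-based) connects nodes i-1, i at midpoint (i - 0.5) h;
  # the last transverse link has midpoint just left of 32 mm
  expect_equal((jumps - 0.5) * 0.125, 31.9375)
  expect_equal(sx[jumps], 0.154 / 16)
  expect_equal(sx[jumps + 1], 0.154)
})

test_that("region map respects the border-left rule and node counts", {
  g <- tissue_geometry(4, 2, h = 0.5, border_x = 2)
  rm <- region_map(g)
  expect_equal(nrow(rm), round(4 / 0.5) * round(2 / 0.5))
  expect_equal(rm$region[rm$x == 2][1], "transverse")  # node on the border
  expect_equal(rm$region[rm$x > 2][1], "longitudinal")
  expect_error(tissue_geometry(4, 2, h = 0.5, border_x = 4), "border")
})

test_that("2D map mirrors directions and the isotropic strip is uniform", {
  g <- tissue_geometry(8, 4, h = 0.5, border_x = 4)
  cm <- build_conductivity(g, AR = 2)
  sp <- 0.154; spp <- sp / 4
  expect_equal(cm$sigx[1, 1], spp)      # transverse region: across fibers in x
  expect_equal(cm$sigy[1, 1], sp)
  expect_equal(cm$sigx[nrow(cm$sigx), 1], sp)  # longitudinal region
  expect_equal(cm$sigy[nrow(cm$sigy), 1], spp)
  # product invariant within each anisotropic region
  expect_equal(cm$sigx[1, 1] * cm$sigy[1, 1], sp * spp)

  gs <- tissue_geometry(8, 4, h = 0.5, border_x = 4, iso_strip_width = 2)
  cms <- build_conductivity(gs, AR = 2)
  mid <- round(nrow(cms$sigx) / 2)
  expect_equal(cms$sigx[mid, 1], sp)
  expect_equal(cms$sigy[mid, 1], sp)
})

test_that("geometry serialises to YAML and back", {
  g <- tissue_geometry(8, 4, h = 0.5, border_x = 3, iso_strip_width = 2)
  f <- tempfile(fileext = ".yaml")
  write_geometry_yaml(g, f)
  g2 <- read_geometry_yaml(f)
  expect_equal(g2[c("width", "height", "h", "border_x", "iso_strip_width")],
               g[c("width", "height", "h", "border_x", "iso_strip_width")])
})
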