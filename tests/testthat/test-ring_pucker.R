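test_that("ideal chairs sit at the poles and amplitude is preserved", {
  p41 <- cremer_pople(ideal_conformer_geometry("4C1", 0.57))
  expect_lt(p41$theta, 1e-6)
  expect_equal(p41$Q, 0.57, tolerance = 1e-9)
  p14 <- cremer_pople(ideal_conformer_geometry("1C4", 0.57))
  expect_gt(p14$theta, 180 - 1e-6)
  expect_equal(sqrt(p14$q2^2 + p14$q3^2), p14$Q, tolerance = 1e-9)
})

test_that("puckering coordinates are invariant under rigid motion", {
  set.seed(42)
  for (name in c("5S1", "1H2", "OE", "2,5B")) {
    g <- ideal_conformer_geometry(name, 0.5)
    p0 <- cremer_pople(g)
    for (rep in 1:5) {
      g2 <- ring_geometry(rotate_translate(g$coords, runif(1, 0, 2 * pi),
                                           rnorm(3), rnorm(3, 0, 5)))
      p1 <- cremer_pople(g2)
      expect_equal(p1$Q, p0$Q, tolerance = 1e-9)
      expect_equal(p1$theta, p0$theta, tolerance = 1e-9)
      dphi <- abs(p1$phi - p0$phi)
      expect_lt(min(dphi, 360 - dphi), 1e-8)
    }
  }
})

test_that("mirror reflection through the mean plane maps theta to 180 - theta", {
  for (name in c("5S1", "OE", "1H2", "4C1")) {
    g <- ideal_conformer_geometry(name, 0.5)
    p0 <- cremer_pople(g)
    pm <- cremer_pople(ring_geometry(g$coords %*% diag(c(1, 1, -1))))
    expect_equal(pm$theta, 180 - p0$theta, tolerance = 1e-8)
  }
})

test_that("degenerate rings are rejected", {
  expect_error(cremer_pople(ring_geometry(planar_hexagon())), "planar")
  bad <- planar_hexagon(); bad[2, ] <- bad[1, ]
  expect_error(ring_geometry(bad), "coincident")
  line <- cbind(seq(0, 5, length.out = 6), 0, 0)
  expect_error(cremer_pople(line), "planar|degenerate|collinear")
})

test_that("classification round-trips every canonical conformer", {
  tab <- conformer_table()
  expect_equal(nrow(tab), 38)
  expect_true(all(tab$theta %in%
    c(0, 50.76848, 54.73561, 90, 125.26439, 129.23152, 180)))
  for (k in seq_len(nrow(tab))) {
    got <- classify_conformer(cremer_pople(ideal_conformer_geometry(tab$name[k])))
    expect_identical(got$name, tab$name[k])
    expect_lt(got$distance, 1e-6)
  }
})

test_that("classification is nearest-neighbour on the sphere with pole dominance", {
  expect_identical(classify_conformer(c(5, 123))$name, "4C1")
  expect_identical(classify_conformer(c(178, 10))$name, "1C4")
  phi5S1 <- conformer_table()$phi[conformer_table()$name == "5S1"]
  expect_identical(classify_conformer(c(90, phi5S1 + 5))$name, "5S1")
  expect_error(classify_conformer(list(theta = NULL, phi = 1)), "theta")
})

test_that("the PL product pathway has the stated endpoints, range and period", {
  expect_equal(pl_path_theta(270), 129)
  expect_equal(pl_path_theta(90), 51)
  expect_equal(pl_path_theta(0), 90)
  phi <- seq(0, 720, by = 0.5)
  expect_equal(range(pl_path_theta(phi)), c(51, 129))
  expect_equal(pl_path_theta(phi), pl_path_theta(phi + 360))
})

test_that("distance to the PL pathway is zero on the curve and matches brute force", {
  for (phi in c(0, 37, 111, 270, 333)) {
    expect_lt(distance_to_pl_path(c(pl_path_theta(phi), phi)), 1e-6)
  }
  ## pole: dense-grid brute force over the curve parameter
  grid <- seq(0, 360, by = 0.01)
  brute <- min(puckerpath:::.sphere_dist(0, 0, pl_path_theta(grid), grid))
  expect_equal(distance_to_pl_path(c(0, 0)), brute, tolerance = 1e-4)
})

test_that("the eight planarity-restricted conformers lie within 3 degrees of the pathway", {
  for (nm in pl_path_conformers()) {
    row <- conformer_table()[conformer_table()$name == nm, ]
    expect_lt(distance_to_pl_path(c(row$theta, row$phi)), 3)
  }
})

test_that("ring reordering restores the convention order", {
  g <- ideal_conformer_geometry("3S1")
  shuffled <- g$coords[c(3, 1, 6, 2, 5, 4), ]
  rownames(shuffled) <- g$atoms[c(3, 1, 6, 2, 5, 4)]
  g2 <- reorder_ring(shuffled)
  expect_equal(g2$coords, g$coords, ignore_attr = TRUE)
  expect_error(reorder_ring(shuffled[1:5, , drop = FALSE]), "missing")
})

test_that("shipped conformer table matches the generator", {
  path <- system.file("extdata", "pyranose_conformers.tsv", package = "puckerpath")
  shipped <- utils::read.table(path, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE)
  expect_equal(shipped$name, conformer_table()$name)
  expect_equal(shipped$theta, conformer_table()$theta, tolerance = 1e-6)
  expect_equal(shipped$phi, conformer_table()$phi, tolerance = 1e-6)
})
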