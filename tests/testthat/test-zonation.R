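test_that("radius graph matches explicit small cases", {
  pts <- data.frame(x = c(0, 10, 40), y = c(0, 0, 0))
  g <- build_graph(pts, neighbor_radius = 15)
  expect_equal(unname(g$edges), cbind(1L, 2L))
  expect_equal(attr(g, "isolated"), 3L)
  g50 <- build_graph(pts, neighbor_radius = 50)
  expect_equal(nrow(g50$edges), 3)  # complete graph on 3 nodes
  expect_error(build_graph(pts[1, ]), "at least 2 cells")
  expect_error(build_graph(data.frame(x = c(0, NA), y = c(0, 1)), 10),
               "non-finite")
})

test_that("radius graph equals brute-force O(n^2) thresholding", {
  set.seed(99)
  for (r in c(8, 30)) {
    x <- runif(200, -100, 100); y <- runif(200, -100, 100)
    g <- build_graph(data.frame(x = x, y = y), neighbor_radius = r)
    expect_equal(unname(g$edges), brute_force_edges(x, y, r))
    expect_equal(g$dist,
                 sqrt((x[g$edges[, 1]] - x[g$edges[, 2]])^2 +
                        (y[g$edges[, 1]] - y[g$edges[, 2]])^2))
  }
})

test_that("iterative smoothing reproduces the hand-traced line graph", {
  # cells on a line at x = 0,10,20,30,40, radius 25:
  # the INT cell at x=30 sees {DZ(10), DZ(20), LZ(40)} -> majority DZ
  ann <- classify_cells(c(1, 1, 1, 0, -1), c(0, 0, 0, 0, 0))
  expect_equal(ann$phenotype, c("DZ", "DZ", "DZ", "INT", "LZ"))
  g <- build_graph(data.frame(x = seq(0, 40, 10), y = rep(0, 5)), 25)
  res <- iterative_smooth(g, ann)
  expect_equal(res$region,
               c(rep("DZ_region", 4), "LZ_region"))
  expect_equal(res$n_iterations, 2)  # change sweep + fixpoint confirmation
  expect_equal(res$changes_per_sweep, c(1L, 0L))
  expect_true(res$converged)
  # purity against ORIGINAL calls: DZ region holds 3 DZ + 1 INT
  expect_equal(res$purity_dz, 0.75)
  expect_equal(res$purity_lz, 1)
})

test_that("smoothing fixpoints, ties and error paths behave as specified", {
  # two separated blocks: nothing changes, one confirming sweep
  g <- build_graph(data.frame(x = c(0, 10, 100, 110), y = rep(0, 4)), 25)
  ann <- classify_cells(c(1, 1, -1, -1), rep(0, 4))
  res <- iterative_smooth(g, ann)
  expect_equal(res$n_iterations, 1)
  expect_equal(res$region, c("DZ_region", "DZ_region",
                             "LZ_region", "LZ_region"))
  # INT cell with exactly one DZ and one LZ neighbor keeps INT (tie rule)
  g3 <- build_graph(data.frame(x = c(0, 10, 20), y = rep(0, 3)), 15)
  res3 <- iterative_smooth(g3, classify_cells(c(1, 0, -1), rep(0, 3)))
  expect_equal(res3$region, c("DZ_region", "unassigned", "LZ_region"))
  expect_error(iterative_smooth(g3, classify_cells(c(1, 1, 1), rep(0, 3))),
               "at least one DZ and one LZ")
  # adversarial case: a cell whose original neighborhood is half DZ and
  # half LZ flips every sweep at a low threshold -> max_iter guard fires
  g2 <- build_graph(data.frame(x = c(0, 10, 20), y = rep(0, 3)), 15)
  expect_error(iterative_smooth(g2, classify_cells(c(1, 1, -1), rep(0, 3)),
                                dissimilar_fraction = 0.4, max_iter = 20),
               "did not converge")
})

test_that("purity check enforces the 70% condition inclusively", {
  res <- manual_region_result(rep(c("DZ_region", "LZ_region"), c(10, 10)))
  res$purity_dz <- 0.70; res$purity_lz <- 1
  expect_true(check_purity(res)$pass)   # 7 of 10: at least 70% passes
  res$purity_dz <- 0.60
  expect_false(check_purity(res)$pass)  # 6 of 10 fails
  res$purity_dz <- NA_real_
  chk <- check_purity(res)
  expect_false(chk$pass)
  expect_match(chk$message, "empty region")
})

test_that("boundary vertices are cross-edge midpoints in order", {
  # two DZ cells facing two LZ cells: all midpoints on the vertical x = 10
  pts <- data.frame(x = c(0, 0, 20, 20), y = c(0, 10, 0, 10))
  g <- build_graph(pts, neighbor_radius = 25)
  res <- manual_region_result(c("DZ_region", "DZ_region",
                                "LZ_region", "LZ_region"))
  b <- extract_boundary(g, res)
  expect_true(all(b$vertices[, 1] == 10))
  expect_equal(sort(b$vertices[, 2]), c(0, 5, 5, 10))  # 4 cross edges
  expect_equal(b$vertices[, 2], sort(b$vertices[, 2]))  # principal-axis order

  # exactly two parallel cross edges give the two midpoints
  pts2 <- data.frame(x = c(0, 0, 10, 10), y = c(0, 10, 0, 10))
  g2 <- build_graph(pts2, neighbor_radius = 10)
  b2 <- extract_boundary(g2, res)
  expect_equal(unname(b2$vertices), cbind(c(5, 5), c(0, 10)))

  res_fail <- manual_region_result(res$region, purity_dz = 0.5)
  expect_error(extract_boundary(g, res_fail), "refusing")
  res_far <- manual_region_result(c("DZ_region", "DZ_region",
                                    "DZ_region", "DZ_region"))
  expect_error(extract_boundary(g, res_far), "no edge joins")
})

test_that("boundary on synthetic tissue tracks the true chord", {
  sim <- generate_gc(synthetic_config(n_cells = 2000, signature_effect = 1.5,
                                      seed = 41))
  rep <- run_gc_pipeline(sim$cells, dz_sig = sim$signatures$DZ,
                         lz_sig = sim$signatures$LZ, subtype_col = NULL,
                         seed = 41)
  err <- abs(rep$boundary$vertices %*% sim$boundary_true$normal -
               sim$boundary_true$offset)
  expect_lt(mean(err), 30)  # within one neighbor radius of the true line
})

test_that("signed distances carry the DZ-negative convention", {
  boundary <- structure(list(vertices = cbind(x = c(10, 10, 10),
                                              y = c(0, 5, 10))),
                        class = "gc_boundary")
  # labeled cells on either side determine the sign of unlabeled queries
  cells <- list(x = c(0, 25, 5, 18, 10), y = c(5, 5, 5, 5, 5))
  res <- manual_region_result(c("DZ_region", "LZ_region", "unassigned",
                                "unassigned", "unassigned"))
  d <- signed_distance(cells, boundary, res)
  expect_equal(d[1], -10)  # DZ side
  expect_equal(d[2], 15)   # LZ side
  expect_equal(d[3], -5)   # nearest labeled cell is DZ
  expect_equal(d[4], 8)    # nearest labeled cell is LZ
  expect_equal(d[5], 0)    # exactly on a vertex
})

test_that("signed distance magnitude equals brute force over vertices", {
  set.seed(7)
  v <- cbind(runif(40, -50, 50), runif(40, -50, 50))
  boundary <- structure(list(vertices = v), class = "gc_boundary")
  cells <- list(x = runif(300, -100, 100), y = runif(300, -100, 100))
  res <- manual_region_result(rep(c("DZ_region", "LZ_region"), 150))
  d <- signed_distance(cells, boundary, res)
  brute <- vapply(seq_along(cells$x), function(i)
    min(sqrt((cells$x[i] - v[, 1])^2 + (cells$y[i] - v[, 2])^2)),
    numeric(1))
  expect_equal(abs(d), brute, tolerance = 1e-12)
})

test_that("regions and signed distances agree with the generator truth", {
  sim <- generate_gc(synthetic_config(n_cells = 2000, signature_effect = 1.5,
                                      label_noise = 0.1, seed = 43))
  rep <- run_gc_pipeline(sim$cells, dz_sig = sim$signatures$DZ,
                         lz_sig = sim$signatures$LZ, subtype_col = NULL,
                         seed = 43)
  tr <- sim$truth[match(rep$annotation$cell_id, sim$truth$cell_id), ]
  agree <- mean((rep$annotation$region == "DZ_region") ==
                  (tr$true_zone == "DZ"))
  expect_gte(agree, 0.9)
  far <- abs(tr$true_distance) > 30
  sign_agree <- mean(sign(rep$annotation$boundary_distance[far]) ==
                       sign(tr$true_distance[far]))
  expect_gte(sign_agree, 0.95)
})
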