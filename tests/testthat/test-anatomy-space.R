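# Order blocks, principal modes, the deformation grid, distance metrics.

test_that("order blocks have the printed column counts and layout", {
  lib <- small_library()
  expect_equal(ncol(extract_order_block(lib, 1)$G), 6L)     # mean locations
  expect_equal(ncol(extract_order_block(lib, 2)$G), 18L)    # ellipsoids
  expect_equal(ncol(extract_order_block(lib, 9)$G), 102L)
  expect_equal(nrow(extract_order_block(lib, 3)$G), length(lib$coeffs))
  # order 1 row = the three monopole coefficients per hemisphere (centres)
  b1 <- extract_order_block(lib, 1)
  expect_equal(b1$G[2, ], unname(c(lib$coeffs[[2]]$coeff[1, , 1],
                                   lib$coeffs[[2]]$coeff[2, , 1])))
  # degree convention shifts the block by one degree
  expect_equal(ncol(extract_order_block(lib, 2, convention = "degree")$G), 30L)
  expect_error(extract_order_block(lib, 99), "order")
})

test_that("principal mode matches a direct SVD oracle on small matrices", {
  set.seed(11)
  for (rep in 1:5) {
    nb <- sample(3:5, 1); nw <- sample(4:12, 1)
    G <- matrix(rnorm(nb * nw), nb, nw)
    blk <- structure(list(order = 2L, degree_l = 1L, G = G,
                          layout = NULL), class = "order_block")
    pm <- principal_mode(blk)
    gh <- sweep(G, 2, colMeans(G))
    sv <- svd(gh)
    expect_equal(pm$S11, sv$d[1]^2, tolerance = 1e-10)
    u <- sv$v[, 1]
    if (u[which.max(abs(u))] < 0) u <- -u
    expect_equal(abs(sum(pm$u1 * u)), 1, tolerance = 1e-10)
    expect_equal(sqrt(sum(pm$u1^2)), 1, tolerance = 1e-12)
  }
})

test_that("two-subject mode is the row difference; identical brains warn", {
  G <- rbind(c(1, 2, 3, 4, 5, 6), c(3, 2, 1, 4, 7, 6))
  blk <- structure(list(order = 1L, degree_l = 0L, G = G, layout = NULL),
                   class = "order_block")
  pm <- principal_mode(blk)
  d <- G[2, ] - G[1, ]
  expect_equal(abs(sum(pm$u1 * d / sqrt(sum(d^2)))), 1, tolerance = 1e-12)
  expect_equal(pm$S11, sum(d^2) / 2, tolerance = 1e-12)  # 2 * |d/2|^2
  blk$G <- rbind(G[1, ], G[1, ])
  expect_warning(pm0 <- principal_mode(blk), "zero-variance")
  expect_equal(pm0$S11, 0)
})

test_that("deformation is linear around the mean and delta = 0 is the mean", {
  lib <- small_library()
  base <- library_mean(lib)
  pm <- principal_mode(extract_order_block(lib, 6))
  expect_equal(apply_deformation(pm, 0, base)$coeff, base$coeff,
               tolerance = 1e-12)
  cp <- apply_deformation(pm, 1.3, base)
  cm <- apply_deformation(pm, -1.3, base)
  expect_equal(cp$coeff + cm$coeff, 2 * base$coeff, tolerance = 1e-12)
  # one delta unit displaces the order block by the library SD along u1
  proj <- extract_order_block(lib, 6)$G %*% pm$u1
  expect_equal(pm$step_scale, stats::sd(proj), tolerance = 1e-10)
  # literal mode rescales the same displacement by S11 / step_scale
  lay <- cbind(pm$layout$hemi, pm$layout$axis, pm$layout$m_col)
  cl <- apply_deformation(pm, 1, base, step_mode = "literal")
  c1 <- apply_deformation(pm, 1, base, step_mode = "sd")
  expect_equal(cl$coeff[lay] - base$coeff[lay],
               (pm$S11 / pm$step_scale) * (c1$coeff[lay] - base$coeff[lay]),
               tolerance = 1e-10)
})

test_that("grid cardinality and origin cell", {
  lib <- small_library()
  g25 <- build_grid(lib, orders = c(4, 6))
  expect_equal(length(g25$surfaces), 25L)
  g81 <- build_grid(lib, orders = c(4, 6),
                    deltas_a = seq(-2, 2, 0.5), deltas_b = seq(-2, 2, 0.5))
  expect_equal(length(g81$surfaces), 81L)
  mean_surface <- reconstruct(library_mean(lib), lib$param)
  expect_equal(g81$surfaces[[5, 5]]$vertices, mean_surface$vertices,
               tolerance = 1e-12)
  # distance grows monotonically along each axis away from the origin
  d <- vapply(1:5, function(i) rms_vertex_distance(g25$surfaces[[i, 3]],
                                                   mean_surface), numeric(1))
  expect_true(all(diff(d[1:3]) < 0) && all(diff(d[3:5]) > 0))
  expect_error(build_grid(lib, orders = c(5, 5)), "distinct")
})

test_that("index-matched distance agrees with the brute-force loop", {
  lib <- small_library()
  g <- build_grid(lib, orders = c(4, 6), deltas_a = c(-2, 2), deltas_b = 0)
  a <- g$surfaces[[1, 1]]; b <- g$surfaces[[2, 1]]
  manual <- mean(vapply(seq_len(nrow(a$vertices)), function(i) {
    sqrt(sum((a$vertices[i, ] - b$vertices[i, ])^2))
  }, numeric(1)))
  expect_equal(rms_vertex_distance(a, b), manual, tolerance = 1e-12)
  expect_equal(rms_vertex_distance(a, b), rms_vertex_distance(b, a))
  expect_equal(rms_vertex_distance(a, a), 0)
  # rigid translation by (3, 4, 0) -> 5 mm exactly
  b2 <- a
  b2$vertices <- sweep(a$vertices, 2, c(3, 4, 0), `+`)
  expect_equal(rms_vertex_distance(a, b2), 5)
})

test_that("nn and Hausdorff match the exhaustive oracle on tiny meshes", {
  p <- sphere_param(c(0, pi / 2, pi / 2, pi), c(0, 0, pi / 2, 0),
                    rbind(c(0, 1, 2), c(1, 2, 3)))
  va <- rbind(c(0, 0, 1), c(1, 0, 0), c(0, 1, 0), c(0, 0, -1))
  vb <- va + 0.4
  vb[2, ] <- c(5, 5, 5)
  a <- cortical_surface(va, p); b <- cortical_surface(vb, p)
  D <- outer(seq_len(4), seq_len(4),
             Vectorize(function(i, j) sqrt(sum((va[i, ] - vb[j, ])^2))))
  nn_oracle <- (mean(apply(D, 1, min)) + mean(apply(D, 2, min))) / 2
  hd_oracle <- max(max(apply(D, 1, min)), max(apply(D, 2, min)))
  expect_equal(nn_distance(a, b), nn_oracle, tolerance = 1e-12)
  expect_equal(hausdorff_distance(a, b), hd_oracle, tolerance = 1e-12)
  expect_equal(nn_distance(a, a), 0, tolerance = 1e-6)
  expect_equal(hausdorff_distance(a, a), 0, tolerance = 1e-6)
  expect_equal(nn_distance(a, b), nn_distance(b, a))
  expect_equal(hausdorff_distance(a, b), hausdorff_distance(b, a))
})

test_that("nn distance never exceeds the index-matched distance", {
  lib <- small_library()
  g <- build_grid(lib, orders = c(4, 6), deltas_a = c(-2, 0, 2), deltas_b = 0)
  a <- g$surfaces[[1, 1]]; b <- g$surfaces[[3, 1]]
  expect_lte(nn_distance(a, b), rms_vertex_distance(a, b))
  # self-distance is zero up to the fp noise of the quadratic distance form
  expect_lt(hausdorff_distance(a, a), 1e-5)
})

test_that("grid manifest serialises provenance", {
  lib <- small_library()
  g <- build_grid(lib, orders = c(4, 6), deltas_a = c(-1, 1), deltas_b = c(0, 1))
  f <- tempfile(fileext = ".json")
  man <- write_grid_manifest(g, f)
  got <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(got$orders, c(4, 6))
  expect_equal(got$step_mode, "sd")
  expect_equal(got$library_hash, man$library_hash)
  unlink(f)
})
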