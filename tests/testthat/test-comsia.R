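test_that("grid construction covers the molecules with the requested margin", {
  # single atom at the origin, margin 2, spacing 2: a 3x3x3 lattice
  m <- point_molecule(rbind(c(0, 0, 0)))
  g <- build_grid(list(m), margin = 2, spacing = 2)
  expect_equal(g$counts, c(3L, 3L, 3L))
  expect_equal(unname(g$origin), c(-2, -2, -2))
  pts <- grid_points(g)
  expect_equal(nrow(pts), 27L)

  # translating the molecules translates the origin exactly
  m2 <- point_molecule(rbind(c(1.5, -2, 0.25)))
  g2 <- build_grid(list(m2), margin = 2, spacing = 2)
  expect_equal(unname(g2$origin - g$origin), c(1.5, -2, 0.25))

  # the 13-PAE set sits inside the box on every axis
  amols <- pae_aligned()
  ga <- build_grid(amols, margin = 2, spacing = 2)
  xyz <- do.call(rbind, lapply(amols, coords))
  hi <- ga$origin + (ga$counts - 1L) * ga$spacing
  expect_true(all(sweep(xyz, 2, ga$origin) >= 0))
  expect_true(all(sweep(xyz, 2, hi) <= ga$spacing))  # cover within one cell

  expect_error(build_grid(list()), "empty")
  expect_error(build_grid(list(m), spacing = 0), "positive")
})

test_that("atom weights implement the per-kind conventions", {
  m <- point_molecule(rbind(c(0, 0, 0)), radius = 1.7, charge = -0.3,
                      logp = 0.12, donor = 0, acceptor = 1)
  expect_equal(atom_weights(m, "S"), 1.7^3)
  expect_equal(atom_weights(m, "E"), -0.3)
  expect_equal(atom_weights(m, "H"), 0.12)
  expect_equal(atom_weights(m, "D"), 0)
  expect_equal(atom_weights(m, "A"), 1)

  bz <- assign_atom_parameters(load_structures(c(b = "c1ccccc1"))$b)
  expect_true(all(atom_weights(bz, "D") == 0))
  expect_lt(abs(sum(atom_weights(bz, "E"))), 1e-3)
})

test_that("similarity fields match brute-force summation to 1e-12", {
  m <- point_molecule(rbind(c(0.3, -0.2, 0.9), c(1.4, 0.8, -0.5)),
                      radius = c(1.7, 1.52), charge = c(0.2, -0.2),
                      logp = c(0.5, -0.3), acceptor = c(0, 1))
  g <- build_grid(list(m), margin = 2, spacing = 1)
  pts <- grid_points(g)
  alpha <- 0.3
  for (kind in c("S", "E", "H", "A")) {
    got <- similarity_field(m, g, kind, alpha = alpha)
    w <- atom_weights(m, kind)
    brute <- sapply(seq_len(nrow(pts)), function(j) {
      s <- 0
      for (i in seq_len(nrow(m$atoms))) {
        d2 <- sum((coords(m)[i, ] - pts[j, ])^2)
        s <- s - w[i] * exp(-alpha * d2)
      }
      s
    })
    expect_equal(got, brute, tolerance = 1e-12)
  }
})

test_that("field arithmetic honors the Gaussian form", {
  # atom exactly on a grid point: contribution is -probe * weight there
  m <- point_molecule(rbind(c(0, 0, 0)), radius = 1.7)
  g <- build_grid(list(m), margin = 2, spacing = 2)
  f <- similarity_field(m, g, "S", alpha = 0.55)
  centre <- which(rowSums(abs(grid_points(g))) == 0)
  expect_equal(f[centre], -1.7^3, tolerance = 1e-12)

  # a far grid point sees essentially nothing
  far <- point_molecule(rbind(c(20, 0, 0)))
  expect_lt(max(abs(similarity_field(far, g, "S", alpha = 0.3))), 1e-20)

  # doubling alpha strictly shrinks |A| away from the atom
  f2 <- similarity_field(m, g, "S", alpha = 1.1)
  off <- setdiff(seq_along(f), centre)
  expect_true(all(abs(f2[off]) < abs(f[off])))
  expect_error(similarity_field(m, g, "S", alpha = 0), "positive")
})

test_that("descriptor assembly block-scales to unit pooled variance", {
  amols <- pae_aligned()[1:6]
  g <- build_grid(amols, margin = 2, spacing = 3)
  blk <- assemble_descriptors(amols, g, kinds = c("S", "E", "H"))
  for (k in c("S", "E", "H")) {
    b <- blk$X[, blk$col_kind == k]
    pooled <- mean(apply(b, 2, var))
    expect_equal(pooled, 1, tolerance = 1e-9)
    expect_equal(unname(colMeans(b)), rep(0, ncol(b)), tolerance = 1e-12)
  }
  # identical molecules give identical rows
  two <- assemble_descriptors(amols[c(1, 1)], g, kinds = "S", scale = FALSE)
  expect_equal(two$X[1, ], two$X[2, ])
})

test_that("descriptors are invariant to a rigid co-transform of set and grid", {
  amols <- pae_aligned()[1:4]
  g <- build_grid(amols, margin = 2, spacing = 3)
  blk <- assemble_descriptors(amols, g, kinds = c("S", "H"))

  R0 <- rotation_about_z(1.1)
  t0 <- c(2, -3, 1)
  moved <- lapply(amols, function(m) {
    xyz <- coords(m) %*% R0 + rep(t0, each = nrow(m$atoms))
    m$atoms$x <- xyz[, 1]; m$atoms$y <- xyz[, 2]; m$atoms$z <- xyz[, 3]
    m
  })
  # co-transform the lattice: same points, expressed in the moved frame
  g2 <- g
  pts2 <- grid_points(g) %*% R0 + rep(t0, each = nrow(grid_points(g)))
  # evaluate by brute force against the transformed lattice point list
  raw <- function(mols, pts, kind) {
    t(sapply(mols, function(m) {
      w <- atom_weights(m, kind)
      xyz <- coords(m)
      d2 <- outer(rowSums(xyz^2), rowSums(pts^2), "+") - 2 * xyz %*% t(pts)
      -drop(crossprod(exp(-0.3 * pmax(d2, 0)), w))
    }))
  }
  expect_equal(raw(moved, pts2, "S"), raw(amols, grid_points(g), "S"),
               tolerance = 1e-9)
})

test_that("low-variance column filtering matches a brute-force recount", {
  blk <- pae_block()
  f0 <- filter_columns(blk, min_sigma = 0)
  expect_equal(ncol(f0$X), ncol(blk$X))  # identity at threshold 0

  thr <- 0.05
  fl <- filter_columns(blk, min_sigma = thr)
  expect_equal(ncol(fl$X), sum(apply(blk$X, 2, sd) >= thr))
  expect_true(all(apply(fl$X, 2, sd) >= thr))
  # a constant column is always dropped for positive thresholds
  blk2 <- blk
  blk2$X[, 5] <- 1
  expect_false(5 %in% filter_columns(blk2, 1e-9)$keep)
  expect_error(filter_columns(blk, min_sigma = 1e9), "every column")
})

test_that("prediction-time transforms reproduce training rows", {
  amols <- pae_aligned()
  blk <- pae_block()
  Xnew <- transform_descriptors(blk, amols[c("DAP", "DPP")])
  expect_equal(unname(Xnew["DAP", ]), unname(blk$X["DAP", ]),
               tolerance = 1e-12)
  expect_equal(unname(Xnew["DPP", ]), unname(blk$X["DPP", ]),
               tolerance = 1e-12)
  # filtering propagates to the prediction transform
  fl <- filter_columns(blk, 0.05)
  expect_equal(ncol(transform_descriptors(fl, amols[1:2])), ncol(fl$X))
})

test_that("field grids export in the volumetric text format", {
  m <- point_molecule(rbind(c(0, 0, 0)))
  g <- build_grid(list(m), margin = 2, spacing = 2)
  f <- similarity_field(m, g, "S")
  tmp <- withr::local_tempfile(fileext = ".grid")
  write_field_grid(f, g, tmp)
  txt <- readLines(tmp)
  expect_equal(sum(!startsWith(txt, "#")), length(f))
  expect_equal(as.numeric(txt[!startsWith(txt, "#")]), f, tolerance = 1e-9)
})
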