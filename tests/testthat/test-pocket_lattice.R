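test_that("build_grid applies both radius predicates", {
  # one receptor bead sitting exactly on a candidate lattice point
  ref <- rbind(c(0, 0, 0), c(0, 0, 7.6))
  rec <- receptor("L", matrix(c(0, 0, 3.8), 1), id = "block")
  g <- build_grid(rec, ref, include_radius = 7.6, exclude_radius = 1.5)
  expect_false(any(apply(g$sites, 1, function(p)
    all(abs(p - c(0, 0, 3.8)) < 1e-9))))

  expect_error(build_grid(rec, ref[0, , drop = FALSE]), "empty")
  # receptor bead on every candidate point -> empty grid
  rec_all <- receptor(rep("L", 0), matrix(numeric(), 0, 3))
  expect_error(build_grid(receptor("L", matrix(c(0, 0, 0), 1)),
                          matrix(c(0, 0, 0), 1),
                          include_radius = 0.5, exclude_radius = 2),
               "empty grid")
})

test_that("grid sites match a brute-force geometric filter on a fixture", {
  fx <- make_groove_receptor(c(3, 3, 4), seed = 5)
  inc <- 7.6; exc <- 1.5; sp <- 3.8
  g <- build_grid(fx$receptor, fx$reference, include_radius = inc,
                  exclude_radius = exc)
  # oracle: full double-loop over an integer box around the reference
  origin <- colMeans(fx$reference)
  rng <- 4
  oracle <- NULL
  for (ix in -rng:rng) for (iy in -rng:rng) for (iz in (-rng):(rng + 4)) {
    p <- origin + sp * c(ix, iy, iz)
    dref <- min(sqrt(colSums((t(fx$reference) - p)^2)))
    drec <- min(sqrt(colSums((t(fx$receptor$coords) - p)^2)))
    if (dref <= inc && drec > exc) oracle <- rbind(oracle, p)
  }
  key <- function(m) unname(sort(apply(round(m, 6), 1, paste,
                                       collapse = ",")))
  expect_identical(key(g$sites), key(oracle))
  # every edge joins sites exactly one spacing apart
  dd <- sqrt(rowSums((g$sites[g$edges[, 1], ] - g$sites[g$edges[, 2], ])^2))
  expect_true(all(abs(dd - sp) < 1e-9))
  # minimum pairwise distance is the spacing
  expect_gt(min(dist(g$sites)), sp - 1e-6)
})

test_that("site count is monotone in the radii", {
  fx <- make_groove_receptor(c(3, 3, 4), seed = 6)
  counts_inc <- vapply(c(4, 6, 7.6, 9), function(r)
    nrow(build_grid(fx$receptor, fx$reference, include_radius = r)$sites), 0)
  expect_true(all(diff(counts_inc) >= 0))
  counts_exc <- vapply(c(0.5, 1.5, 3, 4.5), function(r)
    nrow(build_grid(fx$receptor, fx$reference, exclude_radius = r)$sites), 0)
  expect_true(all(diff(counts_exc) <= 0))
})

test_that("pick_anchors selects nearest sites with deterministic ties", {
  g <- lattice_grid(c(3, 1, 1))
  # endpoint exactly on a site
  st <- pick_anchors(g, rbind(g$sites[2, ], g$sites[3, ]))
  expect_equal(st, c(2L, 3L))
  # equidistant between sites 1 and 2 -> lower index
  mid <- (g$sites[1, ] + g$sites[2, ]) / 2
  st <- pick_anchors(g, rbind(mid, g$sites[3, ]))
  expect_equal(st[1], 1L)
  expect_error(pick_anchors(g, rbind(g$sites[1, ], g$sites[1, ] + 0.1)),
               "same grid site")
  # random endpoints vs argmin oracle
  set.seed(9)
  gg <- lattice_grid(c(3, 2, 2))
  for (rep in 1:10) {
    p <- runif(3, -2, 10)
    qq <- runif(3, -2, 10)
    d1 <- sqrt(colSums((t(gg$sites) - p)^2))
    d2 <- sqrt(colSums((t(gg$sites) - qq)^2))
    if (which.min(d1) == which.min(d2)) next  # would (rightly) error
    st <- pick_anchors(gg, rbind(p, qq))
    expect_equal(st[1], which.min(d1))
    expect_equal(st[2], which.min(d2))
  }
})

test_that("external field sums pair potentials over receptor beads", {
  m <- mj_model()
  g <- lattice_grid(c(2, 1, 2))
  # empty receptor
  f0 <- external_field(g, receptor(character(), matrix(numeric(), 0, 3)), m)
  expect_true(all(f0$E == 0))
  expect_equal(f0$Nc, 0)
  expect_true(all(f0$E0 == 0))
  # bead beyond the cutoff from every site
  far <- receptor("W", matrix(c(100, 0, 0), 1))
  expect_true(all(external_field(g, far, m)$E == 0))
  # single bead: field at each site equals the direct pair potential
  bead <- receptor("F", matrix(c(1.1, 2.2, 3.3), 1))
  fld <- external_field(g, bead, m)
  for (i in seq_len(nrow(g$sites))) {
    r <- sqrt(sum((g$sites[i, ] - c(1.1, 2.2, 3.3))^2))
    for (k in m$codes)
      expect_equal(unname(fld$E[i, k]), unname(pair_potential(k, "F", r, m)))
  }
  # Nc: mean number of beads within the cutoff
  expect_equal(fld$Nc, mean(apply(g$sites, 1, function(p)
    sqrt(sum((p - c(1.1, 2.2, 3.3))^2)) < 8.5)))
  expect_equal(unname(fld$E0), unname(mean_field_offset(NULL, fld$Nc, m)))
})

test_that("clustered models map receptor types through the family map", {
  full <- mj_model()
  cm <- cluster_model(full, 2, restarts = 10, seed = 1)
  bead <- receptor("L", matrix(c(0, 0, 7.0), 1))  # hydrophobic residue
  g <- lattice_grid(c(1, 1, 1))
  fld <- external_field(g, bead, cm)
  famL <- paste0("F", cm$map[["L"]])
  expect_equal(unname(fld$E[1, "F1"]),
               unname(pair_potential("F1", famL, 7.0, cm)))
  stray <- receptor("Z", matrix(c(0, 0, 7), 1))
  expect_error(external_field(g, stray, cm), "cluster map")
})

test_that("anchored grids verify s-t connectivity and serialize", {
  fx <- make_groove_receptor(c(1, 1, 3), seed = 2)
  g <- build_grid(fx$receptor, fx$reference, fx$endpoints)
  expect_false(is.na(g$s_index))
  expect_true(g$s_index != g$t_index)
  path <- tempfile(fileext = ".json")
  write_grid_json(g, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(nrow(back$sites), nrow(g$sites))
  expect_equal(back$s_index, g$s_index)
})
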