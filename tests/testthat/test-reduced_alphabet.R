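test_that("singleton clusters reproduce the matrix exactly", {
  e <- contact_energy_table()$e
  map <- fit_cluster_map(e, D = 20)
  expect_equal(map$loss, 0)
  expect_equal(sort(unname(map$assignment)), 1:20)
  # e' reproduces e through the (canonically relabelled) assignment
  a <- map$assignment[rownames(e)]
  ep <- clustered_energy(e, map)
  expect_equal(unname(ep[a, a]), unname(e))
  alpha <- residue_alphabet()
  sp <- clustered_sigma(alpha, map)
  expect_equal(unname(sp[a]), alpha$sigma)
  fp <- clustered_freq(alpha, map)
  expect_equal(unname(fp[a]), alpha$surface_freq)
})

test_that("exact block structure is recovered with zero loss", {
  codes <- c("a", "b", "c", "d")
  e <- matrix(c(1, 1, 5, 5,
                1, 1, 5, 5,
                5, 5, 9, 9,
                5, 5, 9, 9), 4, 4, dimnames = list(codes, codes))
  map <- fit_cluster_map(e, D = 2)
  expect_equal(map$loss, 0)
  expect_equal(unname(map$assignment), c(1, 1, 2, 2))
  expect_equal(unname(clustered_energy(e, map)),
               matrix(c(1, 5, 5, 9), 2, 2))
})

test_that("heuristic search matches brute force on a random 6x6 matrix", {
  set.seed(42)
  n <- 6
  e <- matrix(rnorm(n * n), n, n); e <- (e + t(e)) / 2
  dimnames(e) <- list(letters[1:n], letters[1:n])
  # oracle: every 2-labeling of 6 items
  best <- Inf
  for (bits in 0:(2^n - 1)) {
    a <- as.integer(intToBits(bits))[1:n] + 1L
    if (length(unique(a)) < 2) next
    best <- min(best, cluster_loss(e, a))
  }
  fit_ex <- fit_cluster_map(e, D = 2, method = "exhaustive")
  fit_an <- fit_cluster_map(e, D = 2, method = "anneal", restarts = 20,
                            seed = 5)
  expect_equal(fit_ex$loss, best, tolerance = 1e-12)
  expect_equal(fit_an$loss, best, tolerance = 1e-12)
})

test_that("clustered energies equal independent group-by means", {
  e <- contact_energy_table()$e
  map <- fit_cluster_map(e, D = 5, restarts = 15, seed = 3)
  ep <- clustered_energy(e, map)
  a <- map$assignment[rownames(e)]
  for (I in 1:5) for (J in 1:5)
    expect_equal(ep[I, J], mean(e[a == I, a == J]))  # tapply-style oracle
  expect_equal(ep, t(ep))
})

test_that("family diameters average and frequencies aggregate to one", {
  alpha <- residue_alphabet()
  # two-residue family: mean of the diameters
  a <- setNames(c(1L, 1L, rep(2L, 18)), alpha$code)
  map <- structure(list(assignment = a, D = 2), class = "cluster_map")
  expect_equal(unname(clustered_sigma(alpha, map)[1]),
               mean(alpha$sigma[1:2]))
  expect_equal(unname(clustered_freq(alpha, map)[1]),
               sum(alpha$surface_freq[1:2]))
  set.seed(11)
  for (rep in 1:5) {
    D <- sample(2:6, 1)
    a <- setNames(c(sample(seq_len(D)), sample(seq_len(D), 20 - D,
                                               replace = TRUE)), alpha$code)
    map <- structure(list(assignment = a, D = D), class = "cluster_map")
    expect_equal(sum(clustered_freq(alpha, map)), 1, tolerance = 1e-9)
  }
})

test_that("loss is non-increasing in D on the packaged table", {
  e <- contact_energy_table()$e
  losses <- vapply(2:6, function(D)
    fit_cluster_map(e, D = D, restarts = 15, seed = 1)$loss, 0)
  expect_true(all(diff(losses) <= 1e-9))
})

test_that("D = 2 separates hydrophobic from polar on the packaged table", {
  # tryptophan, tyrosine, histidine and proline may fall either side
  ambiguous <- c("W", "Y", "H", "P")
  hydrophobic <- c("C", "M", "F", "I", "L", "V")
  polar <- c("A", "G", "T", "S", "N", "Q", "D", "E", "R", "K")
  map <- fit_cluster_map(contact_energy_table()$e, D = 2, restarts = 25,
                         seed = 1)
  a <- map$assignment
  expect_equal(length(unique(a[hydrophobic])), 1)
  expect_equal(length(unique(a[polar])), 1)
  expect_false(unique(a[hydrophobic]) == unique(a[polar]))
  # canonical labels: family 1 has the lower self-energy (hydrophobic)
  expect_equal(unname(unique(a[hydrophobic])), 1L)
})

test_that("cluster model carries effective parameters and maps receptors", {
  full <- mj_model()
  cm <- cluster_model(full, 2, restarts = 15, seed = 1)
  expect_s3_class(cm, "pair_model")
  expect_equal(length(cm$codes), 2)
  expect_equal(sum(cm$freq), 1, tolerance = 1e-9)
  expect_false(is.null(cm$map))
  expect_equal(cm$epsilon, t(cm$epsilon))
  # effective epsilon equals rescaled clustered raw energies
  tab <- attr(full, "contact_table")
  mapobj <- attr(cm, "cluster_map")
  expect_equal(unname(cm$epsilon),
               unname(0.159 * (clustered_energy(tab$e, mapobj) + 2.27)))
})

test_that("cluster maps round-trip through the two-column text format", {
  map <- fit_cluster_map(contact_energy_table()$e, D = 3, restarts = 10,
                         seed = 2)
  path <- tempfile(fileext = ".txt")
  write_cluster_map(map, path)
  back <- read_cluster_map(path)
  expect_equal(back$assignment[names(map$assignment)], map$assignment)
  expect_equal(back$D, 3)
})

test_that("degenerate requests error out", {
  e <- contact_energy_table()$e
  expect_error(fit_cluster_map(e, D = 1), "D must lie")
  expect_error(fit_cluster_map(e, D = 21), "D must lie")
})
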