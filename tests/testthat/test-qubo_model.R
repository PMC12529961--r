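# Term-by-term checks of the design Hamiltonian, each against hand
# expansions or exhaustive truth tables, plus the Ising conversion.

bits_with <- function(registry, on) {
  b <- integer(registry$n_vars)
  b[on] <- 1L
  b
}

test_that("external term places E - E0 (or E, ablated) on site variables", {
  g <- anchored_grid(c(1, 1, 2))
  m <- toy_model_1()
  reg <- variable_registry(g, 1)
  fld <- structure(list(E = matrix(c(-2, 0), 2, 1,
                                   dimnames = list(NULL, "F1")),
                        E0 = c(F1 = -0.5), Nc = 1, types = "F1"),
                   class = "external_field")
  tm <- external_term(fld, reg)
  expect_equal(tm$linear[reg$site_idx[1, 1]], -1.5)
  tm2 <- external_term(fld, reg, ablate_E0 = TRUE)
  expect_equal(tm2$linear[reg$site_idx[1, 1]], -2)
  # zero field, zero offset -> empty term
  fld0 <- structure(list(E = matrix(0, 2, 1, dimnames = list(NULL, "F1")),
                         E0 = c(F1 = 0), Nc = 0, types = "F1"),
                    class = "external_field")
  expect_true(all(external_term(fld0, reg)$linear == 0))
})

test_that("intrachain term couples pairs within cutoff, cancels bonded", {
  m <- toy_model_1(eps = -1)
  # two sites beyond the cutoff: no terms
  gfar <- lattice_grid(c(1, 1, 2), spacing = 9)
  regf <- variable_registry(gfar, 1)
  expect_length(intrachain_term(gfar, m, regf)$qv, 0)

  # non-neighbour pair at distance 7.6: single quadratic coefficient u(r)
  g3 <- anchored_grid(c(1, 1, 3))
  reg3 <- variable_registry(g3, 1)
  tm <- intrachain_term(g3, m, reg3)
  q <- as_qubo(tm)
  u76 <- unname(pair_potential("F1", "F1", 7.6, m))
  b <- bits_with(reg3, c(reg3$site_idx[1, 1], reg3$site_idx[3, 1]))
  expect_equal(qubo_energy(q, b), u76)

  # neighbour pair, valid bonded assignment -> exact cancellation
  b2 <- bits_with(reg3, c(reg3$site_idx[1, 1], reg3$site_idx[2, 1],
                          reg3$bond_idx[1], reg3$anc_idx[1, 1]))
  u38 <- unname(pair_potential("F1", "F1", 3.8, m))
  expect_equal(qubo_energy(q, b2), 0)  # u38 cancelled by the ancilla branch
  # same assignment without the ancilla bit: full nonbonded repulsion
  b3 <- bits_with(reg3, c(reg3$site_idx[1, 1], reg3$site_idx[2, 1],
                          reg3$bond_idx[1]))
  expect_equal(qubo_energy(q, b3), u38)
})

test_that("ancilla penalty is the exact AND truth table", {
  g <- anchored_grid(c(1, 1, 2))
  reg <- variable_registry(g, 1)
  A <- 7
  q <- as_qubo(ancilla_term(reg, A))
  si <- reg$site_idx[1, 1]; bv <- reg$bond_idx[1]; av <- reg$anc_idx[1, 1]
  for (s in 0:1) for (b in 0:1) for (a in 0:1) {
    bits <- integer(reg$n_vars)
    bits[si] <- s; bits[bv] <- b; bits[av] <- a
    expected <- if (a == (s & b)) 0 else A * (3 * a + s * b - 2 * s * a -
                                              2 * b * a)
    expect_equal(qubo_energy(q, bits),
                 A * (3 * a + s * b - 2 * s * a - 2 * b * a))
    expect_equal(qubo_energy(q, bits) == 0, a == (s && b))
    expect_gte(qubo_energy(q, bits), 0)
  }
})

test_that("occupancy penalty counts violating family pairs", {
  g <- anchored_grid(c(1, 1, 1))
  reg <- variable_registry(g, 4)
  A <- 3
  q <- as_qubo(occupancy_term(reg, A))
  expect_equal(qubo_energy(q, bits_with(reg, reg$site_idx[1, 2])), 0)
  expect_equal(qubo_energy(q, bits_with(reg, reg$site_idx[1, c(1, 3)])), A)
  expect_equal(qubo_energy(q, bits_with(reg, reg$site_idx[1, 1:3])), 3 * A)
})

test_that("path term reproduces hand expansions and the valid-path set", {
  g <- anchored_grid(c(1, 1, 3))
  reg <- variable_registry(g, 1)
  A <- 5
  q <- as_qubo(path_term(reg, 1, 3, A))
  # empty configuration: h_s = h_t = 1
  expect_equal(qubo_energy(q, integer(reg$n_vars)), 2 * A)
  # full path: all sites occupied, both bonds on
  full_path <- bits_with(reg, c(reg$site_idx[, 1], reg$bond_idx))
  expect_equal(qubo_energy(q, full_path), 0)
  # exhaustive: zero-penalty set of path+occupancy+ancilla on this grid is
  # exactly the encodings of valid s-t chains
  qa <- as_qubo(pepqubo:::merge_terms(path_term(reg, 1, 3, A),
                                      ancilla_term(reg, A)))
  bits <- all_bits(reg$n_vars)
  zero <- which(abs(qubo_energy(qa, bits)) < 1e-12)
  expect_equal(length(zero), 1L)  # only one s-t chain on a 1x1x3 line
  d <- decode(bits[zero, ], reg, g)
  expect_true(d$flags$valid_path)
  expect_equal(d$path, c(1L, 2L, 3L))
})

test_that("chain-length term and tolerance semantics", {
  g <- anchored_grid(c(2, 2, 2))
  reg <- variable_registry(g, 1)
  w <- 2.5; L0 <- 3
  q <- as_qubo(chain_length_term(reg, L0, w))
  on3 <- bits_with(reg, reg$bond_idx[1:3])
  expect_equal(qubo_energy(q, on3), 0)
  expect_equal(qubo_energy(q, bits_with(reg, reg$bond_idx[1:4])), w)
  expect_equal(qubo_energy(q, bits_with(reg, reg$bond_idx[1:2])), w)
  # w = A/(L0^2 p^2): L0*p extra bonds cost exactly A
  A <- 8; L0 <- 4; p <- 0.5
  w <- chain_w_for_p(L0, p, A)
  q2 <- as_qubo(chain_length_term(reg, L0, w))
  expect_equal(qubo_energy(q2, bits_with(reg, reg$bond_idx[1:6])), A)
  expect_equal(chain_p_for_w(L0, w, A), p)
})

test_that("QUBO to Ising conversion is exact on every bitstring", {
  # single-variable H = q: h = 1/2, offset = 1/2
  q1 <- make_random_qubo(1, seed = 1)
  q1$linear <- 1; q1$offset <- 0; q1$quad <- q1$quad[0, ]
  is1 <- to_ising(q1)
  expect_equal(is1$h, 0.5)
  expect_equal(is1$offset, 0.5)
  # H = q1 q2: J = 1/4, h = 1/4 each, offset = 1/4
  q2 <- make_random_qubo(2, seed = 1)
  q2$linear <- c(0, 0); q2$offset <- 0
  q2$quad <- data.frame(i = 1L, j = 2L, v = 1)
  is2 <- to_ising(q2)
  expect_equal(is2$h, c(0.25, 0.25))
  expect_equal(is2$J$v, 0.25)
  expect_equal(is2$offset, 0.25)
  # random 10-variable model: all 1024 bitstrings agree
  q10 <- make_random_qubo(10, seed = 33)
  is10 <- to_ising(q10)
  bits <- all_bits(10)
  expect_equal(ising_energy(is10, 2 * bits - 1), qubo_energy(q10, bits),
               tolerance = 1e-12)
})

test_that("variable_count matches hand counts and scales linearly in D", {
  vc <- variable_count(1, 1, 2, 1)
  expect_equal(vc$exact, 4)      # 2 sites + 1 bond + 1 ancilla
  expect_equal(vc$estimate, 14)  # 2 * (4 + 3)
  vc2 <- variable_count(3, 3, 10, 5)
  expect_equal(vc2$exact, 1656)  # 450 + 201 + 1005 (201 = 60 + 60 + 81)
  expect_equal(vc2$estimate, 2070)
  est <- vapply(1:6, function(D) variable_count(2, 3, 4, D)$estimate, 0)
  expect_true(all(abs(diff(diff(est))) < 1e-9))
  # the registry realizes the exact count on a full box
  g <- lattice_grid(c(3, 2, 2))
  expect_equal(variable_registry(g, 4)$n_vars, variable_count(3, 2, 2, 4)$exact)
})

test_that("assembly requires anchors and serializes round-trip", {
  g <- lattice_grid(c(1, 1, 3))
  m <- toy_model_1()
  fld <- toy_field(g, m, seed = 1)
  expect_error(assemble(g, fld, m, L0 = 2), "anchors")
  g$s_index <- 1L; g$t_index <- 3L
  q <- assemble(g, fld, m, L0 = 2, A = 10)
  path <- tempfile(fileext = ".json")
  write_qubo_json(q, path)
  back <- read_qubo_json(path)
  expect_equal(length(back$variables), q$registry$n_vars)
  expect_equal(back$offset, q$offset)
  expect_equal(back$params$A, 10)
})
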