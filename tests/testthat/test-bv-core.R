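test_that("bond_valence matches published cells and algebraic identities", {
  # printed valence cell: HS Fe(II)-N at 2.03 A
  expect_equal(round(bond_valence(2.03, 1.76, 0.37), 2), 0.48)
  # d = r0 gives valence 1; d = r0 + b ln 2 gives 1/2
  expect_equal(bond_valence(1.76, 1.76, 0.37), 1.0)
  expect_equal(bond_valence(1.76 + 0.37 * log(2), 1.76, 0.37), 0.5)
  expect_equal(bond_valence(2.1 + 0.2 * log(2), 2.1, 0.2), 0.5)
  # argument validation
  expect_error(bond_valence(-1, 1.76, 0.37), "distance")
  expect_error(bond_valence(2.0, 1.76, 0), "b must be")
})

test_that("bond_valence is monotone decreasing in d, increasing in r0", {
  d <- seq(1.5, 4, by = 0.05)
  v <- bond_valence(d, 1.76, 0.37)
  expect_true(all(diff(v) < 0))
  r0 <- seq(1.2, 2.4, by = 0.05)
  expect_true(all(diff(bond_valence(2.0, r0, 0.37)) > 0))
})

test_that("bvs reproduces all printed worked-example cells to 2 dp", {
  # deoxyhemoglobin site: five N + one O scored with a single R0
  d_a <- c(2.03, 2.06, 2.15, 2.15, 2.16, 3.39)
  cells_a <- rbind(  # per-bond valences as printed, by R0
    `1.57` = c(0.29, 0.27, 0.21, 0.21, 0.20, 0.01),
    `1.76` = c(0.48, 0.44, 0.35, 0.35, 0.34, 0.01),
    `1.86` = c(0.63, 0.58, 0.46, 0.46, 0.44, 0.02)
  )
  for (r0 in rownames(cells_a)) {
    expect_equal(round(bond_valence(d_a, as.numeric(r0), 0.37), 2),
                 unname(cells_a[r0, ]))
  }
  # full-precision sums, rounded at the end
  expect_equal(round(bvs(deoxy_hb(), single_r0_params(1.76)), 2), 1.98)
  expect_equal(round(bvs(deoxy_hb(), single_r0_params(1.86)), 2), 2.59)
  # oxyhemoglobin site: six N under four parameterisations
  d_b <- c(1.75, 1.99, 2.00, 2.01, 2.01, 2.26)
  cells_b <- rbind(
    `1.7` = c(0.87, 0.46, 0.44, 0.43, 0.43, 0.22),
    `1.83` = c(1.24, 0.65, 0.63, 0.61, 0.61, 0.31),
    `1.86` = c(1.35, 0.70, 0.68, 0.67, 0.67, 0.34),
    `1.815` = c(1.19, 0.62, 0.61, 0.59, 0.59, 0.30)
  )
  sums_b <- c(`1.7` = 2.86, `1.83` = 4.06, `1.86` = 4.41, `1.815` = 3.90)
  for (r0 in rownames(cells_b)) {
    expect_equal(round(bond_valence(d_b, as.numeric(r0), 0.37), 2),
                 unname(cells_b[r0, ]))
    p <- single_r0_params(as.numeric(r0), oxidation = 3, ligands = "N")
    expect_equal(round(bvs(oxy_hb(), p), 2), unname(sums_b[r0]))
  }
})

test_that("bvs is additive, zero on empty sites, strict on missing keys", {
  s <- fe_site(c(2.0, 2.1, 2.2))
  p <- make_params("Fe2-N" = 1.76)
  expect_equal(bvs(s, p), sum(bond_valence(c(2.0, 2.1, 2.2), 1.76, 0.37)))
  empty <- binding_site("Fe", character(0), numeric(0), oxidation = 2)
  expect_equal(bvs(empty, p), 0.0)
  het <- binding_site("Fe", c("N", "O"), c(2.0, 2.1), oxidation = 2)
  expect_error(bvs(het, p), "missing-parameter.*Fe2-O")
})

test_that("spin-resolved key lookup has no silent fallback", {
  s <- fe_site(c(2.0, 2.0), spin = "LS")
  # split declared (HS key present) but LS key missing -> error, not plain
  p <- make_params("Fe2-N" = 1.86, "Fe2:HS-N" = 1.76)
  expect_error(bvs(s, p), "Fe2:LS-N")
  # no split declared for this pair -> plain key applies
  p2 <- make_params("Fe2-N" = 1.86)
  expect_equal(bvs(s, p2), 2 * bond_valence(2.0, 1.86, 0.37))
})

test_that("homoleptic_r0 closed form round-trips and matches bisection", {
  # n equal distances with S = n forces R0 = d
  s <- fe_site(rep(2.11, 4), oxidation = 4)
  expect_equal(homoleptic_r0(s), 2.11, tolerance = 1e-12)
  s1 <- fe_site(1.9, oxidation = 1)
  expect_equal(homoleptic_r0(s1), 1.9, tolerance = 1e-12)
  # the published six-distance site, S = 2: cross-check against a
  # bisection oracle on bvs(R0) - S, and the round-trip property
  hb <- binding_site("Fe", rep("N", 6), c(2.03, 2.06, 2.15, 2.15, 2.16, 3.39),
                     oxidation = 2)
  r0 <- homoleptic_r0(hb)
  expect_equal(r0, bisect_r0(hb, bv_params()), tolerance = 1e-10)
  p <- make_params("Fe2-N" = r0)
  expect_equal(bvs(hb, p), 2, tolerance = 1e-12)
  # property: random homoleptic sites round-trip to machine precision
  set.seed(42)
  for (i in 1:20) {
    n <- sample(2:6, 1)
    s <- fe_site(runif(n, 1.8, 2.6), oxidation = sample(1:4, 1))
    key <- bond_type_key("Fe", s$oxidation, "N")
    p_i <- set_param(bv_params(), key, homoleptic_r0(s))
    expect_equal(bvs(s, p_i), s$oxidation, tolerance = 1e-12)
  }
  # errors: heteroleptic and unassigned
  expect_error(homoleptic_r0(binding_site("Fe", c("N", "O"), c(2, 2.1),
                                          oxidation = 2)), "homoleptic")
  expect_error(homoleptic_r0(fe_site(2.0, oxidation = NA)), "unassigned")
})

test_that("delta_r0 shifts restore the sum rule exactly", {
  # V = S gives zero shift
  s <- fe_site(rep(typical_distance(1.76, 2, 6), 6))
  p <- make_params("Fe2-N" = 1.76)
  expect_equal(delta_r0(s, p, "Fe2-N"), 0, tolerance = 1e-12)
  # homoleptic misassignment threshold: S = 4, V = 3 -> b ln(4/3)
  s4 <- fe_site(rep(typical_distance(1.76, 3, 6), 6), oxidation = 4)
  p4 <- make_params("Fe4-N" = 1.76)
  expect_equal(delta_r0(s4, p4, "Fe4-N"), 0.37 * log(4 / 3), tolerance = 1e-12)
  expect_equal(round(delta_r0(s4, p4, "Fe4-N"), 3), 0.106)
  # heteroleptic: re-summation oracle - apply the shift, recompute bvs
  het <- binding_site("Fe", c("N", "N", "O"), c(2.05, 2.12, 2.30),
                      oxidation = 2)
  ph <- make_params("Fe2-N" = 1.76, "Fe2-O" = 1.70)
  for (key in c("Fe2-N", "Fe2-O")) {
    dr <- delta_r0(het, ph, key)
    shifted <- set_param(ph, key, get_r0(ph, key) + dr)
    expect_equal(bvs(het, shifted), 2, tolerance = 1e-12)
  }
  # infeasible: other types alone already exceed S
  far <- binding_site("Fe", c("N", "O"), c(1.2, 2.0), oxidation = 1)
  p1 <- make_params("Fe1-N" = 1.76, "Fe1-O" = 1.70)
  expect_error(delta_r0(far, p1, "Fe1-O"), "no-feasible-shift")
  expect_error(delta_r0(fe_site(2.0), ph, "Fe2-Cl"), "no contact")
})

test_that("typical_distance matches printed cells and inverts bond_valence", {
  expect_equal(round(typical_distance(1.57, 2, 6), 2), 1.98)  # LS Fe(II)-N
  expect_equal(round(typical_distance(1.75, 1, 6), 2), 2.41)  # Na-O
  expect_equal(typical_distance(2.0, 4, 4), 2.0)              # S = n
  # inverse property: n equal bonds at the typical distance sum to S
  set.seed(7)
  for (i in 1:15) {
    r0 <- runif(1, 1.5, 2.5); S <- sample(1:4, 1); n <- sample(2:8, 1)
    d <- typical_distance(r0, S, n)
    expect_equal(n * bond_valence(d, r0, 0.37), S, tolerance = 1e-12)
  }
  expect_error(typical_distance(1.7, 2, 0), "coordination_number")
})

test_that("cutoff_distance matches the divalent offset and inverts exactly", {
  # S = 2, 5%: cutoff = r0 + 0.852 (the 'R0 + 0.85 A' rule of thumb)
  expect_equal(cutoff_distance(1.8, 2), 1.8 - 0.37 * (log(0.05) + log(2)))
  expect_equal(round(cutoff_distance(1.8, 2) - 1.8, 3), 0.852)
  expect_equal(round(cutoff_distance(1.8, 1) - 1.8, 3), 1.108)
  # a contact exactly at the cutoff has valence fraction * S
  for (f in c(0.01, 0.05, 0.2)) {
    for (S in 1:3) {
      d <- cutoff_distance(1.9, S, 0.37, f)
      expect_equal(bond_valence(d, 1.9, 0.37), f * S, tolerance = 1e-12)
    }
  }
  expect_error(cutoff_distance(1.8, 2, fraction = 1.2), "fraction")
})

test_that("parameter containers validate their invariants", {
  p <- bv_params()
  expect_equal(p$b, 0.37)
  expect_error(bv_params(b = -1), "positive")
  expect_error(set_param(p, "Fe2-N", 0.8), "sanity window")
  expect_error(set_param(p, "Fe2-N", 3.6), "sanity window")
  expect_error(set_param(p, "bogus", 1.8), "malformed")
  expect_error(get_r0(make_params("Fe2-N" = 1.76), "Fe3-N"),
               "missing-parameter")
  expect_error(binding_site("Fe", "N", -2), "positive")
  expect_error(binding_site("Fe", "Xx", 2), "element")
  # key round trip
  k <- bond_type_key("Fe", 3, "N", "HS")
  info <- parse_bond_type(k)
  expect_equal(info$metal, "Fe")
  expect_equal(info$oxidation, 3L)
  expect_equal(info$spin, "HS")
  expect_equal(info$ligand, "N")
})
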