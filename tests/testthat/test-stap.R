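test_that("site weights follow q = gamma * rel_affinity", {
  expect_equal(site_weight(1, gamma = 1), 1)        # consensus at gamma 1
  expect_equal(site_weight(exp(-log(2)), 1), 0.5)   # llr_max - ln 2
  expect_equal(site_weight(0.7, 0), 0)              # zero concentration
  s <- site_df(0, 8, rel_affinity = 0.25)
  expect_equal(site_weight(s, 4), 1)
  # isolated consensus site, gamma = 1: fractional occupancy 1/2
  m <- binding_model(NULL, gamma = 1)
  expect_equal(occupancy(site_df(0, 8, 1), m), 0.5)
})

test_that("configuration enumeration respects overlap exclusion", {
  m <- binding_model(NULL, gamma = 1)
  # two non-overlapping sites: 4 configurations
  cfg <- enumerate_configurations(site_df(c(0, 20), c(10, 30), c(0.9, 0.5)), m)
  expect_equal(nrow(cfg), 4)
  expect_equal(sort(cfg$n_primary), c(0, 1, 1, 2))
  expect_equal(cfg$weight[lengths(cfg$bound) == 0], 1)
  # two overlapping sites: both-bound excluded, 3 configurations
  cfg2 <- enumerate_configurations(site_df(c(0, 5), c(10, 15), c(0.9, 0.5)), m)
  expect_equal(nrow(cfg2), 3)
  # no sites: single empty configuration of weight 1
  cfg0 <- enumerate_configurations(site_df(numeric(0), numeric(0)), m)
  expect_equal(nrow(cfg0), 1)
  expect_equal(cfg0$weight, 1)
  expect_equal(occupancy(site_df(numeric(0), numeric(0)), m), 0)
  expect_error(enumerate_configurations(
    site_df(seq(0, 600, by = 20), seq(10, 610, by = 20)), m), "DP")
})

test_that("worked two-site occupancies and the interaction closed form", {
  m <- binding_model(NULL, gamma = 1)
  expect_equal(round(occupancy_brute_force(
    site_df(c(0, 20), c(10, 30), c(0.9, 0.5)), m), 3), 0.807)
  expect_equal(round(occupancy_brute_force(
    site_df(c(0, 20), c(10, 30), c(1.8, 1.0)), m), 3), 1.143)
  # one primary + one in-range secondary with interaction omega:
  # OCC = (q + w q r) / (1 + q + r + w q r); q = r = 1, w = 4 -> 5/7
  mc <- binding_model(NULL, gamma = c(1, 1), omega = 4, d_T = 150,
                      mode = "cooperative")
  sites <- site_df(c(0, 20), c(10, 30), c(1, 1), motif = c(1, 2))
  expect_equal(occupancy_brute_force(sites, mc), 5 / 7, tolerance = 1e-12)
  expect_equal(occupancy(sites, mc), 5 / 7, tolerance = 1e-12)
})

test_that("DP equals independent enumeration on random instances, all modes", {
  set.seed(101)
  for (i in 1:100) {
    n <- sample(2:12, 1)
    inst <- random_site_instance(n)
    mode <- sample(c("single", "cooperative", "antagonistic", "competition"), 1)
    omega <- switch(mode, cooperative = runif(1, 1, 20),
                    antagonistic = runif(1, 0.01, 1), 1)
    dT <- sample(c(10, 30, 150), 1)
    g <- 10^runif(2, 0, 3)
    model <- binding_model(NULL, gamma = g, omega = omega, d_T = dT,
                           mode = mode)
    q <- ifelse(inst$motif == 1, g[1], g[2]) * inst$rel_affinity
    expected <- oracle_occ(inst$start, inst$end, inst$motif, q, omega, dT)
    expect_equal(occupancy(inst, model), expected, tolerance = 1e-9)
    expect_equal(occupancy_brute_force(inst, model), expected,
                 tolerance = 1e-9)
  }
})

test_that("occupancy is monotone in gamma and saturates", {
  set.seed(7)
  inst <- random_site_instance(6, two_motifs = FALSE)
  occs <- vapply(10^seq(-1, 4, by = 0.5), function(g) {
    occupancy(inst, binding_model(NULL, gamma = g))
  }, numeric(1))
  expect_true(all(diff(occs) > 0))
  # doubling gamma less than doubles OCC on the two-site example
  s <- site_df(c(0, 20), c(10, 30), c(0.9, 0.5))
  o1 <- occupancy(s, binding_model(NULL, gamma = 1))
  o2 <- occupancy(s, binding_model(NULL, gamma = 2))
  expect_lt(o2, 2 * o1)
  # bounded by the number of candidate primary sites
  expect_lte(max(occs), 6)
})

test_that("interaction term raises or lowers primary occupancy as designed", {
  sites <- site_df(c(0, 20), c(10, 30), c(0.8, 0.6), motif = c(1, 2))
  base <- occupancy(sites, binding_model(NULL, gamma = c(1, 1), omega = 1,
                                         mode = "competition"))
  for (w in c(2, 5, 20)) {
    up <- occupancy(sites, binding_model(NULL, gamma = c(1, 1), omega = w,
                                         d_T = 150, mode = "cooperative"))
    expect_gt(up, base)
  }
  for (w in c(0.5, 0.1, 0.02)) {
    dn <- occupancy(sites, binding_model(NULL, gamma = c(1, 1), omega = w,
                                         d_T = 150, mode = "antagonistic"))
    expect_lt(dn, base)
  }
  # omega = 1 equals the no-interaction value regardless of d_T
  for (dT in c(0, 30, 150)) {
    expect_equal(occupancy(sites, binding_model(NULL, gamma = c(1, 1),
                                                omega = 1, d_T = dT,
                                                mode = "competition")),
                 base, tolerance = 1e-12)
  }
  # out-of-range pair: cooperative omega has no effect
  far <- site_df(c(0, 200), c(10, 210), c(0.8, 0.6), motif = c(1, 2))
  expect_equal(
    occupancy(far, binding_model(NULL, gamma = c(1, 1), omega = 10,
                                 d_T = 150, mode = "cooperative")),
    occupancy(far, binding_model(NULL, gamma = c(1, 1), omega = 1,
                                 mode = "competition")),
    tolerance = 1e-12)
})

test_that("an overlapping competitor strictly lowers primary occupancy", {
  solo <- site_df(10, 20, 0.9)
  m1 <- binding_model(NULL, gamma = c(1, 5), mode = "competition")
  with_comp <- site_df(c(10, 15), c(20, 25), c(0.9, 0.8), motif = c(1, 2))
  expect_lt(occupancy(with_comp, m1), occupancy(solo, m1))
})

test_that("window prediction composes scanning and occupancy", {
  m <- fix_primary()
  bg <- strrep("A", 120)  # no sites of the GC-rich test motif
  model <- binding_model(m, gamma = 1e4)
  expect_equal(predict_window(bg, model), 0)
  # one consensus site at saturating gamma: occupancy ~ 1
  seq1 <- paste0(strrep("A", 50), consensus_seq(m), strrep("A", 50))
  expect_gte(predict_window(seq1, model), 0.999)
  expect_lte(predict_window(seq1, model), 1 + 1e-9)
  # planted cooperative pair scores higher with omega = 5 than omega = 1
  m2 <- fix_secondary()
  pair_seq <- paste0(strrep("A", 30), consensus_seq(m), strrep("A", 20),
                     consensus_seq(m2), strrep("A", 30))
  co5 <- binding_model(list(m, m2), gamma = c(1, 1), omega = 5, d_T = 150,
                       mode = "cooperative")
  co1 <- binding_model(list(m, m2), gamma = c(1, 1), omega = 1,
                       mode = "competition")
  expect_gt(predict_window(pair_seq, co5), predict_window(pair_seq, co1))
})

test_that("binding_model validates its constraints", {
  expect_error(binding_model(NULL, gamma = 1, omega = 2, mode = "single"),
               "omega")
  expect_error(binding_model(NULL, gamma = 1, omega = 0.5,
                             mode = "cooperative"), "cooperative")
  expect_error(binding_model(NULL, gamma = 1, omega = 2,
                             mode = "antagonistic"), "antagonistic")
  expect_error(binding_model(NULL, gamma = -1), "gamma")
})
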