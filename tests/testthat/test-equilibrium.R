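test_that("parity coefficient and copies-to-molar conversion", {
  expect_equal(parity(1, 1), 2)
  expect_equal(parity(1, 2), 1)
  expect_equal(parity(2, 1), parity(1, 2))
  expect_equal(site_total_concentration(0), 0)
  expect_equal(site_total_concentration(1), 3.964245e-13, tolerance = 1e-6)
  expect_equal(site_total_concentration(1000),
               1000 * site_total_concentration(1))
  expect_error(site_total_concentration(-1), "non-negative")
  cm <- cell_model(10)
  expect_equal(cm$volume_L, (4 / 3) * pi * 1000 * 1e-15, tolerance = 1e-12)
})

test_that("free probe equals total when there is nothing to bind", {
  st <- solve_equilibrium(make_kds(), c(p1 = 5e-9),
                          tibble::tibble(target_id = character(),
                                         site_id = character(),
                                         total_M = numeric()))
  expect_equal(st$probe$free_M, 5e-9)
  expect_true(st$converged)
})

test_that("probe-excess single-site occupancy matches the closed form", {
  kds <- make_kds(site = tibble::tibble(
    probe_id = "p1", target_id = "T", site_id = "s1", kd = 2e-9,
    dg_min = NA_real_))
  st <- solve_equilibrium(kds, c(p1 = 5e-9),
                          tibble::tibble(target_id = "T", site_id = "s1",
                                         total_M = 1e-15))
  p <- site_bound_probability(st)$p
  expect_equal(p, 5e-9 / (5e-9 + 2e-9), tolerance = 1e-6)
})

test_that("fixed point matches the root-finding oracle on random instances", {
  for (seed in 1:10) {
    inst <- random_instance(seed)
    st <- solve_equilibrium(inst$kds, inst$probe_total, inst$sites)
    or <- oracle_equilibrium(inst$kds, inst$probe_total, inst$sites)
    expect_equal(st$probe$free_M, unname(or$probe_free), tolerance = 1e-9)
    expect_equal(st$site$free_M, unname(or$site_free), tolerance = 1e-9)
  }
})

test_that("probe and site mass balances close", {
  for (seed in c(21, 22, 23)) {
    inst <- random_instance(seed)
    st <- solve_equilibrium(inst$kds, inst$probe_total, inst$sites)
    probes <- st$probe$probe_id
    bal <- st$probe$free_M + st$probe$self_M
    for (i in seq_along(probes)) {
      cr <- st$cross[st$cross$probe_i == probes[i] |
                       st$cross$probe_j == probes[i], ]
      bal[i] <- bal[i] +
        sum(ifelse(cr$probe_i == cr$probe_j, 2, 1) * cr$conc_M) +
        sum(st$bound$conc_M[st$bound$probe_id == probes[i]])
    }
    expect_equal(bal, unname(inst$probe_total), tolerance = 1e-8)
    skey <- paste(st$site$target_id, st$site$site_id)
    bound_per_site <- tapply(st$bound$conc_M,
                             paste(st$bound$target_id, st$bound$site_id),
                             sum)[skey]
    bound_per_site[is.na(bound_per_site)] <- 0
    expect_equal(st$site$free_M + as.numeric(bound_per_site),
                 inst$sites$total_M, tolerance = 1e-8)
  }
})

test_that("raising a probe's total never lowers site occupancy", {
  inst <- random_instance(77)
  st1 <- solve_equilibrium(inst$kds, inst$probe_total, inst$sites)
  p1 <- site_bound_probability(st1)$p
  bumped <- inst$probe_total
  bumped[1] <- bumped[1] * 10
  st2 <- solve_equilibrium(inst$kds, bumped, inst$sites)
  p2 <- site_bound_probability(st2)$p
  expect_true(all(p2 >= p1 - 1e-12))
})

test_that("bound fractions are invariant to joint concentration/Kd scaling", {
  inst <- random_instance(55)
  st1 <- solve_equilibrium(inst$kds, inst$probe_total, inst$sites)
  fac <- 100
  kds2 <- inst$kds
  kds2$site$kd <- kds2$site$kd * fac
  kds2$cross$kd <- kds2$cross$kd * fac  # bimolecular only; self untouched
  sites2 <- inst$sites
  sites2$total_M <- sites2$total_M * fac
  st2 <- solve_equilibrium(kds2, inst$probe_total * fac, sites2)
  expect_equal(st2$probe$free_M / st2$probe$total_M,
               st1$probe$free_M / st1$probe$total_M, tolerance = 1e-9)
  expect_equal(st2$site$free_M / st2$site$total_M,
               st1$site$free_M / st1$site$total_M, tolerance = 1e-9)
})

test_that("complex concentrations obey mass action", {
  kds <- make_kds(
    site = tibble::tibble(probe_id = c("p1", "p2"), target_id = "T",
                          site_id = "s1", kd = c(1e-9, 2e-9),
                          dg_min = NA_real_),
    cross = tibble::tibble(probe_i = "p1", probe_j = "p2", kd = 1e-6,
                           dg_min = NA_real_))
  st <- solve_equilibrium(kds, c(p1 = 5e-9, p2 = 5e-9),
                          tibble::tibble(target_id = "T", site_id = "s1",
                                         total_M = 4e-13))
  # no self entry -> zero self-dimer concentration
  expect_equal(st$probe$self_M, c(0, 0))
  # heterodimer concentration follows C_i C_j / Kd
  expect_equal(st$cross$conc_M,
               st$probe$free_M[1] * st$probe$free_M[2] / 1e-6)
  # bound complexes follow C_T,free C_p,free / Kd
  expect_equal(st$bound$conc_M[st$bound$probe_id == "p1"],
               st$site$free_M * st$probe$free_M[1] / 1e-9)
  # recomputing complexes from the state is idempotent
  st2 <- complex_concentrations(st)
  expect_equal(st2$bound$conc_M, st$bound$conc_M)
  # doubling both free probe concentrations quadruples the heterodimer
  st$probe$free_M <- st$probe$free_M * 2
  st3 <- complex_concentrations(st)
  expect_equal(st3$cross$conc_M, 4 * st2$cross$conc_M)
})

test_that("invalid inputs are rejected", {
  expect_error(solve_equilibrium(make_kds(), c(5e-9),
                                 tibble::tibble(target_id = character(),
                                                site_id = character(),
                                                total_M = numeric())),
               "named")
  kds <- make_kds(site = tibble::tibble(
    probe_id = "p1", target_id = "T", site_id = "s1", kd = -1,
    dg_min = NA_real_))
  expect_error(solve_equilibrium(kds, c(p1 = 1e-9),
                                 tibble::tibble(target_id = "T",
                                                site_id = "s1",
                                                total_M = 1e-12)),
               "Kd")
})
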