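fake_state <- function(free, site_tbl, kds) {
  structure(list(
    probe = tibble::tibble(probe_id = names(free), total_M = unname(free),
                           free_M = unname(free), self_M = 0),
    site = site_tbl, kds = kds), class = "fish_equilibrium")
}

test_that("site bound probability follows the occupancy ratio", {
  # single probe with C_free/Kd = 1 -> p = 1/2
  kds <- make_kds(site = tibble::tibble(
    probe_id = "p1", target_id = "T", site_id = "s1", kd = 5e-9,
    dg_min = NA_real_))
  st <- fake_state(c(p1 = 5e-9),
                   tibble::tibble(target_id = "T", site_id = "s1",
                                  total_M = 1e-13, free_M = 1e-13), kds)
  expect_equal(site_bound_probability(st)$p, 0.5)
  # two probes each with C/Kd = 1 -> p = 2/3
  kds2 <- make_kds(site = tibble::tibble(
    probe_id = c("p1", "p2"), target_id = "T", site_id = "s1",
    kd = 5e-9, dg_min = NA_real_))
  st2 <- fake_state(c(p1 = 5e-9, p2 = 5e-9), st$site, kds2)
  expect_equal(site_bound_probability(st2)$p, 2 / 3)
  # no interactions at a site -> p = 0
  st3 <- fake_state(c(p1 = 5e-9), st$site, make_kds())
  expect_equal(site_bound_probability(st3)$p, 0)
})

test_that("bound-count pmf: special cases, enumeration, generating function", {
  expect_equal(bound_count_distribution(c(0.5, 0.5, 0.5)),
               c(1, 3, 3, 1) / 8)
  expect_equal(bound_count_distribution(1), c(0, 1))
  expect_equal(bound_count_distribution(numeric(0)), 1)
  expect_error(bound_count_distribution(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(17)
  # exhaustive 2^12 enumeration
  p12 <- runif(12)
  expect_equal(bound_count_distribution(p12), oracle_pb_enumerate(p12),
               tolerance = 1e-12)
  # generating-function product expanded through a Vandermonde solve
  for (n in c(3, 5, 6)) {
    p <- runif(n)
    expect_equal(bound_count_distribution(p), oracle_pb_genfun(p),
                 tolerance = 1e-12)
  }
  # normalisation and mean identity on random cases
  for (k in 1:10) {
    p <- runif(sample(1:10, 1))
    pmf <- bound_count_distribution(p)
    expect_equal(sum(pmf), 1, tolerance = 1e-12)
    expect_equal(sum((seq_along(pmf) - 1) * pmf), sum(p),
                 tolerance = 1e-12)
    expect_true(all(pmf >= 0))
  }
})

test_that("on/off spectra are expression-weighted and linear", {
  expr <- tibble::tibble(transcript_id = c("on1", "off1", "off2"),
                         expression = c(3, 2, 2))
  pmf_point <- c(0, 0, 1)            # always 2 bound
  pmfs <- list(on1 = pmf_point, off1 = c(0.5, 0.5), off2 = c(0.5, 0.5))
  oc <- on_off_counts(pmfs, expr, "on1")
  expect_equal(oc$n_on, c(0, 0, 3))  # point mass scaled by expression
  expect_equal(oc$n_off, c(2, 2, 0)) # two identical off-targets add
  # zero off-target expression zeroes the off spectrum
  expr0 <- expr; expr0$expression[2:3] <- 0
  expect_true(all(on_off_counts(pmfs, expr0, "on1")$n_off == 0))
  # linearity in expression
  expr2 <- expr; expr2$expression <- expr2$expression * 3
  expect_equal(on_off_counts(pmfs, expr2, "on1")$n_off, 3 * oc$n_off)
  expect_error(on_off_counts(pmfs, expr, "nope"), "unknown on-target")
})

test_that("specificity load is off-bindings per mean on-occupancy", {
  # mean on-target occupancy 10, off-target probe-bindings 20 -> 2.0
  n_on <- c(rep(0, 10), 1)            # single on-target always 10 bound
  n_off <- c(0, 20)                   # 20 off-targets with one probe each
  expect_equal(specificity_load(n_on, n_off), 2)
  expect_equal(specificity_load(n_on, c(1, 0)), 0)
  expect_equal(specificity_load(n_on, 2 * n_off),
               2 * specificity_load(n_on, n_off))
  expect_error(specificity_load(c(1, 0), n_off), "undefined")
})

test_that("off-target attribution decomposes site occupancy by probe", {
  kds <- make_kds(site = tibble::tibble(
    probe_id = c("p1", "p2", "p1"),
    target_id = c("off", "off", "on"),
    site_id = c("s1", "s1", "s2"),
    kd = c(1e-9, 4e-9, 1e-9), dg_min = NA_real_))
  free <- c(p1 = 4e-9, p2 = 4e-9)
  site_tbl <- tibble::tibble(target_id = c("off", "on"),
                             site_id = c("s1", "s2"),
                             total_M = 1e-13, free_M = 1e-13)
  st <- fake_state(free, site_tbl, kds)
  expr <- tibble::tibble(transcript_id = c("on", "off"),
                         expression = c(1, 6))
  acc <- offtarget_accumulation(st, expr, "on",
                                probe_order = c("p1", "p2"))
  # shares: x1 = 4, x2 = 1 -> p1 gets 4/6, p2 1/6 of 6 copies
  expect_equal(acc$expected_offtarget, c(4, 1))
  expect_equal(acc$cumulative, c(4, 5))
  # contributions sum to the site's expected occupancy
  p_site <- site_bound_probability(st)
  expect_equal(sum(acc$expected_offtarget),
               6 * p_site$p[p_site$target_id == "off"])
  expect_true(all(diff(acc$cumulative) >= 0))
  # probe with no off-target sites contributes zero
  kds0 <- make_kds(site = tibble::tibble(
    probe_id = "p1", target_id = "on", site_id = "s2", kd = 1e-9,
    dg_min = NA_real_))
  st0 <- fake_state(free, site_tbl, kds0)
  acc0 <- offtarget_accumulation(st0, expr, "on",
                                 probe_order = c("p1", "p2"))
  expect_equal(acc0$expected_offtarget, c(0, 0))
})

test_that("problem-probe rankings find the planted promiscuous probe", {
  # p2 owns both sites of the off-target; p1 only binds the on-target
  kds <- make_kds(site = tibble::tibble(
    probe_id = c("p1", "p2", "p2"),
    target_id = c("on", "off1", "off1"),
    site_id = c("s0", "s1", "s2"),
    kd = 1e-9, dg_min = NA_real_))
  free <- c(p1 = 4e-9, p2 = 4e-9)
  site_tbl <- tibble::tibble(target_id = c("on", "off1", "off1"),
                             site_id = c("s0", "s1", "s2"),
                             total_M = 1e-13, free_M = 1e-13)
  st <- fake_state(free, site_tbl, kds)
  expr <- tibble::tibble(transcript_id = c("on", "off1"),
                         expression = 1)
  pr <- identify_problem_probes(st, expr, "on")
  expect_equal(pr$probe_id[pr$rank_total == 1], "p2")
  expect_equal(pr$probe_id[pr$rank_multi == 1], "p2")
  expect_gte(pr$loo_multi_reduction[pr$probe_id == "p2"], 0)
  # a clean probe set yields all-zero rankings
  kds_clean <- make_kds(site = tibble::tibble(
    probe_id = c("p1", "p2"), target_id = "on", site_id = c("s0", "s0"),
    kd = 1e-9, dg_min = NA_real_))
  st_clean <- fake_state(free, site_tbl[1, ], kds_clean)
  pr_clean <- identify_problem_probes(st_clean, expr, "on")
  expect_true(all(pr_clean$expected_offtarget == 0))
  expect_true(all(pr_clean$loo_multi_reduction == 0))
})

test_that("SNR is the background-normalised signal excess", {
  expect_equal(snr(100, 60, 20), 2)
  expect_equal(snr(60, 60, 20), 0)
  expect_equal(snr(160, 60, 20), 2 * snr(110, 60, 20))
  expect_error(snr(100, 60, 0), "sigma")
})
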