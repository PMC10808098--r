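test_that("modal founder takes per-locus modes with documented tie-breaks", {
  same <- ht(matrix(c(13L, 13L, 13L), 3, 2))
  expect_equal(unname(modal_founder(same)$repeats), c(13L, 13L))

  maj <- ht(matrix(c(12L, 12L, 13L), 3, 1))
  expect_equal(unname(modal_founder(maj)$repeats), 12L)

  # 2-2 tie with equal total distance: smaller repeat wins
  tie <- ht(matrix(c(12L, 12L, 13L, 13L), 4, 1))
  expect_equal(unname(modal_founder(tie)$repeats), 12L)

  # 2-2 tie where one mode minimizes total distance: distance rule first
  tie2 <- ht(matrix(c(12L, 12L, 14L, 14L, 13L, 15L), 6, 1))
  # totals: v=12 -> 0+0+2+2+1+3 = 8 ; v=14 -> 2+2+0+0+1+1 = 6
  expect_equal(unname(modal_founder(tie2)$repeats), 14L)

  expect_error(modal_founder(ht(matrix(integer(0), 0, 1))), "empty|no complete")
})

test_that("rho statistic is the mean founder distance with sqrt(rho/n) SD", {
  root <- founder_haplotype(c(L1 = 10L, L2 = 10L))
  at_root <- ht(matrix(10L, 4, 2))
  r0 <- rho_statistic(at_root, root)
  expect_equal(r0$rho, 0)
  expect_equal(r0$sd, 0)

  two <- ht(rbind(c(10L, 10L), c(11L, 10L)))
  r <- rho_statistic(two, root)
  expect_equal(r$rho, 0.5)
  expect_equal(r$sd, sqrt(0.5 / 2))

  # invariance under adding a constant at a locus (root shifted too)
  shifted <- two; shifted$repeats[, 1] <- shifted$repeats[, 1] + 5L
  root2 <- founder_haplotype(c(L1 = 15L, L2 = 10L))
  expect_equal(rho_statistic(shifted, root2)$rho, r$rho)
})

test_that("weighted rho reduces to rho under equal rates and upweights slow loci", {
  set.seed(8)
  tab <- random_table(10, 6)
  mu <- 0.002
  rates_eq <- mutation_rate_table(
    stats::setNames(rep(mu, 6), panel_loci(tab)))
  root <- modal_founder(tab)
  r <- rho_statistic(tab, root)
  w <- weighted_rho(tab, root, rates_eq)
  expect_equal(w$rho_w, r$rho, tolerance = 1e-12)
  expect_equal(w$age_generations, r$rho / (6 * mu), tolerance = 1e-12)

  # mutations only at the slow locus: weighted age exceeds mean-rate dating
  toy <- ht(rbind(c(10L, 10L), c(12L, 10L)))
  rates2 <- mutation_rate_table(c(L1 = 0.001, L2 = 0.004))
  root3 <- founder_haplotype(c(L1 = 10L, L2 = 10L))
  w2 <- weighted_rho(toy, root3, rates2)
  mean_rate_age <- rho_statistic(toy, root3)$rho / sum(c(0.001, 0.004))
  expect_gt(w2$age_generations, mean_rate_age)

  # zero founder distance everywhere -> age 0
  w0 <- weighted_rho(ht(matrix(10L, 3, 2)), founder_haplotype(c(L1 = 10L, L2 = 10L)),
                     rates2)
  expect_equal(w0$age_generations, 0)
})

test_that("ASD second-moment dating follows its closed form", {
  root <- founder_haplotype(c(L1 = 20L))
  at_root <- ht(matrix(20L, 5, 1))
  rates <- mutation_rate_table(c(L1 = 0.002))
  expect_equal(asd_quadratic_age(at_root, root, rates)$age_generations, 0)

  pm <- ht(rbind(19L, 21L))
  res <- asd_quadratic_age(pm, root, rates)
  expect_equal(res$asd, 1)
  expect_equal(res$age_generations, 1 / 0.002)
})

test_that("generation-time conversion is a guarded product", {
  expect_equal(to_years(100, 30), 3000)
  expect_equal(to_years(0, 25), 0)
  t <- 3.7
  expect_equal(to_years(t, 30, round_years = FALSE) /
                 to_years(t, 25, round_years = FALSE), 1.2)
  expect_error(to_years(10, 0), "positive")
  expect_error(to_years(-1, 25), "non-negative")
})

test_that("date_population emits the full three-estimator report", {
  mono <- ht(matrix(14L, 6, 3), populations = "Mono")
  rates <- mutation_rate_table(
    stats::setNames(c(0.001, 0.002, 0.004), c("L1", "L2", "L3")))
  rep_mono <- date_population(mono, rates, seed = 4)
  expect_equal(unique(rep_mono$years), 0)
  expect_setequal(rep_mono$method, c("rho", "weighted_rho", "asd_quadratic"))
  expect_setequal(rep_mono$generation_time, c(25, 30))
  expect_equal(nrow(rep_mono), 6L)

  single <- ht(matrix(14L, 1, 3), populations = "One")
  expect_warning(rep_one <- date_population(single, rates, n_bootstrap = 0),
                 "undefined")
  expect_equal(unique(rep_one$statistic[rep_one$method == "rho"]), 0)

  set.seed(2)
  tab <- random_table(8, 3)
  rep_t <- date_population(tab, rates, seed = 11, n_bootstrap = 100)
  expect_true(all(rep_t$years >= 0))
  expect_equal(rep_t$years[rep_t$generation_time == 30 & rep_t$method == "rho"],
               to_years(rep_t$age_generations[rep_t$generation_time == 30 &
                                                rep_t$method == "rho"], 30))
  # bootstrap SDs are seeded and finite for n >= 2
  expect_true(all(is.finite(rep_t$sd_years)))
  rep_t2 <- date_population(tab, rates, seed = 11, n_bootstrap = 100)
  expect_identical(rep_t, rep_t2)
})

test_that("star-genealogy recovery matches the random-walk oracle", {
  mu <- 0.002; L <- 15; n <- 50
  rates_vec <- stats::setNames(rep(mu, L), paste0("L", 1:L))
  rates <- mutation_rate_table(rates_vec)
  reps <- 200
  for (T_true in c(50, 200)) {
    rho_vals <- asd_ages <- numeric(reps)
    for (r in seq_len(reps)) {
      tab <- simulate_star(sim_config(n, rates = rates_vec, tmrca = T_true,
                                      seed = 100000 + 17 * r + T_true))
      root <- founder_haplotype(
        stats::setNames(rep(20L, L), names(rates_vec)))
      rho_vals[r] <- rho_statistic(tab, root)$rho
      asd_ages[r] <- asd_quadratic_age(tab, root, rates)$age_generations
    }
    # rho concentrates on L * E|net walk displacement| (back mutations make
    # this slightly less than T * L * mu)
    expect_lt(abs(mean(rho_vals) - L * expected_abs_walk(mu * T_true)),
              3 * stats::sd(rho_vals) / sqrt(reps))
    # the second moment is linear in time: ASD age is unbiased for T
    expect_lt(abs(mean(asd_ages) - T_true),
              3 * stats::sd(asd_ages) / sqrt(reps) + 1e-9)
  }
})

test_that("analytic SD of rho tracks the empirical replicate SD", {
  mu <- 0.002; L <- 15; n <- 25; T_true <- 100
  rates_vec <- stats::setNames(rep(mu, L), paste0("L", 1:L))
  root <- founder_haplotype(stats::setNames(rep(20L, L), names(rates_vec)))
  rho_vals <- sd_analytic <- numeric(200)
  for (r in 1:200) {
    tab <- simulate_star(sim_config(n, rates = rates_vec, tmrca = T_true,
                                    seed = 55000 + r))
    st <- rho_statistic(tab, root)
    rho_vals[r] <- st$rho
    sd_analytic[r] <- st$sd
  }
  ratio <- mean(sd_analytic) / stats::sd(rho_vals)
  expect_gt(ratio, 1 / 1.5)
  expect_lt(ratio, 1.5)
})
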