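test_that("the generator is deterministic given the seed", {
  cfg <- small_sim_config()
  s1 <- simulate_study(cfg, seed = 7)
  s2 <- simulate_study(cfg, seed = 7)
  expect_identical(s1$phenotypes, s2$phenotypes)
  expect_identical(s1$plates, s2$plates)
  expect_identical(truth_report(s1$truth), truth_report(s2$truth))
  s3 <- simulate_study(cfg, seed = 8)
  expect_false(identical(s1$phenotypes$value, s3$phenotypes$value))
})

test_that("the default configuration reproduces the study dimensions", {
  cfg <- sim_config()
  pop <- simulate_founders_and_cycles(cfg, seed = 1)
  counts <- table(pop$lines$cycle)
  expect_equal(unname(counts["PARENT"]), 8)
  expect_equal(unname(counts["C0"]), 105)
  expect_equal(unname(counts["C1G"]), 87)
  expect_equal(unname(counts["C1P"]), 108)
  expect_equal(unname(counts["C2G"]), 114)
  sim <- simulate_trials(pop, seed = 1)
  # duplicate germination plates per plot x timepoint
  reps <- dplyr::count(sim$plates, plot_id, timepoint)
  expect_true(all(reps$n == 2))
  # checks inserted roughly every 15 malting samples
  ph <- sim$phenotypes[sim$phenotypes$trait == "FAN" &
                         sim$phenotypes$tech_rep == 1, ]
  n_check <- sum(ph$line_id == cfg$check_line)
  n_real <- sum(ph$line_id != cfg$check_line)
  expect_gt(n_check, 0)
  expect_lt(abs(n_check / n_real - 1 / 15), 1 / 60)
  # three years, both malting timepoints in the controlled years only
  expect_setequal(unique(ph$timepoint[ph$year == 2019]), "TP6")
  expect_setequal(unique(ph$timepoint[ph$year == 2020]), c("TP4", "TP6"))
})

test_that("plate counts respect the index bounds by construction", {
  sim <- simulate_study(small_sim_config(), seed = 2)
  gi <- germination_index(sim$plates)
  expect_true(all(gi$GI >= 0 & gi$GI <= 10))
  expect_true(all(gi$GE >= 0 & gi$GE <= 1))
  expect_true(all(sim$plates$n24 + sim$plates$n48 + sim$plates$n72 <=
                    sim$plates$n_plated))
})

test_that("expected after-ripening trajectories are monotone for every allele", {
  cfg <- sim_config()
  for (al in names(cfg$alleles)) {
    a <- cfg$alleles[[al]]
    t <- as.numeric(cfg$tp_days)
    gi <- a$asymptote * t / (t + a$tau)
    expect_true(all(diff(gi) > 0))
    expect_true(all(gi >= 0 & gi <= 10))
  }
})

test_that("latent moments calibrate to the configuration at scale", {
  ## a single biparental family isolates the Mendelian-sampling draw: the
  ## mid-parent is a constant, so C0 carries exactly half the configured
  ## polygenic variance and the configured cross-trait correlations
  cfg <- sim_config(cycle_sizes = c(C0 = 2000L, C1G = 0L, C1P = 0L, C2G = 0L),
                    n_families = 1L,
                    founder_alleles = setNames(rep("N", 8), paste0("P", 1:8)))
  pop <- simulate_founders_and_cycles(cfg, seed = 5)
  c0 <- pop$lines$line_id[pop$lines$cycle == "C0"]
  poly <- pop$polygenic[c0, ]
  tr <- cfg$malt_traits
  for (j in seq_len(nrow(tr))) {
    expect_lt(abs(stats::sd(poly[, tr$trait[j]]) - tr$sd_poly[j] / sqrt(2)),
              0.05 * tr$sd_poly[j] + 1e-9)
    expect_lt(abs(stats::cor(poly[, "GI"], poly[, tr$trait[j]]) - tr$lambda[j]),
              0.05)
  }
  ## the 7-family default adds a between-family component: 1/4 of the founder
  ## variance on top of the segregation half, with 7-draw sampling noise
  cfg7 <- sim_config(cycle_sizes = c(C0 = 2000L, C1G = 0L, C1P = 0L, C2G = 0L),
                     founder_alleles = setNames(rep("N", 8), paste0("P", 1:8)))
  pop7 <- simulate_founders_and_cycles(cfg7, seed = 5)
  poly7 <- pop7$polygenic[pop7$lines$cycle == "C0", ]
  for (j in seq_len(nrow(tr))) {
    expect_equal(stats::sd(poly7[, tr$trait[j]]), sqrt(0.75) * tr$sd_poly[j],
                 tolerance = 0.2 * tr$sd_poly[j] + 1e-9)
  }
})

test_that("index selection against the high-GI allele depletes N* monotonically", {
  drops <- vapply(1:25, function(s) {
    pop <- simulate_founders_and_cycles(sim_config(), seed = 400 + s)
    f <- tapply(pop$lines$allele == "Nstar", pop$lines$cycle, mean)
    f["C0"] > f["C1G"] && f["C1G"] >= f["C2G"]
  }, TRUE)
  expect_gte(mean(drops), 0.95)
})

test_that("neutral selection leaves cycle allele frequencies exchangeable", {
  cfg <- sim_config(selection = list(w_gi = 0, w_protein = 0, phen_error_sd = 1,
                                     per_family = 2L, c2_top_n = 15L))
  ps <- vapply(1:20, function(s) {
    pop <- simulate_founders_and_cycles(cfg, seed = 500 + s)
    li <- pop$lines[pop$lines$cycle %in% c("C0", "C1G"), ]
    tab <- table(li$cycle, li$allele == "Nstar")
    suppressWarnings(stats::chisq.test(tab)$p.value)
  }, 1)
  # no systematic allele-frequency shift: tests rarely reject at 1%
  expect_gte(mean(ps > 0.01), 0.9)
})

test_that("the truth report carries the oracle quantities", {
  sim <- simulate_study(small_sim_config(), seed = 9)
  tr <- truth_report(sim$truth)
  expect_true(all(c("rg_gi_tp1", "cycle_genetic_variance", "nstar_frequency",
                    "sigma2_pltE", "sigma2_dgTP") %in% tr$quantity))
  expect_true("ALL" %in% tr$group[tr$quantity == "rg_gi_tp1"])
  expect_true(all(c("C0", "C1G") %in%
                    tr$group[tr$quantity == "cycle_genetic_variance"]))
  expect_identical(tr, truth_report(simulate_study(small_sim_config(),
                                                   seed = 9)$truth))
})

test_that("noiseless malting reduces to the latent genetic plus fixed structure", {
  tr0 <- default_malt_traits()[default_malt_traits()$trait == "FAN", ]
  tr0$sd_pltE <- 0; tr0$sd_assay <- 0; tr0$sd_dgTP <- 0
  cfg <- sim_config(cycle_sizes = c(C0 = 60L, C1G = 30L, C1P = 30L, C2G = 30L),
                    years = c(2020L, 2021L),
                    germ_timepoints = c("TP1", "TP4", "TP6"),
                    n_markers = 10L, malt_traits = tr0)
  sim <- simulate_study(cfg, seed = 10)
  ph <- sim$phenotypes[sim$phenotypes$line_id != cfg$check_line, ]
  li <- sim$truth$lines
  g <- li$FAN[match(ph$line_id, li$line_id)]
  resid <- ph$value - g
  # residual is pure fixed structure: identical within year x timepoint
  spread <- tapply(resid, paste(ph$year, ph$timepoint), function(v)
    diff(range(v)))
  expect_true(all(spread < 1e-10))
})
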