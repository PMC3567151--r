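test_that("initialization gives a homozygous half-and-half population", {
  p <- model_params()
  cfg <- quick_config(N = 10000L)
  pop <- initialize_population(cfg, p)
  expect_length(pop$sex, 10000)
  expect_equal(sum(pop$sex == "M"), 5000)
  mm <- colMeans(pop$alleles)
  expect_equal(unname(mm[c("m1", "m2")]), c(0, 0))
  expect_equal(unname(mm[c("d1", "d2")]), c(16, 16))
  expect_true(all(pop$alleles[, c("f1", "f2")] == 5))
  # smallest valid population
  tiny <- initialize_population(quick_config(N = 2L), p)
  expect_equal(sort(tiny$sex), c("F", "M"))
  # out-of-range initial value
  bad <- quick_config(initial_alleles = c(male = 0L, female = 5L,
                                          decoy = 16L, neutral = 60L))
  expect_error(initialize_population(bad, p), "allele space")
  expect_error(run_simulation(bad, p), "allele space")
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(N = 999), "even")
  expect_error(sim_config(N = -10), "even")
  expect_error(sim_config(generations = 1000, window = 300), "divisible")
  expect_error(sim_config(mu = 2), "mu")
  expect_error(sim_config(n_replicates = 0), "n_replicates")
})

test_that("realized mating rates match the analytic pair-rate mean", {
  # 4-individual population: Monte-Carlo mean of realized rate equals the
  # mean pairwise mating probability (binomial expectation)
  p <- model_params()
  cfg <- quick_config(N = 4L, n_encounters = 20L)
  pop <- initialize_population(cfg, p)
  # make the two males distinct so the analytic mean is non-trivial
  pop$alleles[pop$sex == "M", c("m1", "m2")] <- c(0L, 4L, 0L, 4L)
  males <- which(pop$sex == "M")
  z_m <- phenotype(pop$alleles[males, "m1"], pop$alleles[males, "m2"], p)
  females <- which(pop$sex == "F")
  i <- females[1]
  z_f <- phenotype(pop$alleles[i, "f1"], pop$alleles[i, "f2"], p)
  z_d <- phenotype(pop$alleles[i, "d1"], pop$alleles[i, "d2"], p)
  p_mean <- mean(decoy_modified_rate(z_m, z_f, z_d, p)$P_modified)
  set.seed(99)
  rates <- replicate(400, encounter_and_mate(pop, p, cfg)$rate[1])
  se <- sqrt(p_mean * (1 - p_mean) / (20 * 400))
  expect_lt(abs(mean(rates) - p_mean), 4 * se)
})

test_that("mating degenerates correctly at rate limits", {
  p <- model_params()
  cfg <- quick_config(N = 20L)
  pop <- initialize_population(
    sim_config(N = 20, generations = 400, window = 100,
               initial_alleles = c(male = 10L, female = 10L, decoy = 40L,
                                   neutral = 30L)), p)
  set.seed(1)
  m <- encounter_and_mate(pop, p, cfg)
  expect_true(all(m$rate == 1))        # identical phenotypes, no decoy
  expect_true(all(lengths(m$mates) == cfg$n_encounters))
  # far-apart phenotypes: rate 0, empty mate lists
  pop$alleles[, c("f1", "f2")] <- 50L
  m0 <- encounter_and_mate(pop, p, cfg)
  expect_true(all(m0$rate == 0))
  expect_true(all(lengths(m0$mates) == 0))
  expect_error(reproduce(pop, m0, p, cfg), "no females mated")
})

test_that("reproduction conserves population size and neutral means", {
  p <- model_params()
  cfg <- sim_config(N = 200, generations = 400, window = 100, mu = 0,
                    initial_alleles = c(male = 10L, female = 10L,
                                        decoy = 40L, neutral = 30L))
  pop <- initialize_population(cfg, p)
  set.seed(5)
  m <- encounter_and_mate(pop, p, cfg)
  nxt <- reproduce(pop, m, p, cfg)
  expect_length(nxt$sex, 200)
  expect_equal(dim(nxt$alleles), c(200, 8))
  # flat fitness (all rates 1) and mu = 0: alleles are a resample of the
  # parental pool, so every value stays in the founding set
  expect_true(all(nxt$alleles[, c("n1", "n2")] == 30))
  expect_true(all(nxt$alleles[, c("m1", "m2")] == 10))
})

test_that("mutation moves alleles stepwise with reflecting boundaries", {
  expect_identical(mutate_gametes(c(5L, 7L), 0, 50L), c(5L, 7L))
  set.seed(11)
  hit0 <- mutate_gametes(rep(0L, 2000), 1, 50L)
  expect_true(all(hit0 == 1L))       # reflect at 0
  hit50 <- mutate_gametes(rep(50L, 2000), 1, 50L)
  expect_true(all(hit50 == 49L))     # reflect at allele_max
  mid <- mutate_gametes(rep(25L, 4000), 1, 50L)
  expect_true(all(mid %in% c(24L, 26L)))
  # mutated fraction matches the binomial expectation within 3 sd
  mu <- 0.01; n <- 1e6
  g <- mutate_gametes(rep(25L, n), mu, 50L)
  frac <- mean(g != 25L)
  expect_lt(abs(frac - mu), 3 * sqrt(mu * (1 - mu) / n))
})

test_that("trajectories have the right shape and stay in the allele space", {
  p <- model_params()
  cfg <- quick_config(N = 100L, generations = 300L, window = 100L)
  tr <- run_simulation(cfg, p)
  expect_s3_class(tr, "trajectory")
  expect_equal(nrow(tr), 301)
  expect_equal(tr$generation, 0:300)
  loci <- c("mean_male", "mean_female", "mean_decoy", "mean_neutral")
  expect_true(all(as.matrix(tr[loci]) >= 0 & as.matrix(tr[loci]) <= 50))
  expect_true(all(tr$mean_mating[-1] >= 0 & tr$mean_mating[-1] <= 1))
})

test_that("with no mutation and uniform rates the means are frozen", {
  p <- model_params()
  cfg <- sim_config(N = 200, generations = 300, window = 100, mu = 0,
                    initial_alleles = c(male = 10L, female = 10L,
                                        decoy = 40L, neutral = 30L))
  tr <- run_simulation(cfg, p)
  expect_true(all(tr$mean_male == 10))
  expect_true(all(tr$mean_female == 10))
  expect_true(all(tr$mean_decoy == 40))
  expect_true(all(tr$mean_neutral == 30))
  expect_true(all(tr$mean_mating[-1] == 1))
})

test_that("identical seeds give identical trajectories, replicates differ", {
  p <- model_params()
  cfg <- quick_config(N = 100L, generations = 200L, window = 100L, seed = 3L)
  t1 <- run_simulation(cfg, p, replicate = 2)
  t2 <- run_simulation(cfg, p, replicate = 2)
  expect_identical(t1, t2)
  t3 <- run_simulation(cfg, p, replicate = 3)
  expect_false(identical(t1$mean_neutral, t3$mean_neutral))
})

test_that("replicate k from a batch equals replicate k run alone", {
  p <- model_params()
  cfg <- quick_config(N = 100L, generations = 200L, window = 100L,
                      seed = 3L, n_replicates = 3L)
  batch <- run_replicates(cfg, p)
  expect_length(batch, 3)
  alone <- run_simulation(cfg, p, replicate = 3)
  expect_identical(batch[[3]], alone)
})

test_that("a permanently inactive decoy reproduces the decoy-free path", {
  # decoy initialized far outside the male-female interval: the full model
  # with theta = 0 everywhere must be bit-identical to the engine run with
  # the decoy term disabled
  p <- model_params()
  cfg <- sim_config(N = 200, generations = 500, window = 100, seed = 13,
                    initial_alleles = c(male = 0L, female = 5L, decoy = 45L,
                                        neutral = 30L))
  on_path <- run_simulation(cfg, p, decoy = TRUE)
  off_path <- run_simulation(cfg, p, decoy = FALSE)
  expect_identical(on_path, off_path)
})

test_that("the two-locus chase keeps mating above P_opt and couples the sexes", {
  # decoy parked outside the interval: classic sexual-conflict chase; the
  # male tracks the female and the mean mating rate sits between the female
  # optimum P_opt and the male optimum 1
  p <- model_params()
  cfg <- sim_config(N = 500, generations = 2000, window = 250, seed = 2,
                    initial_alleles = c(male = 0L, female = 5L, decoy = 50L,
                                        neutral = 30L))
  tr <- run_simulation(cfg, p, decoy = FALSE)
  late <- tr$mean_mating[1001:2001]
  expect_gt(mean(late), p$P_opt)
  expect_lt(mean(late), 1)
  r <- substitution_rates(tr, 250)
  fit <- fit_rate_regression(r$male, r$female)
  expect_gt(fit$slope, 0)
})

test_that("an active decoy between the loci pulls mating below P_opt", {
  # start with the decoy mid-interval at the optimal separation: early
  # generations must show the depressed mating rate of the stalled phase
  p <- model_params()
  cfg <- sim_config(N = 500, generations = 200, window = 100, seed = 4,
                    initial_alleles = c(male = 0L, female = 5L, decoy = 2L,
                                        neutral = 30L))
  with_decoy <- run_simulation(cfg, p, decoy = TRUE)
  without <- run_simulation(cfg, p, decoy = FALSE)
  expect_lt(mean(with_decoy$mean_mating[2:51]), p$P_opt)
  expect_lt(mean(with_decoy$mean_mating[2:51]),
            mean(without$mean_mating[2:51]))
})

test_that("the engine's rate table matches the R model functions exactly", {
  p <- model_params()
  S <- 2 * p$allele_max + 1
  tab_on <- decoysim:::.rate_table_cpp(unclass(p), TRUE)
  tab_off <- decoysim:::.rate_table_cpp(unclass(p), FALSE)
  expect_equal(dim(tab_on), c(S, S, S))
  set.seed(19)
  idx <- cbind(sample(S, 400, TRUE), sample(S, 400, TRUE),
               sample(S, 400, TRUE))
  z <- (idx - 1) / (2 * p$allele_max)   # normalized phenotypes
  eff <- decoy_modified_rate(z[, 1], z[, 2], z[, 3], p)
  expect_equal(tab_on[idx], eff$P_modified, tolerance = 1e-12)
  expect_equal(tab_off[idx], eff$P_MF, tolerance = 1e-12)
  # wherever the decoy is inactive the two tables coincide
  inactive <- eff$theta == 0L
  expect_identical(tab_on[idx][inactive], tab_off[idx][inactive])
})
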