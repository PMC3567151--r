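#' Simulation configuration
#'
#' Run-level settings for the replicated population simulations. Defaults
#' are the published study conditions: populations of N = 10,000 diploid
#' individuals run for 15,000 generations, 20 male encounters per female per
#' generation, a per-locus per-gamete mutation rate of 5e-5, initial allelic
#' values male 0 / female 5 / decoy 16 / neutral 30, substitution rates
#' measured in 500-generation windows, and 20 independent replicates.
#'
#' @param N population size (even, constant across generations).
#' @param generations number of generations to simulate (must be divisible
#'   by \code{window}).
#' @param n_encounters males encountered per female per generation.
#' @param mu mutation rate per locus per transmitted gamete per generation.
#' @param initial_alleles named vector of initial allelic values for the
#'   \code{male}, \code{female}, \code{decoy} and \code{neutral} loci.
#' @param seed base random seed; replicate k uses the deterministic stream
#'   (seed, k), so any replicate is reproducible in isolation.
#' @param n_replicates number of independent runs.
#' @param window generations per substitution-rate window.
#' @return An object of class \code{"sim_config"}.
#' @export
sim_config <- function(N = 10000L, generations = 15000L, n_encounters = 20L,
                       mu = 5e-5,
                       initial_alleles = c(male = 0L, female = 5L,
                                           decoy = 16L, neutral = 30L),
                       seed = 1L, n_replicates = 20L, window = 500L) {
  cfg <- list(N = as.integer(N), generations = as.integer(generations),
              n_encounters = as.integer(n_encounters), mu = mu,
              initial_alleles = initial_alleles, seed = as.integer(seed),
              n_replicates = as.integer(n_replicates),
              window = as.integer(window))
  class(cfg) <- "sim_config"
  if (cfg$N <= 0 || cfg$N %% 2 != 0)
    stop("N must be even and positive", call. = FALSE)
  if (cfg$generations < 1) stop("generations must be >= 1", call. = FALSE)
  if (cfg$generations %% cfg$window != 0)
    stop("generations must be divisible by window", call. = FALSE)
  if (cfg$mu < 0 || cfg$mu > 1) stop("mu must lie in [0, 1]", call. = FALSE)
  if (cfg$n_encounters < 1) stop("n_encounters must be >= 1", call. = FALSE)
  if (cfg$n_replicates < 1) stop("n_replicates must be >= 1", call. = FALSE)
  loci <- c("male", "female", "decoy", "neutral")
  if (!all(loci %in% names(cfg$initial_alleles)))
    stop("initial_alleles must name male, female, decoy and neutral",
         call. = FALSE)
  cfg$initial_alleles <- cfg$initial_alleles[loci]
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("Simulation: N = %d, %d generations, %d encounters/female, mu = %g\n",
              x$N, x$generations, x$n_encounters, x$mu))
  cat(sprintf("  initial alleles: male %d, female %d, decoy %d, neutral %d\n",
              x$initial_alleles["male"], x$initial_alleles["female"],
              x$initial_alleles["decoy"], x$initial_alleles["neutral"]))
  cat(sprintf("  %d replicates, base seed %d, rate window %d generations\n",
              x$n_replicates, x$seed, x$window))
  invisible(x)
}

.locus_cols <- c("m1", "m2", "f1", "f2", "d1", "d2", "n1", "n2")

#' Initialize a population
#'
#' Builds the founding population: N diploid individuals, half male and half
#' female, every individual homozygous at each of the four loci for the
#' configured initial allelic value.
#'
#' @param config a [sim_config()].
#' @param params a [model_params()] (supplies the allele space).
#' @return An object of class \code{"population"}: a list with a character
#'   \code{sex} vector ("M"/"F") and an integer \code{alleles} matrix with
#'   columns \code{m1, m2, f1, f2, d1, d2, n1, n2}.
#' @export
initialize_population <- function(config, params = model_params()) {
  init <- config$initial_alleles
  if (any(init < 0 | init > params$allele_max))
    stop("initial allele value outside allele space [0, ",
         params$allele_max, "]", call. = FALSE)
  alleles <- matrix(rep(as.integer(init), each = 2), nrow = config$N,
                    ncol = 8, byrow = TRUE,
                    dimnames = list(NULL, .locus_cols))
  pop <- list(sex = rep(c("M", "F"), each = config$N / 2), alleles = alleles)
  class(pop) <- "population"
  pop
}

#' @export
print.population <- function(x, ...) {
  n <- length(x$sex)
  cat(sprintf("Population of %d diploid individuals (%d M / %d F)\n",
              n, sum(x$sex == "M"), sum(x$sex == "F")))
  mm <- colMeans(x$alleles)
  cat(sprintf("  mean allelic values: male %.2f, female %.2f, decoy %.2f, neutral %.2f\n",
              mean(mm[1:2]), mean(mm[3:4]), mean(mm[5:6]), mean(mm[7:8])))
  invisible(x)
}

# mean allelic value per locus of a population
population_means <- function(pop) {
  mm <- colMeans(pop$alleles)
  c(male = mean(mm[c("m1", "m2")]), female = mean(mm[c("f1", "f2")]),
    decoy = mean(mm[c("d1", "d2")]), neutral = mean(mm[c("n1", "n2")]))
}

#' Encounter and mating round
#'
#' Each female encounters \code{n_encounters} males drawn uniformly with
#' replacement; each encounter results in mating with probability equal to
#' the pair's (decoy-modified) mating rate, computed with the female's own
#' decoy genotype. This is the reference R implementation of one mating
#' round, operating on a [initialize_population()] object and R's RNG; the
#' compiled engine used by [run_simulation()] implements the identical
#' scheme.
#'
#' @param pop a \code{"population"}.
#' @param params a [model_params()].
#' @param config a [sim_config()] (supplies \code{n_encounters}).
#' @return A list with \code{females} (row indices), \code{rate} (realized
#'   mating rate, matings / encounters, per female) and \code{mates} (list of
#'   mated male row indices per female, with multiplicity).
#' @export
encounter_and_mate <- function(pop, params, config) {
  males <- which(pop$sex == "M")
  females <- which(pop$sex == "F")
  if (length(males) == 0) stop("no males in the population", call. = FALSE)
  a <- pop$alleles
  z_m_all <- phenotype(a[, "m1"], a[, "m2"], params)
  z_f <- phenotype(a[females, "f1"], a[females, "f2"], params)
  z_d <- phenotype(a[females, "d1"], a[females, "d2"], params)
  n_enc <- config$n_encounters
  rate <- numeric(length(females))
  mates <- vector("list", length(females))
  for (i in seq_along(females)) {
    enc <- males[sample.int(length(males), n_enc, replace = TRUE)]
    eff <- decoy_modified_rate(z_m_all[enc], rep(z_f[i], n_enc),
                               rep(z_d[i], n_enc), params)
    mated <- stats::runif(n_enc) < eff$P_modified
    rate[i] <- sum(mated) / n_enc
    mates[[i]] <- enc[mated]
  }
  list(females = females, rate = rate, mates = mates)
}

#' Mutate transmitted alleles
#'
#' Each transmitted allele independently mutates with probability \code{mu};
#' a mutation moves the allelic value by one step up or down (equal
#' probability) with reflecting boundaries at 0 and \code{allele_max}.
#'
#' @param gametes integer vector of allelic values.
#' @param mu mutation probability per allele.
#' @param allele_max upper bound of the allele space.
#' @return The mutated allele vector.
#' @export
mutate_gametes <- function(gametes, mu, allele_max = 50L) {
  if (mu < 0 || mu > 1) stop("mu must lie in [0, 1]", call. = FALSE)
  if (mu == 0 || length(gametes) == 0) return(gametes)
  hit <- which(stats::runif(length(gametes)) < mu)
  if (length(hit)) {
    step <- ifelse(stats::runif(length(hit)) < 0.5, -1L, 1L)
    g <- gametes[hit] + step
    g[g < 0] <- 1L
    g[g > allele_max] <- allele_max - 1L
    gametes[hit] <- g
  }
  gametes
}

#' Reproduction round
#'
#' Forms the next generation of exactly N individuals. Mothers are sampled
#' (with replacement) from the mated females with probability proportional
#' to their fecundity \code{W_f(realized rate)}; each offspring's sire is
#' drawn uniformly from its mother's mate multiset; each parent transmits
#' one allele per locus, chosen independently, subject to mutation; sex is
#' assigned uniformly at random.
#'
#' @param pop a \code{"population"}.
#' @param mating the result of [encounter_and_mate()].
#' @param params a [model_params()].
#' @param config a [sim_config()].
#' @return The next-generation \code{"population"}.
#' @export
reproduce <- function(pop, mating, params, config) {
  mated <- which(lengths(mating$mates) > 0)
  if (length(mated) == 0)
    stop("no females mated; cannot form the next generation", call. = FALSE)
  W <- female_fecundity(mating$rate[mated], params)
  N <- config$N
  mom_pick <- mated[sample.int(length(mated), N, replace = TRUE, prob = W)]
  a <- pop$alleles
  child <- matrix(0L, nrow = N, ncol = 8,
                  dimnames = list(NULL, .locus_cols))
  mom_rows <- mating$females[mom_pick]
  dad_rows <- vapply(mom_pick, function(m) {
    ml <- mating$mates[[m]]
    ml[sample.int(length(ml), 1)]
  }, integer(1))
  for (l in 0:3) {
    mom_a <- ifelse(stats::runif(N) < 0.5, a[cbind(mom_rows, 2 * l + 1)],
                    a[cbind(mom_rows, 2 * l + 2)])
    dad_a <- ifelse(stats::runif(N) < 0.5, a[cbind(dad_rows, 2 * l + 1)],
                    a[cbind(dad_rows, 2 * l + 2)])
    child[, 2 * l + 1] <- mutate_gametes(mom_a, config$mu, params$allele_max)
    child[, 2 * l + 2] <- mutate_gametes(dad_a, config$mu, params$allele_max)
  }
  out <- list(sex = ifelse(stats::runif(N) < 0.5, "M", "F"), alleles = child)
  class(out) <- "population"
  out
}

#' Run one simulation replicate
#'
#' Executes the full generation loop -- encounters and mating, fecundity
#' selection, reproduction with Mendelian inheritance and stepwise mutation
#' -- in the compiled engine, recording the mean allelic value of each locus
#' (and the population mean realized mating rate) every generation. The
#' replicate's random stream is fully determined by \code{(config$seed,
#' replicate)}: the same pair always yields a bit-identical trajectory,
#' independent of R's RNG state.
#'
#' @param config a [sim_config()].
#' @param params a [model_params()].
#' @param replicate replicate index (the RNG stream number).
#' @param decoy logical; if \code{FALSE} the decoy term is disabled and the
#'   model reduces to the two-locus sexual-conflict model (the decoy and
#'   neutral loci still segregate and mutate, but never affect mating).
#' @return A data frame of class \code{"trajectory"} with columns
#'   \code{generation}, \code{mean_male}, \code{mean_female},
#'   \code{mean_decoy}, \code{mean_neutral}, \code{mean_mating}
#'   (\code{generations + 1} rows), and attributes \code{replicate},
#'   \code{seed} and \code{window}.
#' @export
run_simulation <- function(config, params = model_params(), replicate = 1L,
                           decoy = TRUE) {
  check_params_invariants(params)
  init <- config$initial_alleles
  if (any(init < 0 | init > params$allele_max))
    stop("initial allele value outside allele space [0, ",
         params$allele_max, "]", call. = FALSE)
  m <- .sim_engine_cpp(config$N, config$generations, config$n_encounters,
                       config$mu, as.integer(init), unclass(params),
                       isTRUE(decoy), as.double(config$seed),
                       as.double(replicate))
  traj <- as.data.frame(m)
  attr(traj, "replicate") <- as.integer(replicate)
  attr(traj, "seed") <- config$seed
  attr(traj, "window") <- config$window
  class(traj) <- c("trajectory", "data.frame")
  traj
}

#' Run replicated simulations
#'
#' Runs \code{config$n_replicates} independent replicates. Replicate k's
#' random stream depends only on the base seed and k, so a single replicate
#' re-run in isolation reproduces its trajectory from the full batch.
#' Replicates that fail (e.g. every mating rate collapses to zero) are
#' reported and the remaining trajectories returned.
#'
#' @param config a [sim_config()].
#' @param params a [model_params()].
#' @param decoy passed to [run_simulation()].
#' @return A list of \code{"trajectory"} objects (class
#'   \code{"trajectory_set"}); failed replicates are recorded in the
#'   \code{"failed"} attribute as condition messages named by replicate.
#' @export
run_replicates <- function(config, params = model_params(), decoy = TRUE) {
  out <- vector("list", config$n_replicates)
  failed <- character(0)
  for (k in seq_len(config$n_replicates)) {
    res <- tryCatch(run_simulation(config, params, replicate = k,
                                   decoy = decoy),
                    error = function(e) e)
    if (inherits(res, "error")) {
      failed[as.character(k)] <- conditionMessage(res)
      warning("replicate ", k, " failed: ", conditionMessage(res),
              call. = FALSE)
    } else {
      out[[k]] <- res
    }
  }
  out <- out[!vapply(out, is.null, logical(1))]
  attr(out, "failed") <- failed
  class(out) <- "trajectory_set"
  out
}

#' @export
print.trajectory_set <- function(x, ...) {
  cat(sprintf("%d simulation trajectories", length(x)))
  fl <- attr(x, "failed")
  if (length(fl)) cat(sprintf(" (%d replicate(s) failed)", length(fl)))
  cat("\n")
  invisible(x)
}
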