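#' Model parameters for sexual conflict with a female decoy
#'
#' Bundles every parameter of the mating-rate / fecundity model: the conflict
#' between a male-expressed ligand locus (optimal mating rate 1) and a
#' female-expressed receptor locus (optimal mating rate \code{P_opt}), plus a
#' female-expressed decoy locus -- a receptor mimic that binds ligand without
#' effector function -- that modifies the pair's mating rate whenever its
#' phenotype lies strictly between the male and female phenotypes.
#'
#' The component curves are
#' \deqn{P_{MF} = \exp(-(D_{MF}/s_p)^{x_p})}
#' \deqn{W_f = B_{max} \exp(-(|P - P_{opt}|/s_w)^{x_w})}
#' \deqn{P_t = P_{opt} \min(1, (|D_{MF} - D_{opt}|/s_d)^{x_d})}
#' \deqn{P_i = P_{opt} c_0 \min(1, (d_{MD}/s_i)^{x_i})}
#' with the decoy-modified rate \eqn{P' = \min(1, \max(0, P_{opt} - P_t -
#' P_i))} when the decoy is active: the deviation penalty \eqn{P_t} applies
#' regardless of where the decoy sits (this is what stops the decoy simply
#' chasing the male), while the positional interference \eqn{P_i} fades as
#' the decoy approaches the male. Distances are computed on phenotypes
#' normalized by \code{allele_max}, so \code{D_opt} and the deviation scale
#' \code{sd} live on [0, 1].
#'
#' @param P_opt optimal female mating rate (probability per encounter,
#'   strictly between 0 and 1).
#' @param B_max maximum offspring per female.
#' @param s_w,x_w scale and exponent of the fecundity penalty as the realized
#'   mating rate deviates from \code{P_opt}.
#' @param s_p,x_p scale and exponent of the baseline mating-rate decay with
#'   male-female phenotypic distance.
#' @param si,xi scale and exponent of decoy interference \code{Pi} as a
#'   function of male-decoy distance.
#' @param sd,xd scale and exponent of the interference magnitude \code{Pt} as
#'   a function of the deviation of male-female distance from \code{D_opt}.
#' @param c0 magnitude of the positional female-decoy interference as a
#'   fraction of \code{P_opt}: a decoy sitting at the female reduces the
#'   mating rate by \code{c0 * P_opt} even at the optimal separation.
#' @param D_opt optimal male-female phenotypic distance for decoy function
#'   (normalized units).
#' @param allele_max size of the allele space; valid allelic values are the
#'   integers \code{0:allele_max}.
#' @param normalize divide phenotypes by \code{allele_max} before distance
#'   computations (the default; all distance-scale parameters assume it).
#'
#' @return An object of class \code{"conflict_params"} (a named list).
#' @seealso [validate_params()] for the feasibility checks,
#'   [decoy_modified_rate()] for the full pair-rate computation.
#' @export
model_params <- function(P_opt = 0.5, B_max = 10, s_w = 0.3, x_w = 2,
                         s_p = 0.1, x_p = 2, si = 0.05, xi = 2,
                         sd = 0.04, xd = 2, c0 = 0.25, D_opt = 0.08,
                         allele_max = 50L, normalize = TRUE) {
  p <- list(P_opt = P_opt, B_max = B_max, s_w = s_w, x_w = x_w,
            s_p = s_p, x_p = x_p, si = si, xi = xi, sd = sd, xd = xd,
            c0 = c0, D_opt = D_opt, allele_max = as.integer(allele_max),
            normalize = isTRUE(normalize))
  class(p) <- "conflict_params"
  check_params_invariants(p)
  p
}

check_params_invariants <- function(p) {
  stopifnot(inherits(p, "conflict_params"))
  if (!(p$P_opt > 0 && p$P_opt < 1))
    stop("P_opt must lie strictly in (0, 1)", call. = FALSE)
  if (p$B_max <= 0) stop("B_max must be positive", call. = FALSE)
  for (nm in c("s_w", "s_p", "si", "sd"))
    if (p[[nm]] <= 0) stop("scale parameter ", nm, " must be positive", call. = FALSE)
  for (nm in c("x_w", "x_p", "xi", "xd"))
    if (p[[nm]] <= 0) stop("exponent parameter ", nm, " must be positive", call. = FALSE)
  if (p$c0 < 0) stop("c0 must be >= 0", call. = FALSE)
  if (p$allele_max < 1) stop("allele_max must be >= 1", call. = FALSE)
  if (p$normalize && (p$D_opt < 0 || p$D_opt > 1))
    stop("D_opt must lie in [0, 1] on the normalized scale", call. = FALSE)
  invisible(p)
}

#' @export
print.conflict_params <- function(x, ...) {
  cat("Sexual-conflict model parameters\n")
  cat(sprintf("  female optimum P_opt = %.3g, fecundity B_max = %.3g (s_w = %.3g, x_w = %.3g)\n",
              x$P_opt, x$B_max, x$s_w, x$x_w))
  cat(sprintf("  baseline rate: exp(-(D/%.3g)^%.3g)\n", x$s_p, x$x_p))
  cat(sprintf("  decoy: D_opt = %.3g, Pt scale/exp = %.3g/%.3g (+%.3g), Pi scale/exp = %.3g/%.3g\n",
              x$D_opt, x$sd, x$xd, x$c0, x$si, x$xi))
  cat(sprintf("  allele space 0..%d, normalized distances: %s\n",
              x$allele_max, if (x$normalize) "yes" else "no"))
  invisible(x)
}

#' Additive phenotype of a diploid genotype
#'
#' Alleles determine the phenotype additively; the phenotype is the
#' arithmetic mean of the two allelic values, placed on the normalized
#' [0, 1] scale when \code{params$normalize} is on.
#'
#' @param allele_a,allele_b allelic values (integers in
#'   \code{0:params$allele_max}); vectorized.
#' @param params a [model_params()] object.
#' @return Numeric phenotypic value(s).
#' @export
phenotype <- function(allele_a, allele_b, params = model_params()) {
  if (any(allele_a < 0 | allele_a > params$allele_max |
          allele_b < 0 | allele_b > params$allele_max))
    stop("allele outside allele space [0, ", params$allele_max, "]",
         call. = FALSE)
  z <- (allele_a + allele_b) / 2
  if (params$normalize) z <- z / params$allele_max
  z
}

#' Baseline mating rate of a male-female pair
#'
#' The mating rate decays with the phenotypic distance \code{D_MF} between
#' the male and female reproductive loci: \code{exp(-(D_MF/s_p)^x_p)}. A
#' zero distance gives rate 1 (the male optimum); the rate is strictly
#' non-increasing in distance.
#'
#' @param D_MF nonnegative phenotypic distance(s), normalized when the
#'   parameter set is.
#' @param params a [model_params()] object.
#' @return Mating rate(s) in [0, 1].
#' @export
baseline_mating_rate <- function(D_MF, params = model_params()) {
  if (any(D_MF < 0)) stop("phenotypic distance must be >= 0", call. = FALSE)
  exp(-(D_MF / params$s_p)^params$x_p)
}

#' Expected offspring of a female given her realized mating rate
#'
#' Female fecundity is maximal (\code{B_max}) at the optimal mating rate
#' \code{P_opt} and decays symmetrically as the realized rate deviates above
#' or below it: \code{B_max * exp(-(|P - P_opt|/s_w)^x_w)}.
#'
#' @param P realized mating rate(s) in [0, 1].
#' @param params a [model_params()] object.
#' @return Expected offspring number(s) in [0, B_max].
#' @export
female_fecundity <- function(P, params = model_params()) {
  if (any(P < 0 | P > 1)) stop("mating rate must lie in [0, 1]", call. = FALSE)
  params$B_max * exp(-(abs(P - params$P_opt) / params$s_w)^params$x_w)
}

#' Is the decoy active for a given male-female-decoy phenotype triple?
#'
#' The decoy influences the mating rate only when its phenotype lies
#' strictly between the male and female phenotypes; ties give 0.
#'
#' @param z_m,z_f,z_d male, female and decoy phenotypes on a common scale;
#'   vectorized.
#' @return Integer 0/1 activity indicator(s) (theta).
#' @export
decoy_active <- function(z_m, z_f, z_d) {
  as.integer(z_d > pmin(z_m, z_f) & z_d < pmax(z_m, z_f))
}

#' Decoy-modified mating rate of a male-female pair
#'
#' When the decoy is inactive (theta = 0) the pair mates at the baseline
#' rate \code{P_MF}. When active, the decoy draws the rate to the female
#' optimum minus two interference terms: \code{P' = clamp(P_opt - Pt - Pi)}.
#' The interference magnitude \code{Pt} grows as the male-female distance
#' deviates from the optimal separation \code{D_opt} and does not depend on
#' where the decoy sits; the positional interference \code{Pi} vanishes as
#' the decoy approaches the male. \code{Pe}, the decoy effectiveness
#' \code{max(0, P_MF - P_opt)}, is reported as a diagnostic.
#'
#' @param z_m,z_f,z_d male, female and decoy phenotypes on a common
#'   (normalized) scale; vectorized.
#' @param params a [model_params()] object.
#' @return A data frame of class \code{"decoy_effect"} with columns
#'   \code{theta}, \code{P_MF}, \code{Pe}, \code{Pi}, \code{Pt} and
#'   \code{P_modified}.
#' @export
decoy_modified_rate <- function(z_m, z_f, z_d, params = model_params()) {
  check_params_invariants(params)
  D <- abs(z_m - z_f)
  P_MF <- baseline_mating_rate(D, params)
  theta <- decoy_active(z_m, z_f, z_d)
  dev <- abs(D - params$D_opt)
  d_MD <- abs(z_d - z_m)
  Pt <- params$P_opt * pmin(1, (dev / params$sd)^params$xd)
  Pi <- params$P_opt * params$c0 * pmin(1, (d_MD / params$si)^params$xi)
  Pt <- ifelse(theta == 1L, Pt, 0)
  Pi <- ifelse(theta == 1L, Pi, 0)
  P_modified <- ifelse(theta == 1L,
                       pmin(1, pmax(0, params$P_opt - Pt - Pi)),
                       P_MF)
  out <- data.frame(theta = theta, P_MF = P_MF,
                    Pe = pmax(0, P_MF - params$P_opt),
                    Pi = Pi, Pt = Pt, P_modified = P_modified)
  class(out) <- c("decoy_effect", "data.frame")
  out
}

# Pt evaluated at a deviation |D_MF - D_opt| (theta taken as 1)
pt_at_deviation <- function(deviation, params) {
  params$P_opt * pmin(1, (deviation / params$sd)^params$xd)
}

#' Validate a parameter set against the decoy feasibility conditions
#'
#' Beyond the structural invariants, a decoy parameterization is only
#' biologically admissible if three conditions hold. (a) The decoy must
#' have a functional band: male-female separations near \code{D_opt}
#' (deviation at most \code{sd/2}) at which the baseline rate still exceeds
#' \code{P_opt} by a working margin of 0.1, so that decoy effectiveness
#' \code{Pe = P_MF - P_opt} is positive where the decoy operates. (b) Over
#' that band, with the decoy in its evolved male-proximal position, an
#' active decoy must leave female fecundity at least as high as at the
#' unmodified rate -- total interference must not exceed effectiveness
#' (the \code{Pi < Pe} check; en route to the male the decoy may hurt
#' transiently, but its working configuration must help). (c) The penalty
#' for deviating from the optimal separation must be strong: \code{Pt} at
#' deviation 0.5 must be at least \code{0.9 * P_opt}, otherwise the decoy
#' would start a runaway chase with the male.
#'
#' @param params a [model_params()] object.
#' @param grid_n number of male-female distances in the feasibility grid.
#' @return \code{params}, invisibly, if all checks pass; otherwise an error
#'   naming the violated condition.
#' @export
validate_params <- function(params, grid_n = 25) {
  check_params_invariants(params)

  if (pt_at_deviation(0.5, params) < 0.9 * params$P_opt)
    stop(sprintf(
      "Pt~P_opt at 0.5 violated: Pt(0.5) = %.4f < 0.9 * P_opt = %.4f",
      pt_at_deviation(0.5, params), 0.9 * params$P_opt), call. = FALSE)

  # chase band: separations where the baseline rate exceeds P_opt + 0.1,
  # intersected with the decoy's tolerated deviation band |D - D_opt| <= sd/2
  margin <- 0.1
  target <- min(params$P_opt + margin, 1 - 1e-9)
  D_max <- params$s_p * (-log(target))^(1 / params$x_p)
  D_lo <- max(params$D_opt - params$sd / 2, D_max / 100)
  if (D_lo >= D_max)
    stop(sprintf(
      paste0("no functional separation band: baseline mating rate at ",
             "D_opt - sd/2 = %.4f is below P_opt + %.2f, so the decoy has ",
             "no separation at which it is effective (Pe <= 0)"),
      D_lo, margin), call. = FALSE)
  D_grid <- seq(D_lo, D_max, length.out = grid_n)
  frac <- seq(0.1, 0.5, by = 0.1)  # evolved decoy position near the male
  for (D in D_grid) {
    d_MD <- frac * min(params$si, D)
    eff <- decoy_modified_rate(0, D, d_MD, params)
    W_mod <- female_fecundity(eff$P_modified, params)
    W_unmod <- female_fecundity(eff$P_MF, params)
    if (any(W_mod < W_unmod - 1e-9)) {
      i <- which.max(W_unmod - W_mod)
      stop(sprintf(
        paste0("Pi<Pe violated: at D_MF = %.4f with the decoy %.4f from ",
               "the male, interference Pt + Pi = %.4f exceeds decoy ",
               "effectiveness Pe = %.4f (female fecundity drops below the ",
               "unmodified rate)"),
        D, d_MD[i], eff$Pt[i] + eff$Pi[i], eff$Pe[i]), call. = FALSE)
    }
  }
  invisible(params)
}
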