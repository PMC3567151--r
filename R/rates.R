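#' Windowed substitution rates from a trajectory
#'
#' Converts per-generation mean allelic values into per-window substitution
#' rates: the absolute change in the mean allelic value over each window of
#' generations (allele units per window), the simulation proxy for
#' branch-specific dN/dS. Signed changes are retained in the
#' \code{"signed"} attribute for diagnostics.
#'
#' @param traj a \code{"trajectory"} (or any data frame with a
#'   \code{generation} column and \code{mean_<locus>} columns).
#' @param window window length in generations; defaults to the trajectory's
#'   own \code{window} attribute.
#' @return A data frame of class \code{"rate_series"} with a \code{window}
#'   index column and one nonnegative rate column per locus; the signed
#'   changes are stored in \code{attr(, "signed")}.
#' @export
substitution_rates <- function(traj, window = NULL) {
  if (is.null(window)) window <- attr(traj, "window")
  if (is.null(window)) stop("window must be supplied", call. = FALSE)
  n_gen <- nrow(traj) - 1L
  if (n_gen < window || n_gen %% window != 0)
    stop("trajectory length - 1 (", n_gen,
         ") is not divisible by the window (", window, ")", call. = FALSE)
  loci <- grep("^mean_(male|female|decoy|neutral)$", names(traj), value = TRUE)
  idx <- seq(1L, n_gen + 1L, by = window)
  signed <- as.data.frame(lapply(traj[loci], function(v) diff(v[idx])))
  names(signed) <- sub("^mean_", "", loci)
  out <- cbind(window = seq_len(nrow(signed)), abs(signed))
  attr(out, "signed") <- signed
  attr(out, "window_length") <- window
  attr(out, "replicate") <- attr(traj, "replicate")
  class(out) <- c("rate_series", "data.frame")
  out
}

#' Linear regression between two rate series
#'
#' Ordinary least squares of \code{y} on \code{x} (weighted least squares
#' when per-point \code{weights} are supplied), with the two-sided t-test of
#' a zero slope -- the same regression applied to branch-specific dN/dS
#' point estimates.
#'
#' @param x,y numeric rate vectors of equal length (at least 3).
#' @param weights optional nonnegative per-point weights.
#' @param weight_description short label recorded with the fit.
#' @return An object of class \code{"rate_regression"}: a list with
#'   \code{slope}, \code{intercept}, \code{r_squared}, \code{p_value},
#'   \code{slope_se}, \code{n}, \code{df}, \code{weighted} and
#'   \code{weight_description}.
#' @export
fit_rate_regression <- function(x, y, weights = NULL,
                                weight_description = if (is.null(weights))
                                  "unweighted" else "user weights") {
  if (length(x) != length(y))
    stop("x and y must have the same length", call. = FALSE)
  if (length(x) < 3)
    stop("at least 3 points are required", call. = FALSE)
  if (!is.null(weights) && (length(weights) != length(x) || any(weights < 0)))
    stop("weights must be nonnegative and match x in length", call. = FALSE)
  if (stats::var(x) == 0)
    stop(structure(class = c("decoysim_degenerate_fit", "error", "condition"),
                   list(message = "zero-variance x: degenerate fit",
                        call = sys.call(-1))))
  fit <- if (is.null(weights)) stats::lm(y ~ x)
         else stats::lm(y ~ x, weights = weights)
  # summary.lm warns on exact fits; those are legitimate inputs here
  sm <- withCallingHandlers(
    summary(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  co <- stats::coef(sm)
  r2 <- sm$r.squared
  p <- if (nrow(co) < 2 || !is.finite(co[2, 4])) NA_real_ else co[2, 4]
  if (stats::var(y) == 0) {        # constant y: no variance to explain
    r2 <- 0
    p <- NA_real_
  }
  if (!is.finite(r2)) r2 <- 0
  se <- if (nrow(co) >= 2 && is.finite(co[2, 2])) co[2, 2] else NA_real_
  out <- list(slope = unname(stats::coef(fit)[2]),
              intercept = unname(stats::coef(fit)[1]),
              r_squared = r2, p_value = p, slope_se = se,
              n = length(x), df = fit$df.residual,
              weighted = !is.null(weights),
              weight_description = weight_description)
  class(out) <- "rate_regression"
  out
}

#' @export
print.rate_regression <- function(x, ...) {
  cat(sprintf("Rate regression (%s, n = %d)\n", x$weight_description, x$n))
  cat(sprintf("  slope = %.4g, intercept = %.4g, r^2 = %.4g, p = %.4g\n",
              x$slope, x$intercept, x$r_squared, x$p_value))
  invisible(x)
}

#' Classify a rate correlation
#'
#' A correlation is called from the regression slope and its significance:
#' \code{"positive"} if \code{p < alpha} and the slope is positive,
#' \code{"negative"} if \code{p < alpha} and the slope is negative,
#' otherwise \code{"none"} (including unavailable p-values from degenerate
#' fits).
#'
#' @param res a [fit_rate_regression()] result.
#' @param alpha significance level (default 0.05).
#' @return One of \code{"positive"}, \code{"negative"}, \code{"none"}.
#' @export
classify_correlation <- function(res, alpha = 0.05) {
  if (!is.finite(res$p_value) || res$p_value >= alpha) return("none")
  if (res$slope > 0) "positive" else if (res$slope < 0) "negative" else "none"
}

.locus_pairs <- c("male-female", "male-decoy", "male-neutral",
                  "female-decoy", "female-neutral", "decoy-neutral")

#' Per-replicate rate regressions for all locus pairs
#'
#' Computes windowed substitution rates for one trajectory and fits the
#' rate regression for every locus pair, classifying each at level
#' \code{alpha}. Degenerate fits (a rate series with zero variance) are
#' reported as classification \code{"none"} with an \code{NA} slope rather
#' than as errors.
#'
#' @param traj a \code{"trajectory"}.
#' @param window rate window in generations (defaults to the trajectory's).
#' @param alpha significance level for classification.
#' @return A data frame with one row per locus pair: \code{replicate},
#'   \code{pair}, \code{slope}, \code{r_squared}, \code{p_value},
#'   \code{classification}.
#' @export
analyze_trajectory <- function(traj, window = NULL, alpha = 0.05) {
  rates <- substitution_rates(traj, window)
  rep_id <- attr(rates, "replicate")
  if (is.null(rep_id)) rep_id <- NA_integer_
  rows <- lapply(.locus_pairs, function(pair) {
    g <- strsplit(pair, "-", fixed = TRUE)[[1]]
    res <- tryCatch(fit_rate_regression(rates[[g[1]]], rates[[g[2]]]),
                    decoysim_degenerate_fit = function(e) NULL)
    if (is.null(res))
      data.frame(replicate = rep_id, pair = pair, slope = NA_real_,
                 r_squared = NA_real_, p_value = NA_real_,
                 classification = "none")
    else
      data.frame(replicate = rep_id, pair = pair, slope = res$slope,
                 r_squared = res$r_squared, p_value = res$p_value,
                 classification = classify_correlation(res, alpha))
  })
  do.call(rbind, rows)
}

#' Summarize correlation classifications across replicates
#'
#' Counts, for each locus pair, how many replicates were classified
#' positive, negative or none, and tests the decoy-vs-control contrast with
#' Fisher's exact test on a configurable 2x2 table: by default
#' \code{[significant, not significant]} rows for the \code{pair_a}
#' (male-decoy) vs \code{pair_b} (male-neutral) pairs, where "significant"
#' means a negative classification (the anti-correlation the decoy model
#' predicts).
#'
#' @param classifications a data frame as returned by rbinding
#'   [analyze_trajectory()] over replicates.
#' @param pair_a,pair_b the two locus pairs contrasted in the Fisher table.
#' @param significant character vector of classifications counted as
#'   "significant" in the table (default \code{"negative"}).
#' @return An object of class \code{"replicate_summary"}: counts (pair x
#'   classification), the number of replicates, the 2x2 Fisher table and
#'   its one- and two-sided p-values.
#' @export
summarize_replicates <- function(classifications,
                                 pair_a = "male-decoy",
                                 pair_b = "male-neutral",
                                 significant = "negative") {
  cls <- factor(classifications$classification,
                levels = c("positive", "negative", "none"))
  counts <- table(pair = classifications$pair, classification = cls)
  n_rep <- length(unique(classifications$replicate))
  sig_a <- sum(classifications$pair == pair_a & cls %in% significant)
  sig_b <- sum(classifications$pair == pair_b & cls %in% significant)
  tot_a <- sum(classifications$pair == pair_a)
  tot_b <- sum(classifications$pair == pair_b)
  tab <- matrix(c(sig_a, tot_a - sig_a, sig_b, tot_b - sig_b),
                nrow = 2, byrow = TRUE,
                dimnames = list(pair = c(pair_a, pair_b),
                                c("significant", "not significant")))
  out <- list(counts = counts, n_replicates = n_rep, fisher_table = tab,
              fisher_p_one_sided = fisher_exact_2x2(tab, "greater"),
              fisher_p_two_sided = fisher_exact_2x2(tab, "two.sided"),
              significant = significant)
  class(out) <- "replicate_summary"
  out
}

#' @export
print.replicate_summary <- function(x, ...) {
  cat(sprintf("Replicate summary (%d replicates)\n", x$n_replicates))
  print(x$counts)
  cat(sprintf("Fisher's exact test (%s vs %s, '%s' classifications):\n",
              rownames(x$fisher_table)[1], rownames(x$fisher_table)[2],
              paste(x$significant, collapse = "/")))
  cat(sprintf("  one-sided p = %.4g, two-sided p = %.4g\n",
              x$fisher_p_one_sided, x$fisher_p_two_sided))
  invisible(x)
}

#' Fisher's exact test for a 2x2 table
#'
#' Exact hypergeometric test of association in a 2x2 contingency table,
#' computed by direct enumeration of the table's support at fixed margins:
#' the one-sided p-value sums the tail of tables with a first cell at least
#' ("greater") or at most ("less") as large as observed, and the two-sided
#' p-value sums all tables whose conditional probability does not exceed
#' that of the observed table.
#'
#' @param table a 2x2 matrix of nonnegative integer counts.
#' @param sidedness \code{"two.sided"} (default), \code{"greater"} or
#'   \code{"less"} (tail of the [1,1] cell).
#' @return The exact p-value.
#' @export
fisher_exact_2x2 <- function(table,
                             sidedness = c("two.sided", "greater", "less")) {
  sidedness <- match.arg(sidedness)
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2)))
    stop("table must be 2x2", call. = FALSE)
  if (any(table < 0) || any(table != round(table)))
    stop("table entries must be nonnegative integers", call. = FALSE)
  a <- table[1, 1]
  r1 <- sum(table[1, ]); r2 <- sum(table[2, ]); c1 <- sum(table[, 1])
  if (r1 == 0 || r2 == 0 || c1 == 0 || c1 == r1 + r2) return(1)
  support <- max(0, c1 - r2):min(r1, c1)
  dens <- stats::dhyper(support, r1, r2, c1)
  switch(sidedness,
         greater = sum(dens[support >= a]),
         less = sum(dens[support <= a]),
         two.sided = {
           d_obs <- stats::dhyper(a, r1, r2, c1)
           sum(dens[dens <= d_obs * (1 + 1e-7)])
         })
}
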