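#' Read a branch-rate table
#'
#' Reads a tab-separated table of branch-specific evolutionary rates as
#' produced from codon branch-model output: one row per phylogenetic branch
#' with a \code{branch} identifier, the \code{length} of the branch
#' (substitutions per codon) and one column of omega (dN/dS) point estimates
#' per gene. Estimating omega itself is upstream of this package.
#'
#' @param path path to a tab-separated file with a header row.
#' @return A data frame of class \code{"branch_rate_table"}; the gene column
#'   names are stored in \code{attr(, "genes")}.
#' @export
read_branch_rates <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  as_branch_rate_table(tab, source = path)
}

# validate and class a raw data frame of branch rates
as_branch_rate_table <- function(tab, source = "branch-rate table") {
  for (col in c("branch", "length"))
    if (!col %in% names(tab))
      stop("format error in ", source, ": missing column '", col, "'",
           call. = FALSE)
  genes <- setdiff(names(tab), c("branch", "length"))
  if (length(genes) < 1)
    stop("format error in ", source, ": no gene columns", call. = FALSE)
  for (col in c("length", genes)) {
    v <- tab[[col]]
    if (!is.numeric(v) || anyNA(v))
      stop("value error in ", source, ": column '", col,
           "' must be numeric with no missing values (undefined omega must ",
           "be resolved upstream)", call. = FALSE)
    bad <- which(if (col == "length") v <= 0 else v < 0)
    if (length(bad))
      stop("value error in ", source, ": column '", col, "' row ", bad[1],
           if (col == "length") " must be > 0" else " must be >= 0",
           call. = FALSE)
  }
  attr(tab, "genes") <- genes
  class(tab) <- c("branch_rate_table", "data.frame")
  tab
}

#' Write a branch-rate table
#'
#' @param table a \code{"branch_rate_table"}.
#' @param path output path (tab-separated, with header).
#' @return \code{path}, invisibly.
#' @export
write_branch_rates <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Regression of branch-specific rates between two genes
#'
#' Fits the linear regression of gene_y's per-branch omega on gene_x's,
#' either unweighted or weighted by the length of the respective branch
#' (weights proportional to branch length, no normalization).
#'
#' @param table a \code{"branch_rate_table"}.
#' @param gene_x,gene_y gene column names.
#' @param weighted weight each branch by its length.
#' @return A \code{"rate_regression"} (see [fit_rate_regression()]).
#' @export
branch_rate_regression <- function(table, gene_x, gene_y, weighted = FALSE) {
  for (g in c(gene_x, gene_y))
    if (!g %in% names(table))
      stop("gene '", g, "' not present in the branch-rate table",
           call. = FALSE)
  fit_rate_regression(table[[gene_x]], table[[gene_y]],
                      weights = if (weighted) table$length,
                      weight_description = if (weighted) "branch length"
                                           else "unweighted")
}

#' Simulate a branch-rate table
#'
#' Generates a reproducible branch-rate fixture with a configurable linear
#' relationship: gene_x omegas are drawn nonnegative (gamma, mean 1.5),
#' gene_y = max(0, intercept + slope * gene_x + Gaussian noise), and branch
#' lengths come from \code{length_distribution} (default gamma with mean
#' 0.1 substitutions per codon). This emulates the shape of codon
#' branch-model output so the correlation machinery can be exercised without
#' external likelihood software.
#'
#' @param n_branches number of branches (>= 3).
#' @param slope,intercept generating linear relationship.
#' @param noise_sd standard deviation of the Gaussian noise on gene_y.
#' @param length_distribution function of n returning n positive branch
#'   lengths.
#' @param seed integer seed; the global RNG state is left untouched.
#' @return A \code{"branch_rate_table"} with genes \code{gene_x} and
#'   \code{gene_y}.
#' @export
simulate_branch_rates <- function(n_branches, slope, intercept = 0.5,
                                  noise_sd = 0.1,
                                  length_distribution = function(n)
                                    stats::rgamma(n, shape = 2, rate = 20),
                                  seed = 1L) {
  if (n_branches < 3) stop("n_branches must be >= 3", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  x <- stats::rgamma(n_branches, shape = 2, scale = 0.75)
  y <- pmax(0, intercept + slope * x + stats::rnorm(n_branches, 0, noise_sd))
  len <- length_distribution(n_branches)
  if (any(len <= 0)) stop("length_distribution returned non-positive lengths",
                          call. = FALSE)
  tab <- data.frame(branch = paste0("b", seq_len(n_branches)),
                    length = len, gene_x = x, gene_y = y)
  as_branch_rate_table(tab, source = "simulated table")
}
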