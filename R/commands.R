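#' Run the full replicated simulation study
#'
#' End-to-end orchestration: parses the control file (or takes the
#' defaults), runs all replicates, writes one trajectory file per replicate
#' plus a combined file, the per-replicate rate regressions and the
#' replicate summary, and a run manifest recording the configuration echo,
#' the base seed and per-replicate streams, the package version and the
#' output inventory -- enough to re-execute any single replicate.
#'
#' @param config_path optional ctl-style configuration file (see
#'   [parse_config()]).
#' @param out_dir output directory (created if needed; must be writable).
#' @param seed,replicates optional overrides of the configured base seed
#'   and replicate count.
#' @param alpha significance level used in the analysis step.
#' @param decoy logical; disable to run the two-locus model without the
#'   decoy term.
#' @param quiet suppress progress messages.
#' @return The manifest, invisibly (a named list, also written to
#'   \code{manifest.txt}).
#' @export
command_run <- function(config_path = NULL, out_dir, seed = NULL,
                        replicates = NULL, alpha = 0.05, decoy = TRUE,
                        quiet = FALSE) {
  cp <- parse_config(config_path)
  config <- cp$config
  params <- cp$params
  if (!is.null(seed)) config$seed <- as.integer(seed)
  if (!is.null(replicates)) config$n_replicates <- as.integer(replicates)

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  probe <- file.path(out_dir, ".write_probe")
  ok <- tryCatch({ writeLines("x", probe); TRUE },
                 error = function(e) FALSE, warning = function(e) FALSE)
  if (!ok) stop("output directory is not writable: ", out_dir, call. = FALSE)
  unlink(probe)

  trajs <- run_replicates(config, params, decoy = decoy)
  files <- character(0)
  for (traj in trajs) {
    k <- attr(traj, "replicate")
    f <- file.path(out_dir, sprintf("trajectory_%02d.tsv", k))
    write_trajectory(traj, f)
    files <- c(files, f)
    if (!quiet) message("replicate ", k, " written to ", f)
  }
  combined <- do.call(rbind, lapply(trajs, function(t) {
    t$replicate <- attr(t, "replicate"); t$seed <- attr(t, "seed"); t
  }))
  f_comb <- file.path(out_dir, "trajectories.tsv")
  utils::write.table(combined, f_comb, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files <- c(files, f_comb)

  summary_files <- write_analysis(trajs, out_dir, window = config$window,
                                  alpha = alpha)
  files <- c(files, summary_files)

  manifest <- c(
    list(tool = "decoysim", version = as.character(utils::packageVersion("decoysim")),
         date = format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z"),
         base_seed = config$seed,
         replicate_streams = seq_len(config$n_replicates),
         failed_replicates = if (length(attr(trajs, "failed")))
           names(attr(trajs, "failed")) else "none",
         decoy_enabled = decoy, alpha = alpha,
         N = config$N, generations = config$generations,
         n_encounters = config$n_encounters, mu = config$mu,
         window = config$window, replicates = config$n_replicates,
         init_male = config$initial_alleles[["male"]],
         init_female = config$initial_alleles[["female"]],
         init_decoy = config$initial_alleles[["decoy"]],
         init_neutral = config$initial_alleles[["neutral"]]),
    unclass(params)[c("P_opt", "B_max", "s_w", "x_w", "s_p", "x_p",
                      "si", "xi", "sd", "xd", "c0", "D_opt",
                      "allele_max", "normalize")],
    list(files = basename(files)))
  write_keyvalue(manifest, file.path(out_dir, "manifest.txt"))
  if (length(attr(trajs, "failed")))
    warning(length(attr(trajs, "failed")), " replicate(s) failed; see manifest",
            call. = FALSE)
  invisible(manifest)
}

# shared analysis writer used by command_run and command_analyze
write_analysis <- function(trajs, out_dir, window, alpha) {
  cls <- do.call(rbind, lapply(trajs, analyze_trajectory,
                               window = window, alpha = alpha))
  f_cls <- file.path(out_dir, "classifications.tsv")
  utils::write.table(cls, f_cls, sep = "\t", quote = FALSE, row.names = FALSE)

  rates <- do.call(rbind, lapply(trajs, function(t) {
    r <- substitution_rates(t, window)
    r$replicate <- attr(r, "replicate")
    r
  }))
  f_rates <- file.path(out_dir, "rates.tsv")
  utils::write.table(rates, f_rates, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  smr <- summarize_replicates(cls)
  rep_counts <- as.data.frame.matrix(smr$counts)
  f_sum <- file.path(out_dir, "summary.txt")
  kv <- list(replicates = smr$n_replicates, alpha = alpha, window = window)
  for (p in rownames(rep_counts))
    kv[[gsub("-", "_", p)]] <- sprintf("positive=%d negative=%d none=%d",
                                       rep_counts[p, "positive"],
                                       rep_counts[p, "negative"],
                                       rep_counts[p, "none"])
  kv$fisher_table <- as.vector(t(smr$fisher_table))
  kv$fisher_p_one_sided <- smr$fisher_p_one_sided
  kv$fisher_p_two_sided <- smr$fisher_p_two_sided
  write_keyvalue(kv, f_sum)
  c(f_cls, f_rates, f_sum)
}

#' Analyze existing trajectory files
#'
#' Reads trajectory files (or every \code{trajectory_*.tsv} in a
#' directory), computes windowed substitution rates, fits the rate
#' regression for every locus pair in every replicate, classifies the
#' correlations and summarizes the counts with Fisher's exact test.
#'
#' @param paths trajectory file paths, or a single directory.
#' @param alpha significance level.
#' @param window rate window in generations.
#' @param out_dir optional directory for the rate table, classification
#'   table and summary report.
#' @return A \code{"replicate_summary"}; the per-replicate classification
#'   table is attached as \code{attr(, "classifications")}.
#' @export
command_analyze <- function(paths, alpha = 0.05, window = 500L,
                            out_dir = NULL) {
  if (length(paths) == 1 && dir.exists(paths))
    paths <- list.files(paths, pattern = "^trajectory_.*\\.tsv$",
                        full.names = TRUE)
  if (length(paths) < 1) stop("no trajectory files found", call. = FALSE)
  trajs <- lapply(paths, read_trajectory, window = window)
  cls <- do.call(rbind, lapply(trajs, analyze_trajectory,
                               window = window, alpha = alpha))
  smr <- summarize_replicates(cls)
  attr(smr, "classifications") <- cls
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_analysis(trajs, out_dir, window = window, alpha = alpha)
  }
  smr
}

#' Branch-rate correlation report
#'
#' Reads a branch-rate table and reports both the unweighted and the
#' branch-length-weighted regression of gene_y's omega on gene_x's.
#'
#' @param path path to a tab-separated branch-rate table.
#' @param gene_x,gene_y gene column names.
#' @param out optional path for a key=value report.
#' @return A list with elements \code{unweighted} and \code{weighted}
#'   (\code{"rate_regression"} objects).
#' @export
command_branchcorr <- function(path, gene_x, gene_y, out = NULL) {
  tab <- read_branch_rates(path)
  res <- list(unweighted = branch_rate_regression(tab, gene_x, gene_y,
                                                  weighted = FALSE),
              weighted = branch_rate_regression(tab, gene_x, gene_y,
                                                weighted = TRUE))
  if (!is.null(out)) {
    kv <- list(table = path, gene_x = gene_x, gene_y = gene_y,
               n_branches = res$unweighted$n)
    for (w in names(res)) {
      kv[[paste0(w, "_slope")]] <- res[[w]]$slope
      kv[[paste0(w, "_intercept")]] <- res[[w]]$intercept
      kv[[paste0(w, "_r_squared")]] <- res[[w]]$r_squared
      kv[[paste0(w, "_p_value")]] <- res[[w]]$p_value
    }
    write_keyvalue(kv, out)
  }
  res
}
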