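#' Parse a ctl-style configuration file
#'
#' Reads a control file in the simple "key = value" dialect (one pair per
#' line, \code{#} starts a comment, keys are case-sensitive) covering both
#' simulation settings and model parameters. Omitted keys take the
#' published defaults (N = 10000, generations = 15000, n_encounters = 20,
#' mu = 5e-5, window = 500, replicates = 20, initial alleles 0/5/16/30);
#' unknown keys are rejected. The resulting parameter set must pass
#' [validate_params()].
#'
#' @param path path to the control file; \code{NULL} yields the full
#'   default configuration.
#' @return A list with elements \code{config} (a [sim_config()]) and
#'   \code{params} (a validated [model_params()]).
#' @export
parse_config <- function(path = NULL) {
  sim_keys <- c("N", "generations", "n_encounters", "mu", "window",
                "replicates", "seed", "init_male", "init_female",
                "init_decoy", "init_neutral")
  par_keys <- c("P_opt", "B_max", "s_w", "x_w", "s_p", "x_p", "si", "xi",
                "sd", "xd", "c0", "D_opt", "allele_max", "normalize")
  vals <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    lines <- readLines(path, warn = FALSE)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    for (ln in lines) {
      if (!grepl("=", ln, fixed = TRUE))
        stop("configuration error: line without 'key = value': '", ln, "'",
             call. = FALSE)
      key <- trimws(sub("=.*$", "", ln))
      val <- trimws(sub("^[^=]*=", "", ln))
      if (!key %in% c(sim_keys, par_keys))
        stop("configuration error: unknown key ", key, call. = FALSE)
      num <- suppressWarnings(as.numeric(val))
      if (is.na(num)) {
        if (key == "normalize" && tolower(val) %in% c("true", "false"))
          num <- as.numeric(tolower(val) == "true")
        else
          stop("configuration error: non-numeric value for key ", key,
               call. = FALSE)
      }
      vals[[key]] <- num
    }
  }
  pick <- function(key, default) if (!is.null(vals[[key]])) vals[[key]] else default
  config <- sim_config(
    N = pick("N", 10000), generations = pick("generations", 15000),
    n_encounters = pick("n_encounters", 20), mu = pick("mu", 5e-5),
    initial_alleles = c(male = as.integer(pick("init_male", 0)),
                        female = as.integer(pick("init_female", 5)),
                        decoy = as.integer(pick("init_decoy", 16)),
                        neutral = as.integer(pick("init_neutral", 30))),
    seed = pick("seed", 1), n_replicates = pick("replicates", 20),
    window = pick("window", 500))
  params <- model_params(
    P_opt = pick("P_opt", 0.5), B_max = pick("B_max", 10),
    s_w = pick("s_w", 0.3), x_w = pick("x_w", 2),
    s_p = pick("s_p", 0.1), x_p = pick("x_p", 2),
    si = pick("si", 0.05), xi = pick("xi", 2),
    sd = pick("sd", 0.04), xd = pick("xd", 2),
    c0 = pick("c0", 0.25), D_opt = pick("D_opt", 0.08),
    allele_max = pick("allele_max", 50),
    normalize = pick("normalize", 1) != 0)
  validate_params(params)
  list(config = config, params = params)
}

#' Write a trajectory to a tab-separated file
#'
#' Columns: generation, mean_male, mean_female, mean_decoy, mean_neutral,
#' mean_mating, replicate, seed.
#'
#' @param traj a \code{"trajectory"}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  out <- traj
  out$replicate <- attr(traj, "replicate")
  out$seed <- attr(traj, "seed")
  utils::write.table(format(out, digits = 15, scientific = FALSE,
                            trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a trajectory written by [write_trajectory()]
#'
#' @param path path to a tab-separated trajectory file.
#' @param window rate window to attach (optional).
#' @return A \code{"trajectory"} data frame.
#' @export
read_trajectory <- function(path, window = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("generation", "mean_male", "mean_female", "mean_decoy",
            "mean_neutral")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("format error in ", path, ": missing column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  for (col in need) {
    if (!is.numeric(tab[[col]]) || anyNA(tab[[col]])) {
      bad <- which(!is.finite(suppressWarnings(as.numeric(tab[[col]]))))[1]
      stop("format error in ", path, ": non-numeric value in column '",
           col, "', line ", bad + 1L, call. = FALSE)
    }
  }
  attr(tab, "replicate") <- if ("replicate" %in% names(tab))
    tab$replicate[1] else NA_integer_
  attr(tab, "seed") <- if ("seed" %in% names(tab)) tab$seed[1] else NA_integer_
  tab$replicate <- NULL
  tab$seed <- NULL
  attr(tab, "window") <- window
  class(tab) <- c("trajectory", "data.frame")
  tab
}

# write a named list as "key = value" lines
write_keyvalue <- function(x, path) {
  lines <- vapply(names(x), function(k)
    paste0(k, " = ", paste(format(x[[k]], digits = 15), collapse = " ")),
    character(1))
  writeLines(lines, path)
  invisible(path)
}
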