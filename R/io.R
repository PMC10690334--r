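#' Read a trial table
#'
#' Reads the package's CSV trial dialect: comma-separated, UTF-8, header
#' required, columns `subject`, `test`, `group`, `session`, `global_trial`,
#' `contrast`, `response`, `staircase_id` (the last may be absent). Rows
#' violating the record invariants (non-binary response, contrast outside
#' (0, 1], non-positive trial numbers) are rejected with row-numbered
#' messages.
#'
#' @param path Path to a CSV file.
#' @return A validated trial data frame.
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("subject", "test", "group", "session", "global_trial",
                "contrast", "response")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (!"staircase_id" %in% names(df)) df$staircase_id <- 1L
  if (nrow(df) == 0L) return(df)
  bad <- function(cond, what) {
    if (any(cond)) {
      stop("invalid ", what, " in row(s) ",
           paste(utils::head(which(cond), 5), collapse = ", "),
           if (sum(cond) > 5) " ..." else "")
    }
  }
  bad(!df$response %in% c(0L, 1L), "response (must be 0 or 1)")
  bad(!is.finite(df$contrast) | df$contrast <= 0 | df$contrast > 1,
      "contrast (must be in (0, 1])")
  bad(!is.finite(df$global_trial) | df$global_trial < 1, "global_trial")
  bad(!is.finite(df$session) | df$session < 1, "session")
  df
}

#' Write a trial table
#'
#' @param trials Trial data frame.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_trials <- function(trials, path) {
  utils::write.csv(trials, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize posterior samples
#'
#' Writes an `mcff_posterior` as a pair of files: `<prefix>_draws.csv`, a
#' columnar table with one row per chain x sample and one labeled column per
#' parameter, and `<prefix>_meta.json` with the model tag, subject/test ids,
#' convergence diagnostics and the sampler schedule (provenance: seed and
#' schedule travel with the draws).
#'
#' @param posterior An `mcff_posterior`.
#' @param prefix Output path prefix.
#' @return The prefix, invisibly.
#' @export
write_posterior <- function(posterior, prefix) {
  stopifnot(inherits(posterior, "mcff_posterior"))
  d <- posterior$draws
  nc <- dim(d)[1]; ns <- dim(d)[2]
  flat <- matrix(aperm(d, c(2, 1, 3)), nc * ns, dim(d)[3])
  tab <- data.frame(chain = rep(seq_len(nc), each = ns),
                    sample = rep(seq_len(ns), nc))
  tab <- cbind(tab, as.data.frame(flat))
  names(tab) <- c("chain", "sample", dimnames(d)[[3]])
  # parameter labels contain commas; the header must stay quoted
  utils::write.csv(tab, paste0(prefix, "_draws.csv"), row.names = FALSE)
  meta <- list(model = posterior$model, K = posterior$K,
               subjects = posterior$subjects, tests = posterior$tests,
               n_chains = nc, kept_samples = ns,
               convergence = as.list(posterior$convergence),
               converged = posterior$converged,
               beta_fixed = posterior$beta_fixed,
               config = posterior$config[c("model", "n_chains", "kept_samples",
                                           "thin", "burn_in", "adaptation",
                                           "convergence_threshold", "seed")])
  jsonlite::write_json(meta, paste0(prefix, "_meta.json"), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(prefix)
}

#' Read serialized posterior samples
#'
#' Lossless counterpart of [write_posterior()].
#'
#' @param prefix Path prefix used when writing.
#' @param model Optional expected model tag (`"bip"`, `"hbmv"`, `"hbmc"`); a
#'   mismatch raises a schema error.
#' @return An `mcff_posterior`.
#' @export
read_posterior <- function(prefix, model = NULL) {
  draws_path <- paste0(prefix, "_draws.csv")
  meta_path <- paste0(prefix, "_meta.json")
  if (!file.exists(draws_path) || !file.exists(meta_path)) {
    stop("no posterior at prefix ", prefix)
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (!is.null(model) && !identical(meta$model, model)) {
    stop("schema mismatch: stored posterior is '", meta$model,
         "', requested '", model, "'")
  }
  tab <- utils::read.csv(draws_path, check.names = FALSE)
  labels <- setdiff(names(tab), c("chain", "sample"))
  nc <- meta$n_chains; ns <- meta$kept_samples
  if (nrow(tab) != nc * ns) stop("schema mismatch: draw table size")
  draws <- array(NA_real_, c(nc, ns, length(labels)),
                 dimnames = list(NULL, NULL, labels))
  m <- as.matrix(tab[, labels, drop = FALSE])
  for (c in seq_len(nc)) draws[c, , ] <- m[tab$chain == c, , drop = FALSE]
  conv <- unlist(meta$convergence)
  cfg <- meta$config
  config <- sampler_config(cfg$model, cfg$n_chains, cfg$kept_samples,
                           cfg$thin, cfg$burn_in, cfg$adaptation,
                           cfg$convergence_threshold, cfg$seed)
  structure(list(model = meta$model, K = meta$K, draws = draws,
                 subjects = meta$subjects, tests = meta$tests,
                 convergence = conv,
                 converged = if (is.null(meta$converged)) NA else meta$converged,
                 config = config, beta_fixed = meta$beta_fixed),
            class = "mcff_posterior")
}

#' Read a flat key-value configuration file
#'
#' Lines of the form `key = value` (or `key: value`); blank lines and lines
#' starting with `#` are ignored. Comma-separated values become vectors;
#' numeric-looking values are converted.
#'
#' @param path Path to the config file.
#' @return Named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([^=:]+)[=:](.*)$", ln))[[1]]
    if (length(m) != 3) stop("cannot parse config line: ", ln)
    key <- trimws(m[2])
    vals <- trimws(strsplit(m[3], ",")[[1]])
    num <- suppressWarnings(as.numeric(vals))
    out[[key]] <- if (!any(is.na(num))) num else vals
  }
  out
}

#' Write a flat key-value configuration file
#'
#' @param config Named list of scalars or vectors.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_config <- function(config, path) {
  lines <- vapply(names(config), function(k)
    paste0(k, " = ", paste(config[[k]], collapse = ", ")), "")
  writeLines(lines, path)
  invisible(path)
}
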