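# File I/O: covariate tables, assignment CSVs, study configs, manifests.

#' Read a covariate table
#'
#' Reads a delimited text file of numeric covariates, one row per unit.
#' Unit indices are taken from row order (0-based in files written by this
#' package). Blank trailing lines are ignored; any non-numeric or missing
#' cell is a parse error naming its position.
#'
#' @param path File path.
#' @param delimiter Field delimiter, `","` (default) or e.g. `"\t"`.
#' @param header Does the first line hold column names?
#' @return Numeric matrix with column names when a header is present.
#' @export
read_covariates <- function(path, delimiter = ",", header = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- tryCatch(
    read.table(path, sep = delimiter, header = header,
               colClasses = "character", blank.lines.skip = TRUE,
               strip.white = TRUE, check.names = FALSE),
    error = function(e) stop("cannot parse ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  if (nrow(df) == 0L || ncol(df) == 0L) {
    stop("empty covariate file: ", path, call. = FALSE)
  }
  M <- matrix(NA_real_, nrow(df), ncol(df),
              dimnames = list(NULL, if (header) colnames(df) else NULL))
  for (j in seq_len(ncol(df))) {
    v <- suppressWarnings(as.numeric(df[[j]]))
    bad <- which(is.na(v))
    if (length(bad) > 0L) {
      stop(sprintf("non-numeric cell at row %d, column %d ('%s') of %s",
                   bad[1L], j, df[bad[1L], j], path), call. = FALSE)
    }
    M[, j] <- v
  }
  as_covariate_matrix(M)
}

#' Write / read an assignment CSV
#'
#' The assignment format has two columns: `unit_index` (0-based, row order
#' of the covariate file) and `treatment` (0/1). A JSON run manifest is
#' written alongside as `<path>.manifest.json` when supplied.
#'
#' @param path CSV path.
#' @param treatment 0/1 vector.
#' @param manifest Optional [run_manifest()].
#' @return `path` invisibly (write); integer 0/1 vector (read).
#' @export
write_assignment <- function(path, treatment, manifest = NULL) {
  treatment <- check_assignment(treatment)
  df <- data.frame(unit_index = seq_along(treatment) - 1L,
                   treatment = treatment)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (!is.null(manifest)) {
    jsonlite::write_json(unclass(manifest), paste0(path, ".manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}

#' @rdname write_assignment
#' @export
read_assignment <- function(path) {
  df <- read.table(path, sep = ",", header = TRUE)
  if (!all(c("unit_index", "treatment") %in% names(df))) {
    stop("assignment file needs columns unit_index, treatment", call. = FALSE)
  }
  df <- df[order(df$unit_index), , drop = FALSE]
  check_assignment(df$treatment)
}

#' Run manifest
#'
#' Provenance record written next to result files: the command, a hash of
#' the configuration, the seeds in play, the package version and a
#' timestamp.
#'
#' @param command Character label of the operation.
#' @param config Any serializable configuration object.
#' @param seed Integer seed(s) used.
#' @return A list of class `run_manifest`.
#' @export
run_manifest <- function(command, config = NULL, seed = NULL) {
  cfg_json <- jsonlite::toJSON(strip_functions(config), auto_unbox = TRUE,
                               digits = NA, null = "null", force = TRUE)
  tf <- tempfile()
  writeLines(as.character(cfg_json), tf)
  h <- unname(tools::md5sum(tf))
  unlink(tf)
  structure(list(command = command,
                 config_hash = h,
                 seeds = seed,
                 package = "modexp",
                 version = as.character(packageVersion("modexp")),
                 timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
            class = "run_manifest")
}

# manifests hash only the data in a config; closures are represented by
# their deparsed source
strip_functions <- function(x) {
  if (is.function(x)) return(paste(deparse(x), collapse = "\n"))
  if (is.list(x)) return(lapply(x, strip_functions))
  x
}

#' Read a study configuration from YAML or JSON
#'
#' The file mirrors [sim_config()]: scalar fields `n`, `p`, `law`, `model`,
#' `replications`, `seed`, `redraw_covariates`, and a `designs` mapping of
#' label to fields of [design_spec()] (`name`, `kernel` as `"energy"` or
#' `"centered_l2"`, `acceptance`, `M`, `n_quantile_draws`).
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return A [sim_config()].
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  # YAML 1.1 reads a bare `n:` mapping key as the boolean FALSE; undo that
  if (is.null(raw$n) && !is.null(raw[["FALSE"]])) {
    names(raw)[names(raw) == "FALSE"] <- "n"
  }
  designs <- lapply(raw$designs %||% list(cre = list(name = "cre")),
                    function(d) {
    kern <- switch(d$kernel %||% "energy",
                   energy = energy_kernel(),
                   `centered-l2` = ,
                   centered_l2 = centered_l2_kernel(),
                   stop("unknown kernel in config: ", d$kernel, call. = FALSE))
    design_spec(name = d$name, kernel = kern,
                acceptance = d$acceptance,
                M = d$M %||% 500L,
                n_quantile_draws = d$n_quantile_draws %||% 1000L)
  })
  sim_config(n = raw$n, p = raw$p, law = raw$law %||% "uniform",
             model = raw$model %||% "C1", designs = designs,
             replications = raw$replications %||% 1000L,
             seed = raw$seed %||% 1L,
             redraw_covariates = raw$redraw_covariates %||% TRUE)
}
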