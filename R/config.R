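#' Default run configuration
#'
#' One flat list of every tunable threshold used across the pipeline, with
#' the conventional defaults: `min_codons` 50, `max_overlap` 75 bp,
#' promoter `window` 200 bp, variant `min_freq` 0.10, species `demarcation`
#' 0.050 substitutions/site, hr unit window 40-80 bp, no gamma correction.
#'
#' @return Named list of defaults.
#' @export
default_config <- function() {
  list(
    min_codons = 50L,
    max_overlap = 75L,
    window = 200L,
    min_freq = 0.10,
    demarcation = 0.050,
    unit_min = 40L,
    unit_max = 80L,
    min_units = 2L,
    max_units = 6L,
    max_unit_divergence = 0.25,
    cluster_gap = 250L,
    seed_k = 12L,
    min_arm = 3L,
    max_mismatch = 2L,
    gamma = NA_real_,
    kappa = 2,
    bootstrap = 100L,
    seed = 1L
  )
}

#' Read a flat key=value run configuration file
#'
#' Lines of the form `key = value` (or `key=value`); `#` comments and blank
#' lines ignored. Unknown keys are rejected; values are coerced to the type
#' of the corresponding default. Missing keys take their defaults.
#'
#' @param path Path to the config file, or `NULL` for pure defaults.
#' @return Named list (the full configuration).
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) {
    abort_npv(paste0("input not found: ", path), "input_not_found")
  }
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) {
      abort_npv(paste0("malformed config line: ", ln), "bad_config")
    }
    key <- trimws(kv[1]); val <- trimws(kv[2])
    if (!key %in% names(cfg)) {
      abort_npv(paste0("unknown config key: ", key), "unknown_key")
    }
    cfg[[key]] <- if (is.integer(cfg[[key]])) as.integer(val)
      else if (is.numeric(cfg[[key]])) as.numeric(val)
      else val
  }
  cfg
}

#' Write a machine-readable run manifest
#'
#' Records the package version, the subcommand, the full configuration (every
#' threshold echoed), and md5 checksums of the input files, as JSON.
#'
#' @param path Output path for the manifest.
#' @param subcommand Name of the operation run.
#' @param config Configuration list used.
#' @param inputs Character vector of input file paths (checksummed).
#' @param outputs Character vector of output paths produced.
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(path, subcommand, config, inputs = character(0),
                           outputs = character(0)) {
  manifest <- list(
    tool = "npvanno",
    version = as.character(utils::packageVersion("npvanno")),
    subcommand = subcommand,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config,
    inputs = lapply(inputs, function(p) {
      list(path = p, md5 = unname(tools::md5sum(p)))
    }),
    outputs = as.list(outputs)
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(manifest)
}
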