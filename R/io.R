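#' Load a merged run + GA configuration
#'
#' Builds the effective configuration from three layers of increasing
#' precedence: a named profile, an optional YAML or JSON file, and direct
#' overrides. The file may nest fields under `run:` and `ga:` or list them
#' flat; every field name must match a [run_config()] or [ga_config()]
#' argument, and unknown or out-of-range values are reported with the
#' offending key.
#'
#' @param path Optional path to a YAML (`.yml`/`.yaml`) or JSON file.
#' @param profile Base profile name for [profile_config()].
#' @param overrides Named list of field overrides (highest precedence).
#' @return A list with elements `run` and `ga`.
#' @export
#' @examples
#' load_config(profile = "desk", overrides = list(access_ratio = 0.3))
load_config <- function(path = NULL, profile = "desk", overrides = list()) {
  run_fields <- names(formals(run_config))
  ga_fields <- names(formals(ga_config))
  from_file <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) {
      abort(sprintf("config file not found: %s", path))
    }
    from_file <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
      yaml::read_yaml(path)
    } else {
      jsonlite::read_json(path, simplifyVector = TRUE)
    }
    if (!is.list(from_file)) {
      abort(sprintf("config file %s did not parse to a mapping", path))
    }
  }
  flatten_layer <- function(layer, origin) {
    flat <- list()
    for (key in names(layer)) {
      if (key %in% c("run", "ga")) {
        flat <- c(flat, as.list(layer[[key]]))
      } else {
        flat[[key]] <- layer[[key]]
      }
    }
    bad <- setdiff(names(flat), c(run_fields, ga_fields))
    if (length(bad)) {
      abort(sprintf(
        "unknown configuration key(s) in %s: %s",
        origin, paste(bad, collapse = ", ")
      ))
    }
    flat
  }
  merged <- modifyList(
    flatten_layer(from_file, if (is.null(path)) "file" else path),
    flatten_layer(as.list(overrides), "overrides")
  )
  prof_overrides <- merged[names(merged) != ""]
  do.call(profile_config, c(list(name = profile), prof_overrides))
}

#' Save experiment results with a provenance manifest
#'
#' Writes tabular records as CSV, genomes and summaries as JSON, the
#' effective configuration and master seed as a provenance echo, a run log,
#' and a manifest listing every written file with its MD5 content hash.
#' Re-running with identical inputs and seed reproduces identical hashes;
#' only the log timestamp differs. On a write failure all partially written
#' files from this call are removed before the error propagates.
#'
#' @param records Optional tibble of records (written to `records.csv`).
#' @param genomes Optional named list of `group_genome`s (each written to
#'   `<name>.json`).
#' @param out_dir Output directory (created if needed).
#' @param config Optional configuration list echoed to `config.json`.
#' @param seed Optional master seed recorded in the log.
#' @return A tibble manifest (`file`, `md5`), also written to
#'   `manifest.json`.
#' @export
save_results <- function(records = NULL, genomes = NULL, out_dir,
                         config = NULL, seed = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  cleanup <- function() unlink(written)
  tryCatch(
    {
      if (!is.null(records)) {
        p <- file.path(out_dir, "records.csv")
        write.csv(records, p, row.names = FALSE)
        written <- c(written, p)
      }
      for (nm in names(genomes)) {
        p <- file.path(out_dir, paste0(nm, ".json"))
        write_genome(genomes[[nm]], p)
        written <- c(written, p)
      }
      if (!is.null(config)) {
        p <- file.path(out_dir, "config.json")
        jsonlite::write_json(
          lapply(config, unclass), p,
          auto_unbox = TRUE, digits = NA
        )
        written <- c(written, p)
      }
      log_path <- file.path(out_dir, "run.log")
      writeLines(c(
        sprintf("timestamp: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
        sprintf("seed: %s", if (is.null(seed)) "none" else seed),
        sprintf("groupmind: %s", as.character(utils::packageVersion("groupmind"))),
        sprintf("R: %s", R.version.string)
      ), log_path)
      manifest <- tibble(
        file = basename(written),
        md5 = unname(tools::md5sum(written))
      )
      jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
        auto_unbox = TRUE, digits = NA
      )
      manifest
    },
    error = function(e) {
      cleanup()
      abort(sprintf("failed to save results: %s", conditionMessage(e)))
    }
  )
}
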