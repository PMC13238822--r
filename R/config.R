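#' Load and validate a model configuration
#'
#' Reads a YAML configuration, fills every missing field from the default
#' parameterization, rejects unknown keys, applies optional dotted-path
#' overrides, and re-validates the species blocks. An empty (or absent) file
#' yields the full defaults.
#'
#' @param path path to a YAML file, or `NULL` for pure defaults. Top-level
#'   keys mirror [default_parameters()]: `lingcod`, `yelloweye`,
#'   `gamma_scenarios`, `b`, `F_grid`.
#' @param overrides named list of dotted-path overrides applied after the
#'   file, e.g. `list("yelloweye.M" = 0.03)`.
#' @return A validated parameter list as from [default_parameters()].
#' @export
#' @examples
#' p <- load_config(overrides = list("yelloweye.M" = 0.03))
#' p$yelloweye$M
load_config <- function(path = NULL, overrides = list()) {
  defaults <- default_parameters()
  cfg <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    cfg <- yaml::read_yaml(path)
    if (is.null(cfg)) cfg <- list()
  }
  merged <- merge_config(defaults, cfg, prefix = "")
  for (key in names(overrides))
    merged <- apply_override(merged, key, overrides[[key]])
  for (sp in c("lingcod", "yelloweye")) {
    class(merged[[sp]]) <- "species_params"
    validate_species_params(merged[[sp]])
  }
  if (merged$b < 0) stop("'b' must be >= 0")
  if (any(merged$F_grid < 0)) stop("'F_grid' must be >= 0")
  if (any(merged$gamma_scenarios < 0 | merged$gamma_scenarios > 1))
    stop("'gamma_scenarios' must lie in [0, 1]")
  merged
}

# Recursive merge of user config into defaults; unknown keys are an error.
merge_config <- function(defaults, user, prefix) {
  if (!length(user)) return(defaults)
  if (is.null(names(user)) || any(names(user) == ""))
    stop("config entries must be named (at '", prefix, "')")
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ",
         paste0(prefix, unknown, collapse = ", "))
  for (key in names(user)) {
    d <- defaults[[key]]
    u <- user[[key]]
    if (is.list(d) && !is.null(names(d))) {
      defaults[[key]] <- merge_config(d, as.list(u),
                                      prefix = paste0(prefix, key, "."))
    } else if (!is.null(names(d)) && is.numeric(d)) {
      # named numeric (e.g. per-sex vectors): allow partial named update
      u <- unlist(u)
      if (is.null(names(u)) && length(u) == length(d)) {
        names(u) <- names(d)
      }
      bad <- setdiff(names(u), names(d))
      if (length(bad))
        stop("unknown config key(s): ",
             paste0(prefix, key, ".", bad, collapse = ", "))
      d[names(u)] <- u
      defaults[[key]] <- d
    } else {
      defaults[[key]] <- u
    }
  }
  defaults
}

# Apply a single dotted-path override like "yelloweye.M" = 0.03.
apply_override <- function(cfg, key, value) {
  parts <- strsplit(key, ".", fixed = TRUE)[[1]]
  node <- cfg
  for (i in seq_along(parts[-length(parts)])) {
    if (!parts[i] %in% names(node))
      stop("unknown config path: ", key)
    node <- node[[parts[i]]]
  }
  leaf <- parts[length(parts)]
  ok <- leaf %in% names(node) ||
    (is.numeric(node) && is.null(names(node)) && leaf == "")
  if (!ok) stop("unknown config path: ", key)
  cfg[[parts]] <- value
  cfg
}

#' Write scenario results and a run manifest
#'
#' Writes every data.frame in `results` as a CSV under `outdir` (created if
#' missing; existing files are overwritten with a warning) and a
#' `manifest.json` recording the seed, package version, per-file MD5
#' checksums, and any extra metadata — enough to re-run and byte-compare the
#' outputs.
#'
#' @param results named list of data.frames.
#' @param outdir output directory.
#' @param seed the master seed used to produce `results`.
#' @param meta optional named list of extra metadata stored verbatim.
#' @return The manifest, invisibly.
#' @export
write_outputs <- function(results, outdir, seed = NULL, meta = list()) {
  if (!length(names(results)) || any(names(results) == ""))
    stop("'results' must be a named list of data.frames")
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  files <- character(0)
  for (nm in names(results)) {
    path <- file.path(outdir, paste0(nm, ".csv"))
    if (file.exists(path))
      warning("overwriting ", path)
    utils::write.csv(results[[nm]], path, row.names = FALSE)
    files[nm] <- path
  }
  manifest <- list(
    package = "rebuildsim",
    version = as.character(utils::packageVersion("rebuildsim")),
    seed = seed,
    files = lapply(files, function(f)
      list(path = basename(f), md5 = unname(tools::md5sum(f)))),
    meta = meta
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
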