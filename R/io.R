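# Configuration, manifests, and plain-text export.

#' Read a run configuration
#'
#' YAML configuration with any of the [model_params()] fields (plus a
#' `profile` name used as the base) and an optional `cg` section
#' forwarded to [build_slab_system()].
#'
#' @param path YAML file.
#' @return A list with `params` (a `model_params`) and `cg` (a list,
#'   possibly empty).
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  profile <- cfg$profile %||% "fus2022"
  keep <- intersect(names(cfg),
                    c("N2", "beta_eps1", "beta_eps2", "L", "chi",
                      "atp_reservoir_phi", "residue_size_nm"))
  params <- do.call(fus_profile, c(list(name = profile), cfg[keep]))
  if (!is.null(cfg$protein))
    params <- do.call(model_params, c(
      list(protein = do.call(protein_spec, cfg$protein)),
      cfg[keep]))
  list(params = params, cg = cfg$cg %||% list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run manifest for reproducibility
#'
#' Collects every input needed to reproduce a run bit-identically:
#' parameters, tolerances, seed and package version.
#'
#' @param params a [model_params()].
#' @param seed integer seed (NA for deterministic runs).
#' @param extra named list of additional entries (tolerances,
#'   grid sizes, residuals).
#' @return A list suitable for [write_manifest()].
#' @export
run_manifest <- function(params, seed = NA_integer_, extra = list()) {
  stopifnot(inherits(params, "model_params"))
  c(list(package = "phasefus",
         version = as.character(utils::packageVersion("phasefus")),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
         seed = seed,
         protein = unclass(params$protein),
         params = unclass(params)[setdiff(names(params), "protein")]),
    extra)
}

#' Write a manifest as JSON
#'
#' @param manifest list from [run_manifest()].
#' @param path output file.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Write a free-energy curve (or any scan table) as CSV
#'
#' A comment header carries the manifest digest so outputs remain
#' traceable to their inputs.
#'
#' @param table data.frame from [free_energy_curve()], [scan_atp()] or
#'   [scan_binding_energy()].
#' @param path output CSV.
#' @param manifest optional manifest list; its digest is embedded in
#'   the header.
#' @export
write_scan_csv <- function(table, path, manifest = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(manifest)) {
    js <- jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA)
    digest <- sprintf("%08x", sum(utf8ToInt(as.character(js)) *
                                    (seq_len(nchar(js)) %% 31 + 1)) %% .Machine$integer.max)
    writeLines(sprintf("# phasefus manifest digest: %s", digest), con)
  }
  write.csv(table, con, row.names = FALSE)
  invisible(path)
}
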