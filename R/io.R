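#' Read and write the per-run container
#'
#' One container file per run keeps provenance atomic: the dataset, the
#' ground-truth pupils/drift (when simulated), the correction state, a
#' verbatim echo of the configuration, and a log (seeds, package version,
#' intensity trace). The container is an R-native serialized file (RDS,
#' format version 3) whose top level mirrors the layout
#' `dataset / truth / state / config / log`. Writing is bit-reproducible for
#' a fixed library version: a write -> read -> write round trip produces
#' identical payload bytes.
#'
#' @param path File path (conventionally `.rds`).
#' @param dataset,truth,state,sa,config,log Components to store; any may be
#'   `NULL`.
#' @return `write_run_container` returns `path` invisibly;
#'   `read_run_container` returns the stored list.
#' @export
write_run_container <- function(path, dataset = NULL, truth = NULL,
                                state = NULL, sa = NULL, config = NULL,
                                log = NULL) {
  payload <- list(format = "saclass-run", format_version = 1L,
                  package_version =
                    as.character(utils::packageVersion("saclass")),
                  dataset = dataset, truth = truth, state = state, sa = sa,
                  config = config, log = log)
  saveRDS(payload, path, version = 3, compress = "gzip")
  invisible(path)
}

#' @rdname write_run_container
#' @export
read_run_container <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  payload <- tryCatch(readRDS(path), error = function(e)
    stop("format error: ", path, " is not a readable run container"))
  if (!is.list(payload) || !identical(payload$format, "saclass-run"))
    stop("format error: ", path, " is not a saclass run container")
  payload
}

#' Export a phase map (or any real map) as a scaled TIFF with JSON sidecar
#'
#' Writes the map as a single-page TIFF (32-bit by default) after scaling to
#' `[0, 1]`; the affine scale (`offset`, `range`) goes into a JSON sidecar so
#' the map can be restored exactly up to float precision.
#'
#' @param map `n x n` numeric matrix.
#' @param path TIFF path; the sidecar is written at `paste0(path, ".json")`.
#' @param bits Bits per sample: 8, 16 or 32.
#' @param meta Optional named list merged into the sidecar.
#' @return `path`, invisibly.
#' @export
write_map_tiff <- function(map, path, bits = 32L, meta = NULL) {
  map <- as.matrix(map)
  lo <- min(map); hi <- max(map)
  scaled <- if (hi > lo) (map - lo) / (hi - lo) else map * 0
  tiff::writeTIFF(scaled, path, bits.per.sample = as.integer(bits))
  sidecar <- c(list(offset = lo, range = hi - lo,
                    n = nrow(map), bits = bits), meta)
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_map_tiff
#' @export
read_map_tiff <- function(path) {
  img <- tiff::readTIFF(path)
  sidecar <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  img * sidecar$range + sidecar$offset
}

#' Export an interferogram stack as multi-page 16-bit TIFF plus JSON sidecar
#'
#' Camera-like export: all pages share one global intensity scale (recorded
#' in the sidecar with the grid, carrier, reference amplitude and
#' illumination list), quantized to 16 bits.
#'
#' @param holos A list of [synthesize_hologram()] interferograms sharing one
#'   grid and carrier.
#' @param path TIFF path; sidecar at `paste0(path, ".json")`.
#' @param illums Optional [enumerate_illuminations()] set recorded in the
#'   sidecar (one page per illumination).
#' @return `path`, invisibly.
#' @export
write_interferogram_stack <- function(holos, path, illums = NULL) {
  stopifnot(length(holos) >= 1, all(vapply(holos, inherits, TRUE,
                                           "sa_interferogram")))
  g <- holos[[1]]$grid
  peak <- max(vapply(holos, function(h) max(h$intensity), 0))
  pages <- lapply(holos, function(h) h$intensity / peak)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  sidecar <- list(
    n_pages = length(holos), scale = peak,
    grid = list(fov = g$fov, n = g$n, wavelength = g$wavelength),
    carrier = holos[[1]]$carrier,
    ref_amplitude = holos[[1]]$ref_amplitude)
  if (!is.null(illums))
    sidecar$illuminations <- as.data.frame(illums)[, c("p", "q")]
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_interferogram_stack
#' @return `read_interferogram_stack` returns a list with `holos` (list of
#'   `sa_interferogram`), `grid`, `illuminations` (or `NULL`).
#' @export
read_interferogram_stack <- function(path) {
  sidecar <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  grid <- make_grid(sidecar$grid$fov, sidecar$grid$n, sidecar$grid$wavelength)
  holos <- lapply(pages, function(pg)
    structure(list(grid = grid, intensity = pg * sidecar$scale,
                   carrier = as.integer(sidecar$carrier),
                   ref_amplitude = sidecar$ref_amplitude),
              class = "sa_interferogram"))
  list(holos = holos, grid = grid, illuminations = sidecar$illuminations)
}

#' Read or write a run configuration
#'
#' Configurations are YAML on disk and echoed verbatim into the run
#' container, so a config plus the package version determines every output
#' bit.
#'
#' @param config A configuration list (see [default_run_config()]).
#' @param path YAML file path.
#' @return `read_run_config` returns the configuration list.
#' @export
write_run_config <- function(config, path) {
  writeLines(yaml::as.yaml(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  # keep bare y/n tokens (e.g. the grid size key "n") as strings instead of
  # YAML 1.1 booleans; true/false/yes/no still parse as logical
  yaml::yaml.load_file(path, handlers = list(
    "bool#yes" = function(x)
      if (tolower(x) %in% c("true", "yes", "on")) TRUE else x,
    "bool#no" = function(x)
      if (tolower(x) %in% c("false", "no", "off")) FALSE else x))
}
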