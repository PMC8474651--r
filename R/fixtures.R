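#' Deterministic end-to-end fixture specifications
#'
#' A fixture spec names a canonical mock neuron and session; regenerating
#' a fixture from its spec is byte-identical, which the manifest's file
#' checksums certify.  Two presets mirror the canonical low- and
#' mid-information example neurons used throughout the package's
#' demonstrations: `"lo_info"` (0.04 bits/AP at 1 Hz) and `"hi_info"`
#' (2 bits/AP at 1 Hz).
#'
#' @param name fixture name.
#' @param seed RNG seed.
#' @param i_ap target information, bits/AP.
#' @param mean_rate mean firing rate, Hz.
#' @param duration_min session duration, minutes.
#' @param indicator indicator preset name.
#' @return List of class `fixture_spec`.
#' @export
fixture_spec <- function(name, seed, i_ap, mean_rate = 1, duration_min = 10,
                         indicator = "gCaMP6f") {
  structure(list(name = name, seed = as.integer(seed), i_ap = i_ap,
                 mean_rate = mean_rate, duration_min = duration_min,
                 indicator = indicator),
            class = "fixture_spec")
}

#' @rdname fixture_spec
#' @export
fixture_presets <- function() {
  list(lo_info = fixture_spec("lo_info", seed = 101L, i_ap = 0.04),
       hi_info = fixture_spec("hi_info", seed = 202L, i_ap = 2))
}

#' Generate a fixture bundle from a spec
#'
#' Runs the full pipeline (rate map, behavior, spikes, fluorescence)
#' under the spec's seed.  When `dir` is given, writes the bundle as a
#' directory of plain-text files (`ratemap.csv`, `behavior.csv`,
#' `spikes.txt`, `dff.csv`) plus a `manifest.json` recording the spec,
#' package version, and per-file MD5 checksums.
#'
#' @param spec a [fixture_spec()].
#' @param dir output directory (created if needed); `NULL` for an
#'   in-memory bundle only.
#' @return List with `map`, `trace`, `train`, `frames`, `dff`, `spec`,
#'   and (if written) `manifest`.
#' @export
make_fixture <- function(spec, dir = NULL) {
  sub <- derive_seeds(spec$seed, 4L)
  map <- optimize_ratemap(spec$i_ap, mean_rate = spec$mean_rate,
                          seed = sub[1])
  trace <- synth_behavior(spec$duration_min * 60, seed = sub[2])
  cif <- build_cif(map, trace, mean_rate = spec$mean_rate)
  train <- generate_spikes(cif, seed = sub[3])
  frames <- bin_to_frames(train)
  kernel <- preset_kernel(spec$indicator)
  dff <- synth_fluorescence(train, kernel, seed = sub[4])
  bundle <- list(map = map, trace = trace, train = train, frames = frames,
                 dff = dff, spec = spec)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_ratemap_library(list(map), file.path(dir, "ratemap.csv"))
    write_behavior(trace, file.path(dir, "behavior.csv"))
    write_spike_times(train, file.path(dir, "spikes.txt"))
    write_dff(dff, file.path(dir, "dff.csv"))
    files <- c("ratemap.csv", "behavior.csv", "spikes.txt", "dff.csv")
    sums <- tools::md5sum(file.path(dir, files))
    names(sums) <- files
    manifest <- list(
      name = spec$name, seed = spec$seed, i_ap = spec$i_ap,
      mean_rate = spec$mean_rate, duration_min = spec$duration_min,
      indicator = spec$indicator,
      package_version = as.character(utils::packageVersion("fluorinfo")),
      checksums = as.list(sums))
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    bundle$manifest <- manifest
  }
  bundle
}
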