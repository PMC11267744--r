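## Shared small fixtures, built once per test run.

fixture_env <- new.env()

## 36 x 60 folded sheet with noiseless retinotopy and its parcellation
small_world <- function() {
  if (is.null(fixture_env$world)) {
    mesh <- make_mesh(36, 60, 2, seed = 7)
    labels <- make_area_labels(mesh)
    map <- make_retinotopy(mesh, labels, noise_sd = 0,
                           low_snr_fraction = 0, seed = 2)
    parc <- segment_subareas(mesh, labels, map)
    fixture_env$world <- list(mesh = mesh, labels = labels, map = map,
                              parc = parc,
                              ribbon = cortical_ribbon(mesh))
  }
  fixture_env$world
}

## flat sheet (no folds) for constructed-geometry tests
flat_world <- function() {
  if (is.null(fixture_env$flat)) {
    mesh <- make_mesh(30, 30, 0, seed = 1)
    fixture_env$flat <- list(mesh = mesh, ribbon = cortical_ribbon(mesh))
  }
  fixture_env$flat
}

## assignment data frame built directly from pair lists (counting oracle
## input without geometry)
fake_assignments <- function(i, j, length_mm = 10, status = "accepted") {
  n <- length(i)
  data.frame(streamline = seq_len(n), status = rep_len(status, n),
             subarea_i = i, subarea_j = j,
             length_mm = rep_len(length_mm, n),
             stringsAsFactors = FALSE)
}
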