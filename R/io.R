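# CSV/JSON interchange for the scoring pipeline. Band powers travel as
# epoch_index + band_1_3 .. band_31_33 columns; hypnograms as
# epoch_index,label; boundary polygons as GeoJSON-style vertex lists.

#' Read an epoch band-power CSV
#'
#' @param path CSV with columns `epoch_index`, `band_1_3` .. `band_31_33`
#'   (and optionally `valid`).
#' @return Validated band-power tibble.
#' @export
read_band_powers <- function(path) {
  validate_band_powers(readr::read_csv(path, show_col_types = FALSE))
}

#' Write an epoch band-power CSV
#' @param powers Band-power tibble.
#' @param path Output path.
#' @export
write_band_powers <- function(powers, path) {
  readr::write_csv(powers[c("epoch_index", band_cols(),
                            intersect("valid", names(powers)))], path)
}

#' Read a hypnogram CSV (`epoch_index,label`)
#' @param path Input path.
#' @param stages Allowed labels (default `W/N/R/t`).
#' @return Hypnogram tibble.
#' @export
read_hypnogram <- function(path, stages = c("W", "N", "R", "t")) {
  check_hypnogram(readr::read_csv(path, col_types = "ic"), stages = stages)
}

#' Write a hypnogram CSV
#' @param hyp Hypnogram tibble (`epoch_index`, `label`).
#' @param path Output path.
#' @export
write_hypnogram <- function(hyp, path) {
  readr::write_csv(hyp[c("epoch_index", "label")], path)
}

#' Serialize state boundaries and NRt space to a GeoJSON-style JSON file
#' @param bounds `state_boundaries`.
#' @param nrt_space Optional `nrt_space`.
#' @param path Output path.
#' @export
write_boundaries_json <- function(bounds, path, nrt_space = NULL) {
  poly_coords <- function(p) lapply(seq_len(nrow(p)), function(i) c(p$x[i], p$y[i]))
  obj <- list(
    n_polygon = poly_coords(bounds$N$polygon),
    r_polygon = poly_coords(bounds$R$polygon),
    n_centroid = unname(bounds$N$centroid),
    r_centroid = unname(bounds$R$centroid),
    excluded_points = c(N = bounds$N$excluded_points,
                        R = bounds$R$excluded_points)
  )
  if (!is.null(nrt_space)) obj$nrt_hull <- poly_coords(nrt_space$hull)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
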