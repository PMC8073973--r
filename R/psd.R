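#' Pore size distribution of a biomass particle
#'
#' Construct a slit-pore size distribution from solute-exclusion style data:
#' pore widths (in Angstrom) paired with the specific pore volume found at
#' that width (cm3 per g of dry substrate). Bins are *incremental* volumes at
#' representative widths; set `cumulative = TRUE` if the table reports the
#' cumulative volume accessible up to each width (it is then differenced).
#'
#' @param width_angstrom numeric vector of pore widths in Angstrom; strictly
#'   positive and strictly increasing.
#' @param volume_cm3_per_g numeric vector of specific pore volumes, cm3/g dry
#'   substrate, same length as `width_angstrom`; non-negative.
#' @param cumulative logical; if `TRUE` the volumes are cumulative and are
#'   converted to incremental bin volumes.
#' @return An object of class `"psd"`: a data.frame with columns
#'   `width_angstrom` and `volume_cm3_per_g` (incremental).
#' @examples
#' p <- psd(c(40, 80, 200), c(0.05, 0.10, 0.30))
#' total_pore_volume(p)
#' @export
psd <- function(width_angstrom, volume_cm3_per_g, cumulative = FALSE) {
  w <- as.numeric(width_angstrom)
  v <- as.numeric(volume_cm3_per_g)
  if (length(w) < 1L) stop("a pore size distribution needs at least one bin")
  if (length(w) != length(v))
    stop("'width_angstrom' and 'volume_cm3_per_g' must have the same length")
  if (anyNA(w) || anyNA(v)) stop("pore size distribution contains NA values")
  if (any(w <= 0)) stop("pore widths must be strictly positive")
  if (is.unsorted(w, strictly = TRUE))
    stop("pore widths must be strictly increasing")
  if (isTRUE(cumulative)) v <- diff(c(0, v))
  if (any(v < 0)) {
    stop(if (isTRUE(cumulative))
      "cumulative pore volumes must be non-decreasing"
      else "pore volumes must be non-negative")
  }
  structure(
    data.frame(width_angstrom = w, volume_cm3_per_g = v),
    class = c("psd", "data.frame")
  )
}

#' @export
print.psd <- function(x, ...) {
  cat("Pore size distribution:", nrow(x), "bins,",
      format(sum(x$volume_cm3_per_g), digits = 4), "cm3/g total\n")
  print.data.frame(x, ...)
  invisible(x)
}

#' Total specific pore volume
#'
#' @param psd a [psd()] object.
#' @return Total pore volume in cm3 per g dry substrate.
#' @export
total_pore_volume <- function(psd) {
  stopifnot(inherits(psd, "psd"))
  sum(psd$volume_cm3_per_g)
}

# Angstrom -> cm
.ang_to_cm <- 1e-8

#' Enzyme-accessible surface area and pore volume from a slit-pore PSD
#'
#' Pores are treated as parallel-wall slits. A pore of width `w` contributes
#' wall area per unit volume according to how many of its two flat walls a
#' cellulase of diameter `d_E` can reach: both walls (`2 v / w`) when
#' `w >= 2 d_E`, a single wall (`v / w`) when `d_E <= w < 2 d_E`, and nothing
#' when the pore is narrower than the enzyme. Exact-boundary widths are
#' assigned to the higher-accessibility class. Accessible pore volume sums all
#' bins with `w >= d_E`.
#'
#' @param psd a [psd()] object.
#' @param enzyme_diameter_angstrom cellulase footprint diameter in Angstrom
#'   (default 51, the spherical footprint of a lumped cellulase).
#' @return A list with `surface_cm2_per_g` (accessible wall area, cm2/g) and
#'   `volume_cm3_per_g` (enzyme-accessible pore volume, cm3/g).
#' @examples
#' accessible_surface(psd(200, 0.5))  # both walls: 2 * 0.5 / 2e-6 cm
#' @export
accessible_surface <- function(psd, enzyme_diameter_angstrom = 51) {
  stopifnot(inherits(psd, "psd"))
  d_E <- as.numeric(enzyme_diameter_angstrom)
  if (length(d_E) != 1L || !is.finite(d_E) || d_E <= 0)
    stop("'enzyme_diameter_angstrom' must be a single positive number")
  w_cm <- psd$width_angstrom * .ang_to_cm
  v <- psd$volume_cm3_per_g
  walls <- ifelse(psd$width_angstrom >= 2 * d_E, 2,
                  ifelse(psd$width_angstrom >= d_E, 1, 0))
  list(
    surface_cm2_per_g = sum(walls * v / w_cm),
    volume_cm3_per_g = sum(v[psd$width_angstrom >= d_E])
  )
}

#' Binding-site density from accessible surface
#'
#' The accessible cellulose wall area multiplied by the site density parameter
#' sigma, the moles of enzyme binding sites per cm2 of surface (the footprint
#' of a 51 Angstrom sphere gives the default 2.1e-12 mol/cm2).
#'
#' @param surface_cm2_per_g accessible surface in cm2 per g dry substrate.
#' @param sigma_mol_per_cm2 binding sites per surface area, mol/cm2.
#' @return Binding-site density in mol per g dry substrate.
#' @export
binding_site_density <- function(surface_cm2_per_g, sigma_mol_per_cm2 = 2.1e-12) {
  if (any(sigma_mol_per_cm2 <= 0)) stop("'sigma_mol_per_cm2' must be positive")
  if (any(surface_cm2_per_g < 0)) stop("surface area cannot be negative")
  surface_cm2_per_g * sigma_mol_per_cm2
}

#' Read a pore size distribution from CSV
#'
#' Expects a header `width_angstrom,volume_cm3_per_g`.
#'
#' @param path CSV file path.
#' @param cumulative passed to [psd()].
#' @return A [psd()] object.
#' @export
read_psd_csv <- function(path, cumulative = FALSE) {
  df <- utils::read.csv(path)
  need <- c("width_angstrom", "volume_cm3_per_g")
  if (!all(need %in% names(df)))
    stop("PSD CSV must have columns: ", paste(need, collapse = ", "))
  psd(df$width_angstrom, df$volume_cm3_per_g, cumulative = cumulative)
}
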