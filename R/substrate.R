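#' Static physical description of one substrate particle type
#'
#' Bundles the measurable characteristics of a biomass particle that the
#' hydrolysis model consumes: geometry, composition, digestibility and the
#' pore size distribution. Units follow the model convention (cm, g, mol,
#' min); pore widths are entered in Angstrom and converted internally.
#'
#' @param radius_cm particle radius R in cm (the particle is a long cylinder;
#'   everything downstream is per unit length).
#' @param apparent_density_g_cm3 apparent particle density rho_p, g per cm3 of
#'   particle including voids.
#' @param cellulose_fraction cellulose mass fraction of the dry substrate,
#'   in \[0, 1\].
#' @param digestibility fraction of the cellulose that is hydrolyzable at
#'   completion (taken from the final experimental glucose yield), in \[0, 1\].
#' @param cellulose_density_g_cm3 density of cellulose including its
#'   enzyme-inaccessible voids, rho_C^IV, g/cm3.
#' @param psd a [psd()] object.
#' @param label optional substrate identifier.
#' @return An object of class `"substrate_spec"` (a list with the above
#'   fields).
#' @seealso [derive_substrate()], [synthetic_substrate()]
#' @export
substrate_spec <- function(radius_cm,
                           apparent_density_g_cm3,
                           cellulose_fraction,
                           digestibility,
                           cellulose_density_g_cm3 = 1.5,
                           psd,
                           label = "substrate") {
  chk1 <- function(x, nm) {
    if (length(x) != 1L || !is.finite(x)) stop("'", nm, "' must be a single finite number")
    x
  }
  radius_cm <- chk1(radius_cm, "radius_cm")
  apparent_density_g_cm3 <- chk1(apparent_density_g_cm3, "apparent_density_g_cm3")
  cellulose_fraction <- chk1(cellulose_fraction, "cellulose_fraction")
  digestibility <- chk1(digestibility, "digestibility")
  cellulose_density_g_cm3 <- chk1(cellulose_density_g_cm3, "cellulose_density_g_cm3")
  if (radius_cm <= 0) stop("'radius_cm' must be positive")
  if (apparent_density_g_cm3 <= 0) stop("'apparent_density_g_cm3' must be positive")
  if (cellulose_fraction < 0 || cellulose_fraction > 1)
    stop("'cellulose_fraction' must be in [0, 1]")
  if (digestibility < 0 || digestibility > 1)
    stop("'digestibility' must be in [0, 1]")
  if (cellulose_density_g_cm3 <= 0) stop("'cellulose_density_g_cm3' must be positive")
  if (!inherits(psd, "psd")) stop("'psd' must be a psd object")
  structure(
    list(
      label = as.character(label)[1],
      radius_cm = radius_cm,
      apparent_density_g_cm3 = apparent_density_g_cm3,
      cellulose_fraction = cellulose_fraction,
      digestibility = digestibility,
      cellulose_density_g_cm3 = cellulose_density_g_cm3,
      psd = psd
    ),
    class = "substrate_spec"
  )
}

#' @export
print.substrate_spec <- function(x, ...) {
  cat("Substrate spec '", x$label, "'\n", sep = "")
  cat(sprintf("  radius              %g cm (%g um diameter)\n",
              x$radius_cm, 2e4 * x$radius_cm))
  cat(sprintf("  apparent density    %g g/cm3\n", x$apparent_density_g_cm3))
  cat(sprintf("  cellulose fraction  %g\n", x$cellulose_fraction))
  cat(sprintf("  digestibility       %g\n", x$digestibility))
  cat(sprintf("  cellulose density   %g g/cm3 (incl. voids)\n",
              x$cellulose_density_g_cm3))
  cat(sprintf("  PSD                 %d bins, %g cm3/g\n",
              nrow(x$psd), sum(x$psd$volume_cm3_per_g)))
  invisible(x)
}

#' Derive accessibility quantities from a substrate spec
#'
#' Turns the measurable substrate characteristics into the model's geometric
#' and accessibility quantities:
#' \describe{
#'   \item{eps0}{initial accessible porosity, the enzyme-accessible pore
#'     volume times the apparent density (cm3 pore / cm3 particle).}
#'   \item{eps_f}{porosity when all hydrolyzable cellulose is dissolved:
#'     `eps0 + d * f_cell * rho_p / rho_C_IV`.}
#'   \item{surface_cm2_per_g}{accessible slit-pore wall area.}
#'   \item{site_density_mol_per_g}{enzyme binding sites per g substrate.}
#'   \item{cs_max0_mol_per_cm3}{initial maximum bound-enzyme concentration
#'     per total particle volume, `site_density * rho_p`.}
#' }
#'
#' @param spec a [substrate_spec()].
#' @param sigma_mol_per_cm2 binding-site surface density, mol/cm2.
#' @param enzyme_diameter_angstrom cellulase footprint diameter, Angstrom.
#' @param cellulose_only if `TRUE`, scale the accessible wall area by the
#'   cellulose mass fraction so that only cellulose walls carry sites
#'   (default `FALSE`: the whole accessible wall area carries sites).
#' @return An object of class `"substrate_derived"`.
#' @examples
#' sp <- substrate_spec(1.25e-3, 0.8, 0.5, 0.8, 1.5, psd(c(80, 200), c(0.2, 0.3)))
#' derive_substrate(sp)
#' @export
derive_substrate <- function(spec,
                             sigma_mol_per_cm2 = 2.1e-12,
                             enzyme_diameter_angstrom = 51,
                             cellulose_only = FALSE) {
  stopifnot(inherits(spec, "substrate_spec"))
  acc <- accessible_surface(spec$psd, enzyme_diameter_angstrom)
  surf <- acc$surface_cm2_per_g
  if (isTRUE(cellulose_only)) surf <- surf * spec$cellulose_fraction
  site_density <- binding_site_density(surf, sigma_mol_per_cm2)
  eps0 <- acc$volume_cm3_per_g * spec$apparent_density_g_cm3
  eps_f <- eps0 + spec$digestibility * spec$cellulose_fraction *
    spec$apparent_density_g_cm3 / spec$cellulose_density_g_cm3
  if (eps0 >= 1)
    stop("infeasible substrate: initial accessible porosity >= 1 (eps0 = ",
         format(eps0, digits = 4), ")")
  if (eps_f > 1)
    stop("infeasible substrate: exhaustion porosity > 1 (eps_f = ",
         format(eps_f, digits = 4),
         "); check digestibility, composition and densities")
  structure(
    list(
      eps0 = eps0,
      eps_f = eps_f,
      accessible_volume_cm3_per_g = acc$volume_cm3_per_g,
      surface_cm2_per_g = surf,
      site_density_mol_per_g = site_density,
      cs_max0_mol_per_cm3 = site_density * spec$apparent_density_g_cm3,
      sigma_mol_per_cm2 = sigma_mol_per_cm2,
      enzyme_diameter_angstrom = enzyme_diameter_angstrom,
      cellulose_only = isTRUE(cellulose_only)
    ),
    class = "substrate_derived"
  )
}

#' @export
print.substrate_derived <- function(x, ...) {
  cat("Derived substrate accessibility\n")
  cat(sprintf("  accessible surface   %g cm2/g (%.1f m2/g)\n",
              x$surface_cm2_per_g, x$surface_cm2_per_g / 1e4))
  cat(sprintf("  site density         %g mol/g (%.3g umol/g)\n",
              x$site_density_mol_per_g, 1e6 * x$site_density_mol_per_g))
  cat(sprintf("  initial porosity     %g\n", x$eps0))
  cat(sprintf("  exhaustion porosity  %g\n", x$eps_f))
  cat(sprintf("  C_S,max(0)           %g mol/cm3 total volume\n",
              x$cs_max0_mol_per_cm3))
  invisible(x)
}

#' Read / write a substrate spec as YAML or JSON
#'
#' The on-disk schema uses the keys `radius_cm`, `apparent_density_g_cm3`,
#' `cellulose_fraction`, `digestibility`, `cellulose_density_g_cm3`, `label`
#' and `psd` (a list of `{width_angstrom, volume_cm3_per_g}` records). Format
#' is chosen from the file extension (`.yml`/`.yaml` or `.json`).
#'
#' @param path file path.
#' @return `read_substrate()` returns a [substrate_spec()];
#'   `write_substrate()` returns `path` invisibly.
#' @export
read_substrate <- function(path) {
  ext <- tolower(tools::file_ext(path))
  obj <- switch(ext,
    "yml" = ,
    "yaml" = yaml::read_yaml(path),
    "json" = jsonlite::read_json(path, simplifyVector = TRUE),
    stop("unsupported substrate file extension: ", ext)
  )
  substrate_from_list(obj)
}

#' @rdname read_substrate
#' @param spec a [substrate_spec()] to serialize.
#' @export
write_substrate <- function(spec, path) {
  stopifnot(inherits(spec, "substrate_spec"))
  obj <- list(
    label = spec$label,
    radius_cm = spec$radius_cm,
    apparent_density_g_cm3 = spec$apparent_density_g_cm3,
    cellulose_fraction = spec$cellulose_fraction,
    digestibility = spec$digestibility,
    cellulose_density_g_cm3 = spec$cellulose_density_g_cm3,
    psd = lapply(seq_len(nrow(spec$psd)), function(i) list(
      width_angstrom = spec$psd$width_angstrom[i],
      volume_cm3_per_g = spec$psd$volume_cm3_per_g[i]
    ))
  )
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    "yml" = ,
    "yaml" = yaml::write_yaml(obj, path),
    "json" = jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA),
    stop("unsupported substrate file extension: ", ext)
  )
  invisible(path)
}

# Build a substrate_spec from a plain list (parsed YAML/JSON or inline config).
substrate_from_list <- function(obj) {
  need <- c("radius_cm", "apparent_density_g_cm3", "cellulose_fraction",
            "digestibility", "psd")
  miss <- setdiff(need, names(obj))
  if (length(miss))
    stop("substrate spec missing fields: ", paste(miss, collapse = ", "))
  p <- obj$psd
  if (is.data.frame(p)) {
    pd <- psd(p$width_angstrom, p$volume_cm3_per_g)
  } else if (is.list(p) && !is.null(p[[1]]$width_angstrom)) {
    pd <- psd(vapply(p, function(b) as.numeric(b$width_angstrom), 0),
              vapply(p, function(b) as.numeric(b$volume_cm3_per_g), 0))
  } else if (is.list(p) && all(c("width_angstrom", "volume_cm3_per_g") %in% names(p))) {
    pd <- psd(unlist(p$width_angstrom), unlist(p$volume_cm3_per_g))
  } else stop("unrecognized 'psd' structure in substrate spec")
  substrate_spec(
    radius_cm = obj$radius_cm,
    apparent_density_g_cm3 = obj$apparent_density_g_cm3,
    cellulose_fraction = obj$cellulose_fraction,
    digestibility = obj$digestibility,
    cellulose_density_g_cm3 = if (is.null(obj$cellulose_density_g_cm3)) 1.5
                              else obj$cellulose_density_g_cm3,
    psd = pd,
    label = if (is.null(obj$label)) "substrate" else obj$label
  )
}
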