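#' Default run configuration
#'
#' All thresholds of the pipeline in one overridable list.  Defaults are the
#' method's printed operating points: 12.0 A sphere shell, 4.5 A interface
#' and contact distance, 1.0 A clash distance, acceptance filters
#' Nc >= 10, GDC >= 55.0, N4 >= 1, cl <= 2, high-confidence tier Nc >= 25,
#' GDC >= 65, cl <= 1, and cluster merge rules (>80% contact overlap or
#' ligand centroids within 2.0 A).
#'
#' @param ... named overrides of individual thresholds.
#' @return a named list of configuration values.
#' @export
default_config <- function(...) {
  cfg <- list(
    shell_radius = 12.0,
    interface_radius = 4.5,
    contact_cutoff = 4.5,
    clash_cutoff = 1.0,
    nc_min = 10,
    gdc_min = 55.0,
    n4_min = 1,
    cl_max = 2,
    hc_nc_min = 25,
    hc_gdc_min = 65,
    hc_cl_max = 1,
    overlap_frac = 0.80,
    centroid_cutoff = 2.0,
    region_radius = 16.0,
    conserved_cutoff = 4.0,
    unit = "CA",
    burial_min_neighbors = 10,
    burial_radius = 5.0,
    seed = 1L)
  ov <- list(...)
  bad <- setdiff(names(ov), names(cfg))
  if (length(bad) > 0) stop("unknown configuration keys: ",
                            paste(bad, collapse = ", "))
  utils::modifyList(cfg, ov)
}

#' Acceptance filter for a pocket match
#'
#' A match is a predicted binding-site candidate when Nc >= 10 conserved
#' residue pairs, all-atom similarity GDC >= 55.0, at least one predicted
#' contact residue (N4 >= 1), and no more than two residues in steric clash
#' with the transplanted ligand (cl <= 2).  All bounds inclusive as printed.
#'
#' @param nc,gdc,n4,cl match statistics.
#' @param config a [default_config()] list.
#' @return logical.
#' @export
passes_filters <- function(nc, gdc, n4, cl, config = default_config()) {
  nc >= config$nc_min & gdc >= config$gdc_min &
    n4 >= config$n4_min & cl <= config$cl_max
}

#' High-confidence tier for a pocket match
#'
#' Higher confidence is assigned when Nc >= 25, GDC >= 65 and cl <= 1 (the
#' match must also pass the base acceptance filter).
#'
#' @inheritParams passes_filters
#' @return logical.
#' @export
high_confidence <- function(nc, gdc, n4, cl, config = default_config()) {
  passes_filters(nc, gdc, n4, cl, config) &
    nc >= config$hc_nc_min & gdc >= config$hc_gdc_min & cl <= config$hc_cl_max
}
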