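# Reference measurement tables ------------------------------------------------
#
# Published summary statistics for the two study species (a straight-leaved,
# terete one, D. cooperi, and a recurved, triquetrous one, D. ecklonis).
# These printed medians/means are the inputs to the derived-quantity
# computations (ratio tables, parenchyma moduli); the raw per-leaf data are
# archived externally and are not required by the package.

#' Published mechanical-property medians of the two species
#'
#' Median, standard error and sample size per species for the tensile
#' properties of whole leaves and individual tissues, plus Poisson's ratio
#' and turgor, with the published interspecific significance labels.
#' Hydrenchyma and chlorenchyma moduli are themselves derived via
#' [nilsson_parenchyma_modulus()] (no `se`/`n`).
#'
#' @return data frame with columns `property`, `tissue`, `med_ecklonis`,
#'   `se_ecklonis`, `n_ecklonis`, `med_cooperi`, `se_cooperi`, `n_cooperi`,
#'   `stars`.
#' @export
published_mechanics <- function() {
  data.frame(
    property = c(rep("elastic_modulus_mpa", 6L),
                 rep("tensile_strength_mpa", 4L),
                 "poisson_ratio", "turgor_mpa"),
    tissue = c("leaf", "central_vascular_strand", "epidermis_transverse",
               "epidermis_longitudinal", "hydrenchyma", "chlorenchyma",
               "leaf", "central_vascular_strand", "epidermis_transverse",
               "epidermis_longitudinal",
               "leaf", "parenchyma"),
    med_ecklonis = c(1.21, 63.68, 2.88, 3.51, 0.26, 0.26,
                     0.16, 10.99, 0.58, 0.70, 0.35, 0.05),
    se_ecklonis = c(0.11, 7.52, 0.40, 1.21, NA, NA,
                    0.01, 0.70, 0.10, 0.26, 0.03, 0.002),
    n_ecklonis = c(14L, 9L, 6L, 8L, NA, NA, 14L, 9L, 6L, 8L, 14L, 36L),
    med_cooperi = c(0.72, 32.80, 3.62, 5.27, 0.23, 0.27,
                    0.09, 8.80, 1.25, 1.54, 0.29, 0.04),
    se_cooperi = c(0.14, 5.96, 0.27, 0.85, NA, NA,
                   0.01, 0.76, 0.07, 0.11, 0.03, 0.003),
    n_cooperi = c(18L, 8L, 10L, 10L, NA, NA, 13L, 8L, 10L, 10L, 18L, 44L),
    stars = c("***", "**", "*", "ns", "-", "-",
              "***", "**", "**", "**", "*", "ns"),
    stringsAsFactors = FALSE)
}

#' Published parenchyma cell geometry and turgor inputs
#'
#' Median cell diameters and cell-wall thicknesses of the hydrenchyma and
#' chlorenchyma of both species, with the species-level turgor medians and
#' whole-leaf Poisson's ratios; inputs to
#' [nilsson_parenchyma_modulus()] (cell-wall modulus 5.00 MPa).
#'
#' @return data frame with columns `species`, `tissue`, `d_c_um`,
#'   `t_cw_um`, `turgor_mpa`, `poisson`.
#' @export
published_cell_geometry <- function() {
  data.frame(
    species = c("D_ecklonis", "D_ecklonis", "D_cooperi", "D_cooperi"),
    tissue = c("hydrenchyma", "chlorenchyma", "hydrenchyma",
               "chlorenchyma"),
    d_c_um = c(84.73, 73.72, 92.00, 62.50),
    t_cw_um = c(0.37, 0.35, 0.42, 0.42),
    turgor_mpa = c(0.05, 0.05, 0.04, 0.04),
    poisson = c(0.35, 0.35, 0.29, 0.29),
    stringsAsFactors = FALSE)
}

#' Published leaf morphometry of the two species
#'
#' Means and standard errors of the total fresh leaf length, the fresh minor
#' (a) and major (b) leaf diameters, and the tissue thicknesses of the five
#' concentric layers plus the epidermal bladder cells, along the minor and
#' major diameters. Lengths/diameters in mm, thicknesses in micrometres.
#'
#' @return data frame with columns `quantity`, `axis`, `unit`,
#'   `mean_ecklonis`, `se_ecklonis`, `n_ecklonis`, `mean_cooperi`,
#'   `se_cooperi`, `n_cooperi`, `stars`.
#' @export
published_morphometry <- function() {
  data.frame(
    quantity = c("leaf_length", "leaf_diameter", "leaf_diameter",
                 "t_ebc", "t_ebc", "t_epi", "t_epi", "t_chl", "t_chl",
                 "t_nvb", "t_nvb", "t_hyd", "t_hyd", "t_cvs", "t_cvs"),
    axis = c(NA, "a", "b", "a", "b", "a", "b", "a", "b", "a", "b",
             "a", "b", "a", "b"),
    unit = c("mm", "mm", "mm", rep("um", 12L)),
    mean_ecklonis = c(27.4, 2.5, 5.4, 82.6, 84.3, 24.4, 26.7, 364.3,
                      775.3, 55.4, 63.2, 443.7, 1450.6, 50.9, 66.9),
    se_ecklonis = c(1.3, 0.1, 0.2, 5.5, 3.7, 1.9, 1.9, 19.6, 25.0, 2.3,
                    3.0, 30.8, 32.8, 2.9, 2.2),
    n_ecklonis = c(20L, 20L, 20L, rep(20L, 12L)),
    mean_cooperi = c(45.5, 3.4, 3.0, 249.5, 258.4, 40.1, 40.2, 524.9,
                     566.6, 64.4, 65.6, 586.8, 671.2, 54.9, 60.6),
    se_cooperi = c(0.6, 0.1, 0.03, 11.1, 9.5, 2.4, 3.2, 22.1, 16.7, 1.8,
                   1.8, 28.8, 25.0, 1.1, 2.6),
    n_cooperi = c(10L, 10L, 10L, rep(20L, 12L)),
    stars = c("***", "***", "***", "***", "***", "***", "***", "***",
              "***", "**", "ns", "**", "***", "ns", "ns"),
    stringsAsFactors = FALSE)
}

#' Parenchyma moduli of both species from the published inputs
#'
#' Convenience wrapper applying [nilsson_parenchyma_modulus()] to
#' [published_cell_geometry()].
#'
#' @param digits decimals for the reported modulus (default 2, matching the
#'   published precision); `NULL` for unrounded values.
#' @return data frame `species`, `tissue`, `modulus_mpa`.
#' @export
parenchyma_moduli <- function(digits = 2L) {
  geo <- published_cell_geometry()
  E <- mapply(nilsson_parenchyma_modulus,
              d_c_um = geo$d_c_um, t_cw_um = geo$t_cw_um,
              turgor_mpa = geo$turgor_mpa, poisson = geo$poisson)
  if (!is.null(digits)) E <- round_half_away(E, digits)
  data.frame(species = geo$species, tissue = geo$tissue,
             modulus_mpa = E, stringsAsFactors = FALSE)
}

#' Interspecific ratio table of the published mechanical medians
#'
#' Runs [comparison_table()] on [published_mechanics()]
#' (ratio = recurved-species median / straight-species median).
#'
#' @return data frame with `property`, `tissue`, medians, `ratio`, `stars`.
#' @export
mechanics_ratio_table <- function() {
  mech <- published_mechanics()
  med <- data.frame(property = paste(mech$property, mech$tissue, sep = "."),
                    median_a = mech$med_ecklonis,
                    median_b = mech$med_cooperi,
                    stars = mech$stars,
                    stringsAsFactors = FALSE)
  ct <- comparison_table(med)
  data.frame(property = mech$property, tissue = mech$tissue,
             med_ecklonis = mech$med_ecklonis,
             med_cooperi = mech$med_cooperi,
             ratio = ct$ratio, stars = mech$stars,
             stringsAsFactors = FALSE)
}
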