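# Unit conversions used in the study design: population densities to
# effective haploid deme sizes, dispersal kernels to kilometers, error
# rates to Phred scores, generations to years.

#' Effective haploid deme size from a population density
#'
#' Census size = density x cell area; reproductive (diploid) size = census
#' divided by 3 (one third of the population sexually mature); effective
#' haploid size = reproductive size x 2 gene copies. E.g. 0.0675
#' individuals/km2 on a 100-km cell gives K = 450.
#'
#' @param density_per_km2 individuals per square kilometer.
#' @param cell_km cell edge in kilometers (default 100).
#' @param mature_fraction sexually mature fraction (default 1/3).
#' @return effective haploid size in gene copies.
#' @export
K_from_density <- function(density_per_km2, cell_km = 100,
                           mature_fraction = 1 / 3) {
  density_per_km2 * cell_km^2 * mature_fraction * 2
}

#' Mean long-distance dispersal distance in kilometers
#'
#' The gamma kernel mean `shape/rate` is in deme widths; multiplied by the
#' cell edge. Defaults give 1.209 / 0.15046 * 100 km ~ 803.5 km.
#' @param shape,rate gamma kernel parameters.
#' @param cell_km cell edge in kilometers.
#' @export
ldd_mean_km <- function(shape = 1.209, rate = 0.15046, cell_km = 100) {
  shape / rate * cell_km
}

#' Phred-scale quality score of an error rate
#'
#' `-10 log10(eps)`, rounded to the integer Phred convention: 5.7e-5
#' corresponds to Q42.
#' @param eps per-base error probability.
#' @export
phred_from_error <- function(eps) {
  stopifnot(eps > 0, eps <= 1)
  round(-10 * log10(eps))
}

#' Convert generations to years and back
#' @param generations,years values to convert.
#' @param gen_years years per generation (default 25).
#' @export
years_from_generations <- function(generations, gen_years = 25) {
  generations * gen_years
}

#' @rdname years_from_generations
#' @export
generations_from_years <- function(years, gen_years = 25) {
  years / gen_years
}
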