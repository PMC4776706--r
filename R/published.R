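# Published posterior summaries for the best-fitting model (LDDRCop),
# transcribed from the source study's parameter table.  Times are in years
# (25-year generations); sizes in diploid individuals.  These are inputs for
# derived arithmetic identities and for worked examples; nothing in the
# simulation machinery depends on them.

#' Published posterior summaries of the LDDRCop model parameters
#'
#' @return data.frame with columns `param`, `mode`, `mean`, `median`,
#'   `hpdi_lo`, `hpdi_hi`.
#' @export
published_posteriors <- function() {
  tab <- rbind(
    c("T_STARTEXP_years", 80704, 94903, 91777, 80000, 120916),
    c("T_OOA_years",      73568, 65924, 67477, 48276, 80000),
    c("Ne_ANC",           10327, 11795, 11386, 5000, 19098),
    c("K",                  826,  1036,   992,   50, 1992),
    c("LDD_PROP",         0.044, 0.038, 0.040, 0.021, 0.050),
    c("r",                0.429, 0.561, 0.545, 0.200, 0.919),
    c("mu_bar",           5.357, 4.780, 4.946, 3.074, 6.000),
    c("alpha",            1.209, 1.251, 1.249, 0.567, 1.943),
    c("m",                0.110, 0.155, 0.148, 0.050, 0.268),
    c("Nm",                  39,    37,    NA,     3, 241),
    c("LDDNm",                8,     8,     8,     0, 15),
    c("STR_MUTRATE",   1.74e-4, 1.72e-4, 1.72e-4, 1.07e-4, 2.36e-4))
  out <- data.frame(param = tab[, 1], stringsAsFactors = FALSE)
  out[c("mode", "mean", "median", "hpdi_lo", "hpdi_hi")] <-
    lapply(2:6, function(j) as.numeric(tab[, j]))
  out
}

#' Quantities derived from the published posterior means
#'
#' Three arithmetic identities over the posterior-mean parameters:
#' \describe{
#'   \item{ldd_mean_distance_km}{mean LDD travel distance: posterior-mean
#'     kernel mean (demes) times the deme side (km).}
#'   \item{census_density_per_km2}{implied census density: posterior-mean
#'     `K` scaled by a 3:1 census:effective ratio over a deme's area.}
#'   \item{ldd_migrants_pct_of_K}{LDD migrants leaving a deme per
#'     generation, as a percentage of the local effective size `K`.}
#' }
#'
#' @param deme_side_km deme side in km (150 by default).
#' @param census_ratio census:effective population size ratio.
#' @return named numeric vector of the three derived quantities.
#' @export
derived_identities <- function(deme_side_km = 150, census_ratio = 3) {
  tab <- published_posteriors()
  g <- function(p, col = "mean") tab[tab$param == p, col]
  c(ldd_mean_distance_km = g("mu_bar") * deme_side_km,
    census_density_per_km2 = g("K") * census_ratio / deme_side_km^2,
    ldd_migrants_pct_of_K = 100 * g("LDDNm") / g("K"))
}
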