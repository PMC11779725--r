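#' Published cultivar-level stomatal trait summaries
#'
#' Reference mean +/- SD summaries of the 11 stomatal traits for the maize
#' hybrid Jingnongke 728 and its parental inbred lines 2416 and MC01,
#' pooled over reproductive stages and leaf layers. Shipped as a worked
#' example input for the statistics layer: the trait means feed the
#' heterosis-rate computation and the circularity consistency check
#' (4*pi*SA/SP^2 of the 728 means reproduces its published roundness of
#' 0.63 at two decimals).
#'
#' @return data.frame with one row per cultivar and columns
#'   \code{<trait>} (mean) and \code{<trait>_sd} for each of the 11 traits.
#' @examples
#' tab <- cultivarTraitMeans()
#' roundness(tab$SA[tab$cultivar == "728"], tab$SP[tab$cultivar == "728"])
#' @export
cultivarTraitMeans <- function() {
  path <- system.file("extdata", "cultivar_trait_means.csv",
                      package = "stomataMorph", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
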