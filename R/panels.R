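#' Packaged reference affinity panels
#'
#' Small curated tables distributed with the package and used in examples
#' and acceptance checks: the SPR affinity panel of the twelve
#' computationally designed binder candidates (\code{"computational"};
#' \code{kd_nM} is NA for candidates that were not expressed or showed no
#' binding), the lab-scale and micro-scale affinity panel of the four
#' display-selected hits (\code{"experimental"}), and the strength-band
#' sizes of the candidates that reached the simulation stage of the
#' funnel (\code{"md_bands"}).
#'
#' @param which One of \code{"computational"}, \code{"experimental"},
#'   \code{"md_bands"}.
#' @return A data frame.
#' @examples
#' panel <- reference_panel("computational")
#' min(panel$kd_nM, na.rm = TRUE)
#' @export
reference_panel <- function(which = c("computational", "experimental",
                                      "md_bands")) {
  which <- match.arg(which)
  file <- switch(which,
                 computational = "affinity_computational.tsv",
                 experimental = "affinity_experimental.tsv",
                 md_bands = "md_band_sizes.tsv")
  path <- system.file("extdata", file, package = "ubinder")
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, na.strings = "NA")
}
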