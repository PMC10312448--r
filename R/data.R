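#' Metadata of published morphometric benchmark datasets
#'
#' Summary metadata for twenty publicly available landmark-based
#' morphometric datasets commonly used to benchmark shape classifiers:
#' taxonomic family, landmarked anatomy, total sample size, classified
#' trait, number of class levels, number of phenotypic variables
#' (landmarks times dimensions), and classification task (ten binary,
#' ten multi-class). Shipped as a plain CSV under `inst/extdata`.
#'
#' @return Data frame with columns `family`, `anatomy`, `n`, `class`,
#'   `levels`, `variables`, `task`.
#' @examples
#' bd <- benchmark_datasets()
#' tapply(bd$n, bd$task, mean)
#' @export
benchmark_datasets <- function() {
  utils::read.csv(system.file("extdata", "benchmark_datasets.csv",
                              package = "morphoblend"),
                  stringsAsFactors = FALSE)
}
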