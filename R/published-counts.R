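# Reference confusion counts bundled with the package.

#' Published verification confusion counts
#'
#' Confusion counts (and the statistics derived from them, printed to four
#' decimals) reported by published large-scale chest-radiograph
#' verification experiments: the ChestX-ray14 training-set-size and
#' negative-pair-handling series, the foreign-material subsets, and the
#' external CheXpert / COVID-19 evaluations. Bundled so that
#' [confusion_metrics()] can be validated against, and reports reproduced
#' from, the printed count fractions.
#'
#' @return Data frame with columns `experiment`, `setting`, `tp`, `fn`,
#'   `tn`, `fp` and the printed `accuracy`, `specificity`, `recall`,
#'   `precision`, `f1`.
#' @export
published_verification_counts <- function() {
  utils::read.csv(system.file("extdata",
                              "verification_confusion_counts.csv",
                              package = "xrayid", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}
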