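#' @importFrom rlang %||% abort warn inform .data
#' @importFrom tibble tibble as_tibble
#' @importFrom stats sd var rnorm runif rbinom setNames complete.cases optimize aov cor cor.test dist prcomp
#' @importFrom utils head tail combn read.csv write.csv
NULL

# kPa -> N/mm^2 (MPa). The package-wide unit system is mm / N / MPa.
kpa_to_nmm2 <- function(kpa) kpa * 1e-3
nmm2_to_kpa <- function(nmm2) nmm2 * 1e3

stop_input <- function(msg, ...) abort(sprintf(msg, ...), class = "craniomech_error")

assert_scalar_pos <- function(x, what, context = NULL) {
  bad <- !is.numeric(x) | !is.finite(x) | x <= 0
  if (any(bad)) {
    where <- if (!is.null(context)) paste0(" for ", paste(context[bad], collapse = ", ")) else ""
    stop_input("`%s` must be positive and finite%s (got %s)", what, where,
               paste(format(x[bad]), collapse = ", "))
  }
  invisible(x)
}

# canonical 6 significant digit formatting used by the pipeline writers
format_sig <- function(x, digits = 6) {
  ifelse(is.na(x), NA_character_, formatC(signif(x, digits), format = "g", digits = digits))
}
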