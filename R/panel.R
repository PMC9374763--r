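#' Brain cancer cell-line panel: PFKFB3 overexpression calls
#'
#' Western-blot overexpression calls for PFKFB3 across the seven brain
#' cancer cell lines assayed alongside the breast panel: the three
#' neuroblastoma lines IMR-5, IMR-32 and SK-N-AS overexpress PFKFB3,
#' while SK-N-BE(2) and the glioblastoma lines A-172, M059J and M059K do
#' not (PFKFB3 was undetectable in the glioblastoma lines).
#'
#' @return Data frame: `cell_line`, `type`, `pfkfb3_overexpressed`
#'   (integer 0/1).
#' @export
pfkfb3_brain_panel <- function() {
  path <- system.file("extdata", "brain_panel_pfkfb3.tsv",
                      package = "trfkit", mustWork = TRUE)
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  df$pfkfb3_overexpressed <- as.integer(df$pfkfb3_overexpressed)
  df
}

#' Percent of a panel scoring positive
#'
#' @param calls Integer/logical vector of 0/1 calls.
#' @return Percentage, `100 * sum(calls) / length(calls)`.
#' @examples
#' panel <- pfkfb3_brain_panel()
#' panel_positive_percent(panel$pfkfb3_overexpressed) # 42.857...
#' @export
panel_positive_percent <- function(calls) {
  stopifnot(length(calls) > 0L, all(calls %in% c(0L, 1L, TRUE, FALSE)))
  100 * sum(calls) / length(calls)
}
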