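# Warwick-Edinburgh Mental Well-being Scale (WEMWBS) scoring.

#' Score the 14-item WEMWBS
#'
#' Sums the 14 item responses (each 1-5) into the total score, which ranges
#' 14-70 with higher values indicating better mental well-being. No
#' imputation is performed: missing or out-of-range items are an error.
#'
#' @param items numeric vector of 14 responses, or an n x 14 matrix/data
#'   frame (one respondent per row).
#' @return integer score (or vector of scores), between 14 and 70.
#' @examples
#' score_wemwbs(rep(1, 14))  # 14
#' score_wemwbs(rep(5, 14))  # 70
#' @export
score_wemwbs <- function(items) {
  if (is.data.frame(items)) items <- as.matrix(items)
  if (!is.matrix(items)) items <- matrix(items, nrow = 1L)
  if (ncol(items) != 14L) {
    stop("WEMWBS has 14 items; got ", ncol(items), " columns")
  }
  if (anyNA(items)) stop("missing item responses; no imputation is applied")
  if (any(items != round(items)) || any(items < 1) || any(items > 5)) {
    stop("item responses must be integers in 1..5")
  }
  s <- as.integer(rowSums(items))
  if (length(s) == 1L) s[[1L]] else s
}
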