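#' @importFrom rlang %||% abort warn inform
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   left_join inner_join anti_join bind_rows bind_cols distinct n count rename
#'   row_number across all_of if_else first last pull slice slice_max desc
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom purrr map map2 pmap map_dbl map_int map_chr map_lgl imap
#'   list_rbind keep
#' @importFrom stats nls coef dnbinom pchisq p.adjust wilcox.test median
#'   rnorm rpois rnbinom rbinom runif rmultinom setNames optimize sd
#'   model.matrix quantile
#' @importFrom utils head tail
NULL

# parse "chrom:start-end" into a list; also accepts a list/tibble row
parse_region <- function(region) {
  if (is.null(region)) return(NULL)
  if (is.list(region)) {
    stopifnot(all(c("chrom", "start", "end") %in% names(region)))
    return(list(chrom = as.character(region$chrom[1]),
                start = as.integer(region$start[1]),
                end = as.integer(region$end[1])))
  }
  m <- regmatches(region, regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1]]
  if (length(m) != 4L) {
    abort(paste0("invalid region '", region, "'; expected chrom:start-end"))
  }
  list(chrom = m[2], start = as.integer(m[3]), end = as.integer(m[4]))
}

geometric_mean <- function(x) exp(mean(log(x)))

# draw a derived seed for a sub-task; keeps values inside 32-bit range
derive_seed <- function(seed, offset) {
  (as.integer(seed) * 7919L + as.integer(offset) * 104729L) %% 2147483587L
}

#' Mean of the shortest half (shorth location estimator)
#'
#' Robust location estimator used when computing size factors from low,
#' discrete counts: the mean of the shortest interval of the sorted data
#' containing `ceiling(n / 2)` observations.  Ties between equally short
#' intervals are broken by taking the leftmost one.
#'
#' @param x numeric vector with at least one finite value.
#' @return a single numeric value.
#' @examples
#' shorth(c(1, 1.1, 1.2, 5, 9))  # 1.1
#' @export
shorth <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) abort("shorth() needs at least one finite value")
  x <- sort(x)
  n <- length(x)
  h <- ceiling(n / 2)
  if (h == n) return(mean(x))
  widths <- x[h:n] - x[1:(n - h + 1)]
  i <- which.min(widths)  # which.min is leftmost on ties
  mean(x[i:(i + h - 1)])
}
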