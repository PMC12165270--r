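#' Gini coefficient of a usage distribution
#'
#' The Gini coefficient by the mean-absolute-difference definition
#' G = sum_ij |x_i - x_j| / (2 n^2 mu), computed through its sorted-rank
#' identity G = (2 sum_i i x_(i) - (n+1) sum x) / (n sum x). 0 means all
#' patients use the same amount; values near 1 mean use is concentrated in
#' very few patients.
#'
#' @param usages Non-negative usage values, length >= 2, not all zero.
#' @return Gini coefficient in [0, 1).
#' @export
gini <- function(usages) {
  if (length(usages) < 2) stop("need at least 2 values", call. = FALSE)
  if (any(usages < 0)) stop("usages must be non-negative", call. = FALSE)
  if (all(usages == 0)) stop("usages must not be all zero", call. = FALSE)
  x <- sort(usages)
  n <- length(x)
  # perfect equality is exactly 0, with no accumulated rounding
  if (x[1] == x[n]) return(0)
  (2 * sum(seq_len(n) * x) - (n + 1) * sum(x)) / (n * sum(x))
}

#' Classic Lorenz curve points
#'
#' Cumulative population fraction (patients sorted by ascending usage)
#' against cumulative usage fraction, starting at (0, 0) and ending at
#' (1, 1).
#'
#' @inheritParams gini
#' @return Tibble with `p` (population fraction) and `L` (usage share).
#' @export
lorenz_curve <- function(usages) {
  if (any(usages < 0)) stop("usages must be non-negative", call. = FALSE)
  x <- sort(usages)
  n <- length(x)
  tibble::tibble(p = c(0, seq_len(n) / n),
                 L = c(0, cumsum(x) / sum(x)))
}

#' Modified Lorenz curves by subgroup
#'
#' For each subgroup of an age stratum, ranks patients by annual FTD usage
#' in descending order (ties broken by patient id) and reports, at each
#' top-population fraction f, the share of the PARENT stratum's total
#' usage consumed by the subgroup's top `ceiling(f * n)` patients. At
#' f = 1 the subgroup shares of a stratum sum to 1. Set
#' `denominator = "group"` for the classic within-group normalization.
#'
#' @param usage Tibble with columns `patient_id`, `stratum` (e.g. "W"/"O"),
#'   `group` (e.g. "WM-I"), and `usage` (annual FTD MME).
#' @param f Top-population fractions to evaluate; default 1%..100%.
#' @param denominator `"stratum"` (default) or `"group"`.
#' @return Tibble: `stratum`, `group`, `f`, `n_top`, `share`, plus the
#'   per-row `group_total` and `stratum_total`.
#' @export
modified_lorenz <- function(usage, f = seq(0.01, 1, by = 0.01),
                            denominator = c("stratum", "group")) {
  denominator <- match.arg(denominator)
  stopifnot(all(c("patient_id", "stratum", "group", "usage") %in% names(usage)),
            all(f > 0 & f <= 1))
  usage <- dplyr::mutate(
    dplyr::group_by(usage, .data$stratum),
    stratum_total = sum(.data$usage)
  )
  usage <- dplyr::ungroup(usage)
  blocks <- split(usage, paste(usage$stratum, usage$group, sep = "\r"))
  dplyr::bind_rows(lapply(unname(blocks), function(b) {
    if (nrow(b) == 0) stop("empty group", call. = FALSE)
    b <- b[order(-b$usage, b$patient_id), ]
    total <- if (denominator == "stratum") b$stratum_total[1] else sum(b$usage)
    k <- pmin(ceiling(f * nrow(b)), nrow(b))
    tibble::tibble(
      stratum = b$stratum[1], group = b$group[1], f = f, n_top = k,
      share = cumsum(b$usage)[k] / total,
      group_total = sum(b$usage), stratum_total = b$stratum_total[1]
    )
  }))
}

#' Gini coefficients per age stratum
#'
#' Computes the Gini coefficient of patient-level annual FTD usage within
#' each stratum, pooling patient-years across the study period.
#'
#' @inheritParams modified_lorenz
#' @return Tibble with `stratum`, `n`, and `gini`.
#' @export
gini_by_stratum <- function(usage) {
  dplyr::summarise(
    dplyr::group_by(usage, .data$stratum),
    n = dplyr::n(),
    gini = gini(.data$usage),
    .groups = "drop"
  )
}
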