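#' @keywords internal
"_PACKAGE"

#' Stratification constants
#'
#' The unit of computation is a stratum: a 10-year age group crossed with
#' sex and Index of Multiple Deprivation (IMD) quintile (1 = most affluent,
#' 5 = most deprived). Seven age groups x two sexes x five quintiles give
#' 70 strata covering the adult population aged 25 and over.
#'
#' @format `age_groups()` returns a character vector of the seven age-group
#'   labels; `sexes()` the two sex labels; `imd_quintiles()` the integers
#'   1:5.
#' @name strata
NULL

#' @rdname strata
#' @export
age_groups <- function() {
  c("25-34", "35-44", "45-54", "55-64", "65-74", "75-84", "85+")
}

#' @rdname strata
#' @export
sexes <- function() c("male", "female")

#' @rdname strata
#' @export
imd_quintiles <- function() 1:5

#' Map IMD quintiles to socio-economic circumstance (SEC) groups
#'
#' Quintiles 1 and 2 are pooled as the low-deprivation group, quintile 3
#' forms the middle group, and quintiles 4 and 5 the high-deprivation
#' group. This three-group coarsening matches the resolution at which
#' SSB intake and price responsiveness are typically estimable from
#' national diet surveys.
#'
#' @param quintile integer vector of IMD quintiles in 1:5.
#' @param grouping named character vector mapping quintile ("1".."5") to
#'   an SEC group label; the default pools 1+2 and 4+5.
#' @return character vector of SEC group labels ("low", "mid", "high",
#'   read as levels of deprivation).
#' @export
#' @examples
#' sec_group(1:5)
sec_group <- function(quintile, grouping = default_sec_grouping()) {
  q <- as.character(quintile)
  if (!all(q %in% names(grouping))) {
    stop("unknown IMD quintile(s): ",
         paste(setdiff(q, names(grouping)), collapse = ", "))
  }
  unname(grouping[q])
}

#' @rdname sec_group
#' @export
default_sec_grouping <- function() {
  c("1" = "low", "2" = "low", "3" = "mid", "4" = "high", "5" = "high")
}

#' All 70 strata as a data frame
#'
#' @return data.frame with columns `age_group`, `sex`, `imd_quintile`,
#'   ordered by age, then sex, then quintile.
#' @export
stratum_grid <- function() {
  g <- expand.grid(imd_quintile = imd_quintiles(),
                   sex = sexes(),
                   age_group = age_groups(),
                   stringsAsFactors = FALSE,
                   KEEP.OUT.ATTRS = FALSE)
  g <- g[, c("age_group", "sex", "imd_quintile")]
  g <- g[order(match(g$age_group, age_groups()),
               match(g$sex, sexes()),
               g$imd_quintile), , drop = FALSE]
  rownames(g) <- NULL
  g
}

# shared numeric tolerance for "shares sum to 1" style checks
.share_tol <- 1e-9

check_shares <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop(what, " must be fractions in [0, 1]")
  }
  if (abs(sum(x) - 1) > .share_tol) {
    stop(what, " must sum to 1 (got ", format(sum(x), digits = 12), ")")
  }
  invisible(x)
}
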