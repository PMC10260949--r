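#' Construct and validate a stratified baseline table
#'
#' The baseline table holds, per stratum (age group x sex x IMD
#' quintile), everything the mortality engine needs about the reference
#' population in the target year:
#' \describe{
#'   \item{deaths}{projected CHD deaths per year in the stratum.}
#'   \item{population}{persons in the stratum.}
#'   \item{intake}{mean SSB intake, g/day.}
#'   \item{overweight}{prevalence of overweight/obesity (fraction).}
#'   \item{p_diag, p_undiag, p_none}{proportions of CHD deaths occurring
#'     in people with diagnosed CHD, undiagnosed CHD and no prior CHD
#'     diagnosis; must sum to 1.}
#'   \item{surv_diag, surv_undiag, surv_none}{median survival (years)
#'     that a prevented death in each CHD-status group would gain.}
#' }
#'
#' @param df data.frame with columns `age_group`, `sex`, `imd_quintile`
#'   and the fields above, one row per stratum, covering all 70 strata.
#' @return validated data.frame of class `c("baseline_table",
#'   "data.frame")`, ordered by age group, sex, quintile.
#' @export
baseline_table <- function(df) {
  validate_baseline(df)
}

baseline_fields <- function() {
  c("deaths", "population", "intake", "overweight",
    "p_diag", "p_undiag", "p_none",
    "surv_diag", "surv_undiag", "surv_none")
}

#' @rdname baseline_table
#' @param baseline object to validate.
#' @export
validate_baseline <- function(baseline) {
  need <- c("age_group", "sex", "imd_quintile", baseline_fields())
  missing <- setdiff(need, names(baseline))
  if (length(missing)) {
    stop("baseline table is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  df <- as.data.frame(baseline)[, need]
  grid <- stratum_grid()
  key <- function(d) paste(d$age_group, d$sex, d$imd_quintile)
  if (anyDuplicated(key(df))) stop("duplicate strata in baseline table")
  if (!setequal(key(df), key(grid))) {
    stop("baseline table must contain exactly the ", nrow(grid),
         " strata (7 age groups x 2 sexes x 5 IMD quintiles)")
  }
  df <- df[match(key(grid), key(df)), , drop = FALSE]
  rownames(df) <- NULL
  num <- df[baseline_fields()]
  if (any(!vapply(num, is.numeric, logical(1))) ||
      any(!is.finite(as.matrix(num)))) {
    stop("baseline fields must be finite numerics")
  }
  if (any(df$deaths < 0) || any(df$population < 0)) {
    stop("deaths and population must be non-negative")
  }
  if (any(df$intake < 0)) stop("intake must be non-negative")
  if (any(df$overweight < 0 | df$overweight > 1)) {
    stop("overweight must be a fraction in [0, 1]")
  }
  p <- as.matrix(df[c("p_diag", "p_undiag", "p_none")])
  if (any(p < 0 | p > 1) || any(abs(rowSums(p) - 1) > .share_tol)) {
    stop("CHD-status proportions must be fractions summing to 1")
  }
  s <- as.matrix(df[c("surv_diag", "surv_undiag", "surv_none")])
  if (any(s <= 0)) stop("median survival must be positive")
  class(df) <- c("baseline_table", "data.frame")
  df
}

#' Read / write baseline tables as tab-delimited text
#'
#' The on-disk format is a plain TSV with a header naming the stratum
#' keys (`age_group`, `sex`, `imd_quintile`) and the baseline fields
#' documented in [baseline_table()].
#'
#' @param path file path.
#' @param baseline a validated baseline table.
#' @return `read_baseline()` returns a validated baseline table;
#'   `write_baseline()` returns `path` invisibly.
#' @export
read_baseline <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  validate_baseline(df)
}

#' @rdname read_baseline
#' @export
write_baseline <- function(baseline, path) {
  baseline <- validate_baseline(baseline)
  utils::write.table(baseline, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
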