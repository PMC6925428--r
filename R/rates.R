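#' Classify mothers' nationality group
#'
#' The two analysis groups: Spanish nationals and nationals of high-income
#' countries form one category ("Spanish"); nationals of low- and
#' middle-income countries form the other ("LIC"). High income is a gross
#' national per-capita income of at least $12,056 (World Bank threshold),
#' inclusive.
#'
#' @param gni_per_capita GNI per capita in US dollars of the mother's
#'   country of nationality (may be `NA` when `is_spanish` is `TRUE`).
#' @param is_spanish logical; Spanish national.
#' @return character vector, `"Spanish"` or `"LIC"`.
#' @export
classify_nationality <- function(gni_per_capita = NA_real_, is_spanish = FALSE) {
  n <- max(length(gni_per_capita), length(is_spanish))
  gni <- rep_len(gni_per_capita, n)
  sp <- rep_len(is_spanish, n)
  miss <- !sp & (is.na(gni))
  if (any(miss, na.rm = TRUE) || anyNA(sp))
    stop("need either is_spanish = TRUE or a GNI per capita for every record")
  if (any(gni < 0, na.rm = TRUE)) stop("GNI per capita must be non-negative")
  ifelse(sp | (!is.na(gni) & gni >= 12056), "Spanish", "LIC")
}

#' Assign reproductive-age group
#'
#' Maps completed age in years at delivery to the narrow analysis group;
#' every woman aged 15-49 also belongs to the global 15-49 group.
#'
#' @param age integer-valued age(s) in completed years; must lie in 15-49.
#' @return data.frame with `age_group` (narrow label) and `in_15_49`
#'   (always `TRUE`; membership in the global group).
#' @export
assign_age_group <- function(age) {
  if (any(!is.finite(age)) || any(age < 15 | age > 49))
    stop("age must lie within the reproductive range 15-49")
  lab <- cut(age, breaks = c(15, 20, 25, 35, 50), right = FALSE,
             labels = narrow_age_groups)
  data.frame(age_group = as.character(lab), in_15_49 = TRUE,
             stringsAsFactors = FALSE)
}

#' Crude fertility rates per 1000 women
#'
#' Adds the crude rate `1000 * births / women` to a stratified counts
#' table. Cells with zero woman-years are flagged `undefined` and carry an
#' `NA` rate, never a conventional zero.
#'
#' @param counts data.frame with integer columns `births` and `women`
#'   (plus any stratification columns, carried through).
#' @return the input with `rate` (per 1000) and `undefined` columns added.
#' @export
crude_rate <- function(counts) {
  if (!all(c("births", "women") %in% names(counts)))
    stop("counts must have 'births' and 'women' columns")
  if (any(counts$births < 0) || any(counts$women < 0))
    stop("counts must be non-negative")
  undefined <- counts$women == 0
  rate <- ifelse(undefined, NA_real_, 1000 * counts$births / counts$women)
  counts$rate <- rate
  counts$undefined <- undefined
  counts
}

#' Rates table in wide period layout
#'
#' Reshapes crude rates to the reporting layout: one row per age group x
#' nationality, one column per period.
#'
#' @param counts stratified counts data.frame (long).
#' @return wide data.frame `age_group, nationality, <period columns>` of
#'   rates per 1000 (counts pooled over tracts within each cell).
#' @export
rates_table <- function(counts) {
  agg <- stats::aggregate(cbind(births, women) ~ period + age_group + nationality,
                          data = counts, FUN = sum)
  agg <- crude_rate(agg)
  wide <- stats::reshape(agg[, c("age_group", "nationality", "period", "rate")],
                         idvar = c("age_group", "nationality"),
                         timevar = "period", direction = "wide")
  names(wide) <- sub("^rate\\.", "", names(wide))
  rownames(wide) <- NULL
  wide[order(wide$nationality, wide$age_group), , drop = FALSE]
}
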