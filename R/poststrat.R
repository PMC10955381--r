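# Poststratification: re-weighting model-based counterfactual predictions
# to an external target population defined by a banded stratum table.

#' Default banding of continuous covariates for stratification
#'
#' External census-style tables come banded; these defaults use 10-year
#' age bands from 17 and 5-year education bands, matching the education
#' counterfactual grid.
#'
#' @param age_breaks,education_breaks,children_breaks left-closed break
#'   sequences handed to `cut()` (right-open, last band unbounded).
#' @return A list of break vectors, class `strata_bands`.
#' @export
strata_bands <- function(age_breaks = c(17, 27, 37, 47, 57, 67, Inf),
                         education_breaks = c(0, 5, 10, 15, 20, 25, Inf),
                         children_breaks = c(0, 1, 3, 5, Inf)) {
  structure(list(age = age_breaks, education = education_breaks,
                 children = children_breaks), class = "strata_bands")
}

band_label <- function(x, breaks) {
  as.character(cut(x, breaks = breaks, right = FALSE, include.lowest = FALSE))
}

#' Build a stratum table
#'
#' Validates and normalizes an external stratum-weight table. Columns may
#' be any subset of `sex`, `food_insecure`, `age_band`, `education_band`,
#' `children_band` plus a nonnegative `weight` column; weights are
#' normalized to sum to 1. Stratum definitions must be unique.
#'
#' @param df data.frame of strata.
#' @return The normalized table, class `strata_table`.
#' @export
strata_table <- function(df) {
  if (!"weight" %in% names(df)) stop("missing weight column", call. = FALSE)
  vars <- setdiff(names(df), "weight")
  allowed <- c("sex", "food_insecure", "age_band", "education_band",
               "children_band")
  bad <- setdiff(vars, allowed)
  if (length(bad)) stop("unknown stratum column(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  if (length(vars) == 0L) stop("no stratifying columns", call. = FALSE)
  if (any(df$weight < 0) || sum(df$weight) <= 0) {
    stop("weights must be nonnegative with positive sum", call. = FALSE)
  }
  key <- do.call(paste, c(df[vars], sep = "\r"))
  if (anyDuplicated(key)) stop("duplicated stratum definitions", call. = FALSE)
  df$weight <- df$weight / sum(df$weight)
  structure(df, class = c("strata_table", "data.frame"), vars = vars)
}

#' @rdname strata_table
#' @param path CSV path: one column per stratifying covariate plus
#'   `weight`.
#' @export
read_strata_csv <- function(path) {
  strata_table(utils::read.csv(path, stringsAsFactors = FALSE,
                               check.names = FALSE))
}

# Map each individual to a stratum row index; errors list offenders.
assign_strata <- function(table, strata, bands = strata_bands()) {
  vars <- attr(strata, "vars")
  cov <- data.frame(row.names = seq_len(nrow(table)))
  for (v in vars) {
    cov[[v]] <- switch(v,
      sex = as.integer(table$sex),
      food_insecure = as.integer(table$food_insecure),
      age_band = band_label(table$age, bands$age),
      education_band = band_label(table$education, bands$education),
      children_band = band_label(table$children, bands$children))
  }
  skey <- do.call(paste, c(lapply(strata[vars], as.character), sep = "\r"))
  ikey <- do.call(paste, c(lapply(cov, as.character), sep = "\r"))
  if (anyDuplicated(skey)) stop("duplicated stratum definitions", call. = FALSE)
  idx <- match(ikey, skey)
  if (anyNA(idx)) {
    stop("individual(s) matching no stratum: rows ",
         paste(utils::head(which(is.na(idx)), 10L), collapse = ", "),
         call. = FALSE)
  }
  idx
}

#' Poststratify counterfactual predictions to a target population
#'
#' Per posterior draw and exposure level, computes the weighted sum over
#' strata of the mean category-probability vector within each stratum,
#' using the external weights; then summarizes across draws. With weights
#' equal to the empirical stratum frequencies this reproduces
#' [marginalize()]'s pooled output.
#'
#' The target population is external to the sampled sites, so the
#' poststratified estimand averages over the sample's site composition
#' exactly as the individuals do (each individual keeps their site's
#' effects); strata are defined on individual covariates only.
#'
#' @param po a `potential_outcomes` array.
#' @param strata a [strata_table()].
#' @param table the covariate table the array was imputed over (same row
#'   order).
#' @param bands a [strata_bands()].
#' @param prob central interval mass.
#' @return A `counterfactual_summary` data.frame (site column = "target").
#' @export
poststratify <- function(po, strata, table, bands = strata_bands(),
                         prob = 0.95) {
  stopifnot(inherits(po, "potential_outcomes"), inherits(strata, "strata_table"))
  if (nrow(table) != dim(po)[2L]) {
    stop("table rows must match the potential-outcomes array", call. = FALSE)
  }
  idx <- assign_strata(table, strata, bands)
  empty <- setdiff(which(strata$weight > 0), unique(idx))
  if (length(empty)) {
    stop("empty stratum with positive weight: row(s) ",
         paste(empty, collapse = ", "), call. = FALSE)
  }
  dims <- dim(po)
  acc <- array(0, dims[c(1L, 3L, 4L)])
  for (s in unique(idx)) {
    rows <- which(idx == s)
    block <- apply(po[, rows, , , drop = FALSE], c(1L, 3L, 4L), mean)
    acc <- acc + strata$weight[s] * block
  }
  out <- array(acc, c(dims[1L], 1L, dims[3L], dims[4L]),
               dimnames = list(NULL, "target", dimnames(po)[[3]],
                               dimnames(po)[[4]]))
  # strata with zero weight contribute nothing; weights already sum to 1
  # over all strata, and every positive-weight stratum is populated.
  summ <- summarize_unit_draws(out, attr(po, "exposure"), attr(po, "levels"),
                               prob)
  structure(summ, class = c("counterfactual_summary", "data.frame"))
}
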