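SURVEY_COLS <- c("site", "sex", "age", "education", "children",
                 "food_insecure", "think_freq", "ritual_freq")

#' Read and validate a survey CSV
#'
#' Parses the fixed-schema survey file (columns site, sex, age, education,
#' children, food_insecure, think_freq, ritual_freq; empty cells are
#' missing) and validates value domains: ordinal outcomes in 1–5,
#' food_insecure in {0, 1}, sex in {0, 1}, education in [0, 30], age >= 17,
#' children >= 0. Rows with out-of-domain cells are flagged with a reason —
#' not silently dropped — and a per-column missingness report is attached.
#'
#' @param path CSV path.
#' @return The parsed data.frame with attributes `invalid` (data.frame
#'   `row`, `reason`) and `missingness` (named per-column NA counts).
#' @export
read_survey_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                         colClasses = c(site = "character"))
  miss <- setdiff(SURVEY_COLS, names(tab))
  if (length(miss)) {
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  tab <- tab[SURVEY_COLS]
  for (col in setdiff(SURVEY_COLS, "site")) {
    if (!is.numeric(tab[[col]])) {
      suppressWarnings(tab[[col]] <- as.numeric(tab[[col]]))
    }
  }
  rules <- list(
    sex = function(v) v %in% c(0, 1),
    age = function(v) v >= 17,
    education = function(v) v >= 0 & v <= 30,
    children = function(v) v >= 0,
    food_insecure = function(v) v %in% c(0, 1),
    think_freq = function(v) v %in% 1:5,
    ritual_freq = function(v) v %in% 1:5
  )
  invalid <- data.frame(row = integer(), reason = character(),
                        stringsAsFactors = FALSE)
  for (col in names(rules)) {
    v <- tab[[col]]
    bad <- which(!is.na(v) & !rules[[col]](v))
    if (length(bad)) {
      invalid <- rbind(invalid,
                       data.frame(row = bad,
                                  reason = paste0(col, "=", v[bad],
                                                  " out of range"),
                                  stringsAsFactors = FALSE))
    }
  }
  attr(tab, "invalid") <- invalid[order(invalid$row), , drop = FALSE]
  attr(tab, "missingness") <- vapply(tab, function(v) sum(is.na(v)), integer(1))
  tab
}

#' Complete-case filter
#'
#' Retains rows with no missing value among the listed variables (the
#' analysis is complete-case by design) and reports retained/dropped
#' counts per site via `message()`.
#'
#' @param table survey data.frame.
#' @param variables columns that must be non-missing (default: all model
#'   variables of both outcomes).
#' @param quiet suppress the per-site report.
#' @return The filtered table; attribute `dropped` holds the dropped row
#'   count.
#' @export
complete_cases <- function(table, variables = SURVEY_COLS, quiet = FALSE) {
  bad <- setdiff(variables, names(table))
  if (length(bad)) stop("unknown variable(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  keep <- stats::complete.cases(table[variables])
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (!quiet) {
    per_site <- table(ifelse(is.na(table$site), "<missing site>",
                             as.character(table$site)), keep)
    kept <- sum(keep)
    message("complete_cases: retained ", kept, "/", nrow(table), " rows (",
            nrow(table) - kept, " dropped)")
    if (any(!keep)) {
      drops <- per_site[, "FALSE", drop = TRUE]
      drops <- drops[drops > 0]
      message("  dropped by site: ",
              paste(names(drops), drops, sep = "=", collapse = ", "))
    }
  }
  attr(out, "dropped") <- nrow(table) - sum(keep)
  # preserve generator ground-truth attributes under subsetting
  se <- attr(table, "site_effects")
  if (!is.null(se)) attr(out, "site_effects") <- se
  et <- attr(table, "education_type")
  if (!is.null(et)) attr(out, "education_type") <- et[keep]
  out
}

#' Write a counterfactual summary as tidy CSV
#'
#' Columns site, exposure, level, category, mean, lower, upper, interval,
#' preceded by `# key: value` header lines carrying the config hash and
#' seed so reruns are attributable.
#'
#' @param summary a `counterfactual_summary`.
#' @param path output path.
#' @param meta named character vector written as header comments.
#' @return `path`, invisibly.
#' @export
write_summary_csv <- function(summary, path, meta = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(meta)) writeLines(sprintf("# %s: %s", names(meta), meta), con)
  df <- as.data.frame(summary)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) signif(v, 12))
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a counterfactual summary written by [write_summary_csv()]
#' @param path CSV path.
#' @return A data.frame (header comments skipped).
#' @export
read_summary_csv <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}
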