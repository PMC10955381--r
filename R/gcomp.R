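#' Counterfactual exposure grid
#'
#' The hypothetical exposure levels at which potential outcomes are
#' imputed: food insecurity is contrasted at 0 vs 1; education defaults to
#' 0–30 years in increments of five (the observed range of the
#' instrument).
#'
#' @param exposure `"food_insecure"` or `"education"`.
#' @param levels strictly increasing values within the exposure's domain
#'   (defaults: `c(0, 1)`; `seq(0, 30, 5)`).
#' @return An object of class `exposure_grid`.
#' @export
exposure_grid <- function(exposure = c("food_insecure", "education"),
                          levels = NULL) {
  exposure <- match.arg(exposure)
  if (is.null(levels)) {
    levels <- if (exposure == "food_insecure") c(0, 1) else seq(0, 30, by = 5)
  }
  if (length(levels) < 2L || is.unsorted(levels, strictly = TRUE)) {
    stop("levels must be >= 2 strictly increasing values", call. = FALSE)
  }
  dom <- if (exposure == "food_insecure") c(0, 1) else c(0, 30)
  if (any(levels < dom[1L] | levels > dom[2L])) {
    stop("levels outside the ", exposure, " domain [", dom[1L], ", ", dom[2L],
         "]", call. = FALSE)
  }
  structure(list(exposure = exposure, levels = levels), class = "exposure_grid")
}

#' Impute per-individual potential-outcome probabilities
#'
#' The g-computation imputation step: for each posterior draw, individual
#' and grid level, sets the individual's exposure to the level, keeps all
#' other covariates as observed, and records the full category-probability
#' vector (probabilities are retained rather than resampled outcomes,
#' removing an avoidable Monte Carlo layer).
#'
#' @param fit an `ordgcomp_fit`.
#' @param table the complete-case table to impute over (all sites must be
#'   present in the fit).
#' @param grid an [exposure_grid()].
#' @param draw_ids optional subset of draw indices (thinning for large
#'   problems); default all draws.
#' @return An object of class `potential_outcomes`: array
#'   `draw x individual x level x category` with the table's site labels
#'   and the grid attached as attributes.
#' @export
impute_potential_outcomes <- function(fit, table, grid, draw_ids = NULL) {
  stopifnot(inherits(grid, "exposure_grid"))
  spec <- fit$spec
  check_model_table(table, spec)
  if (!all(unique(as.character(table$site)) %in% fit$site_names)) {
    stop("table contains sites absent from the fit", call. = FALSE)
  }
  if (is.null(draw_ids)) draw_ids <- seq_len(n_draws(fit))
  n <- nrow(table)
  nl <- length(grid$levels)
  out <- array(NA_real_,
               c(length(draw_ids), n, nl, spec$K),
               dimnames = list(NULL, NULL, paste0("a", grid$levels),
                               paste0("k", seq_len(spec$K))))
  tabs <- lapply(grid$levels, function(a) {
    t2 <- table
    t2[[grid$exposure]] <- a
    t2
  })
  for (si in seq_along(draw_ids)) {
    d <- as_draw(fit, draw_ids[si])
    for (li in seq_len(nl)) {
      xi <- linear_predictor(tabs[[li]], d, spec)
      out[si, , li, ] <- category_probs(xi, d$kappa)
    }
  }
  structure(out, class = "potential_outcomes", exposure = grid$exposure,
            levels = grid$levels, site = as.character(table$site))
}

# Per-draw site-average (or pooled) probabilities: draw x unit x level x K.
po_unit_means <- function(po, by_site) {
  sites <- attr(po, "site")
  dims <- dim(po)
  if (by_site) {
    units <- sort(unique(sites))
    out <- array(NA_real_, c(dims[1L], length(units), dims[3L], dims[4L]),
                 dimnames = list(NULL, units, dimnames(po)[[3]],
                                 dimnames(po)[[4]]))
    for (ui in seq_along(units)) {
      idx <- which(sites == units[ui])
      block <- po[, idx, , , drop = FALSE]
      out[, ui, , ] <- apply(block, c(1L, 3L, 4L), mean)
    }
  } else {
    out <- array(apply(po, c(1L, 3L, 4L), mean),
                 c(dims[1L], 1L, dims[3L], dims[4L]),
                 dimnames = list(NULL, "pooled", dimnames(po)[[3]],
                                 dimnames(po)[[4]]))
  }
  out
}

summarize_unit_draws <- function(m, exposure, levels, prob) {
  # m: draw x unit x level x K
  lo <- (1 - prob) / 2
  un <- dimnames(m)[[2]]
  rows <- expand.grid(category = seq_len(dim(m)[4L]),
                      level = levels, site = un,
                      stringsAsFactors = FALSE)[, 3:1]
  mean_ <- lower <- upper <- numeric(nrow(rows))
  r <- 1L
  for (ui in seq_along(un)) for (li in seq_along(levels)) {
    for (k in seq_len(dim(m)[4L])) {
      v <- m[, ui, li, k]
      mean_[r] <- mean(v)
      qs <- stats::quantile(v, c(lo, 1 - lo), names = FALSE)
      lower[r] <- qs[1L]; upper[r] <- qs[2L]
      r <- r + 1L
    }
  }
  data.frame(site = rows$site, exposure = exposure, level = rows$level,
             category = rows$category, mean = mean_, lower = lower,
             upper = upper, interval = prob, stringsAsFactors = FALSE)
}

#' Marginalize potential outcomes over the covariate distribution
#'
#' The g-computation standardization step: averages each draw's imputed
#' category probabilities over individuals (within site, or pooled), then
#' summarizes across draws with the posterior mean and a central interval.
#' Per-individual posterior-mean probabilities (the quantities the study's
#' trajectory figures display) are retained as an attribute.
#'
#' @param po a `potential_outcomes` array.
#' @param by_site summarize within site (default, the study's display)
#'   or pooled over the whole sample.
#' @param prob central interval mass (default 0.95).
#' @return A data.frame (class `counterfactual_summary`) with columns
#'   site, exposure, level, category, mean, lower, upper, interval, and
#'   attribute `individual_means` (`individual x level x category`).
#' @export
marginalize <- function(po, by_site = TRUE, prob = 0.95) {
  stopifnot(inherits(po, "potential_outcomes"), prob > 0, prob < 1)
  m <- po_unit_means(po, by_site)
  out <- summarize_unit_draws(m, attr(po, "exposure"), attr(po, "levels"), prob)
  ind <- apply(po, c(2L, 3L, 4L), mean)
  structure(out, class = c("counterfactual_summary", "data.frame"),
            individual_means = ind)
}

#' Contrast marginal probabilities between two exposure levels
#'
#' Per draw, the difference of covariate-averaged category probabilities
#' at `level_b` minus `level_a`, summarized across draws (never as a
#' difference of summaries).
#'
#' @param po a `potential_outcomes` array.
#' @param level_a,level_b levels present in the grid.
#' @inheritParams marginalize
#' @return A data.frame with columns site, category, mean, lower, upper.
#'   Identical levels yield an all-zero contrast (with a note attribute).
#' @export
contrast_levels <- function(po, level_a, level_b, by_site = TRUE, prob = 0.95) {
  stopifnot(inherits(po, "potential_outcomes"))
  levels <- attr(po, "levels")
  ia <- match(level_a, levels); ib <- match(level_b, levels)
  if (is.na(ia) || is.na(ib)) stop("levels must be in the grid", call. = FALSE)
  m <- po_unit_means(po, by_site)
  dm <- m[, , ib, , drop = FALSE] - m[, , ia, , drop = FALSE]
  lo <- (1 - prob) / 2
  un <- dimnames(m)[[2]]
  out <- do.call(rbind, lapply(seq_along(un), function(ui) {
    do.call(rbind, lapply(seq_len(dim(m)[4L]), function(k) {
      v <- dm[, ui, 1L, k]
      data.frame(site = un[ui], category = k, mean = mean(v),
                 lower = stats::quantile(v, lo, names = FALSE),
                 upper = stats::quantile(v, 1 - lo, names = FALSE),
                 stringsAsFactors = FALSE)
    }))
  }))
  out$exposure <- attr(po, "exposure")
  out$level_a <- level_a
  out$level_b <- level_b
  if (level_a == level_b) attr(out, "note") <- "identical levels: zero contrast"
  out
}
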