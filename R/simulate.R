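#' Structural-equation parameters for the synthetic survey generator
#'
#' Bundles the generator's ground truth: effect sizes on the religiosity
#' log-odds scale, structural coefficients for the intermediate variables,
#' monotonic simplexes, cutpoints, and the site-intercept spread. Defaults
#' emulate the study's sampling frame: 14 sites of a few hundred adults
#' (17+), education 0–30 years, binary food-insecurity worry, two 1–5
#' ordinal religiosity outcomes. All defaults live here, in one place.
#'
#' The monotonic coefficients (`beta_edu_on_y`, `beta_age_on_y`,
#' `beta_children_on_y`) are per-increment (average adjacent-level) effects,
#' so the full-range log-odds effect is `beta * D`.
#'
#' @param n_sites,n_per_site sampling frame.
#' @param beta_sex_on_y,beta_m_on_y log-odds effects of the indicator
#'   predictors (male sex; food-insecurity worry) on religiosity.
#' @param beta_edu_on_y,beta_age_on_y,beta_children_on_y per-increment
#'   log-odds effects of the monotonic predictors.
#' @param edu_simplex,age_simplex,children_simplex monotonic shape
#'   simplexes (default: equal weights, i.e. linear effects).
#' @param cutpoints strictly increasing latent thresholds (K - 1 = 4).
#' @param site_effect_sd SD of the Normal site-intercept shifts.
#' @param food_insecurity_coefs logit coefficients (intercept, sex,
#'   age - 17, education, children) for the food-insecurity equation.
#' @param children_rate_coefs log-link coefficients (intercept, education,
#'   age - 17) for the expected number of children.
#' @param education_coefs logit coefficients (intercept, sex, age - 17)
#'   of the Binomial(30) education draw.
#' @param age_beta_shape shape pair of the scaled Beta draw for age - 17
#'   on [0, 60].
#' @param education_type_effect log-odds effect of the latent binary
#'   education-type variable on religiosity (0 disables it).
#' @param education_type_food_effect its log-odds effect on food
#'   insecurity (the confounding scenario).
#' @param seed integer seed making [simulate_population()] deterministic.
#' @return An object of class `scm_params`.
#' @export
scm_params <- function(n_sites = 14L, n_per_site = 150L,
                       beta_sex_on_y = -0.3, beta_m_on_y = 0.8,
                       beta_edu_on_y = -0.02, beta_age_on_y = 0.012,
                       beta_children_on_y = 0.05,
                       edu_simplex = rep(1 / 30, 30),
                       age_simplex = rep(1 / 60, 60),
                       children_simplex = rep(1 / 15, 15),
                       cutpoints = c(-1.5, -0.5, 0.5, 1.5),
                       site_effect_sd = 0.5,
                       food_insecurity_coefs = c(-0.2, 0.25, 0.01, -0.05, 0.15),
                       children_rate_coefs = c(0.3, -0.05, 0.025),
                       education_coefs = c(-0.8, 0.2, -0.012),
                       age_beta_shape = c(1.5, 2.5),
                       education_type_effect = 0,
                       education_type_food_effect = 0,
                       seed = 1L) {
  p <- list(n_sites = as.integer(n_sites), n_per_site = as.integer(n_per_site),
            beta_sex_on_y = beta_sex_on_y, beta_m_on_y = beta_m_on_y,
            beta_edu_on_y = beta_edu_on_y, beta_age_on_y = beta_age_on_y,
            beta_children_on_y = beta_children_on_y,
            edu_simplex = edu_simplex, age_simplex = age_simplex,
            children_simplex = children_simplex, cutpoints = cutpoints,
            site_effect_sd = site_effect_sd,
            food_insecurity_coefs = food_insecurity_coefs,
            children_rate_coefs = children_rate_coefs,
            education_coefs = education_coefs,
            age_beta_shape = age_beta_shape,
            education_type_effect = education_type_effect,
            education_type_food_effect = education_type_food_effect,
            seed = as.integer(seed))
  validate_scm_params(p)
  structure(p, class = "scm_params")
}

validate_scm_params <- function(p) {
  if (p$n_sites < 1L || p$n_per_site < 1L) {
    stop("n_sites and n_per_site must be >= 1", call. = FALSE)
  }
  for (nm in c("edu_simplex", "age_simplex", "children_simplex")) {
    s <- p[[nm]]
    if (any(s < -1e-9) || abs(sum(s) - 1) > 1e-9) {
      stop(nm, " must be nonnegative and sum to 1", call. = FALSE)
    }
  }
  if (is.unsorted(p$cutpoints, strictly = TRUE)) {
    stop("cutpoints must be strictly increasing", call. = FALSE)
  }
  if (p$site_effect_sd < 0) stop("site_effect_sd must be >= 0", call. = FALSE)
  stopifnot(length(p$food_insecurity_coefs) == 5L,
            length(p$children_rate_coefs) == 3L,
            length(p$education_coefs) == 3L,
            length(p$age_beta_shape) == 2L)
  invisible(TRUE)
}

# Age origin of the generator; the instrument's adult cutoff.
AGE_MIN <- 17L

# True linear predictor (without site intercept / latent education type).
scm_linear_predictor <- function(p, sex, age, education, children, food) {
  p$beta_sex_on_y * sex +
    p$beta_m_on_y * food +
    p$beta_edu_on_y * mo(education, p$edu_simplex) +
    p$beta_age_on_y * mo(age - AGE_MIN, p$age_simplex) +
    p$beta_children_on_y * mo(children, p$children_simplex)
}

#' Simulate a cross-site survey population
#'
#' Draws individuals from the generator's structural equations, which
#' follow the study DAG: sex ~ Bernoulli(0.5); age 17 + a truncated Beta
#' draw on [0, 60]; education a sex/age-dependent Binomial on [0, 30];
#' children Poisson with a log rate in education and age (capped at the
#' simplex range); food insecurity Bernoulli with logit linear in sex,
#' age, education and children; both religiosity outcomes drawn
#' independently from the cumulative-logit model at the true monotonic
#' linear predictor plus a Normal(0, site_effect_sd) site intercept.
#' Deterministic given `params$seed`.
#'
#' The returned table carries attributes `site_effects` (the drawn site
#' intercepts) and, when `education_type_effect != 0`, `education_type`
#' (the latent per-individual indicator) — ground truth that
#' [true_marginal_probs()] needs but that is not part of the observed
#' schema.
#'
#' @param params an [scm_params()].
#' @return A data.frame with columns site, sex, age, education, children,
#'   food_insecure, think_freq, ritual_freq.
#' @export
simulate_population <- function(params) {
  if (!inherits(params, "scm_params")) params <- do.call(scm_params, params)
  validate_scm_params(params)
  set.seed(params$seed)
  n <- params$n_sites * params$n_per_site
  site <- rep(sprintf("site_%02d", seq_len(params$n_sites)),
              each = params$n_per_site)
  site_eff <- stats::setNames(stats::rnorm(params$n_sites, 0, params$site_effect_sd),
                              unique(site))
  sex <- stats::rbinom(n, 1L, 0.5)
  age <- AGE_MIN + as.integer(round(60 * stats::rbeta(n, params$age_beta_shape[1L],
                                                      params$age_beta_shape[2L])))
  ec <- params$education_coefs
  education <- stats::rbinom(n, 30L,
                             stats::plogis(ec[1L] + ec[2L] * sex + ec[3L] * (age - AGE_MIN)))
  cc <- params$children_rate_coefs
  children <- pmin(stats::rpois(n, exp(cc[1L] + cc[2L] * education +
                                         cc[3L] * (age - AGE_MIN))),
                   length(params$children_simplex))
  edu_type <- NULL
  fc <- params$food_insecurity_coefs
  food_logit <- fc[1L] + fc[2L] * sex + fc[3L] * (age - AGE_MIN) +
    fc[4L] * education + fc[5L] * children
  if (params$education_type_effect != 0 || params$education_type_food_effect != 0) {
    edu_type <- stats::rbinom(n, 1L, 0.5)
    food_logit <- food_logit + params$education_type_food_effect * edu_type
  }
  food <- stats::rbinom(n, 1L, stats::plogis(food_logit))
  xi <- scm_linear_predictor(params, sex, age, education, children, food) +
    site_eff[site]
  if (!is.null(edu_type)) xi <- xi + params$education_type_effect * edu_type
  pmat <- category_probs(xi, params$cutpoints)
  cum <- t(apply(pmat, 1L, cumsum))
  sample_ord <- function() {
    u <- stats::runif(n)
    as.integer(1L + rowSums(u > cum[, -ncol(cum), drop = FALSE]))
  }
  tab <- data.frame(site = site, sex = sex, age = age, education = education,
                    children = children, food_insecure = food,
                    think_freq = sample_ord(), ritual_freq = sample_ord(),
                    stringsAsFactors = FALSE)
  attr(tab, "site_effects") <- site_eff
  if (!is.null(edu_type)) attr(tab, "education_type") <- edu_type
  tab
}

#' Inject missingness completely at random
#'
#' Sets each cell of each field to missing independently with probability
#' `rate` — used to exercise the complete-case filter the analysis applies.
#'
#' @param table a survey data.frame.
#' @param rate missingness probability in [0, 1).
#' @param seed RNG seed.
#' @return The table with `NA`s injected; generator attributes preserved.
#' @export
inject_missingness <- function(table, rate, seed = 1L) {
  if (!is.numeric(rate) || rate < 0 || rate >= 1) {
    stop("rate must lie in [0, 1)", call. = FALSE)
  }
  if (rate == 0) return(table)
  set.seed(seed)
  out <- table
  for (col in names(out)) {
    hit <- stats::runif(nrow(out)) < rate
    out[[col]][hit] <- NA
  }
  out
}

#' Ground-truth marginal category probabilities under an intervention
#'
#' The g-formula oracle: evaluates the generator's structural equations
#' directly (no outcome sampling), setting the exposure of every
#' individual in `table` to `level` while holding all other covariates —
#' and the site intercepts and any latent education type carried on the
#' table — as observed, and averages the true category-probability
#' vectors.
#'
#' @param params the [scm_params()] that generated (or describe) the table.
#' @param table a survey data.frame (typically from
#'   [simulate_population()]).
#' @param exposure `"food_insecure"` or `"education"`.
#' @param level the counterfactual exposure value.
#' @return Named numeric vector of K category probabilities (sums to 1).
#' @export
true_marginal_probs <- function(params, table, exposure, level) {
  if (!exposure %in% c("food_insecure", "education")) {
    stop("unknown exposure: ", exposure, call. = FALSE)
  }
  if (exposure == "food_insecure" && !level %in% c(0, 1)) {
    stop("food_insecure level must be 0 or 1", call. = FALSE)
  }
  if (exposure == "education" &&
      (level < 0 || level > length(params$edu_simplex))) {
    stop("education level outside domain", call. = FALSE)
  }
  tab <- table
  tab[[exposure]] <- level
  site_eff <- attr(table, "site_effects")
  off <- if (is.null(site_eff)) 0 else site_eff[as.character(tab$site)]
  edu_type <- attr(table, "education_type")
  if (!is.null(edu_type)) off <- off + params$education_type_effect * edu_type
  xi <- scm_linear_predictor(params, tab$sex, tab$age, tab$education,
                             tab$children, tab$food_insecure) + off
  colMeans(category_probs(xi, params$cutpoints))
}

#' Read generator parameters from a flat key-value file
#'
#' Lines of the form `name: value` (or `name = value`); vector-valued
#' fields are comma-separated. Unknown keys are an error; omitted keys
#' keep their [scm_params()] defaults.
#'
#' @param path file path.
#' @return An [scm_params()].
#' @export
scm_params_from_file <- function(path) {
  kv <- read_keyvalue(path)
  defaults <- formals(scm_params)
  unknown <- setdiff(names(kv), names(defaults))
  if (length(unknown)) {
    stop("unknown scm parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  args <- lapply(kv, function(v) as.numeric(strsplit(v, ",")[[1]]))
  do.call(scm_params, args)
}

# Shared flat key-value parser: `key: value` or `key = value`, '#' comments.
read_keyvalue <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !grepl("^#", lines)]
  m <- regmatches(lines, regexec("^([A-Za-z_][A-Za-z0-9_.]*)\\s*[:=]\\s*(.*)$", lines))
  if (any(lengths(m) != 3L)) {
    stop("malformed config line(s): ",
         paste(lines[lengths(m) != 3L], collapse = "; "), call. = FALSE)
  }
  stats::setNames(vapply(m, `[`, character(1), 3L),
                  vapply(m, `[`, character(1), 2L))
}

#' Write a survey table as CSV
#'
#' Fixed header (site, sex, age, education, children, food_insecure,
#' think_freq, ritual_freq); missing cells are written empty.
#'
#' @param table survey data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_survey_csv <- function(table, path) {
  cols <- c("site", "sex", "age", "education", "children", "food_insecure",
            "think_freq", "ritual_freq")
  miss <- setdiff(cols, names(table))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  utils::write.csv(table[cols], path, row.names = FALSE, na = "")
  invisible(path)
}
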