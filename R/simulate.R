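#' Stratum model for the synthetic cohort generator
#'
#' One analyte within one sex is modelled as an inverse-Box-Cox Gaussian
#' with a linear age trend on the transformed scale: at age `a`,
#' y ~ Normal(mu + slope·(a − 14), sigma) and the observed value is
#' x = inverse Box-Cox(y; lambda), restricted to the analyte's valid range
#' (percentages in \[0, 100\], counts nonnegative) by truncation of the
#' normal law. This family is chosen so that the pipeline's own
#' normalization step is exactly correct on clean synthetic data and every
#' downstream stage has a closed-form oracle ([true_reference_interval()]).
#'
#' The constructor verifies that the truncated probability mass outside the
#' valid range stays below 2% at every age 14-100, so the truncation is a
#' tail nuisance rather than a distortion of the model.
#'
#' @param analyte Analyte code (see [ri_analytes()]).
#' @param sex `"M"` or `"F"`.
#' @param lambda True Box-Cox exponent.
#' @param mu Transformed-scale location at reference age 14.
#' @param slope Transformed-scale change per year of age.
#' @param sigma Positive transformed-scale SD.
#' @return A list of class `stratum_model`.
#' @export
stratum_model <- function(analyte, sex, lambda, mu, slope, sigma) {
  stopifnot(length(analyte) == 1, sigma > 0)
  analyte_kind(analyte)  # validates the code
  m <- structure(list(analyte = analyte, sex = validate_sex(sex),
                      lambda = lambda, mu = mu, slope = slope, sigma = sigma),
                 class = "stratum_model")
  for (a in c(14, 57, 100)) {
    zb <- model_z_bounds(m, a)
    mass_out <- 1 - (stats::pnorm(zb[2]) - stats::pnorm(zb[1]))
    if (mass_out > 0.02) {
      stop(sprintf(
        "model %s/%s: %.1f%% of the normal mass falls outside the valid range at age %d",
        analyte, sex, 100 * mass_out, a), call. = FALSE)
    }
  }
  m
}

# Valid y interval implied by the analyte range and the Box-Cox domain.
model_y_bounds <- function(model) {
  l <- model$lambda
  r <- analyte_range(model$analyte)
  ylo <- if (r[1] > 0) boxcox_transform(r[1], l) else
    if (abs(l) < 1e-12) -Inf else if (l > 0) -1 / l else -Inf
  yhi <- if (is.finite(r[2])) boxcox_transform(r[2], l) else
    if (l < 0) -1 / l else Inf
  c(ylo, yhi)
}

# Standardized truncation bounds at a given age (and SD multiplier).
model_z_bounds <- function(model, age, sd_mult = 1) {
  yb <- model_y_bounds(model)
  m <- model$mu + model$slope * (age - 14)
  s <- model$sigma * sd_mult
  (yb - m) / s
}

# Anchor table behind default_stratum_models(): per sex and analyte, the
# exponent, the young-band (ages 14-30) median and central-95% limits, and
# the old-band (76-100) median, on the original scale. Values reflect
# large-hospital adult immunophenotyping panels (single-platform counting):
# CD3+ around 70% / 1.2-1.3e3 cells/ul in young adults, with the familiar
# age decline that is steeper for absolute counts than percentages.
default_model_anchors <- function() {
  tibble::as_tibble(utils::read.csv(text =
"analyte,sex,lambda,med_young,lo_young,hi_young,med_old
cd3_pct,M,2.450906,70.05,51.72,83.08,60.10
cd4_pct,M,0.828792,33.50,21.70,47.90,31.60
cd8_pct,M,0.309667,27.80,16.40,42.60,21.40
cd3_count,M,0.132957,1309,714,2300,910
cd4_count,M,0.120361,630,328,1225,469
cd8_count,M,0.067657,528,251,1037,348
cd3_pct,F,2.450906,72.80,56.00,84.20,63.20
cd4_pct,F,0.828792,36.60,24.70,49.70,34.60
cd8_pct,F,0.309667,27.10,16.30,41.10,23.20
cd3_count,F,0.132957,1289,688,2155,1006
cd4_count,F,0.120361,651,347,1161,544
cd8_count,F,0.067657,482,225,960,331", stringsAsFactors = FALSE))
}

#' Default generative models for all sexes and analytes
#'
#' Converts the original-scale anchors (young-band median and 2.5th/97.5th
#' limits, old-band median) into transformed-scale `(mu, slope, sigma)`:
#' `mu` so the median at the young band's mid-age (22) matches, `slope` from
#' the median change between band mid-ages 22 and 88, `sigma` from the
#' young-band central-95% width on the transformed scale.
#'
#' @return A list of 12 [stratum_model()] objects named `"<sex>.<analyte>"`.
#' @export
default_stratum_models <- function() {
  anchors <- default_model_anchors()
  z95 <- stats::qnorm(0.975)
  models <- vector("list", nrow(anchors))
  names(models) <- paste(anchors$sex, anchors$analyte, sep = ".")
  for (i in seq_len(nrow(anchors))) {
    a <- anchors[i, ]
    by <- boxcox_transform(a$med_young, a$lambda)
    bo <- boxcox_transform(a$med_old, a$lambda)
    slope <- (bo - by) / 66
    sigma <- (boxcox_transform(a$hi_young, a$lambda) -
                boxcox_transform(a$lo_young, a$lambda)) / (2 * z95)
    models[[i]] <- stratum_model(a$analyte, a$sex, a$lambda,
                                 mu = by - 8 * slope, slope = slope,
                                 sigma = sigma)
  }
  models
}

#' Specification of a synthetic cohort
#'
#' @param models List of [stratum_model()]s named `"<sex>.<analyte>"`,
#'   covering both sexes and all six analytes for every stratum with n > 0.
#' @param n_per_stratum Either a single integer (every sex × band stratum)
#'   or a named integer vector keyed by stratum label (`"M 14-30"`, ...).
#' @param duplicate_fraction Fraction of base records that receive one
#'   duplicate visit (same subject key, later date); in \[0, 1).
#' @param contamination_fraction Fraction of records drawn with inflated
#'   spread, emulating pre-analytic errors and admixed non-healthy results;
#'   in \[0, 1).
#' @param contamination_scale SD multiplier (> 1) for contaminated records.
#' @param seed Integer master seed; every random stream is derived from it.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(models, n_per_stratum, duplicate_fraction = 0,
                        contamination_fraction = 0, contamination_scale = 3,
                        seed = 1L) {
  stopifnot(duplicate_fraction >= 0, duplicate_fraction < 1,
            contamination_fraction >= 0, contamination_fraction < 1,
            contamination_scale >= 1)
  strata <- expand.grid(sex = c("M", "F"), band = age_bands()$band,
                        stringsAsFactors = FALSE)
  strata$stratum <- paste(strata$sex, strata$band)
  if (length(n_per_stratum) == 1 && is.null(names(n_per_stratum))) {
    n <- stats::setNames(rep(as.integer(n_per_stratum), nrow(strata)),
                         strata$stratum)
  } else if (is.null(names(n_per_stratum))) {
    stop("n_per_stratum must be a single number or a named vector keyed ",
         "by stratum label", call. = FALSE)
  } else {
    n <- stats::setNames(rep(0L, nrow(strata)), strata$stratum)
    unknown <- setdiff(names(n_per_stratum), strata$stratum)
    if (length(unknown)) {
      stop("unknown stratum label(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    n[names(n_per_stratum)] <- as.integer(n_per_stratum)
  }
  for (s in strata$stratum[n[strata$stratum] > 0]) {
    sex <- strsplit(s, " ")[[1]][1]
    need <- paste(sex, analyte_codes(), sep = ".")
    lack <- setdiff(need, names(models))
    if (length(lack)) {
      stop("stratum ", s, " has n > 0 but no model for: ",
           paste(lack, collapse = ", "), call. = FALSE)
    }
  }
  structure(list(models = models, n_per_stratum = n,
                 duplicate_fraction = duplicate_fraction,
                 contamination_fraction = contamination_fraction,
                 contamination_scale = contamination_scale,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Default cohort specification
#'
#' Uses [default_stratum_models()] with stratum sizes matching the
#' steady-state census of a large hospital checkup population (young and
#' very old bands are thin, the 46-60 band dominates), a 35.6% duplicate
#' share and 1% mild contamination at 3x spread.
#'
#' @param seed Master seed.
#' @param n_per_stratum Optional override of the stratum sizes.
#' @param ... Passed on to [cohort_spec()].
#' @export
default_cohort_spec <- function(seed = 1L, n_per_stratum = NULL, ...) {
  if (is.null(n_per_stratum)) {
    n_per_stratum <- c(
      "M 14-30" = 1926, "M 31-45" = 7178, "M 46-60" = 9081,
      "M 61-75" = 2574, "M 76-100" = 249,
      "F 14-30" = 2321, "F 31-45" = 6450, "F 46-60" = 7280,
      "F 61-75" = 2326, "F 76-100" = 181)
  }
  args <- list(models = default_stratum_models(),
               n_per_stratum = n_per_stratum, seed = seed, ...)
  if (!("duplicate_fraction" %in% names(list(...)))) {
    args$duplicate_fraction <- 0.356
  }
  if (!("contamination_fraction" %in% names(list(...)))) {
    args$contamination_fraction <- 0.01
  }
  do.call(cohort_spec, args)
}

# Deterministic 31-bit stream seed from a master seed and a path of labels,
# so adding a stratum or analyte does not perturb the other streams.
stream_seed <- function(...) {
  s <- paste(unlist(list(...)), collapse = "|")
  h <- 17
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483629
  as.integer(h)
}

with_stream <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Joint upper z cutoff enforcing cd4_count + cd8_count <= cd3_count for the
# comonotone count triple of one sex, at a given age and SD multiplier.
# Returns Inf when the constraint never binds on z in [0, 8].
count_joint_cutoff <- function(models, sex, age, sd_mult = 1) {
  trio <- lapply(c("cd3_count", "cd4_count", "cd8_count"),
                 function(a) models[[paste(sex, a, sep = ".")]])
  g <- function(z) {
    x <- vapply(trio, function(m) {
      inverse_boxcox(m$mu + m$slope * (age - 14) + m$sigma * sd_mult * z,
                     m$lambda)
    }, numeric(1))
    x[2] + x[3] - x[1]
  }
  if (g(0) >= 0) {
    stop(sprintf(
      "count models for sex %s violate cd4 + cd8 <= cd3 at their median (age %d)",
      sex, age), call. = FALSE)
  }
  zz <- seq(0, 8, by = 0.25)
  gv <- vapply(zz, g, numeric(1))
  first <- which(gv > 0)[1]
  if (is.na(first)) return(Inf)
  stats::uniroot(g, c(zz[first - 1], zz[first]), tol = 1e-8)$root
}

# Joint latent bounds for the comonotone count triple: intersection of the
# three per-analyte range bounds and the subset-sum cutoff.
count_joint_bounds <- function(models, sex, age, sd_mult = 1) {
  cm <- lapply(c("cd3_count", "cd4_count", "cd8_count"),
               function(a) models[[paste(sex, a, sep = ".")]])
  zb <- vapply(cm, function(m) model_z_bounds(m, age, sd_mult), numeric(2))
  c(max(zb[1, ]),
    min(min(zb[2, ]), count_joint_cutoff(models, sex, age, sd_mult)))
}

# Truncated-normal draw: u ~ U(0,1) mapped through the inverse CDF of
# Normal(0,1) restricted to [zlo, zhi]. Identical in law to rejection
# sampling (no point masses at the edges).
qnorm_trunc <- function(u, zlo, zhi) {
  plo <- stats::pnorm(zlo)
  phi <- stats::pnorm(zhi)
  stats::qnorm(plo + u * (phi - plo))
}

#' Generate a synthetic LIS-style cohort
#'
#' Draws, for every stratum with n > 0: integer ages uniform over the band;
#' percentage analytes independently from their truncated inverse-Box-Cox
#' Gaussians; the three absolute counts from a single shared standard-normal
#' latent (comonotone coupling) truncated jointly so that
#' cd4_count + cd8_count never exceeds cd3_count — marginals remain exact
#' truncated inverse-Box-Cox Gaussians, which keeps
#' [true_reference_interval()]/[cohort_truth()] exact. A
#' `contamination_fraction` share of records is drawn with
#' `contamination_scale` times the model SD; a `duplicate_fraction` share of
#' base records receives a duplicate visit with the same subject key and a
#' later date. Identical spec and seed give identical cohorts.
#'
#' @param spec A [cohort_spec()].
#' @return A `lis_cohort` with `attr(, "n_base")`, `attr(, "n_duplicates")`
#'   and `attr(, "n_contaminated")`.
#' @examples
#' cohort <- generate_cohort(default_cohort_spec(n_per_stratum = 50, seed = 7))
#' nrow(cohort)
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (sum(spec$n_per_stratum) <= 0) {
    stop("spec requests no records in any stratum", call. = FALSE)
  }
  bands <- age_bands()
  pieces <- list()
  offset <- 0L
  n_contaminated <- 0L
  for (s in names(spec$n_per_stratum)) {
    n <- spec$n_per_stratum[[s]]
    if (n <= 0) next
    parts <- strsplit(s, " ")[[1]]
    sex <- parts[1]; band <- parts[2]
    b <- bands[bands$band == band, ]
    age <- with_stream(stream_seed(spec$seed, s, "age"),
                       sample(b$lo:b$hi, n, replace = TRUE))
    n_cont <- round(spec$contamination_fraction * n)
    cont_idx <- if (n_cont > 0)
      with_stream(stream_seed(spec$seed, s, "contam"), sample(n, n_cont))
    else integer(0)
    sd_mult <- rep(1, n)
    sd_mult[cont_idx] <- spec$contamination_scale
    n_contaminated <- n_contaminated + length(cont_idx)

    rec <- tibble::tibble(
      subject_id = sprintf("S%07d", offset + seq_len(n)),
      name_key = sprintf("K%07d", offset + seq_len(n)),
      sex = sex, age = age,
      visit_date = with_stream(
        stream_seed(spec$seed, s, "date"),
        as.Date("2019-01-01") + sample(0:1003, n, replace = TRUE)))
    offset <- offset + n

    for (a in c("cd3_pct", "cd4_pct", "cd8_pct")) {
      m <- spec$models[[paste(sex, a, sep = ".")]]
      u <- with_stream(stream_seed(spec$seed, s, a), stats::runif(n))
      yb <- model_y_bounds(m)
      loc <- m$mu + m$slope * (age - 14)
      sc <- m$sigma * sd_mult
      z <- qnorm_trunc(u, (yb[1] - loc) / sc, (yb[2] - loc) / sc)
      rec[[a]] <- inverse_boxcox(loc + sc * z, m$lambda)
    }

    # counts: one latent per record, bounds from the three ranges plus the
    # subset-sum cutoff, both depending on (age, sd multiplier)
    u <- with_stream(stream_seed(spec$seed, s, "counts"), stats::runif(n))
    cm <- lapply(c("cd3_count", "cd4_count", "cd8_count"),
                 function(a) spec$models[[paste(sex, a, sep = ".")]])
    combos <- unique(data.frame(age = age, mult = sd_mult))
    zlo <- zhi <- numeric(n)
    for (i in seq_len(nrow(combos))) {
      sel <- age == combos$age[i] & sd_mult == combos$mult[i]
      zb <- count_joint_bounds(spec$models, sex, combos$age[i],
                               combos$mult[i])
      zlo[sel] <- zb[1]
      zhi[sel] <- zb[2]
    }
    z <- qnorm_trunc(u, zlo, zhi)
    for (j in 1:3) {
      m <- cm[[j]]
      rec[[m$analyte]] <- inverse_boxcox(
        m$mu + m$slope * (age - 14) + m$sigma * sd_mult * z, m$lambda)
    }
    pieces[[s]] <- rec
  }
  base <- dplyr::bind_rows(pieces)
  n_base <- nrow(base)

  n_dup <- round(spec$duplicate_fraction * n_base)
  if (n_dup > 0) {
    dup <- with_stream(stream_seed(spec$seed, "duplicates"), {
      rows <- sample(n_base, n_dup)
      d <- base[rows, ]
      d$visit_date <- d$visit_date + sample(30:400, n_dup, replace = TRUE)
      d
    })
    base <- dplyr::bind_rows(base, dup)
  }
  out <- as_cohort(base, provenance = "synthetic", seed = spec$seed)
  attr(out, "n_base") <- n_base
  attr(out, "n_duplicates") <- n_dup
  attr(out, "n_contaminated") <- n_contaminated
  out
}

#' Exact reference limits of a synthetic stratum model
#'
#' Returns the exact quantiles of the age-mixture distribution of one model
#' over an age band: for each integer age the value is a range-truncated
#' inverse-Box-Cox Gaussian, and ages are uniform on the band. With
#' `slope = 0` and no effective truncation this reduces to the closed form
#' inverse-Box-Cox of mu ± z·sigma. `z_bounds` optionally imposes the
#' per-age joint latent bounds used for coherent count triples (see
#' [cohort_truth()], which supplies them automatically).
#'
#' @param model A [stratum_model()].
#' @param band Band label (`"14-30"`) or integer vector of ages.
#' @param coverage Central coverage, in (0, 1); default 0.95.
#' @param z_bounds Optional function(age) returning `c(zlo, zhi)` latent
#'   bounds, intersected with the model's own range bounds.
#' @return Named numeric: `lower`, `median`, `upper` (original scale).
#' @examples
#' m <- stratum_model("cd3_count", "M", lambda = 0, mu = 7, slope = 0,
#'                    sigma = 0.3)
#' true_reference_interval(m, "14-30")
#' @export
true_reference_interval <- function(model, band, coverage = 0.95,
                                    z_bounds = NULL) {
  stopifnot(coverage > 0, coverage < 1)
  ages <- if (is.character(band)) {
    b <- age_bands(); r <- b[b$band == band, ]
    if (nrow(r) != 1) stop("unknown band: ", band, call. = FALSE)
    r$lo:r$hi
  } else as.integer(band)
  alpha <- (1 - coverage) / 2
  yb <- model_y_bounds(model)
  loc <- model$mu + model$slope * (ages - 14)
  zlo <- (yb[1] - loc) / model$sigma
  zhi <- (yb[2] - loc) / model$sigma
  if (!is.null(z_bounds)) {
    jb <- vapply(ages, z_bounds, numeric(2))
    zlo <- pmax(zlo, jb[1, ])
    zhi <- pmin(zhi, jb[2, ])
  }
  plo <- stats::pnorm(zlo); phi <- stats::pnorm(zhi)
  cdf <- function(x) {
    zx <- (boxcox_transform(x, model$lambda) - loc) / model$sigma
    mean(pmin(pmax((stats::pnorm(zx) - plo) / (phi - plo), 0), 1))
  }
  qtl <- function(p) {
    # bracket with the per-age truncated quantiles
    per_age <- stats::qnorm(plo + p * (phi - plo)) * model$sigma + loc
    br <- range(inverse_boxcox(per_age, model$lambda))
    if (br[1] == br[2]) return(br[1])
    stats::uniroot(function(x) cdf(x) - p, br, tol = 1e-10,
                   extendInt = "upX")$root
  }
  c(lower = qtl(alpha), median = qtl(0.5), upper = qtl(1 - alpha))
}

#' Ground-truth interval table for a cohort specification
#'
#' Applies [true_reference_interval()] to every stratum × analyte of a spec,
#' folding in the joint count cutoff that [generate_cohort()] enforces, so
#' the truth matches the generated data's law exactly (for the
#' uncontaminated component).
#'
#' @param spec A [cohort_spec()].
#' @param coverage Central coverage (default 0.95).
#' @return A tibble: `sex`, `band`, `analyte`, `lower`, `median`, `upper`.
#' @export
cohort_truth <- function(spec, coverage = 0.95) {
  rows <- list()
  for (s in names(spec$n_per_stratum)) {
    if (spec$n_per_stratum[[s]] <= 0) next
    parts <- strsplit(s, " ")[[1]]
    sex <- parts[1]; band <- parts[2]
    for (a in analyte_codes()) {
      m <- spec$models[[paste(sex, a, sep = ".")]]
      jz <- if (grepl("count", a)) {
        function(age) count_joint_bounds(spec$models, sex, age)
      } else NULL
      q <- true_reference_interval(m, band, coverage, z_bounds = jz)
      rows[[length(rows) + 1]] <- tibble::tibble(
        sex = sex, band = band, analyte = a,
        lower = q[["lower"]], median = q[["median"]], upper = q[["upper"]])
    }
  }
  dplyr::bind_rows(rows)
}
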