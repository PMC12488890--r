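#' Configure a synthetic longitudinal cohort
#'
#' Describes a generative model for sparse, correlated clinical lab panels
#' with therapy-dependent dynamics, used to exercise every pipeline stage
#' without access to restricted EHR data. Each patient's latent dense
#' trajectory for variable v at bin t (landmark at t = 0) is
#'
#' \deqn{x_{ivt} = b_{iv} + s_{iv} t + (\Lambda z_{it})_v + \gamma_v e_i +
#'   \delta_{c_i v} \max(t, 0) + \epsilon_{ivt}}
#'
#' with patient baseline \eqn{b_{iv} \sim N(\mu_v, \tau_v^2)}, patient slope
#' \eqn{s_{iv}}, shared AR(1) latent factors \eqn{z_{it}} loaded through
#' \eqn{\Lambda} (which plants the cross-variable correlations), an ordinal
#' performance-status effect \eqn{\gamma_v e_i}, a post-landmark
#' treatment-class slope \eqn{\delta_{c v}}, and idiosyncratic noise.
#' Observed records are the latent values thinned cell-wise by independent
#' Bernoulli(1 - missingness) (MCAR) or, optionally, value-dependent
#' thinning (MNAR), then rounded to one decimal.
#'
#' The default configuration mirrors the structure of a sparse oncology lab
#' panel: weekly bins, 94.4% missingness, three correlated lab variables,
#' two therapy classes with opposite hemoglobin dynamics, sex and ECOG
#' statics.
#'
#' @param n_patients Number of patients.
#' @param variables Character vector of variable names.
#' @param baseline_mean,baseline_sd,slope_mean,slope_sd Per-variable numeric
#'   vectors (recycled) for the patient-level baseline and per-bin slope
#'   distributions.
#' @param loading Numeric matrix (variables x factors) of loadings on the
#'   shared AR(1) factors; the implied cross-variable covariance
#'   \eqn{\Lambda\Lambda^T} is positive semi-definite by construction.
#' @param ar_rho AR(1) autocorrelation of the latent factors (stationary unit
#'   variance).
#' @param noise_sd Per-variable idiosyncratic noise standard deviation.
#' @param treatments Named list: class name -> per-variable post-landmark
#'   slope vector (value drift per bin after the landmark).
#' @param treatment_probs Sampling probabilities for the classes.
#' @param ecog_effect Per-variable additive effect per ECOG point.
#' @param missingness Per-variable probability in `[0, 1)` that a latent cell
#'   is *not* observed (scalar recycled).
#' @param mnar_strength MCAR when 0 (default); otherwise the log-odds of
#'   observation decrease by `mnar_strength` per standard deviation the value
#'   lies above the variable mean.
#' @param history_bins,horizon_bins Dense grid: bins `-(history_bins - 1) .. 0`
#'   are history, `1 .. horizon_bins` the forecast period.
#' @param bin_width Raw time units per bin; emitted timestamps are
#'   `bin * bin_width` plus a uniform within-bin offset, so that
#'   [bin_last_observed()] recovers the grid.
#' @param seed Default seed for [simulate_cohort()].
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 100L,
                          variables = c("hemoglobin", "leukocytes", "neutrophils"),
                          baseline_mean = c(13, 7, 4),
                          baseline_sd = 1.2,
                          slope_mean = 0,
                          slope_sd = 0.02,
                          loading = matrix(c(0.6, 0.5, 0.55), ncol = 1L),
                          ar_rho = 0.6,
                          noise_sd = 0.5,
                          treatments = list(
                            chemotherapy = c(-0.08, -0.05, -0.06),
                            immunotherapy = c(0.04, 0.02, 0.02)),
                          treatment_probs = NULL,
                          ecog_effect = c(-0.4, 0, -0.1),
                          missingness = 0.944,
                          mnar_strength = 0,
                          history_bins = 26L,
                          horizon_bins = 13L,
                          bin_width = 7,
                          seed = 1L) {
  p <- length(variables)
  rec <- function(x) rep_len(as.numeric(x), p)
  loading <- as.matrix(loading)
  if (nrow(loading) != p) stop("loading must have one row per variable")
  missingness <- rec(missingness)
  if (any(missingness < 0 | missingness >= 1)) {
    stop("missingness must lie in [0, 1)")
  }
  if (is.null(treatment_probs)) {
    treatment_probs <- rep(1 / length(treatments), length(treatments))
  }
  stopifnot(length(treatments) >= 1L,
            all(vapply(treatments, length, integer(1L)) == p),
            abs(sum(treatment_probs) - 1) < 1e-8,
            abs(ar_rho) < 1)
  structure(list(
    n_patients = as.integer(n_patients), variables = variables,
    baseline_mean = rec(baseline_mean), baseline_sd = rec(baseline_sd),
    slope_mean = rec(slope_mean), slope_sd = rec(slope_sd),
    loading = loading, ar_rho = ar_rho, noise_sd = rec(noise_sd),
    treatments = treatments, treatment_probs = treatment_probs,
    ecog_effect = rec(ecog_effect), missingness = missingness,
    mnar_strength = mnar_strength,
    history_bins = as.integer(history_bins),
    horizon_bins = as.integer(horizon_bins),
    bin_width = bin_width, seed = seed), class = "cohort_config")
}

#' Model-implied cross-variable correlation
#'
#' Stationary correlation between two variables' latent stochastic components
#' (shared factors + idiosyncratic noise), i.e. the correlation planted by
#' the loading matrix before patient-level baseline/slope heterogeneity.
#'
#' @param config A [cohort_config()].
#' @return Symmetric correlation matrix across the configured variables.
#' @export
planted_correlation <- function(config) {
  covm <- tcrossprod(config$loading) + diag(config$noise_sd^2,
                                            length(config$variables))
  stats::cov2cor(covm)
}

#' Preset: a learnable two-variable cohort
#'
#' A deliberately forecastable scenario used to demonstrate that a trainable
#' text backend can beat the copy-forward baseline: two correlated lab-like
#' variables with small patient-level baseline spread (sd 0.4), AR(1) noise
#' (sd 0.25, rho 0.5), no idiosyncratic patient slopes, and two therapy
#' classes with opposite post-landmark drifts (+0.5/-0.3 vs -0.5/+0.3 per
#' week). Because the class drift accumulates linearly over the horizon while
#' the class-conditional residual spread stays constant, the copy-forward
#' error grows with the horizon but a model that learns the class- and
#' week-conditional mean does not. Moderate missingness (0.3) keeps prompts
#' informative and short.
#'
#' @param n_patients Number of patients.
#' @param seed Seed stored in the config.
#' @return A [cohort_config()].
#' @export
learnable_cohort_config <- function(n_patients = 2000L, seed = 1L) {
  cohort_config(
    n_patients = n_patients,
    variables = c("biomarker_a", "biomarker_b"),
    baseline_mean = c(12, 7), baseline_sd = 0.4,
    slope_mean = 0, slope_sd = 0,
    loading = matrix(c(0.2, 0.15), ncol = 1L),
    ar_rho = 0.5, noise_sd = 0.25,
    treatments = list(therapy_a = c(0.5, -0.3), therapy_b = c(-0.5, 0.3)),
    ecog_effect = c(-0.3, 0),
    missingness = 0.3,
    history_bins = 6L, horizon_bins = 4L, bin_width = 7,
    seed = seed)
}

#' Simulate a synthetic cohort
#'
#' Draws a cohort from a [cohort_config()]: dense latent trajectories (the
#' ground truth) plus the sparse observed records obtained by thinning,
#' rounded to one decimal and stamped with raw within-bin times. The therapy
#' class is emitted both as a static attribute and as a `therapy` event
#' observation at the landmark, so therapy-start landmarking works on the
#' observed records alone. Fully reproducible from the seed.
#'
#' @param config A [cohort_config()].
#' @param seed Overrides `config$seed`.
#' @return A list: `cohort` (a raw-timestamp [cohort()]), `truth` (list with
#'   `latent` dense data.frame `patient_id, variable, bin, value` and
#'   `assignments` data.frame of treatment class / sex / ecog per patient).
#' @export
simulate_cohort <- function(config, seed = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  seed <- seed %||% config$seed
  with_seed(seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(config) {
  p <- length(config$variables)
  n <- config$n_patients
  bins <- seq(-(config$history_bins - 1L), config$horizon_bins)
  nt <- length(bins)
  k <- ncol(config$loading)
  classes <- names(config$treatments)

  obs_list <- vector("list", n)
  latent_list <- vector("list", n)
  assign_list <- vector("list", n)

  if (n == 0L) {
    empty_obs <- data.frame(patient_id = character(), variable = character(),
                            time = numeric(), value = character())
    return(list(cohort = cohort(empty_obs),
                truth = list(latent = data.frame(patient_id = character(),
                                                 variable = character(),
                                                 bin = integer(),
                                                 value = numeric()),
                             assignments = data.frame(patient_id = character(),
                                                      treatment = character(),
                                                      sex = character(),
                                                      ecog = integer()))))
  }

  for (i in seq_len(n)) {
    id <- sprintf("P%05d", i)
    cls <- sample(classes, 1L, prob = config$treatment_probs)
    sex <- sample(c("male", "female"), 1L)
    ecog <- sample(0:3, 1L, prob = c(0.35, 0.35, 0.2, 0.1))

    b <- stats::rnorm(p, config$baseline_mean, config$baseline_sd)
    s <- stats::rnorm(p, config$slope_mean, config$slope_sd)
    # stationary AR(1) factors, unit marginal variance
    z <- matrix(0, nt, k)
    z[1L, ] <- stats::rnorm(k)
    if (nt > 1L) {
      innov_sd <- sqrt(1 - config$ar_rho^2)
      for (t in 2:nt) {
        z[t, ] <- config$ar_rho * z[t - 1L, ] + stats::rnorm(k, sd = innov_sd)
      }
    }
    eps <- matrix(stats::rnorm(nt * p, sd = rep(config$noise_sd, each = nt)),
                  nt, p)
    shared <- z %*% t(config$loading)              # nt x p
    drift <- outer(pmax(bins, 0), config$treatments[[cls]])
    trend <- outer(bins, s)
    x <- shared + eps + trend + drift +
      matrix(b + config$ecog_effect * ecog, nt, p, byrow = TRUE)

    latent_list[[i]] <- data.frame(
      patient_id = id,
      variable = rep(config$variables, each = nt),
      bin = rep(bins, p),
      value = as.numeric(x), stringsAsFactors = FALSE)

    # cell-wise thinning
    if (config$mnar_strength == 0) {
      keep <- matrix(stats::runif(nt * p), nt, p) >=
        matrix(config$missingness, nt, p, byrow = TRUE)
    } else {
      zval <- sweep(sweep(x, 2L, config$baseline_mean), 2L,
                    pmax(config$baseline_sd + config$noise_sd, 1e-8), "/")
      logit <- stats::qlogis(1 - config$missingness)
      pobs <- stats::plogis(matrix(logit, nt, p, byrow = TRUE) -
                              config$mnar_strength * zval)
      keep <- matrix(stats::runif(nt * p), nt, p) < pobs
    }
    kept <- which(keep, arr.ind = TRUE)
    if (nrow(kept)) {
      tbin <- bins[kept[, 1L]]
      raw_time <- tbin * config$bin_width +
        floor(stats::runif(nrow(kept)) * config$bin_width)
      obs_list[[i]] <- data.frame(
        patient_id = id,
        variable = config$variables[kept[, 2L]],
        time = raw_time,
        value = render_num(round_half_up(x[kept], 1L), 1L),
        stringsAsFactors = FALSE)
    }
    # therapy event at the landmark anchors therapy_start landmarking
    obs_list[[i]] <- rbind(obs_list[[i]],
      data.frame(patient_id = id, variable = "therapy", time = 0,
                 value = cls, stringsAsFactors = FALSE))
    assign_list[[i]] <- data.frame(patient_id = id, treatment = cls,
                                   sex = sex, ecog = ecog,
                                   stringsAsFactors = FALSE)
  }

  assignments <- do.call(rbind, assign_list)
  statics <- data.frame(
    patient_id = rep(assignments$patient_id, 3L),
    attribute = rep(c("sex", "ecog", "treatment"), each = n),
    value = c(assignments$sex, as.character(assignments$ecog),
              assignments$treatment),
    stringsAsFactors = FALSE)

  list(cohort = cohort(do.call(rbind, obs_list), statics),
       truth = list(latent = do.call(rbind, latent_list),
                    assignments = assignments))
}

#' Summarize a binned cohort
#'
#' Deterministic descriptive statistics: per-variable missingness over the
#' grid `n_patients x n_bins`, number of distinct visit bins per patient, and
#' pairwise cross-variable correlations computed on co-observed
#' (patient, bin) cells.
#'
#' @param x A binned `twin_cohort`.
#' @param variables Numeric variables to summarize (default: all with at
#'   least one parseable numeric value).
#' @param bins Integer vector defining the full bin grid; default is the
#'   observed range across the cohort.
#' @return A list with `missingness` (named vector), `visits_per_patient`
#'   (named integer vector), and `correlation` (matrix, `NA` where fewer than
#'   3 co-observed cells).
#' @export
cohort_summary <- function(x, variables = NULL, bins = NULL) {
  stopifnot(inherits(x, "twin_cohort"))
  obs <- x$observations
  num <- obs_numeric(obs)
  if (is.null(variables)) {
    variables <- sort(unique(obs$variable[!is.na(num)]))
  }
  ids <- cohort_patients(x)
  if (length(ids) == 0L) {
    return(list(missingness = stats::setNames(numeric(0), character(0)),
                visits_per_patient = stats::setNames(integer(0), character(0)),
                correlation = matrix(numeric(0), 0, 0)))
  }
  if (is.null(bins)) {
    tt <- obs$time[obs$variable %in% variables]
    bins <- if (length(tt)) seq(min(tt), max(tt)) else integer(0)
  }
  n_cells <- length(ids) * length(bins)
  missingness <- vapply(variables, function(v) {
    seen <- obs$variable == v & obs$time %in% bins & !is.na(num)
    if (n_cells == 0L) return(NA_real_)
    1 - sum(seen) / n_cells
  }, numeric(1L))

  visits <- vapply(ids, function(id) {
    length(unique(obs$time[obs$patient_id == id & obs$variable %in% variables]))
  }, integer(1L))

  corr <- matrix(NA_real_, length(variables), length(variables),
                 dimnames = list(variables, variables))
  diag(corr) <- 1
  cell_key <- paste(obs$patient_id, obs$time, sep = "\r")
  for (a in seq_along(variables)) {
    for (b in seq_len(a - 1L)) {
      ia <- which(obs$variable == variables[a] & !is.na(num))
      ib <- which(obs$variable == variables[b] & !is.na(num))
      common <- intersect(cell_key[ia], cell_key[ib])
      if (length(common) >= 3L) {
        va <- num[ia][match(common, cell_key[ia])]
        vb <- num[ib][match(common, cell_key[ib])]
        if (stats::sd(va) > 0 && stats::sd(vb) > 0) {
          corr[a, b] <- corr[b, a] <- stats::cor(va, vb)
        }
      }
    }
  }
  list(missingness = missingness, visits_per_patient = visits,
       correlation = corr)
}
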