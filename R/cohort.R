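#' Longitudinal cohort container
#'
#' A cohort bundles the two long-format tables the whole pipeline works on:
#' sparse time-stamped observations (one row per measured value) and static
#' per-patient attributes. No imputation is ever applied; a (patient, variable,
#' time) cell that was not measured simply has no row.
#'
#' @param observations `data.frame` with columns `patient_id`, `variable`,
#'   `time` (numeric; raw timestamps before binning, integer bin offsets
#'   after), and `value` (character; numeric variables parse with
#'   `as.numeric`).
#' @param statics `data.frame` with columns `patient_id`, `attribute`, `value`.
#' @param binned Logical flag: have observations been aggregated to integer
#'   time bins?
#'
#' @return An object of class `twin_cohort`.
#' @export
cohort <- function(observations, statics = NULL, binned = FALSE) {
  need <- c("patient_id", "variable", "time", "value")
  stopifnot(is.data.frame(observations), all(need %in% names(observations)))
  observations <- as.data.frame(observations)[, need]
  observations$patient_id <- as.character(observations$patient_id)
  observations$variable <- as.character(observations$variable)
  observations$time <- as.numeric(observations$time)
  observations$value <- as.character(observations$value)
  if (nrow(observations) && any(!is.finite(observations$time))) {
    stop("non-finite observation timestamps")
  }
  if (is.null(statics)) {
    statics <- data.frame(patient_id = character(), attribute = character(),
                          value = character(), stringsAsFactors = FALSE)
  }
  stopifnot(all(c("patient_id", "attribute", "value") %in% names(statics)))
  statics <- as.data.frame(statics)[, c("patient_id", "attribute", "value")]
  statics$patient_id <- as.character(statics$patient_id)
  statics$attribute <- as.character(statics$attribute)
  statics$value <- as.character(statics$value)
  ord <- order(observations$patient_id, observations$variable, observations$time)
  observations <- observations[ord, , drop = FALSE]
  rownames(observations) <- NULL
  structure(list(observations = observations, statics = statics,
                 binned = isTRUE(binned)),
            class = "twin_cohort")
}

#' @export
print.twin_cohort <- function(x, ...) {
  ids <- cohort_patients(x)
  cat(sprintf("<twin_cohort> %d patients, %d observations of %d variables (%s)\n",
              length(ids), nrow(x$observations),
              length(unique(x$observations$variable)),
              if (x$binned) "binned" else "raw timestamps"))
  invisible(x)
}

#' @export
#' @rdname cohort
cohort_patients <- function(observations) {
  x <- observations
  if (inherits(x, "twin_cohort")) {
    sort(unique(c(x$observations$patient_id, x$statics$patient_id)))
  } else {
    sort(unique(as.character(x$patient_id)))
  }
}

# Named character vector of one patient's static attributes.
patient_statics <- function(cohort, patient_id) {
  s <- cohort$statics[cohort$statics$patient_id == patient_id, , drop = FALSE]
  stats::setNames(s$value, s$attribute)
}

# Numeric view of the observation rows for the given variables (other
# variables untouched elsewhere); non-parseable values become NA.
obs_numeric <- function(observations) {
  suppressWarnings(as.numeric(observations$value))
}

#' Read / write a cohort as a long-format CSV pair
#'
#' The on-disk interchange format is two plain CSVs: an observations table
#' (`patient_id,variable,time,value`) and a statics table
#' (`patient_id,attribute,value`).
#'
#' @param obs_path,statics_path File paths.
#' @param x A `twin_cohort`.
#' @param binned Whether the observation times are already integer bins.
#' @return `read_cohort` returns a `twin_cohort`; `write_cohort` returns the
#'   paths invisibly.
#' @export
read_cohort <- function(obs_path, statics_path = NULL, binned = FALSE) {
  obs <- utils::read.csv(obs_path, stringsAsFactors = FALSE,
                         colClasses = c(patient_id = "character",
                                        variable = "character",
                                        time = "numeric",
                                        value = "character"))
  statics <- if (!is.null(statics_path) && file.exists(statics_path)) {
    utils::read.csv(statics_path, stringsAsFactors = FALSE,
                    colClasses = "character")
  }
  cohort(obs, statics, binned = binned)
}

#' @rdname read_cohort
#' @export
write_cohort <- function(x, obs_path, statics_path = NULL) {
  stopifnot(inherits(x, "twin_cohort"))
  utils::write.csv(x$observations, obs_path, row.names = FALSE, quote = FALSE)
  if (!is.null(statics_path)) {
    utils::write.csv(x$statics, statics_path, row.names = FALSE, quote = FALSE)
  }
  invisible(c(obs_path, statics_path))
}

# Restrict a cohort to a patient-id subset.
cohort_subset <- function(x, ids) {
  cohort(x$observations[x$observations$patient_id %in% ids, , drop = FALSE],
         x$statics[x$statics$patient_id %in% ids, , drop = FALSE],
         binned = x$binned)
}

#' Quantize numeric observations to a fixed reporting precision
#'
#' Rounds every numeric value of the given variables to `digits` decimals
#' (half away from zero, matching the text renderer), so that serializing a
#' value to text and reading it back is lossless.
#'
#' @param x A `twin_cohort`.
#' @param variables Variable names to quantize (typically the numeric
#'   targets).
#' @param digits Decimal places.
#' @return The quantized cohort.
#' @export
quantize_cohort <- function(x, variables, digits = 1L) {
  stopifnot(inherits(x, "twin_cohort"))
  obs <- x$observations
  sel <- obs$variable %in% variables
  if (any(sel)) {
    v <- suppressWarnings(as.numeric(obs$value[sel]))
    ok <- !is.na(v)
    obs$value[sel][ok] <- render_num(round_half_up(v[ok], digits), digits)
  }
  cohort(obs, x$statics, binned = x$binned)
}
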