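#' Read and validate a radius-observation table
#'
#' The package's on-disk observation schema is a plain CSV with columns
#' `patient_id` (optional for single-patient files), `t_days` (days since the
#' patient's first scan), `modality` (`"T1Gd"` or `"T2"`), and `radius_mm`
#' (equivalent spherical radius). Rows are validated individually and sorted
#' by time.
#'
#' @param path Path to a CSV file.
#' @return A tibble sorted by `t_days`.
#' @export
read_observations <- function(path) {
  obs <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_observations(obs, context = path)
}

#' @rdname read_observations
#' @param obs An observation data frame to write.
#' @export
write_observations <- function(obs, path) {
  obs <- validate_observations(obs)
  write_atomic(path, function(p) readr::write_csv(obs, p, progress = FALSE))
  invisible(path)
}

validate_observations <- function(obs, context = "observations") {
  if (!is.data.frame(obs)) abort("observations must be a data frame.")
  need <- c("t_days", "modality", "radius_mm")
  missing_cols <- setdiff(need, names(obs))
  if (length(missing_cols)) {
    abort(sprintf("%s: missing required column(s): %s.",
                  context, paste(missing_cols, collapse = ", ")))
  }
  obs <- as_tibble(obs)
  bad_mod <- which(!obs$modality %in% c("T1Gd", "T2"))
  if (length(bad_mod)) {
    abort(sprintf("%s: row %d has unknown modality '%s' (expected T1Gd or T2).",
                  context, bad_mod[1], obs$modality[bad_mod[1]]))
  }
  bad_r <- which(!is.finite(obs$radius_mm) | obs$radius_mm < 0)
  if (length(bad_r)) {
    abort(sprintf("%s: row %d has invalid radius_mm = %s (must be >= 0).",
                  context, bad_r[1], format(obs$radius_mm[bad_r[1]])))
  }
  bad_t <- which(!is.finite(obs$t_days))
  if (length(bad_t)) {
    abort(sprintf("%s: row %d has non-finite t_days.", context, bad_t[1]))
  }
  arrange(obs, .data$t_days, .data$modality)
}

# atomic file write: write to a sibling temp file, then rename into place,
# so an interrupted rerun never leaves a half-written output.
write_atomic <- function(path, writer) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  tmp <- tempfile(pattern = basename(path), tmpdir = dirname(path))
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) abort(sprintf("could not move output into %s.", path))
  invisible(path)
}

#' Write a JSON result file atomically
#'
#' @param x A list (or other jsonlite-serialisable object).
#' @param path Output path.
#' @param seed,config Optional provenance: when supplied, a `provenance`
#'   block (package version, seed, configuration hash) is attached so every
#'   result can be traced to the exact run that produced it.
#' @return `path`, invisibly.
#' @export
write_result_json <- function(x, path, seed = NULL, config = NULL) {
  if (!is.null(seed) || !is.null(config)) {
    x$provenance <- list(
      package = "gliopi",
      version = as.character(utils::packageVersion("gliopi")),
      seed = seed,
      config_hash = rlang::hash(config)
    )
  }
  write_atomic(path, function(p) {
    jsonlite::write_json(x, p, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
  })
}

#' Read a fractionation plan from disk
#'
#' A plan is a CSV with columns `t_days`, `dose_Gy`; the radiobiological
#' parameters come from a JSON sidecar (same path with extension `.json`,
#' fields `alpha`, `alpha_beta_ratio`) or from the arguments, which take
#' precedence over the sidecar.
#'
#' @param path Path to the plan CSV.
#' @param alpha,alpha_beta_ratio Override/supply radiosensitivity (1/Gy) and
#'   the alpha/beta ratio (Gy).
#' @return A [radiation_plan()].
#' @export
read_radiation_plan <- function(path, alpha = NULL, alpha_beta_ratio = NULL) {
  fx <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("t_days", "dose_Gy") %in% names(fx))) {
    abort(sprintf("%s: plan CSV needs columns t_days, dose_Gy.", path))
  }
  sidecar <- sub("\\.csv$", ".json", path)
  if (file.exists(sidecar) && sidecar != path) {
    meta <- jsonlite::read_json(sidecar)
    if (is.null(alpha)) alpha <- meta$alpha
    if (is.null(alpha_beta_ratio)) alpha_beta_ratio <- meta$alpha_beta_ratio
  }
  if (is.null(alpha)) abort("alpha not given and no JSON sidecar found.")
  if (is.null(alpha_beta_ratio)) alpha_beta_ratio <- 10
  radiation_plan(fx, alpha = as.numeric(alpha),
                 alpha_beta_ratio = as.numeric(alpha_beta_ratio))
}
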