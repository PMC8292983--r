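#' Model parameter set
#'
#' Constructs and validates the full parameter set of the two-compartment
#' clustering/feedback model. Concentrations are in uM, time in seconds;
#' compartment volumes never appear explicitly -- clustering enters only
#' through the dimensionless partition coefficient `partition_k_light`.
#'
#' The defaults are the package's calibrated reference cell: the lit-state
#' iLID/SspB dissociation constant is 0.1 uM (association constant
#' `ka_ilid_light` = 10 /uM), 100-fold tighter than the dark state; the
#' SH2/phosphotyrosine interaction that recruits and activates Src has a
#' 1 uM dissociation constant; basal (autoinhibited) Src activity is weak
#' enough that the dark steady state carries a small but nonzero pZap70
#' pool, and light-induced clustering of LAT by `partition_k_light` = 10
#' ignites the positive feedback loop. See the methods vignette for the
#' calibration rationale.
#'
#' @param lat_total Total LAT, referred to the unclustered membrane
#'   compartment (uM).
#' @param zap70_cyt Cytosolic Zap70, held constant by the fast-exchange
#'   assumption (uM).
#' @param src_cyt Cytosolic Src, held constant (uM).
#' @param ka_ilid_dark Dark-state iLID/SspB association constant (1/uM).
#' @param ka_ilid_light Lit-state iLID/SspB association constant (1/uM);
#'   must be >= `ka_ilid_dark` (light tightens binding).
#' @param ka_sh2 Association constant of the Src SH2 domain for
#'   phosphorylated LAT (1/uM).
#' @param kcat_src_active,km_src_active Michaelis-Menten constants for
#'   phosphorylation of Zap70 by active (pLAT-bound) Src (1/s, uM).
#' @param kcat_src_inactive,km_src_inactive Michaelis-Menten constants for
#'   the slow, leaky phosphorylation of Zap70 by autoinhibited Src
#'   (1/s, uM).
#' @param kdeph_zap70 First-order Zap70 dephosphorylation rate (1/s).
#' @param kcat_pzap70,km_pzap70 Michaelis-Menten constants for
#'   phosphorylation of LAT by pZap70 (1/s, uM).
#' @param k_tethered First-order rate for preferential phosphorylation of
#'   LAT by the pZap70 tethered to it through iLID:SspB (1/s).
#' @param kdeph_lat First-order LAT dephosphorylation rate (1/s).
#' @param ki_pp2 Non-competitive inhibition constant of PP2 against both
#'   Src catalytic rates (uM); must be > 0.
#' @param pp2 Ambient PP2 concentration (uM).
#' @param partition_k_light Lit-state partition coefficient K >= 1: the
#'   factor by which cluster formation shrinks the membrane compartment
#'   and concentrates LAT.
#'
#' @return An object of class `model_parameters` (a named list).
#' @seealso [apply_scenario()], [model_rhs()], [read_parameters()]
#' @examples
#' p <- model_parameters()
#' p$partition_k_light
#' model_parameters(src_cyt = 2)$src_cyt
#' @export
model_parameters <- function(lat_total = 0.5,
                             zap70_cyt = 1,
                             src_cyt = 0.2,
                             ka_ilid_dark = 0.1,
                             ka_ilid_light = 10,
                             ka_sh2 = 1,
                             kcat_src_active = 3.56,
                             km_src_active = 30,
                             kcat_src_inactive = 5e-4,
                             km_src_inactive = 0.1,
                             kdeph_zap70 = 0.1,
                             kcat_pzap70 = 12,
                             km_pzap70 = 50,
                             k_tethered = 0.6,
                             kdeph_lat = 0.1,
                             ki_pp2 = 1,
                             pp2 = 0,
                             partition_k_light = 10) {
  p <- list(
    lat_total = lat_total, zap70_cyt = zap70_cyt, src_cyt = src_cyt,
    ka_ilid_dark = ka_ilid_dark, ka_ilid_light = ka_ilid_light,
    ka_sh2 = ka_sh2,
    kcat_src_active = kcat_src_active, km_src_active = km_src_active,
    kcat_src_inactive = kcat_src_inactive,
    km_src_inactive = km_src_inactive,
    kdeph_zap70 = kdeph_zap70,
    kcat_pzap70 = kcat_pzap70, km_pzap70 = km_pzap70,
    k_tethered = k_tethered, kdeph_lat = kdeph_lat,
    ki_pp2 = ki_pp2, pp2 = pp2,
    partition_k_light = partition_k_light
  )
  validate_parameters(p)
  structure(p, class = "model_parameters")
}

#' Field names of a model parameter set
#' @return Character vector of the 18 parameter names.
#' @keywords internal
parameter_names <- function() {
  c("lat_total", "zap70_cyt", "src_cyt", "ka_ilid_dark", "ka_ilid_light",
    "ka_sh2", "kcat_src_active", "km_src_active", "kcat_src_inactive",
    "km_src_inactive", "kdeph_zap70", "kcat_pzap70", "km_pzap70",
    "k_tethered", "kdeph_lat", "ki_pp2", "pp2", "partition_k_light")
}

validate_parameters <- function(p) {
  extra <- setdiff(names(p), parameter_names())
  if (length(extra))
    stop("unknown parameter field(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  missing <- setdiff(parameter_names(), names(p))
  if (length(missing))
    stop("missing parameter field(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  for (nm in parameter_names()) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", nm, "' must be a single finite number",
           call. = FALSE)
    if (v < 0)
      stop("parameter '", nm, "' must be >= 0 (got ", v, ")",
           call. = FALSE)
  }
  if (p$ki_pp2 <= 0)
    stop("ki_pp2 must be > 0", call. = FALSE)
  if (p$partition_k_light < 1)
    stop("partition_k_light must be >= 1 (clustering concentrates)",
         call. = FALSE)
  if (p$ka_ilid_light < p$ka_ilid_dark)
    stop("ka_ilid_light must be >= ka_ilid_dark (light tightens binding)",
         call. = FALSE)
  invisible(p)
}

#' Update fields of a parameter set
#'
#' @param params A `model_parameters` object.
#' @param ... Named scalar overrides; unknown names are an error.
#' @return The updated, re-validated `model_parameters` object.
#' @examples
#' update_parameters(model_parameters(), src_cyt = 1)
#' @export
update_parameters <- function(params, ...) {
  ov <- list(...)
  if (length(ov) == 0L) return(params)
  bad <- setdiff(names(ov), parameter_names())
  if (length(bad) || is.null(names(ov)) || any(names(ov) == ""))
    stop("unknown parameter field(s): ",
         paste(if (length(bad)) bad else "<unnamed>", collapse = ", "),
         call. = FALSE)
  p <- unclass(params)
  p[names(ov)] <- ov
  validate_parameters(p)
  structure(p, class = "model_parameters")
}

#' @export
print.model_parameters <- function(x, ...) {
  cat("Model parameters (uM, 1/s, 1/uM):\n")
  for (nm in parameter_names())
    cat(sprintf("  %-18s %g\n", nm, x[[nm]]))
  invisible(x)
}

#' Read or write parameter sets and scenario configurations
#'
#' Parameter sets serialize to JSON or YAML (chosen by file extension)
#' with exact field names; an unknown or missing field on read is a hard
#' error, so a typo can never fall back to a default silently.
#'
#' @param path File path ending in `.json`, `.yaml` or `.yml`.
#' @return `read_parameters()` returns a `model_parameters` object;
#'   `write_parameters()` returns `path` invisibly.
#' @examples
#' f <- tempfile(fileext = ".json")
#' write_parameters(model_parameters(), f)
#' identical(read_parameters(f), model_parameters())
#' @export
read_parameters <- function(path) {
  p <- read_config_file(path)
  validate_parameters(p)
  structure(p, class = "model_parameters")
}

#' @rdname read_parameters
#' @param params A `model_parameters` object to serialize.
#' @export
write_parameters <- function(params, path) {
  validate_parameters(params)
  write_config_file(unclass(params), path)
  invisible(path)
}

read_config_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  x <- switch(ext,
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    yaml = ,
    yml  = yaml::read_yaml(path),
    stop("unsupported config format: .", ext,
         " (use .json, .yaml or .yml)", call. = FALSE)
  )
  lapply(as.list(x), function(v) if (is.numeric(v)) as.numeric(v) else v)
}

write_config_file <- function(x, path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    json = jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA),
    yaml = ,
    yml  = yaml::write_yaml(x, path, precision = 15),
    stop("unsupported config format: .", ext,
         " (use .json, .yaml or .yml)", call. = FALSE)
  )
  invisible(path)
}
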