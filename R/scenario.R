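#' Supported experimental scenarios
#'
#' @return Character vector of the seven scenario names.
#' @export
scenario_names <- function() {
  c("ilid_drop", "ilid_only", "zap70_k362e", "zap70_kd", "lat_fff",
    "src_dsh2dsh3", "jurkat_no_recruitment")
}

#' Scenario configuration
#'
#' A `scenario_config` records which experimental regime a simulation
#' emulates and whether the light is on. The mutant scaling factors are
#' stored here so `apply_scenario()` can transform a wild-type parameter
#' set deterministically; for wild-type scenarios they have no effect.
#'
#' @param name One of [scenario_names()].
#' @param light_on Logical; lit phase uses `partition_k_light` (where the
#'   scenario clusters) and `ka_ilid_light`.
#' @param k362e_kcat_factor Scaling (< 1) of `kcat_pzap70` for the
#'   weakly active Zap70-K362E mutant; applied to both phospho-forms.
#' @param k362e_km_factor Scaling (> 1) of `km_pzap70` for Zap70-K362E.
#' @param dsh2_kcat_free_factor Boost (> 1) of `kcat_src_inactive` for
#'   Src lacking its SH2/SH3 domains (autoinhibition relieved).
#' @param dsh2_src_conc_factor Reduction (< 1) of `src_cyt` for the same
#'   mutant, matching its reduced expression.
#' @param basal_pzap70_frac Initial phosphorylated fraction of the Zap70
#'   pools for the `jurkat_no_recruitment` scenario (0-1).
#'
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(name = "ilid_drop",
                            light_on = FALSE,
                            k362e_kcat_factor = 0.1,
                            k362e_km_factor = 10,
                            dsh2_kcat_free_factor = 10,
                            dsh2_src_conc_factor = 0.1,
                            basal_pzap70_frac = 0.01) {
  name <- match.arg(name, scenario_names())
  stopifnot(is.logical(light_on), length(light_on) == 1L)
  if (k362e_kcat_factor < 0 || k362e_kcat_factor >= 1)
    stop("k362e_kcat_factor must be in [0, 1)", call. = FALSE)
  if (k362e_km_factor <= 1)
    stop("k362e_km_factor must be > 1", call. = FALSE)
  if (dsh2_kcat_free_factor <= 1)
    stop("dsh2_kcat_free_factor must be > 1", call. = FALSE)
  if (dsh2_src_conc_factor <= 0 || dsh2_src_conc_factor >= 1)
    stop("dsh2_src_conc_factor must be in (0, 1)", call. = FALSE)
  if (basal_pzap70_frac < 0 || basal_pzap70_frac > 1)
    stop("basal_pzap70_frac must be in [0, 1]", call. = FALSE)
  structure(
    list(name = name, light_on = light_on,
         k362e_kcat_factor = k362e_kcat_factor,
         k362e_km_factor = k362e_km_factor,
         dsh2_kcat_free_factor = dsh2_kcat_free_factor,
         dsh2_src_conc_factor = dsh2_src_conc_factor,
         basal_pzap70_frac = basal_pzap70_frac,
         applied = FALSE),
    class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("Scenario:", x$name, if (x$light_on) "(lit)" else "(dark)", "\n")
  invisible(x)
}

#' Transform a parameter set for an experimental scenario
#'
#' Applies the deterministic equation/parameter modifications that define
#' each experimental regime:
#'
#' * `ilid_drop`: the base scenario -- parameters unchanged.
#' * `ilid_only`: light-insensitive clustering module; `partition_k_light`
#'   is set to 1 so K = 1 in both dark and lit states.
#' * `zap70_k362e`: weakly, constitutively active Zap70 -- both
#'   phosphorylated and non-phosphorylated Zap70 phosphorylate LAT, with
#'   `kcat_pzap70` scaled down and `km_pzap70` scaled up (the tethered
#'   first-order channel is scaled by the same kcat factor and its complex
#'   pool covers all bound LAT). Runs in the `ilid_only` clustering state
#'   (K = 1), mirroring the corresponding experiment.
#' * `zap70_kd`: kinase-dead Zap70 -- `kcat_pzap70` and `k_tethered` set
#'   to 0.
#' * `lat_fff`: non-phosphorylatable LAT -- Src cannot bind pLAT
#'   (`ka_sh2` = 0) and LAT phosphorylation rates are 0.
#' * `src_dsh2dsh3`: feedback-disconnected Src -- `ka_sh2` = 0, the free
#'   (formerly autoinhibited) catalytic rate is boosted and the cellular
#'   Src concentration reduced.
#' * `jurkat_no_recruitment`: clustering without direct Zap70 recruitment
#'   -- both iLID association constants are 0 while clustering (K > 1)
#'   still occurs on illumination; the initial condition seeds the Zap70
#'   phospho-pools at `basal_pzap70_frac` of their totals.
#'
#' The transform is idempotent: applying it to its own output returns the
#' input unchanged.
#'
#' @param name Scenario name, or a `scenario_config` to (re)apply.
#' @param params A `model_parameters` object (wild-type reference).
#' @param overrides Named list passed to [scenario_config()] (factors,
#'   `light_on`, `basal_pzap70_frac`).
#' @return A list with elements `params` (transformed
#'   `model_parameters`) and `config` (`scenario_config` with
#'   `applied = TRUE`).
#' @examples
#' sc <- apply_scenario("zap70_kd", model_parameters())
#' sc$params$kcat_pzap70  # 0
#' @export
apply_scenario <- function(name, params = model_parameters(),
                           overrides = list()) {
  if (inherits(name, "scenario_config")) {
    config <- name
  } else {
    if (!is.character(name) || length(name) != 1L ||
        !(name %in% scenario_names()))
      stop("unknown scenario '", paste(name, collapse = ","),
           "'; valid names: ", paste(scenario_names(), collapse = ", "),
           call. = FALSE)
    config <- do.call(scenario_config, c(list(name = name), overrides))
  }
  validate_parameters(params)
  if (isTRUE(config$applied))
    return(list(params = params, config = config))

  p <- unclass(params)
  switch(config$name,
    ilid_drop = NULL,
    ilid_only = {
      p$partition_k_light <- 1
    },
    zap70_k362e = {
      p$partition_k_light <- 1
      p$kcat_pzap70 <- p$kcat_pzap70 * config$k362e_kcat_factor
      p$km_pzap70 <- p$km_pzap70 * config$k362e_km_factor
      p$k_tethered <- p$k_tethered * config$k362e_kcat_factor
    },
    zap70_kd = {
      p$kcat_pzap70 <- 0
      p$k_tethered <- 0
    },
    lat_fff = {
      p$ka_sh2 <- 0
      p$kcat_pzap70 <- 0
      p$k_tethered <- 0
    },
    src_dsh2dsh3 = {
      p$ka_sh2 <- 0
      p$kcat_src_inactive <- p$kcat_src_inactive *
        config$dsh2_kcat_free_factor
      p$src_cyt <- p$src_cyt * config$dsh2_src_conc_factor
    },
    jurkat_no_recruitment = {
      p$ka_ilid_dark <- 0
      p$ka_ilid_light <- 0
    }
  )
  config$applied <- TRUE
  list(params = structure(validate_parameters(p),
                          class = "model_parameters"),
       config = config)
}

#' Read or write a scenario configuration (JSON/YAML)
#'
#' @param path File path ending in `.json`, `.yaml` or `.yml`.
#' @return `read_scenario()` returns a `scenario_config`.
#' @export
read_scenario <- function(path) {
  x <- read_config_file(path)
  applied <- isTRUE(x$applied)
  x$applied <- NULL
  known <- setdiff(names(formals(scenario_config)), "")
  bad <- setdiff(names(x), known)
  if (length(bad))
    stop("unknown scenario field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  cfg <- do.call(scenario_config, x)
  cfg$applied <- applied
  cfg
}

#' @rdname read_scenario
#' @param config A `scenario_config` to serialize.
#' @export
write_scenario <- function(config, path) {
  stopifnot(inherits(config, "scenario_config"))
  write_config_file(unclass(config), path)
  invisible(path)
}
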