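#' Dark-to-light stimulation protocol
#'
#' @param pre_dark_duration Dark equilibration time before the light
#'   switch (s). The dark phase is always continued to a steady state;
#'   this sets the minimum integration time.
#' @param light_duration Duration of constant illumination (s); default
#'   1200 s (20 min), the standard stimulation used throughout.
#' @param sample_interval Output sampling interval (s).
#' @return A `light_protocol` object.
#' @export
light_protocol <- function(pre_dark_duration = 3600,
                           light_duration = 1200,
                           sample_interval = 5) {
  if (pre_dark_duration < 0 || light_duration < 0)
    stop("durations must be >= 0", call. = FALSE)
  if (sample_interval <= 0)
    stop("sample_interval must be > 0", call. = FALSE)
  if (light_duration > 0 && sample_interval > light_duration)
    stop("sample_interval must not exceed light_duration", call. = FALSE)
  structure(list(pre_dark_duration = pre_dark_duration,
                 light_duration = light_duration,
                 sample_interval = sample_interval),
            class = "light_protocol")
}

## Precompute everything the RHS needs that does not depend on the state.
precompute_phase <- function(params, config, light_on = NULL) {
  eq <- equilibrium_pools(params, config, light_on)
  list(eq = eq,
       kcat_a = pp2_scale(params$kcat_src_active, params$ki_pp2,
                          params$pp2),
       kcat_i = pp2_scale(params$kcat_src_inactive, params$ki_pp2,
                          params$pp2),
       km_a = params$km_src_active, km_i = params$km_src_inactive,
       src_cyt = params$src_cyt,
       src_coef = params$src_cyt * params$ka_sh2 /
         (1 + params$src_cyt * params$ka_sh2),
       zap70_cyt = params$zap70_cyt,
       kn_z = params$kdeph_zap70, kn_l = params$kdeph_lat,
       kcat_z = params$kcat_pzap70, km_z = params$km_pzap70,
       k_teth = params$k_tethered,
       k362e = identical(config$name, "zap70_k362e"))
}

## State-only RHS; pc from precompute_phase(). Unchecked hot path used by
## the integrator; model_rhs() routes through the same arithmetic.
rhs_core <- function(x, pc) {
  eq <- pc$eq
  zn <- eq$zap70_mem - x[1L]
  zn_cyt <- pc$zap70_cyt - x[2L]
  lnf <- eq$lat_free_total - x[3L]
  lnb <- eq$lat_bound_total - x[4L]
  sa <- (x[3L] + x[4L]) * pc$src_coef
  d1 <- pc$kcat_a * sa * zn / (pc$km_a + zn) +
    pc$kcat_i * pc$src_cyt * zn / (pc$km_i + zn) - pc$kn_z * x[1L]
  d2 <- pc$kcat_i * pc$src_cyt * zn_cyt / (pc$km_i + zn_cyt) -
    pc$kn_z * x[2L]
  zap_kin <- if (pc$k362e) eq$zap70_mem else x[1L]
  cfrac <- if (pc$k362e) 1 else
    if (eq$zap70_mem > 0) x[1L] / eq$zap70_mem else 0
  d3 <- pc$kcat_z * zap_kin * lnf / (pc$km_z + lnf) - pc$kn_l * x[3L]
  d4 <- pc$kcat_z * zap_kin * lnb / (pc$km_z + lnb) +
    pc$k_teth * lnb * cfrac - pc$kn_l * x[4L]
  c(d1, d2, d3, d4)
}

timecourse_frame <- function(out, eq) {
  df <- as.data.frame(out)
  names(df) <- c("time", state_names())
  df$plat_frac <- (df$plat_free + df$plat_bound) / eq$lat
  df$pzap_frac <- df$pzap70_mem / eq$zap70_mem
  df
}

#' Integrate the model in time
#'
#' Solves the four phospho-pool ODEs with a stiff-capable adaptive
#' integrator (`deSolve::ode`, `lsoda`) at fixed tolerances, returning
#' the trajectory on a uniform sampling grid together with the derived
#' pLAT and pZap70 fractions.
#'
#' @param params A `model_parameters` object.
#' @param config A `scenario_config`; its `light_on` selects the phase.
#' @param initial A `model_state` (or named numeric vector of length 4).
#' @param t_span Total integration time (s).
#' @param sample_interval Output sampling interval (s).
#' @param light_on Optional logical override of `config$light_on`.
#' @param rtol,atol Integrator tolerances (defaults 1e-8, 1e-10).
#' @return A data.frame of class `timecourse` with columns `time`, the
#'   four state variables, `plat_frac` (total pLAT over total LAT) and
#'   `pzap_frac` (membrane pZap70 over total membrane Zap70). The
#'   equilibrium pools and tolerances are attached as attributes.
#' @examples
#' sc <- apply_scenario("ilid_drop", model_parameters())
#' tc <- integrate_model(sc$params, sc$config, model_state(), 60, 5)
#' tail(tc, 1)
#' @export
integrate_model <- function(params, config, initial = model_state(),
                            t_span, sample_interval,
                            light_on = NULL, rtol = 1e-8, atol = 1e-10) {
  if (t_span <= 0) stop("t_span must be > 0", call. = FALSE)
  if (sample_interval <= 0 || sample_interval > t_span)
    stop("sample_interval must be in (0, t_span]", call. = FALSE)
  pc <- precompute_phase(params, config, light_on)
  x0 <- as.numeric(initial)[1:4]
  ## validate the initial condition against the phase's pool bounds
  model_rhs(x0, params, config, light_on)
  times <- unique(c(seq(0, t_span, by = sample_interval), t_span))
  out <- deSolve::ode(y = x0, times = times,
                      func = function(t, y, parms) list(rhs_core(y, parms)),
                      parms = pc, method = "lsoda",
                      rtol = rtol, atol = atol)
  istate <- attr(out, "istate")[1L]
  if (!is.null(istate) && istate < 0)
    stop("integration failed (istate = ", istate, ") near t = ",
         max(out[, 1]), " s", call. = FALSE)
  if (nrow(out) < length(times))
    stop("integration stopped early at t = ", max(out[, 1]), " s",
         call. = FALSE)
  df <- timecourse_frame(out, pc$eq)
  structure(df, class = c("timecourse", "data.frame"),
            eq = pc$eq, rtol = rtol, atol = atol,
            scenario = config$name,
            light = if (is.null(light_on)) isTRUE(config$light_on) else
              isTRUE(light_on))
}

#' Steady state of the model
#'
#' Finds a state where the infinity norm of the right-hand side is below
#' `tol`, by integrating from `initial` for at least ten times the
#' slowest dephosphorylation timescale and continuing in chunks until the
#' criterion holds, then polishing with damped Newton iterations on the
#' algebraic balance (numerical Jacobian). The basin is identified by the
#' initial condition, which is recorded in the result.
#'
#' @inheritParams integrate_model
#' @param tol Convergence criterion on `max(abs(rhs))` (uM/s).
#' @param max_time Integration budget (s of model time) before giving up.
#' @return A `model_state` with attributes `rhs_norm`, `time_integrated`
#'   and `initial`.
#' @examples
#' sc <- apply_scenario("zap70_kd", model_parameters())
#' ss <- steady_state(sc$params, sc$config)
#' attr(ss, "rhs_norm") < 1e-9
#' @export
steady_state <- function(params, config, initial = model_state(),
                         light_on = NULL, tol = 1e-9, max_time = 1e6,
                         rtol = 1e-8, atol = 1e-10) {
  pc <- precompute_phase(params, config, light_on)
  x <- as.numeric(initial)[1:4]
  model_rhs(x, params, config, light_on)
  chunk <- 10 / min(params$kdeph_zap70, params$kdeph_lat)
  if (!is.finite(chunk) || chunk <= 0) chunk <- 1e4
  t_total <- 0
  repeat {
    out <- deSolve::ode(y = x, times = c(0, chunk),
                        func = function(t, y, parms)
                          list(rhs_core(y, parms)),
                        parms = pc, method = "lsoda",
                        rtol = rtol, atol = atol)
    if (nrow(out) < 2L)
      stop("integration failed during steady-state search", call. = FALSE)
    x <- as.numeric(out[2L, -1L])
    t_total <- t_total + chunk
    if (max(abs(rhs_core(x, pc))) < tol) break
    if (t_total >= max_time) {
      x <- polish_newton(x, pc)
      if (max(abs(rhs_core(x, pc))) < tol) break
      stop("steady state not reached within ", max_time,
           " s of model time (residual ",
           signif(max(abs(rhs_core(x, pc))), 3), " uM/s)", call. = FALSE)
    }
  }
  x <- polish_newton(x, pc)
  st <- model_state(x[1L], x[2L], x[3L], x[4L])
  attr(st, "rhs_norm") <- max(abs(rhs_core(x, pc)))
  attr(st, "time_integrated") <- t_total
  attr(st, "initial") <- as.numeric(initial)[1:4]
  st
}

## Damped Newton polish with forward-difference Jacobian; keeps the
## iterate inside the physical box and only accepts residual reductions.
polish_newton <- function(x, pc, iters = 8L) {
  ub <- c(pc$eq$zap70_mem, pc$zap70_cyt, pc$eq$lat_free_total,
          pc$eq$lat_bound_total)
  f <- rhs_core(x, pc)
  for (i in seq_len(iters)) {
    n0 <- max(abs(f))
    if (n0 == 0) break
    J <- matrix(0, 4, 4)
    h <- pmax(1e-8 * pmax(abs(x), 1e-6), 1e-12)
    for (j in 1:4) {
      xj <- x; xj[j] <- xj[j] + h[j]
      J[, j] <- (rhs_core(xj, pc) - f) / h[j]
    }
    step <- tryCatch(solve(J, -f), error = function(e) NULL)
    if (is.null(step)) break
    lambda <- 1
    repeat {
      xn <- pmin(pmax(x + lambda * step, 0), ub)
      fn <- rhs_core(xn, pc)
      if (max(abs(fn)) < n0) { x <- xn; f <- fn; break }
      lambda <- lambda / 2
      if (lambda < 1e-4) break
    }
    if (lambda < 1e-4) break
  }
  x
}

#' Redistribute pools across an illumination switch
#'
#' When the light state changes, the partition coefficient and the
#' iLID-bound fraction f change instantaneously (fast-equilibrium
#' assumption). Phospho-fractions are conserved: membrane pZap70 keeps
#' its phosphorylated fraction of the (new) total membrane Zap70, the
#' total pLAT keeps its fraction of total LAT, and phospho- and
#' non-phospho-LAT are redistributed proportionally between the bound and
#' free sub-pools according to the new f.
#'
#' @param state `model_state` in the old phase.
#' @param eq_old,eq_new Equilibrium pool lists from
#'   [equilibrium_pools()] for the old and new phases.
#' @return A `model_state` referred to the new phase.
#' @export
redistribute_state <- function(state, eq_old, eq_new) {
  x <- as.numeric(state)[1:4]
  zfrac <- if (eq_old$zap70_mem > 0) x[1L] / eq_old$zap70_mem else 0
  lfrac <- if (eq_old$lat > 0) (x[3L] + x[4L]) / eq_old$lat else 0
  lp_new <- lfrac * eq_new$lat
  model_state(pzap70_mem = zfrac * eq_new$zap70_mem,
              pzap70_cyt = x[2L],
              plat_free = (1 - eq_new$bound_fraction) * lp_new,
              plat_bound = eq_new$bound_fraction * lp_new)
}

#' Dark equilibration followed by a light step
#'
#' Runs the standard stimulation protocol: equilibrate in the dark
#' (K = 1, dark iLID affinity) to steady state, switch instantaneously to
#' the lit phase (scenario-resolved partition coefficient and lit iLID
#' affinity, pools redistributed by [redistribute_state()]), and
#' integrate for the light duration. For the `jurkat_no_recruitment`
#' scenario the dark equilibration starts from the configured basal
#' pZap70 seed.
#'
#' @param params A `model_parameters` object, typically from
#'   [apply_scenario()].
#' @param config The matching `scenario_config`.
#' @param protocol A [light_protocol()].
#' @param tol Steady-state criterion for the dark phase (uM/s).
#' @return A list with `dark_state` (`model_state`), `dark_frac` /
#'   `dark_pzap_frac` (dark steady fractions), `lit_timecourse`
#'   (`timecourse`), `lit_state` (final lit `model_state`), `lit_frac`
#'   and `lit_pzap_frac`.
#' @examples
#' sc <- apply_scenario("ilid_drop", model_parameters())
#' ex <- light_switch_experiment(sc$params, sc$config, light_protocol())
#' c(ex$dark_frac, ex$lit_frac)
#' @export
light_switch_experiment <- function(params, config,
                                    protocol = light_protocol(),
                                    tol = 1e-9) {
  stopifnot(inherits(protocol, "light_protocol"))
  eq_d <- equilibrium_pools(params, config, light_on = FALSE)
  x0 <- model_state()
  if (identical(config$name, "jurkat_no_recruitment")) {
    b <- config$basal_pzap70_frac
    x0 <- model_state(pzap70_mem = b * eq_d$zap70_mem,
                      pzap70_cyt = b * params$zap70_cyt)
  }
  dark <- steady_state(params, config, initial = x0, light_on = FALSE,
                       tol = tol,
                       max_time = max(protocol$pre_dark_duration, 1e6))
  dark_frac <- (dark[3L] + dark[4L]) / eq_d$lat
  dark_pzap <- dark[1L] / eq_d$zap70_mem

  if (protocol$light_duration == 0) {
    out <- cbind(time = 0, t(as.numeric(dark)))
    tc <- timecourse_frame(out, eq_d)
    tc <- structure(tc, class = c("timecourse", "data.frame"),
                    eq = eq_d, scenario = config$name, light = FALSE)
    return(list(dark_state = dark, dark_frac = unname(dark_frac),
                dark_pzap_frac = unname(dark_pzap),
                lit_timecourse = tc, lit_state = dark,
                lit_frac = unname(dark_frac),
                lit_pzap_frac = unname(dark_pzap)))
  }

  eq_l <- equilibrium_pools(params, config, light_on = TRUE)
  x_switch <- seed_basal_pzap70(redistribute_state(dark, eq_d, eq_l),
                                params, config, eq_l)
  tc <- integrate_model(params, config, initial = x_switch,
                        t_span = protocol$light_duration,
                        sample_interval = protocol$sample_interval,
                        light_on = TRUE)
  fin <- tc[nrow(tc), ]
  list(dark_state = dark, dark_frac = unname(dark_frac),
       dark_pzap_frac = unname(dark_pzap),
       lit_timecourse = tc,
       lit_state = model_state(fin$pzap70_mem, fin$pzap70_cyt,
                               fin$plat_free, fin$plat_bound),
       lit_frac = fin$plat_frac, lit_pzap_frac = fin$pzap_frac)
}

## In the no-recruitment scenario the claim under test is that a basal
## pZap70 pool present at light onset can initiate feedback, so the seed
## acts as a floor on the Zap70 phospho-pools at the switch (dark
## equilibration may have decayed it when the leak pathway is off).
seed_basal_pzap70 <- function(state, params, config, eq) {
  if (!identical(config$name, "jurkat_no_recruitment")) return(state)
  b <- config$basal_pzap70_frac
  model_state(pzap70_mem = max(state[[1L]], b * eq$zap70_mem),
              pzap70_cyt = max(state[[2L]], b * params$zap70_cyt),
              plat_free = state[[3L]], plat_bound = state[[4L]])
}

#' Probe for bistability from opposite initial conditions
#'
#' Computes the phase's steady state twice: once from the all-zero
#' phospho state and once from the fully phosphorylated state. Any
#' disagreement beyond tolerance is reported as bistability -- the two
#' states are returned separately, never averaged.
#'
#' @inheritParams steady_state
#' @param state_tol Relative disagreement (on the pLAT fraction) above
#'   which the two basins are flagged as distinct.
#' @return List with `from_low`, `from_high` (`model_state`s), their
#'   pLAT fractions, and `bistable` (logical).
#' @export
hysteresis_probe <- function(params, config, light_on = NULL,
                             tol = 1e-9, state_tol = 1e-4) {
  eq <- equilibrium_pools(params, config, light_on)
  lo <- steady_state(params, config, initial = model_state(),
                     light_on = light_on, tol = tol)
  hi0 <- model_state(eq$zap70_mem, params$zap70_cyt,
                     eq$lat_free_total, eq$lat_bound_total)
  hi <- steady_state(params, config, initial = hi0,
                     light_on = light_on, tol = tol)
  f_lo <- unname(lo[3L] + lo[4L]) / eq$lat
  f_hi <- unname(hi[3L] + hi[4L]) / eq$lat
  list(from_low = lo, from_high = hi,
       frac_low = unname(f_lo), frac_high = unname(f_hi),
       bistable = abs(f_hi - f_lo) > state_tol * max(f_hi, 1e-12))
}

#' Write a timecourse as tidy CSV with a JSON metadata sidecar
#'
#' Long format: columns `time_s`, `scenario`, `light`, `variable`,
#' `value`. Integration metadata (scenario, tolerances) is written to
#' `<path>.json`.
#'
#' @param tc A `timecourse` from [integrate_model()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_timecourse <- function(tc, path) {
  stopifnot(inherits(tc, "timecourse"))
  vars <- setdiff(names(tc), "time")
  long <- do.call(rbind, lapply(vars, function(v)
    data.frame(time_s = tc$time,
               scenario = attr(tc, "scenario") %||% NA_character_,
               light = isTRUE(attr(tc, "light")),
               variable = v, value = tc[[v]])))
  utils::write.csv(long, path, row.names = FALSE)
  meta <- list(scenario = attr(tc, "scenario"),
               light = isTRUE(attr(tc, "light")),
               rtol = attr(tc, "rtol"), atol = attr(tc, "atol"),
               eq = attr(tc, "eq"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
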