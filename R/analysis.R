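#' Simulate the six experimental scenarios
#'
#' Runs the dark-to-light protocol for each scenario and collects the
#' dark steady state and the lit endpoint (20 min by default), i.e. the
#' per-scenario dark/lit pLAT and pZap70 fractions.
#'
#' @param params Wild-type `model_parameters`.
#' @param protocol A [light_protocol()].
#' @param scenarios Character vector of scenario names; defaults to the
#'   six figure-level regimes (the Jurkat prediction is available by
#'   adding `"jurkat_no_recruitment"`).
#' @param overrides Named list forwarded to [apply_scenario()].
#' @return Data.frame with one row per scenario: `scenario`,
#'   `dark_plat_frac`, `lit_plat_frac`, `dark_pzap_frac`,
#'   `lit_pzap_frac`, `lit_dark_ratio`. The full lit timecourses are
#'   attached as the `timecourses` attribute (a named list).
#' @examples
#' \donttest{
#' res <- run_six_scenarios(model_parameters())
#' res[, c("scenario", "lit_plat_frac")]
#' }
#' @export
run_six_scenarios <- function(params = model_parameters(),
                              protocol = light_protocol(),
                              scenarios = c("ilid_drop", "ilid_only",
                                            "zap70_k362e", "zap70_kd",
                                            "lat_fff", "src_dsh2dsh3"),
                              overrides = list()) {
  runs <- lapply(scenarios, function(s) {
    sc <- apply_scenario(s, params, overrides)
    light_switch_experiment(sc$params, sc$config, protocol)
  })
  names(runs) <- scenarios
  res <- data.frame(
    scenario = scenarios,
    dark_plat_frac = vapply(runs, `[[`, 0, "dark_frac"),
    lit_plat_frac = vapply(runs, `[[`, 0, "lit_frac"),
    dark_pzap_frac = vapply(runs, `[[`, 0, "dark_pzap_frac"),
    lit_pzap_frac = vapply(runs, `[[`, 0, "lit_pzap_frac"),
    row.names = NULL)
  res$lit_dark_ratio <- res$lit_plat_frac / pmax(res$dark_plat_frac,
                                                 .Machine$double.xmin)
  attr(res, "timecourses") <- lapply(runs, `[[`, "lit_timecourse")
  res
}

## dark steady -> switch -> lit steady, for scan/titration endpoints
lit_steady_pair <- function(params, config, dark = NULL, tol = 1e-9) {
  eq_d <- equilibrium_pools(params, config, light_on = FALSE)
  if (is.null(dark)) {
    x0 <- model_state()
    if (identical(config$name, "jurkat_no_recruitment")) {
      b <- config$basal_pzap70_frac
      x0 <- model_state(pzap70_mem = b * eq_d$zap70_mem,
                        pzap70_cyt = b * params$zap70_cyt)
    }
    dark <- steady_state(params, config, initial = x0,
                         light_on = FALSE, tol = tol)
  }
  eq_l <- equilibrium_pools(params, config, light_on = TRUE)
  x_switch <- seed_basal_pzap70(redistribute_state(dark, eq_d, eq_l),
                                params, config, eq_l)
  lit <- steady_state(params, config, initial = x_switch,
                      light_on = TRUE, tol = tol)
  list(dark = dark, lit = lit,
       dark_plat_frac = unname((dark[3L] + dark[4L]) / eq_d$lat),
       lit_plat_frac = unname((lit[3L] + lit[4L]) / eq_l$lat),
       dark_pzap_frac = unname(dark[1L] / eq_d$zap70_mem),
       lit_pzap_frac = unname(lit[1L] / eq_l$zap70_mem))
}

#' Steady-state scan over a swept parameter
#'
#' Computes dark and lit steady pLAT and pZap70 fractions as a function
#' of the lit-state partition coefficient (`partition_k_light`) or the
#' cellular Src concentration (`src_cyt`). The dark state does not
#' depend on the lit partition coefficient, so it is computed once and
#' reused for that sweep; for `src_cyt` it is recomputed per value.
#'
#' @param param_name `"partition_k_light"` or `"src_cyt"`.
#' @param values Sorted (increasing) positive sweep values.
#' @param params Wild-type `model_parameters`.
#' @param scenario Scenario name (default `"ilid_drop"`).
#' @param overrides Named list forwarded to [apply_scenario()].
#' @return Data.frame of class `scan_result` with columns `value`,
#'   `dark_plat_frac`, `lit_plat_frac`, `dark_pzap_frac`,
#'   `lit_pzap_frac`; `param_name` is attached as an attribute.
#' @examples
#' \donttest{
#' sr <- scan_parameter("partition_k_light", c(1, 3, 10, 30),
#'                      model_parameters())
#' sr$lit_plat_frac
#' }
#' @export
scan_parameter <- function(param_name, values,
                           params = model_parameters(),
                           scenario = "ilid_drop", overrides = list()) {
  if (!param_name %in% c("partition_k_light", "src_cyt"))
    stop("unsupported scan parameter '", param_name,
         "' (use partition_k_light or src_cyt)", call. = FALSE)
  if (is.unsorted(values, strictly = TRUE))
    stop("values must be strictly increasing", call. = FALSE)
  dark_cache <- NULL
  rows <- lapply(values, function(v) {
    args <- stats::setNames(list(v), param_name)
    p <- do.call(update_parameters, c(list(params), args))
    sc <- apply_scenario(scenario, p, overrides)
    reuse_dark <- param_name == "partition_k_light"
    r <- lit_steady_pair(sc$params, sc$config,
                         dark = if (reuse_dark) dark_cache else NULL)
    if (reuse_dark && is.null(dark_cache)) dark_cache <<- r$dark
    data.frame(value = v,
               dark_plat_frac = r$dark_plat_frac,
               lit_plat_frac = r$lit_plat_frac,
               dark_pzap_frac = r$dark_pzap_frac,
               lit_pzap_frac = r$lit_pzap_frac)
  })
  out <- do.call(rbind, rows)
  structure(out, class = c("scan_result", "data.frame"),
            param_name = param_name, scenario = scenario)
}

#' Partition-coefficient value reaching 90% of the large-K plateau
#'
#' Scans the lit steady pLAT fraction over a log-spaced grid of the
#' partition coefficient K and returns the smallest K at which the curve
#' first reaches the given quantile of its largest-K value, refined by
#' bisection between the bracketing grid points.
#'
#' @param params Wild-type `model_parameters`.
#' @param k_range Scan range (default 1 to 100).
#' @param n_grid Number of log-spaced grid points.
#' @param quantile Fraction of the large-K asymptote (default 0.9).
#' @param refine_tol Relative bisection tolerance on K.
#' @return List with `k_at_quantile`, `asymptote` (the largest-K lit
#'   fraction), and the `scan_result` grid.
#' @export
partition_k_plateau <- function(params = model_parameters(),
                                k_range = c(1, 100), n_grid = 25,
                                quantile = 0.9, refine_tol = 1e-3) {
  ks <- 10^seq(log10(k_range[1]), log10(k_range[2]),
               length.out = n_grid)
  sr <- scan_parameter("partition_k_light", ks, params)
  asym <- sr$lit_plat_frac[n_grid]
  target <- quantile * asym
  idx <- which(sr$lit_plat_frac >= target)[1]
  if (is.na(idx))
    stop("scan never reaches ", quantile, " of its asymptote",
         call. = FALSE)
  k_hit <- ks[idx]
  if (idx > 1L) {
    lit_at <- function(k) {
      p <- update_parameters(params, partition_k_light = k)
      sc <- apply_scenario("ilid_drop", p)
      lit_steady_pair(sc$params, sc$config)$lit_plat_frac
    }
    lo <- ks[idx - 1L]; hi <- ks[idx]
    while (hi / lo - 1 > refine_tol) {
      mid <- sqrt(lo * hi)
      if (lit_at(mid) >= target) hi <- mid else lo <- mid
    }
    k_hit <- hi
  }
  list(k_at_quantile = k_hit, asymptote = asym, scan = sr)
}

#' Src-concentration range with strong light/dark contrast
#'
#' Measures over what contiguous range of cellular Src concentration the
#' lit/dark steady pLAT contrast stays at or above a threshold
#' (default 10-fold). A log-spaced scan brackets the contiguous block
#' and its edges are refined by bisection on the continuous contrast
#' function, so the reported span is a property of the model, not of
#' the grid.
#'
#' @param params Wild-type `model_parameters`.
#' @param scenario Scenario name.
#' @param threshold Contrast threshold (fold).
#' @param src_range Scanned concentration range (uM).
#' @param per_decade Bracketing grid density.
#' @param refine_tol Relative bisection tolerance on the edges.
#' @return List with `lo`, `hi` (uM; `NA` if the threshold is never
#'   reached), `decades` (log10 span, 0 if never reached) and the
#'   bracketing `scan_result`.
#' @export
src_contrast_range <- function(params = model_parameters(),
                               scenario = "ilid_drop",
                               threshold = 10,
                               src_range = c(1e-3, 1e2),
                               per_decade = 4, refine_tol = 1e-3) {
  grid <- 10^seq(log10(src_range[1]), log10(src_range[2]),
                 by = 1 / per_decade)
  sr <- scan_parameter("src_cyt", grid, params, scenario = scenario)
  con <- sr$lit_plat_frac / pmax(sr$dark_plat_frac,
                                 .Machine$double.xmin)
  contrast_at <- function(s) {
    sc <- apply_scenario(scenario,
                         update_parameters(params, src_cyt = s))
    r <- lit_steady_pair(sc$params, sc$config)
    r$lit_plat_frac / max(r$dark_plat_frac, .Machine$double.xmin)
  }
  ok <- con >= threshold
  if (!any(ok))
    return(list(lo = NA_real_, hi = NA_real_, decades = 0, scan = sr))
  ## largest contiguous block on the grid
  runs <- rle(ok)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  block <- which.max(ifelse(runs$values, runs$lengths, 0))
  i1 <- starts[block]; i2 <- ends[block]
  bisect <- function(out_idx, in_idx) {
    lo <- grid[out_idx]; hi <- grid[in_idx]
    while (max(hi, lo) / min(hi, lo) - 1 > refine_tol) {
      mid <- sqrt(lo * hi)
      if (contrast_at(mid) >= threshold) hi <- mid else lo <- mid
    }
    hi
  }
  lo_edge <- if (i1 > 1L) bisect(i1 - 1L, i1) else grid[1L]
  hi_edge <- if (i2 < length(grid)) bisect(i2 + 1L, i2) else
    grid[length(grid)]
  list(lo = lo_edge, hi = hi_edge,
       decades = log10(hi_edge / lo_edge), scan = sr)
}

#' PP2 dose-response of the lit steady state
#'
#' For each inhibitor dose, equilibrates the scenario in the dark,
#' switches on the light and records the lit steady pLAT fraction. PP2
#' acts non-competitively on both Src catalytic constants
#' ([pp2_scale()]).
#'
#' @param pp2_concs Non-negative, strictly increasing doses (uM).
#' @param params Wild-type `model_parameters`.
#' @param scenario Scenario name: `"ilid_drop"` for wild-type Src or
#'   `"src_dsh2dsh3"` for the feedback-disconnected variant.
#' @param overrides Named list forwarded to [apply_scenario()].
#' @return Data.frame of class `dose_response` with columns `pp2_conc`
#'   and `plat_frac`.
#' @examples
#' \donttest{
#' dr <- pp2_titration(c(0, 1, 10), model_parameters())
#' dr$plat_frac
#' }
#' @export
pp2_titration <- function(pp2_concs, params = model_parameters(),
                          scenario = "ilid_drop", overrides = list()) {
  if (any(pp2_concs < 0))
    stop("pp2_concs must be >= 0", call. = FALSE)
  if (is.unsorted(pp2_concs, strictly = TRUE))
    stop("pp2_concs must be strictly increasing", call. = FALSE)
  fr <- vapply(pp2_concs, function(d) {
    p <- update_parameters(params, pp2 = d)
    sc <- apply_scenario(scenario, p, overrides)
    lit_steady_pair(sc$params, sc$config)$lit_plat_frac
  }, 0)
  structure(data.frame(pp2_conc = pp2_concs, plat_frac = fr),
            class = c("dose_response", "data.frame"),
            scenario = scenario)
}

#' Log-spaced PP2 dose grid
#'
#' @param from,to Decade endpoints (uM).
#' @param per_decade Points per decade (default 8).
#' @return Strictly increasing dose vector.
#' @export
pp2_dose_grid <- function(from = 1e-2, to = 1e2, per_decade = 8) {
  10^seq(log10(from), log10(to),
         by = 1 / per_decade)
}

#' Effective dose range of a dose-response curve
#'
#' The largest dose at which the response still exceeds half its
#' zero-dose (or smallest-dose) value, found by linear interpolation in
#' log-dose.
#'
#' @param dr A `dose_response`.
#' @return The half-effect dose (uM), or `Inf` if the curve never drops
#'   below half.
#' @export
half_effect_dose <- function(dr) {
  f0 <- dr$plat_frac[1L]
  below <- which(dr$plat_frac < f0 / 2)
  if (!length(below)) return(Inf)
  i <- below[1L]
  if (i == 1L) return(dr$pp2_conc[1L])
  x1 <- dr$pp2_conc[i - 1L]; x2 <- dr$pp2_conc[i]
  y1 <- dr$plat_frac[i - 1L]; y2 <- dr$plat_frac[i]
  lx <- log10(max(x1, 1e-12)) +
    (f0 / 2 - y1) / (y2 - y1) * (log10(x2) - log10(max(x1, 1e-12)))
  10^lx
}

#' Precompute the normalized PP2 response profile
#'
#' The inhibitor enters the model only through the ratio x = [PP2]/K_I,
#' so the lit steady pLAT fraction is a one-dimensional function g(x).
#' This computes g on a log grid once; [fit_dose_response()] then reuses
#' it to evaluate candidate K_I values cheaply.
#'
#' @param params Wild-type `model_parameters`.
#' @param scenario Scenario name.
#' @param x_range Range of [PP2]/K_I covered by the grid.
#' @param per_decade Grid density.
#' @return A function g(x), vectorized, valid on `x_range` (clamped
#'   outside), with the grid attached as attributes.
#' @export
pp2_response_profile <- function(params = model_parameters(),
                                 scenario = "ilid_drop",
                                 x_range = c(1e-4, 1e4),
                                 per_decade = 8) {
  p1 <- update_parameters(params, ki_pp2 = 1)
  xs <- c(0, 10^seq(log10(x_range[1]), log10(x_range[2]),
                    by = 1 / per_decade))
  g <- pp2_titration(xs, p1, scenario)$plat_frac
  lx <- log10(xs[-1L])
  sf <- stats::splinefun(lx, g[-1L], method = "hyman")
  fun <- function(x) {
    x <- pmax(x, 0)
    out <- numeric(length(x))
    small <- x < xs[2L]
    out[small] <- g[1L] + (g[2L] - g[1L]) * x[small] / xs[2L]
    out[!small] <- sf(pmin(log10(x[!small]), lx[length(lx)]))
    out
  }
  attr(fun, "x") <- xs
  attr(fun, "g") <- g
  fun
}

#' Fit a PP2 dose-response with the mechanistic model
#'
#' Least-squares estimation of the inhibition constant K_I and/or a
#' multiplicative readout amplitude from observed dose-response points.
#' The model curve is `amplitude * g([PP2]/ki_pp2)` with g the lit
#' steady pLAT fraction profile ([pp2_response_profile()]). The search
#' is initialized deterministically from every dose on the observed
#' grid, screened on the interpolated profile, and the best candidate is
#' polished by Levenberg-Marquardt -- against exact steady-state model
#' evaluations when `exact_refine = TRUE` (the default).
#'
#' @param observed Data.frame with columns `pp2_conc` and `plat_frac`
#'   (>= 3 doses, responses in `[0, 1]` up to amplitude scaling).
#' @param params Wild-type `model_parameters` (the true `ki_pp2` field
#'   is ignored when K_I is free).
#' @param scenario Scenario name.
#' @param free Character vector among `"ki_pp2"` and `"amplitude"`.
#' @param profile Optional precomputed [pp2_response_profile()] to
#'   reuse across fits.
#' @param exact_refine Polish the interpolated fit with exact model
#'   evaluations (slower; needed for very-high-precision recovery).
#' @return List with `ki_pp2`, `amplitude`, `residual` (sum of squared
#'   residuals), `fitted` (per-dose fitted values), `at_bound` (named
#'   logical profile-bound flags), and `free`.
#' @examples
#' \donttest{
#' p <- model_parameters()
#' obs <- pp2_titration(c(0.1, 0.3, 1, 3, 10), p)
#' fit_dose_response(obs, p, exact_refine = FALSE)$ki_pp2
#' }
#' @export
fit_dose_response <- function(observed, params = model_parameters(),
                              scenario = "ilid_drop",
                              free = c("ki_pp2", "amplitude"),
                              profile = NULL, exact_refine = TRUE) {
  free <- match.arg(free, c("ki_pp2", "amplitude"),
                    several.ok = TRUE)
  if (!all(c("pp2_conc", "plat_frac") %in% names(observed)))
    stop("observed must have columns pp2_conc and plat_frac",
         call. = FALSE)
  doses <- observed$pp2_conc
  y <- observed$plat_frac
  if (length(doses) < length(free))
    stop("fewer doses than free parameters: under-determined fit",
         call. = FALSE)
  if (length(doses) < 3L)
    stop("need at least 3 doses", call. = FALSE)
  if (is.null(profile))
    profile <- pp2_response_profile(params, scenario)

  fit_ki <- "ki_pp2" %in% free
  fit_amp <- "amplitude" %in% free
  pos <- doses[doses > 0]
  ki_lo <- min(pos) / 1e3
  ki_hi <- max(pos) * 1e3
  g0 <- profile(0)
  amp_fixed <- 1
  pred_interp <- function(ki, amp) amp * profile(doses / ki)

  sse <- function(ki, amp) sum((pred_interp(ki, amp) - y)^2)
  ## deterministic multi-start: every positive dose as a K_I candidate
  ki_starts <- if (fit_ki) pos else params$ki_pp2
  best <- NULL
  for (k0 in ki_starts) {
    a0 <- if (fit_amp) max(y) / g0 else amp_fixed
    par0 <- c(if (fit_ki) log(k0), if (fit_amp) a0)
    res_fun <- function(par) {
      i <- 1L
      ki <- if (fit_ki) { v <- exp(par[i]); i <- i + 1L; v } else
        params$ki_pp2
      amp <- if (fit_amp) par[i] else amp_fixed
      pred_interp(min(max(ki, ki_lo), ki_hi), max(amp, 0)) - y
    }
    fit <- minpack.lm::nls.lm(par = par0, fn = res_fun,
                              control = minpack.lm::nls.lm.control(
                                maxiter = 200))
    ss <- sum(fit$fvec^2)
    if (is.null(best) || ss < best$ss)
      best <- list(par = fit$par, ss = ss)
  }
  unpack <- function(par) {
    i <- 1L
    ki <- if (fit_ki) { v <- exp(par[i]); i <- i + 1L; v } else
      params$ki_pp2
    amp <- if (fit_amp) par[i] else amp_fixed
    list(ki = min(max(ki, ki_lo), ki_hi), amp = max(amp, 0))
  }

  if (exact_refine) {
    pred_exact <- function(ki, amp) {
      p <- update_parameters(params, ki_pp2 = ki)
      amp * vapply(doses, function(d) {
        sc <- apply_scenario(scenario,
                             update_parameters(p, pp2 = d))
        lit_steady_pair(sc$params, sc$config)$lit_plat_frac
      }, 0)
    }
    res_exact <- function(par) {
      u <- unpack(par)
      pred_exact(u$ki, u$amp) - y
    }
    fit <- minpack.lm::nls.lm(par = best$par, fn = res_exact,
                              control = minpack.lm::nls.lm.control(
                                maxiter = 60))
    best <- list(par = fit$par, ss = sum(fit$fvec^2))
    u <- unpack(best$par)
    fitted <- pred_exact(u$ki, u$amp)
  } else {
    u <- unpack(best$par)
    fitted <- pred_interp(u$ki, u$amp)
  }
  list(ki_pp2 = u$ki, amplitude = u$amp, residual = best$ss,
       fitted = fitted,
       at_bound = c(ki_pp2 = fit_ki &&
                      (u$ki <= ki_lo * 1.001 || u$ki >= ki_hi / 1.001),
                    amplitude = fit_amp && u$amp == 0),
       free = free)
}
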