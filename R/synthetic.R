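## Run expr under a fixed seed without disturbing the caller's RNG.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("a single finite seed is required", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(),
                    inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Synthetic calcium-indicator traces with ground-truth labels
#'
#' Emulates the Jurkat-style recordings: a 3-min time course sampled
#' every 5 s, with three cell classes. Responders rise sigmoidally after
#' stimulus onset to a plateau held for the rest of the recording
#' (well over 30 s); "blinkers" show one or two isolated single-sample
#' spikes; non-responders stay at baseline. Noise is multiplicative
#' log-normal (fluorescence is positive and noise scales with signal).
#' Cells are assigned to fields of `field_size` cells, the unit of
#' replication for responder fractions. Deterministic for a fixed seed.
#'
#' @param n_cells Number of cells.
#' @param responder_fraction,blinker_fraction Class proportions; their
#'   sum must be <= 1, the rest are non-responders.
#' @param noise_sd Log-normal noise sigma (relative).
#' @param dt Sampling interval (s); default 5.
#' @param duration Recording length (s); default 180.
#' @param stim_time Stimulus onset (s); samples before it are
#'   pre-stimulus baseline.
#' @param amp_range Fold-change amplitude range of responses.
#' @param field_size Cells per field of view.
#' @param background Constant imaging background added to every value.
#' @param seed RNG seed (required; generators take no implicit entropy).
#' @return List with `traces` (tidy data.frame: `cell_id`, `field_id`,
#'   `channel`, `time_s`, `value`, `background`), `labels` (`cell_id`,
#'   `field_id`, `class`), and `time` (the grid).
#' @examples
#' g <- gen_gcamp_traces(10, seed = 1)
#' table(g$labels$class)
#' @export
gen_gcamp_traces <- function(n_cells,
                             responder_fraction = 0.3,
                             blinker_fraction = 0.3,
                             noise_sd = 0.05,
                             dt = 5, duration = 180,
                             stim_time = 15,
                             amp_range = c(2, 4),
                             field_size = 50,
                             background = 10,
                             seed) {
  if (responder_fraction + blinker_fraction > 1)
    stop("responder_fraction + blinker_fraction must be <= 1",
         call. = FALSE)
  tt <- seq(0, duration, by = dt)
  n_resp <- round(n_cells * responder_fraction)
  n_blink <- round(n_cells * blinker_fraction)
  classes <- rep(c("responder", "blinker", "nonresponder"),
                 c(n_resp, n_blink, n_cells - n_resp - n_blink))
  with_seed(seed, {
    classes <- sample(classes)
    rows <- vector("list", n_cells)
    for (i in seq_len(n_cells)) {
      base <- exp(stats::rnorm(1, log(100), 0.3))
      amp <- stats::runif(1, amp_range[1], amp_range[2])
      shape <- rep(1, length(tt))
      if (classes[i] == "responder") {
        t_on <- stats::runif(1, stim_time + 5, stim_time + 45)
        tau <- stats::runif(1, 5, 15)
        shape <- 1 + (amp - 1) * stats::plogis((tt - t_on) / tau)
      } else if (classes[i] == "blinker") {
        k <- sample(1:2, 1)
        ok <- which(tt >= stim_time + 5 & tt <= duration - 2 * dt)
        at <- sample(ok, k)
        at <- at[c(TRUE, abs(diff(at)) > 2)]  # keep spikes isolated
        shape[at] <- amp
      }
      value <- background +
        base * shape * exp(stats::rnorm(length(tt), 0, noise_sd))
      rows[[i]] <- data.frame(
        cell_id = sprintf("cell%04d", i),
        field_id = sprintf("field%02d", (i - 1) %/% field_size + 1),
        channel = "gcamp", time_s = tt, value = value,
        background = background)
    }
  })
  traces <- do.call(rbind, rows)
  labels <- unique(traces[, c("cell_id", "field_id")])
  labels$class <- classes
  rownames(labels) <- NULL
  list(traces = traces, labels = labels, time = tt)
}

#' Synthetic translocation-reporter trace pairs with analytic AUCs
#'
#' Emulates the fibroblast protocol: 61 time points at 15-s intervals
#' over 15 min. Responder cells show a cytoplasmic/nuclear ratio rising
#' exponentially from 1 toward a plateau (maximal within roughly
#' 10 min); non-responders stay at 1. The noiseless baselined-sum AUC
#' of each cell's ratio is stored as its ground-truth label.
#'
#' @inheritParams gen_gcamp_traces
#' @param responder_fraction Fraction of responding cells.
#' @param plateau_range Plateau C/N ratio range for responders.
#' @param tau_range Rise time-constant range (s).
#' @return List with `traces` (tidy data.frame holding `ktr_cyto` and
#'   `ktr_nuc` channels per cell), `labels` (`cell_id`, `field_id`,
#'   `class`, `true_auc`), and `time`.
#' @examples
#' g <- gen_ktr_traces(4, noise_sd = 0, seed = 1)
#' g$labels$true_auc
#' @export
gen_ktr_traces <- function(n_cells,
                           responder_fraction = 0.5,
                           noise_sd = 0.05,
                           dt = 15, duration = 900,
                           plateau_range = c(2.5, 3.5),
                           tau_range = c(120, 240),
                           field_size = 50,
                           background = 10,
                           seed) {
  tt <- seq(0, duration, by = dt)
  n_resp <- round(n_cells * responder_fraction)
  classes <- rep(c("responder", "nonresponder"),
                 c(n_resp, n_cells - n_resp))
  with_seed(seed, {
    classes <- sample(classes)
    rows <- vector("list", n_cells)
    true_auc <- numeric(n_cells)
    for (i in seq_len(n_cells)) {
      ratio <- rep(1, length(tt))
      if (classes[i] == "responder") {
        plateau <- stats::runif(1, plateau_range[1], plateau_range[2])
        tau <- stats::runif(1, tau_range[1], tau_range[2])
        ratio <- 1 + (plateau - 1) * (1 - exp(-tt / tau))
      }
      true_auc[i] <- sum(ratio - ratio[1L])
      nuc0 <- exp(stats::rnorm(1, log(200), 0.2))
      nuc <- background +
        nuc0 * exp(stats::rnorm(length(tt), 0, noise_sd))
      cyto <- background +
        nuc0 * ratio * exp(stats::rnorm(length(tt), 0, noise_sd))
      cid <- sprintf("cell%04d", i)
      fid <- sprintf("field%02d", (i - 1) %/% field_size + 1)
      rows[[i]] <- rbind(
        data.frame(cell_id = cid, field_id = fid,
                   channel = "ktr_cyto", time_s = tt, value = cyto,
                   background = background),
        data.frame(cell_id = cid, field_id = fid,
                   channel = "ktr_nuc", time_s = tt, value = nuc,
                   background = background))
    }
  })
  traces <- do.call(rbind, rows)
  labels <- data.frame(cell_id = sprintf("cell%04d", seq_len(n_cells)),
                       field_id = sprintf("field%02d",
                                          (seq_len(n_cells) - 1) %/%
                                            field_size + 1),
                       class = classes, true_auc = true_auc)
  list(traces = traces, labels = labels, time = tt)
}

#' Synthetic membrane images before and after cluster formation
#'
#' Generates a pre-clustering frame (uniform membrane intensity with
#' multiplicative noise) and a post-clustering frame in which the same
#' total intensity is redistributed into Gaussian puncta: the post frame
#' is rescaled so its total masked intensity equals the pre frame's
#' exactly, so any change in the coefficient of variation reflects
#' spatial reorganization, not added brightness.
#'
#' @param shape Image dimensions (pixels).
#' @param n_clusters Number of puncta injected inside the mask.
#' @param cluster_amplitude Peak amplitude of each punctum relative to
#'   the uniform membrane intensity (1).
#' @param cluster_sigma Punctum width (pixels).
#' @param noise_sd Multiplicative log-normal noise sigma.
#' @param mask_radius_frac Radius of the circular membrane footprint as
#'   a fraction of the smaller image dimension.
#' @param seed RNG seed (required).
#' @return List with `pre`, `post` (matrices), `mask` (logical matrix)
#'   and `centers` (punctum coordinates).
#' @examples
#' img <- gen_cluster_images(shape = c(32, 32), n_clusters = 4, seed = 1)
#' membrane_cv_timeseries(list(img$pre, img$post), img$mask)[2] > 0
#' @export
gen_cluster_images <- function(shape = c(64, 64),
                               n_clusters = 12,
                               cluster_amplitude = 5,
                               cluster_sigma = 2,
                               noise_sd = 0.05,
                               mask_radius_frac = 0.4,
                               seed) {
  nr <- shape[1]; nc <- shape[2]
  cx <- (nr + 1) / 2; cy <- (nc + 1) / 2
  r2 <- (mask_radius_frac * min(nr, nc))^2
  xs <- matrix(seq_len(nr), nr, nc)
  ys <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  mask <- (xs - cx)^2 + (ys - cy)^2 <= r2
  with_seed(seed, {
    pre <- matrix(exp(stats::rnorm(nr * nc, 0, noise_sd)), nr, nc)
    pre[!mask] <- 0
    spots <- matrix(0, nr, nc)
    centers <- NULL
    if (n_clusters > 0) {
      idx <- sample(which(mask), n_clusters)
      centers <- cbind(row = (idx - 1) %% nr + 1,
                       col = (idx - 1) %/% nr + 1)
      for (k in seq_len(n_clusters)) {
        d2 <- (xs - centers[k, 1])^2 + (ys - centers[k, 2])^2
        spots <- spots + cluster_amplitude *
          exp(-d2 / (2 * cluster_sigma^2))
      }
    }
    post <- (1 + spots) * matrix(exp(stats::rnorm(nr * nc, 0,
                                                  noise_sd)), nr, nc)
    post[!mask] <- 0
    post <- post * sum(pre[mask]) / sum(post[mask])
  })
  list(pre = pre, post = post, mask = mask, centers = centers)
}

#' Noisy steady-state model readouts for parameter-recovery studies
#'
#' Evaluates the lit steady pLAT fraction of the model over a dose (or
#' other design) grid and perturbs it with multiplicative Gaussian
#' noise, truncated to `[0, 1]`. Ground truth (the generating parameter
#' set and the noiseless curve) is recorded in the result.
#'
#' @param params Generating `model_parameters` (ground truth).
#' @param scenario Scenario name.
#' @param doses PP2 dose grid (uM, strictly increasing).
#' @param noise_sd Relative noise standard deviation.
#' @param n_replicates Independent noisy replicates of the whole curve.
#' @param seed RNG seed (required).
#' @param true_curve Optional precomputed [pp2_titration()] result for
#'   `params`/`scenario`/`doses`, to avoid recomputation across calls.
#' @return Data.frame with `replicate`, `pp2_conc`, `plat_frac`
#'   (noisy) and `plat_frac_true`; the generating parameters are the
#'   `true_params` attribute.
#' @examples
#' \donttest{
#' obs <- gen_noisy_readouts(model_parameters(), doses = c(0.1, 1, 10),
#'                           noise_sd = 0, seed = 1)
#' all(obs$plat_frac == obs$plat_frac_true)
#' }
#' @export
gen_noisy_readouts <- function(params = model_parameters(),
                               scenario = "ilid_drop",
                               doses = pp2_dose_grid(0.05, 50, 2),
                               noise_sd = 0.05,
                               n_replicates = 1,
                               seed,
                               true_curve = NULL) {
  if (is.null(true_curve))
    true_curve <- pp2_titration(doses, params, scenario)
  stopifnot(nrow(true_curve) == length(doses))
  out <- with_seed(seed, {
    do.call(rbind, lapply(seq_len(n_replicates), function(r) {
      noisy <- true_curve$plat_frac *
        (1 + stats::rnorm(length(doses), 0, noise_sd))
      data.frame(replicate = r, pp2_conc = doses,
                 plat_frac = pmin(pmax(noisy, 0), 1),
                 plat_frac_true = true_curve$plat_frac)
    }))
  })
  attr(out, "true_params") <- params
  out
}
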