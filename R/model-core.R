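#' LAT concentration in the (possibly shrunken) membrane compartment
#'
#' Cluster formation is modeled as the membrane compartment shrinking by
#' the partition coefficient K, so every membrane species is concentrated
#' K-fold: `[LAT] = K * [LAT]0`.
#'
#' @param partition_k Partition coefficient K (dimensionless, >= 1).
#' @param lat_total Total LAT referred to the unclustered membrane (uM).
#' @return LAT concentration in the cluster compartment (uM).
#' @examples
#' cluster_concentration(10, 0.5)  # 5
#' @export
cluster_concentration <- function(partition_k, lat_total) {
  if (!is.numeric(partition_k) || any(partition_k <= 0))
    stop("partition_k must be positive", call. = FALSE)
  if (any(partition_k < 1))
    stop("partition_k must be >= 1 (clustering concentrates)",
         call. = FALSE)
  if (any(lat_total < 0)) stop("lat_total must be >= 0", call. = FALSE)
  partition_k * lat_total
}

#' Equilibrium partitioning of Zap70 between cytosol and membrane
#'
#' Zap70 reaches the membrane compartment two ways: bound to LAT through
#' the iLID/SspB pair (fast equilibrium, cytosolic Zap70 held constant)
#' and by free diffusion into the cluster. The fraction of LAT occupied
#' by Zap70 is `f = [Zap70]0 KA / (1 + [Zap70]0 KA)`, so the bound pool
#' is `[LAT] * f` and the free pool is simply `[Zap70]0`.
#'
#' @param lat_conc LAT concentration in the membrane compartment (uM),
#'   e.g. from [cluster_concentration()].
#' @param zap70_cyt Cytosolic Zap70 (uM).
#' @param ka_ilid iLID/SspB association constant (1/uM).
#' @return List with `total_mem`, `bound`, `free` (uM) and
#'   `bound_fraction` f, the fraction of LAT carrying a Zap70 -- also
#'   used to split the LAT pool into bound and free sub-pools.
#' @examples
#' zap70_partition(10, 1, 10)$bound  # 100/11
#' @export
zap70_partition <- function(lat_conc, zap70_cyt, ka_ilid) {
  if (any(c(lat_conc, zap70_cyt, ka_ilid) < 0))
    stop("lat_conc, zap70_cyt and ka_ilid must be >= 0", call. = FALSE)
  f <- zap70_cyt * ka_ilid / (1 + zap70_cyt * ka_ilid)
  bound <- lat_conc * f
  list(total_mem = bound + zap70_cyt, bound = bound, free = zap70_cyt,
       bound_fraction = f)
}

#' Equilibrium partitioning of Src into active and inactive forms
#'
#' Src binds phosphorylated LAT through an SH2/phosphotyrosine
#' interaction, which releases its autoinhibition; unbound Src diffuses
#' freely into the cluster but stays autoinhibited. At equilibrium, with
#' the cytosolic Src concentration held constant:
#' `[Src]a = [pLAT] [Src]0 KA / (1 + [Src]0 KA)`, `[Src]i = [Src]0`.
#'
#' @param plat_conc Total phosphorylated LAT concentration in the
#'   membrane compartment (uM) -- the free plus bound phospho-pools.
#' @param src_cyt Cytosolic Src (uM).
#' @param ka_sh2 SH2/pY association constant (1/uM).
#' @return List with `active` and `inactive` concentrations (uM).
#' @examples
#' src_partition(2, 1, 1)  # active 1, inactive 1
#' @export
src_partition <- function(plat_conc, src_cyt, ka_sh2) {
  if (any(c(plat_conc, src_cyt, ka_sh2) < 0))
    stop("plat_conc, src_cyt and ka_sh2 must be >= 0", call. = FALSE)
  list(active = plat_conc * src_cyt * ka_sh2 / (1 + src_cyt * ka_sh2),
       inactive = src_cyt)
}

#' Non-competitive inhibitor scaling of a catalytic rate
#'
#' PP2 scales both Src catalytic rate constants by `K_I / (K_I + [PP2])`.
#'
#' @param kcat Uninhibited catalytic rate constant (1/s).
#' @param ki Inhibition constant K_I (uM, > 0).
#' @param pp2 Inhibitor concentration (uM, >= 0).
#' @return The scaled rate constant (1/s).
#' @examples
#' pp2_scale(3, 1, 1)  # 1.5: half-inhibition at [PP2] = K_I
#' @export
pp2_scale <- function(kcat, ki, pp2) {
  if (!is.numeric(ki) || any(ki <= 0))
    stop("ki must be > 0", call. = FALSE)
  if (any(pp2 < 0)) stop("pp2 must be >= 0", call. = FALSE)
  kcat * ki / (ki + pp2)
}

#' Model state: the four phospho-pool variables
#'
#' @param pzap70_mem Phosphorylated Zap70 in the membrane/cluster
#'   compartment (uM).
#' @param pzap70_cyt Phosphorylated Zap70 in the cytosol (uM).
#' @param plat_free Phosphorylated LAT not bound to Zap70 (uM,
#'   cluster-referred).
#' @param plat_bound Phosphorylated LAT bound to Zap70 via iLID:SspB
#'   (uM, cluster-referred).
#' @return A named numeric vector of class `model_state`.
#' @export
model_state <- function(pzap70_mem = 0, pzap70_cyt = 0,
                        plat_free = 0, plat_bound = 0) {
  x <- c(pzap70_mem = pzap70_mem, pzap70_cyt = pzap70_cyt,
         plat_free = plat_free, plat_bound = plat_bound)
  if (any(!is.finite(x)) || any(x < 0))
    stop("state variables must be finite and >= 0", call. = FALSE)
  structure(x, class = "model_state")
}

state_names <- function() {
  c("pzap70_mem", "pzap70_cyt", "plat_free", "plat_bound")
}

#' Equilibrium pool sizes for a parameter set and illumination phase
#'
#' Resolves the algebraic layer for the current phase: the LAT
#' concentration under the phase's partition coefficient (K = 1 in the
#' dark, `partition_k_light` when lit), the Zap70 partition under the
#' phase's iLID association constant, and the split of LAT into
#' Zap70-bound and free sub-pools by the bound fraction f.
#'
#' @param params A `model_parameters` object.
#' @param config A `scenario_config` (its `light_on` selects the phase
#'   unless `light_on` is given explicitly).
#' @param light_on Optional logical override of `config$light_on`.
#' @return List with `partition_k`, `ka_ilid`, `lat` (total LAT
#'   concentration), `bound_fraction`, `zap70_mem` (total membrane
#'   Zap70), `zap70_bound`, `lat_bound_total`, `lat_free_total`.
#' @export
equilibrium_pools <- function(params, config = scenario_config(),
                              light_on = NULL) {
  lit <- if (is.null(light_on)) isTRUE(config$light_on) else
    isTRUE(light_on)
  k <- if (lit) params$partition_k_light else 1
  ka <- if (lit) params$ka_ilid_light else params$ka_ilid_dark
  lat <- cluster_concentration(k, params$lat_total)
  zp <- zap70_partition(lat, params$zap70_cyt, ka)
  list(partition_k = k, ka_ilid = ka, lat = lat,
       bound_fraction = zp$bound_fraction,
       zap70_mem = zp$total_mem, zap70_bound = zp$bound,
       lat_bound_total = zp$bound_fraction * lat,
       lat_free_total = (1 - zp$bound_fraction) * lat)
}

#' Time derivatives of the four phospho-pools
#'
#' Evaluates the model right-hand side at a state, under the equilibrium
#' pools implied by the parameter set, scenario and illumination phase:
#'
#' * membrane pZap70 gains by Michaelis-Menten phosphorylation of
#'   unphosphorylated membrane Zap70 by active (pLAT-bound) and inactive
#'   Src, and is dephosphorylated first-order;
#' * cytosolic pZap70 gains only from inactive Src;
#' * free pLAT gains by the pZap70 Michaelis-Menten term;
#' * bound pLAT gains by the same term plus first-order phosphorylation
#'   of the iLID:SspB-tethered complexes of unphosphorylated LAT with
#'   pZap70, whose pool is `[LAT]n,bound * [Zap70]p / [Zap70]`;
#' * both LAT pools are dephosphorylated first-order.
#'
#' PP2 scales both Src catalytic constants non-competitively. In the
#' `zap70_k362e` scenario both Zap70 phospho-forms act on LAT, so the
#' kinase concentration in the LAT terms is the total membrane Zap70 and
#' the tethered complex pool covers all bound, unphosphorylated LAT.
#'
#' @param state A `model_state` (or named numeric vector).
#' @param params A `model_parameters` object (typically the `params`
#'   element returned by [apply_scenario()]).
#' @param config A `scenario_config`.
#' @param light_on Optional logical override of `config$light_on`.
#' @param tol Tolerance for the physical-box check on `state`.
#' @return Named numeric vector of derivatives (uM/s), in state order.
#' @examples
#' sc <- apply_scenario("ilid_drop", model_parameters())
#' model_rhs(model_state(), sc$params, sc$config)
#' @export
model_rhs <- function(state, params, config = scenario_config(),
                      light_on = NULL, tol = 1e-8) {
  eq <- equilibrium_pools(params, config, light_on)
  x <- as.numeric(state)[1:4]
  names(x) <- state_names()
  scale <- max(eq$lat, eq$zap70_mem, 1)
  if (x["pzap70_mem"] > eq$zap70_mem + tol * scale ||
      x["pzap70_cyt"] > params$zap70_cyt + tol * scale ||
      x["plat_free"] > eq$lat_free_total + tol * scale ||
      x["plat_bound"] > eq$lat_bound_total + tol * scale ||
      any(x < -tol * scale))
    stop("state outside the physical pool bounds", call. = FALSE)

  zn <- eq$zap70_mem - x["pzap70_mem"]
  zn_cyt <- params$zap70_cyt - x["pzap70_cyt"]
  lnf <- eq$lat_free_total - x["plat_free"]
  lnb <- eq$lat_bound_total - x["plat_bound"]

  kcat_a <- pp2_scale(params$kcat_src_active, params$ki_pp2, params$pp2)
  kcat_i <- pp2_scale(params$kcat_src_inactive, params$ki_pp2,
                      params$pp2)
  src <- src_partition(x["plat_free"] + x["plat_bound"],
                       params$src_cyt, params$ka_sh2)

  d_pzap_mem <- kcat_a * src$active * zn / (params$km_src_active + zn) +
    kcat_i * src$inactive * zn / (params$km_src_inactive + zn) -
    params$kdeph_zap70 * x["pzap70_mem"]
  d_pzap_cyt <- kcat_i * src$inactive * zn_cyt /
    (params$km_src_inactive + zn_cyt) -
    params$kdeph_zap70 * x["pzap70_cyt"]

  k362e <- identical(config$name, "zap70_k362e")
  zap_kinase <- if (k362e) eq$zap70_mem else x[["pzap70_mem"]]
  complex_frac <- if (k362e) 1 else
    if (eq$zap70_mem > 0) x[["pzap70_mem"]] / eq$zap70_mem else 0

  d_plat_free <- params$kcat_pzap70 * zap_kinase * lnf /
    (params$km_pzap70 + lnf) - params$kdeph_lat * x["plat_free"]
  d_plat_bound <- params$kcat_pzap70 * zap_kinase * lnb /
    (params$km_pzap70 + lnb) +
    params$k_tethered * lnb * complex_frac -
    params$kdeph_lat * x["plat_bound"]

  d <- c(d_pzap_mem, d_pzap_cyt, d_plat_free, d_plat_bound)
  names(d) <- state_names()
  d
}
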