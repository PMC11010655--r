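#' Configuration for the synthetic pollen world
#'
#' Defines a synthetic modern calibration universe in which taxa respond
#' unimodally (Gaussian response surfaces) to mean annual temperature and
#' precipitation when human influence is low, and composition is
#' progressively decoupled from climate above two planted HII thresholds:
#' between `theta1` and `theta2` the expected assemblage is a mixture
#' `(1 - w) * native + w * disturbance profile` with `w` rising linearly
#' from 0 at `theta1` to `w_max` at `theta2`; at and above `theta2` the
#' assemblage is a cereal/weed-dominated artificial profile with only a
#' small residual climate-dependent component. Observed counts are drawn
#' multinomially at the configured count depth after lognormal site-level
#' noise.
#'
#' @param n_modern number of modern samples.
#' @param n_native,n_pioneer,n_cereal taxa per guild (native climate
#'   indicators / pioneer disturbance taxa / cereal-weed taxa).
#' @param mat_range,map_range climate gradients (deg C, mm).
#' @param theta1,theta2 planted HII thresholds (native/secondary and
#'   secondary/artificial); `theta1 = 64` disables distortion entirely.
#' @param w_max disturbance mixing weight reached at `theta2`.
#' @param count_depth pollen count per sample (>= 100).
#' @param noise_sd sd of the lognormal site-level compositional noise.
#' @param artificial_climate_w residual native (climate-dependent) share of
#'   artificial assemblages.
#' @param center_lon,center_lat,lon_half_width,lat_half_width the uniform
#'   geographic box samples are scattered over (degrees).
#' @param seed RNG seed; identical config + seed gives identical output.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_modern = 1500, n_native = 30, n_pioneer = 5,
                             n_cereal = 5, mat_range = c(0, 20),
                             map_range = c(200, 1800), theta1 = 22,
                             theta2 = 38, w_max = 0.8, count_depth = 300,
                             noise_sd = 0.25, artificial_climate_w = 0.1,
                             center_lon = 120, center_lat = 30,
                             lon_half_width = 15, lat_half_width = 13,
                             seed = 1) {
  if (theta1 <= 0 || theta1 > 64) stop("theta1 must be in (0, 64]")
  if (theta1 < 64 && (theta2 <= theta1 || theta2 > 64))
    stop("need 0 < theta1 < theta2 <= 64")
  if (theta1 == 64) theta2 <- 64
  if (count_depth < 100) stop("count_depth must be >= 100")
  if (w_max <= 0 || w_max > 1) stop("w_max must be in (0, 1]")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(n_modern = n_modern, n_native = n_native,
                 n_pioneer = n_pioneer, n_cereal = n_cereal,
                 mat_range = mat_range, map_range = map_range,
                 theta1 = theta1, theta2 = theta2, w_max = w_max,
                 count_depth = count_depth, noise_sd = noise_sd,
                 artificial_climate_w = artificial_climate_w,
                 center_lon = center_lon, center_lat = center_lat,
                 lon_half_width = lon_half_width,
                 lat_half_width = lat_half_width, seed = seed),
            class = "synthetic_config")
}

# taxon-level parameters; drawn first so that modern and fossil generators
# share the same taxa under the same config seed
make_taxa_params <- function(cfg) {
  nn <- cfg$n_native; np <- cfg$n_pioneer; nc <- cfg$n_cereal
  taxa <- c(paste0("NativeTaxon", sprintf("%02d", seq_len(nn))),
            paste0("PioneerTaxon", sprintf("%02d", seq_len(np))),
            paste0("CerealWeed", sprintf("%02d", seq_len(nc))))
  u_mat <- stats::runif(nn, cfg$mat_range[1], cfg$mat_range[2])
  u_map <- stats::runif(nn, cfg$map_range[1], cfg$map_range[2])
  amp <- exp(stats::rnorm(nn, 0, 0.5))
  pw <- stats::runif(np, 0.5, 1.5); pw <- pw / sum(pw)
  cw <- stats::runif(nc, 0.5, 1.5); cw <- cw / sum(cw)
  m <- nn + np + nc
  disturbance <- c(rep(0, nn), 0.5 * pw, 0.5 * cw)
  artificial <- c(rep(0, nn), 0.15 * pw, 0.85 * cw)
  list(taxa = taxa, n_native = nn, u_mat = u_mat, u_map = u_map, amp = amp,
       tol_mat = 0.2 * diff(cfg$mat_range),
       tol_map = 0.2 * diff(cfg$map_range),
       base_pioneer = 0.25 * pw, base_cereal = 0.03 * cw,
       disturbance = disturbance, artificial = artificial, m = m)
}

# expected native composition (rows normalized to 1) at given climates
native_expectation <- function(p, mat, map) {
  E <- exp(-0.5 * outer(mat, p$u_mat, "-")^2 / p$tol_mat^2 -
             0.5 * outer(map, p$u_map, "-")^2 / p$tol_map^2)
  E <- sweep(E, 2, p$amp, "*")
  E <- cbind(E, matrix(rep(c(p$base_pioneer, p$base_cereal),
                           each = length(mat)), nrow = length(mat)))
  E / rowSums(E)
}

# expected composition given system label and disturbance weight w
expected_composition <- function(p, cfg, mat, map, system, w) {
  nat <- native_expectation(p, mat, map)
  E <- nat
  sec <- system == "secondary"
  if (any(sec))
    E[sec, ] <- (1 - w[sec]) * nat[sec, , drop = FALSE] +
      outer(w[sec], p$disturbance)
  art <- system == "artificial"
  if (any(art)) {
    aw <- cfg$artificial_climate_w
    E[art, ] <- aw * nat[art, , drop = FALSE] +
      (1 - aw) * matrix(p$artificial, sum(art), p$m, byrow = TRUE)
  }
  E
}

# lognormal site noise + multinomial counting
draw_counts <- function(E, cfg) {
  n <- nrow(E); m <- ncol(E)
  P <- E * exp(matrix(stats::rnorm(n * m, 0, cfg$noise_sd), n, m))
  P <- P / rowSums(P)
  t(vapply(seq_len(n),
           function(i) stats::rmultinom(1, cfg$count_depth, P[i, ])[, 1],
           numeric(m)))
}

hii_system <- function(hii, cfg) {
  ifelse(hii <= cfg$theta1, "native",
         ifelse(hii < cfg$theta2, "secondary", "artificial"))
}

hii_w <- function(hii, cfg) {
  w <- rep(0, length(hii))
  sec <- hii > cfg$theta1 & hii < cfg$theta2
  w[sec] <- cfg$w_max * (hii[sec] - cfg$theta1) / (cfg$theta2 - cfg$theta1)
  w
}

#' Generate a synthetic modern calibration dataset with known truth
#'
#' Climates and HII are drawn uniformly over their ranges (HII over
#' \[0, 64\], so every integer HII bin is populated); sites are scattered
#' uniformly over the configured geographic box. See [synthetic_config()]
#' for the compositional model.
#'
#' @param cfg a [synthetic_config()].
#' @return list with `dataset` (a [modern_dataset()], counts basis) and
#'   `truth` (class `synthetic_truth`: per-sample true climate, system
#'   label and disturbance weight, the planted thresholds, and the taxon
#'   response parameters).
#' @export
generate_modern <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed)
  p <- make_taxa_params(cfg)
  n <- cfg$n_modern
  lon <- stats::runif(n, cfg$center_lon - cfg$lon_half_width,
                      cfg$center_lon + cfg$lon_half_width)
  lat <- stats::runif(n, cfg$center_lat - cfg$lat_half_width,
                      cfg$center_lat + cfg$lat_half_width)
  elev <- stats::runif(n, 0, 1500)
  mat <- stats::runif(n, cfg$mat_range[1], cfg$mat_range[2])
  map <- stats::runif(n, cfg$map_range[1], cfg$map_range[2])
  hii <- stats::runif(n, 0, 64)
  system <- hii_system(hii, cfg)
  w <- hii_w(hii, cfg)
  E <- expected_composition(p, cfg, mat, map, system, w)
  counts <- draw_counts(E, cfg)
  ids <- sprintf("SYN%04d", seq_len(n))
  dimnames(counts) <- list(ids, p$taxa)
  pm <- pollen_matrix(counts, basis = "counts")
  meta <- site_meta(data.frame(sample_id = ids, lon = lon, lat = lat,
                               elev = elev, mat_c = mat, map_mm = map,
                               hii = hii, veg_label = system,
                               stringsAsFactors = FALSE))
  truth <- structure(list(
    samples = data.frame(sample_id = ids, mat_true = mat, map_true = map,
                         hii = hii, system = system, w = w,
                         stringsAsFactors = FALSE),
    theta1 = cfg$theta1, theta2 = cfg$theta2,
    taxa = data.frame(taxon = p$taxa[seq_len(p$n_native)],
                      u_mat = p$u_mat, u_map = p$u_map, amp = p$amp),
    tol_mat = p$tol_mat, tol_map = p$tol_map),
    class = "synthetic_truth")
  list(dataset = modern_dataset(pm, meta), truth = truth)
}

#' Default six-phase fossil plan (native/anthropogenic alternation)
#'
#' Emulates a lower-Yangtze-style stratigraphy: three native phases
#' alternating with three human-affected phases over 6,600 years, under a
#' smooth long-term cooling and drying trend (MAT 18.5 to 12 deg C, MAP
#' 1,700 to 850 mm). Anthropogenic phases are "secondary" assemblages with
#' disturbance weight `w = 0.55`, which puts their expected cereal + weed
#' pollen share near one third of the assemblage.
#'
#' @param w_anthro disturbance weight of the anthropogenic phases.
#' @return data.frame phase plan for [generate_fossil_core()].
#' @export
default_phase_plan <- function(w_anthro = 0.55) {
  bounds <- c(6600, 5000, 3700, 2600, 1800, 500, 0)
  system <- c("native", "secondary", "native", "secondary", "native",
              "secondary")
  mat_at <- function(a) 12 + 6.5 * a / 6600
  map_at <- function(a) 850 + 850 * a / 6600
  data.frame(age_old = bounds[-length(bounds)], age_young = bounds[-1],
             system = system,
             mat_old = mat_at(bounds[-length(bounds)]),
             mat_young = mat_at(bounds[-1]),
             map_old = map_at(bounds[-length(bounds)]),
             map_young = map_at(bounds[-1]),
             w = ifelse(system == "secondary", w_anthro, 0),
             stringsAsFactors = FALSE)
}

#' Generate a synthetic fossil core from a phase plan
#'
#' Each plan row gives an age span (old to young, cal yr BP), the
#' vegetation system of that phase, and linear climate trajectories across
#' the span. Samples are placed every `resolution_yr` years and their
#' assemblages generated with the same taxa and noise model as
#' [generate_modern()] (same config seed, so modern and fossil share one
#' taxon universe).
#'
#' @param cfg a [synthetic_config()].
#' @param plan phase plan data.frame (see [default_phase_plan()]): columns
#'   `age_old`, `age_young`, `system`, `mat_old`, `mat_young`, `map_old`,
#'   `map_young`, optional `w`.
#' @param resolution_yr sampling interval in years.
#' @return list with `record` (a [fossil_record()], counts basis) and
#'   `truth` (per-sample age, true climate, system and phase index).
#' @export
generate_fossil_core <- function(cfg, plan = default_phase_plan(),
                                 resolution_yr = 50) {
  stopifnot(inherits(cfg, "synthetic_config"))
  if (is.null(plan) || !nrow(plan)) stop("phase plan is empty")
  req <- c("age_old", "age_young", "system", "mat_old", "mat_young",
           "map_old", "map_young")
  miss <- setdiff(req, names(plan))
  if (length(miss))
    stop("phase plan missing column(s): ", paste(miss, collapse = ", "))
  plan <- plan[order(-plan$age_old), , drop = FALSE]
  if (any(plan$age_young >= plan$age_old))
    stop("each phase needs age_old > age_young")
  if (nrow(plan) > 1 &&
      any(plan$age_old[-1] > plan$age_young[-nrow(plan)] + 1e-9))
    stop("phase age spans overlap")
  if (!"w" %in% names(plan))
    plan$w <- ifelse(plan$system == "secondary", 0.55, 0)

  set.seed(cfg$seed)
  p <- make_taxa_params(cfg)
  set.seed((cfg$seed %% 100000) * 7919 + 12345)  # independent core draws

  ages <- mat <- map <- w <- numeric(0)
  system <- character(0); phase <- integer(0)
  for (i in seq_len(nrow(plan))) {
    a <- seq(plan$age_old[i] - resolution_yr / 2, plan$age_young[i],
             by = -resolution_yr)
    frac <- (plan$age_old[i] - a) / (plan$age_old[i] - plan$age_young[i])
    ages <- c(ages, a)
    mat <- c(mat, plan$mat_old[i] + frac * (plan$mat_young[i] -
                                              plan$mat_old[i]))
    map <- c(map, plan$map_old[i] + frac * (plan$map_young[i] -
                                              plan$map_old[i]))
    system <- c(system, rep(plan$system[i], length(a)))
    w <- c(w, rep(plan$w[i], length(a)))
    phase <- c(phase, rep(i, length(a)))
  }
  o <- order(ages)                        # youngest first = shallowest
  ages <- ages[o]; mat <- mat[o]; map <- map[o]
  system <- system[o]; w <- w[o]; phase <- phase[o]
  E <- expected_composition(p, cfg, mat, map, system, w)
  counts <- draw_counts(E, cfg)
  ids <- sprintf("FOS%04d", seq_along(ages))
  dimnames(counts) <- list(ids, p$taxa)
  pm <- pollen_matrix(counts, basis = "counts")
  record <- fossil_record(pm, depth_cm = seq_along(ages) * 5 - 2.5,
                          age_calbp = ages)
  truth <- structure(list(
    samples = data.frame(sample_id = ids, age_calbp = ages,
                         mat_true = mat, map_true = map, system = system,
                         w = w, phase = phase, stringsAsFactors = FALSE),
    plan = plan, theta1 = cfg$theta1, theta2 = cfg$theta2),
    class = "synthetic_truth")
  list(record = record, truth = truth)
}
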