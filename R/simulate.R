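#' Group specifications for the cohort simulator
#'
#' Each group is one (tissue class, state) condition with target mean and SD
#' of conductivity at the two anchor frequencies (3 kHz and 1 MHz) and a
#' group size. The defaults reproduce the liver study's six conditions, e.g.
#' in vivo tumor (n = 16): 0.41 +/- 0.10 S/m at 3 kHz and 0.78 +/- 0.24 S/m
#' at 1 MHz.
#'
#' @param tissue_class,state condition labels (see [measurement_record()]).
#' @param n group size (>= 1).
#' @param mean_3khz,sd_3khz target conductivity mean / SD at 3 kHz, S/m.
#' @param mean_1mhz,sd_1mhz target conductivity mean / SD at 1 MHz, S/m.
#' @return `group_spec()`: one-row data frame; `default_group_specs()`: data
#'   frame with the six default conditions.
#' @export
group_spec <- function(tissue_class, state, n, mean_3khz, sd_3khz,
                       mean_1mhz, sd_1mhz) {
  tissue_class <- match.arg(tissue_class, c("normal", "tumor", "cirrhotic"))
  state <- match.arg(state, c("in_vivo", "ex_vivo"))
  if (!is.numeric(n) || n < 1 || n != round(n))
    stop_config("group size n must be an integer >= 1")
  v <- c(mean_3khz, sd_3khz, mean_1mhz, sd_1mhz)
  if (!all(is.finite(v)) || any(v <= 0))
    stop_config("group means and SDs must be positive (got %s)",
                paste(v, collapse = ", "))
  if (mean_1mhz <= mean_3khz)
    stop_config("conductivity must rise with frequency: mean_1mhz must exceed mean_3khz")
  data.frame(tissue_class = tissue_class, state = state, n = as.integer(n),
             mean_3khz = mean_3khz, sd_3khz = sd_3khz,
             mean_1mhz = mean_1mhz, sd_1mhz = sd_1mhz)
}

#' @rdname group_spec
#' @export
default_group_specs <- function() {
  rbind(
    group_spec("normal",    "in_vivo", 15, 0.13, 0.06, 0.49, 0.10),
    group_spec("normal",    "ex_vivo", 16, 0.12, 0.07, 0.38, 0.08),
    group_spec("tumor",     "in_vivo", 16, 0.41, 0.10, 0.78, 0.24),
    group_spec("tumor",     "ex_vivo",  3, 0.27, 0.09, 0.54, 0.14),
    group_spec("cirrhotic", "in_vivo",  3, 0.09, 0.01, 0.41, 0.01),
    group_spec("cirrhotic", "ex_vivo",  3, 0.16, 0.01, 0.40, 0.08)
  )
}

#' Simulation configuration
#'
#' Bundles everything the forward simulator needs: RNG seed, frequency grid,
#' probe geometry (cell constant), parasitic network, per-group conductivity
#' targets and the ranges the Cole characteristic frequency and broadness are
#' drawn from.
#'
#' @param seed integer RNG seed; the whole cohort is reproducible from it.
#' @param grid frequency grid, Hz (default 256-point log sweep 3 kHz - 1 MHz).
#' @param geometry a [probe_geometry()].
#' @param parasitics a [parasitic_model()]; `parasitic_model(0, 0)` disables
#'   instrument distortion.
#' @param group_specs data frame as returned by [default_group_specs()].
#' @param fc_range_hz range the Cole characteristic frequency is drawn from
#'   (uniform), Hz.
#' @param alpha_range range the Cole broadness is drawn from (uniform).
#' @param anchor_correlation latent (Gaussian-copula) correlation between a
#'   patient's 3 kHz and 1 MHz conductivity anchors; marginals stay exactly
#'   the configured truncated normals. Tissues conduct coherently across the
#'   band, so anchors are strongly positively correlated within a patient.
#' @return list with class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L, grid = default_frequency_grid(),
                              geometry = probe_geometry(),
                              parasitics = parasitic_model(),
                              group_specs = default_group_specs(),
                              fc_range_hz = c(1e4, 1e5),
                              alpha_range = c(0.8, 1),
                              anchor_correlation = 0.8) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop_config("seed must be a single integer")
  stopifnot(inherits(geometry, "probe_geometry"),
            inherits(parasitics, "parasitic_model"))
  req <- c("tissue_class", "state", "n", "mean_3khz", "sd_3khz",
           "mean_1mhz", "sd_1mhz")
  if (!is.data.frame(group_specs) || !all(req %in% names(group_specs)) ||
      nrow(group_specs) < 1L)
    stop_config("group_specs must be a data frame with columns %s",
                paste(req, collapse = ", "))
  if (any(duplicated(paste(group_specs$tissue_class, group_specs$state))))
    stop_config("duplicate (tissue_class, state) group in group_specs")
  if (length(fc_range_hz) != 2L || fc_range_hz[1] <= 0 ||
      fc_range_hz[2] < fc_range_hz[1])
    stop_config("fc_range_hz must be an increasing positive range")
  if (length(alpha_range) != 2L || alpha_range[1] <= 0 || alpha_range[2] > 1 ||
      alpha_range[2] < alpha_range[1])
    stop_config("alpha_range must be an increasing range within (0, 1]")
  if (!is.numeric(anchor_correlation) || length(anchor_correlation) != 1L ||
      anchor_correlation < 0 || anchor_correlation >= 1)
    stop_config("anchor_correlation must be in [0, 1)")
  structure(list(seed = as.integer(seed), grid = validate_frequency_grid(grid),
                 geometry = geometry, parasitics = parasitics,
                 group_specs = group_specs, fc_range_hz = fc_range_hz,
                 alpha_range = alpha_range,
                 anchor_correlation = anchor_correlation),
            class = "simulation_config")
}

# ---- truncated normal with moment matching --------------------------------

# Mean and SD of N(mu, sd^2) truncated to (0, Inf).
truncnorm_moments <- function(mu, sd) {
  a <- -mu / sd
  h <- stats::dnorm(a) / stats::pnorm(a, lower.tail = FALSE)
  m <- mu + sd * h
  v <- sd^2 * (1 + a * h - h^2)
  c(mean = m, sd = sqrt(pmax(v, 0)))
}

# Parent-normal parameters whose truncated-to-positive moments equal the
# requested (mean, sd). The configured targets are moments of the *realized*
# distribution, so group means of simulated cohorts are unbiased estimates of
# the configured means. Fails (config error) when the requested SD is not
# attainable under positivity truncation.
truncnorm_params <- function(mean, sd) {
  if (mean <= 0 || sd <= 0)
    stop_config("truncated-normal targets must be positive (mean=%g, sd=%g)", mean, sd)
  obj <- function(p) {
    mo <- truncnorm_moments(p[1], exp(p[2]))
    ((mo["mean"] - mean) / mean)^2 + ((mo["sd"] - sd) / sd)^2
  }
  fit <- stats::optim(c(mean, log(sd)), obj, method = "BFGS",
                      control = list(reltol = 1e-14, maxit = 500))
  fit <- stats::optim(fit$par, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-15, maxit = 2000))
  mu <- fit$par[1]; s <- exp(fit$par[2])
  mo <- truncnorm_moments(mu, s)
  if (abs(mo["mean"] - mean) > 1e-5 * mean || abs(mo["sd"] - sd) > 1e-5 * sd)
    stop_config("infeasible group targets mean=%g, sd=%g: positivity truncation cannot realize this SD",
                mean, sd)
  c(mu = mu, sd = s)
}

# Quantile of N(mu, sd^2) truncated to (0, Inf).
qtruncnorm_pos <- function(u, mu, sd) {
  p0 <- stats::pnorm(0, mu, sd)
  stats::qnorm(p0 + u * (1 - p0), mu, sd)
}

# ---- Cole parameters anchored at the band edges ---------------------------

# Solve (r_inf, delta = r0 - r_inf) so that the Cole conductance matches the
# drawn anchors exactly at the two anchor frequencies:
#   kappa * Re(1/Z(f1)) = sigma_lo,  kappa * Re(1/Z(f2)) = sigma_hi.
# Anchoring at the measurement band edges (not the DC / infinite-frequency
# limits) keeps the realized group distributions on target at the reported
# frequencies. 2D Newton with analytic Jacobian, initialised at the limit
# mapping r0 = kappa/sigma_lo, r_inf = kappa/sigma_hi.
solve_cole_anchors <- function(sigma_lo, sigma_hi, fc, alpha, kappa, f1, f2) {
  g1 <- sigma_lo / kappa
  g2 <- sigma_hi / kappa
  w1 <- 1 / (1 + (1i * f1 / fc)^alpha)
  w2 <- 1 / (1 + (1i * f2 / fc)^alpha)
  r_inf <- 1 / g2
  delta <- 1 / g1 - 1 / g2
  for (it in 1:100) {
    z1 <- r_inf + delta * w1
    z2 <- r_inf + delta * w2
    fvec <- c(Re(1 / z1) - g1, Re(1 / z2) - g2)
    if (max(abs(fvec)) < 1e-14 * max(g1, g2)) break
    jac <- matrix(c(Re(-1 / z1^2), Re(-w1 / z1^2),
                    Re(-1 / z2^2), Re(-w2 / z2^2)),
                  nrow = 2, byrow = TRUE)
    step <- tryCatch(solve(jac, fvec), error = function(e) NULL)
    if (is.null(step)) return(NULL)
    damp <- 1
    repeat {
      cand <- c(r_inf, delta) - damp * step
      if (all(cand > 0)) break
      damp <- damp / 2
      if (damp < 1e-8) return(NULL)
    }
    r_inf <- cand[1]; delta <- cand[2]
  }
  if (max(abs(c(Re(1 / (r_inf + delta * w1)) - g1,
                Re(1 / (r_inf + delta * w2)) - g2))) > 1e-10 * max(g1, g2))
    return(NULL)
  cole_parameters(r0 = r_inf + delta, r_inf = r_inf, fc = fc, alpha = alpha)
}

# Deterministic 31-bit sub-seed from the top seed and a group label, so each
# group has its own stream and adding a group does not perturb the others.
child_seed <- function(seed, label) {
  m <- 2147483647
  h <- seed %% m
  for (ch in utf8ToInt(label)) h <- (h * 31 + ch) %% m
  as.integer(h)
}

#' Generate a synthetic measurement cohort
#'
#' Forward-simulates a full measurement session: for every configured group,
#' per-patient conductivity anchors at 3 kHz and 1 MHz are drawn from
#' positivity-truncated normal distributions matching the configured
#' mean / SD (with the high-frequency anchor forced above the low-frequency
#' one by redrawing); each pair is mapped to Cole dispersion parameters whose
#' conductance hits both anchors exactly; tissue spectra and the three
#' reference-buffer spectra are then passed through the parasitic network.
#' The ground truth (distortion-free conductivity spectra and Cole
#' parameters) is returned alongside for recovery tests.
#'
#' @param cfg a [simulation_config()].
#' @return list with elements
#'   \describe{
#'     \item{records}{cohort of [measurement_record()]s with (distorted)
#'       impedance spectra,}
#'     \item{buffers}{named list of three [reference_buffer()]s with
#'       (distorted) spectra,}
#'     \item{truth}{per-record list: `sigma_true` ([conductivity_spectrum()]
#'       without parasitics), `cole` parameters and the drawn anchors,}
#'     \item{config}{the configuration used.}
#'   }
#' @export
generate_cohort <- function(cfg = simulation_config()) {
  stopifnot(inherits(cfg, "simulation_config"))
  grid <- cfg$grid
  kappa <- cfg$geometry$cell_constant_per_m
  f_lo <- min(grid)
  f_hi <- max(grid)
  records <- list()
  truth <- list()
  pat <- 0L

  for (gi in seq_len(nrow(cfg$group_specs))) {
    gs <- cfg$group_specs[gi, ]
    label <- paste(gs$tissue_class, gs$state, sep = "/")
    set.seed(child_seed(cfg$seed, label))
    p_lo <- truncnorm_params(gs$mean_3khz, gs$sd_3khz)
    p_hi <- truncnorm_params(gs$mean_1mhz, gs$sd_1mhz)
    rho <- cfg$anchor_correlation
    for (i in seq_len(gs$n)) {
      # Per-patient anchors: Gaussian copula with exact truncated-normal
      # marginals. Pairs violating the monotone rise (sigma_1MHz must exceed
      # sigma_3kHz) are redrawn - rare under strong positive correlation, so
      # the marginals are essentially untouched. The drawn (fc, alpha) must
      # allow the dispersion to span the drawn rise within the band;
      # infeasible draws are replaced without touching the anchors, with a
      # deterministic low-fc, alpha -> 1 ladder for strong rises. Anchor
      # pairs whose rise exceeds even that ladder (sub-mS/m outliers) are
      # redrawn entirely.
      cole <- NULL
      for (attempt in 1:100) {
        z1 <- stats::rnorm(1)
        z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(1)
        s_lo <- qtruncnorm_pos(stats::pnorm(z1), p_lo["mu"], p_lo["sd"])
        s_hi <- qtruncnorm_pos(stats::pnorm(z2), p_hi["mu"], p_hi["sd"])
        if (s_hi <= s_lo) next
        for (try in 1:20) {
          fc <- stats::runif(1, cfg$fc_range_hz[1], cfg$fc_range_hz[2])
          alpha <- stats::runif(1, cfg$alpha_range[1], cfg$alpha_range[2])
          cole <- solve_cole_anchors(s_lo, s_hi, fc, alpha, kappa, f_lo, f_hi)
          if (!is.null(cole)) break
        }
        if (is.null(cole)) {
          for (fc_try in c(cfg$fc_range_hz[1], 5e3, 3e3, 2e3, 1e3)) {
            for (alpha_try in unique(c(cfg$alpha_range[2], 1))) {
              cole <- solve_cole_anchors(s_lo, s_hi, fc_try, alpha_try,
                                         kappa, f_lo, f_hi)
              if (!is.null(cole)) break
            }
            if (!is.null(cole)) break
          }
        }
        if (!is.null(cole)) break
      }
      if (is.null(cole))
        stop_config("group %s: could not realize a feasible patient after 100 draws; check targets",
                    label)
      ideal <- cole_impedance(cole, grid)
      pat <- pat + 1L
      id <- sprintf("P%03d", pat)
      is_tumor <- gs$tissue_class == "tumor"
      ttype <- if (is_tumor)
        sample(c("HCC", "MET", "CCA"), 1L, prob = c(0.4, 0.4, 0.2)) else "none"
      dims <- if (is_tumor) {
        d1 <- stats::runif(1, 10, 80)
        round(c(d1, d1 * stats::runif(1, 0.6, 1), d1 * stats::runif(1, 0.5, 1)))
      } else NULL
      records[[pat]] <- measurement_record(
        patient_id = id, tissue_class = gs$tissue_class, state = gs$state,
        tumor_type = ttype,
        spectrum = apply_parasitics(ideal, cfg$parasitics),
        tumor_dims_mm = dims,
        temperature_c = if (gs$state == "in_vivo") 36 else 20)
      truth[[id]] <- list(
        sigma_true = conductivity_spectrum(grid, kappa * conductance(ideal)),
        cole = cole,
        anchors = c(sigma_3khz = s_lo, sigma_1mhz = s_hi),
        group = label)
    }
  }

  buffers <- lapply(names(default_buffer_catalogue()), function(nm) {
    sig <- default_buffer_catalogue()[[nm]]
    reference_buffer(nm, sig,
                     apply_parasitics(buffer_impedance(sig, cfg$geometry, grid),
                                      cfg$parasitics))
  })
  names(buffers) <- names(default_buffer_catalogue())

  list(records = as_cohort(records), buffers = buffers, truth = truth,
       config = cfg)
}
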