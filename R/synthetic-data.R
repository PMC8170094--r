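#' @importFrom rlang .data
#' @importFrom tibble tibble as_tibble
NULL

# Derive an independent integer substream seed from (seed, generator name),
# kept below 2^31 so it is a valid R integer.
derive_seed <- function(seed, name) {
  codes <- utf8ToInt(name)
  h <- 0
  for (cc in codes) h <- (h * 31 + cc) %% 2147483647
  as.integer((as.numeric(seed) %% 2147483647 * 7919 + h) %% 2147483647)
}

with_seed_if <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

check_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min || x != round(x)) {
    stop(sprintf("`%s` must be a single integer >= %d.", name, min), call. = FALSE)
  }
  as.integer(x)
}

check_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("`%s` must be a single positive number.", name), call. = FALSE)
  }
  x
}

#' Simulate energy-gap samples for reactant and product redox states
#'
#' Draws Gaussian potential-energy-gap (`delta U = U_product - U_reactant`)
#' samples for the two redox states of an electron-transfer reaction, with
#' analytically known driving force and reorganization energy. The reactant
#' distribution is centered at `delta_g0 + lambda` and the product at
#' `delta_g0 - lambda`; the reactant standard deviation is the
#' linear-response value `sqrt(2 * lambda * kBT)` and the product standard
#' deviation is `sigma_ratio` times that. With `sigma_ratio = 1` the two
#' free-energy parabolas have equal curvature (classical equal-variance
#' linear response); `sigma_ratio != 1` produces the unequal-curvature case
#' in which the product- and reactant-state reorganization energies differ.
#'
#' @param delta_g0_kcal_mol True free-energy difference (product minus
#'   reactant minimum), kcal/mol. Default -24.5.
#' @param lambda_kcal_mol True reorganization energy, kcal/mol (> 0).
#'   Default 84.5.
#' @param n_samples Samples per state (>= 2). Default 1e4.
#' @param sigma_ratio Product-state sigma divided by reactant-state sigma
#'   (> 0). Default 1.
#' @param temperature_K Temperature in Kelvin. Default 300.
#' @param seed Optional integer seed; the global RNG state is restored
#'   afterwards.
#'
#' @return A tibble with columns `state` ("reactant"/"product") and
#'   `delta_u_kcal_mol`, carrying the generating parameters in
#'   `attr(, "truth")`.
#'
#' @examples
#' gaps <- sim_gap_samples(-20, 83.87, n_samples = 1000, seed = 1)
#' dplyr::count(gaps, state)
#' @export
sim_gap_samples <- function(delta_g0_kcal_mol = -24.5,
                            lambda_kcal_mol = 84.5,
                            n_samples = 1e4,
                            sigma_ratio = 1,
                            temperature_K = 300,
                            seed = NULL) {
  lambda_kcal_mol <- check_pos(lambda_kcal_mol, "lambda_kcal_mol")
  sigma_ratio <- check_pos(sigma_ratio, "sigma_ratio")
  n_samples <- check_count(n_samples, "n_samples", min = 2L)
  th <- thermo(temperature_K)

  sigma_r <- sqrt(2 * lambda_kcal_mol * th$kBT)
  sigma_p <- sigma_ratio * sigma_r
  samples <- with_seed_if(seed, {
    list(
      reactant = stats::rnorm(n_samples, delta_g0_kcal_mol + lambda_kcal_mol, sigma_r),
      product  = stats::rnorm(n_samples, delta_g0_kcal_mol - lambda_kcal_mol, sigma_p)
    )
  })

  out <- tibble(
    state = rep(c("reactant", "product"), each = n_samples),
    delta_u_kcal_mol = c(samples$reactant, samples$product)
  )
  attr(out, "truth") <- list(
    delta_g0_kcal_mol = delta_g0_kcal_mol,
    lambda_kcal_mol = lambda_kcal_mol,
    sigma_reactant = sigma_r,
    sigma_product = sigma_p,
    temperature_K = temperature_K
  )
  out
}

#' Simulate per-window work samples for an alchemical transformation
#'
#' Generates forward and backward work samples for each lambda window of an
#' alchemical (charging/discharging) transformation. Within window `i` with
#' true free-energy difference `dG_i`, forward work is drawn from
#' `Normal(dG_i + sigma_w^2 / (2 kBT), sigma_w)` and backward work from
#' `Normal(-dG_i + sigma_w^2 / (2 kBT), sigma_w)`, which satisfies the
#' Crooks fluctuation relation with free-energy difference `dG_i`, so that
#' exponential averaging and the Bennett acceptance ratio both target the
#' known truth.
#'
#' @param window_delta_g_kcal_mol Numeric vector of true per-window
#'   free-energy differences (kcal/mol), one per lambda window; the default
#'   is 16 equal steps summing to -21.6 kcal/mol.
#' @param sigma_w_kcal_mol Work standard deviation per window (>= 0),
#'   kcal/mol. Default 1.
#' @param n_per_window Samples per window and direction (>= 1). Default 100.
#' @param temperature_K Temperature in Kelvin. Default 300.
#' @param leg Transformation label, `"FEP1"` (discharging the reactant) or
#'   `"FEP2"` (charging the product).
#' @param model Reaction model label, `"I"` or `"II"`.
#' @param seed Optional integer seed.
#'
#' @return A tibble with columns `leg`, `model`, `direction`
#'   ("forward"/"backward"), `window_index`, `lambda_from`, `lambda_to`,
#'   `work_kcal_mol`; generating parameters in `attr(, "truth")`.
#'
#' @examples
#' fep <- sim_fep_windows(rep(-1, 4), sigma_w_kcal_mol = 0.5,
#'                        n_per_window = 50, seed = 2)
#' fep_accumulate(fep, method = "bar")
#' @export
sim_fep_windows <- function(window_delta_g_kcal_mol = rep(-21.6 / 16, 16),
                            sigma_w_kcal_mol = 1,
                            n_per_window = 100,
                            temperature_K = 300,
                            leg = c("FEP1", "FEP2"),
                            model = c("I", "II"),
                            seed = NULL) {
  leg <- match.arg(leg)
  model <- match.arg(model)
  if (length(window_delta_g_kcal_mol) < 1L || !is.numeric(window_delta_g_kcal_mol)) {
    stop("`window_delta_g_kcal_mol` must contain at least one window.", call. = FALSE)
  }
  if (!is.numeric(sigma_w_kcal_mol) || length(sigma_w_kcal_mol) != 1L ||
      sigma_w_kcal_mol < 0) {
    stop("`sigma_w_kcal_mol` must be a single number >= 0.", call. = FALSE)
  }
  n_per_window <- check_count(n_per_window, "n_per_window", min = 1L)
  th <- thermo(temperature_K)

  n_w <- length(window_delta_g_kcal_mol)
  lambda_grid <- seq(0, 1, length.out = n_w + 1L)
  bias <- sigma_w_kcal_mol^2 / (2 * th$kBT)

  draws <- with_seed_if(seed, {
    purrr::map(seq_len(n_w), function(i) {
      dg <- window_delta_g_kcal_mol[i]
      list(
        forward  = stats::rnorm(n_per_window,  dg + bias, sigma_w_kcal_mol),
        backward = stats::rnorm(n_per_window, -dg + bias, sigma_w_kcal_mol)
      )
    })
  })

  out <- purrr::map_dfr(seq_len(n_w), function(i) {
    tibble(
      leg = leg, model = model,
      direction = rep(c("forward", "backward"), each = n_per_window),
      window_index = i,
      lambda_from = c(rep(lambda_grid[i], n_per_window),
                      rep(lambda_grid[i + 1L], n_per_window)),
      lambda_to = c(rep(lambda_grid[i + 1L], n_per_window),
                    rep(lambda_grid[i], n_per_window)),
      work_kcal_mol = c(draws[[i]]$forward, draws[[i]]$backward)
    )
  })
  attr(out, "truth") <- list(
    window_delta_g_kcal_mol = window_delta_g_kcal_mol,
    total_delta_g_kcal_mol = sum(window_delta_g_kcal_mol),
    sigma_w_kcal_mol = sigma_w_kcal_mol,
    temperature_K = temperature_K
  )
  out
}

#' Simulate exponentially distributed bound dwell times
#'
#' Draws independent dwell (residence) times from an exponential
#' distribution with mean `tau_ns`, the model behind the exponential decay
#' of the survival count of bound-ligand simulations.
#'
#' @param tau_ns True characteristic binding time, ns (> 0). Default 4.5.
#' @param n_events Number of dwell times (>= 1). Default 100.
#' @param seed Optional integer seed.
#'
#' @return A tibble with column `duration_ns`; `attr(, "truth")` holds
#'   `tau_ns`.
#' @examples
#' mean(sim_dwell_times(4.5, 1000, seed = 3)$duration_ns)
#' @export
sim_dwell_times <- function(tau_ns = 4.5, n_events = 100, seed = NULL) {
  tau_ns <- check_pos(tau_ns, "tau_ns")
  n_events <- check_count(n_events, "n_events", min = 1L)
  d <- with_seed_if(seed, stats::rexp(n_events, rate = 1 / tau_ns))
  out <- tibble(duration_ns = d)
  attr(out, "truth") <- list(tau_ns = tau_ns)
  out
}

#' Simulate a donor-acceptor distance trace with known binding events
#'
#' Builds a uniformly sampled distance time series between a donor-site
#' reference (the iron-sulfur cluster) and a ligand, containing scheduled
#' binding events: the noiseless trace sits at `baseline_A` when unbound and
#' drops to `bound_A` for the duration of each event. Zero-mean noise,
#' truncated at `noise_A` so that it can never move a frame across the
#' 9/13/20 Angstrom detection thresholds (given the default baseline and
#' bound levels), is added on top; the ground-truth segmentation is obtained
#' by running the hysteresis event detector on the noiseless trace. An
#' optional membrane-normal coordinate `z_A` is generated that stays near
#' the midplane while bound and ramps to `escape_side` after each event,
#' supporting escape-side classification.
#'
#' @param events A data frame with columns `entry_ps` and `dwell_ps`
#'   describing non-overlapping binding events, or `NULL` for an event-free
#'   trace.
#' @param total_ps Total trace length, ps; default extends 2000 ps past the
#'   last event.
#' @param dt_ps Frame spacing, ps (> 0). Default 10.
#' @param baseline_A Unbound distance, Angstrom (> 20). Default 25.
#' @param bound_A Bound distance, Angstrom (< 9). Default 5.
#' @param noise_A Truncation amplitude of the added noise, Angstrom;
#'   the noise is Gaussian with sd `noise_A / 2`, clipped at `+/- noise_A`.
#'   Default 0.5.
#' @param escape_side `"positive"` or `"negative"`: membrane side to which
#'   the generated `z_A` coordinate escapes after each event.
#' @param with_z Include the `z_A` column? Default `TRUE`.
#' @param seed Optional integer seed.
#'
#' @return A tibble with columns `time_ps`, `distance_A` and (optionally)
#'   `z_A`; `attr(, "truth")` holds the ground-truth event table (from the
#'   noiseless trace) and the escape side.
#'
#' @examples
#' tr <- sim_distance_trace(data.frame(entry_ps = 100, dwell_ps = 500),
#'                          total_ps = 2000, seed = 4)
#' attr(tr, "truth")$events
#' @export
sim_distance_trace <- function(events = NULL,
                               total_ps = NULL,
                               dt_ps = 10,
                               baseline_A = 25,
                               bound_A = 5,
                               noise_A = 0.5,
                               escape_side = c("positive", "negative"),
                               with_z = TRUE,
                               seed = NULL) {
  escape_side <- match.arg(escape_side)
  dt_ps <- check_pos(dt_ps, "dt_ps")
  if (bound_A >= 9) stop("`bound_A` must be < 9 Angstrom.", call. = FALSE)
  if (baseline_A <= 20) stop("`baseline_A` must be > 20 Angstrom.", call. = FALSE)
  if (noise_A < 0) stop("`noise_A` must be >= 0.", call. = FALSE)

  if (!is.null(events)) {
    events <- as_tibble(events)
    stopifnot(all(c("entry_ps", "dwell_ps") %in% names(events)))
    events <- dplyr::arrange(events, .data$entry_ps)
    if (nrow(events) > 1L) {
      ends <- events$entry_ps + events$dwell_ps
      if (any(events$entry_ps[-1L] <= ends[-nrow(events)])) {
        stop("scheduled binding events overlap", call. = FALSE)
      }
    }
  }
  if (is.null(total_ps)) {
    total_ps <- if (is.null(events) || nrow(events) == 0L) 2000 else
      max(events$entry_ps + events$dwell_ps) + 2000
  }

  time_ps <- seq(0, total_ps, by = dt_ps)
  n <- length(time_ps)
  d0 <- rep(baseline_A, n)
  z0 <- rep(0, n)
  z_target <- if (escape_side == "positive") 30 else -30
  if (!is.null(events) && nrow(events) > 0L) {
    n_ev <- nrow(events)
    for (k in seq_len(n_ev)) {
      inside <- which(time_ps >= events$entry_ps[k] &
                        time_ps <= events$entry_ps[k] + events$dwell_ps[k])
      if (length(inside) == 0L) next
      d0[inside] <- bound_A
      # z: near the midplane while bound; after unbinding, ramp to the
      # escape side over 50 frames and hold until the next entry
      end_i <- max(inside)
      until <- if (k < n_ev) {
        max(end_i, min(which(time_ps >= events$entry_ps[k + 1L])) - 1L)
      } else n
      post <- seq_len(until - end_i)
      if (length(post) > 0L) {
        z0[end_i + post] <- z_target * pmin(post / 50, 1)
      }
    }
  }

  noise <- with_seed_if(seed, {
    nd <- pmin(pmax(stats::rnorm(n, 0, noise_A / 2), -noise_A), noise_A)
    nz <- pmin(pmax(stats::rnorm(n, 0, noise_A / 2), -noise_A), noise_A)
    list(d = nd, z = nz)
  })

  out <- tibble(time_ps = time_ps, distance_A = pmax(d0 + noise$d, 0))
  if (with_z) out$z_A <- z0 + noise$z

  truth_events <- detect_binding_events(
    tibble(time_ps = time_ps, distance_A = d0)
  )
  attr(out, "truth") <- list(events = truth_events, escape_side = escape_side)
  out
}

# Baseline (no electron transfer) fragment spin densities; sign of the O2
# and semiquinone entries follows the O2 spin orientation. Fe1/Fe2 carry the
# anti-parallel iron spins of the Fe2S2 cluster.
spin_baseline <- function(o2_sign) {
  c(O2 = 2 * o2_sign, SQ = -1 * o2_sign,
    Fe1 = -3.6, Fe2 = 3.8, S1 = -0.25, S2 = -0.3,
    HIS135 = 0.02, HIS156 = 0.01, TYR302 = 0, WAT = 0)
}

#' Simulate labeled fragment spin-density tables
#'
#' Generates per-snapshot fragment spin densities and total energies for the
#' four outcome classes of the quantum-chemistry snapshot ensemble: no
#' electron transfer (O2 spin density near +/-2), electron transfer from the
#' semiquinone (model I; O2 spin near +/-1 with the compensating spin change
#' on the SQ fragment), electron transfer from the iron-sulfur cluster
#' (model II; the compensating change distributed over Fe2/S1/S2 with
#' weights 0.5/0.25/0.25), and energy outliers (spins like the no-transfer
#' class but total energy displaced far from the class median). Defaults for
#' the class counts and energy statistics follow the spin-up column of the
#' reference snapshot ensemble (77/0/44/6 with the model II class 39.3
#' kcal/mol below the no-transfer mean).
#'
#' @param n_no_et,n_model_i,n_model_ii,n_outlier Class counts (>= 0).
#' @param o2_spin_state `"up"` or `"down"`: spin orientation of the O2
#'   fragment (positive or negative spin densities).
#' @param noise_sd Gaussian noise sd added to every fragment spin (>= 0).
#'   Default 0.02.
#' @param energy_mean_kcal_mol,energy_sd_kcal_mol Named numeric vectors
#'   (names `no_ET`, `model_I`, `model_II`) of class energy means and sds,
#'   kcal/mol. Means are relative; the no-transfer mean anchors the scale.
#' @param outlier_offset_kcal_mol Energy displacement of outlier snapshots
#'   from the no-transfer mean, kcal/mol. Default 150.
#' @param seed Optional integer seed.
#'
#' @return A long tibble with columns `snapshot_id`, `o2_spin_state`,
#'   `fragment`, `spin`, `total_energy_kcal_mol`, `converged`;
#'   `attr(, "truth")` holds a tibble of ground-truth labels.
#'
#' @examples
#' tbl <- sim_spin_tables(n_no_et = 5, n_model_ii = 3, n_outlier = 1,
#'                        noise_sd = 0, seed = 5)
#' attr(tbl, "truth")
#' @export
sim_spin_tables <- function(n_no_et = 77, n_model_i = 0, n_model_ii = 44,
                            n_outlier = 6,
                            o2_spin_state = c("up", "down"),
                            noise_sd = 0.02,
                            energy_mean_kcal_mol = c(no_ET = 0, model_I = 2.05,
                                                     model_II = -39.33),
                            energy_sd_kcal_mol = c(no_ET = 14.73, model_I = 11.4,
                                                   model_II = 12.91),
                            outlier_offset_kcal_mol = 150,
                            seed = NULL) {
  o2_spin_state <- match.arg(o2_spin_state)
  counts <- c(no_ET = check_count(n_no_et, "n_no_et"),
              model_I = check_count(n_model_i, "n_model_i"),
              model_II = check_count(n_model_ii, "n_model_ii"),
              outlier = check_count(n_outlier, "n_outlier"))
  if (!is.numeric(noise_sd) || noise_sd < 0) {
    stop("`noise_sd` must be >= 0.", call. = FALSE)
  }
  sgn <- if (o2_spin_state == "up") 1 else -1
  base <- spin_baseline(sgn)
  frags <- names(base)

  labels <- rep(names(counts), counts)
  n_tot <- length(labels)
  if (n_tot == 0L) {
    out <- tibble(snapshot_id = character(), o2_spin_state = character(),
                  fragment = character(), spin = numeric(),
                  total_energy_kcal_mol = numeric(), converged = logical())
    attr(out, "truth") <- tibble(snapshot_id = character(), label = character())
    return(out)
  }

  build <- with_seed_if(seed, {
    spins <- matrix(rep(base, n_tot), nrow = n_tot, byrow = TRUE,
                    dimnames = list(NULL, frags))
    for (i in seq_len(n_tot)) {
      lab <- labels[i]
      if (lab == "model_I") {
        spins[i, "O2"] <- 1 * sgn
        spins[i, "SQ"] <- 0
      } else if (lab == "model_II") {
        # O2 spin change is -sgn; the cluster compensates with +sgn so the
        # snapshot's total spin matches the no-transfer ensemble
        spins[i, "O2"] <- 1 * sgn
        spins[i, "Fe2"] <- base[["Fe2"]] + 0.5 * sgn
        spins[i, "S1"] <- base[["S1"]] + 0.25 * sgn
        spins[i, "S2"] <- base[["S2"]] + 0.25 * sgn
      }
    }
    if (noise_sd > 0) {
      spins <- spins + matrix(stats::rnorm(n_tot * length(frags), 0, noise_sd),
                              nrow = n_tot)
    }
    energy <- numeric(n_tot)
    for (lab in c("no_ET", "model_I", "model_II")) {
      idx <- labels == lab
      if (any(idx)) {
        energy[idx] <- stats::rnorm(sum(idx), energy_mean_kcal_mol[[lab]],
                                    energy_sd_kcal_mol[[lab]])
      }
    }
    idx <- labels == "outlier"
    if (any(idx)) {
      sides <- sample(c(-1, 1), sum(idx), replace = TRUE)
      energy[idx] <- energy_mean_kcal_mol[["no_ET"]] +
        sides * (outlier_offset_kcal_mol + stats::rexp(sum(idx), 1 / 10))
    }
    list(spins = spins, energy = energy)
  })

  ids <- sprintf("snap_%s_%03d", o2_spin_state, seq_len(n_tot))
  out <- tibble(
    snapshot_id = rep(ids, each = length(frags)),
    o2_spin_state = o2_spin_state,
    fragment = rep(frags, times = n_tot),
    spin = as.vector(t(build$spins)),
    total_energy_kcal_mol = rep(build$energy, each = length(frags)),
    converged = TRUE
  )
  attr(out, "truth") <- tibble(snapshot_id = ids, label = labels)
  out
}

#' Write a full synthetic input bundle to disk
#'
#' Generates one instance of every input the pipeline consumes -- a spin
#' table, a set of distance traces with exponentially distributed dwell
#' times, energy-gap samples for both redox states, and a two-leg set of
#' alchemical work samples -- writes them as CSV to `out_dir` together with
#' a ready-to-run pipeline configuration (`config.json`), and returns the
#' file paths plus all ground truths. Each generator receives an
#' independent substream seed derived from `seed` and the generator name.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer master seed.
#' @param n_traces Number of distance traces / unbinding replicas. Default 100.
#' @param tau_ns True characteristic binding time for the traces, ns.
#' @param delta_g0_kcal_mol,lambda_kcal_mol,sigma_ratio,n_gap_samples
#'   Parameters passed to [sim_gap_samples()].
#' @param fep1_delta_g_kcal_mol,fep2_delta_g_kcal_mol Per-window truths for
#'   the two alchemical legs; defaults are 16 equal steps summing to +30 and
#'   -51.6 kcal/mol (combined reaction free energy -21.6 kcal/mol).
#' @param n_fep_samples Work samples per window and direction.
#' @param temperature_K Temperature, K.
#'
#' @return Invisibly, a list with `paths` (named file paths) and `truth`.
#' @export
simulate_bundle <- function(out_dir,
                            seed = 1,
                            n_traces = 100,
                            tau_ns = 4.5,
                            delta_g0_kcal_mol = -24.5,
                            lambda_kcal_mol = 84.5,
                            sigma_ratio = 1,
                            n_gap_samples = 1e4,
                            fep1_delta_g_kcal_mol = rep(30 / 16, 16),
                            fep2_delta_g_kcal_mol = rep(-51.6 / 16, 16),
                            n_fep_samples = 200,
                            temperature_K = 300) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  spin <- sim_spin_tables(seed = derive_seed(seed, "spin"))
  gaps <- sim_gap_samples(delta_g0_kcal_mol, lambda_kcal_mol,
                          n_samples = n_gap_samples, sigma_ratio = sigma_ratio,
                          temperature_K = temperature_K,
                          seed = derive_seed(seed, "gaps"))
  fep1 <- sim_fep_windows(fep1_delta_g_kcal_mol, n_per_window = n_fep_samples,
                          temperature_K = temperature_K, leg = "FEP1",
                          seed = derive_seed(seed, "fep1"))
  fep2 <- sim_fep_windows(fep2_delta_g_kcal_mol, n_per_window = n_fep_samples,
                          temperature_K = temperature_K, leg = "FEP2",
                          seed = derive_seed(seed, "fep2"))
  fep <- dplyr::bind_rows(fep1, fep2)

  dwell <- sim_dwell_times(tau_ns, n_traces, seed = derive_seed(seed, "dwell"))
  traces <- purrr::map_dfr(seq_len(n_traces), function(k) {
    tr <- sim_distance_trace(
      events = tibble(entry_ps = 200, dwell_ps = dwell$duration_ns[k] * 1000),
      total_ps = 200 + dwell$duration_ns[k] * 1000 + 1000,
      seed = derive_seed(seed, paste0("trace", k))
    )
    tr$trace_id <- sprintf("run_%03d", k)
    tr
  })

  paths <- list(
    spin_table = file.path(out_dir, "spin_table.csv"),
    traces = file.path(out_dir, "distance_traces.csv"),
    gaps = file.path(out_dir, "gap_samples.csv"),
    fep = file.path(out_dir, "fep_samples.csv"),
    config = file.path(out_dir, "config.json")
  )
  utils::write.csv(spin, paths$spin_table, row.names = FALSE)
  utils::write.csv(traces, paths$traces, row.names = FALSE)
  utils::write.csv(gaps, paths$gaps, row.names = FALSE)
  utils::write.csv(fep, paths$fep, row.names = FALSE)

  config <- list(
    spin_table_csv = paths$spin_table,
    trace_csv = paths$traces,
    gap_csv = paths$gaps,
    fep_csv = paths$fep,
    temperature_K = temperature_K,
    k_bind_per_s = 2e5,
    k_unbind_per_s = 1e8,
    r_A = 4.87,
    seed = seed
  )
  jsonlite::write_json(config, paths$config, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)

  invisible(list(
    paths = paths,
    truth = list(
      spin_labels = attr(spin, "truth"),
      gap = attr(gaps, "truth"),
      fep1 = attr(fep1, "truth"),
      fep2 = attr(fep2, "truth"),
      tau_ns = tau_ns
    )
  ))
}
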