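#' Reference free-energy parameters and rates for the two reaction models
#'
#' Built-in reference values for the two candidate electron-transfer
#' reactions producing superoxide at the Qo-site: model I (donor:
#' semiquinone) and model II (donor: iron-sulfur cluster). Columns hold the
#' two-state (reorganization) estimate of the driving force, the product-
#' and reactant-state reorganization energies, the alchemical (FEP/BAR)
#' driving force, the snapshot-averaged electron-transfer rate, and the
#' site binding/unbinding kinetics used for the production-rate estimate.
#' The donor-acceptor distance fluctuates between 2 and 10 Angstrom in the
#' bound state.
#'
#' @return A tibble with one row per model.
#' @export
reference_parameters <- function() {
  tibble(
    model = c("I", "II"),
    delta_g_reorg0_kcal_mol = c(-24.5, 122.9),
    lambda_p_kcal_mol = c(84.5, 62.7),
    lambda_r_kcal_mol = c(107.9, 88.3),
    delta_g_fep0_kcal_mol = c(-21.6, 162.7),
    k_et_per_s = c(6.1e5, 1.0e-98),
    k_bind_per_s = 2e5,
    k_unbind_per_s = 1e8,
    r_min_A = 2,
    r_max_A = 10,
    x_sq = 4e-8
  )
}

#' Evaluate the rate chain on the built-in reference parameters
#'
#' Runs the final stage of the analysis on the package's reference
#' parameter set: for each reaction model, the distance-ruler rate at the
#' extremes of the observed donor-acceptor distance range (bracketing the
#' reference electron-transfer rate), the distance implied by that rate,
#' the binding-weighted superoxide production rate in the semiquinone
#' state, and the per-complex rate scaled by the semiquinone occupancy.
#'
#' @return A tibble with one row per model and columns `k_at_r_min_per_s`,
#'   `k_at_r_max_per_s`, `implied_r_A`, `production_rate_per_s`,
#'   `per_complex_rate_per_s` alongside the inputs.
#' @examples
#' demo_rates()
#' @export
demo_rates <- function() {
  ref <- reference_parameters()
  ref |>
    dplyr::rowwise() |>
    dplyr::mutate(
      k_at_r_min_per_s = moser_dutton_rate(.data$delta_g_fep0_kcal_mol,
                                           .data$lambda_p_kcal_mol,
                                           .data$r_min_A),
      k_at_r_max_per_s = moser_dutton_rate(.data$delta_g_fep0_kcal_mol,
                                           .data$lambda_p_kcal_mol,
                                           .data$r_max_A),
      implied_r_A = implied_distance(.data$delta_g_fep0_kcal_mol,
                                     .data$lambda_p_kcal_mol,
                                     .data$k_et_per_s),
      production_rate_per_s = production_rate(.data$k_bind_per_s,
                                              .data$k_unbind_per_s,
                                              .data$k_et_per_s)$production_rate_per_s,
      per_complex_rate_per_s = .data$x_sq * .data$production_rate_per_s
    ) |>
    dplyr::ungroup()
}

read_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  thr <- config$binding_thresholds_A %||% c(9, 13, 20)
  if (length(thr) != 3L || !all(diff(thr) > 0) || any(thr <= 0)) {
    stop("binding thresholds must be three increasing positive distances",
         call. = FALSE)
  }
  config$binding_thresholds_A <- thr
  for (p in c("spin_table_csv", "trace_csv", "gap_csv", "fep_csv",
              "r_series_csv")) {
    if (!is.null(config[[p]]) && !file.exists(config[[p]])) {
      stop("configured input does not exist: ", config[[p]], call. = FALSE)
    }
  }
  config
}

run_stage <- function(report, name, deps = character(), fun) {
  for (d in deps) {
    st <- report$stages[[d]]$status %||% "skipped"
    if (st != "ok") {
      report$stages[[name]] <- list(status = "skipped",
                                    reason = paste0("dependency `", d,
                                                    "` not available"))
      return(report)
    }
  }
  res <- tryCatch(list(status = "ok", result = fun()),
                  error = function(e) list(status = "failed",
                                           reason = conditionMessage(e)))
  report$stages[[name]] <- res
  report
}

#' Run the full analysis pipeline from a configuration
#'
#' Executes the analysis stages in dependency order -- snapshot spin
#' classification, oxygen (un)binding kinetics, energy-gap linear response,
#' alchemical FEP/BAR, and the rate chain -- on the inputs named in the
#' configuration. A stage whose inputs are absent is skipped; a stage that
#' fails marks its dependents skipped and the run exits with a failed
#' status. The rates stage takes its driving force from the FEP stage and
#' its reorganization energy from the linear-response stage when those ran,
#' falling back to `delta_g0_kcal_mol`/`lambda_kcal_mol` in the
#' configuration.
#'
#' Configuration fields (all optional unless a stage needs them): input
#' paths `spin_table_csv`, `trace_csv` (columns `time_ps`, `distance_A`,
#' optional `z_A`, `trace_id`), `gap_csv` (columns `state`,
#' `delta_u_kcal_mol`), `fep_csv` (columns `leg`, `model`, `direction`,
#' `window_index`, `lambda_from`, `lambda_to`, `work_kcal_mol`),
#' `r_series_csv` (column `r_A`) or scalar `r_A`; settings `temperature_K`,
#' `spin_threshold`, `outlier_threshold_kcal_mol`, `binding_thresholds_A`
#' (length 3), `escape_shell_A`, `fit_method`, `fep_method`,
#' `lambda_state` ("product"/"reactant"), `k_bind_per_s`, `k_unbind_per_s`,
#' `coupling_eV`, `x_sq`, `seed`.
#'
#' @param config A named list or a path to a JSON configuration file.
#' @param out_dir Optional directory; when given, the report is written to
#'   `report.json` there.
#'
#' @return A list of class `"pipeline_report"`: `stages` (each with
#'   `status` and `result`), and `provenance` (resolved config, seed,
#'   package version).
#'
#' @examples
#' \dontrun{
#' bundle <- simulate_bundle(tempdir(), seed = 1)
#' report <- run_pipeline(bundle$paths$config)
#' }
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  config <- read_config(config)
  temperature_K <- config$temperature_K %||% 300
  report <- list(stages = list(),
                 provenance = list(config = config,
                                   seed = config$seed %||% NA,
                                   package_version =
                                     as.character(utils::packageVersion("redoxleak"))))

  if (!is.null(config$spin_table_csv)) {
    report <- run_stage(report, "classification", fun = function() {
      spin <- utils::read.csv(config$spin_table_csv)
      cls <- classify_spin_snapshots(
        spin,
        spin_threshold = config$spin_threshold %||% 1.5,
        outlier_threshold = config$outlier_threshold_kcal_mol %||% 50)
      list(stats = class_energy_stats(cls),
           labels = dplyr::select(as_tibble(cls), -"donor_weights"))
    })
  }

  if (!is.null(config$trace_csv)) {
    report <- run_stage(report, "kinetics", fun = function() {
      traces <- utils::read.csv(config$trace_csv)
      if (!"trace_id" %in% names(traces)) traces$trace_id <- "trace_1"
      thr <- config$binding_thresholds_A
      events <- traces |>
        dplyr::group_by(.data$trace_id) |>
        dplyr::group_modify(function(df, key) {
          ev <- detect_binding_events(df, thr[1L], thr[2L], thr[3L])
          if ("z_A" %in% names(df) && nrow(ev) > 0L) {
            ev <- classify_escape_side(df, ev,
                                       config$escape_shell_A %||% 20)
          }
          ev
        }) |>
        dplyr::ungroup()
      fit <- fit_binding_time(events, method = config$fit_method %||% "lsq")
      list(n_events = nrow(events),
           tau_ns = fit$tau_ns, n0 = fit$n0, method = fit$method,
           escape_sides = if ("escape_side" %in% names(events))
             table(events$escape_side) else NULL,
           events = events)
    })
  }

  if (!is.null(config$gap_csv)) {
    report <- run_stage(report, "linear_response", fun = function() {
      gaps <- utils::read.csv(config$gap_csv)
      diagram <- full_linear_response(gaps, temperature_K = temperature_K,
                                      bins = config$bins)
      list(glance = glance(diagram), summaries = diagram$summaries,
           diagram = diagram)
    })
  }

  if (!is.null(config$fep_csv)) {
    report <- run_stage(report, "fep", fun = function() {
      fep <- utils::read.csv(config$fep_csv)
      method <- config$fep_method %||% "bar"
      legs <- split(fep, fep$leg)
      ests <- purrr::map(legs, fep_accumulate, method = method,
                         temperature_K = temperature_K)
      combined <- if (length(ests) == 2L) {
        do.call(combine_fep_legs, unname(ests))
      } else NULL
      list(legs = purrr::map(ests, glance), combined = combined)
    })
  }

  has_fep <- identical(report$stages$fep$status, "ok") &&
    !is.null(report$stages$fep$result$combined)
  has_lr <- identical(report$stages$linear_response$status, "ok")
  delta_g0 <- if (has_fep) {
    report$stages$fep$result$combined$delta_g0_kcal_mol
  } else config$delta_g0_kcal_mol
  lambda_state <- config$lambda_state %||% "product"
  lambda <- if (has_lr) {
    gl <- report$stages$linear_response$result$glance
    if (lambda_state == "product") gl$lambda_p_kcal_mol else
      gl$lambda_r_kcal_mol
  } else config$lambda_kcal_mol

  if (!is.null(delta_g0) && !is.null(lambda) &&
      (!is.null(config$r_A) || !is.null(config$r_series_csv))) {
    report <- run_stage(report, "rates", fun = function() {
      r <- if (!is.null(config$r_series_csv)) {
        utils::read.csv(config$r_series_csv)$r_A
      } else config$r_A
      avg <- average_rate_over_snapshots(r, delta_g0, lambda)
      out <- list(delta_g0_kcal_mol = delta_g0,
                  lambda_kcal_mol = lambda,
                  lambda_state = lambda_state,
                  mean_k_et_per_s = avg$mean_k_et_per_s,
                  n_snapshots = length(r))
      if (!is.null(config$coupling_eV)) {
        out$marcus_k_et_per_s <- marcus_rate(delta_g0, lambda,
                                             config$coupling_eV,
                                             temperature_K)
      }
      if (!is.null(config$k_bind_per_s) && !is.null(config$k_unbind_per_s)) {
        pr <- production_rate(config$k_bind_per_s, config$k_unbind_per_s,
                              avg$mean_k_et_per_s, x_sq = config$x_sq)
        out <- c(out, pr)
      }
      out
    })
  }

  statuses <- purrr::map_chr(report$stages, function(s) s$status)
  report$status <- if (any(statuses == "failed")) "failed" else "ok"
  class(report) <- "pipeline_report"

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    writable <- report_for_json(report)
    jsonlite::write_json(writable, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  }
  report
}

# Drop non-serializable members (model objects, ggplots) before writing
report_for_json <- function(report) {
  stages <- purrr::map(report$stages, function(s) {
    if (!is.null(s$result$diagram)) s$result$diagram <- NULL
    if (!is.null(s$result$events)) {
      s$result$events <- as.data.frame(s$result$events)
    }
    s
  })
  list(status = report$status, stages = stages,
       provenance = report$provenance)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report> status:", x$status, "\n")
  for (nm in names(x$stages)) {
    s <- x$stages[[nm]]
    cat(sprintf("  %-16s %s%s\n", nm, s$status,
                if (s$status != "ok") paste0(" (", s$reason, ")") else ""))
  }
  invisible(x)
}
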