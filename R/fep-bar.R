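logmeanexp <- function(x) {
  m <- max(x)
  m + log(mean(exp(x - m)))
}

#' Exponential (Zwanzig) free-energy estimator for one window
#'
#' Computes `-kBT * log(mean(exp(-W / kBT)))` over the work samples of a
#' single lambda window, using a log-sum-exp evaluation that does not
#' overflow for `|W| / kBT` up to several hundred.
#'
#' @param work Numeric vector of work samples, kcal/mol (>= 1 sample).
#' @param temperature_K Temperature, K. Default 300.
#'
#' @return The window free-energy difference, kcal/mol.
#' @examples
#' fep_exp_estimator(c(2, 2, 2))  # 2
#' @export
fep_exp_estimator <- function(work, temperature_K = 300) {
  if (length(work) == 0L) stop("no work samples", call. = FALSE)
  th <- thermo(temperature_K)
  -th$kBT * logmeanexp(-work / th$kBT)
}

# Delta-method standard error of the exponential estimator
fep_exp_se <- function(work, temperature_K = 300) {
  th <- thermo(temperature_K)
  x <- exp(-(work - min(work)) / th$kBT)
  th$kBT * stats::sd(x) / (sqrt(length(x)) * mean(x))
}

#' Bennett acceptance ratio estimator for one window
#'
#' Combines forward and backward work samples of a lambda window into the
#' minimum-variance two-state free-energy estimate. The estimate solves the
#' Bennett self-consistency condition
#' `mean_F f((W - C)/kBT) = mean_B f((W + C)/kBT)` with
#' `C = dG + kBT * log(n_b / n_f)` and `f` the Fermi function
#' `1 / (1 + exp(x))`; the root is found by bracketed bisection
#' (`stats::uniroot`) to `tol` kcal/mol, initialized from the two
#' exponential estimates. The asymptotic variance is reported alongside.
#'
#' @param forward,backward Numeric work samples, kcal/mol (each in the
#'   direction of its own transformation; >= 1 sample each).
#' @param temperature_K Temperature, K. Default 300.
#' @param tol Root tolerance, kcal/mol. Default 1e-8.
#'
#' @return A list with `delta_g_kcal_mol` and `se_kcal_mol`.
#' @examples
#' fep_bar_estimator(rep(3, 5), rep(-3, 5))$delta_g_kcal_mol  # 3
#' @export
fep_bar_estimator <- function(forward, backward, temperature_K = 300,
                              tol = 1e-8) {
  if (length(forward) == 0L || length(backward) == 0L) {
    stop("BAR needs work samples on both sides", call. = FALSE)
  }
  th <- thermo(temperature_K)
  kBT <- th$kBT
  n_f <- length(forward)
  n_b <- length(backward)
  m <- kBT * log(n_b / n_f)
  fermi <- function(x) 1 / (1 + exp(x))

  # increasing in dg: crosses zero at the self-consistent estimate
  h <- function(dg) {
    c_const <- dg + m
    mean(fermi((forward - c_const) / kBT)) -
      mean(fermi((backward + c_const) / kBT))
  }

  dg_f <- fep_exp_estimator(forward, temperature_K)
  dg_b <- -fep_exp_estimator(backward, temperature_K)
  lo <- min(dg_f, dg_b) - 1e-6
  hi <- max(dg_f, dg_b) + 1e-6
  root <- tryCatch(
    stats::uniroot(h, c(lo, hi), extendInt = "upX", tol = tol,
                   maxiter = 2000L),
    error = function(e) {
      stop("BAR self-consistency root not found in [", signif(lo, 6), ", ",
           signif(hi, 6), "]: ", conditionMessage(e), call. = FALSE)
    }
  )
  dg <- root$root

  c_const <- dg + m
  f_f <- fermi((forward - c_const) / kBT)
  f_b <- fermi((backward + c_const) / kBT)
  var_dg <- kBT^2 * ((mean(f_f^2) / mean(f_f)^2 - 1) / n_f +
                       (mean(f_b^2) / mean(f_b)^2 - 1) / n_b)
  list(delta_g_kcal_mol = dg, se_kcal_mol = sqrt(max(var_dg, 0)))
}

#' Accumulate per-window estimates over an alchemical transformation
#'
#' Estimates each lambda window's free-energy difference by the requested
#' method and sums them into the transformation total. With both directions
#' present, the forward/backward hysteresis
#' `|dG_exp_forward + dG_exp_backward|` (the backward total estimates the
#' negated free energy) is reported as an overlap diagnostic. Window
#' uncertainties are combined in quadrature.
#'
#' @param fep_tbl A tibble with columns `direction`
#'   ("forward"/"backward"), `window_index`, `lambda_from`, `lambda_to`,
#'   `work_kcal_mol`, and optionally `leg`/`model` (must be single-valued;
#'   split multi-leg tables first, e.g. with `dplyr::group_split()`).
#' @param method `"bar"` (default), `"exp_forward"` or `"exp_backward"`.
#' @param temperature_K Temperature, K. Default 300.
#'
#' @return An object of class `"fep_estimate"`: a list with the per-window
#'   tibble `windows` (`delta_delta_g_kcal_mol`, `se_kcal_mol`), the
#'   `total_delta_g_kcal_mol`, `se_kcal_mol`, `hysteresis_kcal_mol`,
#'   `method`, `leg` and `model`. Supports `tidy()`, `glance()` and
#'   `autoplot()`.
#'
#' @examples
#' fep <- sim_fep_windows(rep(-1, 4), sigma_w_kcal_mol = 0.3,
#'                        n_per_window = 100, seed = 1)
#' glance(fep_accumulate(fep))
#' @export
fep_accumulate <- function(fep_tbl, method = c("bar", "exp_forward",
                                               "exp_backward"),
                           temperature_K = 300) {
  method <- match.arg(method)
  fep_tbl <- as_tibble(fep_tbl)
  stopifnot(all(c("direction", "window_index", "work_kcal_mol") %in%
                  names(fep_tbl)))
  for (col in c("leg", "model")) {
    if (col %in% names(fep_tbl) &&
        dplyr::n_distinct(fep_tbl[[col]]) > 1L) {
      stop("`fep_tbl` mixes several values of `", col,
           "`; accumulate one transformation at a time", call. = FALSE)
    }
  }
  leg <- if ("leg" %in% names(fep_tbl)) fep_tbl$leg[1L] else NA_character_
  model <- if ("model" %in% names(fep_tbl)) fep_tbl$model[1L] else NA_character_

  windows <- fep_tbl |>
    dplyr::group_by(.data$window_index) |>
    dplyr::group_modify(function(df, key) {
      fw <- df$work_kcal_mol[df$direction == "forward"]
      bw <- df$work_kcal_mol[df$direction == "backward"]
      est <- switch(method,
        bar = {
          e <- fep_bar_estimator(fw, bw, temperature_K)
          c(e$delta_g_kcal_mol, e$se_kcal_mol)
        },
        exp_forward = c(fep_exp_estimator(fw, temperature_K),
                        fep_exp_se(fw, temperature_K)),
        exp_backward = c(-fep_exp_estimator(bw, temperature_K),
                         fep_exp_se(bw, temperature_K))
      )
      tibble(
        lambda_from = if ("lambda_from" %in% names(df))
          df$lambda_from[df$direction == "forward"][1L] else NA_real_,
        lambda_to = if ("lambda_to" %in% names(df))
          df$lambda_to[df$direction == "forward"][1L] else NA_real_,
        delta_delta_g_kcal_mol = est[1L],
        se_kcal_mol = est[2L]
      )
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$window_index)

  has_f <- any(fep_tbl$direction == "forward")
  has_b <- any(fep_tbl$direction == "backward")
  hysteresis <- if (has_f && has_b) {
    tot_f <- sum(purrr::map_dbl(
      split(fep_tbl$work_kcal_mol[fep_tbl$direction == "forward"],
            fep_tbl$window_index[fep_tbl$direction == "forward"]),
      fep_exp_estimator, temperature_K = temperature_K))
    tot_b <- sum(purrr::map_dbl(
      split(fep_tbl$work_kcal_mol[fep_tbl$direction == "backward"],
            fep_tbl$window_index[fep_tbl$direction == "backward"]),
      fep_exp_estimator, temperature_K = temperature_K))
    abs(tot_f + tot_b)
  } else NA_real_

  structure(
    list(
      windows = windows,
      total_delta_g_kcal_mol = sum(windows$delta_delta_g_kcal_mol),
      se_kcal_mol = sqrt(sum(windows$se_kcal_mol^2)),
      hysteresis_kcal_mol = hysteresis,
      method = method, leg = leg, model = model,
      temperature_K = temperature_K
    ),
    class = "fep_estimate"
  )
}

#' @export
print.fep_estimate <- function(x, ...) {
  cat(sprintf(
    "<fep_estimate> %s%s: dG = %.4g +/- %.2g kcal/mol (%d windows, %s)\n",
    ifelse(is.na(x$leg), "", paste0(x$leg, " ")),
    ifelse(is.na(x$model), "", paste0("model ", x$model)),
    x$total_delta_g_kcal_mol, x$se_kcal_mol, nrow(x$windows), x$method))
  if (is.finite(x$hysteresis_kcal_mol %||% NA)) {
    cat(sprintf("  forward/backward hysteresis: %.3g kcal/mol\n",
                x$hysteresis_kcal_mol))
  }
  invisible(x)
}

#' @export
#' @rdname fep_accumulate
#' @param x A `fep_estimate`.
#' @param ... Unused.
tidy.fep_estimate <- function(x, ...) x$windows

#' @export
#' @rdname fep_accumulate
glance.fep_estimate <- function(x, ...) {
  tibble(total_delta_g_kcal_mol = x$total_delta_g_kcal_mol,
         se_kcal_mol = x$se_kcal_mol,
         hysteresis_kcal_mol = x$hysteresis_kcal_mol,
         n_windows = nrow(x$windows),
         method = x$method, leg = x$leg, model = x$model)
}

#' @export
#' @rdname fep_accumulate
#' @param object A `fep_estimate`.
autoplot.fep_estimate <- function(object, ...) {
  df <- object$windows |>
    dplyr::mutate(
      lambda = dplyr::coalesce(.data$lambda_to,
                               .data$window_index / max(.data$window_index)),
      cum_g = cumsum(.data$delta_delta_g_kcal_mol))
  df0 <- dplyr::bind_rows(tibble(lambda = 0, cum_g = 0),
                          dplyr::select(df, "lambda", "cum_g"))
  ggplot2::ggplot(df0, ggplot2::aes(x = .data$lambda, y = .data$cum_g)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = expression(lambda),
                  y = expression(Delta * G ~ "(kcal/mol)"))
}

#' Combine the two alchemical legs into a reaction free energy
#'
#' The reaction free-energy difference is the sum of the discharging leg
#' (electrostatics off in the reactant) and the charging leg
#' (electrostatics on in the product); leg uncertainties are combined in
#' quadrature. The two estimates must come from the same reaction model.
#'
#' @param fep1,fep2 `"fep_estimate"` objects for the two legs.
#'
#' @return A list with `delta_g0_kcal_mol`, `se_kcal_mol` and `model`.
#' @examples
#' \dontrun{combine_fep_legs(est1, est2)}
#' @export
combine_fep_legs <- function(fep1, fep2) {
  stopifnot(inherits(fep1, "fep_estimate"), inherits(fep2, "fep_estimate"))
  if (!is.na(fep1$model) && !is.na(fep2$model) && fep1$model != fep2$model) {
    stop("legs come from different reaction models (", fep1$model, " vs ",
         fep2$model, ")", call. = FALSE)
  }
  list(
    delta_g0_kcal_mol = fep1$total_delta_g_kcal_mol +
      fep2$total_delta_g_kcal_mol,
    se_kcal_mol = sqrt(fep1$se_kcal_mol^2 + fep2$se_kcal_mol^2),
    model = if (is.na(fep1$model)) fep2$model else fep1$model
  )
}
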