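#' Detect ligand binding events by the 9/13/20 Angstrom hysteresis rule
#'
#' Segments a donor-acceptor distance time series into binding events: an
#' event opens at the first frame with distance below `enter_A` (9 Angstrom)
#' and, while open, the ligand may fluctuate beyond `return_A` (13 Angstrom)
#' without ending the event as long as it comes back; only when the
#' distance reaches `exit_A` (20 Angstrom) does the event close, at the
#' last frame that was within `return_A` before the crossing. An event
#' still open when the trace ends closes at the final frame and is marked
#' unresolved. Threshold semantics: "within 9" is `d < 9`, "within 13" is
#' `d <= 13`, "reaching 20" is `d >= 20`.
#'
#' @param trace A data frame with columns `time_ps` (uniform spacing) and
#'   `distance_A`; an optional `z_A` column is carried along by
#'   [classify_escape_side()].
#' @param enter_A,return_A,exit_A Detection thresholds, Angstrom.
#'   Defaults 9, 13, 20.
#'
#' @return A tibble with one row per event: `event`, `start_index`,
#'   `end_index` (1-based frame indices), `start_ps`, `end_ps`,
#'   `duration_ns` and `resolved`.
#'
#' @examples
#' tr <- tibble::tibble(time_ps = 0:7 * 10,
#'                      distance_A = c(15, 10, 8.5, 11, 14, 12.5, 19, 21))
#' detect_binding_events(tr)
#' @export
detect_binding_events <- function(trace, enter_A = 9, return_A = 13,
                                  exit_A = 20) {
  stopifnot(all(c("time_ps", "distance_A") %in% names(trace)),
            nrow(trace) > 0L,
            enter_A < return_A, return_A < exit_A)
  d <- trace$distance_A
  t_ps <- trace$time_ps
  n <- length(d)

  starts <- integer(0); ends <- integer(0); resolved <- logical(0)
  open <- FALSE; start_i <- NA_integer_; last_in <- NA_integer_
  for (i in seq_len(n)) {
    if (!open) {
      if (d[i] < enter_A) {
        open <- TRUE; start_i <- i; last_in <- i
      }
    } else {
      if (d[i] <= return_A) last_in <- i
      if (d[i] >= exit_A) {
        starts <- c(starts, start_i); ends <- c(ends, last_in)
        resolved <- c(resolved, TRUE)
        open <- FALSE
      }
    }
  }
  if (open) {
    starts <- c(starts, start_i); ends <- c(ends, n)
    resolved <- c(resolved, FALSE)
  }

  dt_ps <- if (n > 1L) t_ps[2L] - t_ps[1L] else NA_real_
  tibble(
    event = seq_along(starts),
    start_index = starts,
    end_index = ends,
    start_ps = t_ps[starts],
    end_ps = t_ps[ends],
    duration_ns = (ends - starts) * dt_ps / 1000,
    resolved = resolved
  )
}

#' Survival histogram of binding events
#'
#' Counts, at each observed duration, how many events remained bound at
#' least that long: `n_bound(t) = #\{duration >= t\}`, evaluated on the
#' sorted unique durations. This is the decreasing step function to which
#' the exponential residence-time model is fitted.
#'
#' @param events An event tibble from [detect_binding_events()] (column
#'   `duration_ns`), or a bare numeric vector of durations in ns.
#'
#' @return A tibble of class `"survival_curve"` with columns `time_ns` and
#'   `n_bound`; the total event count `n0` and the raw durations are
#'   attached as attributes.
#'
#' @examples
#' survival_histogram(c(1, 2, 3))
#' @export
survival_histogram <- function(events) {
  durations <- if (is.numeric(events)) events else events$duration_ns
  if (length(durations) == 0L) {
    stop("no binding events; survival curve undefined", call. = FALSE)
  }
  times <- sort(unique(durations))
  out <- tibble(
    time_ns = times,
    n_bound = vapply(times, function(t) sum(durations >= t), integer(1))
  )
  attr(out, "n0") <- length(durations)
  attr(out, "durations") <- durations
  class(out) <- c("survival_curve", class(out))
  out
}

#' Fit the characteristic binding time
#'
#' Estimates the residence time `tau` of the exponential survival model
#' `n_bound(t) = N0 * exp(-t / tau)`. Two fitting routes are provided:
#' `"lsq"` (default) performs a nonlinear least-squares fit to the survival
#' histogram with both `N0` and `tau` free, initialized at the event count
#' and the mean duration; `"mle"` uses the closed-form exponential maximum
#' likelihood estimate, the sample mean of the durations, with `N0` fixed
#' at the event count.
#'
#' @param x A `"survival_curve"` from [survival_histogram()], an event
#'   tibble, or a numeric vector of durations (ns).
#' @param method `"lsq"` or `"mle"`.
#'
#' @return An object of class `"binding_fit"`: a list with `tau_ns`, `n0`,
#'   `method`, the underlying `curve`, and (for lsq) the `nls` fit object.
#'   Supports [generics::tidy()], [generics::glance()] and
#'   [ggplot2::autoplot()].
#'
#' @examples
#' fit_binding_time(c(2, 2, 4, 8), method = "mle")$tau_ns  # 4
#' @export
fit_binding_time <- function(x, method = c("lsq", "mle")) {
  method <- match.arg(method)
  curve <- if (inherits(x, "survival_curve")) x else survival_histogram(x)
  durations <- attr(curve, "durations")
  n0 <- attr(curve, "n0")

  if (method == "mle") {
    if (is.null(durations)) {
      stop("mle fitting needs raw durations, not only a survival curve",
           call. = FALSE)
    }
    fit <- NULL
    tau <- mean(durations)
    n0_fit <- n0
  } else {
    if (nrow(curve) < 2L) {
      stop("least-squares fitting needs >= 2 distinct durations", call. = FALSE)
    }
    tau_init <- if (!is.null(durations)) mean(durations) else
      mean(curve$time_ns)
    n0_init <- if (!is.null(n0)) n0 else max(curve$n_bound)
    fit <- tryCatch(
      minpack.lm::nlsLM(
        n_bound ~ N0 * exp(-time_ns / tau),
        data = curve,
        start = list(N0 = n0_init, tau = tau_init)
      ),
      error = function(e) {
        stop("survival-curve fit failed to converge: ", conditionMessage(e),
             call. = FALSE)
      }
    )
    co <- stats::coef(fit)
    tau <- unname(co[["tau"]])
    n0_fit <- unname(co[["N0"]])
  }

  structure(
    list(tau_ns = tau, n0 = n0_fit, n_events = n0, method = method,
         curve = curve, fit = fit),
    class = "binding_fit"
  )
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf("<binding_fit> tau = %.4g ns, N0 = %.4g (%s, %d events)\n",
              x$tau_ns, x$n0, x$method, x$n_events %||% NA_integer_))
  invisible(x)
}

#' @export
#' @rdname fit_binding_time
#' @param x A `binding_fit` object.
#' @param ... Unused.
tidy.binding_fit <- function(x, ...) {
  if (!is.null(x$fit)) {
    co <- summary(x$fit)$coefficients
    tibble(term = c("N0", "tau_ns"),
           estimate = c(co["N0", "Estimate"], co["tau", "Estimate"]),
           std.error = c(co["N0", "Std. Error"], co["tau", "Std. Error"]))
  } else {
    # exponential MLE: se(tau) = tau / sqrt(n)
    tibble(term = c("N0", "tau_ns"),
           estimate = c(x$n0, x$tau_ns),
           std.error = c(NA_real_, x$tau_ns / sqrt(x$n_events)))
  }
}

#' @export
#' @rdname fit_binding_time
glance.binding_fit <- function(x, ...) {
  tibble(tau_ns = x$tau_ns, n0 = x$n0, n_events = x$n_events,
         method = x$method)
}

#' @export
#' @rdname fit_binding_time
#' @param object A `binding_fit` or `survival_curve` object.
autoplot.binding_fit <- function(object, ...) {
  grid <- tibble(
    time_ns = seq(0, max(object$curve$time_ns), length.out = 200))
  grid$n_bound <- object$n0 * exp(-grid$time_ns / object$tau_ns)
  autoplot(object$curve) +
    ggplot2::geom_line(data = grid, colour = "firebrick") +
    ggplot2::labs(subtitle = sprintf("tau = %.3g ns (%s)", object$tau_ns,
                                     object$method))
}

#' @export
#' @rdname survival_histogram
autoplot.survival_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_ns, y = .data$n_bound)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "time (ns)", y = "simulations still bound")
}

#' Classify the membrane side through which a ligand escapes
#'
#' After a resolved binding event ends, the first frame at which the
#' membrane-normal coordinate exceeds `shell_A` in magnitude determines the
#' escape side (its sign); if the trace ends first, the escape is
#' unresolved. Positive z is the intermembrane-space (P) side.
#'
#' @param trace A data frame with columns `time_ps`, `distance_A`, `z_A`.
#' @param events Event tibble from [detect_binding_events()].
#' @param shell_A Escape shell radius, Angstrom. Default 20.
#'
#' @return `events` with an added `escape_side` column
#'   (`"positive"`/`"negative"`/`"unresolved"`).
#' @export
classify_escape_side <- function(trace, events, shell_A = 20) {
  if (!"z_A" %in% names(trace)) {
    stop("trace has no membrane-normal coordinate `z_A`; escape side ",
         "cannot be determined", call. = FALSE)
  }
  z <- trace$z_A
  n <- length(z)
  events$escape_side <- vapply(seq_len(nrow(events)), function(k) {
    if (!events$resolved[k]) return("unresolved")
    i <- events$end_index[k] + 1L
    while (i <= n) {
      if (abs(z[i]) > shell_A) {
        return(if (z[i] > 0) "positive" else "negative")
      }
      i <- i + 1L
    }
    "unresolved"
  }, character(1))
  events
}

`%||%` <- function(a, b) if (is.null(a)) b else a
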