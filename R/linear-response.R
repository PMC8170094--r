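#' Energy gap from separately evaluated state energies
#'
#' The reaction coordinate for electron transfer is the potential-energy
#' gap between the product and reactant charge assignments evaluated at the
#' same nuclear coordinates: `delta U = U_product - U_reactant`, computed
#' elementwise over snapshots.
#'
#' @param u_product,u_reactant Numeric vectors of equal length, kcal/mol.
#' @return Numeric vector of gaps, kcal/mol.
#' @examples
#' gap_from_energies(10, 30)  # -20
#' @export
gap_from_energies <- function(u_product, u_reactant) {
  if (length(u_product) != length(u_reactant)) {
    stop("`u_product` and `u_reactant` must have equal length.", call. = FALSE)
  }
  u_product - u_reactant
}

# Adjusted Fisher-Pearson skewness (the small-sample-corrected form)
skewness_adj <- function(x) {
  n <- length(x)
  if (n < 3L) return(NA_real_)
  m <- mean(x)
  s <- stats::sd(x)
  if (s == 0) return(NA_real_)
  g1 <- mean((x - m)^3) / (mean((x - m)^2))^1.5
  g1 * sqrt(n * (n - 1)) / (n - 2)
}

#' Summarize energy-gap samples per state
#'
#' Mean, sample standard deviation and adjusted Fisher-Pearson skewness of
#' the gap samples in each redox state. A noticeable skewness
#' (|skewness| above `skew_warn`) triggers a warning, since the parabolic
#' free-energy construction assumes near-Gaussian gap fluctuations.
#'
#' @param gap_tbl A tibble with columns `state` and `delta_u_kcal_mol`, or
#'   with `u_product_kcal_mol`/`u_reactant_kcal_mol` from which the gap is
#'   computed. Each state needs >= 2 samples.
#' @param skew_warn Warning threshold on |skewness|. Default 0.5.
#'
#' @return A tibble with columns `state`, `n`, `mean_kcal_mol`,
#'   `sd_kcal_mol`, `skewness`.
#' @export
summarize_gaps <- function(gap_tbl, skew_warn = 0.5) {
  gap_tbl <- normalize_gap_tbl(gap_tbl)
  out <- gap_tbl |>
    dplyr::group_by(.data$state) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_kcal_mol = mean(.data$delta_u_kcal_mol),
      sd_kcal_mol = stats::sd(.data$delta_u_kcal_mol),
      skewness = skewness_adj(.data$delta_u_kcal_mol),
      .groups = "drop"
    )
  if (any(out$n < 2L)) {
    stop("each state needs at least 2 gap samples", call. = FALSE)
  }
  bad <- out$state[!is.na(out$skewness) & abs(out$skewness) > skew_warn]
  if (length(bad) > 0L) {
    warning("gap distribution of state(s) ", paste(bad, collapse = ", "),
            " is noticeably skewed (|skewness| > ", skew_warn,
            "); the Gaussian/parabolic approximation may be poor",
            call. = FALSE)
  }
  out
}

normalize_gap_tbl <- function(gap_tbl) {
  gap_tbl <- as_tibble(gap_tbl)
  if (!"delta_u_kcal_mol" %in% names(gap_tbl)) {
    if (all(c("u_product_kcal_mol", "u_reactant_kcal_mol") %in% names(gap_tbl))) {
      gap_tbl$delta_u_kcal_mol <- gap_from_energies(
        gap_tbl$u_product_kcal_mol, gap_tbl$u_reactant_kcal_mol)
    } else {
      stop("gap table needs `delta_u_kcal_mol` or both ",
           "`u_product_kcal_mol` and `u_reactant_kcal_mol`", call. = FALSE)
    }
  }
  if (!"state" %in% names(gap_tbl)) {
    stop("gap table needs a `state` column (reactant/product)", call. = FALSE)
  }
  gap_tbl
}

#' Empirical free-energy curve along the gap coordinate
#'
#' Converts a histogram of gap samples into a free-energy profile via
#' `G = -kBT * log(density)`, offset so the minimum is zero. Empty bins are
#' excluded. Binning defaults to Freedman-Diaconis.
#'
#' @param samples Numeric vector of gap samples, kcal/mol (>= 50 samples;
#'   below that only the parabolic route is meaningful).
#' @param temperature_K Temperature, K. Default 300.
#' @param bins Optional bin count overriding Freedman-Diaconis.
#'
#' @return A tibble with columns `delta_u_kcal_mol` (bin centers) and
#'   `g_kcal_mol`.
#' @export
empirical_free_energy_curve <- function(samples, temperature_K = 300,
                                        bins = NULL) {
  if (length(samples) < 50L) {
    stop("need >= 50 samples for an empirical free-energy curve", call. = FALSE)
  }
  if (diff(range(samples)) == 0) {
    stop("all gap samples identical; histogram degenerate", call. = FALSE)
  }
  th <- thermo(temperature_K)
  breaks <- if (is.null(bins)) "FD" else bins
  h <- graphics::hist(samples, breaks = breaks, plot = FALSE)
  keep <- h$density > 0
  g <- -th$kBT * log(h$density[keep])
  tibble(delta_u_kcal_mol = h$mids[keep], g_kcal_mol = g - min(g))
}

#' Parabolic free-energy curve from Gaussian gap statistics
#'
#' Under Gaussian gap fluctuations the free-energy curve is a parabola with
#' curvature `a = kBT / (2 sigma^2)` and vertex at the mean gap. The
#' returned offset is 0; alignment against a partner state is done by
#' [align_and_extract()].
#'
#' @param mean_kcal_mol Mean gap, kcal/mol.
#' @param sd_kcal_mol Gap standard deviation, kcal/mol (> 0).
#' @param temperature_K Temperature, K. Default 300.
#'
#' @return A list with elements `a` (1/(kcal/mol)), `vertex` (kcal/mol) and
#'   `offset` (kcal/mol).
#' @examples
#' parabola_from_summary(63.87, 10)$a  # kBT / 200
#' @export
parabola_from_summary <- function(mean_kcal_mol, sd_kcal_mol,
                                  temperature_K = 300) {
  if (!is.numeric(sd_kcal_mol) || sd_kcal_mol <= 0) {
    stop("`sd_kcal_mol` must be > 0.", call. = FALSE)
  }
  th <- thermo(temperature_K)
  list(a = th$kBT / (2 * sd_kcal_mol^2), vertex = mean_kcal_mol, offset = 0)
}

eval_parabola <- function(p, x) p$a * (x - p$vertex)^2 + p$offset

#' Align two free-energy parabolas and extract the reaction parameters
#'
#' Shifts the product-state parabola vertically so that the two curves
#' agree at gap zero (the electron-transfer transition condition), then
#' reads off the driving force and the two reorganization energies:
#' `delta G0` is the difference between the product and reactant minima;
#' `Lambda_p` is the product-state curve evaluated at the reactant vertex
#' relative to its own minimum (`a_p * (v_r - v_p)^2`), the energy to
#' reorganize the relaxed product geometry into the reactant equilibrium;
#' `Lambda_r` is the mirror-image quantity on the reactant curve.
#'
#' @param reactant,product Parabolas from [parabola_from_summary()].
#' @param summaries Optional gap summary tibble carried into the result.
#' @param curves Optional named list of empirical curves (tibbles) carried
#'   into the result for plotting.
#'
#' @return An object of class `"free_energy_diagram"`: a list with
#'   `delta_g0_kcal_mol`, `lambda_p_kcal_mol`, `lambda_r_kcal_mol`, the
#'   aligned `parabolas` (named list), and any `summaries`/`curves`
#'   supplied. Supports `tidy()`, `glance()` and `autoplot()`.
#'
#' @examples
#' r <- parabola_from_summary(63.87, 10)
#' p <- parabola_from_summary(-103.87, 10)
#' glance(align_and_extract(r, p))
#' @export
align_and_extract <- function(reactant, product, summaries = NULL,
                              curves = NULL) {
  stopifnot(is.finite(reactant$vertex), is.finite(product$vertex),
            reactant$a > 0, product$a > 0)
  if (reactant$vertex == product$vertex) {
    warning("reactant and product vertices coincide; reorganization energy ",
            "is zero", call. = FALSE)
  }
  reactant$offset <- 0
  # align so G_r(0) = G_p(0)
  product$offset <- reactant$a * reactant$vertex^2 -
    product$a * product$vertex^2

  sep2 <- (reactant$vertex - product$vertex)^2
  out <- list(
    delta_g0_kcal_mol = product$offset,
    lambda_p_kcal_mol = product$a * sep2,
    lambda_r_kcal_mol = reactant$a * sep2,
    parabolas = list(reactant = reactant, product = product),
    summaries = summaries,
    curves = curves
  )
  class(out) <- "free_energy_diagram"
  out
}

#' Full linear-response free-energy analysis
#'
#' Runs the whole energy-gap chain on a two-state gap sample table:
#' per-state Gaussian summaries (with a skewness-based normality check),
#' parabolic free-energy curves, empirical histogram curves over the
#' sampled ranges, vertical alignment at gap zero, and extraction of the
#' driving force and the product/reactant reorganization energies.
#'
#' @inheritParams summarize_gaps
#' @param temperature_K Temperature, K. Default 300.
#' @param bins Optional histogram bin count (default Freedman-Diaconis).
#'
#' @return A `"free_energy_diagram"` (see [align_and_extract()]) with the
#'   per-state summaries and empirical curves attached.
#'
#' @examples
#' gaps <- sim_gap_samples(-20, 83.87, n_samples = 5000, seed = 1)
#' glance(full_linear_response(gaps))
#' @export
full_linear_response <- function(gap_tbl, temperature_K = 300, bins = NULL,
                                 skew_warn = 0.5) {
  gap_tbl <- normalize_gap_tbl(gap_tbl)
  stopifnot(all(c("reactant", "product") %in% gap_tbl$state))
  summ <- summarize_gaps(gap_tbl, skew_warn = skew_warn)
  s_r <- summ[summ$state == "reactant", ]
  s_p <- summ[summ$state == "product", ]
  pr <- parabola_from_summary(s_r$mean_kcal_mol, s_r$sd_kcal_mol, temperature_K)
  pp <- parabola_from_summary(s_p$mean_kcal_mol, s_p$sd_kcal_mol, temperature_K)

  curves <- purrr::map(c(reactant = "reactant", product = "product"),
    function(st) {
      x <- gap_tbl$delta_u_kcal_mol[gap_tbl$state == st]
      if (length(x) >= 50L && diff(range(x)) > 0) {
        empirical_free_energy_curve(x, temperature_K, bins)
      } else NULL
    })

  diagram <- align_and_extract(pr, pp, summaries = summ, curves = curves)
  # vertically place each empirical curve on its aligned parabola
  for (st in names(diagram$curves)) {
    cu <- diagram$curves[[st]]
    if (!is.null(cu)) {
      pb <- diagram$parabolas[[st]]
      cu$g_kcal_mol <- cu$g_kcal_mol + pb$offset
      diagram$curves[[st]] <- cu
    }
  }
  diagram
}

#' @export
print.free_energy_diagram <- function(x, ...) {
  cat(sprintf(paste0("<free_energy_diagram> dG0 = %.4g kcal/mol, ",
                     "Lambda_p = %.4g, Lambda_r = %.4g kcal/mol\n"),
              x$delta_g0_kcal_mol, x$lambda_p_kcal_mol, x$lambda_r_kcal_mol))
  invisible(x)
}

#' @export
#' @rdname align_and_extract
#' @param x A `free_energy_diagram`.
#' @param ... Unused.
tidy.free_energy_diagram <- function(x, ...) {
  purrr::imap_dfr(x$parabolas, function(p, st) {
    tibble(state = st, curvature = p$a, vertex_kcal_mol = p$vertex,
           offset_kcal_mol = p$offset)
  })
}

#' @export
#' @rdname align_and_extract
glance.free_energy_diagram <- function(x, ...) {
  tibble(delta_g0_kcal_mol = x$delta_g0_kcal_mol,
         lambda_p_kcal_mol = x$lambda_p_kcal_mol,
         lambda_r_kcal_mol = x$lambda_r_kcal_mol)
}

#' @export
#' @rdname align_and_extract
#' @param object A `free_energy_diagram`.
autoplot.free_energy_diagram <- function(object, ...) {
  vr <- object$parabolas$reactant$vertex
  vp <- object$parabolas$product$vertex
  span <- abs(vr - vp)
  xs <- seq(min(vr, vp) - 0.6 * span, max(vr, vp) + 0.6 * span,
            length.out = 400)
  par_df <- purrr::imap_dfr(object$parabolas, function(p, st) {
    tibble(state = st, delta_u_kcal_mol = xs,
           g_kcal_mol = eval_parabola(p, xs))
  })
  gg <- ggplot2::ggplot(par_df,
                        ggplot2::aes(x = .data$delta_u_kcal_mol,
                                     y = .data$g_kcal_mol,
                                     colour = .data$state)) +
    ggplot2::geom_line(linewidth = 0.4)
  emp_df <- purrr::imap_dfr(object$curves %||% list(), function(cu, st) {
    if (is.null(cu)) return(tibble())
    dplyr::mutate(cu, state = st)
  })
  if (nrow(emp_df) > 0L) {
    gg <- gg + ggplot2::geom_line(data = emp_df, linewidth = 1.2)
  }
  gg + ggplot2::labs(x = expression(Delta * U ~ "(kcal/mol)"),
                     y = "G (kcal/mol)")
}
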