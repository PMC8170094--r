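DONOR_POOL_SQ <- "SQ"
DONOR_POOL_CLUSTER <- c("Fe1", "Fe2", "S1", "S2")

#' Classify the O2 electron-transfer outcome from its spin density
#'
#' A snapshot's O2 fragment carries a local spin density of magnitude near 2
#' (triplet O2, no electron transferred) or near 1 (an electron of opposite
#' spin has arrived, forming superoxide). The decision boundary is the
#' midpoint `spin_threshold = 1.5`; magnitudes below `anomaly_band = 0.5`,
#' or spin signs inconsistent with the declared O2 spin orientation, are
#' flagged `"anomalous"` (callers typically route those to the outlier
#' class).
#'
#' @param spin_o2 Numeric vector of signed O2 local spin densities.
#' @param o2_spin_state Character vector (`"up"`/`"down"`), recycled to the
#'   length of `spin_o2`; `"up"` requires positive spin, `"down"` negative.
#' @param spin_threshold Magnitude separating the two outcomes. Default 1.5.
#' @param anomaly_band Magnitude below which the spin is anomalous.
#'   Default 0.5.
#'
#' @return Character vector: `"no_ET"`, `"transferred"` or `"anomalous"`.
#' @examples
#' classify_o2_transfer(c(1.98, -1.02), c("up", "down"))
#' @export
classify_o2_transfer <- function(spin_o2, o2_spin_state,
                                 spin_threshold = 1.5, anomaly_band = 0.5) {
  stopifnot(is.numeric(spin_o2), all(o2_spin_state %in% c("up", "down")))
  o2_spin_state <- rep_len(o2_spin_state, length(spin_o2))
  mag <- abs(spin_o2)
  expected_sign <- ifelse(o2_spin_state == "up", 1, -1)
  ok_sign <- sign(spin_o2) == expected_sign
  dplyr::case_when(
    mag < anomaly_band | !ok_sign ~ "anomalous",
    mag > spin_threshold ~ "no_ET",
    TRUE ~ "transferred"
  )
}

#' Per-fragment mean spin densities of the no-transfer reference ensemble
#'
#' Averages the local spin density of each fragment over the snapshots in
#' which no electron transfer occurred; this reference is subtracted from
#' transfer snapshots to localize the donated electron.
#'
#' @param spin_tbl Long-format spin table (columns `snapshot_id`,
#'   `fragment`, `spin`) restricted to no-transfer snapshots. All snapshots
#'   must share an identical fragment set.
#'
#' @return A tibble with columns `fragment` and `mean_spin`.
#' @export
reference_mean_spins <- function(spin_tbl) {
  if (is.null(spin_tbl) || nrow(spin_tbl) == 0L) {
    stop("no no-transfer snapshots available to build the spin reference",
         call. = FALSE)
  }
  counts <- dplyr::count(spin_tbl, .data$snapshot_id)
  frag_sets <- spin_tbl |>
    dplyr::group_by(.data$snapshot_id) |>
    dplyr::summarise(key = paste(sort(.data$fragment), collapse = "|"),
                     .groups = "drop")
  if (dplyr::n_distinct(frag_sets$key) != 1L) {
    stop("snapshots do not share an identical fragment set", call. = FALSE)
  }
  spin_tbl |>
    dplyr::group_by(.data$fragment) |>
    dplyr::summarise(mean_spin = mean(.data$spin), .groups = "drop")
}

#' Spin-density differences relative to the no-transfer reference
#'
#' Computes, for each snapshot and fragment, the difference between the
#' snapshot's local spin density and the no-transfer ensemble mean. On
#' transfer snapshots the fragments whose spin changed by approximately one
#' unit identify the donated electron's origin.
#'
#' @param spin_tbl Long-format spin table (columns `snapshot_id`,
#'   `fragment`, `spin`).
#' @param reference Output of [reference_mean_spins()].
#'
#' @return A tibble with columns `snapshot_id`, `fragment`, `delta_spin`.
#' @export
delta_spin <- function(spin_tbl, reference) {
  missing <- setdiff(unique(spin_tbl$fragment), reference$fragment)
  extra_per_snap <- spin_tbl |>
    dplyr::count(.data$snapshot_id) |>
    dplyr::pull(.data$n)
  if (length(missing) > 0L || any(extra_per_snap != nrow(reference))) {
    stop("fragment sets of snapshots and reference do not match", call. = FALSE)
  }
  spin_tbl |>
    dplyr::inner_join(reference, by = "fragment") |>
    dplyr::transmute(.data$snapshot_id, .data$fragment,
                     delta_spin = .data$spin - .data$mean_spin)
}

#' Attribute the transferred electron to a donor pool
#'
#' Given per-fragment spin differences for snapshots with an observed
#' electron transfer, decides between the two donor hypotheses: the
#' semiquinone (model I) versus the iron-sulfur cluster fragments Fe1, Fe2,
#' S1, S2 (model II). The pool with the larger summed `|delta_spin|` wins;
#' exact ties go to model II. Donor weights are the normalized
#' `|delta_spin|` shares within the winning pool.
#'
#' @param delta_tbl Output of [delta_spin()], possibly for several
#'   snapshots.
#' @param min_pool Minimum summed `|delta_spin|` in the winning pool; below
#'   it the snapshot is labeled `"unattributable"`. Default 0.5.
#'
#' @return A tibble with columns `snapshot_id`, `label` (`"model_I"`,
#'   `"model_II"` or `"unattributable"`) and `donor_weights` (list column of
#'   named shares summing to 1).
#' @export
attribute_donor <- function(delta_tbl, min_pool = 0.5) {
  delta_tbl |>
    dplyr::group_by(.data$snapshot_id) |>
    dplyr::group_modify(function(df, key) {
      ds <- stats::setNames(df$delta_spin, df$fragment)
      sq_sum <- sum(abs(ds[names(ds) %in% DONOR_POOL_SQ]))
      cl_sum <- sum(abs(ds[names(ds) %in% DONOR_POOL_CLUSTER]))
      if (max(sq_sum, cl_sum) < min_pool) {
        return(tibble(label = "unattributable", donor_weights = list(NULL)))
      }
      if (sq_sum > cl_sum) {
        w <- abs(ds[names(ds) %in% DONOR_POOL_SQ])
        label <- "model_I"
      } else {  # ties resolve to the cluster donor
        w <- abs(ds[names(ds) %in% DONOR_POOL_CLUSTER])
        label <- "model_II"
      }
      tibble(label = label, donor_weights = list(w / sum(w)))
    }) |>
    dplyr::ungroup()
}

#' Flag snapshots whose total energy is far from their class median
#'
#' Within each (spin orientation, label) group, snapshots whose total
#' energy deviates from the group median by more than `threshold` are
#' flagged as outliers. The median makes the rule robust to the outliers
#' themselves.
#'
#' @param class_tbl A tibble with columns `snapshot_id`, `o2_spin_state`,
#'   `label`, `total_energy_kcal_mol`.
#' @param threshold Deviation threshold, kcal/mol (> 0). Default 50 --
#'   roughly 3-4 times the typical within-class energy sd.
#'
#' @return Character vector of flagged `snapshot_id`s.
#' @export
flag_outliers <- function(class_tbl, threshold = 50) {
  stopifnot(threshold > 0)
  class_tbl |>
    dplyr::group_by(.data$o2_spin_state, .data$label) |>
    dplyr::mutate(dev = abs(.data$total_energy_kcal_mol -
                              stats::median(.data$total_energy_kcal_mol))) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$dev > threshold) |>
    dplyr::pull(.data$snapshot_id)
}

#' Class-resolved energy statistics
#'
#' Per spin orientation and class label: the number of snapshots, the mean
#' total energy relative to the no-transfer class mean of the same spin
#' orientation, and the sample (n-1) standard deviation. The no-transfer
#' class mean is exactly 0 by construction; outliers are reported with a
#' count only.
#'
#' @param class_tbl A tibble with columns `snapshot_id`, `o2_spin_state`,
#'   `label`, `total_energy_kcal_mol`.
#'
#' @return A tibble with columns `o2_spin_state`, `label`, `n`,
#'   `mean_rel_kcal_mol`, `sd_kcal_mol` (NA for single-member classes and
#'   for outliers).
#' @export
class_energy_stats <- function(class_tbl) {
  if (!any(class_tbl$label == "no_ET")) {
    stop("no no-transfer class present; relative energies are undefined",
         call. = FALSE)
  }
  ref <- class_tbl |>
    dplyr::filter(.data$label == "no_ET") |>
    dplyr::group_by(.data$o2_spin_state) |>
    dplyr::summarise(e_ref = mean(.data$total_energy_kcal_mol), .groups = "drop")
  class_tbl |>
    dplyr::inner_join(ref, by = "o2_spin_state") |>
    dplyr::group_by(.data$o2_spin_state, .data$label) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_rel_kcal_mol = mean(.data$total_energy_kcal_mol - .data$e_ref),
      sd_kcal_mol = stats::sd(.data$total_energy_kcal_mol),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      mean_rel_kcal_mol = ifelse(.data$label == "outlier", NA_real_,
                                 .data$mean_rel_kcal_mol),
      sd_kcal_mol = ifelse(.data$label == "outlier" | .data$n < 2L, NA_real_,
                           .data$sd_kcal_mol)
    )
}

#' Moment-matched Gaussian parameters for class energy distributions
#'
#' Returns, for every class with at least two members, the normal-density
#' parameters (mean, sd) matching the class energy statistics -- the curves
#' overlaid on class energy histograms. No free fit is performed; the
#' parameters are the sample moments.
#'
#' @param stats_tbl Output of [class_energy_stats()].
#'
#' @return A tibble with columns `o2_spin_state`, `label`,
#'   `mean_kcal_mol`, `sd_kcal_mol`, `peak_density` and a logical
#'   `degenerate` flag for sd collapsing to 0.
#' @export
gaussian_class_fit <- function(stats_tbl) {
  fits <- stats_tbl |>
    dplyr::filter(.data$label != "outlier", .data$n >= 2L)
  if (nrow(fits) == 0L) {
    stop("no class with n >= 2; Gaussian parameters undefined", call. = FALSE)
  }
  fits |>
    dplyr::transmute(
      .data$o2_spin_state, .data$label,
      mean_kcal_mol = .data$mean_rel_kcal_mol,
      sd_kcal_mol = .data$sd_kcal_mol,
      degenerate = .data$sd_kcal_mol <= 0 | !is.finite(.data$sd_kcal_mol),
      peak_density = ifelse(.data$degenerate, Inf,
                            1 / (.data$sd_kcal_mol * sqrt(2 * pi)))
    )
}

#' Classify an ensemble of quantum-chemistry snapshots
#'
#' End-to-end classification of a long-format fragment spin table:
#' unconverged snapshots are dropped (with a message), each snapshot's O2
#' spin density decides between no transfer and transfer, transfer
#' snapshots are attributed to a donor pool (model I: semiquinone; model
#' II: iron-sulfur cluster) via spin differences against the no-transfer
#' reference of the same spin orientation, and energy outliers are
#' re-labeled by the median-deviation rule. Anomalous or unattributable
#' snapshots are routed to the outlier class.
#'
#' @param spin_tbl Long tibble with columns `snapshot_id`, `o2_spin_state`,
#'   `fragment`, `spin`, `total_energy_kcal_mol`, `converged`.
#' @param spin_threshold,anomaly_band Passed to [classify_o2_transfer()].
#' @param min_pool Passed to [attribute_donor()].
#' @param outlier_threshold Passed to [flag_outliers()], kcal/mol.
#'
#' @return A tibble of class `"spin_classification"` with columns
#'   `snapshot_id`, `o2_spin_state`, `total_energy_kcal_mol`, `label`
#'   (`no_ET`/`model_I`/`model_II`/`outlier`) and `donor_weights` (list
#'   column; `NULL` outside the transfer classes). The number of dropped
#'   unconverged snapshots is attached as `attr(, "n_unconverged")`.
#'
#' @examples
#' tbl <- sim_spin_tables(n_no_et = 10, n_model_ii = 5, noise_sd = 0, seed = 1)
#' classify_spin_snapshots(tbl)
#' @export
classify_spin_snapshots <- function(spin_tbl,
                                    spin_threshold = 1.5,
                                    anomaly_band = 0.5,
                                    min_pool = 0.5,
                                    outlier_threshold = 50) {
  required <- c("snapshot_id", "o2_spin_state", "fragment", "spin",
                "total_energy_kcal_mol", "converged")
  if (!all(required %in% names(spin_tbl))) {
    stop("spin table must have columns: ", paste(required, collapse = ", "),
         call. = FALSE)
  }
  spin_tbl <- as_tibble(spin_tbl)
  unconv <- spin_tbl |>
    dplyr::distinct(.data$snapshot_id, .data$converged) |>
    dplyr::filter(!.data$converged)
  if (nrow(unconv) > 0L) {
    message(nrow(unconv), " unconverged snapshot(s) dropped")
    spin_tbl <- dplyr::filter(spin_tbl, .data$converged)
  }

  snaps <- spin_tbl |>
    dplyr::filter(.data$fragment == "O2") |>
    dplyr::transmute(.data$snapshot_id, .data$o2_spin_state,
                     spin_o2 = .data$spin, .data$total_energy_kcal_mol) |>
    dplyr::mutate(outcome = classify_o2_transfer(
      .data$spin_o2, .data$o2_spin_state, spin_threshold, anomaly_band))

  donors <- purrr::map_dfr(unique(snaps$o2_spin_state), function(st) {
    transferred <- snaps |>
      dplyr::filter(.data$o2_spin_state == st, .data$outcome == "transferred")
    if (nrow(transferred) == 0L) return(tibble())
    ref_ids <- snaps$snapshot_id[snaps$o2_spin_state == st &
                                   snaps$outcome == "no_ET"]
    ref <- reference_mean_spins(
      dplyr::filter(spin_tbl, .data$snapshot_id %in% ref_ids))
    deltas <- delta_spin(
      dplyr::filter(spin_tbl, .data$snapshot_id %in% transferred$snapshot_id,
                    .data$fragment != "O2"),
      dplyr::filter(ref, .data$fragment != "O2"))
    attribute_donor(deltas, min_pool = min_pool)
  })

  out <- snaps |>
    dplyr::left_join(donors, by = "snapshot_id") |>
    dplyr::mutate(
      label = dplyr::case_when(
        .data$outcome == "no_ET" ~ "no_ET",
        .data$outcome == "anomalous" ~ "outlier",
        is.na(.data$label) | .data$label == "unattributable" ~ "outlier",
        TRUE ~ .data$label
      )
    )
  if (!"donor_weights" %in% names(out)) out$donor_weights <- list(NULL)
  out$donor_weights[out$label %in% c("no_ET", "outlier")] <- list(NULL)

  flagged <- flag_outliers(
    dplyr::select(out, "snapshot_id", "o2_spin_state", "label",
                  "total_energy_kcal_mol"),
    threshold = outlier_threshold)
  out <- out |>
    dplyr::mutate(label = ifelse(.data$snapshot_id %in% flagged, "outlier",
                                 .data$label)) |>
    dplyr::select("snapshot_id", "o2_spin_state", "total_energy_kcal_mol",
                  "label", "donor_weights")
  out$donor_weights[out$label == "outlier"] <- list(NULL)
  attr(out, "n_unconverged") <- nrow(unconv)
  class(out) <- c("spin_classification", class(out))
  out
}

#' Plot class-resolved energy distributions with Gaussian overlays
#'
#' Histograms of snapshot total energies (relative to the no-transfer class
#' mean) per class, with the moment-matched normal densities overlaid.
#'
#' @param class_tbl A classification tibble (e.g. from
#'   [classify_spin_snapshots()]).
#' @param binwidth Histogram bin width, kcal/mol. Default 5.
#' @return A ggplot object.
#' @export
plot_class_energies <- function(class_tbl, binwidth = 5) {
  stats_tbl <- class_energy_stats(class_tbl)
  fits <- gaussian_class_fit(stats_tbl)
  ref <- class_tbl |>
    dplyr::filter(.data$label == "no_ET") |>
    dplyr::group_by(.data$o2_spin_state) |>
    dplyr::summarise(e_ref = mean(.data$total_energy_kcal_mol), .groups = "drop")
  df <- class_tbl |>
    dplyr::filter(.data$label != "outlier") |>
    dplyr::inner_join(ref, by = "o2_spin_state") |>
    dplyr::mutate(e_rel = .data$total_energy_kcal_mol - .data$e_ref)
  curves <- fits |>
    dplyr::filter(!.data$degenerate) |>
    purrr::pmap_dfr(function(o2_spin_state, label, mean_kcal_mol,
                             sd_kcal_mol, ...) {
      x <- seq(mean_kcal_mol - 4 * sd_kcal_mol,
               mean_kcal_mol + 4 * sd_kcal_mol, length.out = 200)
      tibble(o2_spin_state = o2_spin_state, label = label, e_rel = x,
             density = stats::dnorm(x, mean_kcal_mol, sd_kcal_mol))
    })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$e_rel, fill = .data$label)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            binwidth = binwidth, alpha = 0.5,
                            position = "identity") +
    ggplot2::geom_line(data = curves, inherit.aes = FALSE,
                       mapping = ggplot2::aes(x = .data$e_rel,
                                              y = .data$density,
                                              colour = .data$label)) +
    ggplot2::facet_wrap(ggplot2::vars(.data$o2_spin_state), ncol = 1) +
    ggplot2::labs(x = "energy relative to no-transfer mean (kcal/mol)",
                  y = "density", fill = "class", colour = "class")
}
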