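make_spin_tbl <- function(spins_by_snapshot, o2_spin_state = "up",
                          energies = NULL) {
  ids <- names(spins_by_snapshot)
  if (is.null(energies)) energies <- rep(0, length(ids))
  purrr::imap_dfr(spins_by_snapshot, function(s, id) {
    tibble::tibble(snapshot_id = id, o2_spin_state = o2_spin_state,
                   fragment = names(s), spin = unname(s),
                   total_energy_kcal_mol = energies[[match(id, ids)]],
                   converged = TRUE)
  })
}

test_that("O2 spin magnitude and sign decide the transfer outcome", {
  expect_equal(classify_o2_transfer(1.98, "up"), "no_ET")
  expect_equal(classify_o2_transfer(-1.02, "down"), "transferred")
  expect_equal(classify_o2_transfer(2.0, "up"), "no_ET")
  # sign mismatch and sub-band magnitudes are anomalous
  expect_equal(classify_o2_transfer(-1.0, "up"), "anomalous")
  expect_equal(classify_o2_transfer(0.3, "up"), "anomalous")
  # vectorized over snapshots
  expect_equal(classify_o2_transfer(c(1.9, 1.1), c("up", "up")),
               c("no_ET", "transferred"))
})

test_that("no-transfer reference spins are per-fragment means", {
  tbl <- make_spin_tbl(list(a = c(O2 = 2, Fe2 = 3.6), b = c(O2 = 2, Fe2 = 4.0)))
  ref <- reference_mean_spins(tbl)
  expect_equal(ref$mean_spin[ref$fragment == "Fe2"], 3.8)

  one <- make_spin_tbl(list(a = c(O2 = 2, Fe2 = 3.6)))
  ref1 <- reference_mean_spins(one)
  expect_equal(ref1$mean_spin[match(c("O2", "Fe2"), ref1$fragment)],
               c(2, 3.6))

  ragged <- make_spin_tbl(list(a = c(O2 = 2, Fe2 = 3.6), b = c(O2 = 2)))
  expect_error(reference_mean_spins(ragged), "fragment set")
  expect_error(reference_mean_spins(tbl[0, ]), "no no-transfer")
})

test_that("spin differences subtract the reference per fragment", {
  tbl <- make_spin_tbl(list(x = c(SQ = -0.05, Fe2 = 3.2)))
  ref <- tibble::tibble(fragment = c("SQ", "Fe2"), mean_spin = c(-1.0, 3.8))
  ds <- delta_spin(tbl, ref)
  expect_equal(ds$delta_spin[ds$fragment == "SQ"], 0.95)
  expect_equal(ds$delta_spin[ds$fragment == "Fe2"], -0.6)

  same <- delta_spin(make_spin_tbl(list(x = c(SQ = -1.0, Fe2 = 3.8))), ref)
  expect_equal(same$delta_spin, c(0, 0))

  expect_error(delta_spin(make_spin_tbl(list(x = c(SQ = 1, Zn = 0))), ref),
               "do not match")
})

test_that("donor attribution picks the pool with the larger spin change", {
  ds1 <- tibble::tibble(snapshot_id = "s1",
                        fragment = c("SQ", "Fe1", "Fe2", "S1", "S2"),
                        delta_spin = c(0.97, 0.01, -0.02, 0, 0.01))
  a1 <- attribute_donor(ds1)
  expect_equal(a1$label, "model_I")
  expect_equal(unname(a1$donor_weights[[1]][["SQ"]]), 1.0)

  ds2 <- tibble::tibble(snapshot_id = "s2",
                        fragment = c("SQ", "Fe2", "S1", "S2"),
                        delta_spin = c(0.001, -0.5, -0.25, -0.25))
  a2 <- attribute_donor(ds2)
  expect_equal(a2$label, "model_II")
  expect_equal(unname(a2$donor_weights[[1]][c("Fe2", "S1", "S2")]),
               c(0.5, 0.25, 0.25))
  expect_equal(sum(a2$donor_weights[[1]]), 1, tolerance = 1e-6)

  # exact tie resolves to the cluster donor
  tie <- tibble::tibble(snapshot_id = "s3",
                        fragment = c("SQ", "Fe2"),
                        delta_spin = c(0.5, 0.5))
  expect_equal(attribute_donor(tie)$label, "model_II")

  weak <- tibble::tibble(snapshot_id = "s4",
                         fragment = c("SQ", "Fe2"),
                         delta_spin = c(0.1, 0.1))
  expect_equal(attribute_donor(weak)$label, "unattributable")
})

test_that("energy outliers deviate from their class median", {
  tbl <- tibble::tibble(
    snapshot_id = letters[1:4], o2_spin_state = "up", label = "no_ET",
    total_energy_kcal_mol = c(0, 2, 4, -120))
  expect_equal(flag_outliers(tbl, threshold = 50), "d")
  expect_length(flag_outliers(tbl[1:3, ], threshold = 50), 0)
  expect_length(flag_outliers(tbl, threshold = Inf), 0)
})

test_that("class energy statistics are relative to the no-transfer mean", {
  tbl <- tibble::tibble(
    snapshot_id = as.character(1:6), o2_spin_state = "up",
    label = c("no_ET", "no_ET", "no_ET", "model_II", "model_II", "model_I"),
    total_energy_kcal_mol = c(0, 2, 4, -38, -40, 7))
  st <- class_energy_stats(tbl)
  expect_equal(st$mean_rel_kcal_mol[st$label == "no_ET"], 0)
  expect_equal(st$mean_rel_kcal_mol[st$label == "model_II"], -41)
  expect_equal(st$sd_kcal_mol[st$label == "no_ET"], 2)
  # single-member class has no defined sd
  expect_true(is.na(st$sd_kcal_mol[st$label == "model_I"]))
  expect_equal(sum(st$n), 6)

  expect_error(class_energy_stats(dplyr::mutate(tbl, label = "model_I")),
               "no no-transfer")
})

test_that("gaussian class fit moment-matches and flags degeneracy", {
  tbl <- tibble::tibble(
    snapshot_id = as.character(1:4), o2_spin_state = "up",
    label = c("no_ET", "no_ET", "model_II", "model_II"),
    total_energy_kcal_mol = c(-1, 1, 5, 5))
  fit <- gaussian_class_fit(class_energy_stats(tbl))
  no_et <- fit[fit$label == "no_ET", ]
  expect_equal(no_et$mean_kcal_mol, 0)
  expect_equal(no_et$sd_kcal_mol, sqrt(2))
  expect_equal(no_et$peak_density, 1 / sqrt(2 * pi * 2))
  expect_true(fit$degenerate[fit$label == "model_II"])
})

test_that("classification is exact on noiseless tables and robust at sd 0.1", {
  noiseless <- sim_spin_tables(40, 10, 20, 5, o2_spin_state = "down",
                               noise_sd = 0, seed = 61)
  cls <- classify_spin_snapshots(noiseless)
  truth <- attr(noiseless, "truth")
  acc <- mean(dplyr::inner_join(
    dplyr::select(tibble::as_tibble(cls), "snapshot_id", est = "label"),
    truth, by = "snapshot_id")$est ==
      dplyr::inner_join(
        dplyr::select(tibble::as_tibble(cls), "snapshot_id", est = "label"),
        truth, by = "snapshot_id")$label)
  expect_equal(acc, 1)

  noisy <- sim_spin_tables(500, 150, 300, 50, o2_spin_state = "up",
                           noise_sd = 0.1, seed = 62)
  cls2 <- classify_spin_snapshots(noisy)
  j <- dplyr::inner_join(
    dplyr::select(tibble::as_tibble(cls2), "snapshot_id", est = "label"),
    attr(noisy, "truth"), by = "snapshot_id")
  expect_gte(mean(j$est == j$label), 0.99)
})

test_that("within-snapshot spin changes balance for equal total spin", {
  tbl <- sim_spin_tables(30, 10, 10, 0, o2_spin_state = "down",
                         noise_sd = 0, seed = 63)
  cls <- classify_spin_snapshots(tbl)
  transferred <- cls$snapshot_id[cls$label %in% c("model_I", "model_II")]
  ref <- reference_mean_spins(
    dplyr::filter(tbl, .data$snapshot_id %in%
                    cls$snapshot_id[cls$label == "no_ET"]))
  ds <- delta_spin(dplyr::filter(tbl, .data$snapshot_id %in% transferred), ref)
  sums <- tapply(ds$delta_spin, ds$snapshot_id, sum)
  expect_lt(max(abs(sums)), 1e-8)
})

test_that("unconverged snapshots are dropped with a message", {
  tbl <- sim_spin_tables(10, 0, 5, 0, noise_sd = 0, seed = 64)
  tbl$converged[tbl$snapshot_id == tbl$snapshot_id[1]] <- FALSE
  expect_message(cls <- classify_spin_snapshots(tbl), "unconverged")
  expect_equal(attr(cls, "n_unconverged"), 1)
  expect_equal(nrow(cls), 14)
})
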