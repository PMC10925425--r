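test_that("exchangeable amide counting follows the HDX accounting rule", {
  expect_equal(count_exchangeable("GG"), 0L)
  expect_equal(count_exchangeable("GGGGG"), 3L)
  expect_equal(count_exchangeable("GPGPG"), 1L)
  expect_equal(count_exchangeable("P"), 0L)
  expect_error(count_exchangeable("GXZ"), "unknown")
})

test_that("peptide tables load and round-trip the simulator output exactly", {
  peps <- standard_peptides()
  tab <- simulate_hdx(peps, protection = 50, sigma = 0, be = 0, seed = 4)
  f <- tempfile(fileext = ".csv")
  write_peptide_table(tab, f)
  rec <- load_peptide_table(f, dialect = "uptake")
  expect_equal(nrow(rec), nrow(tab))
  truth <- attr(tab, "truth")$peptides
  curves <- uptake_curves(rec, be = 0)
  for (i in seq_along(curves)) {
    expect_equal(curves[[i]]$corrected_uptake, truth[[i]]$true_uptake,
                 tolerance = 1e-9)
  }
})

test_that("centroid dialect subtracts the undeuterated reference", {
  df <- data.frame(state = "s", start = 1L, end = 5L, sequence = "GGGGG",
                   exposure_min = rep(c(0, 1), each = 2), replicate = c(1:2, 1:2),
                   value = c(1000.0, 1000.0, 1001.5, 1001.5))
  f <- tempfile(fileext = ".csv")
  utils::write.csv(df, f, row.names = FALSE, quote = FALSE)
  rec <- load_peptide_table(f, dialect = "centroid")
  expect_equal(rec$uptake[rec$exposure_min == 0], c(0, 0))
  expect_equal(rec$uptake[rec$exposure_min == 1], c(1.5, 1.5))
  # same centroid as reference -> zero uptake
  df$value <- 1000
  utils::write.csv(df, f, row.names = FALSE, quote = FALSE)
  expect_true(all(load_peptide_table(f, "centroid")$uptake == 0))
  # a peptide without a 0 min reference is an error naming it
  df2 <- df[df$exposure_min > 0, ]
  utils::write.csv(df2, f, row.names = FALSE, quote = FALSE)
  expect_error(load_peptide_table(f, "centroid"), "0 min")
})

test_that("back-exchange correction is exact and round-trips", {
  curve <- structure(list(state = "s", start = 1L, end = 8L,
                          sequence = "GGGGGGGG", times = c(0.5, 1),
                          mean_uptake = c(1.5, 3), sd = c(0.1, 0.2),
                          corrected_uptake = c(1.5, 3), corrected_sd = c(0.1, 0.2),
                          n_exchangeable = 6L, n_replicates = c(3L, 3L),
                          be = 0, soft_violation = FALSE),
                     class = "uptake_curve")
  c0 <- correct_back_exchange(curve, 0)
  expect_equal(c0$corrected_uptake, curve$mean_uptake)
  c25 <- correct_back_exchange(curve, 0.25)
  expect_equal(c25$corrected_uptake[1], 2.0)     # 1.5 / 0.75
  expect_equal(c25$corrected_sd, curve$sd / 0.75)
  # forward application of BE is the identity
  expect_equal(c25$corrected_uptake * (1 - 0.25), curve$mean_uptake,
               tolerance = 1e-12)
  expect_error(correct_back_exchange(curve, 1), "\\[0, 1\\)")
})

test_that("corrected uptake recovers truth and respects the exchangeable bound", {
  peps <- standard_peptides()
  tab <- simulate_hdx(peps, protection = 20, sigma = 0.05, be = 0.25, seed = 8)
  curves <- uptake_curves(tab, be = 0.25)
  truth <- attr(tab, "truth")$peptides
  for (i in seq_along(curves)) {
    sem <- 0.05 / sqrt(3) / (1 - 0.25)
    expect_true(all(abs(curves[[i]]$corrected_uptake - truth[[i]]$true_uptake)
                    <= 3 * sem + 1e-9))
  }
  # noiseless: corrected never exceeds the exchangeable count
  tab0 <- simulate_hdx(peps, protection = 1, sigma = 0, be = 0.25, seed = 1)
  for (cv in uptake_curves(tab0, be = 0.25)) {
    expect_true(all(cv$corrected_uptake <= cv$n_exchangeable + 1e-9))
    expect_false(cv$soft_violation)
  }
})

test_that("identical replicate sets compare as non-significant with p = 1", {
  pep <- standard_peptides()[1, ]
  t1 <- simulate_hdx(pep, protection = 10, sigma = 0.05, state = "s1", seed = 5)
  t2 <- t1; t2$state <- "s2"
  cmp <- compare_states(rbind(t1, t2))
  expect_true(all(abs(cmp$per_time$p - 1) < 1e-9))
  expect_false(cmp$significant)
  expect_true(all(abs(cmp$per_time$diff_corrected) < 1e-12))
})

test_that("state comparison has power at large protection differences and controls type I", {
  pep <- standard_peptides()[1, ]
  n <- 60
  hits_alt <- hits_null <- logical(n)
  for (i in seq_len(n)) {
    a <- simulate_hdx(pep, protection = 5, sigma = 0.05, state = "s1",
                      seed = 10000 + i)
    b <- simulate_hdx(pep, protection = 500, sigma = 0.05, state = "s2",
                      seed = 20000 + i)
    hits_alt[i] <- compare_states(rbind(a, b))$significant
    b0 <- simulate_hdx(pep, protection = 5, sigma = 0.05, state = "s2",
                       seed = 30000 + i)
    hits_null[i] <- compare_states(rbind(a, b0))$significant
  }
  expect_gte(mean(hits_alt), 0.95)
  expect_lte(mean(hits_null), 0.10 + 0.05)  # small-n binomial slack
})

test_that("mismatched exposure grids are rejected", {
  pep <- standard_peptides()[1, ]
  a <- simulate_hdx(pep, state = "s1", seed = 1)
  b <- simulate_hdx(pep, state = "s2", times = c(0, 1, 2, 5, 10), seed = 2)
  expect_error(compare_states(rbind(a, b)), "grids differ")
})

test_that("equilibration fits recover rate and t95 on noiseless curves", {
  pep <- data.frame(start = 1L, end = 8L, sequence = "GAGAGAGA")
  # k_int / P = 2 per minute; plateau = 6 exchangeable amides
  tab <- simulate_hdx(pep, protection = 5, k_int = 10, sigma = 0, be = 0,
                      times = c(0, 0.25, 0.5, 1, 2, 4), seed = 1)
  eq <- equilibration_time(uptake_curves(tab, be = 0)[[1]])
  expect_true(eq$reliable)
  expect_equal(eq$rate, 2, tolerance = 0.01)
  expect_equal(eq$t95, log(20) / 2, tolerance = 0.01)
  expect_equal(eq$plateau, 6, tolerance = 0.05)
})

test_that("flat and truncated curves are flagged unreliable, not errors", {
  pep <- data.frame(start = 1L, end = 8L, sequence = "GAGAGAGA")
  tab <- simulate_hdx(pep, protection = 1e9, sigma = 0, be = 0, seed = 1)
  eq <- equilibration_time(uptake_curves(tab, be = 0)[[1]])
  expect_false(eq$reliable)
  # window far shorter than 1/rate: plateau cannot be approached
  slow <- simulate_hdx(pep, protection = 500, k_int = 10, sigma = 0, be = 0,
                       seed = 1)
  eq2 <- equilibration_time(uptake_curves(slow, be = 0)[[1]])
  expect_false(eq2$reliable)
})

test_that("t95 ordering separates fast from slow states under noise", {
  pep <- data.frame(start = 1L, end = 8L, sequence = "GAGAGAGA")
  ok <- logical(40)
  for (i in seq_along(ok)) {
    fast <- simulate_hdx(pep, protection = 10 / 3, k_int = 10, sigma = 0.05,
                         be = 0, seed = 500 + i)     # rate 3 /min
    slow <- simulate_hdx(pep, protection = 10 / 0.3, k_int = 10, sigma = 0.05,
                         be = 0, seed = 900 + i)     # rate 0.3 /min
    tf <- equilibration_time(uptake_curves(fast, be = 0)[[1]])$t95
    ts <- equilibration_time(uptake_curves(slow, be = 0)[[1]])$t95
    ok[i] <- is.finite(tf) && is.finite(ts) && tf < ts
  }
  expect_gte(mean(ok), 0.99)
})

test_that("uptake maps flag active-site peptides and average overlapping coverage", {
  peps <- standard_peptides()
  tab <- simulate_hdx(peps, protection = 10, sigma = 0, be = 0.25, seed = 2)
  curves <- uptake_curves(tab, be = 0.25)
  mapd <- map_uptake_to_structure(curves, shell = c(212L, 310L))
  expect_true(mapd$peptides$active_site[1])    # 210-216 contains 212
  expect_false(any(mapd$peptides$active_site[2:3]))
  # overlapping peptides: add a second peptide covering 210-216's tail
  over <- data.frame(start = 214L, end = 220L, sequence = "AAAAAAA")
  tab2 <- simulate_hdx(rbind(peps[1, ], over), protection = 10, sigma = 0,
                       be = 0.25, seed = 3)
  cv2 <- uptake_curves(tab2, be = 0.25)
  m2 <- map_uptake_to_structure(cv2, shell = integer(0))
  t5 <- m2$residues[m2$residues$time == 5, ]
  both <- t5[t5$residue == 215, ]
  expect_equal(both$n_peptides, 2)
  expect_equal(both$uptake,
               mean(c(cv2[[1]]$corrected_uptake[5], cv2[[2]]$corrected_uptake[5])))
  # peptide beyond the structure numbering is excluded and flagged
  m3 <- map_uptake_to_structure(cv2, shell = integer(0), max_residue = 216)
  expect_true(m3$peptides$excluded[2])
  expect_false(any(m3$residues$residue > 216))
})
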