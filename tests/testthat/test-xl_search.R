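test_that("candidate enumeration finds exactly the planted pair", {
  targets <- c(p1 = "AAKAAASSSR", p2 = "GGGKGGTTR")
  db <- build_database(targets,
                       params = digest_params(min_len = 4, max_len = 50))
  idx <- index_peptides(db)
  i <- which(idx$sequence == "AAKAAASSSR" & !idx$is_decoy)[1]
  j <- which(idx$sequence == "GGGKGGTTR" & !idx$is_decoy)[1]
  target_mass <- idx$mass[i] + idx$mass[j] + mass_constants()$bs3_xlink_delta
  hits <- candidate_pairs(idx, target_mass, tol_ppm = 10)
  # the planted combination is among the hits and every hit is mass-correct
  expect_true(any((hits$iA == min(i, j) & hits$iB == max(i, j))))
  expect_true(all(abs(hits$pair_mass - target_mass) <=
                    target_mass * 10e-6))
  # a perturbed precursor at (near-)zero tolerance matches nothing
  expect_identical(nrow(candidate_pairs(idx, target_mass + 0.5,
                                        tol_ppm = 1e-6)), 0L)
})

test_that("candidate counts equal brute-force pair enumeration", {
  withr::with_seed(33, {
    for (rep in 1:5) {
      targets <- c(pA = random_protein(60, sample.int(1e6, 1)))
      db <- build_database(targets, params = digest_params(min_len = 4))
      idx <- index_peptides(db)
      idx <- idx[seq_len(min(nrow(idx), 30L)), ]
      attr(idx, "proteins") <- attr(db, "proteins")
      ld <- mass_constants()$bs3_xlink_delta
      masses <- runif(4, 1500, 4000)
      for (M in masses) {
        got <- nrow(candidate_pairs(idx, M, tol_ppm = 50, linker_delta = ld))
        tol <- M * 50e-6
        brute <- 0L
        for (a in seq_len(nrow(idx))) for (b in a:nrow(idx))
          if (abs(idx$mass[a] + idx$mass[b] + ld - M) <= tol)
            brute <- brute + 1L
        expect_identical(got, brute)
      }
    }
  })
})

test_that("assumed charges follow the declared-charge rule", {
  pk <- data.frame(mz = 500, intensity = 1)
  p <- search_params()
  expect_identical(assumed_charges(spectrum_record("s", 800, 1L, pk), p), 1L)
  expect_identical(assumed_charges(spectrum_record("s", 800, NA, pk), p),
                   c(2L, 3L))
  expect_identical(assumed_charges(spectrum_record("s", 800, 4L, pk), p), 4L)
})

test_that("a complete noiseless spectrum scores every theoretical ion", {
  x <- example_xl_pair()
  z <- 4L
  theo <- fragment_ions(x, max_fragment_charge = 2L)
  s <- spectrum_record("full", precursor_mz(pair_mass(x), z), z,
                       data.frame(mz = theo$mz, intensity = 1000))
  sc <- match_spectrum(s, x, z, search_params(perm_seed = 1))
  expect_identical(sc$score, sc$n_theoretical)
  # pp is at its maximum for this N: any lower score gives a smaller pp
  p <- search_params(perm_seed = 1)
  expect_gt(sc$pp, 0)
  # empty spectrum: all scores zero
  s0 <- spectrum_record("empty", precursor_mz(pair_mass(x), z), z,
                        data.frame(mz = numeric(), intensity = numeric()))
  sc0 <- match_spectrum(s0, x, z, p)
  expect_identical(c(sc0$score, sc0$pp, sc0$pp2), c(0, 0, 0))
})

test_that("pp is monotone in score and its null p-value is not anti-conservative", {
  # monotonicity: same N and p_rand, increasing matched count
  N <- 60; p_rand <- 0.03
  pp <- -pbinom(0:20 - 1, N, p_rand, lower.tail = FALSE, log.p = TRUE) / log(10)
  expect_true(all(diff(pp) > 0))
  # null simulation: uniform random peak lists should give binomial tail
  # p-values stochastically no smaller than uniform
  x <- example_xl_pair()
  z <- 4L
  prm <- search_params(perm_seed = 1, n_perm = 10)
  pvals <- withr::with_seed(77, {
    vapply(1:500, function(k) {
      peaks <- data.frame(mz = runif(80, 300, 1650),
                          intensity = rlnorm(80, 7, 1))
      sc <- match_spectrum(spectrum_record("n", precursor_mz(pair_mass(x), z),
                                           z, peaks), x, z, prm)
      10^(-sc$pp)
    }, 0)
  })
  # at most ~5% below 0.05 (allow 3 binomial SDs: 0.05 + 3*sqrt(.05*.95/500))
  expect_lte(mean(pvals < 0.05), 0.08)
})

test_that("planted cross-linked pairs are recovered as top PSMs", {
  world <- planted_search_world(n_pairs = 5L, seed = 2L)
  sim <- make_xl_spectra(world$pairs, coverage = 0.8, n_noise = 40,
                         charge = 4L, declare_charge = TRUE, seed = 3L)
  psms <- run_search(sim$spectra, world$db, search_params(perm_seed = 5))
  expect_identical(nrow(psms), 5L)
  expect_identical(n_recovered(psms, sim$truth), 5L)
  expect_false(any(psms$decoy))
  # shuffling spectrum order leaves the PSM set unchanged
  psms2 <- run_search(rev(sim$spectra), world$db, search_params(perm_seed = 5))
  expect_identical(psms[order(psms$spectrum_id), ],
                   psms2[order(psms2$spectrum_id), ])
})

test_that("spectra matching nothing are absent from PSMs but counted", {
  world <- planted_search_world(n_pairs = 2L, seed = 4L)
  sim <- make_xl_spectra(world$pairs, coverage = 0, n_noise = 10,
                         charge = 4L, declare_charge = TRUE, seed = 6L)
  psms <- run_search(sim$spectra, world$db, search_params(perm_seed = 5))
  expect_identical(nrow(psms), 0L)
  rep <- attr(psms, "report")
  expect_identical(rep$n_no_candidate + rep$n_below_threshold, 2L)
})

test_that("the worked-example pair outranks reversed-decoy candidates", {
  targets <- c(sGCa_frag = "YCLFGNNVTLANKFESCSVPR", sGCb_frag = "TETTGEKGK")
  db <- build_database(targets, decoy_mode = "reversed",
                       params = digest_params(min_len = 6, max_len = 50,
                                              max_missed = 2))
  x <- example_xl_pair()
  theo <- fragment_ions(x, max_fragment_charge = 2L)
  s <- spectrum_record("fig_pair", precursor_mz(pair_mass(x), 4L), 4L,
                       data.frame(mz = theo$mz, intensity = 1000))
  psms <- run_search(list(s), db, search_params(perm_seed = 1))
  expect_identical(nrow(psms), 1L)
  expect_false(psms$decoy)
  expect_setequal(c(psms$pepA, psms$pepB),
                  c("YCLFGNNVTLANKFESCSVPR", "TETTGEKGK"))
  expect_setequal(c(psms$posA, psms$posB), c(13L, 7L))
})

test_that("decoy FDR table is monotone and handles degenerate inputs", {
  psms <- data.frame(score = c(10, 9, 8, 7, 6, 5, 4, 3),
                     decoy = c(FALSE, FALSE, FALSE, TRUE, FALSE, TRUE, TRUE,
                               TRUE))
  tab <- decoy_fdr(psms)
  expect_true(all(diff(tab$n_target) <= 0))
  expect_true(all(diff(tab$n_decoy) <= 0))
  expect_equal(tab$fdr[tab$cutoff == 3], 4 / 4)
  # all-decoy input: FDR undefined (no targets)
  tab2 <- decoy_fdr(data.frame(score = c(5, 6), decoy = TRUE))
  expect_true(all(is.na(tab2$fdr)))
  # no decoys: warning and zero FDR
  expect_warning(tab3 <- decoy_fdr(data.frame(score = c(5, 6),
                                              decoy = FALSE)), "no decoy")
  expect_true(all(tab3$fdr == 0))
  expect_true(attr(tab3, "no_decoys"))
})

test_that("equal target and decoy score distributions give FDR near 1 at low cutoffs", {
  withr::with_seed(55, {
    fdrs <- vapply(1:20, function(k) {
      sc <- rnorm(200, 10, 2)
      psms <- data.frame(score = sc, decoy = rep(c(FALSE, TRUE), 100))
      decoy_fdr(psms, cutoffs = min(sc))$fdr
    }, 0)
    expect_equal(mean(fdrs), 1, tolerance = 0.05)
  })
})

test_that("MGF round trip preserves spectra", {
  world <- planted_search_world(n_pairs = 2L, seed = 8L)
  sim <- make_xl_spectra(world$pairs, coverage = 0.5, n_noise = 20,
                         charge = 3L, declare_charge = TRUE, seed = 9L)
  f <- withr::local_tempfile(fileext = ".mgf")
  write_mgf(sim$spectra, f)
  back <- read_mgf(f)
  expect_identical(length(back), 2L)
  for (k in 1:2) {
    expect_identical(back[[k]]$id, sim$spectra[[k]]$id)
    expect_identical(back[[k]]$charge, sim$spectra[[k]]$charge)
    expect_equal(back[[k]]$precursor_mz, sim$spectra[[k]]$precursor_mz,
                 tolerance = 1e-5)
    expect_equal(back[[k]]$peaks$mz, sim$spectra[[k]]$peaks$mz,
                 tolerance = 1e-5)
  }
})
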