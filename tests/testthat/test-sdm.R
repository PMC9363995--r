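test_that("bioclim layers reduce constant climates exactly", {
  n <- 4
  g <- climate_grid(lat = c(30.5, 29.5), lon = c(100.5, 101.5),
                    tmax_c = matrix(25, 12, n), tmin_c = matrix(15, 12, n),
                    precip_mm = matrix(100, 12, n))
  b <- compute_bioclim(g)
  expect_equal(b$bio1, rep(20, n))
  expect_equal(b$bio5, rep(25, n))
  expect_equal(b$bio6, rep(15, n))
  expect_equal(b$bio12, rep(1200, n))
  expect_equal(b$bio18, rep(300, n))
})

test_that("bioclim layers are shift-equivariant under uniform warming", {
  g <- tiny_grid(noise = 1, seed = 2)
  b0 <- compute_bioclim(g)
  b2 <- compute_bioclim(apply_warming_scenario(g, warming_scenario(2)))
  for (nm in c("bio1", "bio5", "bio6"))
    expect_equal(b2[[nm]], b0[[nm]] + 2, tolerance = 1e-12)
  expect_equal(b2$bio12, b0$bio12, tolerance = 1e-12)
})

test_that("warmest-quarter precipitation matches an exhaustive cyclic scan", {
  set.seed(31)
  for (rep in 1:100) {
    tmean <- runif(12, -5, 30)
    prec <- runif(12, 0, 200)
    g <- climate_grid(lat = 25.5, lon = 100.5,
                      tmax_c = matrix(tmean + 5, 12, 1),
                      tmin_c = matrix(tmean - 5, 12, 1),
                      precip_mm = matrix(prec, 12, 1))
    # independent oracle: explicit scan over the 12 cyclic quarters
    best <- -Inf; best_p <- NA
    for (m in 1:12) {
      idx <- ((m - 1):(m + 1)) %% 12 + 1
      if (mean(tmean[idx]) > best) {
        best <- mean(tmean[idx]); best_p <- sum(prec[idx])
      }
    }
    expect_equal(compute_bioclim(g)$bio18, best_p, tolerance = 1e-12)
  }
})

test_that("spatial thinning enforces the minimum distance", {
  # two points ~5 arc-minutes apart: only one survives a 10' threshold
  occ <- occurrence_set(data.frame(lon = c(100, 100), lat = c(25, 25 + 5 / 60)))
  th <- thin_occurrences(occ, 10, seed = 1)
  expect_equal(nrow(th$records), 1L)
  # widely separated points are untouched
  occ2 <- occurrence_set(data.frame(lon = c(100, 101, 102), lat = c(25, 26, 24)))
  expect_equal(nrow(thin_occurrences(occ2, 10, seed = 1)$records), 3L)
  # empty input passes through
  expect_equal(nrow(thin_occurrences(
    occurrence_set(data.frame(lon = numeric(0), lat = numeric(0))), 10)$records), 0L)
})

test_that("randomized thinning is bounded by the exhaustive optimum", {
  mis_size <- function(d, thr) {
    n <- nrow(d)
    best <- 0
    for (mask in 0:(2^n - 1)) {
      idx <- which(bitwAnd(mask, 2^(0:(n - 1))) > 0)
      if (length(idx) <= best) next
      if (all(d[idx, idx][upper.tri(diag(length(idx)))] >= thr))
        best <- length(idx)
    }
    best
  }
  set.seed(17)
  for (rep in 1:5) {
    n <- 10
    pts <- data.frame(lon = 100 + runif(n, 0, 0.5), lat = 25 + runif(n, 0, 0.5))
    occ <- occurrence_set(pts)
    d <- geosphere::distm(as.matrix(pts)) / 1852
    opt <- mis_size(d, 10)
    got <- nrow(thin_occurrences(occ, 10, seed = rep)$records)
    greedy1 <- nrow(thin_occurrences(occ, 10, seed = rep, restarts = 0)$records)
    expect_lte(got, opt)
    expect_gte(got, greedy1)
    # retained set respects the distance constraint
    kept <- thin_occurrences(occ, 10, seed = rep)$records
    dk <- geosphere::distm(as.matrix(kept[, c("lon", "lat")])) / 1852
    expect_true(all(dk[upper.tri(dk)] >= 10))
  }
})

test_that("pseudo-absences exhaust the complement and avoid presences", {
  g <- tiny_grid()
  st <- hybrid_stack(g)
  co <- grid_coords(g)
  pres_cells <- 1:10
  occ <- occurrence_set(data.frame(lon = co$lon[pres_cells],
                                   lat = co$lat[pres_cells]))
  n_free <- ectoclim:::n_cells(g) - 10
  pa <- generate_pseudo_absences(st, occ, n = n_free, seed = 1)
  expect_setequal(pa, setdiff(seq_len(ectoclim:::n_cells(g)), pres_cells))
  pa2 <- generate_pseudo_absences(st, occ, n = 20, seed = 2)
  expect_length(intersect(pa2, pres_cells), 0)
  expect_error(generate_pseudo_absences(st, occ, n = n_free + 1), "exceeds")
})

test_that("pseudo-absence draws are uniform over eligible cells", {
  g <- generate_monthly_climate(list(lat_min = 30, lat_max = 35,
                                     lon_min = 100, lon_max = 110), 60)
  st <- hybrid_stack(g)
  co <- grid_coords(g)
  occ <- occurrence_set(data.frame(lon = co$lon[1], lat = co$lat[1]))
  n_elig <- ectoclim:::n_cells(g) - 1
  draws <- 2000L; k <- 10L
  counts <- integer(ectoclim:::n_cells(g))
  for (s in seq_len(draws)) {
    pa <- generate_pseudo_absences(st, occ, n = k, seed = s)
    counts[pa] <- counts[pa] + 1L
  }
  p <- k / n_elig
  sigma <- sqrt(draws * p * (1 - p))
  expect_true(all(abs(counts[-1] - draws * p) <= 3 * sigma + 1))
  expect_equal(counts[1], 0L)
})

test_that("AUC is the tie-aware rank probability", {
  expect_equal(auc_score(c(0.9, 0.4), c(0.6, 0.2)), 0.75)
  expect_equal(auc_score(c(0.8, 0.9), c(0.1, 0.2)), 1)
  expect_equal(auc_score(c(0.5, 0.3), c(0.5, 0.3)), 0.5)
  expect_error(auc_score(numeric(0), 1), "non-empty")
  # brute-force pairwise oracle
  set.seed(5)
  for (rep in 1:100) {
    p <- round(runif(sample(3:20, 1)), 2)
    a <- round(runif(sample(3:20, 1)), 2)
    wins <- outer(p, a, function(x, y) (x > y) + 0.5 * (x == y))
    expect_equal(auc_score(p, a), mean(wins), tolerance = 1e-12)
  }
})

test_that("max-TSS scan equals exhaustive grid evaluation", {
  ts <- tss_max_threshold(c(0.8, 0.9), c(0.1, 0.2))
  expect_equal(ts$tss_max, 1)
  set.seed(6)
  for (rep in 1:100) {
    # scores on a 0.01 lattice so the 0.001 oracle grid resolves every step
    p <- round(runif(sample(3:30, 1)), 2); a <- round(runif(sample(3:30, 1)), 2)
    got <- tss_max_threshold(p, a)
    grid <- seq(0, 1, by = 0.001)
    tss_grid <- vapply(grid, function(th)
      mean(p >= th) + mean(a < th) - 1, numeric(1))
    expect_equal(got$tss_max, max(tss_grid), tolerance = 1e-12)
    # returned threshold attains the maximum
    expect_equal(mean(p >= got$threshold) + mean(a < got$threshold) - 1,
                 got$tss_max, tolerance = 1e-12)
  }
})

test_that("TSS member weighting keeps survivors in proportion", {
  w <- ectoclim:::tss_weights(c(0.7, 0.65, 0.55), cutoff = 0.6)
  expect_equal(w$kept, c(1L, 2L))
  expect_equal(w$weights, c(0.7, 0.65) / 1.35, tolerance = 1e-12)
  expect_equal(sum(w$weights), 1, tolerance = 1e-12)
  single <- ectoclim:::tss_weights(c(0.3, 0.8), cutoff = 0.6)
  expect_equal(single$weights, 1)
  expect_error(ectoclim:::tss_weights(c(0.2, 0.3), 0.6), "no ensemble")
})

test_that("a trained ensemble honours its structural contracts", {
  g <- tiny_grid(noise = 1.5, seed = 9, res = 60, precip_noise_sd = 0.2)
  tr <- default_traits()
  st <- hybrid_stack(g)
  vsp <- virtual_species(tr, list(
    bio1 = list(type = "gaussian",
                optimum = mean(range(st$layers$bio1)),
                breadth = diff(range(st$layers$bio1)) / 10)))
  truth <- true_suitability(vsp, st$layers)
  occ <- sample_occurrences(vsp, g, truth, n = 150, seed = 10)
  cfg <- list(learners = c("GLM", "MAXENT"), replicates = 2)
  ens <- train_ensemble(st, occ, cfg, seed = 11)
  expect_s3_class(ens, "sdm_ensemble")
  expect_equal(sum(ens$weights), 1, tolerance = 1e-12)
  expect_true(all(vapply(ens$members, `[[`, numeric(1), "tss") > 0.6))
  expect_true(all(ens$evaluation$auc >= 0 & ens$evaluation$auc <= 1))
  expect_true(ens$threshold >= 0 && ens$threshold <= 1)
  # determinism under a fixed seed
  ens2 <- train_ensemble(st, occ, cfg, seed = 11)
  expect_equal(ens2$evaluation, ens$evaluation, tolerance = 1e-12)
  expect_equal(predict_suitability(ens2, st)$suitability,
               predict_suitability(ens, st)$suitability, tolerance = 1e-12)

  # suitability: weighted mean of member scores, verified independently
  suit <- predict_suitability(ens, st)
  X <- ectoclim:::stack_matrix(st)[st$mask, ens$predictors, drop = FALSE]
  manual <- Reduce(`+`, Map(function(m, w)
    w * ectoclim:::member_scores(m, X), ens$members, ens$weights))
  expect_equal(suit$suitability[st$mask], pmin(1, pmax(0, manual)),
               tolerance = 1e-12)
  # bounded by the member score envelope
  scores <- vapply(ens$members, function(m) ectoclim:::member_scores(m, X),
                   numeric(nrow(X)))
  expect_true(all(suit$suitability[st$mask] <= apply(scores, 1, max) + 1e-9))
  expect_true(all(suit$suitability[st$mask] >= apply(scores, 1, min) - 1e-9))
  expect_error(predict_suitability(ens, predictor_stack(
    g, list(bio1 = st$layers$bio1))), "lacks layer")
})

test_that("unlearnable labels leave no ensemble members", {
  g <- tiny_grid(res = 90)
  st <- hybrid_stack(g)
  co <- grid_coords(g)
  set.seed(12)
  cells <- sample(ectoclim:::n_cells(g), 40)
  occ <- occurrence_set(data.frame(lon = co$lon[cells], lat = co$lat[cells]))
  # random presences carry no signal; every member should fail TSS > 0.6
  expect_error(train_ensemble(st, occ, list(learners = c("GLM", "MAXENT"),
                                            replicates = 2), seed = 13),
               "no ensemble")
})

test_that("binarization and latitude-weighted area change count correctly", {
  mk_map <- function(vals, lat = 0.5) {
    structure(list(suitability = vals, mask = rep(TRUE, length(vals)),
                   threshold = 0.5, grid_lat = lat,
                   grid_lon = seq(0.5, by = 1, length.out = length(vals)),
                   resolution_arcmin = 60), class = "suitability_map")
  }
  cur <- mk_map(c(rep(0.9, 40), rep(0.1, 20)))
  expect_equal(binarize_and_area_change(cur, cur)$percent_change, 0)
  gone <- mk_map(rep(0, 60))
  expect_equal(binarize_and_area_change(cur, gone)$percent_change, -100)
  fut <- mk_map(c(rep(0.9, 30), rep(0.1, 30)))
  expect_equal(binarize_and_area_change(cur, fut)$percent_change, -25)
  expect_error(binarize_and_area_change(gone, cur), "zero area")
  # higher-latitude cells weigh less
  hi <- structure(list(suitability = rep(1, 2), mask = c(TRUE, TRUE),
                       threshold = 0.5, grid_lat = c(60.5, 0.5),
                       grid_lon = 100.5, resolution_arcmin = 60),
                  class = "suitability_map")
  rc <- binarize_and_area_change(hi, hi)
  expect_equal(rc$area_current_km2,
               (60 * 1.852)^2 * (cos(60.5 * pi / 180) + cos(0.5 * pi / 180)))
})
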