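#' Five bioclimatic summary layers from monthly normals
#'
#' bio1 annual mean temperature; bio5 maximum temperature of the warmest
#' month; bio6 minimum temperature of the coldest month; bio12 annual
#' precipitation; bio18 precipitation of the warmest quarter (the cyclic
#' three-month window with the highest mean temperature; ties resolved to
#' the earliest starting month).
#'
#' @param grid a \code{\link{climate_grid}}.
#' @return named list of per-cell numeric vectors \code{bio1, bio5, bio6,
#'   bio12, bio18}.
#' @export
compute_bioclim <- function(grid) {
  tmean <- (grid$tmax_c + grid$tmin_c) / 2
  n <- ncol(tmean)
  q_t <- matrix(NA_real_, 12L, n)
  q_p <- matrix(NA_real_, 12L, n)
  for (m in 1:12) {
    idx <- ((m - 1L):(m + 1L)) %% 12L + 1L
    q_t[m, ] <- colMeans(tmean[idx, , drop = FALSE])
    q_p[m, ] <- colSums(grid$precip_mm[idx, , drop = FALSE])
  }
  warmest_q <- apply(q_t, 2L, which.max)  # first index on ties
  list(bio1 = colMeans(tmean),
       bio5 = apply(grid$tmax_c, 2L, max),
       bio6 = apply(grid$tmin_c, 2L, min),
       bio12 = colSums(grid$precip_mm),
       bio18 = q_p[cbind(warmest_q, seq_len(n))])
}

#' Predictor stack
#'
#' Named per-cell predictor layers sharing the geometry of a climate grid,
#' with a validity mask. The canonical hybrid stack holds the five bioclim
#' layers plus the biophysical layers \code{activity_h, max_mr, max_wl,
#' incubation_days, time_window_h}.
#'
#' @param grid the \code{climate_grid} supplying geometry.
#' @param layers named list of per-cell numeric vectors.
#' @param mask logical vector of valid cells (default: cells with no
#'   missing value in any layer).
#' @return object of class \code{predictor_stack}.
#' @export
predictor_stack <- function(grid, layers, mask = NULL) {
  n <- n_cells(grid)
  if (!length(layers) || is.null(names(layers)) ||
      anyDuplicated(names(layers)))
    stop("predictor_stack: layers must be uniquely named")
  for (nm in names(layers))
    if (length(layers[[nm]]) != n)
      stop("predictor_stack: layer '", nm, "' length != number of cells")
  if (is.null(mask))
    mask <- Reduce(`&`, lapply(layers, is.finite))
  if (length(mask) != n)
    stop("predictor_stack: mask length != number of cells")
  if (!any(mask)) stop("predictor_stack: empty mask")
  for (nm in names(layers))
    if (any(!is.finite(layers[[nm]][mask])))
      stop("predictor_stack: layer '", nm, "' has missing values inside the mask")
  structure(list(grid_lat = grid$lat, grid_lon = grid$lon,
                 resolution_arcmin = grid$resolution_arcmin,
                 layers = layers, mask = mask),
            class = "predictor_stack")
}

#' @export
print.predictor_stack <- function(x, ...) {
  cat(sprintf("predictor_stack: %d layers on %d x %d grid (%d masked-in cells)\n",
              length(x$layers), length(x$grid_lat), length(x$grid_lon),
              sum(x$mask)))
  cat("  layers:", paste(names(x$layers), collapse = ", "), "\n")
  invisible(x)
}

stack_matrix <- function(stack, cells = NULL) {
  m <- do.call(cbind, stack$layers)
  if (!is.null(cells)) m <- m[cells, , drop = FALSE]
  m
}

stack_as_grid_stub <- function(stack) {
  list(lat = stack$grid_lat, lon = stack$grid_lon,
       resolution_arcmin = stack$resolution_arcmin)
}

#' Build the hybrid predictor stack
#'
#' Convenience wrapper combining \code{\link{compute_bioclim}} with
#' biophysical layers from \code{\link{compute_biophysical_layers}}.
#'
#' @param grid a \code{climate_grid}.
#' @param bio_layers data.frame from \code{compute_biophysical_layers}
#'   (ordered by cell over all cells), or NULL for a climate-only stack.
#' @export
hybrid_stack <- function(grid, bio_layers = NULL) {
  layers <- compute_bioclim(grid)
  if (!is.null(bio_layers)) {
    stopifnot(nrow(bio_layers) == n_cells(grid))
    layers$activity_h <- bio_layers$activity_h_yr
    layers$max_mr <- bio_layers$max_mr_ml_o2_h
    layers$max_wl <- bio_layers$max_wl_g_h
    if (!is.null(bio_layers$incubation_days)) {
      layers$incubation_days <- bio_layers$incubation_days
      layers$time_window_h <- bio_layers$time_window_h
    }
  }
  predictor_stack(grid, layers)
}

#' Spatially thin occurrence records
#'
#' Greedy randomized thinning: records are visited in random order and kept
#' when at least \code{min_dist_arcmin} (great-circle) from every record
#' already kept; the best (largest) retained set over a fixed number of
#' restarts is returned, the first restart being the deterministic
#' input-order pass. Distances are measured in arc-minutes (1' = 1852 m).
#'
#' @param occ an \code{\link{occurrence_set}}.
#' @param min_dist_arcmin minimum pairwise distance (> 0).
#' @param seed integer seed (restart shuffles).
#' @param restarts number of randomized restarts (default 20).
#' @return a thinned \code{occurrence_set}.
#' @export
thin_occurrences <- function(occ, min_dist_arcmin = 10, seed = 1L,
                             restarts = 20L) {
  if (min_dist_arcmin <= 0) stop("thin_occurrences: min_dist must be > 0")
  rec <- occ$records
  n <- nrow(rec)
  if (n == 0L) return(occ)
  pts <- as.matrix(rec[, c("lon", "lat")])
  d_arcmin <- geosphere::distm(pts, fun = geosphere::distHaversine) / 1852
  greedy <- function(order) {
    kept <- integer(0)
    for (i in order)
      if (!length(kept) || all(d_arcmin[i, kept] >= min_dist_arcmin))
        kept <- c(kept, i)
    kept
  }
  best <- greedy(seq_len(n))
  set.seed(as.integer(seed))
  for (r in seq_len(restarts)) {
    cand <- greedy(sample.int(n))
    if (length(cand) > length(best)) best <- cand
  }
  occurrence_set(rec[sort(best), , drop = FALSE], occ$species_id)
}

#' Pseudo-absence generation (random background)
#'
#' Uniform random draw of cells from the valid mask, excluding cells that
#' contain a presence record ("random background" design).
#'
#' @param stack a \code{\link{predictor_stack}}.
#' @param presences an \code{occurrence_set}.
#' @param n number of pseudo-absence cells (must not exceed eligible cells).
#' @param seed integer seed.
#' @return integer vector of cell indices.
#' @export
generate_pseudo_absences <- function(stack, presences, n, seed = 1L) {
  if (n < 1) stop("generate_pseudo_absences: n must be >= 1")
  g <- stack_as_grid_stub(stack)
  pres_cells <- unique(cell_from_lonlat(g, presences$records$lon,
                                        presences$records$lat))
  eligible <- setdiff(which(stack$mask), pres_cells)
  if (n > length(eligible))
    stop("generate_pseudo_absences: n exceeds the ", length(eligible),
         " eligible cells")
  set.seed(as.integer(seed))
  sort(sample(eligible, n))
}

#' Area under the ROC curve (rank formulation)
#'
#' Probability that a randomly chosen presence outscores a randomly chosen
#' absence, ties counted one half (equivalent to the Mann-Whitney U
#' statistic).
#'
#' @param scores_presence,scores_absence numeric score vectors (non-empty).
#' @return AUC in [0, 1].
#' @export
auc_score <- function(scores_presence, scores_absence) {
  np <- length(scores_presence); na <- length(scores_absence)
  if (!np || !na) stop("auc_score: both score lists must be non-empty")
  r <- rank(c(scores_presence, scores_absence))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * na)
}

#' Maximum true skill statistic and its threshold
#'
#' Scans TSS(theta) = sensitivity + specificity - 1 over the midpoints of
#' sorted unique scores plus the endpoints 0 and 1 (prediction is presence
#' when score >= theta) and returns the maximum with the smallest threshold
#' attaining it.
#'
#' @param scores_presence,scores_absence numeric score vectors (non-empty).
#' @return list with \code{tss_max} and \code{threshold}.
#' @export
tss_max_threshold <- function(scores_presence, scores_absence) {
  if (!length(scores_presence) || !length(scores_absence))
    stop("tss_max_threshold: both score lists must be non-empty")
  s <- sort(unique(c(scores_presence, scores_absence)))
  cand <- sort(unique(c(0, 1, if (length(s) > 1L) (s[-1L] + s[-length(s)]) / 2)))
  tss <- vapply(cand, function(th)
    mean(scores_presence >= th) + mean(scores_absence < th) - 1, numeric(1))
  i <- which.max(tss)  # which.max returns the first (smallest threshold)
  list(tss_max = tss[i], threshold = cand[i])
}

# members with TSS strictly above the cutoff, weighted proportionally to TSS
tss_weights <- function(tss, cutoff) {
  kept <- which(tss > cutoff)
  if (!length(kept))
    stop("no ensemble — every member TSS <= ", cutoff)
  list(kept = kept, weights = tss[kept] / sum(tss[kept]))
}

## ---- learner plugins -------------------------------------------------
## Each learner takes a standardized design matrix and a 0/1 response and
## returns an object whose predict method emits scores in [0, 1]. The five
## slots mirror the conventional correlative-SDM algorithm families.

fit_learner <- function(learner_id, x, y, seed) {
  set.seed(as.integer(seed))
  obj <- switch(
    learner_id,
    GLM = {
      df <- as.data.frame(x)
      df2 <- cbind(df, setNames(as.data.frame(x^2), paste0(colnames(x), "_sq")))
      df2$.y <- y
      suppressWarnings(stats::glm(.y ~ ., family = stats::binomial(),
                                  data = df2))
    },
    GBM = {
      xgboost::xgboost(x, factor(y, levels = c(0, 1)), nrounds = 100L,
                       max_depth = 3L, learning_rate = 0.1,
                       nthreads = 1L, verbosity = 0L)
    },
    MAXENT = {
      # exponential-family presence/background density: ridge-regularized
      # logistic regression on linear + quadratic features
      feat <- cbind(x, x^2)
      colnames(feat) <- c(colnames(x), paste0(colnames(x), "_sq"))
      glmnet::glmnet(feat, y, family = "binomial", alpha = 0,
                     lambda = 0.01, standardize = FALSE)
    },
    RF = {
      df <- as.data.frame(x)
      df$.y <- factor(y, levels = c(0, 1))
      ranger::ranger(.y ~ ., data = df, num.trees = 300L,
                     probability = TRUE, seed = as.integer(seed),
                     num.threads = 1L)
    },
    SVM = {
      e1071::svm(x, factor(y, levels = c(0, 1)), kernel = "radial",
                 probability = TRUE)
    },
    stop("fit_learner: unknown learner '", learner_id, "'"))
  list(learner_id = learner_id, fit = obj, vars = colnames(x))
}

predict_learner <- function(model, x) {
  x <- x[, model$vars, drop = FALSE]
  p <- switch(
    model$learner_id,
    GLM = {
      df <- as.data.frame(x)
      df2 <- cbind(df, setNames(as.data.frame(x^2), paste0(colnames(x), "_sq")))
      # collinear predictors (routine in bioclim stacks) make the fit
      # rank-deficient; predictions remain well-defined via pivoting
      suppressWarnings(
        as.numeric(stats::predict(model$fit, newdata = df2,
                                  type = "response")))
    },
    GBM = as.numeric(stats::predict(model$fit, x)),  # P(class "1")
    MAXENT = {
      feat <- cbind(x, x^2)
      colnames(feat) <- c(colnames(x), paste0(colnames(x), "_sq"))
      as.numeric(stats::predict(model$fit, feat, type = "response"))
    },
    RF = as.numeric(stats::predict(model$fit, as.data.frame(x))$predictions[, "1"]),
    SVM = {
      pr <- stats::predict(model$fit, x, probability = TRUE)
      as.numeric(attr(pr, "probabilities")[, "1"])
    },
    stop("predict_learner: unknown learner"))
  pmin(1, pmax(0, p))
}

#' Train a TSS-weighted hybrid-SDM ensemble
#'
#' Builds a presence / pseudo-absence design on the predictor stack
#' (collapsing presences to one record per cell), then for each learner and
#' replicate fits on a stratified random 70% of the design (predictors
#' standardized to the training split's mean and variance) and evaluates AUC
#' and maximum TSS on the held-out 30%. Members whose TSS does not exceed
#' the cutoff (default 0.6) are discarded; survivors are weighted
#' proportionally to TSS (weights sum to 1). The ensemble's binarization
#' threshold is the max-TSS threshold of the survivors' pooled out-of-sample
#' scores.
#'
#' @param stack a \code{\link{predictor_stack}}.
#' @param presences an \code{\link{occurrence_set}} (>= 20 cells after
#'   collapsing).
#' @param config list of settings: \code{learners} (default all five
#'   families), \code{replicates} (5), \code{train_fraction} (0.7),
#'   \code{tss_cutoff} (0.6), \code{pa_multiplier} (10).
#' @param seed integer seed controlling pseudo-absences, splits and learner
#'   randomness.
#' @return object of class \code{sdm_ensemble}: \code{members} (each with
#'   learner_id, replicate, auc, tss, threshold_at_max_tss, scaler, fit),
#'   \code{weights}, \code{tss_cutoff}, \code{threshold},
#'   \code{evaluation} (data.frame over all fitted members).
#' @export
train_ensemble <- function(stack, presences, config = list(), seed = 1L) {
  cfg <- utils::modifyList(
    list(learners = c("GLM", "GBM", "MAXENT", "RF", "SVM"),
         replicates = 5L, train_fraction = 0.7, tss_cutoff = 0.6,
         pa_multiplier = 10L),
    config)
  if (length(cfg$learners) < 2L)
    stop("train_ensemble: need at least two learners")
  g <- stack_as_grid_stub(stack)
  pres_cells <- unique(stats::na.omit(
    cell_from_lonlat(g, presences$records$lon, presences$records$lat)))
  pres_cells <- pres_cells[stack$mask[pres_cells]]
  if (length(pres_cells) < 20L)
    stop("train_ensemble: fewer than 20 presence cells after collapsing")
  n_pa <- min(cfg$pa_multiplier * length(pres_cells),
              sum(stack$mask) - length(pres_cells))
  pa_cells <- generate_pseudo_absences(
    stack, occurrence_set(data.frame(
      lon = rep(stack$grid_lon, times = length(stack$grid_lat)),
      lat = rep(stack$grid_lat, each = length(stack$grid_lon)))[pres_cells, ],
      presences$species_id),
    n = n_pa, seed = seed)

  cells <- c(pres_cells, pa_cells)
  y <- c(rep(1L, length(pres_cells)), rep(0L, length(pa_cells)))
  X <- stack_matrix(stack, cells)

  members <- list()
  eval_rows <- list()
  pooled_p <- numeric(0); pooled_a <- numeric(0)
  for (r in seq_len(cfg$replicates)) {
    split_seed <- as.integer(seed) + 7919L * r
    set.seed(split_seed)
    n_tr <- function(k) min(k - 1L, max(1L, round(cfg$train_fraction * k)))
    tr_idx <- c(sample(which(y == 1L), n_tr(sum(y == 1L))),
                sample(which(y == 0L), n_tr(sum(y == 0L))))
    te_idx <- setdiff(seq_along(y), tr_idx)
    mu <- colMeans(X[tr_idx, , drop = FALSE])
    sdv <- apply(X[tr_idx, , drop = FALSE], 2L, stats::sd)
    sdv[sdv == 0] <- 1
    scale_m <- function(m) sweep(sweep(m, 2L, mu), 2L, sdv, `/`)
    Xtr <- scale_m(X[tr_idx, , drop = FALSE])
    Xte <- scale_m(X[te_idx, , drop = FALSE])
    for (li in seq_along(cfg$learners)) {
      lid <- cfg$learners[li]
      fit <- fit_learner(lid, Xtr, y[tr_idx],
                         seed = split_seed + 131L * li)
      sc <- predict_learner(fit, Xte)
      sp <- sc[y[te_idx] == 1L]; sa <- sc[y[te_idx] == 0L]
      auc <- auc_score(sp, sa)
      ts <- tss_max_threshold(sp, sa)
      members[[length(members) + 1L]] <- list(
        learner_id = lid, replicate = r, auc = auc, tss = ts$tss_max,
        threshold_at_max_tss = ts$threshold, scaler = list(mu = mu, sd = sdv),
        model = fit, scores_presence = sp, scores_absence = sa)
      eval_rows[[length(eval_rows) + 1L]] <- data.frame(
        learner = lid, replicate = r, auc = auc, tss = ts$tss_max,
        threshold = ts$threshold, kept = ts$tss_max > cfg$tss_cutoff)
    }
  }
  evaluation <- do.call(rbind, eval_rows)
  tw <- tss_weights(evaluation$tss, cfg$tss_cutoff)
  members <- members[tw$kept]
  weights <- tw$weights
  for (m in members) {
    pooled_p <- c(pooled_p, m$scores_presence)
    pooled_a <- c(pooled_a, m$scores_absence)
  }
  pooled <- tss_max_threshold(pooled_p, pooled_a)
  structure(list(members = members, weights = weights,
                 tss_cutoff = cfg$tss_cutoff, threshold = pooled$threshold,
                 predictors = colnames(X), evaluation = evaluation,
                 design = list(cells = cells, y = y)),
            class = "sdm_ensemble")
}

#' Out-of-sample AUC of the weighted ensemble
#'
#' Within each replicate every learner was evaluated on the same held-out
#' 30%; the surviving members' scores are combined with their (renormalized)
#' TSS weights per replicate and the resulting ensemble scores are pooled
#' across replicates into one AUC.
#'
#' @param ensemble an \code{\link{sdm_ensemble}}.
#' @return AUC in [0, 1].
#' @export
ensemble_holdout_auc <- function(ensemble) {
  reps <- unique(vapply(ensemble$members, `[[`, numeric(1), "replicate"))
  pooled_p <- numeric(0); pooled_a <- numeric(0)
  for (r in reps) {
    idx <- which(vapply(ensemble$members, `[[`, numeric(1), "replicate") == r)
    w <- ensemble$weights[idx]; w <- w / sum(w)
    sp <- Reduce(`+`, Map(function(m, wi) wi * m$scores_presence,
                          ensemble$members[idx], w))
    sa <- Reduce(`+`, Map(function(m, wi) wi * m$scores_absence,
                          ensemble$members[idx], w))
    pooled_p <- c(pooled_p, sp); pooled_a <- c(pooled_a, sa)
  }
  auc_score(pooled_p, pooled_a)
}

#' @export
print.sdm_ensemble <- function(x, ...) {
  cat(sprintf("sdm_ensemble: %d members (TSS > %.2f) of %d fitted; threshold %.3f\n",
              length(x$members), x$tss_cutoff, nrow(x$evaluation),
              x$threshold))
  cat(sprintf("  mean member AUC %.3f, mean member TSS %.3f\n",
              mean(vapply(x$members, `[[`, numeric(1), "auc")),
              mean(vapply(x$members, `[[`, numeric(1), "tss"))))
  invisible(x)
}

# member scores over a raw (unscaled) predictor matrix
member_scores <- function(member, X) {
  Xs <- sweep(sweep(X[, names(member$scaler$mu), drop = FALSE], 2L,
                    member$scaler$mu), 2L, member$scaler$sd, `/`)
  predict_learner(member$model, Xs)
}

#' Predict ensemble habitat suitability
#'
#' Weighted mean of member scores per cell; cells outside the stack's mask
#' are NA. Suitability is the 0 (unsuitable) to 1 (optimal) index.
#'
#' @param ensemble an \code{\link{sdm_ensemble}}.
#' @param stack a \code{predictor_stack} holding every trained predictor.
#' @return object of class \code{suitability_map}: per-cell suitability with
#'   the ensemble threshold attached.
#' @export
predict_suitability <- function(ensemble, stack) {
  miss <- setdiff(ensemble$predictors, names(stack$layers))
  if (length(miss))
    stop("predict_suitability: stack lacks layer(s): ",
         paste(miss, collapse = ", "))
  X <- stack_matrix(stack)[, ensemble$predictors, drop = FALSE]
  idx <- which(stack$mask)
  acc <- numeric(length(idx))
  for (k in seq_along(ensemble$members))
    acc <- acc + ensemble$weights[k] *
      member_scores(ensemble$members[[k]], X[idx, , drop = FALSE])
  out <- rep(NA_real_, nrow(X))
  out[idx] <- pmin(1, pmax(0, acc))
  structure(list(suitability = out, mask = stack$mask,
                 threshold = ensemble$threshold,
                 grid_lat = stack$grid_lat, grid_lon = stack$grid_lon,
                 resolution_arcmin = stack$resolution_arcmin),
            class = "suitability_map")
}

#' @export
print.suitability_map <- function(x, ...) {
  v <- x$suitability[x$mask]
  cat(sprintf("suitability_map: %d cells, mean %.3f (range %.3f-%.3f), threshold %.3f\n",
              length(v), mean(v), min(v), max(v), x$threshold))
  invisible(x)
}

#' Binarize suitability maps and quantify range change
#'
#' Presence is suitability >= threshold. Cell areas are latitude-corrected:
#' a cell of r arc-minutes spans (r * 1.852 km)^2 * cos(lat). Percent change
#' is 100 * (future area - current area) / current area.
#'
#' @param current,future \code{suitability_map}s on the same geometry.
#' @param threshold binarization threshold (default: the current map's
#'   ensemble max-TSS threshold).
#' @return list with \code{range_current}, \code{range_future} (logical
#'   per-cell presence), \code{area_current_km2}, \code{area_future_km2},
#'   \code{percent_change}, \code{threshold_used}.
#' @export
binarize_and_area_change <- function(current, future,
                                     threshold = current$threshold) {
  if (length(current$suitability) != length(future$suitability) ||
      max(abs(current$grid_lat - future$grid_lat)) > 1e-9)
    stop("binarize_and_area_change: geometry mismatch")
  if (threshold < 0 || threshold > 1)
    stop("binarize_and_area_change: threshold must lie in [0, 1]")
  cell_lat <- rep(current$grid_lat, each = length(current$grid_lon))
  side_km <- current$resolution_arcmin * 1.852
  areas <- side_km^2 * cos(cell_lat * pi / 180)
  pres_c <- !is.na(current$suitability) & current$suitability >= threshold
  pres_f <- !is.na(future$suitability) & future$suitability >= threshold
  a_c <- sum(areas[pres_c]); a_f <- sum(areas[pres_f])
  if (a_c == 0) stop("binarize_and_area_change: current range has zero area")
  list(range_current = pres_c, range_future = pres_f,
       area_current_km2 = a_c, area_future_km2 = a_f,
       percent_change = 100 * (a_f - a_c) / a_c,
       threshold_used = threshold)
}

#' Write a suitability (or range) map as CSV
#'
#' Columns \code{cell,lon,lat,value}.
#'
#' @param map a \code{suitability_map} or per-cell vector; \code{path} file
#'   path; \code{grid_lat,grid_lon} geometry when a bare vector is given.
#' @export
write_map_csv <- function(map, path) {
  stopifnot(inherits(map, "suitability_map"))
  nlon <- length(map$grid_lon)
  df <- data.frame(cell = seq_along(map$suitability),
                   lon = rep(map$grid_lon, times = length(map$grid_lat)),
                   lat = rep(map$grid_lat, each = nlon),
                   value = map$suitability)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
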