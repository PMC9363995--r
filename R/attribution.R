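#' Ensemble response curve for one predictor
#'
#' Evaluates ensemble suitability along an even grid of one predictor
#' spanning its masked range, all other predictors fixed at their
#' masked-cell means — the marginal response curve used for attribution.
#'
#' @param ensemble an \code{\link{sdm_ensemble}}.
#' @param stack a \code{\link{predictor_stack}}.
#' @param variable predictor name.
#' @param grid_points number of evaluation points (>= 2).
#' @return list with \code{values} (predictor grid) and
#'   \code{suitabilities}.
#' @export
response_curve <- function(ensemble, stack, variable, grid_points = 100L) {
  if (!variable %in% ensemble$predictors)
    stop("response_curve: unknown variable '", variable, "'")
  if (grid_points < 2L) stop("response_curve: grid_points must be >= 2")
  X <- stack_matrix(stack)[stack$mask, ensemble$predictors, drop = FALSE]
  mu <- colMeans(X)
  vals <- seq(min(X[, variable]), max(X[, variable]),
              length.out = grid_points)
  Xq <- matrix(rep(mu, each = grid_points), nrow = grid_points,
               dimnames = list(NULL, names(mu)))
  Xq[, variable] <- vals
  suit <- ensemble_scores(ensemble, Xq)
  list(values = vals, suitabilities = suit)
}

# weighted ensemble scores on a raw predictor matrix
ensemble_scores <- function(ensemble, X) {
  acc <- numeric(nrow(X))
  for (k in seq_along(ensemble$members))
    acc <- acc + ensemble$weights[k] * member_scores(ensemble$members[[k]], X)
  pmin(1, pmax(0, acc))
}

#' Per-variable contribution to projected suitability change
#'
#' For each predictor v: the masked-mean change Dv between the future and
#' current stacks is pushed through the mean-anchored response curve —
#' contribution = R_v(mean_current + Dv) - R_v(mean_current), with every
#' other predictor held at its current masked mean. Contributions are
#' classed increased / unchanged / decreased by comparing the signed value
#' to +/- the class threshold (default 0.01 suitability units).
#'
#' @param ensemble an \code{\link{sdm_ensemble}}.
#' @param current,future \code{predictor_stack}s sharing geometry and
#'   variables.
#' @param threshold classification threshold on |delta suitability|.
#' @return data.frame of class \code{contribution_table}: one row per
#'   predictor with \code{variable, mean_delta, delta_suitability, class}.
#' @export
variable_contribution <- function(ensemble, current, future,
                                  threshold = 0.01) {
  if (length(current$mask) != length(future$mask) ||
      max(abs(current$grid_lat - future$grid_lat)) > 1e-9)
    stop("variable_contribution: geometry mismatch")
  vars <- ensemble$predictors
  if (!all(vars %in% names(future$layers)))
    stop("variable_contribution: future stack lacks trained predictors")
  mask <- current$mask & future$mask
  Xc <- stack_matrix(current)[mask, vars, drop = FALSE]
  Xf <- stack_matrix(future)[mask, vars, drop = FALSE]
  mu <- colMeans(Xc)
  base <- matrix(mu, nrow = 1L, dimnames = list(NULL, vars))
  r0 <- ensemble_scores(ensemble, base)
  rows <- lapply(vars, function(v) {
    dv <- mean(Xf[, v]) - mean(Xc[, v])
    shifted <- base
    shifted[, v] <- mu[v] + dv
    dr <- ensemble_scores(ensemble, shifted) - r0
    data.frame(variable = v, mean_delta = dv, delta_suitability = dr,
               class = if (dr > threshold) "increased"
                       else if (dr < -threshold) "decreased"
                       else "unchanged")
  })
  out <- do.call(rbind, rows)
  attr(out, "class_threshold") <- threshold
  class(out) <- c("contribution_table", "data.frame")
  out
}

#' Permutation importance of ensemble predictors
#'
#' Importance of a predictor is the mean drop in out-of-sample AUC when its
#' column in the evaluation design is randomly permuted, averaged over
#' repeats and over ensemble members with the ensemble weights, floored at
#' zero.
#'
#' @param ensemble an \code{\link{sdm_ensemble}}.
#' @param X raw predictor matrix of the evaluation design (columns named as
#'   the trained predictors).
#' @param y 0/1 response aligned with \code{X}.
#' @param repeats number of permutations per variable (>= 1).
#' @param seed integer seed.
#' @return named numeric vector of importances.
#' @export
permutation_importance <- function(ensemble, X, y, repeats = 5L, seed = 1L) {
  if (repeats < 1L) stop("permutation_importance: repeats must be >= 1")
  if (length(unique(y)) < 2L)
    stop("permutation_importance: degenerate evaluation set (one class)")
  X <- X[, ensemble$predictors, drop = FALSE]
  set.seed(as.integer(seed))
  vars <- ensemble$predictors
  imp <- setNames(numeric(length(vars)), vars)
  for (k in seq_along(ensemble$members)) {
    m <- ensemble$members[[k]]
    s0 <- member_scores(m, X)
    auc0 <- auc_score(s0[y == 1L], s0[y == 0L])
    for (v in vars) {
      drop_sum <- 0
      for (r in seq_len(repeats)) {
        Xp <- X
        Xp[, v] <- X[sample.int(nrow(X)), v]
        sp <- member_scores(m, Xp)
        drop_sum <- drop_sum + (auc0 - auc_score(sp[y == 1L], sp[y == 0L]))
      }
      imp[v] <- imp[v] + ensemble$weights[k] * drop_sum / repeats
    }
  }
  imp[imp < 0] <- 0
  imp
}

#' Write a contribution table as CSV
#'
#' Columns \code{variable,mean_delta,delta_suitability,class}.
#'
#' @param tab a \code{contribution_table}; \code{path} a file path.
#' @export
write_contribution_csv <- function(tab, path) {
  utils::write.csv(as.data.frame(tab), path, row.names = FALSE)
  invisible(path)
}
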