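# Maximum-entropy habitat suitability: L1-regularised maxent fit over
# linear + quadratic climate features, logistic output, binomial threshold
# tests, rank-based AUC, projection to alternate climates, suitable-area
# summaries, and the paired gap-suitability comparison.

#' Cells of a stack that are non-nodata in every layer
#' @param stack a \code{\link{climate_stack}}.
#' @return two-column matrix of (row, col) indices.
#' @export
stack_cells <- function(stack) {
  ok <- Reduce(`&`, lapply(stack, function(r) !is.na(r$values)))
  which(ok, arr.ind = TRUE)
}

# raw environmental matrix (cells x variables) at given (row, col) cells
stack_env <- function(stack, cells) {
  vapply(stack, function(r) r$values[cells], numeric(nrow(cells)))
}

# linear + quadratic features, standardised by the supplied moments
make_features <- function(env, centers, scales) {
  raw <- cbind(env, env^2)
  colnames(raw) <- c(colnames(env), paste0(colnames(env), "_sq"))
  scale(raw, center = centers, scale = scales)
}

cells_df_to_matrix <- function(cells) {
  if (is.data.frame(cells)) as.matrix(cells[, c("row", "col")])
  else as.matrix(cells)
}

soft_threshold <- function(x, t) sign(x) * pmax(abs(x) - t, 0)

#' Fit a maximum-entropy habitat suitability model
#'
#' Maximises the L1-penalised maxent objective
#' \code{mean_presence(lambda . f) - log Z(lambda) - beta sum |lambda|}
#' over linear and quadratic features of the climate layers, standardised
#' to zero mean and unit variance on the background.  \code{Z} normalises
#' \code{q(x) = exp(lambda . f(x)) / Z} over the background cells, so the
#' fitted distribution sums to 1 there.  The optimiser is FISTA (proximal
#' gradient with momentum and backtracking); the fit errors out with
#' diagnostics if the objective has not converged to \code{tol} within
#' \code{max_iter} iterations.
#'
#' @param presences presence cells: data.frame/matrix with columns
#'   \code{row}, \code{col} (grid indices, row 1 = top).
#' @param stack a \code{\link{climate_stack}} of training-period layers.
#' @param background optional background cells (same format); default all
#'   non-nodata cells.
#' @param beta L1 regularisation multiplier (default 1.0).
#' @param max_iter iteration cap (default 500).
#' @param tol convergence threshold on the objective change
#'   (default 1e-5).
#' @return object of class \code{niche_model}: coefficients
#'   \code{lambda}, feature moments, \code{log_z}, entropy \code{h},
#'   training metadata.
#' @export
fit_maxent <- function(presences, stack, background = NULL, beta = 1.0,
                       max_iter = 500, tol = 1e-5) {
  pres <- cells_df_to_matrix(presences)
  if (nrow(pres) < 5L) stop("need >= 5 presence cells")
  bg <- if (is.null(background)) stack_cells(stack)
        else cells_df_to_matrix(background)
  env_bg <- stack_env(stack, bg)
  env_pr <- stack_env(stack, pres)
  if (anyNA(env_pr)) stop("presence cells fall on nodata")
  raw_bg <- cbind(env_bg, env_bg^2)
  centers <- colMeans(raw_bg)
  scales <- apply(raw_bg, 2, sd)
  scales[scales == 0] <- 1
  X_bg <- make_features(env_bg, centers, scales)
  X_pr <- make_features(env_pr, centers, scales)
  f_pr <- colMeans(X_pr)
  d <- ncol(X_bg)
  # per-feature penalty beta * sd_presence(f_j) / sqrt(n_presence), the
  # maxent regularisation convention; the presence sd is floored at 0.1
  # background-sd units so near-constant features stay penalised
  pen <- beta * pmax(apply(X_pr, 2, sd), 0.1) / sqrt(nrow(pres))

  obj <- function(lam) {
    eta <- drop(X_bg %*% lam)
    mx <- max(eta)
    lz <- mx + log(sum(exp(eta - mx)))
    sum(f_pr * lam) - lz - sum(pen * abs(lam))
  }
  grad_smooth <- function(lam) {
    eta <- drop(X_bg %*% lam)
    mx <- max(eta)
    q <- exp(eta - mx); q <- q / sum(q)
    f_pr - drop(crossprod(X_bg, q))
  }
  smooth_part <- function(lam) {
    eta <- drop(X_bg %*% lam)
    mx <- max(eta)
    sum(f_pr * lam) - (mx + log(sum(exp(eta - mx))))
  }
  # FISTA (accelerated proximal gradient) with backtracking and adaptive
  # restart; the penalised objective is concave so the optimum is global
  lam <- lam_prev <- numeric(d)
  y <- lam
  t_m <- 1
  step <- 1
  J_old <- obj(lam)
  converged <- FALSE
  stall <- 0L
  for (it in seq_len(max_iter)) {
    g <- grad_smooth(y)
    sm_y <- smooth_part(y)
    repeat {
      lam_new <- soft_threshold(y + step * g, step * pen)
      dd <- lam_new - y
      if (smooth_part(lam_new) >=
          sm_y + sum(g * dd) - sum(dd^2) / (2 * step) - 1e-12)
        break
      step <- step / 2
      if (step < 1e-12) break
    }
    # adaptive restart when the momentum direction opposes progress
    if (sum((y - lam_new) * (lam_new - lam)) > 0) {
      t_m <- 1
      y <- lam
      next
    }
    t_new <- (1 + sqrt(1 + 4 * t_m^2)) / 2
    y <- lam_new + (t_m - 1) / t_new * (lam_new - lam)
    move <- max(abs(lam_new - lam))
    lam_prev <- lam
    lam <- lam_new
    t_m <- t_new
    step <- step * 1.2
    J <- obj(lam)
    stall <- if (abs(J - J_old) < tol && move < 1e-7) stall + 1L else 0L
    J_old <- J
    if (stall >= 3L) { converged <- TRUE; break }
  }
  if (!converged)
    stop(sprintf(paste0("maxent fit did not converge in %d iterations ",
                        "(objective %.6g still moving more than tol %.3g); ",
                        "raise max_iter or beta"),
                 max_iter, J_old, tol))
  eta <- drop(X_bg %*% lam)
  mx <- max(eta)
  log_z <- mx + log(sum(exp(eta - mx)))
  q <- exp(eta - log_z)
  h <- -sum(q * log(pmax(q, 1e-300)))
  structure(list(lambda = setNames(lam, colnames(X_bg)),
                 centers = centers, scales = scales,
                 variables = names(stack), log_z = log_z, h = h,
                 beta = beta, n_presence = nrow(pres),
                 n_background = nrow(bg), iterations = it,
                 objective = obj(lam)),
            class = "niche_model")
}

#' @export
print.niche_model <- function(x, ...) {
  cat(sprintf(paste0("niche_model: %d features on %s; H = %.3f, ",
                     "beta = %g, %d presences / %d background\n"),
              length(x$lambda), paste(x$variables, collapse = "+"),
              x$h, x$beta, x$n_presence, x$n_background))
  invisible(x)
}

#' Predict logistic habitat suitability
#'
#' \code{LV(x) = e^H q(x) / (1 + e^H q(x))} where
#' \code{q(x) = exp(lambda . f(x)) / Z} with the training normaliser Z,
#' training feature standardisation, and training entropy H; projecting
#' onto a different climate stack (e.g. glacial layers) therefore reuses
#' the training calibration.
#'
#' @param model a \code{niche_model}.
#' @param stack a \code{\link{climate_stack}} with the model's variables.
#' @return an \code{asc_raster} of logistic values in [0, 1]
#'   (\code{NA} where any layer is nodata).
#' @export
predict_logistic <- function(model, stack) {
  if (!all(model$variables %in% names(stack)))
    stop("stack lacks model variable(s): ",
         paste(setdiff(model$variables, names(stack)), collapse = ", "))
  stack <- climate_stack(stack[model$variables])
  cells <- stack_cells(stack)
  env <- stack_env(stack, cells)
  X <- make_features(env, model$centers, model$scales)
  q <- exp(drop(X %*% model$lambda) - model$log_z)
  lv <- exp(model$h) * q / (1 + exp(model$h) * q)
  tmpl <- stack[[1]]
  vals <- matrix(NA_real_, tmpl$nrows, tmpl$ncols)
  vals[cells] <- lv
  raster_grid(vals, tmpl$xllcorner, tmpl$yllcorner, tmpl$cellsize,
              tmpl$nodata_value)
}

#' One-sided binomial test of threshold-predicted presences
#'
#' With \code{a} the fraction of non-nodata cells at or above the
#' threshold (the success rate of a random model with that much suitable
#' area) and k of n test presences predicted suitable, returns the upper
#' binomial tail \code{P(X >= k | n, a)}.
#'
#' @param suit a suitability raster (\code{asc_raster} of LVs).
#' @param test_presences cells (row/col data.frame or matrix).
#' @param threshold logistic threshold in (0, 1).
#' @return list: \code{p_value}, \code{k}, \code{n}, \code{a}.
#' @export
binomial_threshold_test <- function(suit, test_presences, threshold) {
  stopifnot(threshold > 0, threshold < 1)
  cells <- cells_df_to_matrix(test_presences)
  if (nrow(cells) == 0L) stop("no test presences")
  lv <- suit$values[cells]
  if (anyNA(lv)) stop("test presence on nodata cell")
  a <- mean(suit$values >= threshold, na.rm = TRUE)
  k <- sum(lv >= threshold)
  n <- length(lv)
  list(p_value = pbinom(k - 1, n, a, lower.tail = FALSE), k = k, n = n,
       a = a)
}

#' Default set of ten logistic thresholds
#' @return numeric vector of thresholds used by the evaluation loop.
#' @export
default_thresholds <- function() {
  c(0.05, 0.10, 0.15, 0.20, 0.25, 0.30, 0.40, 0.50, 0.60, 0.70)
}

#' Rank-based AUC of presences versus background
#'
#' Mann-Whitney AUC of presence suitability values against background
#' values; ties count one half.
#'
#' @param suit suitability raster.
#' @param presences,background cell sets (row/col).
#' @return AUC in [0, 1].
#' @export
auc_presence_background <- function(suit, presences, background) {
  p <- suit$values[cells_df_to_matrix(presences)]
  b <- suit$values[cells_df_to_matrix(background)]
  p <- p[!is.na(p)]; b <- b[!is.na(b)]
  if (!length(p) || !length(b)) stop("empty presence or background set")
  r <- rank(c(p, b))
  (sum(r[seq_along(p)]) - length(p) * (length(p) + 1) / 2) /
    (length(p) * length(b))
}

#' Suitable area above a logistic threshold
#'
#' @param suit suitability raster.
#' @param threshold logistic cutoff (default 0.1).
#' @param cell_area_km2 area per cell (default 100, i.e. 10-km cells).
#' @param mask optional logical matrix restricting the count.
#' @return area in km^2.
#' @export
suitable_area <- function(suit, threshold = 0.1, cell_area_km2 = 100,
                          mask = NULL) {
  stopifnot(cell_area_km2 > 0)
  v <- suit$values
  if (!is.null(mask)) v[!mask] <- NA
  sum(v >= threshold, na.rm = TRUE) * cell_area_km2
}

#' Paired comparison of suitability over the gap
#'
#' Classical paired t-test of the logistic values of two rasters over the
#' overlapping non-nodata cells of a mask (e.g. current vs glacial
#' suitability over the distribution gap).
#'
#' @param raster_a,raster_b suitability rasters sharing one header.
#' @param gap_mask logical matrix selecting the gap cells.
#' @return list: \code{t}, \code{p_value}, \code{mean_a}, \code{mean_b},
#'   \code{sd_a}, \code{sd_b}, \code{n}.
#' @export
compare_gap_suitability <- function(raster_a, raster_b, gap_mask) {
  if (!same_header(raster_a, raster_b))
    stop("rasters do not share one header")
  ok <- gap_mask & !is.na(raster_a$values) & !is.na(raster_b$values)
  a <- raster_a$values[ok]; b <- raster_b$values[ok]
  if (length(a) < 2L) stop("fewer than 2 paired gap pixels")
  if (all(a == b))
    return(list(t = 0, p_value = 1, mean_a = mean(a), mean_b = mean(b),
                sd_a = sd(a), sd_b = sd(b), n = length(a)))
  tt <- t.test(a, b, paired = TRUE)
  list(t = unname(tt$statistic), p_value = tt$p.value, mean_a = mean(a),
       mean_b = mean(b), sd_a = sd(a), sd_b = sd(b), n = length(a))
}
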