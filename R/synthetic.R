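## Seeded generators of microscopy-like images and single-cell reporter
## populations.
##
## The image generator emulates the one physical premise the localization
## score relies on: a cell holds a fixed expected fluorophore budget F, a
## fraction f of which is concentrated in a small nuclear disk while the
## remainder stays diffuse, on top of a uniform background with Poisson
## shot noise and Gaussian read noise (the standard camera model). In the
## 2D projection the diffuse pool covers the whole cell footprint
## (cytoplasm surrounds the nucleus in z), so the nuclear pool adds on top
## of it: f = 0 gives an exactly uniform cell, and the expected within-cell
## photon sum is F for every f. The trace generator emulates
## reporter populations that are unimodal within a state and bimodal in the
## transition region, with lognormal state components matching the
## multiplicative character of fluorescence distributions.

#' Specification of a synthetic single-cell image
#'
#' @param width,height Frame size in pixels.
#' @param cell_center Cell (ellipse) center `c(x, y)` in pixel coordinates
#'   (row-major raster, origin top-left).
#' @param cell_axes Ellipse semi-axes `c(ax, ay)` in pixels.
#' @param nuc_center Nuclear disk center `c(x, y)`; must lie inside the
#'   cell together with the whole disk.
#' @param nuc_radius Nuclear disk radius in pixels.
#' @param F Total expected cell fluorophore budget (expected photon sum
#'   over the cell, background excluded).
#' @param f Nuclear fraction of the budget, in `[0, 1]`.
#' @param b Background level (expected photons per pixel), `>= 0`.
#' @param sigma Gaussian read-noise standard deviation, `>= 0`.
#' @param seed Integer seed.
#' @return An object of class `image_spec`.
#' @export
image_spec <- function(width = 96L, height = 96L,
                       cell_center = c(48.5, 48.5), cell_axes = c(28, 22),
                       nuc_center = cell_center, nuc_radius = 6,
                       F = 1e5, f = 0, b = 100, sigma = 2, seed = 1L) {
  stopifnot(width >= 8, height >= 8, all(cell_axes > 0), nuc_radius > 0,
            F > 0, f >= 0, f <= 1, b >= 0, sigma >= 0)
  structure(list(width = as.integer(width), height = as.integer(height),
                 cell_center = cell_center, cell_axes = cell_axes,
                 nuc_center = nuc_center, nuc_radius = nuc_radius,
                 F = F, f = f, b = b, sigma = sigma,
                 seed = as.integer(seed)),
            class = "image_spec")
}

## rasterized cell / nucleus masks (row-major, origin top-left)
.spec_masks <- function(spec, cx = spec$cell_center[1],
                        cy = spec$cell_center[2],
                        nx = spec$nuc_center[1], ny = spec$nuc_center[2]) {
  x <- matrix(rep(seq_len(spec$width), each = spec$height),
              spec$height, spec$width)
  y <- matrix(rep(seq_len(spec$height), spec$width),
              spec$height, spec$width)
  cell <- ((x - cx) / spec$cell_axes[1])^2 +
    ((y - cy) / spec$cell_axes[2])^2 <= 1
  nuc <- (x - nx)^2 + (y - ny)^2 <= spec$nuc_radius^2
  if (any(nuc & !cell))
    stop("nucleus is not contained in the cell", call. = FALSE)
  list(cell = cell, nuc = nuc)
}

## expected (noise-free) intensity given masks; conserves the budget:
## sum over cell pixels (background excluded) = F for every f
.expected_intensity <- function(spec, masks) {
  a_cell <- sum(masks$cell)
  a_nuc <- sum(masks$nuc)
  if (a_cell <= a_nuc || a_nuc < 1L)
    stop("degenerate geometry: empty cytoplasm or nucleus", call. = FALSE)
  mu <- matrix(spec$b, spec$height, spec$width)
  mu[masks$cell] <- mu[masks$cell] + (1 - spec$f) * spec$F / a_cell
  mu[masks$nuc] <- mu[masks$nuc] + spec$f * spec$F / a_nuc
  mu
}

.render <- function(mu, sigma) {
  noisy <- stats::rpois(length(mu), lambda = as.vector(mu)) +
    stats::rnorm(length(mu), sd = sigma)
  matrix(pmax(noisy, 0), nrow(mu), ncol(mu))
}

#' Generate a synthetic single-cell fluorescence image
#'
#' Renders one cell according to its [image_spec()]: expected intensity is
#' background everywhere, plus the diffuse pool `(1 - f) * F / area_cell`
#' on every cell pixel and the nuclear pool `f * F / area_nuc` added on
#' nuclear pixels (in the 2D projection cytoplasm surrounds the nucleus,
#' so the pools superimpose; `f = 0` gives an exactly uniform cell and the
#' expected within-cell photon sum is `F` for every `f`). Realized
#' intensity is `Poisson(expected) + Normal(0, sigma)` clipped at zero.
#' Bit-identical under a fixed seed.
#'
#' @param spec An [image_spec()] object.
#' @return A list with `frame` (numeric matrix), `mask` (logical cell
#'   mask), `nuc_mask` (logical nuclear mask) and `f` (ground-truth
#'   nuclear fraction).
#' @examples
#' img <- make_cell_image(image_spec(f = 0.4, seed = 11))
#' mean(img$frame[img$nuc_mask]) > mean(img$frame[img$mask & !img$nuc_mask])
#' @export
make_cell_image <- function(spec) {
  stopifnot(inherits(spec, "image_spec"))
  masks <- .spec_masks(spec)
  mu <- .expected_intensity(spec, masks)
  frame <- withr::with_seed(spec$seed, .render(mu, spec$sigma))
  list(frame = frame, mask = masks$cell, nuc_mask = masks$nuc, f = spec$f)
}

#' Generate a multi-cell synthetic field
#'
#' Places `n_cells` cells (geometry and camera model from `base_spec`, one
#' nuclear fraction per cell) at random non-overlapping positions in a
#' common frame. Placement uses rejection sampling and errors after 1e4
#' failed attempts. The global seed is expanded into per-cell substreams by
#' drawing a table of per-cell seeds up front, so any subset of cells is
#' reproducible.
#'
#' @param n_cells Number of cells.
#' @param f_values Nuclear fractions, recycled to `n_cells`.
#' @param base_spec An [image_spec()]; its `width`/`height` define the
#'   field, its cell/nucleus geometry is reused for every cell (centered on
#'   the drawn position).
#' @param seed Integer seed for placement and noise.
#' @return A list with `frame`, `mask` (integer matrix, 0 = background,
#'   `i` = pixels of cell `i`), `nuc_mask` (logical) and `cells` (a
#'   `data.frame` with per-cell `cell`, `x`, `y`, `f`).
#' @export
make_field <- function(n_cells, f_values, base_spec = image_spec(),
                       seed = 1L) {
  stopifnot(n_cells >= 1)
  f_values <- rep_len(f_values, n_cells)
  ax <- base_spec$cell_axes[1]; ay <- base_spec$cell_axes[2]
  w <- base_spec$width; h <- base_spec$height
  if (2 * ax + 2 >= w || 2 * ay + 2 >= h)
    stop("frame too small for the cell geometry", call. = FALSE)
  seeds <- withr::with_seed(seed, {
    centers <- matrix(NA_real_, n_cells, 2)
    fails <- 0L
    i <- 1L
    while (i <= n_cells) {
      cand <- c(stats::runif(1, ax + 1, w - ax - 1),
                stats::runif(1, ay + 1, h - ay - 1))
      ok <- i == 1L || all(sqrt((centers[seq_len(i - 1L), 1] - cand[1])^2 +
                                (centers[seq_len(i - 1L), 2] - cand[2])^2) >
                           2 * max(ax, ay) + 1)
      if (ok) {
        centers[i, ] <- cand
        i <- i + 1L
      } else {
        fails <- fails + 1L
        if (fails > 1e4)
          stop("could not place ", n_cells,
               " non-overlapping cells in the frame", call. = FALSE)
      }
    }
    list(centers = centers,
         seeds = sample.int(.Machine$integer.max, n_cells))
  })
  centers <- seeds$centers
  mu <- matrix(base_spec$b, h, w)
  label <- matrix(0L, h, w)
  nuc_all <- matrix(FALSE, h, w)
  for (i in seq_len(n_cells)) {
    sp <- base_spec
    sp$f <- f_values[i]
    m <- .spec_masks(sp, cx = centers[i, 1], cy = centers[i, 2],
                     nx = centers[i, 1], ny = centers[i, 2])
    mu_i <- .expected_intensity(sp, m) - sp$b
    mu <- mu + mu_i
    label[m$cell] <- i
    nuc_all <- nuc_all | m$nuc
  }
  frame <- withr::with_seed(seeds$seeds[1], .render(mu, base_spec$sigma))
  list(frame = frame, mask = label, nuc_mask = nuc_all,
       cells = data.frame(cell = seq_len(n_cells), x = centers[, 1],
                          y = centers[, 2], f = f_values))
}

#' Specification of a synthetic single-cell trace population
#'
#' @param n_cells Number of cells.
#' @param weights Mixture weights over the off / plateau / on states
#'   (nonnegative, summing to 1).
#' @param log_mean Per-state natural-log means of reporter intensity
#'   (length 3: off, plateau, on).
#' @param log_sd Per-state natural-log standard deviations (length 3 or 1,
#'   `> 0`).
#' @param timepoints Numeric vector of observation times.
#' @param seed Integer seed.
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(n_cells = 1000L, weights = c(0.7, 0.3, 0),
                            log_mean = log(c(1, 10, 100)),
                            log_sd = 0.3, timepoints = 0, seed = 1L) {
  weights <- weights / sum(weights)
  log_sd <- rep_len(log_sd, 3L)
  stopifnot(n_cells >= 1, length(weights) == 3L, all(weights >= 0),
            length(log_mean) == 3L, all(log_sd > 0),
            length(timepoints) >= 1L)
  structure(list(n_cells = as.integer(n_cells), weights = weights,
                 log_mean = log_mean, log_sd = log_sd,
                 timepoints = timepoints, seed = as.integer(seed)),
            class = "population_spec")
}

#' Generate a synthetic single-cell trace population
#'
#' Each cell draws a state (off / plateau / on) from the mixture weights,
#' then at every timepoint an intensity from the lognormal component of its
#' state. Seeded and reproducible.
#'
#' @param spec A [population_spec()] object.
#' @return A `data.frame` with columns `cell_id`, `time`, `intensity` and
#'   `state` (ground truth: `"off"`, `"plateau"` or `"on"`).
#' @export
make_trace_population <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  states <- c("off", "plateau", "on")
  withr::with_seed(spec$seed, {
    st <- sample.int(3L, spec$n_cells, replace = TRUE, prob = spec$weights)
    nt <- length(spec$timepoints)
    intensity <- stats::rlnorm(spec$n_cells * nt,
                               meanlog = rep(spec$log_mean[st], each = nt),
                               sdlog = rep(spec$log_sd[st], each = nt))
    data.frame(cell_id = rep(seq_len(spec$n_cells), each = nt),
               time = rep(spec$timepoints, spec$n_cells),
               intensity = intensity,
               state = rep(states[st], each = nt))
  })
}

#' Generate a synthetic regulon reporter dataset
#'
#' Runs the hysteretic down-from-rich population sweep of the regulon model
#' cell by cell (with lognormal cell-to-cell variability in the
#' low-affinity transporter amount) and emits thinned reporter
#' trajectories with multiplicative lognormal measurement noise, keyed by
#' external concentration and cell, together with per-cell ground-truth
#' terminal state labels.
#'
#' @param p A [regulon_params()] object.
#' @param s_out_grid External concentration grid (swept downward).
#' @param cv_etL Coefficient of variation of the low-affinity transporter
#'   amount.
#' @param n_cells Number of cells.
#' @param seed Integer seed.
#' @param noise_cv Measurement noise CV (multiplicative lognormal); 0
#'   disables noise.
#' @param duration,dt,record_every Simulation controls per grid point.
#' @return A list with `traces` (a `data.frame`: `s_out`, `cell`, `time`,
#'   `p_plateau`, `p_decoupled`) and `labels` (a `data.frame`: `s_out`,
#'   `cell`, `et_L`, `label` with `"MIXED"`-adjacent ambiguity reported as
#'   `NA`).
#' @export
make_regulon_dataset <- function(p, s_out_grid = .default_sweep_grid(),
                                 cv_etL = 0.3, n_cells = 50L, seed = 4L,
                                 noise_cv = 0.1,
                                 duration = 12 / p$delta,
                                 dt = 0.01 / p$delta,
                                 record_every = 25L) {
  stopifnot(inherits(p, "regulon_params"), n_cells >= 1, noise_cv >= 0)
  sub_seeds <- withr::with_seed(seed, sample.int(.Machine$integer.max, 2L))
  et_L <- if (cv_etL > 0) {
    sdlog <- sqrt(log(1 + cv_etL^2))
    withr::with_seed(sub_seeds[1],
      stats::rlnorm(n_cells, log(p$params_L$et) - sdlog^2 / 2, sdlog))
  } else rep(p$params_L$et, n_cells)
  grid <- rev(sort(s_out_grid))
  init <- regulon_init(p, "off")
  state <- list(e_H = rep(init$e_H, n_cells),
                spl2 = rep(init$spl2, n_cells),
                p_p = rep(init$p_plateau, n_cells),
                p_d = rep(init$p_decoupled, n_cells))
  n_steps <- max(1L, round(duration / dt))
  w_steps <- max(2L, round((1 / p$delta) / dt))
  tol_n <- 0.1 * p$n_mid
  basal <- p$beta_P / p$delta
  traces <- vector("list", length(grid))
  labels <- vector("list", length(grid))
  for (i in seq_along(grid)) {
    res <- .step_population(state, grid[i], p, dt, n_steps, et_L,
                            window_steps = w_steps,
                            record_every = record_every)
    state <- res$state
    rec <- res$rec
    nt <- length(rec$step)
    traces[[i]] <- data.frame(
      s_out = grid[i],
      cell = rep(seq_len(n_cells), each = nt),
      time = rep(rec$step * dt, n_cells),
      p_plateau = as.vector(rec$p_p),
      p_decoupled = as.vector(rec$p_d))
    w <- res$window
    lab <- rep(NA_character_, n_cells)
    lab[w$n < tol_n & w$p_p < 10 * basal & w$p_d < 10 * basal] <- "OFF"
    lab[abs(w$n - p$n_mid) < tol_n & w$p_p > 10 * basal &
          w$p_d <= 10 * basal] <- "PLATEAU"
    lab[w$n > 1 - tol_n & w$p_p > 10 * basal & w$p_d > 10 * basal] <- "ON"
    labels[[i]] <- data.frame(s_out = grid[i], cell = seq_len(n_cells),
                              et_L = et_L, label = lab)
  }
  traces <- do.call(rbind, traces)
  if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    noise <- withr::with_seed(sub_seeds[2],
      stats::rlnorm(2L * nrow(traces), -sdlog^2 / 2, sdlog))
    traces$p_plateau <- traces$p_plateau * noise[seq_len(nrow(traces))]
    traces$p_decoupled <- traces$p_decoupled *
      noise[nrow(traces) + seq_len(nrow(traces))]
  }
  list(traces = traces, labels = do.call(rbind, labels))
}
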