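# Time-dependent observables: mean squared displacement, Einstein-relation
# diffusion with anomalous-regime flagging, and flip-flop event counting.

# F x n x 3 array of monomer centroid positions (Angstrom) across frames.
particle_positions <- function(trajectory, map, species = "amphiphile") {
  ids <- molecule_ids(map, species)
  if (length(ids) == 0) {
    abort(sprintf("no molecules of species %s", paste(species, collapse = "/")),
      class = "vesitraj_selection_error")
  }
  nf <- n_frames(trajectory)
  out <- array(NA_real_, dim = c(nf, length(ids), 3))
  at <- map$atoms[map$atoms$species %in% species, ]
  counts <- as.vector(table(at$molecule_id))
  for (f in seq_len(nf)) {
    cs <- rowsum(frame_coords(trajectory, f)[at$atom, , drop = FALSE], group = at$molecule_id)
    out[f, , ] <- cs / counts
  }
  out
}

# All-origin MSD of one particle via the FFT autocorrelation identity:
# msd(tau) = (1/(F-tau)) * sum_t (|r_t|^2 + |r_{t+tau}|^2) - 2*acf(tau)/(F-tau).
msd_single_fft <- function(x) {
  F <- nrow(x)
  nfft <- 2^ceiling(log2(2 * F))
  acf_raw <- numeric(F)
  for (d in seq_len(ncol(x))) {
    fx <- fft(c(x[, d], rep(0, nfft - F)))
    ac <- Re(fft(fx * Conj(fx), inverse = TRUE)) / nfft
    acf_raw <- acf_raw + ac[1:F]
  }
  d2 <- rowSums(x^2)
  q <- 2 * sum(d2)
  out <- numeric(F)
  for (tau in 0:(F - 1)) {
    if (tau > 0) q <- q - d2[tau] - d2[F - tau + 1]
    out[tau + 1] <- q / (F - tau) - 2 * acf_raw[tau + 1] / (F - tau)
  }
  out[1] <- 0
  pmax(out, 0)
}

#' Mean squared displacement
#'
#' `M(tau) = <|r(t + tau) - r(t)|^2>` averaged over all valid time origins
#' `t` and all selected particles (molecule centroids). The lag grid spacing
#' equals the trajectory timestep. Positions must be unwrapped if the
#' trajectory is periodic (see [unwrap_trajectory()]).
#'
#' @param trajectory a `trajectory` with at least 2 frames.
#' @param map a `molecule_map`.
#' @param species species selection for the tracked molecules.
#' @param max_lag maximum lag in ns; lags at or beyond the trajectory length
#'   are truncated with a warning.
#' @return tibble of class `msd_curve`: `lag_ns`, `msd_nm2`, `n_pairs`.
#' @export
msd <- function(trajectory, map, species = "amphiphile", max_lag = NULL) {
  nf <- n_frames(trajectory)
  if (nf < 2) abort("MSD needs at least 2 frames", class = "vesitraj_spec_error")
  dt <- trajectory$timestep
  max_lag_frames <- nf - 1L
  if (!is.null(max_lag)) {
    want <- floor(max_lag / dt + 1e-9)
    if (want > nf - 1) {
      warn(sprintf("max_lag %g ns exceeds the trajectory; truncated to %g ns",
        max_lag, (nf - 1) * dt))
      want <- nf - 1
    }
    max_lag_frames <- max(1L, as.integer(want))
  }
  pos <- particle_positions(trajectory, map, species)
  np <- dim(pos)[2]
  acc <- numeric(nf)
  for (p in seq_len(np)) acc <- acc + msd_single_fft(pos[, p, ])
  m <- acc[seq_len(max_lag_frames + 1)] / np / 100  # A^2 -> nm^2
  lags <- 0:max_lag_frames
  structure(
    tibble::tibble(
      lag_ns = lags * dt,
      msd_nm2 = m,
      n_pairs = np * (nf - lags)
    ),
    class = c("msd_curve", "tbl_df", "tbl", "data.frame")
  )
}

#' Einstein-relation diffusion coefficient with anomalous-regime flag
#'
#' Fits `M(tau) = 2 E D tau` by least squares over the fit window, and the
#' anomalous exponent from the slope of `log M` vs `log tau` over the same
#' window. When `|alpha_hat - 1|` exceeds the threshold the motion is
#' flagged anomalous and the diffusion coefficient is reported as absent
#' (`NA`), since a constant-D Einstein reading is not meaningful there.
#'
#' @param msd_curve an [msd()] result.
#' @param e_dim dimensionality `E` of the fit (1, 2 or 3).
#' @param fit_window `c(tau_lo, tau_hi)` in ns; default 10%--50% of the
#'   maximum lag, excluding the short-time regime and the poorly averaged
#'   tail.
#' @param anomalous_threshold flag when `|alpha_hat - 1|` exceeds this.
#' @return object of class `diffusion_fit` with fields `d` (nm^2/ns; `NA`
#'   when flagged), `alpha_hat`, `anomalous`, `e_dim`, `fit_window`,
#'   `n_points`. `tidy()` and `glance()` methods are provided. Multiply
#'   `d` by 10 to express it in 1e-5 cm^2/s.
#' @export
diffusion_coefficient <- function(msd_curve, e_dim = 3, fit_window = NULL,
                                  anomalous_threshold = 0.2) {
  stopifnot(e_dim %in% 1:3)
  tau <- msd_curve$lag_ns
  m <- msd_curve$msd_nm2
  max_tau <- max(tau)
  fit_window <- fit_window %||% c(0.1 * max_tau, 0.5 * max_tau)
  inw <- which(tau >= fit_window[1] & tau <= fit_window[2] & tau > 0)
  if (length(inw) < 5) {
    abort("fit window must contain at least 5 positive-lag points",
      class = "vesitraj_fit_error")
  }
  if (any(m[inw] <= 0)) {
    abort("non-positive MSD values inside the fit window: fit undefined",
      class = "vesitraj_fit_error")
  }
  lin <- lm(m[inw] ~ tau[inw])
  slope <- unname(coef(lin)[2])
  loglin <- lm(log(m[inw]) ~ log(tau[inw]))
  alpha_hat <- unname(coef(loglin)[2])
  anomalous <- abs(alpha_hat - 1) > anomalous_threshold
  d <- max(slope, 0) / (2 * e_dim)
  structure(
    list(
      d = if (anomalous) NA_real_ else d,
      d_fit = d,
      alpha_hat = alpha_hat,
      anomalous = anomalous,
      e_dim = e_dim,
      fit_window = fit_window,
      anomalous_threshold = anomalous_threshold,
      n_points = length(inw)
    ),
    class = "diffusion_fit"
  )
}

#' @export
print.diffusion_fit <- function(x, ...) {
  if (x$anomalous) {
    cat(sprintf(
      "<diffusion_fit> anomalous regime (alpha_hat = %.3f); D not reported\n",
      x$alpha_hat))
  } else {
    cat(sprintf("<diffusion_fit> D = %.4g nm^2/ns (E = %d, alpha_hat = %.3f)\n",
      x$d, x$e_dim, x$alpha_hat))
  }
  invisible(x)
}

#' @export
tidy.diffusion_fit <- function(x, ...) {
  tibble::tibble(
    term = c("d", "alpha_hat"),
    estimate = c(x$d, x$alpha_hat)
  )
}

#' @export
glance.diffusion_fit <- function(x, ...) {
  tibble::tibble(
    d = x$d, alpha_hat = x$alpha_hat, anomalous = x$anomalous,
    e_dim = x$e_dim, tau_lo = x$fit_window[1], tau_hi = x$fit_window[2],
    n_points = x$n_points
  )
}

#' Unwrap periodic coordinates
#'
#' Minimum-image unwrapping of per-atom displacements between consecutive
#' frames, required before [msd()] on boxed trajectories. Frames without a
#' box are returned unchanged.
#'
#' @param trajectory a `trajectory`.
#' @return a `trajectory` with continuous (unwrapped) coordinates.
#' @export
unwrap_trajectory <- function(trajectory) {
  nf <- n_frames(trajectory)
  if (nf < 2 || is.null(trajectory$frames[[1]]$box)) return(trajectory)
  frames <- trajectory$frames
  prev <- frames[[1]]$coords
  for (f in 2:nf) {
    box <- frames[[f]]$box
    d <- frames[[f]]$coords - prev
    shift <- sweep(round(sweep(d, 2, box, "/")), 2, box, "*")
    unwrapped <- prev + (d - shift)
    prev <- unwrapped
    frames[[f]]$coords <- unwrapped
  }
  new_trajectory(frames, trajectory$timestep, trajectory$elements)
}

#' Leaflet labels across frames
#'
#' @param trajectory a `trajectory`.
#' @param map a `molecule_map`.
#' @param dead_zone forwarded to [assign_leaflets()].
#' @param frames integer frame indices (default all).
#' @return tibble `frame`, `molecule_id`, `label`.
#' @export
leaflet_timeseries <- function(trajectory, map, dead_zone = 0.2, frames = NULL) {
  frames <- frames %||% seq_len(n_frames(trajectory))
  purrr::map_dfr(frames, function(f) {
    lab <- assign_leaflets(frame_coords(trajectory, f), map, dead_zone = dead_zone)
    tibble::tibble(frame = f, molecule_id = lab$molecule_id, label = lab$label)
  })
}

#' Flip-flop event detection with dwell hysteresis
#'
#' An event is recorded when a monomer's confirmed leaflet label changes to
#' the opposite leaflet and the new label persists for at least `min_dwell`
#' consecutive frames. Excursions through `unassigned`, or flickers shorter
#' than the dwell window, do not count.
#'
#' @param label_timeseries tibble `frame`, `molecule_id`, `label` from
#'   [leaflet_timeseries()].
#' @param min_dwell dwell requirement in frames.
#' @return list of class `flipflop_report`: `events` (tibble `molecule_id`,
#'   `frame_start` = first frame of the persistent new label, `frame_end` =
#'   frame at which the dwell requirement was met, `direction`), `count`.
#' @export
detect_flip_flops <- function(label_timeseries, min_dwell = 20) {
  stopifnot(min_dwell >= 1)
  frames_sorted <- sort(unique(label_timeseries$frame))
  events <- list()
  for (id in unique(label_timeseries$molecule_id)) {
    sub <- label_timeseries[label_timeseries$molecule_id == id, ]
    lab <- sub$label[order(sub$frame)]
    ev <- flip_scan(lab, min_dwell)
    if (nrow(ev) > 0) {
      ev$molecule_id <- id
      ev$frame_start <- frames_sorted[ev$frame_start]
      ev$frame_end <- frames_sorted[ev$frame_end]
      events[[length(events) + 1]] <- ev
    }
  }
  events <- if (length(events) > 0) {
    dplyr::bind_rows(events)[, c("molecule_id", "frame_start", "frame_end", "direction")]
  } else {
    tibble::tibble(molecule_id = integer(0), frame_start = integer(0),
      frame_end = integer(0), direction = character(0))
  }
  events <- dplyr::arrange(events, .data$frame_start, .data$molecule_id)
  structure(list(events = events, count = nrow(events)), class = "flipflop_report")
}

# state machine over one monomer's label sequence (indices, not frame ids)
flip_scan <- function(lab, min_dwell) {
  out <- tibble::tibble(frame_start = integer(0), frame_end = integer(0),
    direction = character(0))
  assigned <- which(lab != "unassigned")
  if (length(assigned) == 0) return(out)
  confirmed <- lab[assigned[1]]
  i <- assigned[1] + 1
  n <- length(lab)
  while (i <= n) {
    if (lab[i] != "unassigned" && lab[i] != confirmed) {
      run_start <- i
      j <- i
      while (j <= n && lab[j] == lab[i]) j <- j + 1
      run_len <- j - run_start
      if (run_len >= min_dwell) {
        out <- dplyr::bind_rows(out, tibble::tibble(
          frame_start = run_start,
          frame_end = run_start + as.integer(min_dwell) - 1L,
          direction = paste0(confirmed, "_to_", lab[i])
        ))
        confirmed <- lab[i]
      }
      i <- j
    } else {
      i <- i + 1
    }
  }
  out
}

#' @export
print.flipflop_report <- function(x, ...) {
  cat(sprintf("<flipflop_report> %d event(s)\n", x$count))
  if (x$count > 0) print(x$events)
  invisible(x)
}
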