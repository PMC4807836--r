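#' Construct a trajectory
#'
#' Ordered coordinate frames for a fixed atom list, with a time stamp per
#' frame. Frames are stored as a list of N x 3 matrices (Angstrom).
#'
#' @param frames list of N x 3 coordinate matrices (Angstrom).
#' @param time frame times (ns), increasing; defaults to 0,1,2,...
#' @param molecule optional reference [molecule()] (atom metadata).
#' @return An object of class `vibrolf_trajectory`.
#' @export
trajectory <- function(frames, time = NULL, molecule = NULL) {
  stopifnot(length(frames) >= 1)
  n <- nrow(frames[[1]])
  if (!all(vapply(frames, nrow, 1L) == n)) {
    stop("all frames must have the same atom count", call. = FALSE)
  }
  if (is.null(time)) time <- seq_along(frames) - 1
  if (any(diff(time) <= 0)) stop("frame times must be increasing", call. = FALSE)
  structure(list(frames = lapply(frames, as.matrix), time = as.numeric(time),
                 molecule = molecule),
            class = "vibrolf_trajectory")
}

#' @export
print.vibrolf_trajectory <- function(x, ...) {
  cat(sprintf("<trajectory: %d frames, %d atoms, t = %g..%g ns>\n",
              length(x$frames), nrow(x$frames[[1]]),
              min(x$time), max(x$time)))
  invisible(x)
}

#' Tidy a trajectory into a long tibble
#'
#' @param x a `vibrolf_trajectory`.
#' @param ... unused.
#' @return Tibble with columns `frame`, `time`, `atom`, `x`, `y`, `z`.
#' @method tidy vibrolf_trajectory
#' @export
tidy.vibrolf_trajectory <- function(x, ...) {
  purrr::map_dfr(seq_along(x$frames), function(i) {
    f <- x$frames[[i]]
    tibble::tibble(frame = i, time = x$time[i], atom = seq_len(nrow(f)),
                   x = f[, 1], y = f[, 2], z = f[, 3])
  })
}

#' Read a multi-frame XYZ trajectory
#'
#' @param path multi-frame XYZ file.
#' @param dt time between frames (ns).
#' @return A [trajectory()].
#' @export
read_trajectory_xyz <- function(path, dt = 1) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[seq_len(max(which(nzchar(trimws(lines))), 0))]
  frames <- list()
  pos <- 1L
  mol <- NULL
  while (pos <= length(lines)) {
    blk <- .parse_xyz_block(lines, pos, path)
    if (is.null(mol)) mol <- blk$mol
    frames[[length(frames) + 1L]] <- coords(blk$mol)
    pos <- blk$next_line
  }
  trajectory(frames, time = (seq_along(frames) - 1) * dt, molecule = mol)
}

#' Write a trajectory as multi-frame XYZ
#'
#' @param traj a [trajectory()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_xyz <- function(traj, path) {
  el <- if (!is.null(traj$molecule)) traj$molecule$element
        else rep("X", nrow(traj$frames[[1]]))
  for (i in seq_along(traj$frames)) {
    f <- traj$frames[[i]]
    write_xyz(tibble::tibble(element = el, x = f[, 1], y = f[, 2], z = f[, 3]),
              path, comment = sprintf("t = %g ns", traj$time[i]),
              append = i > 1)
  }
  invisible(path)
}

#' Rigid-body alignment of trajectory frames
#'
#' Superposes every frame onto the first by least-squares rotation and
#' translation over a reference selection (e.g. the protein backbone), and
#' applies the fitted transform to all atoms of the frame.
#'
#' @param traj a [trajectory()].
#' @param selection integer atom indices used for the fit (>= 3).
#' @return The aligned [trajectory()].
#' @export
align_frames <- function(traj, selection = seq_len(nrow(traj$frames[[1]]))) {
  if (length(selection) < 3) {
    stop("alignment selection needs at least 3 atoms (rotation underdetermined)",
         call. = FALSE)
  }
  ref <- traj$frames[[1]][selection, , drop = FALSE]
  frames <- lapply(traj$frames, function(f) {
    mob <- f[selection, , drop = FALSE]
    cm_m <- colMeans(mob); cm_t <- colMeans(ref)
    A <- sweep(mob, 2, cm_m); B <- sweep(ref, 2, cm_t)
    sv <- svd(crossprod(A, B))
    d <- sign(det(tcrossprod(sv$v, sv$u)))
    R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
    sweep(sweep(f, 2, cm_m) %*% t(R), 2, cm_t, "+")
  })
  trajectory(frames, traj$time, traj$molecule)
}

#' RMSD time series
#'
#' Per-frame root-mean-square deviation of a selection relative to a
#' reference frame of an (already aligned) trajectory.
#'
#' @param traj a [trajectory()].
#' @param selection atom indices (default: all).
#' @param reference_frame index of the reference frame (default 1).
#' @return Tibble with columns `time` and `rmsd` (Angstrom).
#' @export
rmsd_series <- function(traj, selection = seq_len(nrow(traj$frames[[1]])),
                        reference_frame = 1L) {
  if (!length(selection)) stop("empty selection", call. = FALSE)
  ref <- traj$frames[[reference_frame]][selection, , drop = FALSE]
  r <- vapply(traj$frames, function(f) {
    d <- f[selection, , drop = FALSE] - ref
    sqrt(mean(rowSums(d^2)))
  }, 0)
  tibble::tibble(time = traj$time, rmsd = r)
}

#' Interatomic distance time series
#'
#' @param traj a [trajectory()].
#' @param atom_a,atom_b 1-based atom indices.
#' @return Tibble with columns `time` and `distance` (Angstrom).
#' @export
distance_series <- function(traj, atom_a, atom_b) {
  n <- nrow(traj$frames[[1]])
  if (atom_a < 1 || atom_a > n || atom_b < 1 || atom_b > n) {
    stop("atom index out of range 1..", n, call. = FALSE)
  }
  d <- vapply(traj$frames, function(f) sqrt(sum((f[atom_a, ] - f[atom_b, ])^2)), 0)
  tibble::tibble(time = traj$time, distance = d)
}

#' Centered running mean
#'
#' Centered moving average with a shrinking window at the edges, the
#' smoothing used to overlay "dark" averaged lines on raw time series.
#'
#' @param x numeric vector, or a tibble whose last column is smoothed.
#' @param window window size in samples (default 50).
#' @return Same shape as the input with smoothed values.
#' @export
running_mean <- function(x, window = 50L) {
  if (is.data.frame(x)) {
    col <- names(x)[ncol(x)]
    x[[col]] <- running_mean(x[[col]], window)
    return(x)
  }
  n <- length(x)
  if (window < 1) stop("window must be >= 1", call. = FALSE)
  if (window > n) stop("window (", window, ") exceeds series length (", n, ")",
                       call. = FALSE)
  half_lo <- floor((window - 1) / 2)
  half_hi <- ceiling((window - 1) / 2)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half_lo, 1)
  hi <- pmin(seq_len(n) + half_hi, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Nonbonded parameter table
#'
#' @param charge per-atom partial charges (e).
#' @param epsilon Lennard-Jones well depths (kcal/mol, >= 0).
#' @param rmin LJ minimum distances r_min (Angstrom, > 0); pair values use
#'   CHARMM combination rules (arithmetic r_min, geometric epsilon).
#' @param cutoff nonbonded cutoff (Angstrom, default 12).
#' @param switch_on switching inner radius (Angstrom, default 10).
#' @return A tibble of class `vibrolf_nb_params` with attributes `cutoff`
#'   and `switch_on`.
#' @export
nonbonded_params <- function(charge, epsilon, rmin, cutoff = 12, switch_on = 10) {
  stopifnot(length(epsilon) == length(charge), length(rmin) == length(charge))
  if (any(epsilon < 0)) stop("epsilon must be >= 0", call. = FALSE)
  if (any(rmin <= 0)) stop("rmin must be > 0", call. = FALSE)
  if (switch_on >= cutoff) stop("switch_on must be below the cutoff", call. = FALSE)
  p <- tibble::tibble(charge = charge, epsilon = epsilon, rmin = rmin)
  attr(p, "cutoff") <- cutoff
  attr(p, "switch_on") <- switch_on
  class(p) <- c("vibrolf_nb_params", class(p))
  p
}

# CHARMM energy-switching factor on r in [switch_on, cutoff]
.switch_factor <- function(r, r_on, r_off) {
  s <- rep(1, length(r))
  s[r >= r_off] <- 0
  mid <- r > r_on & r < r_off
  if (any(mid)) {
    r2 <- r[mid]^2; on2 <- r_on^2; off2 <- r_off^2
    s[mid] <- (off2 - r2)^2 * (off2 + 2 * r2 - 3 * on2) / (off2 - on2)^3
  }
  s
}

#' Nonbonded interaction-energy time series between two selections
#'
#' Pairwise Coulomb (epsilon_r = 1, constant 332.0636 kcal A / (mol e^2))
#' plus 12-6 Lennard-Jones energies between two disjoint atom groups, with
#' CHARMM-style energy switching between `switch_on` and `cutoff` applied
#' to both terms; pairs beyond the cutoff contribute nothing.
#'
#' @param traj a [trajectory()].
#' @param group_a,group_b disjoint integer atom-index selections.
#' @param params a [nonbonded_params()] covering every atom index used.
#' @return Tibble with columns `time`, `elec`, `vdw`, `total` (kcal/mol).
#' @export
interaction_energy <- function(traj, group_a, group_b, params) {
  if (length(intersect(group_a, group_b))) {
    stop("groups overlap: ", paste(intersect(group_a, group_b), collapse = ","),
         call. = FALSE)
  }
  need <- max(c(group_a, group_b))
  if (need > nrow(params)) {
    stop("missing nonbonded parameters for atom ", need, call. = FALSE)
  }
  if (anyNA(params$charge[c(group_a, group_b)])) {
    bad <- c(group_a, group_b)[which(is.na(params$charge[c(group_a, group_b)]))[1]]
    stop("missing charge for atom ", bad, call. = FALSE)
  }
  r_off <- attr(params, "cutoff")
  r_on <- attr(params, "switch_on")
  qa <- params$charge[group_a]; qb <- params$charge[group_b]
  ea <- params$epsilon[group_a]; eb <- params$epsilon[group_b]
  ra <- params$rmin[group_a]; rb <- params$rmin[group_b]
  qq <- outer(qa, qb) * vibrolf_constants$coulomb_kcal
  eps <- sqrt(outer(ea, eb))
  rmin <- outer(ra, rb, function(a, b) (a + b) / 2)
  res <- t(vapply(traj$frames, function(f) {
    A <- f[group_a, , drop = FALSE]
    B <- f[group_b, , drop = FALSE]
    d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
    r <- sqrt(pmax(d2, 0))
    sw <- matrix(.switch_factor(r, r_on, r_off), nrow(r), ncol(r))
    elec <- sum(sw * qq / r)
    x6 <- (rmin / r)^6
    vdw <- sum(sw * eps * (x6^2 - 2 * x6))
    c(elec = elec, vdw = vdw)
  }, c(elec = 0, vdw = 0)))
  elec <- unname(res[, "elec"]); vdw <- unname(res[, "vdw"])
  tibble::tibble(time = traj$time, elec = elec, vdw = vdw,
                 total = elec + vdw)
}

#' Normalized energy distribution
#'
#' Density-normalized histogram of an energy (or any) series; the area under
#' the histogram is 1.
#'
#' @param series numeric vector, or tibble whose last column is used.
#' @param bins number of bins (equal width over the data range), or a
#'   numeric `bin_width` may be given instead.
#' @param bin_width optional fixed bin width overriding `bins`.
#' @return Tibble with columns `energy` (bin centers), `density`.
#' @export
energy_distribution <- function(series, bins = 30L, bin_width = NULL) {
  x <- if (is.data.frame(series)) series[[ncol(series)]] else series
  if (length(unique(x)) < 2) stop("degenerate series: fewer than 2 distinct values",
                                  call. = FALSE)
  breaks <- if (!is.null(bin_width)) {
    seq(floor(min(x) / bin_width) * bin_width,
        ceiling(max(x) / bin_width) * bin_width, by = bin_width)
  } else {
    seq(min(x), max(x), length.out = bins + 1)
  }
  h <- graphics::hist(x, breaks = breaks, plot = FALSE, include.lowest = TRUE)
  tibble::tibble(energy = h$mids, density = h$density)
}
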